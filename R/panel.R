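#' Construct a genotyping panel
#'
#' Builds a validated [GynPanel] from a target table and optional assay
#' metadata. Assays not listed in `assays` are created with unassigned wells
#' and masses.
#'
#' @param name,version Panel identifiers.
#' @param targets data.frame with columns `gene`, `protein_change`,
#'   `nucleotide_change`, `assay_id` and optionally `added_in_version`.
#' @param assays Optional data.frame with columns `assay_id` and optionally
#'   `well_id`, `primer_mass`.
#' @param alleleMasses Optional named list of allele-product masses per assay
#'   (each a named numeric vector containing `"WT"` plus one entry per mutant
#'   allele site identifier).
#' @return A [GynPanel].
#' @export
GynPanel <- function(name, version, targets, assays = NULL,
                     alleleMasses = list()) {
  targets <- as.data.frame(targets)
  if (nrow(targets)) {
    targets$gene <- as.character(targets$gene)
    targets$protein_change <- normProtein(targets$protein_change)
    targets$nucleotide_change <- normNt(targets$nucleotide_change)
    targets$assay_id <- as.character(targets$assay_id)
    if (is.null(targets$added_in_version)) targets$added_in_version <- version
    targets$added_in_version <- as.character(targets$added_in_version)
  } else {
    targets <- data.frame(gene = character(), protein_change = character(),
                          nucleotide_change = character(), assay_id = character(),
                          added_in_version = character(), stringsAsFactors = FALSE)
  }
  targets <- targets[, c("gene", "protein_change", "nucleotide_change",
                         "assay_id", "added_in_version")]
  ids <- unique(targets$assay_id)
  if (is.null(assays)) {
    assays <- data.frame(assay_id = ids, stringsAsFactors = FALSE)
  }
  assays <- as.data.frame(assays)
  if (nrow(assays) == 0L) {
    assays <- data.frame(assay_id = character(), well_id = character(),
                         primer_mass = numeric(), stringsAsFactors = FALSE)
  } else {
    assays$assay_id <- as.character(assays$assay_id)
    if (is.null(assays$well_id)) assays$well_id <- NA_character_
    if (is.null(assays$primer_mass)) assays$primer_mass <- NA_real_
    assays$well_id <- as.character(assays$well_id)
    assays$primer_mass <- as.numeric(assays$primer_mass)
    assays <- assays[, c("assay_id", "well_id", "primer_mass")]
  }
  rownames(targets) <- rownames(assays) <- NULL
  methods::new("GynPanel", name = as.character(name),
               version = as.character(version), targets = targets,
               assays = assays, alleleMasses = alleleMasses)
}

#' @rdname genes
#' @export
setMethod("genes", "GynPanel", function(x) sort(unique(x@targets$gene)))

#' Panel target table
#' @param x A [GynPanel].
#' @return data.frame of target mutations.
#' @export
panelTargets <- function(x) {
  stopifnot(methods::is(x, "GynPanel"))
  x@targets
}

#' Panel assay table
#' @param x A [GynPanel].
#' @return data.frame of assays (assay_id, well_id, primer_mass).
#' @export
panelAssays <- function(x) {
  stopifnot(methods::is(x, "GynPanel"))
  x@assays
}

#' Allele-product masses of a panel
#' @param x A [GynPanel].
#' @return Named list (by assay_id) of named numeric mass vectors.
#' @export
alleleMasses <- function(x) {
  stopifnot(methods::is(x, "GynPanel"))
  x@alleleMasses
}

#' Panel version string
#' @param x A [GynPanel].
#' @return Character scalar.
#' @export
panelVersion <- function(x) {
  stopifnot(methods::is(x, "GynPanel"))
  x@version
}

#' Derived panel totals
#'
#' Counts genes, target mutations, assays and occupied multiplex wells from
#' panel content (never from metadata), plus per-gene mutation and assay
#' counts.
#'
#' @param p A [GynPanel].
#' @return List with `genes`, `mutations`, `assays`, `wells` (integers) and
#'   `per_gene`, a data.frame of per-gene mutation and assay counts.
#' @export
panelTotals <- function(p) {
  stopifnot(methods::is(p, "GynPanel"))
  tg <- p@targets
  perGene <- if (nrow(tg)) {
    data.frame(
      gene = sort(unique(tg$gene)),
      mutations = as.integer(table(tg$gene)[sort(unique(tg$gene))]),
      assays = vapply(split(tg$assay_id, tg$gene)[sort(unique(tg$gene))],
                      function(a) length(unique(a)), integer(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), mutations = integer(), assays = integer(),
               stringsAsFactors = FALSE)
  }
  list(genes = length(unique(tg$gene)),
       mutations = nrow(tg),
       assays = nrow(p@assays),
       wells = length(unique(stats::na.omit(p@assays$well_id))),
       per_gene = perGene)
}

#' Load a panel definition
#'
#' Reads a panel from JSON (as written by [savePanel()]) or from flat
#' tab-separated text with columns `gene`, `protein_change`,
#' `nucleotide_change`, `assay_id`, `well_id` and optionally
#' `added_in_version`. The format is chosen by file extension
#' (`.json` vs anything else).
#'
#' @param path Path to the panel file.
#' @return A [GynPanel].
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    for (f in c("name", "version", "targets")) {
      if (is.null(x[[f]])) stop("panel JSON lacks field: ", f, call. = FALSE)
    }
    am <- lapply(x$allele_masses, function(m) unlist(m))
    GynPanel(x$name, x$version, as.data.frame(x$targets),
             if (!is.null(x$assays)) as.data.frame(x$assays) else NULL,
             if (length(am)) am else list())
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", comment.char = "#")
    need <- c("gene", "protein_change", "nucleotide_change", "assay_id",
              "well_id")
    if (!all(need %in% names(df))) {
      stop("panel table must name columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    meta <- attr(df, "meta")
    nm <- if (!is.null(df$panel_name)) df$panel_name[1L] else "panel"
    vs <- if (!is.null(df$panel_version)) df$panel_version[1L] else "1.0"
    assays <- unique(df[, c("assay_id", "well_id")])
    assays$well_id[assays$well_id == ""] <- NA_character_
    GynPanel(nm, vs, df[, intersect(names(df), c(need, "added_in_version"))],
             assays)
  }
}

#' Save a panel definition
#'
#' @param p A [GynPanel].
#' @param path Output path.
#' @param format `"json"` (full fidelity, including masses) or `"tsv"` (flat
#'   target-per-row export; masses are dropped).
#' @return Invisibly, `path`.
#' @export
savePanel <- function(p, path, format = c("json", "tsv")) {
  stopifnot(methods::is(p, "GynPanel"))
  format <- match.arg(format)
  if (format == "json") {
    x <- list(name = p@name, version = p@version, targets = p@targets,
              assays = p@assays, allele_masses = lapply(p@alleleMasses, as.list))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  } else {
    df <- merge(p@targets, p@assays, by = "assay_id", sort = FALSE)
    df$panel_name <- p@name
    df$panel_version <- p@version
    df <- df[order(df$gene, df$assay_id, df$protein_change),
             c("gene", "protein_change", "nucleotide_change", "assay_id",
               "well_id", "added_in_version", "panel_name", "panel_version")]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' The packaged 13-gene gynaecological panel (version 2.0)
#'
#' Loads the packaged transcription of the published 13-gene panel: 171
#' target mutations detected by 99 single-site extension assays in 13
#' multiplex wells, covering BRAF, CDKN2A, CTNNB1, FBXW7, FGFR2, FGFR3,
#' FOXL2, HRAS, KRAS, NRAS, PIK3CA, PPP2R1A and PTEN. Targets added in panel
#' version 2.0 carry `added_in_version == "2.0"`. The grouping of same-site
#' alternate alleles into assays and the well layout are synthetic (the
#' published table reports only per-gene assay counts and the well total);
#' they reproduce the published per-gene assay counts exactly.
#'
#' @return A [GynPanel] without analyte masses (see [assignAnalyteMasses()]).
#' @examples
#' p <- gynCartaPanel()
#' panelTotals(p)$mutations
#' @export
gynCartaPanel <- function() {
  path <- system.file("extdata", "gyncarta2_panel.tsv", package = "panelkit",
                      mustWork = TRUE)
  p <- loadPanel(path)
  p@name <- "GynCarta"
  p@version <- "2.0"
  methods::validObject(p)
  p
}

#' Revise a panel: remove and add target mutations
#'
#' Removals are dropped from their assays (assays left with no targets are
#' deleted, freeing their well slot); additions are grouped into new
#' single-site assays, given masses with [assignAnalyteMasses()], and packed
#' into wells with [packMultiplexes()], optionally restricted to a set of
#' wells (panels are revised in practice by concentrating new assays on a few
#' re-run multiplexes).
#'
#' @param p A [GynPanel].
#' @param remove data.frame of targets to remove (`gene`, `protein_change`,
#'   optional `nucleotide_change`); all must exist in `p`.
#' @param add data.frame of targets to add (same columns); none may already
#'   be present.
#' @param newVersion Version string for the revised panel.
#' @param packInto Optional character vector of well ids that new assays may
#'   join (existing assays are never moved); new wells are opened when needed.
#' @param plexCap,minSeparation,seed Passed to mass assignment and packing of
#'   the added assays.
#' @return A revised [GynPanel].
#' @export
revisePanel <- function(p, remove = NULL, add = NULL, newVersion,
                        packInto = NULL, plexCap = 12L, minSeparation = 30,
                        seed = NULL) {
  stopifnot(methods::is(p, "GynPanel"))
  tg <- p@targets
  am <- p@alleleMasses
  keyOf <- function(df) paste(df$gene, normProtein(df$protein_change),
                              normNt(df$nucleotide_change), sep = "\r")
  if (!is.null(remove) && nrow(remove)) {
    remove <- as.data.frame(remove)
    if (is.null(remove$nucleotide_change)) remove$nucleotide_change <- ""
    k <- keyOf(remove)
    have <- keyOf(tg)
    miss <- !(k %in% have)
    if (any(miss)) {
      stop("cannot remove absent target: ", remove$gene[miss][1L], " ",
           remove$protein_change[miss][1L], call. = FALSE)
    }
    dropped <- tg[have %in% k, , drop = FALSE]
    tg <- tg[!(have %in% k), , drop = FALSE]
    for (aid in unique(dropped$assay_id)) {
      if (!is.null(am[[aid]])) {
        gone <- siteId(dropped$protein_change[dropped$assay_id == aid],
                       dropped$nucleotide_change[dropped$assay_id == aid])
        am[[aid]] <- am[[aid]][setdiff(names(am[[aid]]), gone)]
      }
    }
  }
  keepIds <- unique(tg$assay_id)
  assays <- p@assays[p@assays$assay_id %in% keepIds, , drop = FALSE]
  am <- am[intersect(names(am), keepIds)]
  out <- GynPanel(p@name, newVersion, tg, assays, am)
  if (!is.null(add) && nrow(add)) {
    add <- as.data.frame(add)
    if (is.null(add$nucleotide_change)) add$nucleotide_change <- ""
    add$protein_change <- normProtein(add$protein_change)
    add$nucleotide_change <- normNt(add$nucleotide_change)
    if (any(keyOf(add) %in% keyOf(tg))) {
      dup <- add[keyOf(add) %in% keyOf(tg), , drop = FALSE][1L, ]
      stop("cannot add duplicate target: ", dup$gene, " ", dup$protein_change,
           call. = FALSE)
    }
    site <- paste(add$gene, codonOf(add$protein_change))
    add$assay_id <- paste0(add$gene, "_", sub("^p\\.", "", add$protein_change),
                           "_v", gsub("[^0-9A-Za-z]", "", newVersion))
    ## one new assay per site, pooling alternate alleles
    add$assay_id <- ave(add$assay_id, site, FUN = function(x) x[1L])
    add$added_in_version <- newVersion
    tg2 <- rbind(tg, add[, c("gene", "protein_change", "nucleotide_change",
                             "assay_id", "added_in_version")])
    newAssays <- data.frame(assay_id = unique(add$assay_id),
                            well_id = NA_character_, primer_mass = NA_real_,
                            stringsAsFactors = FALSE)
    out <- GynPanel(p@name, newVersion, tg2, rbind(assays, newAssays), am)
    out <- assignAnalyteMasses(out, seed = seed, onlyAssays = newAssays$assay_id)
    out <- packMultiplexes(out, plexCap = plexCap,
                           minSeparation = minSeparation,
                           onlyAssays = newAssays$assay_id,
                           restrictWells = packInto)
  }
  out
}
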