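#' Construct a mutation catalogue
#'
#' Builds a validated [MutationCatalogue] from a data.frame of per-site
#' occurrence counts. Protein changes are normalised to carry the `"p."`
#' prefix; missing nucleotide disambiguators become `""`.
#'
#' @param records data.frame with columns `gene`, `protein_change`,
#'   `nucleotide_change`, `tissue`, `occurrences`, `tested`.
#' @return A [MutationCatalogue].
#' @examples
#' cat <- MutationCatalogue(data.frame(
#'   gene = "PIK3CA", protein_change = "E545K", nucleotide_change = "",
#'   tissue = "cervix", occurrences = 33, tested = 332))
#' length(cat)
#' @export
MutationCatalogue <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records)) {
    records$gene <- as.character(records$gene)
    records$protein_change <- normProtein(records$protein_change)
    records$nucleotide_change <- normNt(records$nucleotide_change)
    records$tissue <- as.character(records$tissue)
    records$occurrences <- as.integer(records$occurrences)
    records$tested <- as.integer(records$tested)
  }
  rownames(records) <- NULL
  methods::new("MutationCatalogue", records = records)
}

#' Access catalogue records
#' @param x A [MutationCatalogue].
#' @return data.frame of records.
#' @export
catalogueRecords <- function(x) {
  stopifnot(methods::is(x, "MutationCatalogue"))
  x@records
}

#' Genes present in a catalogue or panel
#' @param x A [MutationCatalogue] or [GynPanel].
#' @return Character vector of gene symbols (sorted, unique).
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname genes
#' @export
setMethod("genes", "MutationCatalogue",
          function(x) sort(unique(x@records$gene)))

#' Read a mutation catalogue from tab-separated text
#'
#' Expects a UTF-8, tab-separated file with a header row naming the six
#' record columns. Row order is irrelevant; validation errors name the
#' offending record.
#'
#' @param path Path to the file.
#' @return A [MutationCatalogue].
#' @seealso [writeCatalogue()]
#' @export
readCatalogue <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                      colClasses = "character"),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  need <- c("gene", "protein_change", "nucleotide_change", "tissue",
            "occurrences", "tested")
  if (!all(need %in% names(df))) {
    stop("catalogue header must name columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  occ <- suppressWarnings(as.integer(df$occurrences))
  tst <- suppressWarnings(as.integer(df$tested))
  if (nrow(df) && (anyNA(occ) || anyNA(tst))) {
    bad <- which(is.na(occ) | is.na(tst))[1L]
    stop(sprintf("malformed row %d in %s: non-integer counts", bad + 1L, path),
         call. = FALSE)
  }
  df$occurrences <- occ
  df$tested <- tst
  MutationCatalogue(df)
}

#' Write a mutation catalogue as tab-separated text
#' @param x A [MutationCatalogue].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeCatalogue <- function(x, path) {
  stopifnot(methods::is(x, "MutationCatalogue"))
  utils::write.table(x@records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Gene-level tested denominator for one tissue: catalogue rows of a gene in
## one tissue share the gene-level screening denominator, so the per-tissue
## denominator is the maximum over rows; "all" sums the per-tissue maxima.
testedDenominator <- function(df, tissue) {
  if (tissue == "all") {
    sum(vapply(split(df$tested, df$tissue), max, numeric(1)))
  } else {
    max(df$tested)
  }
}

#' Per-site occurrence frequencies for a gene
#'
#' Aggregates catalogue occurrences per site (protein change plus nucleotide
#' disambiguator) for one gene, either within one tissue or pooled over all
#' tissues (`tissue = "all"`).
#'
#' @param cat A [MutationCatalogue].
#' @param gene Gene symbol.
#' @param tissue Tissue label or `"all"`.
#' @return A list of class `"SiteFrequencyTable"`: `gene`, `tissue`,
#'   `site_counts` (named integer vector, decreasing), `total_occurrences`,
#'   `total_tested`.
#' @export
siteFrequencies <- function(cat, gene, tissue = "all") {
  stopifnot(methods::is(cat, "MutationCatalogue"))
  df <- cat@records[cat@records$gene == gene, , drop = FALSE]
  if (nrow(df) == 0L) stop("gene not found in catalogue: ", gene, call. = FALSE)
  if (tissue != "all") {
    df <- df[df$tissue == tissue, , drop = FALSE]
    if (nrow(df) == 0L) {
      stop(sprintf("gene %s has no records for tissue %s", gene, tissue),
           call. = FALSE)
    }
  }
  counts <- tapply(df$occurrences, siteId(df$protein_change, df$nucleotide_change),
                   sum)
  counts <- sort(c(counts), decreasing = TRUE)
  out <- list(gene = gene, tissue = tissue,
              site_counts = counts,
              total_occurrences = sum(df$occurrences),
              total_tested = testedDenominator(df, tissue))
  class(out) <- "SiteFrequencyTable"
  out
}

#' @export
print.SiteFrequencyTable <- function(x, ...) {
  cat(sprintf("Site frequencies for %s (%s): %d occurrences / %d tested over %d sites\n",
              x$gene, x$tissue, x$total_occurrences, x$total_tested,
              length(x$site_counts)))
  print(utils::head(x$site_counts, 10L))
  invisible(x)
}

## Best cumulative top-(maxSites-1) occurrence share for one gene in one
## tissue slice; NA when the gene has no occurrences there.
topShare <- function(counts, maxSites) {
  tot <- sum(counts)
  if (tot == 0L) return(NA_real_)
  sum(utils::head(sort(counts, decreasing = TRUE), maxSites - 1L)) / tot
}

#' Select hotspot genes from a catalogue
#'
#' A gene qualifies as a hotspot gene when, for at least one of the requested
#' tissues, at least `minFraction` of its reported mutation occurrences fall
#' on fewer than `maxSites` distinct sites — i.e. the cumulative share of its
#' top `maxSites - 1` sites reaches `minFraction`. The defaults encode the
#' 30%-on-fewer-than-10-sites rule used to design the gynaecological panel.
#'
#' @param cat A [MutationCatalogue].
#' @param tissues Character vector of tissue labels to examine.
#' @param minFraction Minimum cumulative occurrence share, in (0, 1].
#' @param maxSites Sites bound: the share is computed over the top
#'   `maxSites - 1` sites.
#' @param pooled If `TRUE`, evaluate the rule on counts pooled over `tissues`
#'   instead of per tissue.
#' @return data.frame with columns `gene`, `share` (best qualifying share) and
#'   `tissue` (the tissue achieving it, or `"pooled"`), sorted by decreasing
#'   share with alphabetical tie-break. Zero rows when nothing qualifies.
#' @export
selectHotspotGenes <- function(cat, tissues, minFraction = 0.30,
                               maxSites = 10L, pooled = FALSE) {
  stopifnot(methods::is(cat, "MutationCatalogue"))
  if (!is.numeric(minFraction) || minFraction <= 0 || minFraction > 1) {
    stop("minFraction must be in (0, 1]", call. = FALSE)
  }
  if (maxSites < 1L) stop("maxSites must be >= 1", call. = FALSE)
  empty <- data.frame(gene = character(), share = numeric(),
                      tissue = character(), stringsAsFactors = FALSE)
  df <- cat@records[cat@records$tissue %in% tissues, , drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  rows <- lapply(sort(unique(df$gene)), function(g) {
    gdf <- df[df$gene == g, , drop = FALSE]
    if (pooled) {
      counts <- tapply(gdf$occurrences,
                       siteId(gdf$protein_change, gdf$nucleotide_change), sum)
      sh <- topShare(c(counts), maxSites)
      data.frame(gene = g, share = sh, tissue = "pooled",
                 stringsAsFactors = FALSE)
    } else {
      per <- vapply(split(gdf, gdf$tissue), function(tdf) {
        counts <- tapply(tdf$occurrences,
                         siteId(tdf$protein_change, tdf$nucleotide_change), sum)
        topShare(c(counts), maxSites)
      }, numeric(1))
      per <- per[!is.na(per)]
      if (!length(per)) return(NULL)
      per <- per[order(names(per))]  # alphabetical tissue tie-break
      best <- which.max(per)
      data.frame(gene = g, share = unname(per[best]), tissue = names(per)[best],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[!is.na(out$share) & out$share >= minFraction, , drop = FALSE]
  out <- out[order(-out$share, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene mutation frequency in a tissue
#'
#' Total reported occurrences divided by the number of samples tested, the
#' "283/1309"-style catalogue frequency underlying yield prediction.
#'
#' @inheritParams siteFrequencies
#' @return Fraction in \[0, 1\].
#' @export
geneMutationFrequency <- function(cat, gene, tissue) {
  sf <- siteFrequencies(cat, gene, tissue)
  if (sf$total_tested == 0L) {
    stop(sprintf("undefined frequency: no samples tested for %s in %s",
                 gene, tissue), call. = FALSE)
  }
  sf$total_occurrences / sf$total_tested
}

#' Panel coverage of a gene's catalogued mutations
#'
#' Fraction of all catalogued mutation occurrences of `gene` (in `tissue`, or
#' pooled with `"all"`) that fall on the targeted sites. Sites are identified
#' as in [siteFrequencies()]; targeted sites absent from the catalogue
#' contribute zero occurrences.
#'
#' @inheritParams siteFrequencies
#' @param targets Character vector of site identifiers (protein change,
#'   optionally with the nucleotide disambiguator as `"p.Q61H (C>A)"`; the
#'   `"p."` prefix is optional).
#' @return Fraction in \[0, 1\]; 0 for an empty target set, and 0 when the
#'   gene has no occurrences in the tissue.
#' @export
computeCoverage <- function(cat, targets, gene, tissue = "all") {
  sf <- siteFrequencies(cat, gene, tissue)
  if (length(targets) == 0L) return(0)
  targets <- normProtein(as.character(targets))
  counts <- sf$site_counts
  covered <- sum(counts[names(counts) %in% targets])
  if (sf$total_occurrences == 0L) return(0)
  covered / sf$total_occurrences
}
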