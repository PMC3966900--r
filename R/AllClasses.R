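#' MutationCatalogue: a COSMIC-like somatic mutation catalogue
#'
#' Container for per-site somatic mutation occurrence counts, one row per
#' (gene, protein change, nucleotide disambiguator, tissue). `occurrences` is
#' the number of mutated samples reported at the site and `tested` the number
#' of samples screened for the gene in that tissue; rows for the same gene and
#' tissue therefore typically share `tested`.
#'
#' @slot records data.frame with columns `gene`, `protein_change`,
#'   `nucleotide_change`, `tissue`, `occurrences`, `tested`.
#' @export
setClass("MutationCatalogue", representation(records = "data.frame"))

setValidity("MutationCatalogue", function(object) {
  df <- object@records
  need <- c("gene", "protein_change", "nucleotide_change", "tissue",
            "occurrences", "tested")
  if (!all(need %in% names(df))) {
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(TRUE)
  if (!all(df$tissue %in% TISSUES)) {
    return(paste("tissue must be one of:", paste(TISSUES, collapse = ", ")))
  }
  if (!is.numeric(df$occurrences) || any(df$occurrences < 0) ||
      any(df$occurrences != floor(df$occurrences))) {
    return("occurrences must be non-negative integers")
  }
  if (!is.numeric(df$tested) || any(df$tested < 1) ||
      any(df$tested != floor(df$tested))) {
    return("tested must be positive integers")
  }
  if (any(df$occurrences > df$tested)) {
    bad <- which(df$occurrences > df$tested)[1L]
    return(sprintf("occurrences > tested at row %d (%s %s)",
                   bad, df$gene[bad], df$protein_change[bad]))
  }
  key <- paste(df$gene, df$protein_change, df$nucleotide_change, df$tissue,
               sep = "\r")
  if (anyDuplicated(key)) {
    bad <- df[duplicated(key), , drop = FALSE][1L, ]
    return(sprintf("duplicate record: %s %s (%s) %s",
                   bad$gene, bad$protein_change, bad$nucleotide_change,
                   bad$tissue))
  }
  TRUE
})

#' GynPanel: a multiplexed hotspot genotyping panel
#'
#' The designed product: target mutations grouped into single-site extension
#' assays, assays assigned to multiplex wells, and (once assigned) analyte
#' masses for the unextended extension primer and each allele-specific
#' extension product.
#'
#' @slot name,version Character scalars identifying the panel.
#' @slot targets data.frame with columns `gene`, `protein_change`,
#'   `nucleotide_change`, `assay_id`, `added_in_version`.
#' @slot assays data.frame with columns `assay_id`, `well_id` (NA until
#'   packed), `primer_mass` (NA until masses are assigned).
#' @slot alleleMasses Named list (by assay_id) of named numeric vectors of
#'   extension-product masses in daltons; each contains `"WT"` plus one entry
#'   per mutant allele (named by site identifier). Empty until assigned.
#' @export
setClass("GynPanel",
         representation(name = "character", version = "character",
                        targets = "data.frame", assays = "data.frame",
                        alleleMasses = "list"))

setValidity("GynPanel", function(object) {
  tg <- object@targets
  as <- object@assays
  needT <- c("gene", "protein_change", "nucleotide_change", "assay_id",
             "added_in_version")
  needA <- c("assay_id", "well_id", "primer_mass")
  if (!all(needT %in% names(tg))) {
    return(paste("targets must have columns:", paste(needT, collapse = ", ")))
  }
  if (!all(needA %in% names(as))) {
    return(paste("assays must have columns:", paste(needA, collapse = ", ")))
  }
  if (nrow(tg) > 0L) {
    key <- paste(tg$gene, tg$protein_change, tg$nucleotide_change, sep = "\r")
    if (anyDuplicated(key)) {
      bad <- tg[duplicated(key), , drop = FALSE][1L, ]
      return(sprintf("target present in two assays or duplicated: %s %s (%s)",
                     bad$gene, bad$protein_change, bad$nucleotide_change))
    }
    if (!all(tg$assay_id %in% as$assay_id)) {
      return("targets reference assay_ids missing from the assay table")
    }
    byAssay <- split(tg$gene, tg$assay_id)
    multi <- vapply(byAssay, function(g) length(unique(g)) > 1L, logical(1))
    if (any(multi)) {
      return(sprintf("assay %s spans more than one gene", names(byAssay)[multi][1L]))
    }
    cod <- split(codonOf(tg$protein_change), tg$assay_id)
    multi <- vapply(cod, function(x) length(unique(x)) > 1L, logical(1))
    if (any(multi)) {
      return(sprintf("assay %s targets more than one site", names(cod)[multi][1L]))
    }
  }
  if (anyDuplicated(as$assay_id)) return("duplicate assay_id")
  if (nrow(as) > 0L && !all(as$assay_id %in% tg$assay_id)) {
    return("assay without targets")
  }
  am <- object@alleleMasses
  if (length(am)) {
    if (is.null(names(am)) || !all(names(am) %in% as$assay_id)) {
      return("alleleMasses names must be assay_ids")
    }
    for (aid in names(am)) {
      m <- am[[aid]]
      if (!is.numeric(m) || anyNA(m) || any(m <= 0)) {
        return(sprintf("assay %s has non-positive allele masses", aid))
      }
      if (!"WT" %in% names(m)) {
        return(sprintf("assay %s lacks a WT allele mass", aid))
      }
      tgt <- tg[tg$assay_id == aid, , drop = FALSE]
      want <- siteId(tgt$protein_change, tgt$nucleotide_change)
      if (!setequal(setdiff(names(m), "WT"), want)) {
        return(sprintf("assay %s allele masses do not match its targets", aid))
      }
    }
    pm <- as$primer_mass[match(names(am), as$assay_id)]
    if (anyNA(pm) || any(pm <= 0)) {
      return("assays with allele masses must carry a positive primer mass")
    }
  }
  TRUE
})

#' @describeIn MutationCatalogue Number of catalogue records.
#' @param x A MutationCatalogue.
#' @export
setMethod("length", "MutationCatalogue", function(x) nrow(x@records))

setMethod("show", "MutationCatalogue", function(object) {
  df <- object@records
  cat(sprintf("MutationCatalogue with %d records: %d genes, %d tissues, %d occurrences\n",
              nrow(df), length(unique(df$gene)), length(unique(df$tissue)),
              sum(df$occurrences)))
  if (nrow(df)) {
    print(utils::head(df, 5L), row.names = FALSE)
    if (nrow(df) > 5L) cat(sprintf("... and %d more rows\n", nrow(df) - 5L))
  }
})

setMethod("show", "GynPanel", function(object) {
  tot <- panelTotals(object)
  cat(sprintf("GynPanel '%s' version %s\n", object@name, object@version))
  cat(sprintf("  %d genes, %d target mutations, %d assays, %d multiplex wells\n",
              tot$genes, tot$mutations, tot$assays, tot$wells))
  cat(sprintf("  analyte masses: %s\n",
              if (length(object@alleleMasses)) "assigned" else "not assigned"))
})
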