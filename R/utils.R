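# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding of non-negative values: 0.5 always rounds up. Used for
#' expected mutation counts and integer percentages in reports, where base R's
#' banker's rounding would disagree with the printed tables this package
#' reproduces.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @return Numeric vector of rounded values.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 44.66))
#' @export
roundHalfUp <- function(x) {
  floor(x + 0.5)
}

## Controlled tissue vocabulary.
TISSUES <- c("cervix", "endometrium", "ovary", "vulva", "other")

## Normalise HGVS-p strings: "E545K" and "p.E545K" denote the same change.
normProtein <- function(x) {
  x <- trimws(as.character(x))
  ifelse(x == "" | is.na(x), x, ifelse(startsWith(x, "p."), x, paste0("p.", x)))
}

normNt <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  x
}

## Site identifier: protein change plus nucleotide disambiguator where one
## exists (e.g. "p.Q61H (C>A)" vs "p.Q61H (C>G)" are distinct assay targets).
siteId <- function(protein_change, nucleotide_change) {
  nt <- normNt(nucleotide_change)
  paste0(normProtein(protein_change), ifelse(nt == "", "", paste0(" (", nt, ")")))
}

## Codon number from an HGVS-p string, e.g. "p.E545K" -> 545.
codonOf <- function(protein_change) {
  suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", protein_change)))
}

## Seed handling: run `expr` under `seed` without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

checkFraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    stop(sprintf("%s must be within [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}
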