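#' Expected number of detected mutations in a cohort
#'
#' The panel-corrected yield model: a cohort of `n` samples, a catalogue
#' mutation frequency `frequency` for the gene in that tissue, and the panel's
#' `coverage` of the gene's catalogued mutation occurrences give an expected
#' count of `frequency * coverage * n` detected mutations, rounded half-up to
#' an integer.
#'
#' @param frequency Catalogue mutation frequency, in \[0, 1\] (e.g. 283/1309).
#' @param coverage Panel coverage of the gene, in \[0, 1\].
#' @param n Cohort size (non-negative integer).
#' @return Integer expected count (vectorised over its arguments).
#' @examples
#' expectedCount(283 / 1309, 0.91, 227)  # 45
#' @export
expectedCount <- function(frequency, coverage, n) {
  checkFraction(frequency, "frequency")
  checkFraction(coverage, "coverage")
  if (!is.numeric(n) || anyNA(n) || any(n < 0) || any(n != floor(n))) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  as.integer(roundHalfUp(frequency * coverage * n))
}

#' Build a yield-prediction table
#'
#' One row per gene and tissue: catalogue frequency, panel coverage, expected
#' count for the cohort size, and (when supplied) the observed detected count.
#' Gene/tissue pairs present in `cohorts` but missing from `freqCov` are
#' emitted with `missing_inputs = TRUE` rather than dropped.
#'
#' @param freqCov data.frame with columns `gene`, `tissue`, `occurrences`,
#'   `tested`, `coverage` (fraction in \[0,1\], NA when inapplicable); see
#'   [gynCartaFreqCov()] for the packaged transcription.
#' @param cohorts data.frame with columns `tissue`, `size`.
#' @param observed Optional data.frame with columns `gene`, `tissue`,
#'   `n_detected`.
#' @return data.frame with columns `gene`, `tissue`, `frequency`, `coverage`,
#'   `n_expected`, `n_detected`, `missing_inputs`.
#' @export
yieldTable <- function(freqCov, cohorts, observed = NULL) {
  cohorts <- as.data.frame(cohorts)
  if (nrow(cohorts) == 0L) {
    return(data.frame(gene = character(), tissue = character(),
                      frequency = numeric(), coverage = numeric(),
                      n_expected = integer(), n_detected = integer(),
                      missing_inputs = logical(), stringsAsFactors = FALSE))
  }
  if (any(cohorts$size < 1)) stop("cohort sizes must be >= 1", call. = FALSE)
  freqCov <- as.data.frame(freqCov)
  genesAll <- sort(unique(freqCov$gene))
  rows <- lapply(seq_len(nrow(cohorts)), function(i) {
    ts <- cohorts$tissue[i]
    n <- cohorts$size[i]
    fc <- freqCov[freqCov$tissue == ts, , drop = FALSE]
    out <- data.frame(gene = genesAll, tissue = ts, frequency = NA_real_,
                      coverage = NA_real_, n_expected = NA_integer_,
                      n_detected = NA_integer_, missing_inputs = TRUE,
                      stringsAsFactors = FALSE)
    j <- match(out$gene, fc$gene)
    hit <- !is.na(j)
    out$frequency[hit] <- fc$occurrences[j[hit]] / fc$tested[j[hit]]
    out$coverage[hit] <- fc$coverage[j[hit]]
    ok <- hit & !is.na(out$frequency) & !is.na(out$coverage)
    out$n_expected[ok] <- expectedCount(out$frequency[ok], out$coverage[ok],
                                        rep(n, sum(ok)))
    out$missing_inputs <- !ok
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(observed)) {
    observed <- as.data.frame(observed)
    j <- match(paste(out$gene, out$tissue),
               paste(observed$gene, observed$tissue))
    out$n_detected <- as.integer(observed$n_detected[j])
  }
  rownames(out) <- NULL
  out
}

#' The packaged frequency and coverage table
#'
#' Catalogue frequency fractions (occurrences / samples tested) and panel
#' coverage percentages for the 13 panel genes in the four study tissues and
#' the pooled cohort, as transcribed for the published panel. `coverage` is
#' returned as a fraction; NA marks gene/tissue pairs where coverage was not
#' applicable (no catalogued occurrences).
#'
#' @return data.frame with columns `gene`, `tissue`, `occurrences`, `tested`,
#'   `coverage`.
#' @export
gynCartaFreqCov <- function() {
  path <- system.file("extdata", "gyncarta2_freqcov.tsv", package = "panelkit",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  df$coverage <- df$coverage_pct / 100
  df$coverage_pct <- NULL
  df
}

#' The study cohort sizes
#'
#' Cohort sizes of the four-tissue validation series (205 cervical, 227
#' endometrial, 89 ovarian and 25 vulvar carcinomas).
#'
#' @return data.frame with columns `tissue`, `size`.
#' @export
studyCohorts <- function() {
  data.frame(tissue = c("cervix", "endometrium", "ovary", "vulva"),
             size = c(205L, 227L, 89L, 25L), stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Own implementation by full hypergeometric enumeration: with margins fixed,
#' every admissible table's conditional probability is computed from the
#' hypergeometric distribution (via log binomial coefficients) and the
#' two-sided p-value is the sum of probabilities of all tables no more
#' probable than the observed one, the standard two-sided convention.
#'
#' @param x 2x2 matrix of non-negative integer counts, or the count `a` with
#'   `b`, `c`, `d` supplied.
#' @param b,c,d Remaining cell counts when `x` is scalar.
#' @return List with `p.value` (in (0, 1\]) and `table`.
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p.value  # 1
#' @export
fisherExact2x2 <- function(x, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("x must be 2x2", call. = FALSE)
    a <- x[1L, 1L]; b <- x[1L, 2L]; c <- x[2L, 1L]; d <- x[2L, 2L]
  } else {
    a <- x
  }
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(cells)
  if (n < 1L) stop("undefined test: all margins zero", call. = FALSE)
  r1 <- a + b; c1 <- a + c
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  pObs <- logp[support == a]
  ## relative tolerance guards against ties lost to floating point
  p <- sum(exp(logp)[logp <= pObs + 1e-07])
  list(p.value = min(p, 1), table = matrix(c(a, c, b, d), 2L))
}

## Hypergeometric pmf over the full support of a 2x2 margin set; sums to 1.
hyper2x2Pmf <- function(r1, c1, n) {
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  stats::setNames(exp(lchoose(c1, support) + lchoose(n - c1, r1 - support) -
                        lchoose(n, r1)), support)
}
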