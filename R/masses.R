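#' Assign synthetic analyte masses to panel assays
#'
#' The published panel was designed with vendor tools and its primer masses
#' are not public, so analyte masses here are synthetic. Each assay receives
#' an unextended-primer mass inside the working iPLEX analyte window and one
#' extension-product mass per allele at fixed offsets above the primer:
#' `productOffset` daltons for the first product and `alleleSpacing` daltons
#' between successive products. Under the default `"mutant_first"` ordering
#' policy every mutant extension product sits below the wild-type product, so
#' mutant peaks are detected first and are not shadowed by salt adducts of
#' the wild-type peak; `"none"` places the wild-type product at a random rank.
#'
#' Primer placement is `"stratified"` by default: primers occupy a shuffled,
#' jittered regular grid across the window, emulating the mass scheduling a
#' multiplex design tool performs so that assays can co-exist in few wells.
#' `"uniform"` draws primers independently and uniformly, which packs into
#' noticeably more wells.
#'
#' @param p A [GynPanel].
#' @param window Numeric length-2: analyte mass window in daltons.
#' @param ordering `"mutant_first"` or `"none"`.
#' @param placement `"stratified"` or `"uniform"` primer placement.
#' @param productOffset Daltons between primer and first extension product.
#' @param alleleSpacing Daltons between successive extension products; keep
#'   at or above the packing `minSeparation` so a lone assay is always
#'   internally feasible.
#' @param jitter Half-width of the uniform jitter applied to the stratified
#'   grid, in daltons.
#' @param seed Integer seed; identical seeds give identical masses. `NULL`
#'   uses the current RNG state.
#' @param onlyAssays Optional character vector: assign masses only to these
#'   assays (used when revising a panel), leaving others untouched.
#' @return The panel with `primer_mass` and allele-product masses filled in.
#' @examples
#' p <- assignAnalyteMasses(gynCartaPanel(), seed = 1)
#' range(panelAssays(p)$primer_mass)
#' @export
assignAnalyteMasses <- function(p, window = c(4500, 9000),
                                ordering = c("mutant_first", "none"),
                                placement = c("stratified", "uniform"),
                                productOffset = 250, alleleSpacing = 30,
                                jitter = 10, seed = NULL, onlyAssays = NULL) {
  stopifnot(methods::is(p, "GynPanel"))
  ordering <- match.arg(ordering)
  placement <- match.arg(placement)
  if (!is.numeric(window) || length(window) != 2L || window[1L] >= window[2L] ||
      window[1L] <= 0) {
    stop("window must be an increasing positive mass range", call. = FALSE)
  }
  if (productOffset <= 0 || alleleSpacing <= 0) {
    stop("productOffset and alleleSpacing must be positive", call. = FALSE)
  }
  ids <- if (is.null(onlyAssays)) p@assays$assay_id else {
    if (!all(onlyAssays %in% p@assays$assay_id)) {
      stop("onlyAssays contains unknown assay_ids", call. = FALSE)
    }
    onlyAssays
  }
  if (length(ids) == 0L) return(p)
  ids <- sort(ids)
  tg <- p@targets
  nMut <- vapply(ids, function(aid) sum(tg$assay_id == aid), integer(1))
  if (any(nMut == 0L)) stop("assay without targets cannot receive masses",
                            call. = FALSE)
  width <- productOffset + alleleSpacing * nMut  # primer -> top product
  if (window[2L] - window[1L] <= max(width) + 2 * jitter) {
    stop("mass window too narrow for the requested assays", call. = FALSE)
  }
  withSeed(seed, {
    n <- length(ids)
    primer <- if (placement == "stratified") {
      grid <- seq(window[1L] + jitter, window[2L] - max(width) - jitter,
                  length.out = n)
      grid[sample.int(n)] + stats::runif(n, -jitter, jitter)
    } else {
      window[1L] + stats::runif(n) * (window[2L] - window[1L] - width)
    }
    am <- p@alleleMasses
    for (i in seq_len(n)) {
      aid <- ids[i]
      tgt <- tg[tg$assay_id == aid, , drop = FALSE]
      sites <- siteId(tgt$protein_change, tgt$nucleotide_change)
      m <- nMut[i]
      offsets <- productOffset + alleleSpacing * (0:m)
      labels <- c(sort(sites), "WT")        # mutant products below WT
      if (ordering == "none") labels <- sample(labels)
      masses <- primer[i] + offsets
      names(masses) <- labels
      am[[aid]] <- masses
    }
    assays <- p@assays
    assays$primer_mass[match(ids, assays$assay_id)] <- primer
    methods::new("GynPanel", name = p@name, version = p@version,
                 targets = p@targets, assays = assays, alleleMasses = am)
  })
}

## All analyte masses of one assay (primer + products), or NULL when
## unassigned.
assayMasses <- function(p, assay_id) {
  m <- p@alleleMasses[[assay_id]]
  if (is.null(m)) return(NULL)
  pm <- p@assays$primer_mass[match(assay_id, p@assays$assay_id)]
  c(primer = unname(pm), m)
}
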