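#' Pack assays into multiplex wells
#'
#' First-fit decreasing by extension-primer mass: assays are sorted by
#' decreasing primer mass (ties broken by assay_id) and each is placed into
#' the first existing well that (a) holds fewer than `plexCap` assays and
#' (b) keeps every pair of analyte masses in the well — unextended primers
#' and all extension products — at least `minSeparation` daltons apart; a new
#' well is opened when no existing well admits the assay. The layout is
#' deterministic given the panel's masses.
#'
#' @param p A [GynPanel] with analyte masses assigned (see
#'   [assignAnalyteMasses()]).
#' @param plexCap Maximum assays per well.
#' @param minSeparation Minimum pairwise analyte mass separation in daltons.
#' @param onlyAssays Optional character vector: place only these assays,
#'   leaving existing well assignments untouched (used by [revisePanel()]).
#' @param restrictWells Optional character vector of well ids that the placed
#'   assays may join; new wells are still opened when none admits an assay.
#' @param wellPrefix Prefix for newly opened well ids.
#' @return The panel with `well_id` filled in for the placed assays.
#' @examples
#' p <- assignAnalyteMasses(gynCartaPanel(), seed = 1)
#' p <- packMultiplexes(p)
#' panelTotals(p)$wells
#' @export
packMultiplexes <- function(p, plexCap = 12L, minSeparation = 30,
                            onlyAssays = NULL, restrictWells = NULL,
                            wellPrefix = "W") {
  stopifnot(methods::is(p, "GynPanel"))
  if (plexCap < 1L) stop("plexCap must be >= 1", call. = FALSE)
  if (minSeparation < 0) stop("minSeparation must be >= 0", call. = FALSE)
  assays <- p@assays
  ids <- if (is.null(onlyAssays)) assays$assay_id else onlyAssays
  if (length(ids) == 0L) return(p)
  masses <- lapply(ids, function(a) assayMasses(p, a))
  names(masses) <- ids
  if (any(vapply(masses, is.null, logical(1)))) {
    stop("assign analyte masses before packing", call. = FALSE)
  }
  tol <- 1e-9  # guard against floating-point jitter at exact spacing
  ## a lone assay must satisfy its own internal separation
  for (a in ids) {
    m <- sort(masses[[a]])
    if (length(m) > 1L && min(diff(m)) < minSeparation - tol) {
      stop(sprintf("assay %s is infeasible: internal analyte separation %.1f < %.1f",
                   a, min(diff(m)), minSeparation), call. = FALSE)
    }
  }
  ## seed the open wells with assays that keep their assignment
  keep <- if (is.null(onlyAssays)) character(0) else {
    setdiff(assays$assay_id[!is.na(assays$well_id)], ids)
  }
  wells <- list()
  for (a in keep) {
    w <- assays$well_id[match(a, assays$assay_id)]
    if (is.null(wells[[w]])) wells[[w]] <- list(assays = character(0),
                                                masses = numeric(0))
    wells[[w]]$assays <- c(wells[[w]]$assays, a)
    m <- assayMasses(p, a)
    wells[[w]]$masses <- c(wells[[w]]$masses, m)  # NULL-safe: m may be NULL
  }
  newWells <- character(0)  # wells opened during this call
  admissible <- function(w, m) {
    if (length(wells[[w]]$assays) >= plexCap) return(FALSE)
    wm <- wells[[w]]$masses
    if (length(wm) == 0L) return(TRUE)
    min(abs(outer(m, wm, "-"))) >= minSeparation - tol
  }
  primer <- assays$primer_mass[match(ids, assays$assay_id)]
  order_ids <- ids[order(-primer, ids)]
  assignment <- stats::setNames(rep(NA_character_, length(ids)), ids)
  nNew <- 0L
  for (a in order_ids) {
    m <- masses[[a]]
    placed <- NA_character_
    candidates <- names(wells)
    if (!is.null(restrictWells)) {
      candidates <- candidates[candidates %in% restrictWells |
                                 candidates %in% newWells]
    }
    for (w in candidates) {
      if (admissible(w, m)) { placed <- w; break }
    }
    if (is.na(placed)) {
      repeat {
        nNew <- nNew + 1L
        placed <- sprintf("%s%02d", wellPrefix, nNew)
        if (is.null(wells[[placed]])) break
      }
      wells[[placed]] <- list(assays = character(0), masses = numeric(0))
      newWells <- c(newWells, placed)
    }
    wells[[placed]]$assays <- c(wells[[placed]]$assays, a)
    wells[[placed]]$masses <- c(wells[[placed]]$masses, m)
    assignment[a] <- placed
  }
  assays$well_id[match(ids, assays$assay_id)] <- assignment[ids]
  methods::new("GynPanel", name = p@name, version = p@version,
               targets = p@targets, assays = assays,
               alleleMasses = p@alleleMasses)
}

#' Check multiplex wells against packing constraints
#'
#' Independent exhaustive checker: scans every well of the panel and reports
#' each plex-cap breach and each pair of analyte masses closer than
#' `minSeparation`. An empty result means every well is valid. Assays without
#' masses contribute no separation constraints (their cap occupancy still
#' counts).
#'
#' @param p A [GynPanel].
#' @param plexCap,minSeparation Constraint parameters (see
#'   [packMultiplexes()]).
#' @param wells Optional well ids to check (default: all occupied wells).
#' @return data.frame with columns `well_id`, `type` (`"cap"` or
#'   `"separation"`) and `detail`; zero rows when clean.
#' @export
validateMultiplex <- function(p, plexCap = 12L, minSeparation = 30,
                              wells = NULL) {
  stopifnot(methods::is(p, "GynPanel"))
  assays <- p@assays[!is.na(p@assays$well_id), , drop = FALSE]
  if (!is.null(wells)) assays <- assays[assays$well_id %in% wells, , drop = FALSE]
  out <- list()
  for (w in unique(assays$well_id)) {
    ids <- assays$assay_id[assays$well_id == w]
    if (length(ids) > plexCap) {
      out[[length(out) + 1L]] <- data.frame(
        well_id = w, type = "cap",
        detail = sprintf("%d assays > cap %d", length(ids), plexCap),
        stringsAsFactors = FALSE)
    }
    ml <- lapply(ids, function(a) assayMasses(p, a))
    lab <- unlist(lapply(seq_along(ids), function(i) {
      if (is.null(ml[[i]])) character(0) else paste(ids[i], names(ml[[i]]))
    }))
    m <- unlist(ml)
    if (length(m) > 1L) {
      pairs <- utils::combn(length(m), 2L)
      gap <- abs(m[pairs[1L, ]] - m[pairs[2L, ]])
      for (i in which(gap < minSeparation - 1e-9)) {
        out[[length(out) + 1L]] <- data.frame(
          well_id = w, type = "separation",
          detail = sprintf("%s and %s are %.2f Da apart (< %.2f)",
                           lab[pairs[1L, i]], lab[pairs[2L, i]], gap[i],
                           minSeparation),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(well_id = character(), type = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
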