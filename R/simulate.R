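#' Simulation configuration
#'
#' Bundles and validates everything the cohort and readout simulators need:
#' cohort sizes, per-tissue mutation probabilities, the mutant allele fraction
#' (MAF) distribution, readout noise, salt-adduct artifact rate, DNA-quality
#' distribution and quality-dependent assay failure rates, and replicate-arm
#' fractions.
#'
#' `mutationProbs` rows are gene-level (empty `protein_change`) or
#' target-level. A gene-level row mutates a sample with probability `prob` and
#' assigns the mutation to one target drawn from `targetWeights`; target-level
#' rows mutate each target independently.
#'
#' @param cohorts data.frame with columns `tissue`, `size`.
#' @param mutationProbs data.frame with columns `tissue`, `gene`,
#'   `protein_change` (empty or NA for gene-level rows), `nucleotide_change`,
#'   `prob`.
#' @param targetWeights data.frame with columns `tissue`, `gene`,
#'   `protein_change`, `nucleotide_change`, `weight`; required when
#'   gene-level rows are present.
#' @param mafRange Length-2 numeric: uniform MAF support, default
#'   `c(0.05, 0.6)` so the 5% calling threshold is exercised at its boundary.
#' @param noiseSd Relative (multiplicative, log-normal) peak-intensity noise;
#'   0 gives noiseless readouts.
#' @param artifactProb Per-assay probability of one salt-adduct artifact peak.
#' @param qualityProbs Length-4 probabilities of DNA quality scores 0--3.
#' @param failProbByQuality Length-4 per-assay failure probabilities for
#'   quality scores 0--3; must be non-increasing in quality.
#' @param replicateFractions Named numeric `c(duplicate = , triplicate = )`:
#'   fractions of samples run in duplicate and triplicate.
#' @param seed Integer seed driving all randomness downstream.
#' @return List of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(cohorts, mutationProbs, targetWeights = NULL,
                             mafRange = c(0.05, 0.6), noiseSd = 0.05,
                             artifactProb = 0.02,
                             qualityProbs = c(0.09, 0.11, 0.25, 0.55),
                             failProbByQuality = c(0.10, 0.03, 0.01, 0.005),
                             replicateFractions = c(duplicate = 0.10,
                                                    triplicate = 0.05),
                             seed = 1L) {
  cohorts <- as.data.frame(cohorts)
  stopifnot(all(c("tissue", "size") %in% names(cohorts)))
  if (any(cohorts$size < 1)) stop("cohort sizes must be >= 1", call. = FALSE)
  if (!all(cohorts$tissue %in% TISSUES)) {
    stop("unknown tissue label in cohorts", call. = FALSE)
  }
  mutationProbs <- as.data.frame(mutationProbs)
  stopifnot(all(c("tissue", "gene", "prob") %in% names(mutationProbs)))
  if (is.null(mutationProbs$protein_change)) mutationProbs$protein_change <- ""
  if (is.null(mutationProbs$nucleotide_change)) mutationProbs$nucleotide_change <- ""
  mutationProbs$protein_change[is.na(mutationProbs$protein_change)] <- ""
  mutationProbs$protein_change <- ifelse(mutationProbs$protein_change == "", "",
                                         normProtein(mutationProbs$protein_change))
  mutationProbs$nucleotide_change <- normNt(mutationProbs$nucleotide_change)
  checkFraction(mutationProbs$prob, "mutation probabilities")
  if (!is.null(targetWeights)) {
    targetWeights <- as.data.frame(targetWeights)
    stopifnot(all(c("tissue", "gene", "protein_change", "weight") %in%
                    names(targetWeights)))
    if (is.null(targetWeights$nucleotide_change)) targetWeights$nucleotide_change <- ""
    targetWeights$protein_change <- normProtein(targetWeights$protein_change)
    targetWeights$nucleotide_change <- normNt(targetWeights$nucleotide_change)
    if (any(targetWeights$weight < 0)) stop("weights must be >= 0", call. = FALSE)
  }
  geneLevel <- mutationProbs$protein_change == ""
  if (any(geneLevel) && is.null(targetWeights)) {
    stop("gene-level mutation probabilities require targetWeights",
         call. = FALSE)
  }
  checkFraction(mafRange, "mafRange")
  if (mafRange[1L] > mafRange[2L]) stop("mafRange must be increasing", call. = FALSE)
  if (mafRange[2L] <= 0) stop("mafRange upper bound must be positive", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  checkFraction(artifactProb, "artifactProb")
  stopifnot(length(qualityProbs) == 4L, length(failProbByQuality) == 4L)
  checkFraction(failProbByQuality, "failProbByQuality")
  if (is.unsorted(rev(failProbByQuality))) {
    stop("failProbByQuality must be non-increasing in quality score",
         call. = FALSE)
  }
  qualityProbs <- qualityProbs / sum(qualityProbs)
  checkFraction(replicateFractions, "replicateFractions")
  if (sum(replicateFractions) > 1) {
    stop("replicate fractions must sum to at most 1", call. = FALSE)
  }
  out <- list(cohorts = cohorts, mutationProbs = mutationProbs,
              targetWeights = targetWeights, mafRange = mafRange,
              noiseSd = noiseSd, artifactProb = artifactProb,
              qualityProbs = qualityProbs,
              failProbByQuality = failProbByQuality,
              replicateFractions = replicateFractions,
              seed = as.integer(seed))
  class(out) <- "SimulationConfig"
  out
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf("SimulationConfig: %d cohorts (%d samples), %d probability rows, seed %d\n",
              nrow(x$cohorts), sum(x$cohorts$size), nrow(x$mutationProbs),
              x$seed))
  invisible(x)
}

#' Default simulation configuration from the packaged study tables
#'
#' Gene-level per-tissue mutation probabilities are the detected per-gene
#' frequencies of the published study cohort (mutated samples / cohort size),
#' and per-target weights follow the published per-mutation detection counts,
#' restricted to targets present in the packaged panel. Tissues where a gene
#' was never detected get probability zero.
#'
#' @param cohorts Cohort sizes, default the study cohorts ([studyCohorts()]).
#' @param panel Panel whose targets bound the simulation, default
#'   [gynCartaPanel()].
#' @param ... Passed to [simulationConfig()] (noise, artifacts, quality,
#'   replicate fractions, seed).
#' @return A `"SimulationConfig"`.
#' @export
defaultSimulationConfig <- function(cohorts = studyCohorts(),
                                    panel = gynCartaPanel(), ...) {
  genesPath <- system.file("extdata", "gyncarta2_observed_genes.tsv",
                           package = "panelkit", mustWork = TRUE)
  targetsPath <- system.file("extdata", "gyncarta2_observed_targets.tsv",
                             package = "panelkit", mustWork = TRUE)
  g <- utils::read.delim(genesPath, stringsAsFactors = FALSE, comment.char = "#")
  t <- utils::read.delim(targetsPath, stringsAsFactors = FALSE, comment.char = "#")
  t$protein_change <- normProtein(t$protein_change)
  t$nucleotide_change <- normNt(t$nucleotide_change)
  tg <- panelTargets(panel)
  inPanel <- paste(t$gene, t$protein_change, t$nucleotide_change) %in%
    paste(tg$gene, tg$protein_change, tg$nucleotide_change)
  t <- t[inPanel, , drop = FALSE]
  tissueCols <- intersect(cohorts$tissue,
                          c("cervix", "endometrium", "ovary", "vulva"))
  names(tissueCols) <- tissueCols
  if (length(tissueCols) == 0L) {
    stop("cohorts must name at least one study tissue", call. = FALSE)
  }
  ## detected counts are frequencies of the published study cohorts; the
  ## requested cohort sizes only set how many samples are drawn
  studySizes <- stats::setNames(studyCohorts()$size, studyCohorts()$tissue)
  probs <- do.call(rbind, lapply(names(tissueCols), function(ts) {
    data.frame(tissue = ts, gene = g$gene, protein_change = "",
               nucleotide_change = "",
               prob = g[[tissueCols[[ts]]]] / unname(studySizes[ts]),
               stringsAsFactors = FALSE)
  }))
  weights <- do.call(rbind, lapply(names(tissueCols), function(ts) {
    data.frame(tissue = ts, gene = t$gene, protein_change = t$protein_change,
               nucleotide_change = t$nucleotide_change,
               weight = t[[tissueCols[[ts]]]], stringsAsFactors = FALSE)
  }))
  ## genes detected in a tissue but with no per-target counts there fall back
  ## to that gene's pooled counts
  pooled <- stats::aggregate(cbind(cervix, endometrium, ovary, vulva) ~ gene +
                               protein_change + nucleotide_change, data = t, sum)
  for (ts in names(tissueCols)) {
    for (gn in unique(probs$gene[probs$tissue == ts & probs$prob > 0])) {
      sel <- weights$tissue == ts & weights$gene == gn
      if (sum(weights$weight[sel]) == 0) {
        pg <- pooled[pooled$gene == gn, , drop = FALSE]
        tot <- rowSums(pg[, c("cervix", "endometrium", "ovary", "vulva")])
        j <- match(paste(weights$gene[sel], weights$protein_change[sel],
                         weights$nucleotide_change[sel]),
                   paste(pg$gene, pg$protein_change, pg$nucleotide_change))
        weights$weight[sel] <- ifelse(is.na(j), 0, tot[j])
      }
    }
  }
  simulationConfig(cohorts = cohorts, mutationProbs = probs,
                   targetWeights = weights, ...)
}

#' The qPCR-validated variant set
#'
#' The ten variants checked by allele-specific qPCR in the published
#' validation: seven KRAS codon 12/13 substitutions and three PIK3CA hotspot
#' substitutions.
#'
#' @return data.frame with columns `gene`, `protein_change`,
#'   `nucleotide_change`.
#' @export
validatedVariants <- function() {
  data.frame(
    gene = c(rep("KRAS", 7L), rep("PIK3CA", 3L)),
    protein_change = c("p.G12C", "p.G12R", "p.G12S", "p.G12V", "p.G12A",
                       "p.G12D", "p.G13D", "p.E542K", "p.E545K", "p.H1047R"),
    nucleotide_change = "", stringsAsFactors = FALSE)
}

#' Simulate a cohort of tumour samples
#'
#' Draws per-sample ground truth under the configuration: mutation events per
#' gene or target, a uniform mutant allele fraction for each mutation, an
#' ordinal DNA quality score 0--3, and replicate-arm membership (duplicate /
#' triplicate fractions of each cohort). Fully reproducible from the
#' configuration seed.
#'
#' @param cfg A `"SimulationConfig"`.
#' @return List of class `"SimulatedCohort"` with elements `samples`
#'   (data.frame: `sample_id`, `tissue`, `quality`, `n_replicates`) and
#'   `genotypes` (data.frame: `sample_id`, `gene`, `protein_change`,
#'   `nucleotide_change`, `maf` -- one row per mutation event).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(cfg$seed, {
    samplesL <- list()
    genoL <- list()
    offset <- 0L
    for (i in seq_len(nrow(cfg$cohorts))) {
      ts <- cfg$cohorts$tissue[i]
      n <- cfg$cohorts$size[i]
      ids <- sprintf("S%06d", offset + seq_len(n))
      offset <- offset + n
      quality <- sample(0:3, n, replace = TRUE, prob = cfg$qualityProbs)
      nDup <- roundHalfUp(cfg$replicateFractions[["duplicate"]] * n)
      nTri <- roundHalfUp(cfg$replicateFractions[["triplicate"]] * n)
      reps <- rep(1L, n)
      pick <- sample.int(n, min(n, nDup + nTri))
      reps[pick[seq_len(min(nDup, length(pick)))]] <- 2L
      if (length(pick) > nDup) reps[pick[(nDup + 1L):length(pick)]] <- 3L
      samplesL[[i]] <- data.frame(sample_id = ids, tissue = ts,
                                  quality = quality, n_replicates = reps,
                                  stringsAsFactors = FALSE)
      probs <- cfg$mutationProbs[cfg$mutationProbs$tissue == ts, , drop = FALSE]
      probs <- probs[order(probs$gene, probs$protein_change,
                           probs$nucleotide_change), , drop = FALSE]
      for (j in seq_len(nrow(probs))) {
        p <- probs$prob[j]
        if (p <= 0) next
        hit <- which(stats::runif(n) < p)
        if (!length(hit)) next
        if (probs$protein_change[j] == "") {
          w <- cfg$targetWeights
          w <- w[w$tissue == ts & w$gene == probs$gene[j], , drop = FALSE]
          w <- w[w$weight > 0, , drop = FALSE]
          if (nrow(w) == 0L) {
            stop(sprintf("no positive target weights for %s in %s",
                         probs$gene[j], ts), call. = FALSE)
          }
          k <- sample.int(nrow(w), length(hit), replace = TRUE,
                          prob = w$weight)
          genoL[[length(genoL) + 1L]] <- data.frame(
            sample_id = ids[hit], gene = probs$gene[j],
            protein_change = w$protein_change[k],
            nucleotide_change = w$nucleotide_change[k],
            maf = stats::runif(length(hit), cfg$mafRange[1L], cfg$mafRange[2L]),
            stringsAsFactors = FALSE)
        } else {
          genoL[[length(genoL) + 1L]] <- data.frame(
            sample_id = ids[hit], gene = probs$gene[j],
            protein_change = probs$protein_change[j],
            nucleotide_change = probs$nucleotide_change[j],
            maf = stats::runif(length(hit), cfg$mafRange[1L], cfg$mafRange[2L]),
            stringsAsFactors = FALSE)
        }
      }
    }
    samples <- do.call(rbind, samplesL)
    genotypes <- if (length(genoL)) do.call(rbind, genoL) else {
      data.frame(sample_id = character(), gene = character(),
                 protein_change = character(), nucleotide_change = character(),
                 maf = numeric(), stringsAsFactors = FALSE)
    }
    ## a gene-level draw can in principle pick the same target twice only via
    ## two different probability rows; drop exact duplicates defensively
    genotypes <- genotypes[!duplicated(genotypes[, 1:4]), , drop = FALSE]
    genotypes <- genotypes[order(genotypes$sample_id, genotypes$gene,
                                 genotypes$protein_change), , drop = FALSE]
    rownames(samples) <- rownames(genotypes) <- NULL
    out <- list(samples = samples, genotypes = genotypes)
    class(out) <- "SimulatedCohort"
    out
  })
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat(sprintf("SimulatedCohort: %d samples (%s), %d mutation events\n",
              nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$tissue)),
                            table(x$samples$tissue)), collapse = ", "),
              nrow(x$genotypes)))
  invisible(x)
}

#' Simulate MALDI-TOF two-allele peak readouts
#'
#' For every sample replicate and panel assay, produces one intensity per
#' allele peak (wild type plus each mutant extension product), on an
#' arbitrary-unit scale with total true signal 1. The expected mutant share of
#' total intensity equals the sample's MAF for mutated targets; unmutated
#' mutant alleles carry only baseline noise around zero. Multiplicative
#' log-normal noise (`noiseSd`), salt-adduct artifact peaks (`artifactProb`,
#' placed within 20 Da of a true peak at sub-threshold intensity) and
#' quality-dependent whole-assay failures (`failProbByQuality`) complete the
#' instrument model. Reproducible from the configuration seed.
#'
#' @param cohort A `"SimulatedCohort"`.
#' @param panel A [GynPanel] with masses assigned; every genotype target must
#'   be in the panel.
#' @param cfg The `"SimulationConfig"` used for the cohort.
#' @return data.frame with one row per allele peak: `sample_id`, `replicate`,
#'   `assay_id`, `gene`, `protein_change`, `nucleotide_change` (NA on WT and
#'   adduct rows), `allele` (`"WT"`, a site identifier, or `"ADDUCT"`),
#'   `mass`, `intensity`, `failed`.
#' @export
simulateReadouts <- function(cohort, panel, cfg) {
  stopifnot(inherits(cohort, "SimulatedCohort"), methods::is(panel, "GynPanel"),
            inherits(cfg, "SimulationConfig"))
  if (length(panel@alleleMasses) == 0L) {
    stop("assign analyte masses before simulating readouts", call. = FALSE)
  }
  tg <- panelTargets(panel)
  gkey <- paste(cohort$genotypes$gene, cohort$genotypes$protein_change,
                cohort$genotypes$nucleotide_change)
  tkey <- paste(tg$gene, tg$protein_change, tg$nucleotide_change)
  if (!all(gkey %in% tkey)) {
    stop("cohort genotypes reference targets absent from the panel: ",
         gkey[!gkey %in% tkey][1L], call. = FALSE)
  }
  ## allele table: one row per (assay, allele)
  alleles <- data.table::rbindlist(list(
    data.table::data.table(assay_id = tg$assay_id, gene = tg$gene,
                           protein_change = tg$protein_change,
                           nucleotide_change = tg$nucleotide_change,
                           allele = siteId(tg$protein_change,
                                           tg$nucleotide_change)),
    data.table::data.table(assay_id = panelAssays(panel)$assay_id,
                           gene = NA_character_,
                           protein_change = NA_character_,
                           nucleotide_change = NA_character_,
                           allele = "WT")))
  massOf <- function(assay_id, allele) {
    vapply(seq_along(assay_id),
           function(i) unname(panel@alleleMasses[[assay_id[i]]][allele[i]]),
           numeric(1))
  }
  alleles[, mass := massOf(assay_id, allele)]
  data.table::setkey(alleles, assay_id, allele)

  samples <- data.table::as.data.table(cohort$samples)
  reps <- samples[rep(seq_len(.N), n_replicates)]
  reps[, replicate := seq_len(.N), by = sample_id]
  withSeed(cfg$seed + 1L, {
    ## cross join replicates x alleles
    nA <- nrow(alleles)
    nR <- nrow(reps)
    dt <- data.table::data.table(
      sample_id = rep(reps$sample_id, each = nA),
      replicate = rep(reps$replicate, each = nA),
      quality = rep(reps$quality, each = nA),
      alleles[rep(seq_len(nA), times = nR)])
    geno <- data.table::as.data.table(cohort$genotypes)
    dt <- merge(dt, geno, by = c("sample_id", "gene", "protein_change",
                                 "nucleotide_change"),
                all.x = TRUE, sort = FALSE)
    dt[, share := data.table::fifelse(is.na(maf), 0, maf)]
    dt[allele == "WT", share := NA_real_]
    ## wild-type share absorbs the remainder; rescale if co-mutations exceed 1
    dt[, mutsum := sum(share, na.rm = TRUE),
       by = .(sample_id, replicate, assay_id)]
    dt[mutsum > 1 & allele != "WT", share := share / mutsum]
    dt[allele == "WT", share := pmax(0, 1 - pmin(mutsum, 1))]
    dt[, mutsum := NULL]
    n <- nrow(dt)
    if (cfg$noiseSd > 0) {
      dt[, intensity := data.table::fifelse(
        share > 0, share * exp(stats::rnorm(n, 0, cfg$noiseSd)),
        abs(stats::rnorm(n, 0, 0.2 * cfg$noiseSd)))]
    } else {
      dt[, intensity := share]
    }
    ## quality-dependent whole-assay failures
    grp <- dt[, .(quality = quality[1L]),
              by = .(sample_id, replicate, assay_id)]
    grp[, failed := stats::runif(.N) <
          cfg$failProbByQuality[quality + 1L]]
    dt <- merge(dt, grp[, .(sample_id, replicate, assay_id, failed)],
                by = c("sample_id", "replicate", "assay_id"), sort = FALSE)
    dt[failed == TRUE, intensity := 0]
    ## salt-adduct artifacts near a true peak, capped below threshold share
    grp[, artifact := stats::runif(.N) < cfg$artifactProb]
    art <- grp[artifact == TRUE & failed == FALSE]
    if (nrow(art)) {
      pick <- vapply(art$assay_id, function(a) {
        m <- assayMasses(panel, a)
        unname(m[sample.int(length(m), 1L)])
      }, numeric(1))
      art <- data.table::data.table(
        sample_id = art$sample_id, replicate = art$replicate,
        assay_id = art$assay_id, gene = NA_character_,
        protein_change = NA_character_, nucleotide_change = NA_character_,
        allele = "ADDUCT",
        mass = pick + stats::runif(nrow(art), -20, 20),
        intensity = stats::runif(nrow(art), 0, 0.04),
        failed = FALSE)
    }
    out <- dt[, .(sample_id, replicate, assay_id, gene, protein_change,
                  nucleotide_change, allele, mass, intensity, failed)]
    if (nrow(art) && is.data.frame(art)) {
      out <- data.table::rbindlist(list(out, art), use.names = TRUE)
    }
    data.table::setorder(out, sample_id, replicate, assay_id, allele)
    data.table::setDF(out)
    out
  })
}

#' Simulate allele-specific qPCR calls
#'
#' The orthogonal validation platform: a target is called mutant only when
#' the sample truly carries it at a mutant allele fraction at or above the
#' platform's limit of detection (`lod`, default 20% -- coarser than the 5%
#' mass-spectrometry threshold); otherwise wild type. Failures occur at the
#' sample level with probability `failProb` (a failed sample fails all its
#' qPCR reactions), matching how failed validation reactions were tallied.
#'
#' @param cohort A `"SimulatedCohort"`.
#' @param targets data.frame of assayed variants (default the ten validated
#'   KRAS/PIK3CA variants, [validatedVariants()]).
#' @param lod Limit of detection on the MAF scale, in \[0, 1); the boundary
#'   is inclusive (`maf == lod` is detected) and `lod = 0` detects every true
#'   mutant.
#' @param failProb Per-sample failure probability.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return data.frame with columns `sample_id`, `gene`, `protein_change`,
#'   `nucleotide_change`, `status` (wild_type / mutant / failed).
#' @export
simulateQpcr <- function(cohort, targets = validatedVariants(), lod = 0.20,
                         failProb = 4 / 164, seed = NULL) {
  stopifnot(inherits(cohort, "SimulatedCohort"))
  if (!is.numeric(lod) || lod < 0 || lod >= 1) {
    stop("lod must be inside [0, 1)", call. = FALSE)
  }
  checkFraction(failProb, "failProb")
  targets <- as.data.frame(targets)
  targets$protein_change <- normProtein(targets$protein_change)
  targets$nucleotide_change <- normNt(targets$nucleotide_change)
  ids <- cohort$samples$sample_id
  withSeed(seed, {
    failedSample <- stats::runif(length(ids)) < failProb
    grid <- data.frame(
      sample_id = rep(ids, each = nrow(targets)),
      gene = rep(targets$gene, length(ids)),
      protein_change = rep(targets$protein_change, length(ids)),
      nucleotide_change = rep(targets$nucleotide_change, length(ids)),
      stringsAsFactors = FALSE)
    g <- cohort$genotypes
    j <- match(paste(grid$sample_id, grid$gene, grid$protein_change,
                     grid$nucleotide_change),
               paste(g$sample_id, g$gene, g$protein_change,
                     g$nucleotide_change))
    maf <- g$maf[j]
    grid$status <- ifelse(!is.na(maf) & maf >= lod, "mutant", "wild_type")
    grid$status[rep(failedSample, each = nrow(targets))] <- "failed"
    grid
  })
}
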