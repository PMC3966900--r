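#' Call a genotype from one assay readout
#'
#' Threshold caller on mutant allele peak share: the readout is `failed` when
#' every true-allele peak (wild type and mutants) lies below `noiseFloor`;
#' otherwise each mutant allele's share is its intensity divided by that
#' intensity plus the wild-type intensity, and the assay is called `mutant`
#' when any share reaches `threshold` (inclusive: a 5% mutant peak qualifies
#' under the default 5% threshold). Multi-allele assays report the allele
#' with the highest share. Adduct peaks are ignored.
#'
#' @param intensities Named non-negative numeric vector with a `"WT"` entry
#'   plus one entry per mutant allele.
#' @param threshold Mutant-share calling threshold, default 0.05.
#' @param noiseFloor Intensity below which a peak is indistinguishable from
#'   baseline, on the simulator's arbitrary-unit scale where the total true
#'   signal of a working assay is 1.
#' @return List with `status` (`"wild_type"`, `"mutant"` or `"failed"`),
#'   `maf_estimate` (share of the reported allele; `NA` when failed) and
#'   `allele` (triggering mutant allele, `NA` otherwise).
#' @examples
#' callGenotype(c(WT = 0.7, "p.E545K" = 0.3))
#' @export
callGenotype <- function(intensities, threshold = 0.05, noiseFloor = 0.01) {
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (!"WT" %in% names(intensities)) {
    stop("intensities must contain a WT peak", call. = FALSE)
  }
  checkFraction(threshold, "threshold")
  if (all(intensities < noiseFloor)) {
    return(list(status = "failed", maf_estimate = NA_real_,
                allele = NA_character_))
  }
  wt <- intensities[["WT"]]
  mut <- intensities[setdiff(names(intensities), "WT")]
  if (length(mut) == 0L) {
    return(list(status = "wild_type", maf_estimate = 0, allele = NA_character_))
  }
  share <- mut / (mut + wt)
  share[mut + wt == 0] <- 0
  top <- which.max(share)
  if (share[top] >= threshold) {
    list(status = "mutant", maf_estimate = unname(share[top]),
         allele = names(mut)[top])
  } else {
    list(status = "wild_type", maf_estimate = unname(share[top]),
         allele = NA_character_)
  }
}

#' Call genotypes for a whole readout table
#'
#' Element-wise [callGenotype()] over every (sample, replicate, assay) group
#' of a readout table, vectorised for large cohorts. Output is stably ordered
#' by sample, replicate and assay.
#'
#' @param readouts data.frame as produced by [simulateReadouts()].
#' @param threshold,noiseFloor As in [callGenotype()].
#' @return data.frame with columns `sample_id`, `replicate`, `assay_id`,
#'   `gene`, `protein_change`, `nucleotide_change` (triggering allele, NA
#'   unless mutant), `status`, `maf_estimate`.
#' @export
callCohort <- function(readouts, threshold = 0.05, noiseFloor = 0.01) {
  dt <- data.table::as.data.table(readouts)
  need <- c("sample_id", "replicate", "assay_id", "allele", "intensity")
  if (!all(need %in% names(dt))) {
    stop("readouts must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dt <- dt[allele != "ADDUCT"]
  if (anyNA(dt$intensity) || any(dt$intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(dt[, .(sample_id, replicate, assay_id, allele)])) {
    stop("duplicate (sample, replicate, assay, allele) readout rows",
         call. = FALSE)
  }
  wt <- dt[allele == "WT",
           .(sample_id, replicate, assay_id, wt_intensity = intensity)]
  mut <- dt[allele != "WT"]
  if (nrow(mut) == 0L) stop("readouts contain no mutant allele peaks",
                            call. = FALSE)
  mut <- merge(mut, wt, by = c("sample_id", "replicate", "assay_id"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(mut$wt_intensity)) {
    stop("readout group lacks a WT peak", call. = FALSE)
  }
  mut[, share := data.table::fifelse(intensity + wt_intensity > 0,
                                     intensity / (intensity + wt_intensity),
                                     0)]
  calls <- mut[order(-share),
               .(gene = gene[1L], protein_change = protein_change[1L],
                 nucleotide_change = nucleotide_change[1L],
                 maf_estimate = share[1L],
                 peak_max = max(intensity, wt_intensity[1L])),
               by = .(sample_id, replicate, assay_id)]
  calls[, status := data.table::fifelse(
    peak_max < noiseFloor, "failed",
    data.table::fifelse(maf_estimate >= threshold, "mutant", "wild_type"))]
  calls[status != "mutant", `:=`(gene = NA_character_,
                                 protein_change = NA_character_,
                                 nucleotide_change = NA_character_)]
  calls[status == "failed", maf_estimate := NA_real_]
  calls[, peak_max := NULL]
  data.table::setorder(calls, sample_id, replicate, assay_id)
  data.table::setcolorder(calls, c("sample_id", "replicate", "assay_id",
                                   "gene", "protein_change",
                                   "nucleotide_change", "status",
                                   "maf_estimate"))
  data.table::setDF(calls)
  calls
}

#' Replicate confirmation rate
#'
#' Reproducibility summary over a replicate arm: a mutation detected in the
#' first replicate of a sample is confirmed when every other replicate of
#' that sample calls the same target mutant. The rate is reported as an
#' integer percentage (half-up), the style of the published validation
#' ("95% (40/42) confirmed in duplicate").
#'
#' @param calls data.frame from [callCohort()] (with a `replicate` column).
#' @param samples data.frame with columns `sample_id`, `n_replicates`.
#' @param arm `"duplicate"` (2 replicates) or `"triplicate"` (3).
#' @return List with `detected`, `confirmed` and `rate` (integer percent;
#'   `NA` with a message attribute when nothing was detected, an undefined
#'   rate rather than 0%).
#' @export
confirmationRate <- function(calls, samples, arm = c("duplicate", "triplicate")) {
  arm <- match.arg(arm)
  mult <- if (arm == "duplicate") 2L else 3L
  ids <- samples$sample_id[samples$n_replicates == mult]
  dt <- data.table::as.data.table(calls)
  dt <- dt[sample_id %in% ids]
  first <- dt[replicate == 1L & status == "mutant"]
  detected <- nrow(first)
  if (detected == 0L) {
    out <- list(detected = 0L, confirmed = 0L, rate = NA_real_)
    attr(out, "message") <- "no mutations detected in first replicates; rate undefined"
    return(out)
  }
  others <- dt[replicate > 1L & status == "mutant",
               .(sample_id, assay_id, protein_change, nucleotide_change,
                 replicate)]
  confirmed <- vapply(seq_len(detected), function(i) {
    s <- first$sample_id[i]
    nrep <- mult - 1L
    hit <- others[sample_id == s & assay_id == first$assay_id[i] &
                    protein_change == first$protein_change[i] &
                    nucleotide_change == first$nucleotide_change[i]]
    length(unique(hit$replicate)) == nrep
  }, logical(1))
  list(detected = detected, confirmed = sum(confirmed),
       rate = roundHalfUp(100 * sum(confirmed) / detected))
}

#' Assemble a concordance result from category counts
#'
#' The concordance calculus of the published cross-platform validation:
#' reactions failed on either platform are excluded from the denominator and
#' concordance is (wild-type/wild-type matches + mutant/mutant matches) /
#' (total reactions - failed reactions).
#'
#' @param wtWt,mutMut,discordant,failed Category counts; `discordant`
#'   defaults to the remainder of `totalReactions`.
#' @param totalReactions Total number of compared reactions.
#' @return List of class `"ConcordanceResult"` with the counts and
#'   `concordance`.
#' @examples
#' concordanceResult(wtWt = 1546, mutMut = 45, failed = 40,
#'                   totalReactions = 1640)$concordance  # 0.994375
#' @export
concordanceResult <- function(wtWt, mutMut, discordant = NULL, failed,
                              totalReactions) {
  if (is.null(discordant)) {
    discordant <- totalReactions - wtWt - mutMut - failed
  }
  counts <- c(wtWt, mutMut, discordant, failed, totalReactions)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (wtWt + mutMut + discordant + failed != totalReactions) {
    stop("categories must partition the total reaction count", call. = FALSE)
  }
  if (totalReactions - failed < 1L) {
    stop("no comparable reactions: concordance undefined", call. = FALSE)
  }
  out <- list(wt_wt = as.integer(wtWt), mut_mut = as.integer(mutMut),
              discordant = as.integer(discordant), failed = as.integer(failed),
              total_reactions = as.integer(totalReactions),
              concordance = (wtWt + mutMut) / (totalReactions - failed))
  class(out) <- "ConcordanceResult"
  out
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf(
    "Concordance: (%d + %d) / (%d - %d) = %.3f  [%d discordant]\n",
    x$wt_wt, x$mut_mut, x$total_reactions, x$failed, x$concordance,
    x$discordant))
  invisible(x)
}

#' Cross-platform genotype concordance
#'
#' Compares MALDI-TOF calls with allele-specific qPCR calls over a common
#' sample-by-target grid (default the ten qPCR-validated variants). For each
#' cell the MALDI status of a target is mutant when the assay containing it
#' called that allele mutant, failed when the assay failed, wild type
#' otherwise. Reactions failed on either platform count as failed and leave
#' the concordance denominator.
#'
#' @param maldi data.frame from [callCohort()]; first replicates are used.
#' @param qpcr data.frame from [simulateQpcr()].
#' @param targets data.frame of compared variants ([validatedVariants()]).
#' @param panel Panel mapping targets to assays, default [gynCartaPanel()].
#' @return A `"ConcordanceResult"`.
#' @export
crossPlatformConcordance <- function(maldi, qpcr, targets = validatedVariants(),
                                     panel = gynCartaPanel()) {
  targets <- as.data.frame(targets)
  targets$protein_change <- normProtein(targets$protein_change)
  targets$nucleotide_change <- normNt(targets$nucleotide_change)
  tg <- panelTargets(panel)
  j <- match(paste(targets$gene, targets$protein_change,
                   targets$nucleotide_change),
             paste(tg$gene, tg$protein_change, tg$nucleotide_change))
  if (anyNA(j)) {
    stop("targets absent from the panel: ",
         targets$protein_change[is.na(j)][1L], call. = FALSE)
  }
  targets$assay_id <- tg$assay_id[j]
  md <- data.table::as.data.table(maldi)
  if ("replicate" %in% names(md)) md <- md[replicate == 1L]
  qp <- data.table::as.data.table(qpcr)
  samples <- unique(qp$sample_id)
  if (!all(samples %in% md$sample_id)) {
    stop("MALDI calls do not cover every qPCR sample", call. = FALSE)
  }
  grid <- data.table::CJ(sample_id = samples, idx = seq_len(nrow(targets)))
  grid <- cbind(grid[, .(sample_id)], targets[grid$idx, , drop = FALSE])
  ## qPCR status
  k <- match(paste(grid$sample_id, grid$gene, grid$protein_change,
                   grid$nucleotide_change),
             paste(qp$sample_id, qp$gene, qp$protein_change,
                   qp$nucleotide_change))
  if (anyNA(k)) stop("qPCR calls do not cover the comparison grid",
                     call. = FALSE)
  grid$qpcr <- qp$status[k]
  ## MALDI target-level status from the assay-level call
  k <- match(paste(grid$sample_id, grid$assay_id),
             paste(md$sample_id, md$assay_id))
  if (anyNA(k)) stop("MALDI calls do not cover the comparison grid",
                     call. = FALSE)
  callStatus <- md$status[k]
  callSite <- siteId(md$protein_change[k], md$nucleotide_change[k])
  targetSite <- siteId(grid$protein_change, grid$nucleotide_change)
  grid$maldi <- ifelse(callStatus == "failed", "failed",
                       ifelse(callStatus == "mutant" & callSite == targetSite,
                              "mutant", "wild_type"))
  failed <- grid$maldi == "failed" | grid$qpcr == "failed"
  wtWt <- sum(!failed & grid$maldi == "wild_type" & grid$qpcr == "wild_type")
  mutMut <- sum(!failed & grid$maldi == "mutant" & grid$qpcr == "mutant")
  concordanceResult(wtWt = wtWt, mutMut = mutMut, failed = sum(failed),
                    totalReactions = nrow(grid))
}

#' Tissue-stratified mutation spectrum report
#'
#' Summarises mutant calls per tissue: mutated-sample counts and integer
#' percentages per gene (a sample counts once per gene no matter how many of
#' its mutations hit), per-target mutation counts, samples carrying two or
#' more mutations of the same gene, and the per-sample mutation-count
#' histogram (1 / 2 / 3 / 4+ mutations).
#'
#' @param calls data.frame from [callCohort()]; first replicates are used.
#' @param samples data.frame with columns `sample_id`, `tissue`.
#' @return List of class `"SpectrumReport"`: `gene_counts`, `target_counts`,
#'   `multi_gene`, `histogram`, `totals`.
#' @export
spectrumReport <- function(calls, samples) {
  dt <- data.table::as.data.table(calls)
  if ("replicate" %in% names(dt)) dt <- dt[replicate == 1L]
  samples <- as.data.frame(samples)
  if (!all(dt$sample_id %in% samples$sample_id)) {
    stop("calls reference unknown samples", call. = FALSE)
  }
  cohortSize <- table(samples$tissue)
  mut <- dt[status == "mutant"]
  mut[, tissue := samples$tissue[match(sample_id, samples$sample_id)]]
  geneCounts <- mut[, .(n_samples = data.table::uniqueN(sample_id)),
                    by = .(tissue, gene)]
  geneCounts[, pct := roundHalfUp(100 * n_samples /
                                    as.integer(cohortSize[tissue]))]
  targetCounts <- mut[, .(n = .N),
                      by = .(tissue, gene, protein_change, nucleotide_change)]
  multi <- mut[, .(n_mut = .N), by = .(tissue, gene, sample_id)][n_mut >= 2L]
  multiGene <- multi[, .(n_samples = .N), by = .(tissue, gene)]
  perSample <- mut[, .(n_mut = .N), by = sample_id]
  histo <- c(`1` = sum(perSample$n_mut == 1L),
             `2` = sum(perSample$n_mut == 2L),
             `3` = sum(perSample$n_mut == 3L),
             `4+` = sum(perSample$n_mut >= 4L))
  data.table::setorder(geneCounts, tissue, -n_samples, gene)
  data.table::setorder(targetCounts, tissue, gene, -n, protein_change)
  out <- list(gene_counts = data.table::setDF(geneCounts),
              target_counts = data.table::setDF(targetCounts),
              multi_gene = data.table::setDF(multiGene),
              histogram = histo,
              totals = list(n_samples = nrow(samples),
                            n_samples_mutated = nrow(perSample),
                            n_mutations = nrow(mut)))
  class(out) <- "SpectrumReport"
  out
}

#' @export
print.SpectrumReport <- function(x, ...) {
  cat(sprintf("SpectrumReport: %d mutations in %d of %d samples\n",
              x$totals$n_mutations, x$totals$n_samples_mutated,
              x$totals$n_samples))
  cat("Per-sample mutation histogram:\n")
  print(x$histogram)
  if (nrow(x$gene_counts)) {
    cat("Top gene counts:\n")
    print(utils::head(x$gene_counts, 8L), row.names = FALSE)
  }
  invisible(x)
}

#' PIK3CA exon map for the spectrum contrast
#'
#' Standard PIK3CA hotspot architecture: the helical-domain codons 542, 545
#' and 546 lie on exon 9, the kinase-domain codons 1021, 1025, 1043 and 1047
#' on exon 20; codon 88 belongs to neither and is excluded from the exon
#' contrast.
#'
#' @return data.frame with columns `codon`, `exon`.
#' @export
pik3caExonMap <- function() {
  data.frame(codon = c(542L, 545L, 546L, 1021L, 1025L, 1043L, 1047L, 88L),
             exon = c("exon9", "exon9", "exon9", "exon20", "exon20", "exon20",
                      "exon20", "other"), stringsAsFactors = FALSE)
}

#' Exon-distribution contrast between two tissues
#'
#' Builds the 2x2 contingency table of exon 9 versus exon 20 mutant PIK3CA
#' calls in two tissues (targets mapping to neither exon are excluded) and
#' tests it with the package's own two-sided Fisher's exact test. In the
#' published cohort this contrast separates cervical carcinomas (almost
#' exclusively exon 9) from endometrial carcinomas (an even split).
#'
#' @param calls data.frame from [callCohort()].
#' @param samples data.frame with columns `sample_id`, `tissue`.
#' @param tissueA,tissueB The contrasted tissue labels.
#' @param exonMap data.frame with columns `codon`, `exon`
#'   ([pik3caExonMap()]).
#' @param gene Gene whose calls are contrasted, default `"PIK3CA"`.
#' @return List with `table` (2x2 matrix, rows = tissues, cols = exons) and
#'   `p` (two-sided Fisher p-value).
#' @export
exonDistributionContrast <- function(calls, samples, tissueA, tissueB,
                                     exonMap = pik3caExonMap(),
                                     gene = "PIK3CA") {
  dt <- data.table::as.data.table(calls)
  if ("replicate" %in% names(dt)) dt <- dt[replicate == 1L]
  samples <- as.data.frame(samples)
  gn <- gene
  mut <- dt[status == "mutant" & gene == gn]
  mut[, tissue := samples$tissue[match(sample_id, samples$sample_id)]]
  mut <- mut[tissue %in% c(tissueA, tissueB)]
  mut[, codon := codonOf(protein_change)]
  mut[, exon := exonMap$exon[match(codon, exonMap$codon)]]
  mut <- mut[exon %in% c("exon9", "exon20")]
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c(tissueA, tissueB), c("exon9", "exon20")))
  if (nrow(mut)) {
    cnt <- mut[, .N, by = .(tissue, exon)]
    for (i in seq_len(nrow(cnt))) {
      tab[cnt$tissue[i], cnt$exon[i]] <- cnt$N[i]
    }
  }
  if (sum(tab) == 0L) {
    stop("undefined test: no exon 9/20 mutant calls in the contrasted tissues",
         call. = FALSE)
  }
  list(table = tab, p = fisherExact2x2(tab)$p.value)
}
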