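test_that("the caller's mutant boundary sits exactly at a 5% peak share", {
  ## noiseless sweep of the mutant share in 1% steps
  shares <- seq(0, 1, by = 0.01)
  status <- vapply(shares, function(s) {
    callGenotype(c(WT = 1 - s, "p.G12D" = s))$status
  }, character(1))
  expect_equal(min(shares[status == "mutant"]), 0.05)
  expect_true(all(status[shares >= 0.05] == "mutant"))
  expect_true(all(status[shares < 0.05 & (1 - shares) >= 0.01] == "wild_type"))

  expect_equal(callGenotype(c(WT = 1, "p.G12D" = 0))$status, "wild_type")
  expect_equal(callGenotype(c(WT = 0, "p.G12D" = 0))$status, "failed")
  expect_error(callGenotype(c(WT = -1, "p.G12D" = 0.5)), "non-negative")
  ## multi-allele assays report the triggering (largest-share) allele
  call <- callGenotype(c(WT = 0.5, "p.Q61H (C>A)" = 0.1, "p.Q61K" = 0.4))
  expect_equal(call$allele, "p.Q61K")
  expect_equal(call$maf_estimate, 0.4 / 0.9)
})

test_that("cohort calling equals element-wise single-readout calling", {
  ro <- readoutAtShare(0.30)
  calls <- callCohort(ro)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$status, "mutant")
  expect_equal(calls$maf_estimate, 0.30)

  ## seeded batch: callCohort against mapped callGenotype
  p <- packMultiplexes(assignAnalyteMasses(gynCartaPanel(), seed = 1))
  cfg <- defaultSimulationConfig(
    cohorts = data.frame(tissue = "endometrium", size = 60),
    noiseSd = 0.08, seed = 37)
  ro <- simulateReadouts(simulateCohort(cfg), p, cfg)
  calls <- callCohort(ro)
  expect_equal(nrow(calls), length(unique(paste(ro$sample_id, ro$replicate,
                                                ro$assay_id))))
  key <- paste(ro$sample_id, ro$replicate, ro$assay_id)
  withr::local_seed(1)
  idx <- sample(unique(key), 300)
  for (k in idx) {
    rows <- ro[key == k & ro$allele != "ADDUCT", ]
    single <- callGenotype(setNames(rows$intensity, rows$allele))
    got <- calls[paste(calls$sample_id, calls$replicate, calls$assay_id) == k, ]
    expect_equal(got$status, single$status)
    if (single$status != "failed") {
      expect_equal(got$maf_estimate, single$maf_estimate)
    }
  }

  ## duplicate readout rows are rejected
  i <- which(ro$allele == "WT")[1]
  expect_error(callCohort(rbind(ro[seq_len(i), ], ro[i, ])), "duplicate")
})

test_that("replicate confirmation counts re-detected first-replicate calls", {
  mkCall <- function(sample, rep, status, target = "p.G12D") {
    data.frame(sample_id = sample, replicate = rep, assay_id = "A1",
               gene = ifelse(status == "mutant", "KRAS", NA),
               protein_change = ifelse(status == "mutant", target, NA),
               nucleotide_change = ifelse(status == "mutant", "", NA),
               status = status,
               maf_estimate = ifelse(status == "mutant", 0.3, 0.0))
  }
  ## 42 detected, 40 confirmed: the published duplicate-arm numbers
  calls <- do.call(rbind, c(
    lapply(1:42, function(i) mkCall(sprintf("D%02d", i), 1L, "mutant")),
    lapply(1:40, function(i) mkCall(sprintf("D%02d", i), 2L, "mutant")),
    lapply(41:42, function(i) mkCall(sprintf("D%02d", i), 2L, "wild_type"))))
  samples <- data.frame(sample_id = sprintf("D%02d", 1:42), n_replicates = 2L)
  res <- confirmationRate(calls, samples, "duplicate")
  expect_equal(res$detected, 42L)
  expect_equal(res$confirmed, 40L)
  expect_equal(res$rate, 95)

  ## all confirmed gives 100%; nothing detected gives an undefined rate
  res <- confirmationRate(calls[calls$sample_id %in% sprintf("D%02d", 1:40), ],
                          samples, "duplicate")
  expect_equal(res$rate, 100)
  none <- confirmationRate(mkCall("D01", 1L, "wild_type"), samples, "duplicate")
  expect_true(is.na(none$rate))
  expect_match(attr(none, "message"), "undefined")

  ## a triplicate detection needs both other replicates to agree
  tri <- rbind(mkCall("T1", 1L, "mutant"), mkCall("T1", 2L, "mutant"),
               mkCall("T1", 3L, "wild_type"))
  samples <- data.frame(sample_id = "T1", n_replicates = 3L)
  expect_equal(confirmationRate(tri, samples, "triplicate")$confirmed, 0L)
})

test_that("concordance follows the published exclusion formula", {
  ## the published worked example
  res <- concordanceResult(wtWt = 1546, mutMut = 45, failed = 40,
                           totalReactions = 1640)
  expect_equal(round(res$concordance, 3), 0.994)
  expect_equal(res$discordant, 9L)
  ## partition identity
  expect_equal(res$wt_wt + res$mut_mut + res$discordant + res$failed,
               res$total_reactions)
  expect_error(concordanceResult(10, 10, 10, failed = 0, totalReactions = 20),
               "partition")
  expect_error(concordanceResult(0, 0, 0, failed = 5, totalReactions = 5),
               "undefined")
})

test_that("cross-platform concordance enumerates pair categories", {
  p <- packMultiplexes(assignAnalyteMasses(gynCartaPanel(), seed = 1))
  cfg <- defaultSimulationConfig(
    cohorts = data.frame(tissue = "endometrium", size = 80),
    noiseSd = 0, artifactProb = 0, failProbByQuality = c(0, 0, 0, 0),
    replicateFractions = c(duplicate = 0, triplicate = 0), seed = 41)
  co <- simulateCohort(cfg)
  ro <- simulateReadouts(co, p, cfg)
  calls <- callCohort(ro)
  qp <- simulateQpcr(co, lod = 0.20, failProb = 0.05, seed = 42)
  res <- crossPlatformConcordance(calls, qp, panel = p)
  expect_equal(res$total_reactions, 80L * 10L)
  expect_equal(res$wt_wt + res$mut_mut + res$discordant + res$failed,
               res$total_reactions)

  ## direct enumeration oracle over the sample x target grid
  vv <- validatedVariants()
  cats <- c(wt_wt = 0L, mut_mut = 0L, discordant = 0L, failed = 0L)
  for (s in unique(qp$sample_id)) {
    for (i in seq_len(nrow(vv))) {
      qstat <- qp$status[qp$sample_id == s &
                           qp$protein_change == vv$protein_change[i]]
      truth <- co$genotypes[co$genotypes$sample_id == s &
                              co$genotypes$protein_change == vv$protein_change[i] &
                              co$genotypes$gene == vv$gene[i], ]
      mstat <- if (nrow(truth) && truth$maf >= 0.05) "mutant" else "wild_type"
      if (qstat == "failed") cats["failed"] <- cats["failed"] + 1L
      else if (qstat == mstat && qstat == "wild_type") cats["wt_wt"] <- cats["wt_wt"] + 1L
      else if (qstat == mstat) cats["mut_mut"] <- cats["mut_mut"] + 1L
      else cats["discordant"] <- cats["discordant"] + 1L
    }
  }
  expect_equal(res$wt_wt, unname(cats["wt_wt"]))
  expect_equal(res$mut_mut, unname(cats["mut_mut"]))
  expect_equal(res$failed, unname(cats["failed"]))
  expect_equal(res$discordant, unname(cats["discordant"]))

  ## identical call tables with no failures are fully concordant
  qpPerfect <- simulateQpcr(co, lod = 0.05, failProb = 0, seed = 1)
  resP <- crossPlatformConcordance(calls, qpPerfect, panel = p)
  expect_equal(resP$concordance, 1.0)
  expect_equal(resP$failed, 0L)
})

test_that("spectrum report groups mutant calls per tissue, gene and sample", {
  samples <- data.frame(sample_id = c("S1", "S2"), tissue = "endometrium")
  noMut <- data.frame(sample_id = "S1", replicate = 1L, assay_id = "A1",
                      gene = NA, protein_change = NA, nucleotide_change = NA,
                      status = "wild_type", maf_estimate = 0)
  sp <- spectrumReport(noMut, samples)
  expect_equal(nrow(sp$gene_counts), 0L)
  expect_true(all(sp$histogram == 0))

  ## one sample with two PTEN mutations: sample count 1, mutation count 2
  two <- data.frame(sample_id = "S1", replicate = 1L,
                    assay_id = c("PTEN_130_5", "PTEN_233_11"),
                    gene = "PTEN", protein_change = c("p.R130G", "p.R233*"),
                    nucleotide_change = "", status = "mutant",
                    maf_estimate = 0.3)
  sp <- spectrumReport(two, samples)
  expect_equal(sp$gene_counts$n_samples, 1L)
  expect_equal(sum(sp$target_counts$n), 2L)
  expect_equal(sp$multi_gene$n_samples, 1L)
  expect_equal(unname(sp$histogram["2"]), 1L)
  expect_equal(sp$totals$n_mutations, 2L)
  expect_equal(sp$gene_counts$pct, 50)  # 1 of 2 endometrial samples

  expect_error(spectrumReport(two, samples[samples$sample_id == "S2", ]),
               "unknown samples")
})

test_that("exon contrast builds the 2x2 table and tests it", {
  samples <- data.frame(sample_id = sprintf("S%03d", 1:100),
                        tissue = rep(c("cervix", "endometrium"), each = 50))
  mkMut <- function(s, pc) data.frame(
    sample_id = s, replicate = 1L, assay_id = "x", gene = "PIK3CA",
    protein_change = pc, nucleotide_change = "", status = "mutant",
    maf_estimate = 0.3)
  ## identical exon distributions: no association
  calls <- rbind(mkMut("S001", "p.E545K"), mkMut("S002", "p.H1047R"),
                 mkMut("S051", "p.E545K"), mkMut("S052", "p.H1047R"))
  res <- exonDistributionContrast(calls, samples, "cervix", "endometrium")
  expect_equal(res$p, 1.0)
  expect_equal(sum(res$table), 4L)

  ## codon 88 maps to neither exon and is excluded
  calls <- rbind(calls, mkMut("S003", "p.R88Q"))
  res <- exonDistributionContrast(calls, samples, "cervix", "endometrium")
  expect_equal(sum(res$table), 4L)

  ## empty contrast is an undefined test
  wt <- data.frame(sample_id = "S001", replicate = 1L, assay_id = "x",
                   gene = NA, protein_change = NA, nucleotide_change = NA,
                   status = "wild_type", maf_estimate = 0)
  expect_error(exonDistributionContrast(wt, samples, "cervix", "endometrium"),
               "undefined")
})

test_that("noiseless failure-free pipelines recover ground truth end to end", {
  p <- packMultiplexes(assignAnalyteMasses(gynCartaPanel(), seed = 1))
  cfg <- defaultSimulationConfig(
    cohorts = data.frame(tissue = c("cervix", "endometrium"),
                         size = c(120, 120)),
    noiseSd = 0, artifactProb = 0, failProbByQuality = c(0, 0, 0, 0),
    seed = 53)
  co <- simulateCohort(cfg)
  ro <- simulateReadouts(co, p, cfg)
  calls <- callCohort(ro)

  ## called mutations equal the simulated ground truth exactly
  mut <- calls[calls$status == "mutant" & calls$replicate == 1L, ]
  expect_setequal(paste(mut$sample_id, mut$gene, mut$protein_change,
                        mut$nucleotide_change),
                  paste(co$genotypes$sample_id, co$genotypes$gene,
                        co$genotypes$protein_change,
                        co$genotypes$nucleotide_change))
  expect_equal(mut$maf_estimate[order(mut$sample_id, mut$gene,
                                      mut$protein_change)],
               co$genotypes$maf[order(co$genotypes$sample_id,
                                      co$genotypes$gene,
                                      co$genotypes$protein_change)],
               tolerance = 1e-12)

  ## replicate confirmation is perfect without noise or failures
  for (arm in c("duplicate", "triplicate")) {
    res <- confirmationRate(calls, co$samples, arm)
    if (res$detected > 0) expect_equal(res$rate, 100)
  }

  ## MALDI mutant calls strictly contain qPCR mutant calls at low MAF
  cfgLow <- defaultSimulationConfig(
    cohorts = data.frame(tissue = "endometrium", size = 150),
    mafRange = c(0.05, 0.199), noiseSd = 0, artifactProb = 0,
    failProbByQuality = c(0, 0, 0, 0),
    replicateFractions = c(duplicate = 0, triplicate = 0), seed = 59)
  coLow <- simulateCohort(cfgLow)
  callsLow <- callCohort(simulateReadouts(coLow, p, cfgLow))
  qpLow <- simulateQpcr(coLow, lod = 0.20, failProb = 0, seed = 60)
  expect_equal(sum(qpLow$status == "mutant"), 0L)
  vv <- validatedVariants()
  maldiMut <- callsLow[callsLow$status == "mutant" &
                         paste(callsLow$gene, callsLow$protein_change) %in%
                           paste(vv$gene, vv$protein_change), ]
  expect_gt(nrow(maldiMut), 0L)
})
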