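test_that("zero probabilities simulate a mutation-free cohort", {
  cfg <- simulationConfig(
    cohorts = data.frame(tissue = "cervix", size = 50),
    mutationProbs = data.frame(tissue = "cervix", gene = "KRAS",
                               protein_change = "p.G12D",
                               nucleotide_change = "", prob = 0),
    seed = 3)
  co <- simulateCohort(cfg)
  expect_equal(nrow(co$genotypes), 0L)
  expect_equal(nrow(co$samples), 50L)
})

test_that("simulation is bitwise reproducible from the seed", {
  cfg <- defaultSimulationConfig(seed = 11, noiseSd = 0.05)
  co1 <- simulateCohort(cfg)
  co2 <- simulateCohort(cfg)
  expect_identical(co1, co2)
  p <- packMultiplexes(assignAnalyteMasses(gynCartaPanel(), seed = 1))
  small <- defaultSimulationConfig(
    cohorts = data.frame(tissue = "cervix", size = 40), seed = 11)
  expect_identical(simulateReadouts(simulateCohort(small), p, small),
                   simulateReadouts(simulateCohort(small), p, small))
})

test_that("simulated per-gene frequency matches the configured probability", {
  ## PTEN in endometrium at its published frequency (89/227 = 0.39)
  cfg <- simulationConfig(
    cohorts = data.frame(tissue = "endometrium", size = 10000),
    mutationProbs = data.frame(tissue = "endometrium", gene = "PTEN",
                               protein_change = "", nucleotide_change = "",
                               prob = 0.39),
    targetWeights = data.frame(tissue = "endometrium", gene = "PTEN",
                               protein_change = c("p.R130G", "p.R233*"),
                               nucleotide_change = "", weight = c(35, 7)),
    seed = 19)
  co <- simulateCohort(cfg)
  frac <- length(unique(co$genotypes$sample_id)) / 10000
  se <- sqrt(0.39 * 0.61 / 10000)
  expect_lt(abs(frac - 0.39), 3 * se)
  ## target split follows the configured weights (binomial check)
  pR130G <- mean(co$genotypes$protein_change == "p.R130G")
  expect_lt(abs(pR130G - 35 / 42), 3 * sqrt((35 / 42) * (7 / 42) /
                                              nrow(co$genotypes)))
  ## MAFs live on the configured support
  expect_true(all(co$genotypes$maf >= 0.05 & co$genotypes$maf <= 0.6))
})

test_that("readouts are exact in the noiseless limit", {
  p <- tinyPanel()
  cfg <- simulationConfig(
    cohorts = data.frame(tissue = "cervix", size = 30),
    mutationProbs = data.frame(tissue = "cervix", gene = "KRAS",
                               protein_change = "p.G12D",
                               nucleotide_change = "", prob = 0.5),
    mafRange = c(0.30, 0.30), noiseSd = 0, artifactProb = 0,
    failProbByQuality = c(0, 0, 0, 0),
    replicateFractions = c(duplicate = 0, triplicate = 0), seed = 23)
  co <- simulateCohort(cfg)
  ro <- simulateReadouts(co, p, cfg)
  expect_false(any(ro$failed))
  mutated <- unique(co$genotypes$sample_id)
  mutRows <- ro[ro$allele == "p.G12D" & ro$assay_id == "KRAS_12_1", ]
  share <- mutRows$intensity / (mutRows$intensity +
                                  ro$intensity[ro$allele == "WT" &
                                                 ro$assay_id == "KRAS_12_1"])
  expect_equal(share[mutRows$sample_id %in% mutated],
               rep(0.30, length(mutated)))
  expect_true(all(share[!mutRows$sample_id %in% mutated] == 0))
  ## the unmutated assay carries pure wild-type signal
  expect_true(all(ro$intensity[ro$assay_id == "PIK3CA_545_1" &
                                 ro$allele != "WT"] == 0))
})

test_that("assay failure is more likely at low DNA quality", {
  p <- tinyPanel()
  base <- list(
    cohorts = data.frame(tissue = "cervix", size = 1500),
    mutationProbs = data.frame(tissue = "cervix", gene = "KRAS",
                               protein_change = "p.G12D",
                               nucleotide_change = "", prob = 0.1),
    noiseSd = 0, artifactProb = 0,
    failProbByQuality = c(0.15, 0.05, 0.02, 0.01),
    replicateFractions = c(duplicate = 0, triplicate = 0), seed = 31)
  lowQ <- do.call(simulationConfig, c(base, list(qualityProbs = c(1, 0, 0, 0))))
  highQ <- do.call(simulationConfig, c(base, list(qualityProbs = c(0, 0, 0, 1))))
  failRate <- function(cfg) {
    ro <- simulateReadouts(simulateCohort(cfg), p, cfg)
    mean(tapply(ro$failed, paste(ro$sample_id, ro$assay_id), any))
  }
  expect_gt(failRate(lowQ), failRate(highQ))

  noFail <- do.call(simulationConfig,
                    c(base[names(base) != "failProbByQuality"], list(failProbByQuality = c(0, 0, 0, 0))))
  ro <- simulateReadouts(simulateCohort(noFail), p, noFail)
  expect_equal(sum(ro$failed), 0L)

  ## failure probabilities must be non-increasing in quality
  expect_error(do.call(simulationConfig,
                       c(base[names(base) != "failProbByQuality"], list(failProbByQuality = c(0, 0.1, 0, 0)))),
               "non-increasing")
})

test_that("qPCR calls apply the coarser limit of detection", {
  co <- list(samples = data.frame(sample_id = c("S1", "S2", "S3"),
                                  tissue = "cervix", quality = 3L,
                                  n_replicates = 1L),
             genotypes = data.frame(
               sample_id = c("S1", "S2"), gene = "KRAS",
               protein_change = "p.G12D", nucleotide_change = "",
               maf = c(0.10, 0.20)))
  class(co) <- "SimulatedCohort"
  qp <- simulateQpcr(co, lod = 0.20, failProb = 0, seed = 1)
  get <- function(s) qp$status[qp$sample_id == s &
                                 qp$protein_change == "p.G12D"]
  expect_equal(get("S1"), "wild_type")  # maf below the qPCR detection limit
  expect_equal(get("S2"), "mutant")     # boundary maf is detected
  expect_equal(get("S3"), "wild_type")
  ## lod 0 detects every true mutant
  qp0 <- simulateQpcr(co, lod = 0, failProb = 0, seed = 1)
  expect_equal(sum(qp0$status == "mutant"), 2L)
  expect_error(simulateQpcr(co, lod = 1.2), "lod")
  ## sample-level failures fail all reactions of the sample
  qpf <- simulateQpcr(co, failProb = 1, seed = 1)
  expect_true(all(qpf$status == "failed"))
})

test_that("configuration validation rejects out-of-range probabilities", {
  expect_error(simulationConfig(
    cohorts = data.frame(tissue = "cervix", size = 10),
    mutationProbs = data.frame(tissue = "cervix", gene = "KRAS",
                               protein_change = "p.G12D",
                               nucleotide_change = "", prob = 1.5)),
    "probabilities")
  expect_error(simulationConfig(
    cohorts = data.frame(tissue = "cervix", size = 0),
    mutationProbs = data.frame(tissue = "cervix", gene = "KRAS",
                               protein_change = "p.G12D",
                               nucleotide_change = "", prob = 0.5)),
    "cohort sizes")
  ## gene-level rows need target weights
  expect_error(simulationConfig(
    cohorts = data.frame(tissue = "cervix", size = 10),
    mutationProbs = data.frame(tissue = "cervix", gene = "KRAS",
                               protein_change = "", nucleotide_change = "",
                               prob = 0.5)),
    "targetWeights")
})

test_that("readouts refuse targets missing from the panel", {
  co <- list(samples = data.frame(sample_id = "S1", tissue = "cervix",
                                  quality = 3L, n_replicates = 1L),
             genotypes = data.frame(sample_id = "S1", gene = "TP53",
                                    protein_change = "p.R175H",
                                    nucleotide_change = "", maf = 0.3))
  class(co) <- "SimulatedCohort"
  cfg <- simulationConfig(
    cohorts = data.frame(tissue = "cervix", size = 1),
    mutationProbs = data.frame(tissue = "cervix", gene = "TP53",
                               protein_change = "p.R175H",
                               nucleotide_change = "", prob = 1))
  expect_error(simulateReadouts(co, tinyPanel(), cfg), "absent from the panel")
})
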