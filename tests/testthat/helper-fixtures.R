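# Fixtures built in code: random catalogues, tiny panels, and hand oracles.

## Random COSMIC-like catalogue: nGenes genes, each with up to maxSites sites
## spread over one or more tissues.
makeRandomCatalogue <- function(seed, nGenes = 20, maxSites = 40,
                                tissues = c("cervix", "endometrium", "ovary")) {
  withr::local_seed(seed)
  rows <- list()
  for (g in seq_len(nGenes)) {
    gene <- sprintf("GENE%03d", g)
    for (ts in sample(tissues, sample(1:length(tissues), 1))) {
      nSites <- sample.int(maxSites, 1)
      tested <- sample(200:5000, 1)
      ## skewed site counts so some genes are hotspot-like
      occ <- as.integer(rgeom(nSites, prob = runif(1, 0.05, 0.8)))
      occ <- pmin(occ, tested)
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene,
        protein_change = sprintf("p.X%dY", seq_len(nSites)),
        nucleotide_change = "",
        tissue = ts, occurrences = occ, tested = tested,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df[df$occurrences <= df$tested, , drop = FALSE]
  MutationCatalogue(df)
}

## Brute-force hotspot oracle: per gene, per tissue, sort site counts
## descending, sum the top (maxSites - 1), compare the share to minFraction.
oracleHotspots <- function(cat, tissues, minFraction = 0.30, maxSites = 10) {
  df <- catalogueRecords(cat)
  df <- df[df$tissue %in% tissues, , drop = FALSE]
  hits <- list()
  for (g in unique(df$gene)) {
    best <- -Inf; bestTissue <- NA_character_
    for (ts in sort(unique(df$tissue[df$gene == g]))) {
      sub <- df[df$gene == g & df$tissue == ts, , drop = FALSE]
      counts <- c()
      for (i in seq_len(nrow(sub))) {
        key <- paste0(sub$protein_change[i],
                      ifelse(sub$nucleotide_change[i] == "", "",
                             paste0(" (", sub$nucleotide_change[i], ")")))
        counts[key] <- sum(counts[key], sub$occurrences[i], na.rm = TRUE)
      }
      tot <- sum(counts)
      if (tot == 0) next
      share <- sum(sort(counts, decreasing = TRUE)[seq_len(min(maxSites - 1,
                                                               length(counts)))]) / tot
      if (share > best) { best <- share; bestTissue <- ts }
    }
    if (is.finite(best) && best >= minFraction) {
      hits[[g]] <- data.frame(gene = g, share = best, tissue = bestTissue,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(gene = character(), share = numeric(),
                      tissue = character()))
  }
  out <- out[order(-out$share, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Minimal two-assay panel with hand-set masses, for caller/packing units.
tinyPanel <- function(wtMass = c(5500, 7000), mutOffset = -300) {
  targets <- data.frame(
    gene = c("KRAS", "PIK3CA"),
    protein_change = c("p.G12D", "p.E545K"),
    nucleotide_change = "",
    assay_id = c("KRAS_12_1", "PIK3CA_545_1"),
    added_in_version = "1.0", stringsAsFactors = FALSE)
  assays <- data.frame(assay_id = targets$assay_id, well_id = NA_character_,
                       primer_mass = wtMass + mutOffset - 250,
                       stringsAsFactors = FALSE)
  am <- list(
    KRAS_12_1 = c("p.G12D" = wtMass[1] + mutOffset, WT = wtMass[1]),
    PIK3CA_545_1 = c("p.E545K" = wtMass[2] + mutOffset, WT = wtMass[2]))
  GynPanel("tiny", "1.0", targets, assays, am)
}

## Random assay sets for packing property tests.
makeRandomAssayPanel <- function(seed, nAssays = NULL) {
  withr::local_seed(seed)
  if (is.null(nAssays)) nAssays <- sample(5:60, 1)
  nMut <- sample(1:4, nAssays, replace = TRUE)
  rows <- lapply(seq_len(nAssays), function(i) {
    data.frame(gene = sprintf("G%03d", i),
               protein_change = sprintf("p.A%d%s", 100 + i, LETTERS[seq_len(nMut[i])]),
               nucleotide_change = "",
               assay_id = sprintf("A%03d", i), added_in_version = "1.0",
               stringsAsFactors = FALSE)
  })
  GynPanel("random", "1.0", do.call(rbind, rows))
}

## Noise-free single-assay readout rows at a given mutant share.
readoutAtShare <- function(share, sample_id = "S1", assay_id = "KRAS_12_1") {
  data.frame(
    sample_id = sample_id, replicate = 1L, assay_id = assay_id,
    gene = c("KRAS", NA), protein_change = c("p.G12D", NA),
    nucleotide_change = c("", NA), allele = c("p.G12D", "WT"),
    mass = c(5200, 5500), intensity = c(share, 1 - share),
    failed = FALSE, stringsAsFactors = FALSE)
}
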