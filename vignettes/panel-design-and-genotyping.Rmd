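---
title: "Hotspot panel design and in-silico MALDI-TOF genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot panel design and in-silico MALDI-TOF genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelkit)
```

`panelkit` re-implements, as reusable software, the design and validation
calculus behind a 13-gene MALDI-TOF (iPLEX) somatic mutation panel for
gynaecological carcinomas. This vignette explains the models the package
computes with, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the design decisions
taken where the published description left the choice open.

## The design problem

iPLEX genotyping interrogates one genomic site per assay: a primer ends one
base before the variant position, is extended by a single mass-modified
terminator, and the extension products are resolved by mass. Two constraints
follow. First, only *hotspot* mutations — recurrent, single-site variants —
are assayable, so genes whose mutations scatter widely (TP53-like) are poor
panel candidates regardless of their biological importance. Second, assays
are multiplexed in wells, so every analyte in a well (unextended primers and
all extension products) must be separable by mass.

### Hotspot selection

`selectHotspotGenes()` encodes the inclusion rule: a gene qualifies when, for
at least one tissue of interest, at least a fraction `minFraction` (default
0.30) of its reported mutation occurrences falls on *fewer than* `maxSites`
(default 10) distinct sites — computed as the cumulative occurrence share of
the gene's top `maxSites - 1` sites. "Fewer than 10" is read strictly, hence
the top-9 share. A site is a protein change plus, where one exists, a
nucleotide disambiguator, because alternate nucleotide changes at one residue
(e.g. `p.Q61H (C>A)` vs `p.Q61H (C>G)`) are distinct assay targets. The rule
is evaluated per tissue by default; the published criterion ("for at least
one of the studied cancer types") is ambiguous about pooling, so a
`pooled = TRUE` mode is exposed and per-tissue is the default. When several
tissues achieve the same best share, the alphabetically first is reported.

### Coverage and expected yield

Panel coverage of a gene in a tissue is the fraction of that gene's
catalogued occurrences falling on targeted sites (`computeCoverage()`). The
expected number of detected mutations in a cohort of size $N$ is

$$ \hat{n} = \mathrm{round}\!\left( f \cdot c \cdot N \right), $$

with catalogue frequency $f$ (occurrences/tested), coverage $c$, and
commercial (half-up) rounding (`expectedCount()`). Half-up rounding
reproduces the published table cells that are robust to whether the original
computation used exact fractions or printed integer percentages; cells that
are not reproducible from their own printed inputs under any rounding (the
endometrial KRAS expectation prints 32 where the inputs give 29–31) are
treated as source inconsistencies and not asserted anywhere.

The catalogue `tested` denominator is gene-level: rows of one gene and
tissue share the screening denominator, so per-tissue totals use the maximum
over rows and `"all"` pooling sums the per-tissue denominators.

## Mass assignment and multiplex packing

The published panel was designed with vendor software and its primer masses
are not public; `panelkit` therefore carries a synthetic but structurally
faithful mass model (`assignAnalyteMasses()`):

* primers live in the working iPLEX analyte window, 4500–9000 Da;
* each extension product sits `productOffset` (250 Da, one terminator) above
  the primer, successive alleles `alleleSpacing` (30 Da) apart;
* under the default `mutant_first` policy the wild-type product takes the
  highest mass, so every mutant peak is detected before the wild-type peak
  and a salt adduct of the wild-type product (a +Na/+K satellite a few
  daltons up) cannot be misread as a mutant allele. The policy is soft by
  construction — the generator always satisfies it, user-supplied masses
  need not.

Primer *placement* defaults to a shuffled, jittered regular grid over the
window ("stratified") rather than independent uniform draws. This is a
deliberate design decision: a multiplex design tool schedules analyte masses
so that assays can share wells, it does not draw them blindly. Packing uses
first-fit decreasing by primer mass, which for mass-interval conflicts is
exactly the optimal left-to-right colouring of an interval graph — so the
well count is governed by the mass layout, not the algorithm. With
independent uniform primers the 99 packaged assays need 10–15 wells
depending on the seed; with stratified placement the point-coverage of the
mass axis is nearly deterministic and the same assays pack reproducibly into
10–12 wells, inside the published 13. The `"uniform"` mode remains available
for sensitivity analysis.

`packMultiplexes()` enforces a plex cap (default 12 assays/well) and a
pairwise separation of all analyte masses in a well (default 30 Da, a
conventional iPLEX peak-resolution figure; the source does not state one).
`validateMultiplex()` is the independent checker: an exhaustive pairwise
scan reporting every cap breach and every analyte pair closer than the
minimum separation. The designer's output is tested against the checker,
never against itself. Internal allele spacing equals the default separation,
so a lone assay is always feasible; a numerical tolerance of $10^{-9}$ Da
guards the boundary against floating-point jitter.

`revisePanel()` supports the add/remove lifecycle (version 1.0 → 2.0 in the
modelled panel): removed targets leave their assays (empty assays drop,
freeing well slots), additions are grouped into new single-site assays and
packed into a configurable set of wells, mirroring the practice of
concentrating new assays on a few re-run multiplexes.

## The genotype caller

For each assay the mutant allele fraction is estimated per mutant allele as
$\mathrm{MAF} = I_{mut} / (I_{mut} + I_{WT})$ from peak intensities, which
assumes proportional ionisation across alleles — a stated model assumption,
adequate for the simulator and for relative calling. The assay is called
mutant when any allele share reaches the threshold (default 5%,
*inclusive*: a peak at exactly 5% qualifies, reading "minimum 5% threshold"
as 5% qualifying). Multi-allele assays report the allele with the largest
share. An assay whose true-allele peaks all lie below `noiseFloor` is
`failed`; the source does not quantify its failure floor, so the default
(0.01 on the simulator's unit-total intensity scale) is a configuration
parameter sitting well below the 5% calling threshold and well above the
simulated baseline noise. The published three-investigator manual review is
deliberately replaced by this deterministic rule.

## The synthetic cohort generator

`simulateCohort()`/`simulateReadouts()`/`simulateQpcr()` emulate the
statistical structure the validation study assumes. Defaults are the study
conditions:

* **Cohorts**: 205 cervical, 227 endometrial, 89 ovarian, 25 vulvar samples
  (`studyCohorts()`).
* **Mutation probabilities**: per-tissue per-gene detected frequencies of
  the published cohort (e.g. PTEN in endometrium 89/227 = 0.39), with
  per-target splits proportional to the published per-mutation counts,
  restricted to panel targets (`defaultSimulationConfig()`). Gene-level
  rows draw one target per mutated sample; fully target-level
  configurations (independent per-target Bernoulli draws) are supported and
  can produce the same-gene double mutants the study reports.
* **MAF**: uniform on [0.05, 0.6], so the calling threshold is exercised at
  its boundary; configurable down to 0 for limit-of-detection sweeps.
* **Noise**: multiplicative log-normal with `noiseSd` (default 0.05)
  on true peaks; unmutated mutant alleles carry half-normal baseline noise
  at one fifth of `noiseSd`, so a zero-noise configuration is exactly
  noiseless.
* **Artifacts**: with probability `artifactProb` (default 0.02) per assay, a
  salt-adduct peak lands within ±20 Da of a randomly chosen true peak at an
  intensity capped below the calling-threshold share. The caller ignores
  labelled adduct rows; the artifact model exists to justify and document
  the mutant-first peak ordering, not to defeat the caller.
* **DNA quality**: ordinal score 0–3 (the source mentions scores "0" and
  "≥1" without defining the scale). Default score distribution
  (0.09, 0.11, 0.25, 0.55) puts ~9% of samples at score 0, matching the
  reported 48/546 low-quality fraction; per-assay failure probabilities
  (0.10, 0.03, 0.01, 0.005) are constrained non-increasing in quality and
  are calibrated in *direction* only — the source reports aggregate counts,
  not per-score rates.
* **Replicates**: 10% of samples in duplicate, 5% in triplicate, as in the
  validation arm.
* **qPCR**: the ten validated variants (7 KRAS, 3 PIK3CA), a 20% detection
  limit (inclusive; configurable, 0 allowed for sweeps), and sample-level
  failures (a failed sample fails all ten reactions, the pattern of the
  published failed-reaction tally).

Everything is reproducible from the configuration seed, and mutations are
independent across genes within a sample (the study reports co-mutated
samples but no dependence model).

**What passing simulations do and do not show.** The generator reproduces
the study's *statistical* structure — frequencies, detection limits,
replicate arms, failure direction — so green tests demonstrate that the
calculus (selection, packing, calling, concordance, spectra) is correct and
self-consistent at scale. They do not validate instrument physics (no
isotope envelopes, resolution curves or ionisation bias), tumour biology
(no mutational signatures, purity or clonality structure), or the true
cohort, which is not public; observed-vs-expected discrepancies that made
the study interesting (PIK3CA detected twice as often as predicted) are
inputs here, not outputs.

## Statistics

`fisherExact2x2()` is an own implementation of the two-sided Fisher exact
test by full hypergeometric enumeration: with margins fixed, every
admissible table's conditional probability is computed from log binomial
coefficients and the p-value sums all tables no more probable than the
observed one (with a $1+10^{-7}$ relative tolerance so floating-point noise
cannot drop exact ties). It matches `stats::fisher.test` to $10^{-9}$ over
every table with all margins ≤ 30 in the test suite; the base-R
implementation is used only as a cross-check, never as the engine.
`exonDistributionContrast()` applies it to the exon 9 / exon 20 PIK3CA
split between tissues, with the standard hotspot architecture (codons
542/545/546 on exon 9; 1021/1025/1043/1047 on exon 20; codon 88 excluded) —
the source states the contrast but not the mapping.

Report percentages round half-up to integers, matching the N(%) style of
the published tables; `roundHalfUp()` is exported because base R's banker's
rounding disagrees on .5 cells.

## Problem sizes and numerical choices

The frequency-recovery test simulates 10,000 samples per tissue — chosen so
that three binomial standard errors are ~1.5% at a frequency of 0.39, tight
enough to catch calibration errors while keeping the whole suite fast — and
checks every configured per-gene frequency within 3·SE, with the spectrum
report required to equal a brute-force group-by of the simulated ground
truth exactly under zero noise. Packing is property-tested on 100 seeded
random assay sets against the exhaustive checker. Degenerate inputs are
defined, not accidental: empty target sets have coverage 0, a zero-detected
confirmation rate is *undefined* (NA with a message), an all-failed
concordance denominator is an error, and an empty exon-contrast table is an
undefined test.

## Known limitations

* The packaged panel fixture transcribes the published design table, whose
  internal counts are not perfectly consistent (its FGFR2 column lists more
  entries than its own per-gene total; the printed assay removals disagree
  with the design table; 154 + 19 ≠ 171). The fixture follows the per-gene
  totals row, documents the choices in its header, and no version-1.0
  fixture is shipped because that composition is not reconstructible.
* Assay grouping of same-residue alternate alleles and the well layout are
  synthetic: the published table gives only per-gene assay counts and the
  well total, both of which the fixture reproduces exactly.
* Masses are synthetic throughout; no oligonucleotide design (Tm, hairpins,
  dimerisation) or vendor file formats.
* The caller is deterministic; no consensus-review simulation, no clinical
  interpretation, no HPV modelling.
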