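---
title: "Models and methods: mtDNA heteroplasmy transmission analysis"
author: "mitoHet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mtDNA heteroplasmy transmission analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoHet)
```

# Scope

`mitoHet` analyses per-animal mitochondrial variant-call tables from
pedigree cohorts — typically mutator-mouse N3 offspring genotyped across
nuclear backgrounds that modulate the germline mtDNA bottleneck or
autophagy — and simulates the transmission process that generates such
cohorts. This vignette documents the statistical models, the tunable
parameters, the numerical conventions, and the design decisions taken where
the methodology is genuinely open. It intentionally states no empirical
results beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

# The reference model and functional classification

A `MitoGenome` is one circular contig with gene features (protein, tRNA,
rRNA, noncoding). Coordinates are 1-based inclusive, the mtDNA community
convention; BED input (0-based half-open) is converted at the reader
boundary. Features may overlap, as Atp8/Atp6 do in real mitochondrial
genomes; bases covered by no feature are noncoding. Features themselves may
not wrap the origin — circularity is honoured where it matters analytically
(coldspot detection) rather than in the feature model.

Substitutions are classified under NCBI translation table 2 (vertebrate
mitochondrial: ATA = Met, TGA = Trp, AGA/AGG = stop). For a protein gene
the codon containing the position is rebuilt on the coding strand
(reverse-complementing for minus-strand genes), mutated and re-translated;
an amino-acid-preserving change is synonymous, anything else — including
stop gain and stop loss — is nonsynonymous, because the downstream
statistics only distinguish those two protein-level classes.

Three conventions deserve explicit statement:

* **Overlapping genes.** A variant is classified per overlapping gene for
  per-gene tallies (densities, site counts). The single genome-level class
  used for the N/S ratio is resolved by the precedence
  nonsynonymous > synonymous > tRNA > rRNA > noncoding. Annotation
  pipelines differ here and no consensus exists; precedence is conservative
  (a variant that damages any product counts as damaging) and
  deterministic.
* **Incomplete terminal codons.** Real mtDNA genes can end in a partial
  codon completed by polyadenylation. The trailing 1–2 bases of a protein
  feature have no complete codon on the genome, so they are excluded from
  codon classification and from site counting; a position there falls back
  to the next overlapping feature's class, or to noncoding.
* **Site counting.** `countPossibleSites()` enumerates, for every complete
  codon of every protein gene, all nine single-base substitutions, so per
  gene `possible_S + possible_N = 3 × coding bases` exactly. Overlapping
  genes are tallied independently per gene and the genome-wide totals sum
  the per-gene counts. The test suite verifies the enumeration against an
  independent per-codon brute-force oracle, including minus-strand genes.

# Cohort filtering

Two inclusion rules define the analysed call set:

* **HF threshold** (`hf_min`, default 0.01, strict `>`): calls at or below
  1% HF are treated as below the reliable detection range.
* **Recurrence filter** (`recurrence_max`, default 26, strict `<`): a
  variant allele — identified as the (position, alt) pair — carried by 26
  or more animals is removed entirely, on the rationale that a de novo
  mutation is very unlikely to recur across that many animals, so such
  variants were inherited from a shared subline. The default is specific to
  a ~161-animal cohort; `recurrence_frac` scales the cutoff for other
  cohort sizes.

The order of the two rules is not canonical. The package applies the HF
threshold first, so recurrence is counted among the *analysed* calls — the
recurrence rule is meant to detect inherited variants within the data being
analysed, and sub-threshold calls are already considered unreliable. The
`order = "recurrence_first"` flag swaps this, and the test suite pins the
one fixture where the two orders disagree. Filtering never alters the
animal roster: an animal whose calls are all removed keeps a meaningful
burden of zero. Every filter logs its removal counts.

# Per-animal and per-group statistics

* **Mean HF**: the arithmetic mean of the HFs of all of an animal's
  detected variants. Animals with zero calls carry no HF information and
  are excluded from HF and EMD summaries (with a logged count); they are
  included, as zeros, in burden summaries.
* **Burden**: the number of detected variants per animal.
* **N/S ratio**: `(n_N / possible_N) / (n_S / possible_S)`, per animal,
  using the genome-level precedence class. With zero synonymous variants
  the ratio is undefined; such animals are excluded from group summaries
  (never imputed) and counted. Zero nonsynonymous with at least one
  synonymous variant gives 0. Under neutral uniform placement over coding
  substitution opportunities the ratio is 1 in expectation — the test suite
  and the acceptance script verify this calibration by Monte Carlo
  (10^4 placements, three standard errors).
* **EMD**: the 1-D Wasserstein-1 distance between two animals' empirical HF
  distributions (each variant one unit of mass), computed exactly as the
  integral of the absolute CDF difference over the breakpoint partition.
  For equal sample sizes this equals the mean absolute difference of the
  sorted samples; the tests additionally compare against an independent
  midpoint numeric-integration oracle at 1e-12 and check the metric axioms.
  Group-level variance in heteroplasmy profiles is summarised as the EMD
  over **all unordered within-group animal pairs** (`n(n−1)/2` values).
  Comparing each animal to the pooled rest-of-group distribution is an
  alternative reading of "interindividual differences within a group"; it
  is implemented behind `emd_mode = "pooled"` but is not the default, since
  the pairwise set is the more direct measure of pairwise dissimilarity.
* **Median and mode**: group summaries report the median and a modal value.
  "Mode" of a continuous statistic needs an estimator; the package fixes a
  Gaussian KDE with Silverman's rule-of-thumb bandwidth (`stats::bw.nrd0`),
  evaluated on a 512-point grid spanning [min − 3h, max + 3h], taking the
  grid argmax, with ties resolved to the smallest value. Reported modes are
  therefore reproducible to grid resolution (~1/511 of the padded range);
  `bandwidth` overrides the rule.
* **Hypothesis tests**: each non-control group is compared to the control
  by a two-sided Wilcoxon rank-sum test — exact enumeration when both
  groups have at most 12 values and no ties, otherwise the tie-corrected
  normal approximation with continuity correction, which is the regime for
  ~30-animal groups. A fully tied comparison returns p = 1. Shapiro–Wilk
  (`checkNormality()`) is provided to justify rank tests over t tests in
  report narratives. **No multiple-testing correction is applied**; the
  report records the number of uncorrected comparisons instead, matching
  standard practice in this literature. Within-litter non-independence of
  animals is *not* modelled by the tests (a known caveat; the simulator
  deliberately generates such correlation so its consequences can be
  studied).
* **Coldspots**: maximal runs of ≥ `min_run` (default 9) consecutive
  positions with no variant in the whole cohort, computed on the circular
  genome so a run may wrap the origin (reported with end < start). Wrapping
  can be disabled for linear interpretations.
* **Per-gene densities**: distinct variant alleles per feature divided by
  feature length; a variant in an overlap region counts in every
  overlapping gene; protein genes are additionally split into
  synonymous/nonsynonymous densities using the per-gene classification.

# The transmission simulator

The generator exists so every analysis stage is testable on cohorts whose
generating process is known. It models, per maternal lineage:

1. **Mutation** (founder generation only): Poisson(λ) de novo variants at
   uniform unique positions, alternate allele uniform over the three
   non-reference bases, each starting at HF `1/C0` — one mutant molecule
   among `C0` copies. Mutagenesis in later generations is not modelled,
   matching designs that restrict the mutator allele to a single
   generation.
2. **Segregation**: per generation, `round(g·τ)` rounds of binomial
   resampling of each variant's allele count among `N_b` segregating
   units (an effective Wright–Fisher bottleneck — no claim about oogenesis
   cell counts or nucleoid packaging). Variants segregate independently
   (no linkage): de novo variants arise on distinct molecules and the
   analysis treats variants marginally; this is a stated model limitation.
3. **Selection**: when a variant of a deleterious class exceeds the
   threshold θ, its sampling probability is deflated to
   `p(1−s)/(1−ps)` before the draw — selective removal of a fraction s of
   mutant genomes. Below θ the variant drifts neutrally, implementing the
   threshold interpretation of selective autophagy: selection can only act
   on mitochondria whose mutant load is high enough to impair them.
   Synonymous and noncoding variants are neutral by construction.
4. **Reporting**: after the configured number of generations (default 3,
   founder → N3), variants with final HF above the detection floor
   (default 0.01) and below 1 become calls. Fixed variants (HF = 1) are
   excluded by default — a fixed variant is indistinguishable from the
   reference in resequencing — with `includeFixed` to override.
5. **Litters**: littermates share their dam's lineage state (all
   generations but the last are common), reproducing the within-litter
   correlation real cohorts have.

## Default parameters and their rationale

| parameter | default | meaning / rationale |
|---|---|---|
| `cohortSizes` | 32/32/31/34/32 | the five-group N3 study design (161 animals) |
| `generations` | 3 | founder → N3 transmission depth |
| `founderCopyNumber` C0 | 64 | copies at mutation time, early in germ-cell development; gives initial HF ≈ 1.6%, just above the detection floor, so a de novo variant is detectable before drift acts |
| `bottleneckSize` N_b | 50 | effective segregating units, mid-range of rodent bottleneck estimates |
| `segregationRounds` g | 10 | resampling rounds per generation; with N_b = 50 this yields substantial but incomplete drift per generation |
| `turnover` τ | 1 | bulk-turnover multiplier; the impaired-turnover preset uses τ = 0.5, reducing both effective rounds and selection strength |
| `selection` s | 0.6 (nonsyn, tRNA), 0.2 (rRNA), 0 (syn, noncoding) | per-round removal fraction above threshold |
| `selectionThreshold` θ | 0.25 | HF needed to trigger selective removal |
| `mutationRate` λ | 900 | de novo variants per founder lineage, chosen (with the drift parameters) so the simulated control group's burden and mean HF land in the range such studies report (~tens of variants, mean HF 0.1–0.2) |
| `litterSize` | 4 | typical litter; one dam per litter |

Two calibration points matter and were fixed before the directional test
suite was written. First, C0 must put the initial HF *above* the detection
floor: if founder variants start undetectable, reduced drift would reduce
burden and the impaired-turnover group's burden direction would invert.
Second, θ must sit in the upper tail of the HF distribution. Cumulative
selection exposure is the number of rounds a variant spends above θ; with a
low θ that exposure is dominated by time-to-absorption, which is *longer*
under a wide bottleneck, so a low-θ model makes the control experience more
selection than the tight-bottleneck group — inverting the expected N/S
direction. With θ in the upper tail, crossing the threshold at all is the
limiting event, and the tight bottleneck (which sends more variants to high
HF) experiences stronger selection. That threshold interpretation is
precisely the biological model the simulator encodes.

The group presets scale these defaults: `tfam_het` halves N_b (tighter
bottleneck), `tfam_oe` doubles it, `bcl2l13_ko` zeroes all selection
coefficients (no selective mitophagy), `ulk2_ko` sets τ = 0.5. The numbers
are package defaults spanning clearly separated regimes — no quantitative
bottleneck size or selection coefficient is available for any real
genotype, and the package does not claim to reproduce any study's printed
medians. The shipped tuning script (`inst/scripts/tune-simulator.R`) used
only the control group's order-of-magnitude targets above.

## What the generator emulates — and what it does not

It reproduces: group sizes and labels, tens of low-to-mid-frequency
variants per animal spread over all functional classes in proportion to
substitution opportunities, drift-driven interindividual variance that
responds to bottleneck size, threshold selection that depresses the N/S
ratio, detection censoring, and litter structure. It does not emulate:
sequencing error or depth-dependent call quality, mutational hotspots or
transition/transversion bias (positions and alleles are uniform),
replicative segregation bias, paternal leakage, linkage between variants,
or continued mutagenesis after the founder generation. Tests passing on
simulated cohorts therefore validate the *statistical machinery* under a
known generating process; they cannot certify behaviour under real
sequencing artefacts.

# Numerical conventions and degenerate inputs

* HF is stored as a fraction in (0, 1]; percent-scale tables are converted
  at the reader with an explicit unit flag. Table writing uses 17
  significant digits so round trips are exact; report files round to 6
  significant digits.
* The EMD integrates a step function exactly over its breakpoints — no
  quadrature tolerance is involved; the 1e-12 figure in the tests bounds
  floating-point accumulation only.
* KDE modes: single-value or zero-spread samples return that value
  directly (the bandwidth rule is undefined there); grid ties take the
  smallest value.
* Shapiro–Wilk requires 3 ≤ n ≤ 5000 and errors on zero-variance samples.
* An empty cohort produces headers-only report files, a single full-genome
  coldspot, and NA group summaries; groups with fewer than two call-bearing
  animals yield an empty EMD set (logged) rather than an error when run
  through `cohortStatistics()`.
* All simulator randomness flows from R's global generator seeded once per
  cohort (`config@seed`), making `simulateCohort()` a pure function of
  (config, genome); pipeline provenance records the seed.

# Problem sizes in the shipped checks

The test-suite and acceptance-script problem sizes are the package's own
choices: 10^4–10^5 replicates for Wright–Fisher moment checks, 10^3 random
sample pairs for the EMD oracle, 500 random fixtures for the coldspot
oracle, 10^4 placements for the neutral N/S calibration, and 20 replicate
full cohorts (161 animals each) for the directional sign tests comparing
the tight-bottleneck and impaired-turnover groups to control. These sizes
give three-standard-error margins on every stochastic check while keeping a
full run in the minutes range on one CPU.

# Known limitations

* The Wilcoxon tests ignore litter structure; p-values on simulated
  cohorts are anti-conservative to the degree littermates correlate.
* The bottleneck is a single effective size per group; real germlines may
  have stage-dependent copy-number trajectories.
* The N/S ratio is undefined for animals without synonymous variants,
  which biases group summaries of very-low-burden groups towards animals
  with more variants; the exclusion count is reported so users can judge.
* Selection acts identically on all nonsynonymous variants; no
  variant-specific pathogenicity is modelled (pathogenicity prediction is
  out of scope).
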