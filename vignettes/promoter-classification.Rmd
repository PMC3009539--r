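---
title: "Classifying promoter-associated Pol-II enrichment: methods and design"
author: "PolPromoter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying promoter-associated Pol-II enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

ChIP-seq with an RNA polymerase II (Pol-II) antibody enriches not only gene
promoters but also transcribed gene bodies and other regions, because the
elongating polymerase spreads along the transcription unit and the antibody
is not perfectly specific. Enriched-region lists from such experiments
therefore mix promoter-associated peaks with large numbers of intragenic
peaks. PolPromoter implements a supervised pipeline that discriminates
promoter-associated Pol-II enrichment from enrichment elsewhere, using a
39-dimensional representation of the 500 bp window around each peak, and
then annotates promoters genome wide, including alternative promoters of
the same gene.

The pipeline has six stages, each usable on its own: peak calling, labeled
dataset construction, feature extraction, ensemble classification with the
promoter-prediction metrics, genome-wide annotation, and a synthetic-data
generator that makes every stage testable without any external download.

# Peak calling against a Poisson background

Tag coverage is scanned in sliding windows (default 500 bp, step 50 bp).
Each window's tag count is scored by the upper-tail Poisson probability
under a single global background rate

    lambda = library_size * window_bp / effective_genome_size,

p-values are converted to q-values with Benjamini-Hochberg, windows with
q at or below the target FDR (default 0.001) are kept, and overlapping or
adjacent significant windows are merged into regions. Each region reports a
summit (leftmost base of maximal coverage — a deterministic tie-break), the
total tag count and its best window p- and q-value.

Design notes:

* The FDR criterion is interpreted as Benjamini-Hochberg control at 0.001.
  An alternative reading (an empirical expected-false-peak ratio) exists;
  BH was chosen because it is standard, monotone in the threshold, and
  needs no second null scan. Window size, step, FDR and the effective
  genome size are all configurable so results from other callers can be
  matched; externally called peaks can also be imported from BED and used
  everywhere downstream.
* A single global lambda is deliberate: the synthetic background is
  homogeneous, and for real data a conservative global rate (library mass
  over genome size, i.e. including signal mass) errs toward fewer false
  peaks. Local-lambda models and input subtraction are out of scope.

# The 39 window features

Every record is the 500 bp window from 300 bp upstream to 200 bp
downstream of an anchor (a TSS or a peak summit), oriented by strand.
Internally all coordinates are 1-based closed `GRanges` (the Bioconductor
convention); BED and UCSC-style 0-based inputs are converted once at the
I/O boundary.

**Composition (10).** With `n_x` the count of symbol `x` in the window and
L = 500 fixed: the four base fractions `n_A/L` ... `n_T/L`; the
purine-pyrimidine, amino-keto and weak-strong skews
`(n_A + n_G - n_C - n_T)/L`, `(n_A + n_C - n_G - n_T)/L`,
`(n_A + n_T - n_C - n_G)/L`; and three CpG-island statistics:

* `cpg1 = (2 n_CG + 2 n_GC) / (L - 1)`
* `cpg2`: an 18-term weighted sum of CpG-related trinucleotide counts
  (ACG, AGC, CAG, CCG, CGA, CGC, 2·CGG, CGT, CTG, GAC, GCA, 2·GCC, GCG,
  GCT, 2·GGC, GTC, TCG, TGC) over (L - 2)
* `cpg3 = (4 n_CAG + n_CCG + n_CGG + 4 n_CTG + 4 n_GAC + n_GCC + n_GGC +
  4 n_GTC) / (L - 2)`

N bases contribute 0 to every count while the denominators keep the fixed
window lengths L, L-1, L-2. Windows truncated by a chromosome edge are
N-padded back to 500 bp for the same reason: the feature vector length and
the denominators never change.

**Physico-chemical properties (22).** Each property P is a conversion
table φ_P mapping every k-mer (k = 1, 2, 3 or 4 depending on the property)
to a number: A-philicity, base stacking, B-DNA twist, bending stiffness,
dinucleotide flexibility energy, denaturation, duplex-disrupt and
duplex-free energy, the six helical step parameters (rise, twist, tilt,
roll, shift, slide), propeller twist, protein-induced deformability,
protein-DNA twist, Z-DNA energy, trinucleotide bendability, nucleosome
position preference, tetranucleotide flexibility and EIIP. The feature is

    sum_x n_x * phi_P(x) / (number of N-free k-mer windows),

the mean property per k-mer step. The normalization is a package decision:
it makes the feature independent of window length and satisfies the
identity "constant scale φ ≡ c gives feature c", which the tests assert. A
window with no valid k-mer (all N) scores 0.

The packaged conversion tables
(`inst/extdata/property_scales_synthetic.tsv`, loaded by
`defaultPropertyScales()`) are **synthetic stand-ins**: one value per k-mer
drawn once within a plausible physical range per property. They exercise
the mechanics and give the classifier 22 smooth functions of local
oligonucleotide composition, but they are not the literature tables; users
with the published tables load them through `readPropertyScales()`, which
accepts any TSV of (property, k, kmer, value).

**Experimental signal (7).** Coverage from each sample is converted to tags
per million (TPM) using its own library size, then samples of the same
assay are pooled (default: per-base sum, preserving breadth of evidence;
`pooling = "mean"` available). Features: total CAGE TPM in the window, and
for Pol-II and H3K4me3 the average per-base TPM, the maximum per-base TPM,
and max/avg. The ratio is defined as 0 when the average is 0, so "no
evidence" never produces NaN. Because per-sample TPM is taken first, the
features are invariant to sequencing depth (coverage and library size
scaling together), which the tests assert. Optionally, coverage outside
significant regions (from the peak caller's mask) is zeroed first, so that
only tags belonging to enriched regions contribute; the synthetic benchmark
uses this masking. CAGE is used unstranded by default.

# Labeled dataset construction

Given called peaks and a non-redundant TSS catalog (union of several gene
lists, collapsed on chromosome/position/strand):

* **Promoter records.** A peak whose summit lies within the strand-aware
  window from 300 bp upstream to 200 bp downstream of a known TSS yields
  one promoter record: the 500 bp window anchored on the summit with those
  same offsets, oriented by the matched TSS (nearest TSS on ties, then
  smaller coordinate). Anchoring on the summit means a peak near several
  TSSs still yields exactly one record.
* **Non-promoter records.** A peak qualifies when its summit lies inside a
  gene body, the whole 500 bp record window fits inside that gene, the
  summit is not within -300/+200 bp of any TSS, the host gene's own
  promoter window contains some peak summit (the transcript is actively
  bound), and the record window overlaps no exclusion interval (homologous
  promoters, EST 5' ends — width-1 exclusion anchors are expanded with the
  same -300/+200 window).
* **Cross-tissue deduplication.** After pooling tissues, any non-promoter
  record overlapping (at least 1 bp) any promoter record from any tissue is
  dropped; promoter records are never dropped.
* **Split.** Train/test splitting is random, stratified by label, with a
  stored seed (default 3/4 train).

The summit-in-window reading of "peak falls within" is the default because
a summit is width-independent and deterministic; any-overlap mode is
available (`mode = "overlap"`).

# Classification and evaluation

Two tree ensembles are supported behind one interface: bagging (bootstrap
aggregation of trees using every feature at each split) and random forest
(each split samples floor(sqrt(p)) features). Both are fit through the
randomForest package with 100 trees by default; hyperparameters are
configurable and recorded in the model archive together with the feature
column order, and prediction refuses a mismatched feature matrix.

Evaluation uses the four promoter-prediction metrics, computed from the
confusion counts (promoter = positive):

* sensitivity `SN = 100 TP / (TP + FN)`
* positive predictive value `PPV = 100 TP / (TP + FP)`
* Matthews correlation
  `MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`
* true-positive cost `TPC = FP / TP`, the false positives paid per true
  positive.

A metric whose denominator is zero is reported as 0 and flagged. The MCC
denominator is computed in log space to avoid overflow on large count
products. Cross-validation is stratified with pooled confusion counts; ROC
curves sweep the distinct score thresholds and AUC is the trapezoid area,
which equals the pairwise-comparison probability (ties counted half) — the
test suite checks this equivalence against a brute-force oracle. Variable
importance is the random-forest out-of-bag permutation importance (mean
decrease in accuracy, normalized by its standard error, plus mean decrease
in Gini), averaged over repeated fits (default 100; smaller values are used
in the packaged checks where noted below).

# Genome-wide annotation

Each called peak is scored twice: the -300/+200 window in plus orientation
and in minus orientation (sequence reverse-complemented, offsets flipped).
Windows reaching the probability threshold (default 0.5 — a neutral
posterior cutoff, configurable) become promoter calls; when both
orientations of one peak are called they merge into a single call (union
interval, maximum score). A call is assigned to a gene when its source-peak
summit lies in the strand-aware window from 2000 bp upstream to 500 bp
downstream of the TSS, boundaries inclusive; with several candidates the
nearest TSS wins, exact ties to the smaller coordinate. Unassigned calls
are reported as potential novel promoters. Assigned calls from any number
of samples are clustered per gene by single-linkage interval overlap (at
least 1 bp): each cluster is one distinct promoter, so a gene's promoter
count and the fraction of genes with two or more promoters (alternative
promoter usage) follow directly. Single-linkage with a 1 bp threshold is
the simplest reproducible rule for "the same promoter seen twice"; a
minimum-overlap variant can be obtained by shrinking the call windows
before combining.

# The synthetic-data generator

`simulateGenome()` draws a uniform-composition background sequence and
replaces every truth promoter window (TSS -300/+200, strand-aware) with a
dinucleotide Markov sequence whose CG and GC transition odds are multiplied
by the CpG enrichment factor (default 5), so the CpG features separate
promoters from background. Genes (default 500, bodies 6-9 kb, intergenic
gaps 1-2 kb, random strands) are laid out left to right on one chromosome.

`simulateTags()` draws per-base Poisson counts with rate = background +
signal terms, per assay:

* Pol-II: promoter bump (0.5 tags/bp over the truth window), gene-body
  spread decaying linearly 5'→3' (0.03 → 0.005 tags/bp), and four discrete
  300 bp "pause" bumps (0.3 tags/bp) per gene body, kept clear of the TSS
  window; background 0.01 tags/bp.
* H3K4me3: a 1 kb domain centred on the TSS (0.4 tags/bp) over a 0.005
  background.
* CAGE: a 40 bp footprint at the TSS (2 tags/bp) over a 5e-4 background.

The pause bumps are a package addition on top of the linear decay: decay
alone produces at most one merged enriched region per gene body, whereas
discrete bumps yield distinct internal peaks, which is what the
non-promoter rules need to produce a realistic several-to-one
non-promoter:promoter ratio (the defaults give roughly 450-500 promoter
and 1700-1900 non-promoter records — the deliberately scaled-down
benchmark size). All rates scale with a single `depth` multiplier, and the
library size is the realized tag total, so TPM features stay
depth-invariant.

What the generator does **not** emulate: mappability and GC bias,
fragment-length effects, read-level artifacts (no FASTQ), copy-number
variation, bidirectional or divergent transcription, enhancers with
promoter-like chromatin, and cross-tissue variability. Passing tests on
synthetic data therefore demonstrate that the machinery implements its
contracts and that the statistical structure the method assumes is
recoverable — not that real mouse tissue performance is reproduced, which
would require the original ChIP-seq datasets.

# Numerical choices and degenerate inputs

* Poisson tails use the survival function (`ppois(count - 1, lambda,
  lower.tail = FALSE)`), never `1 - cdf`.
* Summit ties break to the leftmost base; gene-assignment distance ties to
  the smaller TSS coordinate; both documented and asserted.
* `max/avg = 0` when `avg = 0`; all-N windows score 0 on every sequence
  feature; missing assay groups are an error unless explicitly allowed
  (then zero-filled with a warning).
* Windows beyond chromosome ends are N-padded, never shortened.
* Internal coordinates are 1-based closed GRanges everywhere; 0-based
  half-open conventions exist only inside the BED/UCSC readers and writers.
* All randomness (simulation, splits, fits, folds) is funneled through
  explicit integer seeds; identical seeds give byte-identical simulated
  FASTA/bedGraph output, which the tests check via file checksums.

# Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run everything from scratch at
sizes chosen to keep a laptop run comfortable: the global-null FDR check
simulates a 10 Mb background at 0.02 tags/bp; the end-to-end benchmark uses
500 genes (~3.9 Mb genome, ~2200 labeled records), 10-fold cross-validation
with 100 trees, and permutation importance averaged over 5 repeats (the
function default is 100). The published-scale dataset (11,773 promoter /
46,167 non-promoter records) is not re-derivable without the original
tissue data; the package covers it through the metric computations on the
published confusion counts and through arithmetic-consistency checks of its
own bookkeeping.

# Known limitations

* The shipped property scales are synthetic stand-ins (see above); results
  that depend on the literature values require user-supplied tables.
* The peak caller is a minimal global-rate Poisson scan: no control-track
  subtraction, no local background, no broad-mark mode.
* Gene assignment uses the peak summit; a predicted-window mode exists but
  summit-based assignment is the tested default.
* The classifier stack covers bagging and random forest; boosting and
  rotation-forest variants are intentionally out of scope.
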