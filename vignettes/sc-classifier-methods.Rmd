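---
title: "Methods: predicting bacterial structural color from genome content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting bacterial structural color from genome content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iridetect)
```

## The problem

Structural color (SC) in bacteria is a colony-level optical phenotype:
cells pack into a two-dimensional photonic crystal whose periodicity
diffracts light into saturated, angle-dependent colors. The phenotype is
genetically determined to a useful degree — strains carrying a particular
repertoire of ortholog families (gliding motility, pterin, porphyrin,
polysaccharide metabolism and other pathways) tend to form such ordered
colonies. `iridetect` implements the complete computational chain that
turns this observation into a predictor: find phenotype-associated gene
families in a strain collection, turn them into sequence models that can
be searched against any genome or metagenome, summarize the hits with a
random forest, and band the resulting score into likely-positive,
putative, and likely-negative calls. Two companion modules handle the
physics (grating-equation analysis of colony goniometry) and the ecology
(survey statistics over many metagenome scores).

## Association stage (pan-GWAS)

The substrate is a binary strains × ortholog-families presence/absence
matrix (the Roary `gene_presence_absence.csv` dialect) and a three-state
phenotype table (positive / negative / unknown; unknown strains are
excluded from association and training but can still be scored). Three
association statistics are computed per family:

* **Fisher exact test**, two-sided by probability ordering (the sum of
  all hypergeometric tables at the observed margins whose probability
  does not exceed the observed one), Bonferroni-corrected. The
  multiplier is the number of families actually tested — the full matrix
  width — because the alternative (a pre-filtered "relevant" subset) is
  not well defined in general; it is overridable via `n_tests`.
* **Label-permutation test**. Labels are permuted among labeled strains,
  preserving class counts. The default statistic is the tree-aware
  maximum supporting-pair count (below); a plain absolute log odds ratio
  is available (`statistic = "odds_ratio"`) and is much cheaper without
  a tree. The default estimator `(1 + #{perm >= obs})/(1 + n_perm)` is
  valid but *conservative* when the statistic is discrete (ties are
  counted against the hypothesis). For calibration studies the
  randomized tie-broken estimator (`tie_break = "randomized"`) is
  exactly Uniform(0, 1) under the null; it is the right choice when the
  distribution of p-values itself is the object of study, while the
  conservative default is the right choice for significance calls.
* **Contrasting-pairs test**. A contrasting pair is two tips of the
  strain phylogeny differing in both gene and trait state; a pairing is
  a set of such pairs whose tip-to-tip paths share no edge, which makes
  the pairs phylogenetically independent. The maximum pairing size and
  the maximum/minimum number of *supporting* pairs among all maximum
  pairings are found by an exact post-order dynamic program
  (multifurcations are combined natively; tips of identical joint state
  are interchangeable, so greedy within-node matching over signed
  unmatched counts is optimal). Each independent pair supports the
  association with probability 1/2 under the null, giving binomial tail
  p-values for the best and worst maximum pairing. The DP is verified
  against brute-force enumeration of all edge-disjoint pairings on
  randomized trees with up to 8 tips.

The selected feature set is the union of the three statistical streams at
`alpha` (default 0.05) plus any families with experimental (transposon
mutagenesis) evidence, each feature carrying all applicable evidence
flags. Selection is ordered by family id and therefore invariant to the
input order. Ward clustering (`ward.D2` on Euclidean distances between
binary feature columns) is provided for presenting the selected block
structure.

## Sequence-model stage (profile HMMs)

Each selected family's protein alignment becomes a profile HMM with a
simplified Plan7-like architecture: match/insert/delete states, local
(free-flanking) alignment, bit scores. Columns with more than 50% gaps
become insert columns (the usual heuristic); match emissions are observed
counts plus `pseudocount_weight` × background, normalized; transitions
are estimated from the observed alignment paths with add-one smoothing.
Scores are emission log-odds against the background (uniform 1/20 by
default, overridable), with gap penalties derived from the transition
probabilities and normalized so that the pure match path carries no
transition cost — this makes the score of a training sequence against a
profile built from identical ungapped sequences exactly
`L * log2(1/f_bg)`, a convenient analytic anchor. Forward-algorithm
E-values are deliberately out of scope: the pipeline only needs binary
presence calls at clear thresholds, and the HMMER3 `--tblout` reader
provides full-fidelity import when scores from the reference search tool
are preferred (the writer produces the same layout, so the two routes can
be checked against each other).

The per-family presence threshold defaults to 90% of the minimum Viterbi
bit score of the family's own training sequences — i.e. "would we
re-detect the training members, with a 10% margin" — and is logged and
overridable per family; a global fixed cutoff can be used instead. A
genome's feature vector is the vector of presence calls in library
order; a metagenome is scored identically on its pooled protein set,
with the documented caveat that the features of a pooled assembly may
come from different community members.

## Classification stage (random forest)

The forest is implemented from scratch (bagged Gini trees on binary
features) because its bookkeeping is part of the method's surface: per
tree bootstrap and out-of-bag (OOB) index sets, per-sample OOB vote
fractions, OOB error, and Gini importances must be exactly
reconstructable. Defaults follow the conventional classification forest:
500 trees, `mtry = floor(sqrt(p))`, sampling with replacement, trees
grown unpruned to purity or exhaustion of informative splits. Gini ties
break toward the lowest feature index and leaf ties toward the larger
training class, making training bit-reproducible under a fixed seed. The
implementation is cross-checked in the test suite against the reference
`randomForest` package on shared synthetic data.

The **SC score** of a subject is its vote fraction — the fraction of
trees classifying it positive — with resolution `1/n_trees`. Training
strains are scored by their OOB vote fraction, the unbiased training-set
analogue.

Training proceeds in two rounds. After round one, labeled-negative
strains whose OOB score strictly exceeds 0.6 are *flagged* for operator
review; they are never relabeled automatically, mirroring the practice
of re-testing such strains in the laboratory before correcting their
phenotype. Confirmed corrections are passed back as a relabel list, and
round two retrains on the corrected labels (an empty relabel list leaves
the round-one model in place, bit-identical under the same seed).

**Score bands** are derived from the final training scores: the upper
limit is the maximum score among labeled negatives (above it, every
training strain is positive), and the lower limit is the minimum score
among gram-negative labeled positives (below it, no gram-negative
training strain is positive). The reference values from the published
training collection are 0.68 and 0.39. Band comparisons are strict
(`> upper`, `< lower`; equality is putative). If the training scores
separate completely the two limits cross; the bands then collapse to a
single cut at their midpoint and are flagged degenerate. Missing gram
annotations are treated as gram-negative with a warning (gram-positive
SC appears to use different genes and is explicitly not modeled; the
single gram-positive positive control scores low, and the validation
table's seven gram-positive strains all score at or below 0.26).

Validation metrics: rank-based (Mann–Whitney) ROC AUC with half-credit
for ties, checked against an all-pairs concordance oracle; and a
stratified 2/3–1/3 holdout (largest-remainder allocation per class, so
117 samples split 78/39) with redrawing when a class would be absent
from either side.

## Ecology survey statistics

Per-biome summaries (n, median, max, any score above the high cutoff)
pool biomes with fewer than three datasets into "Others". The
bimodality cutoff between low- and high-scoring assemblies is found as
the density minimum between the two highest modes of a Gaussian kernel
estimate (Silverman bandwidth) on [0, 1]; a mode must reach 10% of the
maximum density and be separated by a dip of at least 10% relative depth,
otherwise the distribution is declared unimodal and no cutoff is
invented. Score–depth association uses the tie-corrected Spearman
coefficient (Pearson on mid-ranks) with the t-approximation p-value on
n − 2 degrees of freedom, adequate at survey sample sizes (n ≈ 450); an
exact permutation p-value is available for very small n (default up to
7 — full enumeration of n! permutations). Depth records without numeric
depth are dropped before correlation. The moving average is centered
with shrinking edge windows (default window 20 points), and per-species
score ranges report the mean of the five smallest and five largest
scores for species with at least ten genomes.

## Optics

Angle-resolved reflectance at fixed incidence (−45° by default) is
stored as a wavelength × detection-angle intensity grid with a specular
mask (the mirror band around `-theta_in`, where the measurement
saturates, is excluded rather than rescaled). Spots are local intensity
maxima along wavelength exceeding `prominence` × the median unmasked
intensity. The reflection-grating relation `m·λ = d·(sin θ_in + sin
θ_out)` (angles from the surface normal, diffracted angles positive on
the opposite side) is fitted by least squares through the origin,
`d = Σxy/Σx²`; with several allowed orders each spot is assigned the
order minimizing its residual around an initial median estimate, then
the fit is iterated. Noise-free synthetic spots are recovered exactly;
1% wavelength noise on 25 spots keeps `d` within 1%. Spots at
`sin θ_in + sin θ_out ≈ 0` carry no information about `d` and make the
fit unidentifiable on their own. The published lattice constants
(490/395/440 nm for the three reference strains) are used as generator
inputs in recovery exercises, since the raw goniometer data are not
redistributed.

## Synthetic data: what it emulates, and what it does not

All tests run on seeded generators that emit exactly the formats the
pipeline consumes. The reference configuration (`sim_config()`) is 120
strains, 200 ortholog families, 20 causal families, phenotype positive
at ≥ 10 causal families with 5% label noise, protein length 120 at 5%
per-site divergence, and a 450-record survey targeting a score–depth
Spearman correlation of 0.41.

* The strain tree is a Yule topology with i.i.d. exponential branch
  lengths (mean 0.2), leaves `s1…sn`.
* Background families evolve independently as a two-state Markov chain
  along the branches (symmetric gain/loss 0.5/0.5, stationary presence
  0.5 — the intermediate frequency at which a family is informative).
* The causal families form a co-evolving pathway block: one latent
  pathway state evolves along the tree (rates 0.3/0.3) and each causal
  family copies it with an independent 10% per-tip deviation. This is
  deliberate: phenotype-determining gene sets appear as co-present
  blocks across the positive clade in real pan-genome matrices, and a
  threshold-on-count phenotype over *independently* evolving families
  would carry almost no per-family marginal association — not the
  structure any presence/absence classifier assumes.
* Family sequences are ungapped copies of a random ancestor with i.i.d.
  substitutions (substituted residue uniform over all 20 amino acids, so
  two members agree at a site with probability `(1 − 19r/20)² +
  19(r/20)²`). No indels, no codon structure, no rate heterogeneity:
  enough to exercise alignment-to-HMM-to-presence-call fidelity, not a
  protein evolution model.
* Survey records couple depth and score through a Gaussian copula with
  Pearson parameter `2 sin(π ρ/6)`, hitting a Spearman target without
  distorting the marginals.
* Goniometer spectra are Gaussian ridges on the grating-equation curves
  for orders ±1 plus optional noise, with the specular band marked.

Passing tests on these data therefore demonstrate internal correctness
and end-to-end recoverability (feature selection finds the causal block;
the forest separates simulated phenotypes with held-out AUC above 0.9),
not performance on real genomes, where ortholog inference error,
annotation bias, taxonomic structure, and non-genetic phenotype
determinants all intervene.

## Numerical and design choices

* Fisher's two-sided p uses probability ordering with a `1 + 1e-7`
  relative tolerance when comparing table probabilities, the usual guard
  against floating-point misclassification of equal-probability tables.
* Bonferroni multiplier = matrix width (overridable), as discussed
  above; no FDR procedures are offered because the selection rule is a
  union of fixed-level streams.
* The permutation estimator's tie handling is a documented choice, see
  the association section.
* Problem sizes in the test and acceptance runs (e.g. 99–199
  permutations per family, five generator seeds for median statistics,
  500-tree forests) are the package's reference sizes; they keep the
  full suite within a desk-scale run while leaving every comparison
  comfortably powered.
* The published 199-ortholog × 117-strain training matrix is distributed
  only as PDF supplementary material, so the published OOB errors (6.8%
  initial; 3% after the five operator-confirmed relabels) are quoted as
  reference constants and exercised structurally (two-round training,
  discordant-negative flagging) on synthetic data rather than recomputed.
* Gene calling is outside the package boundary: the native input is
  protein FASTA; genome nucleotide input is expected to pass through an
  external gene caller first.

## Known limitations

* The profile HMMs are uncalibrated (no E-values); presence thresholds
  are relative to training-sequence scores, which is robust for
  well-conserved families and conservative for very divergent ones.
* Metagenome scores treat the pooled assembly as one genome; a high
  score indicates the community carries the repertoire, not that any
  single member does.
* Gram-positive prediction is explicitly unsupported.
* The valley detector assumes at most two substantive modes; more
  complex mixtures return the gap between the two strongest.
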