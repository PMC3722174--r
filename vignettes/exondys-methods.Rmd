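---
title: "Methods: probe-level exon-array analysis of tissue-specific dysregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-level exon-array analysis of tissue-specific dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`exondys` implements an integrated analysis of probe-level exon microarray
data aimed at a specific biological question: how mitochondrial
respiratory-chain (RC) disease reshapes the transcriptome differently in
different tissues — not only which genes move, but what happens inside
genes (UTRs, individual exons, antisense transcription), what that implies
about mRNA stability (AU-rich elements, positional degradation), and which
upstream regulators (transcription-factor target sets, co-expression with a
focal regulator) organize the response. Because the interesting claims are
about sub-gene structure, the package starts from probe intensities rather
than from a summarized expression matrix, and it ships a synthetic-data
generator that plants every effect class the pipeline is designed to
detect, so each stage can be validated against a known truth.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the places where the design was
genuinely open and we had to pick.

# Normalization

`lowess_normalize()` removes intensity-dependent array bias. The reference
is a pseudo-array: the per-probe median across arrays. Each array's log2
ratio against the reference is smoothed by `stats::lowess()` (span
`lowess_span`, default 0.3) as a function of the reference level, and the
fitted curve is subtracted. Two details matter:

* The fitted biases are centered per probe across arrays before
  subtraction. Only array-*relative* bias is removed, so the reference
  pseudo-array is literally unchanged by normalization. Without centering,
  a common component in the fits (e.g. mean-median skew in bright strata)
  walks the whole data set downward on repeated application.
* Normalization is approximately idempotent: a second pass changes a
  typical probe by less than 1e-3 log2 units once the lowess window holds
  enough probes (the leftover is the O(sigma/sqrt(window)) part of the
  noise any smoother retains). On very small arrays the leftover is
  proportionally larger; this is a property of smoothing, not a defect of
  the data.

A caveat that matters for interpreting group differences: normalization
forces each array's typical ratio-to-reference to zero at every intensity,
so if a disease genuinely shifts a sizable fraction of the transcriptome in
one direction, part of that shift is absorbed as "bias". Our recovery
analyses on synthetic data therefore run on unnormalized intensities — the
generator plants no array-level bias, so normalization would be a no-op in
expectation but would attenuate the planted global shifts exactly as it
would attenuate a real global response. The full pipeline keeps the
normalization stage, as any real analysis must.

# Probe summarization: the multiplicative (Li-Wong) model

Each probeset is summarized by the model `PM_ij = theta_j * phi_i + eps`,
where `theta_j` is the per-sample expression index and `phi_i` the probe
affinity. `liwong_summarize()` fits it by alternating least squares:
update `theta` with `phi` fixed, then `phi` with `theta` fixed, rescale so
`sum(phi^2)` equals the number of probes (the identifiability convention;
the scale has to be fixed somewhere and this one leaves `theta` on the
intensity scale), and repeat until the largest relative change in `theta`
drops below `liwong_tol` (1e-6) or `liwong_max_iter` (50) alternations.
The objective (sum of squared residuals over unflagged cells) is
non-increasing across iterations — this is asserted in the test suite.

Outlier handling is deliberately *not* based on the least-squares
residuals: a rank-1 least-squares fit smears a grossly corrupted cell over
the whole probeset, so its own residuals cannot isolate it (we verified
this numerically with a 10x-corrupted cell). Instead, cells are flagged
against a robust rank-1 reference — a median polish of the log2
intensities — when their robust residual exceeds `outlier_sd` (3) times
the MAD-based scale. Probes with a majority of flagged cells are dropped
whole, and the fit is redone once with flagged cells excluded. We
implement the reduced multiplicative model only; the full dChip iterative
outlier schedule is out of scope. Single-probe probesets pass through
unchanged (`theta` = probe row, `phi` = 1).

Gene-level expression repeats the same fit one level up: a gene's sense
probesets' `theta` vectors play the probe role. Antisense probesets are
excluded from gene summaries.

# Effective probesets

Antisense analyses are restricted to probesets whose signal clears array
background. The rule in `detect_effective_probesets()`: a probeset is
effective when its log2 expression exceeds the background mean by at least
`effective_sd` (2) background SDs in at least `effective_fraction` (50%)
of samples. Background is estimated per sample from a designated reference
set — the generator emits dedicated background probesets; on real data the
lowest-decile antisense probesets serve. The cross-probeset background SD
includes probe-affinity scatter, which is the dominant term; this is why a
rare high-affinity background probeset can clear its own group's
threshold.

# Differential expression: SAM

`sam_statistic()` computes `d = (mean_a - mean_b) / (s + s0)` with the
pooled two-group standard error `s`; at `s0 = 0` this is exactly the
pooled-variance t statistic. The fudge factor `s0` stabilizes low-variance
features: `choose_s0()` evaluates the percentiles {0, 5, ..., 100} of the
`s` distribution and keeps the candidate minimizing the coefficient of
variation of window-wise MADs of `d` (features windowed by `s` quantiles),
ties to the smallest; the procedure is deterministic and order-invariant.

`sam_test()` permutes group labels: exhaustively over all `choose(n, na)`
group assignments when that count is at most 10,000 (e.g. all 70 of a
4-vs-4 design), otherwise `sam_n_perm` random assignments. Per-feature
p-values count assignments with `|d_perm| >= |d_obs|` (exact count over
the enumeration; +1-corrected in sampled mode). A pooled mode
(`pool = TRUE`) compares each feature against the permutation null pooled
across features — the classic SAM reference distribution, under which p is
monotone in `|d|` across features; the per-feature default is the exact
formulation. The FDR at each feature's own cut is the SAM median ratio,
`median_perm #{|d_perm| >= c} / #{|d_obs| >= c}`, capped at 1 and without
pi0 correction. Signed significance scores are
`sign(delta) * (-log10 p)` (a bounded `sign(delta) * (1 - p)` variant is
available).

# Sub-gene events

Probesets are grouped into 5'-UTR, exon, 3'-UTR and antisense regions of
their gene. Within each gene region the probeset with the smallest raw p
represents the region (lexicographic tie-break) and is Bonferroni-adjusted
by the number of probesets in that region — the correction is scoped to
the gene region, not the genome, because the selection happened within the
region. An alternative expression event requires `p_adj < 0.05` and either
(a) direction opposite to the gene-level change, or (b) a region p-value
substantially smaller than the gene's. "Substantially smaller" is not
well defined by a p-value alone; we concretize it as
`gene_p / p_raw >= ratio_k` with `ratio_k = 10` by default, exposed in the
configuration. When both arms fire, the opposite-direction reason is
recorded. Region-level summary tables count significantly up- and
down-regulated genes per region and tissue, with antisense rows restricted
to effective probesets.

Sense-antisense concordance correlates baseline abundance and
disease-control differences across sense/antisense pairs; pairs in which
both sides change significantly in opposite directions are reported as
candidate functional antisense transcripts.

# ARE classes and UTR features

AU-rich elements are classified on a five-step ladder anchored at the
AUUUA core: `mer5` (the bare core) through `mer13`
(`WWWWAUUUAWWWW`, W = A/U), assigning each 3'-UTR the longest motif class
with at least one match; sequences are DNA (U read as T) and `N` never
matches. The ladder is nested by construction, so classes are mutually
exclusive by "most complex present". `are_group_change_test()` compares
each class's mean percent 3'-UTR change against the no-ARE class with a
Welch test.

Positional profiles place each UTR probe at its relative transcript
position (0 = 5' end; minus-strand coordinates are flipped), adjust probe
log2 intensity by subtracting the adjacent coding exon of the same gene
(first exon for 5'-UTRs, last for 3'-UTRs; subtraction on the log2 scale
is the simplest adjustment consistent with a multiplicative model), bin
positions into 1% intervals, and average per disease group. The
degradation gradient is the least-squares slope of the lowess-smoothed
disease-minus-control curve per unit relative position. Empty bins are
missing, never zero.

The 5'-UTR baseline association relates each gene's control-group 5'-UTR
level (relative to its whole-gene expression, so abundance and affinity
scale cancel) to its 5'-UTR percent change, using Spearman correlation and
a lowess trend. TOP motifs are called when the sequence starts with C
followed by a run of at least 4 pyrimidines beginning within the first 15
bases; both parameters are arguments.

# Regulators

PWM scanning scores a window as the sum of per-position base
probabilities, min-max scaled per matrix so a similarity of 1 is the best
possible window and the 95% threshold is comparable across motifs
(log-odds scoring is available behind a flag and scaled the same way).
Matrices get a 0.01 pseudocount per cell before column normalization so no
single base can veto a window. Both strands are scanned — a minus-strand
match is found by scanning the reverse-complemented matrix — and reported
in forward coordinates. Target sets contain every gene with at least one
match in the scoped region (promoter or intron); the PWM library is an
input file, one 4 x L block per factor.

Target-set activity is a Welch test of target vs non-target percent
changes; the same operation serves arbitrary gene lists. The interaction
test partitions genes by joint membership in two target sets and contrasts
the both-sites group against each single-site group. The GSEA-style
enrichment score is the extremum of a running sum with
`|stat|^weight`-normalized increments on hits and `1/(N - N_hits)`
decrements on misses (so the sum always ends at zero); significance uses
gene-label permutation — at the sample sizes this pipeline targets,
phenotype permutation has too few distinct relabelings to resolve small
p-values, so set-label permutation (exhaustive when feasible) is the
default. Over-representation of a category in a study subset is the
hypergeometric upper tail.

# Cross-tissue analysis

Genes significant in both tissues fall into four signed quadrants; genes
significant in one tissue into four single-tissue subsets. The inverse
fraction — both-significant genes whose directions disagree — summarizes
how opposed the tissue responses are. The global comparison correlates
signed significance scores across tissues (Pearson).

Correlations between gene pairs are combined across the four tissue x
disease sample groups by DerSimonian-Laird random-effects meta-analysis on
the Fisher-z scale with `v_k = 1/(n_k - 3)` (the standard variance for a
transformed correlation): fixed weights give the heterogeneity statistic
Q, the DL moment estimator gives `tau2`, random-effects weights
`1/(v_k + tau2)` give the combined z, and a normal approximation gives its
p. Correlations of exactly +-1 are clamped at 0.999999 with a warning
before the transform. A focal gene's relationship to a gene set is the
one-sample t-test of the per-member combined correlations against zero.
The correlation screen reports genes positively and significantly
correlated with a focal gene in the disease samples of *both* tissues
(per-tissue p < 0.05 and r > 0 by default; Spearman available).

# The synthetic-data generator

`generator_config()` fixes the study conditions; `simulate_study()` draws
gene models, sequences, a PWM library and probe intensities, plus a truth
table. Defaults, chosen once as a realistic desk-scale analogue of a
two-tissue disease study:

* Two tissues (muscle, fibroblast) x two states (RC, control), 8 arrays
  per cell — the balanced two-group size at which permutation tests are
  exercised throughout the package.
* Each gene: 200 bp 5'-UTR, two 300 bp coding exons flanking a 500 bp
  intron, 800 bp 3'-UTR, a 1 kb promoter; one probeset per segment with 4
  probes (20 on the 3'-UTR so positional profiles have resolution within a
  single probeset); segment order reversed on minus-strand genes.
* Intensity model: `I = theta * phi * 2^eps`, with per-gene baseline
  log2 abundance N(9, 0.8), log-normal probe affinities (sdlog 0.4), and
  log2 noise SD 0.1 — the multiplicative factorization the summarization
  stage assumes, which keeps intensities positive. Background probesets
  sit at log2 = 4, roughly three log2 units under the dimmest expressed
  features, a typical floor for this platform class.
* Planted effect classes are disjoint by design so each downstream
  statistic can be validated in isolation: 25% of genes carry a gene-level
  fold change (|log2 FC| uniform in 0.4–1.2, 60% sign-flipped between the
  tissues, echoing the inverse-dysregulation phenomenon); 30% carry an ARE
  (split over the five classes) with 3'-UTR shifts of +8% (mer5) or +16%
  (extended motifs) in muscle, sign-flipped in fibroblasts; 10% carry a
  positional 3'-UTR gradient (-0.5 log2 per unit position in muscle,
  +0.25 in fibroblasts); 10% carry a 5'-UTR-only override (+-0.6 log2),
  the planted alternative events; a focal gene plus 30-gene positively and
  negatively coupled sets share a latent per-sample factor (log2 SD 0.25)
  for the correlation analyses.
* Half the genes carry an antisense probeset at their 5'-UTR: half of
  those idle at background (the filter's job is to reject them), the rest
  mirror the sense 5'-UTR signal two log2 units lower, with configurable
  fractions of sign-opposite and independent antisense.
* Sequences are planted exactly: 3'-UTRs are scrubbed of accidental AUUUA
  cores before the class motif is inserted with non-W borders, promoters
  and introns are scrubbed of accidental PWM consensus hits before target
  sites are planted, and TOP motifs are controlled at the 5'-UTR start. A
  similarity of 0.95 under the generated PWMs requires an exact consensus
  match, which is what makes truth-table equality of target sets a fair
  test.

Everything is deterministic given the seed; the global seed fans out into
fixed per-stage seeds so stages can be rerun in isolation.

What the generator does *not* emulate: batch structure, spatial chip
artifacts, scanner saturation, cross-hybridization, probe-sequence
composition effects, correlated noise between neighboring probes, and the
genuine annotation uncertainty of real probe-to-gene mappings. Passing
recovery tests on these data therefore shows the statistics do what they
claim under the stated model — it does not certify performance on any
particular real data set.

# Validation scales

The test-suite and acceptance-script scenarios use sizes picked so each
check is informative: oracle equivalences run on tiny enumerable problems
(4-vs-4 designs, 10-gene ranked lists); calibration uses 1,000 null
features or TF draws; recovery scenarios use 100–1,500 genes — e.g. 200
genes per ARE class, so a class mean has a standard error well under the
2-percentage-point tolerance, and 1,200 genes for the cross-tissue
correlation, where the planted 60/40 inverse/concordant mixture puts the
signed-score correlation near -0.35. Recovery checks read the generator's
truth table; nothing in the package consults it.

# Known limitations

* The Li-Wong implementation is the reduced multiplicative model with a
  single robust outlier pass, not the full dChip schedule.
* The SAM FDR is the plain median ratio without pi0 estimation, so it is
  conservative when many features are truly changed.
* The alternative-event "substantially smaller p" arm depends on
  `ratio_k`; there is no external standard for this constant, and event
  lists should be read with that in mind.
* Lowess normalization absorbs part of any genuinely one-sided global
  expression shift; comparisons of class means against an internal
  baseline class (as in the ARE ladder) are robust to this, absolute
  changes are not.
* PWM similarity is a min-max scaled probability sum; thresholds do not
  transfer between this scale and information-content-based scores.
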