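---
title: "Methods: the ceRNA screen, its statistics, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ceRNA screen, its statistics, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernascreen)
```

`cernascreen` re-implements, as a tested and reusable pipeline, the
analysis chain used in stage-resolved bulk RNA-seq studies of ceRNA
(competing endogenous RNA) regulation: novel-lncRNA filtering and
positional classification, expression QC, fixed-dispersion
negative-binomial differential expression, and the three-step
correlation/hypergeometric ceRNA screen, together with the statistics
used for bench validation. This vignette records the model assumptions,
the defaults and why they were chosen, and the numerical decisions that
are not visible from function signatures.

## The screen

Inputs are integer count matrices for lncRNA, mRNA, and miRNA over the
same samples (four developmental stages, at least two replicates each),
plus miRNA→target prediction tables carrying a TargetScan-style score
(higher = more confident) and a miRanda-style binding energy (more
negative = stronger).

1. **Target filtering.** A (miRNA, RNA) interaction is usable iff it
   appears in *both* predictors' outputs and passes both thresholds,
   score ≥ 50 and energy ≤ −10 (inclusive, matching the published
   wording "threshold set at 50" / "set at −10").
2. **Edge filter.** For each usable interaction, the Spearman rank
   correlation (Pearson on mid-ranks; ties receive average ranks) of the
   two expression profiles across the 12 samples must satisfy
   ρ ≤ −0.7 — a miRNA should suppress its targets.
3. **Pair filter.** RNAs competing for a shared miRNA should co-vary:
   candidate pairs (unordered pairs sharing ≥ 1 retained miRNA) must
   have Pearson r ≥ 0.9. The asymmetry — Spearman for miRNA–target,
   Pearson for pair co-expression — follows the published procedure as
   printed; we implement it exactly rather than harmonizing it.
4. **Shared-miRNA test.** With `K` and `n` the *retained* (post-edge
   filter) miRNA sets of the two RNAs and `N` the miRNA universe, the
   overlap `k` is tested with the hypergeometric survivor function
   `p = P(X >= k)`; pairs with raw `p < 0.05` survive. The source
   procedure does not define its universe; we default to
   `universe_mode = "filtered"` (distinct miRNAs with ≥ 1 retained
   edge), with `"all_expressed"` and `"all_predicted"` as alternatives.
   No multiplicity correction is applied across pairs by default (the
   published rule is a raw p cut); `pair_fdr = TRUE` adds BH.

Ambiguities resolved: whether *every* shared miRNA must individually
pass the edge filter for a pair, or at least one, is not stated in the
procedure we follow; the default requires each retained edge to pass
individually and pairs to share ≥ 1 retained miRNA, and
`all_shared = TRUE` additionally demands that every *predicted* shared
miRNA is retained for both members. Pairs are reported lncRNA–mRNA by
default (`pair_types = "all"` also yields lncRNA–lncRNA and mRNA–mRNA).

**DE gating.** The published network is built from differentially
expressed molecules, so by default only features significant in at least
one stage comparison enter the screen (`de_gate = FALSE` disables).

**Connectivity** of an RNA node is the number of distinct miRNAs with
retained targeting edges to it. Ranking ties are broken
lexicographically by id so results are deterministic; the Sankey table
lists every lncRNA → miRNA → mRNA two-edge path among the top three
lncRNAs and top six mRNAs (both depths configurable).

## Differential expression

Both the lncRNA/mRNA and the miRNA tests use one engine: an exact
conditional test on replicate sums under a negative binomial with fixed
dispersion φ (`Var = μ + φμ²`), the parameterization under which the
generator's φ and the test's φ mean the same thing. The published
analysis used DESeq2 for lncRNA and edgeR with dispersion 0.01 for
miRNA; re-implementing two complete estimation frameworks is out of
scope, so the package standardizes on the fixed-dispersion exact test
with median-of-ratios size factors and exposes φ per matrix
(`phi`, `phi_mirna`, both defaulting to 0.01). This is a documented
divergence in tooling, not in the decision rule.

Mechanics: counts are scaled to a common effective library size using
size factors normalized to geometric mean 1, and rounded. Conditional on
a gene's total `T`, the group-A sum follows the distribution induced by
two NB group sums (dispersion φ/n per group); because both groups share
the success probability, this conditional is a negative
hypergeometric and does not depend on the unknown mean — the property
the enumeration oracle in the test suite exploits through an independent
closed form. The two-sided p-value sums all outcomes whose conditional
probability does not exceed the observed one ("small probability mass"
rule, the convention used by exact-test practice), with a relative tie
tolerance of 1e-8 in log space, floored at the observed outcome's own
mass so p ∈ (0, 1]. All-zero genes return p = 1 by convention. The pmf
is evaluated over the full 0..T support in log space; at the package's
default expression levels this costs a few thousand `dnbinom` calls per
gene and keeps the implementation exactly equal to enumeration rather
than approximately so.

Log2 fold changes use size-factor-normalized group means with a
pseudocount of 1 (finite for all-zero groups; the source is silent).
Significance is FDR < 0.05 (BH within each comparison) and
|log2FC| > 1, applied to miRNAs as well since no separate miRNA
thresholds are printed. Set logic over the six comparisons (union,
intersection, Venn region counts) operates on the membership matrix of
features significant anywhere; both the union-of-threshold and
nominal-significance views can be derived from the tidy DE table without
asserting either matches any external tally.

## Normalization and QC

FPKM is `count x 1e9 / (length_bp x library_size)` with library sizes
defaulting to column sums. Size factors are classic median-of-ratios:
features containing any zero are excluded from the geometric-mean
reference; `pseudo_reference = TRUE` switches to geometric means over
positive counts for sparse matrices. PCA and sample correlation default
to `log2(x + 1)`-transformed values (the source does not state its
transform; the raw option is exposed). Zero-variance samples yield `NA`
correlation rows with a warning, never a silent 0.

## The positional classifier

Novel transcripts are retained iff summed exon length ≥ 200 bp, ≥ 2
exons, and all three coding-potential predictors call them non-coding
(intersection rule). Retained lncRNAs are classified against coding
transcripts on the same chromosome in a fixed precedence order —
intronic (fully inside one intron, either strand), antisense (≥
`min_overlap` bp exon-level overlap, opposite strand),
sense-overlapping (≥ `min_overlap` bp span-level overlap, same strand),
bidirectional (no overlap, opposite strand, divergent orientation, TSSs
within `bidirectional_window`), else intergenic. Containment-first
precedence makes the five categories a partition; the source names the
categories but not the tie-breaks. Exon-level semantics for antisense
(the biologically meaningful overlap) versus span-level for
sense-overlapping mirrors the category names themselves. Defaults
`bidirectional_window = 1000` bp and `min_overlap = 1` bp are exposed
because the source states neither. Classification uses coding
*transcripts*, not merged gene spans — simpler and deterministic;
merged-span mode is a non-goal. Note one asymmetry inherent in the
definitions: flipping every strand maps a divergent promoter pair to a
convergent one, so bidirectional calls legitimately fall back to
intergenic under a global strand flip, while antisense, intronic and
sense-overlapping membership is flip-invariant (the property suite
checks exactly this).

## The synthetic study design

The generator emulates the study conditions end to end so the screen can
be validated against a planted truth:

* **Design**: 4 stages × 3 replicates (labels `120dPG, 1mo, 3mo, 10mo`),
  NB counts with φ = 0.01.
* **Annotation**: coding genes are three-exon models on the `+` strand
  of one synthetic chromosome, one per disjoint 50 kb slot; novel
  two-exon transcripts are placed with geometry that *forces* their
  assigned class. Class counts are apportioned by largest-remainder
  rounding of the configured proportions, so a given `n` always yields
  the same tally. The default proportions are published survey values
  (intergenic 52.4%, antisense 13.4%, sense-overlapping 7.2%, intronic
  11.6%, bidirectional 10.22%) — these sum to 94.82% in the source,
  with the remainder unexplained; since the configuration requires a
  full partition, the package renormalizes them to sum to one rather
  than inventing an "other" class. Placing all coding genes on `+`
  keeps the layout simple; minus-strand coverage of the classifier comes
  from the strand-flip property test.
* **Planted triplets** (default 20): each planted miRNA follows a
  strictly monotone geometric ramp across the four stage means with
  total span `fold_span = 8` and geometric mean 1 (so the baseline sets
  the overall level); the partner lncRNA and mRNA follow the reversed
  ramp. Monotone ramps are the simplest trajectories for which
  noise-free Spearman is exactly ±1 and noise-free Pearson between
  partners is exactly +1, which the tests verify in the
  `noise_model = "means"` limit. Each triplet shares
  `mirnas_per_triplet = 2` miRNAs: with a single shared miRNA the
  shared-miRNA test gives `p = 1/N` for k = K = n = 1, which equals
  0.05 exactly at N = 20 retained miRNAs — a boundary artifact under
  the strict `p < 0.05` rule — so two shared regulators is the minimal
  planted structure the published thresholds can detect.
* **Decoys** (default 40 pairs): non-planted lncRNA–mRNA pairs that
  share a passing miRNA in the target tables but have stage-constant,
  independent expression, so only the expression screen can reject
  them; a further `decoy_fail_fraction` of records fails exactly one
  prediction threshold or appears in a single predictor's table, to
  exercise the intersection rule.
* **Free amplitudes**: the source reports no expression magnitudes or
  fold changes for its axis genes, so baselines are drawn log-uniformly
  on `exp([log 50, log 500])` — moderate bulk RNA-seq expression — and
  `fold_span = 8` with multiplicative log-normal sample noise
  (`noise_sd = 0.05`) represents a strong developmental trajectory.
  These were fixed once as realistic values, not calibrated to any
  reported figure.
* **Reproducibility**: every generator derives per-purpose sub-streams
  deterministically from the master seed, so adding features does not
  reshuffle existing ones, and identical seed + config gives
  byte-identical outputs.

What the generator does *not* emulate: read-level noise and alignment
artifacts, splice-graph complexity, sequence-level seed matching,
batch/library-preparation effects, and correlated non-planted structure
(co-regulated modules). Passing tests therefore demonstrate that the
implementation applies the published decision rules correctly and can
recover a clean planted signal — not that the thresholds themselves are
well-calibrated for real tissue data.

## Wet-lab statistics

`ddct()` averages technical replicates at the Ct level (common practice;
the source is silent), computes `dCt = Ct_target − Ct_reference` per
sample, centres on the calibrator-group mean, and returns `2^−ddCt`;
the calibrator's geometric-mean fold is exactly 1 by construction.
`luciferase_relative()` is channel-role-agnostic: the published text
says "ratio of firefly to Renilla", but the construct described places
the reporter insert on the Renilla gene (psiCHECK-2-style design), so
inputs name `reporter` and `normalizer` explicitly instead of guessing.
`one_way_anova()` is the classical F test with the star convention
(*** p < 0.001, ** p < 0.01, * p < 0.05) and returns `F = 0, p = 1, ns`
when all values are identical.

## Numerical choices

* Hypergeometric tail sums run in log space (`lchoose` + log-sum-exp);
  a direct `choose()` path is retained and the suite checks agreement
  to 1e-10 up to N = 500 and exact agreement with exhaustive draw
  enumeration for small universes.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` after
  validation; the suite checks it against the brute-force min-over-tail
  definition.
* Internal coordinates are 0-based half-open; GTF is the only 1-based
  inclusive surface, converted at the boundary. Readers reject rather
  than coerce (line-numbered parse errors, no silent NA→0), and ids
  must match `[A-Za-z0-9._-]+` because assembly-style ids contain dots.
* Correlations: Spearman uses mid-ranks for ties; no correlation
  p-values are computed (the screen thresholds coefficients only).
  Constant profiles are skipped with a warning.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: 1000 transcripts / 200 coding genes for the classifier round
trip; 2000 genes at 3-vs-3 for the null calibration of the exact test;
the default screen at 300 lncRNA × 500 mRNA × 100 miRNA over 12 samples
with 20 planted triplets and 40 decoys; enumeration oracles up to
universe size 12 (exhaustive) and 500 (dual-path). These sizes give
stable statistics while keeping a full run in seconds.

## Limitations

The package screens *static* co-expression: it cannot distinguish
direct sponging from co-regulation, does not model condition-specific
ceRNA activity, and inherits whatever biases the upstream target
predictions carry. The exact test's fixed dispersion is a modelling
choice, not an estimate; for real data a tagwise-dispersion framework
is preferable. GO/KEGG term databases are inputs, not bundled.
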