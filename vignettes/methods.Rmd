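---
title: "Models and methods behind psychspeech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psychspeech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psychspeech)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The scientific question

Cortical function is organized along a hierarchy from primary sensorimotor
(unimodal) to association (transmodal) cortex. Diffusion-map embedding of
functional-connectivity (FC) affinity matrices expresses this hierarchy as
a small number of continuous "gradients": the principal gradient (G1) runs
from sensorimotor to default-mode cortex, the second (G2) separates visual
from somatomotor cortex. In first-episode psychosis this hierarchy is
*compressed* — the functional distance between the visual network (VN) and
the default-mode network (DMN) shrinks — and the structure of spontaneous
speech changes in parallel: semantic graphs become more "concentrated"
(higher closeness centrality and global efficiency, lower small-worldness)
and syntax shifts toward more but shorter predicative structures. The
package implements each analysis stage and a synthetic cohort in which
these group effects are planted at the signal level and must be recovered
by the pipeline itself.

## Gradient extraction

For a time-by-ROI matrix the FC matrix is the Pearson correlation of every
ROI pair, Fisher z-transformed, with `|r|` clipped at `1 - 1e-6` so that
perfectly collinear pairs stay finite. Per row, negative entries are
zeroed and only the strongest `ceiling(0.10 * (R-1))` entries survive
(ties broken toward the lower column index, for reproducibility). Affinity
between two sparsified profiles is the normalized angle
`1 - acos(cos)/pi`, a cosine variant bounded in [0, 1]; plain rescaled
cosine is available as an option because "normalized cosine similarity" is
ambiguous in the literature.

Diffusion embedding density-normalizes the affinity with `alpha = 0.5`,
row-normalizes to a Markov matrix, and eigendecomposes through the
symmetric conjugate for numerical stability. The trivial stationary
eigenvector is dropped; each retained eigenvector is unit-normalized,
sign-fixed (largest-magnitude loading positive) and scaled by its
eigenvalue — the diffusion-time-0 convention. Variance explained is each
eigenvalue over the sum of all positive non-trivial eigenvalues, so it is
non-increasing and sums to at most 1. A disconnected affinity graph is
refused with advice to densify, rather than silently producing block-wise
arbitrary coordinates.

Subjects are aligned to a template by orthogonal Procrustes rotation
(rotation + reflection, no scaling or translation), which preserves every
within-subject pairwise ROI distance. Two template choices were examined:

* a pooled all-subject template, and
* per-group templates, each group's subjects aligned to their own mean-FC
  solution.

The package's cohort-level functions use **per-group templates**. With a
pooled template the 45-parameter rotation fits every subject toward the
common solution so strongly that genuine group differences in dispersion
are absorbed into the rotation; with per-group templates (the convention
the method descends from) the planted compression is recovered in
essentially every replicate. Because eigenvector orientation is arbitrary
per template, group comparisons use the magnitude of the group-mean
dispersion.

Dispersion between networks A and B on gradient *j* is
`mean(G_j[A]) - mean(G_j[B])` — signed and antisymmetric; an `absolute`
flag gives the magnitude. Within-network dispersion is the sum of squared
distances to the subset centroid on the named gradient. The "semantic
network" analysis simply reruns the identical pipeline on a ROI subset (by
default the DMN + limbic blocks of the synthetic parcellation; with real
data, a user-supplied lookup).

## Stepwise functional connectivity

Edges of the SFC graph are ROI pairs whose correlation (recovered as
`tanh(z)`) is significantly **positive**: two-sided t test with the number
of retained volumes as n, BH-FDR across the unique pairs, `q < 0.001`.
The step-k degree from a seed set is the number of length-k walks, via
iterated vector-matrix products. Walks may revisit nodes — that is what
this method computes; counting simple paths would be computationally
intractable and is not attempted. Maps are min-max normalized per step
(a zero-range step maps to zeros by convention) and subject maps are
multiplied elementwise by their group map. Convergence is declared at the
first step whose spatial correlation with the next exceeds 0.999.

## Semantic speech graphs

Units are content-word types or utterances with embedding vectors; the
similarity is `(cos + 1)/2`. Binarization is proportional: threshold `t`
keeps the `round(t * N(N-1)/2)` strongest pairs (round half away from
zero; ties by pair index), and the selected `t` is the smallest grid value
in 0.05 … 0.80 whose mean degree exceeds `2 ln N` — the sparsest graph on
which small-world structure is measurable. If even 0.80 fails the rule
(unavoidable at N = 4, where `round(0.8 * 6) = 5` edges give mean degree
2.5 < 2 ln 4), the graph is built at 0.80 and flagged. Because selection
is rank-based, any strictly monotone similarity rescaling yields identical
graphs, which makes the particular cosine normalization immaterial; this
is asserted by a test. No small-worldness gate (such as sigma > 1.1) is
applied when accepting graphs.

Closeness centrality uses the reachability-scaled convention (so
disconnected graphs are penalized rather than inflated); global efficiency
counts unreachable pairs as zero; nodes with degree below 2 contribute
zero clustering. Small-worldness divides normalized clustering by
normalized path length, with 20 degree-preserving rewired nulls of
`10 * E` attempted swaps each — the null count is a determinism/runtime
compromise (the quantity stabilizes well below 20 nulls at these graph
sizes) and is configurable. Path length is measured on the largest
component. Narratives with fewer than 4 units contribute to unit counts
but not to graph metrics; metrics are averaged over the usable narratives
with equal weights.

## Syntactic trees

Leaves are part-of-speech preterminals, one per token; surface tokens in
the input bracketing are accepted and dropped. Punctuation tags are
removed (recursively pruning emptied phrases), then trees are
right-factored so no node has more than two children; the introduced
`parent|<...>` intermediates are never counted as phrases. Depth (edges
from root to each leaf, in surface order), its mean, and its approximate
entropy are computed **on the binarized tree** — binarization is part of
the published procedure and the same convention is applied to both groups,
which is what matters for contrasts; a test asserts that right-factoring
never decreases leaf depth. ApEn uses the standard Pincus parameters
m = 2, r = 0.2·SD, Chebyshev distance, self-matches included; a constant
series returns 0, series shorter than m + 2 return missing. NP/VP
matching strips functional annotations at the first `-` or `=` (`NP-SBJ`
counts as NP), and nesting counts proper domination at any depth.
Utterance metrics are averaged within narrative, then across narratives —
the two-stage mean weights narratives equally regardless of utterance
counts — with missing values excluded pairwise at each stage.

## Statistics layer

* Welch t with Satterthwaite df; Cohen's d uses the equal-weight pooled SD
  `sqrt((s1² + s2²)/2)`, the convention that reproduces published effect
  sizes from group summaries.
* 2×2 χ² without continuity correction, effect size
  `C = sqrt(χ²/(χ² + n))` — again the convention matching published
  tables.
* Mann-Whitney U: exact enumeration for small untied samples, otherwise
  the tie-corrected normal approximation.
* Partial Spearman: rank everything, residualize on covariates, Pearson on
  residuals, t-based p on `n - 2 - k` df.
* GLMs by IRLS with Gaussian-identity, Gamma-log, or Tweedie-log
  (variance power fixed at 1.5 — between Poisson and Gamma — since
  nothing in the data pins it; profiling the power is out of scope). Wald
  z per coefficient, BH q across coefficients. Signed dispersion responses
  are shifted by `|min| + eps` before log-link fitting (flag-controlled).
* Goodness of fit: the classical scaled-deviance χ² test with
  Pearson-estimated dispersion is reported by default, but for strongly
  skewed Gamma data this plug-in test is markedly anti-conservative
  (~30% rejection under the truth at shape 2, n = 300). A parametric
  bootstrap option (`gof_method = "bootstrap"`) is provided and is
  calibrated by construction; the calibration suite uses it.
* Mass-univariate parcel models: one OLS per ROI on group + age + sex +
  education through a single QR decomposition, BH-FDR across ROIs,
  significance at q < 0.05.

## The synthetic cohort

The generator's defaults are the study conditions: 29 subjects per group,
100 parcels in 7 networks, 240 volumes, 3 narratives per subject, matched
covariates drawn independently of group.

**Time series.** Each network carries a latent factor; factors are
correlated with a structure that decays along the
unimodal-to-transmodal axis (adjacent networks ≈ 0.31, distant ≈ 0.1),
with the visual-default and somatomotor-default pairs pinned at
`c0 = 0.1` for controls and at `c0 + compression·(c1 − c0)` (`c1 = 0.6`)
and `c0·(1 − 0.8·compression)` for patients. ROIs tile the axis on an
even grid with small jitter and load on all factors with weights decaying
in axis distance (`exp(−d/τ)`, τ = 1, rows unit-normalized), plus iid
noise (SD 0.5). Two design points deserve emphasis:

* *Why smooth loadings?* If every ROI loaded only on its own network
  factor, the top-10% row sparsification would keep exclusively
  within-network entries, profiles of different networks would have
  disjoint support, every between-network affinity would collapse to 0.5
  and no principal gradient would exist. Overlapping neighborhoods along
  the axis are what make the gradient recoverable at all — as in real
  cortex.
* *How compression is planted.* Patient loadings are smoother
  (τ multiplied by `1 + compression`), making connectivity profiles
  across the hierarchy globally more similar — the "smaller range"
  compression — in addition to the factor-correlation changes above. The
  effect lives in the raw signal covariance and is recovered only through
  the full pipeline, so gradient-stage recovery remains a genuine test.
  A variant that moved the axis endpoints together was rejected: it
  altered end-of-chain estimation noise and inverted at subject level.

The generator emulates planted hierarchy geometry, not hemodynamics:
no autocorrelation, motion, physiological confounds, or spatial maps.
Passing recovery tests therefore demonstrates that the pipeline detects
covariance-level compression at realistic n and T — not that it would
survive fMRI artifact structure. One known side effect: because
compression raises cross-hierarchy coupling, patient graphs gain
seed-to-DMN walk counts from *both* visual and somatomotor seeds, whereas
the in-vivo finding dissociates the two (fewer V1→DMN links alongside the
smaller VN-DMN gradient distance). A single compression knob cannot
reproduce that dissociation; the SFC direction test asserts the planted
direction. Similarly, the within-network dispersion of the semantic
subset is not constrained by the planted effect and should not be
interpreted directionally on synthetic data.

**Embeddings.** Cluster centers are uniform on the 50-sphere (50
dimensions rather than 300 for speed; configurable); units are center +
isotropic noise (`spread`), renormalized. Under rank-based thresholding
only the *relative* geometry matters: small spread yields sharply
separated topic cliques (high clustering and small-worldness, low
closeness/efficiency), large spread an undifferentiated rank structure
(the opposite). The patient condition therefore uses larger spread
(0.9 vs 0.15) — blurred topic structure — which reproduces the observed
patient direction: higher closeness centrality and global efficiency,
lower sigma. Note the mean *similarity* is monotone decreasing in spread,
so "tighter semantic space" in the similarity sense corresponds to the
blurred-cluster condition here.

**Trees.** A small probabilistic grammar: `S → NP VP`;
`NP → NP PP` with probability `p_np_embed`, else `(DT) JJ* NN`;
`VP → VB VP` (chaining) with probability `p_vp_chain`, else a clausal
(`VB SBAR`, probability `p_sprime`), transitive (`VB NP`, `p_trans`) or
bare expansion; recursion capped at depth 12 with a minimal terminal
expansion at the cap; `mean_len` loosely controls length via the modifier
rate. Control vs patient grammars differ as
{np_embed .15→.03, vp_chain .05→.75, sprime .12→.02, trans .8→.3}:
patients chain verbs instead of embedding clauses and build small NPs.
These values were fixed at design time from large-sample means so that
all nine published contrast directions (more nodes, deeper trees, lower
depth entropy, fewer/shorter/simpler NPs, more but shorter VPs) hold
simultaneously; the chain-only manipulation suggested by the contrast
alone cannot do this, because chains lengthen VPs while the published
patient VPs are shorter — the clausal-complement asymmetry (controls
embed more clauses) supplies the missing length contrast and is
independently documented in the psychosis literature.

## Problem sizes

The recovery suites use 100 seed replicates at the default cohort scale
(29+29, R = 100, T = 240) for the gradient effect, one narrative-scale
embedding set per condition per replicate, and 400 utterances per grammar
per replicate; calibration uses 1000 null parcels and 200 GLM replicates
at n = 500. These sizes put every Monte-Carlo bound several standard
errors from its threshold while keeping the whole suite in a few minutes.

## Known limitations

* The generator plants effects at the covariance/grammar level only; no
  claim is made about preprocessing robustness.
* The axis-endpoint dissociation seen in vivo between SFC link counts and
  gradient distances is not reproducible from a one-knob compression.
* Tweedie variance power is fixed, not estimated.
* The plug-in deviance GOF is anti-conservative for skewed responses; use
  the bootstrap option when its level matters.
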