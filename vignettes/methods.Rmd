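---
title: "Methods: rhythm, differential expression, and network statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm, differential expression, and network statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind each stage, the default
parameters and why they hold those values, and the known caveats of the
permutation constructions. Code chunks are illustrative and not evaluated at
build time.

## Study design and time axis

Each subject contributes one sample per tissue preparation at a single
circadian time: the time of death (TOD). TOD is converted to Zeitgeber Time
anchored at sunrise on the day of death:

$$\mathrm{zt} = (\mathrm{tod} - \mathrm{sunrise}) \bmod 24,$$

then mapped into $[-6, 18)$ so that late-night deaths sort before dawn
(`tod_to_zt()`). An optional day-length rescaling places sunset at ZT12 for
cohorts spanning seasons; it is off by default because it distorts interval
lengths. Expression is analysed on the log2 scale throughout; linear-scale
input to `load_expression()` is transformed as `log2(x + pseudocount)`.

## Cosinor rhythmicity

For protein $i$ the fixed-period (24 h) cosinor model is

$$y = M + b_1 \cos(2\pi t/24) + b_2 \sin(2\pi t/24) + \varepsilon,$$

with amplitude $A = \sqrt{b_1^2 + b_2^2}$ and peak time
$\hat\varphi = \frac{24}{2\pi}\,\mathrm{atan2}(b_2, b_1) \bmod 24$. Because
the model is linear in $(M, b_1, b_2)$, ordinary least squares is the exact
nonlinear optimum; the unit tests verify this against an independent
grid-search-plus-refinement oracle. A minimum of 6 samples per group is
enforced (3 parameters, and permutation nulls degenerate below that).

Significance is empirical. Permuting sample times against fixed expression
is equivalent to permuting expression against a fixed design, so the null is
computed by projecting permuted response vectors onto a centred orthonormal
harmonic basis $Q$: $R^2 = \lVert Q^\top y_c\rVert^2 / \lVert y_c\rVert^2$,
one matrix product per protein. The add-one estimator

$$p = \frac{1 + \#\{R^2_{\mathrm{perm}} \ge R^2_{\mathrm{obs}}\}}{n_{\mathrm{perm}} + 1}$$

never returns 0 and is exact under exchangeability. Per-protein random
streams are keyed by sorted protein id, so results are invariant to row
order and to which subset of proteins is analysed together. The default
`n_perm = 1000` gives a p-value resolution of about 0.001; fewer than 100
permutations triggers a warning.

## Differential rhythmicity (ΔR²)

$\Delta R^2 = R^2_{\mathrm{unaffected}} - R^2_{\mathrm{OUD}}$. The null
re-permutes sample times independently within each group and recomputes the
difference; the tail is one-sided in the direction of the observed sign.
Proteins are tested only if rhythmic (empirical $p < \alpha$) in at least
one group; amplitude, mesor, and phase differences are reported only for the
intersection, with phase differences wrapped circularly into $(-12, 12]$.

**Caveat (documented, deliberate).** This construction is anti-conservative
under a strict no-difference null. Two mechanisms contribute: (a) for a
genuinely rhythmic protein, the sampling spread of $\hat R^2$ across groups
exceeds the spread of the fully de-rhythmed permutation null, so observed
$|\Delta R^2|$ values are systematically larger than null ones; and (b)
restricting to *called*-rhythmic proteins selects instances whose $\hat R^2$
is inflated in one group. On simulated cohorts with identical generative
rhythms in both groups (10% rhythmic proteins, amplitudes 0.5–1, noise SD
0.5, n = 20/group), 7.5–9% of all proteins receive a loss/gain call at
$\alpha = 0.05$ rather than ≤5%. The construction is retained because it is
the method under study; loss/gain counts should be read as descriptive
rather than strictly error-controlled.

## Differential expression

`fit_de()` delegates to limma (`lmFit` + `eBayes`) with design
`~ group + covariates` (default covariates: plex, sex, age, PMI); positive
log2 fold-changes mean higher in OUD. Precision weights are not used; the
limma-trend option is exposed but off by default. Unmoderated statistics
(`moderate = FALSE`) are reconstructed from the `lmFit` components and match
ordinary least squares exactly, which anchors the oracle tests. A rank check
on the design matrix converts silent aliasing into an explicit "collinear"
error naming the offending columns. DE calls use unadjusted $p \le 0.05$
and $|\log_2 FC| \ge 0.26$ (both boundaries inclusive); 0.26 corresponds to
a 20% abundance change, and BH FDR values are reported alongside.

RRHO maps rank both lists by $-\log_{10}(p)\cdot\mathrm{sign}(\log FC)$
(ties broken by id) and fill a step-indexed grid with
$-\log_{10}$ upper-tail hypergeometric p-values of top-set overlaps. The
upper-tail (enrichment-style) map displays anti-concordance as a uniformly
low surface; a depletion-sensitive variant was considered and rejected
because its maximum sits at the grid centre, which is not interpretable as
"discordance in the corners".

## Synapse enrichment

Within each group, synaptosome vs. homogenate values are paired by subject
and tested with a one-sided paired t-test (synaptosome higher), Bonferroni
corrected across proteins. A protein is synapse-enriched when Bonferroni
$p < 0.05$ **and** fold $\ge 1.25$ (inclusive). Downstream synaptosome
analyses use the union of the per-group enriched sets; an empty union is an
error rather than a silent empty result.

## Network modules, MDC, and hubs

Adjacency is $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ (unsigned default).
The soft power is the smallest $\beta \in 1..20$ with scale-free fit
$R^2 \ge 0.8$, falling back to 6. Modules come from average-linkage
clustering of $1 - \mathrm{TOM}$ with a static cut at 0.99 of the tree
height, a minimum size of 30, and iterative eigenprotein merging at
correlation 0.75; a static cut is simpler than dynamic hybrid cutting and
recovers planted block structure (Rand index ≥ 0.95 in tests). Labels are
colour names assigned by decreasing size.

Module differential connectivity is
$\mathrm{MDC} = \bar a^{\mathrm{OUD}} / \bar a^{\mathrm{unaffected}}$, the
ratio of mean off-diagonal within-module adjacency (size-normalised, so
comparable across modules). Two permutation nulls are computed — shuffled
sample-group labels and random same-size member sets — and
$p_{\mathrm{mdc}}$ is the larger of the two one-sided tail probabilities,
with the tail chosen by the observed direction and the add-one estimator.

**Caveat (documented, deliberate).** Choosing the tail after observing the
direction makes each scheme's $P(p \le 0.05)$ about 10% under a symmetric
null, and the max of the two correlated p-values measured ≈8% over 2000
random-module tests on a null cohort. As with ΔR², the construction is
retained as specified; MDC direction calls are descriptive. Note also that
the member-permutation null is only informative when the module is a small
fraction of the analysed proteome — random member sets drawn from a
proteome dominated by one module reproduce the module itself.

Hubs: two members are neighbors when their adjacency strictly exceeds the
90th percentile (type-7 quantile) of off-diagonal within-module adjacency;
NHNN is the node count within `n_hops` (default 1) of a protein in that
graph, and hubs have NHNN strictly above the module mean. In an
all-equal-adjacency module no edge exceeds the quantile and there are no
hubs.

## Synthetic cohorts and calibration nulls

`simulate_cohort()` draws, per sample,

$$\mathrm{value} = \mathrm{mesor} + A_{g}\cos\!\big(2\pi(\mathrm{zt}-\varphi)/24\big)
 + \beta_{\mathrm{DE}}\,[g{=}\mathrm{OUD}] + \text{covariate terms}
 + \text{plex offset} + \text{module factor} + \varepsilon,$$

with exact bookkeeping of which proteins are rhythmic (and lose rhythm in
OUD), DE, synapse-enriched, or module members. Case–control pairs are
adjacent so that every 10-sample TMT plex contains both groups; an early
design with group-contiguous plexes made plex collinear with diagnosis,
which `fit_de()` correctly refuses. TOD is drawn uniformly or from a
night-weighted mixture (`tod_sampling = "empirical-like"`).

Calibration nulls (used to measure type-I error of the rhythm and DE
stages) set `plex_sd = 0` and all covariate slopes to 0. The reason is
dependence, not difficulty: shared per-sample offsets make all "null"
proteins jointly correlated with ZT or group by chance, so the fraction of
$p \le 0.05$ across 2000 proteins has far more than binomial spread between
cohorts even though each single test remains valid. With independent noise
the fraction concentrates near 0.05 and is a meaningful calibration check.
Structured cohorts are still the default for power studies, where the DE
and rhythm models adjust for or absorb those terms.

## Numerical conventions

- Thresholds on p-values for DE are inclusive (≤); rhythmicity set
  membership uses strict `<` as stated for empirical p-values.
- All permutation p-values use the add-one estimator; seeds below $2^{31}$;
  every stochastic function takes an explicit seed and restores the
  caller's RNG state.
- Circular quantities (peak ZT, phase differences) are compared on the
  circle; phase differences live in $(-12, 12]$, with exactly antiphase
  mapped to $+12$.
- Quantile thresholds use R's default type-7 definition; hub and neighbor
  rules use strict inequalities, so saturated/degenerate inputs yield empty
  rather than full sets.

## Limitations

- One time point per subject: within-subject rhythm estimation is
  impossible, and rhythm estimates conflate inter-subject variation with
  circadian variation.
- The ΔR² and MDC permutation constructions are anti-conservative under
  strict nulls (see caveats above).
- Module detection uses a static tree cut; very close or nested modules may
  merge compared with dynamic hybrid methods.
- ORA treats proteins as exchangeable; no abundance- or length-based bias
  correction is applied.
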