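---
title: "Scoring chemical-genetic interaction screens: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring chemical-genetic interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemscreen)
```

## The problem

A chemical-genetic interaction screen asks, for every mutant in an arrayed
collection, whether a compound hurts (or helps) that mutant more than it
hurts the wild type. `chemscreen` implements the four analysis stages such a
screen runs through, together with a synthetic-data generator that plants
known effects so every stage can be tested for parameter recovery:

1. **Colony screen** — quadruplicate colony arrays on paired drug /
   no-drug solid medium; fitness ratios, per-plate Z-normalization, hit
   calling.
2. **Liquid validation** — replicated OD600 growth curves; AUC fitness,
   multiplicative interaction scores, Welch testing, a two-experiment
   intersection rule.
3. **Suppression screen** — overexpression strains; drug/plain AUC ratio
   versus an empty-vector control with fold and corrected-p gates.
4. **SGA scoring** — double-mutant colony arrays against a control query,
   scored under a multiplicative expectation.

## Fitness and the multiplicative model

All stages share one currency: fitness $W$, a growth measure normalized to
a reference. On solid medium it is the colony-size ratio drug/no-drug; in
liquid medium it is the growth-curve AUC divided by the wild-type AUC in
plain medium, so the wild type in plain medium has $W = 1$ by construction.

The interaction score is the deviation from the multiplicative expectation

$$\varepsilon = W_{ij} - W_i \, W_j,$$

where $W_i$ is the wild type's fitness in drug, $W_j$ the mutant's fitness
in plain medium and $W_{ij}$ the mutant's fitness in drug. Under pure
multiplicativity the drug costs every strain the same *fraction* of growth
and $\varepsilon = 0$; $\varepsilon < 0$ means the mutant is sensitized
beyond that expectation, $\varepsilon > 0$ that it resists the drug.
$\varepsilon$ is invariant under a common rescaling of all AUCs, because
the normalization cancels — a property the test suite checks directly.

## Stage parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| `z_pos`, `z_neg` | +3, −1.5 | per-gene Z thresholds for positive / negative colony-screen calls |
| `small_frac` | 0.05 | strains below 5% of the no-drug plate mean are excluded (strict `<`) |
| `neg_thresh`, `pos_thresh` | −0.1, +0.1 | $\varepsilon$ gates, applied to the per-experiment mean (strict) |
| `alpha` | 0.05 | Welch p (liquid) or BH-corrected p (suppression, SGA) gate |
| `fold_thresh` | 2 | suppressor fold-change gate versus the empty-vector control |
| `Q` | 0.8 | SGA query single-mutant fitness (a mistranslating tRNA alone costs ~20% growth) |
| `score_thresh` | −0.1 | SGA score gate |

Calling in the liquid stage requires the gates to pass in **both**
independent experiments; the intersection can therefore never call a strain
that a single experiment would not.

## Normalization choices

**Per-plate Z-scores.** Colony fitness ratios are normalized per plate to
mean 0, SD 1 (sample SD, `ddof = 1`; configurable). This removes the
multiplicative plate effect — a bias common to all colonies of one plate —
exactly. Z is computed on fitness ratios, not raw colony sizes: the ratio
is the quantity with a per-strain interpretation, and normalizing sizes
would conflate plate effects in the two conditions. Excluded strains never
contribute to the plate mean/SD. The outermost well ring is flagged
`is_border` and left out of the plate statistics by default (the classic
edge effect of pinned arrays); border strains still receive a Z on the
plate's scale. A plate whose retained fitness values have zero spread (to
floating-point resolution) cannot be normalized; all its records are
flagged `degenerate_plate` rather than silently zeroed.

**Quadruplicate collapse.** The 2×2 replicate colonies of a strain are
summarized by their mean (median available) *before* the ratio is formed,
so one missing colony perturbs the ratio less than averaging per-colony
ratios would.

**Allele grouping.** Alleles of the same (typically essential) gene are
grouped to one Z per gene, by default the mean of the allele Z-scores; a
`min` rule is available for a more sensitive, less specific call.

**Growth-curve fitness pairing.** Each replicate's AUC is normalized by
the wild-type plain-medium AUC *of the same replicate index*. This makes
the wild type's own $\varepsilon$ exactly zero (its $W_j \equiv 1$ per
replicate) and keeps replicate-level pairing intact for the Welch test. A
scalar mean reference is also accepted by `curve_fitness()` but weakens
the exact-zero identity to an approximate one.

**Welch pairing.** The per-experiment p-value compares the replicate
observed $W_{ij}$ values against the replicate-wise expected products
$W_i^{(k)} W_j^{(k)}$. A paired one-sample variant (per-replicate
$\varepsilon$ against 0) was evaluated during design and discarded as the
default: with 3 replicates it has only 2 degrees of freedom and measurably
less power than the two-sample Welch construction.

**SGA normalization.** Each array plate is divided by the plate-wide mean
of the embedded control-strain colonies, anchoring the plate scale at 1.
The score compares the double-mutant fitness under the mistranslating
query to $Q$ times its fitness under the control query. The p-value tests
the double-mutant replicates against the $Q$-scaled control-query
replicates — testing against the unscaled reference would reject every
null whenever $Q < 1$. This is a deliberately simplified treatment: the
full SGA toolchain additionally corrects row/column and spatial artifacts,
which are out of scope here, so scores from this module and from the full
toolchain are comparable but not identical.

## The logistic growth model

Liquid growth is modelled as
$N(t) = K / \left(1 + \frac{K - N_0}{N_0} e^{-rt}\right)$ with carrying
capacity $K$ (OD units), growth rate $r$ (per hour) and inoculum $N_0$.
`fit_logistic()` fits it by Levenberg–Marquardt least squares with a
deterministic initialization — $K \leftarrow \max(\mathrm{OD})$,
$N_0 \leftarrow$ first positive OD, $r \leftarrow$ the log-linear slope of
the early phase (points up to half-maximal OD) — so repeated fits are
bit-identical and no random restarts are involved. Curves whose OD range
is below `min_signal` (default 0.05 OD) are flagged non-converged; their
empirical AUC is still reported. The default fitness proxy is the
**empirical trapezoid AUC** of the raw readings; the closed-form integral
of the fitted model,
$\mathrm{AUC} = \frac{K}{r}\ln\!\frac{N_0(e^{rT}-1)+K}{K}$, is available
behind `fitted_auc = TRUE`. Both are provided because either convention is
defensible and they differ only through lag/stationary-phase noise.

```{r logistic-example}
tt <- seq(0, 24, by = 0.25)
set.seed(1)
od <- pmax(logistic_od(tt, K = 1.2, r = 0.4, N0 = 0.05) +
             rnorm(length(tt), 0, 0.005), 0)
fit <- fit_logistic(tt, od)
coef(fit)
```

## What the synthetic-data generator emulates

The generator is first-class, tested code; every calibration property in
the test suite is driven by it alone.

**Colony screens** (`simulate_colony_screen`). Colony size is
multiplicative: plate effect × base size × strain vigor × drug multiplier
× lognormal colony noise (multiplicative noise is the standard model for
colony-size measurements). Strains occupy quadruplicate 2×2 blocks of a
1536-format grid. Strain *vigor* (lognormal, sdlog 0.2) affects both
conditions and cancels in the ratio; the per-plate effect (lognormal,
sdlog 0.1) cancels in the per-plate Z. Null strains share the plate-wide
drug multiplier (default 0.6 — the screening dose costs ~40% fitness)
**exactly**: their fitness spread is measurement noise only. Planted
sensitive/resistant strains shift that multiplier by −3 / +4 times the
interaction effect scale (`interaction_sd`, 0.1 fitness units); a 0.5%
"dead" class grows at 1% of normal and must be caught by the small-colony
filter. Default planted fractions are 2% sensitive and 0.5% resistant.

**Growth curves** (`simulate_growth_curves`). Logistic curves from
$N_0 = 0.1$, sampled every 15 min for 24 h. Each curve's growth rate is
solved by monotone root-finding so that its trapezoid AUC *on the sampled
grid* hits the target fitness exactly; planted $\varepsilon$ values are
therefore realized to better than $10^{-3}$ in the noiseless limit.
Biological replicate variability is Gaussian on the target fitness
(default sd 0.05) and measurement noise Gaussian on OD (default 0.003).
The wild-type plain-medium reference curves are realized at their nominal
fitness of 1 (OD noise only): fitness is *defined* relative to this
reference, so the stated fitness noise is the noise of the normalized
fitness values themselves. Putting independent noise on the reference as
well would inflate the effective noise ~1.6-fold past the nominal setting
(reference noise enters every ratio, and squared in the products) and
make the calling power depend strongly on three lucky or unlucky
reference draws.

**Suppression** (`simulate_suppression`). Paired drug/plain curves per
overexpression gene plus an `empty` control whose drug/plain AUC ratio is
centred on 0.183 (a strong screening dose leaves the control ~18% of its
drug-free growth); planted suppressors multiply that ratio by
`suppression_fold`, planted growth-cost genes grow at 70% of control in
plain medium, and replicate variability is lognormal with CV 0.10.

**SGA arrays** (`simulate_sga_array`). Three arrays with allele positions
re-randomized per array, quadruplicate colonies, and all remaining
positions (including the full border) filled with the control strain. On
the normalized scale the double-mutant fitness is
$\mathrm{af} \times Q \times (1 + \mathrm{deviation})$ with array-allele
single-mutant fitness $\mathrm{af} \sim U(0.8, 1)$; the control strain
anchors the plate scale at 1 under both queries, playing the role the
full toolchain's spatial normalization plays in a real screen.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: spatial gradients and neighbor competition
within plates (a config hook is reserved, default off), non-logistic
growth (diauxie, lag-phase heterogeneity), batch effects between
experiments beyond the per-plate multiplier, and biological
strain-to-strain variation of null interactions. The last point matters:
in real screens null strains scatter biologically, the Z distribution has
genuinely heavy tails, and a −1.5 Z cut will always sweep in a
substantial false-positive fraction — which is exactly why this screen
design validates solid-medium hits in liquid medium rather than trusting
the colony-screen calls on their own. The generator's
idealized nulls make planted-effect recovery near-perfect; treat those
numbers as a correctness check of the pipeline, not as the expected
performance on a wet-lab screen.

**Determinism.** One integer master seed fans out to per-plate and
per-experiment substreams via a counter scheme
(`substream_seed(seed, index)`), so regeneration from `(config, seed)` is
bit-identical.

## Numerical conventions and degenerate inputs

- Welch's test: two-sided by default, since both interaction signs are
  biologically meaningful. Both samples constant and equal means: $p = 1$
  by convention; both constant with different means is an error.
- Benjamini–Hochberg: step-up with running minimum, capped at 1, NA
  propagated. Correction families are per experiment batch (all
  overexpression strains; all array alleles). Note the step-up adjustment
  is *not* idempotent — re-adjusting adjusted values re-multiplies by
  $n/\mathrm{rank}$ — so the suite checks order preservation and oracle
  equality instead.
- `zscore`: spread at floating-point rounding level (relative $10^{-12}$)
  counts as degenerate, so a noiseless plate is flagged rather than
  amplified into garbage Z-scores.
- Dose selection: nearest fitness to the target drop; ties go to the
  smaller dose (the cheaper, less toxic choice).
- Overlap percentages round half-up to integer percent, matching the
  usual reporting style of screen overlap figures.

## Problem sizes used in the shipped checks

The calibration tests and the acceptance script run the colony screen at
4,000 strains (11 plate pairs of 1536 colonies), the liquid validation at
200 strains × 3 replicates × 2 experiments, suppression at 50 genes per
batch with 200 planted-suppressor instances, and SGA at 72 alleles × 3
arrays — the scale of the screens the pipeline is designed for, chosen so
the full suite completes in well under a minute on one core.

## Reproducing printed counts from supplementary tables

`reproduce_from_supplements()` ingests supplement-style TSVs through an
explicit column manifest (so renamed columns break loudly), recomputes
headline counts — screen positives/negatives, validated interactions,
per-analog counts and their triple overlap, SGA calls, suppressor counts,
the control AUC ratio — and prints each next to the expected printed
value with a discrepancy flag. Exact reproduction of any published table
depends on conventions the original analysis may not state (quadruplicate
summary statistic, allele grouping rule, Z on ratios versus sizes), so
the report is designed to surface disagreement, never to silently pass.
The shipped tests exercise this machinery on synthetic stand-in tables
with known counts.

## Known limitations

- Plate-level normalization only; no row/column/spatial corrections.
- The logistic model is the only growth model; Gompertz or spline fits
  are out of scope, and strongly diauxic curves will fit poorly (the
  empirical AUC remains valid).
- The SGA module scores a single day-3-style snapshot and does not model
  the mating/selection steps.
- With 3 replicates, Welch p-values cannot fall much below ~$10^{-3}$;
  corrected-p gates therefore interact with the hit density of the batch.
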