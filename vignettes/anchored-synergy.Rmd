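---
title: "Anchored combination screens: models, scoring and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored combination screens: models, scoring and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorscreen)
```

# The screening format

`anchorscreen` analyses *anchored* drug-combination screens in cancer cell
lines. Instead of a full dose matrix, each combination is measured as a
2 × 7 design: an **anchor** drug at two fixed concentrations (chosen for
moderate activity, roughly 50–90% residual viability) crossed with a
7-point dose–response series of a **library** drug. Each plate carries one
(cell line, anchor, library) triple: five replicate anchor-only wells per
anchor concentration, four replicate library-only dose responses, one
combination dose response per anchor concentration, and a fixed control
census (6 untreated, 126 DMSO negatives, 28 medium-only blanks, and
2 × 20 cytotoxic positive controls).

Library concentrations are non-equidistant — four 4-fold steps followed by
two 2-fold steps, densest at the top — spanning 1,024-fold. All doses are
expressed on a standardized log2 scale on which the top concentration is 9,
so the series is `library_doses()` = (−1, 1, 3, 5, 7, 8, 9). Differences on
this scale are log2 fold changes, which makes the potency metric below
unit-free.

# Normalization and plate quality control

Raw well intensities are normalized per plate to relative viability
`(I − B)/(NC − B)` using the blank mean `B` and DMSO negative-control mean
`NC`. Values may leave [0, 1]; the fitted model, not the data, enforces the
range. Plate QC applies:

* coefficient of variation of the DMSO negatives, `CV = σ_N/μ_N ≤ 0.18`;
* a Z-factor `1 − 3(σ_P + σ_N)/|μ_P − μ_N| ≥ 0.3` against each positive
  control to which the cell line is sensitive (`mean(NC)/mean(PC) ≥ 4`);
  sensitivity to both controls requires passing both; sensitivity to
  neither falls back to a blank-based Z-factor;
* a screening-set rule: the mean of all computed plate Z-factors must reach
  0.4 (a plate sensitive to both positive controls contributes two values;
  this averaging convention is our choice, as only the 0.4 threshold itself
  is fixed).

Sample (n − 1) standard deviations are used throughout — control groups are
small. CV is computed on raw DMSO intensities; under multiplicative noise
CV is scale-invariant, so computing it on normalized viabilities instead
would not change a pass/fail decision. Untreated wells are carried in the
tables but do not enter CV, whose definition names the DMSO negatives.
Failed plates are excluded, not repaired.

# Dose–response model

Viability follows a two-parameter logistic in standardized log2 dose:

$$V(x) = \frac{u}{1 + \exp((x - x_\mathrm{mid})/s)}$$

with upper asymptote `u` fixed (1 for monotherapy; the anchor viability `A`
for combinations), lower asymptote 0, position `x_mid` and scale `s > 0`.
Because the lower asymptote is 0, the 50% point between zero and the upper
asymptote is exactly `x_mid`, so IC50 ≡ `x_mid` on the log2 scale. Emax is
the fitted viability at the top tested dose, `V(9)`; *lower* Emax means
more killing. A scale `s` corresponds to a Hill slope of `1/(s log 2)` in
log2 dose; realistic cytotoxicity curves (Hill 1–2) have `s` around
0.7–1.4.

The anchor viability `A` is the mean of the five replicate anchor-only
wells, clipped to (0, 1]. The combination curve is fitted with `u = A`
(the anchor cap) and, by default, the scale tied to the cell line's library
fit so that only `x_mid` is re-estimated. This is the closest executable
reading of taking "cell line parameters from the library fits", and it
stabilizes combination fits, which have a single replicate;
`free_scale = TRUE` frees both parameters.

## Numerical choices

* **Optimizer.** Bounded least squares (`L-BFGS-B`) with `s ∈ [0.05, 10]`,
  `x_mid ∈ [−10, 20]`, three fixed starts (`x_mid` 2, 5, 8) and a restart
  from the incumbent — fits are deterministic. An abnormal line-search exit
  at a point that no parameter perturbation improves is treated as
  converged; this is a documented artifact of tight `factr` tolerances at
  machine-precision optima.
* **Weighting.** Squared residuals are weighted by
  `1/max(viability, 0.1)²` by default. Luminescence viability readouts have
  noise roughly proportional to signal, so relative weighting is the
  statistically efficient choice; the 0.1 floor prevents near-zero wells —
  where additive background noise dominates — from receiving unbounded
  weight. The RMSE used for curve exclusion is always the unweighted root
  mean square error on the viability scale.
* **Validity.** A fit is valid when the optimizer converged and
  RMSE ≤ 0.2. Invalid curves exclude their tuple from synergy calling (the
  exclusions are logged). Extrapolated `x_mid` beyond the tested range is
  reported as-is; the qualifying gate below handles censoring. Flat
  profiles (all viabilities > 0.9) are additionally flagged insensitive.

# Bliss expectation and synergy calling

Under Bliss independence the expected combination response is the product
of the single-agent viabilities, so every point of the expected curve is
`A · V_lib(x)`. Two consequences used throughout: the Bliss Emax is
`A × library Emax`, and — because scaling a lower-asymptote-0 curve leaves
its half-point unchanged — the Bliss IC50 equals the library `x_mid`.

Observed combinations are scored against this expectation:

* `ΔIC50 = Bliss IC50 − combination IC50` (log2 units; positive = potency
  gain),
* `ΔEmax = Bliss Emax − combination Emax` (viability units; positive =
  efficacy gain).

A measurement **qualifies** when the combination IC50 is below twice the
highest screened library concentration (standardized scale: 10). A
qualifying measurement is **synergistic** when `ΔIC50 ≥ 3` (an 8-fold
potency shift) or `ΔEmax ≥ 0.2` (a 20% viability shift). Replicate
measurements of a tuple are summarized by majority (synergistic when half
or more are), and a combination–cell line pair is synergistic when either
anchor concentration is, with pairs synergistic at both tallied as
dual-anchor calls. Synergy-rate denominators count only evaluable
(non-excluded) pairs. All thresholds are parameters
(`synergy_thresholds()`, `qc_thresholds()`, `default_config()`) with the
defaults above; threshold sweeps are supported but no alternative default
is asserted.

Screen-versus-screen reproducibility treats the first screen as ground
truth and reports confusion counts, `F = TP/(TP + 0.5(FP + FN))`, recall,
precision, and per-metric Pearson correlations on matched keys.

# Biomarker discovery

Per (cell line, combination) pair, replicate responses are averaged within
each anchor concentration, then the two anchor concentrations are reduced
by taking the **larger** ΔIC50 and ΔEmax and the **smaller** combination
Emax — capturing the largest combination effect. These, plus the library
IC50, form the response matrix.

Each binary molecular feature (mutation/CNA/methylation flags, or
expression binarized within the analysis context at z ≥ 2 / z ≤ −2 into
`gene_up` / `gene_down` features) is tested against each response column by
fixed-effects ANOVA. Within single-tissue or molecular-basket contexts the
model is feature-only; in pan-tissue contexts tissue enters as an additive
covariate fitted before the feature (the covariate structure is not fixed
by the screening literature, so it is exposed as a choice). Effect sizes
are the two Glass deltas, `|mean_pos − mean_neg|` divided by each group's
sample standard deviation. An association is significant when p ≤ 0.001,
Benjamini–Hochberg FDR ≤ 0.05, and both Glass deltas ≥ 1. The FDR family
defaults to each (context, metric) pair — narrower families are
conservative for cross-metric comparison — with per-context and global
pooling available, since the correct pooling is genuinely ambiguous.
Feature levels need at least 3 observations each (degenerate deltas are
reported as infinite, small groups skipped with a reason). Enrichment
questions (e.g. synergy within a basket of combinations) use the
upper-tail hypergeometric test.

# Network distance analysis

Protein–protein interaction edge lists are filtered (confidence ≥ 0.5 by
default for evidence-scored sources such as IntAct-style exports; no filter
when a source carries no scores, as with pathway-derived networks),
restricted to protein–protein rows, deduplicated as unordered pairs and
stripped of self-loops. The distance between two drugs' target sets — or a
target set and a biomarker's proteins — is the minimum breadth-first
shortest path over the cross product, with the lexicographically smallest
contributing pair reported on ties and unreachable queries flagged rather
than summarized. Identifier mapping to protein IDs is supplied explicitly
as two-column tables; automated ID mapping is out of scope. A shuffle null
permutes biomarker feature assignments without replacement and recomputes
distances, simulating false-positive biomarker associations.

# The synthetic screen generator

Every stage is testable without external data via a generator with planted
ground truth. It emulates:

* plates with the full control census and replicate structure above;
* true library curves with `x_mid ~ U(2, 8)` (screening concentrations are
  chosen in practice so IC50s fall inside the tested window) and
  `s ~ U(0.7, 1.4)`;
* anchor viabilities `~ U(0.5, 0.9)`, the high concentration at least as
  active as the low;
* raw intensities `B + (NC − B) · V · (1 + ε)` with multiplicative Gaussian
  viability noise (σ = 0.05 by default, a typical well-level CV for a
  passing plate) plus additive intensity noise (sd 150 against a
  blank mean of 500 and negative-control mean of 50,000), the only noise
  blanks see;
* positive-control residual viabilities of 0.05 and 0.10;
* planted synergy: a potency shift moves the true combination curve left
  by `δ_pot` log2 units; an efficacy shift re-positions it so its top-dose
  viability equals the Bliss value minus `δ_eff`. Both keep the simulated
  combination inside the anchor-capped sigmoid family. A literal vertical
  subtraction of `δ_eff` would create curves that no member of the fitted
  family matches, which the RMSE ≤ 0.2 exclusion then removes — planted
  synergy would be discarded as bad fits rather than detected. Because a
  top-dose drop of `δ_eff` is only expressible when the Bliss curve leaves
  at least that much viability at the top dose, efficacy-planted tuples
  draw their library `x_mid` from a weak-activity stratum `U(10, 13)`;
  this mirrors the empirical pattern that efficacy synergy arises on weak
  to moderate single-agent activity. The truth object echoes the
  *achieved* true ΔIC50/ΔEmax per tuple, which for floored efficacy
  injections is smaller than requested;
* binary feature matrices with planted associations of stated effect size
  (in within-group standard deviations) plus background features with
  uniform random prevalence 0.2–0.8, and expression matrices with planted
  |z| > 2 outliers;
* one RNG stream per plate derived from (seed, plate index), so identical
  seeds give byte-identical screens and single plates are independently
  reproducible.

It does **not** emulate spatial plate effects (wells are a table, not a
1,536-well geometry), liquid-handling artifacts, edge effects,
seeding-density optimization, batch drift, or correlated biological
replicate structure. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated noise model — not robustness to
the systematic artifacts real screens contain.

# Verification sizes

The test-suite and acceptance-script checks run, by design, at desk scale:
a 30-cell-line × 20-combination screen for curve-parameter recovery
(fitted `x_mid` within ±0.1 log2 of truth on valid replicate-averaged
monotherapy fits — single-replicate combination fits have roughly twice
the standard error, so the recovery bound is assessed where the replicate
structure supports it); a 30 × 24 screen with 30% planted synergy for
sensitivity (δ_pot = 4 or δ_eff = 0.4) and false-positive control on
additive tuples; 50 simulated feature screens (one 2-sd feature in 15 of
30 lines among 200 background features) for biomarker power and null
calibration; and oracle equivalences for BH (brute-force step-up), ANOVA
(pooled t-test, F = t²), set distances (Floyd–Warshall on ≤30-node
graphs) and QC decisions (independent rule re-evaluation on 100 randomized
plates).

# Known limitations

* Replicate handling averages before fitting rather than nesting
  replicates in a joint model; jointly fitted replicate effects would use
  the raw wells more efficiently.
* The combination fit inherits the library scale by default; true
  slope-changing interactions are absorbed into `x_mid` unless
  `free_scale = TRUE`.
* Alternative synergy frameworks (Loewe, HSA, ZIP) and full dose–response
  surface models are out of scope.
* The ANOVA assumes homoscedastic Gaussian responses within feature
  levels; heavy-tailed response metrics (extrapolated IC50s) can inflate
  effect sizes, which the dual Glass-delta gate only partially guards.
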