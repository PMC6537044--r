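---
title: "Methods: anchored screen scoring, synergy models, and in-vivo analytics"
author: "anchorscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored screen scoring, synergy models, and in-vivo analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorscreen)
```

# The anchored-screen design

An anchored screen tests a compound library twice on the same cell model: in
a *single-agent* arm and in a *combination* arm where every well also
receives a fixed concentration of an anchor inhibitor. Compounds whose
combination-arm effect is much stronger than their single-agent effect are
candidates for potentiation by the anchor. The package models the raw data
as one long table of well measurements — plate, 1-based row/column, compound,
role (`compound`, `vehicle_control`, `anchor_control`), arm, concentration in
µmol/L, replicate, and a nonnegative luminescence signal. Alphanumeric well
labels (`A01` … `P24`) and numeric row/column pairs are interchangeable;
viability is always carried internally as a fraction in [0, 1], with percent
inputs converted at the reading boundary.

# Scoring chain: log, B-score, robust Z

Raw viability luminescence is approximately log-normal, so all scoring is
done on the natural-log scale; the natural log (rather than log10) is what
makes the percent-proliferation back-transform a plain `exp()`.

**B-score.** Each (plate, replicate, arm) is normalized separately. The
log-signal matrix of the *compound wells only* is decomposed by a two-way
median polish — iterative subtraction of row medians then column medians
until the absolute residual sum changes by less than `tol` (default 1e-9,
log scale) or `max_iter` (default 100) sweeps. The polish removes the grand,
row and column effects, i.e. edge gradients, dispense patterns and plate
offsets, and is exact on any additive row + column structure. The B-score is
the residual divided by 1.4826 × MAD of the plate's residuals. Control wells
are excluded from the polish (their fixed columns would otherwise absorb
column effects that belong to the artifact model) and receive no B-score.

Two numerical properties of the polish are worth knowing. Medians of
even-length vectors are midpoints, so on noisy plates the alternating sweeps
stall at a fixpoint where residual row/column medians are small but not
exactly zero; tests assert they are negligible against the noise scale
rather than zero. For the same reason, adding constant row and column
offsets to a noisy plate reproduces the same B-scores only approximately
(the package asserts concordance, and exact removal of the injected
offsets), while on noise-free additive plates removal is exact.

**Robust Z.** For each replicate and arm, compound-well B-scores are scored
as `RZ = (b − median) / (1.4826 × MAD)` against a reference population of
all compound-treated wells of the same arm — per plate by default, matching
the per-plate scope of the positional correction (`scope = "global"` pools
plates, with an optional median-of-per-plate-MADs variant via
`pooled_mad = TRUE` for multi-plate pooling). Treated wells, not vehicle
controls, are the reference: the percent-proliferation back-transform is
anchored on the median of all treated wells, and with ≥ 95% of library
compounds inactive the treated median is a robust proxy for no effect. The
1.4826 factor is the usual Gaussian MAD-to-sigma consistency constant,
applied to a single plain MAD. Scoring B-scores (which are already
MAD-scaled residuals) against the treated-well reference re-centers and
re-scales only mildly; the chain is kept in this order deliberately —
positional correction first, population scoring second — and each RZ row
carries its `median_ref`/`mad_ref` so the back-transform is self-contained.

**Hits and ΔRZ.** A compound is a hit when `RZ < −2` *strictly* in every
replicate of the selected arm (default: the combination arm; `strict =
FALSE` gives ≤). Requiring concordance across two independent replicates
squares the null tail probability (about 0.023² ≈ 5×10⁻⁴ for Gaussian
noise), which is what keeps the false-hit rate low without any multiplicity
correction. Compounds scored in fewer than `min_replicates` replicates are
excluded with a warning, never silently dropped. The potentiation score is
`ΔRZ = mean_rep RZ(combo) − mean_rep RZ(single)`; replicate means are used
because the two arms' replicates have no natural pairing, but per-replicate
differences are also emitted. Ranking is by ascending ΔRZ with ties broken
by the combination-arm RZ, and `rank_hits(n = 25)` reproduces a top-25
short-list. The back-transform
`%proliferation = exp(RZ × 1.4826 × mad_ref) × 100` maps RZ = 0 to 100% for
any reference and is strictly increasing.

# Dose-response fitting

Viability against dose is fitted with the four-parameter logistic
`v(d) = bottom + (top − bottom)/(1 + (d/IC50)^hill)` by least squares
(Levenberg–Marquardt on a log-IC50 parametrization, bounds −0.5 ≤ asymptotes
≤ 2, |hill| ≤ 20). Initialization is a deterministic multi-start — IC50 at
the 25/50/75% quantiles of the positive doses crossed with hill slopes 0.5,
1, 2 — and the lowest-RSS converged start wins; with no converged start the
fit is flagged `converged = FALSE` and no sensitivity class is assigned.
Zero dose enters through the closed-form limit (v = top for hill > 0).
Exactly flat dose-means raise a "no dose effect detectable" error rather
than returning an unidentifiable fit. Fits whose hill comes out negative are
re-oriented (hill > 0, top = zero-dose asymptote) so classes read
consistently.

The reported IC50 is the *relative* IC50 — the inflection dose of the fitted
curve; `ic50(fit, "absolute")` gives the dose where the curve crosses 50% of
control, when attainable. Relative IC50 is the default because it is defined
for every converged sigmoid, including partial-inhibition curves.
Classification uses two open bands: sensitive below 4 µmol/L, resistant
above 30 µmol/L, intermediate between — thresholds chosen to match the
published practice for the PRMT5-inhibitor cell-line panel this pipeline
reimplements; both are arguments.

# Combination analysis

Two complementary null models are scored on each two-drug dose matrix
(viability fractions relative to the double-vehicle anchor cell, ladders
including zero).

**Loewe excess.** Loewe additivity declares no interaction when
`d_A/D_A(E) + d_B/D_B(E) = 1`, with `D_X(E)` the dose of drug X alone
producing effect E (inhibition `1 − v`). For every cell the package inverts
the two fitted 4PL curves and solves for E by bisection (tolerance 1e-6 on
the effect) over the overlap of the two attainable effect ranges; the
combination term is strictly decreasing in E on that interval, so the root
is unique. Margin cells reproduce the corresponding single-agent fit
exactly, and cells whose additive effect falls outside the invertible range
are clamped to the nearest bound and flagged. Excess = observed − predicted
inhibition, in percentage points. The 4PL fits (not the median-effect lines)
drive the inversion, for consistency with isobologram-style excess tools;
`me_a`/`me_b` arguments let the caller substitute median-effect curves.

**Chou–Talalay CI.** The median-effect line
`log(fa/fu) = m log d − m log Dm` is fitted to each margin by ordinary least
squares using only points with 0.01 < fa < 0.99 (the logit explodes at the
bounds; the window is an argument). The combination index at an observed
effect is the mutually exclusive two-term form
`CI = d_A/Dx_A + d_B/Dx_B`, `Dx = Dm (fa/(1−fa))^{1/m}`; the nonexclusive
three-term variant is available by flag. CI is *undefined, not fabricated*
at cells with fa at 0 or 1 and at cells whose observed effect exceeds both
single agents' maximal observed effects — the grey-quadrant convention,
since neither single-agent curve can be queried there.

**Calls.** A cell is synergy-leaning when excess > 10 percentage points or
CI < 1, the published interpretation thresholds; antagonistic when excess
< −10. Because CI ≈ 1 is a knife edge — an exactly additive matrix puts
every cell at CI = 1 ± floating-point noise, and half of them below — the
*matrix-level* verdict does not count cells. It uses medians: potentiation
when the median interior excess exceeds the Loewe threshold or the median
defined CI falls below 0.9 (an additivity band of 0.1 under the CI
threshold, the conventional "nearly additive" margin). Per-cell calls remain
at the printed thresholds.

# In-vivo analytics

Relative tumor volume is `RTV(t) = V(t)/V(day 1)` per animal (day 1 =
randomization; baselines are required and validated), summarized as group
mean ± SEM per day. Tumor growth inhibition at a stated day is
`TGI = (1 − mean RTV_treated / mean RTV_control) × 100`; group means (not
medians) match mean ± SEM growth curves, and negative TGI (treated growing
faster) is reported as-is. Endpoint RTVs are compared with a two-tailed
Mann–Whitney test: the exact null distribution when both groups have ≤ 8
animals and no ties — so the classical 7-vs-7 design always takes the exact
branch — and the normal approximation with continuity and tie correction
otherwise. Cell-cycle distributions are compared per phase (G1 vs not-G1,
S vs not-S, G2/M vs not-G2/M) by 2×2 Fisher exact tests on cell counts,
with Benjamini–Hochberg adjustment across that three-test family. Caspase
luminescence is divided by the concomitant viability signal and expressed as
fold change over the vehicle ratio, which cancels any common instrument
gain.

# What the generators emulate — and what they do not

`simulate_screen()` builds log-signals additively: plate offset (Gaussian,
sd 0.05) + row gradient (0.02/row) + column gradient (0.015/column) +
compound effect + potentiation (combination arm only) + Gaussian noise
(sd 0.1, ≈ 10% CV, typical of luminescent viability assays), exponentiated
to raw counts around 2×10⁵. Defaults mirror the screen design this package
reimplements: 1,200 compounds at 10 µmol/L in duplicate on 384-well plates,
vehicle controls in column 1, anchor-alone controls in column 24, 5%
planted actives with log-effects N(−0.6, 0.05) (≈ −6 robust-Z units), half
of them further potentiated by N(−0.5, 0.25) in the combination arm, and a
constant anchor effect of −0.1 on all combination wells. An optional
heavy-tail contamination (a fraction of wells at 5× noise) stress-tests the
robustness of the median/MAD machinery.

`simulate_matrix()` derives margins from true Hill curves (defaults: IC50 1
and 2 µmol/L, hill 1 and 1.5, two-fold ladders 0–10 µmol/L, 5% CV
multiplicative noise) and builds interiors per regime: Loewe-additive cells
solve the Loewe equation on the *true* curves by an independent fine-grid
inversion — deliberately sharing no code with the analysis solver, so each
can serve as the other's oracle; Bliss cells multiply survivals; synergy and
antagonism shift the additive inhibition by ±`interaction_strength`
(default 0.2) at combination cells. `simulate_growth()` uses exponential
growth (control rate 0.08/day), baselines uniform on 60–100 mm³, 7 animals
per group measured twice weekly for four weeks, and sets the treated rate so
the expected endpoint TGI equals the target (default 0.39); with zero
measurement noise the endpoint TGI is exact by construction, which gives the
definitional test its closed form.

All generators are pure functions of their spec (seed included): they save
and restore the global RNG state.

What passing tests on these data do **not** show: real screens have
non-additive spatial artifacts (evaporation rings, dispenser streaks),
batch-varying noise, compound fluorescence/quenching interference, and
edge-well biology that the additive log-normal model does not emulate;
dose matrices can violate the monotone-Hill assumption (biphasic responses);
and tumor growth is only locally exponential. Results on synthetic data
validate the *statistical machinery*, not assay-specific robustness.

# Problem sizes and tolerances used in the checks

The test suite exercises: the median polish against `stats::medpolish` on a
4×4 grid (1e-9); gradient removal on 20 simulated 384-well plates, asserting
the pooled |correlation| between B-scores and the injected gradient is below
0.05 and the median per-plate |correlation| below 0.05 (a per-plate bound at
384 wells is dominated by sampling noise of the correlation itself, sd ≈
0.04, so pooling is the statistically meaningful check — the raw-signal
correlation exceeds 0.5 on every plate); hit recovery on the default
1,200-compound duplicate screen (sensitivity ≥ 0.95, false-hit rate ≤ 0.01);
ΔRZ rank recovery (Spearman ≥ 0.9, top-k precision ≥ 0.8); 200 simulated
8-dose triplicate curves at 5% CV (median relative IC50 error ≤ 5%);
sham self-combinations (CI = 1 within 1e-6 analytically, within 0.05 with
median-effect lines fitted on pooled triplicate margins; Loewe excess within
2 percentage points of zero); the bisection Loewe solver against a 400k-point
grid inversion on 100 random Hill pairs (1e-4); the exact Mann–Whitney
branch against exhaustive enumeration; Fisher + BH against hypergeometric
enumeration over every 2×2 table with grand total ≤ 50 (deduplicated over
the table symmetry group); and byte-identical pipeline reruns.

# Known limitations

* The B-score assumes positional artifacts are additive on the log scale;
  multiplicative-in-log or locally smooth artifacts need loess-type spatial
  models, which are out of scope.
* Median-effect fits weight all retained points equally; counts-based
  weighting would be preferable when fa comes from cell counting.
* CI confidence intervals (bootstrap over replicate matrices) are not
  implemented.
* The Loewe solver requires strictly monotone fitted margins; flat or
  non-sigmoid single agents are rejected rather than approximated.
* TGI compares group means at a single stated day; longitudinal mixed-model
  inference is out of scope.
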