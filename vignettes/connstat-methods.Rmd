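---
title: "Band-limited connectivity and network-based statistics: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-limited connectivity and network-based statistics: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`connstat` implements a complete inference chain for band-limited EEG
functional connectivity: wPLI estimation from region-level source time
series, network-based group statistics with permutation family-wise error
control, post-hoc directional subnetworks, covariate-adjusted
correlations with bootstrap intervals, and leave-one-out classification
of suprathreshold-edge networks. This vignette documents the models, the
estimator conventions, the tunable parameters, and the design decisions
taken where several reasonable choices existed.

## Connectivity estimation

**Parcellation.** All matrices are indexed by the packaged 68-region
Desikan–Killiany atlas (34 regions per hemisphere, FreeSurfer `aparc`
order, left hemisphere first). The atlas ships with a six-lobe grouping
(fronto-insular, sensorimotor, limbic, temporal, parietal, occipital)
used only for descriptive summaries; lobe membership of gyral regions is
a convention, and the table is a versioned data file
(`inst/extdata/dk_atlas.tsv`) that users can replace.

**Bands and filtering.** Default bands are θ 4–8, α 8–13, β 13–30 and
low-γ 30–45 Hz. Band-limiting uses a 4th-order Butterworth band-pass run
forward and backward (`signal::filtfilt`), i.e. an effective 8th-order
zero-phase filter, over a reflect-padded copy of the signal (up to 3 s of
padding, discarded afterwards) so edge transients do not leak into the
retained samples. Band edges at or above Nyquist are rejected.

**Analytic signal.** Instantaneous phase comes from the FFT
half-spectrum construction (negative frequencies zeroed, positive
doubled). No installed package exposes this primitive, so it is
implemented in `analytic_signal()`; its defining identities (real part
equals the input, quadrature pairs differ by π/2, pure tones advance at
their own frequency) are asserted in the test suite.

**wPLI.** For a window of analytic samples, each region pair gets

$$\mathrm{wPLI}_{ij} \;=\; \frac{\bigl|\,\mathrm{mean}_t\,
\Im(z_i \bar z_j)\,\bigr|}{\mathrm{mean}_t\,\bigl|\Im(z_i \bar
z_j)\bigr|},$$

the plain (not debiased-squared) weighted phase lag index: values live
in [0, 1] and are averaged across windows, which is what the reporting
conventions downstream assume. When every imaginary cross-term vanishes
(identical or exactly zero-lag signals) the ratio is 0/0; the package
defines the result as 0 whenever the denominator falls below 1e-12 —
zero-lag coupling reads as "no lagged coupling", which is precisely the
volume-conduction insensitivity that motivates the estimator.

**Windows and epochs.** Dynamic matrices are computed on 1-s windows
with 50 % overlap inside consecutive 30-s epochs (six epochs, 180 s, by
default) and pooled by arithmetic mean into the static matrix. Averaging
within epochs first and then across epochs would be arithmetically
identical for equal-length epochs; pooling was chosen. Up to 1 s is
trimmed from each end of the analytic signal when the recording exceeds
the epoch budget, to suppress residual filter transients. No spectral
taper is applied to the analytic cross-terms; the overlapping-segment
averaging is the Welch element of the procedure.

**Small-sample bias.** The wPLI null expectation is not 0: with $n$
effectively independent cross-terms per window it is of order
$\sqrt{\pi/2n}$, and $n$ is limited by the band width, not the sampling
rate. With 1-s windows the narrow θ and α bands resolve only ~4–5
independent cross-terms, giving a null bias near 0.45–0.50, whereas β
and low-γ sit near 0.27. The test suite asserts the bias ordering and
the sub-0.35 level for the wide bands. The practical consequence, which
the whole statistical design reflects, is that *raw* wPLI levels are not
interpretable on their own — all inference downstream is on
between-group contrasts of identically processed data, for which the
bias cancels.

## Network-based statistic

**Edge-wise model.** At every edge the package fits
`fc ~ intercept + group + covariates` by least squares and reports the
partial F for the group factor,
$F = \frac{(RSS_r - RSS_f)/(k-1)}{RSS_f/(N-k-N_{cov})}$, which reduces
to the classical one-way ANOVA F without covariates. The implementation
is a vectorized QR sweep over all edges; tests pin it against
`anova(lm())` per edge and against the $t^2$ identity for two groups.

**Effect size and primary threshold.** The scan policy starts at the
smallest multiple of the step (default 0.1) whose omega-squared,
$\omega^2 = \frac{df_b(F-1)}{df_b(F-1)+N}$ (floored at 0), reaches the
conventional medium bound 0.06, and raises the threshold stepwise until
the largest suprathreshold component is significant at α. Published
omega-squared estimators differ in small ways (residual-variance terms,
covariate corrections); because protocols sometimes state a starting F
that a given formula does not reproduce exactly, `f_initial` exists as
an explicit override so a reported threshold (e.g. 4.2 for N = 138,
k = 4, where the formula above gives 4.0) can be reproduced verbatim.

**Components and permutation null.** Suprathreshold edges are those with
F *strictly greater* than the threshold; component size is the edge
count (extent). Only the largest component is tested; smaller ones are
reported descriptively (ties broken by smallest node index). The null
distribution shuffles group labels across subjects with group sizes
preserved and covariates fixed to their subjects (simple relabelling —
the literal reading of the randomisation actually described for this
design), recomputes the edge-wise ANCOVA and records the maximum
component size. The FWER p-value is the plain fraction of null maxima at
or above the observed size — no +1 smoothing, so p can be exactly 0; the
conservative direction of the tie-inclusive count is what the FWER
simulation in the acceptance suite verifies. Permuted F maps are
computed once and re-thresholded during the scan, so scanning many
thresholds costs little beyond the single permutation pass.

Note that the smallest-significant-threshold policy tests several nested
hypotheses; the FWER guarantee verified in the acceptance suite is for a
fixed threshold, which is also how the null simulation is run.

## Post-hoc networks

Mean network connectivity (mNC) is the per-subject average of
connectivity over a component's edges. Group differences in mNC use
one-way ANOVA plus Tukey–Kramer comparisons
($q = |\bar x_i - \bar x_j| / \sqrt{(MSW/2)(1/n_i + 1/n_j)}$ against the
studentized range with $k$ means and $N-k$ df), valid for unequal group
sizes and reducing to Tukey's HSD (and, for $k=2$, to the pooled t-test)
in the equal-n case — both reductions are pinned in tests.

Directional subnetworks re-run the Tukey–Kramer comparison at every edge
of a parent component and keep edges whose adjusted p for the named
contrast falls below α, split by the sign of the mean difference; the
"each degree of the selected network" is read as *each connection*, and
no correction beyond Tukey's own family correction is applied across the
parent's edges (a deliberate mirror of common practice, and a caveat:
the retained-edge count under the null is about the per-edge Tukey error
rate).

Summaries report node and link counts, the percentage of parent links
(rounded half-up to one decimal — the convention behind printed values
such as 40/84 → 47.6 %), per-node degree, per-lobe degree shares, and
hemispheric lateralization in **three variants** (node share, link share
with cross-hemisphere links split half-half, degree-mass share), because
published lateralization percentages are often internally inconsistent
across these definitions; the output names the variant.

## Associations with clinical and hormonal variables

Partial Pearson correlation is the correlation of least-squares
residuals of both variables on an intercept plus covariates, with
$t = r\sqrt{(n-2-n_{cov})/(1-r^2)}$ two-sided p-values. Confidence
intervals are nonparametric bootstrap percentiles (default 1000
resamples of subjects, rows resampled jointly); degenerate resamples are
skipped, and more than 20 % of them raises an instability error rather
than a silently unstable interval. Percentile bootstrap was chosen over
BCa/normal approximations as the simplest method whose coverage the
acceptance suite can verify directly (95 % ± 4 % at n = 25 for a true
partial r of 0.5). Binary covariates enter as 0/1 indicators. The
correlation table API is covariate-list-driven per call because
reasonable covariate sets differ between analyses.

## Leave-one-out classification

For each left-out subject, a two-group edge statistic (squared pooled t,
i.e. the two-group F, matching the NBS suprathreshold logic; covariates
can be added via the design machinery) is computed on training subjects
only; edges above the threshold form a graph whose largest connected
component is the feature set (empty selections fall back to the single
best edge, and the count of such folds is reported). Features are
standardized with training-fold statistics, classified with linear
discriminant analysis under empirical priors, and the held-out label and
posterior score are recorded. To keep the discriminant well-posed the
feature count is capped just below the training sample size, preferring
the strongest training-fold edges. Metric confidence intervals bootstrap
the fold-level prediction set — a pragmatic choice, labelled as such,
since a single leave-one-out run does not otherwise yield interval
estimates. The no-leakage property (the held-out subject's data cannot
influence that fold's edge selection) is asserted by a mutation test.

## Synthetic cohorts

The generator exists so that every stage has a ground truth. Two modes:

* **Time-series mode** (`simulate_timeseries`): each region is a sum of
  band-limited stochastic oscillators (white noise band-passed to each
  band — *not* pure sinusoids, which would make wPLI degenerate at 0 or
  1) plus broadband noise (sd 1 by default). A planted effect injects a
  shared band-limited latent source into both endpoint regions of each
  planted edge, rotated by a phase lag strictly inside (0, π) (default
  π/4; 0 and π are rejected because zero-lag/anti-phase coupling is
  invisible to wPLI), scaled by `base_coupling + group_delta`. Latent
  sources are drawn even at zero coupling so that runs differing only in
  coupling strength share their randomness (common random numbers).
* **Direct connectivity mode** (`simulate_fc_directly`): edge weights
  are independent logit-normal draws (bounded to (0, 1) like wPLI),
  location `qlogis(0.3)` and logit-scale sd 0.5 by default, with planted
  edges shifted to `qlogis(0.3 + delta)` for the target group. This is
  the fast path used by the statistical calibration and recovery suites.

Cohort tables default to the four-group structure of the motivating
study population (27/42/30/39 subjects; age, disease duration, LEDD and
BMI drawn from the published group means and standard deviations;
most-affected side Bernoulli(0.55) for patients; sex-specific hormone
panels for patients). Controls get zero disease-duration, medication and
side covariates. `attach_hormone` adds a variable
`a + b·(covariate-residualized mNC) + ε` with `b` solved so the
population partial correlation equals a requested `r_target` — linear
Gaussian by design, since partial Pearson correlation is the downstream
estimand.

**What the generator does not emulate:** volume conduction / source
leakage (wPLI's raison d'être is tested by construction instead, via
zero-lag invariance tests), 1/f background spectra, artifacts, or
non-Gaussian hormone distributions. Passing tests therefore demonstrate
the statistical machinery's calibration and recovery under the model's
assumptions, not robustness to every property of real EEG.

## Numerical conventions and degenerate inputs

* wPLI 0/0 → 0 when the denominator < 1e-12 (zero-lag convention).
* Edges with numerically zero residual variance get F = 0.
* Suprathreshold membership is strict (`F > threshold`); the permutation
  p counts ties (`null ≥ observed`).
* Percentages round half-up (not half-even) to one decimal.
* Zero within-group variance in the omnibus test, zero residual variance
  in correlations, and missing classes in classification metrics are
  flagged (degenerate/NA), not silently propagated.
* All stochastic functions take a `seed` and restore the caller's RNG
  state; identical configuration + seed reproduces results bit-exactly.

## Problem sizes used by the test and acceptance suites

Simulation-backed tests run at desk scale by the package's own choice:
direct-mode cohorts of 20 regions × 4 groups × 12–20 subjects,
time-series simulations at 128–256 Hz with 30–62 s per subject and 3–5
regions, 100–1000 permutations, and 50–500 replicate cohorts depending
on the property. The full protocol scale (1024 Hz, 180 s, 68 regions,
5000 permutations) runs through exactly the same code paths; only the
sizes differ.

## Known limitations

* Pure-R wPLI: at full protocol scale (68 regions, 180 s at 1024 Hz)
  the estimator takes about a minute per band per subject; the hot loop
  is vectorized per region but not compiled.
* The omega-squared starting threshold is formula-dependent;
  `f_initial` is the escape hatch, not a hidden recalibration.
* No intensity-based (summed-F) component size, no TFCE, no
  Freedman–Lane residual permutation in this version; no graph metrics
  beyond degree.
* Bootstrap CIs are percentile-only; leave-one-out CIs are bootstrap
  over folds and should be read as stability summaries, not exact
  frequentist intervals.
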