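---
title: "Quantifying pressure-induced lymphatic chronotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pressure-induced lymphatic chronotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphchron)
```

## The measurement

Collecting lymphatic vessels pump lymph by spontaneous phasic contractions
driven by a muscle-cell pacemaker. A defining feature of this pacemaker is
its pressure sensitivity: raising intraluminal pressure speeds up the
contraction rhythm. In mouse popliteal lymphatics the spontaneous contraction
frequency rises roughly ten-fold — from about 2 to about 20 contractions per
minute — as pressure is stepped from 0.5 to 10 cmH2O, which makes the
*frequency-pressure (F-P) relationship* a sensitive readout of pacemaker
mechanotransduction: interventions that blunt the pressure response (channel
knockouts, inhibitors) compress its slope long before they abolish
contractions altogether.

The experimental unit is one cannulated, pressurized vessel observed by
video edge-tracking of its inner diameter at 30 frames per second while
pressure is held at a sequence of levels (the default protocol:
3, 2, 1, 0.5, 3, 5, 8, 10 cmH2O; 2 min per step, 5 min at 0.5 cmH2O where a
slow vessel needs longer to produce multiple contractions; inflow and
outflow pressure equal throughout, so there is no imposed flow). At the end
of the experiment the vessel is relaxed in Ca2+-free buffer and the same
protocol yields its maximal passive diameters DMAX(P).

`lymphchron` implements the full analysis from the diameter trace to group
statistics, plus a stochastic trace generator with genotype presets so that
every stage can be exercised and tested without raw recordings.

## From trace to events

`segment_by_protocol()` slices a trace into per-step analysis windows,
cross-checking the recorded pressure channel against the protocol (a cheap
guard against file/protocol mix-ups). The first `settle` seconds of each
step (default 20 s) are discarded: after a pressure change the vessel takes
some seconds to re-equilibrate, and how much transient the original
analyses discarded is not documented, so the discard is an explicit,
configurable parameter rather than a hidden constant. All windows are
half-open `[start, end)`.

`detect_contractions()` mirrors a classical peak-detection approach:

1. the diameter channel is smoothed with a centred moving average
   (`smooth_window`, default 0.3 s = 9 samples at 30 Hz) — wide enough to
   suppress pixel-level sensor noise, an order of magnitude narrower than
   the ~1.5 s systolic phase so nadirs are not flattened;
2. candidate nadirs are local minima of the smoothed trace with
   *topographic prominence* of at least `min_amplitude` (default 5 um).
   Prominence — the height of the lower enclosing shoulder above the
   minimum — matches the semantics "a contraction of amplitude at least
   x um"; a plain depth threshold would depend on the absolute baseline.
   The 5 um default excludes the small localized diameter oscillations
   (< 5 um) that do not propel lymph;
3. candidates closer together than `refractory` (default 1 s) are merged,
   keeping the deeper nadir, so one noisy nadir is never counted twice;
4. per event, ESD is the raw-trace minimum within `nadir_neighborhood`
   (default ±0.5 s) of the smoothed nadir; the onset is the last smoothed
   local maximum before the nadir; EDD is the smoothed-trace maximum over
   the diastolic interval from the previous nadir (or window start) to the
   onset.

Whether the original LabVIEW detector used a prominence or a slope
criterion is unknown; prominence is our choice and every threshold is an
exposed parameter. Two numerical consequences of step 4 are worth knowing.
Taking ESD from the raw trace makes the per-event nadir exact on clean
data, but under Gaussian noise the minimum of ~31 samples carries a
negative extreme-value bias (about −2 sd of the noise, i.e. ~−1.2 um at
the default 0.6 um noise), so per-event amplitudes are biased high by a
couple of micrometres; EDD, taken from the smoothed trace, is nearly
unbiased. None of the frequency-derived quantities are affected.

Frequency follows the contraction-by-contraction rule: for nadirs
$t_1 < \dots < t_n$ the instantaneous frequencies are $60/(t_i - t_{i-1})$
and the step frequency is their arithmetic mean. Zero events give frequency
0 (a real observation, never dropped); a single event gives count/duration
— a package convention, since no rule is documented for that corner case.

## Contractile parameters

Per analysis window, with step-mean EDD and ESD and the passive DMAX at the
same pressure:

$$\mathrm{AMP} = \mathrm{EDD}-\mathrm{ESD}, \qquad
\mathrm{normAMP} = \frac{\mathrm{EDD}-\mathrm{ESD}}{\mathrm{DMAX}}\times100,$$
$$\mathrm{EF} = \frac{\mathrm{EDD}^2-\mathrm{ESD}^2}{\mathrm{EDD}^2}, \qquad
\mathrm{TONE} = \frac{\mathrm{DMAX}-\mathrm{EDD}}{\mathrm{DMAX}}\times100,
\qquad \mathrm{FPF} = \mathrm{EF}\cdot\mathrm{FREQ}.$$

Design points:

* Parameters are computed from the step-mean EDD/ESD. Averaging per-event
  EF instead gives a slightly different number (Jensen's inequality); the
  distinction is not documented in standard practice, so the step-mean
  order is the default and `per_event = TRUE` switches order.
* When frequency is zero the amplitude family (AMP, normAMP, EF) is
  reported as missing — an amplitude is undefined without a contraction —
  and FPF is 0. Tone is still reported, computed from the mean smoothed
  diameter of the window standing in for EDD, because tone is meaningful
  for silent vessels (several low-chronotropy genotypes are silent at low
  pressure yet clearly constricted).
* Tone may be slightly negative when noise puts EDD above DMAX; it is
  flagged with a warning, never clipped, so aggregation stays unbiased.

## The chronotropy fit

`fit_fp()` fits frequency against pressure by ordinary least squares over
0.5–5 cmH2O, the range where the response is near-linear; above 5 cmH2O
frequency plateaus and those steps are excluded from the fit (but kept in
summaries). The default protocol visits 3 cmH2O twice; the two visits are
averaged before fitting (`dup_policy` also offers `first`/`last`, since
which visit the original analyses used is not documented). Zero
frequencies enter the fit as 0.

`delta_f()` reports $\Delta F = F(5) - F(0.5)$. A frequency *ratio* over
the same range is undefined for vessels silent at 0.5 cmH2O; the
difference stays finite, which is exactly why it is the companion summary
to the slope. For perfectly linear data $\Delta F = 4.5 \times$ slope.
Degenerate fits use documented conventions: zero-variance frequency gives
slope 0 and $r^2 = 0$ ($r^2$ is mathematically undefined there).
`fit_quality_report()` flags $r^2$ below 0.7 or negative slopes for
review without altering results. Only the slope feeds group statistics;
deltaF is reported alongside.

## The synthetic-data generator

`simulate_vessel()` renders a 30 Hz diameter trace per protocol step:

* **Event times.** Contraction nadirs form a gamma renewal process with
  mean interval $60/f(P)$ and coefficient of variation `interval_cv`
  (default 0.2) — near-regular pacemaking with physiological jitter. No
  interval statistics are published for this preparation; the CV is an
  exposed parameter.
* **Waveform.** Each contraction descends from EDD(P) to
  ESD(P) = EDD(P) − amp(P) along a raised cosine over `systole_s`
  (default 1.5 s), then refills exponentially toward EDD with time
  constant `refill_s` (default 2.5 s), interrupted by the next onset. The
  waveform shape is invented; only its induced EDD/ESD/frequency matter
  downstream.
* **Diameter scale.** $\mathrm{EDD}(P) = (1-\mathrm{tone}(P)/100)\,
  \mathrm{DMAX}(P)$ with the saturating passive curve
  $\mathrm{DMAX}(P) = D_{lo} + (D_{hi}-D_{lo})\,P/(P+P_{1/2})$
  (defaults 80–115 um, $P_{1/2}$ = 2 cmH2O — plausible values for mouse
  popliteal vessels; no analysis target depends on absolute diameters).
* **Noise.** Additive iid Gaussian measurement noise, sd 0.6 um.

`simulate_passive()` renders the matching Ca2+-free recording
(DMAX(P) + noise, no events). The simulator never calls detection or
fitting code — consistency between the two sides is established only
through the public pipeline, so the generator cannot "agree with" the
analyzer by construction. Each simulated trace carries its ground-truth
event table as an attribute for round-trip tests, and `simulate_events()`
exposes the event layer alone for large statistical replication where
rendering 650k-sample waveforms would add cost but no information.

### Genotype presets

`preset_registry()` ships seven conditions whose per-pressure mean
frequencies are *derived*, not hand-tuned: `derive_preset_frequencies()`
solves for the interior grid frequencies by minimum-curvature interpolation
subject to the condition's slope anchor (equality-constrained least squares
on second divided differences), with $f(0.5)$ and $f(10)$ anchored and a
plateau at 8–10 cmH2O. Anchors: WT slope 2.8 with deltaF 12.1 and the
2→20 min⁻¹ range; WT + 1 uM Ani9 (ANO1 inhibitor) 0.3; *Ano1* smKO 0.4
(capped below 3 min⁻¹ at every pressure) vs its floxed control 2.8;
*Itpr1* smKO 0.6 vs control 2.6; *Trpv4*⁻/⁻ 2.7. Conditions with no
separate deltaF anchor use the exactly linear profile
(deltaF = 4.5 × slope). Amplitude (35–50 um) and tone (4–18%) profiles are
plausible invented defaults shared across presets. Infeasible anchor
combinations (e.g. a deltaF far below 4.5 × slope, which no monotone
near-linear profile can satisfy) raise explicit errors.

### What recovery does and does not show

The mean-of-inverse-intervals frequency estimator is biased upward by the
factor $k/(k-1)$ for gamma intervals with shape $k = 1/\mathrm{CV}^2$
(≈ +4.2% at CV 0.2), so recovered slopes sit ~4% above the preset anchors
— a property of the contraction-by-contraction rule itself, visible in the
cohort results and well inside the 2-SEM acceptance bands. Two features of
real data are deliberately not modelled: vessel-to-vessel heterogeneity
(presets have fixed means, so between-vessel slope scatter is far smaller
than in real cohorts, and per-vessel fits are more linear — simulated WT
$r^2 \approx 0.99$ versus ~0.93 reported for real vessels, whose scatter
is biological, not instrumental) and slow drifts/movement artifacts in the
diameter signal. Passing recovery tests therefore validates the
algorithmic chain, not the biological variance structure.

## Group statistics

Matching standard practice in this field: two groups of per-vessel slopes
are compared by the unpaired two-tailed Student t-test (pooled variance;
Welch behind a flag); three or more by one-way ANOVA with Dunnett's
many-to-one post hoc, whose adjusted p-values we compute from the
equicorrelated multivariate-t distribution (numerical integration via
mvtnorm, seeded; cross-checked against multcomp in the test suite).
Pressure-wise parameter profiles use a two-way repeated-measures ANOVA
(pressure within vessel) with per-pressure contrasts Šidák-adjusted over
the number of pressures, $p_{adj} = 1-(1-p)^m$. Unbalanced mixed-model
ANOVA is simplified to complete-case repeated measures: vessels missing
any pressure are dropped and the count is logged — an explicit
approximation to the mixed models used with missing cells. Stars follow
the usual convention (`*` < 0.05 … `****` < 0.0001, `n.s.` otherwise).

The test suite calibrates the t-test's type-I error (10,000 null
simulations; rejection rate required in [0.04, 0.06] at α = 0.05) and its
discriminating power on the pipeline's own output: 200 replicate WT
(n = 20) vs *Ano1* smKO (n = 23) experiments, simulated at the event level
(the waveform + detection path is separately shown to reproduce the event
layer bit-for-bit given the same seeds), must reject at p < 0.001 in at
least 95% of replicates, and a full-pipeline spot replicate must reject
as well.

## Expression summaries

The single-cell module reimplements only two transparent statistics, not a
clustering workflow. `qc_filter_cells()` removes cells with > 10%
mitochondrial counts, < 500 detected genes, < 1,000 UMIs, or a doublet
score ≥ 0.5, then drops genes with zero total count; the filter is
idempotent and its per-criterion removal counts are reported. The doublet
criterion is implemented in the conventional direction (high score =
likely doublet = removed); a flag restores the inverted reading, and the
direction used is always recorded in the report. `dotplot_stats()` gives
per cluster the percent of cells with count > 0 (dot size) and the mean
log1p counts-per-10k expression relative to a reference gene such as
*Acta2* (dot colour). Published dot plots are built on variance-stabilized
(SCTransform) values whose exact scale is not reproducible from a count
matrix alone; the counts-per-10k definition is the transparent
approximation, and by construction the relative level is invariant to
per-cell library size.

## Problem sizes and numerical conventions

Cohort-level checks use the study-scale sizes (18–23 vessels per
condition, full 1140 s protocols at 30 Hz, ≈ 650k samples per cohort);
replication-heavy checks (power, calibration) run at the event level as
described above. Tolerances: formula identities at 1e-10 relative; OLS
against a brute-force normal-equations oracle at 1e-10; noiseless
detection round-trips at 0.5 um and one boundary event; cohort slope
recovery within 2 SEM of each condition anchor. Ties and plateaus in
extremum finding take the plateau midpoint; all windows are half-open;
seeds propagate from a single integer per cohort so every run is
bit-reproducible.
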