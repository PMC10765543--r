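---
title: "Methods: intramural mapping of spatial dispersion of repolarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intramural mapping of spatial dispersion of repolarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrmap)
```

This vignette is the package's own account of what it computes and why
the numerical choices are what they are. The setting is the chronic
AV-block (CAVB) dog model: after ablation of the His bundle and months
of remodeling, an I~Kr~ blocker (dofetilide) reproducibly triggers
Torsade de Pointes (TdP), and high-rate right-ventricular-apex (RVA)
pacing suppresses it. The analysis quantifies the spatial substrate of
those arrhythmias — dispersion of repolarization across an intramural
needle array — along the pacing protocol RVA50 (challenge) →
RVA100 → RVA80 → RVA60, two minutes per fixed-rate block.

## The lattice

`build_mapping_grid()` models 56 intramural needles, four unipolar
electrodes each (224 channels), as level-by-column lattices per wall.
The literature states only that needles were distributed *evenly* over
the septum and both free walls across six base-to-apex levels, so the
per-wall allocation is a package default, chosen once and fully
overridable through a geometry table or JSON file:

* LV free wall: 6 levels × 4 columns (24 needles),
* RV free wall: 5 levels × 4 columns (20),
* septum: 6 levels × 2 columns (12).

Every dispersion statistic depends only on the adjacency structure
(which needles are vertical/horizontal neighbours and which quadruples
form 2 × 2 squares), not on the exact counts, which is why the
allocation is safe to leave configurable. Two structural decisions are
fixed by anatomy: horizontal adjacency wraps circumferentially within
each free-wall ring but the septum is a bounded sheet (no wrap, no
cross-wall pairs); and depth index 0 is epicardial because needles are
inserted from outside. Intra-needle electrode spacing is 4 mm,
inter-needle spacing 10 mm — so the four orientations average over
different physical distances, an inherent feature of needle mapping
that the statistics do not attempt to normalize away.

## Fiducial detection

On a unipolar electrogram, activation time (AT) is the instant of
steepest negative slope of the QRS (the intrinsic deflection) and
repolarization time (RT) the instant of steepest positive slope of the
T wave, whatever the T-wave polarity. `detect_fiducials()` estimates
both from a centred first difference of a moving-average-smoothed
signal, windowed relative to the pacing stimulus:

* QRS window `[0, 150]` ms, T window `(150, 0.9 × RR]` ms. The source
  analyses never state their windows; these brackets comfortably
  contain the wall-mean ATs (≈ 38–63 ms) and RTs (≈ 330–505 ms) seen
  across the protocol while excluding the next stimulus.
* QRS derivative smoothing: 5 ms moving average. The intrinsic
  deflection is 2–3 ms wide at 2048 Hz; 5 ms suppresses sample noise
  without blunting the argmin.
* T derivative smoothing: 20 ms (4 × the QRS width by default). The
  T upstroke is an order of magnitude slower than the intrinsic
  deflection; with a 5 ms kernel the derivative maximum over a
  700 ms search window is dominated by noise, while a symmetric 20 ms
  kernel does not displace the peak.
* Sub-sample RT refinement: the vertex of a quadratic least-squares
  fit to the smoothed derivative over ±12 ms around the coarse argmax.
  The quadratic is clamped to the fit window and skipped when its
  curvature is non-negative (degenerate). This averages residual noise
  over the broad T-derivative peak; both smoothers being symmetric, AT
  and RT remain exactly equivariant under integer sample shifts and
  invariant under positive amplitude scaling.

Flat-line input returns a flagged non-result rather than an error; a
window shorter than the smoothing kernel is a configuration error.

## Channel rejection

Needle recordings are discarded for persistent major injury current,
noise, flat T waves, or cavity potentials from a needle protruding into
the ventricle. `channel_qc()` operationalizes these rules, since the
source describes only the injury criterion numerically (> 80 % of the
T-wave amplitude):

* **Injury**: |median(ST) − median(TQ)| / T peak-to-peak > 0.80, with
  the ST segment sampled 80–120 ms after AT and the TQ segment over the
  last 100 ms of the beat window. Medians make the metric robust to
  noise; the ratio makes it amplitude-scale invariant.
* **Noise**: RMS of the residual after the 5 ms smoother, relative to
  QRS peak-to-peak, > 0.05.
* **Flat T**: T-window peak-to-peak < 0.1 mV.
* **Cavity**: QRS peak-to-peak < 0.6 mV *and* QS-morphology score
  (1 − positive excursion / QRS peak-to-peak) > 0.9. Both conditions
  are required so that a genuinely low-amplitude but biphasic channel
  is not misread as a cavity potential.

The checks run in the order cavity → noise → flat T → injury and the
first hit labels the channel (the labels are mutually exclusive).
Whether the original analysis rejected individual channels or whole
needles is ambiguous ("needle recordings … were disregarded"), so both
granularities are implemented: `mode = "channel"` (default) and
`mode = "needle"`, which additionally disregards a needle once ≥ 2 of
its 4 channels fail. Neither is asserted to be the original behaviour.

## Dispersion statistics

`sdr_orientation()` computes, per spatial unit, max(RT) − min(RT) over
the unit's accepted electrodes, and averages over units:

| orientation | unit | electrodes |
|---|---|---|
| transmural | one needle | ≤ 4 |
| vertical | vertically adjacent needle pair | ≤ 8 |
| horizontal | horizontally adjacent needle pair | ≤ 8 |
| cubic | 2 × 2 needle square | ≤ 16 |

Whether the pair orientations operate on electrode unions or needle
means is not stated in the source; the cubic definition ("within four
squared needles") anchors the union convention, which is used for all
orientations and recorded here as an assumption. With missing
electrodes a unit stays eligible while every member needle retains at
least 2 accepted electrodes; below that the unit is dropped, never
imputed — dropping loses a little power but cannot bias the max−min
upward or downward the way imputation could. An orientation with no
eligible units reports an explicit empty result (`NA`, 0 units), not a
zero. SDR is computed on uncorrected RT: all serial comparisons happen
within fixed-rate blocks, where the Van de Water correction would be a
constant shift that max−min cancels anyway (the polar maps offer the
corrected RT~c~ view, where the correction *does* move absolute cell
values).

dRT is defined as mean(LV RT) − mean(RV RT) over accepted electrodes —
a difference of wall means, not a mean of paired differences — because
that is the arithmetic that reproduces the published wall-mean rows
exactly (e.g. 453 − 363 = 90 ms). The septum contributes to neither
ventricular mean and forms spatial units only within itself.

## Rate correction

`qtc_van_de_water()` / `correct_rt()` implement
QT~c~ = QT − 0.087 (RR − 1000), the correction developed for the
anesthetized dog. The published serial table is reproduced exactly by
this coefficient at all four fixed-rate timepoints (488, 530, 598,
609 ms), which the acceptance checks recompute. Tables round half-up to
1 ms (`round_ms()`); internal values keep full precision.

## Arrhythmia detection and scoring

A TdP is a run of ≥ 5 consecutive ectopic beats with a twisting QRS.
The beat stream carries a scalar morphology index per beat, and
"twisting" is operationalized as ≥ 1 sign change of that index within
the run — an objective surrogate, not a claim about how the original
episodes were adjudicated; monomorphic runs of any length count as
ectopy only. Scoring: a self-terminating episode scores its beat count;
episodes requiring 1 / 2 / ≥ 3 defibrillations score 50 / 75 / 100.
Three gaps in that rule had to be closed:

* **Defibrillation attribution** is not specified; events attach to the
  nearest preceding episode ending within 5 s (or to an episode they
  fall inside). Unattributable events produce a warning and are
  dropped.
* **Severity ordering** when several episodes share a block: any
  defibrillated episode outranks any self-terminating one, then more
  defibrillations, then more beats — the ordering implied by the
  score's construction.
* **Score collision**: a self-terminating run of ≥ 50 beats would
  collide with the defibrillation codes; such scores are capped at 49
  with a warning.

Per block, *all* ectopic beats are counted, including those inside TdP
runs (the cumulative-ectopy convention; configurable by filtering the
stream). The dofetilide-challenge block is anchored by
`rva50_window()`: only the last 2 min before the first TdP onset count,
with a half-open beat window `[onset − 120 s, onset)` and a closed
episode window so that the anchoring TdP itself is scored.

## Restitution

`restitution()` fits wall-mean RT against paced RR per ventricle. A
straight line is the default: four protocol cycle lengths (600, 750,
1000, 1200 ms) cannot constrain more structure, and the observed curves
are smooth and monotone over that range. An exponential
RT = a − b·e^(−RR/τ) is available (`model = "exponential"`, fitted with
`nls`, "port" algorithm so that an exactly colinear/zero-residual fit
does not fail). The divergence report — predicted LV − RV difference at
each observed RR plus the slope difference β~LV~ − β~RV~ — is the
quantitative statement of interventricular dispersion growing at long
cycle lengths. RR is assigned per timepoint as the paced cycle length,
and block-mean RTs (not per-beat values) form the points.

## The synthetic-data generator

No recordings are publicly released, so the pipeline ships with a
generator whose outputs carry exact machine-readable truth. It emulates
the statistical structure the analysis assumes — not the biophysics:

* **Repolarization fields** (`generate_rt_field()`):
  RT = α~w~ + β~w~·RR + apicobasal gradient (4 ms/level) + transmural
  gradient (3 ms/depth) + iid Gaussian dispersion noise. The restitution
  coefficients default to least-squares anchors on the published serial
  wall means (β~LV~ = 0.194 > β~RV~ = 0.111 ms/ms; intercepts 258 and
  277 ms; septum midway), so interventricular divergence is on by
  default. Activation times follow a paced-activation template: wall
  means 40 / 61 / 50 ms (RV / LV / septum, RV earliest under RVA
  pacing) with a −3 ms/level base-to-apex slope and 10 ms noise —
  constrained only by the published wall-mean ATs, since no
  quantitative activation map is available.
* **Dispersion calibration** (`calibrate_dispersion_noise()`): the
  per-timepoint presets must realize stated cubic-dispersion levels
  (103, 125, 49, 62, 107, 101 ms for EB, TdP, RVA100, RVA80, RVA60 and
  the RVA60 retrospective control). The noise SD is obtained by
  inverting the expected range of one square's 16 electrode values
  (deterministic gradient offsets + σZ) with `uniroot` on a Monte-Carlo
  estimate using 4000 common-random-number draws from a fixed internal
  substream — deterministic, smooth in σ, and accurate to well under
  the 10 % tolerance the generator promises.
* **Electrograms** (`generate_egm()`): deflections are sums of logistic
  sigmoid steps, chosen because a steep step has its extreme slope
  exactly at its centre — the constructed AT/RT are the true
  derivative extrema by design, positive or negative T wave alike. The
  family is an invention for testability, not a morphology model.
  Corruptions are applied per label: injury raises the TQ baseline by
  `injury_fraction` × T amplitude (so the ST–TQ shift is exact), flat-T
  scales the T wave to 5 %, noisy adds broadband Gaussian noise, cavity
  substitutes a low-amplitude monophasic QS complex. Windows hold
  `floor(fs × window)` samples from t = 0 — 2457 samples at 2048 Hz and
  1200 ms.
* **Rhythm** (`generate_beat_series()`): paced beats at 60000/rate ms;
  isolated ectopy as a Bernoulli process per beat slot (no
  afterdepolarization model — the pipeline consumes annotations, not
  mechanisms); TdP episodes replace pacing for their duration with
  consecutive ectopic beats whose morphology index alternates in sign
  every second beat; episodes longer than 10 s must be cardioverted and
  defibrillation events are placed at the episode end. The surface lead
  (`generate_surface_lead()`) gives each beat an R deflection at the
  annotated onset and a triangular T wave whose linear terminal limb
  reaches baseline exactly QT later, so a threshold-crossing T-end
  detector (1.5 % of peak, linearly interpolated) measures QT to about
  1 ms.

What passing tests therefore show: the detectors, statistics and scores
are correct against known truth under realistic means, gradients,
restitution slopes and corruption patterns. What they cannot show:
robustness to real T-wave morphologies, drift, fractionated
electrograms, imperfect stimulus annotations or non-stationary rhythms
— none of which the generator attempts.

## Reproducibility and problem sizes

Every stochastic element takes a seed; `run_pipeline()` requires one
and re-runs byte-identically. Statistical test conditions are fixed as
package choices: detector recovery uses 200 clean channels spanning
RT 300–500 ms at 20 dB SNR (noise SD = signal RMS / 10); rejection
accuracy uses 40 clean plus 10 channels per corruption class; oracle
equivalence of the dispersion statistics runs 100 random toy lattices
against an independent brute-force enumeration; directional claims
(LV slope > RV slope; cubic SDR lower at RVA100 than before TdP and
than the RVA60 control) use 20 seeded replicates and a one-sided sign
test.

## Known limitations

* The per-wall needle allocation, QC thresholds beyond the 80 % injury
  rule, analysis windows and smoothing widths are package defaults for
  quantities the source leaves unstated; all are configurable and none
  affect the published-arithmetic checks.
* SDR in different orientations spans different physical distances
  (4 mm vs 1 cm electrode spacing); values across orientations are not
  directly comparable.
* The linear restitution law and the sign-alternating morphology
  surrogate are deliberate simplifications; neither supports inference
  about mechanisms.
* Group-level inferential statistics (mixed ANOVA, non-parametric
  post-hoc tests) are out of scope; `compare_arms()` is descriptive
  only.
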