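---
title: "Methods: simulating and quantifying longitudinal axonal bouton dynamics"
author: "boutondyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying longitudinal axonal bouton dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutondyn)
```

## The quantification problem

In longitudinal two-photon imaging of cortical axons, presynaptic boutons
are scored session by session and followed as identities over weeks. Two
morphological classes are distinguished. *En passant* boutons (EPBs) are
swellings along the axon shaft, scored by their fluorescence intensity
relative to the local backbone: a bouton is present when its peak is at
least **2x** the backbone reference and visible across at least **two
consecutive z-planes**. *Terminaux* boutons (TBs) are short side
protrusions, scored by geometry with a hysteresis: a protrusion becomes a
bouton once it reaches **1.0 um**, remains one while it stays at or above
**0.4 um**, and is lost at the first session it measures below 0.4 um.

From per-session presence the pipeline computes, per axon:

* **density** = N~total~ / axon length (axons shorter than 100 um are
  excluded);
* per consecutive-session interval, **turnover** =
  (gains~B~ + losses~B~) / (N~A~ + N~B~), with **gain** and **loss
  fractions** defined by restricting the numerator, so that
  gain_frac + loss_frac = turnover identically.

The imaging design is nine sessions at 48-h intervals (days -8 ... +8) with
one stimulation session immediately after day 0, so interval-level measures
have four pre-stimulation values and four post-stimulation values (+2, +4,
+6, +8 days), while session-level density has five pre-stimulation values.
Baseline values are the per-axon arithmetic means over those
pre-stimulation entries.

## The synthetic-data generator

No raw images from this kind of experiment are bundled; the package
generates its own ground truth, which every later stage is tested against.

Each axon is a gently wavy 3D polyline rescaled to an exact arc length.
Bouton dynamics follow the simplest process consistent with the study's
observables (stable density, nonzero turnover): the initial cohort is
Poisson with the configured density; between consecutive sessions every
live bouton dies independently with probability `p_loss` and new boutons
arrive as a Poisson process along the axon. By default the gain rate
balances the expected losses (`gain_rate_per_100um = p_loss x density x
100`), which makes the density a stationary birth-death process. A
stimulation effect is a transient multiplicative factor applied to *both*
event rates on configured post-stimulation intervals; the group presets use
full effect at +2 days decaying to none by +8 days, mirroring a transient
response.

Choices worth stating explicitly:

* **Minimum spacing** (`min_sep_um`, default 2 um). Boutons are
  micron-scale structures; uniform placement is conditioned on non-overlap.
  Without it, distinct boutons could sit arbitrarily close and no observer
  (human or algorithmic) could keep their identities apart across sessions.
* **Size trajectories.** Live EPBs carry observable peak ratios in
  ~[2.25, 3.25] and live TBs protrusion lengths in ~[1.25, 2.25], stable up
  to small session-to-session jitter; death removes the structure outright.
  Real boutons presumably shrink through the scoring thresholds; the study
  defines presence only through the thresholds, so the generator keeps live
  structures clearly above them and represents loss as disappearance. The
  0.4-1.0 um hysteresis band is exercised by constructed track fixtures in
  the test suite rather than by rendered data.
* **Baseline event rates are free parameters** (the study reports turnover
  only in figures): wild-type TB axons use `p_loss = 0.05` per 48-h
  interval and amyloidosis (APP) axons 0.03, encoding the reduced baseline
  dynamics of the APP group; EPB presets use 0.04 / 0.025 with no
  stimulation effect. Densities (0.135 and 0.111 boutons/um) follow from
  the reported per-group bouton counts over summed axon length.

### Rendering

`render_stack()` turns a world-session into a 3D grayscale volume:
0.25 um lateral / 1.0 um axial voxels and an anisotropic Gaussian PSF of
sigma 0.3 um (xy) / 1.2 um (z) — typical two-photon scales, since the study
reports no acquisition geometry. The backbone is a uniform line source,
extended a few microns beyond both segment ends (real axons continue
outside the analysed stretch), blurred and then calibrated so the on-axis
plateau equals `backbone_intensity`, plus a constant background. EPBs
multiply the local line density by their ratio over a sigma 0.6 um
Gaussian; because along-axon blur attenuates a Gaussian bump by the known
factor w/sqrt(w^2 + sigma_psf^2), the renderer pre-compensates so that the
*observable* peak-to-backbone ratio equals the ground-truth ratio — the
presence criterion is defined on what is observable, so truth is defined on
that scale too. TBs are side tubes of the session's protrusion length,
perpendicular to the backbone in the imaging plane. Noise is Poisson photon
noise plus Gaussian read noise (SD 2) on a backbone plateau of 100 counts
over a background of 10 — a deliberately high-quality acquisition; the
detection suite requires recall and precision of at least 0.9 under this
preset, and exact agreement with truth only on noiseless renders.

### Stimulation schedule

`itbs_schedule()` encodes the intermittent theta-burst protocol: triplet
pulses at 50 Hz, bursts at 5 Hz for 2-s trains, 8-s inter-train intervals.
Train onsets run 0, 10, ..., 190 s — the session duration is read as the
last onset time, the only reading under which the protocol delivers exactly
its 600 pulses (20 trains x 10 bursts x 3 pulses).

```{r schedule}
itbs_schedule()
```

## Detection

`trace_backbone()` follows the intensity ridge between seed anchors in
0.5 um steps, re-centring each step by an intensity-weighted centroid in
the plane perpendicular to the current heading. Per-step corrections are
clamped to 0.3 um and the heading is exponentially smoothed — the backbone
bends slowly, so larger apparent jumps are bouton pull or noise. The path
is then lightly smoothed and resampled so that centroid jitter does not
inflate the arc length; a persistent failure to progress toward the next
seed is reported as a disconnected ridge. Traced length is within 1% on
straight fixtures and 2% on a quarter-circle of radius 50 um.

`detect_epb()` scores the along-backbone intensity profile. The backbone
reference at each position is a low quantile (20th percentile) of the
profile inside a +/-5 um window, excluding +/-1 um around the scored
position, computed in two passes: candidate swellings flagged by a first
pass are masked out of every window in the second. A plain rolling median —
the natural first choice — fails in dense bouton clusters, where swellings
can occupy most of the window and the median lands on a shoulder; the
masked low quantile tracks the shaft plateau there. (The exported
`backbone_reference_intensity()` keeps the plain median contract for
single-position queries.) Candidates are local maxima of the
background-subtracted ratio profile at or above the 2x threshold — local
maxima rather than run maxima because two nearby boutons can hold the
profile above threshold between them — merged within 1 um toward the
brighter peak. The z-extent is the run of consecutive planes above half the
peak-over-background at the peak's lateral position; candidates below 2
planes are rejected. The profile extends ~2.5 um past the segment ends
(the rendered shaft continues), so end boutons get a two-sided reference.

`detect_tb()` thresholds the volume at background + 30% of the backbone
amplitude, removes voxels inside an elliptical exclusion zone around the
centerline (half-axes 0.7 um laterally, 2.4 um axially — matching the
anisotropic footprint of the blurred shaft, with the centerline
extrapolated beyond the segment ends), and groups the remainder into
6-connected components. A component's length is the largest *lateral*
distance from the centerline among voxels at or above half the backbone
amplitude (FWHM edge localisation), plus half a voxel for the centre-to-edge
offset; the axial PSF far exceeds the voxel size, so the z-extent of a thin
side branch is not resolvable and is not allowed to inflate its length.
All candidates at or above the 0.4 um floor are reported — the
establish/lose decision belongs to tracking. Components within 1 um of arc
merge to the longer one.

## Tracking and presence

Consecutive sessions are matched greedily by arc-length distance with a
2 um tolerance (about twice the lateral PSF; the study does not state a
value). Greedy matching is transparent and, as the test suite asserts on
small instances, attains the optimal assignment cardinality there.
Unmatched observations start new tracks; a track with no correspondent
simply has no observation, and classification turns that into a loss.
A reappearance after a gap is a new track — the study does not define
re-identification across gaps, so the conservative reading (new gain) is
used. `classify_presence()` applies the EPB ratio/z rule per session and
the TB hysteresis as a small state machine (not established -> established
at >= 1.0 um -> lost below 0.4 um, re-establishment again requiring
1.0 um). Gains and losses are presence transitions, which makes
N_B = N_A + gains - losses an identity. The TB rule follows the
protrusion-length contract only; the z-extent of every candidate is
recorded in the observation tables, so a stricter two-plane TB reading
remains available downstream.

## Inference battery

All tests are implemented from their rank formulas and cross-checked
against independent oracles in the test suite (full enumeration for small
samples; `stats::wilcox.test`, `stats::friedman.test` and `stats::aov` as
reference implementations):

* **Mann-Whitney U** with mid-ranks, tie-corrected variance and no
  continuity correction; reported U is min(U1, U2); exact p (via the exact
  U distribution) for untied groups of size <= 12, normal approximation
  otherwise. Rank effect size eta^2 = Z^2/N; mean ranks are reported the
  way study tables print them, and `u_from_mean_rank()` reconstructs U from
  a printed mean rank.
* **Wilcoxon signed-rank**: zeros dropped, mid-ranks of |d|, W the smaller
  signed-rank sum, tie-corrected normal Z (<= 0 by construction) without
  continuity correction — the convention under which Z = -2.67 prints as
  p = 0.008.
* **Friedman** chi-square with the standard tie-correction divisor,
  asymptotic p on k-1 degrees of freedom; a permutation p is available
  behind `exact = TRUE` for very small designs. At the study's shape
  (11 subjects x 5 conditions) the asymptotic test holds its nominal size
  (the acceptance suite simulates this), so the asymptotic p is the
  default.
* **Mixed ANOVA** (one between, one within factor) by the classical
  sums-of-squares decomposition, with Greenhouse-Geisser epsilon estimated
  from the eigenvalues of the double-centred pooled within-group covariance
  and applied to the within and interaction degrees of freedom (fractional
  dfs); effect sizes are partial eta-squared. Huynh-Feldt is deliberately
  not implemented; with two within levels epsilon is exactly 1.
* **Bonferroni** families keep raw p-values and lower the threshold to
  alpha/m, the interpretation used for the four post-stimulation days
  (m = 4).

## Effect calibration and parameter recovery

Turnover is a ratio of small counts, so its expectation is not exactly the
generating event rate: at an axon with ~25 boutons the measured group-mean
increase under a rate factor f deviates from 100(f-1)% by a few percentage
points, more at strongly stimulated intervals. Stimulation presets are
therefore **calibrated on the observable scale**:
`calibrate_stim_factor()` simulates the recovery experiment at the nominal
factor 1 + target/100 and rescales the effect (linear through zero effect
at f = 1) so the expected recovered percent increase equals the target.
Calibration and evaluation use distinct replicate streams. The acceptance
experiment recovers +88% (12 axons, baseline event probability 0.05) and
+213% (11 axons, 0.03) in group-mean TB turnover at the +2-day interval
over 200 replicate simulations per arm, through the same dynamics code
path the real pipeline uses.

## Problem sizes, numerical choices, degenerate inputs

The bundled experiments are sized for a laptop-class run: stacks of roughly
450 x 60 x 9 voxels per axon-session, oracle-equivalence over 20 axons x 9
sessions, 200-replicate recovery experiments, and 2,000-replicate null
calibrations. Degenerate inputs are handled explicitly: fully tied rank
tests warn and return p = 1; all-zero paired differences are an error;
turnover with an empty denominator is NA and flagged; a zero baseline makes
percent change NA with a warning; axons under 100 um are rejected at the
density stage with an explicit error.

## What passing tests do and do not show

The generator emulates the *design* of a longitudinal stimulation
experiment — stable baseline, genotype-dependent event rates, a transient
multiplicative stimulation effect — under idealised conditions:
pre-registered sessions (no motion or registration error), one axon per
stack, no amyloid pathology structure, no depth- or orientation-dependent
effects, and bouton sizes held clear of the scoring thresholds while
alive. Passing the oracle-equivalence and recovery suites therefore shows
that the measurement and inference machinery is correct and unbiased under
the stated model; it does not certify detection performance on real
two-photon data, where registration error, neighbouring neurites and
near-threshold boutons dominate the difficulty.
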