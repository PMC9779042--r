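---
title: "flychron: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flychron: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flychron)
```

# What the package computes

`flychron` analyzes circadian locomotor behavior of individually housed
flies recorded by video in long rectangular chambers (80 × 8 × 8 mm), and
compares that analysis with the classical single-infrared-beam monitor
readout. The pipeline is: grayscale frames → per-second (x, y) centroid
trajectories → displacement activity → sleep bouts and the morning
anticipation index (MAI) → group statistics. Two side pipelines are
included: a virtual beam monitor emulated from the same trajectories
(Trikinetics-style per-minute counts), and a maximum-projection /
threshold-ROI quantifier for fluorescence z-stacks of the kind used to
measure neuropeptide levels in axonal termini at two Zeitgeber times.

All time bookkeeping uses Zeitgeber time (ZT): ZT0 is lights-on, ZT12
lights-off under the default 12:12 LD schedule. Times are stored as integer
seconds from experiment start; ZT is always computed, never stored.

# Behavioral definitions

**Activity** is distance travelled per second: the Euclidean displacement
between consecutive detected 1 Hz positions, in mm. Seconds with an
undetected endpoint are invalid and excluded from every sum (no imputation;
imputing zeros would manufacture quiescence, imputing motion would inflate
MAI denominators).

**Sleep** is the absence of significant activity — displacement of at least
one body length per second — for at least 5 consecutive minutes. Body
length defaults to 2.5 mm (typical adult *Drosophila melanogaster*) and can
be estimated from the tracked blob's major axis or overridden. Invalid
seconds break quiescent runs, so tracking dropouts never count as sleep.

**MAI** for one cycle is total activity in ZT21–24 divided by total
activity in ZT18–24. Time-uniform activity gives 0.5; pre-dawn ramps push
it toward 1. Because single-day MAIs are noisy, the per-fly statistic is
the mean over the first three *complete* days. A complete day here is one
whose ZT18–24 window is fully covered with ≥ 95% valid seconds (the
defining publication-style rule says only "complete"; the 95% cutoff is
this package's operationalization). A zero denominator makes the day's MAI
undefined; undefined days are skipped, not zero-filled, and their count is
reported.

**Beam emulation.** A crossing is a sign change of `x − beam_x` between
consecutive detected seconds (beam at the chamber midpoint by default; an
optional dead band adds hysteresis for finite beam width). Counts aggregate
into minutes — displacement second *t* covers (t−1, t] and therefore
belongs to minute (t−1) ÷ 60 — and monitor-convention sleep is any run of
≥ 5 zero-count minutes. Because a zero-displacement second can never
produce a crossing, beam quiescence is implied by true quiescence, and any
supra-threshold movement that avoids the beam (e.g. foraging confined to
one chamber half) inflates monitor sleep relative to video sleep. That
asymmetry is the mechanism behind the monitor's sleep overestimation, and
the `"confined"` simulation preset reproduces it.

# The synthetic world

The generator is first-class, tested code: every downstream stage is
validated against its ground truth.

A `sim_config` fixes, per ZT phase, a baseline expected displacement rate
while awake (piecewise constant over intervals tiling [0, 24)), plus three
deterministic features: a linear anticipation ramp ending exactly at
lights-on, a lights-on startle increment (default 60 s — the startle is
described as coincident with lights-on but without a stated duration), and
a linear evening ramp ending at lights-off. Each second is labelled by the
ZT at its end, with intervals matched half-open (from, to], so the last
second before lights-on carries the full ramp amplitude — that convention
makes the ramp-endpoint identity exact.

Wake and sleep evolve as a two-state Markov chain with per-phase per-second
transition probabilities. While awake, each second's step has an
exponentially distributed length (mean = the expected intensity) and a
uniform heading; walls reflect (implemented exactly by triangle-wave
folding of the unbounded walk). While asleep the fly jitters within
`micro_move_mm / 2` of the position where it fell asleep, so consecutive
sleeping positions are never more than `micro_move_mm` (default 0.2 mm,
well below the body-length threshold) apart.

Preset magnitudes were chosen once as field-realistic: awake walking rates
of 0.5–3 mm/s (flies walk a few mm/s; siesta and night baselines sit below
the 2.5 mm/s significance threshold, active phases above), night
consolidation via p(fall asleep) ≈ 0.012/s with p(wake) ≈ 0.002/s (bouts of
tens of minutes), a 2 mm/s anticipation ramp from ZT21 for males. The
`"flat"` preset (uniform 1.5 mm/s, uniform sleep pressure) is the MAI = 0.5
null. Because anticipation suppression after mating could mean either a
flat or a declining pre-dawn profile — the source literature does not
resolve which — both `"mated"` (flat pre-dawn) and `"mated_declining"`
presets exist.

Rendering draws an anti-aliased dark disc (edge coverage linear in
distance) on a light background with optional Gaussian pixel noise,
quantized to 8 bits. Anti-aliasing is what lets the intensity-weighted
centroid reach ~0.1 px accuracy, which in turn keeps round-trip distance
errors inside 2%: with a hard-edged disc, per-step quantization noise of
~0.3 px would bias total path length upward on low-motion records.

Synthetic z-stacks place a hard-edged disc blob over uniform background;
slice k carries the blob at contrast × 0.5^|k − k0|, so the noise-free max
projection equals the configured blob intensity exactly and, with noise,
the center slice dominates the per-pixel maximum (adjacent slices sit
2.5 SD below at SNR 5), keeping the projection's upward max-bias small.

**What the generator does not emulate:** body posture and orientation,
grooming micro-movements, wall-following preference, inter-fly variation in
body size, arena illumination gradients, and any free-running (DD)
dynamics. A green test therefore establishes correctness of the *pipeline
mechanics* against a known stochastic world, not behavioral realism of any
particular fly strain.

# Tracking

Background is the per-pixel temporal median over ≤ 101 evenly spaced
frames; a moving fly occupies any pixel a minority of the time. Detection
thresholds the absolute difference image inside the chamber ROI with Otsu's
method (fixed override available — the acquisition literature rarely states
its segmentation, so these are declared defaults, not reconstructions),
keeps the largest 8-connected component of ≥ 4 px, and takes the
intensity-weighted centroid. Gap policy: detection gaps ≤ 5 s are bridged
by linear interpolation; longer gaps remain undetected, are excluded from
activity sums, and break sleep bouts. The rationale is asymmetry of harm:
short dropouts are almost always still-fly frames lost to noise, while long
dropouts are equipment faults that must not be scored as sleep.

# Statistics

The battery is implemented at formula level (base R supplies only
distribution functions and least squares):

* **D'Agostino–Pearson** omnibus K² (skewness z per D'Agostino 1970,
  kurtosis z per Anscombe–Glynn 1983, χ² with 2 df), as the normality gate;
  non-normal positive data is log-transformed and retested before falling
  back to ranks.
* **Kruskal–Wallis** H with tie correction; all-identical data returns
  H = 0, p = 1 rather than 0/0.
* **Dunn's post hoc** z with the tie term, Bonferroni family control by
  default (the conventional meaning of "Dunn's multiple comparisons test");
  Holm and Sidak exposed.
* **One-way ANOVA + Tukey HSD** (Tukey–Kramer for unequal n, studentized
  range p).
* **Two-way ANOVA with Type-II sums of squares** — cohorts here are
  unbalanced and the main effects are the focus, which is the textbook case
  for Type-II; it reduces to the classical decomposition when balanced.
* **Scheirer–Ray–Hare**: mid-rank everything, Type-II SS decomposition on
  the ranks, H = SS/MS_total against χ². Mid-ranks absorb ties with no
  extra correction.
* **Wilcoxon** rank-sum and signed-rank via the tie-corrected normal
  approximation with continuity correction (appropriate for n ≈ 30 with
  ties; exact small-sample enumeration is deliberately out of scope), and
  **Benjamini–Hochberg** step-up for day-family corrections.

Significance is rendered with the four-tier star convention (* < 0.05 down
to **** < 0.0001).

# Numerical and design choices

* Seeds: one master seed; per-fly seeds are master + fly index, so cohorts
  are reproducible and extensible without reshuffling existing flies.
* Otsu operates on a 256-bin histogram of the observed range; the
  threshold is the upper edge of the argmax bin.
* Bout boundary convention: a bout covering seconds (start_s, end_s] is
  split exactly at lights transitions before day/night summation.
* Trajectory CSVs serialize coordinates with 17 significant digits, making
  read(write(x)) bit-exact.
* Image files are ASCII PGM (P2): the execution environment provides no
  TIFF/PNG reader for R, and all artifacts must remain plain text; PGM is
  lossless for the quantized frames this package produces.
* Degenerate inputs are values, not crashes, wherever the field treats
  them that way: a frame with no blob is a missing detection; a
  zero-denominator MAI is undefined with a reason; an all-tied Wilcoxon
  day is p = 1.

# Scaling of the acceptance runs

Three acceptance computations are scaled to fit a single-CPU test budget,
without touching any threshold: the render→track round trip runs on a
1200 s segment (per-frame mechanics are record-length invariant); the
sleep-scorer equivalence uses a vectorized independent boundary oracle for
the 10³ full days and the literal quadratic enumeration oracle on shorter
series; and the null-calibration of the Kruskal–Wallis rejection rate
resamples identically distributed groups from a pool of 60 simulated
flat-cohort per-fly MAI values instead of re-simulating 2000 cohorts.

# Known limitations

* Pure-R tracking costs ~10 ms per frame; production-scale video (days ×
  Hz) would want the same algorithms behind compiled loops.
* The monitor emulator models a zero-width (optionally hysteretic) beam at
  one x position; multi-beam monitors and dwell-time outputs are out of
  scope.
* No free-running period estimation, actogram periodograms, or circular
  statistics.
* The normality gate tests groups separately and applies a shared log
  transform only when every group elects it; heteroscedastic mixtures route
  to ranks via the Levene (Brown–Forsythe) check at α = 0.05.
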