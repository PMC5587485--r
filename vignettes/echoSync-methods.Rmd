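---
title: "Seen but not heard: models and methods behind echoSync"
author: "echoSync authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seen but not heard: models and methods behind echoSync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Acoustic detectors are the workhorse of bat monitoring: a bat is assumed
present when its echolocation pulses are recorded. That assumption fails
if bats fly without vocalizing, or vocalize in ways the detector misses.
Pairing a thermal surveillance camera with an ultrasonic detector lets
the two channels audit each other: a flying bat *seen* on video but not
*heard* within a short matching window is evidence of silent flight (or
of an acoustic detection bias). In a 20-night field study of Hawaiian
hoary bats (*Lasiurus cinereus semotus*) conducted this way, only about
one in three video detections in a night had a synchronous call
recording.

echoSync reimplements that analysis as a tested pipeline — video
detection, call-metric extraction, event matching, correspondence
statistics — together with a synthetic-data generator so that every
stage can be exercised, and the silent-flight fraction recovered, with
no field recordings at all.

## The sensing models

**Camera.** A pinhole model of a 640x480 thermal camera with a 57 degree
horizontal field of view at 30 frames per second
(`cameraModel()`). The focal length in pixels is
`(width_px / 2) / tan(hfov / 2)` = 589.2 px, so a bat of characteristic
size $L$ (default 0.35 m, wingspan scale) at distance $d$ subtends
$f L / d$ pixels. Inverting that relation on the apparent blob size is
the proximity estimate; it is calibrated by a fixed edge-spread
correction (`psf_px`, 1.9 px) measured on rendered targets of known size
at known distance, mirroring the calibration a field deployment does
with physical targets. The camera detects bats consistently out to
about 80 m; beyond that the renderer places targets below the detection
threshold.

**Microphone and channel.** The detector triggers when a pulse's
received level exceeds the noise floor by 18 dB (`micModel()`). One-way
transmission loss is spherical spreading plus linear atmospheric
absorption, with a smooth sonar-beam directivity penalty:

$$ RL = SL - 20\log_{10} d - \alpha d - k\,(1 - \cos\theta), $$

where $SL$ is the source level at 1 m (default 110 dB), $\alpha$ the
absorption (default 0.3 dB/m, representative of ~30 kHz sound in warm
humid air; it yields an on-axis detection radius of roughly 80 m, in
line with bats being heard at 50 m and beyond), and $\theta$ the angle
between the bat's heading and the microphone direction with $k$ = 20 dB.
The off-axis term is zero on-axis and monotone — the weakest smooth model
that captures call directionality. `idealMic()` (noise floor -150 dB,
no directivity) switches the channel off for identifiability
experiments.

## The synthetic night

`simulateFlightPaths()` draws a Poisson number of passes (default 3.3/h
over a 12 h night, the field study's visual-detection scale) and assigns
each a trajectory archetype with weights 0.53 / 0.37 / 0.10
(straight / curved / erratic, the observed flight-type mix). Straight
passes are constant-heading segments, curved passes single circular arcs
with 30-180 degrees of one-signed heading change, erratic passes
piecewise segments with at least two alternating turns above 45 degrees.
Flight speed defaults to 7 m/s: the study region's literature reports
roughly 7 m/s generally and 11.1 m/s for open-airspace foraging; we take
the lower figure as typical of the mixed edge/open setting and leave it
configurable (`speed_mps`).

`renderThermalFrames()` renders bats as bright, sharp-edged ellipses
(logistic edge of 0.3 px, the optics' edge spread) whose major axis
follows the pinhole projection, over a uniform background with Gaussian
sensor noise (SD 0.01 in [0,1] units, target contrast 0.25). Insects
are the nuisance channel: Gaussian spots in two populations, distant
sub-5-pixel specks and closer out-of-focus blurs, both crossing the
frame at high angular speed. What this emulates is the *detection
geometry and filter behaviour* of field video, not infrared radiometry:
real backgrounds drift, real bats deform wing-beat by wing-beat, and
real insect phenology is richer. Passing detector tests on these frames
shows the pipeline's logic is correct, not that its thresholds transfer
unchanged to arbitrary field cameras.

`simulateCallEmissions()` gives each pass a silent flag with probability
`p_silent`, the parameter the whole pipeline exists to recover. Vocal
passes emit search-phase pulses in *bouts*: bout sizes are
3 + Poisson(1) pulses, within-bout interpulse intervals are lognormal
moment-matched to mean 217 ms / SD 98 ms, and inter-bout silences exceed
the recorder's 2 s trigger window (2.2 s + lognormal). The bout
structure is what reconciles the published summary statistics: a mean
IPI of 217 ms together with a mean pulse rate of 6.7 Hz (with rate
defined as $n / [(n-1)\overline{IPI} + d_n]$) is only possible if
sequences are short, three to five pulses; long uninterrupted trains
would drive the mean rate toward $1/\overline{IPI} \approx 4.6$ Hz. The
bout-size parameter was fixed once by forward simulation of that
identity. Spectral parameters are drawn around a 29.3 kHz peak with the
sweep descending from `fmax` (start) to `fmin` (end); with probability
0.10 a pass ends in a terminal buzz (>= 5 pulses at IPI <= 50 ms), with
probability 0.02 low-frequency (< 20 kHz), long (> 10 ms) social pulses
are inserted — the shares of buzz and social files in the published
recordings.

Seeding: one root seed, with deterministic child streams per subsystem
(flight, insects, calls, noise), so each stage is reproducible in
isolation (`simulateNight()`).

## Video detection

Every 10th frame is analyzed (3 frames/s at 30 fps), so an event seen in
two consecutive analyzed frames spans at least 0.3 s — the published
minimum event duration; a single-frame hit is not an event. The
detector is background subtraction against a rolling per-pixel temporal
median (window 90 analyzed frames) with a threshold of 4 robust SDs; the
noise scale is pooled over pixels (a per-pixel MAD over a short window
is far noisier than the spatially homogeneous sensor noise it
estimates). Above-threshold pixels are grouped by 8-connectivity (an
in-package sparse BFS labeller; the choice is the permissive reading of
"contiguous pixels") and components under 5 pixels are discarded — the
absolute small-target filter that also imposes the ~80 m range limit.

Tracks are greedy nearest-neighbour associations. The unit-level
default gate is 60 px per analyzed frame, but the pipeline wrappers use
200 px: a bat at 7 m/s crossing at 10 m subtends ~140 px per analyzed
frame, and a 60 px gate would silently drop exactly the near-range
passes the study cares most about. One skipped analyzed frame is
tolerated. Insect-signature tracks are removed only when *both*
nuisance cues agree (median border sharpness < 0.4 *and* median angular
speed > 100 px/frame); ties favour the bat call, because a missed bat
biases the study's headline proportion while a rare insect admitted as a
bat does not move it measurably.

Flight classification checks erratic first (>= 2 alternating-sign turns
above 45 degrees), then straight (net heading change < 30 degrees),
else curved; using the *net* change for straightness keeps per-step
centroid jitter from accumulating into a spurious curvature call.
Proximity uses the nearest approach (minimum per-blob distance
estimate) with class boundaries at 25 / 50 / 80 m, inclusive on the
near side with a 1e-9 relative tolerance so a boundary distance lands in
the nearer class. Temporally overlapping tracks merge into one
multi-bat event — one visual detection, as the published tallies count
them — and are labelled agonistic when two non-straight tracks approach
within 3 m.

## Acoustic processing

`detectPulses()` computes an STFT with 256-sample windows and 75%
overlap (1.33 ms / 0.33 ms at 192 kHz — short enough to resolve 1 ms
pulses, long enough for 750 Hz bins). The per-file noise floor is the
median spectral magnitude; a pulse is a maximal run of frames whose peak
bin exceeds the floor by 15 dB; `fmin`/`fmax` are the extreme
frequencies within 15 dB of the in-pulse peak (the measurement threshold
is not stated in the source study; we mirror its 15 dB amplitude
criterion, and likewise read both the ">= 15 dB" pulse criterion and
the 18 dB trigger as relative to the noise floor). Onset and duration
are corrected for window overlap: the first hot window starts
`nfft - hop` samples before the pulse, and the hot run overstates the
duration by the same amount; on synthesized sweeps both are then exact
to one hop.

File grouping reproduces the recorder's trigger logic (2 s quiet closes
a file, 15 s caps it). Search-phase sequences are runs of >= 3 pulses
with amplitudes >= 15 dB and onset gaps >= 100 ms; per-pulse bandwidth
is `fmax - fmin` and modulation `100 * bandwidth / fmax` (for a
descending sweep `fmax` is the start frequency, which reconciles the
"percent of start frequency" table heading with the formula's wording).
Pulse rate is `n / span` with the span running to the end of the last
pulse — the literal wording (milliseconds divided by count) yields
ms/pulse, whose reciprocal is the only reading consistent with the
published 217 ms / 6.7 Hz pair. Terminal buzzes are >= 5 consecutive
pulses at IPI <= 50 ms; social flags need >= 2 pulses below 20 kHz
longer than 10 ms; the flags are not exclusive.

## Matching and statistics

A video event is synchronous when at least one call file starts within
±30 s of the event start (two-sided — the published "within 30 s" names
no direction, and the signed 2 s median offset is consistent with a
symmetric window; event starts and trigger starts are the reference
times). Nightly tallies count call files, video events and matched
events; the nightly proportion is `100 * synchronous / visual`, and the
across-night average is unweighted.

`fisherExact()` enumerates every r x c table with the observed margins
(depth-first over row compositions), computes each probability from
log-factorials, and sums those not exceeding the observed table's
probability. The tie tolerance is relative (1e-7 on the log scale): an
absolute tolerance breaks down for strongly unbalanced tables whose
observed probability is itself below it. The enumeration agrees with
`stats::fisher.test` to 1e-7 on every table we throw at both, and the
enumerated probabilities sum to 1 within 1e-9. The published p-values
turn out to be Bonferroni-multiplied with a family of four (the
proximity test plus three per-proximity flight tests): .0011 is 4 x
.000283 and .4692 is 4 x .117285. The package therefore reports raw and
adjusted p side by side (`bonferroni()`).

Sampled-airspace geometry: the camera pyramid `(1/3) W(d) H(d) d` with
the field-of-view footprint rounded to whole metres (54 x 41 m at 50 m,
the published reporting convention — this is what makes the volume
exactly 36,900 m^3), against the microphone hemisphere
`(2/3) pi d^3` = 261,799 m^3 at 50 m; the camera samples ~14% of the
microphone's airspace. Both volumes scale as $d^3$, so the ratio is
distance-invariant up to the rounding.

## Recovery experiments

`recoverSilentFraction()` is the identifiability experiment: near-range
passes (8-20 m) on a regular 90 s grid, an ideal channel, and the
complete render + detect + track + classify + group + match pipeline.
The grid matters: under Poisson arrivals a silent pass frequently falls
within 30 s of a vocal neighbour and borrows its call files, biasing
the recovered silent fraction downward. Silence is assigned by balanced
randomization (exactly `round(n * p_silent)` passes silent, randomly
placed), the standard variance-reduction device, so the comparison
against `(1 - p_silent) * 100` measures pipeline error rather than
binomial noise of the silence draw. At 500 passes the pipeline recovers
0 / 0.3 / 0.7 exactly in our tests.

`recoverCallMetrics()` simulates vocal passes, records them through an
ideal channel, groups the stream into trigger files, extracts
search-phase sequences and summarizes — recovering mean IPI, rate and
peak frequency within a few percent of the generating values at the
published sample size (>= 584 pulses).

## Numerical choices and degenerate inputs

Distances clamp at 0.1 m in the channel; zero-size blobs yield infinite
distance estimates and fall out of range; empty pass lists render valid
noise-only stacks; empty pulse streams group into zero files; nights
with no visual detections report an undefined (NA) proportion and are
excluded from averages; degenerate Fisher margins give p = 1; table
percentages round half away from zero (the printing convention), while
all underlying statistics stay unrounded.

Problem sizes in the test-suite experiments (500 passes per silent
fraction, ~600-800 pulses for call metrics, 42 rendered passes for the
recall check) are the package's chosen defaults for these experiments;
they hold the binomial and sampling errors comfortably inside the
asserted tolerances.

## Known limitations

Single-sensor geometry: range comes only from apparent size, so
proximity is accurate to a few metres and interaction distances are
coarse. The renderer is not radiometric; detector thresholds are tuned
to its noise model and would need re-calibration on real footage. The
insect discriminator encodes the two published cues (blur, speed) and
nothing else; slow blurry insects pass as bats, as they did in the
original manual review. Clock skew between channels is assumed
corrected (the matching window dwarfs the observed few-second drift).
Species identification, weather and moonlight covariates are out of
scope.
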