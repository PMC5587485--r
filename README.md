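# echoSync

Correspondence analysis of thermal-video and ultrasonic-acoustic bat
detections — and a simulator to test it with.

## The problem

Acoustic detectors are the standard tool for monitoring echolocating
bats: a bat is counted as present when its ultrasonic pulses are
recorded. That inference fails if flying bats sometimes *do not call*,
or call in ways the detector misses. Pairing a thermal surveillance
camera with an ultrasonic detector lets the two channels audit each
other: a bat seen on video with no call file recorded within a ±30 s
window of the sighting is a "seen but not heard" event. In a 20-night
field study of Hawaiian hoary bats (*Lasiurus cinereus semotus*) run
this way, only about 31% of nightly video detections had a synchronous
acoustic detection — evidence that silent flight (or a strong acoustic
detection bias) is common.

echoSync is for researchers who want to run, audit or extend that
analysis. It implements:

- **video detection** — rolling-median background subtraction,
  8-connected blob extraction with the <5-pixel small-target filter,
  nearest-neighbour tracking, bat/insect discrimination, and
  classification of each event by proximity (near ≤25 m / mid ≤50 m /
  far ≤80 m, from apparent size through the pinhole relation
  d = f·L/size), flight path (straight/curved/erratic) and conspecific
  interaction;
- **acoustic processing** — STFT pulse detection (256-sample windows,
  75% overlap, 15 dB criterion over the median noise floor), recorder
  trigger-file grouping (2 s window / 15 s cap), search-phase
  extraction (≥3 pulses, IPIs ≥100 ms, ≥15 dB), and the call metrics:
  interpulse interval, pulse rate n/span, bandwidth fmax−fmin,
  modulation 100·bandwidth/fmax, buzz and social flags;
- **event matching and statistics** — ±30 s synchronization, nightly
  tallies and proportions, Pearson correlation, an exact test for r×c
  contingency tables by full enumeration of the margin-constrained
  tables (multivariate hypergeometric probabilities via log-factorials,
  two-sided p as the mass of tables no more probable than observed),
  Bonferroni control, and the sampled-airspace geometry (camera pyramid
  (1/3)·W·H·d vs microphone hemisphere (2/3)·π·d³);
- **a seeded synthetic-data generator** — nights of bat passes with the
  observed flight mix, bout-structured echolocation matched to the
  published call-structure table, a parametric acoustic channel
  (spherical spreading, absorption, beam directivity, 18 dB trigger),
  thermal-frame rendering, insect nuisance targets, and full ground
  truth including a controllable silent-flight probability `p_silent`
  that the pipeline can provably recover.

## Worked example

Published per-night counts ship with the package; the simulator
provides everything else.

```r
library(echoSync)

nc <- exampleNightlyCounts()
tally <- data.frame(night = nc$night, acoustic_n = nc$acoustic_n,
                    visual_n = nc$visual_n,
                    synchronous_n = nc$synchronous_n,
                    proportion_pct = 100 * nc$synchronous_n / nc$visual_n)
averageNightlyProportion(tally)
#> [1] 30.94906            # the "31%" headline
pearsonCorrelation(nc$acoustic_n, nc$visual_n)[c("r", "p")]
#> $r [1] 0.6402141        # nightly acoustic vs visual counts, r = .64
#> $p [1] 0.002361228

samplingVolumes(cameraModel(), 50)
#> $v_camera_m3 36900  $v_mic_m3 261799.4  $ratio_pct 14.09  (54 x 41 m FOV)

# a short simulated night: 10 near-range passes, 69% silent, ideal channel
cfg <- simConfig(p_silent = 0.69, seed = 42, mic = idealMic(),
                 atmosphere = atmosphereModel(0), insect_rate = 0)
sim <- simulateNight(cfg, start_times = seq(45, 855, by = 90),
                     depth_range = c(8, 20))
sim$truth
#> GroundTruthLog: 10 passes (8 silent), 9 emitted pulses (9 recorded)

ana <- analyzeNightClips(sim, night = "2014-09-20", render_insects = FALSE)
ana$tally
#>        night acoustic_n visual_n synchronous_n proportion_pct
#> 1 2014-09-20          2       10             2             20
head(ana$video_events[, c("t_start", "proximity", "distance_m", "flight")], 3)
#>   t_start proximity distance_m   flight
#> 1      45      near  11.334173 straight
#> 2     136      near  16.100505 straight
#> 3     225      near   9.545088   curved
offsetDiagnostics(ana$matches)
#> [1] 0.109745           # median |video - audio| offset, seconds
```

All ten passes were found on video and classified near-range; the two
vocal passes (8 of 10 were silent) produced the only call files, and the
recovered synchronous proportion (20%, i.e. 2/10) estimates
(1 − p_silent)·100 ≈ 31% up to the granularity of ten passes. At scale,
`recoverSilentFraction(p_silent = 0.7, n_passes = 500)` recovers 30.0%.

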