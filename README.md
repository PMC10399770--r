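# cavesong

Detection and population-signature analysis of cavefish click sounds in R.

Mexican cavefish (*Astyanax mexicanus*) produce short broadband clicks —
singly and in rapid multi-pulse trains — and isolated cave populations
differ measurably in the acoustic parameters of these sounds. `cavesong`
implements the full analysis chain for this kind of passive-acoustic
material:

* **Detection** — matched filtering of hydrophone recordings against a
  reference click (per-lag normalized correlation, computed exactly but
  fast with FFT convolution), correlation-maximum picking with
  non-maximum suppression, and *supervised threshold tuning* against
  annotated ground truth so that a chosen fraction (by default 95%) of
  reported signals are true signals;
* **Segmentation** — envelope-based pulse delimitation at the −20 dB
  level with model-based boundary reconstruction when the level sits in
  the noise, and classification into *Single Clicks* (one pulse < 20 ms,
  isolated by > 1 s) and *Serial Clicks* (pulse trains);
* **Acoustic parameters** — duration, dominant frequency and
  band-limited signal-to-noise ratio per single click; pulse number,
  mean pulse duration, mean interpulse duration, pulse rate and total
  duration per serial click;
* **Population signatures** — Kruskal–Wallis tests with Dunn post hoc
  comparisons (plus normality/homoscedasticity assumption checks), PCA
  acoustic spaces with 95% confidence ellipses, permuted discriminant
  function analysis (leave-one-out reclassification against a label
  permutation null), and geography-projected hierarchical clustering;
* **Synthesis** — a seeded soundscape generator (exponentially decaying
  clicks, jittered trains, white/pink noise, exact per-pulse ground
  truth) so every stage can be validated end to end without field
  recordings.

All modelling objects are plain S3 with `print`/`summary`/`predict`/
`plot` methods; internals are base R plus `signal`, `MASS`, `ape`,
`nortest`.

## Worked example

Generate a one-minute survey with 20 planted clicks at a
click-amplitude to noise-RMS ratio of 5, tune the detector on the
ground truth, then segment and measure:

```r
library(cavesong)

spec <- click_soundscape_spec(
  n_clicks = 20, duration_s = 60,
  click = click_spec(dominant_freq = 2000, duration_ms = 5,
                     amplitude = 0.05),
  noise_rms = 0.01, noise_model = "pink", seed = 7)
ss <- synth_soundscape(spec)
ss$recording
#> <recording> synthetic: 60.000 s at 44100 Hz (2646000 samples)

tmpl <- click_template(synth_click(click_spec(2000, 5, 0.05), 44100), 44100)
det <- tune_threshold(ss$recording, tmpl, ss$annotations,
                      target = 0.95, criterion = "recall")
det
#> <tuned_detector> threshold 0.7806 (recall >= 0.95)
#> <detection_metrics> TP 19  FP 0  FN 1 | precision 1.000  recall 0.950 (tol 0.01 s)

hits <- predict(det, ss$recording)
ev <- segment_events(ss$recording, hits)
ev
#> <sound_events> 19 events (19 single, 0 serial, 0 unclassified)

ft <- build_feature_table(ev, ss$recording, group = "demo")
head(ft$single, 3)
#>      event_id group duration_ms dominant_frequency_hz      snr
#> 1 synthetic#1  demo    1.802947              1981.055 5.055337
#> 2 synthetic#2  demo    1.850789              1916.455 3.665997
#> 3 synthetic#3  demo    2.971547              1937.988 2.839541

summary(ft$single$dominant_frequency_hz)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    1916    1976    1992    1992    2013    2035
```

Two synthetic populations whose clicks differ in dominant frequency are
told apart by the signature statistics:

```r
survey <- function(freq, label, seed) {
  ss <- synth_soundscape(click_soundscape_spec(
    20, 60, click_spec(freq, 5, 0.05), noise_rms = 0.0025, seed = seed))
  tmpl <- click_template(synth_click(click_spec(freq, 5, 0.05), 44100), 44100)
  hits <- detect_events(matched_filter(ss$recording, tmpl), 0.5)
  ev <- segment_events(ss$recording, hits)
  build_feature_table(ev, ss$recording, group = label)$single
}
fa <- survey(1900, "cave_a", 81)
fb <- survey(2100, "cave_b", 82)
tab <- structure(rbind(fa, fb), class = class(fa))

compare_groups(tab, "dominant_frequency_hz")
#> <group_comparison> dominant_frequency_hz: Kruskal-Wallis H = 30.26 (df 1), p = 3.77e-08
#>   Dunn post hoc (bonferroni):
#>     cave_a vs cave_b: z = -5.501, p = 3.77e-08

pdfa(tab[, c("duration_ms", "dominant_frequency_hz", "snr")],
     factor(tab$group), n_permutations = 999, seed = 9)
#> <pdfa> overall reclassification 100.0% (LOO), p = 0.001 (999 permutations)
#>   per group: cave_a 100%, cave_b 100%
```

The methods vignette (`vignettes/click-analysis.Rmd`) documents the
generator model, the tuning criteria, the noise-limited boundary
reconstruction, the band-limited SNR definition, and the statistical
layer, including known limitations.

A command-line front end covering the same pipeline
(`synth`, `detect`, `validate`, `segment`, `features`, `signatures`)
is installed at `inst/cli/cavesong`.

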