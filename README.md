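# splinetrend

Spline-based removal of head-motion trends from dual-axis swallowing
accelerometry signals.

Swallowing accelerometry records neck-surface vibrations on two axes
(anterior–posterior, superior–inferior) as a non-invasive screen for
dysphagia.  Head movements superimpose large low-frequency components on
these recordings, which corrupts swallow segmentation and inflates the
apparent statistical persistence of the signals.  This package is for
biomedical-signal researchers who need to strip those components before any
downstream processing.

## Method

A recording per axis is modelled as `g(n) = g_LF(n) + s(n) + w(n)`: the
head-motion trend, the swallowing component and additive noise.  The trend
is estimated as the least-squares spline approximation of `g` on a coarse
knot lattice: with B-splines `beta^n` of degree `n` (default 3, i.e.
fourth-order splines) expanded by an integer factor `m = round(f_s / f_r)`,
the orthogonal projection onto `span{ beta^n((i - t_k)/m) }` is computed by
the classical three-step pipeline

```
prefilter (correlate with b^n_m)  ->  decimate (sample at the knots)
                                  ->  postfilter (inverse Gram solve)
```

and reconstructed by the indirect B-spline transform.  The detrended signal
is `g - ghat_LF`.  The resampling frequency `f_r` (knots per second) sits
above the head-motion band and far below the swallowing band; the
approximation error decays with the `(degree + 1)`-th power of the knot
spacing (Strang–Fix), which is why cubic splines are the default.

Alongside the spline detrender the package ships smoothness priors (SPM),
piecewise polynomial fitting (PPF) and EMD baselines, a synthetic dual-axis
generator with ground truth, Monte-Carlo evaluation experiments (optimal-f_r
sweep, four-method NMSE comparison over 0–30 dB SNR), a variance-threshold
swallow segmenter scored by CSS/NFP/NFN against truth with a strict >90%
capture rule, and detrended fluctuation analysis (DFA) of the scaling
exponent.  See the vignette in `vignettes/` for the full model description
and design rationale.

## Worked example

```r
library(splinetrend)

cfg <- synthetic_config(snr_db = 10, seed = 1)   # 40 s at 1 kHz, 5 swallows
rec <- gen_recording(cfg)
rec
#> <swacc_recording> 40001 samples at 1000 Hz (40 s), 5 events, SNR 10 dB

det <- detrend_recording(rec, method = "spline", fr_ap = 4, fr_si = 4)
nmse(rec$truth$ap$trend, det$data$trend_ap)
#> [1] 0.05750503

seg <- segment_swallows(det$data$detrended_ap, rec$f_s)
score_segmentation(rec$events, seg)
#> <segmentation_score> TNS 5, CSS 5, NFP 0, NFN 0

dfa_alpha(rec$data$ap)$alpha            # persistence with the trend present
#> [1] 1.146447
dfa_alpha(det$data$detrended_ap)$alpha  # after removal
#> [1] 0.5912223
```

The trend estimate recovers the head-motion component to about 6% NMSE at
10 dB SNR, all five simulated swallows are segmented correctly from the
detrended signal, and the DFA exponent drops from strongly persistent
(~1.15, trend-dominated) towards the uncorrelated regime (~0.6) once the
trend is removed.  `autoplot()` methods exist for recordings, detrending
results, sweep/comparison experiments and DFA curves; `tidy()`/`glance()`
return tibbles for every result type.

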