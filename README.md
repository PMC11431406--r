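# qthresh

Self-adaptive Tsallis-entropy multi-level image thresholding for R.

Histogram thresholding segments an image by choosing `m` gray-level
thresholds that partition the intensity axis into `m + 1` classes.
Entropy-based selection maximises the joint entropy of the within-class
distributions; the classical Kapur criterion uses Shannon entropy, which
assumes pixel intensities compose additively. Images produced by a single
physical mechanism — infrared frames, CT slices, satellite bands — carry
long-range correlations among pixels that break that additivity. The
Tsallis entropy

$$S_q = \frac{1 - \sum_i p_i^q}{q - 1}$$

generalises Shannon entropy (the `q -> 1` limit) with a non-extensive
index `q` that calibrates the departure, composing under the
pseudo-additive rule `S_q(A+B) = S_q(A) + S_q(B) + (1-q) S_q(A) S_q(B)`.

This package implements the *self-adaptive* variant: instead of fixing
`q` empirically, `q*` is estimated per image by maximising the
q-redundancy

$$R_T(q) = 1 - S_q / S_q^{\max}, \qquad q^* = \arg\max_q R_T(q),$$

and the `m` thresholds maximise the pseudo-additive Tsallis objective

$$S_q(t_1,\dots,t_m) = \sum_j S_q^j + (1-q)\sum_{j<k} S_q^j S_q^k +
\dots + (1-q)^m \prod_j S_q^j.$$

It is intended for researchers comparing entropy criteria for
segmentation: the Kapur (Shannon) and fixed-`q` Tsallis (default
`q = 0.8`) baselines, PSNR/SSIM quality scoring, batch evaluation with
most-suitable-rate summaries, seeded synthetic image generators, and an
exhaustive oracle plus a reproducible differential-evolution search.

## Worked example

```r
library(qthresh)

# a synthetic scene: broad trimodal background, three small bright objects
background <- mixture_spec(c(50, 110, 170), c(22, 28, 24))
series <- scene_series_spec(background, n_frames = 3, n_objects = 3,
                            size_range = c(4, 9),
                            intensity_range = c(230, 250), seed = 11)
img <- gen_scene_series(series, 200, 200)[[1]]

# how strong are the histogram's correlations? scan the q-redundancy curve
est <- estimate_q(compute_histogram(img)$probs)
est
#> <q_estimate> q* = 0.41 (R_T = 0.0776) over 199 grid points

# segment at four thresholds with the self-adaptive index
seg <- segment_image(img, m = 4, method = "adaptive",
                     cfg = optimizer_config(seed = 1))
glance(seg)
#> # A tibble: 1 × 8
#>   method       m q_used objective optimizer   mse psnr_db  ssim
#>   <chr>    <int>  <dbl>     <dbl> <chr>     <dbl>   <dbl> <dbl>
#> 1 adaptive     4   0.41   145631. de         191.    25.3 0.968

tidy(seg)        # per-class gray ranges, pixel shares, rendered levels
autoplot(seg)    # reconstructed image
autoplot(est)    # redundancy curve with q* marked
```

`q_used = 0.41` is the index maximising the histogram's q-redundancy; the
objective value is the pseudo-additive entropy attained by the five-class
partition, and PSNR ≈ 25 dB means differences between the class-mean
reconstruction and the original are visible but minor. Compare methods over an image set:

```r
frames <- gen_scene_series(series, 200, 200)
names(frames) <- paste0("frame", seq_along(frames))
records <- run_batch(frames, m_values = 4,
                     cfg = optimizer_config(seed = 1))
suitability(records, score = "psnr")   # fraction of images each method wins
```

The repeated-run robustness diagnostic (sorted fitness values over
independently seeded searches; a flat tail means the stochastic optimiser
reproduces its maximum):

```r
prof <- fitness_robustness(img, m = 4, runs = 100, base_seed = 5)
prof
#> <fitness_profile> adaptive, m = 4: best = 145631.329430 attained in 100/100 runs
autoplot(prof)
```

A thin command-line wrapper over these functions ships in
`inst/scripts/qthresh.R` (subcommands `segment`, `metrics`, `qscan`,
`batch`, `gen`, `robustness`).

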