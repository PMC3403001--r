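# tentropy

Transfer entropy estimation and directed-coupling change detection for
short, outlier-contaminated time series — the situation typical of
biomedical recordings, where stationary segments are a few hundred
samples long and heavy-tailed artifacts (sighs, apneas, movement) are
part of the signal.

Transfer entropy quantifies the information that a lagged source value
carries about a target beyond the target's own past:

$$
T_{X \to Y}(\tau) = \sum p(y_i, y_{i-1}, x_{i-\tau})
\log_2 \frac{p(y_i, y_{i-1}, x_{i-\tau})\,p(y_{i-1})}
            {p(y_{i-1}, x_{i-\tau})\,p(y_i, y_{i-1})}
\quad \text{(bits)}.
$$

It is asymmetric (directional), nonparametric, and captures nonlinear
coupling. The hard part on short data is estimating the trivariate
density; the package implements the three standard answers side by side:

* **fixed binning with ranking** — ordinal sampling followed by a
  `Q`-per-dimension histogram plug-in; simplest and fastest, exactly
  invariant to monotone transforms, noticeable upward bias on small
  samples;
* **kernel density estimation (KDE)** — product Gaussian kernels on the
  raw values with rule-of-thumb bandwidths `h = 1.06·α·σ̂·P^(-1/5)`;
  lowest off-coupling estimates, at quadratic cost;
* **Darbellay–Vajda (D-V) adaptive partitioning** extended to three
  dimensions — recursive octant splitting of the rank cube driven by a
  chi-square uniformity test, concentrating resolution where the data
  are.

Around the estimators sit the tools needed for inference: shuffle
surrogates with a 95th-percentile significance rule, lag scanning,
one-sided rank-sum / signed-rank group comparisons, a simulation
benchmark (lag-2 squared coupling, Laplace noise, SNR sweep with
detection thresholds), and a breath-by-breath respiratory pipeline
(minute ventilation, 0.05–0.2 cycles/breath zero-phase Butterworth
band-pass, maximum-variance window, pre/post paired comparison) with a
synthetic cohort generator.

## Worked example

A coupled pair generated by the benchmark model (source drives target
through a squared map at lag 2, SNR 20 dB, 202 samples) ships with the
package:

```r
library(tentropy)

f <- system.file("extdata", "coupled_pair_snr20.csv", package = "tentropy")
x <- read_series(f, column = 1)   # source
y <- read_series(f, column = 2)   # target

estimate_te(x, y, tau = 2, method = "dv")
#> Transfer entropy (dv): 0.3727 bits at tau = 2
#>   params: L = 44
```

0.37 bits means that, knowing the source two steps back, the average
uncertainty in the next target value drops by about a third of a bit
beyond what the target's own previous value explains; `L = 44` is the
number of adaptive boxes the partitioner retained. The three estimators
agree on the order of magnitude, with the characteristic spread (fixed
bins highest, KDE lowest):

```r
dplyr::bind_rows(
  tidy(estimate_te(x, y, 2, "fixed_bin", Q = 4)),
  tidy(estimate_te(x, y, 2, "kde", alpha = 1.5)),
  tidy(estimate_te(x, y, 2, "dv")))
#> # A tibble: 3 × 6
#>   method      tau te_bits     Q alpha     L
#>   <chr>     <int>   <dbl> <int> <dbl> <int>
#> 1 fixed_bin     2   0.428     4  NA      NA
#> 2 kde           2   0.334    NA   1.5    NA
#> 3 dv            2   0.373    NA  NA      44
```

When the coupling lag is unknown, scan lags with surrogate screening —
only the true lag clears its shuffle-null 95th percentile:

```r
sc <- scan_lags(x, y, tau_range = 0:5, method = "dv",
                n_surrogates = 100, seed = 1)
tidy(sc)
#> # A tibble: 6 × 4
#>     tau te_bits percentile_95 significant
#>   <int>   <dbl>         <dbl> <lgl>
#> 1     0  0.145          0.186 FALSE
#> 2     1  0.0658         0.204 FALSE
#> 3     2  0.373          0.187 TRUE
#> 4     3  0.0530         0.185 FALSE
#> 5     4  0.115          0.207 FALSE
#> 6     5  0.121          0.193 FALSE
glance(sc)$best_tau
#> [1] 2
```

`autoplot(sc)` draws the lag profile with its significance reference;
`run_sweep()` / `detection_thresholds()` reproduce the SNR benchmark;
`generate_synthetic_cohort()` / `run_prepost_study()` run the full
pre/post respiratory study on synthetic breath tables. A command-line
front end with the same operations lives at `inst/cli/te.R`
(subcommands `estimate`, `scan`, `simulate`, `sweep`, `table1`,
`cohort-gen`, `respiratory`).

See the methods vignette
(`vignettes/transfer-entropy-methods.Rmd`) for the estimator definitions,
the SNR calibration of the benchmark, the chi-square statistic variants,
and known limitations.

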