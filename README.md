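# mkse — multiscale partition-based Kolmogorov–Sinai entropy for heartbeat series

`mkse` quantifies the complexity of heart rate variability (HRV): given
RR-interval series (the times between consecutive heartbeats, in seconds),
it estimates the **partition-based Kolmogorov–Sinai entropy** of each series
across time scales, and compares the resulting entropy surfaces between
subject groups (e.g. young vs elderly, or healthy vs congestive heart
failure vs atrial fibrillation) with a nonparametric statistical protocol.
It is aimed at physiologists and biostatisticians who work with beat-to-beat
interval data and want a complexity biomarker that does not require choosing
embedding dimensions or tolerance radii.

## The estimator

For a series $x_1,\dots,x_N$, scale factor $\tau$ and partition cardinality
$n$:

1. **Coarse-grain**: $y_j^{(\tau)} = \frac1\tau\sum_{i=(j-1)\tau+1}^{j\tau} x_i$,
   for $j = 1,\dots,\lfloor N/\tau\rfloor$.
2. **Symbolize**: divide a fixed amplitude interval $I=[l,u]$ into $n$
   equal cells and replace each $y_j$ by the index of the cell containing
   it, giving a string $\omega$ over $\{1,\dots,n\}$.
3. **Compress**: parse $\omega$ with a lossless pair-coding dictionary
   compressor (CASToRe family — each new dictionary word is the
   concatenation of the two longest matching known words) and set
   $$\hat h(\tau, n) = \frac{\mathrm{bits}(\omega)}{|\omega|},$$
   the compressed bit length per symbol — the computable surrogate of the
   algorithmic information content whose per-symbol limit, by Brudno's
   theorem, is the partition-based K-S entropy $h_\mu(f, Z)$.

The matrix $\hat h(\tau, n)$ over $\tau = 1,\dots,10$ and $n = 2,\dots,20$
(19 partitions) is the **MKSE surface**; groups are compared cell-by-cell
with Mann–Whitney (two groups) or Kruskal–Wallis plus pairwise follow-ups
(three or more), Bonferroni-corrected over the number of scales at fixed
partition ($\alpha = 0.05/10 = 0.005$; pairwise $0.005/3 \approx 0.0017$).
See `vignette("mkse-methods")` for conventions, finite-length behaviour of
the compression estimate, and design rationale.

## Worked example

Two synthetic cohorts with contrasting beat-to-beat variability (AR(1)
surrogates; the package also reads real RR files, one interval per line or
`time_s,rr_s` CSV):

```r
library(mkse)

young   <- generate_cohort(8, rr_sd = 0.08, series_length = 6000, group = "young",   seed = 101)
elderly <- generate_cohort(8, rr_sd = 0.03, series_length = 6000, group = "elderly", seed = 202)

surf <- mkse(rbind(young, elderly), scales = 1:5, cardinalities = c(2, 6, 10, 14, 18))
surf
#> # A tibble: 400 × 7
#>   subject_id group     tau     n entropy length out_of_range
#>   <chr>      <chr>   <int> <int>   <dbl>  <int>        <int>
#> 1 elderly01  elderly     1     2   0.841   6000            0
#> 2 elderly01  elderly     1     6   0.884   6000            0
#> 3 elderly01  elderly     1    10   1.29    6000            0
#> 4 elderly01  elderly     1    14   1.79    6000            0
#> # ℹ 396 more rows
```

Each row is one cell of one subject's MKSE surface: `entropy` is the
estimated rate in bits per symbol at scale `tau` and partition cardinality
`n` (the amplitude interval defaulted to the cohort's global RR range,
0.600–1.251 s here). Entropy grows with `n` (finer partitions resolve more
of the dynamics) and is higher for the more variable cohort. Comparing the
groups:

```r
cmp <- mkse_mann_whitney(surf, alpha0 = 0.05)
cmp
#> <mkse_grid_test> mann_whitney: elderly vs young
#>   25 cells, threshold 0.01, 25 significant
glance(cmp)
#> # A tibble: 1 × 7
#>   test         n_groups n_cells n_significant    min_p alpha0 alpha_corrected
#>   <chr>           <int>   <int>         <int>    <dbl>  <dbl>           <dbl>
#> 1 mann_whitney        2      25            25 0.000155   0.05            0.01
```

All 25 cells separate the cohorts at the Bonferroni threshold
(`0.05 / 5` scales here; with the default 10 scales the threshold is
0.005). `tidy(cmp)` gives the per-cell p-values, `autoplot(cmp)` the
p-value heatmap, and `plot_mkse(surf)` the median-entropy-vs-scale panels.

The compressor can also be validated directly against sources with known
entropy rate:

```r
s <- generate_symbolic("markov", 1e5,
                       transition = rbind(c(0.9, 0.1), c(0.1, 0.9)), seed = 7)
attr(s, "analytic_rate")   #> 0.469  (closed form, bits/symbol)
estimate_entropy_rate(s)   #> 0.713  (finite-length estimate: the analytic
                           #>         rate plus the dictionary-coder overhead,
                           #>         which decays only like 1/log n)
```

File-based workflows use `read_rr()`, `mkse_config()` (presets
`"fantasia"`: 2 Hz resampling, interval 0.60–1.84 s; `"longterm"`:
10,000-sample truncation, interval 0.32–1.25 s) and `run_pipeline()`, which
writes a tidy surface CSV plus a JSON run manifest. A thin command-line
front end with `synth`, `compress`, `run` and `compare` subcommands is
installed at `system.file("cli", "mkse.R", package = "mkse")`, and a small
synthetic example series at
`system.file("extdata", "synthetic_rr_example.txt", package = "mkse")`.

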