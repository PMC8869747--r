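---
title: "Multiscale partition-based K-S entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale partition-based K-S entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkse)
library(dplyr)
```

## The quantity being estimated

Heartbeat dynamics are observed as RR-interval series: the times between
consecutive R-waves, in seconds. The Kolmogorov–Sinai (K-S) entropy of a
dynamical system is the supremum, over finite partitions of the state space,
of the per-step information production rate; it is infinite for stochastic
systems and requires a *generating* partition to attain — something that is
essentially never available for physiological data. This package therefore
estimates the **partition-based** K-S entropy: the entropy rate of the
symbolic dynamics relative to one *fixed, uniform* partition of the
amplitude range. That quantity is always finite, is monotone in the
refinement of the partition, and turns the choice of partition from a
nuisance into an explicit analysis axis.

Concretely, an RR series is mapped to a symbol string by a uniform partition
of an amplitude interval $I = [l, u]$ into $n$ equal cells: value $v$ gets
symbol $k$ when $v$ falls in cell $k$. The entropy rate of the resulting
string is approximated through its algorithmic information content (AIC):
for typical orbits of ergodic systems, Brudno's theorem equates the
per-symbol algorithmic complexity of the symbolic orbit with the
partition-based K-S entropy, and the AIC — uncomputable in general — is in
turn approximated by the bit length of a lossless compression of the string.
The estimator is

$$\hat h(\tau, n) \;=\; \frac{\text{compressed bits of the symbolized,
coarse-grained series}}{\text{number of symbols}},$$

computed over a grid of coarse-graining scales $\tau$ (non-overlapping
window means of length $\tau$) and partition cardinalities $n$. The matrix
$\hat h(\tau, n)$ is the multiscale K-S entropy (MKSE) surface, the unit of
all downstream comparison.

## The compressor

The compressor is a pair-coding dictionary scheme in the CASToRe family.
The dictionary starts with only the empty word. Each step defines one new
word as the concatenation *prefix·suffix*, where the prefix is the longest
already-defined word (possibly empty) matching the unread input, and the
suffix is the longest already-defined word matching what follows, falling
back to the single next raw symbol when no defined word matches; a final
incomplete word is emitted with an empty suffix. Because each new word
couples two known words, word lengths on regular strings double rather than
grow by one symbol (as in LZ78), which is what makes the scheme converge
fast on predictable series: a constant string of length $N$ is parsed into
$O(\log N)$ words.

The bit cost charged for the event defining word $m$ (so $m$ words,
counting the empty word, are known before it) is
$\lceil\log_2 m\rceil$ for the prefix index, one flag bit, and either
$\lceil\log_2 m\rceil$ for a dictionary suffix or
$\lceil\log_2 a\rceil$ for a literal over an alphabet of size $a$; an empty
terminal suffix costs nothing beyond the flag. This is the minimal
self-delimiting-in-context code for the parse and is fixed so that results
are reproducible across implementations. Losslessness is enforced by
construction and witnessed by `castore_decode()`, which is property-tested
against `castore_parse()` over random strings at all alphabet sizes used.

### Finite-length behaviour, honestly stated

The estimate converges to the source entropy rate from above, but slowly —
the dictionary-coder overhead decays like $1/\log N$. Two consequences
matter for interpretation:

* On **regular** (low-entropy) strings the estimator is excellent: constant
  and periodic strings of $10^4$ symbols measure below 0.02 bits/symbol.
* On **stochastic** strings the absolute level carries a substantial
  overhead at practical lengths: an i.i.d. uniform binary string of $10^5$
  symbols measures about 1.47 bits/symbol against a Shannon rate of 1, and
  a two-state Markov chain with switching probability 0.1 measures about
  0.71 against an analytic 0.469. The overhead is monotone decreasing in
  length (the package tests assert this), but it does not vanish at any
  length a heartbeat recording can reach.

The estimator should therefore be read **comparatively** — across groups,
scales and cardinalities computed under identical conditions (same lengths,
same interval, same grid) — which is exactly how the pipeline uses it. The
pipeline's group discrimination operates entirely on rank statistics of
matched-condition estimates and is unaffected by the common overhead.
Absolute calibration against analytic rates would require either an
overhead-corrected estimator or lengths orders of magnitude beyond
physiological recordings; we deliberately do not subtract an overhead
model, because any such correction would be source-dependent and would
compromise the transparency of the raw statistic.

## Pipeline parameters

| Parameter | Default | Meaning |
|---|---|---|
| `interval` | data range | Amplitude interval $I$ all partitions divide (s) |
| `cardinalities` | `2:20` | Partition sizes $n$ — 19 partitions |
| `scales` | `1:10` | Coarse-graining factors $\tau$ |
| `resample_hz` | `NULL` | Tachogram resampling rate (2 Hz in the short-term protocol) |
| `truncate_len` | `NULL` | Length cap (10,000 samples in the long-term protocol) |
| `min_length` | 1000 | Warning floor for compression input length |

Two preset protocols are shipped via `mkse_config()`: `"fantasia"`
(short-term recordings: resample the tachogram at 2 Hz so all subjects
contribute equal-length series, fixed interval 0.60–1.84 s) and
`"longterm"` (truncate at 10,000 beats, fixed interval 0.32–1.25 s, whose
lower limit reflects arrhythmic phases). Order of operations is fixed:
resample and/or truncate first, then coarse-grain, then symbolize — and
symbolization always uses the one global interval, never a per-scale range,
so that symbols mean the same thing at every scale.

When `interval = NULL`, `mkse()` takes the global minimum and maximum of
the processed series across all subjects in the call. This mirrors how a
fixed study interval is constructed in the first place (the complete range
of interbeat intervals over the population); window means never leave the
range of the raw values, so one interval computed before coarse-graining is
valid at every scale. Passing a fixed interval is the right choice when
comparing against results produced with that interval, or when scoring new
subjects against an existing study range; out-of-range values are then
clamped into the edge cells and counted per cell in the `out_of_range`
column (an auditable, non-fatal policy; a fully out-of-range series is an
error, and a strict `out_of_range = "error"` mode exists).

Numerical conventions, stated because they are easy to get silently wrong:

* Partition cells are left-closed/right-open, with the last cell closed at
  the upper bound, so the cells tile the interval exactly; the midpoint of
  a 2-cell partition belongs to the upper cell.
* Coarse-graining drops a trailing window shorter than $\tau$ (output
  length $\lfloor N/\tau\rfloor$); it conserves the mean of the retained
  values exactly and composes across scales
  ($\tau = ab$ equals $a$ then $b$) when $ab$ divides $N$.
* Resampling interpolates the tachogram (RR as a function of cumulative
  beat time) linearly by default, which cannot overshoot the observed
  amplitude range; a cubic-spline option exists but can leave the interval.
* All entropies are reported in bits; `shannon_entropy()` takes a `base`
  argument for nats.

## The statistical protocol

Surfaces are compared cell-by-cell with nonparametric tests of equal
median: Mann–Whitney for two groups, Kruskal–Wallis plus pairwise
Mann–Whitney follow-ups for three or more. Two conventions follow the
multiscale protocol this estimator belongs to and are worth highlighting:

* the Bonferroni family for the two-group grid is the number of **scales at
  a fixed partition** (10 by default, so $\alpha = 0.05/10 = 0.005$), not
  the full $|\tau| \times |n|$ grid — an unusual but deliberate choice,
  reflecting that each partition cardinality is read as its own analysis;
* pairwise follow-ups divide by the number of group pairs
  ($0.005/3 \approx 0.0017$ for three groups).

Tests are two-sided (the conservative reading of "equal median" with no
stated direction). Ties use midranks with the tie-corrected normal
approximation; for tie-free samples with both groups of size at most 8 the
exact distribution is used instead, since the normal approximation is
misleading there (a 2-vs-2 comparison can never reach $p < 1/3$). A cell
in which every subject produces the identical entropy value carries no
evidence against the null and is assigned $p = 1$.

## What the synthetic generators emulate — and what they do not

`generate_symbolic()` produces the four source classes whose entropy rate
is known in closed form (constant, periodic, i.i.d., first-order Markov);
these validate the compressor in isolation. `logistic_orbit()` adds a
deterministic-chaos benchmark: the logistic map at $r = 4$ read through the
binary partition at $1/2$, which is generating with K-S entropy exactly
1 bit per iteration.

`generate_cohort()` produces surrogate RR cohorts as stationary Gaussian
AR(1) processes around a common mean, clipped into an amplitude interval
(clips are counted, mirroring the clamp policy downstream). AR(1) is the
minimal stationary process exposing the three knobs the pipeline is
sensitive to — amplitude range, marginal variance, and short-range
autocorrelation. Defaults, chosen once as physiologically sensible resting
values: mean 0.9 s (≈67 bpm), lag-1 autocorrelation 0.8, 10,000 beats
(the long-term truncation length, which also keeps the scale-10 series at
the 1000-point compression floor), bounds 0.60–1.84 s. Cohort contrasts in
the validation study use marginal SDs of 0.02 s vs 0.08 s. The surrogates
deliberately do **not** model respiratory sinus arrhythmia, circadian
nonstationarity, ectopy or atrial fibrillation; passing the synthetic
discrimination study shows the pipeline detects variance/complexity
contrasts of plausible magnitude under clean stationary conditions, not
that it classifies clinical recordings.

## Validation study sizes

The shipped validation (tests and `scripts/acceptance.R`) uses: compressor
round-trips over 1000 random strings (lengths 1–500, alphabets 2–20);
rate checks at $10^4$–$10^5$ symbols; and a discrimination study of two
15-subject cohorts at 10,000 beats on the full $10 \times 19$ grid, with
500 label permutations for type-I calibration of both test grids. With the
SD contrast above, every one of the 190 cells separates at the corrected
0.005 threshold (smallest $p \approx 7\times10^{-7}$), exchangeable copies
of one cohort yield zero significant cells, and permutation rejection
rates sit at the nominal 5% level.

## Known limitations

* Absolute entropy levels include the coder overhead discussed above;
  only matched-condition comparisons are calibrated.
* The pair-coding rule and cost model follow the published description of
  the CASToRe family, but bit-exact equivalence with any historical binary
  is not claimed; validation is by the property suite (losslessness,
  regular-string speed, source ordering, overhead decay).
* Coarse-graining assumes beat-indexed (or uniformly resampled) series;
  the scale axis is in beats (or samples), not seconds, unless the series
  was resampled.
* R-peak detection and artifact correction are upstream of this package:
  inputs are assumed to be clean RR series in seconds.
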