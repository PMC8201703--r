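# segpeaks

Supervised changepoint segmentation for ChIP-seq peak calling.

ChIP-seq coverage profiles are series `Y = (y1, ..., yn)` of non-negative
aligned-read counts along a chromosome; the regions of high read density
(peaks) mark histone modifications or binding sites. `segpeaks` detects
peaks by **exact penalized maximum-likelihood changepoint detection**
instead of heuristic filtering, and learns its tuning parameters from
expert labels.

The model: counts in segment *k* follow a noise family `F(theta_k, phi)`
with segment parameter `theta_k` changing at `K - 1` changepoints
`tau_1 < ... < tau_{K-1}`. The solver minimizes

    sum_i loss(y_i, theta_{k(i)}) + lambda * (number of changepoints)

exactly, by functional dynamic programming over piecewise cost functions of
`theta` (the functional-pruning approach used by graph-constrained optimal
partitioning solvers). Two model shapes are supported:

* **unconstrained** — no shape constraint; peaks are derived afterwards by a
  post-processing rule that picks one start from each run of successive up
  changes (Up\*) and one end from the following run of down changes (Dw\*):
  `thinnest` (last up, first down), `largest` (first up, last down), or
  `maxjump` (the up and down change with the largest mean-difference);
* **updown** — segment means must alternate (background Up Down
  background...), so Up-state segments are directly interpretable as peaks.

Three noise families: Poisson (`var = mu`), negative binomial with
dispersion `phi` (`var = mu + mu^2/phi`, smaller `phi` = more
over-dispersion), and Gaussian after the Anscombe transform
`sqrt(y + 3/8)`.

On top of the solver:

* `sequential_search()` — find a penalty reaching a target peak count;
* `crops()` — enumerate every optimal model between two penalties;
* `crocs()` — every optimal model between two *peak-count* bounds;
* `count_errors()` / `accuracy()` — score predictions against the four
  label types (`noPeaks`, `peaks`, `peakStart`, `peakEnd`);
* `error_curve()`, `learn_constant()`, `learn_linear()` — the label error
  as a piecewise-constant function of `lambda`, and supervised learning of
  `(phi, lambda)` by global minimization or squared-hinge interval
  regression of `log lambda`;
* `overdispersion_log2()`, `nid()` — over-dispersion diagnostics and the
  normalized information distance between replicate peak calls;
* `simulate_problem()` — synthetic labeled problems with known truth;
* a command line (`inst/cli/segpeaks`) with subcommands `simulate`,
  `segment`, `crocs`, `learn`, `evaluate`, `diagnose`, `nid` over
  bedGraph/BED files.

## Worked example

```r
library(segpeaks)

sim <- simulate_problem(sim_config(seed = 11))   # 2 planted peaks, n = 1000
sim$profile
#> coverage_profile: chr1:[0,1000), 1000 bases in 881 runs, counts in [0,48]

seg <- solve_penalized(sim$profile, "updown", noise_spec("poisson"),
                       penalty = 10)
seg
#> segmentation (updown, poisson): K=5 segments, 4 changepoints,
#> loss=-21366.1, penalty=10, peaks=2

peaks <- apply_rule(seg, "maxjump")
count_errors(peaks, sim$truth$labels)
#> error_count: fp=0 fn=0 total=0 over 9 labels
```

The segmentation recovers both planted peaks; all nine simulated labels
(background, peak bodies, and start/end windows) are predicted correctly,
an accuracy of 1.

Exploring all models between 0 and 9 peaks and scoring each against the
labels gives the piecewise-constant error curve used for learning:

```r
prob <- labeled_problem(sim$profile, sim$truth$labels)
cv <- error_curve(prob, "updown", noise_spec("poisson"))
cv
#> error_curve: problem chr1, 10 intervals, min total error 0
subset(cv$entries, total == 0)
#>   lambda_lo lambda_hi peaks fp fn total
#> 8  4.559797  1006.998     2  0  0     0
```

Any penalty in `[4.56, 1007)` yields the correct two-peak model;
`learn_constant()` picks the geometric midpoint of the widest such
interval across a training set.

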