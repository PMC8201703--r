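# Synthetic labeled coverage profiles.
#
# Emulates the structure of a labeled ChIP-seq problem: a piecewise
# constant mean (background level with rectangular peaks), counts drawn
# per noise family, and a label set consistent with the truth by
# construction (the true peaks are always a zero-error prediction). The
# layout and the noise use separate seeded streams, so changing the noise
# family keeps the peak layout fixed for paired comparisons.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration of a synthetic labeled problem
#'
#' Defaults describe a realistic single-chunk problem: a 1000-base window,
#' two peaks of 100-200 bases with a 10-fold enrichment over a background
#' mean of 3 reads, at least 100 background bases between features, and
#' boundary label windows of half-width 20 bases (labels tolerate some
#' imprecision in where an annotator draws a boundary).
#'
#' @param n Profile length in bases.
#' @param n_peaks Number of true peaks.
#' @param bg_mean,peak_mean Background and peak mean counts
#'   (`peak_mean > bg_mean > 0`).
#' @param peak_width Length-2 range of peak widths (bases).
#' @param min_gap Minimum background stretch before/between/after peaks.
#' @param family Noise family; `"gaussian"` draws Poisson counts (the
#'   transform is applied at solve time).
#' @param phi Dispersion when `family = "nbinom"`.
#' @param label_halfwidth Half-width of peakStart/peakEnd label windows.
#' @param label_types Which of the four label types to emit.
#' @param seed Integer seed; the same config is bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 1000, n_peaks = 2, bg_mean = 3, peak_mean = 30,
                       peak_width = c(100, 200), min_gap = 100,
                       family = c("poisson", "nbinom", "gaussian"),
                       phi = NULL, label_halfwidth = 20,
                       label_types = c("noPeaks", "peaks", "peakStart",
                                       "peakEnd"),
                       seed = 1) {
  family <- match.arg(family)
  stopifnot(n >= 1, n_peaks >= 0, bg_mean > 0, peak_mean > bg_mean,
            length(peak_width) == 2, peak_width[1] <= peak_width[2],
            min_gap >= 1, label_halfwidth >= 1)
  label_types <- match.arg(label_types, several.ok = TRUE)
  if (family == "nbinom" && (is.null(phi) || phi <= 0)) {
    stop("nbinom simulation requires phi > 0")
  }
  if (n_peaks * peak_width[2] + (n_peaks + 1) * min_gap > n) {
    stop("infeasible layout: peaks and gaps do not fit inside n")
  }
  if (2 * label_halfwidth >= min(peak_width[1], min_gap)) {
    stop("label_halfwidth too large for the peak widths / gaps")
  }
  structure(list(n = as.integer(n), n_peaks = as.integer(n_peaks),
                 bg_mean = bg_mean, peak_mean = peak_mean,
                 peak_width = as.integer(peak_width),
                 min_gap = as.integer(min_gap), family = family, phi = phi,
                 label_halfwidth = as.integer(label_halfwidth),
                 label_types = label_types, seed = as.integer(seed)),
            class = "sim_config")
}

sim_layout <- function(config) {
  with_seed(config$seed, {
    if (config$n_peaks == 0L) {
      return(list(starts = integer(0), ends = integer(0)))
    }
    widths <- sample(seq(config$peak_width[1], config$peak_width[2]),
                     config$n_peaks, replace = TRUE)
    slack <- config$n - sum(widths) - (config$n_peaks + 1L) * config$min_gap
    cuts <- sort(stats::runif(config$n_peaks + 1L))
    extra <- floor(slack * cuts / sum(cuts))
    gaps <- config$min_gap + extra
    starts <- integer(config$n_peaks)
    pos <- 0L
    for (i in seq_len(config$n_peaks)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + widths[i]
    }
    list(starts = starts, ends = starts + widths)
  })
}

sim_labels <- function(config, layout) {
  h <- config$label_halfwidth
  starts <- integer(0); ends <- integer(0); types <- character(0)
  add <- function(s, e, type) {
    if (type %in% config$label_types && s < e) {
      starts <<- c(starts, s); ends <<- c(ends, e); types <<- c(types, type)
    }
  }
  gap_edges <- rbind(cbind(c(0L, layout$ends),
                           c(layout$starts, config$n)))
  for (g in seq_len(nrow(gap_edges))) {
    lo <- gap_edges[g, 1]; hi <- gap_edges[g, 2]
    # stay clear of adjacent boundary label windows
    lo2 <- if (g == 1L) lo else lo + h + 1L
    hi2 <- if (g == nrow(gap_edges)) hi else hi - h - 1L
    if (hi2 - lo2 >= h) add(lo2, hi2, "noPeaks")
  }
  for (i in seq_along(layout$starts)) {
    s <- layout$starts[i]; e <- layout$ends[i]
    add(max(s - h, 0L), s + h, "peakStart")
    add(e - h, min(e + h, config$n), "peakEnd")
    if (e - s > 2L * h + 2L) add(s + h + 1L, e - h - 1L, "peaks")
  }
  label_set("chr1", starts, ends, types)
}

#' Simulate one labeled coverage problem
#'
#' @param config A [sim_config()].
#' @return List with `profile` (a [coverage_profile()]) and `truth`
#'   (class `sim_truth`: true `peaks` as a [peak_set()], per-base `mean`,
#'   and the emitted `labels`). `count_errors(truth$peaks, truth$labels)`
#'   is 0 by construction.
#' @examples
#' sim <- simulate_problem(sim_config(seed = 11))
#' sim$profile
#' @export
simulate_problem <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- sim_layout(config)
  mu <- rep(config$bg_mean, config$n)
  for (i in seq_along(layout$starts)) {
    mu[(layout$starts[i] + 1L):layout$ends[i]] <- config$peak_mean
  }
  noise_seed <- if (is.null(config$noise_seed)) config$seed + 1000003L else
    config$noise_seed
  counts <- with_seed(noise_seed, {
    if (config$family == "nbinom") {
      stats::rnbinom(config$n, mu = mu, size = config$phi)
    } else {
      stats::rpois(config$n, mu)
    }
  })
  labels <- sim_labels(config, layout)
  truth <- structure(
    list(peaks = peak_set("chr1", layout$starts, layout$ends,
                          rep(config$peak_mean, length(layout$starts))),
         mean = mu, labels = labels),
    class = "sim_truth")
  list(profile = profile_from_counts(counts), truth = truth)
}

#' Simulate replicate profiles sharing one truth
#'
#' All replicates share the same peak layout and mean function; only the
#' count noise differs (seeds derived from `config$seed`). This mirrors
#' biological replicates for robustness (NID) experiments.
#'
#' @param config A [sim_config()].
#' @param k Number of replicates (>= 2).
#' @return List of `k` results as returned by [simulate_problem()].
#' @export
simulate_replicates <- function(config, k) {
  stopifnot(inherits(config, "sim_config"), k >= 2)
  lapply(seq_len(k), function(i) {
    ci <- config
    ci$noise_seed <- config$seed + 1000003L + 7919L * (i - 1L)
    simulate_problem(ci)
  })
}
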