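# Penalty-space exploration.
#
# sequential_search(): find a penalty whose optimal segmentation has a
#   target number of peaks, by iterating cost-line intersections.
# crops(): enumerate every model optimal somewhere between two penalties
#   by recursive interval splitting (two models' penalized cost lines, as
#   functions of lambda, cross at
#   (loss_simple - loss_complex) / (changes_complex - changes_simple)).
# crocs(): all optimal models between two PEAK-count bounds: bracket the
#   penalty with sequential_search, fill with crops, then drop the
#   out-of-range entries.

n_changes <- function(seg) length(seg$changepoints)

#' @export
print.penalty_path <- function(x, ...) {
  cat(sprintf("penalty_path: %d entries (%s, %s)\n", length(x$entries),
              x$model, x$noise$family))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.penalty_path <- function(x, ...) {
  data.frame(
    lambda_lo = vapply(x$entries, `[[`, 0, "lambda_lo"),
    lambda_hi = vapply(x$entries, `[[`, 0, "lambda_hi"),
    peaks = vapply(x$entries, `[[`, 0L, "peaks"),
    changepoints = vapply(x$entries, function(e) n_changes(e$segmentation), 0L),
    loss = vapply(x$entries, function(e) e$segmentation$loss, 0))
}

# penalty that provably yields the 0-changepoint model: the cost line of
# the constant model intersects every other model's line below this value
zero_change_penalty <- function(profile, model, noise, seg0 = NULL) {
  if (is.null(seg0)) seg0 <- solve_penalized(profile, model, noise, 0)
  seg1 <- solve_penalized(profile, model, noise, 1e300)
  max(1, seg1$loss - seg0$loss + 1)
}

#' Search for a penalty reaching a target peak count
#'
#' Iterates: keep a bracket of two solved (penalty, model) pairs whose peak
#' counts straddle the target, propose the penalty where their penalized
#' cost lines intersect, re-solve there, and shrink the bracket. Terminates
#' when the target count is hit or no new model exists between the bracket
#' ends. Up-Down peak counts are non-increasing in the penalty, so every
#' count between the extremes is reachable; unconstrained counts can skip
#' values, in which case the target may be unreachable.
#'
#' @inheritParams solve_penalized
#' @param target_peaks Desired number of peaks (>= 0).
#' @param on_unreachable `"error"` (default) or `"closest"`, which returns
#'   the achievable model closest to the target with `status =
#'   "unreachable"`.
#' @return List with `lambda`, `segmentation`, `peaks` and `status`
#'   (`"ok"` or `"unreachable"`).
#' @export
sequential_search <- function(profile, model = c("updown", "unconstrained"),
                              noise = noise_spec("poisson"), target_peaks,
                              on_unreachable = c("error", "closest")) {
  model <- match.arg(model)
  on_unreachable <- match.arg(on_unreachable)
  stopifnot(target_peaks >= 0)
  seg_lo <- solve_penalized(profile, model, noise, 0)
  p_lo <- count_peaks(seg_lo)
  if (p_lo == target_peaks) {
    return(list(lambda = 0, segmentation = seg_lo, peaks = p_lo, status = "ok"))
  }
  lam_hi <- zero_change_penalty(profile, model, noise, seg_lo)
  seg_hi <- solve_penalized(profile, model, noise, lam_hi)
  p_hi <- count_peaks(seg_hi)
  if (p_hi == target_peaks) {
    return(list(lambda = lam_hi, segmentation = seg_hi, peaks = p_hi,
                status = "ok"))
  }
  lam_lo <- 0
  fail <- function() {
    cand <- list(list(lam_lo, seg_lo, p_lo), list(lam_hi, seg_hi, p_hi))
    d <- abs(c(p_lo, p_hi) - target_peaks)
    pick <- cand[[which.min(d)]]
    msg <- sprintf(
      "target of %d peaks unreachable; closest achievable counts: %d (lambda=%g) and %d (lambda=%g)",
      target_peaks, p_lo, lam_lo, p_hi, lam_hi)
    if (on_unreachable == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    list(lambda = pick[[1]], segmentation = pick[[2]], peaks = pick[[3]],
         status = "unreachable")
  }
  if (target_peaks > p_lo) return(fail())
  for (it in 1:200) {
    dc <- n_changes(seg_lo) - n_changes(seg_hi)
    if (dc <= 0) return(fail())
    lam_new <- (seg_hi$loss - seg_lo$loss) / dc
    seg_new <- solve_penalized(profile, model, noise, lam_new)
    p_new <- count_peaks(seg_new)
    if (p_new == target_peaks) {
      return(list(lambda = lam_new, segmentation = seg_new, peaks = p_new,
                  status = "ok"))
    }
    if (n_changes(seg_new) == n_changes(seg_lo) ||
        n_changes(seg_new) == n_changes(seg_hi)) {
      return(fail())
    }
    if (p_new > target_peaks) {
      lam_lo <- lam_new; seg_lo <- seg_new; p_lo <- p_new
    } else {
      lam_hi <- lam_new; seg_hi <- seg_new; p_hi <- p_new
    }
  }
  fail()
}

#' Enumerate all optimal models between two penalties
#'
#' Recursive penalty-interval splitting: solve at both ends; while the
#' changepoint counts differ by two or more, solve at the intersection
#' penalty of the two cost lines and recurse on both halves whenever a new
#' model appears. Every model optimal somewhere in `[lambda_low,
#' lambda_high]` is returned with its exact half-open penalty interval
#' (boundaries at consecutive cost-line intersections; a boundary belongs
#' to the simpler model).
#'
#' @inheritParams solve_penalized
#' @param lambda_low,lambda_high Penalty bounds, `0 <= lambda_low <
#'   lambda_high`.
#' @return An object of class `penalty_path`; `as.data.frame()` gives one
#'   row per entry (`lambda_lo`, `lambda_hi`, `peaks`, `changepoints`,
#'   `loss`).
#' @export
crops <- function(profile, model = c("updown", "unconstrained"),
                  noise = noise_spec("poisson"), lambda_low, lambda_high) {
  model <- match.arg(model)
  if (!(lambda_low >= 0 && lambda_low < lambda_high)) {
    stop("need 0 <= lambda_low < lambda_high")
  }
  models <- new.env()
  keep <- function(seg) {
    key <- sprintf("K%d", n_changes(seg))
    if (is.null(models[[key]]) || seg$loss < models[[key]]$loss) {
      models[[key]] <- seg
    }
  }
  seg_a <- solve_penalized(profile, model, noise, lambda_low)
  seg_b <- solve_penalized(profile, model, noise, lambda_high)
  keep(seg_a); keep(seg_b)
  rec <- function(lo, hi, sl, sh, depth) {
    if (depth > 64 || hi - lo <= 1e-10 * (1 + lo)) return(invisible())
    dc <- n_changes(sl) - n_changes(sh)
    if (dc < 2) return(invisible())
    lam <- (sh$loss - sl$loss) / dc
    if (lam <= lo || lam >= hi) return(invisible())
    sm <- solve_penalized(profile, model, noise, lam)
    keep(sm)
    if (n_changes(sm) != n_changes(sh) && n_changes(sm) != n_changes(sl)) {
      rec(lo, lam, sl, sm, depth + 1)
      rec(lam, hi, sm, sh, depth + 1)
    }
    invisible()
  }
  rec(lambda_low, lambda_high, seg_a, seg_b, 1)
  segs <- as.list(models)
  ord <- order(vapply(segs, n_changes, 0L), decreasing = TRUE)
  segs <- segs[ord]
  # consecutive cost-line intersections give the interval boundaries
  entries <- list()
  lo <- lambda_low
  for (i in seq_along(segs)) {
    if (i < length(segs)) {
      s1 <- segs[[i]]; s2 <- segs[[i + 1]]
      b <- (s2$loss - s1$loss) / (n_changes(s1) - n_changes(s2))
      b <- min(max(b, lambda_low), lambda_high)
    } else {
      b <- lambda_high
    }
    if (b > lo) {
      entries[[length(entries) + 1L]] <- list(
        lambda_lo = lo, lambda_hi = b, segmentation = segs[[i]],
        peaks = count_peaks(segs[[i]]))
      lo <- b
    }
  }
  structure(list(entries = entries, model = model, noise = noise),
            class = "penalty_path")
}

#' All optimal models between two peak-count bounds (CROCS)
#'
#' Brackets the penalty using [sequential_search()] (targeting
#' `min_peaks - 1` and `max_peaks + 1` peaks; the lower target degenerates
#' to the provable 0-changepoint penalty when `min_peaks = 0`), runs
#' [crops()] between the two bounds, and removes path entries whose peak
#' count falls outside `[min_peaks, max_peaks]`. If a bracketing target is
#' unreachable the bracket is widened once by a factor of 10 and, failing
#' that, the closest achievable count is used with a warning.
#'
#' @inheritParams solve_penalized
#' @param min_peaks,max_peaks Peak-count bounds, `0 <= min_peaks <=
#'   max_peaks`.
#' @return A `penalty_path` whose entries all have peak counts in
#'   `[min_peaks, max_peaks]`.
#' @export
crocs <- function(profile, model = c("updown", "unconstrained"),
                  noise = noise_spec("poisson"), min_peaks = 0,
                  max_peaks = 9) {
  model <- match.arg(model)
  stopifnot(min_peaks >= 0, min_peaks <= max_peaks)
  seg0 <- solve_penalized(profile, model, noise, 0)
  # upper penalty bound: below min_peaks
  if (min_peaks == 0) {
    lam_hi <- zero_change_penalty(profile, model, noise, seg0)
  } else {
    up <- sequential_search(profile, model, noise, min_peaks - 1,
                            on_unreachable = "closest")
    lam_hi <- if (up$status == "ok") up$lambda else
      zero_change_penalty(profile, model, noise, seg0)
  }
  # lower penalty bound: above max_peaks
  if (count_peaks(seg0) <= max_peaks) {
    lam_lo <- 0
  } else {
    lo <- sequential_search(profile, model, noise, max_peaks + 1,
                            on_unreachable = "closest")
    lam_lo <- if (lo$status == "ok" || lo$peaks > max_peaks) lo$lambda else 0
  }
  if (lam_lo >= lam_hi) lam_hi <- lam_lo * 10 + 1
  path <- crops(profile, model, noise, lam_lo, lam_hi)
  path$entries <- Filter(function(e) e$peaks >= min_peaks && e$peaks <= max_peaks,
                         path$entries)
  achievable <- unique(vapply(path$entries, `[[`, 0L, "peaks"))
  want <- seq(min_peaks, max_peaks)
  if (!any(want %in% achievable)) {
    warning("no model with a peak count inside the requested bounds exists on the explored path")
  }
  path
}
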