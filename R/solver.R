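# Exact penalized maximum-likelihood segmentation.
#
# solve_penalized() calls the functional dynamic program in src/ and is the
# production path; brute_force_solve() exhaustively enumerates changepoint
# configurations (and, for the Up-Down model, active-constraint pooling
# patterns) and exists purely as an independent test oracle for small n.

family_code <- c(gaussian = 0L, poisson = 1L, nbinom = 2L)

noise_transform <- function(noise, y) {
  if (identical(noise$transform, "identity")) y else anscombe(y)
}

solver_inputs <- function(profile, noise) {
  w <- profile_weights(profile)
  if (noise$family == "gaussian") {
    v <- noise_transform(noise, profile$counts)
    list(values = v, weights = w,
         dom = c(min(v) - 1, max(v) + 1))
  } else {
    list(values = as.numeric(profile$counts), weights = w,
         dom = count_domain(profile))
  }
}

segment_loss <- function(noise, values, weights, theta, starts_run, K) {
  # total unpenalized loss given per-segment theta and run partition
  seg_of_run <- findInterval(seq_along(values) - 1L, starts_run)
  sum(weights * point_loss(noise, values, theta[seg_of_run]))
}

# drop zero-size jumps (cost ties, possible at penalty 0) by merging the
# equal adjacent segments; unconstrained model only -- in the Up-Down model
# equal adjacent parameters are structural (state excursions), not ties
merge_zero_jumps <- function(changepoints, theta, tol = 1e-6) {
  if (length(changepoints) == 0L) {
    return(list(changepoints = changepoints, theta = theta))
  }
  real <- abs(diff(theta)) > tol * (1 + abs(theta[-1L]))
  grp <- cumsum(c(TRUE, real))
  list(changepoints = changepoints[real],
       theta = as.numeric(tapply(theta, grp, `[`, 1L)))
}

new_segmentation <- function(profile, model, noise, penalty, theta, states,
                             changepoints, loss) {
  structure(
    list(chrom = profile$chrom, profile_start = profile$starts[1L],
         n = profile$n, changepoints = changepoints, theta = theta,
         states = states, loss = loss, penalty = penalty, model = model,
         noise = noise, K = length(theta)),
    class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "segmentation (%s, %s%s): K=%d segments, %d changepoints, loss=%.6g, penalty=%g, peaks=%d\n",
    x$model, x$noise$family,
    if (!is.null(x$noise$phi)) sprintf(" phi=%g", x$noise$phi) else "",
    x$K, length(x$changepoints), x$loss, x$penalty, count_peaks(x)))
  invisible(x)
}

#' Solve the penalized segmentation problem exactly
#'
#' Minimizes total noise-model loss plus `penalty` per changepoint over all
#' segmentations, globally and exactly, by functional dynamic programming.
#' Under `model = "updown"` the segment parameters must alternate
#' (non-decreasing change into a peak, non-increasing change out of it), the
#' chain starts and ends in the background (Down) state, and Up-state
#' segments are the peaks; `model = "unconstrained"` has no shape
#' constraint and peaks are obtained afterwards with [apply_rule()].
#' For gaussian noise the counts are Anscombe-transformed internally and
#' `theta` lives on the transformed scale.
#'
#' @param profile A [coverage_profile()].
#' @param model `"updown"` or `"unconstrained"`.
#' @param noise A [noise_spec()].
#' @param penalty Non-negative penalty per changepoint (an Up-Down peak
#'   therefore costs `2 * penalty`).
#' @return An object of class `segmentation` with fields `changepoints`
#'   (0-based base offsets within the profile, exclusive of 0 and n),
#'   `theta`, `states` (0 background / 1 peak, updown only), `loss`
#'   (unpenalized), `penalty`, `model`, `noise` and `K`.
#' @examples
#' p <- profile_from_counts(c(1, 1, 9, 9, 1, 1))
#' solve_penalized(p, "updown", noise_spec("poisson"), penalty = 2)
#' @export
solve_penalized <- function(profile, model = c("updown", "unconstrained"),
                            noise = noise_spec("poisson"), penalty) {
  stopifnot(inherits(profile, "coverage_profile"), inherits(noise, "noise_spec"))
  model <- match.arg(model)
  if (!is.numeric(penalty) || length(penalty) != 1L || penalty < 0) {
    stop("penalty must be a single non-negative number")
  }
  if (profile$n > 1e7) {
    stop("profile longer than 1e7 bases; supply run-length (binned) input")
  }
  inp <- solver_inputs(profile, noise)
  res <- fpop_solve(inp$values, inp$weights, family_code[[noise$family]],
                    if (is.null(noise$phi)) 0 else noise$phi, penalty,
                    model == "updown", inp$dom[1L], inp$dom[2L])
  starts_run <- res$seg_start_run            # 0-based run index per segment
  cumw <- cumsum(inp$weights)
  changepoints <- as.integer(cumw[starts_run[-1L]])
  theta <- res$theta
  states <- if (model == "updown") res$state else NULL
  if (model == "unconstrained") {
    m <- merge_zero_jumps(changepoints, theta)
    changepoints <- m$changepoints; theta <- m$theta
    starts_run <- c(0L, match(changepoints, cumw))
  }
  loss <- segment_loss(noise, inp$values, inp$weights, theta, starts_run,
                       length(theta))
  seg <- new_segmentation(profile, model, noise, penalty, theta, states,
                          changepoints, loss)
  seg$penalized_cost <- loss + penalty * length(changepoints)
  seg
}

all_subsets_cost <- function(noise, y, w, floor_, ceil_) {
  # segment cost C[i,j] for runs i..j at the clamped weighted-mean MLE
  n <- length(y)
  csw <- c(0, cumsum(w))
  csy <- c(0, cumsum(w * y))
  csy2 <- c(0, cumsum(w * y^2))
  phi <- noise$phi
  cost_ij <- function(i, j) {
    len <- csw[j + 1] - csw[i]
    sy <- csy[j + 1] - csy[i]
    m <- sy / len
    if (noise$family != "gaussian") m <- min(max(m, floor_), ceil_)
    switch(noise$family,
      gaussian = (csy2[j + 1] - csy2[i]) - 2 * m * sy + len * m^2,
      poisson = len * m - sy * log(m),
      nbinom = -sy * log(m) + (sy + len * phi) * log(m + phi))
  }
  C <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in i:n) C[i, j] <- cost_ij(i, j)
  C
}

updown_pattern_fit <- function(noise, y, w, bounds, floor_, ceil_) {
  # exact constrained fit for one changepoint configuration by enumerating
  # which alternating constraints are active (adjacent segments pooled);
  # the minimizer over feasible pooled fits is the constrained optimum
  # because every segment MLE (pooled or not) is a weighted mean
  K <- length(bounds) + 1L
  seg_id <- findInterval(seq_along(y) - 1L, bounds) + 1L
  sy <- as.numeric(tapply(w * y, seg_id, sum))
  len <- as.numeric(tapply(w, seg_id, sum))
  phi <- noise$phi
  if (K == 1L) {
    m <- sum(sy) / sum(len)
    if (noise$family != "gaussian") m <- min(max(m, floor_), ceil_)
    cost <- switch(noise$family,
      gaussian = sum(w * (y - m)^2),
      poisson = sum(len) * m - sum(sy) * log(m),
      nbinom = -sum(sy) * log(m) + (sum(sy) + sum(len) * phi) * log(m + phi))
    return(list(cost = cost, theta = m))
  }
  best <- Inf; best_theta <- NULL
  for (pat in 0:(2^(K - 1L) - 1L)) {
    binding <- as.logical(bitwAnd(pat, 2^(0:(K - 2L))))
    grp <- cumsum(c(TRUE, !binding))
    gs <- tapply(sy, grp, sum); gl <- tapply(len, grp, sum)
    gm <- gs / gl
    if (noise$family != "gaussian") gm <- pmin(pmax(gm, floor_), ceil_)
    theta <- gm[grp]
    ok <- TRUE
    for (k in 2:K) {
      if (k %% 2L == 0L) { if (theta[k - 1] > theta[k] + 1e-12) ok <- FALSE }
      else { if (theta[k - 1] < theta[k] - 1e-12) ok <- FALSE }
      if (!ok) break
    }
    if (!ok) next
    cost <- switch(noise$family,
      gaussian = sum(w * (y - theta[seg_id])^2),
      poisson = sum(len * theta - sy * log(theta)),
      nbinom = sum(-sy * log(theta) + (sy + len * phi) * log(theta + phi)))
    if (cost < best - 1e-12) { best <- cost; best_theta <- theta }
  }
  list(cost = best, theta = as.numeric(best_theta))
}

#' Exhaustive-search segmentation oracle
#'
#' Enumerates every changepoint configuration (and for the Up-Down model
#' every active-constraint pooling pattern) and returns the minimum
#' penalized cost. Changepoints live between the runs of the supplied
#' profile, exactly as in [solve_penalized()]. Exponential in the number
#' of runs; a test oracle, not a production solver.
#'
#' @inheritParams solve_penalized
#' @param max_n Refuse profiles with more than this many runs.
#' @return A `segmentation`, as [solve_penalized()] returns.
#' @export
brute_force_solve <- function(profile, model = c("updown", "unconstrained"),
                              noise = noise_spec("poisson"), penalty,
                              max_n = 25L) {
  stopifnot(inherits(profile, "coverage_profile"))
  model <- match.arg(model)
  y <- as.numeric(profile$counts)
  w <- as.numeric(profile_weights(profile))
  n <- length(y)
  if (n > max_n) stop(sprintf("brute force limited to <= %d runs", max_n))
  if (noise$family == "gaussian") y <- noise_transform(noise, y)
  dom <- if (noise$family == "gaussian") c(-Inf, Inf) else count_domain(profile)
  best <- Inf; best_bounds <- integer(0); best_theta <- NULL
  best_states <- NULL
  bits <- if (n >= 2L) 2^(0:(n - 2L)) else numeric(0)
  if (model == "unconstrained") {
    C <- all_subsets_cost(noise, y, w, dom[1L], dom[2L])
    for (mask in 0:(2^(n - 1L) - 1L)) {
      bounds <- which(as.logical(bitwAnd(mask, bits)))
      b <- c(0L, bounds, n)
      cost <- 0
      for (k in seq_len(length(b) - 1L)) cost <- cost + C[b[k] + 1L, b[k + 1L]]
      pcost <- cost + penalty * length(bounds)
      if (pcost < best - 1e-12 ||
          (pcost < best + 1e-12 && length(bounds) < length(best_bounds))) {
        best <- pcost; best_bounds <- bounds
      }
    }
    seg_id <- findInterval(seq_len(n) - 1L, best_bounds) + 1L
    best_theta <- as.numeric(tapply(w * y, seg_id, sum) /
                               tapply(w, seg_id, sum))
    if (noise$family != "gaussian") {
      best_theta <- pmin(pmax(best_theta, dom[1L]), dom[2L])
    }
    m <- merge_zero_jumps(best_bounds, best_theta)
    best_bounds <- m$changepoints; best_theta <- m$theta
  } else {
    for (mask in 0:(2^(n - 1L) - 1L)) {
      bounds <- which(as.logical(bitwAnd(mask, bits)))
      K <- length(bounds) + 1L
      if (K %% 2L == 0L) next  # must start and end in the Down state
      fit <- updown_pattern_fit(noise, y, w, bounds, dom[1L], dom[2L])
      pcost <- fit$cost + penalty * length(bounds)
      if (pcost < best - 1e-12 ||
          (pcost < best + 1e-12 && length(bounds) < length(best_bounds))) {
        best <- pcost; best_bounds <- bounds; best_theta <- fit$theta
      }
    }
    best_states <- rep(c(0L, 1L), length.out = length(best_theta))
  }
  loss <- best - penalty * length(best_bounds)
  cumw <- cumsum(w)
  seg <- new_segmentation(profile, model, noise, penalty, best_theta,
                          best_states, as.integer(cumw[best_bounds]), loss)
  seg$penalized_cost <- best
  seg
}
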