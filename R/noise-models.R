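# The three noise families used to model ChIP-seq count data:
#   poisson  -- mean = variance = theta
#   nbinom   -- mean theta, dispersion phi, variance theta + theta^2/phi
#   gaussian -- constant variance after the Anscombe transform sqrt(y + 3/8)
# Losses are negative log-likelihoods up to data-only additive constants
# (terms in y alone are dropped: argmins and all cost differences used by
# the penalty-path algorithms are unchanged).

#' Noise model specification
#'
#' @param family One of `"poisson"`, `"gaussian"`, `"nbinom"`.
#' @param phi Negative-binomial dispersion (> 0); variance is
#'   `mu + mu^2/phi`, so smaller `phi` means more over-dispersion. Required
#'   for and only legal with `family = "nbinom"`.
#' @param sigma2 Gaussian variance, used only by the dispersion diagnostics
#'   (the gaussian loss itself is scale-free up to the penalty). Optional.
#' @param transform For the gaussian family: `"anscombe"` (default)
#'   transforms counts with [anscombe()] before solving; `"identity"`
#'   takes the profile values as already-transformed reals.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec("poisson")
#' noise_spec("nbinom", phi = 7)
#' @export
noise_spec <- function(family = c("poisson", "gaussian", "nbinom"),
                       phi = NULL, sigma2 = NULL,
                       transform = c("anscombe", "identity")) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (family == "nbinom") {
    if (is.null(phi) || !is.numeric(phi) || length(phi) != 1L || phi <= 0) {
      stop("nbinom noise requires a single dispersion phi > 0")
    }
  } else if (!is.null(phi)) {
    stop(sprintf("phi is only meaningful for the nbinom family, not %s", family))
  }
  if (!is.null(sigma2) && (!is.numeric(sigma2) || sigma2 <= 0)) {
    stop("sigma2 must be a positive number")
  }
  structure(list(family = family, phi = phi, sigma2 = sigma2,
                 transform = if (family == "gaussian") transform else NULL),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  extra <- if (x$family == "nbinom") sprintf(" (phi = %g)", x$phi) else ""
  cat(sprintf("noise_spec: %s%s\n", x$family, extra))
  invisible(x)
}

noise_to_list <- function(noise) {
  out <- list(family = noise$family)
  if (!is.null(noise$phi)) out$phi <- noise$phi
  if (!is.null(noise$sigma2)) out$sigma2 <- noise$sigma2
  out
}

noise_from_list <- function(x) {
  noise_spec(x$family, phi = x$phi, sigma2 = x$sigma2)
}

#' Anscombe variance-stabilizing transform
#'
#' `sqrt(y + 3/8)`: for Poisson counts the transformed values have
#' approximately constant variance 1/4, which justifies segmenting them
#' under a constant-variance gaussian model.
#'
#' @param y Non-negative counts.
#' @return `sqrt(y + 3/8)`, strictly increasing in `y`.
#' @examples
#' anscombe(0:3)
#' @export
anscombe <- function(y) {
  if (any(y < 0)) stop("anscombe transform requires non-negative input")
  sqrt(y + 3 / 8)
}

#' Per-observation loss of a noise family
#'
#' Negative log-likelihood up to data-only constants and scale:
#' poisson `theta - y*log(theta)`; gaussian `(y - theta)^2` (on the
#' Anscombe scale; the constant 1/(2 sigma^2) factor only rescales the
#' penalty, which is learned anyway); nbinom
#' `-y*log(theta) + (y + phi)*log(theta + phi)`.
#' All three are unimodal in `theta` with minimum at `theta = y`.
#'
#' @param noise A [noise_spec()].
#' @param y Observation(s); for gaussian, already transformed reals.
#' @param theta Segment parameter; must be > 0 for the count families.
#' @return Numeric loss, vectorized over `y`.
#' @export
point_loss <- function(noise, y, theta) {
  stopifnot(inherits(noise, "noise_spec"))
  switch(noise$family,
    gaussian = (y - theta)^2,
    poisson = {
      if (any(theta <= 0)) stop("poisson loss requires theta > 0")
      theta - y * log(theta)
    },
    nbinom = {
      if (any(theta <= 0)) stop("nbinom loss requires theta > 0")
      -y * log(theta) + (y + noise$phi) * log(theta + noise$phi)
    })
}

#' Weighted maximum-likelihood segment parameter
#'
#' For all three families the unconstrained MLE of a segment parameter is
#' the weighted mean of its observations. For the count families the value
#' is clamped into the positive domain `[floor, ceil]` (an all-zero segment
#' would otherwise push `theta` to 0 and the log-loss to infinity).
#'
#' @param noise A [noise_spec()].
#' @param values Observations (transformed for gaussian).
#' @param weights Positive integer weights (bases per run); default 1.
#' @param floor,ceil Clamp bounds for the count families.
#' @return The fitted `theta`.
#' @export
segment_mle <- function(noise, values, weights = rep(1, length(values)),
                        floor = 1e-8, ceil = Inf) {
  stopifnot(inherits(noise, "noise_spec"))
  if (length(values) == 0L) stop("segment_mle requires at least one value")
  if (length(weights) != length(values)) stop("weights must align with values")
  if (any(weights <= 0)) stop("weights must be positive")
  m <- sum(weights * values) / sum(weights)
  if (noise$family == "gaussian") m else min(max(m, floor), ceil)
}

#' Theoretical variance of a noise family at a given segment mean
#'
#' poisson: `mu`; nbinom: `mu + mu^2/phi`; gaussian: the constant `sigma2`
#' carried by the [noise_spec()].
#'
#' @param noise A [noise_spec()].
#' @param mu Segment mean(s), >= 0.
#' @return Theoretical variance, vectorized over `mu`.
#' @export
theoretical_variance <- function(noise, mu) {
  stopifnot(inherits(noise, "noise_spec"))
  if (any(mu < 0)) stop("mu must be non-negative")
  switch(noise$family,
    poisson = mu,
    nbinom = mu + mu^2 / noise$phi,
    gaussian = {
      if (is.null(noise$sigma2)) {
        stop("gaussian theoretical variance requires sigma2 in the noise_spec")
      }
      rep(noise$sigma2, length(mu))
    })
}

#' Candidate dispersion grid, evenly spaced on the log scale
#'
#' The default is the 16-value geometric grid from 1 to 10000 over which the
#' dispersion parameter is selected during supervised learning.
#'
#' @param low,high Grid endpoints (0 < low < high).
#' @param m Number of grid values (>= 2).
#' @return Strictly increasing numeric vector of length `m` with
#'   `grid[1] == low` and `grid[m] == high`.
#' @examples
#' default_phi_grid(1, 100, 3)  # 1 10 100
#' @export
default_phi_grid <- function(low = 1, high = 10000, m = 16) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (m < 2) stop("need m >= 2")
  exp(seq(log(low), log(high), length.out = m))
}

# domain clamp bounds for the count families on a given profile
count_domain <- function(profile) {
  pos <- profile$counts[profile$counts > 0]
  if (length(pos) == 0L) {
    c(1e-8, 1)
  } else {
    floor <- max(1e-8, 1e-3 * min(pos) * min(profile_weights(profile)[
      profile$counts > 0]) / profile$n)
    c(floor, max(profile$counts) + 1)
  }
}
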