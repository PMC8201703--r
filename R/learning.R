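# Supervised learning of the penalty (lambda) and, for negative binomial
# noise, the dispersion (phi).
#
# For one labeled problem the label error as a function of lambda is
# piecewise constant: the penalty path holds finitely many optimal models,
# each scored once. Summing curves over problems stays piecewise constant,
# so the global minimizer (phi*, lambda-interval) is found exactly.
#   constant lambda: one shared lambda* = geometric midpoint of the widest
#     minimizing interval of the summed curve.
#   linear lambda: fix phi*, take each problem's widest zero-extra-error
#     interval as a target interval for log(lambda), and fit an affine
#     predictor by squared-hinge interval regression.

#' Bundle a coverage profile with its labels
#'
#' @param profile A [coverage_profile()].
#' @param labels A [label_set()] on the same chromosome.
#' @param id Problem identifier (string).
#' @return An object of class `labeled_problem`.
#' @export
labeled_problem <- function(profile, labels, id = profile$chrom) {
  stopifnot(inherits(profile, "coverage_profile"),
            inherits(labels, "label_set"))
  if (profile$chrom != labels$chrom) stop("profile and labels chromosomes differ")
  structure(list(profile = profile, labels = labels, id = id),
            class = "labeled_problem")
}

#' Piecewise-constant label-error curve of one problem
#'
#' Runs [crocs()] between the peak bounds, converts every path entry to
#' peaks under `rule`, and scores it against the labels. The default upper
#' bound of 9 peaks follows the labeling practice the benchmark datasets
#' were built with.
#'
#' @inheritParams crocs
#' @param problem A [labeled_problem()].
#' @param rule Peak selection rule for unconstrained models.
#' @return Object of class `error_curve`: `phi` (NULL unless nbinom),
#'   `problem_id`, and `entries` (data frame `lambda_lo`, `lambda_hi`,
#'   `peaks`, `fp`, `fn`, `total`). The top interval is unbounded when its
#'   model has no changepoints.
#' @export
error_curve <- function(problem, model = c("updown", "unconstrained"),
                        noise = noise_spec("poisson"),
                        rule = c("maxjump", "thinnest", "largest"),
                        min_peaks = 0, max_peaks = 9) {
  stopifnot(inherits(problem, "labeled_problem"))
  model <- match.arg(model); rule <- match.arg(rule)
  path <- crocs(problem$profile, model, noise, min_peaks, max_peaks)
  rows <- lapply(path$entries, function(e) {
    err <- count_errors(apply_rule(e$segmentation, rule), problem$labels)
    data.frame(lambda_lo = e$lambda_lo, lambda_hi = e$lambda_hi,
               peaks = e$peaks, fp = err$fp, fn = err$fn, total = err$total)
  })
  entries <- do.call(rbind, rows)
  k <- nrow(entries)
  if (k > 0 && n_changes(path$entries[[k]]$segmentation) == 0L) {
    entries$lambda_hi[k] <- Inf
  }
  structure(list(phi = noise$phi, problem_id = problem$id, entries = entries),
            class = "error_curve")
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf("error_curve: problem %s%s, %d intervals, min total error %d\n",
              x$problem_id,
              if (!is.null(x$phi)) sprintf(" (phi=%g)", x$phi) else "",
              nrow(x$entries), min(x$entries$total)))
  invisible(x)
}

# value of a curve at one penalty; constant extension beyond the explored
# range (the end models stay optimal there among the bounded complexities)
curve_row_at <- function(curve, lambda) {
  e <- curve$entries
  i <- findInterval(lambda, e$lambda_lo)
  max(1L, min(i, nrow(e)))
}

#' Sum error curves over problems
#'
#' Interval algebra: breakpoints are the union of the inputs' breakpoints
#' and the error counts add on each refined interval.
#'
#' @param curves List of `error_curve` objects sharing the same `phi`.
#' @return A summed `error_curve` (with `problem_id = "sum"`).
#' @export
sum_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  phis <- unique(vapply(curves, function(cv)
    if (is.null(cv$phi)) NA_real_ else cv$phi, 0))
  if (length(phis) > 1L) stop("cannot sum curves computed at different phi")
  bps <- sort(unique(unlist(lapply(curves, function(cv)
    c(cv$entries$lambda_lo, cv$entries$lambda_hi)))))
  bps <- bps[is.finite(bps)]
  if (length(bps) == 0L) bps <- 0
  edges <- unique(c(bps, Inf))
  lo <- edges[-length(edges)]; hi <- edges[-1L]
  mid <- ifelse(is.finite(hi), (lo + hi) / 2, lo * 2 + 1)
  fp <- fn <- total <- numeric(length(lo))
  for (cv in curves) {
    idx <- vapply(mid, function(l) curve_row_at(cv, l), 0L)
    fp <- fp + cv$entries$fp[idx]
    fn <- fn + cv$entries$fn[idx]
    total <- total + cv$entries$total[idx]
  }
  entries <- data.frame(lambda_lo = lo, lambda_hi = hi, peaks = NA_integer_,
                        fp = fp, fn = fn, total = total)
  # merge adjacent intervals with identical summed errors
  same <- c(FALSE, diff(total) == 0 & diff(fp) == 0 & diff(fn) == 0)
  grp <- cumsum(!same)
  entries <- do.call(rbind, lapply(split(entries, grp), function(d) {
    d$lambda_hi[1] <- d$lambda_hi[nrow(d)]
    d[1, ]
  }))
  rownames(entries) <- NULL
  structure(list(phi = if (is.na(phis)) NULL else phis, problem_id = "sum",
                 entries = entries),
            class = "error_curve")
}

#' Widest penalty interval attaining a curve's minimum error
#'
#' Adjacent minimizing intervals are first merged; among the maximal runs
#' the widest on the log scale wins (an unbounded upper end counts as
#' infinitely wide).
#'
#' @param curve An `error_curve`.
#' @return `c(log_lo, log_hi)` in natural-log penalty units; `log_hi` may
#'   be `Inf` and `log_lo` may be `-Inf`.
#' @export
optimal_penalty_interval <- function(curve) {
  e <- curve$entries
  if (nrow(e) == 0L) stop("empty error curve")
  is_min <- e$total == min(e$total)
  grp <- cumsum(c(TRUE, diff(is_min) != 0))
  best_w <- -Inf; best <- c(NA_real_, NA_real_)
  for (g in unique(grp[is_min])) {
    rows <- which(grp == g & is_min)
    lo <- e$lambda_lo[rows[1L]]; hi <- e$lambda_hi[rows[length(rows)]]
    w <- log(hi) - log(lo)  # Inf when unbounded above or lo == 0
    if (w > best_w) { best_w <- w; best <- c(log(lo), log(hi)) }
  }
  best
}

# lambda* from a log-interval: geometric midpoint, with one-sided rules
# for half-unbounded intervals
interval_lambda_star <- function(loglo, loghi) {
  if (is.finite(loglo) && is.finite(loghi)) return(exp((loglo + loghi) / 2))
  if (is.finite(loglo)) return(exp(loglo) * 10)
  if (is.finite(loghi)) return(exp(loghi) / 10)
  1
}

#' Learn a shared penalty (and dispersion) minimizing training label error
#'
#' For nbinom noise, the summed error curve is computed for every
#' dispersion in `phi_grid` and the (phi, lambda-interval) pair with the
#' global minimum total error wins (ties go to the smaller phi); for
#' poisson/gaussian a single pass learns lambda only. `lambda_star` is the
#' geometric midpoint of the widest minimizing interval.
#'
#' @inheritParams error_curve
#' @param problems List of [labeled_problem()]s.
#' @param family Noise family name.
#' @param phi_grid Candidate dispersions (nbinom only); default
#'   [default_phi_grid()].
#' @return Object of class `learned_params` with `method = "constant"`,
#'   `phi_star` (nbinom only), `lambda_star`, `train_error`,
#'   `train_labels`, and the winning summed `curve`.
#' @export
learn_constant <- function(problems, model = c("updown", "unconstrained"),
                           family = c("poisson", "gaussian", "nbinom"),
                           phi_grid = default_phi_grid(),
                           rule = c("maxjump", "thinnest", "largest"),
                           min_peaks = 0, max_peaks = 9) {
  model <- match.arg(model); family <- match.arg(family)
  rule <- match.arg(rule)
  stopifnot(length(problems) >= 1)
  phis <- if (family == "nbinom") phi_grid else NA_real_
  best <- NULL
  for (phi in phis) {
    noise <- if (family == "nbinom") noise_spec("nbinom", phi = phi) else
      noise_spec(family)
    curves <- lapply(problems, error_curve, model = model, noise = noise,
                     rule = rule, min_peaks = min_peaks, max_peaks = max_peaks)
    sc <- sum_curves(curves)
    err <- min(sc$entries$total)
    if (is.null(best) || err < best$train_error) {
      best <- list(phi = phi, curve = sc, curves = curves, train_error = err)
    }
  }
  iv <- optimal_penalty_interval(best$curve)
  structure(
    list(method = "constant", model = model, family = family, rule = rule,
         phi_star = if (family == "nbinom") best$phi else NULL,
         lambda_star = interval_lambda_star(iv[1], iv[2]),
         interval_log = iv, train_error = best$train_error,
         train_labels = sum(vapply(problems, function(p)
           length(p$labels$starts), 0L)),
         curve = best$curve),
    class = "learned_params")
}

#' @export
print.learned_params <- function(x, ...) {
  cat(sprintf("learned_params (%s): family=%s%s", x$method, x$family,
              if (!is.null(x$phi_star)) sprintf(" phi*=%g", x$phi_star) else ""))
  if (x$method == "constant") {
    cat(sprintf(" lambda*=%g", x$lambda_star))
  } else {
    cat(sprintf(" weights=(%s)", paste(signif(x$weights, 4), collapse = ", ")))
  }
  cat(sprintf("; training error %d/%d labels\n", x$train_error,
              x$train_labels))
  invisible(x)
}

#' Default penalty-prediction features
#'
#' `(intercept, log n, log(1 + mean count), log(1 + count variance))` --
#' the classic problem-size and signal-level covariates for predicting a
#' segmentation penalty.
#'
#' @param problem A [labeled_problem()].
#' @return Named numeric feature vector.
#' @export
default_features <- function(problem) {
  y <- rep(problem$profile$counts, profile_weights(problem$profile))
  c(intercept = 1, log_n = log(problem$profile$n),
    log_mean = log1p(mean(y)), log_var = log1p(stats::var(y)))
}

squared_hinge_objective <- function(w, X, lo, hi, margin) {
  f <- as.numeric(X %*% w)
  a <- pmax(0, ifelse(is.finite(lo), lo + margin - f, 0))
  b <- pmax(0, ifelse(is.finite(hi), f - (hi - margin), 0))
  sum(a^2 + b^2)
}

squared_hinge_gradient <- function(w, X, lo, hi, margin) {
  f <- as.numeric(X %*% w)
  a <- pmax(0, ifelse(is.finite(lo), lo + margin - f, 0))
  b <- pmax(0, ifelse(is.finite(hi), f - (hi - margin), 0))
  as.numeric(crossprod(X, -2 * a + 2 * b))
}

#' Learn a problem-specific penalty predictor by interval regression
#'
#' Each training problem contributes a target interval `(l_m, u_m)` of log
#' penalties attaining its minimum label error ([optimal_penalty_interval()]
#' at the fixed dispersion `phi_star`). An affine predictor
#' `f(x) = w . x` of `log(lambda)` is fitted by minimizing the convex
#' squared-hinge interval-regression loss
#' `sum_m max(0, l_m + margin - f(x_m))^2 + max(0, f(x_m) - (u_m - margin))^2`
#' (terms with infinite endpoints dropped) with BFGS from a zero start.
#' Non-intercept features are standardized internally; reported
#' `coefficients` are on the original feature scale.
#'
#' @inheritParams learn_constant
#' @param phi_star Fixed dispersion (nbinom families), or `NULL`.
#' @param feature_extractor Function mapping a problem to a named numeric
#'   vector; default [default_features()].
#' @param margin Required slack inside each interval, in log-penalty units.
#' @param intervals Optional precomputed matrix (rows = problems, columns
#'   `c(lo, hi)` in log-penalty units) to skip the curve computation.
#' @return `learned_params` with `method = "linear"`, standardized-space
#'   `weights`, original-scale `coefficients`, the feature standardization,
#'   and training diagnostics.
#' @export
learn_linear <- function(problems, model = c("updown", "unconstrained"),
                         family = c("poisson", "gaussian", "nbinom"),
                         phi_star = NULL,
                         feature_extractor = default_features,
                         margin = 1,
                         rule = c("maxjump", "thinnest", "largest"),
                         min_peaks = 0, max_peaks = 9, intervals = NULL) {
  model <- match.arg(model); family <- match.arg(family)
  rule <- match.arg(rule)
  noise <- if (family == "nbinom") noise_spec("nbinom", phi = phi_star) else
    noise_spec(family)
  if (is.null(intervals)) {
    intervals <- t(vapply(problems, function(p) {
      optimal_penalty_interval(
        error_curve(p, model = model, noise = noise, rule = rule,
                    min_peaks = min_peaks, max_peaks = max_peaks))
    }, c(0, 0)))
  }
  lo <- intervals[, 1]; hi <- intervals[, 2]
  X <- t(vapply(problems, feature_extractor,
                feature_extractor(problems[[1]])))
  if (all(!is.finite(lo)) && all(!is.finite(hi))) {
    warning("all target intervals unbounded on both sides; falling back to a constant predictor")
    w <- rep(0, ncol(X))
  }
  center <- apply(X, 2, mean); scale_ <- apply(X, 2, stats::sd)
  is_int <- scale_ == 0 | !is.finite(scale_)
  center[is_int] <- 0; scale_[is_int] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  opt <- stats::optim(rep(0, ncol(X)), squared_hinge_objective,
                      squared_hinge_gradient, X = Xs, lo = lo, hi = hi,
                      margin = margin, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  w <- opt$par
  coef_orig <- w / scale_
  coef_orig[is_int] <- w[is_int] - sum((w * center / scale_)[!is_int])
  names(coef_orig) <- colnames(X)
  preds <- as.numeric(Xs %*% w)
  in_interval <- preds >= ifelse(is.finite(lo), lo, -Inf) &
    preds <= ifelse(is.finite(hi), hi, Inf)
  err <- vapply(seq_along(problems), function(i) {
    cvn <- error_curve(problems[[i]], model = model, noise = noise,
                       rule = rule, min_peaks = min_peaks,
                       max_peaks = max_peaks)
    cvn$entries$total[curve_row_at(cvn, exp(preds[i]))]
  }, 0)
  structure(
    list(method = "linear", model = model, family = family, rule = rule,
         phi_star = phi_star, weights = w, coefficients = coef_orig,
         center = center, scale = scale_, margin = margin,
         objective = opt$value, intervals_log = intervals,
         predictions_log = preds, inside = in_interval,
         train_error = sum(err),
         train_labels = sum(vapply(problems, function(p)
           length(p$labels$starts), 0L))),
    class = "learned_params")
}

#' Predict a penalty for a new problem from learned parameters
#'
#' @param params A `learned_params` object.
#' @param problem A [labeled_problem()] (constant method ignores it).
#' @param feature_extractor Must match the one used for training.
#' @return A penalty value (lambda, natural scale).
#' @export
predict_lambda <- function(params, problem = NULL,
                           feature_extractor = default_features) {
  stopifnot(inherits(params, "learned_params"))
  if (params$method == "constant") return(params$lambda_star)
  x <- feature_extractor(problem)
  xs <- (x - params$center) / params$scale
  exp(sum(params$weights * xs))
}

#' Serialize learned parameters to YAML
#' @param params A `learned_params`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path) {
  keep <- c("method", "model", "family", "rule", "phi_star", "lambda_star",
            "weights", "coefficients", "center", "scale", "margin")
  x <- params[intersect(keep, names(params))]
  x <- lapply(x, function(v) if (is.numeric(v)) as.numeric(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read learned parameters from YAML
#' @param path Path written by [write_params()].
#' @return A `learned_params` object.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "learned_params")
}
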