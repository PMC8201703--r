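make_problem <- function(seed, ...) {
  sim <- simulate_problem(sim_config(seed = seed, ...))
  labeled_problem(sim$profile, sim$truth$labels, id = sprintf("sim%d", seed))
}

test_that("error curve matches the direct solve-rule-score pipeline", {
  set.seed(51)
  prob <- make_problem(1)
  ns <- noise_spec("poisson")
  cv <- suppressWarnings(error_curve(prob, "updown", ns, "maxjump"))
  expect_true(all(diff(vapply(seq_len(nrow(cv$entries)), function(i)
    cv$entries$lambda_lo[i], 0)) > 0))
  expect_lte(max(cv$entries$peaks), 9)
  expect_equal(min(cv$entries$total), 0)
  # non-increasing peak counts in lambda (updown)
  expect_true(all(diff(cv$entries$peaks) <= 0))
  # the curve's domain is the penalty range the bounded-complexity path
  # explores; below it the true optimum has more than 9 peaks
  lams <- exp(runif(25, log(min(cv$entries$lambda_lo) * 1.01),
                    log(3 * max(cv$entries$lambda_lo) + 10)))
  for (lam in lams) {
    direct <- count_errors(
      apply_rule(solve_penalized(prob$profile, "updown", ns, lam), "maxjump"),
      prob$labels)
    row <- cv$entries[segpeaks:::curve_row_at(cv, lam), ]
    expect_equal(row$total, direct$total,
                 label = sprintf("curve value at lambda=%.3f", lam))
  }
})

test_that("summing curves is pointwise addition", {
  mk <- function(bps, totals) {
    structure(list(phi = NULL, problem_id = "x",
                   entries = data.frame(
                     lambda_lo = bps[-length(bps)], lambda_hi = bps[-1],
                     peaks = NA_integer_, fp = totals, fn = 0L,
                     total = totals)),
              class = "error_curve")
  }
  a <- mk(c(0, Inf), 1L)
  b <- mk(c(0, Inf), 2L)
  s <- sum_curves(list(a, b))
  expect_equal(nrow(s$entries), 1)
  expect_equal(s$entries$total, 3)

  set.seed(52)
  cs <- lapply(1:3, function(i) {
    bps <- c(0, sort(runif(4, 0.1, 50)), Inf)
    mk(bps, sample(0:4, 5, replace = TRUE))
  })
  s <- sum_curves(cs)
  for (lam in exp(runif(100, log(0.01), log(100)))) {
    want <- sum(vapply(cs, function(cv)
      cv$entries$total[segpeaks:::curve_row_at(cv, lam)], 0L))
    expect_equal(s$entries$total[segpeaks:::curve_row_at(s, lam)], want)
  }
  m <- sum_curves(list(a, a, a))
  expect_equal(m$entries$total, 3)
})

test_that("optimal interval picks the widest minimizing run on the log scale", {
  mk <- function(lo, hi, tot) {
    structure(list(phi = NULL, problem_id = "x",
                   entries = data.frame(lambda_lo = lo, lambda_hi = hi,
                                        peaks = NA_integer_, fp = tot,
                                        fn = 0L, total = tot)),
              class = "error_curve")
  }
  cv <- mk(c(0.5, 2, 8), c(2, 8, Inf), c(1L, 0L, 2L))
  expect_equal(optimal_penalty_interval(cv), log(c(2, 8)))
  cv2 <- mk(c(0.5, 2), c(2, Inf), c(1L, 0L))
  expect_equal(optimal_penalty_interval(cv2)[2], Inf)
  # two minimizing runs, widths 1 and 3 in log space
  cv3 <- mk(exp(c(0, 1, 2, 5)), exp(c(1, 2, 5, 6)), c(0L, 1L, 0L, 1L))
  expect_equal(optimal_penalty_interval(cv3), c(2, 5))
  expect_equal(segpeaks:::interval_lambda_star(log(2), log(8)), 4)
  expect_equal(segpeaks:::interval_lambda_star(log(3), Inf), 30)
})

test_that("constant learning beats any grid pair on a small problem set", {
  set.seed(53)
  problems <- lapply(1:3, make_problem)
  lp <- suppressWarnings(learn_constant(problems, "updown", "poisson"))
  expect_null(lp$phi_star)
  expect_equal(lp$train_error, 0)
  expect_equal(lp$train_labels, sum(vapply(problems, function(p)
    length(p$labels$starts), 0L)))
  # exhaustive check on a lambda ladder
  ladder <- exp(seq(log(0.05), log(5000), length.out = 100))
  direct <- vapply(ladder, function(lam) {
    sum(vapply(problems, function(pr) {
      count_errors(apply_rule(
        solve_penalized(pr$profile, "updown", noise_spec("poisson"), lam),
        "maxjump"), pr$labels)$total
    }, 0L))
  }, 0)
  expect_lte(lp$train_error, min(direct))
  # the learned lambda attains the training error
  at_star <- sum(vapply(problems, function(pr) {
    count_errors(apply_rule(
      solve_penalized(pr$profile, "updown", noise_spec("poisson"),
                      lp$lambda_star), "maxjump"), pr$labels)$total
  }, 0L))
  expect_equal(at_star, lp$train_error)
})

test_that("interval regression fits inside feasible target intervals", {
  set.seed(54)
  problems <- lapply(1:6, make_problem)
  iv <- cbind(rep(0, 6), rep(3, 6))
  lp <- suppressWarnings(
    learn_linear(problems, "updown", "poisson", intervals = iv,
                 feature_extractor = function(p)
                   c(intercept = 1, log_n = log(p$profile$n))))
  expect_equal(lp$objective, 0, tolerance = 1e-8)
  expect_true(all(lp$predictions_log > 0 & lp$predictions_log < 3))
  lam <- predict_lambda(lp, problems[[1]],
                        function(p) c(intercept = 1, log_n = log(p$profile$n)))
  expect_true(lam > 1 && lam < exp(3))
})

test_that("interval regression recovers a planted slope on log n", {
  set.seed(7)
  n_vals <- round(exp(runif(50, log(200), log(20000))))
  problems <- lapply(seq_along(n_vals), function(i) {
    p <- coverage_profile("chr1", 0L, n_vals[i], 5L)
    labeled_problem(p, label_set("chr1", 0L, 10L, "peaks"), id = i)
  })
  target <- 0.8 * log(n_vals) + rnorm(50, 0, 0.1)
  iv <- cbind(target - 1.5, target + 1.5)
  fx <- function(p) c(intercept = 1, log_n = log(p$profile$n))
  lp <- learn_linear(problems, "updown", "poisson", intervals = iv,
                     feature_extractor = fx, margin = 1)
  expect_lt(abs(lp$coefficients[["log_n"]] - 0.8), 0.15)
})

test_that("squared-hinge objective decreases along the optimizer trajectory", {
  set.seed(55)
  X <- cbind(1, rnorm(20))
  lo <- rnorm(20); hi <- lo + 0.5   # mostly infeasible: forces iterations
  vals <- c()
  obj <- function(w) {
    v <- segpeaks:::squared_hinge_objective(w, X, lo, hi, 1)
    vals <<- c(vals, v)
    v
  }
  optim(c(0, 0), obj, function(w)
    segpeaks:::squared_hinge_gradient(w, X, lo, hi, 1), method = "BFGS")
  accepted <- cummin(vals)
  expect_true(all(diff(accepted) <= 1e-9))
  # analytic gradient matches finite differences
  w0 <- c(0.3, -0.2)
  g <- segpeaks:::squared_hinge_gradient(w0, X, lo, hi, 1)
  num <- vapply(1:2, function(j) {
    e <- rep(0, 2); e[j] <- 1e-6
    (segpeaks:::squared_hinge_objective(w0 + e, X, lo, hi, 1) -
       segpeaks:::squared_hinge_objective(w0 - e, X, lo, hi, 1)) / 2e-6
  }, 0)
  expect_equal(g, num, tolerance = 1e-4)
})

test_that("learned parameters round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  lp <- structure(list(method = "constant", model = "updown",
                       family = "poisson", rule = "maxjump",
                       lambda_star = 4.25), class = "learned_params")
  write_params(lp, f)
  back <- read_params(f)
  expect_equal(back$lambda_star, 4.25)
  expect_equal(back$method, "constant")
})
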