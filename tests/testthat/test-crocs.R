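test_that("sequential search reaches the requested peak count", {
  p <- base_profile(c(1, 1, 9, 9, 1, 1))
  r <- sequential_search(p, "unconstrained", gauss_identity(), 1)
  expect_equal(r$status, "ok")
  expect_equal(r$segmentation$changepoints, c(2L, 4L))
  expect_equal(r$segmentation$theta, c(1, 9, 1), tolerance = 1e-7)
  expect_true(r$lambda >= 0 && r$lambda < 42.67)

  r0 <- sequential_search(p, "unconstrained", gauss_identity(), 0)
  expect_equal(r0$peaks, 0L)
  expect_length(r0$segmentation$changepoints, 0)
})

test_that("sequential search reports unreachable targets with context", {
  p <- base_profile(c(5, 5, 5, 5))
  expect_error(
    sequential_search(p, "unconstrained", noise_spec("poisson"), 1),
    "unreachable.*closest achievable")
  r <- suppressWarnings(
    sequential_search(p, "unconstrained", noise_spec("poisson"), 1,
                      on_unreachable = "closest"))
  expect_equal(r$status, "unreachable")
  expect_equal(r$peaks, 0L)
})

test_that("CROPS worked example splits exactly at the cost-line intersection", {
  p <- base_profile(c(1, 1, 5, 5))
  path <- crops(p, "unconstrained", gauss_identity(), 0.1, 100)
  df <- as.data.frame(path)
  expect_equal(nrow(df), 2)
  expect_equal(df$changepoints, c(1L, 0L))
  expect_equal(df$lambda_lo, c(0.1, 16), tolerance = 1e-9)
  expect_equal(df$lambda_hi, c(16, 100), tolerance = 1e-9)
  expect_equal(df$loss, c(0, 16), tolerance = 1e-9)

  tight <- crops(p, "unconstrained", gauss_identity(), 50, 51)
  expect_equal(nrow(as.data.frame(tight)), 1)
})

test_that("CROPS finds every model a dense penalty grid finds", {
  set.seed(41)
  for (model in c("unconstrained", "updown")) {
    for (rep in 1:6) {
      p <- random_profile(15, sample(c(3, 7), 1))
      path <- crops(p, model, noise_spec("poisson"), 0.01, 100)
      df <- as.data.frame(path)
      lams <- exp(seq(log(0.01), log(100), length.out = 200))
      for (lam in lams) {
        s <- solve_penalized(p, model, noise_spec("poisson"), lam)
        hit <- any(abs(df$loss - s$loss) < 1e-6 &
                     df$changepoints == length(s$changepoints))
        expect_true(hit, label = sprintf(
          "%s rep %d lambda %.3f (K=%d) present in path", model, rep, lam,
          length(s$changepoints)))
      }
    }
  }
})

test_that("path entries re-solve to the same cost at interval midpoints", {
  set.seed(42)
  p <- random_profile(40, 6)
  path <- crops(p, "updown", noise_spec("poisson"), 0.05, 200)
  for (e in path$entries) {
    mid <- sqrt(e$lambda_lo * min(e$lambda_hi, 1e6))
    s <- solve_penalized(p, "updown", noise_spec("poisson"), mid)
    stored <- e$segmentation$loss + mid * length(e$segmentation$changepoints)
    expect_equal(s$penalized_cost, stored,
                 tolerance = 1e-8 * (1 + abs(stored)))
  }
})

test_that("CROCS covers every achievable peak count between the bounds", {
  p <- base_profile(c(1, 1, 9, 9, 1, 1))
  path <- crocs(p, "unconstrained", gauss_identity(), 0, 1)
  df <- as.data.frame(path)
  expect_setequal(df$changepoints, c(0L, 2L))
  expect_setequal(df$peaks, c(0L, 1L))

  p0 <- crocs(p, "unconstrained", gauss_identity(), 0, 0)
  expect_equal(as.data.frame(p0)$changepoints, 0L)

  set.seed(43)
  sim <- simulate_problem(sim_config(n_peaks = 3, seed = 9))
  path <- suppressWarnings(
    crocs(sim$profile, "updown", noise_spec("poisson"), 1, 3))
  peaks <- vapply(path$entries, `[[`, 0L, "peaks")
  expect_true(all(peaks >= 1 & peaks <= 3))
  expect_true(3 %in% peaks)   # the true model is on the path
  # a peak count is achievable iff some penalty makes it optimal; compare
  # against a dense penalty sweep restricted to the bounds
  sweep_counts <- unique(vapply(
    exp(seq(log(0.5), log(3000), length.out = 120)), function(lam)
      count_peaks(solve_penalized(sim$profile, "updown",
                                  noise_spec("poisson"), lam)), 0L))
  expect_true(all(intersect(sweep_counts, 1:3) %in% peaks))
})

test_that("updown peak counts are non-increasing along the penalty path", {
  set.seed(44)
  for (rep in 1:5) {
    sim <- simulate_problem(sim_config(n_peaks = 2, seed = rep + 100))
    path <- suppressWarnings(
      crocs(sim$profile, "updown", noise_spec("poisson"), 0, 9))
    peaks <- vapply(path$entries, `[[`, 0L, "peaks")
    expect_true(all(diff(peaks) <= 0))
  }
})

test_that("crocs validates bounds", {
  p <- base_profile(c(1, 5, 1))
  expect_error(crocs(p, "updown", noise_spec("poisson"), 3, 1))
  expect_error(crops(p, "updown", noise_spec("poisson"), 5, 5), "lambda_low")
})
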