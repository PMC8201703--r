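test_that("unconstrained gaussian worked example recovers the split", {
  p <- base_profile(c(1, 1, 5, 5))
  s <- solve_penalized(p, "unconstrained", gauss_identity(), 1)
  expect_equal(s$changepoints, 2L)
  expect_equal(s$theta, c(1, 5), tolerance = 1e-8)
  expect_equal(s$loss, 0, tolerance = 1e-10)
  expect_equal(s$penalized_cost, 1, tolerance = 1e-10)
})

test_that("penalty extremes give the contract segmentations", {
  set.seed(3)
  for (model in c("unconstrained", "updown")) {
    for (rep in 1:5) {
      p <- random_profile(sample(8:30, 1))
      s <- solve_penalized(p, model, noise_spec("poisson"), 1e12)
      expect_length(s$changepoints, 0)
    }
  }
  y <- c(3.1, 1.4, 4.9, 1.1, 5.5, 9.2)
  p <- base_profile(round(y * 10))
  s <- solve_penalized(p, "unconstrained", noise_spec("gaussian"), 0)
  expect_length(s$changepoints, 5)
  expect_equal(s$loss, 0, tolerance = 1e-9)
})

test_that("updown closure optimum on decreasing counts (frozen from the oracle)", {
  # under the alternating <=/>= constraints the zero-jump excursion
  # theta=(7,7,1) beats the single segment for small penalties
  p <- base_profile(c(9, 5, 1))
  for (lam in c(0.5, 2, 8)) {
    s <- solve_penalized(p, "updown", noise_spec("poisson"), lam)
    b <- brute_force_solve(p, "updown", noise_spec("poisson"), lam)
    expect_equal(s$penalized_cost, b$penalized_cost, tolerance = 1e-9)
  }
  expect_length(solve_penalized(p, "updown", noise_spec("poisson"), 0.5)$changepoints, 2)
  expect_length(solve_penalized(p, "updown", noise_spec("poisson"), 2)$changepoints, 0)
})

test_that("solver equals the exhaustive oracle across models and families", {
  set.seed(11)
  for (model in c("unconstrained", "updown")) {
    for (ns in all_noises()) {
      for (rep in 1:8) {
        n <- if (model == "updown") sample(5:9, 1) else sample(6:12, 1)
        p <- random_profile(n, sample(c(2, 8), 1))
        for (lam in c(0.5, 2, 8)) {
          s <- solve_penalized(p, model, ns, lam)
          b <- brute_force_solve(p, model, ns, lam)
          expect_equal(s$penalized_cost, b$penalized_cost,
                       tolerance = 1e-6,
                       label = sprintf("%s/%s lam=%g", model, ns$family, lam))
        }
      }
    }
  }
})

test_that("stored loss is consistent with recomputed point losses", {
  set.seed(12)
  for (model in c("unconstrained", "updown")) {
    p <- random_profile(40, 6)
    s <- solve_penalized(p, model, noise_spec("poisson"), 3)
    y <- segpeaks:::profile_expand(p)
    seg_id <- findInterval(seq_along(y) - 1L, s$changepoints) + 1L
    recomputed <- sum(point_loss(noise_spec("poisson"), y, s$theta[seg_id]))
    expect_equal(s$loss, recomputed, tolerance = 1e-9)
    expect_equal(s$penalized_cost, s$loss + 3 * length(s$changepoints),
                 tolerance = 1e-9)
  }
})

test_that("penalized cost is monotone in the penalty", {
  set.seed(13)
  for (model in c("unconstrained", "updown")) {
    p <- random_profile(30, 5)
    lams <- sort(runif(10, 0, 20))
    costs <- vapply(lams, function(l)
      solve_penalized(p, model, noise_spec("poisson"), l)$penalized_cost, 0)
    expect_true(all(diff(costs) >= -1e-9))
  }
})

test_that("updown states alternate, start and end in background", {
  set.seed(14)
  for (rep in 1:10) {
    p <- random_profile(40, 8)
    s <- solve_penalized(p, "updown", noise_spec("poisson"), 2)
    expect_equal(s$states[1], 0)
    expect_equal(s$states[s$K], 0)
    if (s$K > 1) expect_true(all(abs(diff(s$states)) == 1))
    # up changes never decrease, down changes never increase
    if (s$K > 1) {
      d <- diff(s$theta)
      up <- s$states[-1] == 1
      expect_true(all(d[up] >= -1e-7))
      expect_true(all(d[!up] <= 1e-7))
    }
  }
})

test_that("run-length and per-base solving agree for the unconstrained model", {
  set.seed(15)
  for (rep in 1:10) {
    y <- rpois(15, 4)
    rle_p <- profile_from_counts(y)
    base_p <- base_profile(y)
    for (lam in c(0.7, 3)) {
      a <- solve_penalized(rle_p, "unconstrained", noise_spec("poisson"), lam)
      b <- solve_penalized(base_p, "unconstrained", noise_spec("poisson"), lam)
      expect_equal(a$penalized_cost, b$penalized_cost, tolerance = 1e-8)
      expect_equal(a$changepoints, b$changepoints)
    }
  }
})

test_that("solver rejects invalid inputs", {
  p <- base_profile(c(1, 2))
  expect_error(solve_penalized(p, "updown", noise_spec("poisson"), -1),
               "non-negative")
  expect_error(brute_force_solve(random_profile(60), "updown",
                                 noise_spec("poisson"), 1),
               "limited to")
})
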