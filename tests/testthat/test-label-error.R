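test_that("the four label rules reproduce the worked error patterns", {
  labels <- worked_labels()   # noPeaks[0,10), peakStart[20,30), peakEnd[40,50)

  perfect <- count_errors(peak_set("chr1", 22L, 45L, 1), labels)
  expect_equal(c(perfect$fp, perfect$fn), c(0L, 0L))

  # no prediction: missed start and end (2x false negative)
  none <- count_errors(peak_set("chr1"), labels)
  expect_equal(c(none$fp, none$fn), c(0L, 2L))

  # an extra peak inside the noPeaks region (1x false positive)
  extra <- count_errors(peak_set("chr1", c(2L, 22L), c(5L, 45L), c(1, 1)),
                        labels)
  expect_equal(c(extra$fp, extra$fn), c(1L, 0L))

  # two starts inside one peakStart label
  two <- count_errors(peak_set("chr1", c(21L, 25L), c(24L, 70L), c(1, 1)),
                      label_set("chr1", 20L, 30L, "peakStart"))
  expect_equal(c(two$fp, two$fn), c(1L, 0L))
})

test_that("peaks labels accept one or more overlapping peaks, never fp", {
  l <- label_set("chr1", 10L, 50L, "peaks")
  expect_equal(count_errors(peak_set("chr1"), l)$fn, 1L)
  expect_equal(count_errors(peak_set("chr1", 20L, 30L, 1), l)$total, 0L)
  many <- peak_set("chr1", c(12L, 35L), c(20L, 45L), c(1, 1))
  expect_equal(count_errors(many, l)$total, 0L)
})

test_that("peak end membership uses the last covered base", {
  l <- label_set("chr1", 40L, 50L, "peakEnd")
  # end coordinate 50 -> last base 49, inside [40,50)
  expect_equal(count_errors(peak_set("chr1", 10L, 50L, 1), l)$total, 0L)
  # end coordinate 40 -> last base 39, outside
  expect_equal(count_errors(peak_set("chr1", 10L, 40L, 1), l)$fn, 1L)
  expect_equal(count_errors(peak_set("chr1", 10L, 41L, 1), l)$total, 0L)
})

test_that("each label yields at most one error and ordering is irrelevant", {
  set.seed(31)
  for (rep in 1:20) {
    sim <- simulate_problem(sim_config(seed = rep))
    s <- solve_penalized(sim$profile, "updown", noise_spec("poisson"),
                         runif(1, 0.5, 50))
    pk <- apply_rule(s, "maxjump")
    err <- count_errors(pk, sim$truth$labels)
    expect_equal(err$total, err$fp + err$fn)
    expect_true(all(table(err$breakdown$verdict %in%
                            c("correct", "fp", "fn"))))
    expect_equal(nrow(err$breakdown), length(sim$truth$labels$starts))
    if (length(pk$starts) > 1) {
      perm <- sample(length(pk$starts))
      pk2 <- peak_set(pk$chrom, pk$starts[perm], pk$ends[perm],
                      pk$heights[perm])
      expect_equal(count_errors(pk2, sim$truth$labels)$total, err$total)
    }
  }
})

test_that("adding a peak never helps noPeaks and never hurts peaks labels", {
  set.seed(32)
  labels <- label_set("chr1", c(0L, 100L), c(50L, 200L), c("noPeaks", "peaks"))
  for (rep in 1:20) {
    k <- sample(0:3, 1)
    starts <- sort(sample(seq(0L, 240L, by = 10L), k))
    pk <- peak_set("chr1", starts, starts + 5L, rep(1, k))
    base <- count_errors(pk, labels)
    extra_start <- sample(setdiff(seq(0L, 240L, by = 10L), starts), 1)
    pk2 <- peak_set("chr1", sort(c(starts, extra_start)),
                    sort(c(starts, extra_start)) + 5L, rep(1, k + 1))
    more <- count_errors(pk2, labels)
    np <- function(e) sum(e$breakdown$type == "noPeaks" & e$breakdown$verdict == "fp")
    ps <- function(e) sum(e$breakdown$type == "peaks" & e$breakdown$verdict == "fn")
    expect_gte(np(more), np(base))
    expect_lte(ps(more), ps(base))
  }
})

test_that("accuracy implements the pooled label formula", {
  l10 <- label_set("chr1", seq(0L, 90L, by = 10L), seq(5L, 95L, by = 10L),
                   rep("peaks", 10))
  e0 <- structure(list(fp = 0L, fn = 0L, total = 0L,
                       breakdown = data.frame()), class = "error_count")
  expect_equal(accuracy(list(e0, e0), list(l10, l10)), 1)
  e3 <- structure(list(fp = 1L, fn = 2L, total = 3L,
                       breakdown = data.frame()), class = "error_count")
  l12 <- label_set("chr1", seq(0L, 110L, by = 10L), seq(5L, 115L, by = 10L),
                   rep("peaks", 12))
  expect_equal(accuracy(list(e3), list(l12)), 0.75)
  eAll <- structure(list(fp = 0L, fn = 10L, total = 10L,
                         breakdown = data.frame()), class = "error_count")
  expect_equal(accuracy(list(eAll), list(l10)), 0)
  expect_error(accuracy(list(), list()), "align|no labels")
})
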