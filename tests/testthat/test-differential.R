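test_that("identical replicate sets yield zero differences and no calls", {
  set.seed(501)
  reps <- make_reps(setNames(lapply(1:10, function(i) rnorm(3, 0.5, 0.1)),
                             as.character(1:10)))
  d <- compare_profiles(reps, reps)
  expect_equal(d$deltaR, rep(0, 10))
  expect_false(any(d$significant))
  expect_true(all(d$direction == "none"))
})

test_that("a clear reactivity drop is called with the expected Welch p", {
  a <- make_reps(list(`1` = c(1.0, 1.1, 0.9)))
  b <- make_reps(list(`1` = c(0.40, 0.50, 0.45)))
  d <- compare_profiles(a, b)
  expect_equal(d$deltaR, 0.55, tolerance = 1e-12)
  expect_equal(d$rel_change, 0.55 / 1.45, tolerance = 1e-12)
  # two-sided Welch t-test value frozen from the hand-coded oracle
  expect_equal(d$p_value, 0.0036599556, tolerance = 1e-8)
  expect_equal(d$p_value, welch_p_oracle(c(1.0, 1.1, 0.9),
                                         c(0.40, 0.50, 0.45)),
               tolerance = 1e-12)
  expect_true(d$significant)
  expect_equal(d$direction, "down_in_2")
})

test_that("thresholds are strict: exactly 0.2 is never significant", {
  # deltaR exactly 0.2 with p = 0 (degenerate zero variance)
  a <- make_reps(list(`1` = rep(0.5, 3)))
  b <- make_reps(list(`1` = rep(0.7, 3)))
  d <- compare_profiles(a, b)
  expect_equal(d$deltaR, 0.2)
  expect_equal(d$p_value, 0)
  expect_false(d$significant)
  # rel_change exactly 0.2 (deltaR 0.25 > 0.2, p = 0)
  a2 <- make_reps(list(`1` = rep(0.50, 3)))
  b2 <- make_reps(list(`1` = rep(0.75, 3)))
  d2 <- compare_profiles(a2, b2)
  expect_equal(d2$rel_change, 0.2, tolerance = 1e-12)
  expect_false(d2$significant)
})

test_that("swapping conditions flips direction but nothing else", {
  set.seed(502)
  a <- make_reps(setNames(lapply(1:40, function(i) rnorm(3, runif(1, 0, 1.2), 0.1)),
                          as.character(1:40)))
  b <- make_reps(setNames(lapply(1:40, function(i) rnorm(3, runif(1, 0, 1.2), 0.1)),
                          as.character(1:40)))
  d_ab <- compare_profiles(a, b)
  d_ba <- compare_profiles(b, a)
  expect_equal(d_ab$deltaR, d_ba$deltaR)
  expect_equal(d_ab$rel_change, d_ba$rel_change)
  expect_equal(d_ab$p_value, d_ba$p_value)
  expect_identical(d_ab$significant, d_ba$significant)
  sig <- d_ab$significant
  expect_identical(d_ab$direction[sig] == "up_in_2",
                   d_ba$direction[sig] == "down_in_2")
})

test_that("relative change lies in [0, 1] for non-negative means", {
  set.seed(503)
  a <- make_reps(setNames(lapply(1:50, function(i) abs(rnorm(3, 0.4, 0.3))),
                          as.character(1:50)))
  b <- make_reps(setNames(lapply(1:50, function(i) abs(rnorm(3, 0.4, 0.3))),
                          as.character(1:50)))
  d <- compare_profiles(a, b)
  expect_true(all(d$rel_change >= 0 & d$rel_change <= 1))
})

test_that("degenerate inputs are flagged, not called", {
  # non-positive mean sum (negative normalized reactivities)
  a <- make_reps(list(`1` = c(-0.30, -0.25, -0.35)))
  b <- make_reps(list(`1` = c(0.05, 0.10, 0.00)))
  d <- compare_profiles(a, b)
  expect_equal(d$flag, "nonpositive_sum")
  expect_true(is.na(d$rel_change))
  expect_false(d$significant)
  # a single usable replicate on one side: no t-test
  a2 <- make_reps(list(`1` = c(0.9, NA, NA)))
  b2 <- make_reps(list(`1` = c(0.1, 0.15, 0.12)))
  d2 <- compare_profiles(a2, b2)
  expect_equal(d2$flag, "insufficient_replicates")
  expect_true(is.na(d2$p_value))
  expect_false(d2$significant)
})

test_that("positions undetermined in either condition are excluded", {
  a <- make_reps(list(`1` = c(0.1, 0.2, 0.15), `2` = c(NA, NA, NA)))
  b <- make_reps(list(`1` = c(0.8, 0.9, 0.85), `2` = c(0.5, 0.4, 0.45)))
  d <- compare_profiles(a, b)
  expect_equal(d$position, 1L)
  # no overlap at all warns and returns an empty frame
  c1 <- make_reps(list(`1` = c(NA, NA, NA)))
  expect_warning(d0 <- compare_profiles(c1, b), "No shared")
  expect_equal(nrow(d0), 0)
})

test_that("significance calls match the brute-force rule on random data", {
  set.seed(504)
  n <- 300
  a <- setNames(lapply(1:n, function(i) rnorm(3, runif(1, -0.1, 1.5), runif(1, 0.01, 0.3))),
                as.character(1:n))
  b <- setNames(lapply(1:n, function(i) rnorm(3, runif(1, -0.1, 1.5), runif(1, 0.01, 0.3))),
                as.character(1:n))
  d <- compare_profiles(make_reps(a), make_reps(b))
  oracle <- vapply(as.character(d$position),
                   function(p) sig_oracle(a[[p]], b[[p]]), logical(1))
  expect_identical(unname(d$significant), unname(oracle))
})

test_that("Benjamini-Hochberg correction can only shrink the call set", {
  set.seed(505)
  a <- make_reps(setNames(lapply(1:60, function(i) rnorm(3, runif(1, 0, 1), 0.15)),
                          as.character(1:60)))
  b <- make_reps(setNames(lapply(1:60, function(i) rnorm(3, runif(1, 0, 1), 0.15)),
                          as.character(1:60)))
  plain <- compare_profiles(a, b)
  bh <- compare_profiles(a, b, p_adjust = "BH")
  expect_true(all(bh$significant <= plain$significant))
})

test_that("the per-class report counts calls and measures tertiary recall", {
  diff <- compare_profiles(
    make_reps(list(`1` = c(0.1, 0.12, 0.11), `2` = c(0.1, 0.11, 0.12),
                   `3` = c(0.15, 0.16, 0.14))),
    make_reps(list(`1` = c(0.9, 0.95, 0.92), `2` = c(0.1, 0.12, 0.11),
                   `3` = c(0.8, 0.82, 0.81)))
  )
  ann <- tibble::tibble(position = c(1L, 3L), class = c("HELIX", "TERT"))
  rep <- mg_differential_report(diff, ann)
  expect_equal(rep$n_significant[rep$class == "HELIX"], 1L)
  expect_equal(rep$n_significant[rep$class == "TERT"], 1L)
  expect_equal(rep$class[rep$n_compared == 1 & rep$n_significant == 0],
               "unannotated")
  expect_equal(attr(rep, "tertiary_recall"), 1)
  # no significant records: all-zero counts
  none <- compare_profiles(make_reps(list(`1` = c(0.5, 0.5, 0.5))),
                           make_reps(list(`1` = c(0.5, 0.5, 0.5))))
  rep0 <- mg_differential_report(none, ann)
  expect_equal(sum(rep0$n_significant), 0L)
})
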