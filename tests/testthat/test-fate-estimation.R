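keratinocyte_counts <- tibble::tibble(size = 2:4, count = c(259, 72, 53))

test_that("the ratio estimator solves the count-ratio identities exactly", {
  est <- estimate_fate_ratio(keratinocyte_counts)
  expect_true(est$feasible)
  expect_equal(est$b_hat, 72 / 259, tolerance = 1e-15)
  expect_equal(est$ac_hat, (72 / 259) * (53 / 72) - (72 / 259)^2,
               tolerance = 1e-15)
  # roots solve x^2 - (1 - b)x + ac = 0 and respect the policy
  a <- est$fate$a
  c <- est$fate$c
  expect_equal(a + c, 1 - est$b_hat, tolerance = 1e-12)
  expect_equal(a * c, est$ac_hat, tolerance = 1e-12)
  expect_gt(a, c)
  flipped <- estimate_fate_ratio(keratinocyte_counts, "c_greater")
  expect_equal(flipped$fate$a, c, tolerance = 1e-12)
  expect_equal(flipped$fate$c, a, tolerance = 1e-12)
})

test_that("plugging the estimate back reproduces the observed ratios", {
  est <- estimate_fate_ratio(keratinocyte_counts)
  r <- ruin_probabilities(4, est$fate)$prob
  expect_equal(r[2] / r[1], 72 / 259, tolerance = 1e-12)
  expect_equal(r[3] / r[2], 53 / 72, tolerance = 1e-12)
})

test_that("degenerate and infeasible count tables are handled gracefully", {
  est <- estimate_fate_ratio(tibble::tibble(size = 2:4,
                                            count = c(100, 50, 25)))
  expect_true(est$feasible)
  expect_equal(est$b_hat, 0.5)
  expect_equal(est$ac_hat, 0, tolerance = 1e-15)
  expect_equal(est$fate$a, 0.5, tolerance = 1e-12)
  expect_equal(est$fate$c, 0, tolerance = 1e-12)

  bad <- estimate_fate_ratio(tibble::tibble(size = 2:4, count = c(10, 1, 9)))
  expect_false(bad$feasible)
  expect_null(bad$fate)
  expect_match(paste(bad$diagnostics, collapse = " "), "discriminant")

  expect_error(
    estimate_fate_ratio(tibble::tibble(size = c(2, 3), count = c(5, 5))),
    "sizes"
  )
  expect_error(estimate_fate_ratio(tibble::tibble(size = 2:4,
                                                  count = c(1, -2, 3))))
})

test_that("tidy and glance expose the estimate broom-style", {
  est <- estimate_fate_ratio(keratinocyte_counts)
  td <- tidy(est)
  expect_equal(td$term, c("a", "b", "c"))
  expect_equal(sum(td$estimate), 1, tolerance = 1e-12)
  gl <- glance(est)
  expect_equal(gl$n_clones, 384)
  expect_true(gl$feasible)
})

test_that("the MLE recovers a fate exactly from its own size distribution", {
  f <- fate_probabilities(0.415, 0.278, 0.307)
  r <- ruin_probabilities(12, f)
  counts <- tibble::tibble(size = r$n, count = round(r$prob * 1e8))
  est <- estimate_fate_mle(counts)
  expect_true(est$feasible)
  expect_equal(est$fate$a, f$a, tolerance = 1e-4)
  expect_equal(est$fate$b, f$b, tolerance = 1e-4)
  expect_equal(est$fate$c, f$c, tolerance = 1e-4)
})

test_that("the MLE recovers parameters from simulated clones", {
  f <- fate_probabilities(0.3, 0.4, 0.3)
  counts <- generate_count_fixture(f, 10000, max_size = 12, seed = 42)
  est <- estimate_fate_mle(counts, n_max = 12)
  expect_true(est$feasible)
  expect_lt(abs(est$fate$a - f$a), 0.03)
  expect_lt(abs(est$fate$b - f$b), 0.03)
  expect_lt(abs(est$fate$c - f$c), 0.03)
})

test_that("counts concentrated at size two drive the MLE to the boundary", {
  counts <- tibble::tibble(size = 2, count = 500)
  est <- estimate_fate_mle(counts, n_max = 4)
  expect_true(est$boundary)
  expect_lt(est$fate$b, 0.01)
})

test_that("bootstrap intervals cover the point estimate and shrink", {
  est <- bootstrap_fate(keratinocyte_counts, replicates = 500, seed = 3)
  ci_b <- est$ci[est$ci$term == "b", ]
  expect_lte(ci_b$conf.low, est$b_hat)
  expect_gte(ci_b$conf.high, est$b_hat)
  expect_error(bootstrap_fate(keratinocyte_counts, replicates = 0), "100")

  widths <- purrr::map_dbl(c(1, 10, 100), function(mult) {
    cts <- dplyr::mutate(keratinocyte_counts, count = count * mult)
    e <- bootstrap_fate(cts, replicates = 300, seed = 11)
    ci <- e$ci[e$ci$term == "b", ]
    ci$conf.high - ci$conf.low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("the ratio estimator is consistent across many fate regimes", {
  # mean absolute error per parameter below 0.02 at 1e5 simulated clones.
  # Regimes keep |a - c| >= 0.1: the moment estimator's discriminant is
  # (a - c)^2 at the truth, so identifiability of the {a, c} pair degrades
  # as the fates balance (see the boundary test below).
  fates <- list(
    fate_probabilities(0.415, 0.278, 0.307),
    fate_probabilities(0.25, 0.30, 0.45),
    fate_probabilities(0.45, 0.30, 0.25),
    fate_probabilities(0.15, 0.55, 0.30),
    fate_probabilities(0.30, 0.55, 0.15),
    fate_probabilities(0.35, 0.20, 0.45),
    fate_probabilities(0.05, 0.45, 0.50),
    fate_probabilities(0.10, 0.60, 0.30),
    fate_probabilities(0.40, 0.35, 0.25),
    fate_probabilities(0.20, 0.35, 0.45)
  )
  errs <- purrr::map_dfr(seq_along(fates), function(i) {
    f <- fates[[i]]
    counts <- generate_count_fixture(f, 100000, seed = 1000 + i)
    policy <- if (f$a >= f$c) "a_greater" else "c_greater"
    est <- estimate_fate_ratio(counts, policy)
    expect_true(est$feasible)
    tibble::tibble(err_a = abs(est$fate$a - f$a),
                   err_b = abs(est$fate$b - f$b),
                   err_c = abs(est$fate$c - f$c))
  })
  expect_lt(mean(errs$err_a), 0.02)
  expect_lt(mean(errs$err_b), 0.02)
  expect_lt(mean(errs$err_c), 0.02)
})

test_that("balanced fates sit on the estimator's identifiability boundary", {
  # at a = c the discriminant (1 - b)^2 - 4ac is zero at the truth, so
  # sampling noise flags roughly half of replicates infeasible; b remains
  # well estimated either way
  f <- fate_probabilities(0.3, 0.4, 0.3)
  runs <- purrr::map(1:12, function(s) {
    counts <- generate_count_fixture(f, 50000, seed = s)
    estimate_fate_ratio(counts, "a_greater")
  })
  feas <- purrr::map_lgl(runs, "feasible")
  expect_gt(mean(feas), 0.1)
  expect_lt(mean(feas), 0.9)
  b_hats <- purrr::map_dbl(runs, "b_hat")
  expect_lt(abs(mean(b_hats) - f$b), 0.01)
})
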