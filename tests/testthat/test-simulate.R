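test_that("fixed seeds reproduce simulations bit for bit", {
  f <- fate_test_sets$skewed
  s1 <- simulate_homeostasis(f, 500, stop_size = 8, seed = 5)
  s2 <- simulate_homeostasis(f, 500, stop_size = 8, seed = 5)
  expect_identical(s1, s2)
  g1 <- simulate_mutation_growth(20, mutation_model(0.1), 500, seed = 6)
  g2 <- simulate_mutation_growth(20, mutation_model(0.1), 500, seed = 6)
  expect_identical(g1, g2)
  t1 <- simulate_mutation_growth(15, mutation_model(0.1), 50,
                                 genotype = TRUE, seed = 7)
  t2 <- simulate_mutation_growth(15, mutation_model(0.1), 50,
                                 genotype = TRUE, seed = 7)
  expect_identical(t1, t2)
  f1 <- generate_count_fixture(f, 2000, seed = 9)
  f2 <- generate_count_fixture(f, 2000, seed = 9)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("pure PD divisions keep exactly one proliferating cell", {
  sim <- simulate_homeostasis(fate_probabilities(0, 1, 0), 200,
                              stop_size = 12, seed = 1)
  expect_true(all(sim$k == 1))
  expect_true(all(sim$n == 12))
  expect_false(any(sim$absorbed))
})

test_that("jump-chain states at a target size match the exact distribution", {
  f <- fate_test_sets$skewed
  n_target <- 5
  reps <- 40000
  sim <- simulate_homeostasis(f, reps, stop_size = n_target, seed = 13)
  exact <- clone_state_distribution(n_target, f)
  for (k in 1:n_target) {
    p_hat <- mean(sim$n == n_target & sim$k == k)
    p <- exact$prob[exact$k == k]
    se <- sqrt(p * (1 - p) / reps)
    expect_lt(abs(p_hat - p), 3 * se + 1e-12)
  }
})

test_that("continuous-time and jump-chain modes agree in distribution", {
  # the embedded chain of the timed process carries the same law: the
  # waiting-time clocks must not perturb the state distribution
  f <- fate_test_sets$balanced
  n_target <- 6
  reps <- 30000
  # three independent replications of the two-sample comparison, combined
  # by Fisher's method so the verdict does not hang on a single draw
  pvals <- purrr::map_dbl(1:3, function(i) {
    jump <- simulate_homeostasis(f, reps, stop_size = n_target,
                                 seed = 29 + 2 * i)
    timed <- simulate_homeostasis(f, reps, stop_size = n_target,
                                  seed = 30 + 2 * i, time = TRUE, beta = 2)
    expect_true(all(is.finite(timed$time)))
    expect_true(all(is.na(jump$time)))
    tab <- rbind(tabulate(jump$k + 1, nbins = n_target + 1),
                 tabulate(timed$k + 1, nbins = n_target + 1))
    suppressWarnings(stats::chisq.test(tab[, colSums(tab) > 0])$p.value)
  })
  fisher <- stats::pchisq(-2 * sum(log(pvals)), df = 6, lower.tail = FALSE)
  expect_gt(fisher, 0.01)
})

test_that("absorption frequency matches the extinction probability", {
  f <- fate_test_sets$skewed   # a > c: extinction probability c/a
  reps <- 30000
  sim <- simulate_homeostasis(f, reps, max_divisions = 2000, seed = 17)
  p0 <- extinction_probability(f)
  se <- sqrt(p0 * (1 - p0) / reps)
  expect_lt(abs(mean(sim$absorbed) - p0), 3 * se)
})

test_that("mutant-free growth and neutral selection reduce correctly", {
  g <- simulate_mutation_growth(50, mutation_model(0), 200, seed = 2)
  expect_true(all(g$m == 0))
  # rho = 1 flows through the identical code path: same seed, same draws
  n1 <- simulate_mutation_growth(30, mutation_model(0.1, rho = 1), 500,
                                 seed = 3)
  n2 <- simulate_mutation_growth(30, mutation_model(0.1), 500, seed = 3)
  expect_identical(n1, n2)
})

test_that("simulated mutant counts match the exact neutral law", {
  k <- 40
  reps <- 50000
  model <- mutation_model(0.05)
  g <- simulate_mutation_growth(k, model, reps, seed = 23)
  exact <- neutral_distribution(k, model)
  emp <- tabulate(g$m + 1, nbins = k) / reps
  expect_lt(tv_dist(emp, exact$prob), 0.015)
})

test_that("count fixtures reflect the ruin probabilities", {
  f <- fate_test_sets$skewed
  fx <- generate_count_fixture(f, 100000, seed = 41)
  n2 <- fx$count[fx$size == 2]
  n3 <- fx$count[fx$size == 3]
  n4 <- fx$count[fx$size == 4]
  # ratios approximate 1 : b : (b^2 + ac) scaled by the size-2 mass
  se_ratio <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  r <- ruin_probabilities(4, f)$prob
  expect_lt(abs(n3 / n2 - r[2] / r[1]), 0.02)
  expect_lt(abs(n4 / n3 - r[3] / r[2]), 0.02)
  expect_gt(attr(fx, "n_censored"), 0)   # a > c: survivors are censored
})

test_that("degenerate DD-only fates give only two-cell clones", {
  fx <- generate_count_fixture(fate_probabilities(0, 0, 1), 500, seed = 4)
  expect_equal(fx$size, 2)
  expect_equal(fx$count, 500)
  expect_equal(attr(fx, "n_censored"), 0)
})

test_that("genotype bookkeeping is internally consistent", {
  sim <- simulate_mutation_growth(25, mutation_model(0.15), 200,
                                  genotype = TRUE, seed = 19)
  by_rep <- split(sim, sim$replicate)
  for (d in by_rep[1:20]) {
    expect_equal(sum(d$cells_genotype), 25)
    expect_true(all(d$cells_lineage >= d$cells_genotype))
    expect_true(all(d$new_mutations[d$clone_id > 0] >= 1))
    expect_true(all(d$total_mutations[d$clone_id > 0] >=
                      d$new_mutations[d$clone_id > 0]))
    expect_equal(d$new_mutations[d$clone_id == 0], 0)
  }
})
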