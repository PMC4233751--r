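# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's recurrences: paths are enumerated step by step, and
# small stochastic processes are expanded over every outcome.

# All up/down step sequences of length n: count those staying >= 0 and
# ending at height k.
enum_dyck <- function(n, k) {
  if (n == 0) return(as.numeric(k == 0))
  steps <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  heights <- t(apply(steps, 1, cumsum))
  if (n == 1) heights <- matrix(heights, ncol = 1)
  sum(apply(heights, 1, function(h) all(h >= 0) && h[n] == k))
}

# Weighted Motzkin mass by enumeration over all 3^n up/flat/down sequences
# (paths from height 0, staying >= 0, ending at k).
enum_motzkin <- function(n, k, fate) {
  if (n == 0) return(as.numeric(k == 0))
  steps <- as.matrix(expand.grid(rep(list(c(1L, 0L, -1L)), n)))
  heights <- t(apply(steps, 1, cumsum))
  if (n == 1) heights <- matrix(heights, ncol = 1)
  ok <- apply(heights, 1, function(h) all(h >= 0) && h[n] == k)
  if (!any(ok)) return(0)
  n_up <- rowSums(steps[ok, , drop = FALSE] == 1L)
  n_down <- rowSums(steps[ok, , drop = FALSE] == -1L)
  sum(fate$a^n_up * fate$b^(n - n_up - n_down) * fate$c^n_down)
}

# P[n, k] by enumeration of division sequences from a single proliferating
# cell with absorption at k = 0 (paths from height 1; for k = 0 the mass of
# first absorption at size exactly n).
enum_clone_state <- function(n, k, fate) {
  total <- 0
  recurse <- function(size, height, weight) {
    if (height == 0) {
      if (k == 0 && size == n) total <<- total + weight
      return()
    }
    if (size == n) {
      if (height == k) total <<- total + weight
      return()
    }
    recurse(size + 1, height + 1, weight * fate$a)
    recurse(size + 1, height, weight * fate$b)
    recurse(size + 1, height - 1, weight * fate$c)
  }
  recurse(1, 1, 1)
  total
}

# Monomial decomposition of the paths (1,1) -> (n,k) avoiding height 0:
# returns a tibble (a_pow, b_pow, c_pow, coef) and the total path count.
enum_clone_state_paths <- function(n, k) {
  stopifnot(k >= 1)
  acc <- list()
  recurse <- function(size, height, na, nb, nc) {
    if (height == 0) return()
    if (size == n) {
      if (height == k) acc[[length(acc) + 1]] <<- c(na, nb, nc)
      return()
    }
    recurse(size + 1, height + 1, na + 1, nb, nc)
    recurse(size + 1, height, na, nb + 1, nc)
    recurse(size + 1, height - 1, na, nb, nc + 1)
  }
  recurse(1, 1, 0, 0, 0)
  m <- do.call(rbind, acc)
  df <- dplyr::count(
    tibble::tibble(a_pow = m[, 1], b_pow = m[, 2], c_pow = m[, 3]),
    a_pow, b_pow, c_pow, name = "coef"
  )
  attr(df, "n_paths") <- nrow(m)
  df
}

# Neutral / selection mutant-count distribution by exhaustive expansion of
# the division tree: at each division the dividing cell is mutant with
# probability rho*m/(rho*m + n); a dividing non-mutant mutates w.p. mu1.
enum_mutant_counts <- function(k, mu1, rho = 1) {
  probs <- numeric(k)   # index m + 1
  recurse <- function(m, n, weight) {
    if (m + n == k) {
      probs[m + 1] <<- probs[m + 1] + weight
      return()
    }
    p_mut <- rho * m / (rho * m + n)
    if (m > 0) recurse(m + 1, n, weight * p_mut)
    recurse(m, n + 1, weight * (1 - p_mut) * (1 - mu1))
    recurse(m + 1, n, weight * (1 - p_mut) * mu1)
  }
  recurse(0, 1, 1)
  probs
}

# Frequency spectrum by exhaustive expansion: origin division uniform over
# 1..k-1, then every uniform choice of dividing cell expanded exactly.
enum_spectrum <- function(k) {
  probs <- numeric(k - 1)
  spread <- function(marked, tot, weight) {
    if (tot == k) {
      probs[marked] <<- probs[marked] + weight
      return()
    }
    spread(marked + 1, tot + 1, weight * marked / tot)
    spread(marked, tot + 1, weight * (tot - marked) / tot)
  }
  for (d in 1:(k - 1)) spread(1, d + 1, 1 / (k - 1))
  probs
}

# Polynomial helpers over monomial tibbles (a_pow, b_pow, c_pow, coef):
# exact integer-coefficient algebra for conservation identities.
poly_add <- function(...) {
  df <- dplyr::bind_rows(...)
  out <- dplyr::summarise(
    dplyr::group_by(df, a_pow, b_pow, c_pow),
    coef = sum(coef), .groups = "drop"
  )
  out[out$coef != 0, ]
}

poly_mul <- function(p, q) {
  grid <- tidyr::crossing(p = seq_len(nrow(p)), q = seq_len(nrow(q)))
  df <- tibble::tibble(
    a_pow = p$a_pow[grid$p] + q$a_pow[grid$q],
    b_pow = p$b_pow[grid$p] + q$b_pow[grid$q],
    c_pow = p$c_pow[grid$p] + q$c_pow[grid$q],
    coef = p$coef[grid$p] * q$coef[grid$q]
  )
  poly_add(df)
}

# (a + b + c)^n as a monomial tibble (trinomial coefficients).
poly_simplex_power <- function(n) {
  idx <- tidyr::crossing(a_pow = 0:n, c_pow = 0:n)
  idx <- idx[idx$a_pow + idx$c_pow <= n, ]
  tibble::tibble(
    a_pow = idx$a_pow,
    b_pow = n - idx$a_pow - idx$c_pow,
    c_pow = idx$c_pow,
    coef = exp(lfactorial(n) - lfactorial(idx$a_pow) -
                 lfactorial(n - idx$a_pow - idx$c_pow) -
                 lfactorial(idx$c_pow))
  ) |> dplyr::mutate(coef = round(coef))
}

poly_equal <- function(p, q) {
  d <- poly_add(p, dplyr::mutate(q, coef = -coef))
  nrow(d) == 0
}

# Total-variation distance between two probability vectors (padded).
tv_dist <- function(p, q) {
  len <- max(length(p), length(q))
  p <- c(p, numeric(len - length(p)))
  q <- c(q, numeric(len - length(q)))
  0.5 * sum(abs(p - q))
}

fate_test_sets <- list(
  balanced = fate_probabilities(0.3, 0.4, 0.3),
  skewed = fate_probabilities(0.415, 0.278, 0.307),
  no_pp = fate_probabilities(0, 0.6, 0.4),
  no_dd = fate_probabilities(0.5, 0.5, 0),
  uniform = fate_probabilities(1 / 3, 1 / 3, 1 / 3)
)
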