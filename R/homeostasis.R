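# Distributions for the progenitor/differentiated jump chain.
#
# A clone founded by a single proliferating cell gains one cell per
# division; the number of proliferating cells k performs a weighted Motzkin
# walk (up a, flat b, down c) absorbed at k = 0. Everything here is indexed
# by clone size n, not time: the embedded jump chain carries the whole law.

new_clone_distribution <- function(df, type, params) {
  structure(df, class = c("clone_distribution", class(df)),
            dist_type = type, params = params)
}

#' Distribution of proliferating cells at a given clone size
#'
#' For a clone grown from one proliferating cell, returns the probability
#' `P[n, k]` of finding `k` proliferating cells when the clone has `n` cells
#' in total. For `k >= 1` this equals the weighted Motzkin number
#' `m[n - 1, k - 1]` (a path from height 1 to height k avoiding the axis);
#' the `k = 0` entry is the probability of absorption at size exactly `n`,
#' `c * m[n - 2, 0]` (the walk reaches the penultimate state (n - 1, 1) and
#' makes an enforced final DD division).
#'
#' Note the `k = 0` entry is a first-passage mass, so the column does not sum
#' to 1 on its own; conservation reads
#' `sum_k>=1 P[n, k] + sum_(j=2..n) P[j, 0] = 1`.
#'
#' @param n Clone size (total cells), `n >= 1`.
#' @param fate A [fate_probabilities()] object (or coercible).
#' @return A tibble with columns `k` (0..n) and `prob`, of class
#'   `clone_distribution` (plottable with [ggplot2::autoplot()]).
#' @examples
#' f <- fate_probabilities(0.415, 0.278, 0.307)
#' clone_state_distribution(2, f) # (c, b, a)
#' @export
clone_state_distribution <- function(n, fate) {
  stopifnot(length(n) == 1L)
  if (n < 1 || n != floor(n)) {
    stop("`n` must be a positive integer.", call. = FALSE)
  }
  fate <- as_fate_probs(fate)
  if (n == 1) {
    probs <- c(0, 1)
    out <- tibble::tibble(k = 0:1, prob = probs)
    return(new_clone_distribution(out, "clone_state",
                                  list(n = n, fate = fate)))
  }
  rows <- motzkin_rows(n - 1, fate$a, fate$b, fate$c)
  probs <- numeric(n + 1)
  probs[(1:n) + 1] <- rows[[n]][1:n]        # P[n, k] = m[n-1, k-1]
  probs[1] <- fate$c * rows[[n - 1]][1]     # P[n, 0] = c m[n-2, 0]
  out <- tibble::tibble(k = 0:n, prob = probs)
  new_clone_distribution(out, "clone_state", list(n = n, fate = fate))
}

#' Exact monomial expansion of P\[n, k\]
#'
#' Symbolic counterpart of [clone_state_distribution()]: the probability of
#' `k` proliferating cells at clone size `n` as an exact integer-coefficient
#' polynomial in (a, b, c). For `k = 0` this is the first-passage mass at
#' size exactly `n`.
#'
#' @inheritParams clone_state_distribution
#' @param k Number of proliferating cells, `0 <= k <= n`.
#' @return A tibble of monomials (`a_pow`, `b_pow`, `c_pow`, `coef`).
#' @examples
#' clone_state_polynomial(5, 3) # 3 a^3 c + 6 a^2 b^2
#' @export
clone_state_polynomial <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L)
  if (n < 1 || k < 0 || k > n) {
    stop("need `n >= 1` and `0 <= k <= n`.", call. = FALSE)
  }
  if (k >= 1) {
    if (n == 1) {
      return(tibble::tibble(a_pow = 0L, b_pow = 0L, c_pow = 0L,
                            coef = as.numeric(k == 1)))
    }
    return(motzkin_polynomial(n - 1, k - 1))
  }
  if (n < 2) {
    return(tibble::tibble(a_pow = integer(), b_pow = integer(),
                          c_pow = integer(), coef = numeric()))
  }
  poly <- motzkin_polynomial(n - 2, 0)
  poly$c_pow <- poly$c_pow + 1L   # enforced final DD division
  poly
}

#' Gambler's-ruin series: probability of a fully differentiated clone
#'
#' `P[n, 0]` is the probability that the clone is absorbed (all cells
#' differentiated) at size exactly `n`. Two routes are provided:
#' `method = "motzkin"` uses `P[n, 0] = c * m[n - 2, 0]`; `method = "series"`
#' expands the generating function
#' `G(t) = (1 - b t - sqrt((1 - b t)^2 - 4 a c t^2)) / (2 a t)`,
#' whose coefficient of `t^(n-1)` is `P[n, 0]`. The two must agree to
#' 1e-12 relative for `n <= 60`; "motzkin" is the reference.
#'
#' @param n_max Largest clone size tabulated (`n_max >= 2`).
#' @inheritParams clone_state_distribution
#' @param method `"motzkin"` (default) or `"series"`.
#' @return A tibble with columns `n` (2..n_max) and `prob`, of class
#'   `clone_distribution`, with attribute `extinction` = overall probability
#'   that the clone ever fully differentiates (NA when b = 1).
#' @examples
#' f <- fate_probabilities(0.415, 0.278, 0.307)
#' ruin_probabilities(5, f) # c, bc, c(b^2 + ac), ...
#' @export
ruin_probabilities <- function(n_max, fate, method = c("motzkin", "series")) {
  method <- match.arg(method)
  if (n_max < 2 || n_max != floor(n_max)) {
    stop("`n_max` must be an integer >= 2.", call. = FALSE)
  }
  fate <- as_fate_probs(fate)
  probs <- switch(method,
    motzkin = {
      rows <- motzkin_rows(n_max - 2, fate$a, fate$b, fate$c)
      fate$c * vapply(2:n_max, function(n) rows[[n - 1]][1], numeric(1))
    },
    series = ruin_series_coefs(n_max, fate$a, fate$b, fate$c)
  )
  ext <- if (fate$a + fate$c > 0) extinction_probability(fate) else NA_real_
  out <- tibble::tibble(n = 2:n_max, prob = probs)
  out <- new_clone_distribution(out, "ruin",
                                list(n_max = n_max, fate = fate,
                                     method = method))
  attr(out, "extinction") <- ext
  out
}

# Taylor coefficients P[n, 0] = [t^(n-1)] G(t) for n = 2..n_max, via a
# power-series square root of the radicand (1 - bt)^2 - 4ac t^2.
ruin_series_coefs <- function(n_max, a, b, c) {
  if (a == 0) {
    # only flat steps then one final down step
    return(c * b^(0:(n_max - 2)))
  }
  w <- c(1, -2 * b, b^2 - 4 * a * c)
  s <- numeric(n_max + 1)
  s[1] <- 1
  for (m in seq_len(n_max)) {
    wm <- if (m <= 2) w[m + 1] else 0
    conv <- if (m >= 2) sum(s[2:m] * s[m:2]) else 0
    s[m + 1] <- (wm - conv) / 2
  }
  num <- -s
  num[1] <- num[1] + 1
  num[2] <- num[2] - b          # series of 1 - b t - s(t)
  # [t^(n-1)] G = num[n] / (2 a)  (num index offset: num[j + 1] = [t^j])
  num[(2:n_max) + 1] / (2 * a)
}

#' Probability that a clone ever becomes fully differentiated
#'
#' Evaluates the ruin generating function at `t = 1`: the total probability
#' that a clone founded by one proliferating cell is eventually absorbed
#' with no proliferating cells left. Equals 1 when `a <= c` (differentiation
#' balanced or dominant) and `c / a` when `a > c`.
#'
#' @inheritParams clone_state_distribution
#' @return A single probability.
#' @examples
#' extinction_probability(fate_probabilities(0.415, 0.278, 0.307)) # 0.307/0.415
#' @export
extinction_probability <- function(fate) {
  fate <- as_fate_probs(fate)
  if (fate$a + fate$c == 0) {
    stop("degenerate fate b = 1: the clone neither differentiates nor ",
         "changes its proliferating count; extinction is undefined.",
         call. = FALSE)
  }
  if (fate$a <= fate$c) 1 else fate$c / fate$a
}

#' First-passage convolution identity diagnostic
#'
#' Checks the renewal identity connecting the ruin series to unrestricted
#' random-walk return probabilities. With `u[n]` the probability that an
#' unrestricted (a, b, c) walk started at height 1 sits at height 0 after
#' `n` steps, and `v[n]` the same from height 0, decomposing on the first
#' visit to 0 gives `u[n] = sum_(r=1..n) f[r] * v[n - r]` where
#' `f[r] = P[r + 1, 0]` is the first-passage (ruin) mass.
#'
#' @param n_max Largest step count checked (`n_max >= 2`).
#' @inheritParams clone_state_distribution
#' @return A tibble with columns `n`, `u`, `u_conv`, `residual`, with
#'   attribute `max_residual`.
#' @export
first_passage_identity_check <- function(n_max, fate) {
  if (n_max < 2 || n_max != floor(n_max)) {
    stop("`n_max` must be an integer >= 2.", call. = FALSE)
  }
  fate <- as_fate_probs(fate)
  a <- fate$a; b <- fate$b; c <- fate$c
  u <- vapply(1:n_max, function(n) {
    x <- 0:((n - 1) %/% 2)
    sum(choose(n, x) * choose(n - x, x + 1) *
          a^x * c^(x + 1) * b^(n - 2 * x - 1))
  }, numeric(1))
  v <- c(1, vapply(1:n_max, function(n) {
    x <- 0:(n %/% 2)
    sum(choose(n, x) * choose(n - x, x) * a^x * c^x * b^(n - 2 * x))
  }, numeric(1)))
  f <- c(ruin_probabilities(n_max + 1, fate)$prob)   # f[r] = P[r+1, 0]
  u_conv <- vapply(1:n_max, function(n) {
    r <- 1:n
    sum(f[r] * v[n - r + 1])
  }, numeric(1))
  out <- tibble::tibble(n = 1:n_max, u = u, u_conv = u_conv,
                        residual = u - u_conv)
  attr(out, "max_residual") <- max(abs(out$residual))
  out
}
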