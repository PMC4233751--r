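# Lattice-path counting engine.
#
# The composition of a clone maps onto lattice paths: a PP division is an up
# step, PD a flat step, DD a down step, and the height of the path is the
# number of proliferating cells. Dyck paths (up/down only) are counted
# exactly; Motzkin paths (up/flat/down) are weighted by the fate
# probabilities (a, b, c). All integer counting is exact: counts are kept as
# doubles but guarded to stay below 2^53, where double arithmetic on
# integers is exact.

.MAX_EXACT <- 2^53

check_exact <- function(x, what) {
  if (any(x >= .MAX_EXACT)) {
    stop(what, " exceeds the exact integer range (2^53); ",
         "reduce the path length.", call. = FALSE)
  }
  x
}

#' Catalan numbers
#'
#' `C_n = choose(2n, n) / (n + 1)` counts Dyck paths of length `2n`: up/down
#' lattice paths from the origin back to height 0 that never dip below the
#' axis. They appear here as the boundary counts of the Dyck triangle.
#'
#' @param n Vector of non-negative integers.
#' @return Exact integer-valued counts (as doubles, guarded against loss of
#'   precision).
#' @examples
#' catalan(0:5) # 1 1 2 5 14 42
#' @export
catalan <- function(n) {
  if (any(n < 0) || any(n != floor(n))) {
    stop("`n` must contain non-negative integers.", call. = FALSE)
  }
  check_exact(choose(2 * n, n) / (n + 1), "Catalan number")
}

#' Dyck triangle counts
#'
#' `dyck_triangle(n, k)` is the number of up/down lattice paths from (0, 0)
#' to (n, k) that never go below the horizontal axis. The count satisfies
#' `D[n, k] = D[n - 1, k - 1] + D[n - 1, k + 1]` and is 0 when `n` and `k`
#' have different parity or `k > n`; the boundary is `D[2n, 0] = C_n`.
#'
#' @param n Number of steps (non-negative integer, scalar).
#' @param k Final height (non-negative integer, scalar).
#' @return Exact path count.
#' @examples
#' dyck_triangle(4, 0) # 2 = catalan(2)
#' dyck_triangle(4, 2) # 3
#' @export
dyck_triangle <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L)
  if (n < 0 || k < 0 || n != floor(n) || k != floor(k)) {
    stop("`n` and `k` must be non-negative integers.", call. = FALSE)
  }
  if (k > n || (n - k) %% 2 != 0) return(0)
  dyck_triangle_row(n)[k + 1]
}

# Row n of the Dyck triangle (heights 0..n) by the one-step recurrence.
dyck_triangle_row <- function(n) {
  row <- c(1, numeric(n))
  if (n == 0) return(row)
  for (s in seq_len(n)) {
    new <- numeric(n + 1)
    # D[s, k] = D[s-1, k-1] + D[s-1, k+1]
    new[2:(n + 1)] <- row[1:n]
    new[1:n] <- new[1:n] + row[2:(n + 1)]
    row <- check_exact(new, "Dyck triangle count")
  }
  row
}

#' Weighted Motzkin path value
#'
#' The probability mass carried by all Motzkin paths (up/flat/down steps,
#' never below the axis) from (0, 0) to (`n`, `k`), with each up step
#' weighted `a`, flat step `b` and down step `c`. Computed by decomposing
#' each path into a Dyck skeleton with `k + i` up and `i` down steps
#' interleaved with `n - k - 2i` flat steps:
#' `m[n, k] = sum_i choose(n, n - k - 2i) * D[k + 2i, k] * a^(k+i) * b^(n-k-2i) * c^i`.
#'
#' An independent route to the same numbers is [motzkin_table()], which uses
#' the one-step recurrence; the two must agree.
#'
#' @param n Number of steps.
#' @param k Final height, `0 <= k <= n`.
#' @param fate A [fate_probabilities()] object (or coercible).
#' @return A single numeric value in \[0, 1\].
#' @examples
#' f <- fate_probabilities(0.415, 0.278, 0.307)
#' weighted_motzkin(4, 2, f) # = 3 a^3 c + 6 a^2 b^2
#' @export
weighted_motzkin <- function(n, k, fate) {
  stopifnot(length(n) == 1L, length(k) == 1L)
  if (n < 0 || k < 0 || n != floor(n) || k != floor(k)) {
    stop("`n` and `k` must be non-negative integers.", call. = FALSE)
  }
  if (k > n) stop("`k` must not exceed `n`.", call. = FALSE)
  fate <- as_fate_probs(fate)
  i <- 0:((n - k) %/% 2)
  dy <- vapply(i, function(ii) dyck_triangle(k + 2 * ii, k), numeric(1))
  sum(choose(n, n - k - 2 * i) * dy *
        fate$a^(k + i) * fate$b^(n - k - 2 * i) * fate$c^i)
}

#' Weighted Motzkin triangle by the one-step recurrence
#'
#' Fills `m[n, k]` for `0 <= k <= n <= n_max` from
#' `m[n + 1, k] = c * m[n, k + 1] + b * m[n, k] + a * m[n, k - 1]` with
#' `m[0, 0] = 1`. This recurrence is the binding definition of the weighted
#' Motzkin numbers; [weighted_motzkin()] is the independent closed-form
#' cross-check.
#'
#' @param n_max Largest number of steps to tabulate.
#' @inheritParams weighted_motzkin
#' @return A tibble with columns `n`, `k`, `value`.
#' @export
motzkin_table <- function(n_max, fate) {
  if (n_max < 0 || n_max != floor(n_max)) {
    stop("`n_max` must be a non-negative integer.", call. = FALSE)
  }
  fate <- as_fate_probs(fate)
  rows <- motzkin_rows(n_max, fate$a, fate$b, fate$c)
  purrr::map_dfr(0:n_max, function(n) {
    vals <- rows[[n + 1]]
    tibble::tibble(n = n, k = 0:n, value = vals)
  })
}

# List of rows: rows[[n + 1]] = m[n, 0..n].
motzkin_rows <- function(n_max, a, b, c) {
  rows <- vector("list", n_max + 1L)
  rows[[1]] <- 1
  if (n_max == 0) return(rows)
  for (n in seq_len(n_max)) {
    prev <- c(rows[[n]], 0)        # m[n-1, 0..n], padded at height n
    # up into k (from k-1), flat at k, down into k (from k+1)
    up <- c(0, prev[1:n])
    down <- c(prev[2:(n + 1)], 0)
    rows[[n + 1]] <- a * up + b * prev[1:(n + 1)] + c * down
  }
  rows
}

# ---- exact polynomial layer -------------------------------------------------
#
# m[n, k] is a polynomial in (a, b, c), homogeneous of degree n, whose
# coefficient of a^i b^(n-i-j) c^j is the exact number of admissible paths
# with i up, j down and n-i-j flat steps. These integer coefficients are kept
# exactly (guarded below 2^53), supporting symbolic results and exact
# identity checks.

# Coefficient matrix representation: mat[i + 1, j + 1] = #paths with i up
# and j down steps (flat count implied by n).
motzkin_poly_rows <- function(n_max) {
  tabs <- vector("list", n_max + 1L)
  tabs[[1]] <- list(matrix(1, 1, 1))   # n = 0, k = 0
  if (n_max == 0) return(tabs)
  for (n in seq_len(n_max)) {
    prev <- tabs[[n]]
    cur <- vector("list", n + 1L)
    for (kk in 0:n) {
      m <- matrix(0, n + 1, n + 1)
      if (kk >= 1 && kk - 1 <= n - 1) {          # up step from height kk-1
        p <- prev[[kk]]
        d <- nrow(p)
        m[2:(d + 1), 1:d] <- m[2:(d + 1), 1:d] + p
      }
      if (kk <= n - 1) {                         # flat step at height kk
        p <- prev[[kk + 1]]
        d <- nrow(p)
        m[1:d, 1:d] <- m[1:d, 1:d] + p
      }
      if (kk + 1 <= n - 1) {                     # down step from height kk+1
        p <- prev[[kk + 2]]
        d <- nrow(p)
        m[1:d, 2:(d + 1)] <- m[1:d, 2:(d + 1)] + p
      }
      cur[[kk + 1]] <- check_exact(m, "polynomial coefficient")
    }
    tabs[[n + 1]] <- cur
  }
  tabs
}

#' Weighted Motzkin value as an exact polynomial in (a, b, c)
#'
#' Returns the exact monomial expansion of `m[n, k]`: each row is one
#' monomial `coef * a^a_pow * b^b_pow * c^c_pow`, with exact integer
#' coefficients (the number of admissible paths of that step composition).
#'
#' @inheritParams weighted_motzkin
#' @return A tibble with columns `a_pow`, `b_pow`, `c_pow`, `coef`, ordered
#'   by decreasing `a_pow`.
#' @examples
#' motzkin_polynomial(4, 2) # 3 a^3 c + 6 a^2 b^2
#' @export
motzkin_polynomial <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L, n >= 0, k >= 0, k <= n)
  mat <- motzkin_poly_rows(n)[[n + 1]][[k + 1]]
  idx <- which(mat != 0, arr.ind = TRUE)
  out <- tibble::tibble(
    a_pow = idx[, 1] - 1L,
    c_pow = idx[, 2] - 1L,
    coef = mat[idx]
  )
  out$b_pow <- n - out$a_pow - out$c_pow
  dplyr::arrange(
    out[, c("a_pow", "b_pow", "c_pow", "coef")],
    dplyr::desc(.data$a_pow), dplyr::desc(.data$c_pow)
  )
}

# Evaluate a coefficient matrix at numeric (a, b, c); degree n implied.
eval_poly_mat <- function(mat, n, a, b, c) {
  idx <- which(mat != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  i <- idx[, 1] - 1L
  j <- idx[, 2] - 1L
  sum(mat[idx] * a^i * b^(n - i - j) * c^j)
}
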