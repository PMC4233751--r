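# Subclonal structure of a grown colony.
#
# Each of the k - 1 divisions may create new mutations; every
# mutation-producing division founds a new clone (a new mutation
# combination). Once present, a marked lineage grows as a Polya urn: if n of
# the current `tot` cells carry the mark, the next division duplicates a
# marked cell with probability n / tot.

#' Conditional spread kernel of a single mutation
#'
#' `spectrum_kernel(j, k)` is the distribution of the number of cells `r`
#' carrying a mutation that arose at the division creating the `j`-th cell
#' (one marked cell among `j`), once the colony has grown to `k` cells.
#' Computed by the Polya-urn recurrence
#' `s[j,k][r] = s[j,k-1][r-1] (r-1)/(k-1) + s[j,k-1][r] (k-1-r)/(k-1)`.
#'
#' @param j Colony size at which the mutation arose (`2 <= j <= k`).
#' @param k Final colony size.
#' @return A tibble with columns `r` (1..k-j+1) and `prob`.
#' @export
spectrum_kernel <- function(j, k) {
  if (j < 2 || k < j) stop("need 2 <= j <= k.", call. = FALSE)
  s <- spread_probs(n_start = 1, tot_start = j, tot_end = k)
  tibble::tibble(r = seq_along(s), prob = s)
}

# Polya-urn spread: start with `n_start` marked among `tot_start`, grow to
# `tot_end`; returns probs over marked count 1..(n_start + tot_end - tot_start).
spread_probs <- function(n_start, tot_start, tot_end) {
  p <- c(rep(0, n_start - 1), 1)
  if (tot_end == tot_start) return(p)
  for (tot in tot_start:(tot_end - 1)) {
    len <- length(p)
    r <- seq_len(len)
    p_new <- numeric(len + 1)
    p_new[r] <- p * (tot - r) / tot          # unmarked cell divides
    p_new[r + 1] <- p_new[r + 1] + p * r / tot   # marked cell divides
    p <- p_new
  }
  p
}

#' Mutation frequency spectrum of a colony
#'
#' Distribution of the number of cells `r` that carry a randomly selected
#' mutation, in a colony of `k` cells. A mutation arises at any of the
#' `k - 1` divisions with equal probability and then spreads as a Polya urn;
#' the spectrum averages the spread kernels over the (uniform) origin:
#' `p[k][r] = (1/(k-1)) sum_(j=2..k-r+1) s[j,k][r]`.
#'
#' @param k Colony size (`>= 2`).
#' @return A tibble with columns `r` (1..k-1) and `prob`, of class
#'   `clone_distribution`.
#' @examples
#' mutation_frequency_spectrum(4) # 2/3, 2/9, 1/9
#' @export
mutation_frequency_spectrum <- function(k) {
  if (length(k) != 1L || k < 2 || k != floor(k)) {
    stop("`k` must be an integer >= 2.", call. = FALSE)
  }
  probs <- numeric(k - 1)
  for (j in 2:k) {
    s <- spread_probs(1, j, k)          # support 1..k-j+1
    idx <- seq_along(s)
    probs[idx] <- probs[idx] + s
  }
  probs <- probs / (k - 1)
  out <- tibble::tibble(r = 1:(k - 1), prob = probs)
  new_clone_distribution(out, "frequency_spectrum", list(k = k))
}

#' Distribution of the number of clones
#'
#' A clone is a set of cells sharing an identical mutation combination; each
#' of the `k - 1` divisions founds a new clone independently with
#' probability `mu1`, so the number of clones `C` satisfies
#' `C - 1 ~ Binomial(k - 1, mu1)`.
#'
#' @param k Colony size (`>= 1`).
#' @param model A [mutation_model()] (or a single `mu1`).
#' @return A tibble with columns `n_clones` (1..k) and `prob`, of class
#'   `clone_distribution`.
#' @examples
#' clone_count_distribution(3, mutation_model(0.5))
#' @export
clone_count_distribution <- function(k, model) {
  check_colony_size(k)
  model <- as_mutation_model(model)
  j <- 0:(k - 1)
  out <- tibble::tibble(n_clones = j + 1,
                        prob = stats::dbinom(j, k - 1, model$mu1))
  new_clone_distribution(out, "clone_count", list(k = k, model = model))
}

#' Size distribution of a randomly selected clone
#'
#' Probability that a randomly selected clone contains `n` cells in a colony
#' of `k` cells. The founding division is uniform over the `k - 1`
#' divisions; a clone founded at division `i` starts as one cell among
#' `i + 1` and grows clonally with probability `n / tot` at each later
#' division (clonal cells keep their clone membership when they divide).
#'
#' This is algebraically the same Polya recursion as
#' [mutation_frequency_spectrum()] (with `j = i + 1`), and the two are
#' required to agree entry for entry; they are computed through separate
#' code paths so the agreement is a real cross-check.
#'
#' @param k Colony size (`>= 2`).
#' @return A tibble with columns `n` (1..k-1) and `prob`, of class
#'   `clone_distribution`.
#' @examples
#' clone_size_distribution(3) # 3/4, 1/4
#' @export
clone_size_distribution <- function(k) {
  if (length(k) != 1L || k < 2 || k != floor(k)) {
    stop("`k` must be an integer >= 2.", call. = FALSE)
  }
  probs <- numeric(k - 1)
  for (i in 1:(k - 1)) {
    # one clonal cell among i + 1; iterate the remaining k - 1 - i divisions
    p <- 1
    if (i < k - 1) {
      for (tot in (i + 1):(k - 1)) {
        nn <- seq_along(p)
        p_new <- numeric(length(p) + 1)
        p_new[nn] <- p * (1 - nn / tot)
        p_new[nn + 1] <- p_new[nn + 1] + p * nn / tot
        p <- p_new
      }
    }
    idx <- seq_along(p)
    probs[idx] <- probs[idx] + p
  }
  probs <- probs / (k - 1)
  out <- tibble::tibble(n = 1:(k - 1), prob = probs)
  new_clone_distribution(out, "clone_size", list(k = k))
}

#' Number of mutations carried by a randomly selected clone
#'
#' A clone founded at division `i` (uniform over `1..k-1`) carries its own
#' founding mutations plus any earlier mutations that fell on its lineage.
#' Mutations per division are Poisson(`lambda`) with `mu0 = exp(-lambda)`;
#' a mutation at the `r`-th division lands in the lineage with probability
#' `1/(r + 1)`. The count is `Z + sum_(r<i) X_r * N_r` with `Z`
#' zero-truncated Poisson(`lambda`) (the founding division has at least one
#' mutation by definition of a clone), `X_r ~ Bernoulli(1/(r+1))`,
#' `N_r ~ Poisson(lambda)`.
#'
#' `mode = "pgf"` expands the product of the component generating functions
#' (numerically, by truncated series convolution) and returns the exact
#' distribution; `mode = "sample"` draws Monte-Carlo samples from the same
#' construction.
#'
#' @param k Colony size (`>= 2`).
#' @param model A [mutation_model()]; `mu0` must lie strictly in (0, 1).
#' @param mode `"pgf"` (exact distribution) or `"sample"`.
#' @param n_samples Number of Monte-Carlo draws in sample mode.
#' @param seed Optional integer seed (sample mode).
#' @return In pgf mode, a tibble with columns `mutations` (1, 2, ...) and
#'   `prob` (class `clone_distribution`); in sample mode, a tibble with
#'   columns `draw`, `mutations`.
#' @examples
#' mutations_per_clone(2, mutation_model(0.1)) # zero-truncated Poisson
#' @export
mutations_per_clone <- function(k, model, mode = c("pgf", "sample"),
                                n_samples = 10000, seed = NULL) {
  mode <- match.arg(mode)
  if (length(k) != 1L || k < 2 || k != floor(k)) {
    stop("`k` must be an integer >= 2.", call. = FALSE)
  }
  model <- as_mutation_model(model)
  lam <- model$lambda
  if (model$mu0 <= 0 || model$mu0 >= 1 || !is.finite(lam)) {
    stop("`mu0` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (mode == "sample") {
    if (!is.null(seed)) set.seed(seed)
    i <- sample.int(k - 1, n_samples, replace = TRUE)
    # zero-truncated Poisson via inverse CDF restricted above P(0)
    u <- stats::runif(n_samples, min = stats::ppois(0, lam), max = 1)
    z <- stats::qpois(u, lam)
    extra <- integer(n_samples)
    if (k > 2) {
      for (r in 1:(k - 2)) {
        act <- which(i > r)
        if (!length(act)) next
        x <- stats::rbinom(length(act), 1, 1 / (r + 1))
        hit <- act[x == 1]
        if (length(hit)) {
          extra[hit] <- extra[hit] + stats::rpois(length(hit), lam)
        }
      }
    }
    return(tibble::tibble(draw = seq_len(n_samples), mutations = z + extra))
  }
  # pgf mode: truncation order capturing essentially all mass
  m_max <- max(10, stats::qpois(1 - 1e-13, lam * (2 + log(k))) + 5)
  pois <- stats::dpois(0:m_max, lam)
  # component pmf for X_r * N_r
  term_pmf <- function(r) {
    p <- pois / (r + 1)
    p[1] <- p[1] + r / (r + 1)
    p
  }
  conv <- function(p, q) {
    out <- numeric(m_max + 1)
    for (s in 0:m_max) {
      out[s + 1] <- sum(p[1:(s + 1)] * q[(s + 1):1])
    }
    out
  }
  # prefix[i] = distribution of sum_(r=1..i-1) X_r N_r; average over i
  cur <- c(1, numeric(m_max))
  avg <- numeric(m_max + 1)
  for (i in 1:(k - 1)) {
    avg <- avg + cur
    if (i < k - 1) cur <- conv(cur, term_pmf(i))
  }
  avg <- avg / (k - 1)
  zt <- pois
  zt[1] <- 0
  zt <- zt / (1 - pois[1])   # zero-truncated founding count
  probs <- conv(avg, zt)
  last <- max(which(probs > 1e-15))
  out <- tibble::tibble(mutations = 1:(last - 1), prob = probs[2:last])
  new_clone_distribution(out, "mutations_per_clone",
                         list(k = k, model = model))
}
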