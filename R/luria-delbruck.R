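# Size-indexed Luria-Delbruck distributions.
#
# A colony grows by pure birth from one non-mutant cell. Conditioning on the
# colony size k (rather than elapsed time) reduces the process to its
# embedded jump chain: at each division the dividing cell is chosen
# proportionally to division rate, and a dividing non-mutant spawns one
# mutant daughter with probability mu1. Only the fitness ratio
# rho = beta_m / beta_n enters the size-indexed law.

#' Mutation model for a growing colony
#'
#' @param mu1 Per-division probability that a dividing non-mutant produces a
#'   mutant daughter. `mu0 = 1 - mu1`.
#' @param rho Relative mutant fitness, the ratio of mutant to non-mutant
#'   division rates (`> 0`; 1 is neutral).
#' @param lambda Mean number of distinct mutations per division, used by the
#'   genotype-level results. Defaults to `-log(mu0)` so that a division
#'   carries at least one mutation with probability `mu1` (Poisson-zero
#'   consistency); supply explicitly to override.
#'
#' @return An object of class `mutation_model` with elements `mu0`, `mu1`,
#'   `rho`, `lambda`.
#' @examples
#' mutation_model(0.05)
#' mutation_model(0.05, rho = 2)
#' @export
mutation_model <- function(mu1, rho = 1, lambda = NULL) {
  if (!is.numeric(mu1) || length(mu1) != 1L || mu1 < 0 || mu1 > 1) {
    stop("`mu1` must be a probability in [0, 1].", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("`rho` must be a positive number.", call. = FALSE)
  }
  mu0 <- 1 - mu1
  if (is.null(lambda)) {
    lambda <- if (mu0 > 0) -log(mu0) else Inf
  }
  structure(list(mu0 = mu0, mu1 = mu1, rho = rho, lambda = lambda),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, digits = 4, ...) {
  cat("<mutation_model>  mu1 =", format(x$mu1, digits = digits),
      " rho =", format(x$rho, digits = digits),
      " lambda =", format(x$lambda, digits = digits), "\n")
  invisible(x)
}

as_mutation_model <- function(x) {
  if (inherits(x, "mutation_model")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(mutation_model(x))
  stop("`model` must be a mutation_model (or a single mu1 value).",
       call. = FALSE)
}

check_colony_size <- function(k) {
  if (length(k) != 1L || k < 1 || k != floor(k)) {
    stop("colony size `k` must be a positive integer.", call. = FALSE)
  }
}

# Shared drift check: probability vectors must stay normalized; we refuse to
# renormalize silently.
check_normalized <- function(p, tol = 1e-10) {
  drift <- abs(sum(p) - 1)
  if (drift > tol) {
    stop("probability mass drifted by ", format(drift),
         " during the recurrence; this indicates a numerical problem.",
         call. = FALSE)
  }
  p
}

#' Neutral mutant-count distribution at a given colony size
#'
#' Exact distribution of the number of mutant cells `m` when a colony grown
#' from a single non-mutant cell reaches size `k`, under neutral fitness
#' (`rho = 1`). Iterates the jump-chain recurrence from size 1:
#' at size `k` with `m` mutants, the next division leaves `m` unchanged with
#' probability `((k - m)/k) * mu0`, and increments it with probability
#' `m/k + ((k - m)/k) * mu1` (a mutant divides, or a non-mutant divides and
#' mutates). Support is `m = 0..k-1`: the founder lineage always retains at
#' least one non-mutant cell.
#'
#' @param k Colony size (`>= 1`).
#' @param model A [mutation_model()] (or a single `mu1` value); `rho` must
#'   be 1 — use [selection_distribution()] otherwise.
#' @return A tibble with columns `m` (0..k-1) and `prob`, of class
#'   `clone_distribution`.
#' @examples
#' neutral_distribution(3, mutation_model(0.1)) # 0.81, 0.135, 0.055
#' @export
neutral_distribution <- function(k, model) {
  check_colony_size(k)
  model <- as_mutation_model(model)
  if (model$rho != 1) {
    stop("`model$rho` must equal 1 for the neutral distribution; ",
         "use selection_distribution() for rho != 1.", call. = FALSE)
  }
  p <- mutant_count_probs(k, model$mu0, model$mu1, rho = 1)
  out <- tibble::tibble(m = 0:(length(p) - 1), prob = p)
  new_clone_distribution(out, "mutant_count", list(k = k, model = model))
}

#' Mutant-count distribution with selection
#'
#' As [neutral_distribution()], but mutants divide at `rho` times the
#' non-mutant rate. In the embedded chain with `m` mutants and `n`
#' non-mutants, the dividing cell is mutant with probability
#' `rho m / (rho m + n)`. The per-division transition probabilities are
#' `(n/(n + rho m)) mu0` (no new mutant) and
#' `rho m/(rho m + n) + (n/(n + rho m)) mu1` (one new mutant).
#'
#' @inheritParams neutral_distribution
#' @return A tibble with columns `m` and `prob`, class `clone_distribution`.
#' @examples
#' selection_distribution(3, mutation_model(0.1, rho = 2))
#' @export
selection_distribution <- function(k, model) {
  check_colony_size(k)
  model <- as_mutation_model(model)
  p <- mutant_count_probs(k, model$mu0, model$mu1, rho = model$rho)
  out <- tibble::tibble(m = 0:(length(p) - 1), prob = p)
  new_clone_distribution(out, "mutant_count", list(k = k, model = model))
}

# Jump-chain iteration over colony sizes 1..k; returns probs over m=0..k-1.
mutant_count_probs <- function(k, mu0, mu1, rho) {
  p <- 1   # size 1: zero mutants
  if (k == 1) return(p)
  for (s in 1:(k - 1)) {
    m <- 0:(s - 1)
    n <- s - m
    w_mut <- rho * m / (rho * m + n)        # mutant divides
    stay <- (1 - w_mut) * mu0               # non-mutant divides, no mutation
    gain <- w_mut + (1 - w_mut) * mu1       # new mutant appears
    p_new <- numeric(s + 1)
    p_new[1:s] <- p * stay
    p_new[2:(s + 1)] <- p_new[2:(s + 1)] + p * gain
    p <- check_normalized(p_new)
  }
  p
}

#' Moments of the non-mutant count
#'
#' Mean and variance of the number of non-mutant cells at colony size `k`
#' under the neutral model. The mean has the closed product form
#' `E[n] = prod_(j=1..k-1) (j + mu0) / j` (each division multiplies the
#' expected non-mutant count by `(j + mu0)/j`); it is cross-checked against
#' the exact distribution. The variance is computed from the distribution.
#'
#' @inheritParams neutral_distribution
#' @return A one-row tibble with columns `k`, `mean_nonmutants`,
#'   `var_nonmutants`, `mean_mutants`.
#' @examples
#' neutral_moments(3, mutation_model(0.1)) # mean 2.755
#' @export
neutral_moments <- function(k, model) {
  check_colony_size(k)
  model <- as_mutation_model(model)
  if (model$rho != 1) {
    stop("moments are implemented for the neutral model (rho = 1).",
         call. = FALSE)
  }
  mean_n <- if (k == 1) 1 else prod((seq_len(k - 1) + model$mu0) /
                                      seq_len(k - 1))
  p <- mutant_count_probs(k, model$mu0, model$mu1, rho = 1)
  m <- 0:(length(p) - 1)
  n <- k - m
  var_n <- sum(p * n^2) - sum(p * n)^2
  tibble::tibble(k = k, mean_nonmutants = mean_n,
                 var_nonmutants = var_n, mean_mutants = k - mean_n)
}
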