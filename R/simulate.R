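# Stochastic simulators. These are the package's independent oracles: the
# exact recurrences are validated against them, and they against the exact
# results. Both jump-chain and continuous-time modes are provided for the
# homeostasis process; the continuous-time embedded chain must be
# distributionally identical to the jump chain (the time-independence
# property the whole size-indexed approach rests on).

#' Simulate progenitor/differentiated clone growth
#'
#' Grows `replicates` clones from a single proliferating cell. Each division
#' is PP / PD / DD with probabilities (a, b, c); the clone size `n` always
#' increases by one, the proliferating count `k` moves up / flat / down and
#' the clone is absorbed at `k = 0`. In continuous-time mode each division
#' additionally waits an exponential time with rate `beta * k`; the sequence
#' of division outcomes (the embedded chain) is unaffected by the clocks.
#'
#' @param fate A [fate_probabilities()] object (or coercible).
#' @param replicates Number of clones to simulate.
#' @param stop_size Stop a clone when its total size reaches this value
#'   (`NULL` to run to absorption or `max_divisions`).
#' @param max_divisions Safety cap on divisions per clone.
#' @param time If `TRUE`, run in continuous time and record the elapsed
#'   time of each clone (rate `beta` per proliferating cell).
#' @param beta Division rate per proliferating cell (continuous time only).
#' @param seed Optional integer seed.
#' @return A tibble with one row per replicate: `replicate`, `n` (final
#'   size), `k` (proliferating cells at stop), `absorbed`, `divisions`,
#'   `time` (`NA` in jump-chain mode).
#' @examples
#' simulate_homeostasis(fate_probabilities(0.3, 0.4, 0.3),
#'                      replicates = 100, stop_size = 5, seed = 1)
#' @export
simulate_homeostasis <- function(fate, replicates, stop_size = NULL,
                                 max_divisions = 10000, time = FALSE,
                                 beta = 1, seed = NULL) {
  fate <- as_fate_probs(fate)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- rep(1L, replicates)
  n <- rep(1L, replicates)
  div <- rep(0L, replicates)
  tm <- if (time) numeric(replicates) else rep(NA_real_, replicates)
  active <- rep(TRUE, replicates)
  if (!is.null(stop_size) && stop_size == 1) active[] <- FALSE
  steps <- 0L
  while (any(active) && steps < max_divisions) {
    idx <- which(active)
    if (time) {
      tm[idx] <- tm[idx] + stats::rexp(length(idx)) / (beta * k[idx])
    }
    u <- stats::runif(length(idx))
    dk <- ifelse(u < fate$a, 1L, ifelse(u < fate$a + fate$b, 0L, -1L))
    k[idx] <- k[idx] + dk
    n[idx] <- n[idx] + 1L
    div[idx] <- div[idx] + 1L
    done <- k[idx] == 0L
    if (!is.null(stop_size)) done <- done | n[idx] >= stop_size
    active[idx[done]] <- FALSE
    steps <- steps + 1L
  }
  tibble::tibble(replicate = seq_len(replicates), n = n, k = k,
                 absorbed = k == 0L, divisions = div, time = tm)
}

#' Simulate colony growth with mutation
#'
#' Grows colonies from a single non-mutant cell to size `k`. At each
#' division the dividing cell is mutant with probability
#' `rho m / (rho m + n)`; a dividing non-mutant produces one mutant daughter
#' with probability `mu1`; mutant divisions always produce two mutants.
#'
#' With `genotype = TRUE` (neutral growth), every division draws
#' Poisson(`lambda`) new, globally unique mutations attached to one
#' daughter; each mutation-producing division founds a new clone. The
#' return then has one row per clone per replicate with both clone-size
#' definitions: `cells_lineage` (all descendants of the founding cell — the
#' definition matched by the exact clone-size recursion) and
#' `cells_genotype` (cells whose mutation set is exactly the clone's).
#'
#' @param k Final colony size (`>= 1`).
#' @param model A [mutation_model()] (or a single `mu1`).
#' @param replicates Number of colonies.
#' @param genotype Track individual mutation labels (requires `rho = 1`).
#' @param seed Optional integer seed.
#' @return Without genotype tracking, a tibble `replicate`, `m` (mutant
#'   cells at size `k`). With it, a tibble `replicate`, `clone_id`,
#'   `founded_at_division`, `new_mutations`, `total_mutations`,
#'   `cells_genotype`, `cells_lineage` (clone 0 is the unmutated founder
#'   clone, `new_mutations = 0`).
#' @export
simulate_mutation_growth <- function(k, model, replicates, genotype = FALSE,
                                     seed = NULL) {
  check_colony_size(k)
  model <- as_mutation_model(model)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!genotype) {
    m <- integer(replicates)
    if (k > 1) {
      rho <- model$rho
      for (s in 1:(k - 1)) {
        n <- s - m
        p_mut_div <- rho * m / (rho * m + n)
        u <- stats::runif(replicates)
        mut_divides <- u < p_mut_div
        new_mut <- mut_divides |
          (stats::runif(replicates) < model$mu1 & !mut_divides)
        m <- m + as.integer(new_mut)
      }
    }
    return(tibble::tibble(replicate = seq_len(replicates), m = m))
  }
  if (model$rho != 1) {
    stop("genotype tracking is implemented for neutral growth (rho = 1).",
         call. = FALSE)
  }
  lam <- model$lambda
  if (!is.finite(lam)) stop("genotype mode needs mu0 > 0.", call. = FALSE)
  out <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    # preallocated buffers: at most k cells and k clones per colony
    cell_clone <- integer(k)
    cell_clone[1] <- 1L              # clone index per cell (1 = founder clone)
    clone_parent <- integer(k)
    clone_q <- integer(k)            # new mutations at founding
    clone_div <- integer(k)
    clone_parent[1] <- NA_integer_
    n_clones <- 1L
    if (k > 1) {
      nmut_all <- stats::rpois(k - 1, lam)
      cells <- stats::runif(k - 1)   # uniform dividing-cell choices
      for (d in 1:(k - 1)) {
        cell <- floor(cells[d] * d) + 1L
        daughter_clone <- cell_clone[cell]
        nmut <- nmut_all[d]
        if (nmut > 0) {
          n_clones <- n_clones + 1L
          clone_parent[n_clones] <- daughter_clone
          clone_q[n_clones] <- nmut
          clone_div[n_clones] <- d
          daughter_clone <- n_clones
        }
        cell_clone[d + 1L] <- daughter_clone
      }
    }
    cell_clone <- cell_clone[1:k]
    clone_parent <- clone_parent[1:n_clones]
    clone_q <- clone_q[1:n_clones]
    clone_div <- clone_div[1:n_clones]
    exact <- tabulate(cell_clone, nbins = n_clones)
    lineage <- exact
    total_q <- clone_q
    if (n_clones > 1) {
      for (ci in n_clones:2) {
        lineage[clone_parent[ci]] <- lineage[clone_parent[ci]] + lineage[ci]
        total_q[ci] <- total_q[ci] + total_q[clone_parent[ci]]
      }
    }
    out[[rep_i]] <- tibble::tibble(
      replicate = rep_i,
      clone_id = seq_len(n_clones) - 1L,
      founded_at_division = clone_div,
      new_mutations = clone_q,
      total_mutations = total_q,
      cells_genotype = exact,
      cells_lineage = lineage
    )
  }
  dplyr::bind_rows(out)
}

#' Generate a synthetic clone-size count table
#'
#' Simulates clones from a single proliferating cell to full differentiation
#' and tabulates their final sizes, mimicking an observed count table of
#' small fully differentiated clones. Clones still proliferating when they
#' reach `max_size` are censored — excluded from the table with their number
#' reported — mirroring the observational exclusion of still-expanding
#' clones.
#'
#' @param fate A [fate_probabilities()] object (or coercible).
#' @param n_clones Number of clones to simulate.
#' @param max_size Censoring size (default 20).
#' @param seed Optional integer seed; fixed seed gives an identical table.
#' @return A tibble with columns `size`, `count` (absorbed clones only) and
#'   attributes `n_censored`, `fate`, `seed`.
#' @examples
#' generate_count_fixture(fate_probabilities(0.415, 0.278, 0.307),
#'                        n_clones = 1000, seed = 1)
#' @export
generate_count_fixture <- function(fate, n_clones, max_size = 20,
                                   seed = NULL) {
  stopifnot(n_clones >= 1, max_size >= 2)
  sim <- simulate_homeostasis(fate, replicates = n_clones,
                              stop_size = max_size,
                              max_divisions = max_size + 1, seed = seed)
  absorbed <- sim[sim$absorbed & sim$n <= max_size, ]
  tab <- dplyr::count(absorbed, size = .data$n, name = "count")
  out <- dplyr::arrange(tibble::as_tibble(tab), .data$size)
  attr(out, "n_censored") <- n_clones - nrow(absorbed)
  attr(out, "fate") <- as_fate_probs(fate)
  attr(out, "seed") <- seed
  out
}
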