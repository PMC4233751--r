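# Estimating the division-fate probabilities (a, b, c) from observed counts
# of small fully differentiated clones.
#
# The ruin series starts {c, bc, c(b^2 + ac), ...} for clone sizes 2, 3, 4,
# so consecutive count ratios isolate b and the product ac:
#   N3/N2 estimates b,   N4/N3 estimates (b^2 + ac)/b.
# With a + c = 1 - b, (a, c) are the two roots of x^2 - (1 - b)x + ac = 0.
# The data cannot tell a from c (the ruin series is symmetric in them);
# `root_policy` breaks the tie.

#' Validate a clone-size count table
#'
#' @param counts A data frame with integer columns `size` (>= 2) and
#'   `count` (>= 0).
#' @param require_234 Require positive counts at sizes 2, 3 and 4 (needed by
#'   the ratio estimator).
#' @return The validated tibble (duplicate sizes summed).
#' @keywords internal
validate_counts <- function(counts, require_234 = FALSE) {
  if (!is.data.frame(counts) || !all(c("size", "count") %in% names(counts))) {
    stop("`counts` must be a data frame with columns `size` and `count`.",
         call. = FALSE)
  }
  counts <- tibble::as_tibble(counts)[, c("size", "count")]
  if (nrow(counts) == 0) stop("`counts` is empty.", call. = FALSE)
  if (anyNA(counts)) stop("`counts` contains missing values.", call. = FALSE)
  if (any(counts$size != floor(counts$size)) || any(counts$size < 2)) {
    stop("clone sizes must be integers >= 2 (a fully differentiated clone ",
         "has at least two cells).", call. = FALSE)
  }
  if (any(counts$count != floor(counts$count)) || any(counts$count < 0)) {
    stop("counts must be non-negative integers.", call. = FALSE)
  }
  if (anyDuplicated(counts$size)) {
    warning("duplicate clone sizes present; summing their counts.",
            call. = FALSE)
    counts <- dplyr::summarise(dplyr::group_by(counts, .data$size),
                               count = sum(.data$count), .groups = "drop")
  }
  counts <- dplyr::arrange(counts, .data$size)
  if (require_234) {
    n234 <- counts$count[match(2:4, counts$size)]
    if (anyNA(n234) || any(n234 <= 0)) {
      stop("the ratio estimator needs positive counts at clone sizes ",
           "2, 3 and 4.", call. = FALSE)
    }
  }
  counts
}

new_fate_estimate <- function(b_hat, ac_hat, root_policy, feasible,
                              fate = NULL, method = "ratio", counts = NULL,
                              diagnostics = character(), ci = NULL,
                              loglik = NULL, boundary = FALSE) {
  structure(
    list(fate = fate, b_hat = b_hat, ac_hat = ac_hat,
         root_policy = root_policy, feasible = feasible, method = method,
         counts = counts, diagnostics = diagnostics, ci = ci,
         loglik = loglik, boundary = boundary),
    class = "fate_estimate"
  )
}

# Solve x^2 - (1 - b)x + ac = 0 and assign roots by policy.
fate_from_moments <- function(b_hat, ac_hat, root_policy) {
  disc <- (1 - b_hat)^2 - 4 * ac_hat
  if (disc < 0) return(NULL)
  r1 <- ((1 - b_hat) + sqrt(disc)) / 2
  r2 <- ((1 - b_hat) - sqrt(disc)) / 2
  if (root_policy == "a_greater") {
    list(a = r1, c = r2)
  } else {
    list(a = r2, c = r1)
  }
}

#' Ratio estimator of the fate probabilities from small-clone counts
#'
#' Estimates (a, b, c) from the observed numbers of fully differentiated
#' clones of sizes 2, 3 and 4, using the count-ratio identities
#' `N3/N2 -> b` and `N4/N3 -> (b^2 + ac)/b`, then solving
#' `x^2 - (1 - b)x + ac = 0` for the pair {a, c}. The data are symmetric in
#' a and c; `root_policy` assigns the larger root to `a` (`"a_greater"`,
#' the default, appropriate when proliferating clones persist) or to `c`.
#'
#' Infeasible moment combinations (`b >= 1`, `ac < 0`, or a negative
#' discriminant) yield `feasible = FALSE` with diagnostics rather than an
#' error.
#'
#' @param counts Data frame with columns `size`, `count`; sizes 2-4 must
#'   have positive counts.
#' @param root_policy `"a_greater"` or `"c_greater"`.
#' @return A `fate_estimate` object; see [tidy.fate_estimate()] and
#'   [glance.fate_estimate()].
#' @examples
#' keratinocytes <- tibble::tibble(size = 2:4, count = c(259, 72, 53))
#' est <- estimate_fate_ratio(keratinocytes)
#' glance(est)
#' @export
estimate_fate_ratio <- function(counts,
                                root_policy = c("a_greater", "c_greater")) {
  root_policy <- match.arg(root_policy)
  counts <- validate_counts(counts, require_234 = TRUE)
  n2 <- counts$count[counts$size == 2]
  n3 <- counts$count[counts$size == 3]
  n4 <- counts$count[counts$size == 4]
  b_hat <- n3 / n2
  ac_hat <- b_hat * (n4 / n3) - b_hat^2
  diag <- character()
  if (b_hat >= 1) diag <- c(diag, "b_hat >= 1")
  if (ac_hat < 0) diag <- c(diag, "ac_hat < 0")
  roots <- fate_from_moments(b_hat, ac_hat, root_policy)
  if (is.null(roots) && length(diag) == 0) {
    diag <- c(diag, "negative discriminant (1 - b_hat)^2 - 4 ac_hat < 0")
  }
  feasible <- length(diag) == 0 && !is.null(roots) &&
    roots$c >= 0 && roots$a <= 1
  fate <- if (feasible) {
    fate_probabilities(roots$a, b_hat, roots$c)
  } else NULL
  new_fate_estimate(b_hat, ac_hat, root_policy, feasible, fate = fate,
                    method = "ratio", counts = counts, diagnostics = diag)
}

#' Maximum-likelihood fate estimate from the full size distribution
#'
#' Extension of the ratio method: fits (a, b, c) to all observed fully
#' differentiated clone sizes `2..n_max` by maximising the multinomial
#' log-likelihood under the conditional size distribution
#' `P[n, 0] / sum_(j=2..n_max) P[j, 0]`. Because the ruin probabilities
#' depend on a and c only through their product, the likelihood is optimised
#' over (b, ac) and the roots are assigned by `root_policy`, exactly as in
#' [estimate_fate_ratio()].
#'
#' @inheritParams estimate_fate_ratio
#' @param n_max Largest clone size used (`>= 4`); defaults to the largest
#'   observed size.
#' @return A `fate_estimate` with the achieved log-likelihood in `loglik`;
#'   `boundary = TRUE` flags solutions pinned to the parameter boundary.
#' @export
estimate_fate_mle <- function(counts, n_max = NULL,
                              root_policy = c("a_greater", "c_greater")) {
  root_policy <- match.arg(root_policy)
  counts <- validate_counts(counts)
  if (is.null(n_max)) n_max <- max(counts$size)
  if (n_max < 4) stop("`n_max` must be >= 4.", call. = FALSE)
  if (any(counts$size > n_max)) {
    stop("`counts` contains sizes above `n_max`.", call. = FALSE)
  }
  sizes <- 2:n_max
  obs <- numeric(length(sizes))
  obs[match(counts$size, sizes)] <- counts$count
  if (sum(obs) == 0) stop("all counts are zero.", call. = FALSE)

  # P[n, 0] depends on (a, c) only through ac: evaluate the ruin series at
  # a = c = sqrt(ac) (the weighted Motzkin return masses carry (ac)^i b^j).
  cond_probs <- function(b, ac) {
    s <- sqrt(ac)
    rows <- motzkin_rows(n_max - 2, s, b, s)
    # P[n, 0] = c * sum_i N_i (ac)^i b^(n-2-2i): the return mass depends on
    # (a, c) only through ac, and the leading factor c is common to every
    # size, so it cancels in the conditional normalization. Evaluating at
    # a = c = sqrt(ac) therefore yields the correct conditional law.
    s * vapply(sizes, function(n) rows[[n - 1]][1], numeric(1))
  }
  negll <- function(par) {
    b <- stats::plogis(par[1])
    t <- stats::plogis(par[2])
    ac <- t * ((1 - b) / 2)^2
    p <- cond_probs(b, ac)
    tot <- sum(p)
    if (!is.finite(tot) || tot <= 0) return(1e10)
    -sum(obs * (log(pmax(p, 1e-300)) - log(tot)))
  }
  init <- tryCatch({
    r <- estimate_fate_ratio(counts[counts$size <= 4, ], root_policy)
    b0 <- min(max(r$b_hat, 1e-4), 1 - 1e-4)
    t0 <- min(max(r$ac_hat / ((1 - b0) / 2)^2, 1e-4), 1 - 1e-4)
    c(stats::qlogis(b0), stats::qlogis(t0))
  }, error = function(e) c(0, 0))
  opt <- stats::optim(init, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  b_hat <- stats::plogis(opt$par[1])
  t_hat <- stats::plogis(opt$par[2])
  ac_hat <- t_hat * ((1 - b_hat) / 2)^2
  diag <- character()
  if (opt$convergence != 0) diag <- c(diag, "optimizer did not converge")
  boundary <- b_hat < 1e-4 || b_hat > 1 - 1e-4 ||
    t_hat < 1e-4 || t_hat > 1 - 1e-4
  if (boundary) diag <- c(diag, "solution at parameter boundary")
  roots <- fate_from_moments(b_hat, ac_hat, root_policy)
  feasible <- opt$convergence == 0 && !is.null(roots)
  fate <- if (!is.null(roots)) {
    fate_probabilities(roots$a, b_hat, roots$c, tol = 1e-6)
  } else NULL
  est <- new_fate_estimate(b_hat, ac_hat, root_policy, feasible, fate = fate,
                           method = "mle", counts = counts,
                           diagnostics = diag, loglik = -opt$value,
                           boundary = boundary)
  est
}

#' Bootstrap confidence intervals for the ratio estimator
#'
#' Multinomial resampling of the observed count vector over its size
#' classes, re-running [estimate_fate_ratio()] on each replicate. Percentile
#' (2.5%, 97.5%) intervals are formed from the feasible replicates;
#' infeasible replicates are counted and reported.
#'
#' @inheritParams estimate_fate_ratio
#' @param replicates Number of bootstrap replicates (`>= 100`).
#' @param seed Integer seed for reproducibility.
#' @return A `fate_estimate` (the point estimate on the original data) whose
#'   `ci` element is a tibble with columns `term`, `conf.low`, `conf.high`,
#'   and attributes `n_infeasible`, `replicates`.
#' @examples
#' keratinocytes <- tibble::tibble(size = 2:4, count = c(259, 72, 53))
#' est <- bootstrap_fate(keratinocytes, replicates = 200, seed = 1)
#' tidy(est)
#' @export
bootstrap_fate <- function(counts, replicates = 2000, seed = NULL,
                           root_policy = c("a_greater", "c_greater")) {
  root_policy <- match.arg(root_policy)
  if (replicates < 100) {
    stop("`replicates` must be at least 100.", call. = FALSE)
  }
  counts <- validate_counts(counts, require_234 = TRUE)
  point <- estimate_fate_ratio(counts, root_policy)
  n_tot <- sum(counts$count)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(replicates, n_tot, counts$count / n_tot)
  reps <- purrr::map(seq_len(replicates), function(i) {
    cts <- tibble::tibble(size = counts$size, count = draws[, i])
    if (any(cts$count[match(2:4, cts$size)] == 0)) return(NULL)
    est <- estimate_fate_ratio(cts, root_policy)
    if (!est$feasible) return(NULL)
    tibble::tibble(a = est$fate$a, b = est$fate$b, c = est$fate$c,
                   b_hat = est$b_hat, ac_hat = est$ac_hat)
  })
  ok <- purrr::compact(reps)
  n_infeasible <- replicates - length(ok)
  if (n_infeasible > replicates / 2) {
    warning(n_infeasible, " of ", replicates,
            " bootstrap replicates were infeasible; intervals are based ",
            "on the remainder and may be unreliable.", call. = FALSE)
  }
  boot <- dplyr::bind_rows(ok)
  ci <- purrr::map_dfr(c("a", "b", "c", "b_hat", "ac_hat"), function(term) {
    q <- stats::quantile(boot[[term]], c(0.025, 0.975), names = FALSE)
    tibble::tibble(term = term, conf.low = q[1], conf.high = q[2])
  })
  attr(ci, "n_infeasible") <- n_infeasible
  attr(ci, "replicates") <- replicates
  point$ci <- ci
  point$method <- "ratio+bootstrap"
  point
}

#' @export
print.fate_estimate <- function(x, digits = 4, ...) {
  cat("<fate_estimate>  method:", x$method,
      " feasible:", x$feasible, "\n")
  cat("  b_hat =", format(x$b_hat, digits = digits),
      "  ac_hat =", format(x$ac_hat, digits = digits),
      "  (root policy:", paste0(x$root_policy, ")"), "\n")
  if (!is.null(x$fate)) {
    cat("  a =", format(x$fate$a, digits = digits),
        "  b =", format(x$fate$b, digits = digits),
        "  c =", format(x$fate$c, digits = digits), "\n")
  }
  if (length(x$diagnostics)) {
    cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  if (!is.null(x$ci)) {
    cat("  bootstrap CIs over", attr(x$ci, "replicates"), "replicates (",
        attr(x$ci, "n_infeasible"), "infeasible )\n")
  }
  invisible(x)
}

#' Tidy a fate estimate
#'
#' One row per fate parameter, broom style, with bootstrap interval columns
#' when available.
#'
#' @param x A `fate_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and, when a bootstrap
#'   was run, `conf.low`, `conf.high`.
#' @method tidy fate_estimate
#' @export
tidy.fate_estimate <- function(x, ...) {
  out <- tibble::tibble(
    term = c("a", "b", "c"),
    estimate = if (is.null(x$fate)) rep(NA_real_, 3) else
      c(x$fate$a, x$fate$b, x$fate$c)
  )
  if (!is.null(x$ci)) {
    out <- dplyr::left_join(out, x$ci[x$ci$term %in% c("a", "b", "c"), ],
                            by = "term")
  }
  out
}

#' Glance at a fate estimate
#'
#' @param x A `fate_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the moment estimates, feasibility, method,
#'   log-likelihood (MLE only) and the number of clones used.
#' @method glance fate_estimate
#' @export
glance.fate_estimate <- function(x, ...) {
  tibble::tibble(
    b_hat = x$b_hat, ac_hat = x$ac_hat, feasible = x$feasible,
    boundary = x$boundary, method = x$method,
    loglik = if (is.null(x$loglik)) NA_real_ else x$loglik,
    n_clones = if (is.null(x$counts)) NA_real_ else sum(x$counts$count)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
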