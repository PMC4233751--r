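# ggplot2 methods for the distribution tibbles and estimate objects.

#' Plot a distribution tibble
#'
#' Column plot of any `clone_distribution` tibble (proliferating-cell
#' distributions, ruin series, mutant counts, frequency spectra, ...).
#'
#' @param object A `clone_distribution` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clone_distribution
#' @export
autoplot.clone_distribution <- function(object, ...) {
  cols <- dist_columns(object)
  type <- attr(object, "dist_type") %||% "distribution"
  labs <- c(
    clone_state = "proliferating cells k",
    ruin = "clone size n at full differentiation",
    mutant_count = "mutant cells m",
    frequency_spectrum = "cells carrying the mutation r",
    clone_count = "number of clones",
    clone_size = "cells in clone n",
    mutations_per_clone = "mutations in clone"
  )
  xlab <- labs[[type]] %||% cols$support
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data[[cols$support]], y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = xlab, y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a fate estimate
#'
#' Point estimates of (a, b, c) with bootstrap intervals when present.
#'
#' @param object A `fate_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fate_estimate
#' @export
autoplot.fate_estimate <- function(object, ...) {
  td <- tidy(object)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "fate parameter", y = "estimate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (all(c("conf.low", "conf.high") %in% names(td))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.15
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
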