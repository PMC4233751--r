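# Reading count tables and writing distributions.
#
# CSV is the interchange format (no domain-standard format exists for
# clone-size count tables); a `#`-prefixed provenance header records the
# generating parameters.

#' Read a clone-size count table
#'
#' Reads a two-column `size,count` table (comma or tab delimited, detected
#' automatically; `#` lines are comments). Duplicate sizes are summed with
#' a warning; non-integer or negative entries are rejected with the
#' offending line number.
#'
#' @param path Path to the file.
#' @return A validated tibble with columns `size`, `count`.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) {
    stop("`", path, "` has no data rows (need a header and at least one ",
         "size,count row).", call. = FALSE)
  }
  delim <- if (grepl("\t", body[1])) "\t" else ","
  header <- tolower(trimws(strsplit(body[1], delim, fixed = TRUE)[[1]]))
  if (!identical(header[1:2], c("size", "count"))) {
    stop("`", path, "` must start with a `size,count` header.",
         call. = FALSE)
  }
  rows <- purrr::map(seq_along(body)[-1], function(i) {
    fields <- trimws(strsplit(body[i], delim, fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (length(fields) < 2 || anyNA(vals)) {
      stop("malformed row at line ", which(lines == body[i])[1], " of `",
           path, "`: ", body[i], call. = FALSE)
    }
    if (any(vals != floor(vals)) || any(vals < 0)) {
      stop("non-integer or negative entry at line ",
           which(lines == body[i])[1], " of `", path, "`: ", body[i],
           call. = FALSE)
    }
    tibble::tibble(size = vals[1], count = vals[2])
  })
  validate_counts(dplyr::bind_rows(rows))
}

# Identify the support / probability columns of a distribution tibble.
dist_columns <- function(dist) {
  if (!is.data.frame(dist) || !("prob" %in% names(dist))) {
    stop("`dist` must be a distribution tibble with a `prob` column.",
         call. = FALSE)
  }
  support <- setdiff(names(dist), "prob")[1]
  list(support = support, prob = "prob")
}

#' Write a distribution table with a provenance header
#'
#' Writes a two-column (support, probability) table as CSV/TSV with
#' `#`-prefixed header lines recording the package version and the
#' generating parameters, or as JSON (`{params, support, probs}`). Refuses
#' to write a vector that is not normalized; note that ruin series
#' ([ruin_probabilities()]) are partial first-passage masses, not a
#' normalized distribution, and are written with their own writer semantics
#' via `check_normalized = FALSE`.
#'
#' @param dist A distribution tibble (e.g. from [neutral_distribution()]).
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @param check_normalized Require the probabilities to sum to 1.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path, format = c("csv", "tsv", "json"),
                               check_normalized = TRUE) {
  format <- match.arg(format)
  cols <- dist_columns(dist)
  total <- sum(dist$prob)
  if (check_normalized && abs(total - 1) > 1e-8) {
    stop("probabilities sum to ", format(total),
         ", not 1; refusing to write (set check_normalized = FALSE for ",
         "partial series such as ruin probabilities).", call. = FALSE)
  }
  params <- attr(dist, "params")
  param_str <- if (is.null(params)) "none" else {
    flat <- unlist(lapply(params, function(p) {
      if (inherits(p, "fate_probs")) c(a = p$a, b = p$b, c = p$c)
      else if (inherits(p, "mutation_model")) {
        c(mu1 = p$mu1, rho = p$rho, lambda = p$lambda)
      } else p
    }))
    paste(names(flat), format(flat, digits = 17, trim = TRUE),
          sep = "=", collapse = " ")
  }
  if (format == "json") {
    obj <- list(
      package = paste0("clonedist ",
                       as.character(utils::packageVersion("clonedist"))),
      type = attr(dist, "dist_type") %||% "distribution",
      params = param_str,
      support = dist[[cols$support]],
      probs = dist$prob
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# clonedist ",
           as.character(utils::packageVersion("clonedist"))),
    paste0("# type: ", attr(dist, "dist_type") %||% "distribution"),
    paste0("# params: ", param_str),
    paste(cols$support, "prob", sep = sep)
  ), con)
  writeLines(paste(dist[[cols$support]],
                   format(dist$prob, digits = 17, trim = TRUE),
                   sep = sep), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
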