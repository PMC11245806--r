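#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an assembly result
#'
#' @param x `seedrecon_assembly` tibble.
#' @param ... Unused.
#' @return Per-seed tibble without the sequence column.
#' @export
tidy.seedrecon_assembly <- function(x, ...) {
  tibble::as_tibble(x)[, setdiff(names(x), "sequence")]
}

#' One-row summary of an assembly result
#'
#' @param x `seedrecon_assembly` tibble.
#' @param ... Unused.
#' @return Tibble with seed counts, failure count and length summaries.
#' @export
glance.seedrecon_assembly <- function(x, ...) {
  tibble::tibble(
    n_seeds = nrow(x),
    n_ok = sum(x$status == "ok"),
    n_failed = sum(x$status == "failed"),
    n_ge_800 = sum(x$length >= 800),
    median_length = stats::median(x$length[x$status == "ok"]),
    total_pairs = sum(x$n_pairs))
}

#' Tidy a sweep result
#'
#' @param x `seedrecon_sweep` tibble.
#' @param ... Unused.
#' @return Plain tibble.
#' @export
tidy.seedrecon_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Pairs-vs-length scatter for an assembly result
#'
#' The per-seed reconstruction picture: collected read pairs on x, contig
#' length on y; failed assemblies sit at y = 0.
#'
#' @param object `seedrecon_assembly` tibble.
#' @param min_report_len Horizontal guide at the minimum reported length.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seedrecon_assembly <- function(object, min_report_len = 800, ...) {
  d <- tidy.seedrecon_assembly(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_pairs, y = .data$length)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = min_report_len, linetype = "dashed") +
    ggplot2::labs(x = "read pairs collected", y = "contig length (nt)") +
    ggplot2::theme_minimal()
}

#' Sweep curves for recruitment counts
#'
#' Correct/incorrect (when available) or assigned pair counts against the
#' swept parameter (identity threshold or multiplicity cap).
#'
#' @param object `seedrecon_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seedrecon_sweep <- function(object, ...) {
  d <- tidy.seedrecon_sweep(object)
  xvar <- if ("min_identity" %in% names(d)) "min_identity" else "max_matches"
  if (all(c("n_correct", "n_incorrect") %in% names(d))) {
    long <- tidyr::pivot_longer(d, c("n_correct", "n_incorrect"),
                                names_to = "class", values_to = "n")
    ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$n,
                                       colour = .data$class)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_colour_manual(values = c(n_correct = "#2e7d32",
                                              n_incorrect = "#c62828")) +
      ggplot2::labs(x = xvar, y = "read pairs") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data$n_assigned)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = xvar, y = "assigned pairs") +
      ggplot2::theme_minimal()
  }
}
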