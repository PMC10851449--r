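#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a coverage report
#'
#' `tidy()` returns the per-SOC table; `glance()` a one-row summary.
#'
#' @param x A `coverage_report` from [coverage_summary()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) {
  x$per_soc
}

#' @rdname tidy.coverage_report
#' @method glance coverage_report
#' @export
glance.coverage_report <- function(x, ...) {
  tibble(
    n_pt_mapped = x$n_pt_mapped,
    n_pt_total = x$n_pt_total,
    pct_pt_mapped = x$pct_pt_mapped
  )
}

#' Tidy a kappa result
#'
#' Both `tidy()` and `glance()` return the one-row agreement summary.
#'
#' @param x A `kappa_result` from [cohen_kappa()].
#' @param ... Unused.
#' @return A one-row tibble: `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n_items`, `degenerate`.
#' @method glance kappa_result
#' @export
glance.kappa_result <- function(x, ...) {
  tibble(
    kappa = x$kappa,
    observed_agreement = x$observed_agreement,
    expected_agreement = x$expected_agreement,
    n_items = x$n_items,
    degenerate = x$degenerate
  )
}

#' @rdname glance.kappa_result
#' @method tidy kappa_result
#' @export
tidy.kappa_result <- function(x, ...) {
  glance.kappa_result(x, ...)
}

#' Plot per-SOC mapped/unmapped coverage
#'
#' Horizontal stacked bars of mapped and unmapped PT counts per system organ
#' class, the usual display for per-SOC coverage.
#'
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) {
  dat <- object$per_soc |>
    tidyr::pivot_longer(c("n_mapped", "n_unmapped"),
      names_to = "status", values_to = "n"
    ) |>
    mutate(status = ifelse(.data$status == "n_mapped", "mapped", "unmapped"))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$n, y = stats::reorder(.data$soc_name, .data$n, sum),
    fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "PT terms", y = NULL, fill = NULL,
      title = sprintf(
        "MedDRA PT coverage: %d/%d (%.2f%%)",
        object$n_pt_mapped, object$n_pt_total, object$pct_pt_mapped
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a coverage trend across snapshots
#'
#' @param trend Tibble from [snapshot_trend()].
#' @param denominator `"release"` plots the percentage over all PTs in the
#'   hierarchy, `"snapshot"` over the PTs present in each snapshot.
#' @return A ggplot object.
#' @export
plot_coverage_trend <- function(trend, denominator = c("release", "snapshot")) {
  denominator <- match.arg(denominator)
  ycol <- if (denominator == "release") "pct_pt_mapped" else "pct_of_snapshot"
  ggplot2::ggplot(trend, ggplot2::aes(
    x = factor(.data$snapshot, levels = unique(.data$snapshot)),
    y = .data[[ycol]], group = 1
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "snapshot", y = "PT terms mapped (%)") +
    ggplot2::theme_minimal()
}
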