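#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' simulated donor/NO/O2 trajectories, product-formation curves with the
#' driving NO overlay, fitted dose-response curves on a log-dose axis, and
#' annotation summaries of differential calls.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name notet-autoplot
NULL

#' @rdname notet-autoplot
#' @export
autoplot.no_timecourse <- function(object, ...) {
  long <- object |>
    dplyr::select("time_s", "donor_uM", "no_uM", "o2_uM") |>
    tidyr::pivot_longer(-"time_s", names_to = "species", values_to = "uM") |>
    dplyr::mutate(species = factor(.data$species,
                                   c("donor_uM", "no_uM", "o2_uM"),
                                   c("donor", "NO", "O2")))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s / 3600, .data$uM)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = "concentration (uM)",
                  title = "NO donor release and autooxidation")
}

#' @rdname notet-autoplot
#' @export
autoplot.activity_timecourse <- function(object, ...) {
  regime <- attr(object, "regime") %||% ""
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s / 3600)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$product_fraction)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$no_uM / max(c(.data$no_uM, 1e-9))),
                       linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "time (h)", y = "product fraction (solid) / scaled NO (dashed)",
                  title = paste("Demethylase activity under NO", regime))
}

#' @rdname notet-autoplot
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  grid <- tibble(dose = 10^seq(log10(min(object$data$dose)),
                               log10(max(object$data$dose)), length.out = 200))
  grid$response <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose, .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response",
                  title = sprintf("4PL fit, IC50 = %.3g", object$ic50))
}

#' Plot a differential-call annotation summary
#'
#' Bar chart of hyper/hypo counts per CpG class and functional element, as
#' produced by [summarize_by_annotation()].
#'
#' @param summary A [summarize_by_annotation()] table.
#' @return A ggplot object.
#' @export
plot_annotation_summary <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(c("n_hyper", "n_hypo"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(direction = sub("^n_", "", .data$direction))
  ggplot2::ggplot(long, ggplot2::aes(.data$category, .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~category_type, scales = "free_x") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "differential positions", fill = NULL)
}
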