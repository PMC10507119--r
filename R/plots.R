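#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: the schedule
#' raster of a DHS partition (step vs thread slot, coloured by node depth),
#' recorded voltage traces of a simulation, the relative-cost sweep, the
#' spike-probability curves, and the training log of a network fit.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name dendrosched-plots
NULL

#' @rdname dendrosched-plots
#' @export
autoplot.dhs_partition <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$step, y = .data$slot,
                                 fill = .data$depth)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$node), size = 3,
                       colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "parallel step", y = "thread slot",
                  title = sprintf("DHS partition, k = %d: %d steps (serial %d)",
                                  object$k, length(object$subsets),
                                  object$n_nodes))
}

#' @rdname dendrosched-plots
#' @export
autoplot.cable_sim <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$v,
                                 colour = factor(.data$node))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane voltage (mV)",
                  colour = "compartment")
}

#' @rdname dendrosched-plots
#' @export
autoplot.dhs_cost_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$relative_cost,
                                       colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "threads per cell (k)",
                  y = "relative cost (DHS steps / serial steps)")
}

#' @rdname dendrosched-plots
#' @export
autoplot.excitability_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_syn, y = .data$spike_prob,
                                       colour = .data$variant,
                                       linetype = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "activated synapses", y = "somatic spike probability")
}

#' @rdname dendrosched-plots
#' @export
autoplot.hpcnet_fit <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("loss", "accuracy"), names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL)
}
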