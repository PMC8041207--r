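#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' One row per model parameter, flagging which were free in the fit.
#'
#' @param x An `ic_fit`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`, `free`.
#' @method tidy ic_fit
#' @export
tidy.ic_fit <- function(x, ...) {
  flat <- par_flatten(x$params)
  free <- x$free_names
  # clock-only fits store bare clock names
  free_full <- ifelse(free %in% names(flat), free, paste0("clock.", free))
  tibble::tibble(parameter = names(flat), value = as.numeric(flat),
                 free = names(flat) %in% free_full)
}

#' Glance at a calibration fit
#'
#' @param x An `ic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `cost`, `n_free`, `iterations`, `starts`,
#'   `condition`.
#' @method glance ic_fit
#' @export
glance.ic_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, n_free = length(x$free_names),
                 iterations = x$iterations, starts = x$starts,
                 condition = x$params$condition)
}

#' Tidy Sobol' sensitivity results
#'
#' @param x A `sobol_result`.
#' @param ... Unused.
#' @return The underlying tibble (one row per output x parameter).
#' @method tidy sobol_result
#' @export
tidy.sobol_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Glance at Sobol' sensitivity results
#'
#' @param x A `sobol_result`.
#' @param ... Unused.
#' @return One-row tibble: `n_base`, `seed`, `n_failed`, `n_parameters`,
#'   `n_outputs`.
#' @method glance sobol_result
#' @export
glance.sobol_result <- function(x, ...) {
  tibble::tibble(n_base = attr(x, "n_base"), seed = attr(x, "seed"),
                 n_failed = attr(x, "n_failed"),
                 n_parameters = length(unique(x$parameter)),
                 n_outputs = length(unique(x$output)))
}

#' Plot a simulated trajectory
#'
#' Faceted time courses of selected state variables.
#'
#' @param object An `ic_trajectory`.
#' @param vars Variables to display (default: the cytokines, damage marker
#'   and the clock proteins entering the coupling).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ic_trajectory
#' @export
autoplot.ic_trajectory <- function(object,
                                   vars = c("tnf", "il6", "il10", "d_dam",
                                            "p_rev", "p_ror", "p_cry"),
                                   ...) {
  vars <- intersect(vars, names(object))
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object),
                  dplyr::all_of(c("time_h", vars))),
    -"time_h", names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time after challenge (h)", y = "level (a.u.)")
}

#' Plot the free-running clock limit cycle
#'
#' @param object A `limit_cycle`.
#' @param vars Variables to display (default: the five mRNAs).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot limit_cycle
#' @export
autoplot.limit_cycle <- function(object,
                                 vars = c("m_per", "m_cry", "m_rev",
                                          "m_ror", "m_bmal1"),
                                 ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$cycle, dplyr::all_of(c("ct_h", vars))),
    -"ct_h", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ct_h, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "circadian time (h)", y = "mRNA (a.u.)",
                  title = sprintf("free-running period %.2f h",
                                  object$period_h))
}

#' Plot severity across the circadian day
#'
#' @param object An `ic_ct_grid` (see [ct_grid_experiment()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ic_ct_grid
#' @export
autoplot.ic_ct_grid <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$ct, y = .data$severity_rel)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(breaks = seq(0, 21, 3)) +
    ggplot2::labs(x = "circadian time of challenge (h)",
                  y = "relative damage severity")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data :=
NULL
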