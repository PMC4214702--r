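# ggplot2 views of trajectories and sensitivity results.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col facet_wrap
#'   labs theme_minimal coord_flip
#' @importFrom rlang .data
NULL

#' Plot radial profiles of a trajectory
#'
#' Field value against radius, one panel per field, coloured by time.
#'
#' @param object An `il35_trajectory`.
#' @param fields Fields to include (default: all ten).
#' @param times Output times to draw (default: up to six, evenly spaced).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot il35_trajectory
#' @export
autoplot.il35_trajectory <- function(object, fields = .fields,
                                     times = NULL, ...) {
  if (is.null(times)) {
    idx <- unique(round(seq(1, length(object$times), length.out = 6)))
    times <- object$times[idx]
  }
  df <- as_tibble(object) |>
    dplyr::filter(.data$field %in% fields, .data$time %in% times)
  ggplot(df, aes(.data$radius, .data$value,
                 colour = factor(.data$time), group = .data$time)) +
    geom_line() +
    facet_wrap(~label, scales = "free_y") +
    labs(x = "radius (cm)", y = "density / concentration (g/cm³)",
         colour = "day") +
    theme_minimal()
}

#' Plot sphere-integrated totals over time
#'
#' @param traj An `il35_trajectory` (or named list of them, overlaid).
#' @param fields Fields to include.
#' @return A ggplot object.
#' @export
plot_totals <- function(traj, fields = c("c", "M", "T", "h")) {
  trajs <- if (inherits(traj, "il35_trajectory")) list(run = traj) else traj
  df <- purrr::imap_dfr(trajs, function(tr, nm)
    dplyr::mutate(field_totals(tr), run = nm)) |>
    dplyr::filter(.data$field %in% fields)
  ggplot(df, aes(.data$time, .data$total, colour = .data$run)) +
    geom_line() +
    facet_wrap(~label, scales = "free_y") +
    labs(x = "time (day)", y = "sphere total (g)", colour = NULL) +
    theme_minimal()
}

#' Plot PRCC estimates
#'
#' Horizontal bars of the partial rank correlation per parameter; by default
#' only parameters significant at p < 0.01 are shown, mirroring the usual
#' presentation of LHS/PRCC screens.
#'
#' @param object An `il35_prcc`.
#' @param alpha Significance cut-off for inclusion (default 0.01; use 1 to
#'   show everything).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot il35_prcc
#' @export
autoplot.il35_prcc <- function(object, alpha = 0.01, ...) {
  df <- tidy(object) |> dplyr::filter(.data$p_value < alpha)
  ggplot(df, aes(stats::reorder(.data$parameter, .data$prcc), .data$prcc)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "PRCC") +
    theme_minimal()
}
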