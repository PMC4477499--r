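#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result into a long tibble
#'
#' @param x a `syncol_result`.
#' @param ... unused.
#' @return Tibble with columns `time_h`, `z_m`, `field`, `value`; fields
#'   are `X` (g/L), dissolved `C_L`, `H_L`, `D_L` (mmol/L), products
#'   `E_L`, `A_L` (g/L), gas `C_G`, `H_G`, `D_G` (mmol/L).
#' @export
tidy.syncol_result <- function(x, ...) {
  purrr::map2_dfr(x$times, x$states, function(t, st) {
    out <- as_tibble(as.data.frame(st))
    out$time_h <- t
    out$z_m <- x$z
    tidyr::pivot_longer(out, cols = dplyr::all_of(.fields),
                        names_to = "field", values_to = "value")
  })
}

#' Axial profile plot of a simulation result
#'
#' Final-state axial profiles of all nine fields (or a chosen snapshot),
#' facetted by field.
#'
#' @param object a `syncol_result`.
#' @param time_h snapshot time to plot (default: final state).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.syncol_result <- function(object, time_h = NULL, ...) {
  tl <- tidy(object)
  tsel <- if (is.null(time_h)) max(tl$time_h) else
    tl$time_h[which.min(abs(unique(tl$time_h) - time_h))]
  dat <- dplyr::filter(tl, .data$time_h == tsel)
  dat$field <- factor(dat$field, levels = .fields)
  ggplot2::ggplot(dat, ggplot2::aes(.data$z_m, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~field, scales = "free_y") +
    ggplot2::labs(x = "axial position z (m)", y = NULL,
                  title = sprintf("Column profiles at t = %.0f h", tsel)) +
    ggplot2::theme_minimal()
}

#' Trend plot of a parameter sweep
#'
#' Plots steady-state responses against the swept parameter, linearly
#' interpolating between the simulated cases (marked by points).
#'
#' @param object a `syncol_sweep`.
#' @param responses metric columns to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.syncol_sweep <- function(object,
                                  responses = c("etoh_gL", "ac_gL", "X_gL",
                                                "co_conversion",
                                                "h2_conversion"), ...) {
  ok <- dplyr::filter(as_tibble(object), is.na(.data$error))
  dat <- tidyr::pivot_longer(ok, cols = dplyr::all_of(responses),
                             names_to = "metric", values_to = "response")
  param <- attr(object, "param") %||% "parameter"
  ggplot2::ggplot(dat, ggplot2::aes(.data$value, .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = param, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
glance.syncol_sweep <- function(x, ...) {
  tibble(n = nrow(x), n_failed = sum(!is.na(x$error)),
         param = attr(x, "param") %||% NA_character_)
}
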