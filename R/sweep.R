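#' Sweep configuration
#'
#' Settings of the single-factor turning-radius sweep: the swept factor, the
#' starting value, the step, the number of models, and the plateau threshold
#' on the per-step relative change of the response.
#'
#' @param factor Swept factor (currently `"r_tt"`).
#' @param start First value, mm (default 0).
#' @param step Increment, mm (default 1).
#' @param count Number of values (default 12).
#' @param threshold Plateau threshold, percent per step (default 5).
#' @return A `sweep_config` object.
#' @export
sweep_config <- function(factor = "r_tt", start = 0, step = 1, count = 12,
                         threshold = 5) {
  if (!identical(factor, "r_tt"))
    stop_ivt("ivtflow_invalid_params", "only the r_tt sweep is supported")
  if (step <= 0) stop_ivt("ivtflow_invalid_params", "step must be > 0")
  if (count < 2) stop_ivt("ivtflow_invalid_params", "count must be >= 2")
  if (threshold <= 0) stop_ivt("ivtflow_invalid_params", "threshold must be > 0")
  structure(list(factor = factor, start = start, step = step, count = count,
                 threshold = threshold), class = "sweep_config")
}

#' Build a sweep curve from values and responses
#'
#' Computes the per-step change rates
#' `rate_i = 100 * |y_i - y_(i-1)| / y_(i-1)` (backward relative difference,
#' percent) and the plateau value for a given threshold.
#'
#' @param values Factor values, mm (strictly increasing).
#' @param responses Pressure differences, mmHg (positive).
#' @param threshold Plateau threshold, percent (default 5).
#' @return An object of class `ivt_sweep`: list with `values`, `responses`,
#'   `change_rates` (length `count - 1`), `threshold`, `plateau_value`
#'   (mm, or `NA` when never reached).
#' @export
sweep_curve <- function(values, responses, threshold = 5) {
  stopifnot(length(values) == length(responses), length(values) >= 2,
            all(diff(values) > 0))
  rates <- 100 * abs(diff(responses)) / head(responses, -1)
  curve <- structure(
    list(values = values, responses = responses, change_rates = rates,
         threshold = threshold, plateau_value = NA_real_),
    class = "ivt_sweep")
  curve$plateau_value <- plateau_radius(curve, threshold)
  curve
}

#' Single-factor turning-radius sweep
#'
#' Evaluates the flow model at `count` turning radii starting from
#' `config$start` in steps of `config$step`, holding the other factors at
#' the base configuration, then computes change rates and the plateau
#' radius. Radii whose geometry is infeasible are dropped with a warning.
#'
#' @param base A [tunnel_params()] object giving the held-fixed factors
#'   (its `r_tt` is ignored).
#' @param config A [sweep_config()].
#' @param model A function `tunnel_params -> delta_p (mmHg)`; default is
#'   [pressure_difference()] at default coefficients.
#' @return An `ivt_sweep` (see [sweep_curve()]).
#' @examples
#' sw <- single_factor_sweep(tunnel_params(30, 0, 0))
#' sw$plateau_value
#' @export
single_factor_sweep <- function(base, config = sweep_config(),
                                model = function(p) pressure_difference(p)$delta_p) {
  stopifnot(inherits(base, "tunnel_params"), inherits(config, "sweep_config"))
  radii <- config$start + config$step * (seq_len(config$count) - 1L)
  vals <- numeric(); resp <- numeric(); dropped <- numeric()
  for (r in radii) {
    p <- tunnel_params(base$d_sa, base$a_lt, r,
                       lumen_diameter = base$lumen_diameter)
    y <- tryCatch(model(p), ivtflow_infeasible_geometry = function(e) NULL)
    if (is.null(y)) dropped <- c(dropped, r)
    else { vals <- c(vals, r); resp <- c(resp, y) }
  }
  if (length(dropped))
    warning(sprintf("dropped %d infeasible radius value(s): %s mm",
                    length(dropped), paste(dropped, collapse = ", ")))
  if (length(vals) < 2)
    stop_ivt("ivtflow_infeasible_geometry",
             "fewer than 2 feasible sweep points")
  sweep_curve(vals, resp, config$threshold)
}

#' Plateau radius of a sweep curve
#'
#' The smallest swept value from which every subsequent per-step change rate
#' stays below the threshold. Requiring all later steps (not just the first)
#' to be quiet avoids false plateaus on noisy curves.
#'
#' @param curve An `ivt_sweep`.
#' @param threshold Percent per step (defaults to the curve's own threshold).
#' @return The plateau value, mm, or `NA_real_` if the curve never settles.
#' @examples
#' r <- 0:11
#' plateau_radius(sweep_curve(r, 2 + 6 * exp(-r / 2)), 5)  # 8
#' @export
plateau_radius <- function(curve, threshold = curve$threshold) {
  stopifnot(inherits(curve, "ivt_sweep"))
  quiet <- curve$change_rates < threshold
  # all subsequent rates quiet <=> suffix product of the flags is 1
  all_after <- rev(cumprod(rev(quiet))) == 1
  idx <- which(all_after)
  if (!length(idx)) return(NA_real_)
  curve$values[idx[1] + 1L]
}

#' @export
print.ivt_sweep <- function(x, ...) {
  cat(sprintf("Turning-radius sweep: %d points, threshold %g%%/step\n",
              length(x$values), x$threshold))
  df <- data.frame(r_tt_mm = x$values,
                   delta_p_mmhg = round(x$responses, 4),
                   change_rate_pct = c(NA, round(x$change_rates, 3)))
  print(df, row.names = FALSE)
  if (is.na(x$plateau_value)) {
    cat("plateau: not reached within the sweep\n")
  } else {
    cat(sprintf("plateau radius: %g mm\n", x$plateau_value))
  }
  invisible(x)
}

#' @export
plot.ivt_sweep <- function(x, ...) {
  op <- par(mar = c(4.5, 4.5, 2, 4.5))
  on.exit(par(op))
  plot(x$values, x$responses, type = "b", pch = 19,
       xlab = "turning radius R_TT (mm)",
       ylab = expression(Delta * P ~ "(mmHg)"), ...)
  if (!is.na(x$plateau_value))
    abline(v = x$plateau_value, lty = 2)
  rate_scaled <- x$change_rates / max(x$change_rates) * max(x$responses)
  lines(x$values[-1], rate_scaled, type = "b", pch = 1, lty = 3)
  axis(4, at = pretty(c(0, max(x$responses))),
       labels = round(pretty(c(0, max(x$responses))) / max(x$responses) *
                        max(x$change_rates), 1))
  mtext("change rate (%/step)", side = 4, line = 3)
  invisible(x)
}
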