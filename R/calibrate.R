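#' Calibrate the loss model against measured responses
#'
#' Least-squares fit of the reduced-order model's free coefficients
#' (`c1`, `c2`, and a shared entrance/exit coefficient `k`) to a design with
#' measured pressure-difference responses, by Levenberg-Marquardt with
#' non-negativity bounds. The fit is deterministic for a fixed start point
#' (the supplied `coeffs0`).
#'
#' @param design An `ivt_design` with complete `delta_p` responses (for
#'   instance [table1_design()]).
#' @param coeffs0 Starting [loss_coeffs()]; the shared `k` starts at the
#'   mean of `k_entrance` and `k_exit`.
#' @param props,bc Fluid properties and boundary conditions held fixed.
#' @param lumen_diameter Lumen diameter applied to every row, mm.
#' @return An object of class `ivt_rom`: list with `coeffs` (fitted
#'   [loss_coeffs()], `k_entrance = k_exit = k`), `sse`, `spearman` (rank
#'   correlation of fitted vs measured), `fitted`, `observed`, `residuals`,
#'   `converged`, `degenerate` (flagged for zero-variance responses),
#'   `message` (optimizer diagnostics), and the `design`.
#' @examples
#' fit <- calibrate_rom(table1_design())
#' coef(fit)
#' fit$spearman
#' @export
calibrate_rom <- function(design, coeffs0 = loss_coeffs(),
                          props = fluid_props(), bc = flow_bc(),
                          lumen_diameter = 13.33) {
  if (!("delta_p" %in% names(design)) || anyNA(design$delta_p))
    stop_ivt("ivtflow_missing_response",
             "calibration needs a complete delta_p column")
  stopifnot(inherits(coeffs0, "loss_coeffs"))
  y <- design$delta_p
  params <- lapply(seq_len(nrow(design)), function(i)
    tunnel_params(design$d_sa[i], design$a_lt[i], design$r_tt[i],
                  lumen_diameter = lumen_diameter))
  predict_all <- function(c1, c2, k) {
    cf <- loss_coeffs(k_entrance = k, k_exit = k, c1 = c1, c2 = c2)
    vapply(params, function(p)
      pressure_difference(p, props = props, bc = bc, coeffs = cf)$delta_p,
      numeric(1))
  }
  resid_fn <- function(par) predict_all(par[1], par[2], par[3]) - y
  start <- c(coeffs0$c1, coeffs0$c2, (coeffs0$k_entrance + coeffs0$k_exit) / 2)

  fit <- minpack.lm::nls.lm(par = start, lower = c(0, 0, 0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning(sprintf("calibration did not converge (info %d): %s",
                    fit$info, fit$message))
  par <- fit$par
  fitted_y <- predict_all(par[1], par[2], par[3])
  degenerate <- stats::sd(y) < 1e-12
  spear <- if (degenerate || stats::sd(fitted_y) < 1e-12) NA_real_
           else cor(fitted_y, y, method = "spearman")
  structure(
    list(coeffs = loss_coeffs(k_entrance = par[3], k_exit = par[3],
                              c1 = par[1], c2 = par[2]),
         sse = sum((fitted_y - y)^2), spearman = spear,
         fitted = fitted_y, observed = y, residuals = fitted_y - y,
         converged = converged, degenerate = degenerate,
         message = fit$message, props = props, bc = bc,
         lumen_diameter = lumen_diameter, design = design),
    class = "ivt_rom"
  )
}

#' @export
print.ivt_rom <- function(x, ...) {
  cat("Reduced-order loss model calibration\n")
  cat(sprintf("  c1 = %.4g, c2 = %.4g, k_entrance = k_exit = %.4g\n",
              x$coeffs$c1, x$coeffs$c2, x$coeffs$k_entrance))
  cat(sprintf("  SSE = %.4g mmHg^2 over %d runs; Spearman rho = %.3f\n",
              x$sse, length(x$observed), x$spearman))
  if (x$degenerate) cat("  note: degenerate fit (constant responses)\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.ivt_rom <- function(object, ...) {
  c(c1 = object$coeffs$c1, c2 = object$coeffs$c2,
    k = object$coeffs$k_entrance)
}

#' @export
fitted.ivt_rom <- function(object, ...) object$fitted

#' @export
residuals.ivt_rom <- function(object, ...) object$residuals

#' Predict pressure differences from a calibrated model
#'
#' @param object An `ivt_rom` fit.
#' @param newdata An `ivt_design` (or data frame with `d_sa`, `a_lt`,
#'   `r_tt`); defaults to the calibration design.
#' @param ... Unused.
#' @return Numeric vector of predicted pressure differences, mmHg.
#' @export
predict.ivt_rom <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  vapply(seq_len(nrow(newdata)), function(i) {
    p <- tunnel_params(newdata$d_sa[i], newdata$a_lt[i], newdata$r_tt[i],
                       lumen_diameter = object$lumen_diameter)
    pressure_difference(p, props = object$props, bc = object$bc,
                        coeffs = object$coeffs)$delta_p
  }, numeric(1))
}
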