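#' Tunnel geometry parameters
#'
#' One geometric configuration of the intraventricular tunnel (IVT): the
#' distance from the ventricular septal defect (VSD) to the aortic-valve
#' plane, the ejection angle of blood entering the tunnel, the turning radius
#' of the tunnel bend, and the lumen bore.
#'
#' The default lumen diameter of 13.33 mm is chosen so that the Reynolds
#' number at the reference inlet velocity of 1 m/s in blood
#' (density 1050 kg/m^3, viscosity 0.0035 Pa.s) is approximately 4000,
#' i.e. the transitional regime expected in the tunnel at peak systole.
#'
#' @param d_sa Distance from the VSD centre to the aortic-valve plane, mm.
#'   Must be positive.
#' @param a_lt Ejection angle of the inlet jet above the valve plane
#'   (horizontal), degrees. `a_lt = 0` gives a full 90-degree bend; larger
#'   angles give gentler bends. Must lie in `[0, 90)`.
#' @param r_tt Turning radius of the tunnel bend, mm. `r_tt = 0` is a sharp
#'   elbow. Must be non-negative.
#' @param lumen_diameter Tunnel bore, mm. Default 13.33 (see Details).
#'
#' @return An object of class `tunnel_params`: a list with the four fields.
#' @examples
#' p <- tunnel_params(d_sa = 20, a_lt = 20, r_tt = 7.5)
#' p
#' @export
tunnel_params <- function(d_sa, a_lt, r_tt, lumen_diameter = 13.33) {
  for (nm in c("d_sa", "a_lt", "r_tt", "lumen_diameter")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_ivt("ivtflow_invalid_params",
               sprintf("'%s' must be a single finite number", nm))
  }
  if (d_sa <= 0)
    stop_ivt("ivtflow_invalid_params", "d_sa must be > 0 mm")
  if (a_lt < 0 || a_lt >= 90)
    stop_ivt("ivtflow_invalid_params", "a_lt must lie in [0, 90) degrees")
  if (r_tt < 0)
    stop_ivt("ivtflow_invalid_params", "r_tt must be >= 0 mm")
  if (lumen_diameter <= 0)
    stop_ivt("ivtflow_invalid_params", "lumen_diameter must be > 0 mm")
  structure(
    list(d_sa = d_sa, a_lt = a_lt, r_tt = r_tt,
         lumen_diameter = lumen_diameter),
    class = "tunnel_params"
  )
}

#' @export
print.tunnel_params <- function(x, ...) {
  cat("IVT configuration:\n")
  cat(sprintf("  D_SA (VSD -> valve plane) : %g mm\n", x$d_sa))
  cat(sprintf("  A_LT (ejection angle)     : %g deg\n", x$a_lt))
  cat(sprintf("  R_TT (turning radius)     : %g mm\n", x$r_tt))
  cat(sprintf("  lumen diameter            : %g mm\n", x$lumen_diameter))
  invisible(x)
}

#' Geometric feasibility of a tunnel configuration
#'
#' A configuration is feasible when the centerline can reach the aortic-valve
#' plane, i.e. when the outlet straight length
#' `L_out = d_sa - l_in * sin(a_lt) - r_tt * cos(a_lt)` is non-negative.
#'
#' @param params A [tunnel_params()] object.
#' @param l_in Inlet straight length before the bend, mm (default 0: the VSD
#'   opens directly into the bend).
#' @return A list with `feasible` (logical) and `reason` (`NA` when feasible,
#'   otherwise a message quantifying the deficit).
#' @examples
#' feasible(tunnel_params(10, 40, 10))$feasible  # TRUE
#' feasible(tunnel_params(5, 0, 10))$feasible    # FALSE: bend overshoots plane
#' @export
feasible <- function(params, l_in = 0) {
  stopifnot(inherits(params, "tunnel_params"))
  l_out <- outlet_length(params, l_in)
  if (l_out < 0) {
    list(feasible = FALSE,
         reason = sprintf(
           "tunnel cannot reach the valve plane: L_out = %.4g mm (deficit %.4g mm)",
           l_out, -l_out))
  } else {
    list(feasible = TRUE, reason = NA_character_)
  }
}

outlet_length <- function(params, l_in = 0) {
  a <- deg2rad(params$a_lt)
  params$d_sa - l_in * sin(a) - params$r_tt * cos(a)
}
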