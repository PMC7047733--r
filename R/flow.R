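#' Blood properties
#'
#' Newtonian, homogeneous, incompressible blood at the values conventional
#' for adult systolic simulation.
#'
#' @param density Density, kg/m^3 (default 1050).
#' @param viscosity Dynamic viscosity, Pa.s (default 0.0035).
#' @return A `fluid_props` object.
#' @export
fluid_props <- function(density = 1050, viscosity = 0.0035) {
  if (density <= 0 || viscosity <= 0)
    stop_ivt("ivtflow_invalid_params", "density and viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Flow boundary conditions
#'
#' Steady peak-systolic conditions: a uniform inlet velocity at the VSD and
#' a pressure outlet at the aortic root.
#'
#' @param inlet_velocity Inlet velocity, m/s (default 1).
#' @param outlet_pressure Outlet pressure, mmHg (default 110).
#' @return A `flow_bc` object.
#' @export
flow_bc <- function(inlet_velocity = 1, outlet_pressure = 110) {
  if (inlet_velocity <= 0 || outlet_pressure <= 0)
    stop_ivt("ivtflow_invalid_params",
             "inlet_velocity and outlet_pressure must be > 0")
  structure(list(inlet_velocity = inlet_velocity,
                 outlet_pressure = outlet_pressure),
            class = "flow_bc")
}

#' Minor-loss model coefficients
#'
#' Parameters of the one-dimensional loss model: sharp-edged entrance and
#' exit coefficients for the small steps at the VSD and the aortic valve,
#' and a bend-loss law `K_bend = c1 * (theta/90)^2 * exp(-c2 * r_tt / D)`.
#' Defaults are conventional hydraulics magnitudes: `k_entrance = 0.5`
#' (sharp-edged entry), `k_exit = 1.0` (full jet discharge), `c1 = 1.2`
#' (miter-bend loss), `c2 = 2.0` (decay per unit `r_tt/D`). All can be refit
#' from measured responses with [calibrate_rom()].
#'
#' @param k_entrance,k_exit,c1,c2 Non-negative dimensionless coefficients.
#' @return A `loss_coeffs` object.
#' @export
loss_coeffs <- function(k_entrance = 0.5, k_exit = 1.0, c1 = 1.2, c2 = 2.0) {
  v <- c(k_entrance, k_exit, c1, c2)
  if (any(!is.finite(v)) || any(v < 0))
    stop_ivt("ivtflow_invalid_params", "all loss coefficients must be >= 0")
  structure(list(k_entrance = k_entrance, k_exit = k_exit, c1 = c1, c2 = c2),
            class = "loss_coeffs")
}

#' Reynolds number
#'
#' `Re = rho * v * D / mu` with the diameter converted from mm to metres.
#'
#' @param props A [fluid_props()] object.
#' @param velocity Mean velocity, m/s.
#' @param diameter Tube diameter, mm.
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds(fluid_props(), 1, 13.33)  # ~ 4000, transitional
#' @export
reynolds <- function(props, velocity, diameter) {
  stopifnot(inherits(props, "fluid_props"))
  if (velocity <= 0 || diameter <= 0)
    stop_ivt("ivtflow_invalid_params", "velocity and diameter must be > 0")
  props$density * velocity * (diameter / 1000) / props$viscosity
}

#' Darcy friction factor
#'
#' Laminar `64/Re` up to Re = 2000, Blasius `0.316 Re^-0.25` from Re = 4000,
#' and linear interpolation in Re across the transitional gap.
#'
#' @param re Reynolds number (> 0); vectorised.
#' @return Darcy friction factor.
#' @examples
#' friction_factor(1000)   # 0.064
#' friction_factor(4000)   # ~0.0397
#' @export
friction_factor <- function(re) {
  if (any(!is.finite(re)) || any(re <= 0))
    stop_ivt("ivtflow_invalid_params", "re must be > 0")
  f_lam <- function(r) 64 / r
  f_turb <- function(r) 0.316 * r^(-0.25)
  ifelse(re <= 2000, f_lam(re),
         ifelse(re >= 4000, f_turb(re),
                f_lam(2000) + (re - 2000) / 2000 * (f_turb(4000) - f_lam(2000))))
}

#' Bend loss coefficient
#'
#' `K = c1 * (theta_bend / 90)^2 * exp(-c2 * r_tt / diameter)`: zero for a
#' straight run, finite (`c1` at a 90-degree bend) in the miter limit
#' `r_tt = 0`, and exponentially decaying as the bend is eased.
#'
#' @param theta_bend Bend angle, degrees, in `[0, 90]`.
#' @param r_tt Turning radius, mm (>= 0).
#' @param diameter Tube diameter, mm.
#' @param coeffs A [loss_coeffs()] object.
#' @return Dimensionless loss coefficient.
#' @export
bend_loss_coefficient <- function(theta_bend, r_tt, diameter,
                                  coeffs = loss_coeffs()) {
  stopifnot(inherits(coeffs, "loss_coeffs"))
  if (any(theta_bend < 0) || any(theta_bend > 90))
    stop_ivt("ivtflow_invalid_params", "theta_bend must lie in [0, 90]")
  if (any(r_tt < 0))
    stop_ivt("ivtflow_invalid_params", "r_tt must be >= 0")
  coeffs$c1 * (theta_bend / 90)^2 * exp(-coeffs$c2 * r_tt / diameter)
}

#' Trans-tunnel pressure difference
#'
#' One-dimensional minor-loss surrogate for the pressure drop across the
#' tunnel at steady peak-systolic flow:
#' `dP = (k_entrance + K_bend + k_exit + f * L / D) * (1/2) rho v^2`,
#' converted to mmHg at 133.322 Pa/mmHg. The entrance and exit terms stand
#' for the physiological steps at the VSD and the aortic valve; the bend
#' term carries the turning-radius dependence; the friction term uses the
#' Darcy factor at the tunnel Reynolds number over the full centerline
#' length.
#'
#' @param params A [tunnel_params()] object.
#' @param props A [fluid_props()] object.
#' @param bc A [flow_bc()] object.
#' @param coeffs A [loss_coeffs()] object.
#' @param l_in Inlet straight length, mm (default 0).
#' @return An `ivt_flow` object: `delta_p` (mmHg), `breakdown` (named numeric
#'   mmHg: entrance, friction, bend, exit), `reynolds`, `mean_velocity` (m/s).
#' @examples
#' pressure_difference(tunnel_params(25, 10, 0))   # sharp elbow, largest dP
#' pressure_difference(tunnel_params(10, 40, 10))  # gentle bend, smallest dP
#' @export
pressure_difference <- function(params, props = fluid_props(),
                                bc = flow_bc(), coeffs = loss_coeffs(),
                                l_in = 0) {
  stopifnot(inherits(params, "tunnel_params"), inherits(props, "fluid_props"),
            inherits(bc, "flow_bc"), inherits(coeffs, "loss_coeffs"))
  l_out <- outlet_length(params, l_in)
  if (l_out < 0)
    stop_ivt("ivtflow_infeasible_geometry", sprintf(
      "infeasible geometry: L_out = %.6g mm < 0 (deficit %.6g mm)",
      l_out, -l_out), deficit = -l_out)
  d <- params$lumen_diameter
  theta <- 90 - params$a_lt
  l_total <- l_in + params$r_tt * deg2rad(theta) + l_out
  v <- bc$inlet_velocity
  re <- reynolds(props, v, d)
  f <- friction_factor(re)
  k_bend <- bend_loss_coefficient(theta, params$r_tt, d, coeffs)
  q <- 0.5 * props$density * v^2  # dynamic pressure, Pa
  br <- c(entrance = coeffs$k_entrance,
          friction = f * l_total / d,
          bend = k_bend,
          exit = coeffs$k_exit) * q / MMHG_PA
  structure(
    list(delta_p = sum(br), breakdown = br, reynolds = re,
         mean_velocity = v, total_length = l_total, params = params),
    class = "ivt_flow"
  )
}

#' @export
print.ivt_flow <- function(x, ...) {
  cat(sprintf("Trans-tunnel pressure difference: %.3f mmHg (Re = %.0f)\n",
              x$delta_p, x$reynolds))
  cat("  breakdown (mmHg): ",
      paste(sprintf("%s %.3f", names(x$breakdown), x$breakdown),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
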