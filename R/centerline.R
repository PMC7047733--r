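#' Build the idealized tunnel centerline
#'
#' Constructs the planar centerline of the idealized IVT in a fixed
#' right-handed frame: x horizontal, y vertical towards the aortic-valve
#' plane, z out of plane. The path starts at the VSD centre (origin) heading
#' at `a_lt` degrees above horizontal, follows an optional inlet straight of
#' length `l_in`, turns through a circular arc of radius `r_tt` spanning
#' `theta_bend = 90 - a_lt` degrees until vertical, and finishes with a
#' straight run of length `L_out = d_sa - l_in*sin(a_lt) - r_tt*cos(a_lt)`
#' ending on the plane `y = d_sa` with direction normal to it. `r_tt = 0`
#' yields a sharp elbow (the two straights meet at the bend angle).
#'
#' @param params A [tunnel_params()] object.
#' @param l_in Inlet straight length, mm (default 0).
#' @param axial_step Target spacing of the sampled polyline vertices, mm.
#' @return An object of class `ivt_centerline`: list with `segments`
#'   (each `list(kind, length, start_direction_angle, turn_radius)`),
#'   `l_in`, `l_out`, `theta_bend` (degrees), `total_length` (mm),
#'   `vertices` (n x 3 matrix, mm, z = 0), `tangents` (n x 3 unit vectors),
#'   and the originating `params`.
#' @examples
#' cl <- build_centerline(tunnel_params(10, 40, 10))
#' cl$l_out           # ~2.34 mm
#' cl$theta_bend      # 50 degrees
#' @export
build_centerline <- function(params, l_in = 0, axial_step = 0.5) {
  stopifnot(inherits(params, "tunnel_params"))
  if (!is.numeric(l_in) || length(l_in) != 1L || l_in < 0)
    stop_ivt("ivtflow_invalid_params", "l_in must be a single number >= 0")
  if (axial_step <= 0)
    stop_ivt("ivtflow_invalid_params", "axial_step must be > 0")

  a <- deg2rad(params$a_lt)
  r <- params$r_tt
  theta_deg <- 90 - params$a_lt
  theta <- deg2rad(theta_deg)
  l_out <- outlet_length(params, l_in)
  if (l_out < 0)
    stop_ivt("ivtflow_infeasible_geometry", sprintf(
      "infeasible geometry: outlet straight length L_out = %.6g mm < 0 (deficit %.6g mm); the bend overshoots the valve plane y = %g mm",
      l_out, -l_out, params$d_sa), deficit = -l_out)

  dir_in <- c(cos(a), sin(a), 0)
  pts <- list(c(0, 0, 0))
  tans <- list(dir_in)
  segments <- list()

  # inlet straight
  p_cur <- c(0, 0, 0)
  if (l_in > 0) {
    n <- max(1L, ceiling(l_in / axial_step))
    for (i in seq_len(n)) {
      pts[[length(pts) + 1L]] <- p_cur + dir_in * (l_in * i / n)
      tans[[length(tans) + 1L]] <- dir_in
    }
    segments[[length(segments) + 1L]] <-
      list(kind = "straight", length = l_in,
           start_direction_angle = params$a_lt, turn_radius = NA_real_)
    p_cur <- p_cur + dir_in * l_in
  }

  # circular arc from direction angle a_lt up to 90 degrees (turn left)
  if (r > 0 && theta_deg > 0) {
    centre <- p_cur + r * c(-sin(a), cos(a), 0)
    n <- max(2L, ceiling(r * theta / axial_step))
    phis <- a + theta * seq_len(n) / n
    for (phi in phis) {
      pts[[length(pts) + 1L]] <- centre + r * c(sin(phi), -cos(phi), 0)
      tans[[length(tans) + 1L]] <- c(cos(phi), sin(phi), 0)
    }
    segments[[length(segments) + 1L]] <-
      list(kind = "arc", length = r * theta,
           start_direction_angle = params$a_lt, turn_radius = r)
    p_cur <- centre + r * c(sin(pi / 2), -cos(pi / 2), 0)
  }

  # outlet straight, vertical
  dir_out <- c(0, 1, 0)
  if (l_out > 0) {
    n <- max(1L, ceiling(l_out / axial_step))
    for (i in seq_len(n)) {
      pts[[length(pts) + 1L]] <- p_cur + dir_out * (l_out * i / n)
      tans[[length(tans) + 1L]] <- dir_out
    }
    segments[[length(segments) + 1L]] <-
      list(kind = "straight", length = l_out,
           start_direction_angle = 90, turn_radius = NA_real_)
  }
  # elbow (r = 0) with zero outlet run still needs the final tangent vertical
  tans[[length(tans)]] <- dir_out

  verts <- do.call(rbind, pts)
  tangs <- do.call(rbind, tans)
  colnames(verts) <- colnames(tangs) <- c("x", "y", "z")
  total <- l_in + r * theta + l_out

  structure(
    list(segments = segments, l_in = l_in, l_out = l_out,
         theta_bend = theta_deg, total_length = total,
         vertices = verts, tangents = tangs, params = params),
    class = "ivt_centerline"
  )
}

#' @export
print.ivt_centerline <- function(x, ...) {
  cat("IVT centerline:\n")
  cat(sprintf("  bend angle  : %g deg (arc radius %g mm)\n",
              x$theta_bend, x$params$r_tt))
  cat(sprintf("  L_in / L_out: %.3f / %.3f mm\n", x$l_in, x$l_out))
  cat(sprintf("  total length: %.3f mm over %d segment(s), %d vertices\n",
              x$total_length, length(x$segments), nrow(x$vertices)))
  invisible(x)
}
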