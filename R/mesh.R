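#' Sweep the lumen surface mesh along a centerline
#'
#' Sweeps a circle of the given diameter along the sampled centerline using
#' rotation-minimizing frames (for the planar centerline the out-of-plane
#' axis is the fixed binormal, which is exactly rotation-minimizing), giving
#' a triangulated tube. With `capped = TRUE` planar fan caps are added at
#' both ends so the mesh is watertight. Vertex ordering is deterministic, so
#' re-export is bit-identical.
#'
#' @param centerline An [build_centerline()] result.
#' @param diameter Tube diameter, mm. Defaults to the lumen diameter of the
#'   centerline's parameters.
#' @param n_circumferential Number of points around the circle (>= 8).
#' @param axial_step Resampling step along the path, mm.
#' @param capped Add planar end caps (default `TRUE`).
#' @return An object of class `ivt_mesh`: list with `vertices` (n x 3, mm),
#'   `triangles` (m x 3 integer, 1-based), `capped`, `n_circumferential`,
#'   `n_rings`.
#' @examples
#' cl <- build_centerline(tunnel_params(20, 20, 7.5))
#' m <- build_surface_mesh(cl)
#' mesh_volume(m) / (pi * (13.33 / 2)^2 * cl$total_length)  # ~1
#' @export
build_surface_mesh <- function(centerline, diameter = NULL,
                               n_circumferential = 64, axial_step = 0.5,
                               capped = TRUE) {
  stopifnot(inherits(centerline, "ivt_centerline"))
  diameter <- diameter %||% centerline$params$lumen_diameter
  if (!is.numeric(n_circumferential) || n_circumferential < 8 ||
      n_circumferential != round(n_circumferential))
    stop_ivt("ivtflow_invalid_resolution",
             "n_circumferential must be an integer >= 8")
  if (!is.numeric(axial_step) || axial_step <= 0)
    stop_ivt("ivtflow_invalid_resolution", "axial_step must be > 0")
  r_tt <- centerline$params$r_tt
  if (centerline$theta_bend > 0 && r_tt < diameter / 2)
    stop_ivt("ivtflow_self_intersection", sprintf(
      "inner wall folds: turning radius %.4g mm < tube radius %.4g mm on a %g-degree bend",
      r_tt, diameter / 2, centerline$theta_bend))

  # resample the path (and analytic tangents) at the requested step
  path <- resample_centerline(centerline, axial_step)
  P <- path$points
  Tn <- path$tangents
  n_ring <- nrow(P)
  m <- as.integer(n_circumferential)
  rad <- diameter / 2
  b <- c(0, 0, 1)  # fixed binormal of the planar path

  psi <- 2 * pi * (seq_len(m) - 1L) / m
  verts <- matrix(0, nrow = n_ring * m, ncol = 3)
  for (i in seq_len(n_ring)) {
    t_i <- Tn[i, ]
    n_i <- c(b[2] * t_i[3] - b[3] * t_i[2],
             b[3] * t_i[1] - b[1] * t_i[3],
             b[1] * t_i[2] - b[2] * t_i[1])  # b x t, unit, in-plane
    ring <- cbind(P[i, 1] + rad * (cos(psi) * n_i[1] + sin(psi) * b[1]),
                  P[i, 2] + rad * (cos(psi) * n_i[2] + sin(psi) * b[2]),
                  P[i, 3] + rad * (cos(psi) * n_i[3] + sin(psi) * b[3]))
    verts[(i - 1L) * m + seq_len(m), ] <- ring
  }

  tris <- vector("list", n_ring - 1L)
  for (i in seq_len(n_ring - 1L)) {
    a0 <- (i - 1L) * m + seq_len(m)
    nxt <- (i - 1L) * m + c(seq_len(m)[-1L], 1L)
    b0 <- a0 + m
    b1 <- nxt + m
    # outward orientation: tangent x ring direction
    tris[[i]] <- rbind(cbind(a0, nxt, b0), cbind(nxt, b1, b0))
  }
  tris <- do.call(rbind, tris)

  if (capped) {
    c_in <- nrow(verts) + 1L
    c_out <- nrow(verts) + 2L
    verts <- rbind(verts, P[1, ], P[n_ring, ])
    first <- seq_len(m)
    last <- (n_ring - 1L) * m + seq_len(m)
    nxt_f <- c(first[-1L], first[1L])
    nxt_l <- c(last[-1L], last[1L])
    tris <- rbind(tris,
                  cbind(rep(c_in, m), nxt_f, first),   # inlet cap faces -t
                  cbind(rep(c_out, m), last, nxt_l))   # outlet cap faces +t
  }
  dimnames(verts) <- list(NULL, c("x", "y", "z"))
  storage.mode(tris) <- "integer"
  dimnames(tris) <- NULL

  structure(
    list(vertices = verts, triangles = tris, capped = capped,
         n_circumferential = m, n_rings = n_ring),
    class = "ivt_mesh"
  )
}

resample_centerline <- function(centerline, axial_step) {
  # rebuild from the analytic segments so tangents are exact at every sample
  p <- centerline$params
  cl <- build_centerline(p, l_in = centerline$l_in, axial_step = axial_step)
  list(points = cl$vertices, tangents = cl$tangents)
}

#' @export
print.ivt_mesh <- function(x, ...) {
  cat(sprintf("IVT surface mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (x$capped) ", capped" else ", open tube"))
  invisible(x)
}

#' Enclosed volume of a triangulated mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; meaningful for closed
#' meshes. Returns the absolute value, in the cube of the vertex unit (mm^3).
#'
#' @param mesh An `ivt_mesh`.
#' @return Volume, mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  t1 <- v[mesh$triangles[, 1], , drop = FALSE]
  t2 <- v[mesh$triangles[, 2], , drop = FALSE]
  t3 <- v[mesh$triangles[, 3], , drop = FALSE]
  det6 <- t1[, 1] * (t2[, 2] * t3[, 3] - t2[, 3] * t3[, 2]) -
          t1[, 2] * (t2[, 1] * t3[, 3] - t2[, 3] * t3[, 1]) +
          t1[, 3] * (t2[, 1] * t3[, 2] - t2[, 2] * t3[, 1])
  abs(sum(det6)) / 6
}

#' Watertightness check
#'
#' A closed (watertight) triangulated surface has every undirected edge
#' shared by exactly two triangles.
#'
#' @param mesh An `ivt_mesh`.
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Write a surface mesh to STL or PLY
#'
#' Binary STL uses the conventional 80-byte header followed by little-endian
#' 50-byte triangle records (normal, three vertices as 32-bit floats, and an
#' attribute short). ASCII STL and ASCII PLY are also supported.
#'
#' @param mesh An `ivt_mesh`.
#' @param path Output file path.
#' @param format One of `"stl-binary"`, `"stl-ascii"`, `"ply"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("stl-binary", "stl-ascii", "ply")) {
  format <- match.arg(format)
  if (!inherits(mesh, "ivt_mesh") || nrow(mesh$triangles) == 0L)
    stop_ivt("ivtflow_invalid_mesh", "mesh is empty or not an ivt_mesh")
  v <- mesh$vertices
  tr <- mesh$triangles
  normals <- triangle_normals(v, tr)
  switch(format,
    "stl-binary" = {
      con <- file(path, "wb")
      on.exit(close(con))
      hdr <- charToRaw(sprintf("%-80s", "ivtflow binary STL"))[1:80]
      writeBin(hdr, con)
      writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
      rec <- t(cbind(normals,
                     v[tr[, 1], , drop = FALSE],
                     v[tr[, 2], , drop = FALSE],
                     v[tr[, 3], , drop = FALSE]))
      for (i in seq_len(ncol(rec))) {
        writeBin(as.numeric(rec[, i]), con, size = 4, endian = "little")
        writeBin(raw(2), con)
      }
    },
    "stl-ascii" = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines("solid ivtflow", con)
      for (i in seq_len(nrow(tr))) {
        writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                           normals[i, 1], normals[i, 2], normals[i, 3]), con)
        writeLines("    outer loop", con)
        for (j in 1:3) {
          p <- v[tr[i, j], ]
          writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
        }
        writeLines("    endloop", con)
        writeLines("  endfacet", con)
      }
      writeLines("endsolid ivtflow", con)
    },
    "ply" = {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(c("ply", "format ascii 1.0",
                   sprintf("element vertex %d", nrow(v)),
                   "property float x", "property float y", "property float z",
                   sprintf("element face %d", nrow(tr)),
                   "property list uchar int vertex_indices", "end_header"), con)
      writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
      writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
    }
  )
  invisible(path)
}

#' Read a surface mesh written by [write_mesh()]
#'
#' @param path File path.
#' @param format One of `"stl-binary"`, `"stl-ascii"`, `"ply"`. STL stores
#'   unindexed triangle soup; the reader rebuilds a vertex index by exact
#'   coordinate matching.
#' @return An `ivt_mesh` (with `capped = NA`: cap status is not stored).
#' @export
read_mesh <- function(path, format = c("stl-binary", "stl-ascii", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_ivt("ivtflow_io_error", sprintf("no such file: %s", path))
  if (format == "ply") {
    lines <- readLines(path)
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
    body <- which(lines == "end_header") + 1L
    v <- do.call(rbind, lapply(strsplit(lines[body:(body + nv - 1L)], " "), as.numeric))
    f <- do.call(rbind, lapply(strsplit(lines[(body + nv):(body + nv + nf - 1L)], " "),
                               function(x) as.integer(x[2:4]) + 1L))
    soup <- NULL
  } else if (format == "stl-binary") {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, raw(), n = 80)
    n <- readBin(con, integer(), size = 4, endian = "little")
    soup <- matrix(0, nrow = 3L * n, ncol = 3)
    for (i in seq_len(n)) {
      vals <- readBin(con, numeric(), n = 12, size = 4, endian = "little")
      readBin(con, raw(), n = 2)
      soup[(3L * (i - 1L) + 1L):(3L * i), ] <- matrix(vals[4:12], ncol = 3, byrow = TRUE)
    }
  } else {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    soup <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  }
  if (!is.null(soup)) {
    key <- apply(soup, 1, paste, collapse = ",")
    uk <- !duplicated(key)
    v <- soup[uk, , drop = FALSE]
    idx <- match(key, key[uk])
    f <- matrix(idx, ncol = 3, byrow = TRUE)
  }
  dimnames(v) <- list(NULL, c("x", "y", "z"))
  storage.mode(f) <- "integer"
  structure(list(vertices = v, triangles = f, capped = NA,
                 n_circumferential = NA, n_rings = NA),
            class = "ivt_mesh")
}

triangle_normals <- function(v, tr) {
  u <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  w <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}
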