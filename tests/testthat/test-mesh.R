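test_that("a near-straight capped tube reproduces the cylinder volume", {
  # theta_bend ~ 0.01 degrees: effectively a straight cylinder
  cl <- build_centerline(tunnel_params(30, 89.99, 7))
  m <- build_surface_mesh(cl, diameter = 13.33)
  expect_true(is_watertight(m))
  expect_lt(abs(mesh_volume(m) / cylinder_volume(13.33, cl$total_length) - 1),
            0.005)
})

test_that("a curved capped tube is watertight with volume near the swept value", {
  cl <- build_centerline(tunnel_params(20, 20, 7.5))
  m <- build_surface_mesh(cl)
  expect_true(is_watertight(m))
  # the centroid of the circle travels the centerline, so the exact swept
  # volume is area x path length (Pappus); also check by numerically
  # integrating cross-section area along the sampled path
  exact <- cylinder_volume(13.33, cl$total_length)
  seglen <- sqrt(rowSums(diff(cl$vertices)^2))
  numeric_swept <- pi * (13.33 / 2)^2 * sum(seglen)
  expect_lt(abs(mesh_volume(m) / exact - 1), 0.02)
  expect_lt(abs(mesh_volume(m) / numeric_swept - 1), 0.02)
})

test_that("halving the axial step changes enclosed volume by < 0.5%", {
  cl <- build_centerline(tunnel_params(20, 20, 7.5))
  v1 <- mesh_volume(build_surface_mesh(cl, axial_step = 1.0))
  v2 <- mesh_volume(build_surface_mesh(cl, axial_step = 0.5))
  expect_lt(abs(v2 / v1 - 1), 0.005)
})

test_that("self-intersecting and invalid resolutions are rejected", {
  cl <- build_centerline(tunnel_params(20, 20, 5))
  expect_error(build_surface_mesh(cl, diameter = 13.33),
               class = "ivtflow_self_intersection")
  cl2 <- build_centerline(tunnel_params(20, 20, 7.5))
  expect_error(build_surface_mesh(cl2, n_circumferential = 7),
               class = "ivtflow_invalid_resolution")
  expect_error(build_surface_mesh(cl2, axial_step = 0),
               class = "ivtflow_invalid_resolution")
})

test_that("triangle count follows the fan-cap formula", {
  cl <- build_centerline(tunnel_params(20, 89.99, 7))
  m <- build_surface_mesh(cl, n_circumferential = 16, axial_step = 2)
  nseg <- m$n_rings - 1L
  expect_equal(nrow(m$triangles), 2L * 16L * nseg + 2L * 16L)
  open_tube <- build_surface_mesh(cl, n_circumferential = 16, axial_step = 2,
                                  capped = FALSE)
  expect_equal(nrow(open_tube$triangles), 2L * 16L * nseg)
  expect_false(is_watertight(open_tube))
})

test_that("binary STL round-trips vertices and is byte-stable on re-export", {
  cl <- build_centerline(tunnel_params(20, 20, 7.5))
  m <- build_surface_mesh(cl, n_circumferential = 12, axial_step = 4)
  p1 <- withr::local_tempfile(fileext = ".stl")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, p1, "stl-binary")
  back <- read_mesh(p1, "stl-binary")
  # vertices survive up to float32 storage precision
  expect_equal(nrow(back$triangles), nrow(m$triangles))
  soup_orig <- m$vertices[t(m$triangles), ]
  soup_back <- back$vertices[t(back$triangles), ]
  expect_lt(max(abs(soup_orig - soup_back)), 1e-4)
  # after one round trip the coordinates are float32-representable, so a
  # further read/write cycle is byte-identical
  write_mesh(back, p2, "stl-binary")
  p3 <- withr::local_tempfile(fileext = ".stl")
  write_mesh(read_mesh(p2, "stl-binary"), p3, "stl-binary")
  expect_identical(readBin(p3, raw(), file.size(p3)),
                   readBin(p2, raw(), file.size(p2)))
})

test_that("ascii STL and PLY round-trip", {
  cl <- build_centerline(tunnel_params(20, 20, 7.5))
  m <- build_surface_mesh(cl, n_circumferential = 12, axial_step = 4)
  for (fmt in c("stl-ascii", "ply")) {
    p <- withr::local_tempfile()
    write_mesh(m, p, fmt)
    back <- read_mesh(p, fmt)
    expect_equal(nrow(back$triangles), nrow(m$triangles))
    soup_orig <- m$vertices[t(m$triangles), ]
    soup_back <- back$vertices[t(back$triangles), ]
    expect_lt(max(abs(soup_orig - soup_back)), 1e-6)
  }
})

test_that("degenerate mesh input is rejected", {
  empty <- structure(list(vertices = matrix(0, 0, 3),
                          triangles = matrix(0L, 0, 3), capped = FALSE),
                     class = "ivt_mesh")
  expect_error(write_mesh(empty, tempfile()), class = "ivtflow_invalid_mesh")
  expect_error(read_mesh(file.path(tempdir(), "absent.stl")),
               class = "ivtflow_io_error")
})
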