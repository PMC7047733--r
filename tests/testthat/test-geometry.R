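test_that("parameter validation enforces the geometric domain", {
  expect_error(tunnel_params(-1, 0, 0), class = "ivtflow_invalid_params")
  expect_error(tunnel_params(10, 90, 0), class = "ivtflow_invalid_params")
  expect_error(tunnel_params(10, -1, 0), class = "ivtflow_invalid_params")
  expect_error(tunnel_params(10, 0, -1), class = "ivtflow_invalid_params")
  expect_error(tunnel_params(10, 0, 0, lumen_diameter = 0),
               class = "ivtflow_invalid_params")
  expect_s3_class(tunnel_params(10, 0, 0), "tunnel_params")
})

test_that("outlet length matches the closed form and a numerically integrated arc", {
  # closed form: L_out = d_sa - r_tt * cos(a_lt)
  cl <- build_centerline(tunnel_params(10, 40, 10))
  expect_equal(cl$l_out, 10 - 10 * cos(40 * pi / 180), tolerance = 1e-12)
  expect_equal(cl$l_out, 2.3396, tolerance = 1e-4)
  # independent oracle: vertical rise across the arc by numerical quadrature
  rise <- integrate(function(phi) 10 * sin(phi),
                    lower = 40 * pi / 180, upper = pi / 2)$value
  expect_equal(cl$l_out, 10 - rise, tolerance = 1e-8)
  expect_equal(cl$theta_bend, 50)
})

test_that("boundary and infeasible configurations are handled", {
  # L_out = 0 is a feasible boundary: the arc ends exactly on the valve plane
  cl <- build_centerline(tunnel_params(10, 0, 10))
  expect_equal(cl$l_out, 0, tolerance = 1e-12)
  expect_equal(unname(cl$vertices[nrow(cl$vertices), "y"]), 10,
               tolerance = 1e-9)
  # overshoot raises a typed error carrying the deficit
  err <- tryCatch(build_centerline(tunnel_params(5, 0, 10)),
                  ivtflow_infeasible_geometry = function(e) e)
  expect_s3_class(err, "ivtflow_infeasible_geometry")
  expect_equal(err$deficit, 5, tolerance = 1e-12)
  expect_match(conditionMessage(err), "deficit")
})

test_that("r_tt = 0 yields a sharp elbow of two straights", {
  cl <- build_centerline(tunnel_params(15, 20, 0), l_in = 3)
  expect_equal(cl$theta_bend, 70)
  expect_equal(length(cl$segments), 2L)
  expect_equal(vapply(cl$segments, `[[`, "", "kind"),
               c("straight", "straight"))
  expect_equal(cl$total_length, 3 + (15 - 3 * sin(20 * pi / 180)),
               tolerance = 1e-12)
  expect_equal(unname(cl$vertices[nrow(cl$vertices), "y"]), 15,
               tolerance = 1e-9)
})

test_that("feasible() agrees with build_centerline on representative cases", {
  expect_false(feasible(tunnel_params(1, 0, 10))$feasible)
  expect_match(feasible(tunnel_params(1, 0, 10))$reason, "deficit")
  expect_true(feasible(tunnel_params(10, 89.9, 0))$feasible)
  d <- table1_design()
  ok <- vapply(seq_len(25), function(i)
    feasible(tunnel_params(d$d_sa[i], d$a_lt[i], d$r_tt[i]))$feasible,
    logical(1))
  expect_true(all(ok))
})

test_that("centerline endpoint always lies on the valve plane with vertical direction", {
  set.seed(7)
  for (i in 1:50) {
    d_sa <- runif(1, 5, 40)
    a_lt <- runif(1, 0, 89)
    r_tt <- runif(1, 0, d_sa / cos(a_lt * pi / 180))  # keeps L_out >= 0
    cl <- build_centerline(tunnel_params(d_sa, a_lt, r_tt))
    endp <- cl$vertices[nrow(cl$vertices), ]
    expect_lt(abs(endp[["y"]] - d_sa), 1e-9)
    expect_equal(unname(cl$tangents[nrow(cl$tangents), ]), c(0, 1, 0),
                 tolerance = 1e-12)
    expect_true(all(abs(cl$vertices[, "z"]) < 1e-12))  # planar
    expect_equal(cl$total_length,
                 cl$l_in + r_tt * cl$theta_bend * pi / 180 + cl$l_out,
                 tolerance = 1e-10)
  }
})

test_that("total length is monotone non-decreasing in d_sa", {
  for (a_lt in c(0, 25, 60)) for (r_tt in c(0, 4, 8)) {
    lens <- vapply(seq(10, 40, by = 2), function(ds)
      build_centerline(tunnel_params(ds, a_lt, r_tt))$total_length,
      numeric(1))
    expect_true(all(diff(lens) >= 0))
  }
})
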