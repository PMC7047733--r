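test_that("the balanced closed form reproduces the frozen decomposition of the fixture", {
  # frozen from an independent general-linear-model fit (stats::aov) of the
  # packaged 25-run responses
  fit <- ivt_anova(table1_design())
  tab <- fit$table
  expect_equal(tab["d_sa", "ss"], 7.598024, tolerance = 1e-6)
  expect_equal(tab["a_lt", "ss"], 81.903184, tolerance = 1e-6)
  expect_equal(tab["r_tt", "ss"], 77.750984, tolerance = 1e-6)
  expect_equal(tab["error", "ss"], 23.490032, tolerance = 1e-6)
  expect_equal(tab["error", "ms"], 1.9575027, tolerance = 1e-6)
  expect_equal(tab["d_sa", "p"], 0.4589943, tolerance = 1e-6)
  expect_equal(tab["a_lt", "p"], 0.000694146, tolerance = 1e-5)
  expect_equal(tab["r_tt", "p"], 0.000874905, tolerance = 1e-5)
  # decomposition conservation
  expect_equal(tab["total", "ss"],
               sum(tab[c("d_sa", "a_lt", "r_tt", "error"), "ss"]),
               tolerance = 1e-9)
  expect_equal(tab[c("d_sa", "a_lt", "r_tt"), "df"], rep(4, 3))
  expect_equal(tab["error", "df"], 12)
})

test_that("closed form agrees with the GLM oracle on random balanced designs", {
  set.seed(101)
  for (i in 1:20) {
    d <- random_balanced_design()
    d$delta_p <- rnorm(25, mean = 5, sd = runif(1, 0.5, 3))
    mine <- ivt_anova(d)$table
    orac <- aov_oracle(d)
    expect_equal(mine[c("d_sa", "a_lt", "r_tt"), "ss"], orac$ss,
                 tolerance = 1e-8)
    expect_equal(mine["error", "ss"], orac$ss_err, tolerance = 1e-8)
    expect_equal(mine[c("d_sa", "a_lt", "r_tt"), "f"], orac$f,
                 tolerance = 1e-8)
    expect_equal(mine[c("d_sa", "a_lt", "r_tt"), "p"], orac$p,
                 tolerance = 1e-8)
  }
})

test_that("degenerate and invalid inputs are diagnosed", {
  d <- table1_design()
  d$delta_p <- rep(3, 25)
  fit <- ivt_anova(d)
  expect_true(fit$zero_variance)
  expect_equal(unname(fit$table[c("d_sa", "a_lt", "r_tt"), "p"]), rep(1, 3))
  expect_true(all(fit$table[, "ss"] < 1e-10))

  no_resp <- table1_design(); no_resp$delta_p <- NULL
  expect_error(ivt_anova(no_resp), class = "ivtflow_missing_response")
  unbal <- table1_design()[-1, ]
  expect_error(ivt_anova(unbal), class = "ivtflow_unbalanced_design")
  expect_match(tryCatch(ivt_anova(unbal), error = conditionMessage),
               "verify_balance")
})

test_that("LSD pairwise tests reproduce the frozen fixture values", {
  lsd <- lsd_pairwise(table1_design(), "r_tt")
  expect_equal(nrow(lsd), 10L)
  # pooled-error SE is constant across pairs in a balanced design
  expect_equal(lsd$se, rep(sqrt(2 * 1.9575027 / 5), 10), tolerance = 1e-6)
  getp <- function(l1, l2) lsd$p[lsd$level_1 == l1 & lsd$level_2 == l2]
  expect_equal(getp(0, 2.5), 0.00440985, tolerance = 1e-5)
  expect_equal(getp(2.5, 5), 0.33228333, tolerance = 1e-5)
  expect_equal(getp(5, 7.5), 0.47937093, tolerance = 1e-5)
  expect_equal(getp(7.5, 10), 0.82155458, tolerance = 1e-5)
  # symmetry up to sign: t of (0, 2.5) mirrors mean ordering
  expect_gt(getp(0, 10), 0)  # two-sided, strictly positive
  expect_equal(lsd$t, lsd$mean_diff / lsd$se, tolerance = 1e-12)
})

test_that("LSD returns t = 0, P = 1 when the compared group means coincide", {
  d <- table1_design()
  # responses depending on d_sa only: all r_tt group means identical
  d$delta_p <- as.numeric(factor(d$d_sa)) * 2
  lsd <- lsd_pairwise(d, "r_tt")
  expect_equal(lsd$t, rep(0, 10), tolerance = 1e-10)
  expect_equal(lsd$p, rep(1, 10), tolerance = 1e-10)
})

test_that("significance ranking flags the turning radius but not the distance", {
  fit <- ivt_anova(table1_design())
  rep <- significance_report(fit, alpha = 0.05)
  expect_true(rep$significant[rep$factor == "r_tt"])
  expect_false(rep$significant[rep$factor == "d_sa"])
  expect_true(all(diff(rep$ss) <= 0))  # sorted descending
})

test_that("the permutation P-value for r_tt brackets the parametric one", {
  d <- table1_design()
  y <- d$delta_p
  fit <- ivt_anova(d)
  f_obs <- fit$table["r_tt", "f"]
  p_param <- fit$table["r_tt", "p"]
  set.seed(123)
  B <- 10000
  f_perm <- numeric(B)
  lev <- lapply(d[c("d_sa", "a_lt", "r_tt")], function(v)
    outer(v, sort(unique(v)), "==") + 0)
  cf_den <- 5
  for (b in seq_len(B)) {
    yy <- sample(y)
    G <- sum(yy); cf <- G^2 / 25
    sst <- sum(yy^2) - cf
    ss <- vapply(lev, function(M) sum(crossprod(M, yy)^2) / cf_den - cf,
                 numeric(1))
    f_perm[b] <- (ss[["r_tt"]] / 4) / ((sst - sum(ss)) / 12)
  }
  p_perm <- (1 + sum(f_perm >= f_obs)) / (B + 1)
  mc_sd <- sqrt(p_param * (1 - p_param) / B)
  expect_lt(abs(p_perm - p_param), max(0.002, 4 * mc_sd))
})
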