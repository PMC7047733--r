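# Shared fixtures and independent oracles for the test suite.

# canonical factor levels of the 25-run experiment
LEVELS <- list(d_sa = c(10, 15, 20, 25, 30),
               a_lt = c(0, 10, 20, 30, 40),
               r_tt = c(0, 2.5, 5, 7.5, 10))

# a balanced L25 with randomly relabelled levels (for property tests)
random_balanced_design <- function() {
  construct_balanced_design(list(
    d_sa = sort(sample(1:1000, 5)),
    a_lt = sort(sample(0:89, 5)) + runif(5, 0, 0.5),
    r_tt = sort(sample(0:500, 5)) / 10
  ))
}

# independent general-linear-model oracle for the balanced main-effects ANOVA
aov_oracle <- function(design) {
  df <- data.frame(y = design$delta_p,
                   A = factor(design$d_sa), B = factor(design$a_lt),
                   C = factor(design$r_tt))
  s <- summary(stats::aov(y ~ A + B + C, data = df))[[1]]
  list(ss = s[["Sum Sq"]][1:3], ss_err = s[["Sum Sq"]][4],
       f = s[["F value"]][1:3], p = s[["Pr(>F)"]][1:3])
}

# closed-form cylinder volume, mm^3
cylinder_volume <- function(diameter, length) pi * (diameter / 2)^2 * length

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %g", object, expected, tol))
}
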