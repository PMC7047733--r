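#' Construct an IVT experimental design object
#'
#' A design is a data frame with one row per model: columns `model`, `d_sa`
#' (mm), `a_lt` (degrees), `r_tt` (mm) and optionally `delta_p` (mmHg).
#'
#' @param d_sa,a_lt,r_tt Numeric vectors of equal length: factor settings.
#' @param delta_p Optional response vector, mmHg.
#' @param model Optional run labels (default `1:n`).
#' @return An `ivt_design` (also a `data.frame`).
#' @export
ivt_design <- function(d_sa, a_lt, r_tt, delta_p = NULL, model = NULL) {
  n <- length(d_sa)
  stopifnot(length(a_lt) == n, length(r_tt) == n)
  df <- data.frame(model = model %||% seq_len(n),
                   d_sa = as.numeric(d_sa), a_lt = as.numeric(a_lt),
                   r_tt = as.numeric(r_tt))
  if (!is.null(delta_p)) {
    stopifnot(length(delta_p) == n)
    df$delta_p <- as.numeric(delta_p)
  }
  class(df) <- c("ivt_design", "data.frame")
  df
}

#' @export
print.ivt_design <- function(x, ...) {
  cat(sprintf("IVT design: %d runs, 3 factors%s\n", nrow(x),
              if ("delta_p" %in% names(x)) " (with responses)" else ""))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' The 25-run orthogonal experiment with its pressure-difference responses
#'
#' The canonical L25(5^3) balanced orthogonal array of the three tunnel
#' factors (D_SA in {10,15,20,25,30} mm, A_LT in {0,10,20,30,40} degrees,
#' R_TT in {0,2.5,5,7.5,10} mm) together with the CFD pressure-difference
#' response of each run, packaged as an immutable fixture.
#'
#' @return An `ivt_design` with 25 rows and a `delta_p` column.
#' @examples
#' d <- table1_design()
#' tapply(d$delta_p, d$r_tt, mean)  # descending in R_TT
#' @export
table1_design <- function() {
  path <- system.file("extdata", "table1.csv", package = "ivtflow",
                      mustWork = TRUE)
  read_design_csv(path)
}

#' Construct a balanced 3-factor, 5-level orthogonal design
#'
#' Builds a 25-run L25(5^3) array by the Latin-square index rule
#' `C = (A + 2B) mod 5`, which guarantees that each level of each factor
#' occurs exactly 5 times and each ordered cross-factor level pair exactly
#' once.
#'
#' @param levels A list of exactly 3 numeric vectors, each with 5 distinct
#'   values, named or in the order `d_sa`, `a_lt`, `r_tt`.
#' @return An `ivt_design` with 25 rows (no responses).
#' @examples
#' d <- construct_balanced_design(list(d_sa = c(10, 15, 20, 25, 30),
#'                                     a_lt = c(0, 10, 20, 30, 40),
#'                                     r_tt = c(0, 2.5, 5, 7.5, 10)))
#' verify_balance(d)$balanced
#' @export
construct_balanced_design <- function(levels) {
  if (!is.list(levels) || length(levels) != 3L)
    stop_ivt("ivtflow_invalid_design", "need exactly 3 factors")
  for (lv in levels) {
    if (length(lv) != 5L || anyDuplicated(lv))
      stop_ivt("ivtflow_invalid_design",
               "each factor needs exactly 5 distinct levels")
  }
  g <- expand.grid(a = 0:4, b = 0:4)
  cidx <- (g$a + 2L * g$b) %% 5L
  ivt_design(d_sa = levels[[1]][g$a + 1L],
             a_lt = levels[[2]][g$b + 1L],
             r_tt = levels[[3]][cidx + 1L])
}

#' Verify orthogonal balance of a design
#'
#' Checks the two defining properties of the 25-run array: every level of
#' every factor occurs exactly 5 times, and for each pair of factors every
#' ordered pair of levels occurs exactly once. Every violation is listed.
#'
#' @param design An `ivt_design` (or data frame with columns `d_sa`, `a_lt`,
#'   `r_tt`).
#' @return A list: `balanced` (logical) and `violations` (character vector).
#' @export
verify_balance <- function(design) {
  fac <- c("d_sa", "a_lt", "r_tt")
  viol <- character()
  if (nrow(design) != 25L)
    viol <- c(viol, sprintf("design has %d rows, expected 25", nrow(design)))
  for (f in fac) {
    tab <- table(design[[f]])
    if (length(tab) != 5L)
      viol <- c(viol, sprintf("factor %s has %d distinct levels, expected 5",
                              f, length(tab)))
    bad <- tab[tab != 5L]
    for (i in seq_along(bad))
      viol <- c(viol, sprintf(
        "factor %s level %s occurs %d times, expected 5 (rows %s)",
        f, names(bad)[i], bad[i],
        paste(which(design[[f]] == as.numeric(names(bad)[i])), collapse = ",")))
  }
  for (pair in list(c("d_sa", "a_lt"), c("d_sa", "r_tt"), c("a_lt", "r_tt"))) {
    tab <- table(design[[pair[1]]], design[[pair[2]]])
    bad <- which(tab != 1L, arr.ind = TRUE)
    for (i in seq_len(nrow(bad))) {
      l1 <- rownames(tab)[bad[i, 1]]; l2 <- colnames(tab)[bad[i, 2]]
      rows <- which(design[[pair[1]]] == as.numeric(l1) &
                    design[[pair[2]]] == as.numeric(l2))
      viol <- c(viol, sprintf(
        "pair (%s=%s, %s=%s) occurs %d times, expected 1%s",
        pair[1], l1, pair[2], l2, tab[bad[i, 1], bad[i, 2]],
        if (length(rows)) paste0(" (rows ", paste(rows, collapse = ","), ")") else ""))
    }
  }
  list(balanced = length(viol) == 0L, violations = viol)
}

#' Evaluate a flow model over every run of a design
#'
#' Fills the `delta_p` column of a design by evaluating a model function on
#' each row's [tunnel_params()]. Rows whose geometry is infeasible are
#' flagged (`NA` response, collected in the `failures` attribute) and the run
#' only aborts if every row fails.
#'
#' @param design An `ivt_design`.
#' @param model A function `tunnel_params -> delta_p (mmHg)`. The default
#'   evaluates [pressure_difference()] at the default coefficients.
#' @param lumen_diameter Lumen diameter passed to each row's parameters, mm.
#' @param csv Optional path: when given, the completed design is written as
#'   CSV.
#' @return The design with responses; attribute `failures` is a data frame
#'   of infeasible rows and messages (zero rows when all succeed).
#' @export
run_experiment <- function(design,
                           model = function(p) pressure_difference(p)$delta_p,
                           lumen_diameter = 13.33, csv = NULL) {
  stopifnot(nrow(design) >= 1L)
  resp <- rep(NA_real_, nrow(design))
  fail_row <- integer(); fail_msg <- character()
  for (i in seq_len(nrow(design))) {
    p <- tunnel_params(design$d_sa[i], design$a_lt[i], design$r_tt[i],
                       lumen_diameter = lumen_diameter)
    r <- tryCatch(model(p), ivtflow_infeasible_geometry = function(e) e)
    if (inherits(r, "condition")) {
      fail_row <- c(fail_row, i)
      fail_msg <- c(fail_msg, conditionMessage(r))
    } else {
      resp[i] <- r
    }
  }
  if (length(fail_row) == nrow(design))
    stop_ivt("ivtflow_infeasible_geometry",
             "every row of the design is geometrically infeasible")
  out <- design
  out$delta_p <- resp
  attr(out, "failures") <- data.frame(row = fail_row, message = fail_msg)
  if (!is.null(csv)) write_design_csv(out, csv)
  out
}
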