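#' Balanced three-factor main-effects ANOVA
#'
#' Fits the additive main-effects model
#' `y_ijk = mu + a_i + b_j + c_k + e` to the responses of a balanced 25-run
#' 3-factor, 5-level orthogonal design using the balanced closed form:
#' for each factor `SS = sum_l T_l^2 / 5 - G^2 / 25` (level totals `T_l`,
#' grand total `G`), `SS_total = sum y^2 - G^2 / 25`, and the error sum of
#' squares by subtraction on 12 degrees of freedom. In a balanced array the
#' type I and type III decompositions coincide, so this closed form is the
#' unique main-effects decomposition. P-values are the upper tail of
#' F(4, 12).
#'
#' If the responses are constant (zero variance) all sums of squares are
#' zero; P is then reported as 1 with `zero_variance = TRUE`.
#'
#' @param design An `ivt_design` with a complete `delta_p` column, balanced
#'   per [verify_balance()].
#' @return An object of class `ivt_anova`: a list with `table` (data frame
#'   rows `d_sa`, `a_lt`, `r_tt`, `error`, `total` and columns `ss`, `df`,
#'   `ms`, `f`, `p`), `grand_mean`, `group_means` (per factor),
#'   `zero_variance`, and `design`.
#' @examples
#' fit <- ivt_anova(table1_design())
#' fit
#' coef(fit)          # grand mean and per-level effects
#' @export
ivt_anova <- function(design) {
  if (!("delta_p" %in% names(design)) || anyNA(design$delta_p))
    stop_ivt("ivtflow_missing_response",
             "design must carry a complete delta_p response column")
  bal <- verify_balance(design)
  if (!bal$balanced)
    stop_ivt("ivtflow_unbalanced_design", paste0(
      "design is not a balanced orthogonal array; see verify_balance():\n  ",
      paste(bal$violations, collapse = "\n  ")))

  y <- design$delta_p
  n <- length(y)                      # 25
  G <- sum(y)
  cf <- G^2 / n                       # correction factor
  ss_total <- sum(y^2) - cf
  fac <- c("d_sa", "a_lt", "r_tt")
  ss <- vapply(fac, function(f) {
    tot <- tapply(y, design[[f]], sum)
    sum(tot^2) / 5 - cf
  }, numeric(1))
  ss_err <- ss_total - sum(ss)
  df_fac <- 4; df_err <- 12
  ms <- ss / df_fac
  ms_err <- ss_err / df_err
  eps <- .Machine$double.eps * max(1, sum(y^2))
  zero_var <- ss_total < eps
  if (zero_var) {
    fstat <- rep(NA_real_, 3)
    p <- rep(1, 3)
  } else if (ms_err < eps) {
    # noise-free responses: factors with signal are unambiguous
    fstat <- ifelse(ss > eps, Inf, 0)
    p <- ifelse(ss > eps, 0, 1)
  } else {
    fstat <- ms / ms_err
    p <- pf(fstat, df_fac, df_err, lower.tail = FALSE)
  }
  tab <- data.frame(
    ss = c(ss, ss_err, ss_total),
    df = c(rep(df_fac, 3), df_err, n - 1),
    ms = c(ms, ms_err, NA),
    f = c(fstat, NA, NA),
    p = c(p, NA, NA),
    row.names = c(fac, "error", "total")
  )
  gm <- lapply(setNames(fac, fac),
               function(f) tapply(y, design[[f]], mean))
  structure(
    list(table = tab, grand_mean = mean(y), group_means = gm,
         zero_variance = zero_var, design = design),
    class = "ivt_anova"
  )
}

#' @export
print.ivt_anova <- function(x, digits = 4, ...) {
  cat("Main-effects ANOVA (balanced L25 orthogonal design)\n\n")
  tab <- x$table
  out <- data.frame(
    SS = round(tab$ss, digits), df = tab$df,
    MS = round(tab$ms, digits), F = round(tab$f, digits),
    P = signif(tab$p, 3), row.names = rownames(tab)
  )
  print(out, na.print = "")
  if (x$zero_variance)
    cat("\nnote: zero-variance responses; P reported as 1\n")
  invisible(x)
}

#' @export
summary.ivt_anova <- function(object, alpha = 0.05, ...) {
  rep_ <- significance_report(object, alpha = alpha)
  cat(sprintf("Grand mean response: %.4g mmHg\n\n", object$grand_mean))
  print(object)
  cat("\nFactors by explained sum of squares:\n")
  print(rep_, row.names = FALSE)
  invisible(rep_)
}

#' @export
coef.ivt_anova <- function(object, ...) {
  eff <- lapply(object$group_means, function(m) m - object$grand_mean)
  c(list(grand_mean = object$grand_mean), eff)
}

#' @export
as.data.frame.ivt_anova <- function(x, ...) {
  cbind(term = rownames(x$table), x$table, row.names = NULL)
}

#' Fisher-LSD pairwise comparisons for one factor
#'
#' Unadjusted pairwise t-tests of the five level means of one factor, using
#' the pooled 12-df error mean square of the balanced main-effects model:
#' `SE = sqrt(2 * MS_err / 5)` (constant across pairs in a balanced design),
#' `t = mean difference / SE`, two-sided P from t(12). No multiplicity
#' adjustment is applied (Fisher's least significant difference).
#'
#' @param design An `ivt_design` with responses, or an `ivt_anova` fit.
#' @param factor One of `"d_sa"`, `"a_lt"`, `"r_tt"`.
#' @return An object of class `ivt_lsd`: data frame with columns `level_1`,
#'   `level_2`, `mean_diff`, `se`, `t`, `p`; attributes `factor`, `ms_err`,
#'   `df_err`.
#' @examples
#' lsd <- lsd_pairwise(table1_design(), "r_tt")
#' subset(as.data.frame(lsd), level_1 == 0)
#' @export
lsd_pairwise <- function(design, factor = c("r_tt", "d_sa", "a_lt")) {
  factor <- match.arg(factor)
  fit <- if (inherits(design, "ivt_anova")) design else ivt_anova(design)
  ms_err <- fit$table["error", "ms"]
  df_err <- fit$table["error", "df"]
  means <- fit$group_means[[factor]]
  lv <- as.numeric(names(means))
  se <- sqrt(2 * ms_err / 5)
  pairs <- utils::combn(seq_along(lv), 2)
  diff <- means[pairs[1, ]] - means[pairs[2, ]]
  if (se > 0) {
    tval <- as.numeric(diff) / se
    p <- 2 * pt(-abs(tval), df_err)
  } else {
    tval <- ifelse(diff == 0, 0, Inf * sign(as.numeric(diff)))
    p <- ifelse(diff == 0, 1, 0)
  }
  out <- data.frame(level_1 = lv[pairs[1, ]], level_2 = lv[pairs[2, ]],
                    mean_diff = as.numeric(diff), se = se, t = tval, p = p)
  structure(out, class = c("ivt_lsd", "data.frame"),
            factor = factor, ms_err = ms_err, df_err = df_err)
}

#' @export
print.ivt_lsd <- function(x, ...) {
  cat(sprintf(
    "Fisher-LSD pairwise comparisons for %s (pooled MS_err = %.4g, %d df)\n\n",
    attr(x, "factor"), attr(x, "ms_err"), attr(x, "df_err")))
  df <- as.data.frame(x)
  df$mean_diff <- round(df$mean_diff, 4)
  df$se <- round(df$se, 4)
  df$t <- round(df$t, 3)
  df$p <- round(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Rank factors by explained variation
#'
#' Orders the three factors by their sum of squares (descending) and flags
#' those significant at the chosen level.
#'
#' @param anova An `ivt_anova` fit.
#' @param alpha Significance threshold (default 0.05).
#' @return A data frame with columns `factor`, `ss`, `f`, `p`,
#'   `significant`, ordered by `ss` descending.
#' @examples
#' significance_report(ivt_anova(table1_design()))
#' @export
significance_report <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "ivt_anova"))
  fac <- c("d_sa", "a_lt", "r_tt")
  tab <- anova$table[fac, ]
  ord <- order(tab$ss, decreasing = TRUE)
  data.frame(factor = fac[ord], ss = tab$ss[ord], f = tab$f[ord],
             p = tab$p[ord], significant = tab$p[ord] < alpha)
}
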