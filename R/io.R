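#' Read and write designs as CSV
#'
#' The CSV dialect is pinned for bit-exact fixture comparison: header
#' `model,d_sa_mm,a_lt_deg,r_tt_mm,delta_p_mmhg`, `.` decimal separator, LF
#' line endings, RFC-4180 quoting. The response column is optional on read.
#'
#' @param path File path.
#' @return [read_design_csv()]: an `ivt_design`. [write_design_csv()]:
#'   `path`, invisibly.
#' @export
read_design_csv <- function(path) {
  if (!file.exists(path))
    stop_ivt("ivtflow_io_error", sprintf("no such file: %s", path))
  df <- read.csv(path)
  need <- c("model", "d_sa_mm", "a_lt_deg", "r_tt_mm")
  if (!all(need %in% names(df)))
    stop_ivt("ivtflow_io_error", sprintf(
      "design CSV %s lacks required columns: %s", path,
      paste(setdiff(need, names(df)), collapse = ", ")))
  ivt_design(d_sa = df$d_sa_mm, a_lt = df$a_lt_deg, r_tt = df$r_tt_mm,
             delta_p = if ("delta_p_mmhg" %in% names(df)) df$delta_p_mmhg,
             model = df$model)
}

#' @rdname read_design_csv
#' @param design An `ivt_design`.
#' @export
write_design_csv <- function(design, path) {
  df <- data.frame(model = design$model, d_sa_mm = design$d_sa,
                   a_lt_deg = design$a_lt, r_tt_mm = design$r_tt)
  if ("delta_p" %in% names(design)) df$delta_p_mmhg <- design$delta_p
  con <- file(path, "wb")  # binary mode pins LF endings on every platform
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, format_csv_num), sep = ",")), con)
  invisible(path)
}

format_csv_num <- function(x) {
  if (is.numeric(x)) sub("\\.?0+$", "", formatC(x, format = "f", digits = 10))
  else as.character(x)
}

#' Write an ANOVA or LSD table as CSV
#'
#' @param x An `ivt_anova` or `ivt_lsd` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "ivt_lsd"))
    df <- cbind(factor = attr(x, "factor"), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep curve as CSV
#'
#' Columns `r_tt_mm,delta_p_mmhg,change_rate_pct` (the first row has an
#' empty change rate).
#'
#' @param curve An `ivt_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(curve, path) {
  df <- data.frame(r_tt_mm = curve$values,
                   delta_p_mmhg = curve$responses,
                   change_rate_pct = c(NA, curve$change_rates))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Load a run configuration from JSON or YAML
#'
#' Recognised top-level keys: `geometry` (`d_sa`, `a_lt`, `r_tt`,
#' `lumen_diameter`, `l_in`), `fluid` (`density`, `viscosity`), `bc`
#' (`inlet_velocity`, `outlet_pressure`), `loss` (`k_entrance`, `k_exit`,
#' `c1`, `c2`), `sweep` (`start`, `step`, `count`, `threshold`), `seed`.
#' Missing keys fall back to the package defaults; unknown keys raise an
#' error naming the offending key.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A `run_config` list with elements `geometry` ([tunnel_params()]),
#'   `l_in`, `fluid`, `bc`, `loss`, `sweep`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_ivt("ivtflow_io_error", sprintf("no such file: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("geometry", "fluid", "bc", "loss", "sweep", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_ivt("ivtflow_invalid_config",
             sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  gk <- raw$geometry %||% list()
  check_keys(gk, c("d_sa", "a_lt", "r_tt", "lumen_diameter", "l_in"), "geometry")
  geom <- tunnel_params(d_sa = gk$d_sa %||% 20, a_lt = gk$a_lt %||% 20,
                        r_tt = gk$r_tt %||% 7.5,
                        lumen_diameter = gk$lumen_diameter %||% 13.33)
  fk <- raw$fluid %||% list()
  check_keys(fk, c("density", "viscosity"), "fluid")
  bk <- raw$bc %||% list()
  check_keys(bk, c("inlet_velocity", "outlet_pressure"), "bc")
  lk <- raw$loss %||% list()
  check_keys(lk, c("k_entrance", "k_exit", "c1", "c2"), "loss")
  sk <- raw$sweep %||% list()
  check_keys(sk, c("factor", "start", "step", "count", "threshold"), "sweep")
  structure(list(
    geometry = geom,
    l_in = gk$l_in %||% 0,
    fluid = fluid_props(density = fk$density %||% 1050,
                        viscosity = fk$viscosity %||% 0.0035),
    bc = flow_bc(inlet_velocity = bk$inlet_velocity %||% 1,
                 outlet_pressure = bk$outlet_pressure %||% 110),
    loss = loss_coeffs(k_entrance = lk$k_entrance %||% 0.5,
                       k_exit = lk$k_exit %||% 1.0,
                       c1 = lk$c1 %||% 1.2, c2 = lk$c2 %||% 2.0),
    sweep = sweep_config(factor = sk$factor %||% "r_tt",
                         start = sk$start %||% 0, step = sk$step %||% 1,
                         count = sk$count %||% 12,
                         threshold = sk$threshold %||% 5),
    seed = raw$seed
  ), class = "run_config")
}

check_keys <- function(x, known, section) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop_ivt("ivtflow_invalid_config", sprintf(
      "unknown key(s) in config section '%s': %s",
      section, paste(extra, collapse = ", ")))
  invisible(TRUE)
}

#' Write a provenance sidecar for generated data
#'
#' Records the seed and generator settings alongside a data artifact so a
#' synthetic dataset can be regenerated exactly.
#'
#' @param path Path of the sidecar JSON file.
#' @param seed Integer seed used.
#' @param spec A list (or `effect_spec`) of generator settings.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, seed, spec) {
  jsonlite::write_json(
    list(generator = "ivtflow", seed = seed, spec = unclass(spec),
         r_version = as.character(getRversion())),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
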