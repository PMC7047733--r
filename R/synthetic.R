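#' Specification of synthetic main effects
#'
#' Describes an additive response surface over a balanced 3x5 design:
#' grand mean, per-factor level offsets (each factor's five offsets summing
#' to zero for identifiability), and Gaussian noise.
#'
#' @param grand_mean Grand mean response, mmHg.
#' @param main_effects A list of up to three numeric vectors of length 5,
#'   named by factor (`d_sa`, `a_lt`, `r_tt`); omitted factors get zero
#'   offsets. Each vector must sum to zero (tolerance 1e-8).
#' @param noise_sd Noise standard deviation, mmHg (>= 0).
#' @param seed Integer seed for reproducibility (optional; may also be set
#'   at generation time).
#' @return An `effect_spec` object.
#' @examples
#' sp <- effect_spec(5, list(r_tt = c(2, 1, 0, -1, -2)), noise_sd = 1, seed = 1)
#' @export
effect_spec <- function(grand_mean, main_effects = list(), noise_sd = 0,
                        seed = NULL) {
  fac <- c("d_sa", "a_lt", "r_tt")
  eff <- setNames(rep(list(rep(0, 5)), 3), fac)
  for (nm in names(main_effects)) {
    if (!nm %in% fac)
      stop_ivt("ivtflow_invalid_params",
               sprintf("unknown factor '%s' in main_effects", nm))
    v <- main_effects[[nm]]
    if (length(v) != 5)
      stop_ivt("ivtflow_invalid_params", "each factor needs 5 level offsets")
    if (abs(sum(v)) > 1e-8)
      stop_ivt("ivtflow_invalid_params",
               sprintf("offsets of '%s' must sum to 0 (got %.3g)", nm, sum(v)))
    eff[[nm]] <- v
  }
  if (noise_sd < 0)
    stop_ivt("ivtflow_invalid_params", "noise_sd must be >= 0")
  structure(list(grand_mean = grand_mean, main_effects = eff,
                 noise_sd = noise_sd, seed = seed),
            class = "effect_spec")
}

#' Generate synthetic responses on a balanced design
#'
#' Draws `y = mu + a_i + b_j + c_k + e`, `e ~ Normal(0, sd^2)`, with level
#' offsets assigned by the rank order of each factor's values in the design.
#' Noise comes from R's Mersenne-Twister stream, so the same seed gives
#' bit-identical responses across runs and platforms.
#'
#' @param design A balanced `ivt_design`.
#' @param spec An [effect_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return The design with a synthetic `delta_p` column.
#' @examples
#' d <- generate_response(table1_design(),
#'                        effect_spec(5, list(r_tt = c(2, 1, 0, -1, -2)),
#'                                    noise_sd = 1, seed = 42))
#' @export
generate_response <- function(design, spec, seed = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  bal <- verify_balance(design)
  if (!bal$balanced)
    stop_ivt("ivtflow_unbalanced_design",
             "generate_response requires a balanced design")
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)
  y <- rep(spec$grand_mean, nrow(design))
  for (f in names(spec$main_effects)) {
    idx <- match(design[[f]], sort(unique(design[[f]])))
    y <- y + spec$main_effects[[f]][idx]
  }
  if (spec$noise_sd > 0)
    y <- y + rnorm(nrow(design), 0, spec$noise_sd)
  out <- design
  out$delta_p <- y
  out
}

#' Generate a synthetic turning-radius sweep curve
#'
#' Emulates the shape of the pressure-difference-versus-radius relation:
#' exponential decay towards an asymptote,
#' `dP(r) = p_inf + amplitude * exp(-r / decay) + e`.
#'
#' @param p_inf Asymptotic pressure difference, mmHg.
#' @param amplitude Decay amplitude, mmHg.
#' @param decay Decay length scale, mm (> 0).
#' @param noise_sd Gaussian noise sd, mmHg (default 0).
#' @param config A [sweep_config()] giving the sampled radii and threshold.
#' @param seed Optional integer seed.
#' @return An `ivt_sweep` curve (see [sweep_curve()]).
#' @examples
#' generate_sweep_curve(2, 6, 2)$plateau_value  # 8 mm at the 5% threshold
#' @export
generate_sweep_curve <- function(p_inf, amplitude, decay, noise_sd = 0,
                                 config = sweep_config(), seed = NULL) {
  if (decay <= 0)
    stop_ivt("ivtflow_invalid_params", "decay must be > 0")
  if (!is.null(seed)) set.seed(seed)
  r <- config$start + config$step * (seq_len(config$count) - 1L)
  y <- p_inf + amplitude * exp(-r / decay)
  if (noise_sd > 0) y <- y + rnorm(length(r), 0, noise_sd)
  sweep_curve(r, y, config$threshold)
}
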