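#' Parameters of the synthetic glucose-solution spectrum generator
#'
#' The generator emulates Raman spectra of glucose dissolved in deionized
#' water as measured with a 785 nm excitation instrument: a strong, smooth
#' fluorescence background (a degree-5 polynomial hump peaking in the first
#' quarter of the axis), concentration-proportional Gaussian analyte bands at
#' the canonical glucose Raman shifts (911, 1060, 1125, 1366 cm^-1), a
#' per-sample multiplicative gain, per-sample jitter of the background shape,
#' and additive Gaussian detector noise. All intensities are clipped at zero,
#' as raw photon counts are non-negative.
#'
#' @param n_points number of points on the shift axis (default 2048).
#' @param shift_range numeric length-2, axis endpoints in cm^-1.
#' @param peak_centers glucose band positions (cm^-1).
#' @param peak_widths Gaussian sd of each band (cm^-1), recycled.
#' @param peak_weights relative amplitude of each band, recycled.
#' @param response_slope intensity gained per mmol/L at a weight-1 band apex.
#' @param baseline_scale peak intensity scale of the fluorescence background.
#' @param baseline_nodes values of the background template at 6 equally spaced
#'   axis fractions (0, 0.2, ..., 1); the degree-5 interpolating polynomial
#'   through `baseline_scale * baseline_nodes` is the background.
#' @param baseline_jitter relative sd of per-sample node perturbations
#'   (fluorescence variability between samples).
#' @param gain_sd relative sd of the per-sample multiplicative gain.
#' @param noise_sd additive Gaussian noise sd (intensity counts).
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_points = 2048,
                             shift_range = c(200, 3200),
                             peak_centers = c(911, 1060, 1125, 1366),
                             peak_widths = 12,
                             peak_weights = c(0.8, 1, 0.9, 0.6),
                             response_slope = 10,
                             baseline_scale = 1000,
                             baseline_nodes = c(0.35, 1, 0.75, 0.45, 0.25, 0.12),
                             baseline_jitter = 0.05,
                             gain_sd = 0.01,
                             noise_sd = 2) {
  stopifnot_scalar_count(n_points, "n_points", min = 2)
  if (length(shift_range) != 2 || diff(shift_range) <= 0) {
    abort_ramanglu("`shift_range` must be an increasing length-2 interval",
                   class = "ramanglu_invalid_params")
  }
  peak_widths <- rep_len(as.numeric(peak_widths), length(peak_centers))
  peak_weights <- rep_len(as.numeric(peak_weights), length(peak_centers))
  if (any(peak_widths <= 0)) {
    abort_ramanglu("all `peak_widths` must be > 0", class = "ramanglu_invalid_params")
  }
  for (nm in c("response_slope", "baseline_scale", "baseline_jitter", "gain_sd", "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      abort_ramanglu(sprintf("`%s` must be a single non-negative number", nm),
                     class = "ramanglu_invalid_params")
    }
  }
  if (length(baseline_nodes) != 6) {
    abort_ramanglu("`baseline_nodes` must have 6 values (degree-5 template)",
                   class = "ramanglu_invalid_params")
  }
  structure(
    list(n_points = as.integer(n_points), shift_range = as.numeric(shift_range),
         peak_centers = as.numeric(peak_centers), peak_widths = peak_widths,
         peak_weights = peak_weights, response_slope = response_slope,
         baseline_scale = baseline_scale, baseline_nodes = as.numeric(baseline_nodes),
         baseline_jitter = baseline_jitter, gain_sd = gain_sd, noise_sd = noise_sd),
    class = "generator_params"
  )
}

#' Shift axis implied by generator parameters
#' @param params a `generator_params` object.
#' @return numeric vector of `n_points` ascending shifts.
#' @export
generator_axis <- function(params) {
  seq(params$shift_range[1], params$shift_range[2], length.out = params$n_points)
}

# degree-5 polynomial through (node_u, node_vals), evaluated at fractions u
interp_poly_eval <- function(node_vals, u) {
  node_u <- seq(0, 1, length.out = length(node_vals))
  V <- outer(node_u, 0:(length(node_vals) - 1), `^`)
  coef <- solve(V, node_vals)
  drop(outer(u, 0:(length(node_vals) - 1), `^`) %*% coef)
}

#' Noise-free expected spectrum of the generator
#'
#' Background polynomial plus concentration-scaled Gaussian bands on the
#' parameter axis, with no jitter, gain, or noise. This is the mean curve
#' around which [generate_spectrum()] scatters samples.
#'
#' @param concentration glucose concentration (mmol/L).
#' @param params a `generator_params` object.
#' @return list with numeric vectors `baseline`, `peaks`, `total`.
#' @export
expected_spectrum <- function(concentration, params) {
  shifts <- generator_axis(params)
  u <- (shifts - params$shift_range[1]) / diff(params$shift_range)
  baseline <- interp_poly_eval(params$baseline_scale * params$baseline_nodes, u)
  peaks <- rep(0, params$n_points)
  for (i in seq_along(params$peak_centers)) {
    peaks <- peaks + params$peak_weights[i] * params$response_slope * concentration *
      exp(-0.5 * ((shifts - params$peak_centers[i]) / params$peak_widths[i])^2)
  }
  list(baseline = baseline, peaks = peaks, total = baseline + peaks)
}

#' Simulate one glucose-solution Raman spectrum
#'
#' Draws, in fixed order, the per-sample background node jitter, the
#' multiplicative gain and the additive noise vector from the supplied seed,
#' so the result is a pure function of `(concentration, params, seed)`.
#'
#' @param concentration glucose concentration (mmol/L), >= 0.
#' @param params a [generator_params()] object.
#' @param seed integer seed for this sample.
#' @param label_code optional label code stored on the spectrum.
#' @param sample_id identifier stored on the spectrum.
#' @return a `raman_spectrum`.
#' @export
generate_spectrum <- function(concentration, params = generator_params(),
                              seed = 1L, label_code = NA_integer_,
                              sample_id = "synthetic") {
  if (!is.numeric(concentration) || concentration < 0) {
    abort_ramanglu("`concentration` must be >= 0", class = "ramanglu_invalid_params")
  }
  shifts <- generator_axis(params)
  u <- (shifts - params$shift_range[1]) / diff(params$shift_range)
  draws <- withr::with_seed(as.integer(seed), {
    list(node_z = rnorm(6), gain_z = rnorm(1), eps = rnorm(params$n_points))
  })
  nodes <- params$baseline_scale * params$baseline_nodes *
    (1 + params$baseline_jitter * draws$node_z)
  baseline <- interp_poly_eval(nodes, u)
  peaks <- rep(0, params$n_points)
  for (i in seq_along(params$peak_centers)) {
    peaks <- peaks + params$peak_weights[i] * params$response_slope * concentration *
      exp(-0.5 * ((shifts - params$peak_centers[i]) / params$peak_widths[i])^2)
  }
  gain <- 1 + params$gain_sd * draws$gain_z
  intensities <- pmax(0, gain * (baseline + peaks) + params$noise_sd * draws$eps)
  new_spectrum(shifts, intensities, label_code = label_code,
               concentration = concentration, sample_id = sample_id)
}

#' Simulate a labelled dataset of glucose-solution spectra
#'
#' Defaults reproduce the study design: 10 concentration levels from 5.0 to
#' 20.0 mmol/L, 5 replicate spectra per level, 2048 points per spectrum.
#' Replicate seeds are derived deterministically from the master seed, so the
#' dataset is bit-identical across runs for fixed arguments.
#'
#' @param levels concentrations in mmol/L (default the 10-level design).
#' @param replicates spectra per level (default 5).
#' @param params a [generator_params()] object.
#' @param seed master integer seed.
#' @return a `raman_dataset` with label codes from [label_map_for_levels()].
#' @export
generate_dataset <- function(levels = table1_label_map()$concentration,
                             replicates = 5, params = generator_params(),
                             seed = 1L) {
  stopifnot_scalar_count(replicates, "replicates", min = 0)
  lm <- label_map_for_levels(levels)
  spectra <- list()
  idx <- 0L
  for (li in seq_along(levels)) {
    code <- lm$code[match(levels[li], lm$concentration)]
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      spectra[[idx]] <- generate_spectrum(
        levels[li], params = params, seed = derive_seed(seed, idx),
        label_code = code,
        sample_id = sprintf("%d-c%s_r%d", code, format(levels[li]), r))
    }
  }
  new_dataset(spectra, label_map = lm)
}
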