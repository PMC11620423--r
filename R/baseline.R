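#' Parameters for fluorescence-background removal
#'
#' Controls the two stages of the Vancouver Raman Algorithm as implemented
#' here: boxcar smoothing (noise reduction) followed by iterative modified
#' polynomial fitting (IModPoly, Zhao et al.) with progressive peak clipping.
#'
#' @param poly_order polynomial degree of the background fit (default 5;
#'   fluorescence backgrounds are conventionally fit with order five or six).
#' @param smooth_window odd boxcar width for the smoothing stage; 1 disables
#'   smoothing (default 7).
#' @param tol relative change in the residual standard deviation (DEV) below
#'   which iteration stops (default 0.005).
#' @param max_iter iteration cap (default 100); hitting it returns a result
#'   flagged `converged = FALSE` rather than an error.
#' @return an object of class `vra_params`.
#' @export
vra_params <- function(poly_order = 5, smooth_window = 7, tol = 0.005,
                       max_iter = 100) {
  stopifnot_scalar_count(poly_order, "poly_order", min = 1)
  stopifnot_scalar_count(max_iter, "max_iter", min = 1)
  stopifnot_scalar_count(smooth_window, "smooth_window", min = 1)
  if (smooth_window %% 2 == 0) {
    abort_ramanglu("`smooth_window` must be odd", class = "ramanglu_invalid_window")
  }
  if (!is.numeric(tol) || length(tol) != 1 || is.na(tol) || tol <= 0) {
    abort_ramanglu("`tol` must be > 0", class = "ramanglu_invalid_params")
  }
  structure(list(poly_order = as.integer(poly_order),
                 smooth_window = as.integer(smooth_window),
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "vra_params")
}

#' Boxcar-smooth a spectrum
#'
#' Moving average with an odd window; at the boundaries the window is
#' truncated to the available points, so constants (and window = 1 inputs)
#' pass through unchanged.
#'
#' @param spectrum a `raman_spectrum` or numeric vector.
#' @param window odd integer, `1 <= window <= N`.
#' @return same type as the input (spectrum with smoothed intensities, or a
#'   numeric vector).
#' @export
smooth_spectrum <- function(spectrum, window) {
  x <- if (inherits(spectrum, "raman_spectrum")) spectrum$intensities else as.numeric(spectrum)
  n <- length(x)
  if (!is.numeric(window) || length(window) != 1 || is.na(window) ||
      window != round(window) || window < 1 || window > n || window %% 2 == 0) {
    abort_ramanglu(sprintf("`window` must be an odd integer in [1, %d]", n),
                   class = "ramanglu_invalid_window")
  }
  h <- (as.integer(window) - 1L) %/% 2L
  if (h == 0L) {
    out <- x
  } else {
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (inherits(spectrum, "raman_spectrum")) {
    s <- spectrum
    s$intensities <- out
    s
  } else {
    out
  }
}

#' Estimate and remove the fluorescence background (IModPoly)
#'
#' Implements the iterative modified polynomial fit: smooth the input, then
#' repeatedly least-squares fit a degree-`poly_order` polynomial to the
#' working spectrum, compute the residual standard deviation DEV, and clip the
#' working spectrum at `fit + DEV` so Raman peaks are progressively excluded
#' from the background estimate. Iteration stops when the relative DEV change
#' drops below `tol` (a DEV of exactly 0 converges immediately) or after
#' `max_iter` iterations. The polynomial is fitted on the shift axis rescaled
#' to \[-1, 1\] for conditioning; the corrected spectrum is the smoothed input
#' minus the final fit and may be negative where the fit overshoots.
#'
#' @param spectrum a `raman_spectrum` or numeric intensity vector (in the
#'   latter case an equispaced axis is assumed).
#' @param params a [vra_params()] object.
#' @return object of class `baseline_result`: list with `baseline`,
#'   `corrected`, `smoothed`, `n_iterations`, `converged`, `dev_history`.
#' @export
fit_baseline_imodpoly <- function(spectrum, params = vra_params()) {
  is_spec <- inherits(spectrum, "raman_spectrum")
  y_raw <- if (is_spec) spectrum$intensities else as.numeric(spectrum)
  shifts <- if (is_spec) spectrum$shifts else seq_along(y_raw)
  n <- length(y_raw)
  if (n <= params$poly_order + 1L) {
    abort_ramanglu("spectrum too short for the requested polynomial order",
                   class = "ramanglu_singular_fit")
  }
  if (length(unique(shifts)) < params$poly_order + 1L) {
    abort_ramanglu("axis has too few distinct shifts for the fit order",
                   class = "ramanglu_singular_fit")
  }
  x <- 2 * (shifts - min(shifts)) / (max(shifts) - min(shifts)) - 1
  basis <- outer(x, 0:params$poly_order, `^`)
  y <- smooth_spectrum(y_raw, params$smooth_window)

  work <- y
  dev_prev <- NA_real_
  dev_history <- numeric(0)
  converged <- FALSE
  fit <- rep(0, n)
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    coefs <- lm.fit(basis, work)$coefficients
    coefs[is.na(coefs)] <- 0
    fit <- drop(basis %*% coefs)
    dev <- sqrt(mean((work - fit)^2))
    dev_history <- c(dev_history, dev)
    if (dev == 0 ||
        (!is.na(dev_prev) && abs(dev - dev_prev) / dev < params$tol)) {
      converged <- TRUE
      break
    }
    work <- pmin(work, fit + dev)
    dev_prev <- dev
  }
  structure(
    list(baseline = fit, corrected = y - fit, smoothed = y,
         n_iterations = iter, converged = converged, dev_history = dev_history),
    class = "baseline_result"
  )
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result> %d points, %d iterations, converged=%s, final DEV=%.4g\n",
              length(x$baseline), x$n_iterations, x$converged,
              if (length(x$dev_history)) x$dev_history[length(x$dev_history)] else NA))
  invisible(x)
}

#' Fluorescence-correct every spectrum of a dataset
#'
#' Applies [fit_baseline_imodpoly()] sample by sample; labels, concentrations
#' and the shift axis are preserved. Corrected intensities may be negative
#' (the positivity rule applies to raw counts, not to background-subtracted
#' residuals).
#'
#' @param dataset a `raman_dataset`.
#' @param params a [vra_params()] object.
#' @return list with `dataset` (corrected `raman_dataset`) and `log` (data
#'   frame of sample_id, n_iterations, converged).
#' @export
correct_dataset <- function(dataset, params = vra_params()) {
  if (length(dataset$spectra) == 0L) {
    abort_ramanglu("dataset is empty", class = "ramanglu_empty_dataset")
  }
  logs <- vector("list", length(dataset$spectra))
  corrected <- vector("list", length(dataset$spectra))
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    res <- tryCatch(
      fit_baseline_imodpoly(s, params),
      error = function(e) abort_ramanglu(
        sprintf("baseline fit failed for sample %s: %s", s$sample_id,
                conditionMessage(e)),
        class = "ramanglu_baseline_failure")
    )
    corrected[[i]] <- new_spectrum(s$shifts, res$corrected,
                                   label_code = s$label_code,
                                   concentration = s$concentration,
                                   sample_id = s$sample_id, raw = FALSE)
    logs[[i]] <- data.frame(sample_id = s$sample_id,
                            n_iterations = res$n_iterations,
                            converged = res$converged)
  }
  list(dataset = new_dataset(corrected, label_map = dataset$label_map),
       log = do.call(rbind, logs))
}
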