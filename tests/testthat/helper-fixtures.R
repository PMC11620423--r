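# Small generator configurations used across the suite. 256/512-point axes
# keep the glucose bands (911..1366 cm-1) on-axis while making forest and SVM
# fits fast enough to run many CV iterations.

tiny_params <- function(...) {
  generator_params(n_points = 256, ...)
}

small_params <- function(...) {
  generator_params(n_points = 512, ...)
}

noiseless_params <- function(n_points = 256, ...) {
  generator_params(n_points = n_points, noise_sd = 0, gain_sd = 0,
                   baseline_jitter = 0, ...)
}

# Independent evaluation of the generator's closed-form mean curve:
# a degree-5 polynomial through the six template nodes plus Gaussian bands.
# Deliberately re-derived here (Vandermonde solve + explicit kernel sum)
# rather than calling the package's own helper.
oracle_mean_curve <- function(concentration, params) {
  shifts <- seq(params$shift_range[1], params$shift_range[2],
                length.out = params$n_points)
  u <- (shifts - params$shift_range[1]) / diff(params$shift_range)
  nodes_u <- seq(0, 1, length.out = 6)
  coef <- solve(outer(nodes_u, 0:5, `^`),
                params$baseline_scale * params$baseline_nodes)
  baseline <- drop(outer(u, 0:5, `^`) %*% coef)
  peaks <- rep(0, length(shifts))
  for (i in seq_along(params$peak_centers)) {
    peaks <- peaks + params$peak_weights[i] * params$response_slope *
      concentration *
      exp(-0.5 * ((shifts - params$peak_centers[i]) / params$peak_widths[i])^2)
  }
  list(shifts = shifts, baseline = baseline, total = baseline + peaks)
}

# Brute-force hotspot oracle: naive per-window statistics, naive ranking with
# the smaller-start-index tie rule, union of covered indices over samples.
oracle_hotspot_mask <- function(samples, l, k) {
  covered <- integer(0)
  for (x in samples) {
    n <- length(x)
    stats <- t(vapply(seq_len(n - l + 1), function(j) {
      w <- x[j:(j + l - 1)]
      m <- sum(w) / l
      c(j = j, v = sum((w - m)^2) / l)
    }, numeric(2)))
    ord <- order(-stats[, "v"], stats[, "j"])
    top <- stats[ord[seq_len(min(k, nrow(stats)))], "j"]
    for (j in top) covered <- union(covered, j:(j + l - 1))
  }
  sort(covered) - 1L  # 0-based
}

# A linearly separable two-class feature matrix with wide margin.
separable_xy <- function(n_per_class = 10, p = 4, gap = 50, seed = 99) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
               matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
    list(x = x, y = rep(1:2, each = n_per_class))
  })
}
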