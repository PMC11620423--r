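#' Sliding-window mean and variance of an intensity array
#'
#' Enumerates every contiguous intensity series of length `l` (window) in a
#' spectrum: a length-N array yields N - l + 1 windows with 0-based start
#' indices 0..N-l. The window variance uses population (1/l) normalization,
#' `V_j = (1/l) * sum((I - mean)^2)`, which is the hotspot score used by
#' [select_hotspots()].
#'
#' @param spectrum a `raman_spectrum` or a bare numeric intensity vector.
#' @param l window length, `1 <= l <= N`.
#' @return data frame with columns `start_index` (0-based), `length`, `mean`,
#'   `variance`, ordered by `start_index`.
#' @export
compute_window_stats <- function(spectrum, l) {
  x <- if (inherits(spectrum, "raman_spectrum")) spectrum$intensities else as.numeric(spectrum)
  n <- length(x)
  if (!is.numeric(l) || length(l) != 1 || is.na(l) || l != round(l) || l < 1 || l > n) {
    abort_ramanglu(sprintf("window length l must be an integer in [1, %d]", n),
                   class = "ramanglu_invalid_window")
  }
  l <- as.integer(l)
  j <- seq_len(n - l + 1L)           # 1-based start positions
  # Direct per-window summation (not a rolling/cumulative-sum update): window
  # scores must be bit-identical to a naive recomputation so that variance
  # ties resolve by start index alone, independent of accumulation order.
  mu <- vapply(j, function(s) sum(x[s:(s + l - 1L)]) / l, numeric(1))
  v <- vapply(j, function(s) {
    w <- x[s:(s + l - 1L)]
    sum((w - sum(w) / l)^2) / l
  }, numeric(1))
  data.frame(start_index = j - 1L, length = l, mean = mu, variance = v)
}

#' Select hotspot windows and build the shared index mask
#'
#' For every sample, ranks all length-`l` windows by variance and keeps the
#' `k` highest (ties resolved toward the smaller start index, making the
#' selection deterministic). The mask is the union, over all samples, of the
#' indices covered by the selected windows — one global mask applied
#' identically to every sample. Defaults are l = 10, k = 500.
#'
#' Computing the mask from the full dataset before any train/test split
#' mirrors the intended workflow but lets test samples influence feature
#' selection; compute the mask on training data only (pass a subset dataset)
#' when leakage matters.
#'
#' @param dataset a `raman_dataset`.
#' @param l window length.
#' @param k number of windows kept per sample (capped at the window count).
#' @return an object of class `index_mask`: list with sorted 0-based
#'   `indices`, `n_total`, `l`, `k`.
#' @export
select_hotspots <- function(dataset, l = 10, k = 500) {
  if (length(dataset$spectra) == 0L) {
    abort_ramanglu("dataset is empty", class = "ramanglu_empty_dataset")
  }
  stopifnot_scalar_count(k, "k", min = 1)
  n <- length(dataset$spectra[[1]]$intensities)
  covered <- logical(n)
  for (s in dataset$spectra) {
    ws <- compute_window_stats(s, l)
    k_eff <- min(as.integer(k), nrow(ws))
    # order(): ties in -variance resolved by ascending start index
    top <- ws$start_index[order(-ws$variance, ws$start_index)][seq_len(k_eff)]
    for (j in top) covered[(j + 1L):(j + ws$length[1])] <- TRUE
  }
  new_index_mask(which(covered) - 1L, n_total = n, l = l, k = k)
}

#' Construct an index mask
#'
#' @param indices sorted unique 0-based spectral indices to retain.
#' @param n_total length of the original axis.
#' @param l,k hotspot parameters that produced the mask (`NA` if hand-built).
#' @return an `index_mask` object.
#' @export
new_index_mask <- function(indices, n_total, l = NA_integer_, k = NA_integer_) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices) || is.unsorted(indices, strictly = TRUE)) {
    abort_ramanglu("mask indices must be strictly increasing and unique",
                   class = "ramanglu_invalid_mask")
  }
  if (length(indices) && (min(indices) < 0L || max(indices) >= n_total)) {
    abort_ramanglu(sprintf("mask indices must lie in [0, %d]", n_total - 1L),
                   class = "ramanglu_invalid_mask")
  }
  structure(list(indices = indices, n_total = as.integer(n_total),
                 l = as.integer(l), k = as.integer(k)),
            class = "index_mask")
}

#' @export
print.index_mask <- function(x, ...) {
  seg <- mask_segments(x)
  cat(sprintf("<index_mask> %d of %d indices (%.1f%%) in %d segments (l=%s, k=%s)\n",
              length(x$indices), x$n_total, 100 * length(x$indices) / x$n_total,
              nrow(seg), x$l, x$k))
  invisible(x)
}

#' @export
length.index_mask <- function(x) length(x$indices)

#' Contiguous segments of an index mask
#'
#' Run-length encodes the retained indices as inclusive `[from, to]` segments,
#' the form in which hotspot masks are usually reported.
#'
#' @param mask an `index_mask`.
#' @return data frame with 0-based inclusive columns `from`, `to`.
#' @export
mask_segments <- function(mask) {
  idx <- mask$indices
  if (length(idx) == 0L) return(data.frame(from = integer(0), to = integer(0)))
  brk <- which(diff(idx) > 1L)
  data.frame(from = idx[c(1L, brk + 1L)], to = idx[c(brk, length(idx))])
}

#' Build an index mask from inclusive segments
#'
#' Inverse of [mask_segments()]: expands 0-based inclusive `[from, to]` ranges
#' into an `index_mask`.
#'
#' @param from,to integer vectors of 0-based inclusive segment bounds.
#' @param n_total original axis length.
#' @return an `index_mask`.
#' @export
mask_from_segments <- function(from, to, n_total) {
  stopifnot(length(from) == length(to), all(to >= from))
  idx <- sort(unique(unlist(mapply(seq, from, to, SIMPLIFY = FALSE))))
  new_index_mask(idx, n_total = n_total)
}

#' Serialize / deserialize an index mask as JSON
#'
#' The JSON form stores `n_total`, `l`, `k` and the run-length-encoded
#' segments.
#'
#' @param mask an `index_mask`.
#' @param path output (input) file path.
#' @return `write_mask_json` returns `path` invisibly; `read_mask_json`
#'   returns an `index_mask`.
#' @export
write_mask_json <- function(mask, path) {
  jsonlite::write_json(
    list(n_total = mask$n_total, l = mask$l, k = mask$k,
         segments = mask_segments(mask)),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mask_from_segments(obj$segments$from, obj$segments$to, obj$n_total)
  m$l <- as.integer(obj$l %||% NA_integer_)
  m$k <- as.integer(obj$k %||% NA_integer_)
  m
}

#' Reduce a dataset to the masked feature matrix
#'
#' Keeps, for every sample, only the intensities at the mask's indices, in
#' ascending index order.
#'
#' @param dataset a `raman_dataset` (or samples-by-points matrix).
#' @param mask an `index_mask` whose `n_total` matches the axis length.
#' @return numeric matrix, samples by `length(mask)`.
#' @export
apply_mask <- function(dataset, mask) {
  m <- if (is.matrix(dataset)) dataset else dataset_matrix(dataset)
  if (ncol(m) != mask$n_total) {
    abort_ramanglu(sprintf("mask built for %d points, data has %d",
                           mask$n_total, ncol(m)),
                   class = "ramanglu_axis_mismatch")
  }
  m[, mask$indices + 1L, drop = FALSE]
}
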