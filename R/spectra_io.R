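#' Construct a Raman spectrum object
#'
#' A spectrum is one measured sample: a strictly ascending Raman-shift axis
#' (cm^-1) and one intensity value per shift. Raw instrument intensities are
#' photon counts and must be non-negative; zero is accepted as a physically
#' meaningful count. Baseline-corrected spectra (which may legitimately dip
#' below zero after subtraction) set `raw = FALSE` to relax that check.
#'
#' @param shifts numeric vector, strictly ascending Raman shifts (cm^-1).
#' @param intensities numeric vector, same length as `shifts`.
#' @param label_code integer class code in `1..n_classes`, or `NA`.
#' @param concentration glucose concentration in mmol/L, or `NA`.
#' @param sample_id character identifier for the sample.
#' @param raw logical; if `TRUE` (default) negative intensities are rejected.
#' @return an object of class `raman_spectrum`.
#' @export
new_spectrum <- function(shifts, intensities, label_code = NA_integer_,
                         concentration = NA_real_, sample_id = "",
                         raw = TRUE) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities)) {
    abort_ramanglu("`shifts` and `intensities` must have equal length",
                   class = "ramanglu_malformed_spectrum")
  }
  if (anyNA(shifts) || anyNA(intensities)) {
    abort_ramanglu("spectrum contains non-numeric or missing values",
                   class = "ramanglu_malformed_spectrum")
  }
  if (length(shifts) >= 2 && any(diff(shifts) <= 0)) {
    abort_ramanglu("shift axis must be strictly ascending",
                   class = "ramanglu_malformed_spectrum")
  }
  if (raw && any(intensities < 0)) {
    abort_ramanglu("raw intensities must be >= 0",
                   class = "ramanglu_malformed_spectrum")
  }
  structure(
    list(shifts = shifts, intensities = intensities,
         label_code = if (is.na(label_code)) NA_integer_ else as.integer(label_code),
         concentration = as.numeric(concentration),
         sample_id = as.character(sample_id)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s: %d points, shift %.1f..%.1f cm-1, label=%s, conc=%s mmol/L\n",
              x$sample_id, length(x$shifts), min(x$shifts), max(x$shifts),
              ifelse(is.na(x$label_code), "?", x$label_code),
              ifelse(is.na(x$concentration), "?", format(x$concentration))))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$shifts)

#' Glucose concentration to label-code map of the study design
#'
#' Ten glucose levels between 5.0 and 20.0 mmol/L, encoded as integer label
#' codes 1..10 in ascending concentration order.
#'
#' @return data frame with columns `concentration` (mmol/L) and `code`.
#' @export
table1_label_map <- function() {
  data.frame(
    concentration = c(5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 10.0, 12.5, 15.0, 20.0),
    code = 1:10
  )
}

#' Build a label map from arbitrary concentration levels
#'
#' Levels present in the canonical 10-level design keep their canonical codes
#' when all levels are drawn from it; otherwise codes are assigned by
#' ascending-concentration rank.
#'
#' @param levels numeric vector of concentrations (mmol/L).
#' @return data frame with columns `concentration` and `code`.
#' @export
label_map_for_levels <- function(levels) {
  levels <- sort(unique(as.numeric(levels)))
  t1 <- table1_label_map()
  if (all(levels %in% t1$concentration)) {
    t1[t1$concentration %in% levels, , drop = FALSE]
  } else {
    data.frame(concentration = levels, code = seq_along(levels))
  }
}

parse_label_prefix <- function(path) {
  base <- basename(path)
  if (!grepl("-", base, fixed = TRUE)) return(NA_integer_)
  prefix <- sub("-.*$", "", base)
  if (!grepl("^[0-9]+$", prefix)) return(NA_integer_)
  as.integer(prefix)
}

#' Read one Raman spectrum from a two-column CSV file
#'
#' Expects comma-separated rows of (raman_shift_cm-1, intensity), one sample
#' per file, rows in ascending shift order. A single non-numeric header row is
#' detected and skipped. The class label is the integer filename prefix before
#' the first `-` character (e.g. `7-sample3.csv` has label code 7); pass
#' `label_code` explicitly for files named otherwise.
#'
#' @param path CSV file path.
#' @param label_code optional integer label overriding the filename prefix.
#' @param raw logical, passed to [new_spectrum()]; raw spectra must be >= 0.
#' @return a [new_spectrum()] object.
#' @export
read_spectrum_csv <- function(path, label_code = NULL, raw = TRUE) {
  if (!file.exists(path)) {
    abort_ramanglu(sprintf("file not found: %s", path), class = "ramanglu_io")
  }
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]+\\s*,", first)
  df <- tryCatch(
    read.csv(path, header = has_header, colClasses = c("numeric", "numeric")),
    error = function(e) abort_ramanglu(
      sprintf("non-numeric row in %s: %s", basename(path), conditionMessage(e)),
      class = "ramanglu_malformed_spectrum")
  )
  if (ncol(df) != 2L || nrow(df) == 0L) {
    abort_ramanglu(sprintf("%s: expected two numeric columns", basename(path)),
                   class = "ramanglu_malformed_spectrum")
  }
  if (is.null(label_code)) {
    label_code <- parse_label_prefix(path)
    if (is.na(label_code)) {
      abort_ramanglu(
        sprintf("no integer label prefix before '-' in filename %s; supply `label_code`",
                basename(path)),
        class = "ramanglu_missing_label")
    }
  }
  new_spectrum(df[[1]], df[[2]], label_code = label_code,
               sample_id = sub("\\.csv$", "", basename(path)), raw = raw)
}

#' Write a spectrum to the package CSV dialect
#'
#' Two comma-separated columns with header `raman_shift_cm-1,intensity`.
#' Values are printed with 17 significant digits so a write/read round trip
#' reproduces every double bit-for-bit.
#'
#' @param spectrum a `raman_spectrum`.
#' @param path output file path. When `NULL`, a path `<label>-<sample_id>.csv`
#'   in `dir` is used so the label survives in the filename prefix.
#' @param dir directory used when `path` is `NULL`.
#' @return the path written, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path = NULL, dir = ".") {
  if (is.null(path)) {
    stopifnot(!is.na(spectrum$label_code))
    id <- if (nzchar(spectrum$sample_id)) spectrum$sample_id else "sample"
    id <- sub(sprintf("^%d-", spectrum$label_code), "", id)
    path <- file.path(dir, sprintf("%d-%s.csv", spectrum$label_code, id))
  }
  lines <- c("raman_shift_cm-1,intensity",
             sprintf("%.17g,%.17g", spectrum$shifts, spectrum$intensities))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a dataset of spectra sharing one shift axis
#'
#' @param spectra list of `raman_spectrum` objects with identical shift axes.
#' @param label_map data frame mapping `concentration` to `code`
#'   (default [table1_label_map()]).
#' @return an object of class `raman_dataset`.
#' @export
new_dataset <- function(spectra, label_map = table1_label_map()) {
  if (length(spectra) > 0) {
    axis <- spectra[[1]]$shifts
    for (s in spectra) {
      if (length(s$shifts) != length(axis) || !isTRUE(all.equal(s$shifts, axis))) {
        abort_ramanglu(
          sprintf("sample %s: shift axis differs from the first sample's", s$sample_id),
          class = "ramanglu_axis_mismatch")
      }
    }
    codes <- vapply(spectra, function(s) s$label_code, integer(1))
    known <- codes[!is.na(codes)]
    if (length(known) && !all(known %in% label_map$code)) {
      abort_ramanglu(
        sprintf("label codes not in label_map: %s",
                paste(sort(unique(setdiff(known, label_map$code))), collapse = ", ")),
        class = "ramanglu_unknown_label")
    }
    # fill concentrations from the map where absent
    spectra <- lapply(spectra, function(s) {
      if (is.na(s$concentration) && !is.na(s$label_code)) {
        hit <- match(s$label_code, label_map$code)
        if (!is.na(hit)) s$concentration <- label_map$concentration[hit]
      }
      s
    })
  }
  structure(list(spectra = spectra, label_map = label_map),
            class = "raman_dataset")
}

#' @export
length.raman_dataset <- function(x) length(x$spectra)

#' @export
print.raman_dataset <- function(x, ...) {
  n <- length(x$spectra)
  np <- if (n) length(x$spectra[[1]]$shifts) else 0L
  labs <- vapply(x$spectra, function(s) s$label_code, integer(1))
  cat(sprintf("<raman_dataset> %d spectra x %d points, %d classes\n",
              n, np, length(unique(labs[!is.na(labs)]))))
  invisible(x)
}

#' Load every label-prefixed spectrum CSV in a directory
#'
#' Files are read in `sort()` order of their names, so loading is independent
#' of filesystem enumeration order. Every file must share the shift axis of
#' the first file read.
#'
#' @param directory path containing `<label>-*.csv` files.
#' @param label_map concentration-to-code map (default [table1_label_map()]).
#' @return a `raman_dataset`.
#' @export
load_dataset <- function(directory, label_map = table1_label_map()) {
  files <- sort(list.files(directory, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) {
    abort_ramanglu(sprintf("no CSV spectra found in %s", directory),
                   class = "ramanglu_empty_dataset")
  }
  new_dataset(lapply(files, read_spectrum_csv), label_map = label_map)
}

#' Write every spectrum of a dataset as label-prefixed CSV files
#'
#' @param dataset a `raman_dataset`.
#' @param dir output directory (created if missing).
#' @param manifest if `TRUE`, also write `manifest.json` listing sample_id,
#'   label_code, concentration and n_points per sample.
#' @return character vector of written spectrum paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, manifest = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(dataset$spectra, write_spectrum_csv, character(1), dir = dir)
  if (manifest) {
    m <- dataset_manifest(dataset)
    jsonlite::write_json(m, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Summarise a dataset as a manifest data frame
#'
#' @param dataset a `raman_dataset`.
#' @return data frame with one row per sample.
#' @export
dataset_manifest <- function(dataset) {
  data.frame(
    sample_id = vapply(dataset$spectra, function(s) s$sample_id, character(1)),
    label_code = vapply(dataset$spectra, function(s) s$label_code, integer(1)),
    concentration = vapply(dataset$spectra, function(s) s$concentration, numeric(1)),
    n_points = vapply(dataset$spectra, function(s) length(s$shifts), integer(1))
  )
}

#' Stack a dataset's intensities into a samples-by-points matrix
#'
#' @param dataset a `raman_dataset`.
#' @return numeric matrix, one row per sample, rownames = sample_id.
#' @export
dataset_matrix <- function(dataset) {
  if (length(dataset$spectra) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  m <- do.call(rbind, lapply(dataset$spectra, function(s) s$intensities))
  rownames(m) <- vapply(dataset$spectra, function(s) s$sample_id, character(1))
  m
}

#' Extract label codes of a dataset
#'
#' @param dataset a `raman_dataset`.
#' @return integer vector of label codes, one per sample.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$spectra, function(s) s$label_code, integer(1))
}
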