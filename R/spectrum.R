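#' Construct a single spectrum
#'
#' A `raman_spectrum` holds one intensity trace on a strictly increasing axis,
#' either a Raman shift axis in cm^-1 or a wavelength axis in nm, together
#' with acquisition metadata (source wavelength, analyte, concentration,
#' replicate id, and any ground-truth fields attached by the simulator).
#'
#' @param axis numeric vector, strictly increasing; cm^-1 for
#'   `axis_kind = "raman_shift_cm1"`, nm for `axis_kind = "wavelength_nm"`.
#' @param intensity numeric vector of the same length (counts or AU).
#' @param axis_kind `"raman_shift_cm1"` or `"wavelength_nm"`.
#' @param meta named list of metadata. For a Raman-shift axis,
#'   `meta$source_wavelength_nm` must be a positive number.
#' @return An object of class `raman_spectrum` with fields `axis`,
#'   `intensity`, `axis_kind`, `meta`.
#' @examples
#' s <- spectrum(seq(400, 3100, 2), rexp(1351), meta = list(source_wavelength_nm = 532))
#' print(s)
#' @export
spectrum <- function(axis, intensity,
                     axis_kind = c("raman_shift_cm1", "wavelength_nm"),
                     meta = list()) {
  axis_kind <- match.arg(axis_kind)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) < 2L) stop("axis must have at least 2 points", call. = FALSE)
  if (length(axis) != length(intensity))
    stop("axis and intensity lengths differ (", length(axis), " vs ",
         length(intensity), ")", call. = FALSE)
  if (anyNA(axis) || anyNA(intensity))
    stop("axis/intensity must not contain NA", call. = FALSE)
  if (any(diff(axis) <= 0))
    stop("axis must be strictly increasing", call. = FALSE)
  if (axis_kind == "raman_shift_cm1") {
    swl <- meta$source_wavelength_nm
    if (!is.null(swl) && (!is.numeric(swl) || swl <= 0))
      stop("meta$source_wavelength_nm must be > 0", call. = FALSE)
  }
  structure(list(axis = axis, intensity = intensity,
                 axis_kind = axis_kind, meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  unit <- if (x$axis_kind == "raman_shift_cm1") "cm^-1" else "nm"
  cat(sprintf("<raman_spectrum> %d channels, %.6g-%.6g %s\n",
              length(x$axis), min(x$axis), max(x$axis), unit))
  if (!is.null(x$meta$analyte))
    cat("  analyte:", x$meta$analyte,
        if (!is.null(x$meta$concentration))
          sprintf("(%.4g mg/mL)", x$meta$concentration) else "", "\n")
  invisible(x)
}

#' Construct an aligned set of spectra
#'
#' A `spectrum_set` is a matrix of spectra (rows) sharing one axis (columns),
#' with a per-row label data frame carrying `analyte`, `concentration`
#' (mg/mL) and `replicate`.
#'
#' @param axis shared numeric axis, strictly increasing.
#' @param mat numeric matrix, `n_spectra x length(axis)`.
#' @param labels data frame with one row per spectrum; missing columns among
#'   `analyte`, `concentration`, `replicate` are filled with defaults.
#' @param axis_kind as in [spectrum()].
#' @param meta set-level metadata list.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(axis, mat, labels = NULL,
                         axis_kind = c("raman_shift_cm1", "wavelength_nm"),
                         meta = list()) {
  axis_kind <- match.arg(axis_kind)
  axis <- as.numeric(axis)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing", call. = FALSE)
  if (ncol(mat) != length(axis))
    stop("matrix has ", ncol(mat), " columns but axis has ",
         length(axis), " points", call. = FALSE)
  if (nrow(mat) < 1L) stop("need at least one spectrum", call. = FALSE)
  if (is.null(labels)) labels <- data.frame(row = seq_len(nrow(mat)))
  labels <- as.data.frame(labels)
  if (nrow(labels) != nrow(mat))
    stop("labels must have one row per spectrum", call. = FALSE)
  if (is.null(labels$analyte)) labels$analyte <- NA_character_
  if (is.null(labels$concentration)) labels$concentration <- NA_real_
  if (is.null(labels$replicate)) labels$replicate <- seq_len(nrow(mat))
  if (any(labels$concentration < 0, na.rm = TRUE))
    stop("concentrations must be >= 0", call. = FALSE)
  structure(list(axis = axis, matrix = mat, labels = labels,
                 axis_kind = axis_kind, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d channels (%.6g-%.6g %s)\n",
              nrow(x$matrix), ncol(x$matrix), min(x$axis), max(x$axis),
              if (x$axis_kind == "raman_shift_cm1") "cm^-1" else "nm"))
  an <- unique(stats::na.omit(x$labels$analyte))
  if (length(an)) cat("  analytes:", paste(an, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one row of a spectrum set as a spectrum
#'
#' @param set a [spectrum_set()].
#' @param i row index.
#' @return A [spectrum()] carrying the row's labels in `meta`.
#' @export
set_spectrum <- function(set, i) {
  stopifnot(inherits(set, "spectrum_set"), i >= 1, i <= nrow(set$matrix))
  meta <- c(set$meta, as.list(set$labels[i, , drop = FALSE]))
  spectrum(set$axis, set$matrix[i, ], axis_kind = set$axis_kind, meta = meta)
}

#' Linearly resample a spectrum onto a new grid
#'
#' Linear interpolation only; the target grid must lie within the spectrum's
#' axis span (no extrapolation). Values at original knots are preserved
#' exactly, so resampling a spectrum onto its own axis is the identity.
#'
#' @param spec a [spectrum()].
#' @param grid numeric vector, strictly increasing, within `range(spec$axis)`.
#' @return A [spectrum()] on `grid`.
#' @export
resample <- function(spec, grid) {
  stopifnot(inherits(spec, "raman_spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (min(grid) < min(spec$axis) || max(grid) > max(spec$axis))
    stop(sprintf(
      "grid [%.6g, %.6g] extends beyond the spectrum span [%.6g, %.6g]; refusing to extrapolate",
      min(grid), max(grid), min(spec$axis), max(spec$axis)), call. = FALSE)
  y <- stats::approx(spec$axis, spec$intensity, xout = grid, method = "linear")$y
  spectrum(grid, y, axis_kind = spec$axis_kind, meta = spec$meta)
}

#' Crop a spectrum set to an axis window
#'
#' The default analysis window for 532 nm carotenoid work is 400-3100 cm^-1,
#' which keeps the carotenoid fundamentals and overtones while excluding the
#' region above 3100 cm^-1 where water subtraction is unreliable.
#'
#' @param set a [spectrum_set()].
#' @param lo,hi window bounds (same units as the axis), `lo < hi`.
#' @return The cropped [spectrum_set()].
#' @export
crop <- function(set, lo = 400, hi = 3100) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  keep <- set$axis >= lo & set$axis <= hi
  if (!any(keep))
    stop(sprintf("crop window [%g, %g] contains no channels of axis [%g, %g]",
                 lo, hi, min(set$axis), max(set$axis)), call. = FALSE)
  spectrum_set(set$axis[keep], set$matrix[, keep, drop = FALSE],
               labels = set$labels, axis_kind = set$axis_kind, meta = set$meta)
}

#' Crop a single spectrum to an axis window
#' @inheritParams crop
#' @param spec a [spectrum()].
#' @return The cropped [spectrum()].
#' @export
crop_spectrum <- function(spec, lo = 400, hi = 3100) {
  stopifnot(inherits(spec, "raman_spectrum"))
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  keep <- spec$axis >= lo & spec$axis <= hi
  if (sum(keep) < 2L)
    stop(sprintf("crop window [%g, %g] leaves fewer than 2 channels", lo, hi),
         call. = FALSE)
  spectrum(spec$axis[keep], spec$intensity[keep],
           axis_kind = spec$axis_kind, meta = spec$meta)
}
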