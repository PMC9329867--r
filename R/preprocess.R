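#' Savitzky-Golay smoothing
#'
#' Local polynomial smoothing with the standard endpoint treatment (the
#' first and last half-windows are reproduced from the polynomial fitted to
#' the edge window), so any polynomial of degree <= `order` passes through
#' unchanged.
#'
#' @param spec a [spectrum()].
#' @param order polynomial order (default 5).
#' @param window odd window length (default 9), `window > order`.
#' @return The smoothed [spectrum()].
#' @export
savgol_smooth <- function(spec, order = 5L, window = 9L) {
  stopifnot(inherits(spec, "raman_spectrum"))
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window <= order) stop("window must exceed the polynomial order", call. = FALSE)
  out <- spec
  out$intensity <- signal::sgolayfilt(spec$intensity, p = order, n = window)
  out
}

#' Extended multiplicative signal correction (EMSC)
#'
#' Decomposes a spectrum into a carotenoid reference component, known
#' interferent spectra (water, BSA), and a Chebyshev polynomial baseline on
#' the axis rescaled to [-1, 1], by ordinary least squares:
#' `y ~ a*ref + sum_j b_j*interferent_j + poly(order p)`. The corrected
#' spectrum is the input minus the fitted interferents and baseline
#' (the analyte contribution and the residual are retained).
#'
#' @param spec a [spectrum()] to correct.
#' @param reference the analyte reference [spectrum()] (paste-spectrum
#'   analogue); for admixtures use the sum of the component references.
#' @param interferents list of interferent [spectrum()]s (typically water
#'   and BSA), possibly empty. List names (or `meta$analyte`) name the
#'   coefficients.
#' @param poly_order baseline polynomial order (default 7).
#' @return An object of class `emsc_fit`: `ref_weight`, `interferent_weights`
#'   (named; `water`/`bsa` exposed as `water_weight`, `bsa_weight`),
#'   `baseline_coeffs`, `residual_norm`, and `corrected` ([spectrum()]).
#' @export
emsc_fit <- function(spec, reference, interferents = list(), poly_order = 7L) {
  stopifnot(inherits(spec, "raman_spectrum"), inherits(reference, "raman_spectrum"))
  same_axis <- function(a) length(a$axis) == length(spec$axis) &&
    all(abs(a$axis - spec$axis) < 1e-9)
  if (!same_axis(reference))
    stop("reference is not on the spectrum's grid; resample() first", call. = FALSE)
  for (i in seq_along(interferents))
    if (!same_axis(interferents[[i]]))
      stop("interferent ", i, " is not on the spectrum's grid; resample() first",
           call. = FALSE)

  inames <- names(interferents)
  if (is.null(inames) || any(inames == ""))
    inames <- vapply(seq_along(interferents), function(i)
      interferents[[i]]$meta$analyte %||% paste0("interferent", i), character(1))
  P <- cheb_basis(spec$axis, poly_order)
  X <- cbind(reference$intensity,
             do.call(cbind, c(lapply(interferents, `[[`, "intensity"), list()))
             , P)
  colnames(X) <- c("reference", inames, paste0("poly", 0:poly_order))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # name the most collinear pair for the error message
    cors <- abs(stats::cor(X[, seq_len(1 + length(interferents)), drop = FALSE]))
    diag(cors) <- 0
    ij <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    stop(sprintf("EMSC design matrix is rank deficient (rank %d < %d); most collinear pair: %s and %s",
                 qrX$rank, ncol(X), colnames(X)[ij[1]], colnames(X)[ij[2]]),
         call. = FALSE)
  }
  beta <- qr.coef(qrX, spec$intensity)
  fitted <- drop(X %*% beta)
  n_int <- length(interferents)
  int_w <- if (n_int) stats::setNames(beta[1L + seq_len(n_int)], inames) else numeric(0)
  subtract <- fitted - beta[1] * reference$intensity  # interferents + baseline
  corrected <- spec
  corrected$intensity <- spec$intensity - subtract
  corrected$meta$emsc_corrected <- TRUE
  structure(list(
    ref_weight = unname(beta[1]),
    interferent_weights = int_w,
    water_weight = unname(int_w["water"]),
    bsa_weight = unname(int_w["bsa"]),
    baseline_coeffs = unname(beta[(2L + n_int):length(beta)]),
    residual_norm = sqrt(sum((spec$intensity - fitted)^2)),
    corrected = corrected,
    design = X), class = "emsc_fit")
}

#' @export
print.emsc_fit <- function(x, ...) {
  cat("<emsc_fit> ref_weight =", format(x$ref_weight, digits = 5),
      "| interferents:",
      paste(names(x$interferent_weights),
            format(x$interferent_weights, digits = 4), collapse = ", "),
      "| residual_norm =", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' Water internal-standard normalization
#'
#' Divides the EMSC-corrected spectrum by the fitted water coefficient.
#' Water content is constant across samples of equal measured volume, so
#' the coefficient tracks the overall collection efficiency and dividing by
#' it cancels measurement-to-measurement intensity variability.
#'
#' @param fit an [emsc_fit()] whose interferents included `water`.
#' @param tol smallest admissible water coefficient.
#' @return The normalized corrected [spectrum()].
#' @export
water_normalize <- function(fit, tol = 1e-6) {
  stopifnot(inherits(fit, "emsc_fit"))
  w <- fit$water_weight
  if (is.null(w) || is.na(w))
    stop("EMSC fit has no 'water' interferent; cannot normalise", call. = FALSE)
  if (w <= tol)
    stop("water coefficient non-positive; cannot normalise", call. = FALSE)
  out <- fit$corrected
  out$intensity <- out$intensity / w
  out$meta$water_weight <- w
  out
}

#' Preprocess a spectrum set: smooth, EMSC-correct, water-normalize, crop
#'
#' Applies the standard 532 nm pipeline row by row: Savitzky-Golay
#' smoothing, EMSC against the supplied reference and interferents, water
#' internal-standard normalization (skipped when no water interferent is
#' given), and cropping to the analysis window. Spectra are cropped
#' *before* the EMSC fit, which avoids the ill-conditioned water-subtraction
#' region above 3100 cm^-1. Row order and labels are preserved.
#'
#' @param set a [spectrum_set()].
#' @param reference analyte reference [spectrum()] on the same grid.
#' @param interferents named list of interferent spectra (e.g.
#'   `list(water = ..., bsa = ...)`).
#' @param sg_order,sg_window Savitzky-Golay parameters (5 / 9).
#' @param poly_order EMSC baseline order (7).
#' @param crop_lo,crop_hi analysis window in cm^-1 (400-3100).
#' @param normalize divide by the water coefficient (default TRUE when a
#'   water interferent is present).
#' @return A list with `set` (the processed [spectrum_set()]) and `fits`
#'   (per-row [emsc_fit()] objects, post-crop).
#' @export
preprocess_set <- function(set, reference, interferents = list(),
                           sg_order = 5L, sg_window = 9L, poly_order = 7L,
                           crop_lo = 400, crop_hi = 3100,
                           normalize = "water" %in% names(interferents)) {
  stopifnot(inherits(set, "spectrum_set"))
  cropped <- crop(set, crop_lo, crop_hi)
  ref_c <- crop_spectrum(resample_to(reference, set$axis), crop_lo, crop_hi)
  ints_c <- lapply(interferents, function(s)
    crop_spectrum(resample_to(s, set$axis), crop_lo, crop_hi))
  n <- nrow(cropped$matrix)
  out <- matrix(NA_real_, n, length(cropped$axis))
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    s <- savgol_smooth(set_spectrum(cropped, i), order = sg_order, window = sg_window)
    fit <- emsc_fit(s, ref_c, ints_c, poly_order = poly_order)
    fits[[i]] <- fit
    out[i, ] <- if (normalize) water_normalize(fit)$intensity else fit$corrected$intensity
  }
  list(set = spectrum_set(cropped$axis, out, labels = cropped$labels,
                          axis_kind = cropped$axis_kind, meta = cropped$meta),
       fits = fits)
}

# Resample onto `axis` only if needed (identity when already aligned).
resample_to <- function(spec, axis) {
  if (length(spec$axis) == length(axis) && all(abs(spec$axis - axis) < 1e-9))
    spec
  else resample(spec, axis[axis >= min(spec$axis) & axis <= max(spec$axis)])
}

#' Preprocess a single spectrum
#'
#' Convenience wrapper around [preprocess_set()] for one spectrum.
#'
#' @inheritParams preprocess_set
#' @param spec a [spectrum()].
#' @return A list with `spectrum` (processed) and `fit` (the [emsc_fit()]).
#' @export
preprocess_spectrum <- function(spec, reference, interferents = list(),
                                sg_order = 5L, sg_window = 9L, poly_order = 7L,
                                crop_lo = 400, crop_hi = 3100,
                                normalize = "water" %in% names(interferents)) {
  set <- spectrum_set(spec$axis, matrix(spec$intensity, 1L),
                      axis_kind = spec$axis_kind, meta = spec$meta)
  res <- preprocess_set(set, reference, interferents, sg_order, sg_window,
                        poly_order, crop_lo, crop_hi, normalize)
  s <- set_spectrum(res$set, 1L)
  s$meta <- spec$meta
  list(spectrum = s, fit = res$fits[[1L]])
}
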