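#' Convert a Raman shift to the Stokes-scattered wavelength
#'
#' `lambda_R = 1 / (1/lambda_L - shift * 1e-7)` nm. At 532 nm excitation a
#' 1519 cm^-1 shift scatters at 578.8 nm (rounds to 579 nm).
#'
#' @param laser_nm excitation wavelength in nm (> 0).
#' @param shift_cm1 Raman shift(s) in cm^-1; must be smaller than the
#'   excitation wavenumber `1e7 / laser_nm`.
#' @return Wavelength(s) in nm.
#' @examples
#' stokes_wavelength(532, 1519) # ~578.8
#' @export
stokes_wavelength <- function(laser_nm, shift_cm1) {
  stopifnot(laser_nm > 0)
  if (any(shift_cm1 >= 1e7 / laser_nm))
    stop("Raman shift must be below the excitation wavenumber ",
         format(1e7 / laser_nm), " cm^-1", call. = FALSE)
  1 / (1 / laser_nm - shift_cm1 * 1e-7)
}

#' Self-absorption transmission factor
#'
#' For total optical depth `u = alpha_L * d1 + alpha_R * d2`, the measured
#' Raman intensity integrated over the illuminated depth is attenuated by
#' `T(u) = (1 - exp(-u)) / u`, with `T(0) = 1` (evaluated by Taylor
#' expansion for small `u`). `T` is strictly decreasing, so the correction
#' factor `1/T` grows with concentration.
#'
#' @param u non-negative optical depth(s).
#' @return Transmission in (0, 1], same length as `u`.
#' @export
attenuation_factor <- function(u) {
  if (any(u < 0)) stop("optical depth u must be >= 0", call. = FALSE)
  out <- ifelse(u < 1e-8, 1 - u / 2, (1 - exp(-u)) / u)
  as.numeric(out)
}

#' Build a self-absorption model from an absorbance spectrum
#'
#' Bundles the laser wavelength, a reference absorbance spectrum (AU on a
#' wavelength axis, measured at concentration `c_ref`), and the effective
#' path factors `d1` (excitation path) and `d2` (collection path). The
#' factors are dimensionless, absorbing pathlength and geometry; the
#' defaults 1.3 and 1.75 are the values obtained for beta-carotene/BSA at
#' 532 nm. Decadic absorbance is converted to natural extinction
#' (`alpha = ln(10) * A * conc / c_ref`) by [alpha_at()].
#'
#' @param absorbance a [spectrum()] on a wavelength axis, in AU. Should be
#'   scatter-background-free (see [subtract_scatter_background()]).
#' @param laser_nm excitation wavelength in nm.
#' @param c_ref concentration (mg/mL) the absorbance was measured at.
#' @param d1,d2 path factors (>= 0); may be `NA` before fitting.
#' @return A list of class `absorption_model`.
#' @export
absorption_model <- function(absorbance, laser_nm = 532, c_ref = 1,
                             d1 = 1.3, d2 = 1.75) {
  stopifnot(inherits(absorbance, "raman_spectrum"),
            absorbance$axis_kind == "wavelength_nm", c_ref > 0)
  if (!is.na(d1) && d1 < 0 || !is.na(d2) && d2 < 0)
    stop("d1 and d2 must be >= 0", call. = FALSE)
  structure(list(absorbance = absorbance, laser_nm = laser_nm,
                 c_ref = c_ref, d1 = d1, d2 = d2),
            class = "absorption_model")
}

#' Subtract the scattering background from an absorbance spectrum
#'
#' Measured absorbance of the cloudy BSA complexes sits on a Mie-like
#' scattering background; the value at 700 nm (beyond the carotenoid bands)
#' is taken as the background level and subtracted from the whole range.
#' Negative residuals are clipped at zero for extinction use; the raw
#' subtracted values are retained in `meta$raw_subtracted`.
#'
#' @param absorbance a [spectrum()] on a wavelength axis covering 700 nm.
#' @return A background-subtracted [spectrum()].
#' @export
subtract_scatter_background <- function(absorbance) {
  stopifnot(inherits(absorbance, "raman_spectrum"),
            absorbance$axis_kind == "wavelength_nm")
  if (min(absorbance$axis) > 700 || max(absorbance$axis) < 700)
    stop("absorbance axis must cover 700 nm", call. = FALSE)
  a700 <- stats::approx(absorbance$axis, absorbance$intensity, xout = 700)$y
  raw <- absorbance$intensity - a700
  meta <- absorbance$meta
  meta$background_700 <- a700
  meta$raw_subtracted <- raw
  spectrum(absorbance$axis, pmax(raw, 0), axis_kind = "wavelength_nm", meta = meta)
}

#' Ordinary least-squares line through absorbance vs concentration
#'
#' Validates Beer-law linearity of the complexes at the band maximum.
#'
#' @param concs concentrations in mg/mL (>= 3 distinct values).
#' @param A_at_peak absorbance (AU) at the band maximum, same length.
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
absorbance_linear_fit <- function(concs, A_at_peak) {
  if (length(concs) != length(A_at_peak)) stop("length mismatch", call. = FALSE)
  if (length(concs) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(concs) == 0) stop("concentrations are constant", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, concs), A_at_peak)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((A_at_peak - mean(A_at_peak))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}

#' Natural extinction at a wavelength and concentration
#'
#' `alpha = ln(10) * A(lambda) * conc / c_ref`, interpolating the model's
#' reference absorbance; pathlength is absorbed into the path factors.
#'
#' @param model an [absorption_model()].
#' @param wavelength_nm wavelength(s) inside the absorbance axis.
#' @param conc concentration in mg/mL.
#' @return Natural extinction value(s) (dimensionless per unit path factor).
#' @export
alpha_at <- function(model, wavelength_nm, conc) {
  stopifnot(inherits(model, "absorption_model"))
  ax <- model$absorbance$axis
  if (any(wavelength_nm < min(ax) | wavelength_nm > max(ax)))
    stop(sprintf("wavelength outside absorbance axis [%g, %g] nm",
                 min(ax), max(ax)), call. = FALSE)
  A <- stats::approx(ax, model$absorbance$intensity, xout = wavelength_nm)$y
  log(10) * A * conc / model$c_ref
}

#' Correct a Raman spectrum for self-absorption
#'
#' Per channel, the optical depth is
#' `u(dnu) = alpha_L * d1 + alpha_R(lambda_R(dnu)) * d2`, where `lambda_R`
#' is the Stokes wavelength of the channel, and the original scattering
#' intensity is recovered as `I_R0 = I_Rm / T(u)`. With
#' `per_channel = FALSE` a single `alpha_R` evaluated at `single_shift_cm1`
#' (default 1519 cm^-1, the nu1 band) is used for the whole spectrum.
#'
#' @param spec a [spectrum()] on a Raman-shift axis.
#' @param model an [absorption_model()] with `d1`, `d2` set.
#' @param conc analyte concentration in mg/mL.
#' @param per_channel use the channel's own Stokes wavelength for `alpha_R`.
#' @param single_shift_cm1 shift used when `per_channel = FALSE`.
#' @return The corrected [spectrum()]; channel-wise >= the input for
#'   non-negative input intensities.
#' @export
correct_self_absorption <- function(spec, model, conc, per_channel = TRUE,
                                    single_shift_cm1 = 1519) {
  stopifnot(inherits(spec, "raman_spectrum"),
            spec$axis_kind == "raman_shift_cm1",
            inherits(model, "absorption_model"))
  if (is.na(model$d1) || is.na(model$d2))
    stop("model has unset path factors; run fit_path_factors() or supply d1/d2",
         call. = FALSE)
  lamR <- stokes_wavelength(model$laser_nm, if (per_channel) spec$axis else single_shift_cm1)
  ax <- model$absorbance$axis
  if (any(lamR < min(ax) | lamR > max(ax)))
    stop("Stokes wavelengths fall outside the absorbance axis; crop the ",
         "spectrum or extend the absorbance measurement", call. = FALSE)
  aL <- alpha_at(model, model$laser_nm, conc)
  aR <- alpha_at(model, lamR, conc)
  u <- aL * model$d1 + aR * model$d2
  out <- spec
  out$intensity <- spec$intensity / attenuation_factor(u)
  out$meta$self_absorption_corrected <- TRUE
  out
}

#' Fit self-absorption path factors from a concentration series
#'
#' Fits `I(c) = k * c * T(alpha_L(c) * d1 + alpha_R(c) * d2)` to peak
#' intensities (typically the nu1 band at ~1519 cm^-1) by bounded nonlinear
#' least squares with a seeded multistart, `d1, d2` in `[0, 20]`, `k > 0`.
#' `alpha_R` is evaluated at the Stokes wavelength of `shift_cm1`.
#'
#' When `alpha_R(c) / alpha_L(c)` is constant across the series, `d1` and
#' `d2` enter only through the combination `u = alpha_L d1 + alpha_R d2`
#' and are not separately identifiable; the fit then still determines that
#' combination (returned as `u_at_cref`) and sets `collinear = TRUE`. With
#' zero absorbance the model degenerates to a straight line; a plain linear
#' fit is returned with `degenerate = TRUE`.
#'
#' @param concs concentrations in mg/mL (>= 4 values spanning the
#'   sub-linear regime).
#' @param peak_intensities measured peak heights, same length.
#' @param model an [absorption_model()] (its `d1`, `d2` are ignored).
#' @param shift_cm1 Raman shift of the monitored band.
#' @param n_starts multistart size (initial `d1`, `d2` log-uniform on
#'   [0.1, 10]).
#' @param seed seed for the multistart draws.
#' @return A list with `d1`, `d2`, `k`, `u_at_cref` (identifiable optical
#'   depth at `model$c_ref`), `residual_norm`, `converged`, `collinear`,
#'   `degenerate`, and the fitted `model` (path factors filled in).
#' @export
fit_path_factors <- function(concs, peak_intensities, model,
                             shift_cm1 = 1519, n_starts = 8L, seed = 1L) {
  stopifnot(inherits(model, "absorption_model"),
            length(concs) == length(peak_intensities))
  if (length(unique(concs)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (all(peak_intensities == 0)) stop("all intensities are zero", call. = FALSE)
  lamR <- stokes_wavelength(model$laser_nm, shift_cm1)
  aL <- vapply(concs, function(c) alpha_at(model, model$laser_nm, c), numeric(1))
  aR <- vapply(concs, function(c) alpha_at(model, lamR, c), numeric(1))

  if (all(aL == 0 & aR == 0)) {
    k <- sum(concs * peak_intensities) / sum(concs^2)
    res <- peak_intensities - k * concs
    out_model <- model; out_model$d1 <- 0; out_model$d2 <- 0
    return(list(d1 = 0, d2 = 0, k = k, u_at_cref = 0,
                residual_norm = sqrt(sum(res^2)), converged = TRUE,
                collinear = TRUE, degenerate = TRUE, model = out_model))
  }

  ratio <- aR[aL > 0] / aL[aL > 0]
  collinear <- length(ratio) > 1 &&
    (max(ratio) - min(ratio)) <= 1e-6 * max(abs(ratio), 1e-12)

  obj <- function(p) {
    k <- exp(p[1]); d1 <- p[2]; d2 <- p[3]
    pred <- k * concs * attenuation_factor(aL * d1 + aR * d2)
    sum((peak_intensities - pred)^2)
  }
  k0 <- max(peak_intensities) / max(concs)
  starts <- with_seed(seed, matrix(exp(stats::runif(2L * n_starts,
                                                    log(0.1), log(10))),
                                   ncol = 2L))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(c(log(k0), starts[i, 1], starts[i, 2]), obj,
                            method = "L-BFGS-B",
                            lower = c(log(k0) - 20, 0, 0),
                            upper = c(log(k0) + 20, 20, 20),
                            control = list(maxit = 500,
                                           ndeps = rep(1e-6, 3L))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("path-factor optimisation failed from every start", call. = FALSE)
  d1 <- best$par[2]; d2 <- best$par[3]; k <- exp(best$par[1])
  aL_ref <- alpha_at(model, model$laser_nm, model$c_ref)
  aR_ref <- alpha_at(model, lamR, model$c_ref)
  out_model <- model; out_model$d1 <- d1; out_model$d2 <- d2
  list(d1 = d1, d2 = d2, k = k,
       u_at_cref = aL_ref * d1 + aR_ref * d2,
       residual_norm = sqrt(best$value),
       converged = best$convergence == 0,
       collinear = collinear, degenerate = FALSE, model = out_model)
}
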