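#' Nominal percentages from a parts ratio
#'
#' `100 * parts_i / sum(parts)`: e.g. 100:50:10 gives 62.5 / 31.25 / 6.25.
#'
#' @param ratio numeric parts vector (>= 0, not all zero).
#' @return Percentages summing to 100.
#' @export
nominal_percent <- function(ratio) {
  ratio <- as.numeric(ratio)
  if (any(ratio < 0) || sum(ratio) == 0)
    stop("parts must be >= 0 and not all zero", call. = FALSE)
  100 * ratio / sum(ratio)
}

#' Self-absorption-aware unmixing of an admixture spectrum
#'
#' Fits `measured ~ T(u_mix) * sum_i A_i * ref_i` by bounded nonlinear
#' least squares over the non-negative component weights `A_i`, where the
#' references are the self-absorption-corrected pure-complex spectra at the
#' stock concentration and the mixture optical depth is additive by Beer's
#' law: `u_mix(dnu) = sum_i A_i * (alpha_L,i * d1 + alpha_R,i(dnu) * d2)`
#' with extinctions evaluated at `stock_conc`. With
#' `per_component_correction = TRUE` each reference is instead attenuated
#' by its own component's optical depth only.
#'
#' @param measured preprocessed (EMSC-corrected, water-normalized, not
#'   self-absorption-corrected) admixture [spectrum()].
#' @param refs list of corrected pure-complex reference [spectrum()]s on
#'   the same grid, one per component.
#' @param models list of [absorption_model()]s matching `refs` order.
#' @param stock_conc stock concentration (mg/mL) the references represent.
#' @param d1,d2 path factors (default: taken from the first model).
#' @param bounds upper bound on each weight (weights in `[0, bounds]`).
#' @param window optional `c(lo, hi)` cm^-1 fit window (default full axis).
#' @param n_starts multistart size; initial weights uniform on the bounds.
#' @param seed seed for the multistart draws.
#' @param per_component_correction attenuate each reference by its own
#'   component's depth instead of the additive mixture depth.
#' @return An object of class `unmix_result`: `weights` (named A_i),
#'   `fitted_pct` (100 * A_i / sum A), `residual_norm`, `converged`,
#'   `degenerate`, and `fitted` (model spectrum on the fit window).
#' @export
fit_admixture <- function(measured, refs, models, stock_conc = 1,
                          d1 = NULL, d2 = NULL, bounds = 2,
                          window = NULL, n_starts = 8L, seed = 1L,
                          per_component_correction = FALSE) {
  stopifnot(inherits(measured, "raman_spectrum"),
            length(refs) == length(models))
  ncomp <- length(refs)
  for (r in refs)
    if (length(r$axis) != length(measured$axis) ||
        any(abs(r$axis - measured$axis) > 1e-9))
      stop("reference grids do not match the measured spectrum; resample first",
           call. = FALSE)
  d1 <- d1 %||% models[[1]]$d1
  d2 <- d2 %||% models[[1]]$d2
  comp_names <- names(refs) %||%
    vapply(refs, function(r) r$meta$analyte %||% "component", character(1))

  keep <- rep(TRUE, length(measured$axis))
  if (!is.null(window)) {
    keep <- measured$axis >= window[1] & measured$axis <= window[2]
    if (!any(keep)) stop("empty fit window", call. = FALSE)
  }
  axis <- measured$axis[keep]
  yobs <- measured$intensity[keep]
  R <- vapply(refs, function(r) r$intensity[keep], numeric(sum(keep)))

  # per-component optical depth per unit weight, at stock_conc
  lamR <- stokes_wavelength(models[[1]]$laser_nm, axis)
  U <- vapply(seq_len(ncomp), function(i) {
    aL <- alpha_at(models[[i]], models[[i]]$laser_nm, stock_conc)
    aR <- alpha_at(models[[i]], lamR, stock_conc)
    aL * d1 + aR * d2
  }, numeric(length(axis)))

  model_fun <- function(A) {
    if (per_component_correction) {
      rowSums(vapply(seq_len(ncomp), function(i)
        A[i] * R[, i] * attenuation_factor(A[i] * U[, i]),
        numeric(length(axis))))
    } else {
      attenuation_factor(drop(U %*% A)) * drop(R %*% A)
    }
  }
  obj <- function(A) sum((yobs - model_fun(A))^2)

  if (max(abs(yobs)) < .Machine$double.eps * 1e3) {
    A <- stats::setNames(rep(0, ncomp), comp_names)
    warning("measured spectrum is identically zero; returning zero weights")
    return(structure(list(weights = A, fitted_pct = rep(0, ncomp),
                          residual_norm = 0, converged = TRUE,
                          degenerate = TRUE, axis = axis,
                          fitted = rep(0, length(axis))),
                     class = "unmix_result"))
  }

  starts <- with_seed(seed,
                      matrix(stats::runif(n_starts * ncomp, 0, bounds), ncol = ncomp))
  starts[1L, ] <- rep(1 / ncomp, ncomp)     # deterministic first start
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                            lower = rep(0, ncomp), upper = rep(bounds, ncomp),
                            control = list(maxit = 1000, factr = 10,
                                           ndeps = rep(1e-6, ncomp))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("admixture optimisation failed from every start", call. = FALSE)
  A <- stats::setNames(pmax(best$par, 0), comp_names)
  tot <- sum(A)
  structure(list(weights = A,
                 fitted_pct = if (tot > 0) 100 * A / tot else rep(0, ncomp),
                 residual_norm = sqrt(best$value),
                 converged = best$convergence == 0,
                 degenerate = FALSE, axis = axis,
                 fitted = model_fun(best$par)),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("<unmix_result> fitted %:",
      paste(sprintf("%s %.2f", names(x$weights), x$fitted_pct), collapse = ", "),
      "| residual_norm =", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' Fitted ratio on the nominal-parts scale
#'
#' Rescales fitted percentages by the total parts of the declared nominal
#' ratio so they are comparable to the as-prepared parts (e.g. nominal
#' 100:50:10 has 160 parts, so fitted% (62.5, 31.25, 6.25) maps back to
#' 100:50:10).
#'
#' @param fitted_pct fitted percentages (summing to 100).
#' @param nominal_ratio the declared parts triple.
#' @return Fitted parts on the nominal scale.
#' @export
fitted_ratio <- function(fitted_pct, nominal_ratio) {
  fitted_pct * sum(nominal_ratio) / 100
}

#' Regression of fitted percentage on nominal percentage
#'
#' Ordinary least squares of fitted% on nominal% across an admixture
#' battery, reporting R-squared and the standard error of the regression
#' `sqrt(SS_res / (n - 2))` in percentage units. When `components` labels
#' are supplied, per-component sub-reports are included.
#'
#' @param nominal_pct,fitted_pct numeric vectors (>= 3 points).
#' @param components optional character labels per point.
#' @return A list of class `recovery_report`: `r_squared`, `std_error_pct`,
#'   `slope`, `intercept`, `n`, and `per_component` (named list of
#'   sub-reports, when labels are given).
#' @export
recovery_regression <- function(nominal_pct, fitted_pct, components = NULL) {
  if (length(nominal_pct) != length(fitted_pct))
    stop("length mismatch", call. = FALSE)
  n <- length(nominal_pct)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, nominal_pct), fitted_pct)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((fitted_pct - mean(fitted_pct))^2)
  out <- list(r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
              std_error_pct = sqrt(ss_res / (n - 2L)),
              slope = unname(fit$coefficients[2]),
              intercept = unname(fit$coefficients[1]),
              n = n)
  if (!is.null(components)) {
    out$per_component <- lapply(split(seq_len(n), components), function(idx) {
      if (length(idx) < 3L)
        return(list(r_squared = NA_real_, std_error_pct = NA_real_, n = length(idx)))
      r <- recovery_regression(nominal_pct[idx], fitted_pct[idx])
      r[c("r_squared", "std_error_pct", "slope", "intercept", "n")]
    })
  }
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> n = %d, R^2 = %.3f, SE = %.2f%%\n",
              x$n, x$r_squared, x$std_error_pct))
  invisible(x)
}
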