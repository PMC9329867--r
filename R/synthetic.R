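#' Configuration for the synthetic 532 nm carotenoid/BSA spectrum generator
#'
#' Builds the parameter set for simulated resonance Raman measurements of
#' carotenoid:BSA complexes in aqueous solution, with the statistical
#' structure the downstream analysis assumes: Lorentzian carotenoid
#' fundamentals (nu4 ~950, nu3 ~1004, nu2 ~1158, nu1 ~1519 cm^-1) plus weak
#' Gaussian overtone/combination bands above 2000 cm^-1, a water spectrum
#' (~1640 cm^-1 bend and broad OH stretch), a BSA spectrum (sharp
#' phenylalanine ~1004 cm^-1, Amide I ~1650 cm^-1, CH ~2900 cm^-1), a
#' slowly varying stray-light baseline, Beer-Lambert self-absorption of both
#' the 532 nm excitation and the Stokes-shifted scattered light, a
#' per-spectrum gain jitter, and multiplicative plus additive noise.
#'
#' The nu1 (C=C stretch) centers are ordered beta-carotene < zeaxanthin <
#' lutein in cm^-1; visible absorbance bands peak at 540/528/486 nm for
#' beta-carotene/zeaxanthin/lutein with peak heights giving resonance at
#' 532 nm in the order zeaxanthin > beta-carotene > lutein.
#'
#' @param grid Raman shift grid in cm^-1 (default 400-3100, step 2).
#' @param laser_nm excitation wavelength (default 532).
#' @param nu1_centers named nu1 band centers in cm^-1; the ordering
#'   beta_carotene < zeaxanthin < lutein is enforced.
#' @param carot_amp peak Raman amplitude (counts) of a carotenoid at
#'   1 mg/mL; resonance makes it dominate water/BSA.
#' @param water_amp,bsa_amp fixed interferent amplitudes (counts).
#' @param baseline_coeffs Chebyshev coefficients (degree 5 by default) of
#'   the stray-light baseline on the grid rescaled to [-1, 1].
#' @param noise_mult per-channel multiplicative Gaussian noise sd (fraction).
#' @param noise_add_frac additive Gaussian noise sd as a fraction of the
#'   spectrum maximum.
#' @param gain_jitter_sd sd of the per-spectrum global intensity gain,
#'   emulating shot-to-shot collection-efficiency variation (what the water
#'   internal standard corrects).
#' @param absorbance named per-carotenoid list with `peak_nm`, `fwhm_nm`,
#'   `peak_au` (AU per mg/mL at the band maximum).
#' @param scatter_a0,scatter_a1,scatter_power Mie-like absorbance
#'   background `(a0 + a1*conc) * (700/lambda)^power`, monotone decreasing
#'   with wavelength.
#' @param abs_grid wavelength grid (nm) for absorbance spectra.
#' @param d1,d2 effective path factors of the self-absorption geometry at
#'   the laser and Raman wavelengths.
#' @param attenuation logical; apply self-absorption to simulated Raman
#'   intensities.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(grid = seq(400, 3100, by = 2),
                         laser_nm = 532,
                         nu1_centers = c(beta_carotene = 1516,
                                         zeaxanthin = 1521,
                                         lutein = 1524),
                         carot_amp = 2000,
                         water_amp = 600,
                         bsa_amp = 150,
                         baseline_coeffs = c(180, -150, 60, -20, 8, -4),
                         noise_mult = 0.01,
                         noise_add_frac = 0.005,
                         gain_jitter_sd = 0.05,
                         absorbance = list(
                           beta_carotene = list(peak_nm = 540, fwhm_nm = 80, peak_au = 0.70),
                           zeaxanthin    = list(peak_nm = 528, fwhm_nm = 80, peak_au = 0.90),
                           lutein        = list(peak_nm = 486, fwhm_nm = 80, peak_au = 0.45)),
                         scatter_a0 = 0.02, scatter_a1 = 0.02, scatter_power = 1.2,
                         abs_grid = seq(400, 700, by = 1),
                         d1 = 1.3, d2 = 1.75,
                         attenuation = TRUE) {
  stopifnot(noise_mult >= 0, noise_add_frac >= 0, gain_jitter_sd >= 0,
            d1 >= 0, d2 >= 0, laser_nm > 0)
  need <- c("beta_carotene", "zeaxanthin", "lutein")
  if (!all(need %in% names(nu1_centers)))
    stop("nu1_centers must name beta_carotene, zeaxanthin and lutein", call. = FALSE)
  if (!(nu1_centers[["beta_carotene"]] < nu1_centers[["zeaxanthin"]] &&
        nu1_centers[["zeaxanthin"]] < nu1_centers[["lutein"]]))
    stop("nu1 centers must be ordered beta_carotene < zeaxanthin < lutein",
         call. = FALSE)
  cfg <- list(grid = grid, laser_nm = laser_nm, nu1_centers = nu1_centers,
              carot_amp = carot_amp, water_amp = water_amp, bsa_amp = bsa_amp,
              baseline_coeffs = baseline_coeffs, noise_mult = noise_mult,
              noise_add_frac = noise_add_frac, gain_jitter_sd = gain_jitter_sd,
              absorbance = absorbance, scatter_a0 = scatter_a0,
              scatter_a1 = scatter_a1, scatter_power = scatter_power,
              abs_grid = abs_grid, d1 = d1, d2 = d2, attenuation = attenuation)
  cfg$peaks <- default_peak_tables(nu1_centers)
  class(cfg) <- "synth_config"
  cfg
}

# Band tables: (center cm^-1, FWHM cm^-1, relative height, shape).
# Fundamentals are Lorentzian (solution-phase vibrational bands), broad
# overtone/combination bands Gaussian. Relative intensities encode the
# reported qualitative differences: nu2/nu3 relatively stronger in
# beta-carotene, >2000 cm^-1 features strongest in zeaxanthin.
default_peak_tables <- function(nu1) {
  pt <- function(...) {
    d <- as.data.frame(rbind(...))
    names(d) <- c("center", "width", "height")
    d$shape <- ifelse(d$center > 2000 | d$center %in% c(1340, 1450, 1640, 1650, 2900, 2935, 3380),
                      "gaussian", "lorentzian")
    d
  }
  list(
    beta_carotene = pt(c(950, 12, 0.06), c(1004, 10, 0.55), c(1158, 11, 0.72),
                       c(nu1[["beta_carotene"]], 13, 1.00),
                       c(2126, 40, 0.05), c(2526, 40, 0.03),
                       c(2679, 40, 0.05), c(3036, 40, 0.04)),
    zeaxanthin    = pt(c(952, 12, 0.06), c(1005, 10, 0.45), c(1159, 11, 0.63),
                       c(nu1[["zeaxanthin"]], 13, 1.00),
                       c(2169, 40, 0.10), c(2526, 40, 0.06),
                       c(2685, 40, 0.08), c(3040, 40, 0.06)),
    lutein        = pt(c(951, 12, 0.06), c(1005, 10, 0.46), c(1159, 11, 0.62),
                       c(nu1[["lutein"]], 13, 1.00),
                       c(2150, 40, 0.06), c(2520, 40, 0.04),
                       c(2679, 40, 0.05), c(3036, 40, 0.04)),
    water         = pt(c(1640, 90, 0.35), c(3330, 440, 1.00)),
    bsa           = pt(c(1004, 10, 0.50), c(1340, 30, 0.20), c(1450, 32, 0.35),
                      c(1650, 50, 0.80), c(2900, 70, 1.00), c(2935, 45, 0.50))
  )
}

eval_peaks <- function(x, table) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(table))) {
    c0 <- table$center[i]; w <- table$width[i]; h <- table$height[i]
    if (table$shape[i] == "lorentzian") {
      g <- w / 2
      y <- y + h * g^2 / ((x - c0)^2 + g^2)
    } else {
      s <- w / 2.35482
      y <- y + h * exp(-(x - c0)^2 / (2 * s^2))
    }
  }
  y
}

#' Noise-free, baseline-free reference spectrum of one component
#'
#' The analogue of a thick-paste reference measurement: the component's band
#' profile on the configured Raman-shift grid, scaled to unit maximum.
#'
#' @param component one of `"beta_carotene"`, `"lutein"`, `"zeaxanthin"`,
#'   `"water"`, `"bsa"`.
#' @param cfg a [synth_config()].
#' @return A [spectrum()] with unit maximum.
#' @export
make_reference_spectrum <- function(component, cfg = synth_config()) {
  tab <- cfg$peaks[[component]]
  if (is.null(tab))
    stop("unknown component '", component, "'; known: ",
         paste(names(cfg$peaks), collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) stop("empty peak table for '", component, "'", call. = FALSE)
  y <- eval_peaks(cfg$grid, tab)
  spectrum(cfg$grid, y / max(y), axis_kind = "raman_shift_cm1",
           meta = list(source_wavelength_nm = cfg$laser_nm,
                       analyte = component, reference = TRUE))
}

# Absorbance band (AU) of a carotenoid per the configured Beer-law model,
# without the scattering background; vectorised over wavelength.
band_absorbance <- function(component, wavelength_nm, conc, cfg) {
  ab <- cfg$absorbance[[component]]
  if (is.null(ab)) stop("no absorbance parameters for '", component, "'", call. = FALSE)
  s <- ab$fwhm_nm / 2.35482
  conc * ab$peak_au * exp(-(wavelength_nm - ab$peak_nm)^2 / (2 * s^2))
}

#' Simulate a visible absorbance spectrum of a carotenoid/BSA complex
#'
#' A concentration-proportional Gaussian absorption band plus a Mie-like
#' scattering background that decreases monotonically with wavelength
#' (`scatter = TRUE`, the as-measured case). With `scatter = FALSE` the pure
#' Beer-law band is returned, the generator's ground-truth extinction used
#' to build self-absorption models.
#'
#' @param component carotenoid id.
#' @param conc concentration in mg/mL (>= 0).
#' @param cfg a [synth_config()].
#' @param scatter include the scattering background.
#' @return A [spectrum()] on the wavelength axis (nm), in AU.
#' @export
simulate_absorbance <- function(component, conc, cfg = synth_config(),
                                scatter = TRUE) {
  if (conc < 0) stop("concentration must be >= 0", call. = FALSE)
  lam <- cfg$abs_grid
  A <- band_absorbance(component, lam, conc, cfg)
  if (scatter)
    A <- A + (cfg$scatter_a0 + cfg$scatter_a1 * conc) * (700 / lam)^cfg$scatter_power
  spectrum(lam, A, axis_kind = "wavelength_nm",
           meta = list(analyte = component, concentration = conc,
                       scatter = scatter))
}

# Per-channel self-absorption transmission for a composition, computed from
# the generator's ground-truth extinction: u(dnu) = sum_i alpha_L,i d1 +
# alpha_R,i(dnu) d2 with alpha = ln(10) * A_band(lambda) (A_band per mg/mL,
# scaled linearly in concentration).
attenuation_profile <- function(composition, cfg) {
  lamR <- stokes_wavelength(cfg$laser_nm, cfg$grid)
  u <- numeric(length(cfg$grid))
  for (comp in names(composition)) {
    conc <- composition[[comp]]
    if (conc == 0) next
    aL <- log(10) * band_absorbance(comp, cfg$laser_nm, conc, cfg)
    aR <- log(10) * band_absorbance(comp, lamR, conc, cfg)
    u <- u + aL * cfg$d1 + aR * cfg$d2
  }
  attenuation_factor(u)
}

#' Simulate one measured Raman spectrum of a (possibly mixed) solution
#'
#' Builds the noise-free response `T(u) * sum_i conc_i * carot_amp * ref_i +
#' water + BSA + baseline`, where `T(u)` is the per-channel self-absorption
#' transmission, then applies a per-spectrum gain, per-channel multiplicative
#' noise, and additive noise. Ground truth (composition, gain, transmission
#' at nu1) is stored in `meta`.
#'
#' @param composition named concentrations in mg/mL, e.g.
#'   `c(beta_carotene = 1)`; names must be carotenoid components.
#' @param cfg a [synth_config()].
#' @param seed integer seed; identical seeds give bit-identical spectra.
#' @return A [spectrum()] on the Raman-shift grid.
#' @export
simulate_measurement <- function(composition, cfg = synth_config(), seed = 1L) {
  composition <- unlist(composition)
  if (any(composition < 0)) stop("concentrations must be >= 0", call. = FALSE)
  bad <- setdiff(names(composition), names(cfg$absorbance))
  if (length(bad)) stop("unknown component(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  signal_part <- numeric(length(cfg$grid))
  for (comp in names(composition))
    signal_part <- signal_part + composition[[comp]] * cfg$carot_amp *
      make_reference_spectrum(comp, cfg)$intensity
  Tu <- if (cfg$attenuation) attenuation_profile(as.list(composition), cfg) else 1
  clean <- Tu * signal_part +
    cfg$water_amp * make_reference_spectrum("water", cfg)$intensity +
    cfg$bsa_amp * make_reference_spectrum("bsa", cfg)$intensity +
    drop(cheb_basis(cfg$grid, length(cfg$baseline_coeffs) - 1L) %*% cfg$baseline_coeffs)
  y <- with_seed(seed, {
    gain <- 1 + stats::rnorm(1, 0, cfg$gain_jitter_sd)
    mult <- 1 + stats::rnorm(length(clean), 0, cfg$noise_mult)
    add <- stats::rnorm(length(clean), 0, cfg$noise_add_frac * max(clean))
    gain * clean * mult + add
  })
  spectrum(cfg$grid, y, axis_kind = "raman_shift_cm1",
           meta = list(source_wavelength_nm = cfg$laser_nm,
                       composition = as.list(composition),
                       seed = seed,
                       attenuation = cfg$attenuation))
}

#' Simulate a concentration series of one carotenoid
#'
#' @param concs concentrations in mg/mL (default 41 levels spanning
#'   0.05-2.0 mg/mL).
#' @param replicates replicate spectra per concentration (default 2, giving
#'   82 spectra for the default levels).
#' @param cfg a [synth_config()].
#' @param seed integer; per-row seeds are derived deterministically.
#' @param analyte which carotenoid to vary.
#' @return A [spectrum_set()] whose labels carry the true concentrations.
#' @export
simulate_concentration_series <- function(concs = seq(0.05, 2, length.out = 41),
                                          replicates = 2L,
                                          cfg = synth_config(), seed = 1L,
                                          analyte = "beta_carotene") {
  if (length(concs) == 0L) stop("concs must be non-empty", call. = FALSE)
  grid_n <- length(cfg$grid)
  n <- length(concs) * replicates
  mat <- matrix(NA_real_, n, grid_n)
  labels <- data.frame(analyte = rep(analyte, n),
                       concentration = rep(concs, each = replicates),
                       replicate = rep(seq_len(replicates), times = length(concs)))
  row_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  for (i in seq_len(n)) {
    comp <- stats::setNames(list(labels$concentration[i]), analyte)
    mat[i, ] <- simulate_measurement(comp, cfg, seed = row_seeds[i])$intensity
  }
  spectrum_set(cfg$grid, mat, labels = labels, axis_kind = "raman_shift_cm1",
               meta = list(source_wavelength_nm = cfg$laser_nm, seed = seed))
}

#' Simulate an admixture spectrum from a B:L:Z parts ratio
#'
#' Component concentrations follow the volume-mixing convention
#' `stock_conc * parts / sum(parts)`; `meta` records the parts and the
#' nominal percentages `100 * parts / sum(parts)`.
#'
#' @param ratio numeric parts triple, order beta-carotene : lutein :
#'   zeaxanthin (e.g. `c(100, 50, 10)`).
#' @param stock_conc stock concentration in mg/mL of each component solution.
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return A [spectrum()] with ground-truth meta.
#' @export
simulate_admixture <- function(ratio, stock_conc = 1, cfg = synth_config(),
                               seed = 1L) {
  ratio <- as.numeric(ratio)
  if (length(ratio) != 3L || any(ratio < 0) || sum(ratio) == 0)
    stop("ratio must be 3 non-negative parts, not all zero", call. = FALSE)
  comp <- stats::setNames(as.list(stock_conc * ratio / sum(ratio)),
                          c("beta_carotene", "lutein", "zeaxanthin"))
  s <- simulate_measurement(comp, cfg, seed = seed)
  s$meta$parts <- ratio
  s$meta$nominal_pct <- 100 * ratio / sum(ratio)
  s$meta$stock_conc <- stock_conc
  s
}

#' The admixture ratio set used for recovery experiments
#'
#' Beta-carotene : lutein : zeaxanthin parts ratios 100:40:20, 100:30:30,
#' 100:50:10 and 100:20:40, i.e. a 5:3 ratio of beta-carotene to the
#' xanthophylls with the lutein:zeaxanthin ratio varied from 5:1 to 1:2.
#'
#' @return A list of parts triples.
#' @export
default_admixture_ratios <- function() {
  list(c(100, 40, 20), c(100, 30, 30), c(100, 50, 10), c(100, 20, 40))
}
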