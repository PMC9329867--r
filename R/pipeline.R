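#' Height of the strongest band in a window
#'
#' Maximum intensity within `center +/- halfwidth`; used to track the nu1
#' (~1519 cm^-1) band across a concentration series.
#'
#' @param spec a [spectrum()].
#' @param center window center in axis units.
#' @param halfwidth half-window width.
#' @return Peak height (numeric).
#' @export
peak_height <- function(spec, center = 1519, halfwidth = 15) {
  keep <- spec$axis >= center - halfwidth & spec$axis <= center + halfwidth
  if (!any(keep)) stop("window contains no channels", call. = FALSE)
  max(spec$intensity[keep])
}

#' Configuration for the end-to-end synthetic experiment
#'
#' Bundles and validates every stage parameter of [run_paper_twin()]:
#' preprocessing (Savitzky-Golay order 5 / window 9, EMSC polynomial order
#' 7, 400-3100 cm^-1 window), self-absorption (532 nm, d1 = 1.3,
#' d2 = 1.75, optional refit), chemometrics (10-fold cross-validation
#' repeated 100 times, 8 latent variables), unmixing (full-window fit,
#' weight bounds), and the generator settings.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param synth a [synth_config()].
#' @param concs calibration concentrations (mg/mL).
#' @param replicates replicates per concentration.
#' @param sg_order,sg_window,emsc_poly preprocessing parameters.
#' @param crop_lo,crop_hi analysis window (cm^-1).
#' @param d1,d2 path factors used for correction.
#' @param fit_path_factors additionally estimate path factors from the
#'   calibration series (reported; correction still uses `d1`, `d2`).
#' @param n_lv latent variables for the final model.
#' @param cv_k,cv_repeats cross-validation folds and repeats.
#' @param pca_reps replicate spectra per carotenoid for the PCA stage.
#' @param admix_ratios list of B:L:Z parts triples.
#' @param admix_reps replicate admixture spectra per ratio.
#' @param unmix_bounds upper bound for unmixing weights.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            synth = synth_config(),
                            concs = seq(0.05, 2, length.out = 41),
                            replicates = 2L,
                            sg_order = 5L, sg_window = 9L, emsc_poly = 7L,
                            crop_lo = 400, crop_hi = 3100,
                            d1 = 1.3, d2 = 1.75,
                            fit_path_factors = TRUE,
                            n_lv = 8L, cv_k = 10L, cv_repeats = 100L,
                            pca_reps = 10L,
                            admix_ratios = default_admixture_ratios(),
                            admix_reps = 3L,
                            unmix_bounds = 2) {
  if (sg_window %% 2L == 0L) stop("sg_window must be odd", call. = FALSE)
  if (sg_window <= sg_order) stop("sg_window must exceed sg_order", call. = FALSE)
  if (emsc_poly < 0) stop("emsc_poly must be >= 0", call. = FALSE)
  if (!(crop_lo < crop_hi)) stop("need crop_lo < crop_hi", call. = FALSE)
  if (d1 < 0 || d2 < 0) stop("path factors must be >= 0", call. = FALSE)
  if (cv_k < 2L) stop("cv_k must be >= 2", call. = FALSE)
  if (any(unlist(concs) < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-twin experiment
#'
#' Executes the whole analysis chain on simulated data: concentration
#' series generation, preprocessing (smooth, EMSC, water normalization,
#' crop), path-factor estimation and self-absorption correction, PLS1
#' calibration with repeated 10-fold cross-validation (RMSECV, LOD,
#' cross-validated R^2), three-class and pairwise PCA, and admixture
#' unmixing with fitted%-vs-nominal% recovery regression. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, intermediate CSVs and a
#'   JSON summary report are written there.
#' @return A list of class `paper_twin_report` with elements `calibration`
#'   (rmsecv_per_lv, rmsecv, r_squared, lod, n_lv, path factor fit),
#'   `pca` (explained variances, class separation, pairwise results),
#'   `unmixing` (pure-fit percentages, recovery table, regression), and
#'   `config`.
#' @export
run_paper_twin <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$synth
  seed <- as.integer(config$seed)
  comps <- c("beta_carotene", "lutein", "zeaxanthin")

  refs <- lapply(stats::setNames(comps, comps), make_reference_spectrum, cfg = cfg)
  interf <- list(water = make_reference_spectrum("water", cfg),
                 bsa = make_reference_spectrum("bsa", cfg))
  models <- lapply(stats::setNames(comps, comps), function(comp)
    absorption_model(simulate_absorbance(comp, 1, cfg, scatter = FALSE),
                     laser_nm = cfg$laser_nm, c_ref = 1,
                     d1 = config$d1, d2 = config$d2))

  ## --- calibration: concentration series -> preprocess -> correct -> PLSR
  series <- simulate_concentration_series(config$concs, config$replicates,
                                          cfg, seed = seed)
  prep <- preprocess_set(series, refs$beta_carotene, interf,
                         sg_order = config$sg_order, sg_window = config$sg_window,
                         poly_order = config$emsc_poly,
                         crop_lo = config$crop_lo, crop_hi = config$crop_hi)
  pset <- prep$set
  heights <- vapply(seq_len(nrow(pset$matrix)), function(i)
    peak_height(set_spectrum(pset, i)), numeric(1))
  pf <- if (config$fit_path_factors)
    fit_path_factors(pset$labels$concentration, heights,
                     models$beta_carotene, seed = seed + 1L)
  else NULL

  corr <- pset
  for (i in seq_len(nrow(corr$matrix))) {
    s <- correct_self_absorption(set_spectrum(pset, i), models$beta_carotene,
                                 conc = pset$labels$concentration[i])
    corr$matrix[i, ] <- s$intensity
  }
  heights_corr <- vapply(seq_len(nrow(corr$matrix)), function(i)
    peak_height(set_spectrum(corr, i)), numeric(1))

  cv <- cross_validate(corr, n_lv_max = config$n_lv, k = config$cv_k,
                       repeats = config$cv_repeats, seed = seed + 2L)
  model <- fit_plsr(corr, n_lv = config$n_lv)
  calibration <- list(
    n = nrow(corr$matrix),
    rmsecv_per_lv = cv$rmsecv_per_lv,
    rmsecv = cv$rmsecv_per_lv[config$n_lv],
    r_squared = cv$r_squared[config$n_lv],
    lod = lod(cv$rmsecv_per_lv[config$n_lv]),
    n_lv = config$n_lv,
    cum_var_y = model$cum_var_y,
    path_fit = if (!is.null(pf))
      pf[c("d1", "d2", "k", "u_at_cref", "collinear")] else NULL,
    linearity_r_before = stats::cor(pset$labels$concentration, heights),
    linearity_r_after = stats::cor(pset$labels$concentration, heights_corr))

  ## --- differentiation: 3 x pca_reps spectra at 1 mg/mL -> PCA
  pca_rows <- list(); pca_labels <- list()
  for (ci in seq_along(comps)) {
    for (r in seq_len(config$pca_reps)) {
      s <- simulate_measurement(stats::setNames(list(1), comps[ci]), cfg,
                                seed = seed + 1000L * ci + r)
      p <- preprocess_spectrum(s, refs[[comps[ci]]], interf,
                               sg_order = config$sg_order,
                               sg_window = config$sg_window,
                               poly_order = config$emsc_poly,
                               crop_lo = config$crop_lo, crop_hi = config$crop_hi)
      sc <- correct_self_absorption(p$spectrum, models[[comps[ci]]], conc = 1)
      pca_rows[[length(pca_rows) + 1L]] <- sc$intensity
      pca_labels[[length(pca_labels) + 1L]] <-
        data.frame(analyte = comps[ci], concentration = 1, replicate = r)
    }
  }
  pca_set <- spectrum_set(crop(series, config$crop_lo, config$crop_hi)$axis,
                          do.call(rbind, pca_rows),
                          labels = do.call(rbind, pca_labels))
  pca <- fit_pca(pca_set)
  pairs <- list(c("lutein", "zeaxanthin"), c("beta_carotene", "zeaxanthin"),
                c("beta_carotene", "lutein"))
  pairwise <- lapply(pairs, function(p) {
    r <- pairwise_pca(pca_set, p)
    list(pair = p, pc1_pct = r$explained_variance_pct[1],
         pc2_pct = r$explained_variance_pct[2])
  })
  pca_report <- list(
    explained_variance_pct = pca$explained_variance_pct[1:min(5, length(pca$explained_variance_pct))],
    pc12_pct = sum(pca$explained_variance_pct[1:2]),
    separation = pca_class_separation(pca),
    pairwise = pairwise)

  ## --- unmixing: corrected pure references, admixture battery, recovery
  sum_ref <- refs$beta_carotene
  sum_ref$intensity <- refs$beta_carotene$intensity + refs$lutein$intensity +
    refs$zeaxanthin$intensity
  pure_seed <- seed + 5000L
  unmix_refs <- list(); pure_meas <- list()
  for (ci in seq_along(comps)) {
    s <- simulate_measurement(stats::setNames(list(1), comps[ci]), cfg,
                              seed = pure_seed + ci)
    p <- preprocess_spectrum(s, sum_ref, interf,
                             sg_order = config$sg_order,
                             sg_window = config$sg_window,
                             poly_order = config$emsc_poly,
                             crop_lo = config$crop_lo, crop_hi = config$crop_hi)
    pure_meas[[comps[ci]]] <- p$spectrum
    unmix_refs[[comps[ci]]] <- correct_self_absorption(p$spectrum,
                                                       models[[comps[ci]]],
                                                       conc = 1)
  }
  pure_fit_pct <- vapply(seq_along(comps), function(ci) {
    fit_admixture(pure_meas[[ci]], unmix_refs, models, stock_conc = 1,
                  d1 = config$d1, d2 = config$d2, bounds = config$unmix_bounds,
                  seed = seed + 7000L + ci)$fitted_pct[ci]
  }, numeric(1))
  names(pure_fit_pct) <- comps

  nominal <- c(); fitted <- c(); comp_lab <- c(); ratio_lab <- c()
  for (ri in seq_along(config$admix_ratios)) {
    parts <- config$admix_ratios[[ri]]
    for (rep in seq_len(config$admix_reps)) {
      mix <- simulate_admixture(parts, stock_conc = 1, cfg,
                                seed = seed + 9000L + 100L * ri + rep)
      pm <- preprocess_spectrum(mix, sum_ref, interf,
                                sg_order = config$sg_order,
                                sg_window = config$sg_window,
                                poly_order = config$emsc_poly,
                                crop_lo = config$crop_lo, crop_hi = config$crop_hi)
      um <- fit_admixture(pm$spectrum, unmix_refs, models, stock_conc = 1,
                          d1 = config$d1, d2 = config$d2,
                          bounds = config$unmix_bounds,
                          seed = seed + 9500L + 100L * ri + rep)
      nominal <- c(nominal, nominal_percent(parts))
      fitted <- c(fitted, um$fitted_pct)
      comp_lab <- c(comp_lab, comps)
      ratio_lab <- c(ratio_lab, rep(paste(parts, collapse = ":"), 3L))
    }
  }
  # pure complexes enter the recovery plot at nominal 100%
  nominal <- c(nominal, rep(100, 3L))
  fitted <- c(fitted, pure_fit_pct)
  comp_lab <- c(comp_lab, comps)
  ratio_lab <- c(ratio_lab, rep("pure", 3L))
  recovery <- recovery_regression(nominal, fitted, components = comp_lab)

  report <- list(calibration = calibration, pca = pca_report,
                 unmixing = list(pure_fit_pct = pure_fit_pct,
                                 table = data.frame(ratio = ratio_lab,
                                                    component = comp_lab,
                                                    nominal_pct = nominal,
                                                    fitted_pct = fitted),
                                 regression = recovery[c("r_squared",
                                                         "std_error_pct",
                                                         "slope", "intercept", "n")]),
                 seed = seed)
  class(report) <- "paper_twin_report"
  if (!is.null(out_dir)) write_twin_report(report, corr, out_dir)
  report
}

# minimum pairwise centroid distance in (PC1, PC2), relative to the largest
# within-class sd of the scores
pca_class_separation <- function(pca) {
  sc <- pca$scores[, 1:2, drop = FALSE]
  cls <- pca$labels$analyte
  cent <- rowsum(sc, cls) / as.vector(table(cls))
  wsd <- max(vapply(split(seq_len(nrow(sc)), cls), function(idx)
    max(apply(sc[idx, , drop = FALSE], 2L, stats::sd)), numeric(1)))
  dmin <- min(stats::dist(cent))
  list(min_centroid_distance = dmin, max_within_sd = wsd,
       ratio = dmin / wsd)
}

write_twin_report <- function(report, corrected_set, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(corrected_set, file.path(out_dir, "corrected_calibration.csv"),
                sidecar = file.path(out_dir, "corrected_calibration.json"))
  utils::write.csv(report$unmixing$table,
                   file.path(out_dir, "recovery_table.csv"), row.names = FALSE)
  jsonlite::write_json(report[c("calibration", "pca", "unmixing", "seed")],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.paper_twin_report <- function(x, ...) {
  cat("<paper_twin_report>\n")
  cat(sprintf("  calibration: n = %d, RMSECV = %.5f mg/mL, CV R^2 = %.5f, LOD = %.5f mg/mL (%d LVs)\n",
              x$calibration$n, x$calibration$rmsecv, x$calibration$r_squared,
              x$calibration$lod, x$calibration$n_lv))
  cat(sprintf("  PCA: PC1 %.2f%%, PC2 %.2f%% (separation ratio %.1f)\n",
              x$pca$explained_variance_pct[1], x$pca$explained_variance_pct[2],
              x$pca$separation$ratio))
  cat(sprintf("  unmixing: pure fits %s%%; recovery R^2 = %.3f, SE = %.2f%%\n",
              paste(sprintf("%.1f", x$unmixing$pure_fit_pct), collapse = "/"),
              x$unmixing$regression$r_squared,
              x$unmixing$regression$std_error_pct))
  invisible(x)
}
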