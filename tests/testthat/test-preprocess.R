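test_that("Savitzky-Golay smoothing reproduces low-degree polynomials and damps noise", {
  x <- seq(400, 600, 2)
  # any polynomial of degree <= the filter order passes unchanged, edges included
  for (deg in c(2, 5)) {
    y <- rowSums(outer(x / 500, 0:deg, `^`))
    s <- savgol_smooth(spectrum(x, y), order = 5L, window = 9L)
    expect_equal(s$intensity, y, tolerance = 1e-10)
  }
  # white noise: output variance strictly below input variance
  set.seed(42)
  noise <- rnorm(length(x))
  sm <- savgol_smooth(spectrum(x, noise), 5L, 9L)
  expect_lt(var(sm$intensity), var(noise))
  # interior channels equal an explicit local least-squares fit
  i <- 57L
  win <- (i - 4L):(i + 4L)
  fit <- lm(noise[win] ~ poly(win, 5, raw = TRUE))
  expect_equal(sm$intensity[i], unname(predict(fit)[5]), tolerance = 1e-8)
  expect_error(savgol_smooth(spectrum(x, noise), 5L, 4L), "odd")
  expect_error(savgol_smooth(spectrum(x, noise), 5L, 5L), "exceed")
})

test_that("EMSC recovers constructed coefficients exactly", {
  cfg <- synth_config()
  ref <- make_reference_spectrum("beta_carotene", cfg)
  ints <- default_interferents(cfg)
  pcoef <- c(10, -5, 3, 1, 0.5, -0.2, 0.1, 0.05)
  y <- 2.5 * ref$intensity + 1.2 * ints$water$intensity +
    0.4 * ints$bsa$intensity +
    drop(carotRaman:::cheb_basis(cfg$grid, 7) %*% pcoef)
  fit <- emsc_fit(spectrum(cfg$grid, y), ref, ints, poly_order = 7L)
  expect_equal(fit$ref_weight, 2.5, tolerance = 1e-8)
  expect_equal(fit$water_weight, 1.2, tolerance = 1e-8)
  expect_equal(fit$bsa_weight, 0.4, tolerance = 1e-8)
  expect_equal(fit$baseline_coeffs, pcoef, tolerance = 1e-8)
  expect_lt(fit$residual_norm, 1e-8)
  # corrected spectrum retains only the analyte contribution
  expect_equal(fit$corrected$intensity, 2.5 * ref$intensity, tolerance = 1e-8)
})

test_that("EMSC of the water reference alone yields weight 1 and a null corrected spectrum", {
  cfg <- synth_config()
  ints <- default_interferents(cfg)
  fit <- emsc_fit(ints$water, make_reference_spectrum("beta_carotene", cfg),
                  ints, poly_order = 7L)
  expect_equal(fit$water_weight, 1, tolerance = 1e-8)
  expect_lt(max(abs(fit$corrected$intensity)), 1e-8 * max(ints$water$intensity))
})

test_that("EMSC residual is orthogonal to every design column", {
  cfg <- synth_config()
  ref <- make_reference_spectrum("beta_carotene", cfg)
  ints <- default_interferents(cfg)
  for (seed in 1:5) {
    m <- simulate_measurement(c(beta_carotene = 0.3 * seed), cfg, seed = seed)
    fit <- emsc_fit(m, ref, ints, poly_order = 7L)
    X <- fit$design
    resid <- m$intensity - drop(X %*% c(fit$ref_weight, fit$interferent_weights,
                                        fit$baseline_coeffs))
    proj <- abs(crossprod(X, resid)) / sqrt(colSums(X^2))
    expect_lt(max(proj) / sqrt(sum(m$intensity^2)), 1e-8)
  }
})

test_that("a rank-deficient EMSC design names the collinear pair", {
  cfg <- synth_config()
  w <- make_reference_spectrum("water", cfg)
  expect_error(emsc_fit(w, w, list(water = w), poly_order = 3L),
               "rank deficient.*(reference.*water|water.*reference)")
})

test_that("EMSC correction of a realistic measurement isolates the carotenoid bands", {
  cfg <- synth_config()
  m <- simulate_measurement(c(beta_carotene = 1), cfg, seed = 5L)
  sm <- savgol_smooth(m)
  fit <- emsc_fit(sm, make_reference_spectrum("beta_carotene", cfg),
                  default_interferents(cfg), poly_order = 7L)
  corr <- fit$corrected
  # three largest well-separated maxima sit at the carotenoid band centers
  ord <- order(corr$intensity, decreasing = TRUE)
  centers <- corr$axis[ord[!duplicated(round(corr$axis[ord] / 60))][1:3]]
  expect_equal(sort(centers), c(1004, 1158, 1516), tolerance = 6)
  # the broad water region is removed: high-wavenumber content is tiny
  # (the weak ~3036 cm^-1 carotenoid overtone remains, the dominant OH band is gone)
  hw <- corr$axis >= 3000
  expect_lt(max(abs(corr$intensity[hw])), 0.1 * max(corr$intensity))
  raw_hw <- max(sm$intensity[hw]) / max(sm$intensity)
  expect_gt(raw_hw, 0.3)
})

test_that("water normalization is scale invariant and reduces replicate variability", {
  cfg0 <- noise_free_config()
  ref <- make_reference_spectrum("beta_carotene", cfg0)
  ints <- default_interferents(cfg0)
  m <- simulate_measurement(c(beta_carotene = 1), cfg0, seed = 1L)
  m2 <- m; m2$intensity <- 3.7 * m$intensity
  n1 <- water_normalize(emsc_fit(m, ref, ints))
  n2 <- water_normalize(emsc_fit(m2, ref, ints))
  expect_equal(n1$intensity, n2$intensity, tolerance = 1e-10)

  # unit water weight makes normalization the identity
  fit1 <- emsc_fit(m, ref, ints)
  fitU <- fit1; fitU$interferent_weights["water"] <- 1; fitU$water_weight <- 1
  expect_equal(water_normalize(fitU)$intensity, fitU$corrected$intensity)

  # replicate jitter: CV of the nu1 peak drops after normalization
  cfgJ <- synth_config(noise_mult = 0, noise_add_frac = 0, gain_jitter_sd = 0.08)
  pk_raw <- pk_norm <- numeric(12)
  for (i in 1:12) {
    mi <- simulate_measurement(c(beta_carotene = 1), cfgJ, seed = 100L + i)
    fi <- emsc_fit(mi, ref, ints)
    pk_raw[i] <- peak_height(fi$corrected)
    pk_norm[i] <- peak_height(water_normalize(fi))
  }
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(pk_norm), cv(pk_raw))

  fit_bad <- fit1; fit_bad$interferent_weights["water"] <- 0; fit_bad$water_weight <- 0
  expect_error(water_normalize(fit_bad), "cannot normalise")
})

test_that("preprocess_set preserves shape and labels, crops, and is not idempotent", {
  cfg <- synth_config()
  set <- simulate_concentration_series(c(0.5, 1, 2), 2L, cfg = cfg, seed = 3L)
  res <- preprocess_set(set, make_reference_spectrum("beta_carotene", cfg),
                        default_interferents(cfg))
  expect_equal(nrow(res$set$matrix), 6L)
  expect_equal(res$set$labels$concentration, set$labels$concentration)
  expect_true(all(res$set$axis >= 400 & res$set$axis <= 3100))
  # smoothing twice is not the same as once: a second pass changes the rows
  # (water is already subtracted, so its coefficient is ~0; skip normalization)
  res2 <- preprocess_set(res$set, make_reference_spectrum("beta_carotene", cfg),
                         default_interferents(cfg), normalize = FALSE)
  expect_false(isTRUE(all.equal(res2$set$matrix, res$set$matrix)))
  # degenerate config: no interferents still runs (reference + baseline only)
  res3 <- preprocess_set(set, make_reference_spectrum("beta_carotene", cfg),
                         interferents = list())
  expect_equal(dim(res3$set$matrix), dim(res$set$matrix))
})

test_that("corrected, normalized nu1 height is concentration-proportional without absorbance", {
  cfg0 <- noise_free_config(attenuation = FALSE)
  set <- simulate_concentration_series(seq(0.1, 2, length.out = 8), 1L,
                                       cfg = cfg0, seed = 1L)
  res <- preprocess_set(set, make_reference_spectrum("beta_carotene", cfg0),
                        default_interferents(cfg0))
  h <- vapply(seq_len(nrow(res$set$matrix)), function(i)
    peak_height(set_spectrum(res$set, i)), numeric(1))
  expect_gt(cor(res$set$labels$concentration, h), 0.999999)
})
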