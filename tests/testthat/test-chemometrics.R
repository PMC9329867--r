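rank1_data <- function(n = 12, seed = 1) {
  cfg <- noise_free_config()
  ref <- make_reference_spectrum("beta_carotene", cfg)$intensity
  concs <- seq(0.1, 2, length.out = n)
  list(X = outer(concs, ref), y = concs, ref = ref)
}

test_that("PLS1 is exact on rank-1 noise-free data", {
  d <- rank1_data()
  m <- fit_plsr(d$X, d$y, n_lv = 1L)
  expect_lt(sqrt(mean((m$fitted - d$y)^2)), 1e-8)
  expect_equal(predict(m, d$X), d$y, tolerance = 1e-8)
  # regression vector points along the component spectrum
  cosine <- sum(m$coefficients * d$ref) /
    sqrt(sum(m$coefficients^2) * sum(d$ref^2))
  expect_gt(cosine, 0.9999)
  expect_error(fit_plsr(d$X, d$y, n_lv = nrow(d$X)), "n_lv")
  expect_error(fit_plsr(d$X, d$y, n_lv = 0L), "n_lv")
})

test_that("training error is monotone in the number of latent variables", {
  set.seed(3)
  X <- matrix(rnorm(30 * 40), 30)
  y <- X %*% rnorm(40) + rnorm(30)
  rmse <- vapply(1:6, function(a) {
    m <- fit_plsr(X, y, n_lv = a)
    sqrt(mean((m$fitted - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
  # cumulative explained variances are non-decreasing and bounded by 100
  m <- fit_plsr(X, y, n_lv = 6L)
  expect_true(all(diff(m$cum_var_y) >= -1e-10))
  expect_true(all(m$cum_var_y <= 100 + 1e-6))
  expect_true(all(diff(m$cum_var_x) >= -1e-10))
})

test_that("PLS1 predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  X <- matrix(rnorm(25 * 60), 25, dimnames = list(NULL, paste0("ch", 1:60)))
  y <- drop(X %*% rnorm(60)) + rnorm(25)
  for (a in c(1L, 3L)) {
    mine <- fit_plsr(X, y, n_lv = a)
    ref <- mixOmics::pls(X, y, ncomp = a, mode = "regression", scale = FALSE)
    pref <- unname(drop(predict(ref, X)$predict[, 1, a]))
    expect_equal(mine$fitted, pref, tolerance = 1e-6)
  }
})

test_that("cross-validation is deterministic and exact on rank-1 data", {
  d <- rank1_data()
  cv1 <- cross_validate(d$X, d$y, n_lv_max = 3L, k = 4L, repeats = 5L, seed = 42L)
  cv2 <- cross_validate(d$X, d$y, n_lv_max = 3L, k = 4L, repeats = 5L, seed = 42L)
  expect_identical(cv1$rmsecv_per_lv, cv2$rmsecv_per_lv)
  cv3 <- cross_validate(d$X, d$y, n_lv_max = 3L, k = 4L, repeats = 5L, seed = 43L)
  expect_false(identical(cv1$rmsecv_per_lv, cv3$rmsecv_per_lv))
  expect_lt(cv1$rmsecv_per_lv[1], 1e-6)
  expect_error(cross_validate(d$X, d$y, 2L, k = 100L), "exceed")
})

test_that("cross-validated predictions are unbiased on a synthetic series", {
  cfg <- synth_config()
  set <- simulate_concentration_series(seq(0.1, 2, length.out = 10), 2L,
                                       cfg = cfg, seed = 8L)
  res <- preprocess_set(set, make_reference_spectrum("beta_carotene", cfg),
                        default_interferents(cfg))
  model <- truth_models(cfg)$beta_carotene
  corr <- res$set
  for (i in seq_len(nrow(corr$matrix)))
    corr$matrix[i, ] <- correct_self_absorption(
      set_spectrum(res$set, i), model, res$set$labels$concentration[i])$intensity
  cv <- cross_validate(corr, n_lv_max = 4L, k = 5L, repeats = 10L, seed = 2L)
  best <- which.min(cv$rmsecv_per_lv)
  bias <- mean(cv$predictions[, best] - corr$labels$concentration)
  expect_lt(abs(bias), 0.5 * cv$rmsecv_per_lv[best])
  expect_lte(best, 4L)
})

test_that("latent-variable selection rules match their definitions", {
  expect_equal(select_n_lv(cumulative_variance = c(60, 95, 99.95, 100),
                           policy = "variance_saturation"), 3L)
  expect_equal(select_n_lv(rmsecv_per_lv = c(5, 1, 1.01, 1.02),
                           policy = "rmsecv_min"), 2L)
  # rank-1 noise-free data: both policies settle on a single LV
  d <- rank1_data()
  m <- fit_plsr(d$X, d$y, n_lv = 3L)
  cv <- cross_validate(d$X, d$y, n_lv_max = 3L, k = 4L, repeats = 3L, seed = 1L)
  expect_equal(select_n_lv(m$cum_var_y, policy = "variance_saturation"), 1L)
  expect_equal(select_n_lv(rmsecv_per_lv = cv$rmsecv_per_lv,
                           policy = "rmsecv_min"), 1L)
})

test_that("the limit of detection is 3.3x RMSECV", {
  expect_equal(lod(0.0032), 0.01056)
  expect_equal(sprintf("%.4f", lod(0.0032)), "0.0106")
  expect_equal(lod(0), 0)
  expect_equal(lod(1), 3.3)
  expect_error(lod(-1), ">= 0")
})

test_that("PCA reconstructs the normalized centered matrix and orders variance", {
  set.seed(5)
  X <- matrix(rnorm(15 * 30), 15)
  p <- fit_pca(X)
  Xn <- X / sqrt(rowSums(X^2))
  recon <- p$scores %*% p$loadings + matrix(p$center, nrow(X), ncol(X), byrow = TRUE)
  expect_lt(max(abs(recon - Xn)), 1e-8)
  expect_true(all(diff(p$explained_variance_pct) <= 1e-10))
  expect_lte(sum(p$explained_variance_pct), 100 + 1e-6)
  # loadings rows orthonormal
  G <- p$loadings %*% t(p$loadings)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  # deterministic sign: largest-magnitude loading element positive
  for (i in seq_len(nrow(p$loadings)))
    expect_gt(p$loadings[i, which.max(abs(p$loadings[i, ]))], 0)
  # two samples: PC1 carries all the variance
  p2 <- fit_pca(X[1:2, ])
  expect_equal(p2$explained_variance_pct[1], 100, tolerance = 1e-8)
  Xz <- X; Xz[3, ] <- 0
  expect_error(fit_pca(Xz), "row 3")
})

test_that("PCA separates the three carotenoid complexes", {
  cfg <- synth_config()
  models <- truth_models(cfg)
  rows <- list(); labs <- list()
  for (ci in seq_along(carot_components)) {
    comp <- carot_components[ci]
    ref <- make_reference_spectrum(comp, cfg)
    for (r in 1:8) {
      m <- simulate_measurement(stats::setNames(list(1), comp), cfg,
                                seed = 300L * ci + r)
      pre <- preprocess_spectrum(m, ref, default_interferents(cfg))$spectrum
      cor_s <- correct_self_absorption(pre, models[[comp]], 1)
      rows[[length(rows) + 1L]] <- cor_s$intensity
      labs[[length(labs) + 1L]] <- data.frame(analyte = comp, concentration = 1,
                                              replicate = r)
    }
  }
  axis <- seq(400, 3100, 2)
  set <- spectrum_set(axis, do.call(rbind, rows), labels = do.call(rbind, labs))
  p <- fit_pca(set)
  expect_gt(sum(p$explained_variance_pct[1:2]), 90)
  sep <- carotRaman:::pca_class_separation(p)
  expect_gt(sep$ratio, 3)

  # pairwise PCA: beta-carotene vs lutein loading has a derivative-like
  # sign change around the shifted nu1 band
  pp <- pairwise_pca(set, c("beta_carotene", "lutein"))
  expect_gt(pp$explained_variance_pct[1], pp$explained_variance_pct[2])
  l1 <- pp$loadings[1, ]
  win <- axis >= 1450 & axis <= 1600
  expect_true(min(l1[win]) < 0 && max(l1[win]) > 0)
  expect_error(pairwise_pca(set, c("beta_carotene", "lycopene")), "not present")

  # identical classes show no separation beyond noise
  X2 <- set$matrix[set$labels$analyte == "beta_carotene", ]
  twin <- spectrum_set(axis, rbind(X2, X2),
                       labels = data.frame(analyte = rep(c("a", "b"), each = 8)))
  pt <- pairwise_pca(twin, c("a", "b"))
  cent <- rowsum(pt$scores[, 1, drop = FALSE], twin$labels$analyte) / 8
  expect_lt(abs(diff(cent[, 1])), sd(pt$scores[, 1]))
})
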