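#' PLS1 regression of concentration on spectra (NIPALS)
#'
#' Fits `Y = XB + E` for a single response by the NIPALS PLS1 algorithm:
#' latent variables are extracted to maximise the covariance between the
#' spectral matrix X and the concentration vector y, then least squares is
#' carried out on the scores. X and y are mean-centered internally.
#'
#' @param X a [spectrum_set()] of preprocessed spectra, or a numeric matrix
#'   (rows = samples).
#' @param y numeric response (concentration, mg/mL); defaults to the set's
#'   concentration labels.
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n-1, p)`.
#' @return An object of class `plsr_model` with `coefficients` (channel
#'   regression vector), `intercept`, `x_loadings`, `x_weights`, `y_loadings`,
#'   `scores`, `cum_var_y` and `cum_var_x` (cumulative % variance explained
#'   per LV), `fitted`, `n_lv`.
#' @export
fit_plsr <- function(X, y = NULL, n_lv) {
  Xm <- if (inherits(X, "spectrum_set")) X$matrix else as.matrix(X)
  if (is.null(y)) {
    if (!inherits(X, "spectrum_set")) stop("y must be supplied", call. = FALSE)
    y <- X$labels$concentration
  }
  n <- nrow(Xm); p <- ncol(Xm)
  if (length(y) != n) stop("y length must match rows of X", call. = FALSE)
  if (n_lv < 1L || n_lv > min(n - 1L, p))
    stop("n_lv must be between 1 and min(n_samples - 1, n_channels) = ",
         min(n - 1L, p), call. = FALSE)
  x_mean <- colMeans(Xm); y_mean <- mean(y)
  Xc <- sweep(Xm, 2L, x_mean); yc <- y - y_mean
  ss_x0 <- sum(Xc^2); ss_y0 <- sum(yc^2)
  W <- P <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  cum_var_x <- cum_var_y <- numeric(n_lv)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * 1e3) { # residual covariance exhausted
      W <- W[, seq_len(a - 1L), drop = FALSE]; P <- P[, seq_len(a - 1L), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1L), drop = FALSE]; q <- q[seq_len(a - 1L)]
      cum_var_x <- cum_var_x[seq_len(a - 1L)]; cum_var_y <- cum_var_y[seq_len(a - 1L)]
      n_lv <- a - 1L
      break
    }
    w <- w / nw
    t <- drop(Xd %*% w); tt <- sum(t^2)
    pvec <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
    cum_var_x[a] <- 100 * (1 - sum(Xd^2) / ss_x0)
    cum_var_y[a] <- 100 * (1 - sum(yd^2) / max(ss_y0, .Machine$double.eps))
  }
  if (n_lv == 0L) stop("X has no covariance with y", call. = FALSE)
  # B = W (P'W)^-1 q
  B <- drop(W %*% solve(crossprod(P, W), q))
  intercept <- y_mean - sum(x_mean * B)
  structure(list(coefficients = B, intercept = intercept,
                 x_weights = W, x_loadings = P, y_loadings = q, scores = Tm,
                 cum_var_x = cum_var_x, cum_var_y = cum_var_y,
                 x_mean = x_mean, y_mean = y_mean, n_lv = n_lv,
                 fitted = drop(Xm %*% B) + intercept),
            class = "plsr_model")
}

#' Predict concentrations from a PLS1 model
#'
#' @param object a `plsr_model`.
#' @param newdata numeric matrix or [spectrum_set()].
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  Xm <- if (inherits(newdata, "spectrum_set")) newdata$matrix else as.matrix(newdata)
  drop(Xm %*% object$coefficients) + object$intercept
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variables, cumulative Y-variance %.4g%%\n",
              x$n_lv, utils::tail(x$cum_var_y, 1)))
  invisible(x)
}

#' Repeated K-fold cross-validation of the PLS1 model
#'
#' For each latent-variable count 1..`n_lv_max`, samples are partitioned at
#' random into `k` near-equal folds, each fold is predicted from a model
#' trained on the others, and the partition is redrawn `repeats` times.
#' RMSECV is the root mean squared held-out error pooled over all repeats
#' and folds. Deterministic for a fixed seed.
#'
#' @param X matrix or [spectrum_set()].
#' @param y response; defaults to concentration labels.
#' @param n_lv_max largest LV count to evaluate.
#' @param k number of folds (default 10; `k = n` gives leave-one-out).
#' @param repeats number of random re-partitions (default 100).
#' @param seed RNG seed for the fold draws.
#' @return A list with `rmsecv_per_lv`, `se_per_lv` (sd of per-repeat
#'   RMSECV / sqrt(repeats)), `predictions` (n x n_lv_max matrix of
#'   CV predictions averaged over repeats), `r_squared` (squared Pearson
#'   correlation of pooled CV predictions vs y, per LV), `k`, `repeats`.
#' @export
cross_validate <- function(X, y = NULL, n_lv_max, k = 10L, repeats = 100L,
                           seed = 1L) {
  Xm <- if (inherits(X, "spectrum_set")) X$matrix else as.matrix(X)
  if (is.null(y)) y <- X$labels$concentration
  n <- nrow(Xm)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  se_acc <- matrix(0, repeats, n_lv_max)    # per-repeat MSE
  pred_sum <- matrix(0, n, n_lv_max)
  folds_all <- with_seed(seed, {
    lapply(seq_len(repeats), function(r)
      sample(rep_len(seq_len(k), n)))
  })
  for (r in seq_len(repeats)) {
    fold <- folds_all[[r]]
    pred_r <- matrix(NA_real_, n, n_lv_max)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- setdiff(seq_len(n), test)
      lv_fit <- min(n_lv_max, length(train) - 1L, ncol(Xm))
      m <- fit_plsr(Xm[train, , drop = FALSE], y[train], n_lv = lv_fit)
      for (a in seq_len(n_lv_max)) {
        aa <- min(a, m$n_lv)
        Ba <- drop(m$x_weights[, seq_len(aa), drop = FALSE] %*%
                     solve(crossprod(m$x_loadings[, seq_len(aa), drop = FALSE],
                                     m$x_weights[, seq_len(aa), drop = FALSE]),
                           m$y_loadings[seq_len(aa)]))
        ia <- m$y_mean - sum(m$x_mean * Ba)
        pred_r[test, a] <- drop(Xm[test, , drop = FALSE] %*% Ba) + ia
      }
    }
    se_acc[r, ] <- colMeans((pred_r - y)^2)
    pred_sum <- pred_sum + pred_r
  }
  rmsecv <- sqrt(colMeans(se_acc))
  pred_mean <- pred_sum / repeats
  r2 <- apply(pred_mean, 2L, function(p) stats::cor(p, y)^2)
  list(rmsecv_per_lv = rmsecv,
       se_per_lv = apply(sqrt(se_acc), 2L, stats::sd) / sqrt(repeats),
       predictions = pred_mean, r_squared = r2, k = k, repeats = repeats)
}

#' Choose the number of latent variables
#'
#' Policies: `"variance_saturation"` returns the first LV whose cumulative
#' explained variance reaches 99.9%; `"rmsecv_min"` applies a one-standard-
#' error-style rule, returning the smallest LV whose RMSECV is within one
#' standard error (if supplied) or 0.1% of the minimum. When every RMSECV is
#' numerically negligible the first LV is returned.
#'
#' @param cumulative_variance % per LV (non-decreasing).
#' @param rmsecv_per_lv RMSECV per LV.
#' @param policy `"variance_saturation"` or `"rmsecv_min"`.
#' @param se_per_lv optional standard errors for the 1-SE rule.
#' @return Integer LV count.
#' @export
select_n_lv <- function(cumulative_variance = NULL, rmsecv_per_lv = NULL,
                        policy = c("variance_saturation", "rmsecv_min"),
                        se_per_lv = NULL) {
  policy <- match.arg(policy)
  if (policy == "variance_saturation") {
    if (is.null(cumulative_variance) || !length(cumulative_variance))
      stop("cumulative_variance required", call. = FALSE)
    i <- which(cumulative_variance >= 99.9)
    return(if (length(i)) min(i) else length(cumulative_variance))
  }
  if (is.null(rmsecv_per_lv) || !length(rmsecv_per_lv))
    stop("rmsecv_per_lv required", call. = FALSE)
  m <- min(rmsecv_per_lv)
  scale <- max(rmsecv_per_lv)
  if (m <= 1e-10 * max(scale, 1)) return(min(which(rmsecv_per_lv <= 1e-8 * max(scale, 1))))
  thr <- m + if (!is.null(se_per_lv)) se_per_lv[which.min(rmsecv_per_lv)] else 1e-3 * m
  min(which(rmsecv_per_lv <= thr))
}

#' Limit of detection from RMSECV
#'
#' `LOD = 3.3 * RMSECV`; with RMSECV = 0.0032 mg/mL this gives
#' 0.01056 mg/mL (0.0106 to display precision).
#'
#' @param rmsecv RMSECV in mg/mL (>= 0).
#' @return LOD in mg/mL.
#' @export
lod <- function(rmsecv) {
  if (any(rmsecv < 0)) stop("rmsecv must be >= 0", call. = FALSE)
  3.3 * rmsecv
}

#' Principal components analysis of a spectrum set
#'
#' Each spectrum is scaled to unit Euclidean norm (vector normalization,
#' when `vector_normalize = TRUE`), columns are mean-centered, and the
#' centered matrix is decomposed by SVD. Loading signs are fixed by making
#' each component's largest-magnitude element positive, so score plots are
#' reproducible.
#'
#' @param X a [spectrum_set()] or numeric matrix (rows = samples).
#' @param vector_normalize scale rows to unit norm first (default TRUE).
#' @param n_pc number of components to keep (default all).
#' @return An object of class `pca_result`: `scores` (n x n_pc),
#'   `loadings` (n_pc x n_channels, orthonormal rows),
#'   `explained_variance_pct`, `center`, `labels`.
#' @export
fit_pca <- function(X, vector_normalize = TRUE, n_pc = NULL) {
  labels <- if (inherits(X, "spectrum_set")) X$labels else NULL
  Xm <- if (inherits(X, "spectrum_set")) X$matrix else as.matrix(X)
  if (nrow(Xm) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (vector_normalize) {
    nr <- sqrt(rowSums(Xm^2))
    if (any(nr == 0))
      stop("row ", which(nr == 0)[1], " has zero norm; cannot vector-normalise",
           call. = FALSE)
    Xm <- Xm / nr
  }
  center <- colMeans(Xm)
  Xc <- sweep(Xm, 2L, center)
  sv <- svd(Xc)
  keep <- min(n_pc %||% length(sv$d), sum(sv$d > sv$d[1] * 1e-12), length(sv$d))
  keep <- max(keep, 1L)
  d <- sv$d[seq_len(keep)]
  load <- t(sv$v[, seq_len(keep), drop = FALSE])   # n_pc x p
  scores <- sv$u[, seq_len(keep), drop = FALSE] %*% diag(d, keep)
  flip <- apply(load, 1L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- load * flip
  scores <- sweep(scores, 2L, flip, `*`)
  structure(list(scores = scores, loadings = load,
                 explained_variance_pct = 100 * sv$d^2 / sum(sv$d^2),
                 center = center, labels = labels,
                 vector_normalized = vector_normalize),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$explained_variance_pct
  cat(sprintf("<pca_result> %d scores x %d PCs; PC1 %.2f%%, PC2 %s%%\n",
              nrow(x$scores), ncol(x$scores), ev[1],
              if (length(ev) > 1) sprintf("%.2f", ev[2]) else "-"))
  invisible(x)
}

#' Pairwise PCA restricted to two analyte classes
#'
#' @param X a [spectrum_set()] with analyte labels.
#' @param pair character vector of two analyte names present in the labels.
#' @param vector_normalize as in [fit_pca()].
#' @return A `pca_result` for the subset.
#' @export
pairwise_pca <- function(X, pair, vector_normalize = TRUE) {
  stopifnot(inherits(X, "spectrum_set"), length(pair) == 2L)
  present <- pair %in% X$labels$analyte
  if (!all(present))
    stop("analyte '", pair[!present][1], "' not present in the set", call. = FALSE)
  keep <- X$labels$analyte %in% pair
  sub <- spectrum_set(X$axis, X$matrix[keep, , drop = FALSE],
                      labels = X$labels[keep, , drop = FALSE],
                      axis_kind = X$axis_kind, meta = X$meta)
  fit_pca(sub, vector_normalize = vector_normalize)
}
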