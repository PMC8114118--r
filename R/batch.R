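#' Empirical-Bayes location/scale batch correction
#'
#' Removes additive (location) and multiplicative (scale) batch effects
#' from a feature-by-sample matrix under the model
#' `Y_wsk = alpha_k + X beta_k + gamma_wk + delta_wk * eps_wsk`,
#' shrinking the per-batch, per-feature location and scale estimates
#' towards their across-feature priors by empirical Bayes before removing
#' them. With a single batch the input is returned unchanged (there is
#' nothing to correct).
#'
#' Steps: (1) per-feature least squares of Y on batch indicators plus the
#' covariates `X` to be preserved; the grand effect `alpha_k` is the
#' batch-size-weighted mean of the batch means, and `sigma_k` the pooled
#' residual sd; (2) standardise `Z = (Y - alpha_k - X beta_k)/sigma_k`;
#' (3) estimate batch locations `gamma_wk` (batch means of Z) and scales
#' `delta2_wk` (batch variances), then shrink them — parametric mode places
#' a normal prior on gamma and an inverse-gamma prior on delta2 with
#' method-of-moments hyperparameters and iterates the coupled posterior
#' updates to convergence; nonparametric mode uses likelihood-weighted
#' averages across the other features; (4) adjust
#' `(sigma_k/delta*_wk) * (Z - gamma*_wk) + alpha_k + X beta_k`.
#'
#' @param mat feature-by-sample matrix.
#' @param batch vector of batch labels, one per column of `mat`.
#' @param design optional numeric matrix of covariates to preserve
#'   (samples x covariates), without intercept.
#' @param mode `"parametric"` (default) or `"nonparametric"`.
#' @param mean_only adjust locations only, leave scales untouched (for
#'   very small batches).
#' @param tol,max_iter convergence control of the parametric EB iteration.
#' @return A list with `model` (class `"batch_model"`: hyperparameters,
#'   `gamma_hat`/`delta2_hat`, posteriors `gamma_star`/`delta2_star`,
#'   `alpha`, `beta`, `sigma`, `mode`) and `matrix`, the adjusted matrix.
#' @export
combat_adjust <- function(mat, batch, design = NULL,
                          mode = c("parametric", "nonparametric"),
                          mean_only = FALSE, tol = 1e-4, max_iter = 200L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat))
  batch <- as.factor(batch)
  if (length(batch) != ncol(mat))
    stop("one batch label per sample required")
  b <- nlevels(batch)
  if (b == 1L)
    return(list(model = structure(list(batches = levels(batch), mode = mode,
                                       note = "single batch: identity"),
                                  class = "batch_model"),
                matrix = mat))
  n_w <- table(batch)
  if (any(n_w == 1L)) {
    if (mode == "nonparametric")
      stop("nonparametric mode needs >= 2 samples per batch ",
           "(within-batch variance undefined)")
    if (!mean_only)
      stop("batch(es) of size 1 (", paste(names(n_w)[n_w == 1L],
           collapse = ", "), "): use mean_only = TRUE")
  }

  cc <- stats::complete.cases(mat)
  if (!all(cc)) {
    warning(sum(!cc), " feature(s) with missing values left unadjusted")
    res <- combat_adjust(mat[cc, , drop = FALSE], batch, design = design,
                         mode = mode, mean_only = mean_only, tol = tol,
                         max_iter = max_iter)
    out <- mat
    out[cc, ] <- res$matrix
    return(list(model = res$model, matrix = out))
  }

  N <- ncol(mat); K <- nrow(mat)
  Bm <- stats::model.matrix(~ 0 + batch)
  if (!is.null(design)) {
    design <- as.matrix(design)
    D <- cbind(Bm, design)
    if (qr(D)$rank < ncol(D))
      stop("design is confounded with batch (singular combined design)")
  } else D <- Bm
  q <- ncol(D) - b

  # per-feature least squares on the combined design
  Bhat <- solve(crossprod(D), t(D) %*% t(mat))        # (b+q) x K
  alpha <- drop((as.numeric(n_w) / N) %*% Bhat[seq_len(b), , drop = FALSE])
  covar_part <- if (q > 0)
    t(D[, -seq_len(b), drop = FALSE] %*%
        Bhat[-seq_len(b), , drop = FALSE]) else matrix(0, K, N)
  fitted <- t(D %*% Bhat)
  sigma2 <- rowMeans((mat - fitted)^2)                 # pooled, 1/N

  zero_var <- sigma2 <= .Machine$double.eps
  if (any(zero_var))
    warning(sum(zero_var), " feature(s) with zero pooled variance left ",
            "unadjusted")
  stand_mean <- alpha + covar_part
  Z <- (mat - stand_mean) / sqrt(sigma2)
  Z[zero_var, ] <- 0

  idx_w <- split(seq_len(N), batch)
  gamma_hat <- t(vapply(idx_w, function(i)
    rowMeans(Z[, i, drop = FALSE]), numeric(K)))
  delta2_hat <- t(vapply(idx_w, function(i) {
    if (length(i) < 2L) rep(1, K)
    else apply(Z[, i, drop = FALSE], 1L, stats::var)
  }, numeric(K)))
  delta2_hat[delta2_hat <= 0] <- 1e-8

  if (mode == "parametric") {
    gamma_bar <- rowMeans(gamma_hat)
    tau2 <- apply(gamma_hat, 1L, stats::var)
    vbar <- rowMeans(delta2_hat)
    s2 <- apply(delta2_hat, 1L, stats::var)
    lambda <- (2 * s2 + vbar^2) / s2
    theta <- (vbar * s2 + vbar^3) / s2

    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (w in seq_len(b)) {
      nw <- length(idx_w[[w]])
      g_old <- gamma_hat[w, ]; d_old <- delta2_hat[w, ]
      for (it in seq_len(max_iter)) {
        g_new <- (tau2[w] * nw * gamma_hat[w, ] + d_old * gamma_bar[w]) /
          (tau2[w] * nw + d_old)
        sum2 <- rowSums((Z[, idx_w[[w]], drop = FALSE] - g_new)^2)
        d_new <- if (mean_only) rep(1, K)
          else (0.5 * sum2 + theta[w]) / (nw / 2 + lambda[w] - 1)
        ch <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                  abs(d_new - d_old) / pmax(d_old, 1e-8))
        g_old <- g_new; d_old <- d_new
        if (ch < tol) break
      }
      if (it == max_iter)
        warning("EB iteration for batch ", levels(batch)[w],
                " stopped at max_iter")
      gamma_star[w, ] <- g_old
      delta2_star[w, ] <- d_old
    }
    hyper <- list(gamma_bar = gamma_bar, tau2 = tau2, lambda = lambda,
                  theta = theta)
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (w in seq_len(b)) {
      Zw <- Z[, idx_w[[w]], drop = FALSE]
      nw <- ncol(Zw)
      for (k in seq_len(K)) {
        j <- setdiff(seq_len(K), k)
        g <- gamma_hat[w, j]; d2 <- delta2_hat[w, j]
        LH <- vapply(seq_along(j), function(m)
          prod(stats::dnorm(Zw[k, ], g[m], sqrt(d2[m]))), 0)
        if (sum(LH) <= 0) next                # keep raw estimates
        gamma_star[w, k] <- sum(g * LH) / sum(LH)
        delta2_star[w, k] <- sum(d2 * LH) / sum(LH)
      }
    }
    if (mean_only) delta2_star[] <- 1
    hyper <- NULL
  }

  adj <- Z
  for (w in seq_len(b)) {
    i <- idx_w[[w]]
    adj[, i] <- (Z[, i, drop = FALSE] - gamma_star[w, ]) /
      sqrt(delta2_star[w, ])
  }
  out <- adj * sqrt(sigma2) + stand_mean
  out[zero_var, ] <- mat[zero_var, , drop = FALSE]

  model <- structure(list(batches = levels(batch), n = as.numeric(n_w),
                          alpha = alpha, sigma = sqrt(sigma2),
                          gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                          gamma_star = gamma_star,
                          delta2_star = delta2_star,
                          hyper = hyper, mode = mode,
                          mean_only = mean_only),
                     class = "batch_model")
  list(model = model, matrix = out)
}

#' Batch-effect diagnostics: PCA and sample distances
#'
#' @param mat feature-by-sample matrix (>= 3 samples).
#' @param batch batch labels, one per sample.
#' @param n_components number of principal components to return
#'   (default 2, capped by the data rank).
#' @return A list with `scores` (data frame: sample, batch, PC columns),
#'   `variance_explained` (percent per component), `dist` (sample distance
#'   matrix for hierarchical clustering) and `batch_feature_means`
#'   (batch x feature matrix).
#' @export
batch_diagnostics <- function(mat, batch, n_components = 2L) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 3L) stop("batch diagnostics need at least 3 samples")
  batch <- as.factor(batch)
  cc <- stats::complete.cases(mat)
  X <- t(mat[cc, , drop = FALSE])
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  scores <- data.frame(sample = colnames(mat), batch = batch,
                       pc$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
  bfm <- t(vapply(split(seq_len(ncol(mat)), batch), function(i)
    rowMeans(mat[, i, drop = FALSE], na.rm = TRUE), numeric(nrow(mat))))
  list(scores = scores, variance_explained = ve[seq_len(k)],
       dist = stats::dist(X), batch_feature_means = bfm)
}

#' Between/within batch variance ratio of a principal component
#'
#' A scalar summary of how strongly a component separates batches: the
#' variance of the per-batch mean scores divided by the pooled within-batch
#' variance.
#'
#' @param diagnostics result of [batch_diagnostics()].
#' @param component component name (default `"PC1"`).
#' @return The ratio.
#' @export
pc_batch_ratio <- function(diagnostics, component = "PC1") {
  sc <- diagnostics$scores
  x <- sc[[component]]
  g <- split(x, sc$batch)
  between <- stats::var(vapply(g, mean, 0))
  within <- mean(vapply(g, stats::var, 0))
  between / within
}
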