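#' Log2 normalisation with a background-level offset
#'
#' Transforms each value y to log2(y - alpha_hat), where `alpha_hat` is an
#' estimate of the median background level (0 for background-corrected
#' data). Values at or below `alpha_hat` are undefined on the log scale and
#' become missing; their count is attached as attribute `n_undefined`.
#'
#' @param mat feature-by-sample matrix.
#' @param alpha_hat background-level estimate (default 0).
#' @return The transformed matrix with attribute `n_undefined`.
#' @export
normalize_log2 <- function(mat, alpha_hat = 0) {
  stopifnot(is.matrix(mat))
  d <- mat - alpha_hat
  und <- !is.na(d) & d <= 0
  if (all(und | is.na(d)))
    stop("no value exceeds alpha_hat; log2 transform undefined everywhere")
  d[und] <- NA_real_
  out <- log2(d)
  attr(out, "n_undefined") <- sum(und)
  out
}

#' MA transform of two arrays and its inverse
#'
#' For single-channel arrays compared pairwise, M = log2(y1/y2) is the
#' log-difference and A = 0.5 * log2(y1*y2) the average log-intensity. The
#' inverse reconstructs y1 = 2^(A + M/2), y2 = 2^(A - M/2).
#'
#' @param y1,y2 positive intensity vectors of equal length.
#' @return `ma_transform`: list with `M`, `A`. `ma_inverse`: list with
#'   `y1`, `y2`.
#' @export
ma_transform <- function(y1, y2) {
  if (length(y1) != length(y2)) stop("y1 and y2 must have equal length")
  if (any(y1 <= 0 | y2 <= 0, na.rm = TRUE))
    stop("MA transform needs strictly positive intensities")
  list(M = log2(y1 / y2), A = 0.5 * log2(y1 * y2))
}

#' @rdname ma_transform
#' @param M,A log-difference and average log-intensity vectors.
#' @export
ma_inverse <- function(M, A) {
  list(y1 = 2^(A + M / 2), y2 = 2^(A - M / 2))
}

#' Native tricube-weighted local regression smoother
#'
#' Local polynomial (default local linear) regression with tricube kernel
#' weights over the `span` fraction of nearest neighbours, and optional
#' robustness iterations that downweight outlying residuals by Tukey's
#' bisquare — the classic LOWESS scheme.
#'
#' @param x,y data.
#' @param span fraction of points in each local neighbourhood (default
#'   0.7).
#' @param degree local polynomial degree, 1 or 2 (default 1).
#' @param iterations robustness iterations (default 3; 0 = plain fit).
#' @param eval_at points at which to evaluate the smoother (default `x`).
#' @return Fitted values at `eval_at`.
#' @export
tricube_loess <- function(x, y, span = 0.7, degree = 1L, iterations = 3L,
                          eval_at = x) {
  ok <- is.finite(x) & is.finite(y)
  x0 <- x[ok]; y0 <- y[ok]
  n <- length(x0)
  if (n < degree + 2L) stop("too few points for loess fit")
  k <- max(degree + 2L, ceiling(span * n))
  k <- min(k, n)

  fit_at <- function(t, rw) {
    d <- abs(x0 - t)
    h <- sort(d, partial = k)[k]
    if (h <= 0) h <- max(d, .Machine$double.eps)
    w <- (1 - pmin(d / h, 1)^3)^3 * rw
    use <- w > 0
    if (sum(use) <= degree) return(sum(w * y0) / sum(w))
    X <- outer(x0[use] - t, 0:degree, `^`)
    fit <- stats::lm.wfit(X, y0[use], w[use])
    fit$coefficients[[1L]]
  }

  rw <- rep(1, n)
  for (it in seq_len(iterations + 1L)) {
    yhat <- vapply(x0, fit_at, 0, rw = rw)
    if (it > iterations) break
    res <- y0 - yhat
    s <- stats::median(abs(res))
    if (s <= 0) break
    rw <- (1 - pmin(abs(res) / (6 * s), 1)^2)^2
  }
  vapply(eval_at, fit_at, 0, rw = rw)
}

#' Pairwise cyclic loess normalisation
#'
#' Removes intensity-dependent differences between arrays: for every
#' distinct pair of arrays a loess curve is fitted to the MA scatter and
#' half of the centred correction is applied to each array of the pair;
#' the full sweep over pairs is repeated `n_cycles` times. Identical arrays
#' are an exact fixed point. The input may be raw (positive) intensities or
#' already log2-transformed values (`input_scale`).
#'
#' @param mat feature-by-sample matrix (>= 2 arrays); strictly positive if
#'   `input_scale = "raw"`.
#' @param span,degree,iterations loess parameters, see [tricube_loess()].
#' @param n_cycles number of sweeps over all pairs (default 3).
#' @param input_scale `"raw"` or `"log2"`.
#' @return Normalised matrix on the input scale.
#' @export
normalize_cyclic_loess <- function(mat, span = 0.7, degree = 1L,
                                   iterations = 3L, n_cycles = 3L,
                                   input_scale = c("raw", "log2")) {
  stopifnot(is.matrix(mat))
  input_scale <- match.arg(input_scale)
  if (ncol(mat) < 2L) stop("cyclic loess needs at least 2 arrays")
  x <- if (input_scale == "raw") {
    if (any(mat <= 0, na.rm = TRUE))
      stop("raw-scale cyclic loess needs strictly positive intensities")
    log2(mat)
  } else mat

  for (cyc in seq_len(n_cycles)) {
    for (i in seq_len(ncol(x) - 1L)) {
      for (j in seq((i + 1L), ncol(x))) {
        ok <- is.finite(x[, i]) & is.finite(x[, j])
        if (sum(ok) < 5L) next
        M <- x[ok, i] - x[ok, j]
        A <- (x[ok, i] + x[ok, j]) / 2
        if (all(abs(M) < 1e-12)) next          # identical: exact fixed point
        mhat <- tricube_loess(A, M, span = span, degree = degree,
                              iterations = iterations)
        x[ok, i] <- x[ok, i] - mhat / 2
        x[ok, j] <- x[ok, j] + mhat / 2
      }
    }
  }
  if (input_scale == "raw") 2^x else x
}

#' Huber-weighted iteratively reweighted least squares
#'
#' @param X design matrix, `y` response, `k` Huber tuning constant,
#'   `max_iter`/`tol` iteration control. Scale is re-estimated each
#'   iteration by the MAD of the residuals.
#' @return list with `coefficients`, `scale`, `weights`, `converged`,
#'   `iterations`.
#' @keywords internal
.huber_irls <- function(X, y, k = 1.345, max_iter = 50L, tol = 1e-6) {
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  converged <- FALSE
  w <- rep(1, length(y))
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- stats::mad(r, center = 0)
    if (s <= .Machine$double.eps) { converged <- TRUE; break }
    u <- abs(r) / s
    w <- ifelse(u <= k, 1, k / u)
    fit <- stats::lm.wfit(X, y, w)
    newb <- fit$coefficients
    newb[is.na(newb)] <- 0
    if (max(abs(newb - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- newb; converged <- TRUE; break
    }
    beta <- newb
  }
  list(coefficients = beta, scale = s, weights = w, converged = converged,
       iterations = it)
}

#' Robust linear model normalisation on control spots
#'
#' Control features (e.g. human IgG/IgM) are printed on every mini-array
#' and should yield constant signal; any systematic departure measures
#' technical slide and block effects. The model
#' `log2 y = intercept + slide_i + block_j + protein_k + error`
#' is fitted to the control values by iteratively reweighted least squares
#' with Huber weights under sum-to-zero constraints on each factor, and the
#' estimated `slide_i + block_j` is then subtracted from every value on
#' that slide/block — controls and antigens alike. Within-(slide, block)
#' contrasts between features are left exactly unchanged.
#'
#' @param mat feature-by-sample matrix on the log2 scale (negative raw
#'   signals must have been replaced upstream, e.g. by the half moving
#'   minimum policy, before logging).
#' @param sample_info data frame with columns `sample`, `slide`, `block`
#'   (one row per column of `mat`; `block` is the block or block-group
#'   label the sample occupies).
#' @param controls character vector of control feature names present in
#'   `mat` on every slide.
#' @param huber_k Huber tuning constant (default 1.345).
#' @param max_iter,tol IRLS iteration control.
#' @return A list with `fit` (class `"rlm_fit"`: `alpha` slide effects,
#'   `beta` block effects, `tau` control-feature effects, `intercept`,
#'   `scale`, `converged`) and `matrix`, the adjusted matrix.
#' @export
normalize_rlm <- function(mat, sample_info, controls, huber_k = 1.345,
                          max_iter = 50L, tol = 1e-6) {
  stopifnot(is.matrix(mat), is.data.frame(sample_info))
  if (!all(c("sample", "slide", "block") %in% names(sample_info)))
    stop("sample_info needs columns sample, slide, block")
  if (!all(colnames(mat) %in% sample_info$sample))
    stop("every matrix column must appear in sample_info")
  si <- sample_info[match(colnames(mat), sample_info$sample), ]
  controls <- intersect(controls, rownames(mat))
  if (!length(controls)) stop("no control features found in matrix")

  cm <- mat[controls, , drop = FALSE]
  long <- data.frame(
    y = as.vector(cm),
    slide = factor(rep(si$slide, each = length(controls))),
    block = factor(rep(si$block, each = length(controls))),
    protein = factor(rep(controls, times = ncol(cm))))
  long <- long[is.finite(long$y), , drop = FALSE]
  for (s in levels(long$slide))
    if (!s %in% unique(long$slide))
      stop("no usable control values on slide ", s)
  if (stats::sd(long$y) == 0)
    stop("control values are constant/saturated; RLM normalisation needs ",
         "informative controls (avoid saturation)")

  ctr <- function(f) if (nlevels(f) > 1L)
    stats::contr.sum(nlevels(f)) else matrix(0, 1L, 0L)
  Xs <- ctr(long$slide)[as.integer(long$slide), , drop = FALSE]
  Xb <- ctr(long$block)[as.integer(long$block), , drop = FALSE]
  Xp <- ctr(long$protein)[as.integer(long$protein), , drop = FALSE]
  X <- cbind(1, Xs, Xb, Xp)

  fit <- .huber_irls(X, long$y, k = huber_k, max_iter = max_iter, tol = tol)
  if (!fit$converged)
    warning("RLM IRLS did not converge in ", max_iter, " iterations")

  unpack <- function(f, cf) {
    if (nlevels(f) > 1L) {
      eff <- drop(ctr(f) %*% cf)
    } else eff <- 0
    stats::setNames(eff, levels(f))
  }
  p <- fit$coefficients
  ns <- ncol(Xs); nb <- ncol(Xb)
  alpha <- unpack(long$slide, p[seq_len(ns) + 1L])
  beta <- unpack(long$block, p[seq_len(nb) + 1L + ns])
  tau <- unpack(long$protein, p[-(seq_len(1L + ns + nb))])

  adj <- alpha[as.character(si$slide)] + beta[as.character(si$block)]
  out <- sweep(mat, 2L, adj, `-`)
  list(fit = structure(list(intercept = p[[1L]], alpha = alpha, beta = beta,
                            tau = tau, scale = fit$scale,
                            converged = fit$converged,
                            iterations = fit$iterations),
                       class = "rlm_fit"),
       matrix = out)
}

#' Generalised log2 transform
#'
#' glog2(u) = log2(u + sqrt(u^2 + 1)) = arsinh(u)/ln 2. Defined for all
#' real u (odd, strictly increasing), and asymptotically equal to
#' log2(2u) for large u.
#'
#' @param u numeric.
#' @return glog2(u).
#' @export
glog2 <- function(u) asinh(u) / log(2)

# h-transform of one array: glog2((y - a)/b)
.vsn_h <- function(y, a, b) glog2((y - a) / b)

# profiled negative log-likelihood of the VSN model:
# h_ik ~ N(mu_k, s2) with common s2; mu_k profiled as the per-feature mean,
# s2 as the mean residual square; the Jacobian of h enters per observation.
.vsn_nll <- function(par, mat, fixed_a) {
  n <- ncol(mat)
  if (fixed_a) { a <- rep(0, n); b <- exp(par) }
  else { a <- par[seq_len(n)]; b <- exp(par[-seq_len(n)]) }
  u <- sweep(sweep(mat, 2L, a, `-`), 2L, b, `/`)
  h <- asinh(u) / log(2)
  # log |dh/dy| = -log(b) - log(sqrt(u^2+1)) - log(log(2))
  ljac <- sweep(-0.5 * log1p(u^2), 2L, log(b), `-`) - log(log(2))
  mu <- rowMeans(h, na.rm = TRUE)
  res <- h - mu
  rss <- sum(res^2, na.rm = TRUE)
  N <- sum(!is.na(h))
  s2 <- max(rss / N, 1e-12)
  0.5 * N * log(s2) + 0.5 * rss / s2 - sum(ljac, na.rm = TRUE)
}

#' Variance-stabilising normalisation (generalised-log transform)
#'
#' Fits, per array i, the transformation h(y) = glog2((y - a_i)/b_i) under
#' the two-component error model in which intensities carry a
#' multiplicative error at high signal and an additive error near zero, so
#' that the variance of h(y) is approximately independent of its mean.
#' Estimation is by a robust trimmed maximum-likelihood criterion:
#' h-transformed values are modelled as normal per feature with a common
#' variance, per-feature means are profiled out and the Jacobian of h is
#' included. Robustness uses concentration steps: after an initial fit on
#' all features, the `trim` fraction with the largest residual sum of
#' squares is set aside and the likelihood re-maximised on the retained
#' features, repeated until the retained set stabilises (at most 5
#' rounds). Trimming inside one joint objective would couple the subset
#' choice to the scale estimate and bias the b_i upwards; selecting
#' outliers against the previous fit avoids that. b_i > 0 is enforced by
#' optimising its logarithm; for background-corrected input the offsets
#' a_i are fixed at 0. Two optimiser starts guard against local minima;
#' the fit is deterministic.
#'
#' @param mat feature-by-sample matrix (>= 2 arrays, >= 20 features with
#'   at least 2 observed values); negative entries are allowed, missing
#'   cells stay missing.
#' @param background_corrected if TRUE (default), fix a_i = 0.
#' @param trim trimmed fraction of features (default 0.1).
#' @return A list with `fit` (class `"vsn_fit"`: `a`, `b`, `sigma_h` the
#'   residual sd on the h scale, `convergence`, `value`) and `matrix`, the
#'   h-transformed matrix.
#' @export
normalize_vsn <- function(mat, background_corrected = TRUE, trim = 0.1) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) stop("VSN needs at least 2 arrays")
  if (nrow(mat) < 20L) stop("VSN needs at least 20 features")
  cc <- rowSums(is.finite(mat)) >= 2L   # features usable in the fit
  if (sum(cc) < 20L)
    stop("fewer than 20 features with >= 2 observed values")
  work <- mat[cc, , drop = FALSE]
  n <- ncol(work)

  # moment-based starts: b ~ per-array spread; second start scaled down to
  # probe the low-intensity curvature regime
  spread <- apply(work, 2L, function(x) stats::mad(x, na.rm = TRUE))
  spread[!is.finite(spread)] <- 1
  spread[spread <= 0] <- 1
  starts <- list(log(spread), log(spread / 10))
  if (!background_corrected) {
    med <- apply(work, 2L, stats::median, na.rm = TRUE)
    starts <- lapply(starts, function(s) c(pmin(med, 0), s))
  }

  run_opt <- function(par, m) stats::optim(
    par, .vsn_nll, mat = m, fixed_a = background_corrected,
    method = "BFGS", control = list(maxit = 500, reltol = 1e-10))

  best <- NULL
  for (st in starts) {
    fit <- run_opt(st, work)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!best$convergence %in% c(0L, 1L))
    stop("VSN optimiser failed to converge (code ", best$convergence, ")")

  # concentration steps: re-select the low-residual feature set under the
  # current fit and re-maximise on it
  keep_old <- integer()
  if (trim > 0) {
    k <- max(2L, floor((1 - trim) * nrow(work)))
    for (round in seq_len(5L)) {
      par <- best$par
      aa <- if (background_corrected) rep(0, n) else par[seq_len(n)]
      bb <- if (background_corrected) exp(par) else exp(par[-seq_len(n)])
      hh <- asinh(sweep(sweep(work, 2L, aa, `-`), 2L, bb, `/`)) / log(2)
      msr <- rowSums((hh - rowMeans(hh, na.rm = TRUE))^2, na.rm = TRUE) /
        pmax(rowSums(!is.na(hh)) - 1L, 1L)
      keep <- sort(order(msr)[seq_len(k)])
      if (identical(keep, keep_old)) break
      keep_old <- keep
      best <- run_opt(best$par, work[keep, , drop = FALSE])
    }
  }

  if (background_corrected) {
    a <- stats::setNames(rep(0, n), colnames(mat))
    b <- exp(best$par)
  } else {
    a <- best$par[seq_len(n)]
    b <- exp(best$par[-seq_len(n)])
  }
  names(a) <- names(b) <- colnames(mat)

  h <- mat
  for (j in seq_len(n)) h[, j] <- .vsn_h(mat[, j], a[j], b[j])
  hm <- rowMeans(h[cc, , drop = FALSE], na.rm = TRUE)
  sigma_h <- sqrt(mean((h[cc, ] - hm)^2, na.rm = TRUE))
  list(fit = structure(list(a = a, b = b, sigma_h = sigma_h,
                            convergence = best$convergence,
                            value = best$value),
                       class = "vsn_fit"),
       matrix = h)
}
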