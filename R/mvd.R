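#' Mean-sd profile of a feature-by-sample matrix
#'
#' For each feature, the mean and sd across samples; features are ordered
#' by their mean rank and a running median of the sd over a centred window
#' of `ceiling(window_fraction * K)` features gives the smoothed meanSd
#' profile used to judge mean-variance dependence.
#'
#' @param mat feature-by-sample matrix (>= 2 samples).
#' @param window_fraction window width as a fraction of the number of
#'   features (default 0.1).
#' @return Data frame, one row per feature with >= 2 observations, ordered
#'   by mean rank: `feature`, `mean`, `sd`, `running_sd`.
#' @export
mean_sd_profile <- function(mat, window_fraction = 0.1) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) stop("mean-sd profile needs at least 2 samples")
  n_obs <- rowSums(is.finite(mat))
  use <- n_obs >= 2L
  m <- rowMeans(mat[use, , drop = FALSE], na.rm = TRUE)
  s <- apply(mat[use, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  o <- order(m)
  K <- length(o)
  w <- max(1L, ceiling(window_fraction * K))
  half <- w %/% 2L
  run <- vapply(seq_len(K), function(i) {
    lo <- max(1L, i - half); hi <- min(K, i + half)
    stats::median(s[o][lo:hi])
  }, 0)
  data.frame(feature = rownames(mat)[use][o], mean = m[o], sd = s[o],
             running_sd = run, row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation between per-feature means and sds
#'
#' The headline mean-variance-dependence statistic: rank correlation (ties
#' mid-ranked) between the feature means and feature sds. Values near 1
#' indicate strong dependence of the spread on the signal level; successful
#' variance stabilisation drives it towards 0.
#'
#' @param mat feature-by-sample matrix (>= 3 features, >= 2 samples).
#' @return A list with `rho` (`NA` when means or sds are constant) and
#'   `tie_flag`.
#' @export
spearman_mvd <- function(mat) {
  stopifnot(is.matrix(mat))
  use <- rowSums(is.finite(mat)) >= 2L
  if (sum(use) < 3L) stop("Spearman MVD needs at least 3 features")
  m <- rowMeans(mat[use, , drop = FALSE], na.rm = TRUE)
  s <- apply(mat[use, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  if (length(unique(m)) < 2L || length(unique(s)) < 2L)
    return(list(rho = NA_real_, tie_flag = TRUE))
  list(rho = stats::cor(m, s, method = "spearman"), tie_flag = FALSE)
}

#' Cox-Stuart and Mann-Kendall trend tests
#'
#' * Cox-Stuart: pairs x_t with x_(t + ceiling(n/2)), counts the signs of
#'   the differences and tests them against Binomial(n_pairs, 1/2) with an
#'   exact two-sided binomial test.
#' * Mann-Kendall: S is the sum of signs over all pairs i < j; the variance
#'   uses the tie correction, and a normal approximation with continuity
#'   correction gives the two-sided p-value.
#'
#' An all-tied sequence returns statistic 0 and p = 1.
#'
#' @param x ordered numeric sequence (length >= 5 for Cox-Stuart, >= 4 for
#'   Mann-Kendall).
#' @param method `"mann_kendall"` (default) or `"cox_stuart"`.
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return A list with `method`, `statistic`, `p_value` (plus `n_pairs`
#'   for Cox-Stuart).
#' @export
trend_test <- function(x, method = c("mann_kendall", "cox_stuart"),
                       alternative = c("two.sided", "increasing",
                                       "decreasing")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  n <- length(x)

  if (method == "cox_stuart") {
    if (n < 5L) stop("Cox-Stuart needs at least 5 values")
    lag <- ceiling(n / 2)
    d <- x[seq_len(n - lag) + lag] - x[seq_len(n - lag)]
    d <- d[d != 0]
    if (!length(d))
      return(list(method = method, statistic = 0, p_value = 1,
                  n_pairs = 0L))
    pos <- sum(d > 0)
    alt <- switch(alternative, two.sided = "two.sided",
                  increasing = "greater", decreasing = "less")
    p <- stats::binom.test(pos, length(d), p = 0.5,
                           alternative = alt)$p.value
    return(list(method = method, statistic = pos, p_value = p,
                n_pairs = length(d)))
  }

  if (n < 4L) stop("Mann-Kendall needs at least 4 values")
  S <- sum(sign(outer(x, x, `-`))[lower.tri(matrix(0, n, n))])
  ties <- table(x)
  ties <- ties[ties > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (varS <= 0 || S == 0) {
    z <- 0
  } else {
    z <- (S - sign(S)) / sqrt(varS)   # continuity correction
  }
  p <- switch(alternative,
              two.sided = if (z == 0 && S == 0) 1 else
                2 * stats::pnorm(-abs(z)),
              increasing = stats::pnorm(z, lower.tail = FALSE),
              decreasing = stats::pnorm(z))
  list(method = method, statistic = S, p_value = min(p, 1))
}

#' Full mean-variance-dependence report
#'
#' Combines the meanSd profile, the Spearman rho and a trend test applied
#' to the running-window sd sequence of the mean-ordered profile.
#'
#' @inheritParams mean_sd_profile
#' @inheritParams trend_test
#' @return A list of class `"mvd_report"` with `profile`, `spearman_rho`,
#'   `tie_flag` and `trend` (the [trend_test()] result).
#' @export
mvd_report <- function(mat, window_fraction = 0.1,
                       method = c("mann_kendall", "cox_stuart"),
                       alternative = "two.sided") {
  method <- match.arg(method)
  prof <- mean_sd_profile(mat, window_fraction)
  sp <- spearman_mvd(mat)
  tr <- trend_test(prof$running_sd, method = method,
                   alternative = alternative)
  structure(list(profile = prof, spearman_rho = sp$rho,
                 tie_flag = sp$tie_flag, trend = tr),
            class = "mvd_report")
}

#' @export
print.mvd_report <- function(x, ...) {
  cat("mvd_report:", nrow(x$profile), "features; Spearman rho(mean, sd) =",
      format(x$spearman_rho, digits = 3), "\n")
  cat("trend test (", x$trend$method, ") on running sd: statistic = ",
      format(x$trend$statistic), ", p = ",
      format(x$trend$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
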