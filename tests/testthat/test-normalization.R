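mat_of <- function(v, nr, nc, prefix = "f")
  matrix(v, nr, nc, dimnames = list(paste0(prefix, seq_len(nr)),
                                    paste0("s", seq_len(nc))))

test_that("log2 normalisation inverts exactly and counts undefined cells", {
  m <- mat_of(c(1024, 2, 0.5, 8, 100, 3), 3, 2)
  out <- normalize_log2(m, alpha_hat = 0)
  expect_equal(out["f1", "s1"], 10)
  expect_equal(2^out + 0, m, ignore_attr = TRUE)

  out2 <- normalize_log2(m, alpha_hat = 2)
  expect_true(is.na(out2["f2", "s1"]))       # y == alpha_hat
  expect_equal(attr(out2, "n_undefined"), 2L)
  expect_equal(2^out2[!is.na(out2)] + 2, m[!is.na(out2)])
  expect_error(normalize_log2(m, alpha_hat = 1e6), "undefined")
})

test_that("MA transform and its inverse are mutually consistent", {
  expect_equal(ma_transform(8, 2), list(M = 2, A = 2))
  expect_equal(ma_transform(32, 32), list(M = 0, A = 5))
  set.seed(4)
  y1 <- rlnorm(200, log(500), 1); y2 <- rlnorm(200, log(500), 1)
  ma <- ma_transform(y1, y2)
  back <- ma_inverse(ma$M, ma$A)
  expect_lt(max(abs(back$y1 - y1) / y1), 1e-12)
  expect_lt(max(abs(back$y2 - y2) / y2), 1e-12)
  expect_error(ma_transform(c(1, -1), c(1, 1)), "positive")
})

test_that("the native loess smoother tracks the reference smoother", {
  set.seed(7)
  x <- sort(runif(150, 0, 10))
  y <- sin(x) + rnorm(150, 0, 0.15)
  mine <- tricube_loess(x, y, span = 0.7, iterations = 0)
  ref <- stats::predict(stats::loess(y ~ x, span = 0.7, degree = 1,
                                     family = "gaussian"))
  expect_lt(stats::median(abs(mine - ref)), 0.05)
  expect_lt(max(abs(mine - ref)), 0.3)
})

test_that("cyclic loess leaves identical arrays exactly fixed", {
  set.seed(1)
  base <- rlnorm(150, log(800), 1)
  m <- mat_of(rep(base, 3), 150, 3)
  out <- normalize_cyclic_loess(m)
  expect_equal(out, m)
})

test_that("cyclic loess removes a constant log2 offset", {
  set.seed(2)
  base <- rlnorm(300, log(800), 1)
  m <- cbind(s1 = base, s2 = base * 2^1.5)   # 1.5 log2-units apart
  rownames(m) <- paste0("f", seq_along(base))
  out <- normalize_cyclic_loess(m, n_cycles = 3)
  resid <- log2(out[, 1] / out[, 2])
  expect_lt(max(abs(resid)), 0.01)
  # both pulled toward the pairwise geometric mean
  expect_lt(max(abs(log2(out[, 1]) - (log2(base) + 0.75))), 0.2)
})

test_that("cyclic loess flattens an intensity-dependent bow", {
  set.seed(3)
  A <- sort(runif(400, 4, 14))
  bow <- 0.8 * sin((A - 4) / 10 * pi)        # injected M = f(A)
  x1 <- A + bow / 2
  x2 <- A - bow / 2
  m <- cbind(s1 = 2^x1, s2 = 2^x2)
  rownames(m) <- paste0("f", seq_along(A))
  out <- normalize_cyclic_loess(m, n_cycles = 3)
  M_post <- log2(out[, 1] / out[, 2])
  A_post <- 0.5 * log2(out[, 1] * out[, 2])
  amp_post <- max(abs(tricube_loess(A_post, M_post)))
  expect_lt(amp_post, 0.1 * max(abs(bow)))
  expect_error(normalize_cyclic_loess(m[, 1, drop = FALSE]), "2 arrays")
})

rlm_fixture <- function(slide_fx = c(0, 0), block_fx = c(0, 0, 0),
                        n_feat = 30, sd = 0.05, seed = 10,
                        outlier = FALSE) {
  set.seed(seed)
  n_slides <- length(slide_fx); n_blocks <- length(block_fx)
  controls <- c("IgG", "IgM")
  feats <- c(paste0("A", seq_len(n_feat)), controls)
  si <- expand.grid(block = seq_len(n_blocks), slide = seq_len(n_slides))
  si <- data.frame(sample = sprintf("S%d_%d", si$slide, si$block),
                   slide = paste0("sl", si$slide), block = si$block)
  base <- c(rlnorm(n_feat, log(1000), 1), 5000, 4000)
  m <- matrix(log2(base), length(feats), nrow(si),
              dimnames = list(feats, si$sample))
  fx <- slide_fx[rep(seq_len(n_slides), each = n_blocks)] +
    block_fx[rep(seq_len(n_blocks), n_slides)]
  m <- sweep(m, 2L, fx, `+`) + rnorm(length(m), 0, sd)
  if (outlier) m["IgG", 1] <- m["IgG", 1] + 6
  list(mat = m, si = si, controls = controls, fx = fx)
}

test_that("RLM estimates vanish when no technical effects are present", {
  f <- rlm_fixture()
  r <- normalize_rlm(f$mat, f$si, f$controls)
  expect_lt(max(abs(r$fit$alpha)), 0.05)
  expect_lt(max(abs(r$fit$beta)), 0.05)
  expect_lt(max(abs(r$matrix - f$mat)), 0.1)
  expect_true(r$fit$converged)
})

test_that("RLM recovers injected slide effects under sum-to-zero", {
  f <- rlm_fixture(slide_fx = c(1, -1))
  r <- normalize_rlm(f$mat, f$si, f$controls)
  expect_equal(unname(r$fit$alpha[c("sl1", "sl2")]), c(1, -1),
               tolerance = 0.05)
  expect_lt(abs(sum(r$fit$alpha)), 1e-8)
  expect_lt(abs(sum(r$fit$beta)), 1e-8)
  # post-adjustment between-slide mean difference of controls < 0.05
  cm <- r$matrix[f$controls, ]
  d <- mean(cm[, f$si$slide == "sl1"]) - mean(cm[, f$si$slide == "sl2"])
  expect_lt(abs(d), 0.05)
})

test_that("RLM adjustment leaves within-block feature contrasts unchanged", {
  f <- rlm_fixture(slide_fx = c(0.7, -0.7), block_fx = c(0.3, 0, -0.3))
  r <- normalize_rlm(f$mat, f$si, f$controls)
  for (s in colnames(f$mat))
    expect_equal(r$matrix["A1", s] - r$matrix["A2", s],
                 f$mat["A1", s] - f$mat["A2", s])
})

test_that("Huber weighting bounds the influence of a gross control outlier", {
  f0 <- rlm_fixture(slide_fx = c(0.5, -0.5), seed = 21)
  f1 <- rlm_fixture(slide_fx = c(0.5, -0.5), seed = 21, outlier = TRUE)
  rob0 <- normalize_rlm(f0$mat, f0$si, f0$controls)$fit$alpha
  rob1 <- normalize_rlm(f1$mat, f1$si, f1$controls)$fit$alpha

  ols_fit <- function(f) {
    long <- data.frame(y = as.vector(f$mat[f$controls, ]),
                       slide = factor(rep(f$si$slide,
                                          each = length(f$controls))),
                       block = factor(rep(f$si$block,
                                          each = length(f$controls))),
                       protein = factor(rep(f$controls, nrow(f$si))))
    cf <- coef(lm(y ~ slide + block + protein, data = long,
                  contrasts = list(slide = "contr.sum",
                                   block = "contr.sum",
                                   protein = "contr.sum")))
    c(cf["slide1"], -cf["slide1"])
  }
  ols_shift <- max(abs(ols_fit(f1) - ols_fit(f0)))
  rob_shift <- max(abs(rob1 - rob0))
  expect_lt(rob_shift, 0.2 * ols_shift)
})

test_that("RLM agrees with an independent robust regression on controls", {
  skip_if_not_installed("MASS")
  f <- rlm_fixture(slide_fx = c(0.8, -0.8), block_fx = c(0.2, -0.1, -0.1),
                   seed = 31)
  r <- normalize_rlm(f$mat, f$si, f$controls)
  long <- data.frame(y = as.vector(f$mat[f$controls, ]),
                     slide = factor(rep(f$si$slide,
                                        each = length(f$controls))),
                     block = factor(rep(f$si$block,
                                        each = length(f$controls))),
                     protein = factor(rep(f$controls, nrow(f$si))))
  ref <- MASS::rlm(y ~ slide + block + protein, data = long, k = 1.345,
                   contrasts = list(slide = "contr.sum",
                                    block = "contr.sum",
                                    protein = "contr.sum"),
                   maxit = 50)
  expect_equal(unname(r$fit$alpha["sl1"]), unname(coef(ref)["slide1"]),
               tolerance = 0.02)
  expect_error(normalize_rlm(f$mat, f$si, "nope"), "control")
})

test_that("glog2 matches arsinh/ln2 and its limits", {
  u <- seq(-1e6, 1e6, length.out = 4001)
  expect_lt(max(abs(glog2(u) - asinh(u) / log(2))), 1e-12)
  expect_identical(glog2(0), 0)
  expect_equal(glog2(1), log2(1 + sqrt(2)))
  expect_lt(abs(glog2(1000) - log2(2000)), 1e-6)
  expect_equal(glog2(-3), -glog2(3))         # odd function
  expect_true(all(diff(glog2(seq(-50, 50, 0.5))) > 0))
})

test_that("VSN recovers per-array scale parameters from the error model", {
  sim <- simulate_two_component(n_features = 50, n_arrays = 6,
                                gain = c(1, 1.2, 0.8, 1.5, 1, 0.9),
                                seed = 5)
  v <- normalize_vsn(sim$mat, trim = 0.1)
  expect_lt(max(abs(v$fit$b - sim$truth$b) / sim$truth$b), 0.15)
})

test_that("VSN stabilises the mean-variance dependence", {
  sim <- simulate_two_component(n_features = 200, n_arrays = 8, seed = 8)
  raw_rho <- spearman_mvd(sim$mat)$rho
  v <- normalize_vsn(sim$mat)
  expect_gt(raw_rho, 0.9)
  expect_lt(abs(spearman_mvd(v$matrix)$rho), 0.3)
})

test_that("the VSN transform is monotone and tolerates negative input", {
  sim <- simulate_two_component(n_features = 60, n_arrays = 3,
                                sigma_eps = 400, mu_meanlog = log(200),
                                seed = 13)
  expect_true(any(sim$mat < 0))
  v <- normalize_vsn(sim$mat)
  for (j in seq_len(ncol(sim$mat))) {
    o <- order(sim$mat[, j])
    expect_true(all(diff(v$matrix[o, j]) > 0))
  }
  expect_true(all(v$fit$b > 0))
})

test_that("normalisations preserve shape and missing-value positions", {
  sim <- simulate_two_component(n_features = 60, n_arrays = 4, seed = 9)
  m <- sim$mat
  m[5, 2] <- NA
  for (f in list(function(x) normalize_log2(abs(x)),
                 function(x) normalize_vsn(x)$matrix)) {
    out <- f(m)
    expect_equal(dim(out), dim(m))
    expect_true(is.na(out[5, 2]))
    expect_equal(sum(is.na(out[-5, ])), 0)
  }
})
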