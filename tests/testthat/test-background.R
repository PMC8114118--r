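make_spots <- function(fg, bg, slide = "s1", block = 1L) {
  data.frame(slide = slide, block = block, row = 1L,
             col = seq_along(fg), feature = paste0("f", seq_along(fg)),
             fg = fg, bg = bg, stringsAsFactors = FALSE)
}

test_that("local and global subtraction follow their definitions", {
  sp <- make_spots(c(500, 200, 100), c(300, 300, 0))
  loc <- bg_correct(sp, "local")
  expect_equal(loc$corrected, c(200, -100, 100))
  expect_equal(loc$neg_flag, c(FALSE, TRUE, FALSE))

  glob <- bg_correct(make_spots(c(100, 100, 100), c(10, 20, 30)), "global")
  expect_equal(glob$corrected, c(80, 80, 80))

  # single-spot slide: global == local
  one <- make_spots(120, 40)
  expect_equal(bg_correct(one, "global")$corrected,
               bg_correct(one, "local")$corrected)

  # two slides corrected independently against a per-slide brute force
  sp2 <- rbind(make_spots(c(100, 200), c(10, 30), slide = "a"),
               make_spots(c(100, 200), c(50, 70), slide = "b"))
  g2 <- bg_correct(sp2, "global")
  expect_equal(g2$corrected,
               sp2$fg - rep(c(median(c(10, 30)), median(c(50, 70))),
                            each = 2))
})

test_that("local/global shift by -c when every bg on a slide gains c", {
  sp <- make_spots(c(500, 400, 800), c(100, 150, 90))
  for (m in c("local", "global")) {
    base <- bg_correct(sp, m)$corrected
    spc <- sp; spc$bg <- spc$bg + 25
    expect_equal(bg_correct(spc, m)$corrected, base - 25)
  }
})

test_that("moving minimum uses the block minimum and resists artefacts", {
  sp <- make_spots(c(50, 40, 60), c(5, 3, 8))
  expect_equal(bg_correct(sp, "moving_min")$corrected, c(47, 37, 57))
  expect_equal(bg_correct(make_spots(70, 9), "moving_min")$corrected,
               bg_correct(make_spots(70, 9), "local")$corrected)

  # inflating one bg reading leaves the block correction unchanged as long
  # as it is not the minimum
  spi <- sp; spi$bg[3] <- spi$bg[3] * 50
  expect_equal(bg_correct(spi, "moving_min")$corrected,
               bg_correct(sp, "moving_min")$corrected)
})

test_that("half moving minimum replaces non-positives by half the minimum positive", {
  # corrected values {-5, 0, 12, 40} -> {6, 6, 12, 40}
  sp <- make_spots(fg = c(0, 5, 17, 45), bg = c(5, 5, 5, 5))
  out <- bg_correct(sp, "half_moving_min")
  expect_equal(out$corrected, c(6, 6, 12, 40))

  sp2 <- make_spots(c(10, 20), c(2, 2))
  expect_equal(bg_correct(sp2, "half_moving_min")$corrected, c(8, 18))

  sp3 <- make_spots(c(1, 4), c(2, 2))   # corrected {-1, 2} -> {1, 2}
  expect_equal(bg_correct(sp3, "half_moving_min")$corrected, c(1, 2))

  expect_gt(min(bg_correct(sp, "half_moving_min")$corrected), 0)
  # no positive value in scope -> error
  sp4 <- make_spots(c(1, 1), c(1, 1))
  sp4$bg <- c(2, 3)
  expect_error(bg_correct(sp4, "half_moving_min"), "no positive")
})

test_that("half moving minimum scope can widen to the slide", {
  sp <- rbind(make_spots(c(1, 50), c(10, 10), block = 1L),
              make_spots(c(30, 60), c(20, 20), block = 2L))
  # block scope: block 1 min bg 10 -> corrected {-9, 40} -> {20, 40}
  blk <- bg_correct(sp, "half_moving_min", scope = "block")
  expect_equal(blk$corrected[1], 40 / 2)
  # slide scope: minimum positive on whole slide is 10 (block 2: {10, 40})
  sld <- bg_correct(sp, "half_moving_min", scope = "slide")
  expect_equal(sld$corrected[1], 10 / 2)
})

test_that("normexp closed form matches the quadrature oracle", {
  params <- list(c(100, 10, 200), c(0, 50, 1000), c(300, 80, 150),
                 c(50, 5, 30), c(1000, 200, 5000))
  for (p in params) {
    fg <- seq(p[1] - 4 * p[2], p[1] + 5 * p[3], length.out = 40)
    got <- normexp_signal(fg, p[1], p[2], p[3])
    want <- normexp_quadrature(fg, p[1], p[2], p[3])
    expect_lt(max(abs(got - want) / want), 1e-6)
    expect_true(all(got > 0))
    expect_true(all(diff(normexp_signal(
      seq(p[1] - 6 * p[2], p[1] + 8 * p[3], length.out = 500),
      p[1], p[2], p[3])) > 0))
  }
})

test_that("normexp agrees with an independent reference implementation", {
  skip_if_not_installed("limma")
  fg <- seq(-200, 5000, length.out = 300)
  mine <- normexp_signal(fg, mu = 100, sigma = 40, theta = 800)
  ref <- limma::normexp.signal(c(100, log(40), log(800)), fg)
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("normexp degenerates to identity as sigma -> 0 with mu = 0", {
  fg <- c(10, 100, 1000)
  expect_equal(normexp_signal(fg, mu = 0, sigma = 1e-6, theta = 500), fg,
               tolerance = 1e-4)
})

test_that("normexp estimation recovers generating parameters", {
  set.seed(11)
  n <- 5000
  mu <- 200; sigma <- 30; theta <- 700
  fg <- rnorm(n, mu, sigma) + rexp(n, 1 / theta)
  bg <- rnorm(n, mu, sigma)
  fit <- normexp_fit(fg, bg, ml_refine = TRUE)
  expect_lt(abs(fit$mu - mu) / mu, 0.1)
  expect_lt(abs(fit$sigma - sigma) / sigma, 0.15)
  expect_lt(abs(fit$theta - theta) / theta, 0.1)
  expect_error(normexp_fit(fg[1:10], bg[1:10]), "30 spots")
  expect_error(normexp_signal(1, 0, -1, 1), "sigma")
  expect_error(normexp_signal(1, 0, 1, 0), "theta")
})

test_that("log-linear interpolation is continuous, positive and monotone", {
  # knot: fg - bg == delta gives exactly delta
  sp <- make_spots(fg = c(103, 500), bg = c(100, 100))
  out <- bg_correct(sp, "log_linear")      # delta = min positive = 3
  expect_equal(out$corrected, c(3, 400))

  # far above the knot: plain subtraction
  sp2 <- make_spots(c(5000, 104), c(100, 100))
  expect_equal(bg_correct(sp2, "log_linear")$corrected[1], 4900)

  # below the knot: smooth positive interpolation, monotone in fg
  bg <- rep(100, 200)
  fg <- seq(1, 120, length.out = 200)
  sp3 <- make_spots(c(fg, 200), c(bg, 100))
  corr <- bg_correct(sp3, "log_linear")$corrected
  expect_true(all(corr > 0))
  expect_true(all(diff(corr[1:200]) > 0))
  # continuity across the knot on a dense grid
  expect_lt(max(abs(diff(corr[1:200]))), 2)
  expect_error(bg_correct(make_spots(10, 20), "log_linear"),
               "no positive")
})

test_that("all methods preserve record count and order", {
  e <- tiny_experiment(seed = 3, n_slides = 1, blocks = 2, n_features = 20)
  for (m in c("local", "global", "moving_min", "half_moving_min",
              "normexp", "log_linear")) {
    out <- bg_correct(e$spots, m)
    expect_equal(nrow(out), nrow(e$spots))
    expect_identical(out$feature, e$spots$feature)
    if (m %in% c("half_moving_min", "normexp", "log_linear"))
      expect_true(all(out$corrected > 0), label = m)
  }
})

test_that("background diagnostics report correlations, blocks and buffers", {
  e <- tiny_experiment(seed = 5, n_slides = 1, blocks = 3, n_features = 20)
  d <- background_diagnostics(e$spots)
  expect_equal(nrow(d$per_block_bg), 3L)
  expect_true(all(abs(d$fg_bg_spearman$rho) <= 1, na.rm = TRUE))
  expect_gt(nrow(d$buffer_spots), 0L)

  # bg proportional to fg -> Spearman 1, matching the rank-formula oracle
  sp <- make_spots(fg = c(10, 40, 25, 90), bg = c(1, 4, 2.5, 9))
  d2 <- suppressWarnings(background_diagnostics(sp))
  expect_equal(d2$fg_bg_spearman$rho, 1)
  expect_equal(d2$fg_bg_spearman$rho,
               brute_force_spearman(sp$fg, sp$bg))

  # constant bg -> undefined correlation with tie flag
  sp3 <- make_spots(fg = c(10, 20, 30), bg = c(5, 5, 5))
  expect_warning(background_diagnostics(sp3), "buffer")
  d3 <- suppressWarnings(background_diagnostics(sp3))
  expect_true(is.na(d3$fg_bg_spearman$rho))
  expect_true(d3$fg_bg_spearman$tie_flag)
  expect_equal(nrow(d3$buffer_spots), 0L)
})
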