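rep_spots <- function(values, sample = "S1", feature = "A") {
  data.frame(slide = "s1", block = 1L, row = 1L, col = seq_along(values),
             feature = feature, corrected = values, sample = sample,
             feature_class = "antigen",
             replicate_index = seq_along(values),
             stringsAsFactors = FALSE)
}

test_that("CV follows the sample-sd definition and flags undefined cases", {
  expect_equal(compute_cv(c(100, 100, 100))$cv_percent, 0)
  cv <- compute_cv(c(90, 110))
  expect_equal(cv$mean, 100)
  expect_equal(cv$sd, sqrt((10^2 + 10^2) / 1))
  expect_equal(cv$cv_percent, 100 * sqrt(200) / 100)
  un <- compute_cv(c(-5, 5))
  expect_true(un$undefined)
  expect_true(is.na(un$cv_percent))
  expect_error(compute_cv(5), "at least 2")
})

test_that("CV is scale invariant", {
  set.seed(1)
  for (i in 1:20) {
    x <- abs(rnorm(sample(2:6, 1), 100, 20)) + 1
    c1 <- compute_cv(x)$cv_percent
    for (c in c(0.01, 3, 1e4))
      expect_equal(compute_cv(c * x)$cv_percent, c1, tolerance = 1e-12)
  }
})

test_that("an outlying replicate is dropped, keeping the best pair", {
  flt <- filter_replicates(rep_spots(c(1000, 1050, 5000)), cv_cutoff = 20)
  r <- flt$report
  expect_equal(r$status, "best_subset")
  expect_equal(r$retained, "1,2")
  expect_equal(nrow(flt$spots), 2L)
  pair_cv <- 100 * sd(c(1000, 1050)) / mean(c(1000, 1050))
  expect_lt(pair_cv, 20)
  expect_equal(best_cv_subset(c(1000, 1050, 5000))$cv_percent, pair_cv)
})

test_that("low-intensity replicate sets are exempted rather than rejected", {
  flt <- filter_replicates(rep_spots(c(10, 18, 25)), cv_cutoff = 20,
                           low_intensity_threshold = 100)
  expect_equal(flt$report$status, "low_intensity_exempt")
  expect_equal(nrow(flt$spots), 3L)
  # without the exemption the same set fails its cutoff
  flt2 <- filter_replicates(rep_spots(c(10, 18, 25)), cv_cutoff = 20,
                            low_intensity_threshold = 0)
  expect_true(flt2$report$status %in% c("best_subset", "fail"))
})

test_that("tight triplicates pass untouched and hopeless ones fail", {
  flt <- filter_replicates(rep_spots(c(100, 101, 102)))
  expect_equal(flt$report$status, "pass")
  expect_equal(flt$report$retained, "1,2,3")
  bad <- filter_replicates(rep_spots(c(100, 1000, 10000)), cv_cutoff = 5)
  expect_equal(bad$report$status, "fail")
  expect_equal(nrow(bad$spots), 0L)
})

test_that("best-subset search equals brute-force enumeration", {
  set.seed(42)
  n_cases <- 300
  for (i in seq_len(n_cases)) {
    n <- sample(3:5, 1)
    x <- round(rlnorm(n, log(500), 1), 2)
    if (i %% 7 == 0) x[1] <- -x[1]          # occasional negative value
    got <- best_cv_subset(x, 2L)
    want <- brute_force_cv_subset(x, 2L)
    expect_equal(got$indices, want$indices,
                 label = paste("case", i, paste(x, collapse = ",")))
    expect_equal(got$cv_percent, want$cv_percent, tolerance = 1e-12)
  }
})

test_that("raising the cutoff or exemption threshold never loses pairs", {
  e <- tiny_experiment(seed = 9, n_slides = 1, blocks = 4,
                       n_features = 30, sigma_eta = 0.35)
  sp <- bg_correct(e$spots, "local")
  sp <- sp[sp$feature_class != "buffer", ]
  kept <- function(cutoff, thr)
    sum(filter_replicates(sp, cutoff, thr)$report$status != "fail")
  expect_lte(kept(10, 0), kept(20, 0))
  expect_lte(kept(20, 0), kept(40, 0))
  expect_lte(kept(10, 0), kept(10, 200))
  expect_lte(kept(10, 200), kept(10, 2000))
})

test_that("replicate averaging produces the feature matrix with NA fails", {
  sp <- rbind(rep_spots(c(1000, 1050, 5000), feature = "A"),
              rep_spots(c(100, 1000, 10000), feature = "B"),
              rep_spots(c(200, 210, 220), feature = "C"))
  flt <- filter_replicates(sp, cv_cutoff = 20)
  mat <- average_replicates(flt$spots, flt$report)
  expect_equal(mat["A", "S1"], 1025)
  expect_true(is.na(mat["B", "S1"]))
  expect_equal(mat["C", "S1"], 210)

  e <- tiny_experiment(seed = 2, n_slides = 1, blocks = 3, n_features = 40)
  spb <- bg_correct(e$spots, "local")
  spb <- spb[spb$feature_class != "buffer", ]
  fl <- filter_replicates(spb, 20, 100)
  m <- average_replicates(fl$spots, fl$report, classes = "antigen")
  expect_equal(dim(m), c(40L, 3L))
})

test_that("tag subtraction removes tag signal, floors, and skips untagged", {
  feats <- data.frame(feature = c("Ag1", "Ag2", "Ag3", "GST"),
                      class = c("antigen", "antigen", "antigen", "tag"),
                      tag = c("GST", "GST", NA, NA))
  blks <- data.frame(slide = "s1", block = 1L, sample = "S1")
  lay <- experiment_layout(feats, blks)
  m <- matrix(c(5000, 200, 750, 300), 4, 1,
              dimnames = list(c("Ag1", "Ag2", "Ag3", "GST"), "S1"))
  out <- subtract_tag(m, lay)
  expect_equal(out["Ag1", 1], 4700)
  expect_equal(out["Ag2", 1], 0)       # floored
  expect_equal(out["Ag3", 1], 750)     # untagged unchanged
  expect_equal(out["GST", 1], 300)

  m2 <- m[c("Ag1", "Ag2", "Ag3"), , drop = FALSE]
  expect_error(subtract_tag(m2, lay), "GST")
})

test_that("the per-sample CV summary counts below/above/out-of-range", {
  sp <- rbind(rep_spots(c(100, 101, 102), feature = "A"),
              rep_spots(c(100, 1000, 10000), feature = "B"),
              rep_spots(c(-5, 5, 0), feature = "C"))
  flt <- filter_replicates(sp, cv_cutoff = 20)
  s <- cv_summary(flt$report, 20)
  expect_equal(s$n_le_cutoff, 1L)
  expect_equal(s$n_gt_cutoff, 1L)
  expect_equal(s$n_out_of_range, 1L)
  expect_equal(s$pct_le_cutoff + s$pct_gt_cutoff, 200 / 3)
})
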