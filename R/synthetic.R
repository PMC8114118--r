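# run code under a temporarily seeded RNG, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic mini-array experiment
#'
#' Defaults emulate a typical malaria antibody-chip design: slides divided into 21
#' mini-arrays (blocks), one serum sample per block, features printed in
#' triplicate, with human-Ig control spots, purification-tag spots (GST,
#' MBP, His6) and printing-buffer spots alongside the antigens. The signal
#' follows the two-component error model (multiplicative noise `e^eta` at
#' high intensity plus additive noise near zero), antigen levels are
#' lognormal across features to create a realistic mean-variance
#' dependence, and optional slide/block/batch effects act multiplicatively
#' (additively on the log2 scale).
#'
#' @param n_slides number of slides (default 2).
#' @param blocks_per_slide mini-arrays per slide (default 21).
#' @param n_features number of antigen features (default 100).
#' @param n_replicates spots printed per feature per block (default 3).
#' @param n_controls,n_buffer number of control / buffer features
#'   (defaults 2 and 4).
#' @param tags tag feature names (default GST, MBP, His6); set
#'   `character()` for an untagged design.
#' @param tagged_fraction fraction of antigens fused to a tag (default
#'   0.3).
#' @param bg_mean,bg_sd local background level and sd in intensity units
#'   (defaults 300 and 40).
#' @param mu_meanlog,mu_sdlog lognormal parameters of the antigen signal
#'   across features (defaults log(1000) and 1).
#' @param control_mu,tag_mu,buffer_mu mean true signal of control, tag and
#'   buffer features (defaults 5000, 400, 0).
#' @param sigma_eta sd of the sample-level multiplicative (proportional)
#'   error, shared by the technical replicates of a feature within a
#'   sample — the biological/serological spread across sera (default 0.2).
#' @param sigma_rep sd of the spot-level multiplicative technical error,
#'   independent per replicate spot (default 0.08, a typical tight
#'   triplicate CV of ~8%).
#' @param sigma_eps sd of the additive error in intensity units
#'   (default 50).
#' @param slide_effects,block_effects optional log2 technical effects:
#'   numeric vectors of length `n_slides` / `blocks_per_slide`
#'   (default 0).
#' @param batch_of_slide batch label per slide (default: slides split into
#'   two batches when `n_slides >= 2`).
#' @param batch_shift_log2,batch_scale named per-batch log2 signal shift
#'   and multiplicative residual-spread factor (defaults 0 and 1 = no
#'   batch effect).
#' @param grid_cols,grid_rows block grid dimensions; by default the grid is
#'   auto-sized (20 columns). An explicit grid too small for
#'   `(features + controls + tags + buffer) * replicates` spots is an
#'   error.
#' @param seed RNG seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_slides = 2L, blocks_per_slide = 21L,
                             n_features = 100L, n_replicates = 3L,
                             n_controls = 2L, n_buffer = 4L,
                             tags = c("GST", "MBP", "His6"),
                             tagged_fraction = 0.3,
                             bg_mean = 300, bg_sd = 40,
                             mu_meanlog = log(1000), mu_sdlog = 1,
                             control_mu = 5000, tag_mu = 400,
                             buffer_mu = 0,
                             sigma_eta = 0.2, sigma_rep = 0.08,
                             sigma_eps = 50,
                             slide_effects = NULL, block_effects = NULL,
                             batch_of_slide = NULL,
                             batch_shift_log2 = NULL, batch_scale = NULL,
                             grid_cols = NULL, grid_rows = NULL,
                             seed = 1L) {
  stopifnot(n_slides >= 1, blocks_per_slide >= 1, n_features >= 1,
            n_replicates >= 1, n_controls >= 0, n_buffer >= 0,
            bg_mean >= 0, bg_sd >= 0, sigma_eta >= 0, sigma_rep >= 0,
            sigma_eps >= 0)
  if (is.null(slide_effects)) slide_effects <- rep(0, n_slides)
  if (is.null(block_effects)) block_effects <- rep(0, blocks_per_slide)
  stopifnot(length(slide_effects) == n_slides,
            length(block_effects) == blocks_per_slide)
  if (is.null(batch_of_slide))
    batch_of_slide <- if (n_slides >= 2L)
      paste0("b", rep(1:2, length.out = n_slides)) else rep("b1", n_slides)
  stopifnot(length(batch_of_slide) == n_slides)

  n_spot_feats <- n_features + n_controls + length(tags) + n_buffer
  n_spots <- n_spot_feats * n_replicates
  if (is.null(grid_cols)) grid_cols <- 20L
  if (is.null(grid_rows)) grid_rows <- as.integer(ceiling(n_spots /
                                                            grid_cols))
  if (grid_rows * grid_cols < n_spots)
    stop("inconsistent config: ", n_spots, " spots per block exceed the ",
         grid_rows, "x", grid_cols, " block grid")

  batches <- unique(batch_of_slide)
  if (is.null(batch_shift_log2))
    batch_shift_log2 <- stats::setNames(rep(0, length(batches)), batches)
  if (is.null(batch_scale))
    batch_scale <- stats::setNames(rep(1, length(batches)), batches)

  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic mini-array experiment with known ground truth
#'
#' Deterministic given `config$seed`. Produces an assembled spot table, its
#' layout and a ground-truth record; when `dir` is given, also writes one
#' GenePix-style (ATF) quantification file per slide, the two layout TSVs
#' and the ground truth as JSON, all parseable by the package's readers.
#'
#' The foreground of each spot is
#' `bg + (mu + tag carry-through) * e^(eta_bio + eta_tech) * 2^(slide +
#' block + batch effects) + eps`, floored at 0 — `eta_bio` is drawn once
#' per (feature, sample) and shared by its technical replicates while
#' `eta_tech` and `eps` are per spot — with the spot's own background
#' reading
#' `bg ~ Normal(bg_mean, bg_sd)` (floored at 0) written to the background
#' column — so with all noise and effects off, fg - bg equals the true
#' signal exactly.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory.
#' @return A list with `spots` (assembled spot table), `layout`, `truth`
#'   (list: `mu` feature x sample matrix of true signals including tag
#'   carry-through, `slide_effects`, `block_effects`, `batch_of_slide`,
#'   `batch_shift_log2`, `batch_scale`, `config`), and `files` (named
#'   paths, when `dir` given).
#' @export
generate_experiment <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config

  antigens <- sprintf("A%03d", seq_len(cf$n_features))
  controls <- if (cf$n_controls > 0)
    c("IgG", "IgM", sprintf("CTRL%02d", seq_len(max(0, cf$n_controls -
        2L))))[seq_len(cf$n_controls)] else character()
  buffers <- if (cf$n_buffer > 0)
    sprintf("BUF%02d", seq_len(cf$n_buffer)) else character()
  feats <- c(antigens, controls, cf$tags, buffers)
  classes <- c(rep("antigen", length(antigens)),
               rep("control", length(controls)),
               rep("tag", length(cf$tags)),
               rep("buffer", length(buffers)))

  out <- .with_seed(cf$seed, {
    n_tagged <- round(cf$tagged_fraction * cf$n_features)
    tag_assign <- rep(NA_character_, length(feats))
    if (length(cf$tags) && n_tagged > 0) {
      which_tagged <- sample(seq_along(antigens), n_tagged)
      tag_assign[which_tagged] <- sample(cf$tags, n_tagged, replace = TRUE)
    }
    features_df <- data.frame(feature = feats, class = classes,
                              tag = tag_assign, stringsAsFactors = FALSE)

    slides <- sprintf("slide%d", seq_len(cf$n_slides))
    blocks_df <- do.call(rbind, lapply(seq_len(cf$n_slides), function(i)
      data.frame(slide = slides[i], block = seq_len(cf$blocks_per_slide),
                 sample = sprintf("S%02d_%02d", i,
                                  seq_len(cf$blocks_per_slide)),
                 batch = cf$batch_of_slide[i], stringsAsFactors = FALSE)))
    layout <- experiment_layout(features_df, blocks_df)

    # true per-feature signal level (constant across samples: the
    # proportional error creates the across-sample spread)
    mu_f <- stats::setNames(numeric(length(feats)), feats)
    mu_f[antigens] <- stats::rlnorm(length(antigens), cf$mu_meanlog,
                                    cf$mu_sdlog)
    mu_f[controls] <- cf$control_mu
    mu_f[cf$tags] <- cf$tag_mu
    mu_f[buffers] <- cf$buffer_mu
    # tag carry-through: tagged antigens also bind anti-tag antibodies
    mu_meas <- mu_f
    tagged <- !is.na(tag_assign)
    mu_meas[tagged] <- mu_f[feats[tagged]] + mu_f[tag_assign[tagged]]

    samples <- blocks_df$sample
    mu_mat <- matrix(rep(mu_meas, length(samples)), nrow = length(feats),
                     dimnames = list(feats, samples))

    # spot grid per block, row-major
    nf <- length(feats)
    fidx <- rep(seq_len(nf), each = cf$n_replicates)
    ridx <- rep(seq_len(cf$n_replicates), times = nf)
    pos_row <- (seq_along(fidx) - 1L) %/% cf$grid_cols + 1L
    pos_col <- (seq_along(fidx) - 1L) %% cf$grid_cols + 1L

    frags <- lapply(seq_len(cf$n_slides), function(i) {
      batch <- cf$batch_of_slide[i]
      per_block <- lapply(seq_len(cf$blocks_per_slide), function(j) {
        n <- length(fidx)
        bg <- pmax(stats::rnorm(n, cf$bg_mean, cf$bg_sd), 0)
        # sample-level proportional error: one draw per feature, shared by
        # the replicates of that feature in this block's sample
        eta_bio <- stats::rnorm(nf, 0, cf$sigma_eta)[fidx]
        eta_tech <- stats::rnorm(n, 0, cf$sigma_rep)
        eps <- stats::rnorm(n, 0, cf$sigma_eps) * cf$batch_scale[[batch]]
        gain <- 2^(cf$slide_effects[i] + cf$block_effects[j] +
                     cf$batch_shift_log2[[batch]])
        sig <- mu_meas[fidx] * exp(eta_bio + eta_tech) * gain + eps
        data.frame(slide = sprintf("slide%d", i), block = j, row = pos_row,
                   col = pos_col, feature = feats[fidx],
                   fg = pmax(bg + sig, 0), bg = bg, flag = 0L,
                   diameter = NA_real_, stringsAsFactors = FALSE)
      })
      do.call(rbind, per_block)
    })
    spots <- assemble_experiment(frags, layout)

    truth <- list(mu = mu_mat, mu_feature = mu_f,
                  tag_of = stats::setNames(tag_assign, feats),
                  slide_effects = stats::setNames(cf$slide_effects, slides),
                  block_effects = cf$block_effects,
                  batch_of_slide = stats::setNames(cf$batch_of_slide,
                                                   slides),
                  batch_shift_log2 = cf$batch_shift_log2,
                  batch_scale = cf$batch_scale, seed = cf$seed)
    list(spots = spots, layout = layout, truth = truth)
  })

  if (!is.null(dir)) {
    out$files <- write_experiment(out, dir)
  }
  out
}

#' Write a synthetic experiment to disk in GPR/TSV/JSON form
#'
#' @param experiment result of [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spots <- experiment$spots
  paths <- c()
  for (s in unique(spots$slide)) {
    p <- file.path(dir, paste0(s, ".gpr"))
    .write_gpr(spots[spots$slide == s, , drop = FALSE], p)
    paths[paste0("gpr_", s)] <- p
  }
  fp <- file.path(dir, "features.tsv")
  bp <- file.path(dir, "blocks.tsv")
  write_layout(experiment$layout, fp, bp)
  paths["features"] <- fp
  paths["blocks"] <- bp
  tp <- file.path(dir, "truth.json")
  tr <- experiment$truth
  tr$mu <- list(features = rownames(tr$mu), samples = colnames(tr$mu),
                values = unname(as.data.frame(tr$mu)))
  jsonlite::write_json(tr, tp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  paths["truth"] <- tp
  paths
}

# ATF-dialect writer: 2 optional header lines, full-precision intensities
.write_gpr <- function(spots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ATF\t1.0", "2\t7",
               "\"Type=GenePix Results 3\"", "\"Wavelength=635\""), con)
  num <- function(x) formatC(x, digits = 17, format = "g")
  tab <- data.frame(Block = spots$block, Row = spots$row,
                    Column = spots$col, Name = spots$feature,
                    `F635 Median` = num(spots$fg),
                    `B635 Median` = num(spots$bg),
                    Flags = spots$flag, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Inject a localised background artefact into an experiment
#'
#' Inflates the recorded local background of a deterministic subset of
#' spots (the first `affected_fraction` in row-major order) inside the
#' listed blocks, emulating a smear or scratch that contaminates the local
#' background annulus of most — but not all — spots of a mini-array. The
#' spot foreground is left untouched, so plain local subtraction
#' over-corrects the affected spots while the block-minimum methods, which
#' pick the background of an unaffected spot, do not.
#'
#' @param experiment result of [generate_experiment()].
#' @param blocks data frame with columns `slide`, `block` naming the
#'   target blocks.
#' @param factor multiplicative background inflation (1 = identity).
#' @param affected_fraction fraction of spots per block affected
#'   (default 0.8).
#' @return The experiment with modified `spots` and an `artefacts` entry
#'   appended to `truth`.
#' @export
inject_artefact <- function(experiment, blocks, factor,
                            affected_fraction = 0.8) {
  spots <- experiment$spots
  for (r in seq_len(nrow(blocks))) {
    i <- which(spots$slide == blocks$slide[r] &
                 spots$block == blocks$block[r])
    if (!length(i))
      stop("unknown block: ", blocks$slide[r], ":", blocks$block[r])
    i <- i[order(spots$row[i], spots$col[i])]
    hit <- i[seq_len(ceiling(affected_fraction * length(i)))]
    spots$bg[hit] <- spots$bg[hit] * factor
  }
  experiment$spots <- spots
  experiment$truth$artefacts <- list(blocks = blocks, factor = factor,
                                     affected_fraction = affected_fraction)
  experiment
}

#' Simulate a matrix from the two-component error model
#'
#' Direct simulation of `y_ik = f_i * (mu_k * e^eta + eps)` with per-array
#' gain factors `f_i`, multiplicative error sd `sigma_eta` and additive
#' error sd `sigma_eps`; `mu_k` lognormal across features. The
#' variance-stabilising glog2 scale parameter implied for array i is
#' `b_i = f_i * sigma_eps / sigma_eta`, returned as ground truth.
#'
#' @param n_features,n_arrays matrix dimensions.
#' @param gain per-array gain factors `f_i` (default 1).
#' @param sigma_eta,sigma_eps error model parameters (defaults 0.2, 50).
#' @param mu_meanlog,mu_sdlog lognormal feature-level parameters.
#' @param seed RNG seed.
#' @return A list with `mat` and `truth` (list: `mu`, `gain`, `b`,
#'   `sigma_eta`, `sigma_eps`).
#' @export
simulate_two_component <- function(n_features = 50L, n_arrays = 6L,
                                   gain = rep(1, n_arrays),
                                   sigma_eta = 0.2, sigma_rep = 0.08,
                             sigma_eps = 50,
                                   mu_meanlog = log(1000), mu_sdlog = 1.2,
                                   seed = 1L) {
  stopifnot(length(gain) == n_arrays, sigma_eta > 0, sigma_eps > 0)
  .with_seed(seed, {
    mu <- stats::rlnorm(n_features, mu_meanlog, mu_sdlog)
    eta <- matrix(stats::rnorm(n_features * n_arrays, 0, sigma_eta),
                  n_features)
    eps <- matrix(stats::rnorm(n_features * n_arrays, 0, sigma_eps),
                  n_features)
    mat <- sweep(mu * exp(eta) + eps, 2L, gain, `*`)
    dimnames(mat) <- list(sprintf("F%04d", seq_len(n_features)),
                          sprintf("arr%02d", seq_len(n_arrays)))
    list(mat = mat,
         truth = list(mu = mu, gain = gain,
                      b = gain * sigma_eps / sigma_eta,
                      sigma_eta = sigma_eta, sigma_eps = sigma_eps))
  })
}

#' Simulate a batch-structured matrix with known batch effects
#'
#' Additive-scale simulation for batch-correction recovery: feature levels
#' plus optional preserved group effects, with per-batch location shifts
#' and residual-scale factors.
#'
#' @param n_features features (default 100).
#' @param n_per_batch samples per batch (default 20).
#' @param batch_shift,batch_scale per-batch additive shift and residual sd
#'   factor (length = number of batches).
#' @param group_effect optional effect size of a two-group covariate split
#'   evenly within each batch (default 0 = none).
#' @param resid_sd within-batch residual sd on the log2 scale (default
#'   0.25, the technical spread left after averaging tight triplicates).
#' @param seed RNG seed.
#' @return A list with `mat`, `batch`, `group` (0/1 vector) and `truth`.
#' @export
simulate_batch_matrix <- function(n_features = 100L, n_per_batch = 20L,
                                  batch_shift = c(0, 2),
                                  batch_scale = c(1, 1.5),
                                  group_effect = 0, resid_sd = 0.25,
                                  seed = 1L) {
  stopifnot(length(batch_shift) == length(batch_scale))
  b <- length(batch_shift)
  .with_seed(seed, {
    N <- b * n_per_batch
    batch <- rep(paste0("b", seq_len(b)), each = n_per_batch)
    group <- rep(rep(0:1, length.out = n_per_batch), times = b)
    base <- stats::rnorm(n_features, 8, 2)
    feat_group <- stats::rnorm(n_features, group_effect,
                               abs(group_effect) / 4 + 1e-12)
    mat <- matrix(base, n_features, N)
    mat <- mat + outer(feat_group, group)
    noise <- matrix(stats::rnorm(n_features * N, 0, resid_sd), n_features)
    noise <- sweep(noise, 2L, batch_scale[match(batch,
                                                unique(batch))], `*`)
    mat <- mat + noise + matrix(batch_shift[match(batch, unique(batch))],
                                n_features, N, byrow = TRUE)
    dimnames(mat) <- list(sprintf("F%04d", seq_len(n_features)),
                          sprintf("s%03d", seq_len(N)))
    list(mat = mat, batch = batch, group = group,
         truth = list(base = base, feat_group = feat_group,
                      batch_shift = batch_shift,
                      batch_scale = batch_scale))
  })
}

#' Sample metadata table of an experiment layout
#'
#' @param layout an [experiment_layout()].
#' @return Data frame with one row per sample: `sample`, `slide`, `block`
#'   (first block of the sample), `batch`.
#' @export
sample_info <- function(layout) {
  bm <- layout$block_map
  first <- !duplicated(bm$sample)
  data.frame(sample = bm$sample[first], slide = bm$slide[first],
             block = bm$block[first],
             batch = unname(layout$batch_of[bm$sample[first]]),
             stringsAsFactors = FALSE)
}
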