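#' Background correction of a spot table
#'
#' Dispatches to one of six strategies for removing background signal from
#' the foreground intensity of each spot. All methods preserve record count
#' and ordering and add (or overwrite) two columns: `corrected` and
#' `neg_flag` (TRUE where the plain subtraction fg - bg is non-positive;
#' informational for the model-based methods, which return positive values).
#'
#' * `local`: fg - bg per spot. Negatives retained and flagged; replacement
#'   is an explicit downstream choice.
#' * `global`: fg minus the median of all local backgrounds on the slide.
#' * `moving_min`: fg minus the minimum local background of the spot's
#'   block, for artefacts localised to a block.
#' * `half_moving_min`: `moving_min`, then every corrected value <= 0 is
#'   replaced by half the minimum positive corrected value in the
#'   replacement scope (block by default).
#' * `normexp`: the expected true signal given the observed foreground under
#'   a normal (background) + exponential (signal) convolution model shared
#'   by the whole slide; see [normexp_signal()].
#' * `log_linear`: plain subtraction above a per-slide threshold, smooth
#'   log-linear interpolation below it; see Details.
#'
#' For `log_linear`, the per-slide threshold `delta` is the smallest
#' positive fg - bg on the slide, floored at 1 intensity unit. Spots with
#' fg - bg >= delta keep fg - bg; below the knot the corrected value is
#' `delta * exp(1 - (bg + delta)/fg)`, a continuous, strictly positive
#' function of fg that is monotone increasing and equals `delta` at the
#' knot.
#'
#' @param spots spot table (see [assemble_experiment()]); needs `fg`, `bg`,
#'   plus `slide` for slide-scoped methods and `block` for block-scoped
#'   ones.
#' @param method one of `"local"`, `"global"`, `"moving_min"`,
#'   `"half_moving_min"`, `"normexp"`, `"log_linear"`.
#' @param scope replacement scope for `half_moving_min`: `"block"`
#'   (default; the unit the method targets) or `"slide"`.
#' @param normexp_params `"estimate"` (default) or a list with elements
#'   `mu`, `sigma`, `theta`; see [normexp_fit()].
#' @param ml_refine logical; refine the moment estimates of the normexp
#'   parameters by maximum likelihood (default TRUE).
#' @return The spot table with `corrected` and `neg_flag` columns.
#' @export
bg_correct <- function(spots,
                       method = c("local", "global", "moving_min",
                                  "half_moving_min", "normexp",
                                  "log_linear"),
                       scope = c("block", "slide"),
                       normexp_params = "estimate", ml_refine = TRUE) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  stopifnot(is.data.frame(spots), all(c("fg", "bg") %in% names(spots)))

  d <- spots$fg - spots$bg
  spots$neg_flag <- d <= 0

  spots$corrected <- switch(method,
    local = d,
    global = {
      med <- stats::ave(spots$bg, spots$slide,
                        FUN = function(x) stats::median(x, na.rm = TRUE))
      spots$fg - med
    },
    moving_min = spots$fg - .block_min_bg(spots),
    half_moving_min = {
      corr <- spots$fg - .block_min_bg(spots)
      grp <- if (scope == "block") paste(spots$slide, spots$block, sep = "\r")
             else spots$slide
      .half_min_replace(corr, grp)
    },
    normexp = {
      out <- numeric(nrow(spots))
      for (s in unique(spots$slide)) {
        i <- spots$slide == s
        par <- if (identical(normexp_params, "estimate"))
          normexp_fit(spots$fg[i], spots$bg[i], ml_refine = ml_refine)
        else normexp_params
        out[i] <- normexp_signal(spots$fg[i], par$mu, par$sigma, par$theta)
      }
      out
    },
    log_linear = {
      out <- numeric(nrow(spots))
      for (s in unique(spots$slide)) {
        i <- spots$slide == s
        di <- d[i]
        pos <- di[di > 0 & !is.na(di)]
        if (!length(pos))
          stop("log_linear: no positive fg - bg on slide ", s)
        delta <- max(min(pos), 1)
        low <- !is.na(di) & di < delta
        oi <- di
        oi[low] <- delta * exp(1 - (spots$bg[i][low] + delta) /
                                 spots$fg[i][low])
        out[i] <- oi
      }
      out
    })
  spots
}

# per-(slide, block) minimum background, aligned with rows
.block_min_bg <- function(spots) {
  if (!"block" %in% names(spots)) stop("block column required")
  grp <- paste(spots$slide, spots$block, sep = "\r")
  stats::ave(spots$bg, grp, FUN = function(x) min(x, na.rm = TRUE))
}

# replace values <= 0 by half the minimum positive value within each group
.half_min_replace <- function(x, grp) {
  for (g in unique(grp)) {
    i <- grp == g
    xi <- x[i]
    nonpos <- !is.na(xi) & xi <= 0
    if (!any(nonpos)) next
    pos <- xi[!is.na(xi) & xi > 0]
    if (!length(pos))
      stop("half-minimum replacement undefined: no positive corrected ",
           "value in scope '", gsub("\r", ":", g), "'")
    xi[nonpos] <- min(pos) / 2
    x[i] <- xi
  }
  x
}

#' Expected true signal under the normal + exponential convolution model
#'
#' Models the observed intensity as X = B + S with background
#' B ~ Normal(mu, sigma^2) and true signal S ~ Exponential(mean theta).
#' The corrected intensity is the posterior mean E[S | X = x], which has the
#' closed form
#' `m + sigma * phi(m/sigma) / Phi(m/sigma)` with `m = x - mu - sigma^2 /
#' theta`, where phi and Phi are the standard normal density and CDF. The
#' map is strictly increasing in x and strictly positive for all real x, so
#' a whole slide sharing one parameter set maps its negative net intensities
#' to a common positive scale.
#'
#' @param x observed foreground intensities.
#' @param mu,sigma mean and sd of the normal background (sigma > 0).
#' @param theta mean of the exponential signal (> 0).
#' @return E[S | X = x], same length as `x`.
#' @export
normexp_signal <- function(x, mu, sigma, theta) {
  if (!(sigma > 0)) stop("sigma must be > 0")
  if (!(theta > 0)) stop("theta must be > 0")
  m <- x - mu - sigma^2 / theta
  z <- m / sigma
  # Mills-ratio form; log scale for numerical stability deep in the tail
  out <- m + sigma * exp(stats::dnorm(z, log = TRUE) -
                           stats::pnorm(z, log.p = TRUE))
  pmax(out, .Machine$double.xmin)
}

#' Marginal log-likelihood of foreground intensities under the normexp model
#'
#' The marginal density of X = B + S is
#' `f(x) = 1/theta * exp((mu - x)/theta + sigma^2/(2 theta^2)) *
#' Phi((x - mu - sigma^2/theta)/sigma)`.
#'
#' @param x observed intensities.
#' @param mu,sigma,theta model parameters.
#' @return The summed log-likelihood.
#' @export
normexp_loglik <- function(x, mu, sigma, theta) {
  z <- (x - mu - sigma^2 / theta) / sigma
  sum(-log(theta) + (mu - x) / theta + sigma^2 / (2 * theta^2) +
        stats::pnorm(z, log.p = TRUE))
}

#' Estimate normexp parameters for one slide
#'
#' Moment initialisation: `mu` is the median and `sigma` the MAD-derived sd
#' of the local background medians on the slide; `theta = max(mean(fg) - mu,
#' eps)` with `eps = 1` intensity unit. Optionally the triple is refined by
#' direct maximisation of the marginal likelihood of the foreground under
#' the convolution model ([normexp_loglik()]).
#'
#' @param fg foreground intensities of the slide (>= 30 spots).
#' @param bg local background intensities of the slide.
#' @param ml_refine refine by maximum likelihood?
#' @return A list with `mu`, `sigma`, `theta` (and `logLik` if refined).
#' @export
normexp_fit <- function(fg, bg, ml_refine = TRUE) {
  if (length(fg) < 30L)
    stop("normexp estimation needs at least 30 spots per slide")
  mu <- stats::median(bg, na.rm = TRUE)
  sigma <- stats::mad(bg, na.rm = TRUE)
  if (!is.finite(sigma) || sigma <= 0) sigma <- max(stats::sd(bg), 1e-3)
  theta <- max(mean(fg, na.rm = TRUE) - mu, 1)
  if (!ml_refine) return(list(mu = mu, sigma = sigma, theta = theta))

  nll <- function(p) {
    v <- -normexp_loglik(fg, p[1L], exp(p[2L]), exp(p[3L]))
    if (!is.finite(v)) 1e300 else v
  }
  fit <- stats::optim(c(mu, log(sigma), log(theta)), nll, method = "BFGS",
                      control = list(maxit = 200))
  if (!fit$convergence %in% c(0L, 1L))
    stop("normexp ML estimation failed (optim code ", fit$convergence,
         "); moment estimates were mu=", signif(mu, 4), " sigma=",
         signif(sigma, 4), " theta=", signif(theta, 4))
  list(mu = fit$par[1L], sigma = exp(fit$par[2L]), theta = exp(fit$par[3L]),
       logLik = -fit$value)
}

#' Background diagnostics guiding the choice of correction method
#'
#' Computes, from the uncorrected spot table: the per-slide Spearman
#' correlation between foreground and background medians (low correlation
#' supports plain local subtraction), per-block background summaries
#' (median and IQR; an inflated block points at a localised artefact and at
#' the moving-minimum methods), and per-sample summaries of the buffer-spot
#' foregrounds (background reactivity / carry-over monitor).
#'
#' @param spots spot table with `fg`, `bg`, `slide`, `block`; buffer
#'   summaries need `feature_class` and `sample`.
#' @return A list of class `"background_diagnostics"` with data frames
#'   `fg_bg_spearman` (`slide`, `rho`, `tie_flag`), `per_block_bg`
#'   (`slide`, `block`, `median`, `iqr`, `n`), `buffer_spots` (`sample`,
#'   `n`, `min`, `median`, `mean`, `max`).
#' @export
background_diagnostics <- function(spots) {
  slides <- unique(spots$slide)
  rho <- vapply(slides, function(s) {
    i <- spots$slide == s
    if (length(unique(spots$bg[i])) < 2L || length(unique(spots$fg[i])) < 2L)
      return(NA_real_)
    stats::cor(spots$fg[i], spots$bg[i], method = "spearman",
               use = "complete.obs")
  }, 0)
  fg_bg <- data.frame(slide = slides, rho = unname(rho),
                      tie_flag = is.na(rho), stringsAsFactors = FALSE)

  grp <- interaction(spots$slide, spots$block, drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(spots)), grp), function(i) {
    data.frame(slide = spots$slide[i][1L], block = spots$block[i][1L],
               median = stats::median(spots$bg[i], na.rm = TRUE),
               iqr = stats::IQR(spots$bg[i], na.rm = TRUE),
               n = length(i), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL

  if ("feature_class" %in% names(spots) &&
      any(spots$feature_class == "buffer")) {
    b <- spots[spots$feature_class == "buffer", , drop = FALSE]
    buf <- do.call(rbind, lapply(split(b$fg, b$sample), function(x) {
      data.frame(n = length(x), min = min(x), median = stats::median(x),
                 mean = mean(x), max = max(x))
    }))
    buf <- cbind(data.frame(sample = rownames(buf),
                            stringsAsFactors = FALSE), buf)
    rownames(buf) <- NULL
  } else {
    warning("no buffer spots found; buffer summary is empty")
    buf <- data.frame(sample = character(), n = integer(), min = numeric(),
                      median = numeric(), mean = numeric(), max = numeric())
  }

  structure(list(fg_bg_spearman = fg_bg, per_block_bg = agg,
                 buffer_spots = buf),
            class = "background_diagnostics")
}
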