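#' Coefficient of variation of a set of technical replicates
#'
#' CV% = 100 * sd / mean, with the sample standard deviation (n - 1
#' denominator). The CV is undefined (returned as `NA` with `undefined =
#' TRUE`) when the mean is non-positive — at that point the ratio carries no
#' information about relative precision.
#'
#' @param values numeric vector of at least 2 finite replicate intensities.
#' @return A list with `mean`, `sd`, `cv_percent`, `undefined`.
#' @export
compute_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("CV needs at least 2 finite replicate values")
  m <- mean(values)
  s <- stats::sd(values)
  if (m <= 0)
    return(list(mean = m, sd = s, cv_percent = NA_real_, undefined = TRUE))
  list(mean = m, sd = s, cv_percent = 100 * s / m, undefined = FALSE)
}

# raw CV% of a subset without the list wrapper; Inf when mean <= 0 so that
# such subsets always lose the minimisation
.cv_raw <- function(x) {
  m <- mean(x)
  if (m <= 0) return(Inf)
  100 * stats::sd(x) / m
}

#' Minimal-CV replicate subset
#'
#' Exhaustive search over all subsets of size >= `min_keep` for the subset
#' with the smallest CV. Ties (within 1e-9 CV units) are broken by the
#' larger subset mean, then by the lexicographically smallest index set.
#'
#' @param values replicate intensities.
#' @param min_keep smallest admissible subset size (default 2).
#' @return A list with `indices`, `cv_percent`, `mean`.
#' @export
best_cv_subset <- function(values, min_keep = 2L) {
  n <- length(values)
  if (n < min_keep) stop("fewer replicates than min_keep")
  best <- NULL
  for (k in seq(n, min_keep)) {
    sets <- utils::combn(n, k, simplify = FALSE)
    for (idx in sets) {
      cv <- .cv_raw(values[idx])
      cand <- list(indices = idx, cv_percent = cv, mean = mean(values[idx]))
      if (is.null(best)) { best <- cand; next }
      d <- cv - best$cv_percent
      if (is.nan(d)) d <- 0          # both subsets undefined: tie on CV
      if (d < -1e-9) best <- cand
      else if (abs(d) <= 1e-9) {
        if (cand$mean > best$mean + 1e-12) best <- cand
        else if (abs(cand$mean - best$mean) <= 1e-12 &&
                 .lex_lt(idx, best$indices)) best <- cand
      }
    }
  }
  best
}

# lexicographic index-set comparison (shorter prefix wins on equality)
.lex_lt <- function(a, b) {
  l <- min(length(a), length(b))
  for (i in seq_len(l)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Filter technical replicates by CV
#'
#' Per (sample, feature) replicate set, applies the acceptance policy:
#' * `pass` — the full-set CV is at or below `cv_cutoff`; all kept.
#' * `low_intensity_exempt` — full-set CV exceeds the cutoff but the mean is
#'   below `low_intensity_threshold`; all kept. Small absolute differences
#'   near the detection floor inflate the CV without signalling a bad spot,
#'   so such CVs are ignored rather than used to reject.
#' * `best_subset` — the minimal-CV subset of size >= `min_keep` meets the
#'   cutoff; only that subset is kept (e.g. 2 of 3 replicates kept, the
#'   outlier excluded).
#' * `fail` — no admissible subset meets the cutoff; nothing kept.
#'
#' Sets with an undefined full-set CV (mean <= 0) are routed through the
#' same policy: exempt if low-intensity, otherwise subset search.
#'
#' @param spots background-corrected spot table with `corrected`,
#'   `sample`, `feature` and `replicate_index` columns.
#' @param cv_cutoff CV% acceptance threshold (default 20).
#' @param low_intensity_threshold intensity below which high CVs are
#'   exempted (default 0 = no exemption).
#' @param min_keep smallest replicate subset that may be retained
#'   (default 2).
#' @return A list with `spots` (input restricted to retained replicates)
#'   and `report`, a data frame with one row per (sample, feature):
#'   `sample`, `feature`, `n_replicates`, `mean`, `sd`, `cv_percent`,
#'   `cv_undefined`, `status`, `retained` (comma-separated replicate
#'   indices).
#' @export
filter_replicates <- function(spots, cv_cutoff = 20,
                              low_intensity_threshold = 0, min_keep = 2L) {
  stopifnot(cv_cutoff > 0, low_intensity_threshold >= 0)
  need <- c("corrected", "sample", "feature", "replicate_index")
  if (!all(need %in% names(spots)))
    stop("spot table needs columns: ", paste(need, collapse = ", "))

  grp <- paste(spots$sample, spots$feature, sep = "\r")
  idx_by <- split(seq_len(nrow(spots)), grp)
  rows <- vector("list", length(idx_by))
  keep <- logical(nrow(spots))

  for (g in seq_along(idx_by)) {
    i <- idx_by[[g]]
    i <- i[order(spots$replicate_index[i])]
    x <- spots$corrected[i]
    n <- length(x)
    m <- mean(x); s <- if (n >= 2L) stats::sd(x) else NA_real_
    cv <- if (n >= 2L && m > 0) 100 * s / m else NA_real_
    undef <- n >= 2L && m <= 0

    if (n < 2L) {
      status <- "pass"; retained <- 1L        # singleton: nothing to filter
    } else if (!is.na(cv) && cv <= cv_cutoff) {
      status <- "pass"; retained <- seq_len(n)
    } else if (m < low_intensity_threshold) {
      status <- "low_intensity_exempt"; retained <- seq_len(n)
    } else if (n > min_keep) {
      bs <- best_cv_subset(x, min_keep)
      if (is.finite(bs$cv_percent) && bs$cv_percent <= cv_cutoff) {
        status <- "best_subset"; retained <- bs$indices
      } else {
        status <- "fail"; retained <- integer()
      }
    } else {
      status <- "fail"; retained <- integer()
    }

    keep[i[retained]] <- TRUE
    rows[[g]] <- data.frame(
      sample = spots$sample[i][1L], feature = spots$feature[i][1L],
      n_replicates = n, mean = m, sd = s, cv_percent = cv,
      cv_undefined = undef, status = status,
      retained = paste(retained, collapse = ","),
      stringsAsFactors = FALSE)
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(spots = spots[keep, , drop = FALSE], report = report)
}

#' Per-sample CV summary table
#'
#' Counts and percentages of (sample, feature) replicate sets at or below /
#' above the CV cutoff, plus the count of out-of-range (undefined, mean <=
#' 0) CVs, per sample.
#'
#' @param report the `report` of [filter_replicates()].
#' @param cv_cutoff the cutoff the report was built with.
#' @return Data frame with columns `sample`, `n_le_cutoff`, `pct_le_cutoff`,
#'   `n_gt_cutoff`, `pct_gt_cutoff`, `n_out_of_range`.
#' @export
cv_summary <- function(report, cv_cutoff = 20) {
  out <- do.call(rbind, lapply(split(report, report$sample), function(r) {
    def <- !is.na(r$cv_percent)
    n_le <- sum(def & r$cv_percent <= cv_cutoff)
    n_gt <- sum(def & r$cv_percent > cv_cutoff)
    data.frame(sample = r$sample[1L], n_le_cutoff = n_le,
               pct_le_cutoff = 100 * n_le / nrow(r), n_gt_cutoff = n_gt,
               pct_gt_cutoff = 100 * n_gt / nrow(r),
               n_out_of_range = sum(r$cv_undefined),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Average retained replicates into a feature-by-sample matrix
#'
#' @param spots retained spot table (output of [filter_replicates()]).
#' @param report the matching CV report; (sample, feature) pairs with
#'   status `"fail"` become missing cells.
#' @param classes feature classes to include as matrix rows (default all
#'   non-buffer classes); pass `"antigen"` for an antigen-only matrix.
#' @return Numeric matrix, features x samples, `NA` for failed cells.
#' @export
average_replicates <- function(spots, report,
                               classes = c("antigen", "control", "tag")) {
  feats <- sort(unique(report$feature))
  if ("feature_class" %in% names(spots)) {
    cls <- spots$feature_class[match(feats, spots$feature)]
    # features whose every replicate set failed carry no class in the
    # retained spots; keep them (as all-NA rows) rather than guessing
    feats <- feats[is.na(cls) | cls %in% classes]
    spots <- spots[spots$feature_class %in% classes, , drop = FALSE]
  }
  samps <- sort(unique(report$sample))
  mat <- matrix(NA_real_, length(feats), length(samps),
                dimnames = list(feats, samps))
  mean_by <- tapply(spots$corrected,
                    list(factor(spots$feature, feats),
                         factor(spots$sample, samps)), mean)
  mat[rownames(mean_by), colnames(mean_by)] <- mean_by
  mat
}

#' Subtract purification-tag signal from tagged antigens
#'
#' Antibody reactivity against the purification tag itself (GST, MBP,
#' His/CD4) contributes to the measured signal of a tagged antigen. For
#' every antigen with a declared tag, the tag feature's replicate-averaged,
#' background-corrected value in the same sample is subtracted; results
#' below `floor` are set to `floor`. This step is optional in the pipeline.
#'
#' @param mat feature-by-sample matrix containing both the antigens and the
#'   tag features ([average_replicates()] with default classes).
#' @param layout an [experiment_layout()].
#' @param floor lower bound after subtraction (default 0).
#' @return The matrix with tagged antigen rows adjusted.
#' @export
subtract_tag <- function(mat, layout, floor = 0) {
  stopifnot(inherits(layout, "experiment_layout"))
  tags <- layout$tag_of[rownames(mat)]
  for (f in rownames(mat)[!is.na(tags)]) {
    t <- tags[[f]]
    if (!t %in% rownames(mat))
      stop("tag feature '", t, "' (for '", f, "') missing from matrix")
    mat[f, ] <- pmax(mat[f, ] - mat[t, ], floor)
  }
  mat
}
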