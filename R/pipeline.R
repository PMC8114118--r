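#' Pipeline configuration
#'
#' Describes a full pre-processing run: data import, background
#' correction, CV-based replicate filtering and averaging, optional
#' purification-tag subtraction, normalisation, and optional batch
#' correction — executed in that fixed order. The whole configuration is
#' serialised into the audit record of the run.
#'
#' @param quantification_files named character vector (or list) of
#'   quantification file paths; names are slide ids (file name stem when
#'   unnamed).
#' @param features_file,blocks_file layout TSV paths.
#' @param out_dir output directory for per-stage matrices and the audit
#'   record.
#' @param dialect a [gpr_dialect()].
#' @param background list: `method`, plus method parameters (see
#'   [bg_correct()]).
#' @param cv list: `cutoff`, `low_intensity_threshold`, `min_keep`.
#' @param tag_subtract `NULL` to skip (optional stage) or a list with
#'   `floor`.
#' @param normalize list: `method` (`"log2"`, `"cyclic_loess"`, `"rlm"`,
#'   `"vsn"`, or `"none"`) plus method parameters (`alpha_hat`; `span`,
#'   `n_cycles`; `controls`; `trim`).
#' @param batch `NULL` to skip (optional stage) or a list with `mode`,
#'   `mean_only`.
#' @param negative_policy how values <= 0 are made loggable before a
#'   log-scale normalisation: `"half_min"` (half the minimum positive
#'   value per sample) or `"na"`.
#' @param seed seed recorded and applied for any stochastic step.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(quantification_files, features_file,
                            blocks_file, out_dir,
                            dialect = gpr_dialect(),
                            background = list(method = "local"),
                            cv = list(cutoff = 20,
                                      low_intensity_threshold = 100,
                                      min_keep = 2),
                            tag_subtract = list(floor = 0),
                            normalize = list(method = "vsn", trim = 0.1),
                            batch = NULL,
                            negative_policy = c("half_min", "na"),
                            seed = 1L) {
  negative_policy <- match.arg(negative_policy)
  structure(list(quantification_files = quantification_files,
                 features_file = features_file, blocks_file = blocks_file,
                 out_dir = out_dir, dialect = dialect,
                 background = background, cv = cv,
                 tag_subtract = tag_subtract, normalize = normalize,
                 batch = batch, negative_policy = negative_policy,
                 seed = seed),
            class = "pipeline_config")
}

# replace non-positive entries per column by half the minimum positive
# value of that column (explicit, counted in the audit record)
.half_min_matrix <- function(mat) {
  n_rep <- 0L
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    bad <- !is.na(x) & x <= 0
    if (!any(bad)) next
    pos <- x[!is.na(x) & x > 0]
    if (!length(pos)) stop("no positive value in sample ", colnames(mat)[j])
    mat[bad, j] <- min(pos) / 2
    n_rep <- n_rep + sum(bad)
  }
  attr(mat, "n_replaced") <- n_rep
  mat
}

#' Run the full pre-processing pipeline
#'
#' Executes the stages of the configuration in order, writing one matrix
#' per stage into `out_dir` together with `audit.json`, a machine-readable
#' record of every stage, its parameters, record counts and warnings.
#' Identical configuration and seed yield identical outputs. On stage
#' failure the run aborts with the stage name and cause; matrices of
#' completed stages remain on disk and a `.partial` marker is left.
#'
#' @param config a [pipeline_config()].
#' @return A list with `matrix` (final feature-by-sample matrix), `stages`
#'   (named list of per-stage matrices), `cv_report`, `fits` (fitted
#'   normalisation / batch parameters) and `audit`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  partial <- file.path(config$out_dir, ".partial")
  file.create(partial)
  audit <- list(list(stage = "config",
                     parameters = .serializable(unclass(config)),
                     package_version =
                       as.character(utils::packageVersion("protarray"))))
  stages <- list()
  fits <- list()
  stage <- "import"

  res <- tryCatch({
    ## import
    qf <- config$quantification_files
    ids <- names(qf)
    if (is.null(ids)) ids <- rep(NA_character_, length(qf))
    frags <- lapply(seq_along(qf), function(i)
      read_quantification_file(qf[[i]], config$dialect,
                               slide_id = if (is.na(ids[i])) NULL
                               else ids[i]))
    layout <- read_layout(config$features_file, config$blocks_file)
    spots <- assemble_experiment(frags, layout)
    audit <- c(audit, list(list(stage = "import",
                                n_spots = nrow(spots),
                                n_slides = length(unique(spots$slide)),
                                n_samples =
                                  length(unique(spots$sample)))))

    ## background correction
    stage <- "background"
    bgp <- config$background
    spots <- do.call(bg_correct, c(list(spots = spots), bgp))
    audit <- c(audit, list(list(stage = "background",
                                parameters = bgp,
                                n_negative_flagged =
                                  sum(spots$neg_flag))))

    ## CV filter + averaging
    stage <- "cv_filter"
    cvp <- config$cv
    flt <- filter_replicates(spots[spots$feature_class != "buffer", ,
                                   drop = FALSE],
                             cv_cutoff = cvp$cutoff,
                             low_intensity_threshold =
                               cvp$low_intensity_threshold,
                             min_keep = cvp$min_keep)
    mat <- average_replicates(flt$spots, flt$report)
    stages$averaged <- mat
    st <- table(flt$report$status)
    audit <- c(audit, list(list(stage = "cv_filter", parameters = cvp,
                                status_counts = as.list(st))))

    ## optional tag subtraction
    if (!is.null(config$tag_subtract)) {
      stage <- "tag_subtract"
      mat <- subtract_tag(mat, layout,
                          floor = config$tag_subtract$floor %||% 0)
      stages$tag_subtracted <- mat
      audit <- c(audit, list(list(stage = "tag_subtract",
                                  parameters = config$tag_subtract)))
    }

    ## normalisation
    stage <- "normalize"
    np <- config$normalize
    extra <- list()
    norm_mat <- switch(np$method %||% "none",
      none = mat,
      log2 = {
        m <- normalize_log2(mat, alpha_hat = np$alpha_hat %||% 0)
        extra$n_undefined <- attr(m, "n_undefined")
        m
      },
      cyclic_loess = {
        m0 <- .half_min_matrix(mat)
        extra$n_negative_replaced <- attr(m0, "n_replaced")
        normalize_cyclic_loess(m0, span = np$span %||% 0.7,
                               n_cycles = np$n_cycles %||% 3L,
                               input_scale = "raw")
      },
      rlm = {
        m0 <- .half_min_matrix(mat)
        extra$n_negative_replaced <- attr(m0, "n_replaced")
        ctrl <- np$controls %||%
          names(layout$feature_class)[layout$feature_class == "control"]
        r <- normalize_rlm(log2(m0), sample_info(layout), controls = ctrl)
        fits$rlm <- r$fit
        r$matrix
      },
      vsn = {
        v <- normalize_vsn(mat, background_corrected = TRUE,
                           trim = np$trim %||% 0.1)
        fits$vsn <- v$fit
        v$matrix
      },
      stop("unknown normalisation method: ", np$method))
    mat <- norm_mat
    stages$normalized <- mat
    audit <- c(audit, list(c(list(stage = "normalize", parameters = np),
                             extra)))

    ## optional batch correction
    if (!is.null(config$batch)) {
      stage <- "batch_correct"
      si <- sample_info(layout)
      bt <- si$batch[match(colnames(mat), si$sample)]
      bc <- combat_adjust(mat, bt,
                          mode = config$batch$mode %||% "parametric",
                          mean_only = isTRUE(config$batch$mean_only))
      fits$batch <- bc$model
      mat <- bc$matrix
      stages$batch_corrected <- mat
      audit <- c(audit, list(list(stage = "batch_correct",
                                  parameters = config$batch,
                                  batches = bc$model$batches)))
    }

    ## persist stage matrices + audit
    stage <- "write"
    for (nm in names(stages))
      write_feature_matrix(stages[[nm]],
                           file.path(config$out_dir,
                                     paste0(nm, ".tsv")),
                           audit = audit, overwrite = TRUE)
    jsonlite::write_json(audit, file.path(config$out_dir, "audit.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    utils::write.table(flt$report,
                       file.path(config$out_dir, "cv_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    file.remove(partial)
    list(matrix = mat, stages = stages, cv_report = flt$report,
         fits = fits, audit = audit)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop non-serialisable bits (functions, environments) from a config list
.serializable <- function(x) {
  if (is.list(x)) return(lapply(x, .serializable))
  if (is.function(x) || is.environment(x)) return(NULL)
  x
}
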