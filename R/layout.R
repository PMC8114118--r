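#' Construct an experiment layout
#'
#' The layout binds the physical slide geometry to the experimental design:
#' it classifies every printed feature (antigen, control, buffer or
#' purification tag), records which purification tag (if any) is fused to an
#' antigen, maps each block (mini-array) of each slide to the serum sample
#' allocated to it, and assigns every sample to a processing batch.
#'
#' @param features data frame with columns `feature`, `class` (one of
#'   `"antigen"`, `"control"`, `"buffer"`, `"tag"`) and optionally `tag`
#'   (tag feature name, `NA`/`""` for untagged features).
#' @param blocks data frame with columns `slide`, `block`, `sample` and
#'   optionally `batch` (defaults to a single batch `"b1"`).
#' @return An object of class `"experiment_layout"`: a list with elements
#'   `feature_class` (named character), `tag_of` (named character, `NA` for
#'   untagged), `block_map` (data frame `slide`, `block`, `sample`) and
#'   `batch_of` (named character, by sample).
#' @examples
#' feats <- data.frame(feature = c("AMA1", "GST"), class = c("antigen", "tag"),
#'                     tag = c("GST", NA))
#' blks <- data.frame(slide = "s1", block = 1:2, sample = c("S1", "S2"))
#' lay <- experiment_layout(feats, blks)
#' @export
experiment_layout <- function(features, blocks) {
  stopifnot(is.data.frame(features), is.data.frame(blocks))
  need_f <- c("feature", "class")
  if (!all(need_f %in% names(features)))
    stop("`features` must have columns: ", paste(need_f, collapse = ", "))
  need_b <- c("slide", "block", "sample")
  if (!all(need_b %in% names(blocks)))
    stop("`blocks` must have columns: ", paste(need_b, collapse = ", "))

  cls <- as.character(features$class)
  ok <- cls %in% c("antigen", "control", "buffer", "tag")
  if (!all(ok))
    stop("unknown feature class(es): ",
         paste(unique(cls[!ok]), collapse = ", "))
  feature_class <- stats::setNames(cls, as.character(features$feature))
  if (anyDuplicated(names(feature_class)))
    stop("duplicated feature names in layout")

  tag <- if ("tag" %in% names(features)) as.character(features$tag) else
    rep(NA_character_, nrow(features))
  tag[!is.na(tag) & tag == ""] <- NA_character_
  tag_of <- stats::setNames(tag, names(feature_class))
  bad_tag <- stats::na.omit(setdiff(tag_of, names(feature_class)))
  if (length(bad_tag))
    stop("tag feature(s) not declared in layout: ",
         paste(bad_tag, collapse = ", "))

  block_map <- data.frame(slide = as.character(blocks$slide),
                          block = as.integer(blocks$block),
                          sample = as.character(blocks$sample),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(block_map[c("slide", "block")]))
    stop("each (slide, block) may map to one sample only")

  if ("batch" %in% names(blocks)) {
    bo <- tapply(as.character(blocks$batch), block_map$sample,
                 function(b) unique(b))
    if (any(lengths(bo) != 1L))
      stop("sample(s) assigned to more than one batch: ",
           paste(names(bo)[lengths(bo) != 1L], collapse = ", "))
    batch_of <- stats::setNames(vapply(bo, `[[`, "", 1L), names(bo))
  } else {
    batch_of <- stats::setNames(rep("b1", length(unique(block_map$sample))),
                                unique(block_map$sample))
  }

  structure(list(feature_class = feature_class, tag_of = tag_of,
                 block_map = block_map, batch_of = batch_of),
            class = "experiment_layout")
}

#' Read a layout from two plain TSV files
#'
#' @param features_path TSV with columns `feature`, `class`, `tag`.
#' @param blocks_path TSV with columns `slide`, `block`, `sample`, `batch`.
#' @return An [experiment_layout()].
#' @export
read_layout <- function(features_path, blocks_path) {
  fe <- utils::read.delim(features_path, stringsAsFactors = FALSE)
  bl <- utils::read.delim(blocks_path, stringsAsFactors = FALSE)
  experiment_layout(fe, bl)
}

#' Write a layout to two plain TSV files
#'
#' @param layout an [experiment_layout()].
#' @param features_path,blocks_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_layout <- function(layout, features_path, blocks_path) {
  stopifnot(inherits(layout, "experiment_layout"))
  fe <- data.frame(feature = names(layout$feature_class),
                   class = unname(layout$feature_class),
                   tag = unname(layout$tag_of), stringsAsFactors = FALSE)
  bl <- layout$block_map
  bl$batch <- unname(layout$batch_of[bl$sample])
  utils::write.table(fe, features_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bl, blocks_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(features_path, blocks_path))
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat("experiment_layout:",
      length(x$feature_class), "features (",
      sum(x$feature_class == "antigen"), "antigens,",
      sum(x$feature_class == "control"), "controls,",
      sum(x$feature_class == "buffer"), "buffer,",
      sum(x$feature_class == "tag"), "tags ),",
      nrow(x$block_map), "blocks,",
      length(unique(x$block_map$sample)), "samples,",
      length(unique(x$batch_of)), "batch(es)\n")
  invisible(x)
}
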