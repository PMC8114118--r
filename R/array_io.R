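#' Parser dialect for GenePix-style quantification files
#'
#' Quantification software (GenePix Pro, ScanArray/ProScanArray, QuantArray)
#' writes tab-delimited files that differ only in the header convention and
#' in the labels of the per-spot intensity columns. A dialect pins both down
#' explicitly; nothing is sniffed silently.
#'
#' @param header `"atf"` for an ATF preamble (`ATF<tab>1.0` on line 1 and a
#'   declared header-line count on line 2), or a non-negative integer giving
#'   a fixed number of lines to skip before the column-label row.
#' @param fg,bg character vectors of accepted column labels for the
#'   foreground and background statistic, tried in order. Defaults are the
#'   median columns; mean columns can be selected by supplying e.g.
#'   `fg = "F635 Mean"`.
#' @param block,row,col,name accepted labels for the coordinate and feature
#'   name columns.
#' @param flag accepted labels for the (optional) scanner flag column.
#' @param diameter accepted labels for the (optional) spot diameter column.
#' @return A list of class `"gpr_dialect"`.
#' @export
gpr_dialect <- function(header = "atf",
                        fg = c("F635 Median", "F532 Median", "FMedian"),
                        bg = c("B635 Median", "B532 Median", "BMedian"),
                        block = c("Block"), row = c("Row"),
                        col = c("Column", "Col"),
                        name = c("Name", "ID"),
                        flag = c("Flags", "Flag"),
                        diameter = c("Dia.", "Diameter")) {
  if (!(identical(header, "atf") ||
        (is.numeric(header) && length(header) == 1L && header >= 0)))
    stop("`header` must be \"atf\" or a non-negative line count")
  structure(list(header = header, fg = fg, bg = bg, block = block,
                 row = row, col = col, name = name, flag = flag,
                 diameter = diameter),
            class = "gpr_dialect")
}

# resolve the first matching alias for a mandatory column, or stop
.resolve_col <- function(labels, aliases, what, path, optional = FALSE) {
  hit <- aliases[aliases %in% labels]
  if (!length(hit)) {
    if (optional) return(NA_character_)
    stop("mandatory column for ", what, " not found in '", basename(path),
         "' (tried: ", paste(aliases, collapse = ", "), ")")
  }
  hit[[1L]]
}

#' Read one GenePix-style quantification file
#'
#' Reads the per-spot table of a single slide into a long-format spot table
#' fragment carrying the block/row/column coordinates, the feature name and
#' the foreground and background intensity statistic named by the dialect.
#' One wavelength channel is processed per run; the channel is chosen by the
#' dialect's column labels.
#'
#' @param path path to a tab-delimited quantification file.
#' @param dialect a [gpr_dialect()].
#' @param slide_id slide identifier; defaults to the file name without
#'   extension.
#' @return A data frame (one row per spot) with columns `slide`, `block`,
#'   `row`, `col`, `feature`, `fg`, `bg`, `flag`, `diameter`.
#' @export
read_quantification_file <- function(path, dialect = gpr_dialect(),
                                     slide_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(slide_id))
    slide_id <- sub("\\.[^.]*$", "", basename(path))

  if (identical(dialect$header, "atf")) {
    head2 <- readLines(path, n = 2L)
    if (length(head2) < 2L || !grepl("^ATF", head2[[1L]]))
      stop("'", basename(path), "' has no ATF preamble; use a numeric ",
           "`header` in the dialect for headerless files")
    n_opt <- suppressWarnings(
      as.integer(strsplit(head2[[2L]], "\t", fixed = TRUE)[[1L]][1L]))
    if (is.na(n_opt)) stop("malformed ATF header-count line in ", path)
    skip <- 2L + n_opt
  } else {
    skip <- as.integer(dialect$header)
  }

  tab <- utils::read.delim(path, skip = skip, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  if (nrow(tab) == 0L) stop("empty data section in ", path)
  labels <- names(tab)

  cget <- function(field, optional = FALSE)
    .resolve_col(labels, dialect[[field]], field, path, optional)
  c_block <- cget("block"); c_row <- cget("row"); c_col <- cget("col")
  c_name <- cget("name"); c_fg <- cget("fg"); c_bg <- cget("bg")
  c_flag <- cget("flag", optional = TRUE)
  c_dia <- cget("diameter", optional = TRUE)

  num <- function(colname, what) {
    v <- tab[[colname]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & v != "")
    if (length(bad))
      stop("non-numeric ", what, " value in '", basename(path),
           "' at data row ", bad[[1L]], ": '", v[bad[[1L]]], "'")
    out
  }

  out <- data.frame(
    slide = slide_id,
    block = as.integer(num(c_block, "block")),
    row = as.integer(num(c_row, "row")),
    col = as.integer(num(c_col, "col")),
    feature = as.character(tab[[c_name]]),
    fg = num(c_fg, "foreground"),
    bg = num(c_bg, "background"),
    flag = if (is.na(c_flag)) 0L else as.integer(num(c_flag, "flag")),
    diameter = if (is.na(c_dia)) NA_real_ else num(c_dia, "diameter"),
    stringsAsFactors = FALSE)
  if (any(out$fg < 0 | out$bg < 0, na.rm = TRUE))
    stop("negative raw intensity in ", path,
         " (raw medians must be non-negative)")
  out
}

#' Assemble spot-table fragments into one annotated spot table
#'
#' Joins per-slide fragments with the layout: each spot receives its sample,
#' feature class, purification tag and batch, and a `replicate_index`
#' numbering the technical replicates of a feature within a sample in
#' row-major (block, row, col) order.
#'
#' @param fragments a data frame as returned by
#'   [read_quantification_file()], or a list of such data frames.
#' @param layout an [experiment_layout()].
#' @return The assembled spot table (data frame) with columns of the
#'   fragments plus `sample`, `feature_class`, `tag`, `batch`,
#'   `replicate_index`.
#' @export
assemble_experiment <- function(fragments, layout) {
  stopifnot(inherits(layout, "experiment_layout"))
  if (is.data.frame(fragments)) fragments <- list(fragments)
  spots <- do.call(rbind, fragments)
  rownames(spots) <- NULL

  key <- paste(spots$slide, spots$block, spots$row, spots$col, sep = "\r")
  if (anyDuplicated(key)) {
    d <- spots[duplicated(key), c("slide", "block", "row", "col")][1L, ]
    stop("duplicate spot coordinates, first at slide ", d$slide,
         " block ", d$block, " row ", d$row, " col ", d$col)
  }

  bm <- layout$block_map
  bkey <- paste(bm$slide, bm$block, sep = "\r")
  skey <- paste(spots$slide, spots$block, sep = "\r")
  hit <- match(skey, bkey)
  if (anyNA(hit)) {
    orphans <- unique(skey[is.na(hit)])
    stop("block(s) not present in layout: ",
         paste(gsub("\r", ":", orphans), collapse = ", "))
  }
  spots$sample <- bm$sample[hit]

  fc <- layout$feature_class[spots$feature]
  if (anyNA(fc))
    stop("feature(s) with no class in layout: ",
         paste(unique(spots$feature[is.na(fc)]), collapse = ", "))
  spots$feature_class <- unname(fc)
  spots$tag <- unname(layout$tag_of[spots$feature])
  spots$batch <- unname(layout$batch_of[spots$sample])

  # replicate index: within-(sample, feature) order of (block, row, col)
  o <- order(spots$sample, spots$feature, spots$block, spots$row, spots$col)
  grp <- paste(spots$sample[o], spots$feature[o], sep = "\r")
  ri <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  spots$replicate_index <- NA_integer_
  spots$replicate_index[o] <- as.integer(ri)
  spots
}

#' Write a feature-by-sample matrix with an audit record
#'
#' Writes the matrix as a TSV (features as rows, samples as columns) at full
#' floating precision, together with a JSON audit companion
#' (`<path>.audit.json`) listing every processing step applied and its
#' parameters.
#'
#' @param mat numeric matrix with feature rownames and sample colnames.
#' @param path output TSV path.
#' @param audit list of audit entries (one per pipeline stage), each a list
#'   with at least a `stage` element.
#' @param overwrite overwrite an existing file?
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(mat, path, audit = list(),
                                 overwrite = FALSE) {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("matrix must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("feature and sample labels must be unique")
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; set overwrite = TRUE to replace it")

  df <- data.frame(feature = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(audit, paste0(path, ".audit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a feature-by-sample matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}
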