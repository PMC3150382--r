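## delimiter by file extension: .csv -> comma, anything else -> tab
sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read/write labelled matrices and label files
#'
#' All tabular interchange uses TSV (or CSV by extension) with a header row
#' and a first column of row labels. Distance/similarity matrices must be
#' square and symmetric within 1e-8.
#'
#' @param path file path.
#' @return `read_matrix_file`: labelled numeric matrix. `read_dist_file`:
#'   validated distance matrix. `read_labels_file`: named character vector
#'   (leaf id -> class). `read_merge_file`: data.frame (item_a, item_b,
#'   height).
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          row.names = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @rdname read_matrix_file
#' @export
read_dist_file <- function(path) as_dist_matrix(read_matrix_file(path))

#' @rdname read_matrix_file
#' @param x matrix / labels / merge table to write.
#' @export
write_matrix_file <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_matrix_file
#' @export
read_labels_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = sep_for(path),
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stop("labels file needs 2 columns: leaf id, class",
                          call. = FALSE)
  if (identical(tolower(as.character(df[1, 1])), "id")) df <- df[-1, ]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_matrix_file
#' @export
write_labels_file <- function(x, path) {
  utils::write.table(data.frame(names(x), unname(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_matrix_file
#' @export
read_merge_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = sep_for(path),
                          stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop("merge table needs 3 columns", call. = FALSE)
  names(df) <- c("item_a", "item_b", "height")
  df$height <- as.numeric(df$height)
  df
}
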