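#' First-principal-component scores of the samples
#'
#' Projects each sample (row) onto the first principal axis of the
#' column-centered data. Used as the external reference for HC-PCA node
#' flipping. The axis sign is fixed so that the loading with the largest
#' magnitude is positive, making the scores deterministic.
#'
#' @param data numeric matrix, samples in rows, features in columns; no
#'   missing values, at least 2 samples.
#' @param scale. standardise columns to unit variance before projecting
#'   (default `FALSE`: centering only).
#' @return named numeric vector, one score per sample.
#' @export
pc1_scores <- function(data, scale. = FALSE) {
  x <- as.matrix(data)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(x)) stop("data contains missing values", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (all(apply(x, 2L, stats::var) < .Machine$double.eps))
    stop("constant data: zero variance in every feature", call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  load1 <- p$rotation[, 1L]
  if (load1[which.max(abs(load1))] < 0) {
    load1 <- -load1
    p$x[, 1L] <- -p$x[, 1L]
  }
  stats::setNames(p$x[, 1L], rownames(x))
}

#' Flip dendrogram nodes against an external reference score
#'
#' Every internal node is flipped iff the mean reference score of its right
#' subtree is strictly less than the mean of its left subtree, so scores read
#' ascending left to right wherever the hierarchy permits. Equal means leave
#' the node untouched. The cluster hierarchy is preserved.
#'
#' @param tree a [sym_tree()].
#' @param ref named numeric vector of finite scores covering every leaf.
#' @return list with `tree` (reordered) and `flipped` (node indices).
#' @export
order_by_reference <- function(tree, ref) {
  miss <- setdiff(tree$labels, names(ref))
  if (length(miss))
    stop("reference scores missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ref[tree$labels])))
    stop("reference scores must be finite", call. = FALSE)
  leafsets <- node_leafsets(tree)
  flipped <- integer(0)
  for (nd in seq_len(nrow(tree$merge))) {
    lfs <- tree$labels[child_leafset(tree, tree$merge[nd, 1L], leafsets)]
    rfs <- tree$labels[child_leafset(tree, tree$merge[nd, 2L], leafsets)]
    if (mean(ref[rfs]) < mean(ref[lfs])) flipped <- c(flipped, nd)
  }
  for (nd in flipped) tree <- flip_node(tree, nd)
  list(tree = tree, flipped = flipped)
}
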