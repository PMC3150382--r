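#' Hierarchical clustering with boundary-seeking leaf reordering
#'
#' One-stop interface: cluster the samples (or accept a precomputed tree),
#' reorder the dendrogram leaves by the requested method, and return a classed
#' result with the displayed order, the reordering log, and -- when class
#' labels are supplied -- supervised seriation quality.
#'
#' Methods:
#' \describe{
#'   \item{`"hc-sym"`}{bilateral-symmetric reordering ([hc_sym()]): at each
#'     selected node, the most similar objects of the left and right subtree
#'     are greedily paired and pulled to the cluster boundary.}
#'   \item{`"hc-pca"`}{node flipping against the samples' first principal
#'     component ([pc1_scores()] + [order_by_reference()]); needs the raw
#'     data matrix.}
#'   \item{`"hc"`}{the clustering's own deterministic default order, no
#'     reordering.}
#' }
#'
#' @param x samples-by-features numeric matrix, or a precomputed symmetric
#'   distance matrix (square, zero diagonal), or a `dist` object.
#' @param method reordering method, see Details.
#' @param metric distance between samples when `x` is a data matrix:
#'   `"pearson"` (1 - Pearson's r, the default) or `"euclidean"`.
#' @param labels optional named vector (leaf id -> class) for supervised
#'   scoring.
#' @param level,br,sr HC-SYM node-selection parameters, see
#'   [select_target_nodes()]; defaults `level = 1`, `br = 0.3`, `sr = 0.03`.
#' @param unpaired_mode placement reference for unpaired members, see
#'   [build_sym_vector()].
#' @param tree optional precomputed [sym_tree()] (skips clustering).
#' @return object of class `"hcsym"`: list with `tree`, `base_tree`, `order`,
#'   `method`, `params`, `dist`, `labels`, `log`, `call`.
#' @examples
#' sim <- make_clustered_data(c(10, 8), dim = 10, separation = 6, seed = 42)
#' fit <- hcsym(sim$data, labels = sim$labels)
#' fit
#' summary(fit)
#' @export
hcsym <- function(x, method = c("hc-sym", "hc", "hc-pca"),
                  metric = c("pearson", "euclidean"), labels = NULL,
                  level = 1L, br = 0.3, sr = 0.03,
                  unpaired_mode = c("own", "adjacent"), tree = NULL) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  unpaired_mode <- match.arg(unpaired_mode)
  check_params(level, br, sr)

  is_distance <- inherits(x, "dist") ||
    (is.matrix(x) && nrow(x) == ncol(x) &&
       !is.null(rownames(x)) && identical(rownames(x), colnames(x)) &&
       max(abs(x - t(x))) < 1e-8 && all(abs(diag(x)) < 1e-8))
  if (is_distance) {
    d <- as_dist_matrix(x)
    data <- NULL
    if (method == "hc-pca")
      stop("method 'hc-pca' needs the raw data matrix, not a distance matrix",
           call. = FALSE)
  } else {
    data <- as.matrix(x)
    if (is.null(rownames(data))) rownames(data) <- as.character(seq_len(nrow(data)))
    d <- row_distances(data, metric)
  }

  base_tree <- if (is.null(tree)) cluster_average_linkage(d) else as_sym_tree(tree)
  check_ids(base_tree$labels, d)

  log <- list()
  out_tree <- base_tree
  if (method == "hc-sym") {
    res <- hc_sym(base_tree, d, level = level, br = br, sr = sr,
                  unpaired_mode = unpaired_mode)
    out_tree <- res$tree
    log <- res$log
  } else if (method == "hc-pca") {
    ref <- pc1_scores(data)
    res <- order_by_reference(base_tree, ref)
    out_tree <- res$tree
    log <- list(list(node = nrow(base_tree$merge), method = "pca-reference",
                     flipped_nodes = res$flipped))
  }

  if (!is.null(labels)) labels <- validate_labels(labels, out_tree$labels)

  structure(list(tree = out_tree, base_tree = base_tree,
                 order = leaf_order(out_tree), method = method,
                 params = list(level = as.integer(level), br = br, sr = sr,
                               unpaired_mode = unpaired_mode, metric = metric),
                 dist = d, labels = labels, log = log, call = match.call()),
            class = "hcsym")
}

#' @export
print.hcsym <- function(x, ...) {
  cat("Leaf-reordered hierarchical clustering ('hcsym')\n")
  cat("  method:", x$method, " leaves:", length(x$order), "\n")
  if (x$method == "hc-sym")
    cat("  params: level =", x$params$level, " br =", x$params$br,
        " sr =", x$params$sr, "\n")
  nflip <- sum(vapply(x$log, function(e) length(e$flipped_nodes), integer(1)))
  if (x$method != "hc") cat("  nodes flipped:", nflip, "\n")
  if (!is.null(x$labels))
    cat("  seriation rate:", format(seriation_rate(x$order, x$labels)$SR,
                                    digits = 4), "\n")
  invisible(x)
}

#' @export
summary.hcsym <- function(object, windows = NULL, ...) {
  out <- list(method = object$method, n = length(object$order),
              params = object$params)
  if (!is.null(object$labels)) {
    sr <- seriation_rate(object$order, object$labels)
    base_sr <- seriation_rate(leaf_order(object$base_tree), object$labels)
    out$SR <- sr$SR
    out$SR_base <- base_sr$SR
    out$classes <- sr$classes
  }
  if (!is.null(windows)) {
    sim <- 1 - object$dist / max(object$dist)
    out$gar <- gar_profile(sim, object$order, windows)
  }
  structure(out, class = "summary.hcsym")
}

#' @export
print.summary.hcsym <- function(x, ...) {
  cat("Reordering method:", x$method, " (", x$n, "leaves )\n")
  if (!is.null(x$SR)) {
    cat(sprintf("Seriation rate: %.4f (default order: %.4f)\n", x$SR, x$SR_base))
    print(x$classes, row.names = FALSE)
  }
  if (!is.null(x$gar)) {
    cat("Generalized anti-Robinson profile:\n")
    print(x$gar)
  }
  invisible(x)
}

#' @export
leaf_order.hcsym <- function(tree, ...) tree$order

#' @export
as.hclust.hcsym <- function(x, ...) as.hclust(x$tree)

#' Plot a reordered dendrogram, optionally with its proximity view
#'
#' @param x an [hcsym()] fit.
#' @param proximity also draw the similarity matrix (1 - scaled distance)
#'   permuted by the displayed leaf order, as a heatmap below the tree.
#' @param ... passed to [graphics::plot()] for the dendrogram.
#' @export
plot.hcsym <- function(x, proximity = FALSE, ...) {
  hc <- as.hclust(x)
  if (proximity) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(1, 4, 2, 1))
    on.exit(graphics::par(op))
    plot(hc, hang = -1, xlab = "", sub = "", ...)
    sim <- 1 - x$dist / max(x$dist)
    P <- sim[x$order, rev(x$order)]
    graphics::image(seq_along(x$order), seq_along(x$order), P,
                    xlab = "", ylab = "", axes = FALSE,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  } else {
    plot(hc, hang = -1, xlab = "", sub = "", ...)
  }
  invisible(x)
}
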