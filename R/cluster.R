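#' Validate a square labelled distance matrix
#'
#' Checks the contract every reordering function relies on: square numeric
#' matrix, unique row/column labels, symmetric within `tol`, zero diagonal,
#' no missing values. Offending cells are named in the error.
#'
#' @param d numeric matrix (or `dist` object, which is expanded).
#' @param tol symmetry/diagonal tolerance (absolute), default 1e-8.
#' @return the validated matrix with `dimnames` set, invisibly usable.
#' @export
as_dist_matrix <- function(d, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d))
    stop("distance input must be a numeric matrix or 'dist' object", call. = FALSE)
  n <- nrow(d)
  if (ncol(d) != n) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- as.character(seq_len(n))
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (!identical(rownames(d), colnames(d)))
    stop("row and column labels differ", call. = FALSE)
  if (anyDuplicated(rownames(d)))
    stop("duplicate labels: ",
         paste(unique(rownames(d)[duplicated(rownames(d))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1, , drop = TRUE]
    stop("distance matrix contains NA, e.g. at (",
         rownames(d)[bad[1]], ", ", colnames(d)[bad[2]], ")", call. = FALSE)
  }
  asym <- abs(d - t(d))
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1, , drop = TRUE]
    stop("distance matrix not symmetric within ", tol, ": d(",
         rownames(d)[bad[1]], ",", colnames(d)[bad[2]], ") = ",
         d[bad[1], bad[2]], " vs ", d[bad[2], bad[1]], call. = FALSE)
  }
  if (max(abs(diag(d))) > tol) {
    bad <- which.max(abs(diag(d)))
    stop("nonzero diagonal at '", rownames(d)[bad], "': ", d[bad, bad],
         call. = FALSE)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Pairwise distances between sample rows
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param metric `"pearson"` for the Pearson correlation distance 1 - r
#'   (r computed across features), or `"euclidean"`.
#' @return labelled symmetric distance matrix (zero diagonal).
#' @export
row_distances <- function(x, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (anyNA(x)) stop("data matrix contains missing values", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  d <- switch(metric,
    pearson = {
      if (ncol(x) < 2L)
        stop("Pearson distance needs at least 2 features", call. = FALSE)
      sds <- apply(x, 1L, stats::sd)
      if (any(sds == 0))
        stop("constant rows (zero variance) have no Pearson correlation: ",
             paste(rownames(x)[sds == 0], collapse = ", "), call. = FALSE)
      1 - stats::cor(t(x))
    },
    euclidean = as.matrix(stats::dist(x))
  )
  dimnames(d) <- list(rownames(x), rownames(x))
  as_dist_matrix(d, tol = 1e-6)
}

#' Deterministic average-linkage agglomerative clustering
#'
#' Standard UPGMA agglomeration with two conventions fixed so that the "HC
#' default" dendrogram is reproducible across platforms:
#' \itemize{
#'   \item tie-break at merge selection: among pairs at the minimum distance,
#'     merge the pair whose smaller original member index is least (then the
#'     least partner index);
#'   \item child order: the cluster containing the lower original index
#'     becomes the left child.
#' }
#' Inter-cluster distances follow the unweighted average (Lance-Williams with
#' size weights), identical to `hclust(method = "average")`.
#'
#' @param dist labelled distance matrix (validated via [as_dist_matrix()]).
#' @return a [sym_tree()].
#' @examples
#' d <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' leaf_order(cluster_average_linkage(d))
#' @export
cluster_average_linkage <- function(dist) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 objects to cluster", call. = FALSE)
  labels <- rownames(d)
  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minidx <- seq_len(n)          # least original index in each cluster
  code <- -seq_len(n)           # merge code of the cluster seated at slot i
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    Dv <- D
    Dv[!active, ] <- Inf
    Dv[, !active] <- Inf
    dmin <- min(Dv)
    cand <- which(Dv <= dmin + abs(dmin) * 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    lo <- pmin(minidx[cand[, 1L]], minidx[cand[, 2L]])
    hi <- pmax(minidx[cand[, 1L]], minidx[cand[, 2L]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    # left child = cluster containing the lower original index
    if (minidx[i] > minidx[j]) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- c(code[i], code[j])
    height[step] <- D[i, j]
    # UPGMA update into slot i
    upd <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    D[i, ] <- upd
    D[, i] <- upd
    D[i, i] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    minidx[i] <- min(minidx[i], minidx[j])
    code[i] <- step
  }
  sym_tree(merge, height, labels)
}
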