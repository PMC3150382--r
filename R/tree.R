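#' Binary dendrogram with significant child order
#'
#' A `sym_tree` stores a rooted binary merge tree the way [stats::hclust()]
#' does -- an (n-1) x 2 merge matrix (negative entries index leaves, positive
#' entries index earlier merge rows), a merge height per row, and leaf labels
#' -- but with one extra contract: the column order of each merge row *is* the
#' displayed left/right order of that node's children. Flipping a node swaps
#' its two entries and nothing else, so the cluster hierarchy is untouched.
#'
#' @param merge integer matrix, (n-1) x 2; negative values -i refer to leaf
#'   `labels[i]`, positive values j refer to the cluster created in row j.
#'   Each leaf and each non-root row must be referenced exactly once, and the
#'   last row is the root.
#' @param height numeric vector of n-1 nonnegative merge heights.
#' @param labels character vector of n unique leaf ids.
#' @return An object of class `sym_tree`.
#' @examples
#' tr <- sym_tree(matrix(c(-1, -2), 1), 0.4, c("a", "b"))
#' leaf_order(tr)
#' @export
sym_tree <- function(merge, height, labels) {
  merge <- matrix(as.integer(merge), ncol = 2L)
  height <- as.numeric(height)
  labels <- as.character(labels)
  tr <- structure(list(merge = merge, height = height, labels = labels),
                  class = "sym_tree")
  validate_sym_tree(tr)
  tr
}

validate_sym_tree <- function(tree) {
  m <- tree$merge
  n <- length(tree$labels)
  if (n < 2L) stop("a dendrogram needs at least 2 leaves", call. = FALSE)
  if (anyDuplicated(tree$labels))
    stop("duplicate leaf labels: ",
         paste(unique(tree$labels[duplicated(tree$labels)]), collapse = ", "),
         call. = FALSE)
  if (nrow(m) != n - 1L || ncol(m) != 2L)
    stop("merge must have n-1 = ", n - 1L, " rows and 2 columns", call. = FALSE)
  if (length(tree$height) != n - 1L)
    stop("height must have n-1 entries", call. = FALSE)
  if (anyNA(m) || anyNA(tree$height))
    stop("merge/height contain missing values", call. = FALSE)
  ref <- as.vector(m)
  leaves <- -ref[ref < 0L]
  rows <- ref[ref > 0L]
  if (any(ref == 0L)) stop("merge entries must be nonzero", call. = FALSE)
  if (!setequal(leaves, seq_len(n)) || anyDuplicated(leaves))
    stop("each of the ", n, " leaves must appear exactly once in merge",
         call. = FALSE)
  if (!setequal(rows, seq_len(n - 1L)[-(n - 1L)]) || anyDuplicated(rows))
    stop("each non-root merge row must be referenced exactly once", call. = FALSE)
  for (i in seq_len(n - 1L)) {
    kids <- m[i, ]
    if (any(kids >= i & kids > 0L))
      stop("merge row ", i, " references a later row", call. = FALSE)
  }
  invisible(tree)
}

#' @export
print.sym_tree <- function(x, ...) {
  cat("Binary dendrogram ('sym_tree')\n")
  cat("  leaves:", length(x$labels), " internal nodes:", nrow(x$merge), "\n")
  ord <- leaf_order(x)
  show <- if (length(ord) > 8) c(ord[1:8], "...") else ord
  cat("  leaf order:", paste(show, collapse = " "), "\n")
  invisible(x)
}

n_leaves <- function(tree) length(tree$labels)

#' Leaf sets under each internal node
#'
#' @param tree a [sym_tree()].
#' @return list of integer vectors (sorted leaf indices), one per merge row.
#' @keywords internal
node_leafsets <- function(tree) {
  m <- tree$merge
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    kids <- m[i, ]
    s <- integer(0)
    for (k in kids) s <- c(s, if (k < 0L) -k else out[[k]])
    out[[i]] <- sort(s)
  }
  out
}

## leaf indices (not labels) under one child entry of a merge row
child_leafset <- function(tree, entry, leafsets = NULL) {
  if (entry < 0L) return(-entry)
  if (!is.null(leafsets)) return(leafsets[[entry]])
  node_leafsets(tree)[[entry]]
}

#' Left-to-right leaf order of a dendrogram
#'
#' Reads the leaves of a tree in display order: an in-order traversal where
#' each merge row's first column is drawn left of its second.
#'
#' @param tree a [sym_tree()] or [hcsym()] fit.
#' @param ... unused.
#' @return character vector of leaf ids, leftmost first.
#' @export
leaf_order <- function(tree, ...) UseMethod("leaf_order")

#' @rdname leaf_order
#' @param node internal node (merge row index) at which to start; defaults to
#'   the root.
#' @export
leaf_order.sym_tree <- function(tree, node = nrow(tree$merge), ...) {
  m <- tree$merge
  out <- integer(n_leaves(tree))
  pos <- 0L
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cur < 0L) {
      pos <- pos + 1L
      out[pos] <- -cur
    } else {
      stack <- c(stack, m[cur, 2L], m[cur, 1L])
    }
  }
  tree$labels[out[seq_len(pos)]]
}

#' Swap the two children of an internal node
#'
#' Exchanges the left and right subtrees of one internal node. The cluster
#' hierarchy (which leaf sets form clades, at which heights) is unchanged;
#' only the displayed leaf order moves. Flipping the same node twice restores
#' the original tree.
#'
#' @param tree a [sym_tree()].
#' @param node internal node index (merge row, 1-based).
#' @return the tree with that node's children swapped.
#' @export
flip_node <- function(tree, node) {
  node <- as.integer(node)
  if (length(node) != 1L || is.na(node) || node < 1L || node > nrow(tree$merge))
    stop("'node' must be an internal node index in 1..", nrow(tree$merge),
         " (leaves cannot be flipped)", call. = FALSE)
  tree$merge[node, ] <- tree$merge[node, 2:1]
  tree
}

#' Clade signature: the hierarchy as a set of leaf sets
#'
#' The leaf-label set below each internal node, canonically sorted. Two trees
#' have equal signatures iff they encode the same cluster hierarchy, so the
#' signature is the test oracle for "reordering never alters the clustering":
#' it is invariant under any sequence of [flip_node()] calls.
#'
#' @param tree a [sym_tree()].
#' @return sorted character vector, one `"\{id,id,...\}"` string per clade.
#' @export
clade_signature <- function(tree) {
  sets <- node_leafsets(tree)
  sig <- vapply(sets, function(s)
    paste(sort(tree$labels[s]), collapse = ","), character(1))
  sort(sig)
}

node_depths <- function(tree) {
  m <- tree$merge
  depth <- integer(nrow(m))
  depth[nrow(m)] <- 0L
  for (i in rev(seq_len(nrow(m)))) {
    for (k in m[i, ]) if (k > 0L) depth[k] <- depth[i] + 1L
  }
  depth
}

## internal nodes in pre-order (parent before children, left before right)
preorder_nodes <- function(tree, node = nrow(tree$merge)) {
  m <- tree$merge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (cur > 0L) {
      out <- c(out, cur)
      stack <- c(stack, m[cur, 2L], m[cur, 1L])
    }
  }
  out
}

#' Convert between sym_tree and hclust
#'
#' @param x a `sym_tree` (or an `hcsym` fit).
#' @param ... unused.
#' @return [stats::hclust] object whose merge/order reflect the displayed
#'   child order.
#' @export
as.hclust.sym_tree <- function(x, ...) {
  ord <- match(leaf_order(x), x$labels)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' @rdname as.hclust.sym_tree
#' @param keep_order if `TRUE` (default) the hclust object's displayed order
#'   is adopted as the tree's left/right child order.
#' @export
as_sym_tree <- function(x, keep_order = TRUE, ...) UseMethod("as_sym_tree")

#' @export
as_sym_tree.hclust <- function(x, keep_order = TRUE, ...) {
  labels <- x$labels
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x$merge) + 1L))
  sym_tree(x$merge, x$height, labels)
}

#' @export
as_sym_tree.sym_tree <- function(x, keep_order = TRUE, ...) x

#' Build a dendrogram from an explicit merge table
#'
#' The inverse of [tree_to_merge_table()]: reconstructs a `sym_tree` from a
#' three-column table listing, in merge order, the two cluster representatives
#' joined at each step and the merge height. A cluster is named by any leaf it
#' contains (its representative is the leaf named when it was last merged),
#' and column order gives the left/right child order.
#'
#' @param merge_table data.frame with columns `item_a`, `item_b`, `height`
#'   (names are positional; any 3-column table works).
#' @param labels optional full leaf id set; defaults to the ids appearing in
#'   the table.
#' @return a [sym_tree()].
#' @export
linkage_to_tree <- function(merge_table, labels = NULL) {
  mt <- as.data.frame(merge_table)
  if (ncol(mt) < 3L) stop("merge table needs 3 columns (item_a, item_b, height)",
                          call. = FALSE)
  a <- as.character(mt[[1]]); b <- as.character(mt[[2]])
  h <- as.numeric(mt[[3]])
  ids <- unique(c(a, b))
  if (is.null(labels)) labels <- ids
  labels <- as.character(labels)
  unknown <- setdiff(ids, labels)
  if (length(unknown))
    stop("merge table references unknown ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(labels)
  if (nrow(mt) != n - 1L)
    stop("merge table has ", nrow(mt), " rows; expected n-1 = ", n - 1L,
         call. = FALSE)
  # representative leaf -> current merge code (negative leaf or row index)
  code <- structure(-seq_len(n), names = labels)
  active <- structure(rep(TRUE, n), names = labels)
  merge <- matrix(0L, n - 1L, 2L)
  for (i in seq_len(n - 1L)) {
    for (nm in c(a[i], b[i])) {
      if (!nm %in% labels) stop("unknown id '", nm, "' in merge table", call. = FALSE)
      if (!active[nm])
        stop("id '", nm, "' used after its cluster was already merged (row ", i, ")",
             call. = FALSE)
    }
    if (a[i] == b[i]) stop("merge row ", i, " joins a cluster with itself", call. = FALSE)
    merge[i, ] <- c(code[a[i]], code[b[i]])
    active[b[i]] <- FALSE
    code[a[i]] <- i
  }
  if (sum(active) != 1L)
    stop("merge table is incomplete: ", sum(active),
         " clusters remain after the last row", call. = FALSE)
  sym_tree(merge, h, labels)
}

#' Export a dendrogram as a merge table
#'
#' @param tree a [sym_tree()].
#' @return data.frame with columns `item_a`, `item_b`, `height`; each cluster
#'   is represented by its leftmost-at-creation leaf.
#' @export
tree_to_merge_table <- function(tree) {
  m <- tree$merge
  rep_of <- character(nrow(m))
  nm <- function(k) if (k < 0L) tree$labels[-k] else rep_of[k]
  a <- character(nrow(m)); b <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    a[i] <- nm(m[i, 1L]); b[i] <- nm(m[i, 2L])
    rep_of[i] <- a[i]
  }
  data.frame(item_a = a, item_b = b, height = tree$height,
             stringsAsFactors = FALSE)
}
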