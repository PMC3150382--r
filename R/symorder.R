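#' Bilateral symmetric distance between two ordered adjacent clusters
#'
#' For a left cluster displayed as `orderL` (leftmost first) and a right
#' cluster displayed as `orderR`, the i-th symmetric pair joins the i-th leaf
#' counting inward from the right end of L with the i-th leaf counting inward
#' from the left end of R. The bilateral symmetric distance is
#' \deqn{B = \sum_{i=1}^{k} d(L_{m-i+1}, R_i), \quad k = \min(|L|, |R|),}
#' the sum of the k symmetric pair distances. B is minimised when similar
#' objects sit at the cluster boundary, inner pairs closest.
#'
#' @param orderL,orderR character vectors of leaf ids, displayed left-to-right;
#'   disjoint and nonempty.
#' @param dist labelled distance matrix covering all ids.
#' @return nonnegative scalar B.
#' @export
bilateral_symmetric_distance <- function(orderL, orderR, dist) {
  check_ids(c(orderL, orderR), dist)
  if (!length(orderL) || !length(orderR))
    stop("both clusters must be nonempty", call. = FALSE)
  if (length(intersect(orderL, orderR)))
    stop("clusters overlap: ", paste(intersect(orderL, orderR), collapse = ", "),
         call. = FALSE)
  m <- length(orderL)
  k <- min(m, length(orderR))
  i <- seq_len(k)
  sum(dist[cbind(match(orderL[m - i + 1], rownames(dist)),
                 match(orderR[i], rownames(dist)))])
}

check_ids <- function(ids, dist) {
  miss <- setdiff(ids, rownames(dist))
  if (length(miss))
    stop("ids missing from distance matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Greedy symmetric pairing of two clusters
#'
#' Repeats k = min(|L|, |R|) times: select the globally minimum-distance pair
#' (x, y) among still-unpaired x in L, y in R, and remove both. Pairs are
#' recorded in selection order, innermost first, so the pair-distance sequence
#' is nondecreasing from the boundary outward by construction. Ties are broken
#' by the lexicographically smallest (x id, y id).
#'
#' @param L_leaves,R_leaves character vectors (or sets) of leaf ids, disjoint,
#'   nonempty.
#' @param dist labelled distance matrix.
#' @return list with `pairs` (data.frame `x`, `y`, `d`, innermost first),
#'   `k`, and `B` (sum of the k pair distances).
#' @export
greedy_symmetric_pairing <- function(L_leaves, R_leaves, dist) {
  L <- as.character(L_leaves); R <- as.character(R_leaves)
  check_ids(c(L, R), dist)
  if (!length(L) || !length(R))
    stop("both clusters must be nonempty", call. = FALSE)
  if (length(intersect(L, R)))
    stop("clusters overlap: ", paste(intersect(L, R), collapse = ", "),
         call. = FALSE)
  M <- dist[L, R, drop = FALSE]
  k <- min(length(L), length(R))
  px <- character(k); py <- character(k); pd <- numeric(k)
  for (i in seq_len(k)) {
    dmin <- min(M)
    hit <- which(M <= dmin + abs(dmin) * 1e-12, arr.ind = TRUE)
    sel <- order(rownames(M)[hit[, 1L]], colnames(M)[hit[, 2L]])[1L]
    px[i] <- rownames(M)[hit[sel, 1L]]
    py[i] <- colnames(M)[hit[sel, 2L]]
    pd[i] <- M[hit[sel, 1L], hit[sel, 2L]]
    M <- M[rownames(M) != px[i], colnames(M) != py[i], drop = FALSE]
  }
  list(pairs = data.frame(x = px, y = py, d = pd, stringsAsFactors = FALSE),
       k = k, B = sum(pd))
}

#' Order unpaired cluster members outward from the paired block
#'
#' Members left without a symmetric counterpart are scored by their mean
#' distance to a reference block and placed outward from it, the most similar
#' member adjacent to the block. For `side = "left"` the result is prepended
#' left of the block (so it reads most-distant first), for `side = "right"`
#' appended (most-similar first). Score ties are broken by leaf id.
#'
#' @param unpaired character vector of leaf ids (may be empty).
#' @param ordered_core nonempty character vector: the block to score against.
#' @param dist labelled distance matrix.
#' @param side `"left"` or `"right"`: which side of the block the members go.
#' @return character vector in display (left-to-right) order.
#' @export
order_unpaired <- function(unpaired, ordered_core, dist,
                           side = c("left", "right")) {
  side <- match.arg(side)
  unpaired <- as.character(unpaired)
  if (!length(unpaired)) return(character(0))
  if (!length(ordered_core))
    stop("cannot score unpaired members against an empty core", call. = FALSE)
  if (length(intersect(unpaired, ordered_core)))
    stop("unpaired members overlap the ordered core", call. = FALSE)
  check_ids(c(unpaired, ordered_core), dist)
  score <- rowMeans(dist[unpaired, ordered_core, drop = FALSE])
  asc <- unpaired[order(score, unpaired)]
  if (side == "left") rev(asc) else asc
}

#' Assemble the SYM reference ordering for one node
#'
#' The target order for the subtree rooted at a node: greedy symmetric pairs
#' occupy the central 2k positions (pair i at distance i from the boundary on
#' each side, so pair 1 is innermost), and unpaired members of the larger
#' cluster extend outward, placed by mean distance to a reference block --
#' their own cluster's paired members (`unpaired_mode = "own"`, the default)
#' or the whole adjacent cluster (`"adjacent"`).
#'
#' @param L_leaves,R_leaves leaf ids of the left and right subtree.
#' @param dist labelled distance matrix.
#' @param unpaired_mode `"own"` or `"adjacent"`.
#' @return list with `order` (character, a permutation of all leaves),
#'   `rank` (named integer vector, id -> position), and `pairing` (the
#'   [greedy_symmetric_pairing()] result).
#' @export
build_sym_vector <- function(L_leaves, R_leaves, dist,
                             unpaired_mode = c("own", "adjacent")) {
  unpaired_mode <- match.arg(unpaired_mode)
  L <- as.character(L_leaves); R <- as.character(R_leaves)
  pr <- greedy_symmetric_pairing(L, R, dist)
  core_x <- rev(pr$pairs$x)          # x_k .. x_1 (innermost at boundary)
  core_y <- pr$pairs$y               # y_1 .. y_k
  up_L <- setdiff(L, pr$pairs$x)
  up_R <- setdiff(R, pr$pairs$y)
  ref_L <- if (unpaired_mode == "own") pr$pairs$x else R
  ref_R <- if (unpaired_mode == "own") pr$pairs$y else L
  sym <- c(order_unpaired(up_L, ref_L, dist, "left"),
           core_x, core_y,
           order_unpaired(up_R, ref_R, dist, "right"))
  list(order = sym,
       rank = stats::setNames(seq_along(sym), sym),
       pairing = pr)
}

#' Flip internal nodes toward a reference SYM ordering
#'
#' Within the subtree under `node`, every internal node is flipped iff the
#' mean SYM rank of the leaves in its right subtree precedes (is strictly
#' less than) the mean SYM rank of the leaves in its left subtree. Equal
#' means leave the node untouched. Decisions are independent across nodes
#' because flipping never changes subtree membership, so all decisions are
#' taken against the incoming tree and then applied together.
#'
#' @param tree a [sym_tree()].
#' @param node internal node index; the reordering is confined to its subtree.
#' @param sym a SYM rank map: named vector (id -> rank) or the list returned
#'   by [build_sym_vector()].
#' @return list with `tree` (flipped) and `flipped` (integer node indices).
#' @export
apply_sym_flips <- function(tree, node = nrow(tree$merge), sym) {
  rank <- if (is.list(sym)) sym$rank else sym
  sub <- preorder_nodes(tree, node)
  leafsets <- node_leafsets(tree)
  covered <- tree$labels[leafsets[[node]]]
  if (!setequal(names(rank), covered))
    stop("SYM vector does not cover exactly the leaves under the node",
         call. = FALSE)
  flipped <- integer(0)
  for (nd in sub) {
    lfs <- tree$labels[child_leafset(tree, tree$merge[nd, 1L], leafsets)]
    rfs <- tree$labels[child_leafset(tree, tree$merge[nd, 2L], leafsets)]
    if (mean(rank[rfs]) < mean(rank[lfs])) flipped <- c(flipped, nd)
  }
  for (nd in flipped) tree <- flip_node(tree, nd)
  list(tree = tree, flipped = flipped)
}

#' Reorder one node by its bilateral symmetric distance
#'
#' The single-node reordering step: build the SYM reference ordering from the
#' node's current left and right subtrees, then flip internal nodes inside the
#' subtree toward it. The cluster hierarchy is preserved exactly; only the
#' displayed order changes.
#'
#' @inheritParams apply_sym_flips
#' @param dist labelled distance matrix covering the node's leaves.
#' @param unpaired_mode see [build_sym_vector()].
#' @return list with `tree`, `sym` (the reference ordering), `pairing`, and
#'   `flipped` (node indices flipped).
#' @export
sym_order <- function(tree, node = nrow(tree$merge), dist,
                      unpaired_mode = c("own", "adjacent")) {
  unpaired_mode <- match.arg(unpaired_mode)
  if (node < 1L || node > nrow(tree$merge))
    stop("'node' must be an internal node index", call. = FALSE)
  L <- leaf_order(tree, node = tree$merge[node, 1L])
  R <- leaf_order(tree, node = tree$merge[node, 2L])
  sv <- build_sym_vector(L, R, dist, unpaired_mode)
  fl <- apply_sym_flips(tree, node, sv)
  list(tree = fl$tree, sym = sv$order, pairing = sv$pairing,
       flipped = fl$flipped)
}

## leaf_order() at a merge entry that may be a leaf code
leaf_order_entry <- function(tree, entry) {
  if (entry < 0L) tree$labels[-entry] else leaf_order(tree, node = entry)
}

#' Select reordering target nodes by level, balance and size
#'
#' Internal nodes at depth 0..level-1 (root = depth 0) are candidates; a
#' candidate is kept when its subtrees are balanced enough,
#' min(|L|,|R|) / max(|L|,|R|) >= `br`, and its smaller subtree is a large
#' enough share of the whole tree, min(|L|,|R|) / n >= `sr`. Targets are
#' returned in pre-order so parents are always reordered before descendants.
#'
#' @param tree a [sym_tree()].
#' @param level integer >= 1: how many depths below (and including) the root
#'   to consider; level 1 is the root only.
#' @param br balance ratio threshold in `[0, 1]` (default 0.3).
#' @param sr minimum smaller-subtree share of all leaves, in `[0, 0.5]`
#'   (default 0.03).
#' @return integer vector of internal node indices, pre-order.
#' @export
select_target_nodes <- function(tree, level = 1L, br = 0.3, sr = 0.03) {
  check_params(level, br, sr)
  n <- n_leaves(tree)
  depth <- node_depths(tree)
  leafsets <- node_leafsets(tree)
  pre <- preorder_nodes(tree)
  keep <- logical(length(pre))
  for (i in seq_along(pre)) {
    nd <- pre[i]
    if (depth[nd] >= level) next
    sl <- length(child_leafset(tree, tree$merge[nd, 1L], leafsets))
    sr_ <- length(child_leafset(tree, tree$merge[nd, 2L], leafsets))
    lo <- min(sl, sr_); hi <- max(sl, sr_)
    keep[i] <- (lo / hi >= br) && (lo / n >= sr)
  }
  pre[keep]
}

check_params <- function(level, br, sr) {
  if (!is.numeric(level) || length(level) != 1L || level < 1 ||
      level != round(level))
    stop("'level' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(br) || length(br) != 1L || br < 0 || br > 1)
    stop("'br' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(sr) || length(sr) != 1L || sr < 0 || sr > 0.5)
    stop("'sr' must lie in [0, 0.5]", call. = FALSE)
  invisible(TRUE)
}

#' HC-SYM: recursive bilateral-symmetric reordering of a dendrogram
#'
#' Applies [sym_order()] top-down to every node selected by
#' [select_target_nodes()]: the root first (level 1 orders the entire tree),
#' then -- for `level` >= 2 -- eligible descendants, each call operating on
#' the tree as already reordered by its ancestors. Subtree membership is
#' flip-invariant, so the target set is fixed up front; only left/right roles
#' may swap between calls. The cluster hierarchy is always preserved.
#'
#' @inheritParams select_target_nodes
#' @param dist labelled distance matrix covering all leaves.
#' @param unpaired_mode see [build_sym_vector()].
#' @return list with `tree` (the reordered [sym_tree()]) and `log`: one entry
#'   per visited node recording subtree sizes, the k pair distances, B, and
#'   the flip decisions.
#' @export
hc_sym <- function(tree, dist, level = 1L, br = 0.3, sr = 0.03,
                   unpaired_mode = c("own", "adjacent")) {
  unpaired_mode <- match.arg(unpaired_mode)
  dist <- as_dist_matrix(dist)
  check_ids(tree$labels, dist)
  targets <- select_target_nodes(tree, level, br, sr)
  log <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    nd <- targets[i]
    sizeL <- length(leaf_order_entry(tree, tree$merge[nd, 1L]))
    sizeR <- length(leaf_order_entry(tree, tree$merge[nd, 2L]))
    res <- sym_order(tree, nd, dist, unpaired_mode)
    tree <- res$tree
    log[[i]] <- list(node = nd, size_left = sizeL, size_right = sizeR,
                     k = res$pairing$k, B = res$pairing$B,
                     pair_distances = res$pairing$pairs$d,
                     flipped_nodes = res$flipped)
  }
  list(tree = tree, log = log, targets = targets)
}
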