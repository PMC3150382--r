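#' Newick export/import of dendrograms
#'
#' Serialisation goes through [ape::write.tree()] / [ape::read.tree()]. Branch
#' lengths are merge-height differences (parent height minus child height,
#' leaves at height 0) and the child order written in the file is the displayed
#' left-to-right order, so `read_newick(write_newick(tree))` reproduces
#' topology, child order, and merge heights.
#'
#' @param tree a [sym_tree()].
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return `write_newick`: the Newick string (invisibly when writing to file).
#'   `read_newick`: a [sym_tree()].
#' @examples
#' tr <- sym_tree(matrix(c(-1, -2), 1), 0.4, c("a", "b"))
#' write_newick(tr)
#' @export
write_newick <- function(tree, file = NULL) {
  phy <- sym_tree_to_phylo(tree)
  txt <- ape::write.tree(phy, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @rdname write_newick
#' @param text a Newick string (used when `file` is `NULL`).
#' @export
read_newick <- function(file = NULL, text = NULL) {
  phy <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: no tree found in input",
                         call. = FALSE)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  phylo_to_sym_tree(phy)
}

## sym_tree -> ape phylo, preserving child order (edge order = display order)
sym_tree_to_phylo <- function(tree) {
  m <- tree$merge
  n <- length(tree$labels)
  nint <- nrow(m)
  # ape numbering: tips 1..n, root n+1, internals follow in preorder
  pre <- preorder_nodes(tree)            # merge-row indices, root first
  apenum <- integer(nint)
  apenum[pre] <- n + seq_len(nint)
  edge <- matrix(0L, 2L * nint, 2L)
  elen <- numeric(2L * nint)
  r <- 0L
  # cladewise (DFS) edge emission: an edge is written when traversed, left
  # child's whole subtree before the right child's
  emit <- function(row) {
    for (k in m[row, ]) {
      r <<- r + 1L
      child_num <- if (k < 0L) -k else apenum[k]
      child_h <- if (k < 0L) 0 else tree$height[k]
      edge[r, ] <<- c(apenum[row], child_num)
      elen[r] <<- tree$height[row] - child_h
      if (k > 0L) emit(k)
    }
  }
  emit(nint)
  structure(list(edge = edge, edge.length = elen,
                 tip.label = tree$labels, Nnode = nint),
            class = "phylo", order = "cladewise")
}

## ape phylo -> sym_tree; node heights rebuilt bottom-up from branch lengths
phylo_to_sym_tree <- function(phy) {
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves", call. = FALSE)
  nint <- phy$Nnode
  if (is.null(phy$edge.length))
    phy$edge.length <- rep(1, nrow(phy$edge))
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  for (node in names(kids)) {
    if (length(kids[[node]]) != 2L)
      stop("non-binary Newick tree: node has ", length(kids[[node]]),
           " children; only binary dendrograms are supported", call. = FALSE)
  }
  if (nint != n - 1L)
    stop("non-binary Newick tree: expected ", n - 1L, " internal nodes, got ",
         nint, call. = FALSE)
  # explicit DFS postorder from the root so children are resolved first
  root <- setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])
  porder <- integer(0)
  stack <- root
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    porder <- c(cur, porder)
    ch <- phy$edge[kids[[as.character(cur)]], 2L]
    stack <- c(stack, ch[ch > n])
  }
  rowof <- integer(n + nint)           # ape node number -> merge row
  hts <- numeric(n + nint)             # reconstructed merge heights
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (i in seq_along(porder)) {
    node <- porder[i]
    eidx <- kids[[as.character(node)]]          # edges in file order
    ch <- phy$edge[eidx, 2L]
    bl <- phy$edge.length[eidx]
    hts[node] <- max(hts[ch] + bl)
    merge[i, ] <- ifelse(ch <= n, -ch, rowof[ch])
    height[i] <- hts[node]
    rowof[node] <- i
  }
  # renumber rows into nondecreasing height order (stable, so children built
  # in postorder stay before equal-height parents), as an agglomeration would
  perm <- order(height)                        # new position -> old row
  newpos <- integer(length(perm)); newpos[perm] <- seq_along(perm)
  merge2 <- merge[perm, , drop = FALSE]
  merge2[merge2 > 0L] <- newpos[merge2[merge2 > 0L]]
  sym_tree(merge2, height[perm], phy$tip.label)
}
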