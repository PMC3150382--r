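# Independent oracles. Each deliberately re-derives a quantity by brute force
# or a second, structurally different implementation; none calls the package
# code path it checks.

# --- flip-orbit enumeration -------------------------------------------------

# all leaf orders reachable by flipping any subset of internal nodes
orbit_leaf_orders <- function(tree) {
  m <- nrow(tree$merge)
  orders <- character(0)
  for (mask in 0:(2^m - 1)) {
    tr <- tree
    for (nd in seq_len(m)) {
      if (bitwAnd(mask, bitwShiftL(1L, nd - 1L)) != 0L) tr <- flip_node(tr, nd)
    }
    orders <- c(orders, paste(leaf_order(tr), collapse = "|"))
  }
  unique(orders)
}

# --- bilateral symmetric distance by explicit index loop --------------------

oracle_bsd <- function(orderL, orderR, dist) {
  m <- length(orderL); n <- length(orderR)
  k <- min(m, n)
  total <- 0
  for (i in seq_len(k)) {
    total <- total + dist[orderL[m - i + 1], orderR[i]]
  }
  total
}

# --- GAR by exhaustive triple loop ------------------------------------------

oracle_gar <- function(sim, order, w) {
  P <- sim[order, order]
  n <- nrow(P)
  count <- 0L
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (j < k && k < i && (i - j) <= w && P[i, j] > P[i, k]) count <- count + 1L
    if (i < j && j < k && (k - i) <= w && P[i, j] < P[i, k]) count <- count + 1L
  }
  count
}

# --- SR via direct definition (no shared code with the package) -------------

oracle_sr <- function(order, labels) {
  pos <- stats::setNames(seq_along(order), order)
  classes <- unique(labels)
  num <- 0; den <- 0
  for (cl in classes) {
    mem <- names(labels)[labels == cl]
    p <- sort(pos[mem])
    m <- length(p)
    if (m < 2) next
    for (a in 1:(m - 1)) for (b in (a + 1):m) num <- num + 1 / (p[b] - p[a])
    cont <- seq_len(m)
    for (a in 1:(m - 1)) for (b in (a + 1):m) den <- den + 1 / (cont[b] - cont[a])
  }
  unname(if (den == 0) 1 else num / den)
}

# --- second implementation of the node-reordering trace ---------------------
# A from-scratch trace of the single-node reordering: greedy min pairing with
# lexicographic ties, own-cluster placement of unpaired members, then a
# recursive flip decision per node by mean target rank. Written against nested
# lists, not merge matrices.

oracle_sym_order <- function(tree, dist) {
  # nested-list view of the tree
  as_nested <- function(entry) {
    if (entry < 0) return(tree$labels[-entry])
    list(as_nested(tree$merge[entry, 1]), as_nested(tree$merge[entry, 2]))
  }
  leaves_of <- function(nd) if (is.character(nd)) nd else
    c(leaves_of(nd[[1]]), leaves_of(nd[[2]]))
  root <- as_nested(nrow(tree$merge))
  L <- leaves_of(root[[1]]); R <- leaves_of(root[[2]])

  # greedy pairing via repeated scan of an explicit candidate data frame
  cand <- expand.grid(x = L, y = R, stringsAsFactors = FALSE)
  cand$d <- mapply(function(a, b) dist[a, b], cand$x, cand$y)
  k <- min(length(L), length(R))
  px <- character(0); py <- character(0)
  for (i in seq_len(k)) {
    sel <- cand[order(cand$d, cand$x, cand$y), ][1, ]
    px <- c(px, sel$x); py <- c(py, sel$y)
    cand <- cand[cand$x != sel$x & cand$y != sel$y, ]
  }
  up <- if (length(L) > length(R)) setdiff(L, px) else setdiff(R, py)
  sym <- c(rev(px), py)
  if (length(up)) {
    ref <- if (length(L) > length(R)) px else py
    sc <- sapply(up, function(u) mean(dist[u, ref]))
    up <- up[order(sc, up)]
    sym <- if (length(L) > length(R)) c(rev(up), sym) else c(sym, up)
  }
  rank <- stats::setNames(seq_along(sym), sym)

  # recursive flip: node drawn with the lower-mean-rank child on the left
  reorder <- function(nd) {
    if (is.character(nd)) return(nd)
    a <- reorder(nd[[1]]); b <- reorder(nd[[2]])
    if (mean(rank[leaves_of(nd[[2]])]) < mean(rank[leaves_of(nd[[1]])]))
      c(b, a) else c(a, b)
  }
  reorder(root)
}
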