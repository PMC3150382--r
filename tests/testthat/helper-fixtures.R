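# Shared fixture builders. Everything is generated in code under fixed seeds.

# random symmetric distance matrix with unique off-diagonal values (no ties)
random_dist <- function(n, seed = NULL, labels = sprintf("t%02d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- stats::runif(n * (n - 1) / 2, 0.1, 10)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  d
}

# random binary dendrogram via average linkage on a random tie-free matrix
random_tree <- function(n, seed = NULL) {
  cluster_average_linkage(random_dist(n, seed))
}

# a fixed 4-leaf caterpillar: (((a,b),c),d) with heights 1,2,3
caterpillar4 <- function() {
  sym_tree(matrix(c(-1, -2,  1, -3,  2, -4), ncol = 2, byrow = TRUE),
           c(1, 2, 3), c("a", "b", "c", "d"))
}

# balanced 4-leaf tree ((a,b),(c,d))
balanced4 <- function() {
  sym_tree(matrix(c(-1, -2,  -3, -4,  1, 2), ncol = 2, byrow = TRUE),
           c(1, 1, 2), c("a", "b", "c", "d"))
}
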