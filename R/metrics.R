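#' Linear distance between two leaf positions
#'
#' The positive linear distance between two leaves in a displayed order where
#' leaves are numbered 1..n from the left: 1 when adjacent, n-1 when at
#' opposite ends.
#'
#' @param pos1,pos2 distinct positions (integers >= 1).
#' @return `abs(pos1 - pos2)`, vectorised.
#' @export
linear_distance <- function(pos1, pos2) {
  if (any(pos1 < 1) || any(pos2 < 1) || any(pos1 != round(pos1)) ||
      any(pos2 != round(pos2)))
    stop("positions must be positive integers", call. = FALSE)
  if (any(pos1 == pos2))
    stop("linear distance is undefined for equal positions", call. = FALSE)
  abs(pos1 - pos2)
}

#' Seriation score of one class in a leaf order
#'
#' Measures how tightly the members of one class are grouped in a displayed
#' order: the sum, over all unordered within-class pairs, of the reciprocal
#' linear distance 1/ld between the two members. The score is maximised
#' exactly when the class occupies a contiguous block; a singleton class
#' scores 0.
#'
#' @param order character vector: the displayed leaf order.
#' @param members character vector of leaf ids belonging to the class.
#' @return nonnegative scalar S(c).
#' @export
seriation_score <- function(order, members) {
  members <- as.character(members)
  pos <- match(members, order)
  if (anyNA(pos))
    stop("class members missing from the order: ",
         paste(members[is.na(pos)], collapse = ", "), call. = FALSE)
  m <- length(pos)
  if (m < 2L) return(0)
  sum(1 / abs(outer(pos, pos, "-"))[upper.tri(diag(m))])
}

#' Maximum seriation score of a class of size m
#'
#' Attained when the class is a contiguous block: gaps g = 1..m-1 occur
#' (m - g) times, giving sum over g of (m - g)/g.
#'
#' @param m class size.
#' @return scalar S_max(m); 0 for m < 2.
#' @export
max_seriation_score <- function(m) {
  vapply(m, function(mi) {
    if (mi < 2L) return(0)
    g <- seq_len(mi - 1L)
    sum((mi - g) / g)
  }, numeric(1))
}

#' Seriation rate of a labelled leaf order
#'
#' The supervised grouping quality of a displayed order: the sum of per-class
#' seriation scores divided by the sum of their maxima (the contiguous-block
#' scores), so SR ranges over \[0, 1\] and equals 1 exactly when every class
#' occupies a contiguous block -- an error-free grouping.
#'
#' @param order character vector: the displayed leaf order.
#' @param labels named character/factor vector mapping every leaf id in
#'   `order` to its class.
#' @return list with `SR`, and a `classes` data.frame of per-class `size`,
#'   `score`, `max_score`.
#' @export
seriation_rate <- function(order, labels) {
  labels <- validate_labels(labels, order)
  cls <- split(names(labels), as.character(labels))
  sc <- vapply(cls, function(m) seriation_score(order, m), numeric(1))
  mx <- max_seriation_score(lengths(cls))
  denom <- sum(mx)
  sr <- if (denom == 0) 1 else sum(sc) / denom   # all-singleton: trivially grouped
  list(SR = sr,
       classes = data.frame(class = names(cls), size = lengths(cls),
                            score = sc, max_score = mx,
                            row.names = NULL, stringsAsFactors = FALSE))
}

validate_labels <- function(labels, order) {
  if (is.null(names(labels)))
    stop("labels must be a named vector (leaf id -> class)", call. = FALSE)
  labels <- labels[!is.na(labels)]
  miss <- setdiff(order, names(labels))
  if (length(miss))
    stop("unlabeled leaves: ", paste(miss, collapse = ", "), call. = FALSE)
  labels[order]
}

#' Generalized anti-Robinson score of an ordered similarity matrix
#'
#' A symmetric similarity matrix is Robinson when similarities never decrease
#' toward the diagonal along any row or column. GAR(w) counts the violations
#' of that form in the matrix permuted by a leaf order, restricted to index
#' triples spanning at most `w` positions: over the lower triangle, triples
#' j < k < i with i - j <= w where p_ij > p_ik, plus the mirrored upper
#' triangle count (i < j < k, k - i <= w, p_ij < p_ik). Ties are compliant,
#' not violations. A perfectly Robinson-ordered matrix scores 0 at every
#' window.
#'
#' @param sim labelled symmetric similarity matrix.
#' @param order character vector permuting the labels of `sim`.
#' @param w window size, an integer in `[2, n-1]`.
#' @return nonnegative integer count of violations.
#' @export
gar_score <- function(sim, order, w) {
  P <- permute_similarity(sim, order)
  n <- nrow(P)
  if (length(w) != 1L || w != round(w) || w < 2 || w > n - 1)
    stop("'w' must be an integer in [2, n-1]", call. = FALSE)
  count <- 0L
  # lower triangle: fixed (i, j), k ranges j+1 .. i-1; span i - j <= w
  for (i in 3:n) {
    for (j in max(1L, i - w):(i - 2L)) {
      ks <- (j + 1L):(i - 1L)
      count <- count + sum(P[i, j] > P[i, ks])
    }
  }
  # upper triangle: fixed (i, j), k ranges j+1 .. min(n, i+w)
  for (i in 1:(n - 2L)) {
    for (j in (i + 1L):min(n - 1L, i + w - 1L)) {
      kmax <- min(n, i + w)
      if (j + 1L > kmax) next
      ks <- (j + 1L):kmax
      count <- count + sum(P[i, j] < P[i, ks])
    }
  }
  as.integer(count)
}

permute_similarity <- function(sim, order) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim))
    stop("similarity must be a square matrix", call. = FALSE)
  if (is.null(rownames(sim))) {
    rownames(sim) <- as.character(seq_len(nrow(sim)))
    colnames(sim) <- rownames(sim)
  }
  if (max(abs(sim - t(sim))) > 1e-8)
    stop("similarity matrix not symmetric", call. = FALSE)
  if (!setequal(order, rownames(sim)) || length(order) != nrow(sim))
    stop("'order' must be a permutation of the similarity labels", call. = FALSE)
  sim[order, order]
}

#' GAR profile over several window sizes
#'
#' @inheritParams gar_score
#' @param windows integer vector of window sizes; default all of 2..n-1.
#' @return named integer vector, one violation count per window; counts are
#'   nondecreasing in w because larger windows only add triples.
#' @export
gar_profile <- function(sim, order, windows = NULL) {
  n <- nrow(as.matrix(sim))
  if (is.null(windows)) windows <- seq(2L, n - 1L)
  stats::setNames(vapply(windows, function(w) gar_score(sim, order, w),
                         integer(1)),
                  as.character(windows))
}
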