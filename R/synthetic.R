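## run expr with a seeded, isolated RNG stream; caller's RNG state untouched
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate multi-class Gaussian expression-like profiles
#'
#' Emulates a labelled sample-by-feature expression matrix with known classes:
#' samples of class c are drawn from N(mu_c, sigma^2 I) with class centers
#' placed on orthogonal coordinate axes so that every pair of centers is
#' exactly `separation * noise` apart. All randomness flows from `seed`;
#' regeneration with the same arguments is bit-identical.
#'
#' Defaults mirror a two-class tumour-profile design (45 + 32 samples) at a
#' moderate separation of 3 standard deviations, the regime where hierarchical
#' clustering groups most samples correctly but misplaces some -- exactly the
#' situation leaf reordering addresses.
#'
#' @param class_sizes integer vector, one size (>= 1) per class.
#' @param dim number of features (>= 2 and >= number of classes).
#' @param separation center separation delta in units of `noise`.
#' @param noise within-class standard deviation sigma (> 0).
#' @param seed integer seed.
#' @return list with `data` (matrix, rows `s001`...), `labels` (named vector
#'   leaf id -> class `c1`, `c2`, ...), and `params`.
#' @export
make_clustered_data <- function(class_sizes = c(45L, 32L), dim = 20L,
                                separation = 3, noise = 1, seed = 1L) {
  if (any(class_sizes < 1) || any(class_sizes != round(class_sizes)))
    stop("class sizes must be positive integers", call. = FALSE)
  k <- length(class_sizes)
  if (dim < 2L || dim < k)
    stop("'dim' must be >= 2 and >= the number of classes", call. = FALSE)
  if (noise <= 0) stop("'noise' must be positive", call. = FALSE)
  if (separation < 0) stop("'separation' must be nonnegative", call. = FALSE)
  n <- sum(class_sizes)
  # centers a * e_c are pairwise a * sqrt(2) apart; want delta * sigma
  a <- separation * noise / sqrt(2)
  with_local_seed(seed, {
    x <- matrix(stats::rnorm(n * dim, sd = noise), n, dim)
    cls <- rep(seq_len(k), class_sizes)
    for (c in seq_len(k)) x[cls == c, c] <- x[cls == c, c] + a
    # samples are stored in random order so that ids and input positions carry
    # no class information (a class-blocked layout would leak labels into any
    # ordering convention based on input indices)
    perm <- sample(n)
    x <- x[perm, , drop = FALSE]
    cls <- cls[perm]
    ids <- sprintf("s%03d", seq_len(n))
    rownames(x) <- ids
    colnames(x) <- sprintf("f%03d", seq_len(dim))
    labels <- stats::setNames(paste0("c", cls), ids)
    list(data = x, labels = labels,
         params = list(class_sizes = as.integer(class_sizes),
                       dim = as.integer(dim), separation = separation,
                       noise = noise, seed = as.integer(seed)))
  })
}

#' Generate a perfect Robinson similarity matrix
#'
#' Places n points on a line and sets s_ij = exp(-decay * |t_i - t_j|), so
#' similarity strictly increases toward the diagonal: a perfect Robinson
#' matrix under the generating order (and its reversal). With `seed` the
#' point spacings are random (uniform); without, points are equally spaced.
#'
#' @param n number of objects (>= 3).
#' @param decay exponential decay rate lambda (> 0).
#' @param seed optional integer seed for random spacings.
#' @return list with `sim` (labelled similarity matrix), `order` (the
#'   generating order, ids `o01`...), and `t` (the line coordinates).
#' @export
make_robinson_similarity <- function(n, decay = 1, seed = NULL) {
  if (n < 3L) stop("'n' must be >= 3", call. = FALSE)
  if (decay <= 0) stop("'decay' must be positive", call. = FALSE)
  t <- if (is.null(seed)) seq(0, 1, length.out = n)
       else with_local_seed(seed, sort(stats::runif(n)))
  ids <- sprintf("o%02d", seq_len(n))
  sim <- exp(-decay * abs(outer(t, t, "-")))
  dimnames(sim) <- list(ids, ids)
  list(sim = sim, order = ids, t = stats::setNames(t, ids))
}

#' Flip random internal nodes of a dendrogram
#'
#' Each internal node is independently flipped with probability `p`; the
#' cluster hierarchy is preserved. `p = 0` is the identity, `p = 1` reverses
#' the leaf order.
#'
#' @param tree a [sym_tree()].
#' @param p flip probability in `[0, 1]`.
#' @param seed integer seed (reproducible flip set).
#' @return the flipped [sym_tree()].
#' @export
random_flips <- function(tree, p = 0.5, seed = 1L) {
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]", call. = FALSE)
  m <- nrow(tree$merge)
  do_flip <- with_local_seed(seed, stats::runif(m) < p)
  for (nd in which(do_flip)) tree <- flip_node(tree, nd)
  tree
}
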