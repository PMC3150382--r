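#' Reproducible reordering runs (the command-line surface)
#'
#' `run_reorder` drives a complete reordering: read a data or distance matrix
#' (and optionally a precomputed tree), cluster if needed, reorder, and write
#' three artifacts into `out_dir`: `tree.nwk` (Newick, child order = display
#' order), `order.txt` (one leaf id per line), and `run_log.json` (every node
#' visited, its pairing distances, flip decisions, and the full
#' configuration). Outputs are deterministic functions of the inputs.
#'
#' @param input path to the input matrix (TSV/CSV, header + label column).
#'   Interpreted as a distance matrix when `as_dist = TRUE` (or when square,
#'   symmetric, zero-diagonal), otherwise as samples x features data.
#' @param out_dir output directory (created if missing).
#' @param method `"hc-sym"`, `"hc"`, or `"hc-pca"`.
#' @param metric `"pearson"` or `"euclidean"` (data input only).
#' @param level,br,sr,unpaired_mode see [hcsym()].
#' @param tree_file optional Newick file with a precomputed dendrogram.
#' @param merge_file optional 3-column merge table (item_a, item_b, height).
#' @param as_dist force distance-matrix interpretation of `input`.
#' @return (invisibly) named list of the written file paths plus the fit.
#' @export
run_reorder <- function(input, out_dir, method = "hc-sym",
                        metric = "pearson", level = 1L, br = 0.3, sr = 0.03,
                        unpaired_mode = "own", tree_file = NULL,
                        merge_file = NULL, as_dist = FALSE) {
  x <- read_matrix_file(input)
  if (as_dist) x <- as_dist_matrix(x)
  tree <- NULL
  if (!is.null(tree_file)) tree <- read_newick(tree_file)
  if (!is.null(merge_file)) tree <- linkage_to_tree(read_merge_file(merge_file))
  fit <- hcsym(x, method = method, metric = metric, level = level, br = br,
               sr = sr, unpaired_mode = unpaired_mode, tree = tree)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(tree = file.path(out_dir, "tree.nwk"),
                order = file.path(out_dir, "order.txt"),
                log = file.path(out_dir, "run_log.json"))
  write_newick(fit$tree, paths$tree)
  writeLines(fit$order, paths$order)
  jsonlite::write_json(
    list(method = method, params = fit$params, input = basename(input),
         n_leaves = length(fit$order), visits = fit$log),
    paths$log, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, list(fit = fit)))
}

#' @rdname run_reorder
#' @param order_file leaf-order file (one id per line) to evaluate.
#' @param labels_file optional 2-column TSV (leaf id, class) for SR.
#' @param sim_file optional similarity matrix (TSV/CSV) for the GAR profile.
#' @param windows integer vector of GAR window sizes (default 2..n-1).
#' @param out path of the JSON report to write (optional).
#' @param profile_tsv optional TSV export path for the GAR profile.
#' @return `run_evaluate`: the report list (SR, per-class scores, GAR
#'   profile), invisibly written to `out` when given.
#' @export
run_evaluate <- function(order_file, labels_file = NULL, sim_file = NULL,
                         windows = NULL, out = NULL, profile_tsv = NULL) {
  if (is.null(labels_file) && is.null(sim_file))
    stop("evaluation needs a labels file (for SR) and/or a similarity matrix (for GAR)",
         call. = FALSE)
  ord <- readLines(order_file)
  ord <- ord[nzchar(ord)]
  report <- list(n = length(ord))
  if (!is.null(labels_file)) {
    labels <- read_labels_file(labels_file)
    miss <- setdiff(ord, names(labels))
    if (length(miss))
      stop("order/labels mismatch; unlabeled ids: ",
           paste(miss, collapse = ", "), call. = FALSE)
    sr <- seriation_rate(ord, labels)
    report$SR <- sr$SR
    report$classes <- sr$classes
  }
  if (!is.null(sim_file)) {
    sim <- read_matrix_file(sim_file)
    if (is.null(windows)) windows <- seq(2L, nrow(sim) - 1L)
    prof <- gar_profile(sim, ord, windows)
    report$gar <- list(window = as.integer(names(prof)),
                       violations = unname(prof))
    if (!is.null(profile_tsv))
      utils::write.table(
        data.frame(window = as.integer(names(prof)), violations = unname(prof)),
        profile_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(report)
}

#' @rdname run_reorder
#' @param class_sizes,dim,separation,noise,seed see [make_clustered_data()].
#' @return `run_simulate`: paths of `data.tsv`, `labels.tsv`, `manifest.json`.
#' @export
run_simulate <- function(out_dir, class_sizes = c(45L, 32L), dim = 20L,
                         separation = 3, noise = 1, seed = 1L) {
  sim <- make_clustered_data(class_sizes, dim, separation, noise, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(data = file.path(out_dir, "data.tsv"),
                labels = file.path(out_dir, "labels.tsv"),
                manifest = file.path(out_dir, "manifest.json"))
  write_matrix_file(sim$data, paths$data)
  write_labels_file(sim$labels, paths$labels)
  jsonlite::write_json(sim$params, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname run_reorder
#' @param png_out output PNG path for the proximity view.
#' @return `run_render`: the PNG path.
#' @export
run_render <- function(sim_file, order_file, png_out) {
  sim <- read_matrix_file(sim_file)
  ord <- readLines(order_file)
  ord <- ord[nzchar(ord)]
  P <- permute_similarity(sim, ord)
  grDevices::png(png_out, width = 720, height = 720)
  on.exit(grDevices::dev.off())
  graphics::image(seq_along(ord), seq_along(ord), P[, rev(seq_along(ord))],
                  xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = "Proximity view")
  invisible(png_out)
}
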