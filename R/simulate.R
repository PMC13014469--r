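#' Simulate a CCIM with planted cluster structure
#'
#' Generates a cell-pair x feature score matrix with `k_clusters` groups of
#' pairs, each elevated by `effect_size` on its own disjoint block of
#' `signature_size` features, plus i.i.d. Gaussian noise.  Pair metadata
#' (sender/receiver ids and types) is synthesized in alignment with the
#' cluster labels so type-colored visualizations are testable.  The defaults
#' are the package's standard planted benchmark.
#'
#' @param n_pairs_per_cluster pairs per cluster; default 200.
#' @param k_clusters number of planted clusters; default 4.
#' @param n_features total number of ligand-receptor features; default 40.
#' @param signature_size features per cluster signature (disjoint blocks);
#'   default 3.
#' @param effect_size mean elevation of signature features; default 3.
#' @param noise_sd Gaussian noise SD; default 1.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return list with `ccim` (a raw [ccim()]) and `truth`: list with `labels`
#'   (cluster id per pair) and `signatures` (list of feature index vectors,
#'   one per cluster).
#' @export
simulate_ccim <- function(n_pairs_per_cluster = 200L, k_clusters = 4L,
                          n_features = 40L, signature_size = 3L,
                          effect_size = 3, noise_sd = 1, seed = 1L) {
  ccb_assert(is_count(n_pairs_per_cluster) && is_count(k_clusters) &&
               is_count(n_features) && is_count(signature_size),
             "ccb_spec_error", "sizes must be positive integers")
  ccb_assert(k_clusters * signature_size <= n_features, "ccb_spec_error",
             "k_clusters * signature_size must not exceed n_features")
  ccb_assert(effect_size > 0, "ccb_spec_error", "effect_size must be positive")
  ccb_assert(is.numeric(noise_sd) && noise_sd >= 0, "ccb_spec_error",
             "noise_sd must be nonnegative")
  n <- n_pairs_per_cluster * k_clusters
  labels <- rep(seq_len(k_clusters), each = n_pairs_per_cluster)
  signatures <- lapply(seq_len(k_clusters), function(c)
    (c - 1L) * signature_size + seq_len(signature_size))
  mean_mat <- matrix(0, n, n_features)
  for (c in seq_len(k_clusters)) {
    mean_mat[labels == c, signatures[[c]]] <- effect_size
  }
  scores <- with_seed(seed, {
    mean_mat + matrix(stats::rnorm(n * n_features, sd = noise_sd), n, n_features)
  })
  pairs <- data.frame(
    sender_id = sprintf("s%04d", seq_len(n)),
    receiver_id = sprintf("r%04d", seq_len(n)),
    sender_type = sprintf("sender_type_%d", labels),
    receiver_type = sprintf("receiver_type_%d", labels),
    stringsAsFactors = FALSE)
  features <- data.frame(ligand = sprintf("L%02d", seq_len(n_features)),
                         receptor = sprintf("R%02d", seq_len(n_features)),
                         stringsAsFactors = FALSE)
  list(ccim = ccim(scores, pairs, features, standardized = FALSE),
       truth = list(labels = labels, signatures = signatures))
}

#' Simulate expression data from cell-type programs
#'
#' Draws a nonnegative cells x genes matrix where each cell type has its own
#' vector of mean expression levels (genes absent from a program default to
#' mean 0).  Values are Gaussian around the program mean, truncated at 0, so
#' that [build_ccim()] on the result shows type-pair-structured scores.
#'
#' @param n_cells_per_type named integer vector: cells to draw per type.
#' @param programs named list (one entry per type) of named numeric vectors
#'   of per-gene mean expression; nonnegative means required.
#' @param db an `lr_database`; its genes define the gene universe together
#'   with the program genes.
#' @param noise_sd Gaussian SD around program means; default 0.1.
#' @param seed RNG seed.
#' @return an [expression_matrix()], cells grouped by type.
#' @export
simulate_expression <- function(n_cells_per_type, programs, db,
                                noise_sd = 0.1, seed = 1L) {
  types <- names(n_cells_per_type)
  ccb_assert(!is.null(types) && all(types %in% names(programs)),
             "ccb_spec_error", "every type needs a program")
  ccb_assert(all(unlist(programs) >= 0), "ccb_spec_error",
             "program means must be nonnegative")
  genes <- unique(c(unlist(lapply(programs, names)), db$ligand, db$receptor))
  n <- sum(n_cells_per_type)
  mean_mat <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  cell_types <- rep(types, times = n_cells_per_type)
  for (ty in types) {
    prog <- programs[[ty]]
    mean_mat[cell_types == ty, names(prog)] <-
      matrix(prog, sum(cell_types == ty), length(prog), byrow = TRUE)
  }
  values <- with_seed(seed, {
    pmax(mean_mat + matrix(stats::rnorm(length(mean_mat), sd = noise_sd),
                           nrow(mean_mat)), 0)
  })
  rownames(values) <- sprintf("cell_%03d", seq_len(n))
  colnames(values) <- genes
  expression_matrix(values, cell_types = cell_types)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two clusterings via the pair-counting
#' contingency formula: 1 for identical partitions, about 0 for independent
#' ones.
#'
#' @param labels_a,labels_b vectors of equal length (any label types).
#' @return a scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  ccb_assert(length(labels_a) == length(labels_b), "ccb_shape_error",
             "labelings differ in length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  expected <- a * b / choose2(n)
  max_index <- (a + b) / 2
  if (max_index == expected) return(0)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Precision and recall of recovered interaction signatures
#'
#' Matches model clusters to planted clusters greedily by label overlap
#' (largest overlap first, each model cluster used at most once), then scores
#' the top-`top_k` ranked features of each matched cluster against the
#' planted signature.  Precision and recall are averaged over planted
#' clusters; an empty list scores 0 for both (documented convention).
#'
#' @param lists list of ranked-interaction data.frames as returned by
#'   [rank_all_interactions()], indexed by cluster.
#' @param assignments integer vector of model cluster indices per pair (from
#'   [assign_clusters()]).
#' @param truth ground-truth list from [simulate_ccim()] (`labels`,
#'   `signatures`).
#' @param features feature metadata data.frame mapping (ligand, receptor) to
#'   feature index (row order defines indices).
#' @param top_k number of top-ranked features scored per cluster.
#' @return list with scalars `precision` and `recall`.
#' @export
feature_recovery <- function(lists, assignments, truth, features, top_k) {
  ccb_assert(is_count(top_k), "ccb_spec_error", "top_k must be a positive integer")
  ccb_assert(length(assignments) == length(truth$labels), "ccb_shape_error",
             "assignments and truth labels differ in length")
  k <- length(truth$signatures)
  overlap <- table(factor(truth$labels, levels = seq_len(k)),
                   factor(assignments, levels = seq_along(lists)))
  matched <- integer(k)  # model cluster matched to each planted cluster
  avail <- rep(TRUE, length(lists))
  ord <- order(-overlap)  # greedy: largest overlaps first
  rows <- (ord - 1L) %% k + 1L
  cols <- (ord - 1L) %/% k + 1L
  done <- rep(FALSE, k)
  for (i in seq_along(ord)) {
    r <- rows[i]; cc <- cols[i]
    if (!done[r] && avail[cc] && overlap[r, cc] > 0) {
      matched[r] <- cc; done[r] <- TRUE; avail[cc] <- FALSE
    }
  }
  fname_all <- feature_names(features)
  prec <- rec <- numeric(k)
  for (c in seq_len(k)) {
    sig <- truth$signatures[[c]]
    if (matched[c] == 0L) next
    lst <- lists[[matched[c]]]
    if (nrow(lst) == 0L) next
    top <- utils::head(lst, top_k)
    got <- match(paste(top$ligand, top$receptor, sep = "_"), fname_all)
    hits <- sum(got %in% sig)
    prec[c] <- hits / nrow(top)
    rec[c] <- hits / length(sig)
  }
  list(precision = mean(prec), recall = mean(rec))
}
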