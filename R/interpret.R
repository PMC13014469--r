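#' Map cluster indices to latent dimensions and signs
#'
#' The 2d soft clusters are laid out as two concatenated blocks: cluster
#' `k in 1..d` is the positive-part cluster of latent dimension `k`, and
#' cluster `d + k` is the negative-part cluster of dimension `k`.
#'
#' @param cluster integer vector of cluster indices in `1..2d`.
#' @param d number of latent dimensions.
#' @return data.frame with columns `cluster`, `dimension`, `sign`
#'   (`+1` for positive-part clusters, `-1` for negative-part).
#' @export
cluster_layout <- function(cluster, d) {
  ccb_assert(all(cluster >= 1 & cluster <= 2 * d), "ccb_validation_error",
             "cluster index out of range 1..%d", 2 * d)
  data.frame(cluster = as.integer(cluster),
             dimension = as.integer((cluster - 1L) %% d + 1L),
             sign = ifelse(cluster <= d, 1L, -1L))
}

#' Hard cluster assignment from soft memberships
#'
#' Assigns every cell pair to the cluster with the highest membership
#' probability (lowest index on ties).  Because the softmax is monotone, this
#' argmax equals the argmax over the pre-softmax split activations.
#'
#' @param P n x 2d row-stochastic matrix from [split_softmax()].
#' @return data.frame with columns `cluster` (integer in `1..2d`) and
#'   `probability` (the row maximum of `P`).
#' @export
assign_clusters <- function(P) {
  P <- as.matrix(P)
  ccb_assert(all(is.finite(P)) && all(P > 0),
             "ccb_validation_error", "P must be strictly positive and finite")
  ccb_assert(max(abs(rowSums(P) - 1)) < 1e-6, "ccb_validation_error",
             "P rows must sum to 1")
  idx <- max.col(P, ties.method = "first")
  data.frame(cluster = idx, probability = P[cbind(seq_len(nrow(P)), idx)])
}

#' Ranked ligand-receptor interactions characterizing one cluster
#'
#' Selects the encoder weights of the cluster's latent dimension that carry
#' the cluster's sign (strictly positive entries for a positive-part cluster,
#' strictly negative for a negative-part cluster), min-max normalizes their
#' magnitudes into importance scores, and returns them sorted in descending
#' order of importance.  Zero weights are unselected features and never
#' appear; a single-entry list gets importance 1 by convention.
#'
#' @param B d x p encoder weight matrix of a trained model.
#' @param cluster_index integer in `1..2d`.
#' @param features data.frame with columns `ligand`, `receptor` (p rows).
#' @return data.frame with columns `cluster`, `rank`, `ligand`, `receptor`,
#'   `importance` (in `[0, 1]`), `raw_weight`; zero rows if no weight of the
#'   required sign exists.
#' @export
rank_interactions <- function(B, cluster_index, features) {
  d <- nrow(B)
  ccb_assert(nrow(features) == ncol(B), "ccb_shape_error",
             "features rows != ncol(B)")
  lay <- cluster_layout(cluster_index, d)
  w <- B[lay$dimension, ]
  idx <- if (lay$sign > 0) which(w > 0) else which(w < 0)
  if (length(idx) == 0L) {
    return(data.frame(cluster = integer(0), rank = integer(0),
                      ligand = character(0), receptor = character(0),
                      importance = numeric(0), raw_weight = numeric(0)))
  }
  mag <- abs(w[idx])
  importance <- if (length(mag) == 1L) 1 else {
    (mag - min(mag)) / (max(mag) - min(mag))
  }
  ord <- order(importance, decreasing = TRUE)
  data.frame(cluster = as.integer(cluster_index),
             rank = seq_along(ord),
             ligand = features$ligand[idx][ord],
             receptor = features$receptor[idx][ord],
             importance = unname(importance[ord]),
             raw_weight = unname(w[idx][ord]),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Ranked interaction lists for all clusters
#'
#' @param model a trained [bae()] model (must have been fit on a [ccim()] so
#'   feature metadata is available, or pass `features`).
#' @param features optional feature metadata overriding `model$features`.
#' @return named list of [rank_interactions()] data.frames, one per cluster
#'   `1..2d` (empty lists included).
#' @export
rank_all_interactions <- function(model, features = NULL) {
  if (is.null(features)) features <- model$features
  ccb_assert(!is.null(features), "ccb_validation_error",
             "no feature metadata available; pass features=")
  out <- lapply(seq_len(model$n_clusters), function(k)
    rank_interactions(model$B, k, features))
  names(out) <- paste0("cluster_", seq_len(model$n_clusters))
  out
}

#' 2D embedding of the latent representation
#'
#' Thin wrapper around UMAP (via uwot) used to visually inspect interaction
#' patterns.  The contract covers shape, finiteness, row-order preservation,
#' and reproducibility under a fixed seed within one library version.
#'
#' @param M numeric matrix (typically the latent representation `Z`; the
#'   cluster probabilities `P` also work).
#' @param neighbors UMAP `n_neighbors`; default 15.
#' @param min_dist UMAP `min_dist`; default 0.1.
#' @param seed RNG seed; default 42.
#' @return n x 2 matrix of coordinates with attribute `"params"`.
#' @export
compute_embedding <- function(M, neighbors = 15L, min_dist = 0.1, seed = 42L) {
  M <- as.matrix(M)
  ccb_assert(nrow(M) >= neighbors + 1L, "ccb_input_size_error",
             "need at least neighbors + 1 = %d rows, got %d",
             neighbors + 1L, nrow(M))
  coords <- with_seed(seed, {
    uwot::umap(M, n_neighbors = neighbors, min_dist = min_dist,
               n_threads = 1L, n_sgd_threads = 1L, verbose = FALSE)
  })
  dimnames(coords) <- list(NULL, c("umap1", "umap2"))
  attr(coords, "params") <- list(neighbors = as.integer(neighbors),
                                 min_dist = min_dist, seed = as.integer(seed))
  coords
}

embedding_plot <- function(df, colour_var, title, discrete) {
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$umap1, y = .data$umap2,
                                        colour = .data[[colour_var]])) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(title = title) +
    ggplot2::theme_minimal()
  if (!discrete) p <- p + ggplot2::scale_colour_viridis_c()
  p
}

#' Export all result modalities of a trained model
#'
#' Writes `assignments.tsv` (pair metadata, cluster, probability),
#' `ranked_interactions.tsv` (cluster, rank, ligand, receptor, importance,
#' raw_weight), `embedding.tsv`, and optionally five static plots of the 2D
#' embedding: colored by cluster, by sender type, by receiver type, by one
#' feature's scores, and by one cluster's membership probability.
#'
#' @param model a trained [bae()] model.
#' @param x the standardized [ccim()] the model was trained on.
#' @param out_dir output directory (created if missing).
#' @param embedding optional precomputed [compute_embedding()] result;
#'   computed from the latent representation when `NULL`.
#' @param plots write PNG plots? Default `TRUE`.
#' @param focus_cluster cluster index used for the probability panel and for
#'   picking the feature panel's feature (its top-ranked interaction);
#'   default: the most populated cluster.
#' @return invisibly, a named character vector of written file paths.
#' @export
export_results <- function(model, x, out_dir, embedding = NULL, plots = TRUE,
                           focus_cluster = NULL) {
  ccb_assert(inherits(x, "ccim"), "ccb_validation_error", "x must be a ccim")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Z <- predict(model, x, type = "latent")
  P <- predict(model, x, type = "probabilities")
  asg <- assign_clusters(P)
  if (is.null(embedding)) embedding <- compute_embedding(Z)
  ccb_assert(nrow(embedding) == nrow(x$scores), "ccb_shape_error",
             "embedding rows != CCIM rows")

  files <- c()
  asg_tab <- cbind(x$pairs, asg)
  f <- file.path(out_dir, "assignments.tsv")
  utils::write.table(asg_tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["assignments"] <- f

  lists <- rank_all_interactions(model, features = x$features)
  ranked <- do.call(rbind, lists)
  f <- file.path(out_dir, "ranked_interactions.tsv")
  utils::write.table(ranked, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["ranked_interactions"] <- f

  f <- file.path(out_dir, "embedding.tsv")
  utils::write.table(as.data.frame(embedding), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["embedding"] <- f

  if (plots) {
    if (is.null(focus_cluster)) {
      focus_cluster <- as.integer(names(sort(table(asg$cluster),
                                             decreasing = TRUE))[1L])
    }
    df <- data.frame(umap1 = embedding[, 1L], umap2 = embedding[, 2L],
                     cluster = factor(asg$cluster),
                     sender_type = x$pairs$sender_type,
                     receiver_type = x$pairs$receiver_type,
                     cluster_probability = P[, focus_cluster])
    panels <- list(
      by_cluster = embedding_plot(df, "cluster", "Cluster assignment", TRUE),
      by_sender = embedding_plot(df, "sender_type", "Sender cell type", TRUE),
      by_receiver = embedding_plot(df, "receiver_type", "Receiver cell type", TRUE),
      by_cluster_probability = embedding_plot(
        df, "cluster_probability",
        sprintf("Membership probability, cluster %d", focus_cluster), FALSE))
    top <- lists[[focus_cluster]]
    if (nrow(top) > 0) {
      fname <- paste(top$ligand[1L], top$receptor[1L], sep = "_")
      df$feature_score <- x$scores[, fname]
      panels$by_feature_score <- embedding_plot(
        df, "feature_score", sprintf("Interaction score: %s", fname), FALSE)
    }
    for (nm in names(panels)) {
      f <- file.path(out_dir, paste0("embedding_", nm, ".png"))
      ggplot2::ggsave(f, panels[[nm]], width = 5, height = 4, dpi = 120)
      files[paste0("plot_", nm)] <- f
    }
  }
  invisible(files)
}
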