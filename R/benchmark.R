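#' Training configuration used for the planted benchmark
#'
#' The package's standard evaluation fits a d = 4 model to the default
#' [simulate_ccim()] data (4 planted clusters of 200 pairs, 40 features,
#' 3-feature signatures, effect size 3, unit noise).  The benchmark uses a
#' single-layer linear decoder (analyzable, and empirically the most stable
#' choice for alternating boosting/gradient updates), 50 epochs with two
#' boosting updates per dimension per epoch, and the default multi-start
#' selection by final reconstruction loss.
#'
#' @param seed training seed.
#' @param d latent dimensions; default 4 (one per planted cluster).
#' @param epochs training epochs; default 50.
#' @return a [bae_config()].
#' @export
benchmark_config <- function(seed = 1L, d = 4L, epochs = 50L) {
  bae_config(d = d, epochs = epochs, seed = seed,
             decoder_hidden = integer(0), activation = "linear",
             boosting = boosting_config(updates_per_epoch = 2L))
}

#' Run the planted-benchmark evaluation
#'
#' Simulates the default planted CCIM, trains one model per training seed
#' with [benchmark_config()], and scores each model: adjusted Rand index of
#' the hard cluster assignments against the planted labels, top-k
#' precision/recall of the ranked interaction lists against the planted
#' signatures, initial and final reconstruction loss, and the maximum
#' absolute pairwise Pearson correlation between latent dimensions.
#'
#' @param train_seeds integer vector of training seeds (one model each).
#' @param data_seed seed of the simulated benchmark data; default 1.
#' @param top_k ranked features scored per cluster; default the planted
#'   signature size (3).
#' @return data.frame with one row per training seed and columns `seed`,
#'   `ari`, `precision`, `recall`, `initial_loss`, `final_loss`,
#'   `max_latent_cor`.
#' @export
run_planted_benchmark <- function(train_seeds = 1:5, data_seed = 1L,
                                  top_k = 3L) {
  sim <- simulate_ccim(seed = data_seed)
  x <- standardize_features(filter_active_features(sim$ccim, 0.05))
  rows <- lapply(train_seeds, function(s) {
    model <- bae(x, benchmark_config(seed = s))
    P <- predict(model, x, type = "probabilities")
    asg <- assign_clusters(P)
    lists <- rank_all_interactions(model, features = x$features)
    fr <- feature_recovery(lists, asg$cluster, sim$truth, x$features, top_k)
    Z <- predict(model, x, type = "latent")
    cors <- stats::cor(Z)
    data.frame(seed = s,
               ari = adjusted_rand_index(asg$cluster, sim$truth$labels),
               precision = fr$precision, recall = fr$recall,
               initial_loss = model$initial_loss,
               final_loss = model$loss_trace[length(model$loss_trace)],
               max_latent_cor = max(abs(cors[upper.tri(cors)])))
  })
  do.call(rbind, rows)
}
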