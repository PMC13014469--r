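#' Save a trained model checkpoint
#'
#' Writes a text-only checkpoint: the sparse encoder weights as a triplet TSV
#' (`dimension`, `feature_index`, `feature_name`, `weight`), the decoder
#' parameters as JSON, the effective configuration (including the derived
#' soft-cluster count `n_clusters = 2 * d`) as JSON, the per-epoch loss trace
#' as TSV, and the feature metadata.
#'
#' @param model a trained [bae()] model.
#' @param dir checkpoint directory (created if missing).
#' @return invisibly, `dir`.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(model$B != 0, arr.ind = TRUE)
  trip <- data.frame(dimension = nz[, 1L], feature_index = nz[, 2L],
                     feature_name = colnames(model$B)[nz[, 2L]],
                     weight = model$B[nz])
  trip <- trip[order(trip$dimension, trip$feature_index), , drop = FALSE]
  utils::write.table(trip, file.path(dir, "encoder_weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dec <- model$decoder
  jsonlite::write_json(list(sizes = dec$sizes, activation = dec$activation,
                            seed = dec$seed, W = dec$W, b = dec$b),
                       file.path(dir, "decoder.json"), digits = NA)
  cfg <- model$config
  cfg_out <- list(d = cfg$d, n_clusters = model$n_clusters,
                  epochs = cfg$epochs, learning_rate = cfg$learning_rate,
                  decoder_hidden = cfg$decoder_hidden,
                  activation = cfg$activation, seed = cfg$seed,
                  decoder_steps = cfg$decoder_steps,
                  n_starts = cfg$n_starts,
                  n_features = ncol(model$B),
                  boosting = unclass(cfg$boosting))
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(epoch = seq_along(model$loss_trace), loss = model$loss_trace,
               new_features = model$new_features),
    file.path(dir, "loss_trace.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(model$features)) {
    utils::write.table(model$features, file.path(dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param dir checkpoint directory.
#' @return a [bae()] model object.
#' @export
load_checkpoint <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  ccb_assert(file.exists(cfg_path), "ccb_io_error", "no config.json in %s", dir)
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  dec_raw <- jsonlite::read_json(file.path(dir, "decoder.json"),
                                 simplifyVector = TRUE)
  theta <- structure(list(W = lapply(dec_raw$W, as.matrix),
                          b = lapply(dec_raw$b, as.numeric),
                          sizes = as.integer(dec_raw$sizes),
                          activation = dec_raw$activation,
                          seed = dec_raw$seed),
                     class = "bae_decoder")
  features <- NULL
  fpath <- file.path(dir, "features.tsv")
  if (file.exists(fpath)) {
    features <- utils::read.table(fpath, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE,
                                  colClasses = "character")
  }
  B <- matrix(0, cfg$d, cfg$n_features)
  if (!is.null(features)) colnames(B) <- feature_names(features)
  trip <- utils::read.table(file.path(dir, "encoder_weights.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  if (nrow(trip) > 0) {
    B[cbind(trip$dimension, trip$feature_index)] <- trip$weight
  }
  trace_tab <- utils::read.table(file.path(dir, "loss_trace.tsv"), sep = "\t",
                                 header = TRUE)
  config <- bae_config(
    d = cfg$d, epochs = cfg$epochs, learning_rate = cfg$learning_rate,
    decoder_hidden = as.integer(cfg$decoder_hidden),
    activation = cfg$activation, seed = cfg$seed,
    decoder_steps = cfg$decoder_steps, n_starts = cfg$n_starts,
    boosting = boosting_config(
      step_size = cfg$boosting$step_size,
      updates_per_epoch = cfg$boosting$updates_per_epoch,
      disentanglement = cfg$boosting$disentanglement,
      disentanglement_mode = cfg$boosting$disentanglement_mode,
      epsilon = cfg$boosting$epsilon))
  structure(list(B = B, decoder = theta, config = config,
                 loss_trace = trace_tab$loss,
                 initial_loss = NA_real_,
                 new_features = trace_tab$new_features,
                 features = features, n_clusters = 2L * config$d),
            class = "bae")
}
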