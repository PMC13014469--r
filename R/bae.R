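# run code under a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Training configuration for the boosting autoencoder
#'
#' @param d number of latent dimensions; the split-softmax layer exposes
#'   `2 * d` soft clusters (a positive- and a negative-part cluster per
#'   dimension).
#' @param epochs number of training epochs (0 is a valid degenerate run:
#'   all-zero encoder, uniform cluster probabilities).
#' @param learning_rate decoder gradient-descent step size; default 1e-2.
#' @param decoder_hidden integer vector of hidden-layer widths; default one
#'   hidden layer of width `2 * d`.  `integer(0)` gives a linear decoder.
#' @param activation hidden-layer activation: `"tanh"` (default), `"relu"`,
#'   or `"linear"`.
#' @param seed integer seed for the decoder parameter initialization (the
#'   only source of randomness in training).
#' @param boosting a [boosting_config()].
#' @param decoder_steps decoder gradient steps per epoch; default 20.
#' @param n_starts number of restarts from decoder seeds derived
#'   deterministically from `seed`; the run with the lowest final
#'   reconstruction loss is kept (the alternating optimization is sensitive
#'   to the decoder initialization, as k-means is to its centers).
#'   Default 5.
#' @return a `bae_config` list.
#' @export
bae_config <- function(d, epochs = 100L, learning_rate = 0.5,
                       decoder_hidden = NULL,
                       activation = c("tanh", "relu", "linear"),
                       seed = 1L, boosting = boosting_config(),
                       decoder_steps = 20L, n_starts = 5L) {
  ccb_assert(is_count(d), "ccb_validation_error", "d must be a positive integer")
  ccb_assert(is.numeric(epochs) && epochs >= 0 && epochs == floor(epochs),
             "ccb_validation_error", "epochs must be a nonnegative integer")
  ccb_assert(is.numeric(learning_rate) && learning_rate > 0,
             "ccb_validation_error", "learning_rate must be positive")
  ccb_assert(inherits(boosting, "boosting_config"), "ccb_validation_error",
             "boosting must be a boosting_config()")
  ccb_assert(is_count(decoder_steps), "ccb_validation_error",
             "decoder_steps must be a positive integer")
  ccb_assert(is_count(n_starts), "ccb_validation_error",
             "n_starts must be a positive integer")
  if (is.null(decoder_hidden)) decoder_hidden <- 2L * as.integer(d)
  structure(list(d = as.integer(d), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 decoder_hidden = as.integer(decoder_hidden),
                 activation = match.arg(activation),
                 seed = as.integer(seed), boosting = boosting,
                 decoder_steps = as.integer(decoder_steps),
                 n_starts = as.integer(n_starts)),
            class = "bae_config")
}

#' Linear encoder
#'
#' The encoder is a single linear layer with no bias and no nonlinearity:
#' `Z = X %*% t(B)`.  Its weight matrix `B` (latent dimensions x features) is
#' the interpretable core of the model; it is fit by componentwise boosting
#' and stays sparse.
#'
#' @param X n x p matrix of standardized interaction scores.
#' @param B d x p encoder weight matrix.
#' @return n x d latent representation.
#' @export
encode <- function(X, B) {
  ccb_assert(ncol(X) == ncol(B), "ccb_shape_error",
             "X has %d columns but B has %d", ncol(X), ncol(B))
  X %*% t(B)
}

#' Split-softmax soft-clustering transformation
#'
#' Splits each latent activation into its positive and negative parts,
#' doubling the dimensionality from d to 2d, and applies a row-wise softmax
#' (with max-subtraction for numerical stability).  Each of the 2d output
#' dimensions is a soft cluster: columns `1..d` are the positive-part
#' clusters of dimensions `1..d`, columns `d+1..2d` the negative-part
#' clusters.  Splitting lets positive and negative signals contribute
#' equally, where a direct softmax would push negative activations toward
#' zero probability.
#'
#' @param Z n x d latent matrix (finite).
#' @return n x 2d row-stochastic matrix of cluster membership probabilities.
#' @export
split_softmax <- function(Z) {
  Z <- as.matrix(Z)
  ccb_assert(all(is.finite(Z)), "ccb_numerical_error", "non-finite latent activations")
  S <- cbind(pmax(Z, 0), pmax(-Z, 0))
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# decoder parameters: list(W = list, b = list, sizes, activation)
decoder_init <- function(input_width, hidden, output_width, activation, seed) {
  sizes <- c(input_width, hidden, output_width)
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (i in seq_along(W)) {
      lim <- sqrt(6 / (sizes[i] + sizes[i + 1L]))  # Glorot uniform
      W[[i]] <- matrix(stats::runif(sizes[i] * sizes[i + 1L], -lim, lim),
                       sizes[i], sizes[i + 1L])
      b[[i]] <- rep(0, sizes[i + 1L])
    }
    structure(list(W = W, b = b, sizes = sizes, activation = activation,
                   seed = seed),
              class = "bae_decoder")
  })
}

act_fun <- function(x, activation) {
  switch(activation, tanh = tanh(x), relu = pmax(x, 0), linear = x)
}
act_grad <- function(pre, post, activation) {
  switch(activation, tanh = 1 - post^2,
         relu = (pre > 0) + 0,
         linear = matrix(1, nrow(pre), ncol(pre)))
}

# forward pass through the decoder, keeping per-layer caches for backprop
decoder_forward <- function(P, theta, cache = FALSE) {
  nl <- length(theta$W)
  A <- P
  pres <- posts <- if (cache) vector("list", nl)
  for (i in seq_len(nl)) {
    pre <- sweep(A %*% theta$W[[i]], 2L, theta$b[[i]], "+")
    A <- if (i < nl) act_fun(pre, theta$activation) else pre  # linear output
    if (cache) { pres[[i]] <- pre; posts[[i]] <- A }
  }
  if (cache) list(out = A, pres = pres, posts = posts, input = P) else A
}

#' Decoder forward pass
#'
#' Maps the split-softmax representation back into the ligand-receptor
#' interaction space.  Hidden layers use the configured activation; the
#' output layer is linear.
#'
#' @param P n x 2d matrix of cluster membership probabilities.
#' @param theta decoder parameters created during [bae()] training.
#' @return n x p reconstruction matrix.
#' @export
decode <- function(P, theta) {
  ccb_assert(ncol(P) == theta$sizes[1L], "ccb_shape_error",
             "P has %d columns, decoder expects %d", ncol(P), theta$sizes[1L])
  decoder_forward(P, theta, cache = FALSE)
}

#' Mean squared reconstruction loss
#'
#' Mean over all `n * p` entries of the squared deviation between input and
#' reconstruction.
#'
#' @param X,X_hat matrices of identical shape.
#' @return a nonnegative scalar.
#' @export
reconstruction_loss <- function(X, X_hat) {
  ccb_assert(all(dim(X) == dim(X_hat)), "ccb_shape_error",
             "X and X_hat shapes differ")
  mean((X - X_hat)^2)
}

# full forward pass X -> Z -> P -> X_hat with caches
bae_forward <- function(X, B, theta) {
  Z <- encode(X, B)
  P <- split_softmax(Z)
  dec <- decoder_forward(P, theta, cache = TRUE)
  list(Z = Z, P = P, X_hat = dec$out, dec = dec)
}

# backprop of dL/dX_hat through the decoder; returns dL/dP and parameter grads
decoder_backward <- function(delta_out, theta, dec) {
  nl <- length(theta$W)
  gW <- vector("list", nl); gb <- vector("list", nl)
  delta <- delta_out
  for (i in rev(seq_len(nl))) {
    A_in <- if (i == 1L) dec$input else dec$posts[[i - 1L]]
    gW[[i]] <- crossprod(A_in, delta)
    gb[[i]] <- colSums(delta)
    delta <- delta %*% t(theta$W[[i]])
    if (i > 1L) {
      delta <- delta * act_grad(dec$pres[[i - 1L]], dec$posts[[i - 1L]],
                                theta$activation)
    }
  }
  list(dP = delta, gW = gW, gb = gb)
}

# dL/dZ given dL/dP, the probabilities P and the latent Z.
# Softmax backward: dL/ds = P * (G - rowSums(G * P)); split backward uses the
# symmetric subgradient 1/2 for both parts at z = 0, so that training can
# leave the all-zero initialization (both one-sided derivatives are 0 there).
split_softmax_backward <- function(dP, P, Z) {
  d <- ncol(Z)
  GS <- P * (dP - rowSums(dP * P))
  Dpos <- (Z > 0) + 0.5 * (Z == 0)
  Dneg <- (Z < 0) + 0.5 * (Z == 0)
  GS[, seq_len(d), drop = FALSE] * Dpos -
    GS[, d + seq_len(d), drop = FALSE] * Dneg
}

#' Pseudo-responses for the boosting step
#'
#' Computes the negative gradient of the mean-squared reconstruction loss
#' with respect to the latent representation, through the split-softmax layer
#' and the decoder at the current parameters, then mean-centers each column
#' (the boosting base learner is an intercept-free univariate fit).
#'
#' @param X n x p standardized score matrix.
#' @param B current d x p encoder weight matrix.
#' @param theta current decoder parameters.
#' @return n x d matrix of centered pseudo-responses.
#' @export
compute_pseudo_responses <- function(X, B, theta) {
  fw <- bae_forward(X, B, theta)
  delta_out <- 2 * (fw$X_hat - X) / length(X)
  bk <- decoder_backward(delta_out, theta, fw$dec)
  dZ <- split_softmax_backward(bk$dP, fw$P, fw$Z)
  ccb_assert(all(is.finite(dZ)), "ccb_numerical_error",
             "non-finite gradient in pseudo-response computation")
  U <- -dZ
  sweep(U, 2L, colMeans(U))
}

#' Train a boosting autoencoder on a standardized CCIM
#'
#' Alternating end-to-end optimization: per epoch, (1) a forward pass gives
#' the current latent representation, cluster probabilities, and
#' reconstruction; (2) pseudo-responses (negative loss gradients with respect
#' to the latent representation) are computed; (3) one componentwise boosting
#' pass updates the sparse encoder weight matrix; (4) the decoder parameters
#' take `decoder_steps` gradient-descent steps against the reconstruction
#' loss with the updated encoder.  The encoder starts from all zeros, so
#' after `t` epochs each latent dimension has at most
#' `t * updates_per_epoch` nonzero weights.
#'
#' @param x a standardized [ccim()], or a plain standardized numeric matrix.
#' @param config a [bae_config()].
#' @return an object of class `bae`: list with elements `B` (encoder weights,
#'   d x p, feature names as column names), `decoder`, `config`,
#'   `loss_trace` (epoch-end loss per epoch), `initial_loss` (loss before the
#'   first update), `new_features` (newly selected feature count per epoch),
#'   `features` (feature metadata if `x` was a ccim), and `n_clusters`
#'   (`2 * d`).
#' @export
bae <- function(x, config) {
  ccb_assert(inherits(config, "bae_config"), "ccb_validation_error",
             "config must be a bae_config()")
  features <- NULL
  if (inherits(x, "ccim")) {
    ccb_assert(x$standardized, "ccb_validation_error",
               "CCIM must be standardized; run standardize_features() first")
    features <- x$features
    X <- x$scores
  } else {
    X <- as.matrix(x)
  }
  n_starts <- if (config$epochs == 0L) 1L else config$n_starts
  best <- NULL
  for (i in seq_len(n_starts)) {
    init_seed <- (config$seed + (i - 1L) * 10007) %% 2147483647
    fit <- bae_fit_single(X, config, init_seed)
    final <- if (config$epochs > 0L) fit$loss_trace[config$epochs] else fit$initial_loss
    if (is.null(best) || final < best_final) {
      best <- fit
      best_final <- final
    }
  }
  structure(c(best, list(config = config, features = features,
                         n_clusters = 2L * config$d)),
            class = "bae")
}

# one full training run from a given decoder initialization seed
bae_fit_single <- function(X, config, init_seed) {
  d <- config$d
  p <- ncol(X)
  B <- matrix(0, d, p, dimnames = list(NULL, colnames(X)))
  theta <- decoder_init(2L * d, config$decoder_hidden, p,
                        config$activation, init_seed)
  loss_trace <- numeric(config$epochs)
  new_features <- integer(config$epochs)
  initial_loss <- reconstruction_loss(X, decode(split_softmax(encode(X, B)), theta))
  for (epoch in seq_len(config$epochs)) {
    U <- compute_pseudo_responses(X, B, theta)
    # Rescale the responses by one shared factor (the largest column RMS)
    # before the boosting pass.  The raw responses carry the 1/(n*p) factor
    # of the averaged loss, which makes every boosting coefficient minuscule
    # and freezes training in the zero-weight regime.  A single global
    # factor keeps the relative gradient magnitudes across latent dimensions
    # intact, so dimensions with little remaining signal take accordingly
    # small updates; per-feature selection is invariant to the rescaling.
    urms <- max(sqrt(colMeans(U^2)))
    if (urms > 0) U <- U / urms
    nz_before <- sum(B != 0)
    B <- boosting_update(B, X, U, config$boosting)
    attr(B, "selected") <- NULL
    new_features[epoch] <- sum(B != 0) - nz_before
    for (s in seq_len(config$decoder_steps)) {
      fw <- bae_forward(X, B, theta)
      bk <- decoder_backward(2 * (fw$X_hat - X) / length(X), theta, fw$dec)
      for (i in seq_along(theta$W)) {
        theta$W[[i]] <- theta$W[[i]] - config$learning_rate * bk$gW[[i]]
        theta$b[[i]] <- theta$b[[i]] - config$learning_rate * bk$gb[[i]]
      }
    }
    loss_trace[epoch] <-
      reconstruction_loss(X, decode(split_softmax(encode(X, B)), theta))
  }
  list(B = B, decoder = theta, loss_trace = loss_trace,
       initial_loss = initial_loss, new_features = new_features)
}

#' @export
print.bae <- function(x, ...) {
  cat(sprintf(paste0("bae: %d latent dimensions (%d soft clusters), ",
                     "%d features, %d nonzero encoder weights, %d epochs\n"),
              x$config$d, x$n_clusters, ncol(x$B), sum(x$B != 0),
              x$config$epochs))
  invisible(x)
}

#' Model outputs on (new) standardized scores
#'
#' @param object a trained [bae()] model.
#' @param x a standardized [ccim()] or matrix; defaults are not stored, so
#'   the training input must be passed again for training-set outputs.
#' @param type `"latent"` (n x d), `"probabilities"` (n x 2d) or
#'   `"reconstruction"` (n x p).
#' @param ... unused.
#' @return the requested matrix.
#' @export
predict.bae <- function(object, x, type = c("latent", "probabilities",
                                            "reconstruction"), ...) {
  type <- match.arg(type)
  X <- if (inherits(x, "ccim")) x$scores else as.matrix(x)
  Z <- encode(X, object$B)
  if (type == "latent") return(Z)
  P <- split_softmax(Z)
  if (type == "probabilities") return(P)
  decode(P, object$decoder)
}
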