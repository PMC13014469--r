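#' Componentwise boosting configuration
#'
#' Hyperparameters of the componentwise L2-boosting updates that fit the
#' linear encoder.  Per boosting call and latent dimension, only the single
#' feature whose univariate linear fit to the pseudo-response improves the
#' residual sum of squares the most receives a shrunken coefficient update.
#'
#' @param step_size shrinkage factor \eqn{\nu \in (0, 1]} applied to each
#'   selected coefficient; default 0.1.
#' @param updates_per_epoch number of boosting updates per latent dimension
#'   per call; default 1.
#' @param disentanglement apply the disentanglement constraint (see
#'   [residualize()])? Default `TRUE`.
#' @param disentanglement_mode `"residualize"` (project the pseudo-response
#'   off the other dimensions' activations; default) or `"mask"` (exclude
#'   features already selected by other dimensions from the candidate set).
#' @param epsilon denominator guard added to the column norm; default 1e-12.
#' @return a `boosting_config` list.
#' @export
boosting_config <- function(step_size = 0.1, updates_per_epoch = 1L,
                            disentanglement = TRUE,
                            disentanglement_mode = c("residualize", "mask"),
                            epsilon = 1e-12) {
  ccb_assert(is.numeric(step_size) && step_size > 0 && step_size <= 1,
             "ccb_validation_error", "step_size must be in (0, 1]")
  ccb_assert(is_count(updates_per_epoch), "ccb_validation_error",
             "updates_per_epoch must be a positive integer")
  ccb_assert(is.numeric(epsilon) && epsilon > 0, "ccb_validation_error",
             "epsilon must be positive")
  structure(list(step_size = step_size,
                 updates_per_epoch = as.integer(updates_per_epoch),
                 disentanglement = isTRUE(disentanglement),
                 disentanglement_mode = match.arg(disentanglement_mode),
                 epsilon = epsilon),
            class = "boosting_config")
}

#' Select the best single feature for a response
#'
#' For every allowed column j of the design matrix, the univariate
#' least-squares coefficient \eqn{\hat\beta_j = x_j'u / (x_j'x_j + \epsilon)}
#' is computed and the column giving the largest reduction in residual sum of
#' squares, \eqn{(x_j'u)^2 / (x_j'x_j + \epsilon)}, is returned (on
#' standardized columns this is the argmax of \eqn{|x_j'u|}).  Ties are broken
#' by the lowest index.
#'
#' @param X n x p numeric design matrix (columns standardized upstream).
#' @param u length-n numeric response (centered upstream).
#' @param candidate_mask optional logical length-p vector of allowed columns.
#' @param epsilon denominator guard; default 1e-12.
#' @return list with `index` (integer) and `coefficient` (the univariate OLS
#'   coefficient of the selected column).
#' @export
select_feature <- function(X, u, candidate_mask = NULL, epsilon = 1e-12) {
  p <- ncol(X)
  if (is.null(candidate_mask)) candidate_mask <- rep(TRUE, p)
  ccb_assert(length(candidate_mask) == p, "ccb_shape_error",
             "candidate_mask length != ncol(X)")
  ccb_assert(any(candidate_mask), "ccb_no_candidate_error",
             "empty candidate set")
  xtu <- drop(crossprod(X, u))
  xtx <- colSums(X^2)
  beta <- xtu / (xtx + epsilon)
  gain <- xtu^2 / (xtx + epsilon)
  gain[!candidate_mask] <- -Inf
  j <- which.max(gain)  # which.max takes the first maximum: lowest-index ties
  list(index = j, coefficient = beta[j])
}

#' Residualize a response against other latent dimensions
#'
#' Removes from `u` its least-squares projection (with intercept) onto the
#' column space of `Z_other`.  This is the disentanglement mechanism: fitting
#' each dimension only to the part of its pseudo-response that the other
#' dimensions' activations cannot already explain pushes dimensions toward
#' uncorrelated, distinctly characterized factors.  Rank-deficient `Z_other`
#' is handled by the pivoted QR least-squares solve and never errors.
#'
#' @param u length-n numeric response.
#' @param Z_other n x m matrix of the other dimensions' current activations
#'   (m may be 0, in which case `u` is returned unchanged).
#' @return the adjusted response, orthogonal to every column of `Z_other`.
#' @export
residualize <- function(u, Z_other) {
  if (is.null(Z_other) || ncol(Z_other) == 0L) return(u)
  ccb_assert(nrow(Z_other) == length(u), "ccb_shape_error",
             "Z_other rows != length(u)")
  A <- cbind(1, Z_other)
  qr_A <- qr(A)  # LINPACK pivoting: rank-deficiency handled
  drop(qr.resid(qr_A, u))
}

#' One componentwise-boosting pass over the encoder weight matrix
#'
#' For each latent dimension l in order: take that dimension's pseudo-response,
#' apply the disentanglement constraint against the *current* activations of
#' the other dimensions, select the best feature, and add
#' `step_size * coefficient` to `B[l, j]`.  Dimension-l activations are
#' recomputed before dimension l+1 is processed, so later dimensions see the
#' update.  At most `updates_per_epoch` weights change per dimension per call.
#'
#' @param B d x p encoder weight matrix (initialized to zeros before training).
#' @param X n x p standardized design matrix.
#' @param U n x d pseudo-response matrix (one column per latent dimension).
#' @param cfg a [boosting_config()].
#' @return the updated weight matrix, with attribute `"selected"` giving the
#'   feature index chosen per dimension and update (0 for skipped updates).
#' @export
boosting_update <- function(B, X, U, cfg = boosting_config()) {
  d <- nrow(B)
  ccb_assert(ncol(B) == ncol(X), "ccb_shape_error", "B and X column mismatch")
  ccb_assert(ncol(U) == d && nrow(U) == nrow(X), "ccb_shape_error",
             "U must be nrow(X) x nrow(B)")
  ccb_assert(all(is.finite(U)), "ccb_numerical_error",
             "non-finite pseudo-responses")
  selected <- matrix(0L, d, cfg$updates_per_epoch)
  for (l in seq_len(d)) {
    u <- U[, l]
    if (cfg$disentanglement && d > 1L) {
      if (cfg$disentanglement_mode == "residualize") {
        Z_other <- X %*% t(B[-l, , drop = FALSE])
        u <- residualize(u, Z_other)
      } else {
        taken <- colSums(abs(B[-l, , drop = FALSE])) > 0 & B[l, ] == 0
        mask <- !taken
        if (!any(mask)) mask <- rep(TRUE, ncol(X))
      }
    }
    mask <- if (cfg$disentanglement && d > 1L &&
                cfg$disentanglement_mode == "mask") mask else NULL
    for (m in seq_len(cfg$updates_per_epoch)) {
      sel <- select_feature(X, u, candidate_mask = mask, epsilon = cfg$epsilon)
      if (sel$coefficient == 0) break
      B[l, sel$index] <- B[l, sel$index] + cfg$step_size * sel$coefficient
      selected[l, m] <- sel$index
      if (m < cfg$updates_per_epoch) {
        u <- u - cfg$step_size * sel$coefficient * X[, sel$index]
      }
    }
  }
  attr(B, "selected") <- selected
  B
}
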