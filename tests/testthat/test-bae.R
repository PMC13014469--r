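test_that("encode is the exact linear map X B'", {
  set.seed(1)
  X <- matrix(rnorm(35), 7, 5)
  B <- matrix(rnorm(15), 3, 5)
  Z <- encode(X, B)
  # naive triple loop oracle
  Zo <- matrix(0, 7, 3)
  for (i in 1:7) for (l in 1:3) for (j in 1:5) {
    Zo[i, l] <- Zo[i, l] + X[i, j] * B[l, j]
  }
  expect_lt(max(abs(Z - Zo)), 1e-12)
  expect_equal(encode(X, matrix(0, 3, 5)), matrix(0, 7, 3))
  # unit-vector rows select columns of X
  Bsel <- rbind(c(1, 0, 0, 0, 0), c(0, 0, 1, 0, 0))
  expect_equal(encode(X, Bsel), X[, c(1, 3)])
  expect_error(encode(X, matrix(0, 3, 4)), class = "ccb_shape_error")
})

test_that("split_softmax matches closed forms", {
  # zero activation: exactly uniform
  expect_equal(split_softmax(matrix(0, 1, 2))[1, ], rep(0.25, 4))
  # d=2, z=(1,-1): s=(1,0,0,1), probabilities (e,1,1,e)/(2e+2)
  P <- split_softmax(matrix(c(1, -1), 1, 2))
  e <- exp(1)
  expect_equal(P[1, ], c(e, 1, 1, e) / (2 * e + 2), tolerance = 1e-12)
  expect_error(split_softmax(matrix(c(1, NA), 1)), class = "ccb_numerical_error")
})

test_that("split_softmax rows are stochastic and sign-flip equivariant", {
  set.seed(7)
  Z <- matrix(rnorm(1000 * 3, sd = 4), 1000, 3)
  P <- split_softmax(Z)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_true(all(P > 0 & P < 1))
  Pm <- split_softmax(-Z)
  swapped <- cbind(P[, 4:6], P[, 1:3])
  expect_lt(max(abs(Pm - swapped)), 1e-12)
})

test_that("decode is deterministic and the identity map recovers P", {
  theta <- structure(list(W = list(diag(4)), b = list(rep(0, 4)),
                          sizes = c(4L, 4L), activation = "linear", seed = 0L),
                     class = "bae_decoder")
  P <- split_softmax(matrix(rnorm(10 * 2), 10, 2))
  expect_equal(decode(P, theta), P)
  theta2 <- cciboost:::decoder_init(4L, 8L, 5L, "tanh", seed = 3L)
  out1 <- decode(P, theta2)
  out2 <- decode(P, theta2)
  expect_identical(out1, out2)
  expect_error(decode(P[, 1:3], theta2), class = "ccb_shape_error")
})

test_that("decoder parameter gradients match central finite differences", {
  set.seed(12)
  d <- 2
  P <- split_softmax(matrix(rnorm(4 * d), 4, d))
  X <- matrix(rnorm(4 * 3), 4, 3)
  theta <- cciboost:::decoder_init(2L * d, 2L * d, 3L, "tanh", seed = 5L)
  fw <- cciboost:::decoder_forward(P, theta, cache = TRUE)
  bk <- cciboost:::decoder_backward(2 * (fw$out - X) / length(X), theta, fw)
  loss_at <- function(theta) mean((cciboost:::decoder_forward(P, theta) - X)^2)
  h <- 1e-6
  for (layer in seq_along(theta$W)) {
    for (k in seq_len(min(6, length(theta$W[[layer]])))) {
      tp <- theta; tp$W[[layer]][k] <- tp$W[[layer]][k] + h
      tm <- theta; tm$W[[layer]][k] <- tm$W[[layer]][k] - h
      fd <- (loss_at(tp) - loss_at(tm)) / (2 * h)
      expect_lt(abs(fd - bk$gW[[layer]][k]), 1e-4)
    }
    tp <- theta; tp$b[[layer]][1] <- tp$b[[layer]][1] + h
    tm <- theta; tm$b[[layer]][1] <- tm$b[[layer]][1] - h
    fd <- (loss_at(tp) - loss_at(tm)) / (2 * h)
    expect_lt(abs(fd - bk$gb[[layer]][1]), 1e-4)
  }
})

test_that("pseudo-responses equal centered negative finite-difference gradients", {
  set.seed(30)
  n <- 5; p <- 3; d <- 2
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(d * p, sd = 0.8), d, p)  # Z entries away from 0
  theta <- cciboost:::decoder_init(2L * d, 2L * d, p, "tanh", seed = 9L)
  U <- compute_pseudo_responses(X, B, theta)
  Z <- encode(X, B)
  loss_of_Z <- function(Z) {
    mean((cciboost:::decoder_forward(split_softmax(Z), theta) - X)^2)
  }
  h <- 1e-5
  G <- matrix(0, n, d)
  for (i in 1:n) for (l in 1:d) {
    Zp <- Z; Zp[i, l] <- Zp[i, l] + h
    Zm <- Z; Zm[i, l] <- Zm[i, l] - h
    G[i, l] <- (loss_of_Z(Zp) - loss_of_Z(Zm)) / (2 * h)
  }
  U_fd <- sweep(-G, 2, colMeans(-G))
  expect_lt(max(abs(U - U_fd)), 1e-4)
})

test_that("gradients are linear in the loss scale and vanish for a zero residual", {
  set.seed(31)
  n <- 6; p <- 4; d <- 2
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(d * p, sd = 0.5), d, p)
  theta <- cciboost:::decoder_init(2L * d, integer(0), p, "linear", seed = 2L)
  fw <- cciboost:::bae_forward(X, B, theta)
  delta <- 2 * (fw$X_hat - X) / length(X)
  g1 <- cciboost:::decoder_backward(delta, theta, fw$dec)
  g2 <- cciboost:::decoder_backward(2 * delta, theta, fw$dec)
  expect_equal(g2$dP, 2 * g1$dP, tolerance = 1e-12)
  expect_equal(cciboost:::split_softmax_backward(g2$dP, fw$P, fw$Z),
               2 * cciboost:::split_softmax_backward(g1$dP, fw$P, fw$Z),
               tolerance = 1e-12)
  # zero-output decoder on all-zero input: no residual, no responses
  theta0 <- theta
  theta0$W[[1]][] <- 0
  U0 <- compute_pseudo_responses(matrix(0, n, p), B, theta0)
  expect_equal(U0, matrix(0, n, d))
})

test_that("reconstruction loss matches its closed form and an elementwise oracle", {
  X <- matrix(0, 2, 3)
  expect_equal(reconstruction_loss(X, X + 1), 1)
  expect_equal(reconstruction_loss(X, X), 0)
  set.seed(3)
  A <- matrix(rnorm(24), 6, 4); Bm <- matrix(rnorm(24), 6, 4)
  acc <- 0
  for (i in 1:6) for (j in 1:4) acc <- acc + (A[i, j] - Bm[i, j])^2
  expect_lt(abs(reconstruction_loss(A, Bm) - acc / 24), 1e-12)
  expect_error(reconstruction_loss(A, Bm[, 1:3]), class = "ccb_shape_error")
})

test_that("zero-epoch training gives zero weights and uniform probabilities", {
  x <- standardize_features(random_ccim(n = 24, p = 6, seed = 13))
  m <- bae(x, bae_config(d = 3, epochs = 0))
  expect_true(all(m$B == 0))
  expect_length(m$loss_trace, 0)
  P <- predict(m, x, type = "probabilities")
  expect_equal(unname(P), matrix(1 / 6, 24, 6))
  Z <- predict(m, x, type = "latent")
  expect_true(all(Z == 0))
})

test_that("training is reproducible and refuses unstandardized input", {
  sim <- simulate_ccim(n_pairs_per_cluster = 30, k_clusters = 2,
                       n_features = 10, signature_size = 2, seed = 4)
  expect_error(bae(sim$ccim, bae_config(d = 2)), class = "ccb_validation_error")
  x <- standardize_features(sim$ccim)
  cfg <- bae_config(d = 2, epochs = 10, seed = 17, n_starts = 2)
  m1 <- bae(x, cfg)
  m2 <- bae(x, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$B, m2$B)
})

test_that("a d=1 model separates a two-block CCIM by latent sign", {
  sim <- simulate_ccim(n_pairs_per_cluster = 50, k_clusters = 2,
                       n_features = 10, signature_size = 2, seed = 6)
  x <- standardize_features(sim$ccim)
  m <- bae(x, benchmark_config(seed = 1, d = 1))
  z <- drop(predict(m, x, type = "latent"))
  signs <- sign(z)
  expect_true(all(signs[sim$truth$labels == 1] == signs[sim$truth$labels == 1][1]))
  expect_true(all(signs[sim$truth$labels == 2] == signs[sim$truth$labels == 2][1]))
  expect_true(signs[1] != signs[100])
  # descent on the fixture
  expect_lt(m$loss_trace[length(m$loss_trace)], m$loss_trace[1])
  # sparsity bound: at most updates_per_epoch * epochs nonzeros per row
  expect_true(all(rowSums(m$B != 0) <=
                    m$config$epochs * m$config$boosting$updates_per_epoch))
})
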