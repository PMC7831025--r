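test_that("sigmoid has the textbook values and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  x <- seq(-8, 8, by = 0.5)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, length(x)))
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_lt(1 - sigmoid(30), 1e-12)
})

test_that("backpropagated gradients match finite differences on a tiny net", {
  spec <- autoencoder_spec(input_dim = 2, hidden = 3, bottleneck = 2)
  set.seed(41)
  params <- channelprint:::ae_init_params(spec$widths)
  X <- matrix(runif(10), 5, 2)
  g <- channelprint:::ae_grad(params, X, "sigmoid")
  eps <- 1e-6
  for (part in c("W", "b")) {
    for (l in seq_along(params[[part]])) {
      for (idx in seq_len(min(4, length(params[[part]][[l]])))) {
        p_plus <- params; p_minus <- params
        p_plus[[part]][[l]][idx] <- p_plus[[part]][[l]][idx] + eps
        p_minus[[part]][[l]][idx] <- p_minus[[part]][[l]][idx] - eps
        fd <- (channelprint:::ae_loss(p_plus, X, "sigmoid") -
                 channelprint:::ae_loss(p_minus, X, "sigmoid")) / (2 * eps)
        an <- g[[part]][[l]][idx]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
      }
    }
  }
})

test_that("reconstruction error equals the loop oracle and basic identities", {
  X <- matrix(runif(60), 10, 6)
  spec <- autoencoder_spec(input_dim = 6, hidden = 4, bottleneck = 2)
  m <- train_autoencoder(X, spec, train_hyperparams(epochs = 3, seed = 1))
  R <- reconstruct(m, X)
  oracle <- mean(vapply(seq_len(nrow(X)),
                        function(i) sum((R[i, ] - X[i, ])^2), numeric(1)))
  expect_lt(abs(reconstruction_error(m, X) - oracle), 1e-10)
  # permutation invariance of J
  perm <- sample(nrow(X))
  expect_equal(reconstruction_error(m, X[perm, ]), reconstruction_error(m, X))
  # encode/decode composition = reconstruct; duplicated rows map identically
  emb <- encode(m, X)
  expect_equal(dim(emb), c(10, 2))
  expect_true(all(emb > 0 & emb < 1))
  X2 <- X[c(1, 1, 2), ]
  e2 <- encode(m, X2)
  expect_identical(e2[1, ], e2[2, ])
  expect_error(encode(m, X[, 1:3]), "dimension")
})

test_that("training descends, is seed-deterministic, and learns a 1-D manifold", {
  X <- sine_manifold(400, 200)
  hp <- train_hyperparams(epochs = 120, seed = 3)
  m <- train_autoencoder(X, autoencoder_spec(bottleneck = 2), hp)
  J_final <- min(m$training_log)
  expect_lte(J_final, m$training_log[1])  # descent contract
  expect_lt(J_final, 0.5)                 # frozen from the reference run (~0.08)
  m2 <- train_autoencoder(X, autoencoder_spec(bottleneck = 2), hp)
  expect_identical(m$training_log, m2$training_log)
  expect_identical(m$params, m2$params)
  # a 1-point bottleneck on richer 2-D-manifold data fits worse
  grid <- seq(0, 2 * pi, length.out = 200)
  set.seed(44)
  X2 <- t(sapply(1:300, function(i) {
    0.5 + 0.25 * sin(grid + runif(1, 0, 2 * pi)) +
      0.2 * cos(2 * grid + runif(1, 0, 2 * pi))
  }))
  hp2 <- train_hyperparams(epochs = 60, seed = 5)
  J2 <- min(train_autoencoder(X2, autoencoder_spec(bottleneck = 2), hp2)$training_log)
  J1 <- min(train_autoencoder(X2, autoencoder_spec(bottleneck = 1), hp2)$training_log)
  expect_gt(J1, J2)
})

test_that("bottleneck sweep is non-increasing on smooth data up to training noise", {
  grid <- seq(0, 2 * pi, length.out = 20)
  rhos <- vapply(1:5, function(s) {
    set.seed(100 + s)
    X <- t(sapply(1:250, function(i) {
      0.5 + 0.3 * sin(grid + runif(1, 0, 2 * pi)) +
        0.1 * cos(2 * grid + runif(1, 0, 2 * pi))
    }))
    sw <- bottleneck_sweep(X, c(1, 2, 3, 5, 20), hidden = c(16, 8),
                           hp = train_hyperparams(epochs = 120, seed = s))
    stats::cor(sw$dim, sw$J, method = "spearman")
  }, numeric(1))
  expect_lte(mean(rhos), 0)
  expect_error(bottleneck_sweep(matrix(runif(40), 4), integer(0)), "nonempty")
})
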