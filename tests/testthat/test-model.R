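# Adversarial model: forward maps, value function, gradients, training
# contracts, scoring and ranking, checkpoints, engine parity.

test_that("encoder_forward applies affine + ReLU layers", {
  m <- manual_model(
    input_dim = 2, latent_dim = 2,
    encoder = list(list(W = diag(2), b = c(0, 0))),
    generator = list(list(W = diag(2), b = c(0, 0))),
    discriminator = list(list(W = matrix(0, 1, 4), b = 0)))
  # single linear layer: identity (no ReLU on the output layer)
  expect_identical(encoder_forward(m, c(1, -2)), c(1, -2))
  # hidden ReLU zeroes negatives
  m2 <- manual_model(
    input_dim = 2, latent_dim = 2,
    encoder = list(list(W = diag(2), b = c(0, 0)),
                   list(W = diag(2), b = c(0, 0))),
    generator = list(list(W = diag(2), b = c(0, 0))),
    discriminator = list(list(W = matrix(0, 1, 4), b = 0)))
  expect_identical(encoder_forward(m2, c(1, -2)), c(1, 0))
  expect_identical(encoder_forward(m2, c(0, 0)), c(0, 0))
  # deterministic
  x <- c(0.3, 0.7)
  expect_identical(encoder_forward(m2, x), encoder_forward(m2, x))
  expect_error(encoder_forward(m2, c(1, 2, 3)), "length/width 2")
})

test_that("generator_forward maps latent codes to feature space", {
  net <- network_config(input_dim = 10, latent_dim = 4,
                        hidden_encoder = c(8, 5),
                        hidden_discriminator = c(8, 4))
  model <- bigan_init(net, seed = 2)
  z <- rnorm(net$latent_dim)
  out <- generator_forward(model, z)
  expect_length(out, 10)
  # sigmoid output stays in (0, 1) by default
  expect_true(all(out > 0 & out < 1))
  # two different codes give different outputs
  expect_false(isTRUE(all.equal(out, generator_forward(model, z + 1))))
  # linear single layer with zero bias maps 0 to 0
  m0 <- manual_model(
    input_dim = 2, latent_dim = 2,
    encoder = list(list(W = diag(2), b = c(0, 0))),
    generator = list(list(W = diag(2), b = c(0, 0))),
    discriminator = list(list(W = matrix(0, 1, 4), b = 0)),
    generator_out_act = "linear")
  expect_identical(generator_forward(m0, c(0, 0)), c(0, 0))
  expect_error(generator_forward(model, rnorm(99)), "length/width")
})

test_that("discriminator_forward is a probability with sigmoid(0) = 0.5", {
  m <- identity_model(3)
  expect_identical(discriminator_forward(m, c(1, 2, 3), c(0, 0, 1)), 0.5)
  # monotone and bounded in the logit
  m$discriminator[[1]]$b <- 50
  expect_gt(discriminator_forward(m, rep(0, 3), rep(0, 3)), 1 - 1e-10)
  m$discriminator[[1]]$b <- -50
  expect_lt(discriminator_forward(m, rep(0, 3), rep(0, 3)), 1e-10)
  # deterministic
  m$discriminator[[1]]$b <- 0.7
  p1 <- discriminator_forward(m, c(1, 0, 1), c(0, 1, 0))
  p2 <- discriminator_forward(m, c(1, 0, 1), c(0, 1, 0))
  expect_identical(p1, p2)
})

test_that("bigan_value agrees with its defining expectation", {
  net <- tiny_net(input_dim = 6)
  model <- bigan_init(net, seed = 4)
  X <- matrix(runif(5 * 6), 5, 6)
  Z <- matrix(rnorm(4 * net$latent_dim), 4, net$latent_dim)
  p_real <- discriminator_forward(model, X, encoder_forward(model, X))
  p_fake <- discriminator_forward(model, generator_forward(model, Z), Z)
  expect_equal(bigan_value(model, X, Z),
               mean(log(p_real)) + mean(log(1 - p_fake)),
               tolerance = 1e-12)
  expect_error(bigan_value(model, X[0, , drop = FALSE], Z), "empty batch")
})

test_that("a discriminator frozen at 1/2 sits at the -2 log 2 equilibrium", {
  m <- identity_model(4)  # zero output layer: D is exactly 0.5 everywhere
  X <- matrix(runif(12), 3, 4)
  Z <- matrix(rnorm(8), 2, 4)
  expect_identical(bigan_value(m, X, Z), -2 * log(2))
})

test_that("analytic discriminator gradients match finite differences", {
  net <- network_config(input_dim = 2, latent_dim = 1,
                        hidden_encoder = 3, hidden_generator = 3,
                        hidden_discriminator = 3,
                        generator_out_act = "linear")
  model <- bigan_init(net, seed = 8)
  set.seed(21)
  X <- matrix(runif(8), 4, 2)
  Z <- matrix(rnorm(3), 3, 1)
  grads <- lncgan:::.bigan_value_disc_grads(model, X, Z)
  eps <- 1e-6
  worst <- 0
  for (l in seq_along(model$discriminator)) {
    for (p in c("W", "b")) {
      theta <- model$discriminator[[l]][[p]]
      for (i in seq_along(theta)) {
        up <- model; up$discriminator[[l]][[p]][i] <- theta[i] + eps
        dn <- model; dn$discriminator[[l]][[p]][i] <- theta[i] - eps
        fd <- (bigan_value(up, X, Z) - bigan_value(dn, X, Z)) / (2 * eps)
        an <- grads[[l]][[p]][i]
        if (abs(fd) > 1e-10) {
          worst <- max(worst, abs(an - fd) / max(abs(fd), abs(an)))
        } else {
          expect_lt(abs(an), 1e-8)
        }
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training is deterministic and respects the batch-size guard", {
  feats <- small_features()
  net <- tiny_net()
  m1 <- train_bigan(feats, net, tiny_train())
  m2 <- train_bigan(feats, net, tiny_train())
  expect_identical(m1$encoder, m2$encoder)
  expect_identical(m1$discriminator, m2$discriminator)
  # epochs = 0 returns the initialised model
  m0 <- train_bigan(feats, net, tiny_train(epochs = 0))
  seed0 <- lncgan:::.derive_seed(lncgan:::.derive_seed(3L, 11L), 1L)
  init <- bigan_init(net, seed = seed0)
  expect_identical(m0$encoder, init$encoder)
  expect_identical(m0$generator, init$generator)
  # too few positives for one batch
  expect_error(train_bigan(feats, net, tiny_train(batch_size = 10000)),
               "smaller batch_size")
})

test_that("training improves the discriminator's real-pair recognition", {
  feats <- small_features()
  net <- tiny_net()
  trained <- train_bigan(feats, net, tiny_train(epochs = 20))
  init <- train_bigan(feats, net, tiny_train(epochs = 0))
  X <- feats$x[feats$pairs$label == 1, , drop = FALSE]
  bce_real <- function(model) {
    p <- discriminator_forward(model, X, encoder_forward(model, X))
    mean(-log(pmin(pmax(p, 1e-7), 1 - 1e-7)))
  }
  expect_lt(bce_real(trained), bce_real(init))
  expect_true(all(is.finite(unlist(trained$encoder))))
  expect_true(all(is.finite(unlist(trained$discriminator))))
})

test_that("compiled and reference training engines agree", {
  feats <- small_features()
  net <- tiny_net()
  tc <- tiny_train(epochs = 4, n_members = 2, snapshot_every = 1,
                   snapshot_start_frac = 0.5, lr_decay = "linear")
  mc <- train_bigan(feats, net, tc, engine = "compiled")
  mr <- train_bigan(feats, net, tc, engine = "reference")
  for (part in c("encoder", "generator", "discriminator")) {
    for (l in seq_along(mc[[part]])) {
      expect_equal(mc[[part]][[l]]$W, mr[[part]][[l]]$W, tolerance = 1e-10)
      expect_equal(mc[[part]][[l]]$b, mr[[part]][[l]]$b, tolerance = 1e-10)
    }
  }
  expect_identical(length(mc$members[[1]]$snapshots),
                   length(mr$members[[1]]$snapshots))
  expect_gt(length(mc$members[[1]]$snapshots), 0L)
})

test_that("score_pairs returns probabilities in input order, invariant to it", {
  feats <- small_features()
  model <- train_bigan(feats, tiny_net(), tiny_train())
  st <- score_pairs(model, feats)
  expect_identical(nrow(st), nrow(feats$pairs))
  expect_identical(st$disease_id, feats$pairs$disease_id)
  expect_true(all(st$score > 0 & st$score < 1))
  expect_equal(st$score, 1 / (1 + exp(-st$logit)), tolerance = 1e-12)
  # submitting pairs in a different order permutes but does not change scores
  ord <- rev(seq_len(nrow(feats$pairs)))
  feats_rev <- structure(list(x = feats$x[ord, , drop = FALSE],
                              pairs = feats$pairs[ord, ]),
                         class = "pair_features")
  st_rev <- score_pairs(model, feats_rev)
  key <- paste(st$disease_id, st$lncrna_id)
  key_rev <- paste(st_rev$disease_id, st_rev$lncrna_id)
  expect_identical(st_rev$score[match(key, key_rev)], st$score)
  # identical feature vectors get identical scores
  dup <- structure(list(x = feats$x[c(1, 1), , drop = FALSE],
                        pairs = feats$pairs[c(1, 1), ]),
                   class = "pair_features")
  sd2 <- score_pairs(model, dup)
  expect_identical(sd2$score[1], sd2$score[2])
})

test_that("rank_candidates orders by score with lexicographic tie-break", {
  st <- data.frame(
    disease_id = rep("d1", 5),
    lncrna_id = c("l5", "l2", "l9", "l1", "l3"),
    score = c(0.1, 0.9, 0.1, 0.1, 0.1),
    logit = qlogis(c(0.1, 0.9, 0.1, 0.1, 0.1)),
    known_flag = c(0, 0, 0, 0, 1))
  class(st) <- c("score_table", "data.frame")
  expect_identical(rank_candidates(st, "d1", 2), c("l2", "l1"))
  # k beyond the candidate count returns all candidates, no padding
  expect_identical(rank_candidates(st, "d1", 10), c("l2", "l1", "l5", "l9"))
  # all-equal scores: lexicographic order
  st$score <- 0.4
  st$logit <- qlogis(0.4)
  expect_identical(rank_candidates(st, "d1", 3), c("l1", "l2", "l5"))
  expect_error(rank_candidates(st, "dX", 3), "not present")
})

test_that("checkpoints round-trip to identical scores", {
  feats <- small_features()
  model <- train_bigan(feats, tiny_net(), tiny_train())
  path <- withr::local_tempfile(fileext = ".rds")
  save_bigan(model, path)
  reloaded <- load_bigan(path)
  expect_identical(score_pairs(reloaded, feats)$score,
                   score_pairs(model, feats)$score)
})
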