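# Bidirectional adversarial model: encoder E maps feature vectors to a
# latent code, generator G maps latent noise back to feature space, and the
# discriminator D judges joint (feature, latent) tuples -- (x, E(x)) from
# the data branch versus (G(z), z) from the noise branch. Networks are
# plain fully connected ReLU stacks trained with Adam on the binary
# cross-entropy form of the adversarial value function.

#' Network architecture configuration
#'
#' The encoder maps `input_dim -> latent_dim` through ReLU hidden layers,
#' the generator mirrors it (`latent_dim -> input_dim`), and the
#' discriminator maps the concatenated `(input_dim + latent_dim)` tuple to
#' a single sigmoid probability. Defaults (two hidden layers 1024/256,
#' latent 100) are sized for feature vectors of several thousand
#' dimensions; smaller problems should taper proportionally.
#'
#' @param input_dim Feature vector length (`nd + nl`).
#' @param latent_dim Latent code length; default 100.
#' @param hidden_encoder Integer vector of encoder hidden layer sizes.
#' @param hidden_generator Generator hidden sizes; default mirrors the
#'   encoder.
#' @param hidden_discriminator Discriminator hidden sizes.
#' @param generator_out_act Activation of the generator's output layer.
#'   Similarity feature vectors live in \[0, 1\], so the default
#'   `"sigmoid"` keeps generated vectors in the data range and the
#'   adversarial game informative; `"linear"` gives an unconstrained
#'   output.
#' @return A `network_config` list.
#' @export
network_config <- function(input_dim, latent_dim = 100,
                           hidden_encoder = c(1024, 256),
                           hidden_generator = rev(hidden_encoder),
                           hidden_discriminator = c(512, 128),
                           generator_out_act = c("sigmoid", "linear")) {
  generator_out_act <- match.arg(generator_out_act)
  stopifnot(.is_count(input_dim), .is_count(latent_dim),
            all(vapply(hidden_encoder, .is_count, logical(1))),
            all(vapply(hidden_generator, .is_count, logical(1))),
            all(vapply(hidden_discriminator, .is_count, logical(1))))
  structure(list(input_dim = as.integer(input_dim),
                 latent_dim = as.integer(latent_dim),
                 hidden_encoder = as.integer(hidden_encoder),
                 hidden_generator = as.integer(hidden_generator),
                 hidden_discriminator = as.integer(hidden_discriminator),
                 generator_out_act = generator_out_act),
            class = "network_config")
}

#' Training configuration
#'
#' Defaults follow the reference protocol: 5 epochs, batch size 64, Adam
#' with learning rate 1e-3 and betas (0.9, 0.999).
#'
#' @param epochs Number of passes over the positive-pair features
#'   (`epochs = 0` returns the freshly initialised model).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size for the discriminator.
#' @param learning_rate_eg Adam step size for the encoder+generator step;
#'   defaults to `learning_rate`.
#' @param lr_decay `"none"` for a constant step size, `"linear"` to anneal
#'   both step sizes linearly to zero over the epochs. Annealing settles
#'   the adversarial game instead of letting it oscillate, which matters
#'   on small training sets.
#' @param n_members Number of independently initialised models trained;
#'   scoring averages the discriminator logits over all members. An
#'   ensemble of restarts smooths over initialisation-dependent adversarial
#'   dynamics.
#' @param snapshot_every Record an (encoder, discriminator) snapshot every
#'   this many epochs during the tail of training (0 disables snapshots);
#'   scoring averages logits over the recorded snapshots, a temporal
#'   ensemble over the oscillating game.
#' @param snapshot_start_frac Fraction of training after which snapshots
#'   begin.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed Integer seed controlling initialisation, batch order and
#'   latent noise; training is deterministic given the seed.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 5, batch_size = 64, learning_rate = 1e-3,
                         learning_rate_eg = learning_rate,
                         lr_decay = c("none", "linear"), n_members = 1,
                         snapshot_every = 0, snapshot_start_frac = 0.5,
                         beta1 = 0.9, beta2 = 0.999, seed = 1L) {
  lr_decay <- match.arg(lr_decay)
  stopifnot(length(epochs) == 1, epochs >= 0, epochs == round(epochs),
            .is_count(batch_size), learning_rate > 0, learning_rate_eg > 0,
            .is_count(n_members),
            length(snapshot_every) == 1, snapshot_every >= 0,
            snapshot_every == round(snapshot_every),
            .is_prob(snapshot_start_frac),
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 learning_rate_eg = learning_rate_eg,
                 lr_decay = lr_decay,
                 n_members = as.integer(n_members),
                 snapshot_every = as.integer(snapshot_every),
                 snapshot_start_frac = snapshot_start_frac,
                 beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed), optimizer = "adam"),
            class = "train_config")
}

## ---- minimal MLP machinery -------------------------------------------------

.init_layer <- function(n_in, n_out) {
  # seeded uniform fan-in scaling
  limit <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -limit, limit),
                  nrow = n_out, ncol = n_in),
       b = numeric(n_out))
}

.init_mlp <- function(dims) {
  lapply(seq_len(length(dims) - 1L),
         function(i) .init_layer(dims[i], dims[i + 1L]))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass. X: (m x n_in), one sample per row. Hidden layers are ReLU;
# the output layer is linear or sigmoid. Returns activations and
# pre-activations for backprop.
.mlp_forward <- function(layers, X, out_act = c("linear", "sigmoid")) {
  out_act <- match.arg(out_act)
  L <- length(layers)
  a <- vector("list", L + 1L)
  z <- vector("list", L)
  a[[1L]] <- X
  m <- nrow(X)
  for (l in seq_len(L)) {
    zl <- tcrossprod(a[[l]], layers[[l]]$W) + rep(layers[[l]]$b, each = m)
    z[[l]] <- zl
    a[[l + 1L]] <- if (l < L) {
      pmax(zl, 0)
    } else if (out_act == "sigmoid") {
      .sigmoid(zl)
    } else {
      zl
    }
  }
  list(a = a, z = z, out = a[[L + 1L]])
}

# Backward pass from the gradient w.r.t. the LAST pre-activation. Returns
# per-layer gradients and the gradient w.r.t. the network input.
.mlp_backward <- function(layers, cache, d_z_last) {
  L <- length(layers)
  grads <- vector("list", L)
  dz <- d_z_last
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(dz, cache$a[[l]]),
                       b = colSums(dz))
    da <- dz %*% layers[[l]]$W
    if (l > 1L) {
      dz <- da * (cache$z[[l - 1L]] > 0)
    } else {
      dz <- da
    }
  }
  list(grads = grads, d_input = dz)
}

.adam_init <- function(layers) {
  list(t = 0L,
       m = lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b)),
       v = lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b)))
}

.adam_step <- function(layers, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[p]] / bc1
      vhat <- state$v[[l]][[p]] / bc2
      layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

## ---- model construction and forward maps ----------------------------------

#' Initialise an untrained bidirectional adversarial model
#'
#' Weights use seeded uniform fan-in initialisation; the latent prior is a
#' standard normal over `latent_dim`.
#'
#' @param net_cfg A [network_config()].
#' @param seed Integer seed for the weight draw.
#' @return A `bigan_model` list with `encoder`, `generator`,
#'   `discriminator` layer lists, the `config`, and the `seed`.
#' @export
bigan_init <- function(net_cfg, seed = 1L) {
  stopifnot(inherits(net_cfg, "network_config"))
  .with_seed(seed, {
    enc <- .init_mlp(c(net_cfg$input_dim, net_cfg$hidden_encoder,
                       net_cfg$latent_dim))
    gen <- .init_mlp(c(net_cfg$latent_dim, net_cfg$hidden_generator,
                       net_cfg$input_dim))
    dis <- .init_mlp(c(net_cfg$input_dim + net_cfg$latent_dim,
                       net_cfg$hidden_discriminator, 1L))
    structure(list(encoder = enc, generator = gen, discriminator = dis,
                   config = net_cfg, seed = as.integer(seed)),
              class = "bigan_model")
  })
}

.as_row_matrix <- function(x, dim_needed, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != dim_needed) {
    stop(sprintf("%s must have length/width %d, got %d", what, dim_needed,
                 ncol(x)), call. = FALSE)
  }
  x
}

#' Encoder forward map
#'
#' Affine layers with ReLU activations; the final layer is linear and emits
#' the `latent_dim`-dimensional code E(x).
#'
#' @param model A `bigan_model`.
#' @param x Feature vector of length `input_dim`, or a matrix with one
#'   vector per row.
#' @return Latent code(s): a vector for vector input, otherwise a matrix.
#' @export
encoder_forward <- function(model, x) {
  vec <- is.null(dim(x))
  X <- .as_row_matrix(x, model$config$input_dim, "encoder input")
  out <- .mlp_forward(model$encoder, X, "linear")$out
  if (vec) drop(out) else out
}

#' Generator forward map
#'
#' Mirrors the encoder: affine ReLU layers mapping a latent code z to a
#' vector in feature space of length `input_dim`.
#'
#' @inheritParams encoder_forward
#' @param z Latent vector of length `latent_dim`, or a matrix of rows.
#' @return Generated feature vector(s).
#' @export
generator_forward <- function(model, z) {
  vec <- is.null(dim(z))
  Z <- .as_row_matrix(z, model$config$latent_dim, "generator input")
  out <- .mlp_forward(model$generator, Z, .gen_act(model))$out
  if (vec) drop(out) else out
}

.gen_act <- function(model) {
  act <- model$config$generator_out_act
  if (is.null(act)) "linear" else act
}

#' Discriminator forward map
#'
#' Concatenates the feature vector and latent code, applies the hidden
#' layers and a final logistic sigmoid `1 / (1 + exp(-theta))`, returning
#' the probability that the tuple comes from the data branch (x, E(x))
#' rather than the noise branch (G(z), z). Output is strictly inside
#' (0, 1) for finite logits.
#'
#' @inheritParams encoder_forward
#' @param z Latent vector(s) paired row-wise with `x`.
#' @return Probability (or vector of probabilities, one per row).
#' @export
discriminator_forward <- function(model, x, z) {
  vec <- is.null(dim(x)) && is.null(dim(z))
  X <- .as_row_matrix(x, model$config$input_dim, "discriminator x input")
  Z <- .as_row_matrix(z, model$config$latent_dim, "discriminator z input")
  if (nrow(X) != nrow(Z)) stop("x and z batches differ in size", call. = FALSE)
  out <- .mlp_forward(model$discriminator, cbind(X, Z), "sigmoid")$out
  if (vec) drop(out) else drop(out)
}

#' Empirical adversarial value function
#'
#' The empirical value of the minimax game,
#' `mean(log D(x, E(x))) + mean(log(1 - D(G(z), z)))`, averaged over the
#' supplied data batch and noise batch. Discriminator outputs are clamped
#' to `[clamp, 1 - clamp]` inside the logs so the value stays finite. With
#' the discriminator frozen at 1/2 the value is exactly `-2 log 2`, the
#' equilibrium of the game.
#'
#' @param model A `bigan_model`.
#' @param real_batch Matrix of feature vectors (one per row), the data
#'   branch X.
#' @param noise_batch Matrix of latent vectors (one per row), the noise
#'   branch Z.
#' @param clamp Probability clamping bound; default 1e-7.
#' @return A finite scalar.
#' @export
bigan_value <- function(model, real_batch, noise_batch, clamp = 1e-7) {
  X <- .as_row_matrix(real_batch, model$config$input_dim, "real batch")
  Z <- .as_row_matrix(noise_batch, model$config$latent_dim, "noise batch")
  if (nrow(X) == 0 || nrow(Z) == 0) stop("empty batch", call. = FALSE)
  ex <- .mlp_forward(model$encoder, X, "linear")$out
  gz <- .mlp_forward(model$generator, Z, .gen_act(model))$out
  p_real <- .mlp_forward(model$discriminator, cbind(X, ex), "sigmoid")$out
  p_fake <- .mlp_forward(model$discriminator, cbind(gz, Z), "sigmoid")$out
  p_real <- pmin(pmax(p_real, clamp), 1 - clamp)
  p_fake <- pmin(pmax(p_fake, clamp), 1 - clamp)
  mean(log(p_real)) + mean(log(1 - p_fake))
}

# Analytic gradient of the value function w.r.t. the discriminator
# parameters (encoder/generator treated as fixed). Used by training (up to
# sign/scaling) and by the finite-difference gradient check.
.bigan_value_disc_grads <- function(model, real_batch, noise_batch) {
  X <- .as_row_matrix(real_batch, model$config$input_dim, "real batch")
  Z <- .as_row_matrix(noise_batch, model$config$latent_dim, "noise batch")
  ex <- .mlp_forward(model$encoder, X, "linear")$out
  gz <- .mlp_forward(model$generator, Z, .gen_act(model))$out
  cache_r <- .mlp_forward(model$discriminator, cbind(X, ex), "sigmoid")
  cache_f <- .mlp_forward(model$discriminator, cbind(gz, Z), "sigmoid")
  # d/dtheta mean(log sigmoid(theta)) = (1 - p)/m ;
  # d/dtheta mean(log(1 - sigmoid(theta))) = -p/m
  gr <- .mlp_backward(model$discriminator, cache_r,
                      (1 - cache_r$out) / nrow(X))$grads
  gf <- .mlp_backward(model$discriminator, cache_f,
                      -cache_f$out / nrow(Z))$grads
  mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b), gr, gf,
         SIMPLIFY = FALSE)
}

## ---- training --------------------------------------------------------------

#' Train the bidirectional adversarial model
#'
#' Trains on the feature vectors of verified (label 1) pairs only: these
#' define the real-data distribution, while generator fakes supply the
#' adversarial negatives. Each minibatch takes one discriminator ascent
#' step (binary cross-entropy, labels 1 for (x, E(x)) and 0 for
#' (G(z), z)) followed by one joint encoder+generator step on the
#' non-saturating objective (labels flipped). Optimisation uses Adam.
#'
#' When `train_cfg` asks for several ensemble members and/or tail
#' snapshots, each member is an independently seeded restart and scoring
#' ([score_pairs()]) averages discriminator logits over all members and
#' snapshots; the returned model's `encoder`/`generator`/`discriminator`
#' fields hold the first member's final parameters, which is what the
#' single-network forward maps use. Training is deterministic given
#' `train_cfg$seed`.
#'
#' @param features A `pair_features` object; rows with label 1 are used.
#'   (A plain numeric matrix of positive-pair feature vectors is also
#'   accepted.)
#' @param net_cfg A [network_config()]; defaults to `network_config(ncol)`.
#' @param train_cfg A [train_config()].
#' @param engine `"compiled"` runs the RcppArmadillo training loop;
#'   `"reference"` runs the pure-R loop. Both consume the same random
#'   stream (shuffles precomputed per epoch, latent noise drawn per batch)
#'   and agree to floating-point accuracy.
#' @return A trained `bigan_model` (with a `members` list holding every
#'   member's final parameters and snapshots).
#' @export
train_bigan <- function(features, net_cfg = NULL, train_cfg = train_config(),
                        engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  X <- if (inherits(features, "pair_features")) {
    features$x[features$pairs$label == 1, , drop = FALSE]
  } else {
    as.matrix(features)
  }
  dimnames(X) <- NULL
  n <- nrow(X)
  if (is.null(net_cfg)) net_cfg <- network_config(input_dim = ncol(X))
  if (ncol(X) != net_cfg$input_dim) {
    stop("feature width does not match net_cfg$input_dim", call. = FALSE)
  }
  if (n < train_cfg$batch_size) {
    stop(sprintf(paste0("only %d positive-pair feature vectors but batch_size",
                        " is %d; use a smaller batch_size"),
                 n, train_cfg$batch_size), call. = FALSE)
  }
  members <- lapply(seq_len(train_cfg$n_members), function(j) {
    .train_one_member(X, net_cfg, train_cfg,
                      seed = .derive_seed(train_cfg$seed, 10L + j),
                      engine = engine)
  })
  structure(list(encoder = members[[1]]$encoder,
                 generator = members[[1]]$generator,
                 discriminator = members[[1]]$discriminator,
                 members = members, config = net_cfg,
                 train_config = train_cfg, seed = train_cfg$seed),
            class = "bigan_model")
}

# One seeded restart. The RNG protocol is fixed so the compiled and
# reference engines consume identical streams: (1) weight init under a
# derived seed (state restored), (2) one sample.int(n) per epoch for the
# batch shuffles, (3) per batch, m*latent sequential rnorm draws filling
# the noise matrix column-major.
.train_one_member <- function(X, net_cfg, train_cfg, seed, engine) {
  n <- nrow(X)
  epochs <- train_cfg$epochs
  .with_seed(seed, {
    init <- bigan_init(net_cfg, seed = .derive_seed(seed, 1L))
    if (epochs == 0) {
      return(list(encoder = init$encoder, generator = init$generator,
                  discriminator = init$discriminator, snapshots = list()))
    }
    shuffles <- t(vapply(seq_len(epochs), function(e) sample.int(n),
                         integer(n)))
    snap_start <- if (train_cfg$snapshot_every > 0) {
      as.integer(floor(epochs * train_cfg$snapshot_start_frac))
    } else {
      epochs
    }
    if (engine == "compiled") {
      res <- .bigan_train_cpp(
        X, init$encoder, init$generator, init$discriminator,
        epochs, train_cfg$batch_size,
        train_cfg$learning_rate, train_cfg$learning_rate_eg,
        train_cfg$beta1, train_cfg$beta2,
        as.integer(train_cfg$lr_decay == "linear"),
        as.integer(identical(net_cfg$generator_out_act, "sigmoid")),
        net_cfg$latent_dim, shuffles, snap_start, train_cfg$snapshot_every)
    } else {
      res <- .bigan_train_r(X, init, net_cfg, train_cfg, shuffles, snap_start)
    }
    res$snapshots <- lapply(res$snapshots, function(s) {
      list(encoder = .relist_layers(s$encoder),
           discriminator = .relist_layers(s$discriminator))
    })
    list(encoder = .relist_layers(res$encoder),
         generator = .relist_layers(res$generator),
         discriminator = .relist_layers(res$discriminator),
         snapshots = res$snapshots)
  })
}

# Rcpp hands back b as a one-column matrix; restore plain numeric vectors.
.relist_layers <- function(layers) {
  lapply(layers, function(l) list(W = as.matrix(l$W),
                                  b = as.numeric(l$b)))
}

# Pure-R reference engine; mirrors src/bigan_train.cpp step for step.
.bigan_train_r <- function(X, init, net_cfg, train_cfg, shuffles,
                           snap_start) {
  n <- nrow(X)
  latent <- net_cfg$latent_dim
  input_dim <- net_cfg$input_dim
  b1 <- train_cfg$beta1
  b2 <- train_cfg$beta2
  gen_act <- if (identical(net_cfg$generator_out_act, "sigmoid"))
    "sigmoid" else "linear"
  enc <- init$encoder
  gen <- init$generator
  dis <- init$discriminator
  st_e <- .adam_init(enc)
  st_g <- .adam_init(gen)
  st_d <- .adam_init(dis)
  snapshots <- list()

  for (epoch in seq_len(train_cfg$epochs)) {
    fac <- if (train_cfg$lr_decay == "linear") {
      1 - (epoch - 1) / train_cfg$epochs
    } else {
      1
    }
    lr_d <- train_cfg$learning_rate * fac
    lr_eg <- train_cfg$learning_rate_eg * fac
    ord <- shuffles[epoch, ]
    for (s in seq(1L, n, by = train_cfg$batch_size)) {
      idx <- ord[s:min(s + train_cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      m <- nrow(Xb)
      Zb <- matrix(stats::rnorm(m * latent), nrow = m, ncol = latent)

      ## E/G forwards are shared by both phases: the discriminator step
      ## only needs their outputs, and E/G do not change until their own
      ## update
      ce <- .mlp_forward(enc, Xb, "linear")
      cg <- .mlp_forward(gen, Zb, gen_act)
      real_in <- cbind(Xb, ce$out)
      fake_in <- cbind(cg$out, Zb)

      ## discriminator step (E, G fixed)
      cr <- .mlp_forward(dis, real_in, "sigmoid")
      cf <- .mlp_forward(dis, fake_in, "sigmoid")
      # BCE: d/dtheta = (p - y)/m with y = 1 (real), y = 0 (fake)
      gr <- .mlp_backward(dis, cr, (cr$out - 1) / m)$grads
      gf <- .mlp_backward(dis, cf, cf$out / m)$grads
      gd <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   gr, gf, SIMPLIFY = FALSE)
      up <- .adam_step(dis, gd, st_d, lr_d, b1, b2)
      dis <- up$layers
      st_d <- up$state

      ## encoder + generator step (D fixed), non-saturating labels:
      ## generator wants D(G(z), z) -> 1, encoder wants D(x, E(x)) -> 0
      cr2 <- .mlp_forward(dis, real_in, "sigmoid")
      cf2 <- .mlp_forward(dis, fake_in, "sigmoid")
      back_f <- .mlp_backward(dis, cf2, (cf2$out - 1) / m)
      back_r <- .mlp_backward(dis, cr2, cr2$out / m)
      d_gen_out <- back_f$d_input[, seq_len(input_dim), drop = FALSE]
      d_enc_out <- back_r$d_input[, input_dim + seq_len(latent),
                                  drop = FALSE]
      if (gen_act == "sigmoid") {
        # chain through the generator's logistic output layer
        d_gen_out <- d_gen_out * cg$out * (1 - cg$out)
      }
      gg <- .mlp_backward(gen, cg, d_gen_out)$grads
      ge <- .mlp_backward(enc, ce, d_enc_out)$grads
      up <- .adam_step(gen, gg, st_g, lr_eg, b1, b2)
      gen <- up$layers
      st_g <- up$state
      up <- .adam_step(enc, ge, st_e, lr_eg, b1, b2)
      enc <- up$layers
      st_e <- up$state
    }
    if (train_cfg$snapshot_every > 0 && epoch > snap_start &&
        epoch %% train_cfg$snapshot_every == 0) {
      snapshots[[length(snapshots) + 1L]] <-
        list(encoder = enc, discriminator = dis)
    }
  }
  list(encoder = enc, generator = gen, discriminator = dis,
       snapshots = snapshots)
}

## ---- scoring and ranking ---------------------------------------------------

#' Score (disease, lncRNA) pairs
#'
#' The association score of a pair with feature vector x is
#' `D(x, E(x))`: the discriminator's probability that the pair's joint
#' (feature, latent) tuple comes from the real-data branch. When the model
#' carries ensemble members and/or tail snapshots, the pre-sigmoid logit
#' of `D(x, E(x))` is averaged over all of them before the sigmoid is
#' applied. Rows are returned in input order.
#'
#' The table also carries the pre-sigmoid `logit`: the sigmoid is strictly
#' monotone, so ranking by logit and by score is the same ordering, but the
#' logit does not saturate in double precision when the discriminator is
#' confident, and is therefore what the ranking-based evaluation uses.
#'
#' @param model A trained `bigan_model`.
#' @param features A `pair_features` object.
#' @return A `score_table` data frame with columns `disease_id`,
#'   `lncrna_id`, `score` (in (0, 1)), `logit` and `known_flag`.
#' @export
score_pairs <- function(model, features) {
  stopifnot(inherits(features, "pair_features"))
  X <- features$x
  if (ncol(X) != model$config$input_dim) {
    stop("feature width does not match the model input dimension",
         call. = FALSE)
  }
  units <- .scoring_units(model)
  theta <- 0
  for (u in units) {
    ex <- .mlp_forward(u$encoder, X, "linear")$out
    cache <- .mlp_forward(u$discriminator, cbind(X, ex), "sigmoid")
    theta <- theta + drop(cache$z[[length(u$discriminator)]])
  }
  theta <- theta / length(units)
  out <- data.frame(disease_id = features$pairs$disease_id,
                    lncrna_id = features$pairs$lncrna_id,
                    score = as.numeric(.sigmoid(theta)),
                    logit = as.numeric(theta),
                    known_flag = as.integer(features$pairs$label),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

# Every (encoder, discriminator) pair that contributes to scoring: each
# member's tail snapshots when recorded, otherwise its final parameters.
.scoring_units <- function(model) {
  if (is.null(model$members)) {
    return(list(list(encoder = model$encoder,
                     discriminator = model$discriminator)))
  }
  units <- list()
  for (member in model$members) {
    if (length(member$snapshots)) {
      units <- c(units, member$snapshots)
    } else {
      units <- c(units, list(list(encoder = member$encoder,
                                  discriminator = member$discriminator)))
    }
  }
  units
}

#' Top-k candidate lncRNAs for a disease
#'
#' Unverified (known_flag 0) lncRNAs for the disease, ordered by
#' descending score with lexicographic lncRNA-id tie-break.
#'
#' @param scores A `score_table` from [score_pairs()].
#' @param disease_id Disease to rank candidates for.
#' @param k Maximum number of candidates returned.
#' @return Character vector of at most `k` lncRNA ids.
#' @export
rank_candidates <- function(scores, disease_id, k) {
  stopifnot(.is_count(k))
  if (!disease_id %in% scores$disease_id) {
    stop(sprintf("disease '%s' not present in the score table", disease_id),
         call. = FALSE)
  }
  cand <- scores[scores$disease_id == disease_id & scores$known_flag == 0, ,
                 drop = FALSE]
  key <- if ("logit" %in% names(cand)) cand$logit else cand$score
  ord <- order(-key, cand$lncrna_id, method = "radix")
  utils::head(cand$lncrna_id[ord], k)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding every weight matrix, the
#' network configuration and the training seed; it round-trips exactly
#' (identical scores after reload).
#'
#' @param model A `bigan_model`.
#' @param path File path for the checkpoint.
#' @return `save_bigan` returns `path` invisibly; `load_bigan` returns the
#'   model.
#' @export
save_bigan <- function(model, path) {
  stopifnot(inherits(model, "bigan_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_bigan
#' @export
load_bigan <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "bigan_model")) {
    stop("checkpoint does not contain a bigan_model", call. = FALSE)
  }
  model
}

#' @export
print.bigan_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<bigan_model: input %d, latent %d; encoder %s, ",
                     "generator %s, discriminator %s>\n"),
              cfg$input_dim, cfg$latent_dim,
              paste(cfg$hidden_encoder, collapse = "-"),
              paste(cfg$hidden_generator, collapse = "-"),
              paste(cfg$hidden_discriminator, collapse = "-")))
  invisible(x)
}
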