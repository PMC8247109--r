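# Independent oracles and small fixture builders shared across tests.

# Exhaustive-recursion edit-distance oracle (memoised on suffix pairs).
# Independent of the package implementation: plain recursion over the three
# edit operations.
edit_oracle <- function(s1, s2, sub = 2, indel = 1) {
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    key <- paste(a, b, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- if (nchar(a) == 0) {
      nchar(b) * indel
    } else if (nchar(b) == 0) {
      nchar(a) * indel
    } else {
      ra <- substr(a, 2, nchar(a))
      rb <- substr(b, 2, nchar(b))
      head_cost <- if (substr(a, 1, 1) == substr(b, 1, 1)) 0 else sub
      min(rec(ra, rb) + head_cost,
          rec(ra, b) + indel,
          rec(a, rb) + indel)
    }
    memo[[key]] <- out
    out
  }
  rec(s1, s2)
}

# All strings over `alphabet` of length 0..max_len.
all_strings <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (len in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

# Brute-force O(P*N) Mann-Whitney concordance AUC with half credit for ties.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# A hand-assembled model whose layer weights the test controls directly.
# dims: list(input, latent, enc = list of layers, ...). Layers are given as
# list(W, b) with W of shape (out x in).
manual_model <- function(input_dim, latent_dim, encoder, generator,
                         discriminator,
                         generator_out_act = "linear") {
  cfg <- network_config(
    input_dim = input_dim, latent_dim = latent_dim,
    hidden_encoder = if (length(encoder) > 1)
      vapply(encoder[-length(encoder)], function(l) nrow(l$W), integer(1))
    else integer(0),
    hidden_generator = if (length(generator) > 1)
      vapply(generator[-length(generator)], function(l) nrow(l$W), integer(1))
    else integer(0),
    hidden_discriminator = if (length(discriminator) > 1)
      vapply(discriminator[-length(discriminator)], function(l) nrow(l$W),
             integer(1))
    else integer(0),
    generator_out_act = generator_out_act)
  structure(list(encoder = encoder, generator = generator,
                 discriminator = discriminator, config = cfg, seed = 0L),
            class = "bigan_model")
}

# Identity-ish single-layer model on a d-dimensional input with latent = d.
identity_model <- function(d) {
  manual_model(
    input_dim = d, latent_dim = d,
    encoder = list(list(W = diag(d), b = numeric(d))),
    generator = list(list(W = diag(d), b = numeric(d))),
    discriminator = list(list(W = matrix(0, 1, 2 * d), b = 0)))
}

# Small planted dataset used by training-related tests: large enough to
# train with a reduced batch size, small enough to run in seconds.
small_dataset <- function(seed = 5) {
  simulate_dataset(simulation_config(
    nd = 12, nl = 30, n_blocks = 2, seq_length_range = c(40L, 60L),
    seed = seed))
}

# A small pair-feature fixture derived from small_dataset().
small_features <- function(seed = 5) {
  ds <- small_dataset(seed)
  pair_feature_pipeline(ds$sequences, ds$ontology, ds$associations)$features
}

# Tiny network configuration compatible with small_dataset() features.
tiny_net <- function(input_dim = 42) {
  network_config(input_dim = input_dim, latent_dim = 4,
                 hidden_encoder = c(16, 8),
                 hidden_discriminator = c(16, 4),
                 generator_out_act = "linear")
}

tiny_train <- function(..., epochs = 3, batch_size = 16, seed = 3) {
  train_config(epochs = epochs, batch_size = batch_size, seed = seed, ...)
}

# Chain ontology r -> ... -> leaf of the given depth (depth edges).
chain_ontology <- function(depth) {
  nodes <- paste0("n", 0:depth)
  disease_ontology(data.frame(parent = nodes[-(depth + 1)],
                              child = nodes[-1]))
}
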