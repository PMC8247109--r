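# The package's standard evaluation protocol for the planted synthetic
# benchmark.

#' Standard configurations for the synthetic benchmark
#'
#' Returns the network and training configurations the package uses to
#' evaluate itself on the default synthetic dataset (50 diseases x 120
#' lncRNAs, feature length 170). The architecture tapers the reference
#' layer sizes, which target feature vectors of several thousand
#' dimensions, down to the 170-dimensional problem: latent 32, encoder
#' 170-128-64-32, generator mirrored, discriminator 202-128-32-1. Training
#' keeps the reference optimiser settings (Adam, batch 64, learning rate
#' 1e-3) and, because the synthetic training sets are roughly two orders
#' of magnitude smaller than the association databases the defaults were
#' tuned on, replaces the five long passes appropriate at that scale with
#' an ensemble of eight short annealed runs whose discriminator logits are
#' snapshot-averaged (see the package vignette for the rationale).
#'
#' @param input_dim Feature vector length (`nd + nl`).
#' @param seed Training seed.
#' @return List with elements `net` (a [network_config()]) and `train`
#'   (a [train_config()]).
#' @export
benchmark_configs <- function(input_dim = 170, seed = 1L) {
  list(net = network_config(input_dim = input_dim, latent_dim = 32,
                            hidden_encoder = c(128, 64),
                            hidden_discriminator = c(128, 32),
                            generator_out_act = "linear"),
       train = train_config(epochs = 75, batch_size = 64,
                            learning_rate = 1e-3, lr_decay = "linear",
                            n_members = 8, snapshot_every = 10,
                            snapshot_start_frac = 0.2, seed = seed))
}
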