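# Synthetic benchmark generator. Plants recoverable block structure: each
# block couples a family of mutated sibling sequences (high sequence
# similarity) with a clade of ontology terms (high semantic similarity),
# and associations are drawn much more densely inside blocks than across
# them. Every module is therefore testable without external downloads.

#' Configuration for the synthetic benchmark generator
#'
#' Defaults define the package's standard benchmark: 50 diseases x 120
#' lncRNAs in 5 blocks, within-block association probability 0.6 against a
#' 0.02 background, sequence families of length 180-240 nt with 5%
#' per-site substitution, and a depth-3 ontology (global root, one clade
#' root per block, `branching` intermediate terms).
#'
#' @param nd,nl Numbers of diseases and lncRNAs.
#' @param n_blocks Number of planted blocks.
#' @param within_block_assoc_prob,background_assoc_prob Association
#'   probabilities inside vs across blocks; within must exceed background,
#'   otherwise nothing is recoverable.
#' @param seq_length_range Integer interval for ancestor sequence lengths.
#' @param mutation_rate Per-site substitution probability applied to each
#'   family member.
#' @param ontology_depth Depth of disease terms below the global root
#'   (>= 2).
#' @param branching Intermediate terms per clade at each internal level.
#' @param indels Also apply rare single-base insertions/deletions (at one
#'   tenth of `mutation_rate` per site) when mutating family members.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(nd = 50, nl = 120, n_blocks = 5,
                              within_block_assoc_prob = 0.6,
                              background_assoc_prob = 0.02,
                              seq_length_range = c(180L, 240L),
                              mutation_rate = 0.05,
                              ontology_depth = 3, branching = 2,
                              indels = FALSE, seed = 1L) {
  stopifnot(.is_count(nd), .is_count(nl), .is_count(n_blocks),
            n_blocks <= nd, n_blocks <= nl,
            .is_prob(within_block_assoc_prob),
            .is_prob(background_assoc_prob),
            .is_prob(mutation_rate),
            length(seq_length_range) == 2,
            seq_length_range[1] >= 1,
            seq_length_range[2] >= seq_length_range[1],
            .is_count(ontology_depth), ontology_depth >= 2,
            .is_count(branching))
  if (within_block_assoc_prob <= background_assoc_prob) {
    stop("within-block association probability must exceed the background",
         call. = FALSE)
  }
  structure(list(nd = as.integer(nd), nl = as.integer(nl),
                 n_blocks = as.integer(n_blocks),
                 within_block_assoc_prob = within_block_assoc_prob,
                 background_assoc_prob = background_assoc_prob,
                 seq_length_range = as.integer(seq_length_range),
                 mutation_rate = mutation_rate,
                 ontology_depth = as.integer(ontology_depth),
                 branching = as.integer(branching),
                 indels = isTRUE(indels), seed = as.integer(seed)),
            class = "simulation_config")
}

.mutate_sequence <- function(chars, rate, indels) {
  n <- length(chars)
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    # substitute with a uniformly chosen *different* base
    repl <- vapply(chars[hit],
                   function(b) sample(setdiff(.SEQ_ALPHABET, b), 1L),
                   character(1))
    chars[hit] <- repl
  }
  if (indels) {
    del <- stats::runif(length(chars)) < rate / 10
    chars <- chars[!del]
    ins_at <- which(stats::runif(length(chars)) < rate / 10)
    for (i in rev(ins_at)) {
      chars <- append(chars, sample(.SEQ_ALPHABET, 1L), after = i)
    }
    if (length(chars) == 0) chars <- sample(.SEQ_ALPHABET, 1L)
  }
  chars
}

#' Generate a synthetic lncRNA-disease dataset with planted structure
#'
#' LncRNAs in the same block are independently mutated copies of a common
#' ancestor sequence, so within-block sequence similarity is high.
#' Diseases in the same block sit in the same ontology clade beneath a
#' shared global root, so within-block semantic similarity is high.
#' Association entries are Bernoulli draws with the within-block
#' probability when disease and lncRNA share a block and the background
#' probability otherwise.
#'
#' @param cfg A [simulation_config()].
#' @return An `lnc_dataset` list: `sequences`, `ontology`, `associations`,
#'   `blocks` (list with `disease` and `lncrna` block index vectors) and
#'   `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed, {
    disease_ids <- sprintf("D%03d", seq_len(cfg$nd))
    lncrna_ids <- sprintf("L%03d", seq_len(cfg$nl))
    d_block <- sort(rep_len(seq_len(cfg$n_blocks), cfg$nd))
    l_block <- sort(rep_len(seq_len(cfg$n_blocks), cfg$nl))

    ## sequences: one ancestor per block, mutated copies for the members
    seqs <- character(cfg$nl)
    for (b in seq_len(cfg$n_blocks)) {
      len <- sample(seq(cfg$seq_length_range[1], cfg$seq_length_range[2]), 1L)
      ancestor <- sample(.SEQ_ALPHABET, len, replace = TRUE)
      for (i in which(l_block == b)) {
        seqs[i] <- paste(.mutate_sequence(ancestor, cfg$mutation_rate,
                                          cfg$indels), collapse = "")
      }
    }
    names(seqs) <- lncrna_ids
    sequences <- sequence_set(seqs)

    ## ontology: global root -> per-block clade roots -> intermediate
    ## levels -> diseases
    edges <- data.frame(parent = character(0), child = character(0),
                        stringsAsFactors = FALSE)
    for (b in seq_len(cfg$n_blocks)) {
      clade_root <- sprintf("B%02d", b)
      edges <- rbind(edges, data.frame(parent = "ROOT", child = clade_root,
                                       stringsAsFactors = FALSE))
      level <- clade_root
      if (cfg$ontology_depth > 2) {
        for (t in seq_len(cfg$ontology_depth - 2L)) {
          nxt <- sprintf("%s_T%d_%d", clade_root, t, seq_len(cfg$branching *
                                                             length(level)))
          parent_of <- rep(level, each = cfg$branching)
          edges <- rbind(edges, data.frame(parent = parent_of, child = nxt,
                                           stringsAsFactors = FALSE))
          level <- nxt
        }
      }
      members <- disease_ids[d_block == b]
      attach_to <- sample(level, length(members), replace = TRUE)
      edges <- rbind(edges, data.frame(parent = attach_to, child = members,
                                       stringsAsFactors = FALSE))
    }
    ontology <- disease_ontology(edges)

    ## associations: dense inside blocks, sparse background elsewhere
    same_block <- outer(d_block, l_block, "==")
    p <- ifelse(same_block, cfg$within_block_assoc_prob,
                cfg$background_assoc_prob)
    a <- matrix(stats::rbinom(cfg$nd * cfg$nl, 1L, as.vector(p)),
                nrow = cfg$nd, ncol = cfg$nl,
                dimnames = list(disease_ids, lncrna_ids))
    associations <- association_matrix(a)

    structure(list(sequences = sequences, ontology = ontology,
                   associations = associations,
                   blocks = list(disease = stats::setNames(d_block,
                                                           disease_ids),
                                 lncrna = stats::setNames(l_block,
                                                          lncrna_ids)),
                   config = cfg),
              class = "lnc_dataset")
  })
}

#' Label-permuted null control
#'
#' Returns the association matrix with its entries uniformly shuffled
#' across all positions, preserving the total number of verified pairs but
#' destroying any block structure. The seeded shuffle is reproducible.
#'
#' @param A An [association_matrix()].
#' @param seed Integer seed.
#' @return An [association_matrix()] of the same shape and positive count.
#' @export
permute_labels <- function(A, seed = 1L) {
  v <- as.vector(unclass(A))
  .with_seed(seed, {
    v <- v[sample.int(length(v))]
  })
  m <- matrix(v, nrow = nrow(A), ncol = ncol(A), dimnames = dimnames(A))
  association_matrix(m)
}

#' @export
print.lnc_dataset <- function(x, ...) {
  cat(sprintf(paste0("<lnc_dataset: %d diseases x %d lncRNAs, %d verified",
                     " pairs, %d blocks>\n"),
              nrow(x$associations), ncol(x$associations),
              sum(x$associations), x$config$n_blocks))
  invisible(x)
}
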