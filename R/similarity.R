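# Similarity layer: weighted edit-distance sequence similarity, DAG-based
# disease semantic similarity, Gaussian interaction profile (GIP) kernels on
# association profiles, their unweighted integration, and per-pair feature
# vectors.

#' Weighted edit distance between two nucleotide sequences
#'
#' Minimum total cost of transforming `s1` into `s2` with unit-cost
#' insertions/deletions and a (default) cost-2 substitution, i.e. the
#' weighted Levenshtein distance. With these defaults a substitution ties
#' with a deletion plus an insertion. Sequences are case-folded and U is
#' treated as T before comparison. Costs are integer-valued.
#'
#' @param s1,s2 Nucleotide strings over A/C/G/T/U (empty strings allowed).
#' @param sub_cost,indel_cost Non-negative integer costs for substitution
#'   and insertion/deletion.
#' @return The minimum edit cost (non-negative number); 0 iff the
#'   normalised sequences are identical. Symmetric in its arguments.
#' @examples
#' edit_cost("ACGT", "ACGA") # 2: one substitution
#' edit_cost("AA", "")       # 2: two deletions
#' @export
edit_cost <- function(s1, s2, sub_cost = 2, indel_cost = 1) {
  stopifnot(length(s1) == 1, length(s2) == 1,
            sub_cost >= 0, indel_cost >= 0,
            sub_cost == round(sub_cost), indel_cost == round(indel_cost))
  s1 <- .normalise_sequence(s1, "s1")
  s2 <- .normalise_sequence(s2, "s2")
  as.numeric(utils::adist(s1, s2, costs = list(insertions = indel_cost,
                                               deletions = indel_cost,
                                               substitutions = sub_cost)))
}

#' LncRNA sequence similarity matrix
#'
#' Pairwise similarity `1 - cost(l_i, l_j) / (len(l_i) + len(l_j))` where
#' `cost` is the weighted edit distance of [edit_cost()]. Deleting one
#' sequence and inserting the other bounds the cost by the length sum, so
#' entries lie in \[0, 1\] with an exact unit diagonal.
#'
#' @param seqs A [sequence_set()] (or a named character vector coerced to
#'   one).
#' @inheritParams edit_cost
#' @return A [similarity_matrix()] of kind `"sequence"` over the sequence
#'   ids, in input order.
#' @export
sequence_similarity <- function(seqs, sub_cost = 2, indel_cost = 1) {
  if (!inherits(seqs, "sequence_set")) seqs <- sequence_set(seqs)
  d <- utils::adist(seqs, costs = list(insertions = indel_cost,
                                       deletions = indel_cost,
                                       substitutions = sub_cost))
  lens <- nchar(seqs)
  sim <- 1 - d / outer(lens, lens, "+")
  diag(sim) <- 1
  similarity_matrix(sim, ids = names(seqs), kind = "sequence")
}

# All ancestors of `d` in the ontology (including d itself), via upward BFS
# over the parent map.
.ancestor_set <- function(onto, d) {
  seen <- d
  frontier <- d
  while (length(frontier)) {
    up <- unique(unlist(onto$parents[frontier], use.names = FALSE))
    up <- setdiff(up, seen)
    seen <- c(seen, up)
    frontier <- up
  }
  seen
}

#' Semantic value profile of a disease
#'
#' Within the ancestor DAG of disease `d`, the semantic value of `d` itself
#' is 1 and the value of every ancestor `x` is `mu` times the maximum value
#' among the children of `x` that lie on a path from `x` down to `d`. The
#' contribution therefore decays by the factor `mu` per generation; on a
#' pure chain the value at depth `k` above `d` is `mu^k`. Values are
#' memoised per node, so dense DAGs are handled without enumerating paths.
#'
#' @param onto A [disease_ontology()].
#' @param d Disease id present in the ontology.
#' @param mu Semantic contribution factor in (0, 1); default 0.5.
#' @return Named numeric vector mapping each node of the ancestor DAG
#'   (including `d`) to its semantic value in (0, 1\].
#' @examples
#' onto <- disease_ontology(data.frame(parent = "p", child = "d"))
#' semantic_values(onto, "d") # d: 1, p: 0.5
#' @export
semantic_values <- function(onto, d, mu = 0.5) {
  stopifnot(inherits(onto, "disease_ontology"), .is_prob(mu), mu > 0, mu < 1)
  if (!d %in% onto$nodes) {
    stop(sprintf("disease '%s' is not a node of the ontology", d),
         call. = FALSE)
  }
  anc <- .ancestor_set(onto, d)
  memo <- new.env(parent = emptyenv())
  sv <- function(x) {
    if (x == d) return(1)
    key <- x
    if (!is.null(memo[[key]])) return(memo[[key]])
    kids <- intersect(onto$children[[x]], anc)
    val <- mu * max(vapply(kids, sv, numeric(1)))
    memo[[key]] <- val
    val
  }
  out <- vapply(anc, sv, numeric(1))
  names(out) <- anc
  out
}

#' Disease semantic similarity matrix
#'
#' For diseases `i` and `j` with semantic value profiles over their ancestor
#' DAGs `G_i` and `G_j`, the similarity is the sum of both profiles over the
#' shared nodes divided by the sum of both full profiles:
#' `sum_{x in Gi & Gj} (SV_i(x) + SV_j(x)) / (sum SV_i + sum SV_j)`.
#' Identical DAGs give 1; disjoint DAGs give 0.
#'
#' @inheritParams semantic_values
#' @param disease_ids Ordered disease ids for the matrix rows/columns.
#' @param missing How to treat diseases absent from the ontology:
#'   `"error"` raises a lookup error; `"singleton"` assigns the isolated
#'   single-node DAG `{d}`, making the disease semantically dissimilar to
#'   every other disease (its GIP similarity then carries the integrated
#'   similarity).
#' @return A [similarity_matrix()] of kind `"semantic"`.
#' @export
semantic_similarity <- function(onto, disease_ids, mu = 0.5,
                                missing = c("error", "singleton")) {
  missing <- match.arg(missing)
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids", call. = FALSE)
  profiles <- lapply(disease_ids, function(d) {
    if (!d %in% onto$nodes) {
      if (missing == "error") {
        stop(sprintf("disease '%s' is not a node of the ontology", d),
             call. = FALSE)
      }
      return(stats::setNames(1, d))
    }
    semantic_values(onto, d, mu = mu)
  })
  totals <- vapply(profiles, sum, numeric(1))
  n <- length(disease_ids)
  sim <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      pi_ <- profiles[[i]]
      for (j in seq((i + 1), n)) {
        pj <- profiles[[j]]
        shared <- intersect(names(pi_), names(pj))
        num <- sum(pi_[shared]) + sum(pj[shared])
        sim[i, j] <- sim[j, i] <- num / (totals[i] + totals[j])
      }
    }
  }
  similarity_matrix(sim, ids = disease_ids, kind = "semantic")
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Kernel `exp(-lambda * ||p_i - p_j||^2)` over binary interaction profiles,
#' with the bandwidth set from the data: `lambda = 1 / mean(||p||^2)`, the
#' reciprocal of the mean squared profile norm (for lncRNAs the profiles are
#' association-matrix columns, for diseases rows; the disease bandwidth
#' likewise averages over the `nd` disease profiles).
#'
#' @param profiles Numeric matrix with one binary profile per row.
#' @param ids Profile ids; default rownames.
#' @param kind `"gip_lncrna"` or `"gip_disease"`.
#' @return A [similarity_matrix()] with attributes `lambda` (the bandwidth)
#'   and `mean_sq_norm` (its reciprocal).
#' @export
gip_kernel <- function(profiles, ids = rownames(profiles),
                       kind = c("gip_lncrna", "gip_disease")) {
  kind <- match.arg(kind)
  profiles <- as.matrix(profiles)
  norms2 <- rowSums(profiles^2)
  msn <- mean(norms2)
  if (msn == 0) {
    stop("degenerate GIP bandwidth: all interaction profiles are zero",
         call. = FALSE)
  }
  lambda <- 1 / msn
  d2 <- as.matrix(stats::dist(profiles))^2
  k <- exp(-lambda * d2)
  diag(k) <- 1
  out <- similarity_matrix(k, ids = ids, kind = kind)
  attr(out, "lambda") <- lambda
  attr(out, "mean_sq_norm") <- msn
  out
}

#' @describeIn gip_kernel GIP kernel over lncRNA profiles (columns of the
#'   association matrix).
#' @param A An [association_matrix()].
#' @export
gip_lncrna <- function(A) {
  gip_kernel(t(unclass(A)), ids = colnames(A), kind = "gip_lncrna")
}

#' @describeIn gip_kernel GIP kernel over disease profiles (rows of the
#'   association matrix).
#' @export
gip_disease <- function(A) {
  gip_kernel(unclass(A), ids = rownames(A), kind = "gip_disease")
}

#' Integrate two similarity matrices
#'
#' Element-wise mean of two similarity matrices over the same ids, the
#' unweighted fusion of the base similarity with the GIP kernel. Symmetry,
#' the unit diagonal and the \[0, 1\] range are preserved.
#'
#' @param sim_a,sim_b [similarity_matrix()] objects with identical ids in
#'   identical order.
#' @param kind Output kind; inferred from the input kinds when possible
#'   (lncRNA-side inputs give `"integrated_lncrna"`, disease-side
#'   `"integrated_disease"`).
#' @return A [similarity_matrix()] of the integrated kind.
#' @export
integrate_similarity <- function(sim_a, sim_b, kind = NULL) {
  ids_a <- rownames(sim_a)
  ids_b <- rownames(sim_b)
  if (!identical(ids_a, ids_b)) {
    diff <- union(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    stop("similarity matrices are not aligned; id mismatch: ",
         if (length(diff)) paste(diff, collapse = ", ") else "same ids in different order",
         call. = FALSE)
  }
  if (is.null(kind)) {
    kinds <- c(attr(sim_a, "kind"), attr(sim_b, "kind"))
    lnc <- c("sequence", "gip_lncrna", "integrated_lncrna")
    dis <- c("semantic", "gip_disease", "integrated_disease")
    kind <- if (all(kinds %in% lnc)) "integrated_lncrna"
            else if (all(kinds %in% dis)) "integrated_disease"
            else stop("cannot infer integrated kind from inputs; pass `kind`",
                      call. = FALSE)
  }
  similarity_matrix((unclass(sim_a) + unclass(sim_b)) / 2, ids = ids_a,
                    kind = kind)
}

#' Build per-pair similarity feature vectors
#'
#' The feature vector of a (disease, lncRNA) pair is the concatenation of
#' the disease's row of the integrated disease similarity `Ds` and the
#' lncRNA's row of the integrated lncRNA similarity `Ls` (disease block
#' first), giving length `nd + nl`. Labels are copied from the association
#' matrix. With `pairs = NULL`, all `nd x nl` pairs are generated in
#' row-major order (lncRNA index fastest).
#'
#' @param Ds Integrated disease similarity (`nd x nd`).
#' @param Ls Integrated lncRNA similarity (`nl x nl`).
#' @param A An [association_matrix()] with matching ids.
#' @param pairs Optional data frame with columns `disease_id`, `lncrna_id`.
#' @return A `pair_features` list: `x` (feature matrix, one row per pair)
#'   and `pairs` (data frame `disease_id`, `lncrna_id`, `label`).
#' @export
build_pair_features <- function(Ds, Ls, A, pairs = NULL) {
  nd_ids <- rownames(A)
  nl_ids <- colnames(A)
  if (!identical(rownames(Ds), nd_ids)) {
    stop("Ds ids do not match the association matrix diseases", call. = FALSE)
  }
  if (!identical(rownames(Ls), nl_ids)) {
    stop("Ls ids do not match the association matrix lncRNAs", call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- data.frame(
      disease_id = rep(nd_ids, each = length(nl_ids)),
      lncrna_id = rep(nl_ids, times = length(nd_ids)),
      stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(disease_id = as.character(pairs$disease_id),
                        lncrna_id = as.character(pairs$lncrna_id),
                        stringsAsFactors = FALSE)
    bad_d <- setdiff(unique(pairs$disease_id), nd_ids)
    bad_l <- setdiff(unique(pairs$lncrna_id), nl_ids)
    if (length(bad_d) || length(bad_l)) {
      stop("unknown id(s) in pairs: ", paste(c(bad_d, bad_l), collapse = ", "),
           call. = FALSE)
    }
  }
  x <- cbind(unclass(Ds)[pairs$disease_id, , drop = FALSE],
             unclass(Ls)[pairs$lncrna_id, , drop = FALSE])
  rownames(x) <- NULL
  pairs$label <- unclass(A)[cbind(pairs$disease_id, pairs$lncrna_id)]
  structure(list(x = x, pairs = pairs), class = "pair_features")
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf("<pair_features: %d pairs x %d features (%d labelled 1)>\n",
              nrow(x$x), ncol(x$x), sum(x$pairs$label == 1)))
  invisible(x)
}

#' Full similarity feature pipeline
#'
#' Computes the four base similarity matrices (sequence, semantic, and the
#' two GIP kernels from the association matrix), the two integrated
#' matrices, and the per-pair feature vectors, in one call. The GIP kernels
#' are computed from the supplied association matrix only, so passing a
#' training-fold matrix keeps held-out labels out of the features.
#'
#' @param sequences A [sequence_set()].
#' @param ontology A [disease_ontology()].
#' @param A An [association_matrix()]; its column order must match the
#'   sequence order.
#' @param pairs Optional pair data frame (see [build_pair_features()]).
#' @param mu Semantic contribution factor.
#' @param label_from Optional [association_matrix()] from which pair labels
#'   are copied (defaults to `A`).
#' @return List with elements `L_sim`, `D_sim`, `GKL`, `GKD`, `Ls`, `Ds`
#'   and `features` (a `pair_features`).
#' @export
pair_feature_pipeline <- function(sequences, ontology, A, pairs = NULL,
                                  mu = 0.5, label_from = A) {
  nl_ids <- colnames(A)
  if (!all(names(sequences) %in% nl_ids)) {
    stop("sequence ids not present in the association matrix: ",
         paste(setdiff(names(sequences), nl_ids), collapse = ", "),
         call. = FALSE)
  }
  if (identical(names(sequences), nl_ids)) {
    L_sim <- sequence_similarity(sequences)
  } else {
    # lncRNAs without a sequence get an identity-indicator row; their GIP
    # kernel then carries the integrated similarity.
    present <- nl_ids[nl_ids %in% names(sequences)]
    sub <- sequence_similarity(sequences[present])
    full <- diag(1, length(nl_ids))
    dimnames(full) <- list(nl_ids, nl_ids)
    full[present, present] <- unclass(sub)[present, present]
    L_sim <- similarity_matrix(full, ids = nl_ids, kind = "sequence")
  }
  D_sim <- semantic_similarity(ontology, rownames(A), mu = mu,
                               missing = "singleton")
  GKL <- gip_lncrna(A)
  GKD <- gip_disease(A)
  Ls <- integrate_similarity(L_sim, GKL)
  Ds <- integrate_similarity(D_sim, GKD)
  features <- build_pair_features(Ds, Ls, label_from, pairs = pairs)
  list(L_sim = L_sim, D_sim = D_sim, GKL = GKL, GKD = GKD, Ls = Ls, Ds = Ds,
       features = features)
}
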