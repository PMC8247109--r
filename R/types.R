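# Core containers: sequence sets, disease ontologies, association and
# similarity matrices. Kept as lightweight classed base objects so that
# standard matrix algebra applies directly.

.SEQ_ALPHABET <- c("A", "C", "G", "T")

# Uppercase, map RNA U to DNA T, and reject anything outside the nucleotide
# alphabet, naming the offending id and position.
.normalise_sequence <- function(seq, id = "<sequence>") {
  s <- chartr("U", "T", toupper(seq))
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0) {
    stop(sprintf("sequence '%s' contains invalid character '%s' at position %d",
                 id, substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

#' Construct a set of lncRNA sequences
#'
#' Sequences are case-folded to upper case and the RNA base U is treated as
#' T, so DNA- and RNA-style inputs compare identically. Ids must be unique
#' and sequences non-empty; the stored order defines the lncRNA order used
#' throughout the package.
#'
#' @param seqs Named character vector of nucleotide strings (names are
#'   lncRNA ids).
#' @return A `sequence_set`: a named character vector over the A/C/G/T
#'   alphabet.
#' @examples
#' sequence_set(c(l1 = "acgu", l2 = "ACGT"))
#' @export
sequence_set <- function(seqs) {
  if (length(seqs) == 0 || is.null(names(seqs)) || anyNA(names(seqs)) ||
      any(names(seqs) == "")) {
    stop("sequences must be a non-empty named character vector", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate lncRNA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  empty <- names(seqs)[!nzchar(seqs)]
  if (length(empty)) {
    stop("empty sequence for id(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(names(seqs), function(id) .normalise_sequence(seqs[[id]], id),
                character(1))
  structure(out, class = "sequence_set")
}

#' Construct a disease ontology from a parent-child edge list
#'
#' The ontology is the directed acyclic graph (DAG) from which per-disease
#' ancestor DAGs and semantic value profiles are derived. Edges point from
#' parent (more general term) to child (more specific term).
#'
#' @param edges Data frame (or matrix) with columns `parent` and `child`
#'   (first two columns are used). May have zero rows.
#' @param nodes Optional character vector of additional isolated node ids.
#' @return A `disease_ontology` list with elements `nodes`, `edges`,
#'   `parents` (named list: node -> parent ids), `children` and `roots`.
#' @export
disease_ontology <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(parent = character(0), child = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(parent = as.character(edges[[1]]),
                        child = as.character(edges[[2]]),
                        stringsAsFactors = FALSE)
  }
  all_nodes <- unique(c(edges$parent, edges$child, as.character(nodes)))
  if (any(all_nodes == "")) stop("empty node id in ontology", call. = FALSE)
  if (nrow(edges) > 0) {
    if (any(edges$parent == edges$child)) {
      stop("self-loop in ontology edge list", call. = FALSE)
    }
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = all_nodes)
    if (!igraph::is_dag(g)) {
      stop("ontology edge list contains a cycle", call. = FALSE)
    }
  }
  parents <- split(edges$parent, factor(edges$child, levels = all_nodes))
  children <- split(edges$child, factor(edges$parent, levels = all_nodes))
  roots <- all_nodes[lengths(parents) == 0]
  structure(list(nodes = all_nodes, edges = edges,
                 parents = lapply(parents, unique),
                 children = lapply(children, unique),
                 roots = roots),
            class = "disease_ontology")
}

#' Construct a binary disease x lncRNA association matrix
#'
#' Rows are diseases, columns are lncRNAs; entry 1 marks an experimentally
#' verified association, 0 an unverified pair.
#'
#' @param values Numeric matrix of 0/1 entries.
#' @param disease_ids,lncrna_ids Unique row and column ids; taken from
#'   `dimnames(values)` when omitted.
#' @return An `association_matrix` (a classed binary matrix with dimnames).
#' @export
association_matrix <- function(values, disease_ids = rownames(values),
                               lncrna_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(disease_ids) || is.null(lncrna_ids)) {
    stop("disease and lncRNA ids are required", call. = FALSE)
  }
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids", call. = FALSE)
  if (anyDuplicated(lncrna_ids)) stop("duplicate lncRNA ids", call. = FALSE)
  if (nrow(values) != length(disease_ids) || ncol(values) != length(lncrna_ids)) {
    stop("id lists do not match matrix dimensions", call. = FALSE)
  }
  if (!all(values %in% c(0, 1))) {
    stop("association matrix entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(disease_ids, lncrna_ids)
  structure(values, class = c("association_matrix", "matrix", "array"))
}

.SIM_KINDS <- c("sequence", "semantic", "gip_lncrna", "gip_disease",
                "integrated_lncrna", "integrated_disease")

#' Construct a similarity matrix
#'
#' A square symmetric matrix with unit diagonal and entries in \[0, 1\],
#' tagged with the kind of similarity it holds.
#'
#' @param values Square numeric matrix.
#' @param ids Row/column ids (taken from rownames when omitted).
#' @param kind One of `"sequence"`, `"semantic"`, `"gip_lncrna"`,
#'   `"gip_disease"`, `"integrated_lncrna"`, `"integrated_disease"`.
#' @param tol Absolute tolerance for the symmetry/diagonal/range checks.
#' @return A `similarity_matrix` (classed matrix with a `kind` attribute).
#' @export
similarity_matrix <- function(values, ids = rownames(values), kind, tol = 1e-9) {
  kind <- match.arg(kind, .SIM_KINDS)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square",
                                         call. = FALSE)
  if (is.null(ids) || length(ids) != nrow(values)) {
    stop("ids must match the matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate ids", call. = FALSE)
  if (max(abs(values - t(values))) > tol) {
    stop("similarity matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(values) - 1)) > tol) {
    stop("similarity matrix diagonal must be 1", call. = FALSE)
  }
  if (min(values) < -tol || max(values) > 1 + tol) {
    stop("similarity entries must lie in [0, 1]", call. = FALSE)
  }
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 1
  dimnames(values) <- list(ids, ids)
  structure(values, kind = kind,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix kind=%s, %d x %d>\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                   drop = FALSE], ...)
  invisible(x)
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set of %d lncRNAs; lengths %d-%d>\n", length(x),
              min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf("<disease_ontology: %d nodes, %d edges, %d root(s)>\n",
              length(x$nodes), nrow(x$edges), length(x$roots)))
  invisible(x)
}
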