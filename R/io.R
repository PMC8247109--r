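# Readers and writers for the standard input/output formats: FASTA
# sequences, TSV association pair lists, TSV ontology edge lists, TSV
# similarity matrices, TSV score tables and JSON cross-validation reports.
# TSV dialect: tab-separated, UTF-8, '#'-prefixed comment lines ignored.

#' Read lncRNA sequences from a FASTA file
#'
#' The lncRNA id is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return A [sequence_set()] in file order.
#' @export
read_sequences <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  sequence_set(stats::setNames(as.character(x), ids))
}

#' Write lncRNA sequences to a FASTA file
#'
#' @param seqs A [sequence_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  x <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.read_tsv <- function(path, col_names) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < length(col_names)) {
    stop(sprintf("malformed TSV '%s': expected %d columns", path,
                 length(col_names)), call. = FALSE)
  }
  df <- df[, seq_along(col_names), drop = FALSE]
  names(df) <- col_names
  # header line is optional; drop it if present
  if (nrow(df) > 0 && all(tolower(unlist(df[1, ])) == col_names)) {
    df <- df[-1, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read verified associations from a TSV pair list
#'
#' Two columns `disease_id<TAB>lncrna_id`, one verified pair per line
#' (header optional). Ids absent from the supplied universes are an error;
#' when no universes are given they are taken from the file in order of
#' first appearance.
#'
#' @param path TSV file path.
#' @param disease_ids,lncrna_ids Optional id universes fixing the matrix
#'   row/column order.
#' @return An [association_matrix()].
#' @export
read_associations <- function(path, disease_ids = NULL, lncrna_ids = NULL) {
  df <- .read_tsv(path, c("disease_id", "lncrna_id"))
  if (is.null(disease_ids)) disease_ids <- unique(df$disease_id)
  if (is.null(lncrna_ids)) lncrna_ids <- unique(df$lncrna_id)
  bad <- c(setdiff(df$disease_id, disease_ids),
           setdiff(df$lncrna_id, lncrna_ids))
  if (length(bad)) {
    stop(sprintf("association file '%s' contains unknown id(s): %s", path,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  a <- matrix(0, length(disease_ids), length(lncrna_ids),
              dimnames = list(disease_ids, lncrna_ids))
  if (nrow(df)) a[cbind(df$disease_id, df$lncrna_id)] <- 1
  association_matrix(a)
}

#' Write verified associations as a TSV pair list
#'
#' @param A An [association_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(A, path) {
  idx <- which(unclass(A) == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(disease_id = rownames(A)[idx[, 1]],
                   lncrna_id = colnames(A)[idx[, 2]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease ontology from a TSV edge list
#'
#' Two columns `parent_id<TAB>child_id` (header optional).
#'
#' @param path TSV file path.
#' @param nodes Optional extra isolated nodes.
#' @return A [disease_ontology()].
#' @export
read_ontology <- function(path, nodes = NULL) {
  df <- .read_tsv(path, c("parent_id", "child_id"))
  disease_ontology(data.frame(parent = df$parent_id, child = df$child_id,
                              stringsAsFactors = FALSE), nodes = nodes)
}

#' Write a disease ontology as a TSV edge list
#'
#' @param onto A [disease_ontology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(onto, path) {
  df <- data.frame(parent_id = onto$edges$parent,
                   child_id = onto$edges$child)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a similarity matrix as TSV
#'
#' TSV with an id header row and id column.
#'
#' @param path File path.
#' @param kind Similarity kind (see [similarity_matrix()]).
#' @return `read_similarity` returns a [similarity_matrix()];
#'   `write_similarity` returns `path` invisibly.
#' @export
read_similarity <- function(path, kind) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE,
                                   comment.char = "#"))
  similarity_matrix(m, ids = rownames(m), kind = kind)
}

#' @rdname read_similarity
#' @param sim A [similarity_matrix()].
#' @export
write_similarity <- function(sim, path) {
  utils::write.table(format(unclass(sim), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read / write a score table as TSV
#'
#' Columns: `disease_id`, `lncrna_id`, `score`, `known_flag`.
#'
#' @param path File path.
#' @return `read_scores` returns a `score_table` data frame;
#'   `write_scores` returns `path` invisibly.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("disease_id", "lncrna_id", "score", "known_flag") %in%
                names(df)))
  class(df) <- c("score_table", "data.frame")
  df
}

#' @rdname read_scores
#' @param scores A `score_table` from [score_pairs()].
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise / read a cross-validation report as JSON
#'
#' Per-fold metrics, means and (optionally) the ROC/PR curve points.
#'
#' @param report A `cv_report` from [cross_validate()].
#' @param path File path.
#' @param curves Include the curve points in the JSON.
#' @return `write_cv_report` returns `path` invisibly; `read_cv_report`
#'   returns the report as a list.
#' @export
write_cv_report <- function(report, path, curves = FALSE) {
  out <- list(k = report$k, seed = report$seed,
              folds = report$folds, mean = as.list(report$mean))
  if (curves && !is.null(report$curves)) out$curves <- report$curves
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_cv_report
#' @export
read_cv_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a simulated dataset as the three standard input files
#'
#' Creates `sequences.fasta`, `ontology.tsv` and `associations.tsv` in
#' `dir`, plus `blocks.tsv` recording the planted ground truth.
#'
#' @param dataset An `lnc_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sequences = file.path(dir, "sequences.fasta"),
             ontology = file.path(dir, "ontology.tsv"),
             associations = file.path(dir, "associations.tsv"),
             blocks = file.path(dir, "blocks.tsv"))
  write_sequences(dataset$sequences, paths[["sequences"]])
  write_ontology(dataset$ontology, paths[["ontology"]])
  write_associations(dataset$associations, paths[["associations"]])
  blocks <- rbind(data.frame(id = names(dataset$blocks$disease),
                             type = "disease",
                             block = unname(dataset$blocks$disease)),
                  data.frame(id = names(dataset$blocks$lncrna),
                             type = "lncrna",
                             block = unname(dataset$blocks$lncrna)))
  utils::write.table(blocks, paths[["blocks"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a dataset from the three standard input files
#'
#' @param sequences,ontology,associations File paths (FASTA, TSV edge
#'   list, TSV pair list).
#' @return An `lnc_dataset`-shaped list with `sequences`, `ontology` and
#'   `associations` (rows ordered by the ontology-independent first
#'   appearance of diseases in the association file, columns by FASTA
#'   order).
#' @export
read_dataset <- function(sequences, ontology, associations) {
  seqs <- read_sequences(sequences)
  onto <- read_ontology(ontology)
  A <- read_associations(associations, lncrna_ids = names(seqs))
  structure(list(sequences = seqs, ontology = onto, associations = A),
            class = "lnc_dataset")
}
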