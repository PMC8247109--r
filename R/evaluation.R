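# Evaluation harness: fold plans over the verified pairs, threshold-free
# ranking metrics (ROC/AUC, precision-recall/AUPR), thresholded confusion
# metrics (accuracy, F1, MCC), and the full k-fold cross-validation loop
# with per-fold masking of held-out positives.

#' Plan k folds over the verified pairs
#'
#' Positives are partitioned into `k` folds whose sizes differ by at most
#' one; the assignment is a seeded uniform shuffle and is reproducible from
#' the seed. Folds split by pair, not by disease or lncRNA.
#'
#' @param positive_pairs Data frame with columns `disease_id`, `lncrna_id`
#'   (one verified pair per row).
#' @param k Number of folds (2 or more, at most the number of positives).
#' @param seed Integer seed.
#' @return A `fold_plan` list: `k`, `assignments` (integer fold index per
#'   pair, named `disease_id::lncrna_id`), `pairs`, `seed`.
#' @export
make_folds <- function(positive_pairs, k, seed = 1L) {
  n <- nrow(positive_pairs)
  if (!.is_count(k) || k < 2) stop("k must be an integer >= 2", call. = FALSE)
  if (k > n) {
    stop(sprintf("k = %d exceeds the number of verified pairs (%d)", k, n),
         call. = FALSE)
  }
  assignments <- integer(n)
  .with_seed(seed, {
    ord <- sample.int(n)
    assignments[ord] <- rep_len(seq_len(k), n)
  })
  names(assignments) <- paste(positive_pairs$disease_id,
                              positive_pairs$lncrna_id, sep = "::")
  structure(list(k = as.integer(k), assignments = assignments,
                 pairs = positive_pairs, seed = as.integer(seed)),
            class = "fold_plan")
}

.check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("ranking metrics are undefined with a single class present",
         call. = FALSE)
  }
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold (ties grouped), with
#' the (0, 0) and (1, 1) endpoints; both coordinates are monotone
#' nondecreasing.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 positive, 0 negative).
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  .check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(diff(s) != 0, TRUE)  # last index of every tie group
  data.frame(fpr = c(0, fp[keep] / sum(labels == 0)),
             tpr = c(0, tp[keep] / sum(labels == 1)))
}

#' Area under a ROC curve
#'
#' Trapezoidal area under the curve points; on the tie-grouped points of
#' [roc_points()] this equals the Mann-Whitney concordance probability
#' with ties counted 1/2.
#'
#' @param points Data frame from [roc_points()].
#' @return Number in \[0, 1\].
#' @export
auc_from_points <- function(points) {
  sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                          utils::tail(points$tpr, -1)) / 2)
}

#' @describeIn auc_from_points AUC directly from scores and labels.
#' @inheritParams roc_points
#' @export
auc_score <- function(scores, labels) {
  auc_from_points(roc_points(scores, labels))
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over distinct score
#' thresholds (ties grouped): `sum (R_i - R_{i-1}) * P_i`.
#'
#' @inheritParams roc_points
#' @return Number in \[0, 1\].
#' @export
aupr_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  .check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(diff(s) != 0, TRUE)
  rec <- tp[keep] / sum(labels == 1)
  prec <- tp[keep] / (tp[keep] + fp[keep])
  sum(diff(c(0, rec)) * prec)
}

#' Precision-recall curve points
#'
#' @inheritParams roc_points
#' @return Data frame with columns `recall`, `precision`, one row per
#'   distinct threshold.
#' @export
pr_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  .check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(diff(s) != 0, TRUE)
  data.frame(recall = tp[keep] / sum(labels == 1),
             precision = tp[keep] / (tp[keep] + fp[keep]))
}

#' Confusion counts at a threshold
#'
#' @inheritParams roc_points
#' @param threshold Scores strictly above the threshold are predicted
#'   positive.
#' @return List with elements `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  list(TP = sum(pred == 1 & labels == 1),
       FP = sum(pred == 1 & labels == 0),
       TN = sum(pred == 0 & labels == 0),
       FN = sum(pred == 0 & labels == 1))
}

#' Accuracy, F1 and Matthews correlation from confusion counts
#'
#' Standard definitions: accuracy `(TP+TN)/total`;
#' F1 `2 TP / (2 TP + FP + FN)` (harmonic mean of precision and recall,
#' 0 when no positive predictions or positives exist);
#' MCC `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as
#' 0 when the denominator vanishes.
#'
#' @param counts List with elements `TP`, `FP`, `TN`, `FN` (all
#'   non-negative, not all zero).
#' @return List with elements `accuracy`, `f1`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  accuracy <- (tp + tn) / total
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(accuracy = accuracy, f1 = f1, mcc = mcc)
}

## ---- cross-validation ------------------------------------------------------

#' Per-fold training inputs with held-out positives masked
#'
#' Builds everything a fold's training stage sees: the association matrix
#' with that fold's held-out positives zeroed, the GIP kernels recomputed
#' from the masked matrix only, the integrated similarities, and the
#' training feature vectors (remaining positives). Held-out labels can
#' therefore not leak into a fold's training inputs.
#'
#' @param A Full [association_matrix()].
#' @param L_sim,D_sim Base sequence and semantic similarity matrices (fold
#'   independent).
#' @param plan A [make_folds()] plan over the positives of `A`.
#' @param fold Fold index in `1..k`.
#' @return List with `A_train`, `GKL`, `GKD`, `Ls`, `Ds`, `train_features`
#'   and `held_out` (data frame of the fold's masked positives).
#' @export
fold_training_inputs <- function(A, L_sim, D_sim, plan, fold) {
  stopifnot(inherits(plan, "fold_plan"), fold >= 1, fold <= plan$k)
  held <- plan$pairs[plan$assignments == fold, , drop = FALSE]
  train_pos <- plan$pairs[plan$assignments != fold, , drop = FALSE]
  A_train <- unclass(A)
  A_train[cbind(held$disease_id, held$lncrna_id)] <- 0
  A_train <- association_matrix(A_train)
  GKL <- gip_lncrna(A_train)
  GKD <- gip_disease(A_train)
  Ls <- integrate_similarity(L_sim, GKL)
  Ds <- integrate_similarity(D_sim, GKD)
  train_features <- build_pair_features(Ds, Ls, A_train, pairs = train_pos)
  list(A_train = A_train, GKL = GKL, GKD = GKD, Ls = Ls, Ds = Ds,
       train_features = train_features, held_out = held)
}

#' k-fold cross-validation of the full pipeline
#'
#' For every fold: mask the held-out positives, recompute the GIP kernels
#' and integrated similarities from the masked matrix, train the model on
#' the remaining positives' feature vectors, score the held-out positives
#' together with all unverified pairs, and compute AUC/AUPR over the full
#' candidate set. Accuracy, F1 and MCC are computed at threshold 0.5 on a
#' balanced negative sample (as many seeded uniformly drawn unverified
#' pairs as held-out positives), since the fully imbalanced candidate set
#' has no meaningful fixed threshold.
#'
#' @param dataset List with elements `sequences` ([sequence_set()]),
#'   `ontology` ([disease_ontology()]) and `associations`
#'   ([association_matrix()]), e.g. from [simulate_dataset()].
#' @param net_cfg A [network_config()]; default sized from the data.
#' @param train_cfg A [train_config()]; its seed is re-derived per fold
#'   from `seed`.
#' @param k Number of folds.
#' @param seed Root seed for fold assignment, per-fold training and
#'   negative sampling.
#' @param mu Semantic contribution factor.
#' @param keep_curves Store per-fold ROC and PR points in the report.
#' @return A `cv_report`: `folds` (per-fold metric data frame), `mean`
#'   (named metric means), `curves`, `k`, `seed`.
#' @export
cross_validate <- function(dataset, net_cfg = NULL,
                           train_cfg = train_config(), k = 10, seed = 1L,
                           mu = 0.5, keep_curves = TRUE) {
  A <- dataset$associations
  pos_idx <- which(unclass(A) == 1, arr.ind = TRUE)
  positives <- data.frame(disease_id = rownames(A)[pos_idx[, 1]],
                          lncrna_id = colnames(A)[pos_idx[, 2]],
                          stringsAsFactors = FALSE)
  if (nrow(positives) < k) {
    stop("fewer verified pairs than folds", call. = FALSE)
  }
  L_sim <- sequence_similarity(dataset$sequences)
  D_sim <- semantic_similarity(dataset$ontology, rownames(A), mu = mu,
                               missing = "singleton")
  plan <- make_folds(positives, k, seed = .derive_seed(seed, 100L))

  zeros_idx <- which(unclass(A) == 0, arr.ind = TRUE)
  zeros <- data.frame(disease_id = rownames(A)[zeros_idx[, 1]],
                      lncrna_id = colnames(A)[zeros_idx[, 2]],
                      stringsAsFactors = FALSE)

  fold_rows <- vector("list", k)
  curves <- if (keep_curves) vector("list", k) else NULL
  for (f in seq_len(k)) {
    inputs <- fold_training_inputs(A, L_sim, D_sim, plan, f)
    tc <- train_cfg
    tc$seed <- .derive_seed(seed, 200L + f)
    model <- train_bigan(inputs$train_features, net_cfg = net_cfg,
                         train_cfg = tc)
    test_pairs <- rbind(inputs$held_out, zeros)
    test_features <- build_pair_features(inputs$Ds, inputs$Ls, A,
                                         pairs = test_pairs)
    st <- score_pairs(model, test_features)
    labels <- test_features$pairs$label
    # rank on the logit: same ordering as the probability, but free of
    # double-precision saturation when the discriminator is confident
    auc <- auc_score(st$logit, labels)
    aupr <- aupr_score(st$logit, labels)

    n_pos <- nrow(inputs$held_out)
    neg_pick <- .with_seed(.derive_seed(seed, 300L + f),
                           sample.int(nrow(zeros), min(n_pos, nrow(zeros))))
    bal_idx <- c(seq_len(n_pos), n_pos + neg_pick)
    cm <- classification_metrics(
      confusion_counts(st$logit[bal_idx], labels[bal_idx], threshold = 0))
    fold_rows[[f]] <- data.frame(fold = f, auc = auc, aupr = aupr,
                                 accuracy = cm$accuracy, f1 = cm$f1,
                                 mcc = cm$mcc, n_test_pos = n_pos,
                                 n_test_neg = nrow(zeros))
    if (keep_curves) {
      curves[[f]] <- list(roc = roc_points(st$logit, labels),
                          pr = pr_points(st$logit, labels))
    }
  }
  folds <- do.call(rbind, fold_rows)
  metric_cols <- c("auc", "aupr", "accuracy", "f1", "mcc")
  structure(list(folds = folds,
                 mean = colMeans(folds[, metric_cols]),
                 curves = curves, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d folds>\n", x$k))
  print(round(x$mean, 4))
  invisible(x)
}

#' Plot cross-validated ROC and PR curves
#'
#' @param report A `cv_report` with stored curves.
#' @param which `"roc"`, `"pr"` or both.
#' @return Invisibly, the report.
#' @export
plot_cv_curves <- function(report, which = c("roc", "pr")) {
  which <- match.arg(which, several.ok = TRUE)
  if (is.null(report$curves)) stop("report carries no curves", call. = FALSE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(report$k, "Dark 3")
  if ("roc" %in% which) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR",
                   ylab = "TPR", main = sprintf(
                     "ROC (%d-fold, mean AUC %.3f)", report$k,
                     report$mean[["auc"]]))
    graphics::abline(0, 1, lty = 2, col = "grey")
    for (f in seq_len(report$k)) {
      graphics::lines(report$curves[[f]]$roc, col = cols[f])
    }
  }
  if ("pr" %in% which) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                   ylab = "Precision", main = sprintf(
                     "PR (%d-fold, mean AUPR %.3f)", report$k,
                     report$mean[["aupr"]]))
    for (f in seq_len(report$k)) {
      graphics::lines(report$curves[[f]]$pr, col = cols[f])
    }
  }
  invisible(report)
}
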