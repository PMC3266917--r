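# k-fold cross-validated evaluation with the standard confusion-matrix
# metrics: sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP),
# precision PRE = TP/(TP+FP), accuracy ACC = (TP+TN)/(TP+TN+FP+FN).

#' Confusion-matrix metrics
#'
#' Computes sensitivity, specificity, precision and accuracy from TP / TN /
#' FP / FN counts. A metric whose denominator is zero is undefined and
#' reported as \code{NA} (never as 0), with a message.
#'
#' @param tp,tn,fp,fn Nonnegative integer counts. Alternatively pass a
#'   single named list/vector as \code{tp}.
#' @return Named numeric vector with elements \code{se}, \code{sp},
#'   \code{pre}, \code{acc}.
#' @export
#' @examples
#' confusion_metrics(tp = 8, tn = 5, fp = 2, fn = 1)
confusion_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || length(tp) == 4L)) {
    counts <- tp
    tp <- counts[["tp"]]; tn <- counts[["tn"]]
    fp <- counts[["fp"]]; fn <- counts[["fn"]]
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if (any(counts != round(counts))) stop("confusion counts must be integers")
  ratio <- function(num, den, name) {
    if (den == 0) {
      message("metric '", name, "' undefined (zero denominator); reported NA")
      return(NA_real_)
    }
    num / den
  }
  c(se  = ratio(tp, tp + fn, "se"),
    sp  = ratio(tn, tn + fp, "sp"),
    pre = ratio(tp, tp + fp, "pre"),
    acc = ratio(tp + tn, tp + tn + fp + fn, "acc"))
}

#' Cross-validated evaluation of the pair classifier
#'
#' Stratified k-fold cross-validation: pairs are partitioned into k folds
#' preserving class balance (fold sizes within a class differ by at most
#' one); for each fold the classifier is trained on the remaining folds
#' (including a fresh Platt calibration), the held-out pairs are classified
#' at the probability-0.5 threshold, and confusion counts accumulate.
#' Reported are per-fold metrics, their unweighted mean (the headline
#' figure) and the metrics of the pooled counts. Deterministic given
#' \code{seed}.
#'
#' \code{split = "protein"} gives a protein-disjoint alternative:
#' proteins, not pairs, are assigned to folds; a fold's test set contains
#' the pairs with both proteins in that fold and its training set the pairs
#' with neither, so no protein is shared between them. This is the harder
#' regime and typically lowers accuracy.
#'
#' @param data Labeled pair data frame (\code{id_a}, \code{id_b},
#'   \code{label}).
#' @param db A \code{\link{protein_db}}.
#' @param hyperparams Passed to \code{\link{train_svm}}.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for fold construction and inner splits.
#' @param split \code{"pair"} (default) or \code{"protein"}.
#' @param map Residue class map.
#' @return An object of class \code{cv_result}: list with \code{per_fold}
#'   (data frame of counts and metrics per fold), \code{mean} (unweighted
#'   fold mean of each metric), \code{pooled} (metrics of summed counts),
#'   \code{counts} (pooled confusion counts), \code{k}, \code{seed},
#'   \code{split}.
#' @export
cross_validate <- function(data, db, hyperparams = svm_hyperparams(),
                           k = 5L, seed = 20120126L,
                           split = c("pair", "protein"),
                           map = residue_class_map()) {
  split <- match.arg(split)
  data <- validate_pairs(data)
  if (k < 2L) stop("k must be at least 2")
  n_by_class <- table(data$label)
  if (split == "pair" && any(n_by_class < k)) {
    stop("each class needs at least k pairs for stratified k-fold CV")
  }

  if (split == "pair") {
    fold_of_pair <- with_seed(seed, stratified_folds(data$label, k))
    test_sets <- lapply(seq_len(k), function(i) which(fold_of_pair == i))
    train_sets <- lapply(seq_len(k), function(i) which(fold_of_pair != i))
  } else {
    proteins <- sort(unique(c(data$id_a, data$id_b)))
    fold_of_prot <- with_seed(seed,
      stats::setNames(sample(rep_len(seq_len(k), length(proteins))), proteins))
    fa <- fold_of_prot[data$id_a]
    fb <- fold_of_prot[data$id_b]
    test_sets <- lapply(seq_len(k), function(i) which(fa == i & fb == i))
    train_sets <- lapply(seq_len(k), function(i) which(fa != i & fb != i))
  }

  per_fold <- data.frame(fold = seq_len(k), tp = 0L, tn = 0L, fp = 0L,
                         fn = 0L, se = NA_real_, sp = NA_real_,
                         pre = NA_real_, acc = NA_real_)
  for (i in seq_len(k)) {
    tr <- data[train_sets[[i]], , drop = FALSE]
    te <- data[test_sets[[i]], , drop = FALSE]
    if (nrow(te) == 0L || length(unique(tr$label)) < 2L) next
    model <- train_svm(tr, db, hyperparams = hyperparams, map = map,
                       seed = seed + i)
    X_te <- pair_feature_matrix(te$id_a, te$id_b, db, map)
    X_te_rev <- pair_feature_matrix(te$id_b, te$id_a, db, map)
    p <- (predict_prob_matrix(model, X_te) +
            predict_prob_matrix(model, X_te_rev)) / 2
    pred_pos <- p > 0.5
    truth_pos <- te$label == "interact"
    per_fold$tp[i] <- sum(pred_pos & truth_pos)
    per_fold$tn[i] <- sum(!pred_pos & !truth_pos)
    per_fold$fp[i] <- sum(pred_pos & !truth_pos)
    per_fold$fn[i] <- sum(!pred_pos & truth_pos)
    m <- suppressMessages(confusion_metrics(per_fold$tp[i], per_fold$tn[i],
                                            per_fold$fp[i], per_fold$fn[i]))
    per_fold[i, c("se", "sp", "pre", "acc")] <- m
  }
  pooled_counts <- c(tp = sum(per_fold$tp), tn = sum(per_fold$tn),
                     fp = sum(per_fold$fp), fn = sum(per_fold$fn))
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[, c("se", "sp", "pre", "acc")], na.rm = TRUE),
    pooled = suppressMessages(confusion_metrics(as.list(pooled_counts))),
    counts = pooled_counts,
    k = k, seed = seed, split = split),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s split, seed %d)\n",
              x$k, x$split, x$seed))
  cat(sprintf("  mean  SE %.3f  SP %.3f  PRE %.3f  ACC %.3f\n",
              x$mean["se"], x$mean["sp"], x$mean["pre"], x$mean["acc"]))
  cat(sprintf("  pooled counts: TP %d  TN %d  FP %d  FN %d\n",
              x$counts["tp"], x$counts["tn"], x$counts["fp"],
              x$counts["fn"]))
  invisible(x)
}

#' Write a cross-validation report to TSV
#'
#' Emits the per-fold rows followed by the unweighted mean row.
#'
#' @param cv A \code{cv_result}.
#' @param path Output path.
#' @export
write_cv_report <- function(cv, path) {
  rep <- cv$per_fold
  rep$fold <- as.character(rep$fold)
  mean_row <- data.frame(fold = "mean", tp = NA, tn = NA, fp = NA, fn = NA,
                         se = cv$mean["se"], sp = cv$mean["sp"],
                         pre = cv$mean["pre"], acc = cv$mean["acc"])
  utils::write.table(rbind(rep, mean_row), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
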