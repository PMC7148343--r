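# Cross-dataset signature transfer.
#
# An in vitro smoke-exposure signature is carried to an independent in vivo
# cohort: each dataset is min-max normalized per transcript (which removes
# additive per-transcript platform offsets), the joined matrix is clustered
# by UPGMA on correlation distance, a random forest with cross-validation
# measures the signature's classification power (ROC/AUC, confusion matrix),
# robustness is probed by removing the features most correlated with the
# label, and direction-of-deregulation consistency between the datasets is
# quantified.

#' Per-transcript min-max normalization
#'
#' Rescales every row (transcript) to the range \[0, 1\]:
#' `(x - min) / (max - min)`. Constant rows cannot be rescaled and map to
#' all-zero with a warning.
#'
#' @param values numeric matrix, transcripts x samples (or an
#'   [expression_matrix()], whose values are used).
#' @return matrix of the same shape with every non-constant row spanning
#'   exactly \[0, 1\]; attribute `"constant_rows"` lists rows mapped to zero.
#' @export
minmax_normalize <- function(values) {
  if (inherits(values, "expression_matrix")) values <- values$values
  stop_if(!is.matrix(values) || !is.numeric(values),
          "'values' must be a numeric matrix")
  stop_if(ncol(values) < 2, "min-max normalization needs >= 2 samples")
  rmin <- apply(values, 1L, min)
  rmax <- apply(values, 1L, max)
  rng <- rmax - rmin
  const <- rng == 0
  rng[const] <- 1
  out <- (values - rmin) / rng
  out[const, ] <- 0
  if (any(const))
    warning(sum(const), " constant row(s) mapped to all-zero: ",
            paste(head(rownames(values)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "", call. = FALSE)
  attr(out, "constant_rows") <- rownames(values)[const]
  out
}

# Correlation distance between the columns of m: d = 1 - Pearson r, in
# [0, 2]. Zero-variance columns have undefined correlation; it is set to 0
# (distance 1) with a warning.
correlation_distance <- function(m) {
  sds <- apply(m, 2L, sd)
  if (any(sds == 0))
    warning("zero-variance leaf/leaves; their correlations set to 0: ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  r <- suppressWarnings(cor(m))
  r[is.na(r)] <- 0
  diag(r) <- 1
  as.dist(1 - r)
}

#' UPGMA clustering on correlation distance
#'
#' Average-linkage (UPGMA) agglomeration on `d = 1 - r` (Pearson), over the
#' rows or the columns of the matrix. Ties in the merge order follow the
#' deterministic convention of [stats::hclust()] (first pair in index
#' order).
#'
#' @param values numeric matrix (typically a [minmax_normalize()]d one).
#' @param axis `"columns"` (default: cluster samples) or `"rows"`.
#' @return list of class `"upgma_clustering"`: `hclust` (the tree),
#'   `order` (leaf labels in dendrogram order), `axis`.
#' @export
upgma_cluster <- function(values, axis = c("columns", "rows")) {
  if (inherits(values, "expression_matrix")) values <- values$values
  axis <- match.arg(axis)
  m <- if (axis == "rows") t(values) else values
  stop_if(ncol(m) < 2, "need at least two leaves to cluster")
  hc <- hclust(correlation_distance(m), method = "average")
  structure(list(hclust = hc, order = hc$labels[hc$order], axis = axis),
            class = "upgma_clustering")
}

#' @export
print.upgma_clustering <- function(x, ...) {
  cat(sprintf("<upgma_clustering> %d %s, correlation distance, average linkage\n",
              length(x$order), x$axis))
  cat("  leaf order:", paste(head(x$order, 8), collapse = ", "),
      if (length(x$order) > 8) ", ..." else "", "\n")
  invisible(x)
}

#' Write a UPGMA tree as Newick
#'
#' @param clustering an `"upgma_clustering"`.
#' @param path output file.
#' @export
write_newick <- function(clustering, path) {
  stop_if(!inherits(clustering, "upgma_clustering"),
          "'clustering' must be an upgma_clustering")
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Join two datasets on a shared signature and cluster the samples
#'
#' Restricts to transcripts significant (`q < q_cut`) in *both* DE
#' comparisons — with no filter on the direction of deregulation — then
#' min-max normalizes each dataset independently (so per-transcript platform
#' offsets cancel), concatenates the samples, and clusters the columns by
#' UPGMA on correlation distance.
#'
#' @param de_a,de_b `"de_result"`s of the two comparisons.
#' @param mat_a,mat_b the matching [expression_matrix()] objects.
#' @param q_cut FDR threshold applied to both comparisons (default 0.05).
#' @return list of class `"joined_clustering"`: `values` (combined
#'   normalized matrix), `transcripts`, `sample_origin`, and `clustering`
#'   (`NULL` when only one sample column exists).
#' @export
join_and_cluster <- function(de_a, de_b, mat_a, mat_b, q_cut = 0.05) {
  sig_a <- select_signature(de_a, q_cut)$transcript
  sig_b <- select_signature(de_b, q_cut)$transcript
  shared <- intersect(sig_a, sig_b)
  stop_if(length(shared) == 0,
          "no transcript is significant in both comparisons at this q_cut")
  shared <- sort(shared)
  na <- minmax_normalize(mat_a$values[shared, , drop = FALSE])
  nb <- minmax_normalize(mat_b$values[shared, , drop = FALSE])
  combined <- cbind(na, nb)
  clustering <- if (ncol(combined) >= 2) upgma_cluster(combined, "columns")
  structure(list(values = combined, transcripts = shared,
                 sample_origin = rep(c("A", "B"), c(ncol(na), ncol(nb))),
                 clustering = clustering),
            class = "joined_clustering")
}

#' Rank features by correlation with a binary label
#'
#' Absolute Pearson correlation of each feature (row) with the 0/1-coded
#' label, sorted descending; ties (including exact duplicates) are broken by
#' feature id. Zero-variance features score 0.
#'
#' @param values numeric matrix, features x samples.
#' @param labels binary labels, one per sample (factor, logical or 2-valued).
#' @return data.frame with `feature` and `score`, best first.
#' @export
rank_features_by_correlation <- function(values, labels) {
  if (inherits(values, "expression_matrix")) values <- values$values
  y <- as.numeric(factor(labels)) - 1
  stop_if(length(unique(y)) != 2, "'labels' must take exactly two values")
  stop_if(length(y) != ncol(values), "one label per sample required")
  score <- abs(suppressWarnings(
    apply(values, 1L, function(v) cor(v, y))))
  score[is.na(score)] <- 0
  ord <- order(-score, rownames(values))
  data.frame(feature = rownames(values)[ord], score = score[ord],
             row.names = NULL)
}

# Stratified fold assignment; degrades to leave-one-out when the smaller
# class has fewer members than the requested fold count.
make_folds <- function(labels, folds) {
  n <- length(labels)
  if (min(table(labels)) < folds) {
    message("a class has fewer members than the requested ", folds,
            " folds; using leave-one-out cross-validation")
    return(seq_len(n))
  }
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated random-forest classification of a signature
#'
#' Stratified k-fold cross-validation of a random forest restricted to the
#' signature transcripts. Out-of-fold vote fractions are pooled into a ROC
#' curve and AUC; the confusion matrix uses a 0.5 vote threshold (vote
#' fraction >= 0.5 predicts the positive class). When the smaller class has
#' fewer members than `folds`, the scheme degrades to leave-one-out with a
#' message. Defaults mirror a standard workbench random forest: 100 trees,
#' 10 features per split.
#'
#' @param values features x samples matrix (typically min-max normalized).
#' @param labels two-class factor (or coercible), one per sample.
#' @param signature feature ids to use (default: all rows).
#' @param folds cross-validation folds (default 50).
#' @param n_trees trees per forest (default 100).
#' @param features_per_split candidate features per split (default 10,
#'   capped at the signature size).
#' @param seed integer seed (required; recorded in the report).
#' @param positive label treated as the positive class (default: second
#'   factor level).
#' @return an object of class `"classification_report"`: list with
#'   `roc_points` (FPR/TPR data.frame), `auc`, `confusion_matrix`,
#'   `votes`, `labels`, and the hyper-parameters used.
#' @export
rf_classify_cv <- function(values, labels, signature = NULL, folds = 50L,
                           n_trees = 100L, features_per_split = 10L, seed,
                           positive = NULL) {
  if (inherits(values, "expression_matrix")) values <- values$values
  stop_if(missing(seed), "'seed' is required for rf_classify_cv()")
  check_number(seed, "seed")
  labels <- factor(labels)
  stop_if(nlevels(labels) != 2,
          paste("exactly two classes required; got:",
                paste(levels(labels), collapse = ", ")))
  stop_if(any(table(labels) == 0), "one class has no samples")
  stop_if(length(labels) != ncol(values), "one label per sample required")
  signature <- signature %||% rownames(values)
  missing_feats <- setdiff(signature, rownames(values))
  stop_if(length(missing_feats) > 0,
          paste("signature features not in the matrix:",
                paste(head(missing_feats, 5), collapse = ", ")))
  positive <- positive %||% levels(labels)[2]
  stop_if(!positive %in% levels(labels), "'positive' must be a label level")

  x <- t(values[signature, , drop = FALSE])       # samples x features
  colnames(x) <- make.names(colnames(x))
  mtry <- min(features_per_split, ncol(x))
  set.seed(as.integer(seed))
  fold <- make_folds(labels, folds)
  votes <- numeric(length(labels))
  for (k in sort(unique(fold))) {
    test <- fold == k
    fit <- randomForest::randomForest(
      x = x[!test, , drop = FALSE], y = droplevels(labels[!test]),
      ntree = n_trees, mtry = mtry)
    votes[test] <- predict(fit, x[test, , drop = FALSE],
                           type = "prob")[, positive]
  }

  roc <- pROC::roc(response = labels, predictor = votes,
                   levels = c(setdiff(levels(labels), positive), positive),
                   direction = "<", quiet = TRUE)
  roc_points <- data.frame(fpr = 1 - roc$specificities,
                           tpr = roc$sensitivities)
  roc_points <- roc_points[order(roc_points$fpr, roc_points$tpr), ]
  pred <- factor(ifelse(votes >= 0.5, positive,
                        setdiff(levels(labels), positive)),
                 levels = levels(labels))
  confusion <- table(truth = labels, predicted = pred)

  structure(list(roc_points = roc_points, auc = as.numeric(roc$auc),
                 confusion_matrix = confusion, votes = votes,
                 labels = labels, positive = positive,
                 cv_scheme = if (length(unique(fold)) == length(labels))
                   "leave-one-out" else sprintf("%d-fold", folds),
                 n_trees = n_trees, features_per_split = mtry,
                 seed = as.integer(seed), signature = signature),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s CV, %d trees, %d features/split, seed %d\n",
              x$cv_scheme, x$n_trees, x$features_per_split, x$seed))
  cat(sprintf("  AUC = %.3f (positive class: %s)\n", x$auc, x$positive))
  print(x$confusion_matrix)
  invisible(x)
}

#' @export
plot.classification_report <- function(x, ...) {
  plot.default(x$roc_points$fpr, x$roc_points$tpr, type = "s",
               xlab = "False-positive rate", ylab = "True-positive rate",
               main = sprintf("ROC, AUC = %.3f", x$auc), xlim = c(0, 1),
               ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Feature-ablation robustness of the classification
#'
#' Ranks the signature features by [rank_features_by_correlation()] on the
#' full dataset (the ranking is computed once, before cross-validation;
#' the optimistic bias of this two-stage scheme is deliberate and
#' documented), removes the `k_remove` highest-ranking features, and reruns
#' [rf_classify_cv()] with identical settings and seed.
#'
#' @param values,labels,signature,folds,n_trees,features_per_split,seed,positive
#'   as in [rf_classify_cv()].
#' @param k_remove how many top-correlated features to drop
#'   (`0 <= k_remove < length(signature)`).
#' @return list with `full` and `reduced` classification reports and
#'   `removed` (the dropped feature ids).
#' @export
ablate_and_reclassify <- function(values, labels, signature = NULL,
                                  k_remove = 10L, folds = 50L, n_trees = 100L,
                                  features_per_split = 10L, seed,
                                  positive = NULL) {
  if (inherits(values, "expression_matrix")) values <- values$values
  signature <- signature %||% rownames(values)
  check_number(k_remove, "k_remove", lower = 0)
  stop_if(k_remove >= length(signature),
          sprintf("k_remove = %d would empty the %d-feature signature",
                  k_remove, length(signature)))
  ranking <- rank_features_by_correlation(values[signature, , drop = FALSE],
                                          labels)
  removed <- head(ranking$feature, k_remove)
  full <- rf_classify_cv(values, labels, signature, folds, n_trees,
                         features_per_split, seed, positive)
  reduced <- rf_classify_cv(values, labels, setdiff(signature, removed),
                            folds, n_trees, features_per_split, seed, positive)
  list(full = full, reduced = reduced, removed = removed)
}

#' Direction-of-deregulation overlap between two DE results
#'
#' Partitions the shared transcript universe into significant-in-A-only,
#' significant-in-B-only and significant-in-both (at `q < q_cut`); among the
#' shared significant transcripts, those deregulated in the same direction
#' (equal non-zero sign of the log fold change, or both exactly zero) are
#' counted as consistent.
#'
#' @param de_a,de_b `"de_result"`s sharing transcript ids.
#' @param q_cut FDR threshold (default 0.05).
#' @return an object of class `"overlap_report"`: counts `n_only_a`,
#'   `n_only_b`, `n_shared`, `n_consistent`, `consistent_fraction` (`NA`
#'   when nothing is shared), and `scatter_pairs` (per shared transcript:
#'   `transcript`, `logFC_a`, `logFC_b`, `consistent`).
#' @export
direction_overlap <- function(de_a, de_b, q_cut = 0.05) {
  stop_if(!inherits(de_a, "de_result") || !inherits(de_b, "de_result"),
          "'de_a' and 'de_b' must be de_result objects")
  check_number(q_cut, "q_cut", lower = 0, upper = 1)
  common <- intersect(de_a$transcript, de_b$transcript)
  stop_if(length(common) == 0, "the DE results share no transcript ids")
  a <- de_a[match(common, de_a$transcript), ]
  b <- de_b[match(common, de_b$transcript), ]
  sig_a <- a$q_value < q_cut
  sig_b <- b$q_value < q_cut
  shared <- sig_a & sig_b
  # equal sign; a zero logFC matches only another zero (documented convention)
  cons <- sign(a$log_fold_change) == sign(b$log_fold_change)
  scatter <- data.frame(transcript = common[shared],
                        logFC_a = a$log_fold_change[shared],
                        logFC_b = b$log_fold_change[shared],
                        consistent = cons[shared])
  n_shared <- sum(shared)
  structure(list(n_only_a = sum(sig_a & !sig_b),
                 n_only_b = sum(sig_b & !sig_a),
                 n_shared = n_shared,
                 n_consistent = sum(cons[shared]),
                 consistent_fraction = if (n_shared > 0)
                   sum(cons[shared]) / n_shared else NA_real_,
                 scatter_pairs = scatter, q_cut = q_cut),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> q < %g\n", x$q_cut))
  cat(sprintf("  A only: %d, B only: %d, shared: %d\n",
              x$n_only_a, x$n_only_b, x$n_shared))
  if (x$n_shared > 0)
    cat(sprintf("  consistent direction: %d / %d (%.1f%%)\n", x$n_consistent,
                x$n_shared, 100 * x$consistent_fraction))
  else cat("  consistent fraction undefined (no shared transcripts)\n")
  invisible(x)
}
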