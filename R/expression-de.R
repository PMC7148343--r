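# Per-transcript linear-model differential expression.
#
# Expression is assumed already normalized and on a log scale; the entry
# point is a transcripts x samples matrix with sample metadata. Each
# transcript is fit by ordinary least squares with cell-means condition
# coding plus donor covariates (design ~ 0 + condition + donor), the
# condition contrast is tested with a per-transcript t-test, and p-values
# are adjusted across transcripts by Benjamini-Hochberg step-up. Unlike
# moderated-variance approaches, no information is shared across
# transcripts by default; an optional pooled-variance mode is provided.

#' Construct an expression matrix with sample metadata
#'
#' @param values numeric matrix, transcripts x samples, with unique
#'   transcript ids as rownames and sample ids as colnames.
#' @param metadata data.frame with a `sample` column matching the matrix
#'   columns plus metadata fields (e.g. `condition`, `donor`, `cohort`).
#'   Extra metadata rows are tolerated (with a warning); missing ones are an
#'   error.
#' @return an object of class `"expression_matrix"` (list with `values`,
#'   `metadata` aligned to the columns).
#' @export
expression_matrix <- function(values, metadata) {
  stop_if(!is.matrix(values) || !is.numeric(values),
          "'values' must be a numeric matrix")
  stop_if(is.null(rownames(values)), "'values' must have transcript rownames")
  stop_if(anyDuplicated(rownames(values)) > 0,
          paste("duplicate transcript ids:",
                paste(unique(rownames(values)[duplicated(rownames(values))]),
                      collapse = ", ")))
  stop_if(is.null(colnames(values)), "'values' must have sample colnames")
  stop_if(!"sample" %in% names(metadata), "'metadata' needs a 'sample' column")
  missing <- setdiff(colnames(values), metadata$sample)
  stop_if(length(missing) > 0,
          paste("metadata missing for sample(s):", paste(missing, collapse = ", ")))
  extra <- setdiff(metadata$sample, colnames(values))
  if (length(extra) > 0)
    warning("metadata rows without matching samples ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  metadata <- metadata[match(colnames(values), metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d transcripts x %d samples\n",
              nrow(x$values), ncol(x$values)))
  meta_cols <- setdiff(names(x$metadata), "sample")
  if (length(meta_cols)) cat("  metadata:", paste(meta_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)` over the
#' sorted p-values, capped at 1, returned in the original order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stop_if(!is.numeric(p_values) || anyNA(p_values),
          "'p_values' must be numeric without NA")
  stop_if(any(p_values < 0 | p_values > 1), "p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-transcript linear-model differential expression
#'
#' Ordinary least squares per transcript with the design
#' `~ 0 + condition (+ donor)`: cell-means coding of the condition plus donor
#' covariates when a donor column is given (paired design; a donor's
#' constant offset is absorbed by its covariate). The requested condition
#' contrast is tested per transcript (two-sided t), and q-values are
#' computed across transcripts with [bh_adjust()].
#'
#' @param mat an [expression_matrix()] (log-scale values).
#' @param contrast character length 2: `c(numerator, denominator)` condition
#'   levels; `log_fold_change = mean(numerator) - mean(denominator)` adjusted
#'   for donors.
#' @param condition_col,donor_col metadata column names; set
#'   `donor_col = NULL` for an unpaired design.
#' @param var_mode `"per_transcript"` (default) or `"pooled"` (single
#'   variance pooled across transcripts; a simple alternative for very small
#'   sample sizes).
#' @return an object of class `"de_result"`: data.frame with `transcript`,
#'   `log_fold_change`, `t`, `p_value`, `q_value`, `direction` (-1/0/1).
#' @export
fit_linear_de <- function(mat, contrast, condition_col = "condition",
                          donor_col = "donor",
                          var_mode = c("per_transcript", "pooled")) {
  stop_if(!inherits(mat, "expression_matrix"),
          "'mat' must be an expression_matrix")
  var_mode <- match.arg(var_mode)
  meta <- mat$metadata
  stop_if(!condition_col %in% names(meta),
          sprintf("metadata has no '%s' column", condition_col))
  cond <- factor(meta[[condition_col]])
  stop_if(length(contrast) != 2 || !all(contrast %in% levels(cond)),
          paste("'contrast' must name two levels of the condition;",
                "available:", paste(levels(cond), collapse = ", ")))
  stop_if(any(table(cond)[contrast] < 2), "need >= 2 samples per condition")

  df <- data.frame(condition = cond)
  form <- ~ 0 + condition
  if (!is.null(donor_col)) {
    stop_if(!donor_col %in% names(meta),
            sprintf("metadata has no '%s' column", donor_col))
    stop_if(anyNA(meta[[donor_col]]),
            sprintf("'%s' contains NA; use donor_col = NULL for unpaired designs",
                    donor_col))
    df$donor <- factor(meta[[donor_col]])
    if (nlevels(df$donor) > 1) form <- ~ 0 + condition + donor
  }
  X <- model.matrix(form, df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is not full rank; confounded column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  Y <- t(mat$values)                             # samples x transcripts
  beta <- qr.coef(qr_x, Y)                       # p x m
  res <- Y - X %*% beta
  df_resid <- nrow(X) - ncol(X)
  stop_if(df_resid < 1, "no residual degrees of freedom in the design")
  s2 <- colSums(res^2) / df_resid
  if (var_mode == "pooled") s2 <- rep(mean(s2), length(s2))

  cvec <- setNames(numeric(ncol(X)), colnames(X))
  cvec[paste0("condition", contrast[1])] <- 1
  cvec[paste0("condition", contrast[2])] <- -1
  xtx_inv <- chol2inv(qr.R(qr_x))
  cvar <- drop(t(cvec) %*% xtx_inv %*% cvec)

  lfc <- drop(crossprod(cvec, beta))
  se <- sqrt(cvar * s2)
  t_stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- 2 * pt(-abs(t_stat), df_resid)
  out <- data.frame(transcript = rownames(mat$values),
                    log_fold_change = lfc, t = t_stat, p_value = p,
                    q_value = bh_adjust(p), direction = sign(lfc),
                    row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "df_resid") <- df_resid
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("<de_result> %d transcripts, contrast %s - %s, df = %d\n",
              nrow(x), ct[1], ct[2], attr(x, "df_resid")))
  cat(sprintf("  q < 0.05: %d transcripts\n", sum(x$q_value < 0.05)))
  print(head(as.data.frame(x[order(x$q_value), ]), 5), row.names = FALSE)
  invisible(x)
}

#' Select a significant signature from a DE result
#'
#' Transcripts with `q_value < q_cut`, ordered by increasing q (ties by
#' decreasing absolute log fold change, then id), each tagged with its
#' direction of deregulation.
#'
#' @param de a `"de_result"`.
#' @param q_cut FDR threshold (default 0.05).
#' @return data.frame with `transcript`, `log_fold_change`, `q_value`,
#'   `direction`.
#' @export
select_signature <- function(de, q_cut = 0.05) {
  stop_if(!inherits(de, "de_result"), "'de' must be a de_result")
  check_number(q_cut, "q_cut", lower = 0, upper = 1)
  sel <- de[de$q_value < q_cut, , drop = FALSE]
  sel <- sel[order(sel$q_value, -abs(sel$log_fold_change), sel$transcript), ]
  out <- as.data.frame(sel)[, c("transcript", "log_fold_change", "q_value",
                                "direction")]
  rownames(out) <- NULL
  out
}
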