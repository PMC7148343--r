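# Normalization, UPGMA, random-forest transfer, ablation, direction overlap.

test_that("min-max normalization is exact, warns on constant rows, and is idempotent", {
  m <- matrix(c(2, 4, 6,
                5, 5, 5,
                0, 1, 0.5), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  expect_warning(n <- minmax_normalize(m), "constant")
  expect_equal(unname(n["a", ]), c(0, 0.5, 1))
  expect_equal(unname(n["b", ]), c(0, 0, 0))
  expect_equal(attr(n, "constant_rows"), "b")
  n2 <- minmax_normalize(n[c("a", "c"), ])
  expect_equal(n2, n[c("a", "c"), ], ignore_attr = TRUE)  # idempotent
  # every non-constant row spans exactly [0, 1]; column order untouched
  set.seed(2); r <- matrix(rnorm(40), 4, dimnames = list(1:4, 1:10))
  nr <- minmax_normalize(r)
  expect_equal(unname(apply(nr, 1, range)), rbind(rep(0, 4), rep(1, 4)))
  expect_equal(order(r[1, ]), order(nr[1, ]))
})

test_that("upgma_cluster agrees with the exhaustive average-linkage oracle", {
  # identical columns merge first at height 0
  m <- cbind(x = c(1, 2, 3, 5), y = c(1, 2, 3, 5), z = c(4, 1, 0, 2))
  cl <- upgma_cluster(m)
  expect_equal(cl$hclust$height[1], 0)
  expect_setequal(cl$hclust$labels[-cl$hclust$merge[1, ]], c("x", "y"))

  # anti-correlated pair sits at distance 2 and merges last in a 3-leaf toy
  m2 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2.1, 2.9))
  cl2 <- upgma_cluster(m2)
  expect_equal(max(cl2$hclust$height), (2 + (1 - cor(m2)["b", "c"])) / 2,
               tolerance = 1e-12)
  expect_true("b" %in% cl2$order[c(1, 3)])  # last merge joins {a, c} with {b}

  # random matrices, 4-6 leaves: cophenetic distances match the oracle exactly
  set.seed(5)
  for (i in 1:20) {
    k <- sample(4:6, 1)
    m3 <- matrix(rnorm(8 * k), 8, k, dimnames = list(NULL, letters[1:k]))
    cl3 <- upgma_cluster(m3)
    coph_pkg <- as.matrix(stats::cophenetic(cl3$hclust))[letters[1:k], letters[1:k]]
    coph_oracle <- upgma_brute_cophenetic(as.matrix(1 - cor(m3)))
    dimnames(coph_oracle) <- dimnames(coph_pkg)
    expect_equal(coph_pkg, coph_oracle, tolerance = 1e-12)
    expect_equal(sort(cl3$hclust$height),
                 sort(unique(coph_oracle[upper.tri(coph_oracle)])),
                 tolerance = 1e-12)
  }

  expect_warning(upgma_cluster(cbind(a = c(1, 1, 1), b = c(1, 2, 3),
                                     c = c(3, 1, 2))), "zero-variance")
})

test_that("correlation feature ranking scores and tie-breaks as documented", {
  labels <- factor(rep(c("ctl", "exp"), each = 6))
  y <- as.numeric(labels) - 1
  set.seed(8)
  m <- rbind(perfect = y, dup_b = y * 2 + 1, noise = rnorm(12),
             weak = y + rnorm(12, sd = 2))
  rk <- rank_features_by_correlation(m, labels)
  expect_equal(rk$feature[1:2], c("dup_b", "perfect"))  # |r| = 1, id tie-break
  expect_equal(rk$score[1:2], c(1, 1))
  expect_lt(rk$score[rk$feature == "noise"], 0.6)
  # label-independent features concentrate near 0 over replicates
  set.seed(9)
  null_scores <- replicate(200, rank_features_by_correlation(
    matrix(rnorm(12), 1, dimnames = list("f", NULL)), labels)$score)
  expect_lt(mean(null_scores), 0.35)
})

test_that("random-forest CV is deterministic, degrades to LOO, and nails separable data", {
  set.seed(1)
  n <- 24
  labels <- factor(rep(c("ctl", "exp"), each = n / 2))
  sep <- rbind(matrix(rnorm(5 * n, sd = 0.2), 5) +
                 outer(rep(2, 5), as.numeric(labels) - 1),
               matrix(rnorm(20 * n), 20))
  rownames(sep) <- sprintf("f%02d", 1:25)
  colnames(sep) <- sprintf("s%02d", 1:n)
  r1 <- rf_classify_cv(sep, labels, folds = 6, seed = 5)
  r2 <- rf_classify_cv(sep, labels, folds = 6, seed = 5)
  expect_identical(r1$votes, r2$votes)
  expect_identical(r1$auc, r2$auc)
  expect_gte(r1$auc, 0.95)
  expect_equal(sum(r1$confusion_matrix), n)

  # a single perfectly separating feature gives AUC 1
  one <- matrix(c(rep(0, 12), rep(1, 12)), 1,
                dimnames = list("only", colnames(sep)))
  expect_equal(rf_classify_cv(one, labels, folds = 6, seed = 2)$auc, 1)

  # small classes force leave-one-out with a message
  expect_message(
    r_loo <- rf_classify_cv(sep[, c(1:4, 13:16)], labels[c(1:4, 13:16)],
                            folds = 50, seed = 3),
    "leave-one-out")
  expect_equal(r_loo$cv_scheme, "leave-one-out")
  expect_error(rf_classify_cv(sep, factor(rep("ctl", n)), folds = 5, seed = 1),
               "two classes")
})

test_that("ablation removes the top-correlated features and degrades as constructed", {
  set.seed(3)
  n <- 60
  labels <- factor(rep(c("ctl", "exp"), each = n / 2))
  y <- as.numeric(labels) - 1
  # signal concentrated in exactly 10 features
  conc <- rbind(outer(rep(3, 10), y) + matrix(rnorm(10 * n, sd = 0.3), 10),
                matrix(rnorm(40 * n), 40))
  rownames(conc) <- sprintf("f%02d", 1:50)
  colnames(conc) <- sprintf("s%02d", 1:n)
  ab0 <- ablate_and_reclassify(conc, labels, k_remove = 0, folds = 5, seed = 9)
  expect_identical(ab0$full$auc, ab0$reduced$auc)   # k = 0: same report
  ab <- ablate_and_reclassify(conc, labels, k_remove = 10, folds = 5, seed = 9)
  expect_setequal(ab$removed, sprintf("f%02d", 1:10))
  expect_gte(ab$full$auc, 0.95)
  expect_lt(ab$reduced$auc, 0.7)                    # near chance without signal
  expect_error(ablate_and_reclassify(conc, labels, signature = sprintf("f%02d", 1:5),
                                     k_remove = 5, folds = 5, seed = 1),
               "empty")
})

test_that("join_and_cluster filters to doubly significant transcripts and co-clusters exposure", {
  g <- generate_two_cohort_expression(two_cohort_spec(
    n_transcripts = 300, n_signature = 40, effect_size = 3,
    invitro_donors = 5, invivo_smokers = 12, invivo_nonsmokers = 12,
    platform_shift_sd = 3, noise_sd = 0.4, discordant_fraction = 0, seed = 19))
  ma <- expression_matrix(g$invitro$values, g$invitro$metadata)
  mb <- expression_matrix(g$invivo$values, g$invivo$metadata)
  de_a <- fit_linear_de(ma, c("smoke", "air"))
  de_b <- fit_linear_de(mb, c("smoker", "nonsmoker"), donor_col = NULL)
  j <- join_and_cluster(de_a, de_b, ma, mb, 0.05)
  expect_true(all(j$transcripts %in% g$truth$transcript[g$truth$is_signature]))
  expect_equal(ncol(j$values), 10 + 24)
  # exposure labels dominate the 2-cut column clustering despite the platform shift
  exposure <- c(ma$metadata$condition %in% "smoke",
                mb$metadata$condition %in% "smoker")
  k2 <- stats::cutree(j$clustering$hclust, k = 2)[colnames(j$values)]
  expect_gt(ari(k2, exposure), 0.8)

  # disjoint significant sets are rejected
  de_b_flip <- de_b
  de_b_flip$q_value <- ifelse(de_a$q_value[match(de_b$transcript, de_a$transcript)] < 0.05, 1, 0)
  expect_error(join_and_cluster(de_a, de_b_flip, ma, mb, 0.05),
               "no transcript")
})

test_that("direction overlap counts shared directions with the zero convention", {
  pm <- make_paired_matrix(n_transcripts = 40, n_shift = 12, effect = 3,
                           noise_sd = 0.2, seed = 6)
  de <- fit_linear_de(pm$mat, c("smoke", "air"))
  self <- direction_overlap(de, de, 0.05)
  expect_equal(self$consistent_fraction, 1)
  expect_equal(self$n_only_a, 0)
  expect_equal(self$n_shared, nrow(select_signature(de, 0.05)))

  # swapping A and B swaps the only-A/only-B labels, nothing else
  pm2 <- make_paired_matrix(n_transcripts = 40, n_shift = 20, effect = 3,
                            noise_sd = 0.2, seed = 66)
  de2 <- fit_linear_de(pm2$mat, c("smoke", "air"))
  o_ab <- direction_overlap(de, de2, 0.05)
  o_ba <- direction_overlap(de2, de, 0.05)
  expect_equal(o_ab$n_only_a, o_ba$n_only_b)
  expect_equal(o_ab$n_shared, o_ba$n_shared)
  expect_equal(o_ab$n_consistent, o_ba$n_consistent)

  # a zero logFC only matches another zero
  mk <- function(lfc, q) structure(
    data.frame(transcript = c("t1", "t2"), log_fold_change = lfc,
               t = 0, p_value = q, q_value = q, direction = sign(lfc)),
    class = c("de_result", "data.frame"))
  oz <- direction_overlap(mk(c(0, 0), c(0.01, 0.01)),
                          mk(c(1, 0), c(0.01, 0.01)))
  expect_equal(oz$n_consistent, 1)
  # zero shared transcripts: counts returned, fraction flagged undefined
  on <- direction_overlap(mk(c(1, 1), c(0.01, 1)), mk(c(1, 1), c(1, 0.01)))
  expect_equal(on$n_shared, 0)
  expect_true(is.na(on$consistent_fraction))
  expect_equal(on$n_only_a, 1)
})
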