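# Independent oracles used across the suite. These are deliberately naive
# implementations written from first principles; they must never call the
# package functions they are used to check.

# Benjamini-Hochberg step-up by definition: for each p_i,
# q_i = min over { j : p_(j) >= p_i } of m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    cand <- which(ps >= pi)
    min(1, min(m * ps[cand] / cand))
  }, numeric(1))
}

# Brute-force UPGMA on a distance matrix: returns the cophenetic distance
# matrix, which uniquely encodes merge order and heights. Average linkage:
# d(A+B, C) = (|A| d(A,C) + |B| d(B,C)) / (|A| + |B|).
upgma_brute_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  d <- D
  sizes <- rep(1L, n)
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b && d[active[a], active[b]] < best_d) {
        best_d <- d[active[a], active[b]]; best <- c(active[a], active[b])
      }
    }
    i <- best[1]; j <- best[2]
    for (x in clusters[[i]]) for (y in clusters[[j]])
      coph[x, y] <- coph[y, x] <- best_d
    # update distances to the merged cluster, stored in slot i
    for (k in setdiff(active, best))
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  coph
}

# Adjusted Rand index between two label vectors (contingency-table formula).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# A small paired two-condition expression matrix with known shifts.
make_paired_matrix <- function(n_transcripts = 60, n_shift = 10, effect = 3,
                               n_donors = 4, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("G%03d", seq_len(n_transcripts))
  base <- rnorm(n_transcripts, 8, 1)
  meta <- data.frame(
    sample = sprintf("S%02d_%s", rep(seq_len(n_donors), each = 2),
                     c("air", "smoke")),
    condition = rep(c("air", "smoke"), n_donors),
    donor = sprintf("D%02d", rep(seq_len(n_donors), each = 2)))
  donor_eff <- matrix(rnorm(n_transcripts * n_donors, sd = 0.5),
                      n_transcripts)
  dirs <- integer(n_transcripts)
  dirs[seq_len(n_shift)] <- rep_len(c(1L, -1L), n_shift)
  vals <- base + donor_eff[, rep(seq_len(n_donors), each = 2)] +
    outer(dirs * effect, as.numeric(meta$condition == "smoke")) +
    matrix(rnorm(n_transcripts * nrow(meta), sd = noise_sd), n_transcripts)
  dimnames(vals) <- list(ids, meta$sample)
  list(mat = expression_matrix(vals, meta), true_direction = dirs)
}
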