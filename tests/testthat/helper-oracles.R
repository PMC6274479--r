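# Independent scalar-loop oracles. These deliberately avoid every vectorized
# code path of the package: plain for-loops over dense vectors, direct
# transcription of the defining formulas. They are the reference the
# implementation is checked against.

oracle_asmtp <- function(x, y, mu, lam) {
  num <- 0
  den <- 0
  for (j in seq_along(x)) {
    if (x[j] > 0 && y[j] > 0) {
      num <- num + 0.5 * (1 + exp(-((x[j] - y[j]) / mu[j])^2))
      den <- den + 1
    } else if (x[j] == 0 && y[j] == 0) {
      # no contribution
    } else {
      num <- num - lam
      den <- den + 1
    }
  }
  stopifnot(den > 0)
  (num / den + lam) / (1 + lam)
}

oracle_mu <- function(mat) {
  # mat: molecules x features dense matrix -> mean of non-zero values per col
  vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j][mat[, j] != 0]
    if (length(v)) mean(v) else 1.0
  }, numeric(1))
}

oracle_tanimoto_cont <- function(x, y) {
  num <- sum(x * y)
  num / (sum(x^2) + sum(y^2) - num)
}

oracle_recall <- function(ranked_ids, actives, pct) {
  n <- length(ranked_ids)
  k <- max(1, round(pct * n / 100))
  hits <- 0
  for (i in seq_len(k)) if (ranked_ids[i] %in% actives) hits <- hits + 1
  100 * hits / length(actives)
}

oracle_ef <- function(ranked_ids, actives, pct) {
  n <- length(ranked_ids)
  k <- max(1, round(pct * n / 100))
  a <- sum(ranked_ids[seq_len(k)] %in% actives)
  (a / k) / (length(actives) / n)
}

# AUC as the probability a random active outscores a random inactive,
# ties counting one half (Mann-Whitney form; independent of the trapezoid
# construction used by the package).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

oracle_bedroc <- function(active_ranks, n, n_actives, alpha) {
  ra <- n_actives / n
  s <- 0
  for (r in active_ranks) s <- s + exp(-alpha * r / n)
  rie <- s / (ra * (1 - exp(-alpha)) / (exp(alpha / n) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

# ---- fixture builders ------------------------------------------------------

# random ~sparse count fingerprint as a dense vector
rand_dense_fp <- function(M = 1024, density = 0.10, max_count = 6) {
  v <- integer(M)
  nz <- sample(M, max(1, round(M * density)))
  v[nz] <- sample.int(max_count, length(nz), replace = TRUE)
  v
}

dense_to_fp <- function(id, v, M = length(v)) {
  count_fingerprint(id, as.integer(v), M = M, dense = TRUE)
}

make_scaling <- function(mu, n = NULL, mode = "nonzero-mean") {
  structure(list(mu = as.numeric(mu),
                 n = if (is.null(n)) rep(2L, length(mu)) else as.integer(n),
                 mode = mode, source_size = 2L, M = length(mu)),
            class = "feature_scaling")
}

# a ranking object directly from an already-ordered id/score sequence
make_ranking <- function(ids, scores, distance = FALSE, query_id = "q",
                         measure = "test", activity_class = NULL) {
  r <- structure(
    list(query_id = query_id, measure = measure, ids = ids,
         scores = as.numeric(scores), distance = distance, n = length(ids)),
    class = "ranking")
  if (!is.null(activity_class)) r$activity_class <- activity_class
  r
}

# a tiny labelled dataset used across screening/evaluation tests
tiny_dataset <- function(n_classes = 2, per_class = 12, n_decoys = 30,
                         M = 64, seed = 99) {
  generate_dataset(synth_config(
    M = M, n_classes = n_classes, actives_per_class = per_class,
    n_decoys = n_decoys, sparsity = 0.75, class_core_size = 8,
    core_retention = 0.9, seed = seed))
}
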