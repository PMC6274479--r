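#' Per-feature scaling statistics for ASMTP
#'
#' For every feature j of a dataset, computes the number of molecules with a
#' non-zero count (`n_j`) and the mean of those non-zero counts (`mu_j`), the
#' scale that divides the count difference inside ASMTP's Gaussian term.
#' The original text-processing formulation used the standard deviation of
#' the non-zero values instead; that variant is available as mode
#' `"nonzero-stddev"`.
#'
#' Features never seen in the dataset (`n_j = 0`) get the sentinel scale 1.0.
#' The sentinel is provably never consumed by ASMTP: the Gaussian branch
#' fires only when both compared molecules have the feature, which forces
#' `n_j >= 1` whenever both molecules belong to the dataset. In stddev mode
#' the same sentinel is used when fewer than two non-zero values exist or the
#' spread is exactly zero.
#'
#' @param dataset A [fingerprint_dataset()]; scaling is computed over the
#'   whole screened database, references included.
#' @param mode `"nonzero-mean"` (ASMTP, default) or `"nonzero-stddev"`
#'   (original SMTP behaviour).
#' @return An object of class `feature_scaling` with fields `mu` (length-M
#'   scale vector), `n` (length-M non-zero counts), `mode`, `source_size`.
#' @examples
#' ds <- fingerprint_dataset(list(
#'   count_fingerprint("a", c(`0` = 2L), M = 2),
#'   count_fingerprint("b", c(`0` = 4L, `1` = 1L), M = 2)))
#' compute_feature_scaling(ds)$mu  # c(3, 1)
#' @export
compute_feature_scaling <- function(dataset,
                                    mode = c("nonzero-mean",
                                             "nonzero-stddev")) {
  mode <- match.arg(mode)
  if (!inherits(dataset, "fingerprint_dataset")) {
    stop("`dataset` must be a fingerprint_dataset", call. = FALSE)
  }
  if (n_molecules(dataset) == 0L) {
    stop("cannot compute feature scaling on an empty dataset", call. = FALSE)
  }
  X <- dataset$counts
  n <- Matrix::colSums(X != 0)
  s1 <- Matrix::colSums(X)
  mu <- ifelse(n > 0, s1 / pmax(n, 1), 1.0)
  if (mode == "nonzero-stddev") {
    s2 <- Matrix::colSums(X^2)
    var <- ifelse(n >= 2, (s2 - n * mu^2) / (n - 1), 0)
    var[var < 0] <- 0  # guard FP round-off
    sd <- sqrt(var)
    mu <- ifelse(n >= 2 & sd > 0, sd, 1.0)
  }
  structure(
    list(mu = as.numeric(mu), n = as.integer(n), mode = mode,
         source_size = n_molecules(dataset), M = dataset$M),
    class = "feature_scaling"
  )
}

#' @export
print.feature_scaling <- function(x, ...) {
  cat(sprintf("<feature_scaling> mode=%s over %d molecules, %d/%d features seen\n",
              x$mode, x$source_size, sum(x$n > 0), x$M))
  invisible(x)
}

#' Similarity configuration
#'
#' Holds the mismatch penalty `lambda` and the scaling mode. `lambda` is the
#' small constant subtracted for every feature present in exactly one of the
#' two molecules; its published working range is 0.01 down to 0.0001, with
#' 0.0001 as the tested default. Any positive value is accepted, but values
#' above 0.01 trigger a warning.
#'
#' @param lam Positive penalty constant (default `1e-4`).
#' @param scaling_mode `"nonzero-mean"` or `"nonzero-stddev"`.
#' @return An object of class `similarity_config`.
#' @export
similarity_config <- function(lam = 1e-4,
                              scaling_mode = c("nonzero-mean",
                                               "nonzero-stddev")) {
  scaling_mode <- match.arg(scaling_mode)
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0) {
    stop("`lam` must be a single positive number", call. = FALSE)
  }
  if (lam > 0.01) {
    warning("lambda = ", lam, " is above the recommended range (0.0001, 0.01]",
            call. = FALSE)
  }
  structure(list(lam = lam, scaling_mode = scaling_mode),
            class = "similarity_config")
}

.as_count_vector <- function(m) {
  if (inherits(m, "count_fingerprint")) as.numeric(as_dense(m))
  else as.numeric(m)
}

#' ASMTP similarity between two count fingerprints
#'
#' The Adapted Similarity Measure of Text Processing scores each feature by
#' case: a feature present in both molecules contributes
#' `0.5 * (1 + exp(-((x1 - x2) / mu_j)^2))` -- a Gaussian in the count
#' difference with lower bound 0.5, scaled by the dataset mean of the
#' feature's non-zero values; a feature present in exactly one molecule
#' contributes the fixed penalty `-lambda`; a feature absent from both
#' contributes nothing and is excluded from the denominator. The case sums
#' are divided by the number of features present in at least one molecule,
#' giving `F`, and the final score is `(F + lambda) / (1 + lambda)`, which
#' lies in [0, 1] exactly: identical fingerprints score 1, fingerprints with
#' disjoint support score 0.
#'
#' @param m1,m2 `count_fingerprint` objects (or dense count vectors) over the
#'   same dimension as `scaling`.
#' @param scaling A [compute_feature_scaling()] result for the dataset both
#'   molecules are compared within.
#' @param config A [similarity_config()].
#' @return Similarity score in [0, 1].
#' @examples
#' ds <- fingerprint_dataset(list(
#'   count_fingerprint("a", c(`0` = 2L, `2` = 1L), M = 3),
#'   count_fingerprint("b", c(`0` = 2L, `1` = 3L), M = 3)))
#' sc <- compute_feature_scaling(ds)
#' asmtp(get_fingerprint(ds, "a"), get_fingerprint(ds, "b"), sc,
#'       similarity_config(lam = 0.01))
#' @export
asmtp <- function(m1, m2, scaling, config = similarity_config()) {
  x <- .as_count_vector(m1)
  y <- .as_count_vector(m2)
  if (length(x) != length(y)) stop("dimension mismatch between fingerprints",
                                   call. = FALSE)
  if (!inherits(scaling, "feature_scaling") || length(scaling$mu) != length(x)) {
    stop("dimension mismatch between fingerprints and scaling", call. = FALSE)
  }
  lam <- config$lam
  both <- x > 0 & y > 0
  union <- sum(x > 0 | y > 0)
  if (union == 0L) {
    stop("degenerate input: both fingerprints are empty", call. = FALSE)
  }
  shared <- sum(0.5 * (1 + exp(-((x[both] - y[both]) / scaling$mu[both])^2)))
  # algebraically identical to ((shared - lam*mismatch)/union + lam)/(1+lam)
  # but exact at the boundaries: disjoint supports give 0, identity gives 1
  (shared + lam * sum(both)) / (union * (1 + lam))
}

# ASMTP of one dense query against every row of a sparse dataset matrix.
# Returns NA for rows whose union with the query is empty.
.asmtp_matrix <- function(q, X, mu, lam) {
  qi <- which(q > 0)
  a <- length(qi)
  nnz_row <- Matrix::rowSums(X != 0)
  n <- nrow(X)
  shared_sum <- numeric(n)
  shared_n <- integer(n)
  if (a > 0L) {
    sub <- methods::as(X[, qi, drop = FALSE], "TsparseMatrix")
    if (length(sub@x)) {
      qv <- q[qi][sub@j + 1L]
      sv <- mu[qi][sub@j + 1L]
      g <- 0.5 * (1 + exp(-((sub@x - qv) / sv)^2))
      agg <- rowsum(cbind(g, 1), sub@i + 1L)
      at <- as.integer(rownames(agg))
      shared_sum[at] <- agg[, 1L]
      shared_n[at] <- as.integer(agg[, 2L])
    }
  }
  union <- a + nnz_row - shared_n
  # same exact-boundary rearrangement as the pairwise form
  s <- (shared_sum + lam * shared_n) / (union * (1 + lam))
  s[union == 0] <- NA_real_
  as.numeric(s)
}

#' Tanimoto similarity, continuous form
#'
#' `sum(x*y) / (sum(x^2) + sum(y^2) - sum(x*y))` on the raw count vectors;
#' the standard fingerprint association coefficient for non-binary data
#' (identical to the extended Jaccard coefficient of the text-retrieval
#' literature).
#'
#' @inheritParams asmtp
#' @return Similarity in [0, 1].
#' @export
tanimoto_continuous <- function(m1, m2) {
  x <- .as_count_vector(m1); y <- .as_count_vector(m2)
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  dot <- sum(x * y)
  den <- sum(x^2) + sum(y^2) - dot
  if (den == 0) stop("degenerate input: both fingerprints are empty",
                     call. = FALSE)
  dot / den
}

#' Tanimoto similarity, binary form
#'
#' Counts are binarized to presence/absence and the classic `c / (a + b - c)`
#' is computed, where `a` and `b` are the on-bit counts of each molecule and
#' `c` the number of bits on in both.
#'
#' @inheritParams asmtp
#' @return Similarity in [0, 1].
#' @export
tanimoto_binary <- function(m1, m2) {
  x <- .as_count_vector(m1) > 0; y <- .as_count_vector(m2) > 0
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  a <- sum(x); b <- sum(y); cc <- sum(x & y)
  if (a + b == 0) stop("degenerate input: both fingerprints are empty",
                       call. = FALSE)
  cc / (a + b - cc)
}

#' Baseline similarity/distance coefficients
#'
#' The text-retrieval coefficients used as comparison baselines, evaluated on
#' the raw count vectors: Dice `2*x.y / (x.x + y.y)`, cosine, Euclidean
#' distance (smaller = more similar; rankings sort it ascending) and the
#' extended Jaccard coefficient (= continuous Tanimoto).
#'
#' @param name One of `"dice"`, `"cosine"`, `"euclidean"`,
#'   `"extended_jaccard"`.
#' @inheritParams asmtp
#' @return A similarity score, or a distance for `"euclidean"`.
#' @export
baseline_measure <- function(name = c("dice", "cosine", "euclidean",
                                      "extended_jaccard"), m1, m2) {
  name <- match.arg(name)
  x <- .as_count_vector(m1); y <- .as_count_vector(m2)
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  dot <- sum(x * y); xx <- sum(x^2); yy <- sum(y^2)
  switch(name,
    dice = {
      if (xx + yy == 0) stop("degenerate input: both fingerprints are empty",
                             call. = FALSE)
      2 * dot / (xx + yy)
    },
    cosine = {
      if (xx == 0 || yy == 0) {
        stop("degenerate input: zero-norm vector for cosine", call. = FALSE)
      }
      dot / (sqrt(xx) * sqrt(yy))
    },
    euclidean = sqrt(xx + yy - 2 * dot),
    extended_jaccard = tanimoto_continuous(x, y)
  )
}

# ---- measure registry ------------------------------------------------------

# Each entry: pairwise(x, y, ctx), matrix(q, X, ctx) -> scores per row
# (NA = degenerate), distance flag. ctx carries $scaling and $lam.
.measures <- local({
  dot_stats <- function(q, X) {
    list(dot = as.numeric(X %*% q), xx = Matrix::rowSums(X^2), qq = sum(q^2))
  }
  list(
    asmtp = list(
      distance = FALSE,
      pairwise = function(x, y, ctx)
        asmtp(x, y, ctx$scaling, similarity_config(ctx$lam, ctx$scaling$mode)),
      matrix = function(q, X, ctx) .asmtp_matrix(q, X, ctx$scaling$mu, ctx$lam)
    ),
    tanimoto = list(
      distance = FALSE,
      pairwise = function(x, y, ctx) tanimoto_continuous(x, y),
      matrix = function(q, X, ctx) {
        s <- dot_stats(q, X)
        den <- s$xx + s$qq - s$dot
        out <- s$dot / den
        out[den == 0] <- NA_real_
        out
      }
    ),
    tanimoto_binary = list(
      distance = FALSE,
      pairwise = function(x, y, ctx) tanimoto_binary(x, y),
      matrix = function(q, X, ctx) {
        qb <- as.numeric(q > 0)
        B <- X != 0
        cc <- as.numeric(B %*% qb)
        den <- sum(qb) + Matrix::rowSums(B) - cc
        out <- cc / den
        out[den == 0] <- NA_real_
        out
      }
    ),
    dice = list(
      distance = FALSE,
      pairwise = function(x, y, ctx) baseline_measure("dice", x, y),
      matrix = function(q, X, ctx) {
        s <- dot_stats(q, X)
        den <- s$xx + s$qq
        out <- 2 * s$dot / den
        out[den == 0] <- NA_real_
        out
      }
    ),
    cosine = list(
      distance = FALSE,
      pairwise = function(x, y, ctx) baseline_measure("cosine", x, y),
      matrix = function(q, X, ctx) {
        s <- dot_stats(q, X)
        den <- sqrt(s$xx) * sqrt(s$qq)
        out <- s$dot / den
        out[den == 0] <- NA_real_
        out
      }
    ),
    euclidean = list(
      distance = TRUE,
      pairwise = function(x, y, ctx) baseline_measure("euclidean", x, y),
      matrix = function(q, X, ctx) {
        s <- dot_stats(q, X)
        sqrt(pmax(s$xx + s$qq - 2 * s$dot, 0))
      }
    ),
    extended_jaccard = list(
      distance = FALSE,
      pairwise = function(x, y, ctx) baseline_measure("extended_jaccard", x, y),
      matrix = function(q, X, ctx) {
        s <- dot_stats(q, X)
        den <- s$xx + s$qq - s$dot
        out <- s$dot / den
        out[den == 0] <- NA_real_
        out
      }
    )
  )
})

#' Registered similarity measure names
#'
#' @return Character vector of names accepted wherever a `measure` argument
#'   appears: `asmtp`, `tanimoto`, `tanimoto_binary`, `dice`, `cosine`,
#'   `euclidean`, `extended_jaccard`.
#' @export
similarity_measures <- function() names(.measures)

.get_measure <- function(name) {
  m <- .measures[[name]]
  if (is.null(m)) {
    stop("unknown measure '", name, "'; available: ",
         paste(similarity_measures(), collapse = ", "), call. = FALSE)
  }
  m
}

#' Is a registered measure a distance?
#'
#' Distances (currently only `euclidean`) rank ascending; similarities rank
#' descending.
#' @param measure Measure name, see [similarity_measures()].
#' @export
is_distance_measure <- function(measure) .get_measure(measure)$distance
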