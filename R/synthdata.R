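#' Synthetic dataset configuration
#'
#' Describes a class-structured sparse count-fingerprint world with the
#' statistical shape of folded circular count fingerprints: ~90% of the
#' features of any molecule are zero, each activity class shares a random
#' "core" set of features that its actives carry with probability
#' `core_retention`, and the remaining non-zero features are background
#' noise. Decoys carry background features only. Non-zero counts follow a
#' shifted geometric law (heavy-tailed, mean `count_mean`).
#'
#' `core_retention` controls structural homogeneity: 0.9 emulates a
#' homogeneous activity class (members closely related), 0.5 a heterogeneous
#' one.
#'
#' @param M Feature dimension (default 1024).
#' @param n_classes Number of activity classes (default 5).
#' @param actives_per_class Actives per class (default 50).
#' @param n_decoys Unlabelled decoy molecules (default 2000).
#' @param sparsity Target per-molecule zero fraction in (0, 1), default 0.90.
#' @param class_core_size Features in each class core (default 60).
#' @param core_retention Probability an active keeps each core feature
#'   (default 0.9).
#' @param count_mean Mean of the positive count distribution (default 2).
#' @param seed Integer seed (default 1).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(M = 1024L, n_classes = 5L, actives_per_class = 50L,
                         n_decoys = 2000L, sparsity = 0.90,
                         class_core_size = 60L, core_retention = 0.9,
                         count_mean = 2, seed = 1L) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("`M` must be positive", call. = FALSE)
  if (sparsity <= 0 || sparsity >= 1) stop("`sparsity` must be in (0, 1)",
                                           call. = FALSE)
  if (core_retention < 0 || core_retention > 1) {
    stop("`core_retention` must be in [0, 1]", call. = FALSE)
  }
  if (count_mean < 1) stop("`count_mean` must be >= 1", call. = FALSE)
  n_nz <- as.integer(round(M * (1 - sparsity)))
  if (n_nz < 1L) stop("infeasible config: sparsity leaves no non-zero budget",
                      call. = FALSE)
  if (class_core_size > n_nz) {
    stop(sprintf(
      "infeasible config: class_core_size (%d) exceeds the per-molecule ",
      class_core_size), "non-zero budget (", n_nz, ")", call. = FALSE)
  }
  if (n_classes * class_core_size > M) {
    stop("infeasible config: class cores would exceed the feature space",
         call. = FALSE)
  }
  structure(
    list(M = M, n_classes = as.integer(n_classes),
         actives_per_class = as.integer(actives_per_class),
         n_decoys = as.integer(n_decoys), sparsity = sparsity,
         class_core_size = as.integer(class_core_size),
         core_retention = core_retention, count_mean = count_mean,
         seed = as.integer(seed), n_nonzero = n_nz),
    class = "synth_config"
  )
}

#' Preset retention levels for class homogeneity
#'
#' Convenience presets: structurally homogeneous classes (members closely
#' related, retention 0.9) versus heterogeneous ones (diverse members,
#' retention 0.5).
#' @param kind `"homogeneous"` or `"heterogeneous"`.
#' @return Core-retention probability.
#' @export
retention_preset <- function(kind = c("homogeneous", "heterogeneous")) {
  switch(match.arg(kind), homogeneous = 0.9, heterogeneous = 0.5)
}

# positive counts: 1 + geometric, mean = count_mean
.draw_counts <- function(n, count_mean) {
  if (count_mean == 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / count_mean)
}

#' Generate a synthetic fingerprint dataset
#'
#' Draws, deterministically under `config$seed`: one disjoint random core
#' feature set per class; for each active, the core features it retains
#' (each kept with probability `core_retention`) plus uniform background
#' features (outside every core) filling the molecule up to its non-zero
#' budget `round(M * (1 - sparsity))`; for each decoy, background features
#' only. All retained features receive shifted-geometric counts. Every
#' molecule therefore has exactly the target non-zero fraction, and actives
#' of one class overlap heavily on their core, which is what similarity
#' screening must detect.
#'
#' @param config A [synth_config()].
#' @return A [fingerprint_dataset()]; actives are labelled `class01`, ...,
#'   decoys have `NA` class.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    M <- config$M
    n_nz <- config$n_nonzero
    all_feat <- seq_len(M) - 1L  # 0-based
    cores <- list()
    pool <- all_feat
    for (k in seq_len(config$n_classes)) {
      core <- sort(sample(pool, config$class_core_size))
      cores[[k]] <- core
      pool <- setdiff(pool, core)
    }
    background <- pool  # features outside every class core
    fps <- list()
    cls <- character(0)
    for (k in seq_len(config$n_classes)) {
      label <- sprintf("class%02d", k)
      for (i in seq_len(config$actives_per_class)) {
        keep <- cores[[k]][stats::runif(config$class_core_size) <
                             config$core_retention]
        n_bg <- n_nz - length(keep)
        feats <- sort(c(keep, sample(background, n_bg)))
        cnt <- .draw_counts(length(feats), config$count_mean)
        names(cnt) <- feats
        id <- sprintf("%s_A%04d", label, i)
        fps[[id]] <- count_fingerprint(id, cnt, M = M)
        cls <- c(cls, label)
      }
    }
    for (i in seq_len(config$n_decoys)) {
      feats <- sort(sample(background, n_nz))
      cnt <- .draw_counts(length(feats), config$count_mean)
      names(cnt) <- feats
      id <- sprintf("DEC_%05d", i)
      fps[[id]] <- count_fingerprint(id, cnt, M = M)
      cls <- c(cls, NA_character_)
    }
    fingerprint_dataset(unname(fps), activity_class = cls)
  })
}
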