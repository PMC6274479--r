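#' Recall of actives at a percentage cutoff
#'
#' The fraction (in percent) of a class's actives retrieved in the top
#' `pct`% of the ranked database. The selection size is
#' `k = max(1, round(pct * N / 100))` with banker's rounding (round-half-even,
#' R's default); ties at the k-th position are resolved by the ranking's own
#' deterministic order, not fractionally.
#'
#' @param ranking A `ranking` (see [rank_database()]).
#' @param actives Character vector of active molecule ids (subset of the
#'   ranked database).
#' @param pct Cutoff percentage in (0, 100].
#' @return Recall in [0, 100].
#' @export
recall_at_cutoff <- function(ranking, actives, pct) {
  .check_actives(ranking, actives)
  if (length(pct) != 1L || pct <= 0 || pct > 100) {
    stop("`pct` must lie in (0, 100]", call. = FALSE)
  }
  k <- max(1L, as.integer(round(pct * ranking$n / 100)))
  100 * sum(ranking$ids[seq_len(k)] %in% actives) / length(actives)
}

.check_actives <- function(ranking, actives) {
  if (!length(actives)) stop("`actives` must be non-empty", call. = FALSE)
  if (!all(actives %in% ranking$ids)) {
    stop("`actives` must be a subset of the ranked database", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sensitivity and specificity of a top-k selection
#'
#' Treating the top `k` ranked molecules as "selected", sensitivity is
#' `TP / (TP + FN)` (truly active compounds selected) and specificity is
#' `TN / (TN + FP)` (truly inactive compounds correctly discarded).
#'
#' @inheritParams recall_at_cutoff
#' @param k Selection size, `0 <= k <= N`.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sensitivity_specificity <- function(ranking, actives, k) {
  .check_actives(ranking, actives)
  A <- length(unique(actives))
  I <- ranking$n - A
  if (I == 0L) stop("no inactives in the database", call. = FALSE)
  if (k < 0 || k > ranking$n) stop("`k` must lie in [0, N]", call. = FALSE)
  sel <- ranking$ids[seq_len(k)]
  tp <- sum(sel %in% actives)
  fp <- k - tp
  c(sensitivity = tp / A, specificity = (I - fp) / I)
}

#' ROC curve and AUC of a ranking
#'
#' Traces the receiver operating characteristic by descending score
#' threshold (ascending for distance rankings); molecules with exactly equal
#' scores enter as a single threshold step, and the area under the curve is
#' computed with the trapezoid rule, which credits ties one half each. An
#' AUC of 1 means every active outranks every inactive.
#'
#' @inheritParams recall_at_cutoff
#' @param max_fpr Optional truncation: only the ROC segment with false
#'   positive rate `<= max_fpr` is kept and the area is normalised by
#'   `max_fpr` (non-default alternative reading of "ROC at a cutoff").
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(ranking, actives, max_fpr = NULL) {
  .check_actives(ranking, actives)
  lab <- ranking$ids %in% actives
  A <- sum(lab)
  I <- ranking$n - A
  if (A == 0L || I == 0L) {
    stop("ROC needs at least one active and one inactive", call. = FALSE)
  }
  sc <- if (ranking$distance) -ranking$scores else ranking$scores
  last <- !duplicated(sc, fromLast = TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(lab)[last] / A)
  fpr <- c(0, cumsum(!lab)[last] / I)
  if (!is.null(max_fpr)) {
    if (max_fpr <= 0 || max_fpr > 1) stop("`max_fpr` must be in (0, 1]",
                                          call. = FALSE)
    keep <- fpr <= max_fpr
    # interpolate the crossing point so the truncated area is well defined
    if (any(!keep)) {
      i <- which(!keep)[1L]
      t <- (max_fpr - fpr[i - 1L]) / (fpr[i] - fpr[i - 1L])
      fpr <- c(fpr[keep], max_fpr)
      tpr <- c(tpr[keep], tpr[i - 1L] + t * (tpr[i] - tpr[i - 1L]))
    }
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2) /
      max_fpr
  } else {
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Enrichment factor at a percentage cutoff
#'
#' `EF = (a / k) / (A / N)`: the concentration of actives in the top `pct`%
#' of the ranking relative to their concentration in the whole database;
#' `k` is chosen exactly as in [recall_at_cutoff()]. Selecting the whole
#' database gives EF = 1 by construction.
#'
#' @inheritParams recall_at_cutoff
#' @return Enrichment factor `>= 0`.
#' @export
enrichment_factor <- function(ranking, actives, pct) {
  .check_actives(ranking, actives)
  if (length(pct) != 1L || pct <= 0 || pct > 100) {
    stop("`pct` must lie in (0, 100]", call. = FALSE)
  }
  N <- ranking$n
  A <- length(unique(actives))
  k <- max(1L, as.integer(round(pct * N / 100)))
  a <- sum(ranking$ids[seq_len(k)] %in% actives)
  (a / k) / (A / N)
}

#' BEDROC early-recognition score
#'
#' Boltzmann-enhanced discrimination of ROC (Truchon & Bayly): active ranks
#' are weighted exponentially, `exp(-alpha * r / N)`, so actives retrieved
#' very early dominate the score. With `R_a = A / N`,
#' `RIE = sum_i exp(-alpha r_i / N) / (R_a (1 - e^{-alpha}) / (e^{alpha/N} - 1))`
#' and
#' `BEDROC = RIE * R_a sinh(alpha/2) / (cosh(alpha/2) - cosh(alpha/2 - alpha R_a))
#'   + 1 / (1 - e^{alpha (1 - R_a)})`,
#' bounded in [0, 1]. `alpha = 20` focuses on roughly the first 8% of the
#' list and is the conventional reporting choice.
#'
#' @inheritParams recall_at_cutoff
#' @param alpha Early-recognition exponent (> 0), default 20.
#' @return BEDROC score in [0, 1].
#' @export
bedroc <- function(ranking, actives, alpha = 20) {
  .check_actives(ranking, actives)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  N <- ranking$n
  r <- which(ranking$ids %in% actives)
  A <- length(r)
  if (A == N) stop("BEDROC undefined when every molecule is active",
                   call. = FALSE)
  ra <- A / N
  rie <- sum(exp(-alpha * r / N)) /
    (ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  b <- rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
  # the closed form overshoots 1 by ~1e-15 at a perfect ranking; clamp
  min(max(b, 0), 1)
}

#' Evaluate a screening run
#'
#' Computes, for every ranking of a [screen()] result, the recall at each
#' configured cutoff, the full-ranking AUC, the enrichment factor at
#' `ef_pct`% and BEDROC; then averages per class over that class's
#' references. The actives of a query are all database molecules sharing its
#' activity class; by the inclusive convention the reference itself stays in
#' both the database and the active set (set `exclude_references = TRUE` to
#' drop each query from its own active set instead).
#'
#' @param result A [screen()] result (or a list of `ranking` objects each
#'   carrying an `activity_class`, plus `cutoffs`).
#' @param dataset The screened [fingerprint_dataset()].
#' @param cutoffs Recall cutoffs (percent); defaults to the screen config's.
#' @param ef_pct Enrichment-factor cutoff (default 1).
#' @param alpha BEDROC exponent (default 20).
#' @param exclude_references Drop the query from its own active set.
#' @return An `evaluation_report`: `per_query` and `per_class` data frames,
#'   `overall` (mean and median over classes of each metric), `measure`.
#' @export
evaluate_screen <- function(result, dataset, cutoffs = NULL, ef_pct = 1,
                            alpha = 20, exclude_references = FALSE) {
  rankings <- if (inherits(result, "screen_result")) result$rankings else
    result
  if (is.null(cutoffs)) {
    cutoffs <- if (inherits(result, "screen_result"))
      result$config$cutoffs else c(1, 5)
  }
  if (!length(rankings)) stop("no rankings to evaluate", call. = FALSE)
  ids <- molecule_ids(dataset)
  rows <- lapply(rankings, function(r) {
    if (is.null(r$activity_class) || is.na(r$activity_class)) {
      stop("ranking for query ", r$query_id, " has no activity class",
           call. = FALSE)
    }
    if (!setequal(r$ids, ids)) {
      stop("ranking and dataset molecule universes differ", call. = FALSE)
    }
    actives <- ids[!is.na(dataset$activity_class) &
                     dataset$activity_class == r$activity_class]
    if (exclude_references) actives <- setdiff(actives, r$query_id)
    rec <- vapply(cutoffs, function(p) recall_at_cutoff(r, actives, p),
                  numeric(1))
    out <- data.frame(measure = r$measure, class = r$activity_class,
                      query_id = r$query_id, stringsAsFactors = FALSE)
    for (i in seq_along(cutoffs)) {
      out[[sprintf("recall_%g", cutoffs[i])]] <- rec[i]
    }
    out$auc <- roc_auc(r, actives)$auc
    out[[sprintf("ef_%g", ef_pct)]] <- enrichment_factor(r, actives, ef_pct)
    out$bedroc <- bedroc(r, actives, alpha)
    out
  })
  per_query <- do.call(rbind, rows)
  rownames(per_query) <- NULL
  metric_cols <- setdiff(names(per_query), c("measure", "class", "query_id"))
  per_class <- stats::aggregate(per_query[metric_cols],
                                by = list(measure = per_query$measure,
                                          class = per_query$class),
                                FUN = mean)
  per_class <- per_class[order(per_class$class), , drop = FALSE]
  rownames(per_class) <- NULL
  overall <- data.frame(
    measure = per_class$measure[1L],
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_class[[m]]), numeric(1)),
    median = vapply(metric_cols, function(m) stats::median(per_class[[m]]),
                    numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(overall) <- NULL
  structure(
    list(per_query = per_query, per_class = per_class, overall = overall,
         measure = per_query$measure[1L], cutoffs = cutoffs),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s over %d classes\n", x$measure,
              nrow(x$per_class)))
  print(x$overall)
  invisible(x)
}

#' Summarize evaluation reports across measures
#'
#' Joins per-class results of several measures evaluated on identical query
#' sets, and tallies for each metric how many classes each measure "wins"
#' (attains the maximum per-class mean; ties credit every tied measure --
#' the "shaded cells" convention of screening comparison tables). Euclidean
#' AUC/recall are compared like any other measure; note its per-query values
#' already account for ascending ranking.
#'
#' @param reports List of `evaluation_report` objects, one per measure.
#' @return An `evaluation_summary`: `per_class` (long), `overall` (long),
#'   `best_per_class` (measure x metric counts).
#' @export
summarize_evaluations <- function(reports) {
  if (!length(reports)) stop("no reports given", call. = FALSE)
  keysets <- lapply(reports, function(r)
    sort(paste(r$per_query$class, r$per_query$query_id), method = "radix"))
  if (length(unique(keysets)) != 1L) {
    stop("reports were not evaluated on identical query sets", call. = FALSE)
  }
  per_class <- do.call(rbind, lapply(reports, `[[`, "per_class"))
  overall <- do.call(rbind, lapply(reports, `[[`, "overall"))
  rownames(per_class) <- rownames(overall) <- NULL
  metric_cols <- setdiff(names(per_class), c("measure", "class"))
  measures <- unique(per_class$measure)
  best <- expand.grid(measure = measures, metric = metric_cols,
                      stringsAsFactors = FALSE)
  best$n_best <- 0L
  for (cl in unique(per_class$class)) {
    sub <- per_class[per_class$class == cl, , drop = FALSE]
    for (mc in metric_cols) {
      winners <- sub$measure[sub[[mc]] == max(sub[[mc]])]
      sel <- best$metric == mc & best$measure %in% winners
      best$n_best[sel] <- best$n_best[sel] + 1L
    }
  }
  structure(
    list(per_class = per_class, overall = overall, best_per_class = best),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("<evaluation_summary>\n")
  print(x$overall)
  cat("best-per-class tallies:\n")
  print(x$best_per_class)
  invisible(x)
}

#' Write an evaluation report as tidy CSV
#'
#' Long format, one metric value per row:
#' `measure,class,query_id,metric,cutoff,value`. Per-class rows use
#' `query_id = ""` (the mean over the class's references).
#'
#' @param report An `evaluation_report`.
#' @param path Output CSV path.
#' @export
write_evaluation <- function(report, path) {
  tidy_block <- function(df, qcol) {
    metric_cols <- setdiff(names(df), c("measure", "class", "query_id"))
    blocks <- lapply(metric_cols, function(mc) {
      parts <- strsplit(mc, "_", fixed = TRUE)[[1L]]
      cutoff <- if (length(parts) > 1L &&
                    !is.na(suppressWarnings(as.numeric(parts[2L]))))
        parts[2L] else ""
      data.frame(measure = df$measure, class = df$class,
                 query_id = qcol(df),
                 metric = parts[1L], cutoff = cutoff, value = df[[mc]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  }
  pq <- tidy_block(report$per_query, function(d) d$query_id)
  pc <- tidy_block(report$per_class, function(d) rep("", nrow(d)))
  out <- rbind(pq, pc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
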