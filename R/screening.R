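#' Screening run configuration
#'
#' Bundles the knobs of the simulated virtual-screening protocol: how many
#' reference structures are drawn per activity class (10 in the published
#' protocol), the random seed driving that draw, the recall cutoffs (percent
#' of the ranked database), the similarity measure, and the ASMTP penalty
#' `lambda` / scaling mode.
#'
#' @param n_references References drawn per class (default 10).
#' @param seed Integer seed; the same seed reproduces the same reference
#'   draw, and the draw does not depend on the measure, so different
#'   measures screened under one seed use identical (unified) references.
#' @param cutoffs Percentage cutoffs in (0, 100] (default `c(1, 5)`).
#' @param measure Measure name, see [similarity_measures()].
#' @param lam ASMTP mismatch penalty (default `1e-4`).
#' @param scaling_mode Scaling for ASMTP's Gaussian term, see
#'   [compute_feature_scaling()].
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_references = 10L, seed = 1L, cutoffs = c(1, 5),
                          measure = "asmtp", lam = 1e-4,
                          scaling_mode = c("nonzero-mean", "nonzero-stddev")) {
  scaling_mode <- match.arg(scaling_mode)
  .get_measure(measure)
  n_references <- as.integer(n_references)
  if (is.na(n_references) || n_references < 1L) {
    stop("`n_references` must be >= 1", call. = FALSE)
  }
  if (!length(cutoffs) || any(cutoffs <= 0) || any(cutoffs > 100)) {
    stop("`cutoffs` must lie in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(lam) || lam <= 0) stop("`lam` must be positive",
                                         call. = FALSE)
  structure(
    list(n_references = n_references, seed = as.integer(seed),
         cutoffs = as.numeric(cutoffs), measure = measure, lam = lam,
         scaling_mode = scaling_mode),
    class = "screen_config"
  )
}

# Deterministic per-class seed so every class draws an independent stream
# while the overall run stays reproducible and measure-independent.
.class_seed <- function(seed, dataset, activity_class) {
  classes <- active_classes(dataset)
  k <- match(activity_class, classes)
  if (is.na(k)) stop("unknown activity class: ", activity_class, call. = FALSE)
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Randomly select reference structures from an activity class
#'
#' Draws `n` distinct actives of the class under a seeded generator. The
#' draw depends only on the dataset, class and seed -- never on the
#' similarity measure -- so the selection is "unified": every measure
#' screened with the same seed queries the same references.
#'
#' @param dataset A [fingerprint_dataset()].
#' @param activity_class Class label to draw from.
#' @param n Number of references (default 10).
#' @param seed Integer seed.
#' @return Character vector of `n` molecule ids, sorted.
#' @export
select_references <- function(dataset, activity_class, n = 10L, seed = 1L) {
  if (!activity_class %in% active_classes(dataset)) {
    stop("unknown activity class: ", activity_class, call. = FALSE)
  }
  members <- molecule_ids(dataset)[
    !is.na(dataset$activity_class) & dataset$activity_class == activity_class]
  if (length(members) < n) {
    stop(sprintf("class '%s' has %d actives, fewer than n = %d",
                 activity_class, length(members), n), call. = FALSE)
  }
  members <- sort(members, method = "radix")
  picked <- withr::with_seed(
    .class_seed(seed, dataset, activity_class),
    sample(members, n)
  )
  sort(picked, method = "radix")
}

#' Rank a database against one query fingerprint
#'
#' Scores every molecule of the database (including the query itself, if
#' present) with the requested measure and returns the full ranking:
#' decreasing score order for similarities, increasing for distances, ties
#' broken by ascending molecule id so the ordering is deterministic. A
#' database molecule whose pair with the query is degenerate for the measure
#' (e.g. an empty fingerprint under cosine) is warned about and placed at
#' the bottom of the ranking.
#'
#' @param query A `count_fingerprint` (typically a reference structure from
#'   the database).
#' @param dataset The [fingerprint_dataset()] to rank.
#' @param measure Measure name, see [similarity_measures()].
#' @param scaling [compute_feature_scaling()] result for `dataset`; required
#'   for `measure = "asmtp"`, ignored otherwise.
#' @param config A [screen_config()] (supplies `lam`); optional.
#' @return An object of class `ranking`: fields `query_id`, `measure`, `ids`
#'   (ranked molecule ids, a permutation of the database), `scores` (aligned
#'   with `ids`), `distance`, `n`.
#' @export
rank_database <- function(query, dataset, measure = "asmtp", scaling = NULL,
                          config = NULL) {
  m <- .get_measure(measure)
  lam <- if (!is.null(config)) config$lam else 1e-4
  if (inherits(query, "count_fingerprint") && query$M != dataset$M) {
    stop("dimension mismatch between query and dataset", call. = FALSE)
  }
  q <- .as_count_vector(query)
  if (identical(measure, "asmtp")) {
    if (is.null(scaling)) {
      stop("asmtp requires `scaling` computed on the dataset", call. = FALSE)
    }
    if (length(scaling$mu) != dataset$M) {
      stop("scaling dimension does not match dataset", call. = FALSE)
    }
  }
  ctx <- list(scaling = scaling, lam = lam)
  scores <- m$matrix(q, dataset$counts, ctx)
  ids <- molecule_ids(dataset)
  bad <- is.na(scores)
  if (any(bad)) {
    warning(sum(bad), " molecule(s) degenerate under '", measure,
            "'; ranked last", call. = FALSE)
    scores[bad] <- if (m$distance) Inf else -Inf
  }
  key <- if (m$distance) scores else -scores
  o <- order(key, ids, method = "radix")
  qid <- if (inherits(query, "count_fingerprint")) query$molecule_id else
    "<query>"
  structure(
    list(query_id = qid, measure = measure, ids = ids[o],
         scores = as.numeric(scores[o]), distance = m$distance,
         n = length(ids)),
    class = "ranking"
  )
}

#' @export
print.ranking <- function(x, ...) {
  cat(sprintf("<ranking> query %s under %s: %d molecules, top: %s (%.4f)\n",
              x$query_id, x$measure, x$n, x$ids[1L], x$scores[1L]))
  invisible(x)
}

#' Run the full simulated screening protocol
#'
#' For every activity class of the dataset, draws `n_references` random
#' actives (seeded, unified across measures) and ranks the whole database
#' against each of them with the configured measure. Feature scaling for
#' ASMTP is computed once over the entire database, references included.
#'
#' @param dataset A [fingerprint_dataset()] with at least one activity class.
#' @param config A [screen_config()].
#' @return An object of class `screen_result`: `rankings` (flat named list,
#'   one per class x reference, each carrying `activity_class`), `references`
#'   (per-class id vectors), `config`, `scaling`.
#' @export
screen <- function(dataset, config = screen_config()) {
  classes <- active_classes(dataset)
  if (!length(classes)) stop("dataset has no labelled activity classes",
                             call. = FALSE)
  scaling <- if (identical(config$measure, "asmtp")) {
    compute_feature_scaling(dataset, config$scaling_mode)
  } else NULL
  refs <- lapply(classes, function(cl) {
    select_references(dataset, cl, n = config$n_references,
                      seed = config$seed)
  })
  names(refs) <- classes
  rankings <- list()
  for (cl in classes) {
    for (rid in refs[[cl]]) {
      r <- rank_database(get_fingerprint(dataset, rid), dataset,
                         measure = config$measure, scaling = scaling,
                         config = config)
      r$activity_class <- cl
      rankings[[paste(cl, rid, sep = "/")]] <- r
    }
  }
  structure(
    list(rankings = rankings, references = refs, config = config,
         scaling = scaling),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: %d rankings (%d classes x %d references)\n",
              x$config$measure, length(x$rankings), length(x$references),
              x$config$n_references))
  invisible(x)
}

#' Serialize screening rankings to CSV
#'
#' One row per (query, rank): `query_id,measure,rank,molecule_id,score`.
#'
#' @param result A [screen()] result.
#' @param path Output CSV path.
#' @export
write_rankings <- function(result, path) {
  dfs <- lapply(result$rankings, function(r) {
    data.frame(query_id = r$query_id, measure = r$measure,
               rank = seq_len(r$n), molecule_id = r$ids, score = r$scores,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read rankings written by [write_rankings()]
#'
#' Query classes are recovered from the dataset's labels; the rankings are
#' validated against the dataset (same molecule universe).
#'
#' @param path Rankings CSV.
#' @param dataset The [fingerprint_dataset()] the rankings were computed on.
#' @return Named list of `ranking` objects.
#' @export
read_rankings <- function(path, dataset) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(query_id = "character",
                                       molecule_id = "character"))
  need <- c("query_id", "measure", "rank", "molecule_id", "score")
  if (!all(need %in% names(df))) stop("malformed rankings file: ", path,
                                      call. = FALSE)
  ids <- sort(molecule_ids(dataset), method = "radix")
  out <- list()
  for (key in unique(paste(df$measure, df$query_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- df[df$measure == parts[1L] & df$query_id == parts[2L], ]
    sub <- sub[order(sub$rank), ]
    if (!identical(sort(sub$molecule_id, method = "radix"), ids)) {
      stop("rankings do not match the dataset (molecule universe differs)",
           call. = FALSE)
    }
    qid <- parts[2L]
    cl <- unname(dataset$activity_class[qid])
    r <- structure(
      list(query_id = qid, measure = parts[1L], ids = sub$molecule_id,
           scores = sub$score, distance = is_distance_measure(parts[1L]),
           n = nrow(sub), activity_class = cl),
      class = "ranking"
    )
    out[[paste(cl, qid, sep = "/")]] <- r
  }
  out
}
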