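#' Construct a count fingerprint
#'
#' A count fingerprint is a fixed-length vector of non-negative integer
#' feature counts, stored sparsely: only strictly positive counts are kept,
#' indexed by their 0-based feature position. This is the natural container
#' for folded circular count fingerprints (ECFC-style), where typically ~90%
#' of features are zero.
#'
#' @param molecule_id Single character string identifying the molecule.
#' @param counts Named integer vector of strictly positive counts; names are
#'   0-based feature indices. Alternatively a dense integer vector of length
#'   `M` (zeros allowed, dropped on storage) when `dense = TRUE`.
#' @param M Feature dimension (default 1024).
#' @param dense If `TRUE`, `counts` is interpreted as a dense length-`M`
#'   vector.
#' @return An object of class `count_fingerprint` with fields `molecule_id`,
#'   `idx` (sorted 0-based indices), `count` (positive integer counts) and
#'   `M`.
#' @examples
#' fp <- count_fingerprint("mol1", c(`1` = 2L, `3` = 1L), M = 4)
#' as_dense(fp)
#' @export
count_fingerprint <- function(molecule_id, counts, M = 1024L, dense = FALSE) {
  if (!is.character(molecule_id) || length(molecule_id) != 1L ||
      is.na(molecule_id) || !nzchar(molecule_id)) {
    stop("`molecule_id` must be a single non-empty string", call. = FALSE)
  }
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("`M` must be a positive integer", call. = FALSE)
  if (dense) {
    if (length(counts) != M) {
      stop("dense `counts` must have length M = ", M, call. = FALSE)
    }
    idx <- which(counts != 0) - 1L
    cnt <- counts[idx + 1L]
  } else {
    if (length(counts) && is.null(names(counts))) {
      stop("sparse `counts` must be named by 0-based feature index",
           call. = FALSE)
    }
    idx <- as.integer(names(counts))
    cnt <- unname(counts)
  }
  cnt <- as.numeric(cnt)
  if (any(is.na(idx)) || any(idx < 0L) || any(idx >= M)) {
    stop("feature indices must lie in [0, M)", call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("duplicate feature indices", call. = FALSE)
  if (any(is.na(cnt)) || any(cnt <= 0) || any(cnt != floor(cnt))) {
    stop("stored counts must be strictly positive integers", call. = FALSE)
  }
  o <- order(idx)
  structure(
    list(molecule_id = molecule_id, idx = idx[o], count = as.integer(cnt[o]),
         M = M),
    class = "count_fingerprint"
  )
}

#' Dense view of a count fingerprint
#'
#' @param x A `count_fingerprint`.
#' @return Integer vector of length `x$M` with zeros at absent features.
#' @export
as_dense <- function(x) UseMethod("as_dense")

#' @export
as_dense.count_fingerprint <- function(x) {
  v <- integer(x$M)
  v[x$idx + 1L] <- x$count
  v
}

#' @export
print.count_fingerprint <- function(x, ...) {
  cat(sprintf("<count_fingerprint> %s: %d/%d non-zero features, total count %d\n",
              x$molecule_id, length(x$idx), x$M, sum(x$count)))
  invisible(x)
}

#' @export
format.count_fingerprint <- function(x, ...) {
  paste(sprintf("%d:%d", x$idx, x$count), collapse = " ")
}

#' Fold a fingerprint to a smaller feature dimension
#'
#' Maps each feature index to `index %% M` and sums counts at colliding
#' indices; the standard operation used to reduce an open-ended circular
#' fingerprint feature space to a fixed working dimension. Total count is
#' conserved, and folding to the current dimension is the identity.
#'
#' @param x A `count_fingerprint` or `fingerprint_dataset`.
#' @param M Target dimension, `1 <= M <= x$M`.
#' @return Object of the same class over dimension `M`.
#' @export
fold <- function(x, M) UseMethod("fold")

#' @export
fold.count_fingerprint <- function(x, M) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("target dimension M must be >= 1", call. = FALSE)
  if (M > x$M) stop("cannot fold to a larger dimension (M > source M)",
                    call. = FALSE)
  new_idx <- x$idx %% M
  agg <- rowsum(as.numeric(x$count), new_idx)
  cnt <- as.integer(agg[, 1L])
  names(cnt) <- rownames(agg)
  count_fingerprint(x$molecule_id, cnt, M = M)
}

#' @export
fold.fingerprint_dataset <- function(x, M) {
  fps <- lapply(molecule_ids(x), function(id) fold(get_fingerprint(x, id), M))
  fingerprint_dataset(fps, activity_class = unname(x$activity_class), M = M)
}

#' Assemble a fingerprint dataset
#'
#' A `fingerprint_dataset` is an ordered collection of molecules sharing one
#' feature dimension, held internally as a sparse molecules-by-features count
#' matrix; it is the unit over which per-feature scaling statistics are
#' computed and the database that screening ranks.
#'
#' @param fingerprints List of `count_fingerprint` objects with unique
#'   molecule ids and identical `M`.
#' @param activity_class Optional character vector of activity-class labels,
#'   one per molecule (`NA` marks decoys / unlabelled molecules).
#' @param M Feature dimension; required only for an empty dataset, otherwise
#'   taken from (and checked against) the member fingerprints.
#' @return An object of class `fingerprint_dataset` with fields `counts`
#'   (a `dgCMatrix`, rownames = molecule ids), `activity_class` (named) and
#'   `M`.
#' @export
fingerprint_dataset <- function(fingerprints, activity_class = NULL, M = NULL) {
  ok <- vapply(fingerprints, inherits, logical(1), "count_fingerprint")
  if (!all(ok)) stop("all elements must be count_fingerprint objects",
                     call. = FALSE)
  ids <- vapply(fingerprints, `[[`, character(1), "molecule_id")
  if (anyDuplicated(ids)) {
    stop("molecule ids must be unique within a dataset (duplicated: ",
         ids[duplicated(ids)][1L], ")", call. = FALSE)
  }
  Ms <- vapply(fingerprints, `[[`, integer(1), "M")
  if (length(fingerprints)) {
    if (length(unique(Ms)) != 1L) {
      stop("all fingerprints must share the same dimension M", call. = FALSE)
    }
    if (!is.null(M) && as.integer(M) != Ms[1L]) {
      stop("explicit M disagrees with member fingerprints", call. = FALSE)
    }
    M <- Ms[1L]
  } else {
    if (is.null(M)) stop("an empty dataset needs an explicit M", call. = FALSE)
    M <- as.integer(M)
  }
  nnz <- vapply(fingerprints, function(f) length(f$idx), integer(1))
  i <- rep.int(seq_along(fingerprints), nnz)
  j <- unlist(lapply(fingerprints, `[[`, "idx"), use.names = FALSE)
  v <- unlist(lapply(fingerprints, `[[`, "count"), use.names = FALSE)
  counts <- Matrix::sparseMatrix(
    i = i, j = j + 1L, x = as.numeric(v),
    dims = c(length(fingerprints), M),
    dimnames = list(ids, NULL)
  )
  if (is.null(activity_class)) {
    activity_class <- rep(NA_character_, length(ids))
  }
  if (length(activity_class) != length(ids)) {
    stop("activity_class must have one entry per molecule", call. = FALSE)
  }
  activity_class <- as.character(activity_class)
  names(activity_class) <- ids
  structure(
    list(counts = counts, activity_class = activity_class, M = M),
    class = "fingerprint_dataset"
  )
}

#' @export
print.fingerprint_dataset <- function(x, ...) {
  cls <- active_classes(x)
  cat(sprintf(
    "<fingerprint_dataset> %d molecules x %d features (%.1f%% zeros)\n",
    nrow(x$counts), x$M,
    100 * (1 - Matrix::nnzero(x$counts) / prod(dim(x$counts)))))
  if (length(cls)) {
    tab <- table(x$activity_class[!is.na(x$activity_class)])
    cat("  classes:",
        paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  cat("  decoys/unlabelled:", sum(is.na(x$activity_class)), "\n")
  invisible(x)
}

#' Molecule identifiers of a dataset, in stable order
#' @param dataset A `fingerprint_dataset`.
#' @export
molecule_ids <- function(dataset) rownames(dataset$counts)

#' Distinct activity-class labels present in a dataset
#'
#' Returns the sorted unique non-`NA` labels; molecules with `NA` labels are
#' treated as decoys.
#' @param dataset A `fingerprint_dataset`.
#' @export
active_classes <- function(dataset) {
  sort(unique(dataset$activity_class[!is.na(dataset$activity_class)]),
       method = "radix")
}

#' Number of molecules in a dataset
#' @param dataset A `fingerprint_dataset`.
#' @export
n_molecules <- function(dataset) nrow(dataset$counts)

#' Extract one molecule's fingerprint from a dataset
#' @param dataset A `fingerprint_dataset`.
#' @param molecule_id Identifier of the molecule to extract.
#' @return A `count_fingerprint`.
#' @export
get_fingerprint <- function(dataset, molecule_id) {
  if (!molecule_id %in% rownames(dataset$counts)) {
    stop("unknown molecule id: ", molecule_id, call. = FALSE)
  }
  row <- dataset$counts[molecule_id, ]
  idx <- which(row != 0)
  cnt <- as.integer(row[idx])
  names(cnt) <- idx - 1L
  count_fingerprint(molecule_id, cnt, M = dataset$M)
}

# Dense numeric row for one molecule (internal fast path).
.dense_row <- function(dataset, molecule_id) {
  as.numeric(dataset$counts[molecule_id, ])
}
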