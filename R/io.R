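#' Read count fingerprints from a delimited text file
#'
#' Two plain-text layouts are supported:
#' \describe{
#'   \item{`dense-csv`}{header `molecule_id,activity_class,f0,...,f{M-1}`,
#'     one integer count per feature column.}
#'   \item{`sparse-pairs`}{header `molecule_id,activity_class,features`; the
#'     third field holds space-separated `idx:count` pairs with ascending
#'     0-based indices (empty field = empty fingerprint).}
#' }
#' An empty `activity_class` field is read as `NA` (decoy / unlabelled).
#'
#' @param path Path to the file.
#' @param format `"dense-csv"` or `"sparse-pairs"`.
#' @param M Feature dimension; required for `sparse-pairs` (the dense header
#'   fixes it implicitly). If given for `dense-csv` it is checked.
#' @return A [fingerprint_dataset()].
#' @export
read_fingerprints <- function(path, format = c("sparse-pairs", "dense-csv"),
                              M = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file (missing header): ", path, call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  body <- body[nzchar(body)]

  if (format == "dense-csv") {
    if (length(header) < 2L || header[1L] != "molecule_id" ||
        header[2L] != "activity_class") {
      stop("malformed dense-csv header in ", path, call. = FALSE)
    }
    M_file <- length(header) - 2L
    if (!is.null(M) && M_file != M) {
      stop("dimension error: file has M=", M_file, ", expected ", M,
           call. = FALSE)
    }
    M <- M_file
    fps <- vector("list", length(body))
    cls <- character(length(body))
    for (k in seq_along(body)) {
      fields <- strsplit(body[k], ",", fixed = TRUE)[[1L]]
      if (length(fields) != M + 2L) {
        stop(sprintf("parse error at line %d: expected %d fields, got %d",
                     k + 1L, M + 2L, length(fields)), call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(fields[-(1:2)]))
      if (any(is.na(vals)) || any(vals < 0) || any(vals != floor(vals))) {
        stop(sprintf("parse error at line %d: counts must be non-negative integers",
                     k + 1L), call. = FALSE)
      }
      fps[[k]] <- count_fingerprint(fields[1L], as.integer(vals), M = M,
                                    dense = TRUE)
      cls[k] <- fields[2L]
    }
  } else {
    if (!identical(header, c("molecule_id", "activity_class", "features"))) {
      stop("malformed sparse-pairs header in ", path, call. = FALSE)
    }
    if (is.null(M)) {
      stop("`M` is required when reading sparse-pairs", call. = FALSE)
    }
    fps <- vector("list", length(body))
    cls <- character(length(body))
    for (k in seq_along(body)) {
      fields <- strsplit(body[k], ",", fixed = TRUE)[[1L]]
      if (length(fields) < 2L || length(fields) > 3L) {
        stop(sprintf("parse error at line %d: expected 3 fields", k + 1L),
             call. = FALSE)
      }
      feat <- if (length(fields) == 3L) fields[3L] else ""
      cnt <- .parse_pairs(feat, line = k + 1L)
      fps[[k]] <- tryCatch(
        count_fingerprint(fields[1L], cnt, M = M),
        error = function(e) {
          stop(sprintf("parse error at line %d: %s", k + 1L,
                       conditionMessage(e)), call. = FALSE)
        })
      cls[k] <- fields[2L]
    }
  }
  cls[!nzchar(cls)] <- NA_character_
  fingerprint_dataset(fps, activity_class = cls, M = M)
}

# "idx:count idx:count" -> named integer vector; validates syntax only,
# range/positivity checks happen in count_fingerprint().
.parse_pairs <- function(s, line) {
  s <- trimws(s)
  if (!nzchar(s)) return(stats::setNames(integer(0), character(0)))
  toks <- strsplit(s, " +")[[1L]]
  parts <- strsplit(toks, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop(sprintf("parse error at line %d: malformed idx:count pair", line),
         call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1L)))
  cnt <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (any(is.na(idx)) || any(is.na(cnt))) {
    stop(sprintf("parse error at line %d: non-numeric idx:count pair", line),
         call. = FALSE)
  }
  stats::setNames(cnt, idx)
}

#' Write count fingerprints to a delimited text file
#'
#' Inverse of [read_fingerprints()]; `read_fingerprints(write_fingerprints(d))`
#' reproduces `d` exactly for both formats.
#'
#' @param dataset A [fingerprint_dataset()].
#' @param path Output path.
#' @param format `"dense-csv"` or `"sparse-pairs"`.
#' @export
write_fingerprints <- function(dataset, path,
                               format = c("sparse-pairs", "dense-csv")) {
  format <- match.arg(format)
  ids <- molecule_ids(dataset)
  cls <- dataset$activity_class
  cls[is.na(cls)] <- ""
  if (format == "dense-csv") {
    header <- paste(c("molecule_id", "activity_class",
                      paste0("f", seq_len(dataset$M) - 1L)), collapse = ",")
    dense <- as.matrix(dataset$counts)
    rows <- vapply(seq_along(ids), function(k) {
      paste(c(ids[k], cls[k], format(dense[k, ], scientific = FALSE,
                                     trim = TRUE)),
            collapse = ",")
    }, character(1))
  } else {
    header <- "molecule_id,activity_class,features"
    rows <- vapply(seq_along(ids), function(k) {
      fp <- get_fingerprint(dataset, ids[k])
      paste(ids[k], cls[k], format(fp), sep = ",")
    }, character(1))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Convert SMILES structures to folded circular count fingerprints
#'
#' Optional adapter that shells out to a local `python` with RDKit installed
#' and computes hashed Morgan count fingerprints of radius 2 (the open-source
#' analogue of ECFC_4), folded to `M` features. This approximates, but does
#' not reproduce, commercial ECFC_4 pipelines; fingerprints from different
#' toolkits are not interchangeable.
#'
#' @param path Text file with one molecule per line: `id<TAB>smiles`.
#' @param M Target folded dimension (default 1024).
#' @param python Python interpreter to invoke (must have `rdkit`).
#' @return A [fingerprint_dataset()] with all activity classes `NA`.
#' @export
smiles_to_fingerprints <- function(path, M = 1024L, python = "python") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  script <- system.file("python", "smiles_fp.py", package = "asmtp",
                        mustWork = TRUE)
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(out), add = TRUE)
  status <- system2(python, c(script, shQuote(path), as.integer(M),
                              shQuote(out)),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) {
    stop("SMILES fingerprint adapter failed (is rdkit available?)",
         call. = FALSE)
  }
  read_fingerprints(out, format = "sparse-pairs", M = M)
}
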