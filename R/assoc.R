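#' Build a labeled binary association matrix from an edge table
#'
#' Converts a long table of (microbe, disease) pairs into the dense 0/1
#' association matrix the pipeline consumes. Row order is the first appearance
#' of each microbe, column order the first appearance of each disease;
#' duplicated pairs collapse to a single 1. Names are matched exactly after
#' trimming surrounding whitespace.
#'
#' @param edges A data frame whose first two columns (or the columns named by
#'   `microbe_col` / `disease_col`) hold microbe and disease names.
#' @param microbe_col,disease_col Column names; default to the first two
#'   columns.
#' @return A numeric 0/1 matrix with microbe rownames and disease colnames.
#' @examples
#' edges <- tibble::tibble(
#'   microbe = c("m1", "m2", "m1"),
#'   disease = c("d1", "d1", "d2")
#' )
#' association_matrix(edges)
#' @export
association_matrix <- function(edges, microbe_col = NULL, disease_col = NULL) {
  if (!is.data.frame(edges)) abort("`edges` must be a data frame.")
  if (ncol(edges) < 2L) abort("`edges` needs at least two columns (microbe, disease).")
  microbe_col <- microbe_col %||% names(edges)[1L]
  disease_col <- disease_col %||% names(edges)[2L]
  microbes <- trimws(as.character(edges[[microbe_col]]))
  diseases <- trimws(as.character(edges[[disease_col]]))
  keep <- nzchar(microbes) & nzchar(diseases) & !is.na(microbes) & !is.na(diseases)
  microbes <- microbes[keep]
  diseases <- diseases[keep]
  if (length(microbes) == 0L) abort("No associations found in `edges`.")
  microbe_ids <- unique(microbes)
  disease_ids <- unique(diseases)
  A <- matrix(0, length(microbe_ids), length(disease_ids),
              dimnames = list(microbe_ids, disease_ids))
  A[cbind(match(microbes, microbe_ids), match(diseases, disease_ids))] <- 1
  A
}

#' Read an association edge list from a delimited file
#'
#' @param path Path to a TSV/CSV file with at least two columns
#'   (microbe, disease). Extra columns are ignored.
#' @param header Whether the first row is a header (default `FALSE`).
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` means comma, anything else tab).
#' @return A tibble with columns `microbe` and `disease`, one row per listed
#'   pair (duplicates retained; [association_matrix()] collapses them).
#' @export
read_edge_list <- function(path, header = FALSE, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, col_names = header,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE)
  if (nrow(tab) == 0L) abort(sprintf("Empty edge list: %s", path))
  if (ncol(tab) < 2L) abort(sprintf("Edge list needs at least two columns: %s", path))
  out <- tibble::tibble(microbe = tab[[1L]], disease = tab[[2L]])
  out <- dplyr::filter(out, !is.na(.data$microbe), !is.na(.data$disease))
  if (nrow(out) == 0L) abort(sprintf("Zero associations after parsing: %s", path))
  out
}

#' Convert an association matrix back to a tidy edge list
#'
#' @param A A binary association matrix (microbes x diseases).
#' @return A tibble with columns `microbe` and `disease` for every 1-cell, in
#'   row-major order.
#' @export
as_edge_list <- function(A) {
  A <- validate_association(A)
  idx <- which(t(A) == 1)
  nd <- ncol(A)
  tibble::tibble(
    microbe = rownames(A)[(idx - 1L) %/% nd + 1L],
    disease = colnames(A)[(idx - 1L) %% nd + 1L]
  )
}

#' Read a dense labeled 0/1 association matrix
#'
#' Expects a TSV whose first row holds disease ids, first column microbe ids,
#' and whose cells are exactly 0 or 1.
#'
#' @param path Path to the TSV file.
#' @return A numeric 0/1 matrix with dimnames.
#' @export
read_association_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("Input file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, row.names = NULL, fill = FALSE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) abort(sprintf("Matrix file needs row labels plus >= 1 column: %s", path))
  rn <- trimws(as.character(tab[[1L]]))
  if (anyDuplicated(rn)) abort("Duplicate microbe labels in matrix file.")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  cn <- trimws(colnames(vals))
  if (anyDuplicated(cn)) abort("Duplicate disease labels in matrix file.")
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals) || !all(vals %in% c(0, 1))) {
    abort(sprintf("non-binary entry in matrix file: %s", path))
  }
  dimnames(vals) <- list(rn, cn)
  validate_association(vals)
}

#' Write a dense labeled matrix as TSV
#'
#' Inverse of [read_association_matrix()]; also used for dumping intermediate
#' similarity matrices.
#'
#' @param M A matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(M, path) {
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    abort("Matrix must carry row and column names.")
  }
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Coerce/validate the association matrix contract: numeric 0/1 matrix, unique
# dimnames, at least one association.
validate_association <- function(A) {
  if (is.data.frame(A)) A <- association_matrix(A)
  if (!is.matrix(A) || !is.numeric(A)) {
    abort("Association input must be a numeric matrix or an edge data frame.")
  }
  if (is.null(rownames(A))) rownames(A) <- paste0("m", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("d", seq_len(ncol(A)))
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A))) {
    abort("Association matrix labels must be unique.")
  }
  if (anyNA(A) || !all(A %in% c(0, 1))) {
    abort("Association matrix entries must all be 0 or 1.")
  }
  if (sum(A) == 0) {
    abort("Association matrix has no associations; the pipeline needs at least one 1.")
  }
  A
}
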