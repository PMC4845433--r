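# The 20 canonical amino acids, in the conventional one-letter order used
# throughout the package (also fixes the dimer ordering of the 2-mer encoder).
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Symbols that occur in real databases but are outside the 20-letter alphabet:
# ambiguity codes, rare residues and stop marks.
NONSTANDARD_SYMBOLS <- c("B", "J", "O", "U", "X", "Z", "*")

#' Sanitize an amino-acid sequence
#'
#' Uppercases the sequence, removes whitespace, and applies the chosen policy
#' to symbols outside the 20-letter amino-acid alphabet (B, J, O, U, X, Z, *).
#' Sanitization is idempotent.
#'
#' @param sequence Character string of amino-acid symbols.
#' @param policy How to treat nonstandard symbols: `"strip"` removes them,
#'   `"reject"` signals that the whole record should be dropped (returns
#'   `NA_character_`), `"error"` raises an error.
#' @return The sanitized sequence (possibly empty), or `NA_character_` under
#'   `policy = "reject"` when a nonstandard symbol is present. The number of
#'   characters removed is attached as attribute `"n_removed"`.
#' @examples
#' sanitize_sequence("mkxv")          # "MKV", one symbol stripped
#' sanitize_sequence("MKV", "error")  # unchanged
#' @export
sanitize_sequence <- function(sequence, policy = c("strip", "reject", "error")) {
  policy <- match.arg(policy)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(gsub("[[:space:]]", "", sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AMINO_ACIDS)
  if (any(bad)) {
    if (policy == "error") {
      stop("sequence contains symbols outside the 20-letter alphabet: ",
           paste(unique(chars[bad]), collapse = ", "))
    }
    if (policy == "reject") {
      out <- NA_character_
      attr(out, "n_removed") <- sum(bad)
      return(out)
    }
    s <- paste(chars[!bad], collapse = "")
  }
  attr(s, "n_removed") <- sum(bad)
  s
}

#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file, sanitizes each
#' sequence, applies a minimum-length filter, and returns a named character
#' vector of validated sequences. Record ids are taken as the first
#' whitespace-delimited token of each header.
#'
#' Gold-standard PPI sets are commonly restricted to proteins of at least 50
#' residues; pass `min_length = 50` to apply that filter (the library default
#' keeps everything non-empty).
#'
#' @param path Path to a FASTA file.
#' @param min_length Minimum (sanitized) sequence length to retain; default 1.
#' @param policy Nonstandard-residue policy passed to [sanitize_sequence()]:
#'   `"strip"` (default) removes the offending symbols, `"reject"` drops the
#'   whole record, `"error"` aborts.
#' @return Named character vector of uppercase sequences over the 20-letter
#'   alphabet. Attributes `"n_affected"` (records that contained nonstandard
#'   symbols) and `"n_filtered"` (records removed by the length filter or
#'   rejection) report what happened; a warning summarizes them.
#' @export
read_fasta <- function(path, min_length = 1L,
                       policy = c("strip", "reject", "error")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(aa)
  clean <- vapply(seqs, function(s) {
    out <- sanitize_sequence(s, policy)
    n_rem <- attr(out, "n_removed")
    paste0(n_rem, ":", if (is.na(out)) "" else out)
  }, character(1), USE.NAMES = FALSE)
  n_removed <- as.integer(sub(":.*$", "", clean))
  seq_clean <- sub("^[0-9]+:", "", clean)
  rejected <- policy == "reject" & n_removed > 0L
  keep <- !rejected & nchar(seq_clean) >= max(1L, min_length)
  n_affected <- sum(n_removed > 0L)
  n_filtered <- sum(!keep)
  if (n_affected > 0L || n_filtered > 0L) {
    warning(sprintf(
      "read_fasta: %d record(s) contained nonstandard symbols (policy = %s); %d record(s) dropped",
      n_affected, policy, n_filtered))
  }
  if (!any(keep)) stop("no sequences left after filtering: ", path)
  out <- seq_clean[keep]
  names(out) <- ids[keep]
  attr(out, "n_affected") <- n_affected
  attr(out, "n_filtered") <- n_filtered
  out
}

#' Read a labeled protein-pair list
#'
#' Reads a two-protein-plus-label table (tab- or comma-delimited, auto-detected
#' from the first line; optional header detected by a non-numeric third
#' column). Every id must resolve to a loaded protein and every label must be
#' 0 (non-interacting) or 1 (interacting).
#'
#' @param path Path to a delimited text file with columns id_a, id_b, label.
#' @param proteins Named character vector of sequences, as from [read_fasta()].
#' @return A `data.frame` with character columns `id_a`, `id_b` and integer
#'   column `label`.
#' @export
read_pairs <- function(path, proteins) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty pair file: ", path)
    return(data.frame(id_a = character(), id_b = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad_shape <- which(lengths(fields) < 3L)
  if (length(bad_shape)) {
    stop("malformed pair line(s) (need 3 columns): line ",
         paste(bad_shape, collapse = ", "))
  }
  first <- trimws(fields[[1]][3])
  has_header <- is.na(suppressWarnings(as.numeric(first)))
  if (has_header) fields <- fields[-1L]
  if (length(fields) == 0L) {
    warning("pair file has a header but no data rows: ", path)
    return(data.frame(id_a = character(), id_b = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  id_a <- trimws(vapply(fields, `[[`, character(1), 1L))
  id_b <- trimws(vapply(fields, `[[`, character(1), 2L))
  lab_raw <- trimws(vapply(fields, `[[`, character(1), 3L))
  lab <- suppressWarnings(as.numeric(lab_raw))
  if (anyNA(lab) || !all(lab %in% c(0, 1))) {
    stop("labels must be 0 or 1; offending value(s): ",
         paste(unique(lab_raw[is.na(lab) | !(lab %in% c(0, 1))]), collapse = ", "))
  }
  unknown <- setdiff(unique(c(id_a, id_b)), names(proteins))
  if (length(unknown)) {
    stop("pair file references unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  }
  data.frame(id_a = id_a, id_b = id_b, label = as.integer(lab),
             stringsAsFactors = FALSE)
}

#' Write a feature matrix as delimited text
#'
#' Writes one sample per row as CSV, with full double precision so that a
#' write/read round trip reproduces the matrix to better than 1e-12. An
#' optional label column is appended last.
#'
#' @param x Numeric matrix (samples in rows) or list of equal-length numeric
#'   vectors.
#' @param path Output file path.
#' @param labels Optional integer/numeric label per row, written as a final
#'   `label` column.
#' @return Invisibly, the path written.
#' @seealso [read_feature_matrix()]
#' @export
write_feature_matrix <- function(x, path, labels = NULL) {
  if (is.list(x)) {
    if (length(x) == 0L) stop("empty feature collection")
    dims <- lengths(x)
    if (length(unique(dims)) != 1L) {
      stop("mixed feature dimensionality: ", paste(unique(dims), collapse = ", "))
    }
    x <- do.call(rbind, x)
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (nrow(x) == 0L) stop("empty feature collection")
  df <- as.data.frame(x)
  if (is.null(colnames(x))) names(df) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) stop("labels length must match rows")
    df$label <- labels
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A list with `x` (numeric matrix) and `labels` (integer vector or
#'   NULL if the file has no `label` column).
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("feature matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  list(x = as.matrix(df), labels = labels)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width; default 60.
#' @return Invisibly, the path written.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(length(proteins) > 0L, !is.null(names(proteins)))
  aa <- Biostrings::AAStringSet(unname(proteins))
  names(aa) <- names(proteins)
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Write a labeled pair list as TSV
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  utils::write.table(pairs[, c("id_a", "id_b", "label")], path,
                     sep = "\t", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}
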