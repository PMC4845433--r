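# Six physicochemical residue classes used by the global-encoding descriptor:
#   C1 aliphatic {A,V,L,I,M,C}, C2 aromatic {F,W,Y}, C3 polar {S,T,N,Q},
#   C4 positive {K,R,H}, C5 negative {D,E}, C6 special conformation {G,P}.
# Histidine, the third basic residue, goes with the positively charged class
# so the map covers all 20 standard amino acids.
AA_CLASSES <- list(
  c("A", "V", "L", "I", "M", "C"),
  c("F", "W", "Y"),
  c("S", "T", "N", "Q"),
  c("K", "R", "H"),
  c("D", "E"),
  c("G", "P")
)

# symbol -> class index lookup
.aa_class_map <- local({
  m <- integer(0)
  for (k in seq_along(AA_CLASSES)) m[AA_CLASSES[[k]]] <- k
  m
})

# The ten complementary 3-vs-3 class partitions, in canonical order. Each row
# lists the three classes whose residues map to bit 1; the other three map to
# bit 0. C1 joined with each 2-subset of {C2..C6} — every split with C1 on
# the positive side — which enumerates all 10 distinct complementary
# partitions of the 6 classes.
GE_MODES <- list(
  c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 2L, 5L), c(1L, 2L, 6L),
  c(1L, 3L, 4L), c(1L, 3L, 5L), c(1L, 3L, 6L),
  c(1L, 4L, 5L), c(1L, 4L, 6L),
  c(1L, 5L, 6L)
)

#' Physicochemical class of an amino-acid residue
#'
#' Maps each of the 20 standard amino acids to one of six classes:
#' 1 aliphatic (A,V,L,I,M,C), 2 aromatic (F,W,Y), 3 polar (S,T,N,Q),
#' 4 positively charged (K,R,H), 5 negatively charged (D,E),
#' 6 special conformations (G,P).
#'
#' @param symbol Character vector of single-letter residue codes.
#' @return Integer vector of class indices in 1..6.
#' @examples
#' classify_residue(c("A", "G"))  # 1 6
#' @export
classify_residue <- function(symbol) {
  idx <- .aa_class_map[symbol]
  if (anyNA(idx)) {
    stop("symbol(s) outside the 20-letter amino-acid alphabet: ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  unname(idx)
}

#' Binarize a protein sequence under one transformation mode
#'
#' Produces the characteristic sequence of a protein under one of the ten
#' 3-vs-3 class partitions: position i is 1 when the class of residue i
#' belongs to the mode's positive class set, else 0.
#'
#' @param sequence Sanitized amino-acid sequence (single string).
#' @param mode Either a mode index in 1..10 (canonical order, see `GE_MODES`)
#'   or an integer vector of 3 class indices forming the positive set.
#' @return Integer 0/1 vector of the same length as the sequence.
#' @examples
#' binarize("AK", 1)  # A in C1 -> 1, K in C4 -> 0
#' @export
binarize <- function(sequence, mode) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  pos <- if (length(mode) == 1L) {
    if (!(mode %in% 1:10)) stop("mode index must be in 1..10")
    GE_MODES[[mode]]
  } else {
    if (length(mode) != 3L || !all(mode %in% 1:6) || anyDuplicated(mode)) {
      stop("a mode is a set of 3 distinct class indices in 1..6")
    }
    as.integer(mode)
  }
  cls <- classify_residue(strsplit(sequence, "", fixed = TRUE)[[1]])
  as.integer(cls %in% pos)
}

#' Prefix partition of a characteristic sequence
#'
#' Splits a binary sequence of length n into L nested prefix subsequences:
#' the k-th subsequence consists of the first floor(k*n/L) symbols, so the
#' L-th equals the full sequence and each is a prefix of the next.
#'
#' @param bits Integer 0/1 vector (or a "01" character string).
#' @param L Number of subsequences; requires `n >= L` so every subsequence is
#'   non-empty.
#' @return List of L integer vectors.
#' @examples
#' lengths(partition_prefix(rep(0L, 10), 5))  # 2 4 6 8 10
#' @export
partition_prefix <- function(bits, L) {
  bits <- .as_bits(bits)
  n <- length(bits)
  L <- as.integer(L)
  if (L < 1L) stop("L must be a positive integer")
  if (n < L) stop(sprintf("sequence length n = %d is shorter than L = %d", n, L))
  lens <- floor(seq_len(L) * n / L)
  lapply(lens, function(k) bits[seq_len(k)])
}

#' Composition descriptor of a binary subsequence
#'
#' Frequencies of 0 and 1, as fractions in `[0, 1]` summing to one.
#'
#' @param bits Integer 0/1 vector or "01" string.
#' @return Numeric vector `c(f0, f1)`.
#' @export
composition <- function(bits) {
  bits <- .as_bits(bits)
  if (length(bits) == 0L) stop("empty subsequence")
  f1 <- sum(bits) / length(bits)
  c(f0 = 1 - f1, f1 = f1)
}

#' Transition descriptor of a binary subsequence
#'
#' Counts the adjacent positions where the bit changes: the number of '1-0'
#' switches plus the number of '0-1' switches. The value is a raw count
#' (the descriptor's published worked example yields 18, not 18/27); divide
#' by `length - 1` via `normalize = TRUE` for a length-free variant.
#'
#' @param bits Integer 0/1 vector or "01" string.
#' @param normalize If TRUE return the switch count divided by `len - 1`
#'   (0 for length-1 subsequences). Default FALSE: the descriptor's published
#'   worked example is the raw count. The feature encoders default to the
#'   normalized form instead — see [encode_protein()].
#' @return A single non-negative number, at most `length(bits) - 1`.
#' @seealso [transition_counts()] for the '1-0' and '0-1' counts separately.
#' @export
transition <- function(bits, normalize = FALSE) {
  tc <- transition_counts(bits)
  tot <- tc[["n10"]] + tc[["n01"]]
  if (normalize) {
    n <- tc[["len"]]
    if (n <= 1L) return(0) else return(tot / (n - 1L))
  }
  tot
}

#' '1-0' and '0-1' switch counts of a binary subsequence
#'
#' @param bits Integer 0/1 vector or "01" string.
#' @return Named integer vector with `n10` (positions where 1 is followed by
#'   0), `n01` (0 followed by 1) and `len` (subsequence length).
#' @export
transition_counts <- function(bits) {
  bits <- .as_bits(bits)
  n <- length(bits)
  if (n == 0L) stop("empty subsequence")
  if (n == 1L) return(c(n10 = 0L, n01 = 0L, len = 1L))
  a <- bits[-n]
  b <- bits[-1L]
  c(n10 = sum(a == 1L & b == 0L),
    n01 = sum(a == 0L & b == 1L),
    len = n)
}

#' Global-encoding feature vector of one protein
#'
#' The full descriptor: for each of the ten transformation modes in canonical
#' order, the characteristic sequence is prefix-partitioned into L
#' subsequences, and each subsequence contributes `[f0, f1, transition]`.
#' Total length 10 * L * 3 (150 at the default L = 5).
#'
#' @param sequence Sanitized amino-acid sequence of length >= L.
#' @param L Partition parameter; default 5.
#' @param normalize_transition Use the length-normalized transition variant
#'   (switch frequency, in `[0, 1]`); default TRUE. Normalization puts the
#'   transition entries on the same scale as the composition fractions, so
#'   Euclidean distances and reconstruction residuals between feature
#'   vectors are not dominated by sequence length; the raw switch counts of
#'   the descriptor definition are available with `FALSE`.
#' @return Named numeric vector of length `10 * L * 3`; names are
#'   `m<mode>.s<k>.<f0|f1|tr>`.
#' @export
encode_protein <- function(sequence, L = 5L, normalize_transition = TRUE) {
  L <- as.integer(L)
  cls <- classify_residue(strsplit(sequence, "", fixed = TRUE)[[1]])
  n <- length(cls)
  if (n < L) stop(sprintf("sequence length n = %d is shorter than L = %d", n, L))
  lens <- floor(seq_len(L) * n / L)
  out <- numeric(10L * L * 3L)
  nm <- character(10L * L * 3L)
  # cumulative 1-counts and switch counts let every prefix descriptor be
  # read off in O(1) once the characteristic sequence is scanned
  i <- 0L
  for (m in 1:10) {
    bits <- as.integer(cls %in% GE_MODES[[m]])
    cum1 <- cumsum(bits)
    if (n > 1L) {
      a <- bits[-n]; b <- bits[-1L]
      cumsw <- c(0L, cumsum(as.integer(a != b)))
    } else cumsw <- 0L
    for (k in seq_len(L)) {
      len_k <- lens[k]
      f1 <- cum1[len_k] / len_k
      tr <- cumsw[len_k]
      if (normalize_transition) tr <- if (len_k > 1L) tr / (len_k - 1L) else 0
      out[i + 1L] <- 1 - f1
      out[i + 2L] <- f1
      out[i + 3L] <- tr
      nm[i + 1L] <- sprintf("m%d.s%d.f0", m, k)
      nm[i + 2L] <- sprintf("m%d.s%d.f1", m, k)
      nm[i + 3L] <- sprintf("m%d.s%d.tr", m, k)
      i <- i + 3L
    }
  }
  names(out) <- nm
  out
}

#' Global-encoding feature vector of a protein pair
#'
#' Concatenation of the two protein vectors in the given order, giving a
#' `2 * 10 * L * 3`-dimensional pair descriptor (300 at L = 5).
#'
#' @param seq_a,seq_b Sanitized amino-acid sequences.
#' @inheritParams encode_protein
#' @return Named numeric vector of length `2 * 10 * L * 3` (prefixes `a.`
#'   and `b.`).
#' @export
encode_pair <- function(seq_a, seq_b, L = 5L, normalize_transition = TRUE) {
  va <- encode_protein(seq_a, L, normalize_transition)
  vb <- encode_protein(seq_b, L, normalize_transition)
  out <- c(va, vb)
  names(out) <- c(paste0("a.", names(va)), paste0("b.", names(vb)))
  out
}

#' 2-mer (dimer frequency) baseline descriptor
#'
#' The 400 normalized frequencies of ordered amino-acid pairs, in fixed
#' lexicographic order over the package's residue ordering. Entries are
#' `count / (n - 1)` and sum to 1 for any sequence of length >= 2.
#'
#' @param sequence Sanitized amino-acid sequence of length >= 2.
#' @return Named numeric vector of length 400.
#' @export
encode_2mer <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) stop("2-mer descriptor requires sequence length >= 2")
  classify_residue(chars)  # validates the alphabet
  dimers <- paste0(chars[-n], chars[-1L])
  all_dimers <- as.vector(t(outer(AMINO_ACIDS, AMINO_ACIDS, paste0)))
  counts <- table(factor(dimers, levels = all_dimers))
  out <- as.numeric(counts) / (n - 1L)
  names(out) <- all_dimers
  out
}

#' Encode a labeled pair list into a feature matrix
#'
#' Applies [encode_pair()] (or the 2-mer baseline) to every row of a pair
#' table, returning a samples-in-rows matrix ready for [wsrc_fit()].
#'
#' @param pairs Data frame with columns `id_a`, `id_b` and optionally `label`.
#' @param proteins Named character vector of sequences.
#' @param L Partition parameter for the global encoding; default 5.
#' @param encoder `"ge"` (global encoding, default) or `"2mer"`.
#' @param normalize_transition Passed to [encode_protein()].
#' @return List with `x` (numeric matrix, one row per pair) and `labels`
#'   (integer vector or NULL).
#' @export
encode_pairs <- function(pairs, proteins, L = 5L,
                         encoder = c("ge", "2mer"),
                         normalize_transition = TRUE) {
  encoder <- match.arg(encoder)
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  unknown <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(proteins))
  if (length(unknown)) {
    stop("pairs reference unknown protein id(s): ",
         paste(unknown, collapse = ", "))
  }
  # encode each distinct protein once
  ids <- unique(c(pairs$id_a, pairs$id_b))
  enc1 <- if (encoder == "ge") {
    lapply(proteins[ids], encode_protein, L = L,
           normalize_transition = normalize_transition)
  } else {
    lapply(proteins[ids], encode_2mer)
  }
  names(enc1) <- ids
  x <- t(vapply(seq_len(nrow(pairs)), function(i) {
    c(enc1[[pairs$id_a[i]]], enc1[[pairs$id_b[i]]])
  }, numeric(2L * length(enc1[[1L]]))))
  d1 <- names(enc1[[1L]])
  colnames(x) <- c(paste0("a.", d1), paste0("b.", d1))
  rownames(x) <- paste(pairs$id_a, pairs$id_b, sep = "|")
  labels <- if ("label" %in% names(pairs)) as.integer(pairs$label) else NULL
  list(x = x, labels = labels)
}

#' Augment a pair feature matrix with swapped-order duplicates
#'
#' A pair vector is the concatenation of two protein vectors in an arbitrary
#' order. Symmetrization appends, for every training pair, the same features
#' with the two protein halves swapped (b then a), making a trained
#' classifier invariant to the order in which a pair's proteins are listed.
#'
#' @param x Pair feature matrix (rows are pairs; columns split into two
#'   equal protein halves).
#' @param labels Optional label vector to duplicate alongside.
#' @return List with the augmented `x` (2x the rows) and `labels`
#'   (or NULL).
#' @export
symmetrize_pairs <- function(x, labels = NULL) {
  stopifnot(is.matrix(x), ncol(x) %% 2L == 0L)
  h <- ncol(x) %/% 2L
  swapped <- x[, c((h + 1L):(2L * h), seq_len(h)), drop = FALSE]
  colnames(swapped) <- colnames(x)
  list(x = rbind(x, swapped),
       labels = if (is.null(labels)) NULL else rep(labels, 2L))
}

# Accept bits as integer vector or "01" string; validate.
.as_bits <- function(bits) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1L)
    bits <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
  }
  bits <- as.integer(bits)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("bits must be a 0/1 vector or a string over {0,1}")
  }
  bits
}
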