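# Synthetic benchmark generator.
#
# Real gold-standard PPI sets pair interacting proteins (positives) against
# pairs drawn from different subcellular compartments (negatives). The
# generator emulates that structure with a planted, descriptor-detectable
# signal: "interactor-prone" proteins are drawn with residue probabilities
# tilted toward the aliphatic (C1) and positively charged (C4) classes —
# hydrophobic and charged residues being the classic drivers of interface
# propensity — so interacting pairs differ from background pairs in exactly
# the class-composition space the global encoding summarizes.
#
# Pairs are protein-disjoint (a random perfect matching within each group:
# every protein occurs in at most one pair), so cross-validated performance
# measures generalization to unseen proteins rather than memorization of
# proteins shared between folds; with no planted signal the two classes are
# then exactly exchangeable and CV accuracy sits at chance.

#' Default generator configuration
#'
#' @param n_proteins Number of proteins to simulate (split into
#'   interactor-prone and background groups in the positive:negative pair
#'   ratio). Default `NULL` derives the minimum for protein-disjoint
#'   pairing: `2 * (n_positive + n_negative)`.
#' @param length_range Inclusive residue-length range, uniform; default
#'   c(50, 150) — at least the conventional 50-residue floor of curated PPI
#'   sets, short enough for quick benchmarks.
#' @param n_positive,n_negative Pair counts per class; default 100 each
#'   (balanced classes, as in curated gold standards).
#' @param signal_strength Tilt of the prone residue distribution, in
#'   `[0, 1]`: prone proteins draw residues from the mixture
#'   `(1 - s) * uniform + s * uniform-over-C1-and-C4`, i.e. `s` is the
#'   fraction of residue mass diverted to the aliphatic and positively
#'   charged classes. 0 means no signal (null); 1 means prone proteins
#'   contain only C1/C4 residues. Default 0.5.
#' @param seed Integer seed; required for generation.
#' @return List of class `"ppi_sim_config"`.
#' @export
sim_config <- function(n_proteins = NULL, length_range = c(50L, 150L),
                       n_positive = 100L, n_negative = 100L,
                       signal_strength = 0.5, seed = NULL) {
  if (is.null(n_proteins)) n_proteins <- 2L * (n_positive + n_negative)
  stopifnot(n_proteins >= 2L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[2] >= length_range[1],
            n_positive >= 1L, n_negative >= 1L,
            signal_strength >= 0, signal_strength <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 signal_strength = signal_strength,
                 seed = seed),
            class = "ppi_sim_config")
}

# residue sampling distribution: uniform for background; for prone proteins
# a mixture that diverts a fraction signal_strength of the mass to C1/C4
.residue_probs <- function(signal_strength, prone) {
  p <- rep(1 / 20, length(AMINO_ACIDS))
  names(p) <- AMINO_ACIDS
  if (prone && signal_strength > 0) {
    tilt_res <- c(AA_CLASSES[[1]], AA_CLASSES[[4]])
    p <- (1 - signal_strength) * p
    p[tilt_res] <- p[tilt_res] + signal_strength / length(tilt_res)
  }
  p
}

#' Generate random protein sequences
#'
#' Sequences are i.i.d. over the 20-letter alphabet; the first half of the
#' proteins are "interactor-prone" and drawn from the tilted residue
#' distribution (see [sim_config()]), the second half from the uniform
#' background distribution. Output is byte-identical for a fixed seed.
#'
#' @param config A [sim_config()] (its `seed` must be set).
#' @return Named character vector of sequences with attribute `"prone"`, a
#'   logical vector marking the interactor-prone proteins.
#' @export
generate_proteins <- function(config) {
  stopifnot(inherits(config, "ppi_sim_config"))
  if (is.null(config$seed)) stop("config$seed must be set")
  set.seed(as.integer(config$seed))
  n <- config$n_proteins
  # prone share follows the positive:negative pair ratio so disjoint
  # pairing capacity is honored for unbalanced class counts too
  frac_pos <- config$n_positive / (config$n_positive + config$n_negative)
  prone <- seq_len(n) <= round(n * frac_pos)
  len_choices <- seq(config$length_range[1], config$length_range[2])
  lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
  p_prone <- .residue_probs(config$signal_strength, TRUE)
  p_bg <- .residue_probs(config$signal_strength, FALSE)
  seqs <- vapply(seq_len(n), function(i) {
    p <- if (prone[i]) p_prone else p_bg
    paste(sample(AMINO_ACIDS, lens[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("prot%04d", seq_len(n))
  attr(seqs, "prone") <- prone
  seqs
}

#' Generate a labeled protein-pair dataset with a planted signal
#'
#' Positive (interacting) pairs are a random perfect matching of
#' interactor-prone proteins; negative pairs a matching of background
#' proteins — mirroring gold standards whose negatives come from proteins of
#' different subcellular compartments. Every protein occurs in at most one
#' pair, so no protein is shared between training and test folds downstream.
#' Exact class counts are honored.
#'
#' @param config A [sim_config()] with `seed` set.
#' @return List with `proteins` (named character vector) and `pairs`
#'   (data.frame `id_a`, `id_b`, `label`).
#' @export
generate_pair_dataset <- function(config) {
  proteins <- generate_proteins(config)
  prone <- attr(proteins, "prone")
  ids_pos <- names(proteins)[prone]
  ids_neg <- names(proteins)[!prone]
  cap_pos <- length(ids_pos) %/% 2L
  cap_neg <- length(ids_neg) %/% 2L
  if (config$n_positive > cap_pos || config$n_negative > cap_neg) {
    stop(sprintf(
      "requested pairs exceed disjoint-pairing capacity: %d positive of %d possible, %d negative of %d possible",
      config$n_positive, cap_pos, config$n_negative, cap_neg))
  }
  # seed state continues from generate_proteins, so the whole dataset is a
  # deterministic function of the config
  match_pairs <- function(ids, n_pairs, label) {
    ids <- sample(ids)
    odd <- seq(1L, 2L * n_pairs, by = 2L)
    data.frame(id_a = ids[odd], id_b = ids[odd + 1L],
               label = label, stringsAsFactors = FALSE)
  }
  pairs <- rbind(match_pairs(ids_pos, config$n_positive, 1L),
                 match_pairs(ids_neg, config$n_negative, 0L))
  rownames(pairs) <- NULL
  list(proteins = proteins, pairs = pairs)
}

#' Write a generated dataset as FASTA + TSV fixtures
#'
#' Emits the standard on-disk form (`proteins.fasta`, `pairs.tsv`) so that
#' simulated data flows through the command-line interface unchanged.
#'
#' @param dataset Result of [generate_pair_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the two file paths.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteins.fasta")
  tsv <- file.path(dir, "pairs.tsv")
  write_fasta(dataset$proteins, fasta)
  write_pairs(dataset$pairs, tsv)
  invisible(list(fasta = fasta, pairs = tsv))
}
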