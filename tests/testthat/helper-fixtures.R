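# Shared fixtures.
#
# The 57-symbol characteristic sequence and its published prefix partition
# (L = 6), used as the frozen worked example for the partition and
# descriptor operations.
example_seq_57 <- "101001111001101010101011001101011010010110110101000100010"
example_sub_28 <- "1010011110011010101010110011"  # its third prefix subsequence

# small FASTA/pair fixture written into a tempdir
write_tiny_dataset <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "prot.fasta")
  writeLines(c(
    ">p1 first protein", "MKVLAAGGDE", ">p2", "RRKKWWYYPP",
    ">p3", paste(rep("ACDEF", 4), collapse = "")), fasta)
  pairs <- file.path(dir, "pairs.tsv")
  writeLines(c("p1\tp2\t1", "p1\tp3\t0", "p2\tp3\t1"), pairs)
  list(dir = dir, fasta = fasta, pairs = pairs)
}

# deterministic random amino-acid sequence for property tests
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}
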