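# Shared test fixtures, all built in code.

random_dna <- function(n, len = 101L, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n),
         function(i) paste(sample(alphabet, len, replace = TRUE),
                           collapse = ""),
         character(1L))
}

# small genome FASTA on disk; returns the path and the raw sequences
write_test_genome <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "genome.fa")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# quick labeled toy dataset: positives carry a fixed planted 8-mer,
# negatives are uniform random; linearly separable enough to learn fast
toy_dataset <- function(n_per_class, seed, domain_label = "target",
                        motif = "GCACGTGC") {
  set.seed(seed)
  pos <- random_dna(n_per_class)
  at <- sample.int(101 - nchar(motif) + 1, n_per_class, replace = TRUE)
  for (i in seq_len(n_per_class)) {
    substr(pos[i], at[i], at[i] + nchar(motif) - 1) <- motif
  }
  neg <- random_dna(n_per_class)
  data.frame(seq = c(pos, neg),
             binding_label = rep(c("positive", "negative"),
                                 each = n_per_class),
             domain_label = domain_label,
             origin = "synthetic", stringsAsFactors = FALSE)
}

tiny_config <- function(max_epochs = 2L, patience = 2L, ...) {
  dann_config(n_kernels_1 = 3L, n_kernels_2 = 4L, fc_width = 8L,
              batch_size = 32L, max_epochs = max_epochs,
              patience = patience, ...)
}
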