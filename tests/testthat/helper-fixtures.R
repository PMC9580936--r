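# Small deterministic fixtures shared across tests.

tiny_ref <- function() {
  aligned_ref(
    id = c("r1", "r2", "r3"),
    aligned_seq = c("ACGT-ACG", "ACGTTACG", "ACGA-ACG"),
    taxonomy = c("Bacteria;A", "Bacteria;B", NA)
  )
}

random_aligned_seqs <- function(n, len, gap_prob = 0.1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "-"), len, replace = TRUE,
                 prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)),
          collapse = "")
  }, "")
}

write_tmp_fasta <- function(headers, seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}

mutate_seq <- function(s, k = 1) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  paste(ch, collapse = "")
}

# Manual sampling plan for tiny embedding tests (bypasses the N > m guard).
manual_plan <- function(partners, distances) {
  structure(
    list(partners = partners, distances = distances,
         dilated_ranks = integer(0), N = nrow(partners),
         n = 0L, m = ncol(partners), f = NA_real_),
    class = "sampling_plan"
  )
}
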