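#' Read merged, quality-filtered amplicon reads
#'
#' Consumes the FASTA/FASTQ output of upstream pair merging and quality
#' filtering (see the package README for the documented external `vsearch`
#' commands; merging and expected-error filtering are deliberately not
#' re-implemented here). Reads are uppercased; reads containing `N` or any
#' symbol outside `A/C/G/T`, or outside the length window, are discarded and
#' counted.
#'
#' @param path FASTA or FASTQ file (format inferred from the first character).
#' @param sample_id Sample label; defaults to the file name.
#' @param min_len,max_len Retained length window, defaults 225-275 (the
#'   standard V4 merged-read filter).
#' @return A `read_set`: list with `sample_id`, `reads` (character vector),
#'   and a `dropped` tibble of discard counts by reason.
#' @export
read_reads <- function(path, sample_id = basename(path),
                       min_len = 225, max_len = 275) {
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  read_set(seqs, sample_id = sample_id, min_len = min_len, max_len = max_len)
}

#' Construct a read set from in-memory sequences
#'
#' Applies the same alphabet and length filters as [read_reads()].
#'
#' @param reads Character vector of read sequences.
#' @param sample_id Sample label.
#' @param min_len,max_len Retained length window.
#' @return A `read_set` list.
#' @export
read_set <- function(reads, sample_id = "sample", min_len = 225,
                     max_len = 275) {
  reads <- toupper(reads)
  bad_symbol <- grepl("[^ACGT]", reads)
  len <- nchar(reads)
  bad_len <- !bad_symbol & (len < min_len | len > max_len)
  keep <- !bad_symbol & !bad_len
  dropped <- tibble::tibble(
    reason = c("non_acgt_symbol", "length_window"),
    n = c(sum(bad_symbol), sum(bad_len))
  )
  structure(
    list(sample_id = sample_id, reads = unname(reads[keep]),
         dropped = dropped, min_len = min_len, max_len = max_len),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> sample ", x$sample_id, ": ", length(x$reads),
      " reads retained (", sum(x$dropped$n), " discarded)\n", sep = "")
  invisible(x)
}

#' Dereplicate reads with singleton removal
#'
#' Exact-string dereplication of a single sample. Sequences occurring fewer
#' than `min_unique` times (singletons, by default) are dropped; the rest are
#' sorted by descending count, ties broken lexicographically by sequence.
#'
#' @param reads A `read_set` (or plain character vector of reads).
#' @param min_unique Minimum copies for a unique sequence to be kept
#'   (default 2).
#' @return A tibble of class `unique_seq_tbl` with columns `sequence`,
#'   `count`, and attributes `sample_id`, `n_raw_reads`,
#'   `n_dropped_singleton`.
#' @export
dereplicate_reads <- function(reads, min_unique = 2) {
  sample_id <- "sample"
  if (inherits(reads, "read_set")) {
    sample_id <- reads$sample_id
    reads <- reads$reads
  }
  tab <- table(reads)
  keep <- tab >= min_unique
  out <- tibble::tibble(
    sequence = as.character(names(tab)[keep]),
    count = as.integer(tab[keep])
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$count), .data$sequence)
  attr(out, "sample_id") <- sample_id
  attr(out, "n_raw_reads") <- length(reads)
  attr(out, "n_dropped_singleton") <- sum(tab[!keep])
  class(out) <- unique(c("unique_seq_tbl", class(out)))
  out
}

#' Write a unique-sequence table as size-annotated FASTA
#'
#' Uses the `;size=` header dialect understood by the USEARCH/VSEARCH family
#' of tools.
#'
#' @param tbl A `unique_seq_tbl`.
#' @param path Output FASTA path.
#' @param prefix Record id prefix.
#' @return `path`, invisibly.
#' @export
write_size_fasta <- function(tbl, path, prefix = "uniq") {
  writeLines(paste0(">", prefix, seq_len(nrow(tbl)), ";size=", tbl$count,
                    "\n", tbl$sequence), path)
  invisible(path)
}
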