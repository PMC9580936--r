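#' Aligned reference sets
#'
#' An aligned reference set is a tibble with one row per reference record and
#' columns `id` (character, unique), `aligned_seq` (character, all the same
#' width, alphabet `A`, `C`, `G`, `T`, `-`) and `taxonomy` (character, `NA`
#' when absent). The shared width is the alignment column frame every
#' downstream distance computation relies on.
#'
#' @param id Character vector of record identifiers.
#' @param aligned_seq Character vector of aligned sequences (same length as
#'   `id`), all of identical width, over `A/C/G/T/-`.
#' @param taxonomy Optional character vector of taxonomy strings.
#'
#' @return A tibble of class `aligned_ref`.
#' @export
aligned_ref <- function(id, aligned_seq, taxonomy = NULL) {
  if (is.null(taxonomy)) taxonomy <- rep(NA_character_, length(id))
  out <- tibble::tibble(
    id = as.character(id),
    aligned_seq = toupper(as.character(aligned_seq)),
    taxonomy = as.character(taxonomy)
  )
  validate_aligned_ref(out)
}

validate_aligned_ref <- function(ref) {
  if (nrow(ref) == 0L) {
    stop("reference set is empty", call. = FALSE)
  }
  if (anyDuplicated(ref$id)) {
    stop("reference ids must be unique", call. = FALSE)
  }
  widths <- nchar(ref$aligned_seq)
  if (length(unique(widths)) != 1L) {
    stop(
      "alignment-frame error: sequences have unequal lengths (",
      paste(utils::head(unique(widths), 5L), collapse = ", "), ")",
      call. = FALSE
    )
  }
  bad <- grepl("[^ACGT-]", ref$aligned_seq)
  if (any(bad)) {
    stop(
      "reference sequences contain symbols outside {A,C,G,T,-} ",
      "(ambiguity codes are not supported); first offending record: ",
      ref$id[which(bad)[1L]],
      call. = FALSE
    )
  }
  class(ref) <- unique(c("aligned_ref", class(ref)))
  ref
}

#' Number of alignment columns of a reference set
#' @param ref An `aligned_ref` tibble.
#' @return Integer, the shared alignment width.
#' @export
n_columns <- function(ref) {
  nchar(ref$aligned_seq[1L])
}

#' Read an aligned reference collection from FASTA
#'
#' Records must all have the same aligned width. Text after the first
#' whitespace in a header is kept as the record's taxonomy string.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `aligned_ref` tibble in file order.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) {
    stop("input error: no FASTA records in ", path, call. = FALSE)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  taxonomy <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    NA_character_
  )
  aligned_ref(id = id, aligned_seq = as.character(set), taxonomy = taxonomy)
}

#' Write an aligned reference set to FASTA
#'
#' @param ref An `aligned_ref` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(ref, path) {
  header <- ifelse(is.na(ref$taxonomy), ref$id, paste(ref$id, ref$taxonomy))
  writeLines(paste0(">", header, "\n", ref$aligned_seq), path)
  invisible(path)
}

# Character matrix view of the alignment (records x columns).
ref_char_matrix <- function(ref) {
  matrix(
    unlist(strsplit(ref$aligned_seq, "", fixed = TRUE), use.names = FALSE),
    nrow = nrow(ref), byrow = TRUE
  )
}

# Integer-coded view: gap = 0L, A=1, C=2, G=3, T=4.
ref_code_matrix <- function(ref) {
  m <- ref_char_matrix(ref)
  code <- match(m, c("A", "C", "G", "T"), nomatch = 0L)
  dim(code) <- dim(m)
  code
}

collapse_rows <- function(m) {
  apply(m, 1L, paste, collapse = "")
}

#' Drop alignment columns that are mostly gaps
#'
#' A column is retained when the fraction of records carrying a base (not a
#' gap) at that column is at least `min_frac`. The default 0.001 removes
#' positions present in fewer than 0.1% of records; a column exactly at the
#' threshold is kept.
#'
#' @param ref An `aligned_ref` tibble.
#' @param min_frac Minimum non-gap fraction for a column to be kept, in
#'   `[0, 1]`.
#' @return An `aligned_ref` tibble with the same records over the retained
#'   columns.
#' @export
filter_sparse_columns <- function(ref, min_frac = 0.001) {
  ref <- validate_aligned_ref(ref)
  stopifnot(min_frac >= 0, min_frac <= 1)
  m <- ref_char_matrix(ref)
  frac <- colMeans(m != "-")
  keep <- frac >= min_frac
  if (!any(keep)) {
    stop("degenerate output: all alignment columns removed", call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(ref),
    aligned_seq = collapse_rows(m[, keep, drop = FALSE])
  )
  validate_aligned_ref(out)
}

#' Trim the alignment to a column window
#'
#' Coordinates are 0-based and half-open: `trim_to_region(ref, 0, n_columns(ref))`
#' is the identity.
#'
#' @param ref An `aligned_ref` tibble.
#' @param start_col First column to keep (0-based).
#' @param end_col One past the last column to keep.
#' @return An `aligned_ref` tibble over columns `[start_col, end_col)`.
#' @export
trim_to_region <- function(ref, start_col, end_col) {
  ref <- validate_aligned_ref(ref)
  C <- n_columns(ref)
  if (start_col < 0 || end_col > C || start_col >= end_col) {
    stop(
      "bounds error: window [", start_col, ", ", end_col,
      ") invalid for ", C, " columns",
      call. = FALSE
    )
  }
  out <- dplyr::mutate(
    tibble::as_tibble(ref),
    aligned_seq = substr(.data$aligned_seq, start_col + 1L, end_col)
  )
  validate_aligned_ref(out)
}

#' Collapse identical aligned sequences
#'
#' One record per distinct aligned sequence is kept; the representative is the
#' first-seen record, and the ids of all merged records are retained in a
#' `members` list-column.
#'
#' @param ref An `aligned_ref` tibble.
#' @return An `aligned_ref` tibble with unique `aligned_seq` and a `members`
#'   list-column of merged ids.
#' @export
dereplicate_reference <- function(ref) {
  ref <- validate_aligned_ref(ref)
  grp <- match(ref$aligned_seq, unique(ref$aligned_seq))
  members <- split(ref$id, grp)
  first <- which(!duplicated(grp))
  out <- tibble::as_tibble(ref)[first, ]
  out$members <- unname(members[as.character(grp[first])])
  validate_aligned_ref(out)
}

#' Write a dereplication map
#'
#' @param ref A dereplicated `aligned_ref` tibble with a `members` column.
#' @param path Output TSV path (`representative_id`, `member_ids`).
#' @return `path`, invisibly.
#' @export
write_derep_map <- function(ref, path) {
  stopifnot(!is.null(ref$members))
  tab <- tibble::tibble(
    representative_id = ref$id,
    member_ids = vapply(ref$members, paste, "", collapse = ",")
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove gap characters
#'
#' @param seqs Character vector of aligned sequences.
#' @return Character vector with all `-` removed.
#' @export
degap <- function(seqs) {
  gsub("-", "", seqs, fixed = TRUE)
}

#' One-hot encode a sequence
#'
#' Returns an `L x A` binary matrix with `matrix[i, k] = 1` iff the i-th
#' symbol equals `alphabet[k]`. Rows past the end of the sequence (when
#' `pad_to` exceeds its length) are all zero.
#'
#' @param seq A single sequence string.
#' @param alphabet Ordered symbol vector; default `c("A","C","G","T")`.
#' @param pad_to Optional total row count `>= nchar(seq)`.
#' @return A binary matrix with `length(alphabet)` columns.
#' @export
one_hot_encode <- function(seq, alphabet = c("A", "C", "G", "T"),
                           pad_to = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    stop(
      "encoding error: symbol(s) outside alphabet: ",
      paste(unique(chars[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  L <- if (is.null(pad_to)) length(chars) else pad_to
  if (L < length(chars)) {
    stop("pad_to is shorter than the sequence", call. = FALSE)
  }
  m <- matrix(0, nrow = L, ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  if (length(chars)) {
    m[cbind(seq_along(chars), idx)] <- 1
  }
  m
}
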