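#' Alignment distance between two aligned sequences
#'
#' Counts alignment columns where the two symbols differ. A gap opposite a
#' base counts as a difference; a gap opposite a gap does not. Units are base
#' pairs, and the function is a metric on sequences sharing an alignment
#' frame.
#'
#' @param x,y Aligned sequence strings of equal length over `A/C/G/T/-`.
#' @return Non-negative integer distance.
#' @export
pairwise_distance <- function(x, y) {
  if (nchar(x) != nchar(y)) {
    stop("alignment-frame error: sequences have unequal lengths", call. = FALSE)
  }
  a <- strsplit(x, "", fixed = TRUE)[[1L]]
  b <- strsplit(y, "", fixed = TRUE)[[1L]]
  sum(a != b)
}

#' All pairwise alignment distances of a reference set
#'
#' Column-mismatch (Hamming) distance over the shared alignment frame,
#' computed for all pairs at once via per-symbol match counts and BLAS
#' multiplications.
#'
#' @param ref An `aligned_ref` tibble.
#' @return An `N x N` symmetric integer-valued matrix of distances.
#' @export
reference_distance_matrix <- function(ref) {
  code <- ref_code_matrix(ref)
  C <- ncol(code)
  matches <- matrix(0, nrow(code), nrow(code))
  for (s in 0:4) {
    ind <- (code == s) * 1
    matches <- matches + tcrossprod(ind)
  }
  D <- C - matches
  # guard tiny BLAS round-off: distances are exact column counts
  round(D)
}
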