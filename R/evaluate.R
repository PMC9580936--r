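#' Ground truth for a mock community
#'
#' @param v4_sequence Character vector of expected V4 sequences (unaligned).
#' @param expected_fraction Expected relative abundances; must sum to 1 over
#'   intended rows.
#' @param intended Logical; `FALSE` marks known contaminants (fraction may be
#'   `NA`).
#' @return A tibble of class `ground_truth`.
#' @export
ground_truth <- function(v4_sequence, expected_fraction,
                         intended = TRUE) {
  out <- tibble::tibble(
    v4_sequence = toupper(v4_sequence),
    expected_fraction = expected_fraction,
    intended = rep_len(intended, length(v4_sequence))
  )
  if (anyDuplicated(out$v4_sequence)) {
    stop("ground-truth sequences must be distinct", call. = FALSE)
  }
  s <- sum(out$expected_fraction[out$intended])
  if (abs(s - 1) > 1e-6) {
    stop("intended fractions must sum to 1 (got ", format(s), ")",
         call. = FALSE)
  }
  class(out) <- unique(c("ground_truth", class(out)))
  out
}

#' Read/write ground truth TSV
#'
#' @param path TSV with columns `v4_sequence`, `expected_fraction`,
#'   `intended`.
#' @return A `ground_truth` tibble.
#' @export
read_ground_truth <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  ground_truth(tab$v4_sequence, tab$expected_fraction, tab$intended)
}

#' @rdname read_ground_truth
#' @param truth A `ground_truth` tibble.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply the low-abundance / low-identity quality filters
#'
#' An ASV is removed iff any of the three rules fires (all comparisons
#' strict): identity below 92%; abundance below 0.01% and identity below 99%;
#' abundance below 0.001% and identity below 100%.
#'
#' @param asvs An annotated `asv_tbl` with `identity` and
#'   `relative_abundance`.
#' @return The filtered `asv_tbl`; removed rows are attached as attribute
#'   `filtered_out`.
#' @export
apply_quality_filters <- function(asvs) {
  stopifnot(!is.null(asvs$identity), !is.null(asvs$relative_abundance))
  ident <- asvs$identity
  ab <- asvs$relative_abundance
  removed <- (ident < 0.92) |
    (ab < 1e-4 & ident < 0.99) |
    (ab < 1e-5 & ident < 1)
  out <- asvs[!removed, , drop = FALSE]
  attr(out, "filtered_out") <- asvs[removed, , drop = FALSE]
  out
}

#' Score filtered ASVs against ground truth
#'
#' True positives are filtered ASVs whose sequence matches a known reference
#' at 100% identity (`exact_match`), whether intentionally added or not;
#' everything else surviving the filters is a false positive. Recall is
#' counted against the set of distinct expected sequences in the ground
#' truth.
#'
#' @param filtered A filtered, annotated `asv_tbl`.
#' @param truth A `ground_truth` tibble.
#' @return A one-row tibble (`evaluation_report`): counts, precision and
#'   recall in percent.
#' @export
score_asvs <- function(filtered, truth) {
  tp <- sum(filtered$exact_match)
  fp <- sum(!filtered$exact_match)
  found_expected <- sum(truth$v4_sequence %in% filtered$sequence)
  precision <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  recall <- 100 * found_expected / nrow(truth)
  out <- tibble::tibble(
    filtered_asv_count = nrow(filtered),
    true_positives = tp,
    false_positives = fp,
    expected_found = found_expected,
    expected_total = nrow(truth),
    precision = precision,
    recall = recall,
    empty_result = tp + fp == 0
  )
  class(out) <- unique(c("evaluation_report", class(out)))
  out
}

#' Bhattacharyya coefficient between two abundance vectors
#'
#' `sum(sqrt(p * q))` after normalizing each vector to sum 1. Equals 1 iff
#' the normalized distributions are identical and 0 iff their supports are
#' disjoint. Vectors must already be matched over a common support (absent
#' categories as 0); see [bhattacharyya_tables()] to match by sequence.
#'
#' @param p,q Non-negative numeric vectors of equal length.
#' @return Coefficient in `[0, 1]`.
#' @export
bhattacharyya <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (sum(p) == 0 || sum(q) == 0) {
    stop("domain error: all-zero abundance vector", call. = FALSE)
  }
  sum(sqrt((p / sum(p)) * (q / sum(q))))
}

#' Bhattacharyya coefficient between truth and detected abundances
#'
#' Matches ground-truth fractions and detected ASV abundances over the union
#' of their sequences (absent sequences count 0) and applies
#' [bhattacharyya()].
#'
#' @param truth A `ground_truth` tibble (intended rows are used).
#' @param asvs An `asv_tbl` with `relative_abundance`.
#' @return Coefficient in `[0, 1]`.
#' @export
bhattacharyya_tables <- function(truth, asvs) {
  truth <- truth[truth$intended, , drop = FALSE]
  support <- union(truth$v4_sequence, asvs$sequence)
  p <- truth$expected_fraction[match(support, truth$v4_sequence)]
  q <- asvs$relative_abundance[match(support, asvs$sequence)]
  p[is.na(p)] <- 0
  q[is.na(q)] <- 0
  bhattacharyya(p, q)
}

#' Evaluate an annotated ASV table against a mock-community truth
#'
#' Applies the quality filters, scores precision/recall, and computes the
#' Bhattacharyya abundance concordance (reported both as a coefficient and
#' x100 as conventionally tabulated).
#'
#' @param asvs An annotated `asv_tbl`.
#' @param truth A `ground_truth` tibble.
#' @return A one-row `evaluation_report` tibble with `bhattacharyya` and
#'   `bhattacharyya_x100` columns appended.
#' @export
evaluate_asvs <- function(asvs, truth) {
  filtered <- apply_quality_filters(asvs)
  report <- score_asvs(filtered, truth)
  bc <- bhattacharyya_tables(truth, filtered)
  report$bhattacharyya <- bc
  report$bhattacharyya_x100 <- 100 * bc
  report
}

#' Trimmed-mean / log / PCA phenotype projection
#'
#' Normalizes each sample's ASV counts by its trimmed mean (5% trimmed at
#' each tail by default), applies `log1p`, and projects the samples onto the
#' first three principal components (centered, unscaled). Component signs
#' follow a deterministic convention (largest-magnitude loading positive).
#'
#' @param counts A samples x ASVs numeric matrix or data frame of
#'   non-negative counts (rownames = sample ids), at least 4 samples.
#' @param trim_frac Fraction trimmed from each tail of a sample's counts when
#'   computing its normalization factor (default 0.05).
#' @return A tibble with `sample` and `PC1`..`PC3`; loadings and explained
#'   variance are attached as attributes `rotation` and `variance_explained`.
#' @export
phenotype_project <- function(counts, trim_frac = 0.05) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 4) {
    stop("insufficient data: need at least 4 samples", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  factors <- apply(counts, 1L, mean, trim = trim_frac)
  factors[factors == 0] <- 1
  norm <- log1p(counts / factors)
  pca <- stats::prcomp(norm, center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pca$x))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  out <- tibble::as_tibble(scores)
  names(out) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(
    tibble::tibble(sample = rownames(counts) %||% as.character(seq_len(nrow(counts)))),
    out
  )
  attr(out, "rotation") <- rot
  attr(out, "variance_explained") <-
    (pca$sdev^2 / sum(pca$sdev^2))[seq_len(k)]
  class(out) <- unique(c("phenotype_projection", class(out)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
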