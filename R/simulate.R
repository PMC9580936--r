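#' Generate a synthetic aligned reference collection
#'
#' Sequences evolve along a random binary tree: starting from one random root
#' sequence, a random leaf is repeatedly split into two children, each child
#' receiving `Poisson(divergence)` point substitutions at random columns.
#' Sibling leaves therefore differ by about `2 * divergence` substitutions in
#' expectation, and the leaf set mixes near-identical (down to 1 bp) and
#' divergent pairs. With `indel_rate > 0`, each child may additionally gap
#' out a random column (realized as a gap character, keeping one shared
#' alignment frame). Records carry a coarse taxonomy label derived from their
#' top-level clade.
#'
#' @param n_seqs Number of leaf sequences (>= 2).
#' @param length Alignment columns (default 320, the V4 frame width).
#' @param divergence Expected substitutions per tree edge (default 3).
#' @param indel_rate Probability a child gains one gap column (default 0).
#' @param seed Integer seed.
#' @return An `aligned_ref` tibble of `n_seqs` records (not dereplicated:
#'   very low divergence can yield duplicate sequences, as in real
#'   collections).
#' @export
generate_reference <- function(n_seqs, length = 320, divergence = 3,
                               indel_rate = 0, seed = 0) {
  stopifnot(n_seqs >= 2, length >= 1, divergence >= 0)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  mutate_child <- function(seq_chars) {
    k <- stats::rpois(1L, divergence)
    if (k > 0) {
      pos <- sample.int(length, min(k, length))
      for (p in pos) {
        cur <- seq_chars[p]
        opts <- if (cur %in% bases) setdiff(bases, cur) else bases
        seq_chars[p] <- sample(opts, 1L)
      }
    }
    if (indel_rate > 0 && stats::runif(1L) < indel_rate) {
      seq_chars[sample.int(length, 1L)] <- "-"
    }
    seq_chars
  }

  root <- sample(bases, length, replace = TRUE)
  leaves <- list(root)
  clade <- 1L
  while (base::length(leaves) < n_seqs) {
    i <- sample.int(base::length(leaves), 1L)
    parent <- leaves[[i]]
    leaves[[i]] <- mutate_child(parent)
    leaves[[base::length(leaves) + 1L]] <- mutate_child(parent)
    if (base::length(leaves) == 2L) clade <- c(1L, 2L)
    else clade <- c(clade, clade[i])
  }
  aligned_ref(
    id = sprintf("ref%04d", seq_len(n_seqs)),
    aligned_seq = vapply(leaves, paste, "", collapse = ""),
    taxonomy = paste0("Bacteria;clade_", clade)
  )
}

#' Specify a synthetic mock community
#'
#' @param variants Tibble/data frame with `sequence` (unaligned, A/C/G/T) and
#'   `true_fraction` columns; fractions (with contaminants) must sum to 1.
#' @param contaminants Optional tibble with the same columns for unintended
#'   community members.
#' @param total_reads Reads to simulate.
#' @param per_base_error Independent per-base substitution probability, in
#'   `[0, 0.05]`.
#' @param seed Integer seed.
#' @return A list of class `mock_spec`.
#' @export
mock_community_spec <- function(variants, contaminants = NULL,
                                total_reads = 200000, per_base_error = 0.002,
                                seed = 0) {
  stopifnot(per_base_error >= 0, per_base_error <= 0.05, total_reads >= 1)
  all_frac <- sum(variants$true_fraction,
                  if (!is.null(contaminants)) contaminants$true_fraction else 0)
  if (abs(all_frac - 1) > 1e-9) {
    stop("fractions (variants + contaminants) must sum to 1", call. = FALSE)
  }
  structure(
    list(variants = tibble::as_tibble(variants),
         contaminants = if (is.null(contaminants)) NULL
                        else tibble::as_tibble(contaminants),
         total_reads = as.integer(total_reads),
         per_base_error = per_base_error, seed = seed),
    class = "mock_spec"
  )
}

#' Choose mock-community members from a reference
#'
#' Picks `n_variants` dereplicated, gap-free reference sequences that are
#' pairwise at least `min_edit_sep` edits apart (distinct organisms, not
#' sequencing-error neighbors) and assigns them log-spaced abundances between
#' `frac_range[1]` and `frac_range[2]`, normalized to sum 1 — emulating mock
#' designs whose input abundances span several orders of magnitude.
#'
#' @param ref An `aligned_ref` tibble.
#' @param n_variants Community size (default 20).
#' @param frac_range Smallest and largest abundance before normalization
#'   (default `c(1e-4, 0.4)`).
#' @param min_edit_sep Minimum pairwise edit distance between chosen members
#'   (default 3).
#' @param n_contaminants Extra low-level members drawn the same way
#'   (default 0), each at `contaminant_fraction`.
#' @param contaminant_fraction Fraction for each contaminant (default 5e-4).
#' @param seed Integer seed.
#' @return A tibble with `sequence`, `true_fraction`, `intended`,
#'   `reference_id`.
#' @export
design_mock_community <- function(ref, n_variants = 20,
                                  frac_range = c(1e-4, 0.4),
                                  min_edit_sep = 3, n_contaminants = 0,
                                  contaminant_fraction = 5e-4, seed = 0) {
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  derep <- dereplicate_reference(ref)
  plain <- degap(derep$aligned_seq)
  total <- n_variants + n_contaminants
  cand <- sample.int(nrow(derep))
  chosen <- integer(0)
  for (i in cand) {
    if (length(chosen) == total) break
    if (length(chosen) == 0L ||
        all(utils::adist(plain[i], plain[chosen])[1, ] >= min_edit_sep)) {
      chosen <- c(chosen, i)
    }
  }
  if (length(chosen) < total) {
    stop("could not find ", total, " members at least ", min_edit_sep,
         " edits apart; generate a more divergent reference", call. = FALSE)
  }
  fracs <- exp(seq(log(frac_range[1]), log(frac_range[2]),
                   length.out = n_variants))
  contam_total <- n_contaminants * contaminant_fraction
  fracs <- fracs / sum(fracs) * (1 - contam_total)
  tibble::tibble(
    sequence = plain[chosen],
    true_fraction = c(sort(fracs, decreasing = TRUE),
                      rep(contaminant_fraction, n_contaminants)),
    intended = rep(c(TRUE, FALSE), c(n_variants, n_contaminants)),
    reference_id = derep$id[chosen]
  )
}

#' Simulate error-bearing mock-community reads
#'
#' Each read is drawn from a community member with probability equal to its
#' fraction; each base is then substituted independently with probability
#' `per_base_error`, uniformly to one of the three other bases.
#'
#' @param spec A [mock_community_spec()].
#' @return A list with `reads` (a `read_set`) and `truth` (a `ground_truth`
#'   tibble of the intended members; contaminants listed with
#'   `intended = FALSE`).
#' @export
generate_mock_reads <- function(spec) {
  stopifnot(inherits(spec, "mock_spec"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(spec$seed)

  members <- dplyr::bind_rows(
    dplyr::mutate(spec$variants, intended = TRUE),
    if (!is.null(spec$contaminants)) {
      dplyr::mutate(spec$contaminants, intended = FALSE)
    }
  )
  src <- sample.int(nrow(members), spec$total_reads, replace = TRUE,
                    prob = members$true_fraction)
  reads <- members$sequence[src]

  if (spec$per_base_error > 0) {
    lens <- nchar(reads)
    n_err <- stats::rbinom(length(reads), lens, spec$per_base_error)
    has <- which(n_err > 0L)
    bases <- c("A", "C", "G", "T")
    for (r in has) {
      chars <- strsplit(reads[r], "", fixed = TRUE)[[1L]]
      pos <- sample.int(lens[r], n_err[r])
      for (p in pos) {
        chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      }
      reads[r] <- paste(chars, collapse = "")
    }
  }

  lens <- nchar(members$sequence)
  # contaminant fractions are reported on the same scale as the intended
  # members (intended fractions renormalized to 1)
  truth <- ground_truth(
    v4_sequence = members$sequence,
    expected_fraction = members$true_fraction /
      sum(members$true_fraction[members$intended]),
    intended = members$intended
  )
  rs <- read_set(reads, sample_id = "synthetic_mock",
                 min_len = min(lens), max_len = max(lens))
  list(reads = rs, truth = truth)
}
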