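#' Denoising parameters
#'
#' Defaults follow the published operating point: up to 20 latent-space
#' nearest neighbors within a 15 bp-equivalent radius, a parent at least
#' 20-fold more abundant than the child, and at most 1 base difference per
#' 64 aligned bases (98.5% match) confirmed by exact edit distance.
#'
#' @param max_neighbors Maximum candidate parents per sequence.
#' @param latent_radius Latent-space search radius, base-pair-equivalent
#'   units.
#' @param min_fold Minimum parent/child abundance ratio (inclusive).
#' @param max_error_per_base Maximum edit distance per aligned base
#'   (inclusive).
#' @return A list of class `denoise_params`.
#' @export
denoise_params <- function(max_neighbors = 20, latent_radius = 15,
                           min_fold = 20, max_error_per_base = 1 / 64) {
  stopifnot(max_neighbors > 0, latent_radius > 0, min_fold > 0,
            max_error_per_base > 0)
  structure(
    list(max_neighbors = as.integer(max_neighbors),
         latent_radius = latent_radius, min_fold = min_fold,
         max_error_per_base = max_error_per_base),
    class = "denoise_params"
  )
}

#' Attach latent coordinates to a unique-sequence table
#'
#' @param tbl A `unique_seq_tbl` from [dereplicate_reads()].
#' @param model A trained `encoder_model`.
#' @return `tbl` with a `latent` matrix column.
#' @export
encode_unique_sequences <- function(tbl, model) {
  tbl$latent <- encode_sequences(model, tbl$sequence)
  tbl
}

# Number of rows (table sorted by descending count) whose count is at least
# `thr`; counts ties included.
eligible_prefix <- function(counts, thr) {
  findInterval(-thr, -counts)
}

#' Find candidate parents in latent space
#'
#' For each unique sequence, returns up to `max_neighbors` rows that are
#' within `latent_radius` (Euclidean) in the latent space and at least
#' `min_fold` times more abundant, in ascending latent-distance order. The
#' table must be sorted by descending count (as [dereplicate_reads()]
#' returns it), so the abundance-eligible rows form a prefix that is scanned
#' exactly; results equal a brute-force scan by construction.
#'
#' @param tbl A `unique_seq_tbl` with a `latent` matrix column.
#' @param params A [denoise_params()].
#' @return A list (one element per row) of tibbles with `index`,
#'   `latent_dist`.
#' @export
find_parent_candidates <- function(tbl, params = denoise_params()) {
  stopifnot("latent" %in% names(tbl))
  counts <- tbl$count
  if (is.unsorted(rev(counts))) {
    stop("table must be sorted by descending count", call. = FALSE)
  }
  X <- tbl$latent
  sq <- rowSums(X^2)
  r2 <- params$latent_radius^2
  lapply(seq_len(nrow(tbl)), function(s) {
    p <- eligible_prefix(counts, params$min_fold * counts[s])
    empty <- tibble::tibble(index = integer(0), latent_dist = numeric(0))
    if (p < 1L) return(empty)
    pre <- seq_len(p)
    pre <- pre[pre != s]
    if (!length(pre)) return(empty)
    d2 <- pmax(sq[pre] + sq[s] - 2 * drop(X[pre, , drop = FALSE] %*% X[s, ]), 0)
    keep <- which(d2 <= r2)
    if (!length(keep)) return(empty)
    ord <- keep[order(d2[keep])]
    ord <- ord[seq_len(min(length(ord), params$max_neighbors))]
    tibble::tibble(index = pre[ord], latent_dist = sqrt(d2[ord]))
  })
}

# Edit distance and optimal global-alignment path length between one child
# and candidate sequences, via the C Levenshtein implementation with
# operation counts. Path length = matches + substitutions + insertions +
# deletions = nchar(child) + insertions.
edit_distance_stats <- function(child, candidates) {
  d <- utils::adist(child, candidates, counts = TRUE)
  cnt <- attr(d, "counts")
  ins <- cnt[1, , "ins"]
  tibble::tibble(
    edit_distance = as.integer(d[1, ]),
    align_length = nchar(child) + as.integer(ins)
  )
}

#' Confirm parent candidates by exact edit distance
#'
#' A candidate is retained iff its edit distance to the child, divided by the
#' optimal global-alignment path length, is at most
#' `params$max_error_per_base`.
#'
#' @param child Child sequence string.
#' @param candidates Character vector of candidate parent sequences.
#' @param params A [denoise_params()].
#' @return A tibble with `edit_distance`, `align_length`, `error_rate`,
#'   `keep` for each candidate, in input order.
#' @export
confirm_by_edit_distance <- function(child, candidates,
                                     params = denoise_params()) {
  if (!length(candidates)) {
    return(tibble::tibble(edit_distance = integer(0),
                          align_length = integer(0),
                          error_rate = numeric(0), keep = logical(0)))
  }
  st <- edit_distance_stats(child, candidates)
  st$error_rate <- st$edit_distance / st$align_length
  st$keep <- st$error_rate <= params$max_error_per_base
  st
}

#' Select the likely parent among confirmed candidates
#'
#' The closest candidate by edit distance wins; ties favor the more abundant
#' candidate, remaining ties the lower row index (stable).
#'
#' @param retained A tibble/data frame with columns `index`, `edit_distance`,
#'   `count`.
#' @return The winning `index`, or `NA_integer_` if `retained` is empty (the
#'   child is then an ASV in its own right).
#' @export
select_parent <- function(retained) {
  if (is.null(retained) || nrow(retained) == 0L) return(NA_integer_)
  pick <- order(retained$edit_distance, -retained$count, retained$index)[1L]
  retained$index[pick]
}

#' Compute child-to-parent links for a whole sample
#'
#' One pass over the abundance-sorted unique-sequence table: latent-space
#' candidate search, edit-distance confirmation, and parent selection per
#' sequence.
#'
#' @param tbl A `unique_seq_tbl` with a `latent` matrix column, sorted by
#'   descending count.
#' @param params A [denoise_params()].
#' @return A tibble of links with `child`, `parent` (row indices into `tbl`)
#'   and `edit_distance`; sequences with no parent are absent.
#' @export
find_parent_links <- function(tbl, params = denoise_params()) {
  cands <- find_parent_candidates(tbl, params)
  links <- lapply(seq_len(nrow(tbl)), function(s) {
    cand <- cands[[s]]
    if (nrow(cand) == 0L) return(NULL)
    conf <- confirm_by_edit_distance(tbl$sequence[s], tbl$sequence[cand$index],
                                     params)
    ok <- which(conf$keep)
    if (!length(ok)) return(NULL)
    parent <- select_parent(tibble::tibble(
      index = cand$index[ok],
      edit_distance = conf$edit_distance[ok],
      count = tbl$count[cand$index[ok]]
    ))
    ed <- conf$edit_distance[ok][match(parent, cand$index[ok])]
    tibble::tibble(child = s, parent = parent, edit_distance = ed)
  })
  out <- dplyr::bind_rows(links)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(child = integer(0), parent = integer(0),
                          edit_distance = integer(0))
  }
  out
}

#' Aggregate parent/child links into ASVs
#'
#' Traverses child-to-parent links until a parentless sequence is reached;
#' each parentless sequence becomes an ASV whose abundance is its own count
#' plus that of all descendants. The abundance-fold rule makes the links
#' acyclic; this is asserted at runtime.
#'
#' @param tbl A `unique_seq_tbl` (with or without latent coordinates).
#' @param links Link tibble from [find_parent_links()].
#' @return A tibble of class `asv_tbl` with `asv_id`, `sequence`, `count`,
#'   `relative_abundance`, a `members` list-column of constituent row
#'   indices, and (when present in `tbl`) the root's `latent` coordinates.
#' @export
resolve_asvs <- function(tbl, links) {
  n <- nrow(tbl)
  parent <- rep(NA_integer_, n)
  parent[links$child] <- links$parent
  root <- integer(n)
  for (s in seq_len(n)) {
    cur <- s
    steps <- 0L
    while (!is.na(parent[cur])) {
      cur <- parent[cur]
      steps <- steps + 1L
      if (steps > n) {
        stop("internal-consistency error: cycle in parent links",
             call. = FALSE)
      }
    }
    root[s] <- cur
  }
  roots <- sort(unique(root))
  agg <- vapply(roots, function(r) sum(tbl$count[root == r]), numeric(1))
  ord <- order(-agg, tbl$sequence[roots])
  roots <- roots[ord]
  agg <- agg[ord]
  out <- tibble::tibble(
    asv_id = paste0("asv", seq_along(roots)),
    sequence = tbl$sequence[roots],
    count = as.integer(agg),
    relative_abundance = agg / sum(agg),
    members = lapply(roots, function(r) which(root == r))
  )
  if ("latent" %in% names(tbl)) {
    out$latent <- tbl[["latent"]][roots, , drop = FALSE]
  }
  attr(out, "sample_id") <- attr(tbl, "sample_id")
  class(out) <- unique(c("asv_tbl", class(out)))
  out
}

#' Annotate ASVs with their nearest known reference
#'
#' Finds the latent-space nearest reference for each ASV, then computes the
#' percent identity to that reference by exact global alignment (gaps removed
#' from the reference). `exact_match` is true iff identity is 100%.
#'
#' @param asvs An `asv_tbl` with a `latent` matrix column.
#' @param ref The dereplicated `aligned_ref` the latent space was built from.
#' @param space The `latent_space` over `ref`.
#' @return `asvs` with `nearest_reference`, `identity`, `exact_match` and
#'   `taxonomy` columns.
#' @export
annotate_asvs <- function(asvs, ref, space) {
  stopifnot("latent" %in% names(asvs), nrow(ref) == nrow(space$coords))
  R <- space$coords
  sqR <- rowSums(R^2)
  ref_plain <- degap(ref$aligned_seq)
  nearest <- vapply(seq_len(nrow(asvs)), function(i) {
    x <- asvs$latent[i, ]
    which.min(sqR - 2 * drop(R %*% x))
  }, integer(1))
  ident <- vapply(seq_len(nrow(asvs)), function(i) {
    a <- asvs$sequence[i]
    b <- ref_plain[nearest[i]]
    if (a == b) return(1)
    # identity = matched columns / alignment path length
    st <- edit_distance_stats(a, b)
    (st$align_length - count_nonmatch_columns(a, b)) / st$align_length
  }, numeric(1))
  asvs$nearest_reference <- ref$id[nearest]
  asvs$identity <- ident
  asvs$exact_match <- asvs$sequence == ref_plain[nearest]
  asvs$taxonomy <- ref$taxonomy[nearest]
  asvs
}

# Number of non-match alignment columns (substitutions + insertions +
# deletions) on an optimal unit-cost global alignment.
count_nonmatch_columns <- function(a, b) {
  d <- utils::adist(a, b, counts = TRUE)
  cnt <- attr(d, "counts")
  sum(cnt[1, 1, c("ins", "del", "sub")])
}

#' Drop externally flagged chimeric ASVs
#'
#' Chimera detection itself is delegated to an external
#' `uchime_denovo`-compatible tool (feed it [write_size_fasta()] output);
#' this applies its verdict.
#'
#' @param asvs An `asv_tbl`.
#' @param flagged_ids Character vector of `asv_id`s flagged as chimeric.
#' @return `asvs` without the flagged rows; surviving counts unchanged.
#' @export
remove_chimeras_external <- function(asvs, flagged_ids) {
  unknown <- setdiff(flagged_ids, asvs$asv_id)
  if (length(unknown)) {
    warning("ignoring unknown flagged ids: ", paste(unknown, collapse = ", "))
  }
  out <- asvs[!asvs$asv_id %in% flagged_ids, , drop = FALSE]
  attr(out, "n_chimeras_removed") <- sum(asvs$asv_id %in% flagged_ids)
  out
}

#' Denoise one sample end to end
#'
#' Convenience wrapper: encodes the unique sequences, links children to
#' parents, aggregates ASVs, and annotates them against the reference.
#'
#' @param tbl A `unique_seq_tbl` from [dereplicate_reads()].
#' @param model A trained `encoder_model`.
#' @param ref Dereplicated `aligned_ref`.
#' @param space `latent_space` over `ref`.
#' @param params A [denoise_params()].
#' @return An annotated `asv_tbl`; the link table is attached as attribute
#'   `links`.
#' @export
denoise_sample <- function(tbl, model, ref, space,
                           params = denoise_params()) {
  tbl <- encode_unique_sequences(tbl, model)
  links <- find_parent_links(tbl, params)
  asvs <- resolve_asvs(tbl, links)
  asvs <- annotate_asvs(asvs, ref, space)
  attr(asvs, "links") <- links
  asvs
}

#' Write an ASV table to TSV
#'
#' @param asvs An annotated `asv_tbl`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(asvs, path) {
  cols <- intersect(
    c("asv_id", "sequence", "count", "relative_abundance",
      "nearest_reference", "identity", "exact_match", "taxonomy"),
    names(asvs)
  )
  utils::write.table(as.data.frame(asvs[, cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
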