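#' Dilation factor for exponential rank sampling
#'
#' Solves `N = n * f^(m - n)` for the factor `f` used to pick comparison
#' partners at exponentially spaced ranks `n * f^i` in each sequence's
#' distance-sorted neighbor list, so that the schedule reaches the most
#' distant sequence exactly at the last dilated sample.
#'
#' @param N Total number of unique sequences.
#' @param m Total samplings per sequence.
#' @param n Number of nearest neighbors included before dilation starts.
#' @return The dilation factor `f = exp(log(N / n) / (m - n))`.
#' @export
dilation_factor <- function(N, m, n) {
  if (n < 1 || m <= n) stop("require m > n >= 1", call. = FALSE)
  if (N <= n) {
    stop("domain error: N must exceed n (sampling schedule degenerate)",
         call. = FALSE)
  }
  exp(log(N / n) / (m - n))
}

#' Build the pairwise-comparison sampling plan
#'
#' For every reference sequence the plan lists `m` distinct comparison
#' partners: the `n` nearest by alignment distance, then `m - n` partners at
#' exponentially dilated ranks `round(n * f^i)` of the distance-sorted list
#' (1-based ranks counted with the sequence itself at rank 1). A dilated rank
#' that collides with an already-chosen partner advances to the next unused
#' rank upward (wrapping downward from the end if needed), so each list has
#' exactly `m` distinct entries and the final dilated rank is `N`, the most
#' distant sequence. Ties in distance are broken by record index.
#'
#' @param ref An `aligned_ref` tibble of `N` dereplicated records, `N >= m + 1`.
#' @param n Nearest-neighbor count (default 300, as used at full reference
#'   scale).
#' @param m Total partners per sequence (default 500).
#' @param dist_matrix Optional precomputed `N x N` alignment distance matrix;
#'   computed with [reference_distance_matrix()] when missing.
#' @return An object of class `sampling_plan`: a list with integer matrices
#'   `partners` and `distances` (`N x m`, row i = partners of sequence i and
#'   their alignment distances), the raw `dilated_ranks`, and scalars
#'   `N`, `n`, `m`, `f`.
#' @export
build_sampling_plan <- function(ref, n = 300, m = 500, dist_matrix = NULL) {
  N <- nrow(ref)
  if (N <= m) {
    stop("insufficient reference: need more than m = ", m, " sequences, got ",
         N, call. = FALSE)
  }
  f <- dilation_factor(N, m, n)
  if (is.null(dist_matrix)) dist_matrix <- reference_distance_matrix(ref)
  dilated_ranks <- round(n * f^seq_len(m - n))

  partners <- matrix(0L, nrow = N, ncol = m)
  distances <- matrix(0L, nrow = N, ncol = m)
  for (i in seq_len(N)) {
    di <- dist_matrix[i, ]
    di[i] <- -Inf                       # self is rank 1 by construction
    ord <- order(di)                    # stable: distance ties break by index
    chosen <- logical(N)
    chosen[1L] <- TRUE                  # self
    chosen[2:(n + 1L)] <- TRUE          # the n nearest
    sel <- ord[2:(n + 1L)]
    for (k in seq_len(m - n)) {
      r <- max(dilated_ranks[k], 2L)
      while (r <= N && chosen[r]) r <- r + 1L
      if (r > N) {
        r <- N
        while (chosen[r]) r <- r - 1L
      }
      chosen[r] <- TRUE
      sel <- c(sel, ord[r])
    }
    partners[i, ] <- sel
    distances[i, ] <- dist_matrix[i, sel]
  }

  structure(
    list(partners = partners, distances = distances,
         dilated_ranks = dilated_ranks, N = N, n = n, m = m, f = f),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat("<sampling_plan> N =", x$N, " n =", x$n, " m =", x$m,
      " f =", format(x$f, digits = 7), "\n")
  invisible(x)
}
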