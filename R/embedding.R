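#' Loss for one latent/alignment distance pair
#'
#' The squared relative error `((d - D) / (D + epsilon))^2`. Relative scaling
#' makes small alignment distances count heavily, so the optimized space
#' resolves single-base differences, while `epsilon ~ 1` regularizes the loss
#' for vanishing distances.
#'
#' @param d Latent-space Euclidean distance(s).
#' @param D Alignment distance(s), base pairs.
#' @param epsilon Positive regularizer, default 1.
#' @return Non-negative loss value(s).
#' @export
embedding_loss <- function(d, D, epsilon = 1) {
  stopifnot(epsilon > 0)
  ((d - D) / (D + epsilon))^2
}

#' Euclidean distance between latent coordinates
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
latent_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(sum((a - b)^2))
}

#' Training configuration for the latent space
#'
#' @param dim Latent dimensionality (default 10).
#' @param epsilon Loss regularizer (default 1).
#' @param sigma_init Standard deviation of the centered Gaussian used to
#'   initialize coordinates (default 10).
#' @param learning_rate Fixed gradient-descent step size (default 4; the
#'   relative loss makes gradients small in absolute terms, so steps of order
#'   1 are stable).
#' @param max_iterations Iteration cap (default 4000).
#' @param convergence_tol Stop when the relative change of the mean loss
#'   between consecutive iterations falls below this (default 1e-5, i.e.
#'   stable to five significant digits).
#' @param seed Integer seed for the Gaussian initialization.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(dim = 10, epsilon = 1, sigma_init = 10,
                             learning_rate = 4, max_iterations = 4000,
                             convergence_tol = 1e-5, seed = 0) {
  stopifnot(dim >= 1, epsilon > 0, sigma_init > 0, learning_rate > 0,
            max_iterations >= 1, convergence_tol > 0)
  structure(
    list(dim = dim, epsilon = epsilon, sigma_init = sigma_init,
         learning_rate = learning_rate, max_iterations = max_iterations,
         convergence_tol = convergence_tol, seed = seed),
    class = "embedding_config"
  )
}

#' Train the distance-preserving latent space
#'
#' Places every reference sequence at a point in a low-dimensional Euclidean
#' space such that latent distances `d` reproduce alignment distances `D`
#' over all pairs of the sampling plan. Coordinates start i.i.d.
#' `Normal(0, sigma_init^2)` and are adjusted by full-batch gradient descent
#' on the mean of [embedding_loss()] over planned pairs; both endpoints of a
#' pair receive gradient, each point stepping by `learning_rate` times the
#' average gradient over its own pairs. Training stops when the relative
#' change in mean loss drops below `convergence_tol` or at `max_iterations`.
#'
#' @param ref An `aligned_ref` tibble (dereplicated).
#' @param plan A [build_sampling_plan()] result for `ref`.
#' @param config An [embedding_config()].
#' @return An object of class `latent_space`: list with `coords` (`N x dim`
#'   matrix, rownames = reference ids; units approximate base-pair
#'   differences), `loss_history`, `iterations`, `converged`, and the config.
#' @export
train_embedding <- function(ref, plan, config = embedding_config()) {
  stopifnot(inherits(plan, "sampling_plan"), inherits(config, "embedding_config"))
  N <- plan$N
  if (N != nrow(ref)) {
    stop("plan was built for ", N, " sequences but ref has ", nrow(ref),
         call. = FALSE)
  }
  m <- plan$m
  ii <- rep(seq_len(N), each = m)
  jj <- as.integer(t(plan$partners))
  Dv <- as.numeric(t(plan$distances))
  eps <- config$epsilon
  lr <- config$learning_rate
  denom2 <- (Dv + eps)^2
  n_touch <- m + tabulate(jj, nbins = N)   # pairs touching each coordinate

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)
  X <- matrix(stats::rnorm(N * config$dim, sd = config$sigma_init),
              nrow = N, ncol = config$dim)

  loss_history <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    diff <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
    d <- sqrt(rowSums(diff^2))
    resid <- d - Dv
    mean_loss <- mean(resid^2 / denom2)
    if (!is.finite(mean_loss)) {
      stop("divergence: non-finite loss at iteration ", it,
           "; lower the learning_rate", call. = FALSE)
    }
    loss_history <- c(loss_history, mean_loss)
    if (abs(prev - mean_loss) / max(mean_loss, .Machine$double.eps) <
          config$convergence_tol) {
      converged <- TRUE
      break
    }
    prev <- mean_loss
    g <- 2 * resid / denom2 / pmax(d, 1e-12)
    gp <- diff * g
    G <- rowsum(gp, ii, reorder = TRUE)
    Gj <- rowsum(gp, jj, reorder = TRUE)
    jrows <- as.integer(rownames(Gj))
    G[jrows, ] <- G[jrows, ] - Gj
    X <- X - lr * G / n_touch
  }

  rownames(X) <- ref$id
  structure(
    list(coords = X, loss_history = loss_history,
         iterations = length(loss_history), converged = converged,
         config = config),
    class = "latent_space"
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.latent_space <- function(x, ...) {
  cat("<latent_space> ", nrow(x$coords), " sequences in ", ncol(x$coords),
      " dimensions; final mean loss ",
      format(utils::tail(x$loss_history, 1), digits = 5),
      if (x$converged) " (converged)" else " (iteration cap reached)",
      "\n", sep = "")
  invisible(x)
}

#' Tidy a latent space into a tibble
#'
#' @param x A `latent_space`.
#' @param ... Unused.
#' @return A tibble with `id` and one `dim1..dimK` column per coordinate.
#' @method tidy latent_space
#' @export
tidy.latent_space <- function(x, ...) {
  coords <- x$coords
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  dplyr::bind_cols(tibble::tibble(id = rownames(coords)),
                   tibble::as_tibble(coords))
}

#' One-row training summary of a latent space
#'
#' @param x A `latent_space`.
#' @param ... Unused.
#' @return A tibble with sequence count, dimensionality, iteration count,
#'   initial and final mean loss and convergence flag.
#' @method glance latent_space
#' @export
glance.latent_space <- function(x, ...) {
  tibble::tibble(
    n_sequences = nrow(x$coords),
    dim = ncol(x$coords),
    iterations = x$iterations,
    initial_loss = x$loss_history[1],
    final_loss = utils::tail(x$loss_history, 1),
    converged = x$converged
  )
}

#' Write latent coordinates to TSV
#'
#' @param space A `latent_space`.
#' @param path Output TSV path (id + one column per dimension).
#' @return `path`, invisibly.
#' @export
write_latent_space <- function(space, path) {
  utils::write.table(tidy.latent_space(space), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read latent coordinates from TSV
#'
#' @param path TSV written by [write_latent_space()].
#' @return A `latent_space` with coordinates only (no loss history).
#' @export
read_latent_space <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(X) <- list(tab[[1]], NULL)
  structure(
    list(coords = X, loss_history = numeric(0), iterations = 0L,
         converged = NA, config = NULL),
    class = "latent_space"
  )
}
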