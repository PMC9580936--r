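#' Encoder configuration
#'
#' Describes the fully convolutional network that maps one-hot encoded,
#' unaligned V4 sequences to latent coordinates: a stack of 1-D convolutions
#' over the length axis, each but the last followed by batch normalization
#' and ReLU, with one width-2 max-pooling inserted after the first
#' `maxpool_after` convolutions, and a final global average over the valid
#' (unpadded) length yielding the `output_dim` vector.
#'
#' The full-scale recipe uses 32 convolutional layers, batches of 200 and
#' 50,000 Adam steps at learning rate 1e-4; the defaults here are a desk-scale
#' preset (6 convolutional layers, batches of 64, 1,500 Adam steps at 2e-3)
#' calibrated so a reference of a few hundred sequences trains in minutes
#' with every training sequence mapped nearer its own latent target than any
#' other.
#'
#' @param input_length Fixed input frame in bases; shorter sequences are
#'   zero-padded on the right. Default 280, covering 225-275 bp merged reads.
#'   Must be even (one max-pooling halves the frame).
#' @param alphabet Ordered input alphabet (fixed to A, C, G, T).
#' @param conv_layers Number of convolutional layers (>= 3).
#' @param channels Output-channel schedule, one entry per convolution; the
#'   last must equal `output_dim`. Default: 32, 32, then 48s, then
#'   `output_dim`.
#' @param kernels Kernel-width schedule (odd widths); default 7, then 3s,
#'   then 1.
#' @param maxpool_after Number of initial convolutions before the single
#'   max-pooling layer (default 2).
#' @param output_dim Latent dimensionality (default 10; must match the
#'   trained latent space).
#' @param learning_rate Adam learning rate (default 2e-3 at desk scale;
#'   1e-4 in the full-scale recipe).
#' @param batch_size Sequences per training batch (default 64 at desk scale;
#'   200 at full scale).
#' @param total_batches Number of training batches (default 1500 at desk
#'   scale; 50,000 at full scale).
#' @param seed Integer seed governing parameter initialization and batch
#'   sampling.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(input_length = 280,
                           alphabet = c("A", "C", "G", "T"),
                           conv_layers = 6,
                           channels = NULL,
                           kernels = NULL,
                           maxpool_after = 2,
                           output_dim = 10,
                           learning_rate = 2e-3,
                           batch_size = 64,
                           total_batches = 1500,
                           seed = 0) {
  if (conv_layers < 3) {
    stop("config error: conv_layers must be at least 3", call. = FALSE)
  }
  if (input_length %% 2L != 0L) {
    stop("config error: input_length must be even", call. = FALSE)
  }
  if (is.null(channels)) {
    channels <- c(32, 32, rep(48, conv_layers - 3L), output_dim)
  }
  if (is.null(kernels)) {
    kernels <- c(7L, rep(3L, conv_layers - 2L), 1L)
  }
  if (length(channels) != conv_layers) {
    stop("config error: channels schedule length (", length(channels),
         ") must equal conv_layers (", conv_layers, ")", call. = FALSE)
  }
  if (length(kernels) != conv_layers || any(kernels %% 2L == 0L)) {
    stop("config error: kernels must give one odd width per layer",
         call. = FALSE)
  }
  if (channels[conv_layers] != output_dim) {
    stop("config error: last channel count must equal output_dim",
         call. = FALSE)
  }
  if (maxpool_after < 1 || maxpool_after >= conv_layers) {
    stop("config error: maxpool_after must lie strictly inside the stack",
         call. = FALSE)
  }
  structure(
    list(input_length = as.integer(input_length), alphabet = alphabet,
         conv_layers = as.integer(conv_layers),
         channels = as.integer(channels), kernels = as.integer(kernels),
         maxpool_after = as.integer(maxpool_after),
         output_dim = as.integer(output_dim),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         total_batches = as.integer(total_batches), seed = seed),
    class = "encoder_config"
  )
}

#' Build an untrained encoder
#'
#' Allocates the network described by an [encoder_config()], with He-scaled
#' Gaussian weight initialization seeded by `config$seed`.
#'
#' @param config An [encoder_config()].
#' @return An `encoder_model` (untrained).
#' @export
build_encoder <- function(config) {
  stopifnot(inherits(config, "encoder_config"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)
  new_encoder(config)
}

# Allocate an encoder using the current RNG state (callers manage seeding).
new_encoder <- function(config) {
  in_ch <- length(config$alphabet)
  layers <- vector("list", config$conv_layers)
  for (i in seq_len(config$conv_layers)) {
    out_ch <- config$channels[i]
    k <- config$kernels[i]
    fan_in <- in_ch * k
    layers[[i]] <- list(
      W = matrix(stats::rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)),
                 nrow = out_ch),
      b = numeric(out_ch),
      kernel = k, in_ch = in_ch, out_ch = out_ch,
      bn = i < config$conv_layers,
      gamma = rep(1, out_ch), beta = numeric(out_ch),
      run_mean = numeric(out_ch), run_var = rep(1, out_ch)
    )
    in_ch <- out_ch
  }
  structure(
    list(config = config, layers = layers, trained = FALSE,
         target_center = numeric(config$output_dim), target_scale = 1,
         loss_curve = numeric(0), space_checksum = NA_character_),
    class = "encoder_model"
  )
}

#' @export
print.encoder_model <- function(x, ...) {
  cfg <- x$config
  cat("<encoder_model> ", cfg$conv_layers, " conv layers (channels ",
      paste(cfg$channels, collapse = "-"), "), input frame ",
      cfg$input_length, ", output dim ", cfg$output_dim,
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}

# Pack sequences into the 4 x (L*B) one-hot layout; returns the matrix and
# each sequence's valid length.
pack_onehot <- function(seqs, config) {
  L <- config$input_length
  B <- length(seqs)
  lens <- nchar(seqs)
  if (any(lens > L)) {
    stop("encoding error: sequence longer than input_length (", L, ")",
         call. = FALSE)
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  codes <- lapply(chars, function(ch) {
    idx <- match(ch, config$alphabet)
    if (anyNA(idx)) {
      stop("encoding error: symbol(s) outside alphabet: ",
           paste(unique(ch[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    idx
  })
  X <- matrix(0, length(config$alphabet), L * B)
  col <- unlist(lapply(seq_len(B), function(b) (b - 1L) * L + seq_len(lens[b])),
                use.names = FALSE)
  X[cbind(unlist(codes, use.names = FALSE), col)] <- 1
  list(X = X, valid = lens, B = B)
}

encoder_forward <- function(model, X, valid, B, training = FALSE,
                            bn_momentum = 0.1) {
  cfg <- model$config
  L <- cfg$input_length
  caches <- vector("list", cfg$conv_layers)
  pool_cache <- NULL
  for (i in seq_len(cfg$conv_layers)) {
    ly <- model$layers[[i]]
    cv <- conv_forward(X, ly$W, ly$b, ly$kernel, L, B)
    cache <- list(X_in = cv$X, L = L)
    X <- cv$Y
    if (ly$bn) {
      bn <- bn_forward(X, ly$gamma, ly$beta,
                       list(mean = ly$run_mean, var = ly$run_var), training,
                       momentum = bn_momentum)
      if (training) {
        model$layers[[i]]$run_mean <- bn$running$mean
        model$layers[[i]]$run_var <- bn$running$var
      }
      cache$xhat <- bn$xhat
      cache$invstd <- bn$invstd
      X <- bn$Y
      relu_mask <- X > 0
      cache$relu_mask <- relu_mask
      X <- X * relu_mask
    }
    caches[[i]] <- cache
    if (i == cfg$maxpool_after) {
      mp <- maxpool_forward(X, L, B)
      pool_cache <- list(take_a = mp$take_a, idx = mp$idx, C = nrow(X), L = L)
      X <- mp$Y
      L <- L %/% 2L
      valid <- pmax(1L, ceiling(valid / 2))
    }
  }
  M <- gap_matrix(valid, L, B)
  list(Y = X %*% M, model = model, caches = caches, pool_cache = pool_cache,
       gap_M = M, pre_gap = X, L_final = L)
}

encoder_backward <- function(model, fw, dY, B) {
  cfg <- model$config
  grads <- vector("list", cfg$conv_layers)
  dX <- tcrossprod(dY, fw$gap_M)
  for (i in rev(seq_len(cfg$conv_layers))) {
    if (i == cfg$maxpool_after) {
      pc <- fw$pool_cache
      dX <- maxpool_backward(dX, pc$take_a, pc$idx, pc$C, pc$L, B)
    }
    ly <- model$layers[[i]]
    cache <- fw$caches[[i]]
    g <- list()
    if (ly$bn) {
      dX <- dX * cache$relu_mask
      bb <- bn_backward(dX, cache$xhat, cache$invstd, ly$gamma)
      g$gamma <- bb$dgamma
      g$beta <- bb$dbeta
      dX <- bb$dX
    }
    cb <- conv_backward(dX, cache$X_in, ly$W, ly$kernel, cache$L, B)
    g$W <- cb$dW
    g$b <- cb$db
    dX <- cb$dX
    grads[[i]] <- g
  }
  grads
}

#' Train the encoder against a latent space
#'
#' Minimizes the mean Euclidean distance between the network output and each
#' training sequence's precomputed latent coordinate, over randomly sampled
#' batches (Adam optimizer). Training sequences are the dereplicated reference
#' with gaps removed. Targets are centered and jointly rescaled internally for
#' conditioning; predictions are mapped back to latent units, and the reported
#' loss curve is in latent (base-pair-equivalent) units.
#'
#' @param sequences Character vector of unaligned training sequences
#'   (gaps removed), one per latent point.
#' @param space A `latent_space` from [train_embedding()], or a numeric
#'   matrix of target coordinates with one row per sequence.
#' @param config An [encoder_config()].
#' @return A trained `encoder_model` with a `loss_curve` of per-batch mean
#'   Euclidean errors.
#' @export
train_encoder <- function(sequences, space, config = encoder_config()) {
  targets <- if (inherits(space, "latent_space")) space$coords else space
  targets <- as.matrix(targets)
  if (length(sequences) != nrow(targets)) {
    stop("need one target coordinate per training sequence", call. = FALSE)
  }
  if (ncol(targets) != config$output_dim) {
    stop("config error: output_dim (", config$output_dim,
         ") does not match the latent space (", ncol(targets), ")",
         call. = FALSE)
  }

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)
  model <- new_encoder(config)   # batch sampling continues the same stream

  center <- colMeans(targets)
  scale <- stats::sd(sweep(targets, 2, center))
  if (!is.finite(scale) || scale == 0) scale <- 1
  Tstd <- t((t(targets) - center) / scale)   # N x dim
  model$target_center <- center
  model$target_scale <- scale

  N <- length(sequences)
  packed_all <- pack_onehot(sequences, config)
  L <- config$input_length
  bsz <- min(config$batch_size, N)

  states <- lapply(model$layers, function(ly) {
    s <- list(W = adam_init(list(ly$W))[[1]], b = adam_init(list(ly$b))[[1]])
    if (ly$bn) {
      s$gamma <- adam_init(list(ly$gamma))[[1]]
      s$beta <- adam_init(list(ly$beta))[[1]]
    }
    s
  })

  loss_curve <- numeric(config$total_batches)
  sample_cols <- function(idx) {
    cols <- as.integer(outer(seq_len(L), (idx - 1L) * L, `+`))
    packed_all$X[, cols, drop = FALSE]
  }

  for (t in seq_len(config$total_batches)) {
    idx <- sample.int(N, bsz, replace = FALSE)
    X <- sample_cols(idx)
    fw <- encoder_forward(model, X, packed_all$valid[idx], bsz,
                          training = TRUE)
    model <- fw$model
    R <- fw$Y - t(Tstd[idx, , drop = FALSE])   # dim x B residuals (std units)
    d <- sqrt(colSums(R^2))                    # per-sample Euclidean norm
    d <- pmax(d, 1e-12)
    loss_curve[t] <- mean(d) * scale
    if (!is.finite(loss_curve[t])) {
      stop("divergence: non-finite encoder loss at batch ", t, call. = FALSE)
    }
    dY <- sweep(R, 2, d, "/") / bsz
    grads <- encoder_backward(model, fw, dY, bsz)
    for (i in seq_along(model$layers)) {
      for (nm in names(grads[[i]])) {
        st <- adam_step(model$layers[[i]][[nm]], grads[[i]][[nm]],
                        states[[i]][[nm]], config$learning_rate, t)
        model$layers[[i]][[nm]] <- st$p
        states[[i]][[nm]] <- st$state
      }
    }
  }

  # freeze batch-norm statistics at their exact full-training-set values so
  # inference matches the converged training distribution
  fw <- encoder_forward(model, packed_all$X, packed_all$valid, N,
                        training = TRUE, bn_momentum = 1)
  model <- fw$model

  model$trained <- TRUE
  model$loss_curve <- loss_curve
  model$space_checksum <- sprintf("n%d_d%d_%.6e", nrow(targets),
                                  ncol(targets), sum(targets))
  model
}

#' Map sequences into the latent space
#'
#' Runs the trained encoder in inference mode; no alignment is performed.
#'
#' @param model A trained `encoder_model`.
#' @param seqs Character vector of sequences over `A/C/G/T`, each no longer
#'   than the model's `input_length`.
#' @param chunk Sequences per forward pass (memory knob).
#' @return A numeric matrix with one row per input sequence and
#'   `output_dim` columns.
#' @export
encode_sequences <- function(model, seqs, chunk = 512L) {
  stopifnot(inherits(model, "encoder_model"))
  if (!model$trained) {
    warning("encoding with an untrained model")
  }
  n <- length(seqs)
  out <- matrix(NA_real_, n, model$config$output_dim)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    packed <- pack_onehot(seqs[idx], model$config)
    fw <- encoder_forward(model, packed$X, packed$valid, packed$B,
                          training = FALSE)
    out[idx, ] <- t(fw$Y) * model$target_scale +
      matrix(model$target_center, length(idx), model$config$output_dim,
             byrow = TRUE)
  }
  out
}

#' One-row training summary of an encoder
#'
#' @param x An `encoder_model`.
#' @param ... Unused.
#' @return A tibble with layer counts, batch statistics and the final
#'   smoothed training loss (latent units).
#' @method glance encoder_model
#' @export
glance.encoder_model <- function(x, ...) {
  k <- min(50L, length(x$loss_curve))
  tibble::tibble(
    conv_layers = x$config$conv_layers,
    parameters = sum(vapply(x$layers, function(l) {
      length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
    }, numeric(1))),
    total_batches = x$config$total_batches,
    batch_size = x$config$batch_size,
    final_loss = if (k > 0) mean(utils::tail(x$loss_curve, k)) else NA_real_,
    trained = x$trained
  )
}
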