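# Minimal 1-D convolutional network used by the sequence encoder.
#
# Activations are stored channels-by-positions: a batch of B sequences of
# frame length L with C channels is a C x (L*B) matrix whose columns are
# grouped by sample (sample b occupies columns (b-1)*L + 1 .. b*L). All
# heavy operations reduce to BLAS matrix products via im2col.

# ---- im2col convolution -----------------------------------------------------

# Shift the position axis of X (C x L*B) by `o` within each sample,
# zero-filling at the sample boundaries. Output position l reads input
# position l + o. In the flattened (C*L) x B per-sample view this is a
# contiguous row-block shift, which keeps the copy cache-friendly.
shift_cols <- function(X, o, L, B) {
  if (o == 0L) return(X)
  C <- nrow(X)
  flat <- X
  dim(flat) <- c(C * L, B)
  out <- matrix(0, C * L, B)
  if (o > 0L) {
    out[seq_len((L - o) * C), ] <- flat[(o * C + 1L):(C * L), ]
  } else {
    out[(-o * C + 1L):(C * L), ] <- flat[seq_len((L + o) * C), ]
  }
  dim(out) <- c(C, L * B)
  out
}

# Convolution as a sum over kernel offsets: Y = b + sum_o W_o %*% shift(X, o),
# where W_o is the C_out x C_in block of W for offset o (blocks ordered
# left-to-right). Equivalent to im2col + one large product, with less
# allocation.
conv_forward <- function(X, W, b, k, L, B) {
  h <- (k - 1L) %/% 2L
  C_in <- ncol(W) %/% k
  Y <- matrix(b, nrow(W), ncol(X))
  for (oi in seq_len(k)) {
    o <- oi - h - 1L
    Wo <- W[, (oi - 1L) * C_in + seq_len(C_in), drop = FALSE]
    Y <- Y + Wo %*% shift_cols(X, o, L, B)
  }
  list(Y = Y, X = X)
}

conv_backward <- function(dY, X, W, k, L, B) {
  h <- (k - 1L) %/% 2L
  C_in <- ncol(W) %/% k
  dW <- matrix(0, nrow(W), ncol(W))
  dX <- matrix(0, C_in, ncol(dY))
  for (oi in seq_len(k)) {
    o <- oi - h - 1L
    cols <- (oi - 1L) * C_in + seq_len(C_in)
    Xo <- shift_cols(X, o, L, B)
    dW[, cols] <- tcrossprod(dY, Xo)
    # forward read position l+o contributes to output l, so gradients flow
    # back with the opposite shift
    dX <- dX + shift_cols(crossprod(W[, cols, drop = FALSE], dY), -o, L, B)
  }
  list(dX = dX, dW = dW, db = rowSums(dY))
}

# ---- batch normalization ----------------------------------------------------

bn_forward <- function(X, gamma, beta, running, training, momentum = 0.1,
                       eps = 1e-5) {
  if (training) {
    mu <- rowMeans(X)
    v <- rowMeans(X^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (X - mu) * invstd
  list(Y = gamma * xhat + beta, xhat = xhat, invstd = invstd,
       running = running)
}

bn_backward <- function(dY, xhat, invstd, gamma) {
  M <- ncol(dY)
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  dX <- (invstd / M) * (M * dxhat - rowSums(dxhat) - xhat * dgamma)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- max pooling (width 2, stride 2) ----------------------------------------

pool_cols <- function(L, B) {
  # column indices of odd / even positions in the C x (L*B) layout
  l <- rep.int(seq_len(L), B)
  list(a = which(l %% 2L == 1L), b = which(l %% 2L == 0L))
}

maxpool_forward <- function(X, L, B) {
  stopifnot(L %% 2L == 0L)
  idx <- pool_cols(L, B)
  Xa <- X[, idx$a, drop = FALSE]
  Xb <- X[, idx$b, drop = FALSE]
  take_a <- Xa >= Xb
  list(Y = pmax(Xa, Xb), take_a = take_a, idx = idx)
}

maxpool_backward <- function(dY, take_a, idx, C, L, B) {
  dX <- matrix(0, C, L * B)
  dX[, idx$a] <- dY * take_a
  dX[, idx$b] <- dY * (!take_a)
  dX
}

# ---- masked global average pooling ------------------------------------------

# Average over the valid (unpadded) positions of each sample. `valid` gives
# each sample's valid length in the current frame of length L.
gap_matrix <- function(valid, L, B) {
  M <- matrix(0, L * B, B)
  for (b in seq_len(B)) {
    v <- max(1L, min(valid[b], L))
    M[(b - 1L) * L + seq_len(v), b] <- 1 / v
  }
  M
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), state = state)
}
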