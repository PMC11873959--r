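# Low-level neural-network operations.
#
# All operations work on batched activations stored as (C, P, B) arrays,
# where C = channels, P = number of spatial positions (column-major flatten
# of the 2D/3D grid) and B = batch size. Convolutions are stride-1,
# zero-padded "same", realised as an im2col gather followed by one BLAS
# matrix multiply, so the same code serves 2D and 3D grids.

# Precompute gather indices for a stride-1 same convolution on a grid with
# spatial dims `sp` (length 2 or 3) and odd kernel width `k`.
conv_geom <- function(sp, k) {
  stopifnot(k %% 2 == 1, all(sp >= 1))
  d <- length(sp)
  pad <- (k - 1L) %/% 2L
  spp <- sp + 2L * pad

  # linear index (into the padded grid) of the receptive-field origin of
  # each output position
  base <- array(0, dim = sp)
  mult <- 1
  for (j in seq_len(d)) {
    base <- sweep(base, j, (seq_len(sp[j]) - 1) * mult, "+")
    mult <- mult * spp[j]
  }
  base <- as.vector(base) + 1

  # linear offsets of the k^d kernel taps
  off <- array(0, dim = rep(k, d))
  mult <- 1
  for (j in seq_len(d)) {
    off <- sweep(off, j, (seq_len(k) - 1) * mult, "+")
    mult <- mult * spp[j]
  }
  off <- as.vector(off)

  # interior positions of the padded grid (where the unpadded grid lives)
  interior <- array(0, dim = sp)
  mult <- 1
  for (j in seq_len(d)) {
    interior <- sweep(interior, j, (seq_len(sp[j]) - 1 + pad) * mult, "+")
    mult <- mult * spp[j]
  }
  interior <- as.vector(interior) + 1

  idx <- outer(off, base, "+") # K x P, kernel tap varies fastest

  # map each (tap, output position) to its source in the unpadded grid
  # (0 = tap falls into the zero padding)
  pad_src <- integer(prod(spp))
  pad_src[interior] <- seq_len(prod(sp))
  gidx <- pad_src[as.vector(idx)]

  list(sp = sp, d = d, K = as.integer(round(k^d)),
       P = as.integer(prod(sp)), gidx = as.integer(gidx))
}

# X: (C, P, B); W: (C_out, C*K). Returns Y (C_out, P, B) and the im2col
# matrix needed for the backward pass.
conv_forward <- function(X, W, g, retain = TRUE) {
  C <- dim(X)[1L]; B <- dim(X)[3L]
  cols <- im2col_batch(X, g$gidx, C, g$P, B, g$K)
  Y <- W %*% cols
  dim(Y) <- c(nrow(W), g$P, B)
  list(Y = Y, cols = if (retain) cols else NULL)
}

# Permutation that turns W (C_out, C_in*K) into the channel-transposed,
# spatially flipped kernel Wf (C_in, C_out*K) used for the input gradient:
# for odd kernels and symmetric zero padding, the transpose of a stride-1
# same convolution is a same convolution with the flipped kernel.
conv_flip_idx <- function(C_in, C_out, K) {
  ci <- rep(seq_len(C_in), times = C_out * K)
  j <- rep(seq_len(C_out * K) - 1L, each = C_in)
  co <- j %% C_out
  k <- K - 1L - j %/% C_out
  co + 1L + C_out * ((ci - 1L) + C_in * k)
}

conv_backward <- function(dY, W, cols, g, C_in, B, flip, need_dx = TRUE) {
  C_out <- dim(dY)[1L]
  dim(dY) <- c(C_out, g$P * B)
  dW <- tcrossprod(dY, cols)
  dX <- NULL
  if (need_dx) {
    dim(dY) <- c(C_out, g$P, B)
    Wf <- matrix(W[flip], C_in, C_out * g$K)
    dX <- conv_forward(dY, Wf, g, retain = FALSE)$Y
  }
  list(dX = dX, dW = dW)
}

# Non-overlapping pooling with window `w` along every spatial dim.
pool_geom <- function(sp, w = 2L) {
  stopifnot(all(sp %% w == 0))
  d <- length(sp)
  spo <- sp %/% w
  base <- array(0, dim = spo)
  mult <- 1
  for (j in seq_len(d)) {
    base <- sweep(base, j, (seq_len(spo[j]) - 1) * w * mult, "+")
    mult <- mult * sp[j]
  }
  base <- as.vector(base) + 1
  off <- array(0, dim = rep(w, d))
  mult <- 1
  for (j in seq_len(d)) {
    off <- sweep(off, j, (seq_len(w) - 1) * mult, "+")
    mult <- mult * sp[j]
  }
  members <- lapply(as.vector(off), function(o) base + o)
  list(sp_in = sp, sp_out = spo, P_in = as.integer(prod(sp)),
       P_out = as.integer(prod(spo)), members = members)
}

pool_forward <- function(X, g, type = c("avg", "max"), retain = TRUE) {
  type <- match.arg(type)
  nm <- length(g$members)
  if (type == "avg") {
    Y <- X[, g$members[[1L]], , drop = FALSE]
    for (m in 2:nm) Y <- Y + X[, g$members[[m]], , drop = FALSE]
    Y <- Y / nm
    list(Y = Y, argmax = NULL)
  } else {
    Y <- X[, g$members[[1L]], , drop = FALSE]
    am <- array(1L, dim(Y))
    for (m in 2:nm) {
      Xm <- X[, g$members[[m]], , drop = FALSE]
      upd <- Xm > Y
      Y[upd] <- Xm[upd]
      am[upd] <- m
    }
    list(Y = Y, argmax = if (retain) am else NULL)
  }
}

pool_backward <- function(dY, g, type, argmax, C, B) {
  nm <- length(g$members)
  dX <- array(0, c(C, g$P_in, B))
  if (type == "avg") {
    dYm <- dY / nm
    for (m in seq_len(nm)) dX[, g$members[[m]], ] <- dYm
  } else {
    for (m in seq_len(nm)) dX[, g$members[[m]], ] <- dY * (argmax == m)
  }
  dX
}

# Channel-wise batch normalisation over all spatial positions and batch
# members. Running statistics follow the usual exponential update.
bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  C <- dim(X)[1L]
  N <- length(X) / C
  dm <- dim(X)
  dim(X) <- c(C, N)
  if (training) {
    mu <- .rowMeans(X, C, N)
    xc <- X - mu
    v <- .rowMeans(xc * xc, C, N)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * N / max(N - 1, 1)
  } else {
    mu <- run_mean
    v <- run_var
    xc <- X - mu
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  Y <- gamma * xhat + beta
  dim(Y) <- dm
  list(Y = Y, xhat = xhat, istd = istd, run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dY, gamma, xhat, istd) {
  C <- length(gamma)
  N <- length(dY) / C
  dm <- dim(dY)
  dim(dY) <- c(C, N)
  dgamma <- .rowSums(dY * xhat, C, N)
  dbeta <- .rowSums(dY, C, N)
  dxhat <- dY * gamma
  dX <- (istd / N) * (N * dxhat - .rowSums(dxhat, C, N) -
                        xhat * .rowSums(dxhat * xhat, C, N))
  dim(dX) <- dm
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# The cached `mask` is the pointwise derivative, reused by the backward pass.
lrelu_forward <- function(X, slope = 0.01) {
  mask <- slope + (1 - slope) * (X > 0)
  list(Y = X * mask, mask = mask)
}

lrelu_backward <- function(dY, mask, slope = 0.01) {
  dY * mask
}

# Adam update; `state` carries first/second moments and the step counter.
adam_init <- function(params) {
  flat <- rapply(params, function(p) p * 0, how = "replace")
  list(m = flat, v = flat, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- Map(walk, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

# Separable linear (bilinear/trilinear) or nearest-neighbour upsampling of a
# spatial grid, with half-pixel centre alignment (no corner alignment).
interp_matrix <- function(n_in, n_out, method = c("linear", "nearest")) {
  method <- match.arg(method)
  scale <- n_out / n_in
  src <- (seq_len(n_out) - 0.5) / scale + 0.5
  L <- matrix(0, n_out, n_in)
  if (method == "nearest") {
    j <- pmin(pmax(round(src), 1L), n_in)
    L[cbind(seq_len(n_out), j)] <- 1
  } else {
    src <- pmin(pmax(src, 1), n_in)
    j0 <- pmin(floor(src), n_in - 1L)
    if (n_in == 1L) j0 <- rep(1L, n_out)
    j1 <- pmin(j0 + 1L, n_in)
    w1 <- src - j0
    L[cbind(seq_len(n_out), j0)] <- L[cbind(seq_len(n_out), j0)] + (1 - w1)
    L[cbind(seq_len(n_out), j1)] <- L[cbind(seq_len(n_out), j1)] + w1
  }
  L
}

apply_along_dim <- function(x, M, dim) {
  d <- length(dim(x))
  perm <- c(dim, setdiff(seq_len(d), dim))
  xp <- aperm(x, perm)
  dm <- dim(xp)
  dim(xp) <- c(dm[1L], prod(dm[-1L]))
  yp <- M %*% xp
  dim(yp) <- c(nrow(M), dm[-1L])
  aperm(yp, order(perm))
}

#' Upsample a coarse spatial map
#'
#' Resizes a 2D or 3D array to `out_dims` by separable linear interpolation
#' (half-pixel centres, no corner alignment) or nearest-neighbour
#' replication.
#'
#' @param x numeric 2D or 3D array.
#' @param out_dims integer vector of output dimensions, same length as
#'   `dim(x)`.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return numeric array with dimensions `out_dims`.
#' @export
upsample_map <- function(x, out_dims, method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(length(out_dims) == length(dim(x)))
  for (j in seq_along(out_dims)) {
    x <- apply_along_dim(x, interp_matrix(dim(x)[j], out_dims[j], method), j)
  }
  x
}
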