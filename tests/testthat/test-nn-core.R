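# Numerical correctness of the network primitives against independent
# oracles: direct-summation convolution, manual pooling, and central-
# difference gradients through the full model.

naive_conv2d <- function(X, W, k) {
  # X: (C_in, H, W) array; W: (C_out, C_in*k^2); direct summation oracle
  C_in <- dim(X)[1]; H <- dim(X)[2]; Wd <- dim(X)[3]
  C_out <- nrow(W)
  pad <- (k - 1) / 2
  Y <- array(0, c(C_out, H, Wd))
  for (co in seq_len(C_out)) for (y in seq_len(H)) for (x in seq_len(Wd)) {
    acc <- 0
    for (ci in seq_len(C_in)) for (ky in seq_len(k)) for (kx in seq_len(k)) {
      sy <- y + ky - 1 - pad; sx <- x + kx - 1 - pad
      if (sy >= 1 && sy <= H && sx >= 1 && sx <= Wd) {
        wi <- ci + C_in * ((ky - 1) + k * (kx - 1))
        acc <- acc + W[co, wi] * X[ci, sy, sx]
      }
    }
    Y[co, y, x] <- acc
  }
  Y
}

test_that("im2col convolution matches direct-summation oracle (2D)", {
  set.seed(1)
  for (trial in 1:3) {
    H <- 6L; C_in <- 2L; C_out <- 3L; k <- 3L
    g <- lilac:::conv_geom(c(H, H), k)
    X <- array(rnorm(C_in * H * H), c(C_in, H * H, 1))
    W <- matrix(rnorm(C_out * C_in * k * k), C_out, C_in * k * k)
    got <- lilac:::conv_forward(X, W, g)$Y
    Xsp <- X; dim(Xsp) <- c(C_in, H, H)
    want <- naive_conv2d(Xsp, W, k)
    dim(want) <- c(C_out, H * H, 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("batched convolution equals per-image convolution", {
  set.seed(2)
  g <- lilac:::conv_geom(c(8, 8), 3)
  W <- matrix(rnorm(4 * 2 * 9), 4, 18)
  X <- array(rnorm(2 * 64 * 5), c(2, 64, 5))
  batch <- lilac:::conv_forward(X, W, g)$Y
  for (b in 1:5) {
    single <- lilac:::conv_forward(X[, , b, drop = FALSE], W, g)$Y
    expect_equal(batch[, , b, drop = FALSE], single, tolerance = 1e-12)
  }
})

test_that("average and max pooling match manual 2x2 reductions", {
  g <- lilac:::pool_geom(c(4, 4), 2)
  X <- array(0, c(1, 16, 1))
  m <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                9, 10, 11, 12,
                13, 14, 15, 16), 4, 4, byrow = TRUE)
  X[1, , 1] <- as.vector(m) # column-major
  avg <- lilac:::pool_forward(X, g, "avg")$Y
  mx <- lilac:::pool_forward(X, g, "max")$Y
  # 2x2 blocks of m: means and maxima
  expect_equal(as.vector(avg), as.vector(matrix(c(3.5, 5.5, 11.5, 13.5),
                                                2, 2, byrow = TRUE)))
  expect_equal(as.vector(mx), as.vector(matrix(c(6, 8, 14, 16),
                                               2, 2, byrow = TRUE)))
})

test_that("full-model parameter gradients match central differences", {
  set.seed(3)
  cfg <- lilac_config(spatial = c(16, 16), channels = c(2, 2, 3, 3),
                      metadata_dim = 1, task = "interval")
  m <- lilac_model(cfg)
  m$params$w <- rnorm(cfg$head_dim, sd = 0.1)
  B <- 2
  I1 <- lapply(1:B, function(i) matrix(runif(256), 16, 16))
  I2 <- lapply(1:B, function(i) matrix(runif(256), 16, 16))
  M1 <- matrix(rnorm(B), 1, B)
  M2 <- matrix(rnorm(B), 1, B)
  tgt <- rnorm(B)
  loss_of <- function(model) {
    out <- lilac:::compare_forward(model, I1, I2, M1, M2,
                                   training = TRUE, retain = TRUE)
    list(loss = mean((out$r - tgt)^2), out = out)
  }
  lf <- loss_of(m)
  dr <- 2 * (lf$out$r - tgt) / B
  dw <- as.vector((lf$out$z1 - lf$out$z2) %*% dr)
  dpair <- outer(m$params$w[seq_len(cfg$feature_dim)], dr)
  gb <- lilac:::extractor_backward(m, lf$out$fw$caches, cbind(dpair, -dpair))

  eps <- 1e-6
  check_some <- function(get, set, analytic, n_probe = 4) {
    p0 <- get(m)
    probe <- seq(1, length(p0), length.out = min(n_probe, length(p0)))
    for (i in unique(round(probe))) {
      up <- p0; up[i] <- p0[i] + eps
      dn <- p0; dn[i] <- p0[i] - eps
      num <- (loss_of(set(m, up))$loss - loss_of(set(m, dn))$loss) / (2 * eps)
      expect_equal(analytic[i], num, tolerance = 1e-4)
    }
  }
  check_some(function(m) m$params$w,
             function(m, p) { m$params$w <- p; m }, dw)
  for (b in c(1L, 4L)) {
    check_some(function(m) as.vector(m$params$blocks[[b]]$W),
               function(m, p) {
                 dim(p) <- dim(m$params$blocks[[b]]$W)
                 m$params$blocks[[b]]$W <- p; m
               },
               as.vector(gb[[b]]$W))
    check_some(function(m) m$params$blocks[[b]]$gamma,
               function(m, p) { m$params$blocks[[b]]$gamma <- p; m },
               gb[[b]]$gamma)
  }
})

test_that("nearest upsampling replicates blocks exactly and linear keeps constants", {
  x <- matrix(c(1, 2, 3, 4), 2, 2)
  up <- upsample_map(x, c(4, 4), "nearest")
  expect_equal(up, x[rep(1:2, each = 2), rep(1:2, each = 2)])
  const <- matrix(5, 3, 3)
  expect_equal(upsample_map(const, c(9, 9), "linear"), matrix(5, 9, 9))
  # linear interpolation midway between two cells
  v <- matrix(c(0, 1), 1, 2)
  upl <- upsample_map(v, c(1, 4), "linear")
  expect_equal(as.vector(upl), c(0, 0.25, 0.75, 1))
  # mass conservation for nearest block replication
  ind <- matrix(0, 2, 2); ind[2, 1] <- 1
  expect_equal(sum(upsample_map(ind, c(8, 8), "nearest")), 16)
})

test_that("Adam drives a quadratic toward its minimum deterministically", {
  params <- list(w = c(5, -3))
  st <- lilac:::adam_init(params)
  for (i in 1:2000) {
    g <- list(w = 2 * (params$w - c(1, 2)))
    up <- lilac:::adam_step(params, g, st, lr = 0.05)
    params <- up$params; st <- up$state
  }
  expect_equal(params$w, c(1, 2), tolerance = 1e-3)
})
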