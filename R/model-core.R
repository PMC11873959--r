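# The LILAC comparison network: a shared ("Siamese") convolutional feature
# extractor applied to both images of a pair, followed by a bias-free linear
# head on the difference of the (optionally metadata-augmented) feature
# vectors:
#
#   r(I1, I2) = w' ((f(I1) ++ M1) - (f(I2) ++ M2)),   ++ = concatenation.
#
# Because the head is linear and bias-free in the feature difference, the
# score is reflexive (r(a,a) = 0), antisymmetric (r(a,b) = -r(b,a)) and
# additively transitive (r(a,b) + r(b,c) = r(a,c)).

POOL_FACTOR <- 16L # four blocks, each halving every spatial dim

#' Configure a LILAC comparison model
#'
#' The feature extractor has four convolutional blocks, each a stride-1
#' same-padded convolution, batch normalisation, leaky ReLU and a
#' window-2 pooling layer. After four blocks every spatial dimension is
#' reduced 16-fold; the final activation grid is flattened (not globally
#' pooled) into the feature vector, which is what makes element-wise
#' saliency attribution possible downstream.
#'
#' @param spatial integer vector of input dimensions, length 2 or 3; every
#'   entry must be divisible by 16.
#' @param channels four positive integers, output channels per block.
#' @param kernel odd convolution kernel width (default 3).
#' @param pooling `"avg"` or `"max"`, optionally one per block. Average
#'   pooling is the default for comparison models; max pooling is
#'   conventional for the single-image baseline.
#' @param metadata_dim number of per-timepoint scalar covariates
#'   concatenated to each feature vector (0 for none).
#' @param task `"ordering"` (binary chronological-order classification),
#'   `"interval"` (time-interval regression) or `"score"` (target-change
#'   regression).
#' @param lrelu_slope negative-side slope of the leaky ReLU.
#' @param bn_momentum,bn_eps batch-normalisation running-statistics
#'   momentum and variance floor.
#' @return an object of class `lilac_config`.
#' @export
lilac_config <- function(spatial = c(64, 64), channels = c(8, 16, 32, 32),
                         kernel = 3L, pooling = "avg", metadata_dim = 0L,
                         task = c("ordering", "interval", "score"),
                         lrelu_slope = 0.01, bn_momentum = 0.1,
                         bn_eps = 1e-5) {
  task <- match.arg(task)
  spatial <- as.integer(spatial)
  if (!length(spatial) %in% 2:3)
    stop("`spatial` must have length 2 or 3")
  if (any(spatial %% POOL_FACTOR != 0))
    stop("every spatial dimension must be divisible by ", POOL_FACTOR,
         " (four /2 pooling stages); got ", paste(spatial, collapse = "x"))
  if (length(channels) != 4L || any(channels < 1))
    stop("`channels` must be four positive integers (four blocks)")
  if (kernel %% 2 != 1) stop("`kernel` must be odd")
  pooling <- rep_len(match.arg(pooling, c("avg", "max"), several.ok = TRUE),
                     4L)
  feature_dim <- as.integer(channels[4L] * prod(spatial %/% POOL_FACTOR))
  structure(list(spatial = spatial, channels = as.integer(channels),
                 kernel = as.integer(kernel), pooling = pooling,
                 metadata_dim = as.integer(metadata_dim), task = task,
                 feature_dim = feature_dim,
                 head_dim = feature_dim + as.integer(metadata_dim),
                 lrelu_slope = lrelu_slope, bn_momentum = bn_momentum,
                 bn_eps = bn_eps),
            class = "lilac_config")
}

build_geoms <- function(config) {
  sp <- config$spatial
  c_in <- c(1L, config$channels[1:3])
  lapply(1:4, function(b) {
    spb <- sp %/% as.integer(2^(b - 1))
    cg <- conv_geom(spb, config$kernel)
    list(conv = cg, pool = pool_geom(spb, 2L),
         flip = conv_flip_idx(c_in[b], config$channels[b], cg$K))
  })
}

init_extractor_params <- function(config) {
  c_in <- c(1L, config$channels[1:3])
  lapply(1:4, function(b) {
    fan_in <- c_in[b] * config$kernel^length(config$spatial)
    list(W = matrix(stats::rnorm(config$channels[b] * fan_in,
                                 sd = sqrt(2 / fan_in)),
                    config$channels[b], fan_in),
         gamma = rep(1, config$channels[b]),
         beta = rep(0, config$channels[b]))
  })
}

init_extractor_state <- function(config) {
  lapply(1:4, function(b) list(run_mean = rep(0, config$channels[b]),
                               run_var = rep(1, config$channels[b])))
}

#' Build a LILAC comparison model
#'
#' Initialises the four-block feature extractor (He-scaled random
#' convolution weights, unit batch-norm scale) and the bias-free head.
#' The head weight vector starts at zero, so the comparison starts
#' unbiased (zero logit, order probability 0.5) and, after training, feature
#' positions that never receive gradient signal contribute nothing to the
#' score or to saliency maps. Extractor initialisation uses the current R
#' random-number stream, so wrap in `set.seed()` for reproducibility.
#'
#' @param config a [lilac_config()].
#' @return an object of class `lilac_model` with elements `config`,
#'   `params` (blocks and head weights) and `state` (batch-norm running
#'   statistics).
#' @export
lilac_model <- function(config = lilac_config()) {
  stopifnot(inherits(config, "lilac_config"))
  params <- list(blocks = init_extractor_params(config),
                 w = rep(0, config$head_dim))
  structure(list(config = config, params = params,
                 state = init_extractor_state(config),
                 geoms = build_geoms(config)),
            class = "lilac_model")
}

#' @export
print.lilac_model <- function(x, ...) {
  cfg <- x$config
  cat("LILAC comparison model (", cfg$task, " task)\n", sep = "")
  cat("  input: ", paste(cfg$spatial, collapse = "x"),
      ", channels ", paste(cfg$channels, collapse = "-"),
      ", kernel ", cfg$kernel, ", pooling ", cfg$pooling[1L], "\n", sep = "")
  cat("  features: ", cfg$feature_dim, " (+", cfg$metadata_dim,
      " metadata), parameters: ", n_params(x), "\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#' @param model a `lilac_model` or `sirb_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(unlist(rapply(model$params, length, how = "unlist")))
}

#' Min-max normalise an image to the unit interval
#'
#' Constant images map to all zeros.
#'
#' @param img numeric array.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
normalize_image <- function(img) {
  rng <- range(img)
  if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
}

# Stack a list of images into a (1, P, B) activation array.
stack_images <- function(images, spatial, normalize = TRUE) {
  P <- prod(spatial)
  B <- length(images)
  X <- array(0, c(1L, P, B))
  for (b in seq_len(B)) {
    img <- images[[b]]
    if (!identical(as.integer(dim(img)), as.integer(spatial)))
      stop("image ", b, " has dimensions ", paste(dim(img), collapse = "x"),
           "; model expects ", paste(spatial, collapse = "x"))
    if (normalize) img <- normalize_image(img)
    X[1L, , b] <- img
  }
  X
}

# Forward pass through the extractor. Returns flattened features, the
# last-block activation grid (retained for saliency work) and, when
# `retain = TRUE`, the caches needed for backpropagation. In training mode
# batch statistics are used and running statistics updated (returned in
# `state`); in inference mode running statistics make the pass
# deterministic.
extractor_forward <- function(model, X, training = FALSE, retain = training) {
  cfg <- model$config
  caches <- vector("list", 4L)
  state <- model$state
  for (b in 1:4) {
    g <- model$geoms[[b]]
    p <- model$params$blocks[[b]]
    cv <- conv_forward(X, p$W, g$conv, retain = retain)
    bn <- bn_forward(cv$Y, p$gamma, p$beta, state[[b]]$run_mean,
                     state[[b]]$run_var, training = training,
                     momentum = cfg$bn_momentum, eps = cfg$bn_eps)
    state[[b]]$run_mean <- bn$run_mean
    state[[b]]$run_var <- bn$run_var
    lr <- lrelu_forward(bn$Y, cfg$lrelu_slope)
    pl <- pool_forward(lr$Y, g$pool, cfg$pooling[b], retain = retain)
    if (retain)
      caches[[b]] <- list(cols = cv$cols, xhat = bn$xhat, istd = bn$istd,
                          mask = lr$mask, argmax = pl$argmax,
                          C_in = dim(X)[1L], B = dim(X)[3L])
    X <- pl$Y
  }
  B <- dim(X)[3L]
  feats <- X
  dim(feats) <- c(cfg$feature_dim, B)
  list(features = feats, last_grid = X, caches = caches, state = state)
}

# Backpropagate d(loss)/d(features) through the extractor; returns
# per-block parameter gradients.
extractor_backward <- function(model, caches, dfeat) {
  cfg <- model$config
  B <- ncol(dfeat)
  dX <- dfeat
  dim(dX) <- c(cfg$channels[4L], prod(cfg$spatial %/% POOL_FACTOR), B)
  grads <- vector("list", 4L)
  for (b in 4:1) {
    g <- model$geoms[[b]]
    p <- model$params$blocks[[b]]
    ch <- caches[[b]]
    dX <- pool_backward(dX, g$pool, cfg$pooling[b], ch$argmax,
                        cfg$channels[b], ch$B)
    dX <- lrelu_backward(dX, ch$mask, cfg$lrelu_slope)
    bb <- bn_backward(dX, p$gamma, ch$xhat, ch$istd)
    cb <- conv_backward(bb$dX, p$W, ch$cols, g$conv, ch$C_in, ch$B, g$flip,
                        need_dx = b > 1L) # block 1's input is the image
    grads[[b]] <- list(W = cb$dW, gamma = bb$dgamma, beta = bb$dbeta)
    dX <- cb$dX
  }
  grads
}

check_metadata <- function(cfg, M1, M2, B) {
  if (cfg$metadata_dim == 0L) {
    if (!is.null(M1) || !is.null(M2))
      stop("model was configured without metadata but metadata was supplied")
    return(list(M1 = NULL, M2 = NULL))
  }
  if (is.null(M1) || is.null(M2))
    stop("model expects metadata of length ", cfg$metadata_dim,
         " for both images")
  as_mat <- function(M) {
    M <- as.matrix(M)
    if (nrow(M) != cfg$metadata_dim && ncol(M) == cfg$metadata_dim) M <- t(M)
    if (nrow(M) != cfg$metadata_dim || ncol(M) != B)
      stop("metadata must be ", cfg$metadata_dim, " x ", B)
    M
  }
  list(M1 = as_mat(M1), M2 = as_mat(M2))
}

# Full pairwise forward pass. Both branches are stacked into one batch so
# batch-normalisation statistics are shared across branches. Returns the
# comparison logits r plus everything needed for backprop/saliency.
compare_forward <- function(model, images1, images2, M1 = NULL, M2 = NULL,
                            training = FALSE, retain = training,
                            normalize = TRUE) {
  cfg <- model$config
  B <- length(images1)
  stopifnot(length(images2) == B)
  md <- check_metadata(cfg, M1, M2, B)
  X <- stack_images(c(images1, images2), cfg$spatial, normalize = normalize)
  fw <- extractor_forward(model, X, training = training, retain = retain)
  f1 <- fw$features[, seq_len(B), drop = FALSE]
  f2 <- fw$features[, B + seq_len(B), drop = FALSE]
  z1 <- if (is.null(md$M1)) f1 else rbind(f1, md$M1)
  z2 <- if (is.null(md$M2)) f2 else rbind(f2, md$M2)
  r <- as.vector(crossprod(model$params$w, z1 - z2))
  list(r = r, f1 = f1, f2 = f2, z1 = z1, z2 = z2, fw = fw)
}

#' Compare two longitudinal images
#'
#' Computes the comparison logit \eqn{r = w^T((f(I_1) \oplus M_1) - (f(I_2) \oplus M_2))},
#' the dot product of the bias-free head weights with the difference of the
#' concatenated feature/metadata vectors. For the ordering task the
#' chronological-order probability `sigma(r)` is attached.
#'
#' @param model a `lilac_model`.
#' @param I1,I2 images (numeric arrays matching the model's spatial
#'   dimensions), or lists of such images for a batch.
#' @param M1,M2 optional metadata vectors (or `metadata_dim x B` matrices),
#'   both present or both absent.
#' @param normalize min-max normalise inputs first (default `TRUE`).
#' @return an object of class `lilac_comparison`: list with logit `r`,
#'   `probability` (ordering task only) and per-branch feature matrices
#'   `f1`, `f2`.
#' @export
compare <- function(model, I1, I2, M1 = NULL, M2 = NULL, normalize = TRUE) {
  if (!is.list(I1)) I1 <- list(I1)
  if (!is.list(I2)) I2 <- list(I2)
  out <- compare_forward(model, I1, I2, M1, M2, training = FALSE,
                         retain = FALSE, normalize = normalize)
  structure(list(r = out$r,
                 probability = if (model$config$task == "ordering")
                   predict_order_probability(out$r) else NULL,
                 f1 = out$f1, f2 = out$f2),
            class = "lilac_comparison")
}

#' Chronological-order probability from a comparison logit
#'
#' The logistic sigmoid of the comparison score: `sigma(0) = 0.5`, and
#' `sigma(r) + sigma(-r) = 1`.
#'
#' @param r numeric vector of comparison logits.
#' @return probabilities in `(0, 1)`.
#' @export
predict_order_probability <- function(r) {
  stopifnot(all(is.finite(r)))
  1 / (1 + exp(-r))
}

# ---- Single-image regression baseline (SIRB) --------------------------------

#' Configure and build the single-image regression baseline
#'
#' SIRB uses the same extractor family but regresses the target (e.g. age)
#' from one image at a time with an ordinary linear head (with bias);
#' metadata, when present, is concatenated to the flattened features before
#' the head. Change between two images is the difference of the two
#' single-image predictions. Max pooling is the customary default for this
#' baseline.
#'
#' @param config a [lilac_config()]; its `task` is ignored (always
#'   regression).
#' @return an object of class `sirb_model`.
#' @export
sirb_model <- function(config = lilac_config(pooling = "max")) {
  stopifnot(inherits(config, "lilac_config"))
  params <- list(blocks = init_extractor_params(config),
                 w = rep(0, config$head_dim), b = 0)
  structure(list(config = config, params = params,
                 state = init_extractor_state(config),
                 geoms = build_geoms(config)),
            class = "sirb_model")
}

sirb_forward <- function(model, images, M = NULL, training = FALSE,
                         retain = training, normalize = TRUE) {
  cfg <- model$config
  B <- length(images)
  if (cfg$metadata_dim > 0L) {
    M <- check_metadata(cfg, M, M, B)$M1
  } else if (!is.null(M)) {
    stop("model was configured without metadata but metadata was supplied")
  }
  X <- stack_images(images, cfg$spatial, normalize = normalize)
  fw <- extractor_forward(model, X, training = training, retain = retain)
  z <- if (is.null(M)) fw$features else rbind(fw$features, M)
  pred <- as.vector(crossprod(model$params$w, z)) + model$params$b
  list(pred = pred, z = z, fw = fw)
}

#' Single-image baseline prediction and pairwise change
#'
#' `sirb_predict()` regresses the target from single images;
#' `sirb_change()` is the difference of the predictions for the second and
#' first image of a pair, `g(I2, M2) - g(I1, M1)`.
#'
#' @param model a `sirb_model`.
#' @param I,I1,I2 an image or list of images.
#' @param M,M1,M2 optional metadata (see [compare()]).
#' @param normalize min-max normalise inputs first.
#' @return numeric vector of predictions (or changes).
#' @export
sirb_predict <- function(model, I, M = NULL, normalize = TRUE) {
  if (!is.list(I)) I <- list(I)
  sirb_forward(model, I, M, training = FALSE, retain = FALSE,
               normalize = normalize)$pred
}

#' @rdname sirb_predict
#' @export
sirb_change <- function(model, I1, I2, M1 = NULL, M2 = NULL,
                        normalize = TRUE) {
  sirb_predict(model, I2, M2, normalize = normalize) -
    sirb_predict(model, I1, M1, normalize = normalize)
}
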