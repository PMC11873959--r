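# Saliency localization for pairwise comparison models.
#
# Because the extractor flattens its last activation grid instead of
# globally average-pooling it, Grad-CAM's channel-level importance weights
# are replaced by element-wise ones: the gradient of the comparison logit r
# with respect to each last-block activation element multiplies that
# element directly; channels are then summed and rectified. For the
# bias-free linear head this gradient is (plus or minus) the image part of
# the head weight vector, reshaped onto the activation grid.

#' Modified Grad-CAM saliency for a longitudinal pair
#'
#' Multiplies last-block activations element-wise with the gradient of
#' the predicted-class comparison score with respect to those activations
#' (the differentiated scalar is the presigmoid logit `r`, taken with
#' positive sign for nonnegative `r` and negated otherwise, so the map always
#' shows evidence *for* the prediction actually made), sums over
#' channels, rectifies, and upsamples to the input resolution.
#'
#' `branch = "first"` or `"second"` attributes one image with the other
#' held fixed, the form used for overlay figures. `branch = "pair"` (the
#' default for quantitative analyses) sums the two signed branch maps
#' before rectification; because the head is linear in the feature
#' difference, this map decomposes the score exactly into per-cell
#' contributions and is invariant to the pair's presentation order. Peak
#' ties are broken by the lowest linear index.
#'
#' @param model a trained `lilac_model`.
#' @param I1,I2 the two images of the pair.
#' @param M1,M2 optional metadata (see [compare()]).
#' @param branch `"pair"`, `"first"` or `"second"`.
#' @param upsample `"linear"` (default) or `"nearest"`.
#' @param normalize min-max normalise inputs first.
#' @return object of class `lilac_saliency`: list with `coarse` (the
#'   nonnegative last-grid map), `map` (upsampled to input resolution),
#'   `peak` (1-based grid coordinates on the coarse grid), `peak_index`
#'   (linear), `r` (the pair's logit) and `branch`.
#' @export
modified_gradcam <- function(model, I1, I2, M1 = NULL, M2 = NULL,
                             branch = c("pair", "first", "second"),
                             upsample = c("linear", "nearest"),
                             normalize = TRUE) {
  branch <- match.arg(branch)
  upsample <- match.arg(upsample)
  stopifnot(inherits(model, "lilac_model"))
  out <- compare_forward(model, list(I1), list(I2), M1, M2,
                         training = FALSE, retain = FALSE,
                         normalize = normalize)
  cfg <- model$config
  coarse_sp <- cfg$spatial %/% POOL_FACTOR
  C4 <- cfg$channels[4L]
  P4 <- prod(coarse_sp)
  A1 <- out$fw$last_grid[, , 1L]
  A2 <- out$fw$last_grid[, , 2L]
  dim(A1) <- dim(A2) <- c(C4, P4)
  # gradient of the predicted-class score w.r.t. each branch's last grid:
  # +- the head weights on the image features, sign-adjusted to the
  # prediction
  G <- model$params$w[seq_len(cfg$feature_dim)] * (if (out$r < 0) -1 else 1)
  dim(G) <- c(C4, P4)
  pre <- switch(branch,
                first = .colSums(A1 * G, C4, P4),
                second = -.colSums(A2 * G, C4, P4),
                pair = .colSums((A1 - A2) * G, C4, P4))
  coarse <- pmax(pre, 0)
  dim(coarse) <- coarse_sp
  structure(list(coarse = coarse,
                 map = upsample_map(coarse, cfg$spatial, upsample),
                 peak = as.integer(arrayInd(which.max(coarse), coarse_sp)),
                 peak_index = which.max(coarse),
                 r = out$r, branch = branch),
            class = "lilac_saliency")
}

#' Occlusion-sensitivity map (reference oracle)
#'
#' Model-agnostic saliency: slides a zero patch over the chosen branch's
#' image on the coarse activation grid and records `|r - r_baseline|` per
#' patch position. Used as an independent check of [modified_gradcam()].
#'
#' @inheritParams modified_gradcam
#' @param patch patch width in pixels (default: the coarse-grid cell size,
#'   so the occlusion grid matches the Grad-CAM grid).
#' @return list with `map` (array on the occlusion grid), `peak` (1-based
#'   grid coordinates) and `r_baseline`.
#' @export
occlusion_map <- function(model, I1, I2, M1 = NULL, M2 = NULL,
                          branch = c("first", "second"), patch = NULL,
                          normalize = TRUE) {
  branch <- match.arg(branch)
  cfg <- model$config
  if (is.null(patch)) patch <- POOL_FACTOR
  stopifnot(all(cfg$spatial %% patch == 0))
  grid <- cfg$spatial %/% as.integer(patch)
  if (normalize) {
    I1 <- normalize_image(I1)
    I2 <- normalize_image(I2)
  }
  base <- compare(model, I1, I2, M1, M2, normalize = FALSE)$r

  tgt <- if (branch == "first") I1 else I2
  n_pos <- prod(grid)
  occluded <- vector("list", n_pos)
  for (p in seq_len(n_pos)) {
    at <- (arrayInd(p, grid) - 1L) * patch
    img <- tgt
    ranges <- lapply(seq_along(grid), function(d) at[d] + seq_len(patch))
    if (length(cfg$spatial) == 2L) {
      img[ranges[[1]], ranges[[2]]] <- 0
    } else {
      img[ranges[[1]], ranges[[2]], ranges[[3]]] <- 0
    }
    occluded[[p]] <- img
  }
  fixed <- if (branch == "first") I2 else I1
  rep_list <- function(x) rep(list(x), n_pos)
  rep_M <- function(M) if (is.null(M)) NULL else
    matrix(rep(as.numeric(M), n_pos), ncol = n_pos)
  r_occ <- if (branch == "first") {
    compare(model, occluded, rep_list(fixed), rep_M(M1), rep_M(M2),
            normalize = FALSE)$r
  } else {
    compare(model, rep_list(fixed), occluded, rep_M(M1), rep_M(M2),
            normalize = FALSE)$r
  }
  m <- abs(r_occ - base)
  dim(m) <- grid
  list(map = m, peak = as.integer(arrayInd(which.max(m), grid)),
       r_baseline = base)
}

#' Explainability score
#'
#' Per-case goodness of prediction, `tau = 1 - (y - yhat)^2 / (y - ybar)^2`,
#' where `ybar` is the mean of the ground-truth values in the training
#' data. `tau` is 1 for a perfect prediction and 0 when the prediction is
#' no better than the training-mean baseline; for binary ordering tasks
#' `yhat` is the predicted probability and `tau` acts as a per-sample
#' pseudo-score. Undefined (`NA`) when `y == ybar`; such cases are
#' excluded from gated saliency summaries.
#'
#' @param y ground-truth value(s).
#' @param y_hat predicted value(s).
#' @param y_bar_train mean of the training-set ground truth.
#' @return numeric vector of scores (each at most 1), `NA` where undefined.
#' @export
explainability_score <- function(y, y_hat, y_bar_train) {
  tau <- 1 - (y - y_hat)^2 / (y - y_bar_train)^2
  tau[y == y_bar_train] <- NA_real_
  tau
}

#' Population-average saliency peak map
#'
#' Summarises where a model's saliency peaks across a test population:
#' each included case contributes a binary coarse-grid indicator with 1 at
#' its peak; indicators are upsampled to full resolution
#' (nearest-neighbour by default, so each case contributes a crisp block)
#' and averaged. Cases with explainability score at or below the threshold
#' (or undefined) are excluded.
#'
#' @param saliencies list of `lilac_saliency` objects sharing a coarse
#'   grid shape.
#' @param tau numeric vector of explainability scores, one per saliency.
#' @param tau_threshold inclusion threshold (default 0.7, strict).
#' @param upsample `"nearest"` (default) or `"linear"`.
#' @return list with `map` (full-resolution average peak-frequency array),
#'   `n_included`, `n_total`.
#' @export
population_peak_map <- function(saliencies, tau = rep(1, length(saliencies)),
                                tau_threshold = 0.7,
                                upsample = c("nearest", "linear")) {
  upsample <- match.arg(upsample)
  stopifnot(length(tau) == length(saliencies))
  keep <- !is.na(tau) & tau > tau_threshold
  if (!any(keep))
    stop("no cases with explainability score above ", tau_threshold)
  kept <- saliencies[keep]
  coarse_dim <- dim(kept[[1]]$coarse)
  full_dim <- dim(kept[[1]]$map)
  acc <- array(0, full_dim)
  for (s in kept) {
    stopifnot(identical(dim(s$coarse), coarse_dim))
    ind <- array(0, coarse_dim)
    ind[s$peak_index] <- 1
    acc <- acc + upsample_map(ind, full_dim, upsample)
  }
  list(map = acc / length(kept), n_included = length(kept),
       n_total = length(saliencies))
}

#' Render a saliency overlay PNG
#'
#' Writes the (2D) image in grayscale with the saliency map blended into
#' the red channel; the map is normalised to `[0, 1]` for display only.
#'
#' @param image 2D numeric array (any scale; min-max normalised for
#'   display).
#' @param map 2D nonnegative saliency map with the same dimensions.
#' @param path output PNG path.
#' @param alpha maximum blend weight of the saliency colour.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, map, path, alpha = 0.6) {
  stopifnot(length(dim(image)) == 2L, identical(dim(image), dim(map)))
  base <- normalize_image(image)
  m <- if (max(map) > 0) map / max(map) else map
  w <- alpha * m
  rgb <- array(0, c(dim(image), 3L))
  rgb[, , 1] <- pmin(base * (1 - w) + w, 1)
  rgb[, , 2] <- base * (1 - w)
  rgb[, , 3] <- base * (1 - w)
  png::writePNG(rgb, path)
  invisible(path)
}

#' Does a saliency peak fall inside a region mask?
#'
#' Maps the coarse-grid peak to its block of full-resolution pixels and
#' reports whether any pixel of that block lies in the mask.
#'
#' @param saliency a `lilac_saliency`.
#' @param mask logical array at full image resolution.
#' @return logical scalar.
#' @export
peak_in_mask <- function(saliency, mask) {
  coarse_dim <- dim(saliency$coarse)
  full_dim <- dim(mask)
  factor <- full_dim %/% coarse_dim
  at <- (saliency$peak - 1L) * factor
  ranges <- lapply(seq_along(full_dim), function(d) at[d] + seq_len(factor[d]))
  block <- do.call(`[`, c(list(mask), ranges))
  any(block)
}
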