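test_that("explainability score matches its defining formula", {
  expect_equal(explainability_score(2, 2, 0), 1) # perfect prediction
  expect_equal(explainability_score(2, 0, 0), 0) # mean-baseline prediction
  expect_equal(explainability_score(3, 2, 1), 0.75)
  expect_true(is.na(explainability_score(1, 0.4, 1))) # undefined at y == ybar
  expect_equal(explainability_score(c(2, 3), c(2, 2), c(0, 1)), c(1, 0.75))
  expect_true(all(explainability_score(c(0, 1), c(0.9, 0.2), 0.5) <= 1))
})

test_that("a model blind to the image yields an all-zero saliency map", {
  set.seed(1)
  m <- lilac_model(tiny_config(metadata_dim = 1))
  m$params$w <- c(rep(0, m$config$feature_dim), 1) # metadata weight only
  sal <- modified_gradcam(m, rand_img(), rand_img(), M1 = 1, M2 = 3)
  expect_equal(max(sal$coarse), 0)
  expect_equal(sal$peak_index, 1L) # tie broken at the lowest linear index
  expect_true(all(sal$map == 0))
})

test_that("coarse maps are nonnegative and peak at their argmax", {
  set.seed(2)
  m <- lilac_model(tiny_config())
  m$params$w <- rnorm(m$config$head_dim, sd = 0.1)
  for (branch in c("pair", "first", "second")) {
    sal <- modified_gradcam(m, rand_img(), rand_img(), branch = branch)
    expect_true(all(sal$coarse >= 0))
    expect_equal(sal$peak_index, which.max(sal$coarse))
    expect_equal(dim(sal$map), c(32, 32))
  }
})

test_that("negating the head mirrors the rectified signal", {
  set.seed(3)
  m <- lilac_model(tiny_config())
  m$params$w <- rnorm(m$config$head_dim, sd = 0.1)
  a <- rand_img(); b <- rand_img()
  s_pos <- modified_gradcam(m, a, b, branch = "first")
  m2 <- m
  m2$params$w <- -m$params$w
  s_neg <- modified_gradcam(m2, a, b, branch = "first")
  # sign flip negates r; the predicted-class adjustment flips with it, so
  # the first-branch map sees gradient  sign(-r) * (-w) = sign(r) * w
  expect_equal(s_neg$coarse, s_pos$coarse, tolerance = 1e-12)
  # holding the prediction sign fixed instead mirrors the map: positive
  # and negative parts swap
  pre_pos <- lilac:::compare_forward(m, list(a), list(b))
  A1 <- pre_pos$fw$last_grid[, , 1]
  dim(A1) <- c(m$config$channels[4], prod(m$config$spatial %/% 16L))
  W <- matrix(m$params$w[seq_len(m$config$feature_dim)], nrow(A1))
  pre <- colSums(A1 * W) * (if (pre_pos$r < 0) -1 else 1)
  expect_equal(as.vector(s_pos$coarse), pmax(pre, 0))
})

test_that("stub models with known sensitive regions localize correctly", {
  set.seed(7)
  n <- 20
  in_region <- 0
  near_occlusion <- 0
  for (s in seq_len(n)) {
    rr <- sample(1:3, 1); cc <- sample(1:3, 1)
    cells <- as.vector(outer(rr:(rr + 1), (cc:(cc + 1) - 1) * 4, "+"))
    stub <- region_stub(cells)
    I1 <- rand_img(c(64, 64)); I2 <- rand_img(c(64, 64))
    sal <- modified_gradcam(stub, I1, I2, branch = "pair")
    occ <- occlusion_map(stub, I1, I2, branch = "second")
    in_region <- in_region + (sal$peak_index %in% cells)
    # the occlusion oracle's resolution is bounded below by the receptive
    # field (~3 coarse cells), so its identified region is the peak's
    # one-cell neighbourhood
    near_occlusion <- near_occlusion + all(abs(sal$peak - occ$peak) <= 1)
  }
  expect_gte(in_region / n, 0.9)
  expect_gte(near_occlusion / n, 0.9)
})

test_that("population peak maps are indicator averages with conserved mass", {
  set.seed(4)
  m <- lilac_model(tiny_config())
  m$params$w <- rnorm(m$config$head_dim, sd = 0.1)
  sals <- lapply(1:4, function(i)
    modified_gradcam(m, rand_img(), rand_img(), upsample = "nearest"))

  # single case: the map is the upsampled indicator of its peak
  pop1 <- population_peak_map(sals[1], tau = 1)
  ind <- array(0, dim(sals[[1]]$coarse))
  ind[sals[[1]]$peak_index] <- 1
  expect_equal(pop1$map, upsample_map(ind, c(32, 32), "nearest"))

  # identical peaks average to the same indicator
  pop2 <- population_peak_map(sals[c(1, 1)], tau = c(1, 1))
  expect_equal(pop2$map, pop1$map)

  # mass conservation: each case contributes one coarse cell of mass
  pop4 <- population_peak_map(sals, tau = rep(1, 4))
  cell_mass <- prod(c(32, 32) %/% dim(sals[[1]]$coarse))
  expect_equal(sum(pop4$map), cell_mass)

  # gating excludes low-tau and undefined cases; all-excluded errors
  pop_gated <- population_peak_map(sals, tau = c(1, 0.2, NA, 0.9))
  expect_equal(pop_gated$n_included, 2)
  expect_error(population_peak_map(sals, tau = rep(0, 4)), "0.7")
})

test_that("overlay rendering writes a valid RGB PNG", {
  dir <- withr::local_tempdir()
  img <- matrix(runif(32 * 32), 32, 32)
  map <- matrix(0, 32, 32); map[10:14, 20:24] <- 1
  path <- write_overlay_png(img, map, file.path(dir, "overlay.png"))
  out <- png::readPNG(path)
  expect_equal(dim(out), c(32, 32, 3))
  # saliency region is redder than it is green
  expect_gt(mean(out[10:14, 20:24, 1] - out[10:14, 20:24, 2]), 0.3)
})

test_that("peak_in_mask maps coarse peaks onto full-resolution regions", {
  sal <- list(coarse = matrix(c(0, 0, 1, 0), 2, 2), peak = c(1L, 2L),
              peak_index = 3L)
  class(sal) <- "lilac_saliency"
  mask <- matrix(FALSE, 32, 32)
  mask[1:16, 17:32] <- TRUE # block of coarse cell (1, 2)
  expect_true(peak_in_mask(sal, mask))
  expect_false(peak_in_mask(sal, !mask))
})
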