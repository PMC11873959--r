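# Synthetic longitudinal cohorts with known ground truth.
#
# Every subject carries a monotone change process with a subject-specific
# rate: a bright disk (2D) or ball (3D) whose radius grows linearly with
# the process state. An optional second, spatially disjoint process (a
# shrinking disk with the same rate for every subject) emulates a
# concurrent confounding dynamic such as normal aging alongside a
# disease-specific change. Nuisance variation - rotation, translation,
# multiplicative intensity drift and additive noise - is drawn
# independently per frame, so it carries no ordering signal. Shapes are
# isotropic and rendered analytically at transformed centres, so the
# rigid-motion nuisance is exact rather than resampled.

#' Configure a synthetic longitudinal cohort
#'
#' @param image_size pixels per side (square/cubic grid), at least 32 and
#'   divisible by 16.
#' @param dims 2 for images, 3 for volumes.
#' @param n_subjects number of subjects; group labels (control/treatment)
#'   alternate so any subset stays balanced.
#' @param n_timepoints frames per subject (single count, or a length-2
#'   range sampled per subject).
#' @param change_rate_mean,change_rate_sd normal distribution of the
#'   subject-specific change rate, in units of process state (= pixels of
#'   disk radius) per unit time.
#' @param group_effect additive change-rate difference for the treatment
#'   group.
#' @param confound_rate mean rate of the second, spatially disjoint
#'   shrinking process; 0 disables it.
#' @param confound_rate_sd subject-to-subject standard deviation of the
#'   confound rate, drawn independently of the change rate (so the
#'   confound's image signal is informative about elapsed time but not
#'   about the subject's change process beyond it, as for individual
#'   aging rates alongside a disease process).
#' @param rotation_max,translation_max,intensity_drift,noise_sd nuisance
#'   levels: maximum rotation (degrees, about the grid centre), maximum
#'   translation (pixels per axis), multiplicative intensity-drift
#'   fraction, and additive Gaussian noise standard deviation. All drawn
#'   independently of time.
#' @param time_step time units between consecutive frames.
#' @param change_model `"disk"` (radius grows linearly with state) or
#'   `"division"` (blob count doubles at integer states, emulating
#'   cleavage, with per-blob radius shrinking to conserve area).
#' @param layout `"central"` places one change region at the grid centre;
#'   `"offset"` uses the two-region geometry (small change region on one
#'   side, second region on the other) even without a confound process,
#'   which keeps the change mask compact for localization studies;
#'   `"auto"` (default) picks `"offset"` exactly when `confound_rate > 0`.
#' @param target_noise_sd additive noise on the recorded scalar target
#'   (the change-process state).
#' @param seed integer; identical config + seed reproduce the cohort
#'   exactly.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(image_size = 64L, dims = 2L, n_subjects = 10L,
                         n_timepoints = 12L, change_rate_mean = 1,
                         change_rate_sd = 0.2, group_effect = 0,
                         confound_rate = 0, confound_rate_sd = 0,
                         rotation_max = 5,
                         translation_max = 2, intensity_drift = 0.1,
                         noise_sd = 0.02, time_step = 1,
                         change_model = c("disk", "division"),
                         layout = c("auto", "central", "offset"),
                         target_noise_sd = 0, seed = 1L) {
  change_model <- match.arg(change_model)
  layout <- match.arg(layout)
  stopifnot(image_size >= 32, image_size %% 16 == 0, dims %in% 2:3,
            n_subjects >= 1, all(n_timepoints >= 2),
            length(n_timepoints) %in% 1:2,
            is.finite(change_rate_mean), is.finite(change_rate_sd),
            change_rate_sd >= 0, is.finite(group_effect),
            is.finite(confound_rate), confound_rate >= 0,
            confound_rate_sd >= 0,
            rotation_max >= 0, translation_max >= 0, intensity_drift >= 0,
            noise_sd >= 0, time_step > 0)
  cfg <- structure(list(image_size = as.integer(image_size),
                        dims = as.integer(dims),
                        n_subjects = as.integer(n_subjects),
                        n_timepoints = as.integer(n_timepoints),
                        change_rate_mean = change_rate_mean,
                        change_rate_sd = change_rate_sd,
                        group_effect = group_effect,
                        confound_rate = confound_rate,
                        confound_rate_sd = confound_rate_sd,
                        rotation_max = rotation_max,
                        translation_max = translation_max,
                        intensity_drift = intensity_drift,
                        noise_sd = noise_sd, time_step = time_step,
                        change_model = change_model, layout = layout,
                        target_noise_sd = target_noise_sd,
                        seed = as.integer(seed)),
                   class = "synth_config")
  # reject configs whose shapes could leave the field of view at a
  # +3 SD change rate
  check_sizing(cfg, max(cfg$change_rate_mean + abs(cfg$group_effect) +
                          3 * cfg$change_rate_sd, 0.01))
  cfg
}

use_offset_layout <- function(cfg) {
  identical(cfg$layout, "offset") ||
    (!identical(cfg$layout, "central") && cfg$confound_rate > 0)
}

synth_geometry <- function(cfg) {
  s <- cfg$image_size
  ctr <- rep((s + 1) / 2, cfg$dims)
  if (use_offset_layout(cfg)) {
    # two disjoint shapes placed on opposite diagonal corners: the extra
    # separation keeps them apart by more than the network's receptive
    # field, so saliency can genuinely distinguish them
    c1 <- ctr; c1[1:2] <- s * 0.27
    c2 <- ctr; c2[1:2] <- s * 0.73
    list(change_center = c1, confound_center = c2,
         base_radius = s / 12, confound_radius = s / 8)
  } else {
    list(change_center = ctr, confound_center = NULL,
         base_radius = s / 8, confound_radius = NULL)
  }
}

max_times <- function(cfg) (max(cfg$n_timepoints) - 1) * cfg$time_step

check_sizing <- function(cfg, rate) {
  geo <- synth_geometry(cfg)
  t_max <- max_times(cfg)
  edge <- 1.5
  margin <- cfg$translation_max + edge +
    sqrt(sum((geo$change_center - (cfg$image_size + 1) / 2)^2)) *
    sin(pi * cfg$rotation_max / 180) + 1
  r_max <- geo$base_radius + rate * t_max
  # room available: distance from centre to nearest image edge, or to the
  # midline separating the two processes
  room <- if (use_offset_layout(cfg)) {
    sep <- sqrt(sum((geo$confound_center - geo$change_center)^2))
    min(min(geo$change_center - 1, cfg$image_size - geo$change_center),
        sep / 2 - 1)
  } else {
    cfg$image_size / 2 - 1
  }
  if (r_max + margin > room)
    stop("sizing error: change process (radius up to ", round(r_max, 1),
         " px + margin ", round(margin, 1), ") exceeds the available field (",
         round(room, 1), " px); reduce rates, times or nuisance levels")
  if (cfg$confound_rate > 0 &&
      geo$confound_radius -
        (cfg$confound_rate + 3 * cfg$confound_rate_sd) * t_max < 1)
    stop("sizing error: confound process shrinks below 1 px at the final ",
         "timepoint; reduce confound_rate or n_timepoints")
  invisible(TRUE)
}

# Soft-edged ball: intensity 1 inside, linear fall-off over ~1.5 px.
render_shapes <- function(size, dims, centers, radii, edge = 1.5) {
  ax <- seq_len(size)
  img <- array(0, dim = rep(size, dims))
  for (s in seq_along(radii)) {
    ctr <- centers[[s]]
    if (dims == 2L) {
      d2 <- outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+")
    } else {
      d2 <- outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"),
                  (ax - ctr[3])^2, "+")
    }
    img <- pmax(img, pmin(pmax((radii[s] - sqrt(d2)) / edge + 0.5, 0), 1))
  }
  img
}

# In-plane rotation about the grid centre plus translation, applied to
# shape centres (shapes are isotropic, so this equals transforming the
# image).
transform_center <- function(ctr, size, theta, shift) {
  mid <- rep((size + 1) / 2, length(ctr))
  v <- ctr - mid
  rot <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  v[1:2] <- rot %*% v[1:2]
  mid + v + shift
}

# Blob layout for the "division" variant: n blobs on a golden-angle spiral
# inside the change region, radius shrinking as 1/sqrt(n) (area conserved).
division_centers <- function(center, region_radius, n) {
  if (n == 1L) return(list(center))
  golden <- pi * (3 - sqrt(5))
  lapply(seq_len(n), function(i) {
    rad <- region_radius * 0.55 * sqrt((i - 0.5) / n)
    ang <- (i - 1) * golden
    out <- center
    out[1] <- out[1] + rad * cos(ang)
    out[2] <- out[2] + rad * sin(ang)
    out
  })
}

subject_seed <- function(seed, subject_index) {
  as.integer((as.double(seed) * 7919 + as.double(subject_index) * 104729) %%
               2147483647)
}

#' Generate one subject's longitudinal sequence
#'
#' Draws the subject-specific change rate, renders every frame with
#' time-independent nuisance perturbations, and returns both the records
#' and the ground truth (rate, group, sex, per-frame states, change and
#' confound region masks). Deterministic in (config seed, subject index).
#'
#' @param config a [synth_config()].
#' @param subject_index 1-based subject number (also fixes the group:
#'   even indices are treatment).
#' @return list with `records` (data frame with `image` list-column and
#'   metadata columns `meta_time`, `meta_sex_time`) and `ground_truth`.
#' @export
generate_sequence <- function(config, subject_index) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(subject_seed(config$seed, subject_index))
  geo <- synth_geometry(config)
  group <- if (subject_index %% 2 == 0) "treatment" else "control"
  sex <- sample(0:1, 1)
  rate <- stats::rnorm(1, config$change_rate_mean +
                         config$group_effect * (group == "treatment"),
                       config$change_rate_sd)
  rate <- max(rate, 0) # keep the process monotone (non-decreasing)
  confound_rate <- if (config$confound_rate > 0) {
    max(stats::rnorm(1, config$confound_rate, config$confound_rate_sd), 0)
  } else {
    0
  }
  check_sizing(config, rate)
  n_t <- if (length(config$n_timepoints) == 2L)
    sample(config$n_timepoints[1]:config$n_timepoints[2], 1)
  else config$n_timepoints
  times <- (seq_len(n_t) - 1) * config$time_step
  states <- rate * times
  size <- config$image_size

  frames <- vector("list", n_t)
  for (k in seq_len(n_t)) {
    theta <- stats::runif(1, -config$rotation_max, config$rotation_max) *
      pi / 180
    shift <- stats::runif(config$dims, -config$translation_max,
                          config$translation_max)
    drift <- 1 + stats::runif(1, -config$intensity_drift,
                              config$intensity_drift)

    if (config$change_model == "division") {
      n_blobs <- as.integer(2^min(floor(states[k]), 4))
      centers <- division_centers(geo$change_center, geo$base_radius +
                                    min(states[k], 1), n_blobs)
      radii <- rep(geo$base_radius * 0.8 / sqrt(n_blobs), n_blobs)
    } else {
      centers <- list(geo$change_center)
      radii <- geo$base_radius + states[k]
    }
    if (use_offset_layout(config)) {
      centers <- c(centers, list(geo$confound_center))
      radii <- c(radii, geo$confound_radius - confound_rate * times[k])
    }
    centers <- lapply(centers, transform_center, size = size, theta = theta,
                      shift = shift)
    img <- render_shapes(size, config$dims, centers, radii)
    img <- img * drift
    if (config$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, config$noise_sd)
    frames[[k]] <- pmin(pmax(img, 0), 1)
  }

  target <- states + if (config$target_noise_sd > 0)
    stats::rnorm(n_t, 0, config$target_noise_sd) else 0
  sid <- sprintf("S%03d", subject_index)
  records <- data.frame(subject_id = sid, time = times, path = NA_character_,
                        target = target, meta_time = times,
                        meta_sex_time = sex * times)
  records$image <- frames
  attr(records, "metadata_cols") <- c("meta_time", "meta_sex_time")

  gt <- list(subject_id = sid, rate = rate, confound_rate = confound_rate,
             group = group, sex = sex, times = times, states = states,
             change_mask = region_mask(config, "change"),
             confound_mask = region_mask(config, "confound"))
  list(records = records, ground_truth = gt)
}

#' Ground-truth region masks for a synthetic configuration
#'
#' The change mask covers everywhere the change process can place
#' intensity across the configured rate range (+3 SD) and nuisance
#' motion; analogously for the confound mask. The two are disjoint by
#' construction.
#'
#' @param config a [synth_config()].
#' @param which `"change"` or `"confound"`.
#' @return logical array of the image dimensions (all-`FALSE` for
#'   `"confound"` when no confound process is configured).
#' @export
region_mask <- function(config, which = c("change", "confound")) {
  which <- match.arg(which)
  geo <- synth_geometry(config)
  if (which == "confound" && is.null(geo$confound_center))
    return(array(FALSE, dim = rep(config$image_size, config$dims)))
  rate_hi <- max(config$change_rate_mean + abs(config$group_effect) +
                   3 * config$change_rate_sd, 0.01)
  ctr <- if (which == "change") geo$change_center else geo$confound_center
  r <- if (which == "change") {
    geo$base_radius + rate_hi * max_times(config)
  } else {
    geo$confound_radius
  }
  margin <- config$translation_max + 1.5 +
    sqrt(sum((ctr - (config$image_size + 1) / 2)^2)) *
    sin(pi * config$rotation_max / 180)
  ax <- seq_len(config$image_size)
  d2 <- if (config$dims == 2L) {
    outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+")
  } else {
    outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, "+"), (ax - ctr[3])^2, "+")
  }
  d2 <= (r + margin)^2
}

#' Generate a synthetic cohort
#'
#' Builds every subject's sequence in memory; when `dir` is given, also
#' writes one image file per frame (TIFF for 2D, NIfTI for 3D, or PNG with
#' `format = "png"`), a `manifest.csv` (subject_id, time, path, target,
#' metadata columns) and a `ground_truth.json` sidecar with per-subject
#' rates, groups, sexes and the region masks. A failed write removes all
#' partial outputs before rethrowing.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed), or `NULL` for an
#'   in-memory cohort.
#' @param format `"tiff"` (32-bit float), `"png"` (8-bit) or `"nifti"`;
#'   default picks TIFF for 2D and NIfTI for 3D.
#' @return object of class `synth_cohort`: list with `records` (all
#'   subjects, images loaded), `ground_truth` (data frame of per-subject
#'   scalars), `states` (list of per-subject state vectors), `change_mask`,
#'   `confound_mask`, `config`, and `dir`/`manifest` when written.
#' @export
generate_cohort <- function(config, dir = NULL, format = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(format))
    format <- if (config$dims == 2L) "tiff" else "nifti"
  format <- match.arg(format, c("tiff", "png", "nifti"))
  if (config$dims == 3L && format != "nifti")
    stop("3D cohorts must use the NIfTI format")

  seqs <- lapply(seq_len(config$n_subjects), function(i)
    generate_sequence(config, i))
  records <- do.call(rbind, lapply(seqs, `[[`, "records"))
  rownames(records) <- NULL
  attr(records, "metadata_cols") <- c("meta_time", "meta_sex_time")
  gts <- lapply(seqs, `[[`, "ground_truth")
  gt_df <- data.frame(subject_id = vapply(gts, `[[`, "", "subject_id"),
                      rate = vapply(gts, `[[`, 0, "rate"),
                      group = vapply(gts, `[[`, "", "group"),
                      sex = vapply(gts, `[[`, 0L, "sex"))
  cohort <- structure(list(records = records, ground_truth = gt_df,
                           states = lapply(gts, `[[`, "states"),
                           change_mask = gts[[1]]$change_mask,
                           confound_mask = gts[[1]]$confound_mask,
                           config = config, dir = dir, manifest = NULL),
                      class = "synth_cohort")
  if (is.null(dir)) return(cohort)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ext <- switch(format, tiff = "tiff", png = "png", nifti = "nii.gz")
  tryCatch({
    for (row in seq_len(nrow(records))) {
      fn <- file.path(dir, sprintf("%s_t%03d.%s", records$subject_id[row],
                                   row_time_index(records, row), ext))
      write_image(records$image[[row]], fn)
      written <- c(written, fn)
      records$path[row] <- fn
    }
    manifest <- file.path(dir, "manifest.csv")
    utils::write.csv(records[, c("subject_id", "time", "path", "target",
                                 "meta_time", "meta_sex_time")],
                     manifest, row.names = FALSE)
    written <- c(written, manifest)
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(list(subjects = gt_df,
                              states = lapply(cohort$states, as.numeric),
                              change_mask = cohort$change_mask * 1L,
                              confound_mask = cohort$confound_mask * 1L,
                              config = unclass(config)),
                         gt_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, gt_path)
  }, error = function(e) {
    unlink(written)
    stop("cohort write failed (partial outputs removed): ",
         conditionMessage(e))
  })
  cohort$records <- records
  cohort$dir <- dir
  cohort$manifest <- file.path(dir, "manifest.csv")
  cohort
}

row_time_index <- function(records, row) {
  sum(records$subject_id[seq_len(row)] == records$subject_id[row])
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("synthetic cohort:", x$config$n_subjects, "subjects,",
      nrow(x$records), "frames of",
      paste(rep(x$config$image_size, x$config$dims), collapse = "x"), "\n")
  invisible(x)
}
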