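# High-level pipeline plumbing: prediction tables, checkpoints with model
# cards, and the command-line entry points (simulate / train / predict /
# localize / evaluate). Every run writes a resolved-config JSON copy next
# to its outputs so any artifact is re-derivable from config + seed.

#' Predict comparison outputs for a pair set
#'
#' Runs the model in inference mode over every pair and returns a tidy
#' per-pair table: the presigmoid logit `r`, the chronological-order
#' probability (ordering task), or the predicted change (regression
#' tasks), together with the pair bookkeeping columns.
#'
#' @param object a `lilac_model`.
#' @param pairs a `lilac_pairs` object with loaded images.
#' @param batch_size evaluation batch size.
#' @param ... unused.
#' @return data frame with columns `subject_id`, `i`, `j`, `delta_time`,
#'   `order_label`, `delta_target`, `r` and `probability` or
#'   `predicted_change`.
#' @export
predict.lilac_model <- function(object, pairs, batch_size = 64L, ...) {
  stopifnot(inherits(pairs, "lilac_pairs"))
  ev <- eval_pairs(object, pairs, batch_size = batch_size)
  out <- pairs$pairs[, c("subject_id", "i", "j", "delta_time",
                         "order_label", "delta_target")]
  out$r <- ev$r
  if (object$config$task == "ordering") {
    out$probability <- predict_order_probability(ev$r)
  } else {
    out$predicted_change <- ev$r
  }
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles parameters, batch-norm statistics and the full
#' configuration; a human-readable `<path>.card.json` model card (task,
#' input geometry, metadata schema, training seed, training-target mean)
#' is written alongside.
#'
#' @param model a `lilac_model` or `sirb_model`.
#' @param path checkpoint file path (RDS).
#' @param seed training seed to record, if any.
#' @param train_target_mean mean of the training-pair targets, recorded
#'   for explainability scoring at prediction time.
#' @return `path`, invisibly (`save_checkpoint`); the model with a
#'   `card` attribute (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path, seed = NA_integer_,
                            train_target_mean = NA_real_) {
  card <- list(class = class(model), task = model$config$task,
               spatial = model$config$spatial,
               channels = model$config$channels,
               pooling = model$config$pooling,
               metadata_dim = model$config$metadata_dim,
               n_params = n_params(model), seed = seed,
               train_target_mean = train_target_mean)
  saveRDS(list(model = model, card = card), path)
  jsonlite::write_json(card, paste0(path, ".card.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- obj$model
  attr(model, "card") <- obj$card
  model
}

write_resolved_config <- function(config, dir, name = "resolved_config.json") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       file.path(dir, name), auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(file.path(dir, name))
}

cli_spec <- list(
  simulate = list(
    out = list(type = "character", help = "output directory", required = TRUE),
    seed = list(type = "integer", default = 1L),
    subjects = list(type = "integer", default = 10L),
    timepoints = list(type = "integer", default = 12L),
    size = list(type = "integer", default = 64L),
    dims = list(type = "integer", default = 2L),
    `group-effect` = list(type = "double", default = 0),
    `confound-rate` = list(type = "double", default = 0),
    rotation = list(type = "double", default = 0),
    translation = list(type = "double", default = 0),
    drift = list(type = "double", default = 0),
    noise = list(type = "double", default = 0.02)),
  train = list(
    manifest = list(type = "character", required = TRUE),
    out = list(type = "character", required = TRUE),
    task = list(type = "character", default = "ordering"),
    seed = list(type = "integer", default = 1L),
    epochs = list(type = "integer", default = 30L),
    `batch-size` = list(type = "integer", default = 32L),
    lr = list(type = "double", default = 1e-3),
    patience = list(type = "integer", default = 10L),
    metadata = list(type = "flag", default = FALSE),
    `curriculum-start` = list(type = "double", default = NA_real_),
    `val-fraction` = list(type = "double", default = 0.25)),
  predict = list(
    model = list(type = "character", required = TRUE),
    manifest = list(type = "character", required = TRUE),
    out = list(type = "character", required = TRUE),
    seed = list(type = "integer", default = 1L)),
  localize = list(
    model = list(type = "character", required = TRUE),
    manifest = list(type = "character", required = TRUE),
    out = list(type = "character", required = TRUE),
    `tau-threshold` = list(type = "double", default = 0.7),
    seed = list(type = "integer", default = 1L)),
  evaluate = list(
    model = list(type = "character", required = TRUE),
    manifest = list(type = "character", required = TRUE),
    out = list(type = "character", required = TRUE),
    group = list(type = "character", default = NA_character_),
    seed = list(type = "integer", default = 1L)))

parse_cli_args <- function(spec, args) {
  vals <- lapply(spec, function(s) if (identical(s$type, "flag")) FALSE
                 else s$default)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (!key %in% names(spec)) stop("unknown flag: --", key)
    if (identical(spec[[key]]$type, "flag")) {
      vals[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("flag --", key, " needs a value")
      raw <- args[i + 1L]
      vals[[key]] <- switch(spec[[key]]$type,
                            integer = as.integer(raw),
                            double = as.numeric(raw),
                            character = raw)
      i <- i + 2L
    }
  }
  for (key in names(spec)) {
    if (isTRUE(spec[[key]]$required) &&
        (is.null(vals[[key]]) || is.na(vals[[key]])))
      stop("missing required flag: --", key)
  }
  vals
}

cli_train_task <- function(manifest, opts) {
  records <- read_manifest(manifest, load_images = TRUE)
  task <- match.arg(opts$task, c("ordering", "interval", "score"))
  md <- attr(records, "metadata_cols")
  mdim <- if (isTRUE(opts$metadata)) length(md) else 0L
  spatial <- dim(records$image[[1]])
  splits <- split_subjects(records, c(1 - opts$`val-fraction`,
                                      opts$`val-fraction`),
                           seed = opts$seed)
  set.seed(opts$seed)
  train_pairs <- make_pairs(splits$train, task)
  val_pairs <- make_pairs(splits$val, task)
  set.seed(opts$seed)
  model <- lilac_model(lilac_config(spatial = spatial,
                                    metadata_dim = mdim, task = task))
  curriculum <- if (!is.na(opts$`curriculum-start`))
    list(start_threshold = opts$`curriculum-start`) else NULL
  control <- train_control(learning_rate = opts$lr,
                           batch_size = opts$`batch-size`,
                           max_epochs = opts$epochs,
                           patience = opts$patience,
                           curriculum = curriculum, seed = opts$seed)
  fit <- train_lilac(model, train_pairs, val_pairs, control)
  list(fit = fit, train_pairs = train_pairs, task = task, control = control)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `train`, `predict`, `localize`
#' and `evaluate`; see the `inst/cli/lilac.R` script for shell usage.
#' Every subcommand seeds all randomness from `--seed` and writes a
#' resolved-config JSON next to its outputs.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status (0 on success), invisibly.
#' @export
lilac_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args))
      stop("usage: lilac <simulate|train|predict|localize|evaluate> [flags]")
    sub <- args[1]
    if (!sub %in% names(cli_spec)) stop("unknown subcommand: ", sub)
    opts <- parse_cli_args(cli_spec[[sub]], args[-1])

    if (sub == "simulate") {
      cfg <- synth_config(image_size = opts$size, dims = opts$dims,
                          n_subjects = opts$subjects,
                          n_timepoints = opts$timepoints,
                          group_effect = opts$`group-effect`,
                          confound_rate = opts$`confound-rate`,
                          rotation_max = opts$rotation,
                          translation_max = opts$translation,
                          intensity_drift = opts$drift,
                          noise_sd = opts$noise, seed = opts$seed)
      generate_cohort(cfg, dir = opts$out)
      write_resolved_config(cfg, opts$out)
      message("cohort written to ", opts$out)
    } else if (sub == "train") {
      res <- cli_train_task(opts$manifest, opts)
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      ybar <- mean(pair_target(res$task, res$train_pairs$pairs))
      save_checkpoint(res$fit$model, file.path(opts$out, "best.ckpt"),
                      seed = opts$seed, train_target_mean = ybar)
      utils::write.csv(res$fit$report, file.path(opts$out, "trainlog.csv"),
                       row.names = FALSE)
      write_resolved_config(c(unclass(res$control), task = res$task),
                            opts$out)
      message("best epoch ", res$fit$best_epoch, "; checkpoint in ",
              opts$out)
    } else {
      model <- load_checkpoint(opts$model)
      card <- attr(model, "card")
      records <- read_manifest(opts$manifest, load_images = TRUE)
      set.seed(opts$seed)
      pairs <- make_pairs(records, model$config$task)

      if (sub == "predict") {
        preds <- predict(model, pairs)
        target <- pair_target(model$config$task, pairs$pairs)
        yhat <- if (model$config$task == "ordering")
          predict_order_probability(preds$r) else preds$r
        preds$tau <- explainability_score(target, yhat,
                                          card$train_target_mean)
        utils::write.csv(preds, opts$out, row.names = FALSE)
        write_resolved_config(opts, dirname(opts$out))
      } else if (sub == "localize") {
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        pairs <- max_interval_pairs(pairs)
        loc <- localize_pairs(model, pairs, card$train_target_mean)
        ext <- if (length(model$config$spatial) == 2L) "tiff" else "nii.gz"
        for (k in seq_len(nrow(pairs$pairs))) {
          fn <- file.path(opts$out, sprintf("saliency_%s.%s",
                                            pairs$pairs$subject_id[k], ext))
          write_image(loc$saliencies[[k]]$map /
                        max(loc$saliencies[[k]]$map, 1e-12), fn)
        }
        utils::write.csv(loc$peaks, file.path(opts$out, "peaks.csv"),
                         row.names = FALSE)
        pop <- tryCatch(population_peak_map(loc$saliencies, loc$peaks$tau,
                                            opts$`tau-threshold`),
                        error = function(e) NULL)
        if (!is.null(pop))
          write_image(pop$map / max(pop$map, 1e-12),
                      file.path(opts$out, paste0("population_peaks.", ext)))
        write_resolved_config(opts, opts$out)
      } else { # evaluate
        preds <- predict(model, pairs)
        report <- if (model$config$task == "ordering") {
          evaluate_ordering(preds$order_label, preds$r, seed = opts$seed)
        } else {
          target <- pair_target(model$config$task, pairs$pairs)
          evaluate_regression(target, preds$r, preds$delta_time)
        }
        anch <- anchored_pairs(pairs)
        apred <- predict(model, anch)
        lme_data <- data.frame(subject = apred$subject_id,
                               time = apred$delta_time, change = apred$r)
        if (!is.na(opts$group)) {
          gmap <- utils::read.csv(opts$group, stringsAsFactors = FALSE)
          lme_data$group <- gmap$group[match(lme_data$subject,
                                             gmap$subject_id)]
        }
        lme <- lme_fit(lme_data)
        out <- list(report = unclass(report),
                    lme = list(slope = lme$slope,
                               group_effect = lme$group_effect,
                               sigma_b2 = lme$sigma_b2,
                               lrt_random = lme$lrt_random,
                               lrt_group = lme$lrt_group))
        out$report$pcc <- unclass(out$report$pcc)
        jsonlite::write_json(out, opts$out, auto_unbox = TRUE, digits = NA,
                             force = TRUE)
        write_resolved_config(opts, dirname(opts$out))
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Saliency maps with explainability gating for a pair set
#'
#' Computes the modified Grad-CAM map for every pair, along with each
#' case's explainability score.
#'
#' @param model a trained `lilac_model`.
#' @param pairs a `lilac_pairs` object with loaded images.
#' @param train_target_mean training-target mean used as the baseline in
#'   [explainability_score()].
#' @param branch which activations to attribute (default `"pair"`, the
#'   presentation-invariant contribution map; see [modified_gradcam()]).
#' @return list with `saliencies` (list of `lilac_saliency`) and `peaks`
#'   (data frame: subject, pair indices, coarse peak coordinates, `tau`).
#' @export
localize_pairs <- function(model, pairs, train_target_mean,
                           branch = "pair") {
  df <- pairs$pairs
  md_use <- model$config$metadata_dim > 0
  sal <- vector("list", nrow(df))
  tau <- numeric(nrow(df))
  for (k in seq_len(nrow(df))) {
    inp <- batch_inputs(pairs, k, md_use)
    sal[[k]] <- modified_gradcam(model, inp$I1[[1]], inp$I2[[1]],
                                 inp$M1, inp$M2, branch = branch)
    target <- pair_target(model$config$task, df[k, , drop = FALSE])
    yhat <- if (model$config$task == "ordering")
      predict_order_probability(sal[[k]]$r) else sal[[k]]$r
    tau[k] <- explainability_score(target, yhat, train_target_mean)
  }
  peaks <- data.frame(subject_id = df$subject_id, i = df$i, j = df$j,
                      peak = vapply(sal, function(s)
                        paste(s$peak, collapse = "x"), ""),
                      peak_index = vapply(sal, `[[`, 0L, "peak_index"),
                      tau = tau)
  list(saliencies = sal, peaks = peaks)
}
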