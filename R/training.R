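# Task losses, Adam optimisation loop, curriculum scheduling, early
# stopping and validation-based model selection.

#' Training control parameters
#'
#' @param learning_rate Adam learning rate (default `1e-3`; Adam moment
#'   parameters are the conventional beta1 = 0.9, beta2 = 0.999,
#'   eps = 1e-8, no weight decay).
#' @param batch_size pairs per minibatch.
#' @param max_epochs maximum number of epochs.
#' @param patience early stopping: halt when the validation loss has not
#'   decreased for this many consecutive epochs (default 10).
#' @param curriculum `NULL`, or a list with elements `start_threshold`
#'   (initial minimum `|delta time|`), `step_epochs` (threshold update
#'   cadence, default 2) and `warmup_epochs` (epochs until all pairs are
#'   admitted, default 10); see [curriculum_filter()].
#' @param shuffle_orders for the ordering task without both-orders pairs,
#'   re-randomise each pair's presentation order every epoch (default
#'   `TRUE`), keeping label balance 1:1 in expectation.
#' @param seed integer seed controlling initial shuffling, presentation
#'   orders and minibatch composition for the whole run.
#' @param verbose print per-epoch progress.
#' @return a list of class `train_control`.
#' @export
train_control <- function(learning_rate = 1e-3, batch_size = 32L,
                          max_epochs = 30L, patience = 10L,
                          curriculum = NULL, shuffle_orders = TRUE,
                          seed = 1L, verbose = FALSE) {
  stopifnot(learning_rate >= 0, patience >= 1, max_epochs >= 1,
            batch_size >= 1)
  if (!is.null(curriculum)) {
    curriculum <- utils::modifyList(
      list(start_threshold = NULL, step_epochs = 2L, warmup_epochs = 10L),
      curriculum)
    if (is.null(curriculum$start_threshold) || curriculum$start_threshold <= 0)
      stop("curriculum needs a positive `start_threshold`")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), curriculum = curriculum,
                 shuffle_orders = isTRUE(shuffle_orders),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_control")
}

#' Task loss and its gradient with respect to the comparison logit
#'
#' Ordering: mean binary cross-entropy of `sigma(r)` against the
#' chronological-order label (computed in the numerically stable
#' logit form). Interval and score: mean squared error of `r` against the
#' time or target difference.
#'
#' @param task `"ordering"`, `"interval"` or `"score"`.
#' @param r numeric vector of comparison logits.
#' @param target labels in `{0, 1}` (ordering) or finite differences
#'   (regression).
#' @return list with `loss` (scalar) and `grad` (d loss / d r, same length
#'   as `r`).
#' @export
pair_loss <- function(task, r, target) {
  n <- length(r)
  stopifnot(length(target) == n, all(is.finite(target)))
  if (task == "ordering") {
    if (!all(target %in% c(0, 1))) stop("ordering labels must be 0 or 1")
    loss <- mean(pmax(r, 0) - r * target + log1p(exp(-abs(r))))
    grad <- (1 / (1 + exp(-r)) - target) / n
  } else {
    loss <- mean((r - target)^2)
    grad <- 2 * (r - target) / n
  }
  if (!is.finite(loss))
    stop("non-finite ", task, " loss (max |r| = ", max(abs(r)), ")")
  list(loss = loss, grad = grad)
}

pair_target <- function(task, pairs_df) {
  switch(task,
         ordering = pairs_df$order_label,
         interval = pairs_df$delta_time,
         score = {
           if (anyNA(pairs_df$delta_target))
             stop("score task requires a target column in the manifest")
           pairs_df$delta_target
         })
}

# Gather images / metadata for a block of pair rows. Metadata is supplied
# only when the model consumes it (use_metadata).
batch_inputs <- function(pairs, rows, use_metadata = FALSE) {
  df <- pairs$pairs[rows, , drop = FALSE]
  imgs <- pairs$records$image
  out <- list(I1 = imgs[df$i], I2 = imgs[df$j], M1 = NULL, M2 = NULL)
  md <- attr(pairs$records, "metadata_cols")
  if (use_metadata && length(md)) {
    out$M1 <- t(as.matrix(pairs$records[df$i, md, drop = FALSE]))
    out$M2 <- t(as.matrix(pairs$records[df$j, md, drop = FALSE]))
  }
  out
}

# One evaluation pass (inference mode) over a pair set; returns loss plus
# the task metric (AUC for ordering, R^2 for regression) and raw logits.
eval_pairs <- function(model, pairs, batch_size = 64L) {
  task <- model$config$task
  df <- pairs$pairs
  n <- nrow(df)
  r <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n)
    inp <- batch_inputs(pairs, rows, model$config$metadata_dim > 0)
    out <- compare_forward(model, inp$I1, inp$I2, inp$M1, inp$M2,
                           training = FALSE, retain = FALSE)
    r[rows] <- out$r
  }
  target <- pair_target(task, df)
  loss <- pair_loss(task, r, target)$loss
  metric <- if (task == "ordering") {
    if (length(unique(target)) < 2) NA_real_ else auc(target, r)
  } else {
    regression_metrics(target, r)$r_squared
  }
  list(loss = loss, metric = metric, r = r)
}

# Flip presentation order for the given pair rows (swap images, flip label,
# negate deltas).
flip_pairs <- function(df, flip) {
  tmp <- df$i[flip]
  df$i[flip] <- df$j[flip]
  df$j[flip] <- tmp
  df$order_label[flip] <- 1 - df$order_label[flip]
  df$delta_time[flip] <- -df$delta_time[flip]
  if (!is.null(df$delta_target))
    df$delta_target[flip] <- -df$delta_target[flip]
  df
}

#' Train a LILAC comparison model
#'
#' Minimises the task loss with Adam. Each epoch optionally applies the
#' curriculum filter, shuffles the admitted pairs, and (for the ordering
#' task) re-randomises presentation orders. After every epoch the
#' validation loss and metric are computed in inference mode; training
#' stops early when the validation loss has not improved for `patience`
#' consecutive epochs, and the parameters and batch-norm statistics from
#' the best-validation-loss epoch are restored.
#'
#' @param model a `lilac_model` (or `sirb_model`, see [train_sirb()]).
#' @param train_pairs,val_pairs `lilac_pairs` objects from [make_pairs()];
#'   their subject sets must be disjoint.
#' @param control a [train_control()].
#' @return list of class `lilac_fit` with elements `model` (the selected
#'   model), `report` (a data frame of per-epoch train/validation loss and
#'   validation metric), `best_epoch` and `stopped_early`.
#' @export
train_lilac <- function(model, train_pairs, val_pairs,
                        control = train_control()) {
  stopifnot(inherits(model, "lilac_model"))
  task <- model$config$task
  shared <- intersect(unique(train_pairs$records$subject_id),
                      unique(val_pairs$records$subject_id))
  if (length(shared))
    stop("subject leakage between train and validation sets: ",
         paste(shared, collapse = ", "))

  set.seed(control$seed)
  opt <- adam_init(model$params)
  base_df <- train_pairs$pairs
  best <- list(loss = Inf, epoch = NA_integer_, params = model$params,
               state = model$state)
  bad_epochs <- 0L
  log <- vector("list", control$max_epochs)

  for (epoch in seq_len(control$max_epochs)) {
    df <- base_df
    if (!is.null(control$curriculum)) {
      cc <- control$curriculum
      keep <- curriculum_keep(df$delta_time, epoch - 1L, cc$start_threshold,
                              cc$step_epochs, cc$warmup_epochs)
      if (!any(keep)) {
        warning("curriculum admitted no pairs at epoch ", epoch,
                "; relaxing threshold")
        ahead <- epoch - 1L
        while (!any(keep) && curriculum_threshold(ahead, cc$start_threshold,
                                                  cc$step_epochs,
                                                  cc$warmup_epochs) > 0) {
          ahead <- ahead + cc$step_epochs
          keep <- curriculum_keep(df$delta_time, ahead, cc$start_threshold,
                                  cc$step_epochs, cc$warmup_epochs)
        }
      }
      df <- df[keep, , drop = FALSE]
    }
    if (task == "ordering" && control$shuffle_orders &&
        !isTRUE(train_pairs$both_orders)) {
      df <- flip_pairs(df, stats::runif(nrow(df)) < 0.5)
    }
    df <- df[sample.int(nrow(df)), , drop = FALSE]

    epoch_pairs <- list(records = train_pairs$records, pairs = df)
    train_loss <- 0
    n_seen <- 0L
    for (start in seq(1L, nrow(df), by = control$batch_size)) {
      rows <- start:min(start + control$batch_size - 1L, nrow(df))
      inp <- batch_inputs(epoch_pairs, rows, model$config$metadata_dim > 0)
      out <- compare_forward(model, inp$I1, inp$I2, inp$M1, inp$M2,
                             training = TRUE, retain = TRUE)
      model$state <- out$fw$state
      tl <- pair_loss(task, out$r, pair_target(task, df[rows, , drop = FALSE]))
      train_loss <- train_loss + tl$loss * length(rows)
      n_seen <- n_seen + length(rows)

      # head gradient, then shared-extractor gradient for both branches
      dw <- as.vector((out$z1 - out$z2) %*% tl$grad)
      fdim <- model$config$feature_dim
      dpair <- outer(model$params$w[seq_len(fdim)], tl$grad)
      dfeat <- cbind(dpair, -dpair)
      gblocks <- extractor_backward(model, out$fw$caches, dfeat)
      step <- adam_step(model$params, list(blocks = gblocks, w = dw), opt,
                        lr = control$learning_rate)
      model$params <- step$params
      opt <- step$state
    }

    val <- eval_pairs(model, val_pairs)
    log[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss / n_seen,
                               val_loss = val$loss, val_metric = val$metric)
    if (control$verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  metric %.4f",
                      epoch, train_loss / n_seen, val$loss, val$metric))

    if (val$loss < best$loss) {
      best <- list(loss = val$loss, epoch = epoch, params = model$params,
                   state = model$state)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= control$patience) break
    }
  }

  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, report = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
                 best_epoch = best$epoch,
                 stopped_early = bad_epochs >= control$patience),
            class = "lilac_fit")
}

#' @export
print.lilac_fit <- function(x, ...) {
  cat("LILAC fit:", nrow(x$report), "epochs, best epoch", x$best_epoch,
      if (x$stopped_early) "(early stop)" else "", "\n")
  cat("  best val loss:", format(min(x$report$val_loss)),
      " val metric:", format(x$report$val_metric[x$best_epoch]), "\n")
  invisible(x)
}

#' Train the single-image regression baseline
#'
#' Fits the SIRB regressor to predict each record's target (the `time`
#' column for interval-style use, or the `target` column) from single
#' images with MSE loss, mirroring the optimisation settings of
#' [train_lilac()].
#'
#' @param model a `sirb_model`.
#' @param train_records,val_records record data frames (see
#'   [read_manifest()]) with loaded images; targets taken from `target_col`.
#' @param target_col `"time"` or `"target"`.
#' @param control a [train_control()].
#' @return list of class `sirb_fit` with `model`, `report`, `best_epoch`.
#' @export
train_sirb <- function(model, train_records, val_records,
                       target_col = c("time", "target"),
                       control = train_control()) {
  stopifnot(inherits(model, "sirb_model"))
  target_col <- match.arg(target_col)
  md <- attr(train_records, "metadata_cols")
  get_M <- function(records, rows) {
    if (model$config$metadata_dim == 0L || !length(md)) NULL
    else t(as.matrix(records[rows, md, drop = FALSE]))
  }
  set.seed(control$seed)
  opt <- adam_init(model$params)
  y_tr <- train_records[[target_col]]
  y_va <- val_records[[target_col]]
  stopifnot(all(is.finite(y_tr)), all(is.finite(y_va)))

  eval_loss <- function() {
    preds <- numeric(nrow(val_records))
    for (start in seq(1L, nrow(val_records), by = 64L)) {
      rows <- start:min(start + 63L, nrow(val_records))
      preds[rows] <- sirb_forward(model, val_records$image[rows],
                                  get_M(val_records, rows),
                                  training = FALSE, retain = FALSE)$pred
    }
    mean((preds - y_va)^2)
  }

  best <- list(loss = Inf, epoch = NA_integer_, params = model$params,
               state = model$state)
  bad_epochs <- 0L
  log <- vector("list", control$max_epochs)
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(nrow(train_records))
    train_loss <- 0
    for (start in seq(1L, length(ord), by = control$batch_size)) {
      rows <- ord[start:min(start + control$batch_size - 1L, length(ord))]
      out <- sirb_forward(model, train_records$image[rows],
                          get_M(train_records, rows),
                          training = TRUE, retain = TRUE)
      model$state <- out$fw$state
      err <- out$pred - y_tr[rows]
      loss <- mean(err^2)
      train_loss <- train_loss + loss * length(rows)
      dpred <- 2 * err / length(rows)
      dw <- as.vector(out$z %*% dpred)
      db <- sum(dpred)
      fdim <- model$config$feature_dim
      dfeat <- outer(model$params$w[seq_len(fdim)], dpred)
      gblocks <- extractor_backward(model, out$fw$caches, dfeat)
      step <- adam_step(model$params, list(blocks = gblocks, w = dw, b = db),
                        opt, lr = control$learning_rate)
      model$params <- step$params
      opt <- step$state
    }
    vloss <- eval_loss()
    log[[epoch]] <- data.frame(epoch = epoch,
                               train_loss = train_loss / nrow(train_records),
                               val_loss = vloss, val_metric = NA_real_)
    if (vloss < best$loss) {
      best <- list(loss = vloss, epoch = epoch, params = model$params,
                   state = model$state)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= control$patience) break
    }
  }
  model$params <- best$params
  model$state <- best$state
  structure(list(model = model,
                 report = do.call(rbind, log[!vapply(log, is.null, TRUE)]),
                 best_epoch = best$epoch),
            class = "sirb_fit")
}
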