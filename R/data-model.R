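# Manifest I/O, image loading, subject-wise splitting, within-subject pair
# construction for the three tasks, and the curriculum schedule.
#
# A record set is a data.frame with columns subject_id (character), time
# (numeric), path (character, may be NA when images are in memory), target
# (numeric, may be NA) and an `image` list-column of numeric arrays once
# loaded. Additional numeric covariate columns are tracked through the
# "metadata_cols" attribute and concatenated to the feature vector by
# metadata-aware models.

#' Read a longitudinal image manifest
#'
#' The manifest is a UTF-8 CSV with a header and required columns
#' `subject_id`, `time`, `path`; optional `target`; every remaining numeric
#' column is treated as a per-timepoint metadata covariate. Records are
#' returned sorted by (subject, time); duplicate (subject, time) rows are an
#' error.
#'
#' @param path manifest CSV path.
#' @param load_images read the images now (via [load_images()]).
#' @return a record data.frame (see package overview) with attribute
#'   `metadata_cols`.
#' @export
read_manifest <- function(path, load_images = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "time", "path")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!is.numeric(df$time))
    stop("manifest column `time` must be numeric")
  if (anyNA(df$time) || any(!is.finite(df$time)))
    stop("manifest column `time` contains missing or non-finite values")
  df$subject_id <- as.character(df$subject_id)
  if (is.null(df$target)) df$target <- NA_real_
  dup <- duplicated(df[c("subject_id", "time")])
  if (any(dup))
    stop("duplicate (subject_id, time) rows in manifest: ",
         paste(unique(df$subject_id[dup]), collapse = ", "))
  extra <- setdiff(names(df), c(required, "target"))
  meta_cols <- extra[vapply(df[extra], is.numeric, TRUE)]
  df <- df[order(df$subject_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "metadata_cols") <- meta_cols
  if (load_images) df <- load_images(df) else df$image <- vector("list", nrow(df))
  df
}

#' Load the images referenced by a record set
#'
#' Format is chosen by file extension: PNG and TIFF for 2D single-channel
#' images (first channel used if more are present), NIfTI for 3D volumes.
#'
#' @param records a record data.frame with a `path` column.
#' @return the records with a populated `image` list-column.
#' @export
load_images <- function(records) {
  records$image <- lapply(records$path, read_image)
  records
}

read_image <- function(path) {
  if (is.na(path) || !file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    nii = ,
    gz = as.array(RNifti::readNifti(path)),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L && ext %in% c("png", "tif", "tiff"))
    img <- img[, , 1L] # single-channel convention for 2D formats
  img
}

write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 32L,
                           compression = "none"),
    nii = ,
    gz = RNifti::writeNifti(RNifti::asNifti(img), path),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Split records subject-wise into train/validation/test sets
#'
#' Every subject's records land wholly in exactly one split (no leakage);
#' subject counts per split follow the fractions by largest-remainder
#' rounding. 10 subjects at (0.6, 0.2, 0.2) give 6/2/2.
#'
#' @param records record data.frame.
#' @param fractions positive, summing to 1; default `c(0.6, 0.2, 0.2)`.
#' @param seed integer seed making the split deterministic.
#' @return named list `train`, `val`, `test` of record data.frames (each
#'   retaining the `metadata_cols` attribute).
#' @export
split_subjects <- function(records, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-8)
  subjects <- unique(records$subject_id)
  k <- length(fractions)
  if (length(subjects) < k)
    stop("need at least ", k, " subjects for ", k, " splits; got ",
         length(subjects))
  set.seed(seed)
  subjects <- sample(subjects)
  counts <- floor(fractions * length(subjects))
  rem <- length(subjects) - sum(counts)
  if (rem > 0) {
    frac_part <- fractions * length(subjects) - counts
    counts[order(frac_part, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac_part, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  ends <- cumsum(counts)
  starts <- c(1, utils::head(ends, -1) + 1)
  md <- attr(records, "metadata_cols")
  out <- lapply(seq_len(k), function(i) {
    sub <- records[records$subject_id %in% subjects[starts[i]:ends[i]], ,
                   drop = FALSE]
    rownames(sub) <- NULL
    attr(sub, "metadata_cols") <- md
    sub
  })
  names(out) <- c("train", "val", "test")[seq_len(k)]
  out
}

#' Build within-subject longitudinal pairs
#'
#' Enumerates all unordered within-subject timepoint pairs. For the
#' ordering task each pair is given a random presentation order (so labels
#' are balanced 1:1 in expectation); with `both_orders = TRUE` each pair is
#' emitted in both orders for exact balance. `delta_time` and
#' `delta_target` are signed following the presentation order
#' (second minus first), and `order_label` is 1 exactly when
#' `delta_time > 0`. Subjects with a single timepoint are skipped with a
#' warning.
#'
#' @param records record data.frame (images need not be loaded yet).
#' @param task `"ordering"`, `"interval"` or `"score"`.
#' @param both_orders emit each unordered pair in both presentation orders.
#' @param max_pairs_per_subject optional cap for long sequences; when a
#'   subject generates more pairs, a uniform subsample of this size is
#'   kept.
#' @return object of class `lilac_pairs`: list with `records`, `pairs`
#'   (data frame of indices `i`, `j` into `records`, `subject_id`,
#'   `order_label`, `delta_time`, `delta_target`), `task`, `both_orders`.
#' @export
make_pairs <- function(records, task = c("ordering", "interval", "score"),
                       both_orders = FALSE, max_pairs_per_subject = Inf) {
  task <- match.arg(task)
  singletons <- names(which(table(records$subject_id) < 2))
  if (length(singletons))
    warning("skipping subject(s) with a single timepoint: ",
            paste(singletons, collapse = ", "))
  idx_by_subject <- split(seq_len(nrow(records)), records$subject_id)
  idx_by_subject <- idx_by_subject[lengths(idx_by_subject) >= 2]
  if (!length(idx_by_subject)) stop("no subject has two or more timepoints")

  build <- function(rows) {
    cmb <- utils::combn(rows, 2L)
    if (ncol(cmb) > max_pairs_per_subject)
      cmb <- cmb[, sample.int(ncol(cmb), max_pairs_per_subject), drop = FALSE]
    i <- cmb[1L, ]
    j <- cmb[2L, ] # records are time-sorted within subject, so time_i < time_j
    if (both_orders) {
      data.frame(i = c(i, j), j = c(j, i))
    } else {
      flip <- stats::runif(length(i)) < 0.5
      data.frame(i = ifelse(flip, j, i), j = ifelse(flip, i, j))
    }
  }
  df <- do.call(rbind, lapply(idx_by_subject, build))
  rownames(df) <- NULL
  df$subject_id <- records$subject_id[df$i]
  df$delta_time <- records$time[df$j] - records$time[df$i]
  df$order_label <- as.integer(df$delta_time > 0)
  df$delta_target <- records$target[df$j] - records$target[df$i]
  structure(list(records = records, pairs = df, task = task,
                 both_orders = both_orders),
            class = "lilac_pairs")
}

#' @export
print.lilac_pairs <- function(x, ...) {
  cat("lilac_pairs:", nrow(x$pairs), "pairs,",
      length(unique(x$pairs$subject_id)), "subjects, task", x$task, "\n")
  invisible(x)
}

curriculum_threshold <- function(epoch, start_threshold, step_epochs = 2L,
                                 warmup_epochs = 10L) {
  steps_done <- (epoch %/% step_epochs) * step_epochs
  max(0, start_threshold * (1 - steps_done / warmup_epochs))
}

curriculum_keep <- function(delta_time, epoch, start_threshold,
                            step_epochs = 2L, warmup_epochs = 10L) {
  abs(delta_time) > curriculum_threshold(epoch, start_threshold, step_epochs,
                                         warmup_epochs)
}

#' Curriculum filter over longitudinal pairs
#'
#' Warm-up schedule for hard tasks: early epochs train only on pairs with
#' a large absolute time separation, then the threshold decays linearly to
#' zero, stepping every `step_epochs` epochs, so that after
#' `warmup_epochs` epochs every pair is admitted. At epoch 0 only pairs
#' with `|delta_time| > start_threshold` pass.
#'
#' @param pairs a `lilac_pairs` object.
#' @param epoch 0-based epoch index.
#' @param start_threshold initial minimum `|delta_time|` (e.g. 50 for
#'   month-scaled brain studies); 0 disables filtering.
#' @param step_epochs cadence of threshold updates (default 2).
#' @param warmup_epochs epochs until all pairs pass (default 10).
#' @return a `lilac_pairs` object containing the admitted subset.
#' @export
curriculum_filter <- function(pairs, epoch, start_threshold,
                              step_epochs = 2L, warmup_epochs = 10L) {
  stopifnot(inherits(pairs, "lilac_pairs"), step_epochs >= 1,
            start_threshold >= 0)
  if (start_threshold == 0) return(pairs)
  keep <- curriculum_keep(pairs$pairs$delta_time, epoch, start_threshold,
                          step_epochs, warmup_epochs)
  pairs$pairs <- pairs$pairs[keep, , drop = FALSE]
  rownames(pairs$pairs) <- NULL
  pairs
}

#' Keep one pair per subject with the largest time separation
#'
#' Population-level saliency summaries weigh subjects equally by using, for
#' every subject, only the pair with the maximum `|delta_time|` (ties:
#' first in pair order).
#'
#' @param pairs a `lilac_pairs` object.
#' @return a `lilac_pairs` object with at most one pair per subject.
#' @export
max_interval_pairs <- function(pairs) {
  df <- pairs$pairs
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$subject_id),
                        function(rows) rows[which.max(abs(df$delta_time[rows]))]))
  pairs$pairs <- df[sort(keep), , drop = FALSE]
  rownames(pairs$pairs) <- NULL
  pairs
}
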