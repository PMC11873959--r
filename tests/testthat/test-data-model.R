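write_test_manifest <- function(df,
                                dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_manifest validates, sorts and collects metadata columns", {
  df <- data.frame(subject_id = c("s2", "s1", "s1"),
                   time = c(1, 2, 0.5),
                   path = NA_character_,
                   target = c(3, 2, 1),
                   meta_age = c(60, 61, 60))
  rec <- read_manifest(write_test_manifest(df))
  expect_equal(nrow(rec), 3)
  expect_equal(rec$subject_id, c("s1", "s1", "s2")) # sorted by subject, time
  expect_equal(rec$time, c(0.5, 2, 1))
  expect_equal(attr(rec, "metadata_cols"), "meta_age")

  dup <- df; dup$time <- c(2, 2, 2); dup$subject_id <- "s1"
  expect_error(read_manifest(write_test_manifest(dup)), "duplicate")
  expect_error(read_manifest(write_test_manifest(df[, c("subject_id", "time")])),
               "missing required column")
  bad_time <- df; bad_time$time <- c("a", "b", "c")
  expect_error(read_manifest(write_test_manifest(bad_time)), "numeric")
  expect_error(read_manifest("no/such/file.csv"), "not found")
})

test_that("manifest images round-trip through TIFF and PNG", {
  dir <- withr::local_tempdir()
  img <- matrix(runif(32 * 32), 32, 32)
  tif <- file.path(dir, "a.tiff")
  lilac:::write_image(img, tif)
  expect_equal(lilac:::read_image(tif), img, tolerance = 1e-6)
  png_path <- file.path(dir, "a.png")
  lilac:::write_image(img, png_path)
  expect_equal(lilac:::read_image(png_path), img, tolerance = 1 / 255)
})

test_that("subject-wise splits follow rounded fractions with no leakage", {
  rec <- data.frame(subject_id = rep(sprintf("s%02d", 1:10), each = 3),
                    time = rep(1:3, 10), path = NA, target = NA)
  sp <- split_subjects(rec, c(0.6, 0.2, 0.2), seed = 7)
  counts <- vapply(sp, function(x) length(unique(x$subject_id)), 1L)
  expect_equal(unname(counts), c(6L, 2L, 2L))
  ids <- lapply(sp, function(x) unique(x$subject_id))
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$val, ids$test), 0)
  sp2 <- split_subjects(rec, c(0.6, 0.2, 0.2), seed = 7)
  expect_identical(lapply(sp2, `[[`, "subject_id"),
                   lapply(sp, `[[`, "subject_id"))
  expect_error(split_subjects(rec[rec$subject_id %in% c("s01", "s02"), ],
                              c(0.6, 0.2, 0.2)), "at least 3 subjects")
})

test_that("make_pairs enumerates within-subject pairs with consistent labels", {
  rec <- data.frame(subject_id = c(rep("a", 3), "b"),
                    time = c(0, 4, 9, 1), path = NA, target = c(1, 3, 6, 0))
  set.seed(1)
  expect_warning(p <- make_pairs(rec, "ordering"), "single timepoint")
  expect_equal(nrow(p$pairs), 3) # C(3,2)
  expect_equal(p$pairs$order_label, as.integer(p$pairs$delta_time > 0))

  set.seed(1)
  expect_warning(pb <- make_pairs(rec, "ordering", both_orders = TRUE))
  expect_equal(nrow(pb$pairs), 6)
  expect_equal(sum(pb$pairs$order_label), 3L)

  # signs follow presentation order: reversing flips label and deltas
  with_pair <- pb$pairs
  fwd <- with_pair[with_pair$order_label == 1, ]
  rev <- with_pair[with_pair$order_label == 0, ]
  key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
  m <- match(key(fwd), key(rev))
  expect_equal(fwd$delta_time, -rev$delta_time[m])
  expect_equal(fwd$delta_target, -rev$delta_target[m])

  # interval task: reversed presentation of times (0, 4) gives -4
  expect_true(all(abs(pb$pairs$delta_time) %in% c(4, 5, 9)))
})

test_that("curriculum filter starts wide and admits everything after warmup", {
  rec <- data.frame(subject_id = "a", time = c(0, 10, 45, 80, 140),
                    path = NA, target = NA)
  set.seed(2)
  p <- make_pairs(rec, "interval")
  f0 <- curriculum_filter(p, epoch = 0, start_threshold = 50)
  expect_true(all(abs(f0$pairs$delta_time) > 50))
  expect_lt(nrow(f0$pairs), nrow(p$pairs))
  f10 <- curriculum_filter(p, epoch = 10, start_threshold = 50)
  expect_equal(nrow(f10$pairs), nrow(p$pairs))
  expect_equal(nrow(curriculum_filter(p, 0, 0)$pairs), nrow(p$pairs))
  # threshold decays stepwise every 2 epochs
  thr <- vapply(0:10, lilac:::curriculum_threshold, 0, start_threshold = 50)
  expect_equal(thr[1:2], c(50, 50))
  expect_true(all(diff(thr) <= 0))
  expect_equal(thr[11], 0)
})

test_that("max_interval_pairs keeps one widest pair per subject", {
  rec <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                    time = c(0, 1, 5, 2, 3, 4), path = NA, target = NA)
  set.seed(3)
  p <- max_interval_pairs(make_pairs(rec, "ordering"))
  expect_equal(nrow(p$pairs), 2)
  expect_equal(sort(abs(p$pairs$delta_time)), c(2, 5))
})
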