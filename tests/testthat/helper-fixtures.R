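# Shared fixtures: tiny configs for unit tests and memoised trained models
# for the end-to-end checks (each model is trained once per test run and
# reused across test files).

# testthat attaches after the package under test and its deprecated
# compare() would otherwise mask the comparison head
compare <- lilac::compare

tiny_config <- function(...) {
  lilac_config(spatial = c(32, 32), channels = c(2, 3, 3, 4), ...)
}

rand_img <- function(sp = c(32, 32)) array(runif(prod(sp)), dim = sp)

# Brute-force state extractor: recover the disk radius of a noiseless
# render from its foreground area.
extract_disk_radius <- function(frame, threshold = 0.5) {
  sqrt(sum(frame > threshold) / pi)
}

# Cohort used for the ordering + localization end-to-end checks: compact
# off-centre change region so the change mask covers only ~11% of the
# field.
localization_cohort <- function() {
  generate_cohort(synth_config(n_subjects = 10, n_timepoints = 12,
                               change_rate_mean = 0.2, change_rate_sd = 0.05,
                               rotation_max = 2, translation_max = 1,
                               layout = "offset", seed = 11))
}

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, builder(), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# LILAC-o trained on the localization cohort (60/20/20 subject split).
ordering_experiment <- function() {
  cached("ordering", function() {
    cohort <- localization_cohort()
    splits <- split_subjects(cohort$records, c(0.6, 0.2, 0.2), seed = 1)
    set.seed(1)
    tr <- make_pairs(splits$train, "ordering")
    va <- make_pairs(splits$val, "ordering")
    te <- make_pairs(splits$test, "ordering")
    set.seed(1)
    model <- lilac_model(lilac_config(spatial = c(64, 64), task = "ordering"))
    fit <- train_lilac(model, tr, va,
                       train_control(max_epochs = 10, seed = 1))
    list(cohort = cohort, train = tr, val = va, test = te, fit = fit)
  })
}

# LILAC-t trained on the central-disk cohort.
interval_experiment <- function() {
  cached("interval", function() {
    cohort <- generate_cohort(synth_config(n_subjects = 10, seed = 5))
    splits <- split_subjects(cohort$records, c(0.6, 0.2, 0.2), seed = 2)
    set.seed(2)
    tr <- make_pairs(splits$train, "interval")
    va <- make_pairs(splits$val, "interval")
    te <- make_pairs(splits$test, "interval")
    set.seed(2)
    model <- lilac_model(lilac_config(spatial = c(64, 64), task = "interval"))
    fit <- train_lilac(model, tr, va,
                       train_control(max_epochs = 12, seed = 2))
    list(cohort = cohort, train = tr, val = va, test = te, fit = fit)
  })
}

# LILAC-s with metadata (t, sex*t) on the two-process cohort.
score_experiment <- function() {
  cached("score", function() {
    cohort <- generate_cohort(synth_config(n_subjects = 10, n_timepoints = 12,
                                           change_rate_mean = 0.3,
                                           change_rate_sd = 0.1,
                                           confound_rate = 0.15,
                                           confound_rate_sd = 0.05,
                                           rotation_max = 2,
                                           translation_max = 1, seed = 6))
    splits <- split_subjects(cohort$records, c(0.6, 0.2, 0.2), seed = 3)
    set.seed(3)
    tr <- make_pairs(splits$train, "score")
    va <- make_pairs(splits$val, "score")
    te <- make_pairs(splits$test, "score")
    set.seed(3)
    model <- lilac_model(lilac_config(spatial = c(64, 64), metadata_dim = 2,
                                      task = "score"))
    fit <- train_lilac(model, tr, va,
                       train_control(max_epochs = 12, seed = 3))
    list(cohort = cohort, train = tr, val = va, te = te, test = te, fit = fit)
  })
}

# Stub comparison model with a known sensitive region: random extractor,
# head weights supported only on the features of a block of coarse cells.
region_stub <- function(cells, spatial = c(64, 64)) {
  model <- lilac_model(lilac_config(spatial = spatial))
  C4 <- model$config$channels[4L]
  P4 <- prod(spatial %/% 16L)
  w <- matrix(0, C4, P4)
  w[, cells] <- rnorm(C4 * length(cells))
  model$params$w <- as.vector(w)
  model
}
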