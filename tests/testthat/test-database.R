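## small labelled files for database tests, built from the simulator truth
make_labelled <- function(n, seed) {
  sim <- simulate_sample(fx_model(), sample_spec(n_events = n, seed = seed))
  list(em = prepare_events(sim$em, sim$spill), labels = sim$truth)
}

test_that("initial templates match per-population sample medians exactly", {
  tax <- fx_tax()
  f <- make_labelled(2e4, 301)
  db <- init_database(f$em, f$labels, tax, file_id = "a")
  mk <- db$markers
  for (p in c("Neutrophils", "CD5+ T-cells", "Naive CD5+ B-cells")) {
    idx <- f$labels == p
    expect_equal(db$templates[[p]]$location,
                 apply(f$em$values[idx, mk], 2, median))
    expect_identical(db$templates[[p]]$n, sum(idx))
  }
  ## populations absent from the file are absent from the database
  expect_false("No such" %in% names(db$templates))
  expect_error(init_database(f$em, character(0), tax),
               class = "agiflow_value_error")
  expect_error(init_database(f$em, rep("Bogus", nrow(f$em$values)), tax),
               class = "agiflow_value_error")
})

test_that("a single-population file yields a one-template database", {
  tax <- fx_tax()
  f <- make_labelled(5000, 303)
  keep <- f$labels == "Neutrophils"
  em <- f$em
  em$values <- em$values[keep, , drop = FALSE]
  db <- init_database(em, f$labels[keep], tax)
  expect_identical(names(db$templates), "Neutrophils")
})

test_that("merging is commutative and pooling multiplies counts", {
  tax <- fx_tax()
  fa <- make_labelled(1.5e4, 305)
  fb <- make_labelled(1.5e4, 307)
  ab <- classify_and_merge(init_database(fa$em, fa$labels, tax, "a"),
                           fb$em, fb$labels, "b")
  ba <- classify_and_merge(init_database(fb$em, fb$labels, tax, "b"),
                           fa$em, fa$labels, "a")
  for (p in names(ab$templates)) {
    expect_identical(ab$templates[[p]]$n, ba$templates[[p]]$n)
    expect_equal(ab$templates[[p]]$location, ba$templates[[p]]$location,
                 tolerance = 1e-9)
  }
  ## merging a file from identical templates moves locations < 0.1 units
  base <- init_database(fa$em, fa$labels, tax, "a")
  big <- names(which(vapply(base$templates, `[[`, numeric(1), "n") > 500))
  for (p in big)
    expect_lt(max(abs(ab$templates[[p]]$location -
                        base$templates[[p]]$location)), 0.1)
  ## merge of k identical files: n multiplied, location unchanged
  twice <- classify_and_merge(base, fa$em, fa$labels, "a2")
  for (p in big) {
    expect_identical(twice$templates[[p]]$n, 2L * base$templates[[p]]$n)
    expect_equal(twice$templates[[p]]$location,
                 base$templates[[p]]$location, tolerance = 1e-12)
  }
  ## input database unchanged; a population unseen before creates a template
  expect_identical(length(base$log), 1L)
  ## merging updates the build log
  expect_identical(length(ab$log), 2L)
})

test_that("headless merge classifies the new file with the database", {
  tax <- fx_tax()
  fa <- make_labelled(2e4, 309)
  db <- init_database(fa$em, fa$labels, tax, "a")
  fb <- make_labelled(5000, 311)
  merged <- classify_and_merge(db, fb$em, file_id = "b", seed = 5)
  expect_gt(length(unique(merged$events[file_id == "b"]$population)), 3)
  expect_identical(length(merged$log), 2L)
})

test_that("provenance is complete and the store is thinned", {
  tax <- fx_tax()
  fa <- make_labelled(2e4, 313)
  db <- init_database(fa$em, fa$labels, tax, "a", thin = 100, seed = 2)
  expect_true(all(db$events$file_id == "a"))
  expect_lte(max(table(db$events$population)), 100)
  ## templates still reflect full data (medians computed before thinning)
  idx <- fa$labels == "Neutrophils"
  expect_equal(db$templates[["Neutrophils"]]$location,
               apply(fa$em$values[idx, db$markers], 2, median))
})

test_that("homogeneous cohorts pass the leave-one-file-out check", {
  tax <- fx_tax()
  db <- NULL
  for (i in 1:5) {
    f <- make_labelled(1.5e4, 400 + i)
    db <- if (is.null(db)) init_database(f$em, f$labels, tax, paste0("f", i),
                                         thin = 2000)
    else classify_and_merge(db, f$em, f$labels, paste0("f", i), thin = 2000)
  }
  rep <- consistency_check(db)
  chk <- rep[rep$skipped == FALSE & !is.na(rep$flagged), ]
  expect_gt(nrow(chk), 20)
  expect_gt(mean(!chk$flagged), 0.9)
  ## populations present in a single file are skipped, listed
  one_file <- names(which(vapply(db$templates, function(t)
    length(t$file_ns), integer(1)) == 1))
  if (length(one_file))
    expect_true(all(rep$skipped[rep$population %in% one_file]))
})

test_that("a planted marker shift is flagged by the consistency check", {
  tax <- fx_tax()
  db <- NULL
  for (i in 1:4) {
    sim <- simulate_sample(fx_model(),
      sample_spec(n_events = 1.5e4, seed = 500 + i,
                  mfi_shift = if (i == 4) c(CD27 = 2) else NULL))
    em <- prepare_events(sim$em, sim$spill)
    db <- if (is.null(db)) init_database(em, sim$truth, tax, paste0("f", i),
                                         thin = 2000)
    else classify_and_merge(db, em, sim$truth, paste0("f", i), thin = 2000)
  }
  rep <- consistency_check(db)
  mbc <- rep[grepl("^MBC .*CD27\\+", rep$population) & rep$skipped == FALSE, ]
  shifted <- mbc[mbc$file_id == "f4", ]
  expect_gt(mean(shifted$flagged, na.rm = TRUE), 0.5)
})

test_that("databases survive a save/load round trip", {
  tax <- fx_tax()
  f <- make_labelled(1e4, 601)
  db <- init_database(f$em, f$labels, tax, "a", thin = 500)
  dir <- withr::local_tempdir()
  save_database(db, dir)
  back <- load_database(dir, tax)
  expect_setequal(names(back$templates), names(db$templates))
  for (p in names(db$templates)) {
    expect_equal(back$templates[[p]]$location, db$templates[[p]]$location)
    expect_equal(back$templates[[p]]$n, db$templates[[p]]$n)
    expect_equal(back$templates[[p]]$cov, db$templates[[p]]$cov,
                 tolerance = 1e-8)
  }
})
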