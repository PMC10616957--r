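test_that("FCS round trip preserves values at float32 precision and metadata", {
  sim <- fx_sample(n = 1000, seed = 3)
  em <- sim$em
  path <- withr::local_tempfile(fileext = ".fcs")
  write_events(em, path)
  back <- read_events(path)
  expect_equal(back$stage, "raw")
  expect_identical(colnames(back$values), colnames(em$values))
  expect_equal(back$values, em$values, tolerance = 1e-6)
  ## float32: representable values identical
  expect_lt(max(abs(back$values - em$values) /
                  pmax(abs(em$values), 1)), 1e-6)
  expect_equal(back$sample_id, em$sample_id)
})

test_that("labelled export stores an integer label channel with dictionary", {
  sim <- fx_sample(n = 1000, seed = 3)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_events(sim$em, path, labels = sim$truth)
  back <- read_events(path)
  expect_identical(attr(back, "labels"), sim$truth)
  ## CSV dialect carries the same labels
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_events(sim$em, pcsv, labels = sim$truth)
  bcsv <- read_events(pcsv)
  expect_identical(attr(bcsv, "labels"), sim$truth)
})

test_that("CSV twin of an FCS file yields the identical matrix", {
  sim <- fx_sample(n = 500, seed = 11)
  pf <- withr::local_tempfile(fileext = ".fcs")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_events(sim$em, pf)
  write_events(sim$em, pc)
  ef <- read_events(pf)
  ec <- read_events(pc)
  ## CSV stores full doubles, FCS float32; compare at float32 precision
  expect_equal(ef$values, ec$values, tolerance = 1e-6)
  expect_identical(colnames(ef$values), colnames(ec$values))
})

test_that("empty event matrices survive a round trip", {
  em <- event_matrix(matrix(numeric(0), 0, 4,
                            dimnames = list(NULL, c("FSC-A", "FSC-H",
                                                    "SSC-A", "CD19"))),
                     stage = "raw")
  for (ext in c(".fcs", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_events(em, path)
    back <- read_events(path)
    expect_equal(nrow(back$values), 0L)
    expect_identical(colnames(back$values), colnames(em$values))
  }
})

test_that("unresolvable channels raise a panel-mismatch error naming them", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CD99,CD19", "1,2"), path)
  expect_error(read_events(path), "CD99",
               class = "agiflow_panel_mismatch")
  expect_error(event_matrix(matrix(1, 1, 1,
                                   dimnames = list(NULL, "CD99"))),
               class = "agiflow_panel_mismatch")
})

test_that("truncated FCS files raise a parse error", {
  sim <- fx_sample(n = 200, seed = 5)
  path <- withr::local_tempfile(fileext = ".fcs")
  write_events(sim$em, path)
  full <- readBin(path, "raw", file.size(path))
  trunc <- withr::local_tempfile(fileext = ".fcs")
  writeBin(full[seq_len(length(full) - 2000)], trunc)
  expect_error(read_events(trunc), class = "agiflow_parse_error")
})

test_that("compensation solves the spillover system and round-trips", {
  ## 2-channel hand oracle: spill [[1, .1], [0, 1]] on event (100, 10)
  vals <- matrix(c(100, 10), 1, dimnames = list(NULL, c("CD19", "CD45")))
  em <- event_matrix(vals, stage = "raw")
  spill <- matrix(c(1, 0, 0.1, 1), 2,
                  dimnames = list(c("CD19", "CD45"), c("CD19", "CD45")))
  comp <- compensate(em, spill)
  expect_equal(unname(comp$values[1, ]), c(100, 0))
  expect_equal(comp$stage, "compensated")

  ## identity spillover leaves values unchanged
  id <- diag(2); dimnames(id) <- dimnames(spill)
  expect_equal(compensate(em, id)$values, em$values)

  ## full-panel inverse round trip within 1e-6 relative
  sim <- fx_sample(n = 2000, seed = 13)
  spill18 <- default_spillover()
  comp18 <- compensate(sim$em, spill18)
  fl <- agi_markers()
  re <- comp18$values[, fl] %*% spill18
  expect_lt(max(abs(re - sim$em$values[, fl]) /
                  pmax(abs(sim$em$values[, fl]), 1)), 1e-6)

  ## singular spillover is rejected
  bad <- matrix(c(1, 1, 1, 1), 2, dimnames = dimnames(spill))
  diag(bad) <- 1
  expect_error(compensate(em, bad), class = "agiflow_singular_spill")
})

test_that("display transform is exact and rank-preserving", {
  expect_equal(asinh(0), 0)
  vals <- matrix(c(0, 150, 300), 3, 1, dimnames = list(NULL, "CD19"))
  em <- event_matrix(vals, stage = "raw")
  em$stage <- "compensated"
  tr <- apply_transform(em, transform_spec(cofactor = 150))
  expect_equal(unname(tr$values[2, 1]), asinh(1))
  expect_equal(unname(tr$values[1, 1]), 0)
  expect_equal(tr$stage, "transformed")

  ## identity spec leaves values unchanged
  id <- apply_transform(em, identity_transform_spec())
  expect_equal(id$values, em$values)

  ## monotonicity: rank order preserved on every fluorescence channel
  sim <- fx_sample(n = 3000, seed = 17)
  emc <- sim$em; emc$stage <- "compensated"
  tr2 <- apply_transform(emc)
  for (m in agi_markers())
    expect_identical(order(tr2$values[, m]), order(emc$values[, m]))

  expect_error(transform_spec(cofactor = -1), class = "agiflow_config_error")
})
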