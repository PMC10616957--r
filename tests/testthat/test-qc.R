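## The fixture files here use a cell-count threshold rescaled to the file
## size (2000 B singlets per 1e5 events mirrors the 1e5-per-~6e6 rule).
fixture_criteria <- function(...) qc_criteria(min_b_singlets = 2000, ...)

test_that("criterion i counts B-gate singlets and applies >= threshold", {
  tax <- fx_tax()
  ## planted: events exactly at B-leaf template locations, no noise
  tpl <- fx_model()$templates[["Naive CD5- CD21+ CD62L+ B-cells"]]
  loc <- tpl$loc
  m <- matrix(rep(loc, each = 300), 300, dimnames = list(NULL, names(loc)))
  em <- event_matrix(m, stage = "raw"); em$stage <- "transformed"
  expect_identical(count_b_gate_singlets(em, tax), 300L)

  ## neutrophil-only sample contains no B-gate events
  tpln <- fx_model()$templates[["Neutrophils"]]
  mn <- matrix(rep(tpln$loc, each = 100), 100,
               dimnames = list(NULL, names(tpln$loc)))
  emn <- event_matrix(mn, stage = "raw"); emn$stage <- "transformed"
  expect_identical(count_b_gate_singlets(emn, tax), 0L)

  ## pass/fail exactly at the threshold
  crit <- fixture_criteria()
  expect_false(1999 >= crit$min_b_singlets)
  expect_true(2000 >= crit$min_b_singlets)

  ## appending B singlets can never flip criterion i pass -> fail
  m2 <- rbind(m, m)
  em2 <- event_matrix(m2, stage = "raw"); em2$stage <- "transformed"
  expect_gte(count_b_gate_singlets(em2, tax),
             count_b_gate_singlets(em, tax))
})

test_that("flow stability follows the Poisson binning oracle", {
  sim <- fx_sample(n = 5e4, seed = 21)
  st <- assess_flow_stability(sim$em_t)
  ## uniform times, 100 bins: CV ~ sqrt(bins / n)
  expect_lt(abs(st$cv - sqrt(100 / 5e4)), 0.02)
  expect_true(st$pass)

  ## a planted 30 s gap fails
  gap <- simulate_sample(fx_model(),
                         sample_spec(n_events = 2e4, seed = 22,
                                     flow_gap = c(100, 30)))
  emg <- prepare_events(gap$em, gap$spill)
  stg <- assess_flow_stability(emg)
  expect_gt(stg$max_gap, 25)
  expect_false(stg$pass)

  ## degenerate input
  tiny <- fx_sample(n = 2000, seed = 23)
  shrunk <- tiny$em_t
  shrunk$values <- shrunk$values[1:10, , drop = FALSE]
  expect_error(assess_flow_stability(shrunk),
               class = "agiflow_not_assessable")
  no_time <- tiny$em_t
  no_time$values <- no_time$values[, colnames(no_time$values) != "Time"]
  expect_error(assess_flow_stability(no_time),
               class = "agiflow_not_assessable")
})

test_that("compensation check flags a planted residual and only that pair", {
  tax <- fx_tax()
  clean <- fx_sample(n = 5e4, seed = 7)
  ok <- assess_compensation(clean$em_t, tax)
  expect_true(ok$pass)
  checkable <- ok$pairs[ok$pairs$checkable == TRUE, ]
  expect_gt(nrow(checkable), 50)
  expect_lt(max(checkable$metric), 0.15)

  ## 15% residual CD19 -> CD5 exceeds the tolerance for that pair
  dirty <- simulate_sample(fx_model(),
    sample_spec(n_events = 5e4, seed = 29,
                residual_spill = list(from = "CD19", to = "CD5",
                                      value = 0.15)))
  emd <- prepare_events(dirty$em, dirty$spill)
  bad <- assess_compensation(emd, tax)
  expect_false(bad$pass)
  hot <- bad$pairs[bad$pairs$checkable & bad$pairs$metric > 0.5, ]
  ## every clearly elevated pair points at the contaminated CD5 channel,
  ## and the CD19-positive control is among the flagged primaries
  expect_true(all(hot$spill == "CD5"))
  expect_true("CD19" %in% hot$primary)

  ## phenotypically positive / absent control pairs are uncheckable, not
  ## failed
  expect_true(any(!ok$pairs$checkable))
})

test_that("staining-range check localises an injected marker shift", {
  tax <- fx_tax()
  clean <- fx_sample(n = 5e4, seed = 7)
  ok <- assess_mfi_ranges(clean$em_t, tax)
  expect_true(ok$pass)

  shifted <- simulate_sample(fx_model(),
    sample_spec(n_events = 5e4, seed = 31, mfi_shift = c(CD20 = 3)))
  ems <- prepare_events(shifted$em, shifted$spill)
  bad <- assess_mfi_ranges(ems, tax)
  expect_false(bad$pass)
  failed <- bad$markers[bad$markers$pass == FALSE, ]
  expect_true("CD20" %in% failed$marker)
  expect_false(any(setdiff(agi_markers(), "CD20") %in% failed$marker))

  ## inverted range in config is a config error
  rng <- default_mfi_ranges(tax)
  rng$low[1] <- rng$high[1] + 1
  expect_error(qc_criteria(mfi_ranges = rng), class = "agiflow_config_error")
})

test_that("run_qc attributes failure to the first failing criterion", {
  tax <- fx_tax()
  crit <- fixture_criteria()
  clean <- fx_sample(n = 5e4, seed = 7)
  rep_ok <- run_qc(clean$em_t, tax, crit)
  expect_true(rep_ok$overall_pass)
  expect_identical(rep_ok$failure_stage, "none")

  ## failing i and iv together attributes to cell_count, but all four
  ## metrics are still reported
  both <- simulate_sample(fx_model(),
    sample_spec(n_events = 5e4, seed = 37,
                frequencies = c(B = 0.01),
                mfi_shift = c(CD20 = 3)))
  emb <- prepare_events(both$em, both$spill)
  rep_b <- run_qc(emb, tax, crit)
  expect_false(rep_b$overall_pass)
  expect_identical(rep_b$failure_stage, "cell_count")
  expect_false(rep_b$mfi_range$pass)
  expect_true(is.finite(rep_b$flow_stability$cv))

  ## determinism
  rep_b2 <- run_qc(emb, tax, crit)
  expect_identical(rep_b$failure_stage, rep_b2$failure_stage)
  expect_identical(rep_b$cell_count$metric, rep_b2$cell_count$metric)
})
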