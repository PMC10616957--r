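## Datafile quality control: the four inclusion criteria and the sequential
## selection flowchart used to admit datafiles into the reference database.
##   i)   enough B-lymphocyte singlets in the CD19+ CD45+ FSClo/SSClo gate;
##   ii)  stable flow rate over acquisition time;
##   iii) clean compensation residuals between channel pairs;
##   iv)  control-population staining medians inside their expected ranges.

#' QC criteria
#'
#' @param min_b_singlets Minimum events in the B-lymphocyte singlet gate
#'   (default 1e5, the database inclusion rule for ~6e6-event files).
#' @param flow_cv_max Maximum CV of events per time bin (fraction).
#' @param flow_gap_max Maximum tolerated acquisition gap (seconds).
#' @param comp_tolerance Maximum compensation residual (transformed units).
#' @param mfi_ranges `data.frame(marker, pop_type, low, high)` of expected
#'   control-population median ranges; `NULL` uses [default_mfi_ranges()].
#' @param min_control_events Control populations smaller than this are
#'   reported as uncheckable rather than failed.
#' @return A `qc_criteria` list.
#' @export
qc_criteria <- function(min_b_singlets = 1e5, flow_cv_max = 0.25,
                        flow_gap_max = 2.0, comp_tolerance = 0.15,
                        mfi_ranges = NULL, min_control_events = 50L) {
  if (min_b_singlets <= 0 || flow_cv_max <= 0 || flow_gap_max <= 0 ||
      comp_tolerance <= 0)
    stop_agi("agiflow_config_error", "QC thresholds must be positive")
  if (!is.null(mfi_ranges) && any(mfi_ranges$low >= mfi_ranges$high))
    stop_agi("agiflow_config_error",
             "mfi_ranges must satisfy low < high for every marker")
  structure(list(min_b_singlets = min_b_singlets, flow_cv_max = flow_cv_max,
                 flow_gap_max = flow_gap_max, comp_tolerance = comp_tolerance,
                 mfi_ranges = mfi_ranges,
                 min_control_events = as.integer(min_control_events)),
            class = "qc_criteria")
}

#' Default expected staining ranges
#'
#' Surrogate control-population median ranges derived from the population
#' model's level grammar: expected level centre +/- 2 template SDs.  These
#' stand in for laboratory-calibrated ranges and are fully user-editable.
#'
#' @param tax Taxonomy (provides the control populations and phenotypes).
#' @param sd Template SD used for the +/- 2 SD band.
#' @return `data.frame(marker, pop_type, population, low, high)`.
#' @export
default_mfi_ranges <- function(tax = default_taxonomy(), sd = 0.35) {
  lm <- default_level_means()
  rows <- list()
  for (i in seq_len(nrow(tax$controls))) {
    m <- tax$controls$marker[i]
    for (ptype in c("pos", "neg")) {
      pop <- tax$controls[[paste0(ptype, "_pop")]][i]
      lv <- pop_phenotype_level(tax, pop, m)
      if (lv %in% c("mixed", "het")) next
      centre <- lm[lm$marker == m, lv]
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m, pop_type = ptype, population = pop,
        low = centre - 2 * sd, high = centre + 2 * sd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

b_gate_mask <- function(em, tax) {
  bp <- tax$breakpoints
  art <- flag_artifacts(em, tax)
  rule <- parse_rule("CD19:pos,hi&CD45:pos,hi&FSC-A:neg,lo&SSC-A:neg,lo")
  eval_rule(em$values, rule, bp) & !art$doublet
}

#' Count B-lymphocyte-gate singlets (QC criterion i)
#'
#' Events inside the CD19+ CD45+ FSClo / SSClo gate after doublet exclusion.
#'
#' @param em Transformed [event_matrix()].
#' @param tax Taxonomy supplying breakpoints and artifact rules.
#' @return Integer count.
#' @export
count_b_gate_singlets <- function(em, tax) {
  if (em$stage != "transformed")
    stop_agi("agiflow_stage_error", "QC expects transformed events")
  sum(b_gate_mask(em, tax))
}

#' Flow-rate stability (QC criterion ii)
#'
#' Acquisition is split into 100 equal-duration bins; the metric is the CV
#' of events per bin, and the criterion passes when that CV is below
#' `flow_cv_max` and the longest inter-event gap is below `flow_gap_max`.
#'
#' @param em Event matrix with a Time channel and at least 1000 events.
#' @param criteria [qc_criteria()].
#' @return List `(cv, max_gap, pass)`.
#' @export
assess_flow_stability <- function(em, criteria = qc_criteria()) {
  if (!"Time" %in% colnames(em$values))
    stop_agi("agiflow_not_assessable", "no time channel present")
  times <- em$values[, "Time"]
  if (length(times) < 1000L)
    stop_agi("agiflow_not_assessable",
             "flow stability needs >= 1000 events, got %d", length(times))
  rng <- range(times)
  counts <- tabulate(
    findInterval(times, seq(rng[1], rng[2], length.out = 101L),
                 rightmost.closed = TRUE), nbins = 100L)
  cv <- sd(counts) / mean(counts)
  max_gap <- max(diff(sort(times)))
  list(cv = cv, max_gap = max_gap,
       pass = cv <= criteria$flow_cv_max & max_gap <= criteria$flow_gap_max)
}

## gated per-population medians (and SDs) in every channel, for control
## lookups
control_medians <- function(em, tax, labels = NULL) {
  if (is.null(labels)) labels <- boolean_gate(em, tax)$labels
  pops <- unique(c(tax$controls$pos_pop, tax$controls$neg_pop))
  out <- list()
  for (p in pops) {
    idx <- labels %in% node_label_set_safe(tax, p)
    out[[p]] <- list(n = sum(idx),
                     med = if (any(idx))
                       apply(em$values[idx, , drop = FALSE], 2, median)
                     else NULL,
                     sd = if (sum(idx) > 1)
                       apply(em$values[idx, , drop = FALSE], 2, sd)
                     else NULL)
  }
  out
}

## standard error of a median difference between two control populations
median_diff_se <- function(ma, mb, channel) {
  1.2533 * sqrt(ma$sd[channel]^2 / ma$n + mb$sd[channel]^2 / mb$n)
}

node_label_set_safe <- function(tax, p) {
  if (p %in% tax$nodes$name[tax$nodes$compartment == "artifact"]) p
  else node_label_set(tax, p)
}

#' Compensation residuals (QC criterion iii)
#'
#' For every ordered (primary, spill) fluorescence channel pair whose
#' primary-positive control population is phenotypically negative for the
#' spill channel, the metric is the absolute difference between that
#' population's spill-channel median and the spill channel's negative
#' control median.  The pass threshold for each pair is `comp_tolerance`
#' plus twice the standard error of the median difference, so that small
#' control populations do not trigger false alarms through sampling noise.
#' Pairs whose control populations are too small or phenotypically
#' positive are reported as uncheckable.
#'
#' @param em Transformed [event_matrix()].
#' @param tax Taxonomy.
#' @param criteria [qc_criteria()].
#' @param labels Optional precomputed gate labels (saves re-gating).
#' @return List `(pairs, pass)`; `pairs` is a `data.table` with columns
#'   `primary`, `spill`, `metric`, `checkable`.
#' @export
assess_compensation <- function(em, tax, criteria = qc_criteria(),
                                labels = NULL) {
  med <- control_medians(em, tax, labels)
  ctl <- tax$controls
  mk <- ctl$marker
  rows <- list()
  for (i in seq_along(mk)) {
    prim <- mk[i]; pop <- ctl$pos_pop[i]
    for (j in seq_along(mk)) {
      if (i == j) next
      sp <- mk[j]
      neg <- ctl$neg_pop[j]
      checkable <- pop_phenotype_level(tax, pop, sp) == "neg" &&
        pop_phenotype_level(tax, neg, sp) == "neg" &&
        med[[pop]]$n >= criteria$min_control_events &&
        med[[neg]]$n >= criteria$min_control_events
      metric <- thr <- NA_real_
      if (checkable) {
        metric <- abs(med[[pop]]$med[sp] - med[[neg]]$med[sp])
        thr <- criteria$comp_tolerance +
          2 * median_diff_se(med[[pop]], med[[neg]], sp)
      }
      rows[[length(rows) + 1L]] <- data.table::data.table(
        primary = prim, spill = sp, metric = as.numeric(metric),
        threshold = as.numeric(thr), checkable = checkable)
    }
  }
  pairs <- data.table::rbindlist(rows)
  ok <- pairs$checkable
  list(pairs = pairs,
       pass = !any(pairs$metric[ok] > pairs$threshold[ok], na.rm = TRUE))
}

#' Staining-range check (QC criterion iv)
#'
#' Each marker's positive and negative control-population median must lie
#' inside its configured expected range.
#'
#' @inheritParams assess_compensation
#' @return List `(markers, pass)`; `markers` is a `data.table` with
#'   `marker`, `pop_type`, `metric`, `low`, `high`, `pass`, `checkable`.
#' @export
assess_mfi_ranges <- function(em, tax, criteria = qc_criteria(),
                              labels = NULL) {
  rng <- criteria$mfi_ranges
  if (is.null(rng)) rng <- default_mfi_ranges(tax)
  if (any(rng$low >= rng$high))
    stop_agi("agiflow_config_error", "mfi range with low >= high")
  miss <- setdiff(agi_markers(), rng$marker)
  if (length(miss))
    stop_agi("agiflow_config_error", "no mfi range configured for: %s",
             paste(miss, collapse = ", "))
  med <- control_medians(em, tax, labels)
  rows <- lapply(seq_len(nrow(rng)), function(i) {
    pop <- rng$population[i]
    checkable <- med[[pop]]$n >= criteria$min_control_events
    metric <- if (checkable) med[[pop]]$med[rng$marker[i]] else NA_real_
    data.table::data.table(
      marker = rng$marker[i], pop_type = rng$pop_type[i],
      metric = as.numeric(metric), low = rng$low[i], high = rng$high[i],
      pass = !checkable | (metric >= rng$low[i] & metric <= rng$high[i]),
      checkable = checkable)
  })
  markers <- data.table::rbindlist(rows)
  list(markers = markers, pass = all(markers$pass))
}

#' Run the full sequential QC flowchart
#'
#' Evaluates criteria i-iv in order; all four metrics are reported and the
#' failure stage is the first criterion that fails.
#'
#' @param em Transformed [event_matrix()].
#' @param tax Taxonomy.
#' @param criteria [qc_criteria()].
#' @return A `qc_report`: per-criterion results, `overall_pass`, and
#'   `failure_stage` in `none`, `cell_count`, `flow_stability`,
#'   `compensation`, `mfi_range`.
#' @export
run_qc <- function(em, tax, criteria = qc_criteria()) {
  labels <- boolean_gate(em, tax)$labels
  bcount <- count_b_gate_singlets(em, tax)
  c1 <- list(metric = bcount, threshold = criteria$min_b_singlets,
             pass = bcount >= criteria$min_b_singlets)
  c2 <- tryCatch(assess_flow_stability(em, criteria),
                 agiflow_not_assessable = function(e)
                   list(cv = NA_real_, max_gap = NA_real_, pass = FALSE,
                        reason = conditionMessage(e)))
  c3 <- assess_compensation(em, tax, criteria, labels)
  c4 <- assess_mfi_ranges(em, tax, criteria, labels)
  passes <- c(cell_count = c1$pass, flow_stability = isTRUE(c2$pass),
              compensation = c3$pass, mfi_range = c4$pass)
  failure_stage <- if (all(passes)) "none" else names(passes)[!passes][1]
  structure(list(cell_count = c1, flow_stability = c2, compensation = c3,
                 mfi_range = c4, overall_pass = all(passes),
                 failure_stage = failure_stage),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> overall: %s (failure stage: %s)\n",
              if (x$overall_pass) "PASS" else "FAIL", x$failure_stage))
  cat(sprintf("  i   cell count      %d (>= %g): %s\n", x$cell_count$metric,
              x$cell_count$threshold, x$cell_count$pass))
  cat(sprintf("  ii  flow stability  cv=%.3f gap=%.2fs: %s\n",
              x$flow_stability$cv, x$flow_stability$max_gap,
              isTRUE(x$flow_stability$pass)))
  cat(sprintf("  iii compensation    max residual %.3f: %s\n",
              suppressWarnings(max(x$compensation$pairs$metric, na.rm = TRUE)),
              x$compensation$pass))
  cat(sprintf("  iv  staining ranges %d/%d in range: %s\n",
              sum(x$mfi_range$markers$pass), nrow(x$mfi_range$markers),
              x$mfi_range$pass))
  invisible(x)
}
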