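## Synthetic whole-blood sample generator.  Events are drawn per population
## template in the transformed analysis space (multivariate normal with
## independent channels; "het" markers uniform across the lo-pos span), then
## mapped back to raw instrument units, spilled with the nominal spillover
## matrix, and given acquisition times -- so the full compensate / transform
## / gate pipeline is exercised end to end with known ground truth.

#' Default population model for the simulator
#'
#' One template per gating leaf of the taxonomy (plus a debris template),
#' realising each subset's symbolic phenotype on the numeric level scale.
#' Compartment frequencies default to the study's blood medians: total
#' B-lymphocytes 4.9% and plasma cells 0.06% of nucleated cells; subset
#' frequencies within a compartment are uniform.
#'
#' @param tax An `agiflow_taxonomy`.
#' @param seed Optional seed; only consumed when `location_jitter > 0`
#'   (template locations themselves are deterministic from the phenotype
#'   grammar).
#' @param fluor_sd,scatter_sd Per-channel template standard deviations
#'   (transformed units).
#' @param location_jitter SD of optional random template-location jitter.
#' @return An object of class `agiflow_model`.
#' @export
default_panel_model <- function(tax = default_taxonomy(), seed = NULL,
                                fluor_sd = 0.35, scatter_sd = 0.2,
                                location_jitter = 0) {
  lm <- default_level_means()
  chans <- c("FSC-A", "FSC-H", "SSC-A", agi_markers())
  leaves <- tax_leaves(tax)
  jit <- if (location_jitter > 0)
    with_seed(seed, matrix(rnorm(length(leaves) * length(chans),
                                 sd = location_jitter),
                           length(leaves), length(chans)))
  else matrix(0, length(leaves), length(chans))
  tmpl <- vector("list", length(leaves))
  names(tmpl) <- leaves
  for (i in seq_along(leaves)) {
    ph <- tax$nodes$phenotype_parsed[[match(leaves[i], tax$nodes$name)]]
    loc <- numeric(length(chans)); names(loc) <- chans
    het <- character(0)
    for (j in seq_along(chans)) {
      m <- chans[j]
      lv <- if (m %in% names(ph)) ph[[m]] else "neg"
      if (lv == "het") het <- c(het, m)
      loc[j] <- lm[lm$marker == if (m == "FSC-H") "FSC-A" else m, lv]
    }
    loc["FSC-H"] <- loc["FSC-A"]
    sds <- ifelse(chans %in% c("FSC-A", "FSC-H", "SSC-A"),
                  scatter_sd, fluor_sd)
    names(sds) <- chans
    tmpl[[i]] <- list(name = leaves[i], loc = loc + jit[i, ], sd = sds,
                      het = het)
  }
  debris_loc <- stats::setNames(rep(0.3, length(chans)), chans)
  debris_loc[c("FSC-A", "FSC-H", "SSC-A")] <- 0.2
  tmpl[["Debris"]] <- list(name = "Debris", loc = debris_loc,
                           sd = stats::setNames(rep(0.15, length(chans)),
                                                chans),
                           het = character(0))

  comp_freq <- c(Neutrophils = 0.55, Monocytes = 0.08, Eosinophils = 0.03,
                 `CD5+ T-cells` = 0.22, `CD5- NK-cells` = 0.05,
                 B = 0.049, PC = 0.0006)
  comp_freq["Other nucleated cells"] <- 1 - sum(comp_freq)

  b_leaves <- setdiff(tax_leaves(tax, "B-lymphocytes"), character(0))
  b_leaves <- b_leaves[b_leaves %in% leaves]
  pc_leaves <- tax_leaves(tax, "Plasma cells")
  pc_leaves <- pc_leaves[pc_leaves %in% leaves]
  leaf_comp <- stats::setNames(rep(NA_character_, length(leaves)), leaves)
  leaf_comp[b_leaves] <- "B"
  leaf_comp[pc_leaves] <- "PC"
  for (nm in names(comp_freq)) if (nm %in% leaves) leaf_comp[nm] <- nm

  structure(list(
    templates = tmpl, channels = chans,
    compartment_freq = comp_freq, leaf_compartment = leaf_comp,
    trajectories = list(
      preGC = list(stages = c("Immature B-cells", "Naive CD5+ B-cells",
                              "Naive CD5- B-cells"),
                   markers = c("CD38", "CD5")),
      PC = list(stages = c("CD20+CD138- PC", "CD20-CD138- PC",
                           "CD20-CD138+ PC"),
                markers = c("CD20", "CD138"))),
    taxonomy = tax
  ), class = "agiflow_model")
}

#' @export
print.agiflow_model <- function(x, ...) {
  cat(sprintf("<agiflow_model> %d templates over %d channels\n",
              length(x$templates), length(x$channels)))
  invisible(x)
}

## expected leaf frequencies (fractions of all nucleated events)
model_leaf_freqs <- function(model, frequencies = NULL,
                             leaf_weights = NULL) {
  cf <- model$compartment_freq
  if (!is.null(frequencies)) {
    bad <- setdiff(names(frequencies), names(cf))
    if (length(bad))
      stop_agi("agiflow_config_error", "unknown compartment '%s'", bad[1])
    cf[names(frequencies)] <- frequencies
  }
  lc <- model$leaf_compartment
  f <- stats::setNames(numeric(length(lc)), names(lc))
  for (comp in unique(lc)) {
    idx <- names(lc)[lc == comp]
    w <- rep(1, length(idx))
    if (!is.null(leaf_weights)) {
      ov <- leaf_weights[idx]
      w <- ifelse(is.na(ov), 1, ov)
    }
    f[idx] <- cf[comp] * w / sum(w)
  }
  f / sum(f) * sum(cf)  # keep compartment totals exact
}

#' Specification of one synthetic sample
#'
#' @param n_events Total events to generate (default one million, the desk
#'   scale of a lysed-whole-blood acquisition).
#' @param seed Seed controlling every random draw in the sample.
#' @param frequencies Named overrides of compartment frequencies
#'   (`B`, `PC`, `Neutrophils`, ...), fractions of nucleated cells.
#' @param leaf_weights Named relative weights of individual leaf subsets
#'   within their compartment.
#' @param doublet_rate,debris_rate Fractions of events synthesised as cell
#'   doublets / debris.
#' @param duration Acquisition duration in seconds.
#' @param flow_gap Optional `c(start, length)` seconds: a planted
#'   acquisition gap.
#' @param residual_spill Optional list `(from=, to=, value=)`: residual
#'   spillover left uncorrected by the nominal matrix.
#' @param mfi_shift Optional named numeric: per-marker shift in transformed
#'   units applied to all events.
#' @param continuum Draw the maturation compartments as a continuum along
#'   their stage trajectory (with planted change-points) instead of
#'   quasi-discrete stage clumps.
#' @return A `sample_spec` list.
#' @export
sample_spec <- function(n_events = 1e6, seed = 1L, frequencies = NULL,
                        leaf_weights = NULL, doublet_rate = 0.02,
                        debris_rate = 0.03, duration = 300,
                        flow_gap = NULL, residual_spill = NULL,
                        mfi_shift = NULL, continuum = FALSE) {
  if (n_events <= 0)
    stop_agi("agiflow_value_error", "n_events must be positive")
  if (doublet_rate < 0 || debris_rate < 0 ||
      doublet_rate + debris_rate > 1)
    stop_agi("agiflow_value_error",
             "artifact rates must be nonnegative and sum to at most 1")
  structure(list(n_events = as.integer(n_events), seed = as.integer(seed),
                 frequencies = frequencies, leaf_weights = leaf_weights,
                 doublet_rate = doublet_rate, debris_rate = debris_rate,
                 duration = duration, flow_gap = flow_gap,
                 residual_spill = residual_spill, mfi_shift = mfi_shift,
                 continuum = continuum),
            class = "sample_spec")
}

#' Default nominal spillover matrix
#'
#' Unit diagonal with 2% spill from each fluorescence detector into its
#' right neighbour, over the 18 panel detectors.
#' @param panel Panel data frame.
#' @return Square matrix with detector dimnames.
#' @export
default_spillover <- function(panel = default_panel()) {
  det <- panel$detector[panel$kind == "fluorescence"]
  s <- diag(length(det))
  for (i in seq_len(length(det) - 1)) s[i, i + 1] <- 0.02
  dimnames(s) <- list(det, det)
  s
}

## piecewise-linear trajectory through stage anchor locations
traj_interp <- function(anchors, t) {
  S <- nrow(anchors)
  u <- t * (S - 1)
  k <- pmin(floor(u), S - 2)
  w <- u - k
  anchors[k + 1, , drop = FALSE] * (1 - w) + anchors[k + 2, , drop = FALSE] * w
}

#' Simulate one whole-blood sample
#'
#' @param model An `agiflow_model`.
#' @param spec A [sample_spec()].
#' @param spill Nominal spillover applied to the generated raw fluorescence
#'   (the matrix a user would compensate with).
#' @param tspec Transform used to map templates to raw units.
#' @return List with `em` (raw [event_matrix()] including a Time channel),
#'   `truth` (per-event planted labels), `spec` and `spill`.
#' @export
simulate_sample <- function(model, spec = sample_spec(),
                            spill = default_spillover(),
                            tspec = transform_spec()) {
  stopifnot(inherits(model, "agiflow_model"), inherits(spec, "sample_spec"))
  with_seed(spec$seed, {
    n <- spec$n_events
    chans <- model$channels
    leaf_f <- model_leaf_freqs(model, spec$frequencies, spec$leaf_weights)
    cats <- c(names(leaf_f), "Debris", "Doublets")
    p <- c(leaf_f * (1 - spec$doublet_rate - spec$debris_rate),
           spec$debris_rate, spec$doublet_rate)
    truth <- sample(cats, n, replace = TRUE, prob = p)
    vals <- matrix(0, n, length(chans), dimnames = list(NULL, chans))

    singlet <- truth != "Doublets"
    for (nm in unique(truth[singlet])) {
      idx <- which(truth == nm)
      tpl <- model$templates[[nm]]
      m <- length(idx)
      draw <- matrix(rnorm(m * length(chans), mean = rep(tpl$loc, each = m),
                           sd = rep(tpl$sd, each = m)), m, length(chans))
      colnames(draw) <- chans
      for (h in tpl$het) draw[, h] <- runif(m, 1, 3.5)
      draw[, "FSC-H"] <- draw[, "FSC-A"]
      vals[idx, ] <- draw
    }

    ## maturation continua: overwrite trajectory markers by position along
    ## the piecewise-linear stage path, with planted change-points
    if (isTRUE(spec$continuum)) {
      for (tr in model$trajectories) {
        anchors <- t(vapply(tr$stages, function(s) {
          leaves <- intersect(node_label_set(model$taxonomy, s),
                              names(model$templates))
          colMeans(do.call(rbind, lapply(model$templates[leaves],
                                         function(x) x$loc[tr$markers])))
        }, numeric(length(tr$markers))))
        S <- length(tr$stages)
        cuts <- c(0, (seq_len(S - 1) - 0.5) / (S - 1), 1)
        for (k in seq_len(S)) {
          leaves <- intersect(node_label_set(model$taxonomy, tr$stages[k]),
                              names(model$templates))
          idx <- which(truth %in% leaves)
          if (!length(idx)) next
          tt <- runif(length(idx), cuts[k], cuts[k + 1])
          vals[idx, tr$markers] <- traj_interp(anchors, tt) +
            matrix(rnorm(length(idx) * length(tr$markers), sd = 0.2),
                   length(idx))
        }
      }
    }

    if (!is.null(spec$mfi_shift)) {
      for (m in names(spec$mfi_shift))
        vals[, m] <- vals[, m] + spec$mfi_shift[[m]]
    }

    ## to raw instrument units
    fl <- agi_markers()
    co <- tspec$cofactor[match(fl[1], tspec$marker)]
    sdiv <- tspec$cofactor[match("FSC-A", tspec$marker)]
    raw <- vals
    raw[, fl] <- sinh(vals[, fl]) * co
    sc <- c("FSC-A", "FSC-H", "SSC-A")
    raw[, sc] <- vals[, sc] * sdiv
    raw[, "FSC-H"] <- raw[, "FSC-A"] / pmax(rnorm(n, 1, 0.05), 0.6)

    ## doublets: raw signal sums of two random singlets; pulse height stays
    ## at the larger single-cell height so the area/height ratio doubles
    dbl <- which(truth == "Doublets")
    if (length(dbl)) {
      pool <- which(singlet)
      a <- sample(pool, length(dbl), replace = TRUE)
      b <- sample(pool, length(dbl), replace = TRUE)
      raw[dbl, ] <- raw[a, , drop = FALSE] + raw[b, , drop = FALSE]
      raw[dbl, "FSC-H"] <- pmax(raw[a, "FSC-H"], raw[b, "FSC-H"])
    }

    ## nominal (plus any residual) spillover in raw space
    s_tot <- spill
    if (!is.null(spec$residual_spill)) {
      rs <- spec$residual_spill
      det <- default_panel()
      di <- det$detector[match(c(rs$from, rs$to), det$marker)]
      s_tot[di[1], di[2]] <- s_tot[di[1], di[2]] + rs$value
    }
    det_fl <- default_panel()
    fl_det <- det_fl$detector[det_fl$kind == "fluorescence"]
    raw[, fl] <- raw[, fl, drop = FALSE] %*%
      s_tot[fl_det, fl_det, drop = FALSE]

    times <- sort(runif(n, 0, spec$duration))
    if (!is.null(spec$flow_gap))
      times[times > spec$flow_gap[1]] <-
        times[times > spec$flow_gap[1]] + spec$flow_gap[2]
    out <- cbind(raw, Time = times)

    em <- event_matrix(out, stage = "raw",
                       sample_id = sprintf("sim-%d", spec$seed))
    list(em = em, truth = truth, spec = spec, spill = spill)
  })
}

#' Simulate a cohort of samples with between-sample frequency jitter
#'
#' Per-sample compartment frequencies are drawn log-normally around the
#' model medians and clamped to the population reference ranges
#' (B-lymphocytes 0.5--13%, plasma cells <0.001--0.8% of nucleated cells);
#' leaf weights get milder multiplicative jitter.
#'
#' @param model An `agiflow_model`.
#' @param n_samples Number of samples.
#' @param n_events Events per sample.
#' @param seed Master seed; per-sample seeds are derived deterministically.
#' @param jitter Named list of log-normal SDs: `b`, `pc`, `nonb`, `leaf`.
#'   Zero everywhere gives identical frequencies across samples.
#' @param ... Further arguments passed to [sample_spec()].
#' @return List of [simulate_sample()] results.
#' @export
simulate_cohort <- function(model, n_samples, n_events = 1e5, seed = 1L,
                            jitter = list(b = 0.4, pc = 1.0, nonb = 0.15,
                                          leaf = 0.3),
                            ...) {
  stopifnot(n_samples >= 1)
  seeds <- derive_seeds(seed, 3L * n_samples)
  sim_seeds <- seeds[seq_len(n_samples)]
  jit_seeds <- seeds[n_samples + seq_len(n_samples)]
  lapply(seq_len(n_samples), function(i) {
    par <- with_seed(jit_seeds[i], {
      cf <- model$compartment_freq
      f <- c(
        B = min(max(cf[["B"]] * rlnorm(1, 0, jitter$b), 0.005), 0.13),
        PC = min(max(cf[["PC"]] * rlnorm(1, 0, jitter$pc), 1e-5), 0.008)
      )
      nb <- setdiff(names(cf), c("B", "PC"))
      w <- cf[nb] * rlnorm(length(nb), 0, jitter$nonb)
      f2 <- w / sum(w) * (1 - sum(f))
      lw <- rlnorm(length(model$leaf_compartment), 0, jitter$leaf)
      names(lw) <- names(model$leaf_compartment)
      list(frequencies = c(f, f2), leaf_weights = lw)
    })
    simulate_sample(model,
                    sample_spec(n_events = n_events, seed = sim_seeds[i],
                                frequencies = par$frequencies,
                                leaf_weights = par$leaf_weights, ...))
  })
}
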