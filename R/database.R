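## Reference database: per-population statistical templates (count, location,
## shrinkage covariance) plus a thinned store of labelled events with
## per-file provenance, built by iterative classify-and-merge.

db_markers <- function() c("FSC-A", "SSC-A", agi_markers())

## Covariance with diagonal-target shrinkage (closed-form intensity).
## The intensity is estimated on at most `cap` rows; the covariance itself
## uses everything supplied.
shrink_intensity <- function(X, S, cap = 5000L) {
  n <- nrow(X)
  if (n < 4) return(1)
  if (n > cap) {
    X <- X[seq(1, n, length.out = cap), , drop = FALSE]
    n <- nrow(X)
  }
  Xc <- sweep(X, 2, colMeans(X))
  Ssub <- crossprod(Xc) / (n - 1)
  var_s <- n / ((n - 1)^3) * (crossprod(Xc^2) - ((n - 1) * Ssub)^2 / n)
  off <- upper.tri(S) | lower.tri(S)
  denom <- sum(Ssub[off]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(var_s[off]) / denom))
}

shrink_cov <- function(S, X_for_lambda, var_floor = 1e-4) {
  d <- ncol(S)
  lambda <- shrink_intensity(X_for_lambda, S)
  out <- lambda * diag(diag(S), d) + (1 - lambda) * S
  diag(out) <- pmax(diag(out), var_floor)
  dimnames(out) <- dimnames(S)
  out
}

cov_from_events <- function(X, var_floor = 1e-4, default_var = 0.1225) {
  d <- ncol(X)
  if (nrow(X) < 3)
    return(diag(rep(default_var, d)) |>
             `dimnames<-`(list(colnames(X), colnames(X))))
  S <- cov(X)
  shrink_cov(S, X, var_floor)
}

cov_from_moments <- function(n, sx, sxx, X_for_lambda,
                             var_floor = 1e-4, default_var = 0.1225) {
  d <- length(sx)
  if (n < 3)
    return(diag(rep(default_var, d)) |>
             `dimnames<-`(list(names(sx), names(sx))))
  S <- (sxx - outer(sx, sx) / n) / (n - 1)
  dimnames(S) <- list(names(sx), names(sx))
  shrink_cov(S, X_for_lambda, var_floor)
}

new_template <- function(name, X, file_id) {
  n <- nrow(X)
  med <- apply(X, 2, median)
  list(name = name, n = n, sx = colSums(X), sxx = crossprod(X),
       file_ns = stats::setNames(n, file_id),
       file_medians = matrix(med, 1, dimnames = list(file_id, colnames(X))),
       location = med,
       cov = cov_from_events(X))
}

template_location <- function(tpl) {
  drop(crossprod(tpl$file_medians, tpl$file_ns) / sum(tpl$file_ns))
}

thin_events <- function(X, labels, file_id, thin, seed) {
  keep <- with_seed(seed, unlist(lapply(split(seq_along(labels), labels),
    function(idx) if (length(idx) > thin) sample(idx, thin) else idx),
    use.names = FALSE))
  keep <- sort(keep)
  dt <- data.table::as.data.table(X[keep, , drop = FALSE])
  dt[, `:=`(file_id = file_id, population = labels[keep])]
  dt
}

#' Initialise a reference database from one labelled datafile
#'
#' One template per observed leaf (or artifact) population: count, median
#' location, and diagonal-shrinkage covariance in the transformed marker
#' space, with per-file provenance and a thinned labelled-event store.
#'
#' @param em Transformed [event_matrix()].
#' @param labels Per-event labels (e.g. from [boolean_gate()] or
#'   expert-confirmed AGI output).
#' @param tax Taxonomy; labels must exist in it.
#' @param file_id Provenance identifier for this datafile.
#' @param thin Maximum stored events per population per file.
#' @param seed Seed for the thinning subsample.
#' @return An object of class `agiflow_refdb`.
#' @export
init_database <- function(em, labels, tax, file_id = "file1", thin = 1e4,
                          seed = 1L) {
  stopifnot(inherits(em, "agiflow_events"))
  if (!length(labels))
    stop_agi("agiflow_value_error", "empty label vector")
  if (length(labels) != n_events(em))
    stop_agi("agiflow_value_error", "labels length != event count")
  bad <- setdiff(unique(labels), tax$nodes$name)
  if (length(bad))
    stop_agi("agiflow_value_error", "label '%s' not in taxonomy", bad[1])
  keep_lab <- c(tax_leaves(tax),
                tax$nodes$name[tax$nodes$compartment == "artifact"])
  use <- labels %in% keep_lab
  X <- em$values[use, db_markers(), drop = FALSE]
  lab <- labels[use]
  templates <- lapply(split(seq_along(lab), lab), function(idx)
    new_template(lab[idx[1]], X[idx, , drop = FALSE], file_id))
  db <- structure(list(
    templates = templates,
    events = thin_events(X, lab, file_id, thin, seed),
    markers = db_markers(), taxonomy = tax,
    log = sprintf("init: %s (%d events, %d populations)", file_id,
                  sum(use), length(templates))
  ), class = "agiflow_refdb")
  db
}

#' Classify a new datafile against the database and merge it in
#'
#' If `labels` is not supplied the file is classified headlessly with the
#' two-step AGI algorithm against the current database and the assignments
#' accepted as-is (the expert-confirmation step is modelled as the optional
#' `labels` override).  Returns a new database; the input is unchanged.
#'
#' @param db An `agiflow_refdb`.
#' @param em Transformed [event_matrix()] of the new file.
#' @param labels Optional confirmed per-event labels.
#' @param file_id Provenance identifier.
#' @inheritParams init_database
#' @return The merged `agiflow_refdb`.
#' @export
classify_and_merge <- function(db, em, labels = NULL, file_id = NULL,
                               thin = 1e4, seed = 1L) {
  stopifnot(inherits(db, "agiflow_refdb"))
  if (!identical(colnames(em$values)[colnames(em$values) %in% db$markers],
                 db$markers[db$markers %in% colnames(em$values)]) ||
      !all(db$markers %in% colnames(em$values)))
    stop_agi("agiflow_panel_mismatch", "event matrix does not cover the
             database marker space")
  if (is.null(file_id))
    file_id <- sprintf("file%d", length(unique(db$events$file_id)) + 1L)
  if (is.null(labels))
    labels <- two_step_classify(em, db)$labels
  keep_lab <- c(tax_leaves(db$taxonomy),
                db$taxonomy$nodes$name[db$taxonomy$nodes$compartment ==
                                         "artifact"])
  use <- labels %in% keep_lab
  X <- em$values[use, db$markers, drop = FALSE]
  lab <- labels[use]
  out <- db
  for (p in unique(lab)) {
    Xi <- X[lab == p, , drop = FALSE]
    if (is.null(out$templates[[p]])) {
      out$templates[[p]] <- new_template(p, Xi, file_id)
    } else {
      tpl <- out$templates[[p]]
      tpl$n <- tpl$n + nrow(Xi)
      tpl$sx <- tpl$sx + colSums(Xi)
      tpl$sxx <- tpl$sxx + crossprod(Xi)
      tpl$file_ns <- c(tpl$file_ns, stats::setNames(nrow(Xi), file_id))
      tpl$file_medians <- rbind(tpl$file_medians, apply(Xi, 2, median))
      rownames(tpl$file_medians)[nrow(tpl$file_medians)] <- file_id
      tpl$location <- template_location(tpl)
      out$templates[[p]] <- tpl
    }
  }
  new_ev <- thin_events(X, lab, file_id, thin, seed)
  out$events <- data.table::rbindlist(list(out$events, new_ev),
                                      use.names = TRUE)
  ## recompute covariances from pooled moments (shrinkage intensity from
  ## the thinned store)
  for (p in unique(lab)) {
    tpl <- out$templates[[p]]
    Xl <- as.matrix(out$events[population == p, db$markers, with = FALSE])
    tpl$cov <- cov_from_moments(tpl$n, tpl$sx, tpl$sxx, Xl)
    out$templates[[p]] <- tpl
  }
  out$log <- c(out$log, sprintf("merge: %s (%d events, %d populations)",
                                file_id, sum(use), length(unique(lab))))
  out
}

#' @export
print.agiflow_refdb <- function(x, ...) {
  cat(sprintf("<agiflow_refdb> %d templates, %d stored events, %d files\n",
              length(x$templates), nrow(x$events),
              length(unique(x$events$file_id))))
  invisible(x)
}

## resolve a (possibly internal or aggregate) population to a template by
## pooling member leaf templates
get_template <- function(db, name) {
  if (!is.null(db$templates[[name]])) return(db$templates[[name]])
  members <- intersect(node_label_set(db$taxonomy, name),
                       names(db$templates))
  if (!length(members))
    stop_agi("agiflow_value_error", "no template for population '%s'", name)
  tls <- db$templates[members]
  n <- sum(vapply(tls, `[[`, numeric(1), "n"))
  sx <- Reduce(`+`, lapply(tls, `[[`, "sx"))
  sxx <- Reduce(`+`, lapply(tls, `[[`, "sxx"))
  loc <- Reduce(`+`, lapply(tls, function(t) t$location * t$n)) / n
  Xl <- as.matrix(db$events[population %in% members, db$markers,
                            with = FALSE])
  list(name = name, n = n, sx = sx, sxx = sxx,
       location = loc, cov = cov_from_moments(n, sx, sxx, Xl))
}

#' Leave-one-file-out consistency check of the database
#'
#' For every population present in at least two source files, each file's
#' events are projected into the 2-D principal-component plane and the 2-D
#' canonical plane (population vs its nearest-neighbour population) fitted
#' on the remaining files; the file passes when its projected median lies
#' within the 2-SD ellipse and at least `frac` of its events fall within
#' 2 SD.
#'
#' @param db An `agiflow_refdb`.
#' @param frac Required within-tolerance event fraction (default 0.95).
#' @param min_events Minimum stored events a file must contribute to a
#'   population for the fraction test to be meaningful (below 1/(1-frac)
#'   a single event decides the outcome); smaller contributions are
#'   skipped.
#' @return `data.table` with one row per population x file, plus skipped
#'   populations (present in a single file, or contributing fewer than
#'   `min_events` events) flagged in column `skipped`.
#' @export
consistency_check <- function(db, frac = 0.95, min_events = 20L) {
  ev <- db$events
  mk <- db$markers
  rows <- list()
  pops <- setdiff(names(db$templates), c("Doublets", "Debris"))
  for (p in pops) {
    files <- names(db$templates[[p]]$file_ns)
    if (length(files) < 2) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        population = p, file_id = files[1], pca_median_in = NA,
        pca_frac = NA_real_, ca_median_in = NA, ca_frac = NA_real_,
        flagged = NA, skipped = TRUE)
      next
    }
    ## nearest-neighbour population by Mahalanobis between locations
    others <- setdiff(pops, p)
    dloc <- vapply(others, function(q) {
      dd <- db$templates[[p]]$location - db$templates[[q]]$location
      sqrt(drop(t(dd) %*% solve_psd(db$templates[[p]]$cov, dd)))
    }, numeric(1))
    neigh <- others[which.min(dloc)]
    Xn <- as.matrix(ev[population == neigh, mk, with = FALSE])
    for (f in files) {
      Xf <- as.matrix(ev[population == p & file_id == f, mk, with = FALSE])
      Xr <- as.matrix(ev[population == p & file_id != f, mk, with = FALSE])
      if (nrow(Xf) < min_events || nrow(Xr) < 10) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          population = p, file_id = f, pca_median_in = NA,
          pca_frac = NA_real_, ca_median_in = NA, ca_frac = NA_real_,
          flagged = NA, skipped = TRUE)
        next
      }
      ## PCA plane from the remaining files
      ctr <- colMeans(Xr)
      pr <- svd(sweep(Xr, 2, ctr), nu = 0, nv = 2)$v
      Pr <- sweep(Xr, 2, ctr) %*% pr
      Pf <- sweep(Xf, 2, ctr) %*% pr
      pca <- ellipse_membership(Pf, Pr)
      ## CA plane: population (rest) vs nearest neighbour
      tmpl_rest <- list(name = p, n = nrow(Xr),
                        location = apply(Xr, 2, median),
                        cov = cov_from_events(Xr))
      tmpl_nb <- list(name = neigh, n = nrow(Xn),
                      location = apply(Xn, 2, median),
                      cov = cov_from_events(Xn))
      ca <- tryCatch({
        pl <- fit_canonical_plane(list(tmpl_rest, tmpl_nb), mk)
        Cr <- project_plane(pl, Xr)
        Cf <- project_plane(pl, Xf)
        ellipse_membership(Cf, Cr)
      }, error = function(e) list(median_in = NA, frac = NA_real_))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        population = p, file_id = f,
        pca_median_in = pca$median_in, pca_frac = pca$frac,
        ca_median_in = ca$median_in, ca_frac = ca$frac,
        flagged = !isTRUE(pca$median_in) || !isTRUE(ca$median_in) ||
          (!is.na(pca$frac) && pca$frac < frac) ||
          (!is.na(ca$frac) && ca$frac < frac),
        skipped = FALSE)
    }
  }
  data.table::rbindlist(rows)
}

## Membership of projected points relative to a reference cloud.  The
## median is tested against the 2-SD ellipse; individual events are counted
## inside the 99% tolerance contour (a 2-D Gaussian puts only ~86% of its
## mass inside 2 SD, so a per-event 2-SD count could never reach the 0.95
## pass fraction even for a perfectly homogeneous population).
ellipse_membership <- function(P_test, P_ref) {
  mu <- colMeans(P_ref)
  S <- cov(P_ref)
  d2 <- mahalanobis_psd(P_test, mu, S)
  med <- matrix(apply(P_test, 2, median), 1)
  list(median_in = mahalanobis_psd(med, mu, S) <= 4,
       frac = mean(d2 <= stats::qchisq(0.99, 2)))
}

solve_psd <- function(S, b) {
  tryCatch(solve(S, b),
           error = function(e) solve(S + diag(1e-6, nrow(S)), b))
}

mahalanobis_psd <- function(X, mu, S) {
  X <- if (is.matrix(X)) X else matrix(X, 1)
  tryCatch(mahalanobis(X, mu, S),
           error = function(e)
             mahalanobis(X, mu, S + diag(1e-6, nrow(S))))
}

## ---- serialisation --------------------------------------------------------

#' Save / load a reference database as a directory of CSV files
#'
#' `templates.csv` (counts and locations), `moments.csv` (second-moment
#' accumulators), `file_stats.csv` (per-file provenance), `events.csv`
#' (thinned labelled events) and `log.txt`.
#'
#' @param db An `agiflow_refdb`.
#' @param path Directory to create/read.
#' @return `load_database()` returns the reconstructed `agiflow_refdb`.
#' @export
save_database <- function(db, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  mk <- db$markers
  tdt <- data.table::rbindlist(lapply(db$templates, function(t) {
    dt <- data.table::data.table(population = t$name, n = t$n)
    loc <- data.table::as.data.table(as.list(t$location))
    sx <- data.table::as.data.table(as.list(t$sx))
    data.table::setnames(loc, paste0("loc_", mk))
    data.table::setnames(sx, paste0("sx_", mk))
    cbind(dt, loc, sx)
  }))
  data.table::fwrite(tdt, file.path(path, "templates.csv"))
  mo <- data.table::rbindlist(lapply(db$templates, function(t) {
    data.table::data.table(population = t$name,
                           row = rep(mk, times = length(mk)),
                           col = rep(mk, each = length(mk)),
                           sxx = as.vector(t$sxx),
                           cov = as.vector(t$cov))
  }))
  data.table::fwrite(mo, file.path(path, "moments.csv"))
  fs <- data.table::rbindlist(lapply(db$templates, function(t) {
    dt <- data.table::data.table(population = t$name,
                                 file_id = names(t$file_ns),
                                 n = as.numeric(t$file_ns))
    md <- data.table::as.data.table(t$file_medians)
    data.table::setnames(md, paste0("med_", mk))
    cbind(dt, md)
  }))
  data.table::fwrite(fs, file.path(path, "file_stats.csv"))
  data.table::fwrite(db$events, file.path(path, "events.csv"))
  writeLines(db$log, file.path(path, "log.txt"))
  invisible(path)
}

#' @rdname save_database
#' @param tax Taxonomy to attach (defaults to the shipped default).
#' @export
load_database <- function(path, tax = default_taxonomy()) {
  mk <- db_markers()
  tdt <- data.table::fread(file.path(path, "templates.csv"))
  mo <- data.table::fread(file.path(path, "moments.csv"))
  fs <- data.table::fread(file.path(path, "file_stats.csv"))
  ev <- data.table::fread(file.path(path, "events.csv"))
  templates <- list()
  for (i in seq_len(nrow(tdt))) {
    p <- tdt$population[i]
    moi <- mo[population == p]
    sxx <- matrix(moi$sxx, length(mk), length(mk),
                  dimnames = list(mk, mk))
    fsi <- fs[population == p]
    fm <- as.matrix(fsi[, paste0("med_", mk), with = FALSE])
    dimnames(fm) <- list(fsi$file_id, mk)
    tpl <- list(name = p, n = tdt$n[i],
                sx = stats::setNames(as.numeric(tdt[i, paste0("sx_", mk),
                                                    with = FALSE]), mk),
                sxx = sxx,
                file_ns = stats::setNames(fsi$n, fsi$file_id),
                file_medians = fm,
                location = stats::setNames(
                  as.numeric(tdt[i, paste0("loc_", mk), with = FALSE]), mk))
    tpl$cov <- matrix(moi$cov, length(mk), length(mk),
                      dimnames = list(mk, mk))
    templates[[p]] <- tpl
  }
  structure(list(templates = templates, events = ev, markers = mk,
                 taxonomy = tax,
                 log = readLines(file.path(path, "log.txt"))),
            class = "agiflow_refdb")
}
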