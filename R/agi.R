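## Automated gating and identification (AGI): density-peak clustering on a
## K-nearest-neighbour graph, canonical-analysis (discriminant) cluster
## classification against the reference database, a maturation-trajectory
## classifier for continuous stages, and the two-step / hierarchical
## orchestrations.

#' K-nearest-neighbour density
#'
#' Per-event density defined as the reciprocal of the mean Euclidean
#' distance to the K nearest neighbours in the selected marker subspace.
#' Neighbours are exact (brute force); duplicated events (zero mean
#' distance) are guarded to `density_cap`.
#'
#' @param X Numeric events x markers matrix (transformed units).
#' @param K Number of neighbours (default 10).
#' @param density_cap Density assigned where the mean neighbour distance
#'   is zero.
#' @return List `(density, nn_idx, nn_dist)`; neighbour matrices are
#'   events x K.
#' @export
knn_density <- function(X, K = 10L, density_cap = 1e12) {
  X <- as.matrix(X)
  if (nrow(X) <= K)
    stop_agi("agiflow_degenerate_scope",
             "scope has %d events, needs more than K=%d", nrow(X), K)
  nn <- .knn_brute(X, as.integer(K))
  md <- rowMeans(nn$dist)
  dens <- ifelse(md > 0, 1 / md, density_cap)
  list(density = dens, nn_idx = nn$idx, nn_dist = nn$dist)
}

#' Density-peak clustering on the KNN graph
#'
#' Each event links to the highest-density event among its K neighbours
#' with density strictly above its own; link-free events are mode apices.
#' For mode pairs adjacent in the KNN graph a saddle density is computed
#' (maximum over boundary edges of the smaller endpoint density).  The
#' pair's separation on the 0-20 scale is a noise-referenced dip score:
#' the log peak-to-saddle ratio is expressed in units of the sampling
#' noise of the K-NN density estimate (`sigma = 1/sqrt(2K)`), three noise
#' SDs are forgiven, and the excess mapped as
#' `20 * (1 - exp(-(z - 3)))` (zero for dips within noise, approaching 20
#' for unambiguous valleys).  Modes are merged in increasing-separation
#' order while the separation is below `cutoff`; modes never adjacent in
#' the KNN graph cannot merge.
#'
#' Scopes larger than `max_events` (default 1e4) are clustered on a seeded uniform
#' subsample; the remaining events join the nearest cluster centroid.
#'
#' @param X Numeric events x markers matrix.
#' @param K Neighbours for the density graph.
#' @param cutoff Separation cutoff on the 0-20 scale (default 0.9).
#' @param max_events Clustering subsample cap.
#' @param seed Seed for the subsample.
#' @param density_cap See [knn_density()].
#' @return An `agiflow_clusters` list: `cluster` (per-event id), `clusters`
#'   (`data.table` of id, n, peak density), `centroids`, per-cluster `covs`,
#'   and the `merge_trace`.
#' @export
cluster_events <- function(X, K = 10L, cutoff = 0.9, max_events = 1e4,
                           seed = 1L, density_cap = 1e12) {
  X <- as.matrix(X)
  n <- nrow(X)
  sub <- seq_len(n)
  if (n > max_events)
    sub <- with_seed(seed, sort(sample.int(n, max_events)))
  Xs <- X[sub, , drop = FALSE]
  kd <- knn_density(Xs, K, density_cap)
  dens <- kd$density
  m <- nrow(Xs)

  ## link to the highest-density neighbour with strictly higher density
  nbr_dens <- matrix(dens[kd$nn_idx], m)
  best <- max.col(nbr_dens, ties.method = "first")
  bi <- cbind(seq_len(m), best)
  parent <- ifelse(nbr_dens[bi] > dens, kd$nn_idx[bi], seq_len(m))
  ## pointer jumping to the mode apex
  repeat {
    nxt <- parent[parent]
    if (identical(nxt, parent)) break
    parent <- nxt
  }
  mode_of <- parent

  ## saddle densities between adjacent modes
  ei <- rep(seq_len(m), ncol(kd$nn_idx))
  ej <- as.vector(kd$nn_idx)
  cross <- mode_of[ei] != mode_of[ej]
  sa <- pmin(mode_of[ei], mode_of[ej])[cross]
  sb <- pmax(mode_of[ei], mode_of[ej])[cross]
  w <- pmin(dens[ei], dens[ej])[cross]
  if (any(cross)) {
    key <- paste(sa, sb)
    agg <- tapply(w, key, max)
    pr <- do.call(rbind, strsplit(names(agg), " "))
    sad_a <- as.integer(pr[, 1])
    sad_b <- as.integer(pr[, 2])
    sad_s <- as.numeric(agg)
  } else {
    sad_a <- sad_b <- integer(0)
    sad_s <- numeric(0)
  }
  peak <- dens  # peak density looked up at apex index

  ## dip z-score vs the K-NN density estimation noise, mapped onto 0-20
  sigma_k <- 1 / sqrt(2 * K)
  sep_of <- function(s, pa, pb) {
    z <- log(pmin(pa, pb) / pmax(s, 1e-300)) / sigma_k
    20 * (1 - exp(-pmax(0, z - 3)))
  }
  trace <- list()
  repeat {
    if (!length(sad_s)) break
    sep <- sep_of(sad_s, peak[sad_a], peak[sad_b])
    ## ties in separation break on the numerically smallest apex pair so
    ## the merge order (and hence the partition) is reproducible
    i <- order(sep, sad_a, sad_b)[1]
    if (sep[i] >= cutoff) break
    a <- sad_a[i]; b <- sad_b[i]
    trace[[length(trace) + 1L]] <- data.table::data.table(
      into = a, from = b, separation = sep[i])
    mode_of[mode_of == b] <- a
    peak[a] <- max(peak[a], peak[b])
    sad_a[sad_a == b] <- a
    sad_b[sad_b == b] <- a
    swap <- sad_a > sad_b
    if (any(swap)) {
      tmp <- sad_a[swap]
      sad_a[swap] <- sad_b[swap]
      sad_b[swap] <- tmp
    }
    keep <- sad_a != sad_b
    sad_a <- sad_a[keep]; sad_b <- sad_b[keep]; sad_s <- sad_s[keep]
    if (length(sad_s)) {
      key <- paste(sad_a, sad_b)
      agg <- tapply(sad_s, key, max)
      pr <- do.call(rbind, strsplit(names(agg), " "))
      sad_a <- as.integer(pr[, 1])
      sad_b <- as.integer(pr[, 2])
      sad_s <- as.numeric(agg)
    }
  }

  ids <- match(mode_of, sort(unique(mode_of)))
  centroids <- do.call(rbind, lapply(sort(unique(ids)), function(k)
    colMeans(Xs[ids == k, , drop = FALSE])))
  cluster <- integer(n)
  cluster[sub] <- ids
  rest <- setdiff(seq_len(n), sub)
  if (length(rest))
    cluster[rest] <- .nn_assign(X[rest, , drop = FALSE], centroids)
  covs <- lapply(sort(unique(ids)), function(k) {
    Xi <- X[cluster == k, , drop = FALSE]
    if (nrow(Xi) >= 3) cov(Xi) else diag(1e-4, ncol(X))
  })
  apex <- sort(unique(mode_of))
  structure(list(
    cluster = cluster,
    clusters = data.table::data.table(id = sort(unique(ids)),
                                      n = tabulate(cluster, max(ids)),
                                      peak = peak[apex]),
    centroids = centroids, covs = covs,
    merge_trace = if (length(trace)) data.table::rbindlist(trace)
                  else data.table::data.table(into = integer(),
                                              from = integer(),
                                              separation = numeric())),
    class = "agiflow_clusters")
}

#' @export
print.agiflow_clusters <- function(x, ...) {
  cat(sprintf("<agiflow_clusters> %d events in %d clusters\n",
              length(x$cluster), nrow(x$clusters)))
  invisible(x)
}

## ---- canonical analysis ---------------------------------------------------

#' Fit a 2-D canonical (discriminant) plane from population templates
#'
#' Axes span the top two generalised eigenvectors of the between- vs
#' pooled-within-scatter problem.  With exactly two populations only one
#' discriminant direction exists; the second axis is then the top
#' within-scatter principal direction orthogonal to axis 1.
#'
#' @param templates List of >= 2 templates (each with `location`, `cov`,
#'   `n`).
#' @param markers Marker subset defining the space (defaults to the
#'   template's markers).
#' @return An `agiflow_caplane` with the projection `axes` (markers x 2)
#'   and per-population projected means and 2x2 covariances.
#' @export
fit_canonical_plane <- function(templates, markers = NULL) {
  if (length(templates) < 2)
    stop_agi("agiflow_value_error", "need at least two templates")
  if (is.null(markers)) markers <- names(templates[[1]]$location)
  locs <- t(vapply(templates, function(t) t$location[markers],
                   numeric(length(markers))))
  ns <- vapply(templates, function(t) as.numeric(t$n), numeric(1))
  covs <- lapply(templates, function(t) t$cov[markers, markers, drop = FALSE])
  W <- Reduce(`+`, Map(function(S, n) S * n, covs, ns)) / sum(ns)
  mbar <- drop(crossprod(locs, ns) / sum(ns))
  Bm <- Reduce(`+`, lapply(seq_along(ns), function(i) {
    d <- locs[i, ] - mbar
    ns[i] * outer(d, d)
  })) / sum(ns)
  if (sum(Bm^2) < 1e-18)
    stop_agi("agiflow_value_error",
             "zero between-population scatter (identical templates)")
  eW <- eigen(W, symmetric = TRUE)
  vals <- pmax(eW$values, max(eW$values) * 1e-10)
  Wi2 <- eW$vectors %*% diag(1 / sqrt(vals)) %*% t(eW$vectors)
  M <- Wi2 %*% Bm %*% Wi2
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_disc <- min(2L, length(templates) - 1L,
                sum(eM$values > max(eM$values) * 1e-8))
  axes <- Wi2 %*% eM$vectors[, seq_len(n_disc), drop = FALSE]
  axes <- apply(axes, 2, function(a) a / sqrt(sum(a^2)))
  if (ncol(axes) < 2) {
    a1 <- axes[, 1]
    P <- diag(length(a1)) - outer(a1, a1)
    Wp <- P %*% W %*% P
    a2 <- eigen((Wp + t(Wp)) / 2, symmetric = TRUE)$vectors[, 1]
    a2 <- a2 - a1 * sum(a2 * a1)
    axes <- cbind(axes, a2 / sqrt(sum(a2^2)))
  }
  rownames(axes) <- markers
  proj_means <- locs %*% axes
  proj_covs <- lapply(covs, function(S) t(axes) %*% S %*% axes)
  structure(list(axes = axes, markers = markers,
                 populations = vapply(templates, `[[`, "", "name"),
                 proj_means = proj_means, proj_covs = proj_covs),
            class = "agiflow_caplane")
}

#' Project events into a canonical plane
#' @param plane An `agiflow_caplane`.
#' @param X Events x markers matrix covering `plane$markers`.
#' @return Events x 2 matrix.
#' @export
project_plane <- function(plane, X) {
  as.matrix(X)[, plane$markers, drop = FALSE] %*% plane$axes
}

## ---- cluster classification ----------------------------------------------

template_mahalanobis <- function(x, tpl, markers) {
  mu <- tpl$location[markers]
  S <- tpl$cov[markers, markers, drop = FALSE]
  sqrt(mahalanobis_psd(matrix(x, 1), mu, S))
}

#' Classify one cluster of events against reference templates
#'
#' Candidates are ranked by Mahalanobis distance from the cluster median to
#' each template.  For successive competitor pairs a pairwise canonical
#' plane is fitted; the cluster is assigned to the nearer template in that
#' plane if its projected median falls inside that template's 2-SD ellipse,
#' otherwise the next pair is tried; if no template admits the cluster it
#' is returned as `"unclassified"` (or the nearest template when
#' `force = TRUE`).  A single candidate admits the cluster when the
#' full-space Mahalanobis distance is at most 2.
#'
#' @param X_cluster Events x markers matrix of the cluster's events.
#' @param db An `agiflow_refdb`.
#' @param candidates Character vector of candidate population names
#'   (leaves, internal nodes or aggregates).
#' @param markers Marker subspace used for the comparison.
#' @param force Assign the Mahalanobis-nearest candidate when no 2-SD
#'   ellipse admits the cluster.
#' @param max_pairs Competitor pairs tried before giving up.
#' @return Population name or `"unclassified"`.
#' @export
classify_cluster <- function(X_cluster, db, candidates,
                             markers = db$markers, force = FALSE,
                             max_pairs = 4L) {
  if (!length(candidates))
    stop_agi("agiflow_value_error", "empty candidate list")
  X_cluster <- as.matrix(X_cluster)
  med <- apply(X_cluster[, markers, drop = FALSE], 2, median)
  tls <- lapply(candidates, function(p) get_template(db, p))
  d <- vapply(tls, function(t) template_mahalanobis(med, t, markers),
              numeric(1))
  ## ties: larger template n, then name
  ord <- order(d, -vapply(tls, `[[`, numeric(1), "n"), candidates)
  if (length(candidates) == 1L)
    return(if (d[1] <= 2) candidates[1] else
           if (force) candidates[1] else "unclassified")
  for (i in seq_len(min(max_pairs, length(candidates) - 1L))) {
    t1 <- tls[[ord[i]]]; t2 <- tls[[ord[i + 1L]]]
    pl <- tryCatch(fit_canonical_plane(list(t1, t2), markers),
                   error = function(e) NULL)
    if (is.null(pl)) next
    pm <- matrix(apply(project_plane(pl, X_cluster), 2, median), 1)
    d2 <- vapply(1:2, function(k)
      mahalanobis_psd(pm, pl$proj_means[k, ], pl$proj_covs[[k]]),
      numeric(1))
    winner <- which.min(d2)
    if (d2[winner] <= 4)
      return(pl$populations[winner])
  }
  if (force) candidates[ord[1]] else "unclassified"
}

#' Two-step AGI: cluster, then classify each cluster
#'
#' Step one performs density-peak clustering of all in-scope events; step
#' two classifies every cluster against the reference templates (candidate
#' populations plus the doublet and debris templates); events inherit their
#' cluster's label.  Scopes of at most K events bypass clustering and are
#' classified as singleton clusters.
#'
#' @param em Transformed [event_matrix()] (or numeric matrix).
#' @param db An `agiflow_refdb`.
#' @param candidates Candidate populations (default: all database leaf
#'   templates).
#' @param markers Marker subspace.
#' @param scope Optional integer indices restricting the classified events.
#' @param include_artifacts Add the doublet and debris templates to the
#'   candidate list (the flat algorithm's default; hierarchical refinement
#'   stages drop them because artifacts are excluded by rule up front).
#' @param event_fallback For clusters no template admits, rescue individual
#'   events to the nearest candidate template when within 2 SD
#'   (Mahalanobis); remaining events stay unclassified.
#' @inheritParams cluster_events
#' @inheritParams classify_cluster
#' @return An `agiflow_result` when `em` is an event matrix, otherwise the
#'   per-event label vector.
#' @export
two_step_classify <- function(em, db, candidates = NULL,
                              markers = db$markers, scope = NULL,
                              K = 10L, cutoff = 0.9, max_events = 1e4,
                              seed = 1L, force = FALSE,
                              include_artifacts = TRUE,
                              event_fallback = FALSE) {
  X_all <- if (inherits(em, "agiflow_events")) em$values else as.matrix(em)
  full_run <- is.null(scope)
  if (is.null(scope)) scope <- seq_len(nrow(X_all))
  if (is.null(candidates)) candidates <- names(db$templates)
  if (include_artifacts) {
    art <- intersect(c("Doublets", "Debris"), names(db$templates))
    candidates <- unique(c(candidates, art))
  } else {
    candidates <- setdiff(candidates, c("Doublets", "Debris"))
  }
  labels <- character(length(scope))
  if (!length(scope)) {
    if (inherits(em, "agiflow_events") && full_run)
      return(new_result(character(0), db$taxonomy))
    return(labels)
  }
  X <- X_all[scope, markers, drop = FALSE]
  if (length(scope) <= K) {
    for (i in seq_along(scope))
      labels[i] <- classify_cluster(X[i, , drop = FALSE], db, candidates,
                                    markers, force)
  } else {
    cl <- cluster_events(X, K = K, cutoff = cutoff, max_events = max_events,
                         seed = seed)
    lab_by_cl <- vapply(cl$clusters$id, function(k)
      classify_cluster(X[cl$cluster == k, , drop = FALSE], db, candidates,
                       markers, force), "")
    labels <- lab_by_cl[cl$cluster]
  }
  ## per-event rescue pass: an event left unclassified, or sitting beyond
  ## 2 SD of its cluster's template while within 2 SD of another candidate
  ## (the minority of a wrongly merged cluster), moves to the nearest
  ## admitting template
  if (event_fallback) {
    tls <- lapply(candidates, function(p) get_template(db, p))
    lab_idx <- match(labels, candidates)
    n_s <- length(scope)
    best_d2 <- rep(Inf, n_s)
    best_k <- rep(NA_integer_, n_s)
    own_d2 <- rep(Inf, n_s)
    for (k in seq_along(candidates)) {
      t <- tls[[k]]
      d2 <- mahalanobis_psd(X, t$location[markers],
                            t$cov[markers, markers, drop = FALSE])
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      best_k[upd] <- k
      own <- which(lab_idx == k)
      own_d2[own] <- d2[own]
    }
    ## membership region scaled to the subspace dimension (chi-square 95%)
    thr <- stats::qchisq(0.95, length(markers))
    move <- (is.na(lab_idx) | own_d2 > thr) & best_d2 <= thr
    labels[move] <- candidates[best_k[move]]
  }
  if (inherits(em, "agiflow_events") && full_run) {
    return(new_result(labels, db$taxonomy,
                      provenance = rep("two_step", length(labels))))
  }
  labels
}

## ---- maturation trajectory ------------------------------------------------

#' Maturation-trajectory stage assignment
#'
#' Events are projected onto the piecewise-linear trajectory through the
#' ordered stage template locations; the normalised arc-length position in
#' [0, 1] is cut at `cutoffs` (defaults: the normalised positions of the
#' midpoints between consecutive stage locations).  Interval ties go to the
#' later stage.
#'
#' @param X Events x markers matrix.
#' @param stage_templates Ordered list of >= 2 templates with `location`.
#' @param markers Trajectory marker subset.
#' @param cutoffs Numeric vector of length `stages - 1` in (0, 1).
#' @return Integer stage index per event.
#' @export
maturation_assign <- function(X, stage_templates, markers = NULL,
                              cutoffs = NULL) {
  if (length(stage_templates) < 2)
    stop_agi("agiflow_value_error", "need >= 2 ordered stage templates")
  if (is.null(markers)) markers <- names(stage_templates[[1]]$location)
  anchors <- t(vapply(stage_templates, function(t) t$location[markers],
                      numeric(length(markers))))
  if (anyDuplicated(anchors))
    stop_agi("agiflow_value_error", "duplicate stage template locations")
  S <- nrow(anchors)
  seg <- diff(anchors)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[S]
  X <- as.matrix(X)[, markers, drop = FALSE]
  n <- nrow(X)
  best_d <- rep(Inf, n)
  pos <- numeric(n)
  for (k in seq_len(S - 1)) {
    v <- seg[k, ]
    t_par <- (sweep(X, 2, anchors[k, ]) %*% v) / sum(v^2)
    t_par <- pmin(pmax(drop(t_par), 0), 1)
    proj <- anchors[rep(k, n), , drop = FALSE] + outer(t_par, v)
    d <- rowSums((X - proj)^2)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    pos[upd] <- (cum[k] + t_par[upd] * seg_len[k]) / total
  }
  if (is.null(cutoffs)) cutoffs <- (cum[-S] + cum[-1]) / 2 / total
  if (length(cutoffs) != S - 1)
    stop_agi("agiflow_value_error", "need %d cutoffs, got %d", S - 1,
             length(cutoffs))
  ## right-closed intervals; a position exactly at a cutoff -> later stage
  as.integer(1L + rowSums(outer(pos, cutoffs, `>=`)))
}

## ---- hierarchical orchestration -------------------------------------------

#' Default hierarchical stage plan
#'
#' Encodes the staged strategy: major leukocyte populations first, then the
#' B-cell compartment (pre-GC / memory / plasma cells), maturation-stage
#' assignment inside the pre-GC and PC compartments, and per-branch
#' two-step refinement down to the gating leaves.
#'
#' @param tax Taxonomy the plan refers to.
#' @return List of stage descriptors (class `agiflow_plan`).
#' @export
default_stage_plan <- function(tax = default_taxonomy()) {
  iso_markers <- c("IgM", "IgD", "IgG1", "IgG2", "IgG3", "IgG4",
                   "IgA1", "IgA2")
  stages <- list(
    list(name = "majors", scope = "Leukocytes", method = "two_step",
         markers = c("FSC-A", "SSC-A", "CD45", "CD19", "CD5", "CD27",
                     "CD24", "CD38"),
         targets = c("Neutrophils", "Eosinophils", "Monocytes",
                     "CD5+ T-cells", "CD5- NK-cells",
                     "Other nucleated cells", "B-cells")),
    list(name = "b_compartment", scope = "B-cells", method = "two_step",
         markers = c("CD19", "CD20", "CD38", "CD24", "CD21", "CD27",
                     "CD45", "CD138", "IgD", "IgM"),
         targets = c("Pre-GC B-cells", "Memory B-cells", "Plasma cells")),
    list(name = "pregc_maturation", scope = "Pre-GC B-cells",
         method = "maturation", markers = c("CD38", "CD5"),
         targets = c("Immature B-cells", "Naive CD5+ B-cells",
                     "Naive CD5- B-cells")),
    list(name = "pc_maturation", scope = "Plasma cells",
         method = "maturation", markers = c("CD20", "CD138"),
         targets = c("CD20+CD138- PC", "CD20-CD138- PC", "CD20-CD138+ PC")),
    list(name = "naive_cd5neg", scope = "Naive CD5- B-cells",
         method = "two_step", markers = c("CD21", "CD24", "CD62L"),
         targets = c("Naive CD5- CD21+ CD62L+ B-cells",
                     "Naive CD5- CD21+ CD62L- B-cells",
                     "Naive CD5- CD21- CD24+ B-cells",
                     "Naive CD5- CD21- CD24- B-cells")),
    list(name = "mbc_isotype", scope = "Memory B-cells",
         method = "two_step", markers = iso_markers,
         targets = sprintf("MBC %s", ISOTYPES))
  )
  for (iso in ISOTYPES) {
    stages[[length(stages) + 1L]] <- list(
      name = sprintf("mbc_%s", iso), scope = sprintf("MBC %s", iso),
      method = "two_step", markers = c("CD21", "CD20", "CD24", "CD27"),
      targets = c(sprintf("MBC %s CD21+CD20+ CD27%s", iso, c("-", "+")),
                  sprintf("MBC %s CD21-CD20++ CD24%s CD27%s", iso,
                          rep(c("-", "+"), each = 2), c("-", "+"))))
  }
  for (st in c("CD20+CD138- PC", "CD20-CD138- PC", "CD20-CD138+ PC")) {
    stages[[length(stages) + 1L]] <- list(
      name = sprintf("pc_%s", gsub("[^A-Za-z0-9]", "", st)), scope = st,
      method = "two_step", markers = iso_markers,
      targets = sprintf("%s %s", st, ISOTYPES))
  }
  structure(stages, class = "agiflow_plan")
}

#' Write / load a stage plan configuration file
#'
#' Tab-separated, one stage per line: name, scope, method, markers
#' (comma-separated), targets (pipe-separated).
#'
#' @param plan An `agiflow_plan`.
#' @param path File path; [load_stage_plan()] defaults to the shipped
#'   configuration equal to [default_stage_plan()].
#' @return `load_stage_plan()` returns an `agiflow_plan`.
#' @export
write_stage_plan <- function(plan, path) {
  dt <- data.table::rbindlist(lapply(plan, function(st)
    data.table::data.table(name = st$name, scope = st$scope,
                           method = st$method,
                           markers = paste(st$markers, collapse = ","),
                           targets = paste(st$targets, collapse = "|"))))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_stage_plan
#' @export
load_stage_plan <- function(path = system.file("extdata",
                              "bigh_imm_stage_plan.tsv",
                              package = "agiflow")) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("name", "scope", "method", "markers", "targets")
  if (!all(need %in% names(dt)))
    stop_agi("agiflow_config_error", "stage plan config missing columns")
  structure(lapply(seq_len(nrow(dt)), function(i) list(
    name = dt$name[i], scope = dt$scope[i], method = dt$method[i],
    markers = strsplit(dt$markers[i], ",", fixed = TRUE)[[1]],
    targets = strsplit(dt$targets[i], "|", fixed = TRUE)[[1]])),
    class = "agiflow_plan")
}

## Stage scopes and targets must exist in the taxonomy; targets whose
## populations simply carry no events in the training data are tolerated
## (their candidates are skipped at run time).
validate_plan <- function(plan, db) {
  known <- c(db$taxonomy$nodes$name)
  missing <- unlist(lapply(plan, function(st)
    setdiff(c(st$scope, st$targets), known)))
  if (length(missing))
    stop_agi("agiflow_plan_error", "plan names unknown populations: %s",
             paste(unique(missing), collapse = ", "))
  invisible(plan)
}

has_template <- function(db, name) {
  !is.null(db$templates[[name]]) ||
    length(intersect(node_label_set(db$taxonomy, name),
                     names(db$templates))) > 0
}

#' Hierarchical multi-step AGI classification
#'
#' Applies the stage plan: doublet/debris exclusion, major leukocyte
#' populations, the B-cell compartment, maturation stages within the
#' pre-GC and plasma-cell compartments, and per-branch refinement to the
#' leaves.  Events that no stage can place remain at their deepest
#' confidently assigned label.
#'
#' @param em Transformed [event_matrix()].
#' @param db An `agiflow_refdb`.
#' @param plan Stage plan, see [default_stage_plan()].
#' @param seed Seed for the clustering subsamples.
#' @param force_assign Force every cluster to its nearest template instead
#'   of allowing `"unclassified"`.
#' @inheritParams cluster_events
#' @return An `agiflow_result`.
#' @export
hierarchical_classify <- function(em, db, plan = default_stage_plan(db$taxonomy),
                                  seed = 1L, force_assign = FALSE,
                                  K = 10L, cutoff = 0.9, max_events = 1e4) {
  stopifnot(inherits(em, "agiflow_events"))
  if (em$stage != "transformed")
    stop_agi("agiflow_stage_error",
             "hierarchical_classify expects transformed events")
  validate_plan(plan, db)
  tax <- db$taxonomy
  n <- nrow(em$values)
  labels <- rep(tax_root(tax), n)
  provenance <- rep("root", n)
  art <- flag_artifacts(em, tax)
  labels[art$doublet] <- "Doublets"
  labels[art$debris] <- "Debris"
  provenance[art$doublet | art$debris] <- "artifact_rule"
  seeds <- derive_seeds(seed, length(plan))
  for (si in seq_along(plan)) {
    st <- plan[[si]]
    scope <- which(labels == st$scope)
    if (!length(scope)) next
    if (st$method == "two_step") {
      ## classify against the unimodal leaf templates under each target,
      ## then roll the winning leaf up to its owning target label
      owner <- unlist(lapply(st$targets, function(t) {
        leaves <- intersect(node_label_set(tax, t), names(db$templates))
        stats::setNames(rep(t, length(leaves)), leaves)
      }))
      if (!length(owner)) next  # no training events under this stage
      lab <- two_step_classify(em, db, candidates = names(owner),
                               markers = st$markers, scope = scope,
                               K = K, cutoff = cutoff,
                               max_events = max_events, seed = seeds[si],
                               force = force_assign,
                               include_artifacts = FALSE,
                               event_fallback = TRUE)
      ok <- lab %in% names(owner)
      labels[scope[ok]] <- owner[lab[ok]]
      provenance[scope[ok]] <- st$name
    } else if (st$method == "maturation") {
      if (!all(vapply(st$targets, has_template, logical(1), db = db)))
        next  # a stage anchor has no training events
      tls <- lapply(st$targets, function(p) get_template(db, p))
      stage_idx <- maturation_assign(em$values[scope, , drop = FALSE],
                                     tls, markers = st$markers)
      labels[scope] <- st$targets[stage_idx]
      provenance[scope] <- st$name
    } else {
      stop_agi("agiflow_plan_error", "unknown stage method '%s'", st$method)
    }
  }
  new_result(labels, tax, provenance = provenance)
}
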