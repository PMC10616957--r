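test_that("knn density matches hand-computed and brute-force values", {
  ## 3 collinear points at 0, 1, 3 with K = 1
  X <- matrix(c(0, 1, 3), 3, 1)
  kd <- knn_density(X, K = 1)
  expect_equal(kd$density, c(1, 1, 0.5))
  expect_equal(kd$nn_idx[, 1], c(2L, 1L, 2L))

  ## duplicated events: zero distance guarded to the configured cap
  Xd <- matrix(rep(c(1, 2), each = 12), 12, 2)
  kd2 <- knn_density(Xd, K = 3, density_cap = 999)
  expect_true(all(kd2$density == 999))

  ## uniform grid: all interior densities equal, matching the oracle
  g <- as.matrix(expand.grid(1:7, 1:7))
  kd3 <- knn_density(g, K = 4)
  orc <- oracle_knn(g, 4)
  expect_equal(kd3$density, orc$density, tolerance = 1e-12)
  interior <- g[, 1] %in% 2:6 & g[, 2] %in% 2:6
  expect_equal(var(kd3$density[interior]), 0)

  ## degenerate scope
  expect_error(knn_density(matrix(1:4, 4, 1), K = 10),
               class = "agiflow_degenerate_scope")
})

test_that("knn and clustering match brute-force oracles on random scopes", {
  set.seed(99)
  for (rep in 1:6) {
    n <- sample(60:400, 1)
    d <- sample(2:5, 1)
    k <- sample(3:8, 1)
    centers <- matrix(rnorm(3 * d, sd = 8), 3, d)
    X <- centers[sample(1:3, n, replace = TRUE), ] +
      matrix(rnorm(n * d), n, d)
    kd <- knn_density(X, K = k)
    orc <- oracle_knn(X, k)
    expect_equal(kd$density, orc$density, tolerance = 1e-12)
    cl <- cluster_events(X, K = k, cutoff = 0.9)
    ocl <- oracle_cluster(X, k, 0.9)
    ## identical partitions up to label permutation
    ct <- table(cl$cluster, ocl)
    expect_true(all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1))
  }
})

test_that("cluster counts follow mode separation", {
  set.seed(5)
  ## two 10-SD-separated Gaussian blobs -> exactly 2 clusters
  X <- rbind(matrix(rnorm(1000 * 2), 1000, 2),
             matrix(rnorm(1000 * 2, mean = 10), 1000, 2))
  cl <- cluster_events(X, K = 10, cutoff = 0.9)
  expect_identical(nrow(cl$clusters), 2L)
  blob <- rep(1:2, each = 1000)
  expect_true(all(rowSums(table(cl$cluster, blob) > 0) == 1))

  ## one blob -> 1 cluster at the 0.9 cutoff
  X1 <- matrix(rnorm(2000 * 2), 2000, 2)
  cl1 <- cluster_events(X1, K = 10, cutoff = 0.9)
  expect_identical(nrow(cl1$clusters), 1L)

  ## cutoff 0 never merges: clusters = modes
  cl0 <- cluster_events(X1, K = 10, cutoff = 0)
  expect_identical(nrow(cl0$merge_trace), 0L)
  expect_gte(nrow(cl0$clusters), nrow(cl1$clusters))

  ## scale equivariance: common positive rescaling leaves the partition
  cl_s <- cluster_events(X * 3.7, K = 10, cutoff = 0.9)
  expect_identical(cl$cluster, cl_s$cluster)
})

test_that("canonical plane equals the generalised eigen oracle", {
  ## two spherical populations differing only in one marker: axis 1 is that
  ## basis vector up to sign
  mk <- c("CD27", "CD21", "CD24")
  I3 <- diag(3); dimnames(I3) <- list(mk, mk)
  t1 <- toy_template("a", stats::setNames(c(0, 1, 1), mk), I3)
  t2 <- toy_template("b", stats::setNames(c(3, 1, 1), mk), I3)
  pl <- fit_canonical_plane(list(t1, t2), mk)
  expect_equal(abs(pl$axes[, 1]), c(CD27 = 1, CD21 = 0, CD24 = 0),
               tolerance = 1e-8)

  ## hand-built template sets vs the independent eigen oracle
  set.seed(11)
  for (case in 1:4) {
    d <- 4
    mk4 <- paste0("M", 1:d)
    locs <- matrix(rnorm(3 * d, sd = 3), 3, d)
    covs <- lapply(1:3, function(i) {
      A <- matrix(rnorm(d * d, sd = 0.3), d)
      S <- crossprod(A) + diag(d)
      dimnames(S) <- list(mk4, mk4); S
    })
    ns <- c(200, 300, 150)
    tls <- lapply(1:3, function(i)
      toy_template(letters[i], stats::setNames(locs[i, ], mk4), covs[[i]],
                   ns[i]))
    pl4 <- fit_canonical_plane(tls, mk4)
    W <- Reduce(`+`, Map(function(S, n) S * n, covs, ns)) / sum(ns)
    mbar <- colSums(locs * ns) / sum(ns)
    B <- Reduce(`+`, lapply(1:3, function(i)
      ns[i] * tcrossprod(locs[i, ] - mbar))) / sum(ns)
    v <- oracle_lda_axis(W, B)
    a1 <- pl4$axes[, 1]
    expect_equal(abs(sum(a1 * v)), 1, tolerance = 1e-6)
  }

  ## three collinear-mean spherical populations: axis 1 along the mean line
  t3 <- lapply(0:2, function(i)
    toy_template(paste0("c", i), stats::setNames(c(i, 2 * i, 0), mk), I3,
                 100))
  pl3 <- fit_canonical_plane(t3, mk)
  dirv <- c(1, 2, 0) / sqrt(5)
  expect_equal(abs(sum(pl3$axes[, 1] * dirv)), 1, tolerance = 1e-8)

  ## identical templates: zero between-scatter flagged
  expect_error(fit_canonical_plane(list(t1, t1), mk),
               class = "agiflow_value_error")
  expect_error(fit_canonical_plane(list(t1), mk),
               class = "agiflow_value_error")
})

test_that("cluster classification accepts, rejects and tie-breaks", {
  db <- fx_db()
  tax <- fx_tax()
  model <- fx_model()
  set.seed(3)
  ## a cluster sampled from a template is labelled as that template
  tpl <- db$templates[["CD5+ T-cells"]]
  X <- MASS_free_mvn(500, tpl$location, tpl$cov)
  expect_identical(classify_cluster(X, db, c("CD5+ T-cells",
                                             "CD5- NK-cells",
                                             "Neutrophils")),
                   "CD5+ T-cells")
  ## single candidate within 2 SD
  expect_identical(classify_cluster(X, db, "CD5+ T-cells"), "CD5+ T-cells")

  ## a cluster midway between two equal-covariance templates 8 SD apart is
  ## unclassified
  mk <- db$markers
  S <- diag(length(mk)) * 0.01; dimnames(S) <- list(mk, mk)
  la <- stats::setNames(rep(0, length(mk)), mk)
  lb <- la; lb[1] <- 0.8  # 8 SD apart in the first marker
  dbx <- db
  dbx$templates[["__A"]] <- toy_template("__A", la, S, 1000)
  dbx$templates[["__B"]] <- toy_template("__B", lb, S, 1000)
  mid <- matrix(rep((la + lb) / 2, each = 50), 50,
                dimnames = list(NULL, mk))
  expect_identical(classify_cluster(mid, dbx, c("__A", "__B")),
                   "unclassified")
  expect_true(classify_cluster(mid, dbx, c("__A", "__B"), force = TRUE)
              %in% c("__A", "__B"))
  expect_error(classify_cluster(X, db, character(0)),
               class = "agiflow_value_error")
})

test_that("maturation assignment follows the trajectory contract", {
  mk <- c("CD20", "CD138")
  tpl <- list(
    toy_template("s1", stats::setNames(c(3, 0.5), mk), NULL),
    toy_template("s2", stats::setNames(c(0.5, 0.5), mk), NULL),
    toy_template("s3", stats::setNames(c(0.5, 3), mk), NULL))
  ## stage-template locations map to their own stages
  X <- rbind(c(3, 0.5), c(0.5, 0.5), c(0.5, 3))
  colnames(X) <- mk
  expect_identical(maturation_assign(X, tpl, mk), c(1L, 2L, 3L))
  ## exact midpoint ties to the later stage
  mid <- rbind(c(1.75, 0.5)); colnames(mid) <- mk
  expect_identical(maturation_assign(mid, tpl, mk), 2L)
  ## errors
  expect_error(maturation_assign(X, tpl[1], mk), class = "agiflow_value_error")
  expect_error(maturation_assign(X, list(tpl[[1]], tpl[[1]]), mk),
               class = "agiflow_value_error")
  expect_error(maturation_assign(X, tpl, mk, cutoffs = 0.5),
               class = "agiflow_value_error")
})

test_that("continuum simulation recovers the planted change-points", {
  model <- fx_model()
  tax <- fx_tax()
  sim <- simulate_sample(model,
                         sample_spec(n_events = 2e5, seed = 61,
                                     frequencies = c(PC = 0.05),
                                     continuum = TRUE))
  em <- prepare_events(sim$em, sim$spill)
  pc_stages <- c("CD20+CD138- PC", "CD20-CD138- PC", "CD20-CD138+ PC")
  stage_of <- function(lab) {
    out <- rep(NA_integer_, length(lab))
    for (k in 1:3)
      out[lab %in% agiflow:::tax_subtree(tax, pc_stages[k])] <- k
    out
  }
  truth_stage <- stage_of(sim$truth)
  idx <- which(!is.na(truth_stage))
  tpl <- lapply(pc_stages, function(s) {
    leaves <- intersect(agiflow:::node_label_set(tax, s),
                        names(model$templates))
    loc <- colMeans(do.call(rbind, lapply(model$templates[leaves],
                                          function(x) x$loc)))
    toy_template(s, loc, NULL)
  })
  got <- maturation_assign(em$values[idx, ], tpl, c("CD20", "CD138"))
  agree <- mean(got == truth_stage[idx])
  expect_gt(agree, 0.9)
  ## boundary recovery: the observed change-points along the planted
  ## positions sit within +-0.05 of the planted cutoffs (0.25, 0.75)
  pos_truth <- (truth_stage[idx] - 1) / 2  # stage centres 0, .5, 1
  for (k in 1:2) {
    b_lo <- max(pos_truth[got <= k])
    b_hi <- min(pos_truth[got > k])
    planted <- c(0.25, 0.75)[k]
    mism <- mean((got > k) != (pos_truth > planted))
    expect_lt(mism, 0.1)
  }
})

test_that("two-step handles pure, tiny and empty scopes", {
  db <- fx_db()
  model <- fx_model()
  ## pure debris sample classifies to debris
  sim <- simulate_sample(model, sample_spec(n_events = 3000, seed = 67,
                                            doublet_rate = 0,
                                            debris_rate = 1))
  em <- prepare_events(sim$em, sim$spill)
  res <- two_step_classify(em, db, seed = 1)
  expect_gt(mean(res$labels == "Debris"), 0.9)
  ## empty scope
  lab0 <- two_step_classify(em, db, scope = integer(0))
  expect_identical(lab0, character(0))
})

test_that("hierarchical classification is deterministic and conserving", {
  db <- fx_db()
  sim <- fx_sample(n = 5e4, seed = 7)
  r1 <- hierarchical_classify(sim$em_t, db, seed = 11)
  r2 <- hierarchical_classify(sim$em_t, db, seed = 11)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$counts, r2$counts)
  ## partition: every event exactly one label
  expect_identical(length(r1$labels), nrow(sim$em_t$values))
  expect_false(any(is.na(r1$labels)))
  ## a sample without PC events yields PC count 0, no errors
  sim0 <- simulate_sample(fx_model(),
                          sample_spec(n_events = 2e4, seed = 71,
                                      frequencies = c(PC = 0)))
  em0 <- prepare_events(sim0$em, sim0$spill)
  r0 <- hierarchical_classify(em0, db, seed = 3)
  pc_n <- r0$counts$n[r0$counts$population == "Plasma cells"]
  expect_lt(pc_n, 20)
  ## a plan referencing unknown targets errors
  plan <- default_stage_plan(fx_tax())
  plan[[1]]$targets <- c(plan[[1]]$targets, "No such population")
  expect_error(hierarchical_classify(sim$em_t, db, plan = plan),
               class = "agiflow_plan_error")
})
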