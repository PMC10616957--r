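## Shared fixtures.  Heavy objects (taxonomy, model, a small training
## database, cohorts) are built once per test run and memoised here.

fixture_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fx_tax <- function() fx("tax", default_taxonomy)

fx_model <- function() fx("model", function() default_panel_model(fx_tax()))

## one prepared (compensated+transformed) sample with truth
fx_sample <- function(n = 5e4, seed = 7, ...) {
  key <- sprintf("sample_%g_%d", n, seed)
  fx(key, function() {
    sim <- simulate_sample(fx_model(), sample_spec(n_events = n, seed = seed,
                                                   ...))
    sim$em_t <- prepare_events(sim$em, sim$spill)
    sim
  })
}

## training database built from boolean-gated simulated files
fx_db <- function(n_files = 3, n = 1e5, seed0 = 100) {
  key <- sprintf("db_%d_%g_%d", n_files, n, seed0)
  fx(key, function() {
    tax <- fx_tax()
    db <- NULL
    for (i in seq_len(n_files)) {
      sim <- simulate_sample(fx_model(),
                             sample_spec(n_events = n, seed = seed0 + i))
      em <- prepare_events(sim$em, sim$spill)
      lab <- boolean_gate(em, tax)$labels
      db <- if (is.null(db))
        init_database(em, lab, tax, file_id = paste0("f", i))
      else classify_and_merge(db, em, lab, file_id = paste0("f", i),
                              seed = i)
    }
    db
  })
}

## gating leaves, and the planted-truth quantifiable populations of a sample
fx_leaves <- function() fx("leaves", function() agiflow:::tax_leaves(fx_tax()))

quantifiable_truth_pops <- function(truth) {
  tc <- table(truth)
  thr <- ifelse(endsWith(names(tc), " PC"), 20, 50)
  intersect(names(tc)[tc > thr], fx_leaves())
}

## tiny hand-made event matrix in transformed space
toy_events <- function(vals, markers = colnames(vals),
                       stage = "transformed") {
  event_matrix(vals, stage = stage, sample_id = "toy")
}

## template constructor for hand-built canonical-analysis cases
toy_template <- function(name, loc, cov, n = 100) {
  list(name = name, n = n, location = loc, cov = cov)
}

## tiny multivariate-normal sampler (keeps tests dependency-free)
MASS_free_mvn <- function(n, mu, S) {
  L <- chol(S + diag(1e-8, nrow(S)))
  X <- matrix(rnorm(n * length(mu)), n) %*% L
  sweep(X, 2, mu, `+`) |> `colnames<-`(names(mu))
}
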