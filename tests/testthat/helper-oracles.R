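## Independent brute-force oracles, kept deliberately naive and separate
## from the package implementation paths they are used to check.

## all-pairs KNN via base dist()
oracle_knn <- function(X, K) {
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  idx <- t(apply(D, 1, function(r) order(r)[seq_len(K)]))
  dst <- t(vapply(seq_len(nrow(X)),
                  function(i) D[i, idx[i, ]], numeric(K)))
  list(idx = idx, dist = dst, density = 1 / rowMeans(dst))
}

## naive re-implementation of the density-peak clustering (O(n^2) matrices,
## explicit loops) used to cross-check cluster_events on small scopes
oracle_cluster <- function(X, K, cutoff) {
  n <- nrow(X)
  kn <- oracle_knn(X, K)
  dens <- kn$density
  parent <- seq_len(n)
  for (i in seq_len(n)) {
    nb <- kn$idx[i, ]
    cand <- nb[order(dens[nb], decreasing = TRUE)[1]]
    if (dens[cand] > dens[i]) parent[i] <- cand
  }
  mode_of <- seq_len(n)
  for (i in seq_len(n)) {
    cur <- i
    while (parent[cur] != cur) cur <- parent[cur]
    mode_of[i] <- cur
  }
  peak <- dens
  sigma_k <- 1 / sqrt(2 * K)
  sep_of <- function(s, pa, pb) {
    z <- log(pmin(pa, pb) / pmax(s, 1e-300)) / sigma_k
    20 * (1 - exp(-pmax(0, z - 3)))
  }
  saddle <- list()
  for (i in seq_len(n)) for (j in kn$idx[i, ]) {
    a <- min(mode_of[i], mode_of[j]); b <- max(mode_of[i], mode_of[j])
    if (a == b) next
    key <- paste(a, b)
    w <- min(dens[i], dens[j])
    saddle[[key]] <- max(saddle[[key]] %||% -Inf, w)
  }
  repeat {
    if (!length(saddle)) break
    keys <- names(saddle)
    ab <- do.call(rbind, strsplit(keys, " "))
    a <- as.integer(ab[, 1]); b <- as.integer(ab[, 2])
    sep <- sep_of(unlist(saddle), peak[a], peak[b])
    i <- order(sep, a, b)[1]
    if (sep[i] >= cutoff) break
    keep <- a[i]; gone <- b[i]
    mode_of[mode_of == gone] <- keep
    peak[keep] <- max(peak[keep], peak[gone])
    new_saddle <- list()
    for (k in seq_along(saddle)) {
      aa <- a[k]; bb <- b[k]
      if (aa == gone) aa <- keep
      if (bb == gone) bb <- keep
      lo <- min(aa, bb); hi <- max(aa, bb)
      if (lo == hi) next
      key <- paste(lo, hi)
      new_saddle[[key]] <- max(new_saddle[[key]] %||% -Inf, saddle[[k]])
    }
    saddle <- new_saddle
  }
  match(mode_of, sort(unique(mode_of)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## generalised eigenproblem oracle: leading eigenvector of solve(W) %*% B
oracle_lda_axis <- function(W, B) {
  e <- eigen(solve(W) %*% B)
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sqrt(sum(v^2))
}

## textbook formulas
oracle_r2 <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

oracle_cv <- function(x) 100 * sd(x) / mean(x)
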