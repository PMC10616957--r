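## Method-comparison and reproducibility statistics: per-population Pearson
## correlation of paired counts, replicate coefficients of variation,
## Bland-Altman bias, and paired / unpaired rank tests.

#' Per-population squared Pearson correlation between two methods
#'
#' Both inputs are samples x populations count matrices (aligned rows).
#' For each population, only samples where the first (reference) method's
#' count is quantifiable enter the pair set; populations with fewer than
#' three quantifiable pairs are flagged not evaluable, as are populations
#' with zero variance in either vector.
#'
#' @param a,b Numeric matrices, samples x populations, identical dimnames
#'   (a = reference method).
#' @param tax Taxonomy (supplies the per-population quantifiability rule).
#' @param adjust P-value adjustment method (`"none"` by default; the raw
#'   per-population p-values are reported as printed, `"BH"` available).
#' @return `data.table`: `population`, `n_pairs`, `r2`, `slope`, `p`,
#'   `evaluable`.
#' @export
per_population_r2 <- function(a, b, tax = default_taxonomy(),
                              adjust = "none") {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) ||
      !identical(colnames(a), colnames(b)) ||
      (!is.null(rownames(a)) && !identical(rownames(a), rownames(b))))
    stop_agi("agiflow_value_error",
             "count tables must share samples and populations")
  is_pc <- vapply(colnames(a), function(p) {
    i <- match(p, tax$nodes$name)
    !is.na(i) && identical(tax$nodes$count_class[i], "PC")
  }, logical(1))
  rows <- lapply(seq_len(ncol(a)), function(j) {
    q <- a[, j] > min_quantifiable(is_pc[j])
    x <- a[q, j]; y <- b[q, j]
    if (sum(q) < 3 || var(x) == 0 || var(y) == 0)
      return(data.table::data.table(population = colnames(a)[j],
                                    n_pairs = sum(q), r2 = NA_real_,
                                    slope = NA_real_, p = NA_real_,
                                    evaluable = FALSE))
    ct <- cor.test(x, y)
    data.table::data.table(population = colnames(a)[j], n_pairs = sum(q),
                           r2 = unname(ct$estimate)^2,
                           slope = cov(x, y) / var(x),
                           p = ct$p.value, evaluable = TRUE)
  })
  out <- data.table::rbindlist(rows)
  out$p_adj <- p.adjust(out$p, method = adjust)
  out[]
}

#' Replicate reproducibility: per-population CV
#'
#' CV = 100 * SD / mean over replicate analyses of the same sample.
#'
#' @param counts Numeric matrix, populations x replicates (>= 2 columns).
#' @param method Label stored in the report.
#' @return A `repro_report`: per-population `cv` and `sd`, plus the median
#'   CV over populations with nonzero mean.
#' @export
reproducibility_cv <- function(counts, method = "method") {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2)
    stop_agi("agiflow_value_error", "need >= 2 replicates")
  mu <- rowMeans(counts)
  sds <- apply(counts, 1, sd)
  cv <- ifelse(mu > 0, 100 * sds / mu, NA_real_)
  structure(list(
    table = data.table::data.table(
      population = rownames(counts) %||% paste0("pop", seq_len(nrow(counts))),
      mean = mu, sd = sds, cv = cv, evaluable = mu > 0),
    median_cv = median(cv, na.rm = TRUE), method = method),
    class = "repro_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Paired comparison of two methods' CV distributions
#'
#' Paired t-test on the per-population CVs of two [reproducibility_cv()]
#' reports (populations evaluable in both).
#'
#' @param ra,rb `repro_report` objects over the same populations.
#' @return `htest` from [t.test()].
#' @export
compare_cv <- function(ra, rb) {
  m <- merge(ra$table[, .(population, cv_a = cv)],
             rb$table[, .(population, cv_b = cv)], by = "population")
  m <- m[is.finite(cv_a) & is.finite(cv_b)]
  if (nrow(m) < 2)
    stop_agi("agiflow_value_error", "need >= 2 jointly evaluable populations")
  t.test(m$cv_a, m$cv_b, paired = TRUE)
}

#' Bland-Altman bias between paired measurements
#'
#' @param a,b Numeric vectors of paired measurements (>= 2 pairs).
#' @return List `(bias, sd, loa_lower, loa_upper)`; limits of agreement are
#'   bias +/- 1.96 SD of the differences.
#' @export
bland_altman_bias <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop_agi("agiflow_value_error", "need >= 2 aligned pairs")
  d <- a - b
  list(bias = mean(d), sd = sd(d),
       loa_lower = mean(d) - 1.96 * sd(d),
       loa_upper = mean(d) + 1.96 * sd(d))
}

#' Rank-based comparison of two methods
#'
#' Reports the Wilcoxon statistic (signed-rank when `paired`, rank-sum /
#' Mann-Whitney otherwise) and the Kruskal-Wallis test as descriptive
#' outputs; no multiple-testing correction is applied.
#'
#' @param a,b Numeric vectors (aligned samples when `paired`).
#' @param paired Logical.
#' @return List with both `htest` objects and their p-values.
#' @export
compare_methods <- function(a, b, paired = TRUE) {
  if (!length(a) || !length(b))
    stop_agi("agiflow_value_error", "empty input")
  if (paired && length(a) != length(b))
    stop_agi("agiflow_value_error", "paired data must be aligned")
  if (length(a) < 2 || length(b) < 2)
    stop_agi("agiflow_value_error", "need >= 2 observations per method")
  w <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
  kw <- kruskal.test(list(a, b))
  list(wilcoxon = w, kruskal = kw,
       p_wilcoxon = w$p.value, p_kruskal = kw$p.value)
}

#' Counts matrix from a list of classification results
#'
#' Convenience: stacks per-sample [population_counts()] of several
#' `agiflow_result`s into a samples x populations matrix restricted to
#' counted subsets.
#'
#' @param results List of `agiflow_result` objects.
#' @param tax Taxonomy.
#' @param classes Count classes to keep (default all counted subsets).
#' @return Numeric matrix with sample rows and population columns.
#' @export
counts_matrix <- function(results, tax = default_taxonomy(),
                          classes = c("preGC", "MBC", "PC", "nonB")) {
  pops <- tax$nodes$name[tax$nodes$counted &
                           tax$nodes$count_class %in% classes]
  out <- t(vapply(results, function(r) {
    v <- r$counts$n[match(pops, r$counts$population)]
    ifelse(is.na(v), 0, v)
  }, numeric(length(pops))))
  colnames(out) <- pops
  rownames(out) <- paste0("sample", seq_along(results))
  out
}
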