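## Population taxonomy: the B-lymphocyte / plasma-cell gating hierarchy, its
## Boolean phenotype rules, expression-level breakpoints, and the counting
## conventions that enumerate 117 B + PC subsets (32 PC, 85 B-lymphocyte)
## and 123 populations overall.

LEVELS <- c("neg", "lo", "pos", "hi")

## level -> set of elementary bands; "het" spans the bands between neg and hi
level_band_sets <- list(
  neg = 1L, lo = 2L, pos = 3L, hi = 4L, het = c(2L, 3L), any = 1:4
)

#' Default expression-level breakpoints
#'
#' Per-marker numeric breakpoints (transformed units) delimiting the
#' neg / lo / pos / hi bands.  Fluorescence markers share one default;
#' CD45 and the scatter channels have their own scales.
#'
#' @return `data.frame` with columns `marker`, `b1`, `b2`, `b3`.
#' @export
default_breakpoints <- function() {
  mk <- agi_markers()
  bp <- data.frame(marker = c(mk, "FSC-A", "FSC-H", "SSC-A"),
                   b1 = 1.0, b2 = 1.75, b3 = 3.6)
  bp[bp$marker == "CD45", c("b1", "b2", "b3")] <- c(0.8, 2.8, 3.8)
  sc <- bp$marker %in% c("FSC-A", "FSC-H", "SSC-A")
  bp[sc, "b1"] <- 0.4; bp[sc, "b2"] <- 1.6; bp[sc, "b3"] <- 2.8
  bp
}

#' Numeric centres of the symbolic expression levels
#'
#' Where population templates sit on each marker's transformed scale for the
#' symbolic phenotype levels.  `het` has no fixed centre (events are spread
#' across the lo-pos span); it is reported as the span midpoint.
#'
#' @return `data.frame` with one row per marker and one column per level.
#' @export
default_level_means <- function() {
  mk <- agi_markers()
  lm <- data.frame(marker = c(mk, "FSC-A", "FSC-H", "SSC-A"),
                   neg = 0.5, lo = 1.5, pos = 3.0, hi = 4.2, het = 2.25)
  lm[lm$marker == "CD45", c("neg", "lo", "pos", "hi")] <-
    c(0.3, 1.5, 3.3, 4.2)
  sc <- lm$marker %in% c("FSC-A", "FSC-H", "SSC-A")
  lm[sc, c("neg", "lo", "pos", "hi", "het")] <- rep(c(0.2, 1.0, 2.2, 3.4, 1.6),
                                                    each = sum(sc))
  lm
}

band_of <- function(x, bp_row) {
  findInterval(x, c(bp_row$b1, bp_row$b2, bp_row$b3)) + 1L
}

## ---- rule grammar ---------------------------------------------------------
## A rule is an OR of clauses; a clause an AND of terms; a term allows a set
## of levels on one marker.  Text form:
##   "CD19:pos,hi&CD45:pos,hi | CD38:hi&CD24:neg,lo"

parse_rule <- function(txt) {
  txt <- trimws(txt)
  if (!nchar(txt)) return(list())
  lapply(strsplit(txt, "|", fixed = TRUE)[[1]], function(cl) {
    terms <- strsplit(trimws(cl), "&", fixed = TRUE)[[1]]
    out <- list()
    for (t in terms) {
      kv <- strsplit(trimws(t), ":", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        stop_agi("agiflow_config_error", "malformed rule term '%s'", t)
      lv <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
      bad <- setdiff(lv, names(level_band_sets))
      if (length(bad))
        stop_agi("agiflow_config_error", "unknown level '%s'", bad[1])
      out[[trimws(kv[1])]] <- lv
    }
    out
  })
}

rule_markers <- function(rule) unique(unlist(lapply(rule, names)))

levels_disjoint <- function(lv_a, lv_b) {
  a <- unique(unlist(level_band_sets[lv_a]))
  b <- unique(unlist(level_band_sets[lv_b]))
  length(intersect(a, b)) == 0L
}

clauses_disjoint <- function(cl_a, cl_b) {
  shared <- intersect(names(cl_a), names(cl_b))
  any(vapply(shared, function(m) levels_disjoint(cl_a[[m]], cl_b[[m]]),
             logical(1)))
}

rules_disjoint <- function(rule_a, rule_b) {
  if (!length(rule_a) || !length(rule_b)) return(FALSE)
  all(vapply(rule_a, function(ca)
    all(vapply(rule_b, function(cb) clauses_disjoint(ca, cb), logical(1))),
    logical(1)))
}

parse_phenotype <- function(txt) {
  txt <- trimws(txt)
  if (!nchar(txt)) return(character(0))
  kv <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) trimws(x[2]), ""),
                  vapply(kv, function(x) trimws(x[1]), ""))
}

fmt_phenotype <- function(ph) paste(names(ph), ph, sep = "=", collapse = ";")

fmt_rule <- function(rule) {
  paste(vapply(rule, function(cl)
    paste(names(cl), vapply(cl, paste, "", collapse = ","),
          sep = ":", collapse = "&"), ""), collapse = " | ")
}

## ---- default taxonomy construction ---------------------------------------

ISOTYPES <- c("IgMD", "IgG1", "IgG2", "IgG3", "IgG4", "IgA1", "IgA2", "IgHneg")

iso_rule <- function(iso) {
  igm <- c("IgM", "IgG1", "IgG2", "IgG3", "IgG4", "IgA1", "IgA2")
  expressed <- switch(iso, IgMD = "IgM", IgHneg = character(0), iso)
  terms <- c(
    if (length(expressed)) sprintf("%s:pos,hi", expressed),
    sprintf("%s:neg,lo", setdiff(igm, expressed))
  )
  paste(terms, collapse = "&")
}

iso_phenotype <- function(iso, igd_when_igmd = "pos") {
  switch(iso,
    IgMD = c(IgM = "pos", IgD = igd_when_igmd),
    IgHneg = character(0),
    stats::setNames("pos", iso))
}

node_row <- function(name, parent, type = "node", compartment = "internal",
                     count_class = NA_character_, counted = FALSE,
                     rule = "", phenotype = character(0), members = "") {
  data.frame(name = name, parent = parent, type = type,
             compartment = compartment, count_class = count_class,
             counted = counted, rule = rule,
             phenotype = fmt_phenotype(phenotype),
             members = members, stringsAsFactors = FALSE)
}

build_default_nodes <- function() {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- node_row(...)

  add("Leukocytes", NA_character_)

  ## major non-B populations
  add("Neutrophils", "Leukocytes", compartment = "nonB",
      count_class = "nonB", counted = TRUE,
      rule = "SSC-A:hi&CD45:neg,lo&CD24:pos,hi",
      phenotype = c(`FSC-A` = "pos", `SSC-A` = "hi", CD45 = "lo",
                    CD24 = "pos"))
  add("Eosinophils", "Leukocytes", compartment = "nonB",
      count_class = "nonB", counted = TRUE,
      rule = "SSC-A:hi&CD45:pos,hi&CD27:pos,hi",
      phenotype = c(`FSC-A` = "pos", `SSC-A` = "hi", CD45 = "hi",
                    CD27 = "pos", IgM = "pos"))
  add("Monocytes", "Leukocytes", compartment = "nonB",
      count_class = "nonB", counted = TRUE,
      rule = "SSC-A:pos&CD45:pos,hi&CD19:neg,lo&CD38:neg,lo",
      phenotype = c(`FSC-A` = "pos", `SSC-A` = "pos", CD45 = "hi"))
  add("CD5+ T-cells", "Leukocytes", compartment = "nonB",
      count_class = "nonB", counted = TRUE,
      rule = "SSC-A:neg,lo&CD45:pos,hi&CD19:neg,lo&CD5:pos,hi&CD38:neg,lo,pos",
      phenotype = c(`FSC-A` = "lo", `SSC-A` = "lo", CD45 = "hi", CD5 = "hi",
                    CD62L = "pos"))
  add("CD5- NK-cells", "Leukocytes", compartment = "nonB",
      count_class = "nonB", counted = TRUE,
      rule = "SSC-A:neg,lo&CD45:pos,hi&CD19:neg,lo&CD5:neg,lo&CD38:neg,lo,pos",
      phenotype = c(`FSC-A` = "lo", `SSC-A` = "lo", CD45 = "hi"))
  add("Other nucleated cells", "Leukocytes", compartment = "nonB",
      count_class = "nonB", counted = TRUE,
      rule = "SSC-A:neg,lo&CD45:neg,lo&CD19:neg,lo&CD38:neg,lo,pos",
      phenotype = c(`FSC-A` = "lo", `SSC-A` = "lo", CD45 = "lo"))

  ## B-cell compartment (B-lymphocytes + plasma cells)
  add("B-cells", "Leukocytes",
      rule = paste("CD19:pos,hi&CD45:pos,hi&SSC-A:neg,lo&CD38:neg,lo,pos",
                   "CD38:hi&CD24:neg,lo&CD21:neg,lo&SSC-A:neg,lo,pos",
                   sep = " | "))

  add("Plasma cells", "B-cells",
      rule = "CD38:hi&CD24:neg,lo&CD21:neg,lo")
  add("B-lymphocytes", "B-cells",
      rule = "CD19:pos,hi&CD45:pos,hi&CD38:neg,lo,pos")

  ## --- pre-germinal-centre B-cells (10 counted subsets) ---
  add("Pre-GC B-cells", "B-lymphocytes",
      rule = paste("CD38:pos,hi&CD24:pos,hi&CD27:neg,lo",
                   "IgD:hi&CD27:neg,lo&CD38:neg,lo", sep = " | "))
  bly <- c(CD19 = "pos", CD45 = "hi", `FSC-A` = "lo", `SSC-A` = "lo",
           CD20 = "pos")
  add("Immature B-cells", "Pre-GC B-cells", compartment = "preGC",
      count_class = "preGC", counted = TRUE,
      rule = "CD38:pos,hi&CD24:pos,hi",
      phenotype = c(bly, CD38 = "pos", CD24 = "pos", CD21 = "het",
                    IgM = "hi", IgD = "pos", CD5 = "lo"))
  add("Naive B-cells", "Pre-GC B-cells", compartment = "preGC",
      count_class = "preGC", counted = TRUE, rule = "CD38:neg,lo")
  add("Naive CD5+ B-cells", "Naive B-cells", compartment = "preGC",
      count_class = "preGC", counted = TRUE, rule = "CD5:pos,hi",
      phenotype = c(bly, CD24 = "het", CD21 = "pos", IgM = "pos",
                    IgD = "hi", CD5 = "pos"))
  add("Naive CD5- B-cells", "Naive B-cells", compartment = "preGC",
      count_class = "preGC", counted = TRUE, rule = "CD5:neg,lo")
  add("Naive CD5- CD21+ B-cells", "Naive CD5- B-cells", compartment = "preGC",
      count_class = "preGC", counted = TRUE, rule = "CD21:pos,hi")
  add("Naive CD5- CD21- B-cells", "Naive CD5- B-cells", compartment = "preGC",
      count_class = "preGC", counted = TRUE, rule = "CD21:neg,lo")
  nbase <- c(bly, IgM = "pos", IgD = "hi")
  add("Naive CD5- CD21+ CD62L+ B-cells", "Naive CD5- CD21+ B-cells",
      compartment = "preGC", count_class = "preGC", counted = TRUE,
      rule = "CD62L:pos,hi",
      phenotype = c(nbase, CD21 = "pos", CD24 = "pos", CD62L = "pos"))
  add("Naive CD5- CD21+ CD62L- B-cells", "Naive CD5- CD21+ B-cells",
      compartment = "preGC", count_class = "preGC", counted = TRUE,
      rule = "CD62L:neg,lo",
      phenotype = c(nbase, CD21 = "pos", CD24 = "pos"))
  add("Naive CD5- CD21- CD24+ B-cells", "Naive CD5- CD21- B-cells",
      compartment = "preGC", count_class = "preGC", counted = TRUE,
      rule = "CD24:pos,hi",
      phenotype = c(nbase, CD24 = "pos"))
  add("Naive CD5- CD21- CD24- B-cells", "Naive CD5- CD21- B-cells",
      compartment = "preGC", count_class = "preGC", counted = TRUE,
      rule = "CD24:neg,lo",
      phenotype = nbase)

  ## --- memory B-cells (8 isotypes x 9 counted + 3 aggregates = 75) ---
  add("Memory B-cells", "B-lymphocytes",
      rule = "CD38:neg,lo&CD20:pos,hi&IgD:neg,lo,pos&CD5:neg,lo")
  mbase <- c(CD19 = "pos", CD45 = "hi", `FSC-A` = "lo", `SSC-A` = "lo")
  for (iso in ISOTYPES) {
    iso_node <- sprintf("MBC %s", iso)
    add(iso_node, "Memory B-cells", compartment = "MBC",
        count_class = "MBC", counted = TRUE, rule = iso_rule(iso))
    bA <- sprintf("MBC %s CD21+CD20+", iso)
    bB <- sprintf("MBC %s CD21-CD20++", iso)
    add(bA, iso_node, compartment = "MBC", count_class = "MBC",
        counted = TRUE, rule = "CD21:pos,hi")
    add(bB, iso_node, compartment = "MBC", count_class = "MBC",
        counted = TRUE, rule = "CD21:neg,lo")
    phA <- c(mbase, CD20 = "pos", CD21 = "pos", CD24 = "pos",
             iso_phenotype(iso))
    phB <- c(mbase, CD20 = "hi", iso_phenotype(iso))
    for (cd27 in c("-", "+")) {
      lv27 <- if (cd27 == "+") "pos" else "neg"
      add(sprintf("%s CD27%s", bA, cd27), bA, compartment = "MBC",
          count_class = "MBC", counted = TRUE,
          rule = sprintf("CD27:%s", if (cd27 == "+") "pos,hi" else "neg,lo"),
          phenotype = c(phA, CD27 = lv27))
      for (cd24 in c("-", "+")) {
        lv24 <- if (cd24 == "+") "pos" else "neg"
        add(sprintf("%s CD24%s CD27%s", bB, cd24, cd27), bB,
            compartment = "MBC", count_class = "MBC", counted = TRUE,
            rule = sprintf("CD24:%s&CD27:%s",
                           if (cd24 == "+") "pos,hi" else "neg,lo",
                           if (cd27 == "+") "pos,hi" else "neg,lo"),
            phenotype = c(phB, CD24 = lv24, CD27 = lv27))
      }
    }
  }
  add("IgG MBC", NA_character_, type = "aggregate", compartment = "aggregate",
      count_class = "MBC", counted = TRUE,
      members = paste(sprintf("MBC IgG%d", 1:4), collapse = "|"))
  add("IgA MBC", NA_character_, type = "aggregate", compartment = "aggregate",
      count_class = "MBC", counted = TRUE,
      members = paste(sprintf("MBC IgA%d", 1:2), collapse = "|"))
  add("Class-switched MBC", NA_character_, type = "aggregate",
      compartment = "aggregate", count_class = "MBC", counted = TRUE,
      members = paste(c(sprintf("MBC IgG%d", 1:4), sprintf("MBC IgA%d", 1:2)),
                      collapse = "|"))

  ## --- plasma cells: 3 maturation stages x 8 isotypes + 8 aggregates = 32 ---
  pc_stages <- c("CD20+CD138- PC", "CD20-CD138- PC", "CD20-CD138+ PC")
  pc_rules <- c("CD20:pos,hi&CD138:neg,lo", "CD20:neg,lo&CD138:neg,lo",
                "CD20:neg,lo&CD138:pos,hi")
  pc_ph <- list(c(CD20 = "pos"), character(0), c(CD138 = "pos"))
  pbase <- c(CD19 = "lo", CD45 = "lo", CD38 = "hi", `FSC-A` = "pos",
             `SSC-A` = "pos")
  for (s in seq_along(pc_stages)) {
    add(pc_stages[s], "Plasma cells", rule = pc_rules[s])
    for (iso in ISOTYPES) {
      add(sprintf("%s %s", pc_stages[s], iso), pc_stages[s],
          compartment = "PC", count_class = "PC", counted = TRUE,
          rule = iso_rule(iso),
          phenotype = c(pbase, pc_ph[[s]], iso_phenotype(iso)))
    }
  }
  for (iso in ISOTYPES) {
    add(sprintf("%s PC", iso), NA_character_, type = "aggregate",
        compartment = "aggregate", count_class = "PC", counted = TRUE,
        members = paste(sprintf("%s %s", pc_stages, iso), collapse = "|"))
  }

  ## acquisition artifacts (kept outside the gating tree)
  add("Doublets", NA_character_, compartment = "artifact")
  add("Debris", NA_character_, compartment = "artifact",
      phenotype = c(`FSC-A` = "neg", `SSC-A` = "neg", CD45 = "neg"))

  do.call(rbind, rows)
}

default_controls <- function() {
  mk <- agi_markers()
  pos <- c(CD19 = "Naive CD5- B-cells", CD45 = "CD5+ T-cells",
           CD38 = "Immature B-cells", CD20 = "Naive CD5- B-cells",
           CD24 = "Neutrophils", CD21 = "Naive CD5- CD21+ B-cells",
           CD27 = "Eosinophils", CD5 = "CD5+ T-cells",
           CD62L = "Naive CD5- CD21+ CD62L+ B-cells",
           CD138 = "CD20-CD138+ PC",
           IgM = "Naive CD5- B-cells", IgD = "Naive CD5- B-cells",
           IgG1 = "MBC IgG1", IgG2 = "MBC IgG2", IgG3 = "MBC IgG3",
           IgG4 = "MBC IgG4", IgA1 = "MBC IgA1", IgA2 = "MBC IgA2")
  neg <- stats::setNames(rep("CD5+ T-cells", length(mk)), mk)
  neg["CD5"] <- "CD5- NK-cells"
  neg["CD62L"] <- "CD5- NK-cells"
  neg["CD45"] <- "Debris"
  data.frame(marker = mk, pos_pop = pos[mk], neg_pop = neg[mk],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The default B-cell / plasma-cell population taxonomy
#'
#' Builds the shipped gating hierarchy: 6 major non-B leukocyte populations,
#' 10 counted pre-germinal-centre subsets, 75 counted memory-B subsets and
#' 32 counted plasma-cell subsets (117 B + PC in total, 123 overall), plus
#' doublet and debris artifact labels.
#'
#' @param breakpoints Per-marker level breakpoints, see
#'   [default_breakpoints()].
#' @return An object of class `agiflow_taxonomy`.
#' @export
default_taxonomy <- function(breakpoints = default_breakpoints()) {
  new_taxonomy(build_default_nodes(), breakpoints)
}

new_taxonomy <- function(nodes, breakpoints = default_breakpoints()) {
  nodes$rule_parsed <- lapply(nodes$rule, parse_rule)
  nodes$phenotype_parsed <- lapply(nodes$phenotype, parse_phenotype)
  nodes$members_parsed <- lapply(nodes$members, function(m)
    if (nchar(m)) strsplit(m, "|", fixed = TRUE)[[1]] else character(0))
  tax <- structure(list(nodes = nodes, breakpoints = breakpoints,
                        controls = default_controls(),
                        doublet_ratio = 1.5, debris_fsc = 0.4),
                   class = "agiflow_taxonomy")
  validate_taxonomy(tax)
}

validate_taxonomy <- function(tax) {
  nd <- tax$nodes
  tree <- nd[nd$type == "node" & nd$compartment != "artifact", ]
  roots <- tree$name[is.na(tree$parent)]
  if (length(roots) != 1L)
    stop_agi("agiflow_taxonomy_error", "taxonomy must have exactly one root")
  known <- c(agi_markers(), "FSC-A", "FSC-H", "SSC-A")
  for (i in seq_len(nrow(nd))) {
    mk <- rule_markers(nd$rule_parsed[[i]])
    bad <- setdiff(mk, known)
    if (length(bad))
      stop_agi("agiflow_config_error", "node '%s' uses unknown marker '%s'",
               nd$name[i], bad[1])
    if (!is.na(nd$parent[i]) && !nd$parent[i] %in% nd$name)
      stop_agi("agiflow_taxonomy_error", "unknown parent '%s'", nd$parent[i])
  }
  ## sibling rules must be pairwise disjoint on at least one shared marker
  for (p in unique(stats::na.omit(tree$parent))) {
    sibs <- tree[!is.na(tree$parent) & tree$parent == p, ]
    if (nrow(sibs) < 2) next
    for (i in seq_len(nrow(sibs) - 1)) for (j in (i + 1):nrow(sibs)) {
      if (!rules_disjoint(sibs$rule_parsed[[i]], sibs$rule_parsed[[j]]))
        stop_agi("agiflow_taxonomy_error",
                 "sibling rules overlap: '%s' vs '%s'",
                 sibs$name[i], sibs$name[j])
    }
  }
  ## aggregates must reference known nodes
  for (i in which(nd$type == "aggregate")) {
    bad <- setdiff(nd$members_parsed[[i]], nd$name)
    if (length(bad))
      stop_agi("agiflow_taxonomy_error",
               "aggregate '%s' references unknown member '%s'",
               nd$name[i], bad[1])
  }
  tax
}

#' @export
print.agiflow_taxonomy <- function(x, ...) {
  cat(sprintf(paste0("<agiflow_taxonomy> %d nodes; counted subsets: ",
                     "B+PC %d (PC %d, B %d), total %d\n"),
              nrow(x$nodes), count_subsets(x, "B+PC"), count_subsets(x, "PC"),
              count_subsets(x, "B"), count_subsets(x, "all")))
  invisible(x)
}

## ---- config file round trip ----------------------------------------------

#' Write / load a taxonomy configuration file
#'
#' One node per line, tab-separated: name, parent, type, compartment,
#' count class, counted flag, rule, phenotype, aggregate members.
#'
#' @param tax An `agiflow_taxonomy`.
#' @param path File path; [load_taxonomy()] defaults to the shipped
#'   configuration reproducing the default hierarchy.
#' @return `load_taxonomy()` returns a validated `agiflow_taxonomy`.
#' @export
write_taxonomy <- function(tax, path) {
  cols <- c("name", "parent", "type", "compartment", "count_class",
            "counted", "rule", "phenotype", "members")
  data.table::fwrite(tax$nodes[, cols], path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @param breakpoints Breakpoints table to attach.
#' @export
load_taxonomy <- function(path = system.file("extdata",
                            "bigh_imm_taxonomy.tsv", package = "agiflow"),
                          breakpoints = default_breakpoints()) {
  nd <- as.data.frame(data.table::fread(path, sep = "\t",
                                        na.strings = c("NA", "")))
  need <- c("name", "parent", "type", "compartment", "count_class",
            "counted", "rule", "phenotype", "members")
  miss <- setdiff(need, names(nd))
  if (length(miss))
    stop_agi("agiflow_config_error", "taxonomy config missing column '%s'",
             miss[1])
  for (ch in c("rule", "phenotype", "members"))
    nd[[ch]][is.na(nd[[ch]])] <- ""
  nd$counted <- as.logical(nd$counted)
  new_taxonomy(nd, breakpoints)
}

## ---- counting -------------------------------------------------------------

#' Count taxonomy subsets by compartment
#'
#' Applies the shipped counting convention: a subset is any node or
#' aggregate flagged as counted.  `"B"` covers pre-GC plus memory
#' B-lymphocyte subsets (85), `"PC"` the plasma-cell subsets (32),
#' `"B+PC"` their union (117), and `"all"` additionally the 6 major non-B
#' populations (123).
#'
#' @param tax An `agiflow_taxonomy`.
#' @param compartment One of `"B+PC"`, `"B"`, `"PC"`, `"preGC"`, `"MBC"`,
#'   `"nonB"`, `"all"`.
#' @return Integer count.
#' @export
count_subsets <- function(tax, compartment = "B+PC") {
  cls <- switch(compartment,
    "B+PC" = c("preGC", "MBC", "PC"),
    "B" = c("preGC", "MBC"),
    "PC" = "PC", "preGC" = "preGC", "MBC" = "MBC", "nonB" = "nonB",
    "all" = c("preGC", "MBC", "PC", "nonB"),
    stop_agi("agiflow_value_error", "unknown compartment '%s'", compartment))
  sum(tax$nodes$counted & tax$nodes$count_class %in% cls, na.rm = TRUE)
}

#' Quantifiability rule for a population
#'
#' A subset is quantifiable when more than 50 cells are identified, except
#' plasma-cell subsets which require more than 20.
#'
#' @param tax Taxonomy (used to look the population's compartment up), or
#'   `NULL` if `is_pc` is given directly.
#' @param population Population name.
#' @param count Observed cell count.
#' @param is_pc Directly state whether the population is a PC subset.
#' @return Logical.
#' @export
is_quantifiable <- function(count, population = NULL, tax = NULL,
                            is_pc = FALSE) {
  if (!is.null(tax) && !is.null(population)) {
    i <- match(population, tax$nodes$name)
    if (is.na(i))
      stop_agi("agiflow_value_error", "unknown population '%s'", population)
    is_pc <- identical(tax$nodes$count_class[i], "PC")
  }
  count > min_quantifiable(is_pc)
}

min_quantifiable <- function(is_pc) ifelse(is_pc, 20L, 50L)

## ---- tree helpers ---------------------------------------------------------

tax_children <- function(tax, name) {
  nd <- tax$nodes
  nd$name[nd$type == "node" & !is.na(nd$parent) & nd$parent == name]
}

tax_root <- function(tax) {
  nd <- tax$nodes
  nd$name[nd$type == "node" & is.na(nd$parent) &
          nd$compartment != "artifact"][1]
}

#' @keywords internal
tax_subtree <- function(tax, name) {
  out <- name
  todo <- tax_children(tax, name)
  while (length(todo)) {
    out <- c(out, todo)
    todo <- unlist(lapply(todo, tax_children, tax = tax))
  }
  out
}

tax_leaves <- function(tax, below = tax_root(tax)) {
  sub <- tax_subtree(tax, below)
  sub[vapply(sub, function(n) length(tax_children(tax, n)) == 0L, logical(1))]
}

tax_ancestors <- function(tax, name) {
  nd <- tax$nodes
  out <- character(0)
  cur <- nd$parent[match(name, nd$name)]
  while (!is.na(cur)) {
    out <- c(cur, out)
    cur <- nd$parent[match(cur, nd$name)]
  }
  out
}

## expand an aggregate or node to the set of tree labels it covers
node_label_set <- function(tax, name) {
  i <- match(name, tax$nodes$name)
  if (is.na(i)) stop_agi("agiflow_value_error", "unknown population '%s'", name)
  if (tax$nodes$type[i] == "aggregate")
    unique(unlist(lapply(tax$nodes$members_parsed[[i]],
                         node_label_set, tax = tax)))
  else tax_subtree(tax, name)
}

## phenotype level of a population for one marker ("neg" default; "mixed"
## when member leaves disagree)
pop_phenotype_level <- function(tax, name, marker) {
  leaves <- intersect(node_label_set(tax, name), tax_leaf_cache(tax))
  if (!length(leaves)) leaves <- name
  lv <- vapply(leaves, function(l) {
    ph <- tax$nodes$phenotype_parsed[[match(l, tax$nodes$name)]]
    if (marker %in% names(ph)) ph[[marker]] else "neg"
  }, "")
  u <- unique(lv)
  if (length(u) == 1L) u else "mixed"
}

tax_leaf_cache <- function(tax) {
  c(tax_leaves(tax), tax$nodes$name[tax$nodes$compartment == "artifact"])
}

## ---- Boolean gating -------------------------------------------------------

eval_term <- function(x, marker, levels, bp) {
  row <- bp[bp$marker == marker, ]
  if (!nrow(row))
    stop_agi("agiflow_config_error", "no breakpoints for marker '%s'", marker)
  bands <- unique(unlist(level_band_sets[levels]))
  band_of(x, row) %in% bands
}

eval_clause <- function(vals, clause, bp) {
  ok <- rep(TRUE, nrow(vals))
  for (m in names(clause)) {
    if (!m %in% colnames(vals))
      stop_agi("agiflow_taxonomy_coverage",
               "marker '%s' required by the taxonomy is absent", m)
    ok <- ok & eval_term(vals[, m], m, clause[[m]], bp)
    if (!any(ok)) break
  }
  ok
}

eval_rule <- function(vals, rule, bp) {
  if (!length(rule)) return(rep(TRUE, nrow(vals)))
  ok <- rep(FALSE, nrow(vals))
  for (cl in rule) ok <- ok | eval_clause(vals, cl, bp)
  ok
}

#' Identify doublets and debris
#'
#' Doublets: forward-scatter area/height ratio above `tax$doublet_ratio`
#' (default 1.5).  Debris: forward-scatter area below `tax$debris_fsc`
#' transformed units and CD45 negative.
#'
#' @param em Transformed [event_matrix()].
#' @param tax Taxonomy (carries the thresholds).
#' @return List with logical vectors `doublet` and `debris`.
#' @export
flag_artifacts <- function(em, tax) {
  fsca <- em_col(em, "FSC-A")
  fsch <- em_col(em, "FSC-H")
  ratio <- fsca / pmax(fsch, 1e-9)
  doublet <- ratio > tax$doublet_ratio
  cd45 <- em_col(em, "CD45")
  bp45 <- tax$breakpoints[tax$breakpoints$marker == "CD45", ]
  debris <- !doublet & fsca < tax$debris_fsc & cd45 < bp45$b1
  list(doublet = doublet, debris = debris)
}

#' Boolean (manual-style) gating of an event matrix
#'
#' Reproduces expert sequential Boolean gating: after doublet and debris
#' exclusion, every event is assigned the deepest taxonomy node whose full
#' ancestor rule chain it satisfies; events matching no child rule at an
#' internal node are retained at that node.
#'
#' @param em Transformed [event_matrix()].
#' @param tax An `agiflow_taxonomy`.
#' @return An `agiflow_result` (see [population_counts()]).
#' @export
boolean_gate <- function(em, tax) {
  stopifnot(inherits(em, "agiflow_events"))
  if (em$stage != "transformed")
    stop_agi("agiflow_stage_error", "boolean_gate expects transformed events")
  vals <- em$values
  n <- nrow(vals)
  labels <- rep(tax_root(tax), n)
  art <- flag_artifacts(em, tax)
  labels[art$doublet] <- "Doublets"
  labels[art$debris] <- "Debris"
  active <- which(!art$doublet & !art$debris)
  bp <- tax$breakpoints
  recurse <- function(node, idx) {
    kids <- tax_children(tax, node)
    if (!length(kids) || !length(idx)) return()
    taken <- rep(FALSE, length(idx))
    for (k in kids) {
      rule <- tax$nodes$rule_parsed[[match(k, tax$nodes$name)]]
      hit <- eval_rule(vals[idx, , drop = FALSE], rule, bp)
      hit <- hit & !taken
      if (any(hit)) {
        labels[idx[hit]] <<- k
        recurse(k, idx[hit])
      }
      taken <- taken | hit
    }
  }
  recurse(tax_root(tax), active)
  new_result(labels, tax, provenance = rep("boolean_gate", n))
}

## ---- results container ----------------------------------------------------

new_result <- function(labels, tax, provenance = NULL) {
  structure(list(labels = labels, provenance = provenance,
                 counts = population_counts(labels, tax),
                 taxonomy_hash = length(tax$nodes$name)),
            class = "agiflow_result")
}

#' @export
print.agiflow_result <- function(x, ...) {
  cat(sprintf("<agiflow_result> %d events, %d populations with events\n",
              length(x$labels), sum(x$counts$n > 0)))
  invisible(x)
}

#' Per-population counts and frequencies
#'
#' Counts events per counted subset (internal subsets accumulate their whole
#' subtree; aggregates sum their members) and reports each as a percentage
#' of all leukocytes (events that are neither doublets nor debris).
#'
#' @param labels Character vector of per-event deepest labels.
#' @param tax Taxonomy.
#' @return `data.table` with columns `population`, `count_class`, `n`,
#'   `pct_leukocytes`, `quantifiable`.
#' @export
population_counts <- function(labels, tax) {
  nd <- tax$nodes
  tab <- table(factor(labels, levels = nd$name))
  n_leuk <- sum(tab) - tab["Doublets"] - tab["Debris"]
  subtree_n <- function(name) sum(tab[node_label_set(tax, name)])
  rows <- nd[nd$counted | nd$compartment == "artifact" |
             nd$name %in% c(tax_root(tax), "B-cells", "B-lymphocytes",
                            "Plasma cells", "Pre-GC B-cells",
                            "Memory B-cells"), ]
  cnt <- vapply(rows$name, subtree_n, numeric(1))
  out <- data.table::data.table(
    population = rows$name,
    count_class = rows$count_class,
    counted = rows$counted,
    n = as.numeric(cnt),
    pct_leukocytes = 100 * as.numeric(cnt) / max(as.numeric(n_leuk), 1)
  )
  out$quantifiable <- out$n > min_quantifiable(
    !is.na(out$count_class) & out$count_class == "PC")
  out[]
}
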