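test_that("shipped default taxonomy loads and matches the in-code builder", {
  path <- system.file("extdata", "bigh_imm_taxonomy.tsv", package = "agiflow")
  expect_true(nchar(path) > 0)
  tax <- load_taxonomy(path)
  ref <- fx_tax()
  expect_identical(tax$nodes$name, ref$nodes$name)
  expect_identical(tax$nodes$rule, ref$nodes$rule)
  expect_identical(count_subsets(tax, "all"), count_subsets(ref, "all"))
})

test_that("subset tallies follow the counting convention", {
  tax <- fx_tax()
  expect_identical(count_subsets(tax, "B+PC"), 117L)
  expect_identical(count_subsets(tax, "PC"), 32L)
  expect_identical(count_subsets(tax, "B"), 85L)
  expect_identical(count_subsets(tax, "preGC"), 10L)
  expect_identical(count_subsets(tax, "MBC"), 75L)
  expect_identical(count_subsets(tax, "nonB"), 6L)
  expect_identical(count_subsets(tax, "all"), 123L)
  ## arithmetic: PC + B = B+PC
  expect_identical(count_subsets(tax, "PC") + count_subsets(tax, "B"),
                   count_subsets(tax, "B+PC"))
  expect_error(count_subsets(tax, "nope"), class = "agiflow_value_error")
})

test_that("overlapping sibling rules are rejected at load", {
  nodes <- agiflow:::build_default_nodes()
  i <- which(nodes$name == "CD5- NK-cells")
  nodes$rule[i] <- nodes$rule[which(nodes$name == "CD5+ T-cells")]
  expect_error(agiflow:::new_taxonomy(nodes),
               "CD5", class = "agiflow_taxonomy_error")
  ## unknown marker in a rule
  nodes2 <- agiflow:::build_default_nodes()
  nodes2$rule[nodes2$name == "Neutrophils"] <- "CD99:pos"
  expect_error(agiflow:::new_taxonomy(nodes2),
               class = "agiflow_config_error")
})

test_that("a minimal 3-node tree loads and counts 2 leaves", {
  nodes <- rbind(
    agiflow:::node_row("Leukocytes", NA_character_),
    agiflow:::node_row("A", "Leukocytes", compartment = "nonB",
                       count_class = "nonB", counted = TRUE,
                       rule = "CD19:pos,hi"),
    agiflow:::node_row("B", "Leukocytes", compartment = "nonB",
                       count_class = "nonB", counted = TRUE,
                       rule = "CD19:neg,lo"))
  tax <- agiflow:::new_taxonomy(nodes)
  expect_identical(count_subsets(tax, "all"), 2L)
})

test_that("boolean gating recovers planted labels and known phenotypes", {
  tax <- fx_tax()
  sim <- fx_sample(n = 5e4, seed = 7)
  res <- boolean_gate(sim$em_t, tax)

  ## an event planted exactly at the naive CD5+ template location gates
  ## to the naive CD5+ leaf
  tpl <- fx_model()$templates[["Naive CD5+ B-cells"]]
  loc <- tpl$loc
  loc[tpl$het] <- 2.2
  em1 <- event_matrix(rbind(loc), stage = "raw")
  em1$stage <- "transformed"
  expect_identical(boolean_gate(em1, tax)$labels, "Naive CD5+ B-cells")

  ## FSC-A/FSC-H ratio 2 is excluded as a doublet before any rule
  loc2 <- loc; loc2["FSC-A"] <- 2 * loc2["FSC-H"]
  em2 <- event_matrix(rbind(loc2), stage = "raw")
  em2$stage <- "transformed"
  expect_identical(boolean_gate(em2, tax)$labels, "Doublets")

  ## >= 95% per-event recovery over quantifiable planted populations
  qp <- quantifiable_truth_pops(sim$truth)
  inq <- sim$truth %in% qp
  expect_gt(mean(res$labels[inq] == sim$truth[inq]), 0.95)

  ## idempotence
  res2 <- boolean_gate(sim$em_t, tax)
  expect_identical(res$labels, res2$labels)
})

test_that("gate counts are conserved and exclusive", {
  tax <- fx_tax()
  sim <- fx_sample(n = 5e4, seed = 7)
  res <- boolean_gate(sim$em_t, tax)
  lab <- res$labels
  ## every event exactly one label
  expect_identical(length(lab), nrow(sim$em_t$values))
  ## parent count = sum of child subtree counts + events retained at node
  tab <- table(factor(lab, levels = tax$nodes$name))
  for (node in c("Leukocytes", "B-cells", "B-lymphocytes",
                 "Memory B-cells")) {
    kids <- agiflow:::tax_children(tax, node)
    kid_n <- sum(vapply(kids, function(k)
      sum(tab[agiflow:::tax_subtree(tax, k)]), numeric(1)))
    node_n <- sum(tab[agiflow:::tax_subtree(tax, node)])
    expect_equal(unname(node_n), unname(kid_n + tab[[node]]))
  }
  ## totals: root subtree + doublets + debris = all events
  expect_equal(
    sum(tab[agiflow:::tax_subtree(tax, "Leukocytes")]) +
      tab[["Doublets"]] + tab[["Debris"]],
    length(lab))
})

test_that("quantifiability thresholds are >50 cells (>20 for PC subsets)", {
  tax <- fx_tax()
  mbc <- "MBC IgG1 CD21+CD20+ CD27+"
  pc <- "CD20-CD138+ PC IgG1"
  expect_true(is_quantifiable(51, mbc, tax))
  expect_false(is_quantifiable(50, mbc, tax))
  expect_true(is_quantifiable(21, pc, tax))
  expect_false(is_quantifiable(20, pc, tax))
  expect_false(is_quantifiable(0, mbc, tax))
  expect_false(is_quantifiable(0, pc, tax))
})
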