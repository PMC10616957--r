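# agiflow

Automated database-guided gating and identification (AGI) of human blood
B-lymphocyte and plasma-cell (PC) populations from multiparameter flow
cytometry, with the full supporting workflow: event-file I/O, datafile
quality control, a Boolean-gating population taxonomy, reference-database
construction, two AGI algorithms (flat two-step and hierarchical
multi-step), a synthetic whole-blood simulator with planted ground truth,
and method-comparison statistics.

## Who this is for

Computational immunologists and cytometry bioinformaticians who want a
reproducible, scriptable alternative to expert manual gating for the
in-depth dissection of the B-cell compartment (117 B-lymphocyte + PC
subsets; 123 blood populations overall) measured with an 18-marker
immune-monitoring panel — and a fully synthetic test bed for developing
and validating database-guided classification methods.

## The method in brief

Events are compensated (right-multiplication by the inverse spillover
matrix) and transformed (`asinh(x/150)` for fluorescence, linear scaling
for scatter). Classification proceeds in two steps:

1. **Clustering** — per-event density is `1 / (mean Euclidean distance to
   the K = 10 nearest neighbours)`; events link to their highest-density
   neighbour, link-free events are mode apices, and modes are merged while
   their separation `20·(1 − saddle/min(peak))` falls below 0.9 on a 0–20
   scale.
2. **Classification** — each cluster is compared against reference
   population templates (median location, shrinkage covariance) by
   Mahalanobis ranking and pairwise 2-D canonical (linear-discriminant)
   planes with a 2-SD ellipse acceptance rule.

The hierarchical algorithm applies this machinery stage by stage (major
leukocyte populations → B-cell compartment → maturation stages within
pre-GC B cells and PC via a trajectory classifier → per-branch subset
refinement), with per-event provenance. The reference database is built
iteratively: gate one file, classify the next against the database, merge,
repeat; a leave-one-file-out canonical/principal-component projection
check guards its internal consistency.

## Worked example

```r
library(agiflow)

tax   <- default_taxonomy()
model <- default_panel_model(tax)

## simulate a training file, gate it, initialise the reference database
train <- simulate_sample(model, sample_spec(n_events = 1e5, seed = 1))
em    <- prepare_events(train$em, train$spill)
db    <- init_database(em, boolean_gate(em, tax)$labels, tax, "train1")

## classify an independent sample hierarchically
test  <- simulate_sample(model, sample_spec(n_events = 1e5, seed = 2))
emt   <- prepare_events(test$em, test$spill)
res   <- hierarchical_classify(emt, db, seed = 7)

mean(res$labels == test$truth)
#> [1] 0.98795

subset(res$counts, population %in%
       c("B-lymphocytes", "Plasma cells", "Naive CD5+ B-cells"))
#>            population count_class counted     n pct_leukocytes quantifiable
#>                <char>      <char>  <lgcl> <num>          <num>       <lgcl>
#> 1:       Plasma cells        <NA>   FALSE    50     0.05209364        FALSE
#> 2:      B-lymphocytes        <NA>   FALSE  4740     4.93847741         TRUE
#> 3: Naive CD5+ B-cells       preGC    TRUE    86     0.08960107         TRUE
```

98.8% of events recover their planted leaf label; total B-lymphocytes
come out at ~4.9% of leukocytes and PC at ~0.05%, matching the blood
medians the simulator is calibrated to (PC, at 50 events here, sits
right at the quantifiability boundary for a 10^5-event sample). The
numbers above are the output of the exact calls shown.

`count_subsets(tax, "B+PC")` returns 117 (32 PC + 85 B-lymphocyte
subsets); `taxonomy-report` on the command line prints the same tallies.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/agiflow simulate --out s1.csv --n 100000 --seed 1
Rscript inst/cli/agiflow qc --in s1.csv --min-b-singlets 2000
Rscript inst/cli/agiflow build-db --in s1.csv --out dbdir
Rscript inst/cli/agiflow classify --in s2.csv --db dbdir --out counts.csv
```

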