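## Panel description: the 18-marker B-cell / plasma-cell immune-monitoring
## antibody combination plus light scatter and acquisition time.

#' Marker names of the B-cell immune-monitoring panel
#'
#' The 18 antibody markers measured by the panel, in canonical order.
#' @return Character vector of length 18.
#' @export
agi_markers <- function() {
  c("CD19", "CD45", "CD38", "CD20", "CD24", "CD21", "CD27", "CD5",
    "CD62L", "CD138", "IgM", "IgD", "IgG1", "IgG2", "IgG3", "IgG4",
    "IgA1", "IgA2")
}

#' Default acquisition panel
#'
#' Describes every acquired channel: detector name, the marker it reports,
#' and its kind (scatter, fluorescence or time).  The default maps each of
#' the 18 markers to its own fluorescence detector and adds FSC-A, FSC-H,
#' SSC-A and Time.
#'
#' @return A `data.frame` with columns `detector`, `marker`, `kind`.
#' @export
default_panel <- function() {
  fl <- agi_markers()
  data.frame(
    detector = c("FSC-A", "FSC-H", "SSC-A",
                 sprintf("FL%02d-A", seq_along(fl)), "TIME"),
    marker = c("FSC-A", "FSC-H", "SSC-A", fl, "Time"),
    kind = c("scatter", "scatter", "scatter",
             rep("fluorescence", length(fl)), "time"),
    stringsAsFactors = FALSE
  )
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("detector", "marker", "kind") %in% names(panel)))
  if (anyDuplicated(panel$marker))
    stop_agi("agiflow_panel_error", "duplicate marker names in panel")
  if (sum(panel$kind == "time") > 1L)
    stop_agi("agiflow_panel_error", "panel declares more than one time channel")
  invisible(panel)
}

fluor_markers <- function(panel) panel$marker[panel$kind == "fluorescence"]
scatter_markers <- function(panel) panel$marker[panel$kind == "scatter"]
time_marker <- function(panel) {
  m <- panel$marker[panel$kind == "time"]
  if (length(m)) m else NULL
}

#' Construct an event matrix
#'
#' The uniform event container used throughout the package: an events x
#' channels numeric matrix with channel metadata and a processing stage.
#'
#' @param values Numeric matrix, one row per event; columns named by marker.
#' @param panel Panel data frame (see [default_panel()]); subset to the
#'   columns present in `values`.
#' @param stage One of `"raw"`, `"compensated"`, `"transformed"`.
#' @param sample_id Sample identifier stored with the matrix.
#' @return An object of class `agiflow_events`.
#' @export
event_matrix <- function(values, panel = default_panel(),
                         stage = c("raw", "compensated", "transformed"),
                         sample_id = "sample") {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (anyNA(values))
    stop_agi("agiflow_value_error", "event matrix contains missing values")
  validate_panel(panel)
  miss <- setdiff(colnames(values), panel$marker)
  if (length(miss))
    stop_agi("agiflow_panel_mismatch",
             "channel(s) not in panel: %s", paste(miss, collapse = ", "))
  panel <- panel[match(colnames(values), panel$marker), , drop = FALSE]
  structure(list(values = values, panel = panel, stage = stage,
                 sample_id = sample_id),
            class = "agiflow_events")
}

#' @export
print.agiflow_events <- function(x, ...) {
  cat(sprintf("<agiflow_events> %s: %d events x %d channels (stage: %s)\n",
              x$sample_id, nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.agiflow_events <- function(x) dim(x$values)

n_events <- function(em) nrow(em$values)

em_col <- function(em, marker) {
  if (!marker %in% colnames(em$values))
    stop_agi("agiflow_taxonomy_coverage",
             "required channel '%s' absent from event matrix", marker)
  em$values[, marker]
}
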