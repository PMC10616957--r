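## Event-data input/output: minimal FCS 3.1 list-mode reader/writer, a CSV
## dialect, spillover compensation and display transforms.
##
## The FCS support is intentionally small: one dataset per file, list mode,
## single-precision float data ($DATATYPE/F, with /D accepted on read),
## little- or big-endian byte order.  That covers files written by this
## package and plainly-structured instrument exports.

FCS_PAD <- 12L  # fixed width for offset keywords so TEXT length is stable

#' Write events to an FCS 3.1 or CSV file
#'
#' The output format follows the file extension: `.fcs` writes a minimal
#' FCS 3.1 list-mode file with float32 data; anything else writes the CSV
#' dialect (header of detector names, one row per event, "." decimal
#' separator).  Optional per-event labels are stored as one extra integer
#' channel (`LABEL`) with the integer-to-name dictionary in the metadata.
#'
#' @param em An [event_matrix()].
#' @param path Output path.
#' @param labels Optional character vector, one label per event.
#' @return `path`, invisibly.
#' @export
write_events <- function(em, path, labels = NULL) {
  stopifnot(inherits(em, "agiflow_events"))
  if (!is.null(labels) && length(labels) != n_events(em))
    stop_agi("agiflow_value_error", "labels length != event count")
  dir.ok <- dir.exists(dirname(path))
  if (!dir.ok) stop_agi("agiflow_io_error", "unwritable path: %s", path)
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    write_fcs(em, path, labels)
  } else {
    write_events_csv(em, path, labels)
  }
  invisible(path)
}

#' Read events from an FCS or CSV file
#'
#' Channels are resolved against `panel` by detector name first, then by
#' marker name; an unresolvable channel raises a panel-mismatch error naming
#' it.  Event order is preserved as stored.
#'
#' @param path Input path (FCS 3.x, or the package's CSV dialect).
#' @param panel Panel data frame, see [default_panel()].
#' @return An [event_matrix()]; if the file carries a label channel, the
#'   decoded labels are attached as attribute `"labels"`.
#' @export
read_events <- function(path, panel = default_panel()) {
  if (!file.exists(path)) stop_agi("agiflow_io_error", "no such file: %s", path)
  magic <- readBin(path, "raw", n = 3L)
  if (identical(rawToChar(magic), "FCS")) read_fcs(path, panel)
  else read_events_csv(path, panel)
}

resolve_channels <- function(chan_names, panel, markers = NULL) {
  ## detector or marker name -> marker; error on unknowns
  out <- character(length(chan_names))
  for (i in seq_along(chan_names)) {
    nm <- chan_names[i]
    j <- match(nm, panel$detector)
    if (is.na(j)) j <- match(nm, panel$marker)
    if (!is.na(j)) { out[i] <- panel$marker[j]; next }
    if (!is.null(markers) && nm %in% markers) { out[i] <- nm; next }
    if (nm == "LABEL") { out[i] <- "LABEL"; next }
    stop_agi("agiflow_panel_mismatch",
             "channel '%s' cannot be resolved against the panel", nm)
  }
  out
}

## ---- CSV dialect ----------------------------------------------------------

write_events_csv <- function(em, path, labels = NULL) {
  hdr <- em$panel$detector
  dt <- data.table::as.data.table(em$values)
  data.table::setnames(dt, hdr)
  meta <- sprintf("#agiflow stage=%s sample_id=%s", em$stage, em$sample_id)
  lines <- meta
  if (!is.null(labels)) {
    dict <- sort(unique(labels))
    dt[, LABEL := match(labels, dict)]
    lines <- c(lines, paste0("#labels ", paste(sprintf("%d:%s",
      seq_along(dict), dict), collapse = "|")))
  }
  con <- file(path, "w")
  writeLines(lines, con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE, dec = ".")
}

read_events_csv <- function(path, panel) {
  hdr <- readLines(path, n = 5L)
  meta <- grep("^#", hdr, value = TRUE)
  stage <- "raw"; sample_id <- basename(path); dict <- NULL
  m <- grep("^#agiflow ", meta, value = TRUE)
  if (length(m)) {
    stage <- sub(".*stage=(\\S+).*", "\\1", m[1])
    sample_id <- sub(".*sample_id=(\\S+).*", "\\1", m[1])
  }
  l <- grep("^#labels ", meta, value = TRUE)
  if (length(l)) {
    ent <- strsplit(sub("^#labels ", "", l[1]), "|", fixed = TRUE)[[1]]
    dict <- sub("^[0-9]+:", "", ent)
  }
  dt <- data.table::fread(path, skip = length(meta), header = TRUE, dec = ".")
  if (!nrow(dt) && !ncol(dt))
    stop_agi("agiflow_parse_error", "empty or truncated CSV file: %s", path)
  markers <- resolve_channels(names(dt), panel)
  labels <- NULL
  if ("LABEL" %in% markers) {
    li <- which(markers == "LABEL")
    labels <- if (is.null(dict)) as.character(dt[[li]]) else dict[dt[[li]]]
    dt <- dt[, -li, with = FALSE]
    markers <- markers[-li]
  }
  vals <- as.matrix(dt)
  colnames(vals) <- markers
  em <- event_matrix(vals, panel, stage = stage, sample_id = sample_id)
  if (!is.null(labels)) attr(em, "labels") <- labels
  em
}

## ---- minimal FCS 3.1 ------------------------------------------------------

write_fcs <- function(em, path, labels = NULL) {
  vals <- em$values
  dict <- NULL
  if (!is.null(labels)) {
    dict <- sort(unique(labels))
    vals <- cbind(vals, LABEL = match(labels, dict))
  }
  npar <- ncol(vals); ntot <- nrow(vals)
  detectors <- c(em$panel$detector, if (!is.null(labels)) "LABEL")
  markers <- c(em$panel$marker, if (!is.null(labels)) "LABEL")
  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = strrep("0", FCS_PAD), "$ENDDATA" = strrep("0", FCS_PAD),
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(npar), "$TOT" = as.character(ntot),
    "AGIFLOWSTAGE" = em$stage, "AGIFLOWSAMPLE" = em$sample_id
  )
  if (!is.null(dict))
    kv <- c(kv, AGIFLOWLABELS = paste(sprintf("%d:%s", seq_along(dict), dict),
                                      collapse = "|"))
  for (i in seq_len(npar)) {
    kv[sprintf("$P%dN", i)] <- detectors[i]
    kv[sprintf("$P%dS", i)] <- markers[i]
    kv[sprintf("$P%dB", i)] <- "32"
    kv[sprintf("$P%dE", i)] <- "0,0"
    kv[sprintf("$P%dR", i)] <- "262144"
  }
  text_body <- paste0("/", paste(names(kv), unname(kv), sep = "/",
                                 collapse = "/"), "/")
  text_begin <- 58L
  text_end <- text_begin + nchar(text_body) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * npar * ntot - 1L
  if (ntot == 0L) { data_begin <- 0L; data_end <- 0L }
  pad <- function(x) formatC(x, width = FCS_PAD, flag = "0")
  text_body <- sub(paste0("/\\$BEGINDATA/", strrep("0", FCS_PAD)),
                   paste0("/$BEGINDATA/", pad(data_begin)), text_body)
  text_body <- sub(paste0("/\\$ENDDATA/", strrep("0", FCS_PAD)),
                   paste0("/$ENDDATA/", pad(data_end)), text_body)
  hdr8 <- function(x) formatC(x, width = 8L)
  header <- paste0("FCS3.1    ", hdr8(text_begin), hdr8(text_end),
                   hdr8(if (data_end <= 99999999) data_begin else 0),
                   hdr8(if (data_end <= 99999999) data_end else 0),
                   hdr8(0), hdr8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_body, con, eos = NULL)
  if (ntot > 0L)
    writeBin(as.vector(t(vals)), con, size = 4L, endian = "little")
  invisible(path)
}

read_fcs <- function(path, panel) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header) < 58L)
    stop_agi("agiflow_parse_error", "truncated FCS header: %s", path)
  version <- substr(header, 1, 6)
  if (!startsWith(version, "FCS3"))
    stop_agi("agiflow_parse_error", "unsupported FCS version '%s'", version)
  off <- suppressWarnings(as.integer(substring(header,
    10 + 8 * (0:5) + 1, 10 + 8 * (1:6))))
  text_begin <- off[1]; text_end <- off[2]
  if (is.na(text_begin) || is.na(text_end) || text_end > sz)
    stop_agi("agiflow_parse_error", "truncated FCS file: %s", path)
  seek(con, text_begin)
  text <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kv <- parts[seq(2, length(parts), 2)]
  names(kv) <- toupper(parts[seq(1, length(parts), 2)])
  need <- function(k) {
    if (!k %in% names(kv))
      stop_agi("agiflow_parse_error", "FCS missing keyword %s", k)
    kv[[k]]
  }
  npar <- as.integer(need("$PAR")); ntot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D"))
    stop_agi("agiflow_parse_error", "unsupported $DATATYPE '%s'", dtype)
  endian <- if (startsWith(need("$BYTEORD"), "1")) "little" else "big"
  data_begin <- as.integer(off[3]); data_end <- as.integer(off[4])
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(kv[["$BEGINDATA"]])
    data_end <- as.integer(kv[["$ENDDATA"]])
  }
  nbytes <- if (dtype == "F") 4L else 8L
  nvals <- npar * ntot
  if (ntot > 0L) {
    if (data_end > sz)
      stop_agi("agiflow_parse_error", "truncated FCS data segment: %s", path)
    seek(con, data_begin)
    x <- readBin(con, "numeric", n = nvals, size = nbytes, endian = endian)
    if (length(x) < nvals)
      stop_agi("agiflow_parse_error", "truncated FCS data segment: %s", path)
    vals <- matrix(x, nrow = ntot, ncol = npar, byrow = TRUE)
  } else {
    vals <- matrix(numeric(0), 0L, npar)
  }
  detectors <- vapply(seq_len(npar),
                      function(i) need(sprintf("$P%dN", i)), "")
  colnames(vals) <- resolve_channels(detectors, panel)
  stage <- if ("AGIFLOWSTAGE" %in% names(kv)) kv[["AGIFLOWSTAGE"]] else "raw"
  sample_id <- if ("AGIFLOWSAMPLE" %in% names(kv)) kv[["AGIFLOWSAMPLE"]]
               else basename(path)
  labels <- NULL
  if ("LABEL" %in% colnames(vals)) {
    li <- which(colnames(vals) == "LABEL")
    code <- as.integer(round(vals[, li]))
    vals <- vals[, -li, drop = FALSE]
    if ("AGIFLOWLABELS" %in% names(kv)) {
      ent <- strsplit(kv[["AGIFLOWLABELS"]], "|", fixed = TRUE)[[1]]
      labels <- sub("^[0-9]+:", "", ent)[code]
    } else labels <- as.character(code)
  }
  em <- event_matrix(vals, panel, stage = stage, sample_id = sample_id)
  if (!is.null(labels)) attr(em, "labels") <- labels
  em
}

## ---- spillover & compensation --------------------------------------------

#' Read / write a spillover matrix as CSV
#'
#' Square matrix over fluorescence detectors with a header row and a leading
#' column of detector names; diagonal must be exactly 1.
#' @param path CSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_spillover <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  rn <- dt[[1]]
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- rn
  validate_spillover(m)
  m
}

#' @rdname read_spillover
#' @param spill Spillover matrix.
#' @export
write_spillover <- function(spill, path) {
  validate_spillover(spill)
  dt <- data.table::data.table(detector = rownames(spill))
  dt <- cbind(dt, data.table::as.data.table(spill))
  data.table::fwrite(dt, path)
  invisible(path)
}

validate_spillover <- function(spill) {
  if (!is.matrix(spill) || nrow(spill) != ncol(spill))
    stop_agi("agiflow_value_error", "spillover must be a square matrix")
  if (any(abs(diag(spill) - 1) > 1e-12))
    stop_agi("agiflow_value_error", "spillover diagonal must be exactly 1")
  if (!all(is.finite(spill)) || rcond(spill) < 1e-12)
    stop_agi("agiflow_singular_spill", "spillover matrix is not invertible")
  invisible(spill)
}

#' Apply spillover compensation
#'
#' Fluorescence values are right-multiplied by the inverse spillover matrix;
#' scatter and time channels are untouched.  `em` must be at stage `"raw"`.
#'
#' @param em An [event_matrix()] at stage raw.
#' @param spill Square spillover matrix over (a subset of) the fluorescence
#'   markers or detectors, unit diagonal.
#' @return The compensated event matrix (stage `"compensated"`).
#' @export
compensate <- function(em, spill) {
  stopifnot(inherits(em, "agiflow_events"))
  if (em$stage != "raw")
    stop_agi("agiflow_stage_error", "compensate expects a raw event matrix")
  validate_spillover(spill)
  chans <- resolve_channels(rownames(spill), em$panel)
  fl <- fluor_markers(em$panel)
  if (!all(chans %in% fl))
    stop_agi("agiflow_panel_mismatch",
             "spillover channels not a subset of fluorescence channels")
  vals <- em$values
  vals[, chans] <- vals[, chans, drop = FALSE] %*% solve(spill)
  out <- em
  out$values <- vals
  out$stage <- "compensated"
  out
}

## ---- display transforms ---------------------------------------------------

#' Per-channel display transform specification
#'
#' Fluorescence channels use the inverse hyperbolic sine with a per-channel
#' cofactor (default 150); scatter channels are scaled linearly onto a
#' compact range; the time channel is left in seconds.
#'
#' @param cofactor Positive asinh cofactor for fluorescence channels.
#' @param scatter_divisor Raw scatter units mapped to 1 transformed unit.
#' @return A `data.frame` of per-marker transforms.
#' @export
transform_spec <- function(cofactor = 150, scatter_divisor = 262144 / 4.5,
                           panel = default_panel()) {
  if (any(cofactor <= 0) || scatter_divisor <= 0)
    stop_agi("agiflow_config_error", "transform cofactors must be positive")
  data.frame(
    marker = panel$marker,
    type = ifelse(panel$kind == "fluorescence", "asinh",
                  ifelse(panel$kind == "scatter", "linear", "identity")),
    cofactor = ifelse(panel$kind == "fluorescence", cofactor,
                      ifelse(panel$kind == "scatter", scatter_divisor, 1)),
    stringsAsFactors = FALSE
  )
}

#' @rdname transform_spec
#' @param panel Panel data frame.
#' @return For `identity_transform_spec()`: a spec leaving every channel
#'   unchanged.
#' @export
identity_transform_spec <- function(panel = default_panel()) {
  data.frame(marker = panel$marker, type = "identity", cofactor = 1,
             stringsAsFactors = FALSE)
}

#' Apply the display transform
#'
#' @param em A compensated [event_matrix()].
#' @param spec A [transform_spec()].
#' @return The transformed event matrix (stage `"transformed"`).
#' @export
apply_transform <- function(em, spec = transform_spec(panel = em$panel)) {
  stopifnot(inherits(em, "agiflow_events"))
  if (em$stage != "compensated")
    stop_agi("agiflow_stage_error",
             "apply_transform expects a compensated event matrix")
  if (any(spec$cofactor <= 0))
    stop_agi("agiflow_config_error", "transform cofactors must be positive")
  vals <- em$values
  for (m in colnames(vals)) {
    j <- match(m, spec$marker)
    if (is.na(j)) next
    vals[, m] <- switch(spec$type[j],
      asinh = asinh(vals[, m] / spec$cofactor[j]),
      linear = vals[, m] / spec$cofactor[j],
      identity = vals[, m],
      stop_agi("agiflow_config_error", "unknown transform '%s'", spec$type[j]))
  }
  out <- em
  out$values <- vals
  out$stage <- "transformed"
  out
}

#' Compensate and transform in one call
#'
#' Convenience wrapper taking a raw event matrix to analysis scale.
#' @inheritParams compensate
#' @inheritParams apply_transform
#' @return Transformed event matrix.
#' @export
prepare_events <- function(em, spill = NULL,
                           spec = transform_spec(panel = em$panel)) {
  if (em$stage == "raw") {
    em <- if (is.null(spill)) {
      out <- em; out$stage <- "compensated"; out
    } else compensate(em, spill)
  }
  if (em$stage == "compensated") em <- apply_transform(em, spec)
  em
}
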