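#' Plain-text session serialization
#'
#' A session is stored as three/four sibling files under one prefix:
#' `<prefix>_lfp.csv` (wide voltage matrix, one column per structure),
#' `<prefix>_events.csv` (trial table; lick intervals serialized as
#' `start:end;start:end`), `<prefix>_meta.json` (fs, rat id, session
#' label, seed) and optionally `<prefix>_truth.json` (simulator ground
#' truth). Everything is text so fixtures and outputs stay portable.
#'
#' @name session_io
NULL

serialize_licks <- function(licks) {
  vapply(licks, function(m) {
    if (is.null(m) || nrow(m) == 0L) return("")
    paste(sprintf("%.6f:%.6f", m[, 1L], m[, 2L]), collapse = ";")
  }, character(1))
}

deserialize_licks <- function(s) {
  lapply(s, function(one) {
    if (is.na(one) || !nzchar(one)) {
      return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
    }
    parts <- strsplit(strsplit(one, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, as.numeric))
    dimnames(m) <- list(NULL, c("start", "end"))
    m
  })
}

#' Write a session recording (and optional ground truth) to disk
#'
#' @param session either a `session_recording` or a `(recording, truth)`
#'   list from [generate_session()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix, default the session label.
#' @return the prefix path, invisibly.
#' @export
write_session <- function(session, dir, prefix = NULL) {
  rec <- if (inherits(session, "session_recording")) session else session$recording
  truth <- if (inherits(session, "session_recording")) NULL else session$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- prefix %||% rec$metadata$session_label
  base <- file.path(dir, prefix)
  data.table::fwrite(as.data.frame(rec$signals), paste0(base, "_lfp.csv"))
  ev <- rec$trials
  ev$licks <- serialize_licks(ev$licks)
  data.table::fwrite(ev, paste0(base, "_events.csv"))
  meta <- c(rec$metadata, list(fs = rec$fs, structures = colnames(rec$signals)))
  jsonlite::write_json(meta, paste0(base, "_meta.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    tr <- truth
    class(tr) <- NULL
    tr$gains <- as.data.frame(tr$gains)
    tr$burst_phases <- as.data.frame(tr$burst_phases)
    tr$artifact_intervals <- as.data.frame(tr$artifact_intervals)
    jsonlite::write_json(tr, paste0(base, "_truth.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(base)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory holding the files.
#' @param prefix file name prefix.
#' @return list `(recording, truth)`; `truth` is `NULL` when no sidecar
#'   exists.
#' @export
read_session <- function(dir, prefix) {
  base <- file.path(dir, prefix)
  meta <- jsonlite::read_json(paste0(base, "_meta.json"), simplifyVector = TRUE)
  sig <- as.matrix(data.table::fread(paste0(base, "_lfp.csv")))
  colnames(sig) <- meta$structures
  ev <- as.data.frame(data.table::fread(paste0(base, "_events.csv"),
                                        colClasses = list(character = "licks")))
  ev$licks <- deserialize_licks(ev$licks)
  recording <- structure(
    list(signals = sig, fs = meta$fs, trials = ev,
         metadata = meta[setdiff(names(meta), c("fs", "structures"))]),
    class = "session_recording"
  )
  truth_path <- paste0(base, "_truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    demat <- function(d) {
      m <- as.matrix(d)
      rownames(m) <- NULL
      m
    }
    truth$gains <- demat(truth$gains)
    truth$burst_phases <- demat(truth$burst_phases)
    truth$artifact_intervals <- demat(truth$artifact_intervals)
    class(truth) <- "ground_truth"
  }
  list(recording = recording, truth = truth)
}

#' Validate on-disk session inputs
#'
#' Structural checks before analysis: files present, CSV schemas, strictly
#' increasing non-overlapping nose-poke intervals, events within the
#' recording, sampling rate adequate for the beta band.
#'
#' @param dir directory holding the files.
#' @param prefix file name prefix.
#' @return character vector of violations (empty when well-formed).
#' @export
validate_inputs <- function(dir, prefix) {
  v <- character(0)
  base <- file.path(dir, prefix)
  need <- paste0(base, c("_lfp.csv", "_events.csv", "_meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    return(paste("missing file:", missing))
  }
  meta <- jsonlite::read_json(paste0(base, "_meta.json"), simplifyVector = TRUE)
  if (is.null(meta$fs) || meta$fs < 200) {
    v <- c(v, "fs below 200 Hz: beta band too close to Nyquist")
  }
  ev <- as.data.frame(data.table::fread(paste0(base, "_events.csv")))
  need_cols <- c("trial", "nose_poke_start", "nose_poke_end", "odor", "side", "correct")
  miss <- setdiff(need_cols, names(ev))
  if (length(miss)) v <- c(v, paste("events.csv missing column:", miss))
  if (all(c("nose_poke_start", "nose_poke_end") %in% names(ev))) {
    if (any(ev$nose_poke_end <= ev$nose_poke_start)) {
      v <- c(v, "nose_poke_end <= nose_poke_start for some trial")
    }
    if (is.unsorted(ev$nose_poke_start, strictly = TRUE)) {
      v <- c(v, "trials not strictly ordered by nose_poke_start")
    } else if (nrow(ev) > 1L &&
               any(ev$nose_poke_start[-1L] < ev$nose_poke_end[-nrow(ev)])) {
      v <- c(v, "overlapping trials")
    }
  }
  hdr <- names(data.table::fread(paste0(base, "_lfp.csv"), nrows = 0L))
  if (!is.null(meta$structures) && !setequal(hdr, meta$structures)) {
    v <- c(v, "lfp.csv columns do not match metadata structures")
  }
  v
}
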