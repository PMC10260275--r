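# Delimited-text I/O for hypnograms, artifact annotations, event tables,
# subject summaries and recognition responses. All time coordinates are
# seconds from recording start, intervals half-open [start, end).

#' Default sleep-stage token mapping
#'
#' Maps common scoring dialects onto the canonical stage set
#' {W, N1, N2, N3, REM}.
#' @return named character vector (token -> stage).
#' @export
default_stage_map <- function() {
  c(W = "W", WAKE = "W", "0" = "W",
    N1 = "N1", S1 = "N1", "1" = "N1",
    N2 = "N2", S2 = "N2", "2" = "N2",
    N3 = "N3", S3 = "N3", S4 = "N3", SWS = "N3", "3" = "N3", "4" = "N3",
    REM = "REM", R = "REM", "5" = "REM")
}

#' Construct a hypnogram
#' @param stages character vector of stages in {W, N1, N2, N3, REM}.
#' @param epoch_s epoch length in seconds (30 by convention).
#' @return list of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  ok <- stages %in% c("W", "N1", "N2", "N3", "REM")
  if (!all(ok))
    stop("unknown sleep stage(s): ", paste(unique(stages[!ok]), collapse = ", "),
         call. = FALSE)
  structure(list(stages = stages, epoch_s = epoch_s), class = "hypnogram")
}

#' Read a hypnogram from delimited text
#'
#' One stage token per 30-s epoch; tokens may sit one per line or be
#' separated by commas/semicolons/whitespace. Unrecognized tokens raise a
#' parse error reporting the line number.
#'
#' @param path text file.
#' @param epoch_s epoch length, seconds.
#' @param map token-to-stage mapping, see [default_stage_map()]; matching is
#'   case-insensitive.
#' @param recording optional [psg_recording()]; when given, checks that the
#'   hypnogram does not outrun the recording by more than one epoch.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_s = 30, map = default_stage_map(),
                           recording = NULL) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  names(map) <- toupper(names(map))
  stages <- character(0)
  for (i in seq_along(lines)) {
    toks <- strsplit(lines[i], "[,;\t ]+")[[1]]
    toks <- toupper(toks[nzchar(toks)])
    unknown <- setdiff(toks, names(map))
    if (length(unknown))
      stop(sprintf("hypnogram parse error at line %d: unknown token '%s'",
                   i, unknown[1]), call. = FALSE)
    stages <- c(stages, unname(map[toks]))
  }
  h <- hypnogram(stages, epoch_s)
  if (!is.null(recording)) {
    dur <- recording_duration(recording)
    if (length(stages) * epoch_s > dur + epoch_s)
      stop(sprintf("hypnogram spans %.0f s but recording lasts %.0f s",
                   length(stages) * epoch_s, dur), call. = FALSE)
  }
  h
}

#' @rdname read_hypnogram
#' @param hyp a [hypnogram()] to write (one token per line).
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(hyp$stages, path)
  invisible(path)
}

#' Read / write artifact annotations
#'
#' Tab-separated with header `start_s`, `end_s` and optional `channel`
#' (empty = all channels). Intervals may overlap; they are merged on use.
#'
#' @param path TSV file.
#' @return data.frame with columns `start_s`, `end_s`, `channel`.
#' @export
read_artifacts <- function(path) {
  if (!file.exists(path)) stop("artifact file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fill = TRUE)
  if (!all(c("start_s", "end_s") %in% names(df)))
    stop("artifact table must have start_s and end_s columns", call. = FALSE)
  if (is.null(df$channel)) df$channel <- NA_character_
  df$channel[!nzchar(trimws(as.character(df$channel)))] <- NA_character_
  artifact_set(df$start_s, df$end_s, df$channel)
}

#' @rdname read_artifacts
#' @param artifacts an artifact data.frame as from [artifact_set()].
#' @export
write_artifacts <- function(artifacts, path) {
  utils::write.table(artifacts, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Construct an artifact interval set
#' @param start_s,end_s interval bounds in seconds (start < end).
#' @param channel optional per-interval channel scope (`NA` = all channels).
#' @return data.frame of class `artifact_set`.
#' @export
artifact_set <- function(start_s = numeric(0), end_s = numeric(0),
                         channel = NA_character_) {
  if (length(start_s) && any(start_s >= end_s))
    stop("artifact intervals require start_s < end_s", call. = FALSE)
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   channel = rep_len(as.character(channel),
                                     length.out = length(start_s)),
                   stringsAsFactors = FALSE)
  class(df) <- c("artifact_set", "data.frame")
  df
}

# merge overlapping/adjacent intervals; returns matrix [start, end)
merge_intervals <- function(start_s, end_s) {
  if (!length(start_s)) return(matrix(numeric(0), ncol = 2))
  o <- order(start_s)
  s <- start_s[o]; e <- end_s[o]
  out_s <- s[1]; out_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], e[i])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i])
    }
  }
  cbind(out_s, out_e, deparse.level = 0)
}

#' Write / read event tables
#'
#' One row per detected event. Spindle and SO tables share the columns
#' `subject`, `channel`, `start_s`, `end_s`, `peak_s`, `amplitude_uv`,
#' `duration_s`; SO-spindle pair tables add `phase_rad` and `distance_rad`.
#' Column order is deterministic and the round trip preserves times to at
#' least six decimals.
#'
#' @param events event data.frame (may be empty: a header-only file is
#'   written).
#' @param path output TSV.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read / write recognition response tables
#'
#' Long format CSV: `subject`, `retrieval` (immediate/12h/24h), `item_id`,
#' `emotion` (neutral/emotional), `is_target` (logical), `response`
#' (recollected/familiar/new). Numeric button codes 1/2/0 are mapped to
#' recollected/familiar/new at ingest.
#'
#' @param path CSV file.
#' @return response data.frame.
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("response file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  need <- c("subject", "retrieval", "item_id", "emotion", "is_target", "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("response table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  codes <- c("1" = "recollected", "2" = "familiar", "0" = "new")
  r <- as.character(df$response)
  df$response <- ifelse(r %in% names(codes), codes[r], r)
  bad <- setdiff(unique(df$response), c("recollected", "familiar", "new"))
  if (length(bad))
    stop("unknown response value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$is_target <- as.logical(df$is_target)
  df
}

#' @rdname read_responses
#' @param responses response data.frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.table(responses, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
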