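# Recognition-memory scoring: hit and false-alarm rates from
# recollected/familiar/new responses, signal-detection d' with
# extreme-rate correction, and the difference scores used in follow-up
# regressions.

RETRIEVALS <- c("immediate", "12h", "24h")
EMOTIONS <- c("neutral", "emotional")

#' The recognition task design
#'
#' Three retrievals, each showing 50 previously encoded targets intermixed
#' with 50 unseen foils, 25 neutral and 25 emotional within each set; 150
#' pictures are encoded and 150 distinct foils used, 300 stimuli in total.
#'
#' @return list: `retrievals`, `emotions`, `n_targets_cell`, `n_foils_cell`,
#'   `n_targets_retrieval`, `n_foils_retrieval`, `n_encoded`,
#'   `n_stimuli_total`.
#' @export
task_design <- function() {
  list(retrievals = RETRIEVALS, emotions = EMOTIONS,
       n_targets_cell = 25L, n_foils_cell = 25L,
       n_targets_retrieval = 50L, n_foils_retrieval = 50L,
       n_encoded = 150L,
       n_stimuli_total = 150L + 3L * 50L)
}

#' Check response-table design invariants
#'
#' Per subject and retrieval: 50 targets and 50 foils, split 25/25 by
#' emotion within each.
#'
#' @param responses response data.frame (see [read_responses()]).
#' @param lenient only warn instead of erroring (for ragged synthetic data).
#' @return `TRUE` invisibly (or an error/warning).
#' @export
check_response_table <- function(responses, lenient = FALSE) {
  bad <- character(0)
  for (s in unique(responses$subject)) {
    for (r in RETRIEVALS) {
      sub <- responses[responses$subject == s & responses$retrieval == r, ]
      if (!nrow(sub)) { bad <- c(bad, sprintf("%s/%s: empty", s, r)); next }
      for (e in EMOTIONS) {
        nt <- sum(sub$emotion == e & sub$is_target)
        nf <- sum(sub$emotion == e & !sub$is_target)
        if (nt != 25L || nf != 25L)
          bad <- c(bad, sprintf("%s/%s/%s: %d targets, %d foils", s, r, e, nt, nf))
      }
    }
  }
  if (length(bad)) {
    msg <- paste0("response table violates the 50/50, 25/25 design:\n  ",
                  paste(head(bad, 5), collapse = "\n  "))
    if (lenient) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Hit and false-alarm rates per subject x retrieval x emotion
#'
#' Total mode counts "recollected" or "familiar" as an old judgment;
#' recollection mode counts "recollected" only. Hits are old judgments to
#' targets, false alarms old judgments to foils.
#'
#' @param responses response data.frame.
#' @param mode `"total"` or `"recollection"`.
#' @return data.frame: `subject`, `retrieval`, `emotion`, `n_targets`,
#'   `n_foils`, `hits`, `fas`, `hit_rate`, `fa_rate`.
#' @export
score_rates <- function(responses, mode = c("total", "recollection")) {
  mode <- match.arg(mode)
  old <- if (mode == "total") c("recollected", "familiar") else "recollected"
  rows <- list()
  for (s in unique(responses$subject)) {
    for (r in intersect(RETRIEVALS, unique(responses$retrieval))) {
      for (e in intersect(EMOTIONS, unique(responses$emotion))) {
        sub <- responses[responses$subject == s & responses$retrieval == r &
                           responses$emotion == e, ]
        nt <- sum(sub$is_target); nf <- sum(!sub$is_target)
        if (nt == 0L || nf == 0L)
          stop(sprintf("cannot score cell %s/%s/%s: %d targets, %d foils",
                       s, r, e, nt, nf), call. = FALSE)
        h <- sum(sub$is_target & sub$response %in% old)
        f <- sum(!sub$is_target & sub$response %in% old)
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s, retrieval = r, emotion = e,
                     n_targets = nt, n_foils = nf, hits = h, fas = f,
                     hit_rate = h / nt, fa_rate = f / nf,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Signal-detection d'
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with z the standard-normal
#' quantile. Extreme rates are corrected before the quantile: with the
#' default `"rate_2n"` rule, 0 becomes `1/(2n)` and 1 becomes `1 - 1/(2n)`
#' (n = trials in the cell); `"loglinear"` instead adds 0.5 to each count
#' and 1 to each n for all cells.
#'
#' @param hit,fa rates in [0, 1] (vectorized).
#' @param n_targets,n_foils trials behind each rate.
#' @param correction `"rate_2n"` or `"loglinear"`.
#' @return d' (finite by construction).
#' @export
dprime <- function(hit, fa, n_targets = 25, n_foils = 25,
                   correction = c("rate_2n", "loglinear")) {
  correction <- match.arg(correction)
  if (any(hit < 0 | hit > 1 | fa < 0 | fa > 1, na.rm = TRUE))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (correction == "rate_2n") {
    hit <- pmin(pmax(hit, 1 / (2 * n_targets)), 1 - 1 / (2 * n_targets))
    fa <- pmin(pmax(fa, 1 / (2 * n_foils)), 1 - 1 / (2 * n_foils))
  } else {
    hit <- (hit * n_targets + 0.5) / (n_targets + 1)
    fa <- (fa * n_foils + 0.5) / (n_foils + 1)
  }
  stats::qnorm(hit) - stats::qnorm(fa)
}

#' Score a response table into retrieval-level d' scores
#'
#' Combines [score_rates()] (both modes) and [dprime()]: per subject x
#' retrieval x emotion, total-mode hit/fa rates with total d' and
#' recollection-based d'.
#'
#' @param responses response data.frame.
#' @param correction extreme-rate correction passed to [dprime()].
#' @param lenient passed to [check_response_table()].
#' @return data.frame with columns of [score_rates()] plus `dprime`,
#'   `dprime_recollection`.
#' @export
score_responses <- function(responses, correction = "rate_2n",
                            lenient = FALSE) {
  check_response_table(responses, lenient = lenient)
  tot <- score_rates(responses, "total")
  rec <- score_rates(responses, "recollection")
  tot$dprime <- dprime(tot$hit_rate, tot$fa_rate, tot$n_targets, tot$n_foils,
                       correction)
  tot$dprime_recollection <- dprime(rec$hit_rate, rec$fa_rate,
                                    rec$n_targets, rec$n_foils, correction)
  tot
}

#' Difference scores from retrieval-level d'
#'
#' Per subject: the retention deltas (immediate - 12h and 12h - 24h d',
#' per emotion and pooled over emotions) and the emotional difference
#' (neutral - emotional d', per retrieval and pooled over retrievals).
#' Missing cells propagate as NA.
#'
#' @param scores data.frame from [score_responses()] (needs `subject`,
#'   `retrieval`, `emotion` and a score column).
#' @param value score column to difference (default `"dprime"`).
#' @return one row per subject with columns
#'   `time_imm_12h_neutral`, `time_imm_12h_emotional`, `time_imm_12h`,
#'   `time_12h_24h_neutral`, `time_12h_24h_emotional`, `time_12h_24h`,
#'   `emo_diff_immediate`, `emo_diff_12h`, `emo_diff_24h`, `emo_diff`.
#' @export
difference_scores <- function(scores, value = "dprime") {
  subs <- unique(scores$subject)
  get <- function(s, r, e) {
    v <- scores[[value]][scores$subject == s & scores$retrieval == r &
                           scores$emotion == e]
    if (length(v) == 1L) v else NA_real_
  }
  rows <- lapply(subs, function(s) {
    d <- sapply(RETRIEVALS, function(r) sapply(EMOTIONS, function(e) get(s, r, e)))
    # d: 2 x 3 matrix, rows neutral/emotional, cols immediate/12h/24h
    pooled <- colMeans(d)
    data.frame(subject = s,
               time_imm_12h_neutral = d[1, 1] - d[1, 2],
               time_imm_12h_emotional = d[2, 1] - d[2, 2],
               time_imm_12h = pooled[1] - pooled[2],
               time_12h_24h_neutral = d[1, 2] - d[1, 3],
               time_12h_24h_emotional = d[2, 2] - d[2, 3],
               time_12h_24h = pooled[2] - pooled[3],
               emo_diff_immediate = d[1, 1] - d[2, 1],
               emo_diff_12h = d[1, 2] - d[2, 2],
               emo_diff_24h = d[1, 3] - d[2, 3],
               emo_diff = mean(d[1, ] - d[2, ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Arrange scores as a subjects x retrieval x emotion array
#'
#' @param scores data.frame from [score_responses()].
#' @param value score column (default `"dprime"`).
#' @return numeric array `n_subjects x 3 x 2` with dimnames
#'   (subject, retrieval, emotion).
#' @export
scores_array <- function(scores, value = "dprime") {
  subs <- unique(scores$subject)
  arr <- array(NA_real_, dim = c(length(subs), 3L, 2L),
               dimnames = list(subject = as.character(subs),
                               retrieval = RETRIEVALS, emotion = EMOTIONS))
  for (i in seq_along(subs)) for (r in seq_len(3L)) for (e in seq_len(2L)) {
    v <- scores[[value]][scores$subject == subs[i] &
                           scores$retrieval == RETRIEVALS[r] &
                           scores$emotion == EMOTIONS[e]]
    if (length(v) == 1L) arr[i, r, e] <- v
  }
  arr
}
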