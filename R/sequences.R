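#' Segment a gesture stream into sequence units
#'
#' Splits each signaller's gesture stream (within each communication) into
#' sequence units under an explicit (end point, cutoff) convention: a new
#' unit starts whenever the interval from the chosen phase end point of the
#' previous gesture to the onset of the next reaches the cutoff — that pause
#' marks response waiting, so the two gestures belong to different sequences.
#' The default convention is a 1-s minimum interval; whether it is measured
#' from the gesture-action end (the traditional convention) or from the MAU
#' end (the point at which the gesture's core information is in place) is the
#' caller's choice, and the two conventions can disagree about the same
#' stream.
#'
#' The comparison is `interval >= cutoff` by default (an interval of exactly
#' the cutoff marks response waiting); `strict = TRUE` uses `>` instead,
#' since prior conventions are ambiguous on the boundary. A boundary whose
#' interval is undecidable (unknown end point or onset) conservatively opens
#' a new unit and is flagged.
#'
#' Gestures by other individuals do not break a signaller's units; streams
#' are segmented per (communication, signaller).
#'
#' @param x a [CommunicationSet-class].
#' @param endpoint `"MAU_end"` or `"GA_end"`.
#' @param cutoff seconds, default 1.0.
#' @param strict logical; use `>` instead of `>=` at the boundary.
#' @return `data.frame` with one row per gesture record: `communication_id`,
#'   `signaller_id`, `record_id`, `unit` (unit index within the
#'   communication-signaller stream, 1-based), `boundary_interval` (seconds
#'   from the previous record's end point to this record's onset; `NA` for
#'   the first record of a stream or an undecidable boundary) and
#'   `undecidable` (logical flag).
#' @examples
#' cs <- CommunicationSet(
#'   data.frame(communication_id = "c1"),
#'   data.frame(record_id = c("r1", "r2"), communication_id = "c1",
#'              gesture_action = "Reach", g_start_ms = c(0L, 5500L),
#'              mau_end_ms = c(4000L, 9000L), ga_end_ms = c(5000L, 9000L),
#'              g_end_ms = c(5200L, 9500L)))
#' segmentSequences(cs, "GA_end")$unit   # 1 1 (interval 0.5 s)
#' segmentSequences(cs, "MAU_end")$unit  # 1 2 (interval 1.5 s)
#' @export
segmentSequences <- function(x, endpoint = c("MAU_end", "GA_end"),
                             cutoff = 1.0, strict = FALSE) {
  stopifnot(is(x, "CommunicationSet"), cutoff >= 0)
  endpoint <- match.arg(endpoint)
  col <- if (endpoint == "MAU_end") "mau_end_ms" else "ga_end_ms"
  recs <- records(x)
  if (nrow(recs) == 0L)
    return(data.frame(communication_id = character(), signaller_id = character(),
                      record_id = character(), unit = integer(),
                      boundary_interval = numeric(), undecidable = logical(),
                      stringsAsFactors = FALSE))
  sig <- ifelse(is.na(recs$signaller_id), "<NA>", recs$signaller_id)
  stream <- paste(recs$communication_id, sig, sep = "\r")
  out <- vector("list", length(unique(stream)))
  names(out) <- unique(stream)
  for (key in unique(stream)) {
    rr <- recs[stream == key, , drop = FALSE]
    n <- nrow(rr)
    unit <- integer(n)
    interval <- rep(NA_real_, n)
    undec <- logical(n)
    unit[1] <- 1L
    if (n >= 2L) {
      for (i in 2:n) {
        iv <- msToS(rr$g_start_ms[i] - rr[[col]][i - 1L])
        interval[i] <- iv
        if (is.na(iv)) {
          ## undecidable boundary: split conservatively, flag it
          undec[i] <- TRUE
          unit[i] <- unit[i - 1L] + 1L
        } else {
          split <- if (strict) iv > cutoff else iv >= cutoff
          unit[i] <- unit[i - 1L] + as.integer(split)
        }
      }
    }
    out[[key]] <- data.frame(
      communication_id = rr$communication_id, signaller_id = rr$signaller_id,
      record_id = rr$record_id, unit = unit, boundary_interval = interval,
      undecidable = undec, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Number of sequence units per stream
#'
#' @param segmentation output of [segmentSequences()].
#' @return `data.frame` with `communication_id`, `signaller_id`, `n_units`.
#' @export
sequenceUnitCounts <- function(segmentation) {
  sig <- ifelse(is.na(segmentation$signaller_id), "<NA>",
                segmentation$signaller_id)
  key <- paste(segmentation$communication_id, sig, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    s <- segmentation[key == k, , drop = FALSE]
    data.frame(communication_id = s$communication_id[1],
               signaller_id = s$signaller_id[1],
               n_units = max(s$unit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a follow-up sequence unit as persistence or elaboration
#'
#' After a failed request, continued gesturing towards the same goal is
#' *persistence* when the follow-up unit uses only gesture types already
#' deployed, and *persistence with elaboration* when it introduces new
#' types. What counts as "the same gesture type" depends on the morph
#' resolution at which the unit keys were computed (see [morphKey()]): two
#' reaches with different laterality are the same type at action-level
#' resolution but different types at full-modifier resolution.
#'
#' @param prev_keys character vector of morph keys used in the earlier
#'   unit(s).
#' @param next_keys character vector of morph keys of the follow-up unit.
#' @return `"persistence"` or `"persistence_with_elaboration"`.
#' @examples
#' classifyFollowup("Reach", "Reach")    # persistence
#' classifyFollowup("Reach", "Beckon")   # persistence_with_elaboration
#' @export
classifyFollowup <- function(prev_keys, next_keys) {
  stopifnot(length(prev_keys) > 0L, length(next_keys) > 0L)
  if (all(next_keys %in% prev_keys)) "persistence"
  else "persistence_with_elaboration"
}
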