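## internal: ms difference -> seconds (exact, ms resolution kept)
msToS <- function(ms) as.numeric(ms) / 1000

#' Phase durations of gesture records
#'
#' Computes, for every gesture record, the durations of the coded action
#' phases from the four measured time points, in seconds:
#' \describe{
#'   \item{mau_duration}{gesture start to MAU end — the minimum action unit,
#'     the initial movement carrying the minimal information needed to
#'     recognise the gesture action;}
#'   \item{ga_duration}{gesture start to gesture-action end — the action
#'     stroke plus any optional hold/repetition phase;}
#'   \item{full_duration}{gesture start to gesture end — neutral position to
#'     neutral position, including recovery;}
#'   \item{hold_duration}{gesture-action end minus MAU end — the optional
#'     hold/repetition phase (0 for stable action types);}
#'   \item{recovery_duration}{gesture end minus gesture-action end.}
#' }
#' Any duration touching an unknown (`NA`) time point is undefined (`NA`)
#' and excluded from downstream summaries.
#'
#' @param x a [CommunicationSet-class] or a record-level `data.frame` with
#'   the four time-point columns.
#' @return `data.frame` with `record_id`, `communication_id`,
#'   `gesture_action` and the five duration columns (seconds).
#' @examples
#' cs <- CommunicationSet(
#'   data.frame(communication_id = "c1"),
#'   data.frame(record_id = "r1", communication_id = "c1",
#'              gesture_action = "Reach", g_start_ms = 0L, mau_end_ms = 740L,
#'              ga_end_ms = 740L, g_end_ms = 1000L))
#' phaseDurations(cs)
#' @export
phaseDurations <- function(x) {
  recs <- if (is(x, "CommunicationSet")) records(x) else as.data.frame(x)
  miss <- setdiff(RECORD_TIME_COLS, names(recs))
  if (length(miss) > 0L)
    stop("missing time-point column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    record_id = if ("record_id" %in% names(recs)) recs$record_id
                else as.character(seq_len(nrow(recs))),
    communication_id = if ("communication_id" %in% names(recs))
      recs$communication_id else NA_character_,
    gesture_action = if ("gesture_action" %in% names(recs))
      recs$gesture_action else NA_character_,
    mau_duration = msToS(recs$mau_end_ms - recs$g_start_ms),
    ga_duration = msToS(recs$ga_end_ms - recs$g_start_ms),
    full_duration = msToS(recs$g_end_ms - recs$g_start_ms),
    hold_duration = msToS(recs$ga_end_ms - recs$mau_end_ms),
    recovery_duration = msToS(recs$g_end_ms - recs$ga_end_ms),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify gesture instances as continued or minimised
#'
#' An instance of a variable gesture action type is *continued* when the
#' signaller made use of the optional hold/repetition phase (hold duration
#' above the tolerance) and *minimised* otherwise. Instances of stable
#' action types are always minimised. An undefined hold duration yields
#' `"unknown"`.
#'
#' @param x a [CommunicationSet-class] or record-level `data.frame`.
#' @param catalogue a [GestureCatalogue-class].
#' @param zero_hold_tolerance seconds; holds at or below this are treated as
#'   absent. Default 0 (strict: coding is at millisecond resolution, so exact
#'   equality is meaningful).
#' @return character vector, one of `"continued"`, `"minimised"`,
#'   `"unknown"` per record.
#' @export
classifyInstance <- function(x, catalogue, zero_hold_tolerance = 0) {
  recs <- if (is(x, "CommunicationSet")) records(x) else as.data.frame(x)
  stopifnot(is(catalogue, "GestureCatalogue"), zero_hold_tolerance >= 0)
  phase <- classifyActionPhase(recs$gesture_action, catalogue)
  hold <- msToS(recs$ga_end_ms - recs$mau_end_ms)
  out <- rep("unknown", nrow(recs))
  out[phase == "stable"] <- "minimised"
  variable <- phase == "variable"
  out[variable & !is.na(hold) & hold > zero_hold_tolerance] <- "continued"
  out[variable & !is.na(hold) & hold <= zero_hold_tolerance] <- "minimised"
  out
}

#' Recipient response latency of a communication
#'
#' The latency from a phase end point of the communication's final gesture to
#' the outcome time (the moment the signaller's goal is fulfilled):
#' `MAU_end` gives the MAU-to-outcome latency (response waiting measured from
#' the point at which the gesture's core information is in place), `GA_end`
#' the gesture-action-to-outcome latency (the traditional convention,
#' measured from when the signaller stopped displaying the gesture).
#' Negative latencies are legal: the recipient may respond before the phase
#' completes.
#'
#' The final gesture is the record whose chosen end point is latest (closest
#' to the outcome). If the chosen end point of the temporally last record is
#' unknown, the latest record with a known end point is used and the result
#' is flagged (`fallback = TRUE`). Communications with an unknown outcome
#' time, or no usable end point, get `NA` latencies.
#'
#' @param x a [CommunicationSet-class].
#' @param endpoint `"MAU_end"` or `"GA_end"`.
#' @return `data.frame` with one row per communication: `communication_id`,
#'   `latency` (seconds), `final_record_id`, `fallback` (logical),
#'   `outcome_status`.
#' @examples
#' cs <- CommunicationSet(
#'   data.frame(communication_id = "c1", outcome_status = "success",
#'              outcome_ms = 3450L),
#'   data.frame(record_id = "r1", communication_id = "c1",
#'              gesture_action = "Reach", g_start_ms = 0L, mau_end_ms = 1000L,
#'              ga_end_ms = 1800L, g_end_ms = 2000L))
#' responseLatency(cs, "MAU_end")$latency  # 2.45
#' @export
responseLatency <- function(x, endpoint = c("MAU_end", "GA_end")) {
  stopifnot(is(x, "CommunicationSet"))
  endpoint <- match.arg(endpoint)
  col <- if (endpoint == "MAU_end") "mau_end_ms" else "ga_end_ms"
  comms <- communications(x)
  recs <- records(x)
  out <- data.frame(
    communication_id = comms$communication_id,
    latency = NA_real_, final_record_id = NA_character_, fallback = FALSE,
    outcome_status = comms$outcome_status, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(comms))) {
    rr <- recs[recs$communication_id == comms$communication_id[i], , drop = FALSE]
    if (nrow(rr) == 0L) next
    ep <- rr[[col]]
    known <- which(!is.na(ep))
    if (length(known) == 0L) next
    fin <- known[which.max(ep[known])]
    ## flag when the temporally last record could not provide the end point
    last_start <- suppressWarnings(max(rr$g_start_ms, na.rm = TRUE))
    last_idx <- which(!is.na(rr$g_start_ms) & rr$g_start_ms == last_start)
    fb <- length(last_idx) > 0L && all(is.na(ep[last_idx]))
    out$final_record_id[i] <- rr$record_id[fin]
    out$fallback[i] <- fb
    if (!is.na(comms$outcome_ms[i]))
      out$latency[i] <- msToS(comms$outcome_ms[i] - ep[fin])
  }
  out
}

#' Inter-gesture interval between two gesture records
#'
#' The interval from a phase end point of the earlier gesture to the onset of
#' the next gesture by the same signaller: with `endpoint = "GA_end"` the
#' interval starts when the signaller stopped displaying the first gesture
#' (the traditional convention); with `"MAU_end"` it starts when the first
#' gesture's core information was in place, which can only lengthen the
#' interval. Negative intervals indicate overlapping production. An unknown
#' end point or onset makes the interval undefined (`NA`).
#'
#' @param g1,g2 single-row record `data.frame`s (e.g. slices of
#'   [records()]); `g1` must precede `g2` by start time, and both must come
#'   from the same communication and signaller.
#' @param endpoint `"MAU_end"` or `"GA_end"`.
#' @return interval in seconds, or `NA`.
#' @seealso [gestureIntervals()] for all consecutive intervals of a set.
#' @export
interGestureInterval <- function(g1, g2, endpoint = c("MAU_end", "GA_end")) {
  endpoint <- match.arg(endpoint)
  g1 <- as.data.frame(g1); g2 <- as.data.frame(g2)
  stopifnot(nrow(g1) == 1L, nrow(g2) == 1L)
  if (!identical(g1$communication_id, g2$communication_id))
    stop("records belong to different communications; pre-filter before computing intervals")
  s1 <- g1$signaller_id; s2 <- g2$signaller_id
  if (!is.na(s1) && !is.na(s2) && s1 != s2)
    stop("records belong to different signallers; pre-filter before computing intervals")
  if (!is.na(g1$g_start_ms) && !is.na(g2$g_start_ms) &&
      g1$g_start_ms > g2$g_start_ms)
    stop("g1 must precede g2 by start time")
  ep <- if (endpoint == "MAU_end") g1$mau_end_ms else g1$ga_end_ms
  msToS(g2$g_start_ms - ep)
}

#' Consecutive inter-gesture intervals within communications
#'
#' Vectorised companion to [interGestureInterval()]: for every pair of
#' consecutive records of the same signaller within each communication,
#' the interval from the chosen end point of the earlier record to the onset
#' of the later one.
#'
#' @param x a [CommunicationSet-class].
#' @param endpoint `"MAU_end"` or `"GA_end"`.
#' @return `data.frame` with `communication_id`, `signaller_id`,
#'   `from_record`, `to_record`, `interval` (seconds, `NA` if undecidable).
#' @export
gestureIntervals <- function(x, endpoint = c("MAU_end", "GA_end")) {
  stopifnot(is(x, "CommunicationSet"))
  endpoint <- match.arg(endpoint)
  col <- if (endpoint == "MAU_end") "mau_end_ms" else "ga_end_ms"
  recs <- records(x)
  out <- list()
  sig <- ifelse(is.na(recs$signaller_id), "<NA>", recs$signaller_id)
  for (key in unique(paste(recs$communication_id, sig, sep = "\r"))) {
    rr <- recs[paste(recs$communication_id, sig, sep = "\r") == key, , drop = FALSE]
    if (nrow(rr) < 2L) next
    i <- seq_len(nrow(rr) - 1L)
    out[[key]] <- data.frame(
      communication_id = rr$communication_id[i],
      signaller_id = rr$signaller_id[i],
      from_record = rr$record_id[i], to_record = rr$record_id[i + 1L],
      interval = msToS(rr$g_start_ms[i + 1L] - rr[[col]][i]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(communication_id = character(), signaller_id = character(),
                      from_record = character(), to_record = character(),
                      interval = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Grouped descriptive summaries
#'
#' Per-group descriptive statistics of a duration or latency column:
#' group size, number of undefined values excluded, median, mean, sample
#' standard deviation (n-1 denominator), minimum and maximum. Medians of
#' even-sized groups are the midpoint of the two central values. An empty
#' group yields a row with `n = 0` and all statistics `NA`.
#'
#' @param data `data.frame` of values (e.g. from [phaseDurations()] or
#'   [responseLatency()]).
#' @param value name of the numeric column to summarise.
#' @param by character vector of grouping column names; `NULL` for a single
#'   overall group.
#' @return `data.frame` with the grouping columns and `n`, `n_excluded`,
#'   `median`, `mean`, `sd`, `min`, `max`.
#' @examples
#' d <- data.frame(g = c("a", "a", "b"), v = c(1, 2, 10))
#' summariseBy(d, "v", "g")
#' @export
summariseBy <- function(data, value, by = NULL) {
  data <- as.data.frame(data)
  stopifnot(value %in% names(data))
  if (is.null(by)) {
    data$.all <- "all"
    by <- ".all"
  }
  stopifnot(all(by %in% names(data)))
  key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
  groups <- levels(key)
  rows <- lapply(groups, function(g) {
    v <- data[[value]][key == g]
    excl <- sum(is.na(v))
    v <- v[!is.na(v)]
    n <- length(v)
    stats <- if (n == 0L) rep(NA_real_, 5L) else c(
      stats::median(v), mean(v),
      if (n >= 2L) stats::sd(v) else NA_real_, min(v), max(v))
    cbind(unique(data[key == g, by, drop = FALSE])[1, , drop = FALSE],
          data.frame(n = n, n_excluded = excl, median = stats[1],
                     mean = stats[2], sd = stats[3], min = stats[4],
                     max = stats[5]))
  })
  out <- do.call(rbind, rows)
  if (".all" %in% names(out)) out$.all <- NULL
  rownames(out) <- NULL
  out
}
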