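#' Read a published worked-example table
#'
#' Loads the flat CSV layout used by the GesturalOrigins worked-example
#' tables (`Worked_example_1_data.csv`, `Worked_example_2.1_data.csv`,
#' `Worked_example_2.2_data.csv`, distributed in the framework's public
#' repository and not redistributed with this package): one row per gesture
#' record with the measured time points as columns. Column headers are
#' matched case-insensitively after stripping non-alphanumeric characters,
#' so `G_start_T`, `g.start.t` and `G start T` all match.
#'
#' Recognised columns (all optional except the gesture action and at least
#' one time point): `Gesture_action` (or `Gesture_record`), `G_start_T`,
#' `MAU_end_T`, `GA_end_T`, `G_end_T`, `Outcome_T`, `Species`, `Group`,
#' `Signaller` (or `Signaller_ID`), `Recipient`, `Goal`,
#' `Communication_number` (or `Communication_ID`). Rows sharing a
#' communication id are grouped into one communication; without a
#' communication column every row is its own communication.
#'
#' @param path CSV file path.
#' @param time_unit unit of the time columns: `"s"` (default; the published
#'   tables print seconds) or `"ms"`.
#' @return a [CommunicationSet-class].
#' @export
readWorkedExample <- function(path, time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  nm <- norm(names(df))
  pick <- function(cands) {
    i <- which(nm %in% norm(cands))[1]
    if (is.na(i)) NULL else df[[i]]
  }
  action <- pick(c("Gesture_action", "Gesture_record", "action"))
  if (is.null(action)) stop("no gesture-action column found")
  n <- nrow(df)
  toMs <- function(x) {
    if (is.null(x)) return(rep(NA_integer_, n))
    x <- suppressWarnings(as.numeric(x))
    as.integer(round(if (time_unit == "s") x * 1000 else x))
  }
  comm_id <- pick(c("Communication_number", "Communication_ID", "Communication"))
  if (is.null(comm_id)) comm_id <- sprintf("wc%04d", seq_len(n))
  comm_id <- as.character(comm_id)
  recs <- data.frame(
    record_id = sprintf("wr%04d", seq_len(n)),
    communication_id = comm_id,
    signaller_id = {
      s <- pick(c("Signaller", "Signaller_ID"))
      if (is.null(s)) NA_character_ else as.character(s)
    },
    recipient_id = {
      r <- pick(c("Recipient", "Recipient_ID"))
      if (is.null(r)) NA_character_ else as.character(r)
    },
    gesture_action = as.character(action),
    g_start_ms = toMs(pick(c("G_start_T", "Gesture_start_time"))),
    mau_end_ms = toMs(pick(c("MAU_end_T", "MAU_end_time"))),
    ga_end_ms = toMs(pick(c("GA_end_T", "Gesture_action_end_time"))),
    g_end_ms = toMs(pick(c("G_end_T", "Gesture_end_time"))),
    stringsAsFactors = FALSE)
  out_t <- toMs(pick(c("Outcome_T", "Outcome_time")))
  species <- pick("Species")
  goal <- pick("Goal")
  grp <- pick("Group")
  first <- !duplicated(comm_id)
  comms <- data.frame(
    communication_id = comm_id[first],
    species = if (is.null(species)) NA_character_
              else as.character(species)[first],
    group = if (is.null(grp)) NA_character_ else as.character(grp)[first],
    goal = if (is.null(goal)) NA_character_ else as.character(goal)[first],
    outcome_status = ifelse(is.na(out_t[first]), "unknown", "success"),
    outcome_ms = out_t[first],
    stringsAsFactors = FALSE)
  CommunicationSet(comms, recs)
}

#' Phase-duration summary of a worked-example table
#'
#' Convenience pipeline: [phaseDurations()] on a loaded table, summarised per
#' gesture action with [summariseBy()] for each of the three phase
#' durations.
#'
#' @param x a [CommunicationSet-class] (e.g. from [readWorkedExample()]).
#' @return named list of summary `data.frame`s: `mau`, `ga`, `full`.
#' @export
workedExampleDurationSummary <- function(x) {
  pd <- phaseDurations(x)
  list(mau = summariseBy(pd, "mau_duration", "gesture_action"),
       ga = summariseBy(pd, "ga_duration", "gesture_action"),
       full = summariseBy(pd, "full_duration", "gesture_action"))
}

#' Latency summary of a worked-example table
#'
#' Response latencies of the final gesture of each successful communication
#' under both phase end points, summarised per species.
#'
#' @param x a [CommunicationSet-class].
#' @return named list of summary `data.frame`s: `mau_outcome`, `ga_outcome`.
#' @export
workedExampleLatencySummary <- function(x) {
  comms <- communications(x)
  lat_m <- responseLatency(x, "MAU_end")
  lat_g <- responseLatency(x, "GA_end")
  lat_m$species <- comms$species[match(lat_m$communication_id,
                                       comms$communication_id)]
  lat_g$species <- comms$species[match(lat_g$communication_id,
                                       comms$communication_id)]
  keep <- function(d) d[d$outcome_status == "success", , drop = FALSE]
  list(mau_outcome = summariseBy(keep(lat_m), "latency", "species"),
       ga_outcome = summariseBy(keep(lat_g), "latency", "species"))
}
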