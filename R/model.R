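#' Structural validation of gesture records
#'
#' Checks every gesture record of a [CommunicationSet-class] against the
#' phase-time model and the controlled vocabularies and returns the
#' violations as data, one row per violation (an empty frame means the data
#' are clean). Validation never throws on bad data and is idempotent.
#'
#' Rules checked (severity in parentheses):
#' \itemize{
#'   \item time ordering `g_start <= mau_end <= ga_end <= g_end` over all
#'     pairs of known time points (error);
#'   \item stable actions must end with the MAU: `ga_end == mau_end` when both
#'     are known (error);
#'   \item the gesture action must exist in the catalogue (error);
#'   \item modifier values must be legal per the vocabulary (error);
#'   \item flexion/orientation only for free-limb actions, repetition count
#'     only for repetition actions, contacted body part only for contact
#'     actions (warning).
#' }
#'
#' @param x a [CommunicationSet-class].
#' @param catalogue a [GestureCatalogue-class].
#' @param vocab a [VocabularySet-class], or `NULL` to skip vocabulary checks.
#' @return `data.frame` with columns `record_id`, `field`, `rule`,
#'   `severity` (`"error"`/`"warning"`), `message`.
#' @seealso [validateCommunications()]
#' @export
validateRecords <- function(x, catalogue, vocab = NULL) {
  stopifnot(is(x, "CommunicationSet"), is(catalogue, "GestureCatalogue"))
  recs <- records(x)
  out <- emptyViolations()
  if (nrow(recs) == 0L) return(out)

  defs <- matchAction(recs$gesture_action, catalogue)
  unknown <- is.na(defs$action)
  out <- addViolation(out, recs$record_id[unknown], "gesture_action",
                      "action_in_catalogue", "error",
                      sprintf("unknown gesture action '%s'",
                              recs$gesture_action[unknown]))

  ## time ordering over consecutive known pairs
  tp <- RECORD_TIME_COLS
  for (i in seq_len(length(tp) - 1L)) {
    for (j in seq(i + 1L, length(tp))) {
      a <- recs[[tp[i]]]; b <- recs[[tp[j]]]
      bad <- !is.na(a) & !is.na(b) & a > b
      out <- addViolation(out, recs$record_id[bad], tp[j], "time_ordering",
                          "error",
                          sprintf("%s (%d ms) precedes %s (%d ms)",
                                  tp[j], b[bad], tp[i], a[bad]))
    }
  }

  stable <- !is.na(defs$phase_class) & defs$phase_class == "stable"
  bad <- stable & !is.na(recs$mau_end_ms) & !is.na(recs$ga_end_ms) &
    recs$mau_end_ms != recs$ga_end_ms
  out <- addViolation(out, recs$record_id[bad], "ga_end_ms",
                      "stable_action_ends_with_mau", "error",
                      "stable action must end with MAU (ga_end != mau_end)")

  ## modifier gating by action attributes
  free <- !is.na(defs$free_limb) & defs$free_limb
  for (col in c("flexion", "orientation")) {
    bad <- !free & !is.na(defs$action) & !isNoValue(recs[[col]]) &
      tolower(trimws(recs[[col]])) != "none"
    out <- addViolation(out, recs$record_id[bad], col, "free_limb_only",
                        "warning",
                        sprintf("'%s' coded for non-free-limb action", col))
  }
  rep_act <- !is.na(defs$repetition) & defs$repetition
  bad <- !rep_act & !is.na(defs$action) & !isNoValue(recs$repetition_count)
  out <- addViolation(out, recs$record_id[bad], "repetition_count",
                      "repetition_actions_only", "warning",
                      "repetition count coded for non-repetition action")
  contact <- !is.na(defs$contact) & defs$contact
  bad <- !contact & !is.na(defs$action) & !isNoValue(recs$body_part_contact) &
    tolower(trimws(recs$body_part_contact)) != "none"
  out <- addViolation(out, recs$record_id[bad], "body_part_contact",
                      "contact_actions_only", "warning",
                      "contacted body part coded for non-contact action")

  if (!is.null(vocab)) {
    vars <- intersect(MODIFIER_VARIABLES, vocabularyVariables(vocab))
    for (col in vars) {
      vals <- recs[[col]]
      check <- which(!isNoValue(vals))
      for (k in check) {
        verdict <- validateValue(col, vals[k], vocab)
        if (!verdict$accepted)
          out <- addViolation(out, recs$record_id[k], col, "vocabulary",
                              "error", verdict$message)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Structural validation of communications
#'
#' Communication-level checks, returned as violations data (see
#' [validateRecords()] for conventions):
#' \itemize{
#'   \item records within a communication in temporal order (error, names the
#'     offending pair);
#'   \item a known outcome time must not precede the communication's earliest
#'     gesture start (error);
#'   \item a successful outcome without an outcome time (warning: "successful
#'     outcome lacks time") — legal, since outcome times may be unknown, but
#'     worth flagging because such communications drop out of latency
#'     analyses.
#' }
#'
#' @param x a [CommunicationSet-class].
#' @return violations `data.frame`; `record_id` holds the communication id
#'   for communication-level rules.
#' @export
validateCommunications <- function(x) {
  stopifnot(is(x, "CommunicationSet"))
  comms <- communications(x)
  recs <- records(x)
  out <- emptyViolations()

  bad <- comms$outcome_status == "success" & is.na(comms$outcome_ms)
  out <- addViolation(out, comms$communication_id[bad], "outcome_ms",
                      "success_has_outcome_time", "warning",
                      "successful outcome lacks time")

  for (cid in comms$communication_id) {
    rr <- recs[recs$communication_id == cid, , drop = FALSE]
    if (nrow(rr) == 0L) next
    st <- rr$g_start_ms
    if (nrow(rr) >= 2L) {
      known <- which(!is.na(st))
      if (length(known) >= 2L) {
        prev <- known[-length(known)]; nxt <- known[-1L]
        ooo <- st[prev] > st[nxt]
        out <- addViolation(out, cid, "g_start_ms", "record_ordering", "error",
                            sprintf("records out of order: %s (%d ms) before %s (%d ms)",
                                    rr$record_id[prev[ooo]], st[prev[ooo]],
                                    rr$record_id[nxt[ooo]], st[nxt[ooo]]))
      }
    }
    ot <- comms$outcome_ms[comms$communication_id == cid]
    if (!is.na(ot) && any(!is.na(st)) && ot < min(st, na.rm = TRUE))
      out <- addViolation(out, cid, "outcome_ms", "outcome_after_first_gesture",
                          "error",
                          sprintf("outcome at %d ms precedes first gesture start at %d ms",
                                  ot, min(st, na.rm = TRUE)))
  }
  rownames(out) <- NULL
  out
}

emptyViolations <- function() {
  data.frame(record_id = character(), field = character(), rule = character(),
             severity = character(), message = character(),
             stringsAsFactors = FALSE)
}

addViolation <- function(out, ids, field, rule, severity, message) {
  if (length(ids) == 0L || length(message) == 0L) return(out)
  rbind(out, data.frame(record_id = as.character(ids), field = field,
                        rule = rule, severity = severity,
                        message = as.character(message),
                        stringsAsFactors = FALSE))
}
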