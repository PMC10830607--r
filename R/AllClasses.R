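#' @import methods
NULL

## Canonical modifier variables, in the fixed order used for morph keys:
## action first, then body part, laterality, object, flexion, orientation,
## repetition, contact; audibility and directionality close the list.
MODIFIER_VARIABLES <- c(
  "body_part", "laterality", "object_used", "flexion", "orientation",
  "repetition_count", "body_part_contact", "audibility", "directionality"
)

INTENTIONALITY_FLAGS <- c("audience_checking", "response_waiting", "goal_persistence")

RECORD_TIME_COLS <- c("g_start_ms", "mau_end_ms", "ga_end_ms", "g_end_ms")

RECORD_REQUIRED <- c("record_id", "communication_id", "gesture_action")

RECORD_COLS <- c(
  "record_id", "communication_id", "signaller_id", "recipient_id",
  "gesture_action", RECORD_TIME_COLS, MODIFIER_VARIABLES, INTENTIONALITY_FLAGS
)

COMMUNICATION_COLS <- c(
  "communication_id", "species", "group", "signaller_id", "recipient_id",
  "context_pre", "context_post", "goal", "outcome_status", "outcome_ms",
  "gesture_recipient", "vocalisation_recipient",
  "behavioural_change_1", "behavioural_change_2",
  "location_signaller", "location_recipient", "visibility", "distance"
)

PHASE_CLASSES <- c("stable", "variable")
OUTCOME_STATUSES <- c("success", "failure", "unknown")

#' Gesture-action catalogue
#'
#' An S4 container for the catalogue of legal gesture actions. Each action
#' carries its phase class (`"stable"` actions end with the minimum action
#' unit; `"variable"` actions have an optional hold or repetition phase),
#' and flags stating whether the action requires contact with the recipient,
#' is a rhythmically repeated action, or is a free-limb action (one with no
#' required contact with an object, substrate or body part, for which the
#' flexion and orientation modifiers are meaningful).
#'
#' Construct with [GestureCatalogue()], read from CSV with [readCatalogue()],
#' or use the bundled [defaultCatalogue()].
#'
#' @slot actions a `data.frame` with columns `action`, `phase_class`,
#'   `contact`, `repetition`, `free_limb`, `definition`.
#' @seealso [classifyActionPhase()], [readCatalogue()]
#' @export
setClass("GestureCatalogue", representation(actions = "data.frame"))

setValidity("GestureCatalogue", function(object) {
  df <- object@actions
  need <- c("action", "phase_class", "contact", "repetition", "free_limb", "definition")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    return(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L)
    return("no actions defined")
  key <- tolower(trimws(df$action))
  if (anyDuplicated(key))
    return(sprintf("duplicate action name(s): %s",
                   paste(unique(df$action[duplicated(key)]), collapse = ", ")))
  bad <- setdiff(unique(df$phase_class), PHASE_CLASSES)
  if (length(bad) > 0L)
    return(sprintf("unknown phase-class label(s): %s", paste(bad, collapse = ", ")))
  if (!all(vapply(df[c("contact", "repetition", "free_limb")], is.logical, logical(1))))
    return("contact, repetition and free_limb must be logical")
  ## a repetition action is by definition continuable, hence variable
  if (any(df$repetition & df$phase_class != "variable"))
    return("repetition actions must have phase_class 'variable'")
  TRUE
})

#' Controlled-vocabulary set
#'
#' Legal values per modifier or communication-level variable. A variable
#' either enumerates its allowed values or is free text (e.g. the repetition
#' count). Value matching is case-insensitive and whitespace-trimmed; the
#' stored spelling is canonical.
#'
#' @slot values a `data.frame` with columns `variable`, `value`.
#' @slot free_text character vector of variable names that accept free text.
#' @seealso [validateValue()], [readVocabulary()], [defaultVocabulary()]
#' @export
setClass("VocabularySet",
         representation(values = "data.frame", free_text = "character"))

setValidity("VocabularySet", function(object) {
  df <- object@values
  if (!all(c("variable", "value") %in% names(df)))
    return("values must have columns 'variable' and 'value'")
  enumerated <- unique(df$variable)
  empty <- enumerated[vapply(enumerated, function(v)
    all(is.na(df$value[df$variable == v]) | !nzchar(trimws(df$value[df$variable == v]))),
    logical(1))]
  empty <- setdiff(empty, object@free_text)
  if (length(empty) > 0L)
    return(sprintf("variable(s) with no allowed values and no free-text flag: %s",
                   paste(empty, collapse = ", ")))
  TRUE
})

#' A set of coded gestural communications
#'
#' The central GestureKit container: a communication-level table (one row per
#' bounded interaction, with participants, contexts, goal, outcome status and
#' outcome time) and a record-level table (one row per gesture instance, with
#' the four measured time points, the modifier values, and the coded
#' intentionality flags).
#'
#' Time points are integer milliseconds from media start; `NA` is the explicit
#' "unknown" marker (never 0 or a negative sentinel). Records are kept ordered
#' by communication, then gesture start time, ties broken by record id.
#'
#' The four time points per gesture record are the gesture start, the end of
#' the minimum action unit (MAU), the end of the gesture action (equal to the
#' MAU end for stable action types), and the gesture end (body part back in
#' its neutral position).
#'
#' Structural validation beyond basic typing is deliberately not part of the
#' class validity: [validateRecords()] and [validateCommunications()] return
#' violations as data so that partially coded data can be inspected.
#'
#' @slot communications one row per communication; see [CommunicationSet()].
#' @slot records one row per gesture record.
#' @seealso [CommunicationSet()], [phaseDurations()], [responseLatency()],
#'   [segmentSequences()]
#' @export
setClass("CommunicationSet",
         representation(communications = "data.frame", records = "data.frame"))

setValidity("CommunicationSet", function(object) {
  comms <- object@communications
  recs <- object@records
  miss <- setdiff(COMMUNICATION_COLS, names(comms))
  if (length(miss) > 0L)
    return(sprintf("communications: missing column(s) %s", paste(miss, collapse = ", ")))
  miss <- setdiff(RECORD_COLS, names(recs))
  if (length(miss) > 0L)
    return(sprintf("records: missing column(s) %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(comms$communication_id))
    return("duplicate communication_id")
  if (anyDuplicated(recs$record_id))
    return("duplicate record_id")
  orphan <- setdiff(recs$communication_id, comms$communication_id)
  if (length(orphan) > 0L)
    return(sprintf("records reference unknown communication(s): %s",
                   paste(utils::head(orphan, 5L), collapse = ", ")))
  for (col in RECORD_TIME_COLS)
    if (!is.numeric(recs[[col]]))
      return(sprintf("records$%s must be numeric (ms)", col))
  if (!is.numeric(comms$outcome_ms))
    return("communications$outcome_ms must be numeric (ms)")
  tm <- unlist(recs[RECORD_TIME_COLS], use.names = FALSE)
  if (any(tm < 0, na.rm = TRUE))
    return("known time points must be >= 0 ms")
  if (any(comms$outcome_ms < 0, na.rm = TRUE))
    return("known outcome times must be >= 0 ms")
  bad <- setdiff(unique(comms$outcome_status), c(OUTCOME_STATUSES, NA))
  if (length(bad) > 0L)
    return(sprintf("unknown outcome_status label(s): %s", paste(bad, collapse = ", ")))
  TRUE
})

#' Construct a CommunicationSet
#'
#' Builds the central container from a communication-level and a record-level
#' `data.frame`. Missing optional columns are filled with `NA`; records are
#' ordered by communication, gesture start time (unknown starts last) and
#' record id. Time columns are coerced to integer milliseconds.
#'
#' @param communications `data.frame` with at least `communication_id`.
#'   Recognised columns: `species`, `group`, `signaller_id`, `recipient_id`,
#'   `context_pre`, `context_post`, `goal`, `outcome_status` (one of
#'   `"success"`, `"failure"`, `"unknown"`), `outcome_ms`,
#'   `gesture_recipient`, `vocalisation_recipient`, `behavioural_change_1`,
#'   `behavioural_change_2`, `location_signaller`, `location_recipient`,
#'   `visibility`, `distance`.
#' @param records `data.frame` with at least `record_id`, `communication_id`,
#'   `gesture_action`. Recognised columns: `signaller_id`, `recipient_id`, the
#'   four time points `g_start_ms`, `mau_end_ms`, `ga_end_ms`, `g_end_ms`
#'   (integer milliseconds, `NA` = unknown), the modifier variables
#'   (`body_part`, `laterality`, `object_used`, `flexion`, `orientation`,
#'   `repetition_count`, `body_part_contact`, `audibility`,
#'   `directionality`) and the logical intentionality flags
#'   (`audience_checking`, `response_waiting`, `goal_persistence`).
#' @return a [CommunicationSet-class] object.
#' @examples
#' cs <- CommunicationSet(
#'   communications = data.frame(communication_id = "c1",
#'                               outcome_status = "success", outcome_ms = 3450L),
#'   records = data.frame(record_id = "r1", communication_id = "c1",
#'                        gesture_action = "Reach", g_start_ms = 0L,
#'                        mau_end_ms = 740L, ga_end_ms = 740L, g_end_ms = 1000L)
#' )
#' nRecords(cs)
#' @export
CommunicationSet <- function(communications, records) {
  communications <- as.data.frame(communications, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"communication_id" %in% names(communications))
    stop("communications must have a 'communication_id' column")
  miss <- setdiff(RECORD_REQUIRED, names(records))
  if (nrow(records) > 0L && length(miss) > 0L)
    stop("records missing required column(s): ", paste(miss, collapse = ", "))

  communications <- fillColumns(communications, COMMUNICATION_COLS,
                                numeric_cols = "outcome_ms")
  records <- fillColumns(records, RECORD_COLS,
                         numeric_cols = RECORD_TIME_COLS,
                         logical_cols = INTENTIONALITY_FLAGS)
  for (col in RECORD_TIME_COLS) records[[col]] <- asMilliseconds(records[[col]])
  communications$outcome_ms <- asMilliseconds(communications$outcome_ms)
  communications$communication_id <- as.character(communications$communication_id)
  records$communication_id <- as.character(records$communication_id)
  records$record_id <- as.character(records$record_id)
  if (all(is.na(communications$outcome_status)))
    communications$outcome_status <- rep("unknown", nrow(communications))
  communications$outcome_status[is.na(communications$outcome_status)] <- "unknown"

  ## canonical ordering: communication (table order), start time, record id
  comm_rank <- match(records$communication_id, communications$communication_id)
  ord <- order(comm_rank, records$g_start_ms, records$record_id,
               na.last = TRUE, method = "radix")
  records <- records[ord, RECORD_COLS, drop = FALSE]
  rownames(records) <- NULL
  communications <- communications[, COMMUNICATION_COLS, drop = FALSE]
  rownames(communications) <- NULL
  new("CommunicationSet", communications = communications, records = records)
}

fillColumns <- function(df, cols, numeric_cols = character(),
                        logical_cols = character()) {
  for (col in setdiff(cols, names(df))) {
    df[[col]] <- rep(if (col %in% numeric_cols) NA_integer_
                     else if (col %in% logical_cols) NA
                     else NA_character_, nrow(df))
  }
  for (col in setdiff(setdiff(cols, numeric_cols), logical_cols))
    if (!is.character(df[[col]])) df[[col]] <- as.character(df[[col]])
  df
}

asMilliseconds <- function(x) {
  if (is.character(x)) x <- suppressWarnings(as.numeric(x))
  if (is.double(x)) {
    if (any(abs(x - round(x)) > 1e-6, na.rm = TRUE))
      stop("time points must be whole milliseconds")
    x <- round(x)
  }
  as.integer(x)
}

#' @rdname accessors
#' @export
setMethod("records", "CommunicationSet", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("communications", "CommunicationSet", function(x) x@communications)

#' @rdname accessors
#' @export
setMethod("nRecords", "CommunicationSet", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setMethod("nCommunications", "CommunicationSet", function(x) nrow(x@communications))

#' @rdname accessors
#' @export
setMethod("actions", "GestureCatalogue", function(x) x@actions)

#' @rdname accessors
#' @export
setMethod("vocabularyVariables", "VocabularySet", function(x)
  sort(unique(c(x@values$variable, x@free_text))))

setMethod("show", "GestureCatalogue", function(object) {
  df <- object@actions
  cat(sprintf("GestureCatalogue with %d gesture action(s)\n", nrow(df)))
  cat(sprintf("  stable: %d, variable: %d\n",
              sum(df$phase_class == "stable"), sum(df$phase_class == "variable")))
  cat("  actions:", paste(utils::head(df$action, 10L), collapse = ", "),
      if (nrow(df) > 10L) "..." else "", "\n")
})

setMethod("show", "VocabularySet", function(object) {
  vars <- vocabularyVariables(object)
  cat(sprintf("VocabularySet with %d variable(s)\n", length(vars)))
  for (v in utils::head(vars, 12L)) {
    if (v %in% object@free_text) {
      cat(sprintf("  %s: <free text>\n", v))
    } else {
      vals <- object@values$value[object@values$variable == v]
      cat(sprintf("  %s: %s%s\n", v, paste(utils::head(vals, 6L), collapse = ", "),
                  if (length(vals) > 6L) ", ..." else ""))
    }
  }
})

setMethod("show", "CommunicationSet", function(object) {
  cat(sprintf("CommunicationSet: %d communication(s), %d gesture record(s)\n",
              nCommunications(object), nRecords(object)))
  acts <- sort(table(object@records$gesture_action), decreasing = TRUE)
  if (length(acts) > 0L)
    cat("  actions:", paste(sprintf("%s (%d)", utils::head(names(acts), 6L),
                                    utils::head(as.integer(acts), 6L)),
                            collapse = ", "), "\n")
  st <- table(factor(object@communications$outcome_status, OUTCOME_STATUSES))
  cat(sprintf("  outcomes: %d success, %d failure, %d unknown\n",
              st[["success"]], st[["failure"]], st[["unknown"]]))
})
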