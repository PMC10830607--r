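#' Read a gesture-action catalogue from CSV
#'
#' The catalogue file is plain CSV (UTF-8, header row) with columns
#' `action, phase_class, contact, repetition, free_limb, definition`.
#' `phase_class` is `"stable"` or `"variable"`; the flag columns accept
#' TRUE/FALSE (or yes/no, 1/0). Action names must be unique
#' case-insensitively.
#'
#' The same schema is used when adapting spreadsheet-based action catalogues:
#' one row per action, with the stable/variable assignment made by whether the
#' action's description documents an optional hold or repetition phase.
#'
#' @param path CSV file path.
#' @return a [GestureCatalogue-class].
#' @seealso [writeCatalogue()], [defaultCatalogue()]
#' @export
readCatalogue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("action", "phase_class", "contact", "repetition", "free_limb")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("catalogue is missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("no actions defined")
  if (!"definition" %in% names(df)) df$definition <- ""
  df$action <- trimws(as.character(df$action))
  df$phase_class <- tolower(trimws(as.character(df$phase_class)))
  for (col in c("contact", "repetition", "free_limb")) df[[col]] <- asFlag(df[[col]], col)
  df$definition <- as.character(df$definition)
  new("GestureCatalogue",
      actions = df[, c("action", "phase_class", "contact", "repetition",
                       "free_limb", "definition")])
}

asFlag <- function(x, col) {
  if (is.logical(x)) return(x)
  x0 <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x0))
  out[x0 %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x0 %in% c("false", "f", "no", "n", "0")] <- FALSE
  if (anyNA(out)) stop(sprintf("column '%s' has non-boolean entries", col))
  out
}

#' Write a gesture-action catalogue to CSV
#'
#' Inverse of [readCatalogue()]: `readCatalogue(writeCatalogue(x, f))` is
#' value-identical to `x`.
#'
#' @param catalogue a [GestureCatalogue-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCatalogue <- function(catalogue, path) {
  stopifnot(is(catalogue, "GestureCatalogue"))
  utils::write.csv(actions(catalogue), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a catalogue from a data.frame
#'
#' @param actions `data.frame` with columns `action`, `phase_class`,
#'   `contact`, `repetition`, `free_limb` and optionally `definition`.
#' @return a [GestureCatalogue-class].
#' @export
GestureCatalogue <- function(actions) {
  actions <- as.data.frame(actions, stringsAsFactors = FALSE)
  if (!"definition" %in% names(actions)) actions$definition <- ""
  new("GestureCatalogue", actions = actions)
}

#' Default gesture-action catalogue
#'
#' A starter catalogue covering common great-ape gesture actions. Variable
#' actions are those with an optional hold phase (reach, raise, present) or a
#' rhythmic repetition phase (hit, stomp); stable actions (beckon, fling,
#' push, touch) move from the action stroke directly into recovery, so their
#' gesture action always ends with the minimum action unit. Free-limb actions
#' are those with no required contact with an object, substrate or body part;
#' only for these are the flexion and orientation modifiers meaningful.
#'
#' The catalogue is a demonstration default and is meant to be extended per
#' study (and per species) via [readCatalogue()].
#'
#' @return a [GestureCatalogue-class].
#' @examples
#' classifyActionPhase("Reach", defaultCatalogue())
#' @export
defaultCatalogue <- function() {
  GestureCatalogue(data.frame(
    action = c("Reach", "Raise", "Present", "Beckon", "Fling",
               "Hit", "Stomp", "Push", "Touch"),
    phase_class = c("variable", "variable", "variable", "stable", "stable",
                    "variable", "variable", "stable", "stable"),
    contact = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    repetition = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    free_limb = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    definition = c(
      "Coordinated extension of a limb towards the recipient; optional hold.",
      "Limb lifted and kept in position towards the recipient; optional hold.",
      "Body part exposed/offered to the recipient; held until outcome.",
      "Scooping movement away from and back towards the signaller.",
      "Loose rapid throw-out of the limb away from the body.",
      "Forceful contact of a body part with the recipient; may repeat.",
      "Foot brought down forcefully on a surface; may repeat.",
      "Sustained directed pressure against the recipient, mechanically ineffective.",
      "Brief light contact of a body part with the recipient."),
    stringsAsFactors = FALSE))
}

#' Look up the phase class of a gesture action
#'
#' Matching is case-insensitive and whitespace-trimmed.
#'
#' @param name action name.
#' @param catalogue a [GestureCatalogue-class].
#' @return `"stable"` or `"variable"`.
#' @examples
#' classifyActionPhase("beckon", defaultCatalogue())  # "stable"
#' @export
classifyActionPhase <- function(name, catalogue) {
  stopifnot(is(catalogue, "GestureCatalogue"), length(name) >= 1L)
  df <- actions(catalogue)
  i <- match(tolower(trimws(name)), tolower(trimws(df$action)))
  if (anyNA(i))
    stop("unknown gesture action(s): ",
         paste(unique(name[is.na(i)]), collapse = ", "))
  df$phase_class[i]
}

## case/whitespace-insensitive catalogue lookup; NA for unknown names
matchAction <- function(name, catalogue) {
  df <- actions(catalogue)
  df[match(tolower(trimws(name)), tolower(trimws(df$action))), , drop = FALSE]
}

#' Construct a vocabulary set
#'
#' @param values `data.frame` with columns `variable`, `value` (one row per
#'   allowed value).
#' @param free_text character vector of variable names that accept free text
#'   (e.g. the repetition count).
#' @return a [VocabularySet-class].
#' @export
VocabularySet <- function(values = data.frame(variable = character(),
                                              value = character()),
                          free_text = character()) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  values$variable <- as.character(values$variable)
  values$value <- as.character(values$value)
  new("VocabularySet", values = values, free_text = as.character(free_text))
}

#' Read a controlled-vocabulary table from CSV
#'
#' The vocabulary file is plain CSV with columns `variable, value` and an
#' optional logical `free_text` column; any row with `free_text = TRUE` marks
#' its variable as free text (the row's `value` may be empty).
#'
#' @param path CSV file path.
#' @return a [VocabularySet-class].
#' @seealso [writeVocabulary()], [defaultVocabulary()]
#' @export
readVocabulary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  miss <- setdiff(c("variable", "value"), names(df))
  if (length(miss) > 0L)
    stop("vocabulary is missing required column(s): ", paste(miss, collapse = ", "))
  ft <- character()
  if ("free_text" %in% names(df)) {
    flag <- asFlag(ifelse(is.na(df$free_text) | df$free_text == "", "FALSE",
                          df$free_text), "free_text")
    ft <- unique(df$variable[flag])
    df <- df[!flag | nzchar(trimws(df$value)), , drop = FALSE]
  }
  df <- df[nzchar(trimws(df$value)), c("variable", "value"), drop = FALSE]
  VocabularySet(df, free_text = ft)
}

#' Write a controlled-vocabulary table to CSV
#'
#' @param vocab a [VocabularySet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "VocabularySet"))
  df <- vocab@values
  df$free_text <- FALSE
  if (length(vocab@free_text) > 0L)
    df <- rbind(df, data.frame(variable = vocab@free_text, value = "",
                               free_text = TRUE, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Default controlled vocabularies
#'
#' Starter vocabularies for the modifier variables describing the physical
#' production of a gesture (body part, laterality, object use, flexion,
#' orientation, repetition count, contacted recipient body part, audibility,
#' directionality) and for the communication-level context and goal
#' variables. The repetition count is a free-text variable.
#'
#' @return a [VocabularySet-class].
#' @export
defaultVocabulary <- function() {
  v <- list(
    body_part = c("Arm", "Hand", "Leg", "Foot", "Head", "Body", "Fingers"),
    laterality = c("Left", "Right", "Both", "Unknown"),
    object_used = c("None", "Branch", "Stone", "Vegetation", "Other"),
    flexion = c("None", "Elbow", "Wrist", "Fingers", "Multiple", "Unknown"),
    orientation = c("Up", "Down", "Side", "Towards", "Away", "Unknown"),
    body_part_contact = c("None", "Arm", "Hand", "Leg", "Foot", "Head",
                          "Back", "Torso", "Unknown"),
    audibility = c("Silent", "Audible", "Unknown"),
    directionality = c("Present", "Absent", "Unknown"),
    context = c("Resting", "Grooming", "Feeding", "Travelling", "Playing",
                "Sex", "Aggression", "Other", "Unknown"),
    goal = c("Grooming", "Travel", "Food", "Play", "Sex", "StopBehaviour",
             "Attention", "Other", "Unknown")
  )
  VocabularySet(
    data.frame(variable = rep(names(v), lengths(v)),
               value = unlist(v, use.names = FALSE), stringsAsFactors = FALSE),
    free_text = "repetition_count")
}

#' Validate a coded value against a controlled vocabulary
#'
#' Accepts the value if the variable allows free text or if the value matches
#' one of the variable's allowed values (case-insensitive, trimmed). `NA` and
#' `"no value"` are always accepted: absence of a value is legal coding.
#'
#' @param variable_name variable to check against.
#' @param value the coded value.
#' @param vocab a [VocabularySet-class].
#' @return a list with elements `accepted` (logical), `variable`, `value`,
#'   `canonical` (the catalogue spelling when accepted) and `message`.
#' @examples
#' validateValue("body_part", "arm", defaultVocabulary())$accepted  # TRUE
#' @export
validateValue <- function(variable_name, value, vocab) {
  stopifnot(is(vocab, "VocabularySet"))
  if (!variable_name %in% vocabularyVariables(vocab))
    stop("unknown variable name: ", variable_name)
  if (isNoValue(value))
    return(list(accepted = TRUE, variable = variable_name, value = value,
                canonical = NA_character_, message = "no value"))
  if (variable_name %in% vocab@free_text)
    return(list(accepted = TRUE, variable = variable_name, value = value,
                canonical = as.character(value), message = "free-text variable"))
  allowed <- vocab@values$value[vocab@values$variable == variable_name]
  i <- match(tolower(trimws(value)), tolower(trimws(allowed)))
  if (is.na(i))
    return(list(accepted = FALSE, variable = variable_name, value = value,
                canonical = NA_character_,
                message = sprintf("value '%s' not in vocabulary for '%s'",
                                  value, variable_name)))
  list(accepted = TRUE, variable = variable_name, value = value,
       canonical = allowed[i], message = "ok")
}

## "no value" marker: NA, empty, or an explicit "no value" label
isNoValue <- function(x) {
  is.na(x) | !nzchar(trimws(as.character(x))) |
    tolower(trimws(as.character(x))) %in% c("no value", "no_value", "na")
}
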