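#' Canonical morph key of gesture records
#'
#' A *morph* is a recurring combination of a gesture action with modifier
#' values, constructed bottom-up after coding with no a-priori assumption
#' about gesture "types". The morph key is the canonical name of such a
#' combination at a chosen resolution: the gesture action (catalogue
#' spelling) followed by the included modifier values in a fixed variable
#' order — body part, laterality, object used, flexion, orientation,
#' repetition count, contacted body part, audibility, directionality —
#' joined with `|`. Modifiers not named in `resolution` are ignored
#' (lumping); unknown / "no value" entries are omitted from the key, so
#' missing data lump rather than split, unless `strict_unknown = TRUE`,
#' which keys unknowns as an explicit `?` level.
#'
#' @param x a [CommunicationSet-class] or record-level `data.frame`.
#' @param resolution character vector of modifier variables to include
#'   (subset of `body_part`, `laterality`, `object_used`, `flexion`,
#'   `orientation`, `repetition_count`, `body_part_contact`, `audibility`,
#'   `directionality`); empty for action-level keys.
#' @param catalogue optional [GestureCatalogue-class]; when given, action
#'   names are canonicalised to the catalogue spelling (and unknown actions
#'   are an error).
#' @param strict_unknown treat unknown modifier values as their own level.
#' @return character vector of keys, one per record.
#' @examples
#' r <- data.frame(record_id = "r1", communication_id = "c1",
#'                 gesture_action = "Reach", body_part = "Arm",
#'                 laterality = "Right", flexion = "Elbow",
#'                 orientation = "Side")
#' morphKey(r, c("body_part", "laterality", "flexion", "orientation"))
#' # "Reach|Arm|Right|Elbow|Side"
#' @export
morphKey <- function(x, resolution = character(), catalogue = NULL,
                     strict_unknown = FALSE) {
  recs <- if (is(x, "CommunicationSet")) records(x) else as.data.frame(x)
  bad <- setdiff(resolution, MODIFIER_VARIABLES)
  if (length(bad) > 0L)
    stop("unknown modifier variable(s) in resolution: ",
         paste(bad, collapse = ", "))
  action <- trimws(recs$gesture_action)
  if (!is.null(catalogue)) {
    defs <- matchAction(action, catalogue)
    if (anyNA(defs$action))
      stop("unknown gesture action(s): ",
           paste(unique(action[is.na(defs$action)]), collapse = ", "))
    action <- defs$action
  }
  ## fixed canonical variable order, independent of the order given
  resolution <- MODIFIER_VARIABLES[MODIFIER_VARIABLES %in% resolution]
  parts <- lapply(resolution, function(var) {
    v <- if (var %in% names(recs)) trimws(as.character(recs[[var]]))
         else rep(NA_character_, nrow(recs))
    no_val <- isNoValue(v)
    v[no_val] <- if (strict_unknown) "?" else NA_character_
    v
  })
  keys <- action
  for (p in parts) {
    add <- !is.na(p)
    keys[add] <- paste(keys[add], p[add], sep = "|")
  }
  keys
}

#' Build a gesture repertoire at a chosen resolution
#'
#' Counts morph keys (see [morphKey()]) per group, yielding the repertoire —
#' the inventory of distinct gesture forms — and its size. Coarsening the
#' resolution (dropping modifier variables) can only merge keys, so the
#' repertoire size is monotone non-increasing under coarsening.
#'
#' @param x a [CommunicationSet-class] or record-level `data.frame`.
#' @param resolution modifier variables to include; see [morphKey()].
#' @param group_by character vector of record-level grouping columns (e.g.
#'   `"signaller_id"`), or `NULL` for one overall repertoire.
#' @param catalogue,strict_unknown passed to [morphKey()].
#' @return `data.frame` with the grouping columns, `morph`, `n` (instance
#'   count), sorted by group and decreasing count; the per-group number of
#'   distinct keys is available via [repertoireSize()].
#' @export
buildRepertoire <- function(x, resolution = character(), group_by = NULL,
                            catalogue = NULL, strict_unknown = FALSE) {
  recs <- if (is(x, "CommunicationSet")) records(x) else as.data.frame(x)
  if (nrow(recs) == 0L) {
    out <- data.frame(morph = character(), n = integer(),
                      stringsAsFactors = FALSE)
    for (g in rev(group_by)) out <- cbind(stats::setNames(
      data.frame(character(), stringsAsFactors = FALSE), g), out)
    return(out)
  }
  keys <- morphKey(recs, resolution, catalogue, strict_unknown)
  if (is.null(group_by)) {
    tab <- table(keys)
    out <- data.frame(morph = names(tab), n = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n, out$morph), , drop = FALSE]
  } else {
    stopifnot(all(group_by %in% names(recs)))
    df <- cbind(recs[, group_by, drop = FALSE], morph = keys)
    agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                            by = df[, c(group_by, "morph"), drop = FALSE],
                            FUN = sum)
    out <- agg[do.call(order, c(agg[group_by], list(-agg$n, agg$morph))), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Repertoire sizes from a repertoire table
#'
#' @param repertoire output of [buildRepertoire()].
#' @param group_by the grouping columns used, or `NULL`.
#' @return `data.frame` of the grouping columns and `size` (number of
#'   distinct morphs); a single total when ungrouped.
#' @export
repertoireSize <- function(repertoire, group_by = NULL) {
  if (is.null(group_by))
    return(data.frame(size = length(unique(repertoire$morph))))
  agg <- stats::aggregate(list(size = repertoire$morph),
                          by = repertoire[, group_by, drop = FALSE],
                          FUN = function(v) length(unique(v)))
  rownames(agg) <- NULL
  agg
}

#' Export a morph feature matrix
#'
#' One row per gesture record, one column per action/modifier variable, for
#' use with external clustering tools that group morphs probabilistically.
#' No clustering is performed here.
#'
#' @param x a [CommunicationSet-class] or record-level `data.frame`.
#' @param resolution modifier variables to include (default: all).
#' @return `data.frame` with `record_id`, `gesture_action` and one column
#'   per included modifier.
#' @export
morphFeatureMatrix <- function(x, resolution = MODIFIER_VARIABLES) {
  recs <- if (is(x, "CommunicationSet")) records(x) else as.data.frame(x)
  bad <- setdiff(resolution, MODIFIER_VARIABLES)
  if (length(bad) > 0L)
    stop("unknown modifier variable(s): ", paste(bad, collapse = ", "))
  cols <- c("record_id", "gesture_action",
            MODIFIER_VARIABLES[MODIFIER_VARIABLES %in% resolution])
  out <- recs[, intersect(cols, names(recs)), drop = FALSE]
  rownames(out) <- NULL
  out
}
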