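#' Default tier map for the GestureKit EAF template
#'
#' Names the annotation tiers that hold each piece of the data model:
#' the communication grouping tier, the gesture-record (parent) tier, the
#' alignable child tiers marking the minimum-action-unit and gesture-action
#' phase ends, the outcome-time tier, and the reference-annotation child
#' tiers carrying modifier and communication-level variables. Pass a modified
#' copy to [assembleRecords()] / [writeEAF()] to adapt to other templates
#' (e.g. ones that code communication membership by file rather than by
#' tier).
#'
#' @return a named list understood by [assembleRecords()] and [writeEAF()].
#' @export
defaultTierMap <- function() {
  list(
    communication_tier = "Communication",
    record_tier = "Gesture_record",
    record_id_tier = "Record_ID",
    mau_tier = "MAU",
    ga_tier = "Gesture_action",
    outcome_time_tier = "Outcome_time",
    modifier_tiers = c(
      body_part = "Body_part", laterality = "Signaller_laterality",
      object_used = "Object_used", flexion = "Flexion",
      orientation = "Orientation", repetition_count = "Repetition_count",
      body_part_contact = "Body_part_contact", audibility = "Audibility",
      directionality = "Directionality"),
    record_field_tiers = c(
      signaller_id = "Signaller", recipient_id = "Recipient",
      audience_checking = "Audience_checking",
      response_waiting = "Response_waiting",
      goal_persistence = "Goal_persistence"),
    comm_field_tiers = c(
      species = "Species", group = "Group",
      signaller_id = "Comm_signaller", recipient_id = "Comm_recipient",
      context_pre = "Context_pre", context_post = "Context_post",
      goal = "Goal", outcome_status = "Outcome_status",
      gesture_recipient = "Gesture_recipient",
      vocalisation_recipient = "Vocalisation_recipient",
      behavioural_change_1 = "Behavioural_change_1",
      behavioural_change_2 = "Behavioural_change_2",
      location_signaller = "Location_signaller",
      location_recipient = "Location_recipient",
      visibility = "Visibility", distance = "Distance")
  )
}

#' Parse an ELAN EAF annotation file
#'
#' Reads an EAF (ELAN XML) document: time slots are resolved to millisecond
#' time points (slots without a `TIME_VALUE` become `NA` = unknown), and
#' reference annotations (child-tier annotations linked to a parent
#' annotation rather than to time slots) inherit their parent's resolved
#' times, following chains of references.
#'
#' @param path EAF file path.
#' @return an object of class `elanDocument`: a list with
#'   \describe{
#'     \item{tiers}{`data.frame(tier_id, parent_tier_id, participant)`}
#'     \item{annotations}{`data.frame(annotation_id, tier_id, start_ms,
#'       end_ms, value, ref)` where `ref` is the parent annotation id for
#'       reference annotations and `NA` for alignable ones}
#'     \item{media}{character vector of media URLs}
#'   }
#' @seealso [parseTabExport()], [assembleRecords()], [writeEAF()]
#' @export
parseEAF <- function(path) {
  doc <- xml2::read_xml(path)
  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_id <- xml2::xml_attr(slots, "TIME_SLOT_ID")
  slot_val <- suppressWarnings(as.integer(xml2::xml_attr(slots, "TIME_VALUE")))
  names(slot_val) <- slot_id

  tier_nodes <- xml2::xml_find_all(doc, ".//TIER")
  tiers <- data.frame(
    tier_id = xml2::xml_attr(tier_nodes, "TIER_ID"),
    parent_tier_id = xml2::xml_attr(tier_nodes, "PARENT_REF"),
    participant = xml2::xml_attr(tier_nodes, "PARTICIPANT"),
    stringsAsFactors = FALSE)

  ann_list <- lapply(seq_along(tier_nodes), function(i) {
    tn <- tier_nodes[[i]]
    al <- xml2::xml_find_all(tn, ".//ALIGNABLE_ANNOTATION")
    rf <- xml2::xml_find_all(tn, ".//REF_ANNOTATION")
    rbind(
      data.frame(
        annotation_id = xml2::xml_attr(al, "ANNOTATION_ID"),
        tier_id = rep(tiers$tier_id[i], length(al)),
        ts1 = xml2::xml_attr(al, "TIME_SLOT_REF1"),
        ts2 = xml2::xml_attr(al, "TIME_SLOT_REF2"),
        value = xml2::xml_text(xml2::xml_find_first(al, "./ANNOTATION_VALUE")),
        ref = rep(NA_character_, length(al)), stringsAsFactors = FALSE),
      data.frame(
        annotation_id = xml2::xml_attr(rf, "ANNOTATION_ID"),
        tier_id = rep(tiers$tier_id[i], length(rf)),
        ts1 = rep(NA_character_, length(rf)),
        ts2 = rep(NA_character_, length(rf)),
        value = xml2::xml_text(xml2::xml_find_first(rf, "./ANNOTATION_VALUE")),
        ref = xml2::xml_attr(rf, "ANNOTATION_REF"), stringsAsFactors = FALSE))
  })
  ann <- do.call(rbind, c(ann_list, list(emptyAnnotationFrame(ts = TRUE))))

  dangling <- setdiff(stats::na.omit(c(ann$ts1, ann$ts2)), slot_id)
  if (length(dangling) > 0L)
    stop("dangling TIME_SLOT reference(s): ", paste(dangling, collapse = ", "))
  ann$start_ms <- unname(slot_val[ann$ts1])
  ann$end_ms <- unname(slot_val[ann$ts2])

  dangling <- setdiff(stats::na.omit(ann$ref), ann$annotation_id)
  if (length(dangling) > 0L)
    stop("reference annotation points to missing parent id(s): ",
         paste(dangling, collapse = ", "))
  ## resolve reference chains to time points
  repeat {
    i <- which(!is.na(ann$ref) & is.na(ann$start_ms) & is.na(ann$end_ms))
    if (length(i) == 0L) break
    p <- match(ann$ref[i], ann$annotation_id)
    st <- ann$start_ms[p]; en <- ann$end_ms[p]
    changed <- !is.na(st) | !is.na(en)
    if (!any(changed)) break
    ann$start_ms[i[changed]] <- st[changed]
    ann$end_ms[i[changed]] <- en[changed]
  }
  ann <- ann[, c("annotation_id", "tier_id", "start_ms", "end_ms", "value", "ref")]
  rownames(ann) <- NULL

  media <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//HEADER/MEDIA_DESCRIPTOR"), "MEDIA_URL")
  structure(list(tiers = tiers, annotations = ann, media = media),
            class = "elanDocument")
}

emptyAnnotationFrame <- function(ts = FALSE) {
  df <- data.frame(annotation_id = character(), tier_id = character(),
                   value = character(), ref = character(),
                   stringsAsFactors = FALSE)
  if (ts) { df$ts1 <- character(); df$ts2 <- character() }
  else { df$start_ms <- integer(); df$end_ms <- integer() }
  df[, if (ts) c("annotation_id", "tier_id", "ts1", "ts2", "value", "ref")
     else c("annotation_id", "tier_id", "start_ms", "end_ms", "value", "ref")]
}

#' @export
print.elanDocument <- function(x, ...) {
  cat(sprintf("elanDocument: %d tier(s), %d annotation(s)\n",
              nrow(x$tiers), nrow(x$annotations)))
  invisible(x)
}

#' Parse a tab-delimited ELAN export
#'
#' Reads the flat tab-delimited export of a tiered document: one row per
#' annotation with its tier, begin/end time and value. Reference links
#' between parent and child annotations are not present in exports; they are
#' recovered later by temporal containment in [assembleRecords()].
#'
#' Column headers are matched case-insensitively; accepted names are
#' `tier`/`tier_id`, `start_ms`/`begin time - msec`/`begin`, `end_ms`/
#' `end time - msec`/`end`, and `value`/`annotation`.
#'
#' @param path tab-delimited file path.
#' @return an `elanDocument` (see [parseEAF()]) with `ref` all `NA`.
#' @export
parseTabExport <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          encoding = "UTF-8")
  nm <- tolower(trimws(names(df)))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("tab export is missing a ", what, " column")
    df[[i]]
  }
  tier <- as.character(pick(c("tier", "tier_id"), "tier"))
  start_raw <- pick(c("start_ms", "begin time - msec", "begin_time_msec", "begin", "start"), "start-time")
  end_raw <- pick(c("end_ms", "end time - msec", "end_time_msec", "end"), "end-time")
  value <- as.character(pick(c("value", "annotation"), "value"))
  toMs <- function(x, what) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0L)
      stop(sprintf("unparseable %s time in row(s): %s", what,
                   paste(bad, collapse = ", ")))
    out
  }
  start_ms <- toMs(start_raw, "begin")
  end_ms <- toMs(end_raw, "end")
  if (nrow(df) == 0L) warning("empty export: no annotations")
  bad <- which(!is.na(start_ms) & !is.na(end_ms) & end_ms < start_ms)
  if (length(bad) > 0L)
    stop("end time precedes start time in row(s): ", paste(bad, collapse = ", "))
  ann <- data.frame(
    annotation_id = sprintf("t%d", seq_len(nrow(df))),
    tier_id = tier, start_ms = start_ms, end_ms = end_ms, value = value,
    ref = rep(NA_character_, nrow(df)), stringsAsFactors = FALSE)
  tiers <- data.frame(tier_id = unique(tier),
                      parent_tier_id = rep(NA_character_, length(unique(tier))),
                      participant = rep(NA_character_, length(unique(tier))),
                      stringsAsFactors = FALSE)
  structure(list(tiers = tiers, annotations = ann, media = character()),
            class = "elanDocument")
}

#' Write a tab-delimited export of a parsed document
#'
#' Produces the flat `tier / start_ms / end_ms / value` export corresponding
#' to a parsed `elanDocument`, mimicking what annotation software exports
#' (reference links are dropped, times are kept).
#'
#' @param doc an `elanDocument`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTabExport <- function(doc, path) {
  stopifnot(inherits(doc, "elanDocument"))
  ann <- doc$annotations
  utils::write.table(
    data.frame(tier = ann$tier_id, start_ms = ann$start_ms,
               end_ms = ann$end_ms, value = ann$value,
               stringsAsFactors = FALSE),
    path, sep = "\t", row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

## midpoint temporal-containment linking (half-open [start, end) spans):
## a child is attached to the parent annotation whose span contains the
## child's midpoint; ties go to the earliest-starting candidate parent.
containingParent <- function(child_start, child_end, parents) {
  if (nrow(parents) == 0L) return(NA_integer_)
  if (is.na(child_start)) return(NA_integer_)
  if (is.na(child_end)) child_end <- child_start
  mid <- (as.numeric(child_start) + as.numeric(child_end)) / 2
  ok <- which(!is.na(parents$start_ms) & !is.na(parents$end_ms) &
                mid >= parents$start_ms &
                (mid < parents$end_ms | parents$start_ms == parents$end_ms))
  if (length(ok) == 0L) return(NA_integer_)
  ok[order(parents$start_ms[ok])][1]
}

#' Assemble communications and gesture records from parsed annotations
#'
#' Turns an `elanDocument` (from [parseEAF()] or [parseTabExport()]) into a
#' [CommunicationSet-class] under a tier map (see [defaultTierMap()]).
#' Child values are attached to their gesture record by annotation reference
#' where available (EAF) and by midpoint temporal containment otherwise (tab
#' exports, and the alignable MAU / gesture-action phase tiers). Gesture
#' records are attached to the communication annotation whose span contains
#' them. A record lacking a phase-end annotation gets an unknown (`NA`) time
#' point, never an error.
#'
#' @param doc an `elanDocument`.
#' @param catalogue optional [GestureCatalogue-class]; when supplied together
#'   with `vocab`, assembled data are validated and the violations are
#'   attached as attribute `"violations"`.
#' @param vocab optional [VocabularySet-class].
#' @param tier_map tier map, default [defaultTierMap()].
#' @return a [CommunicationSet-class]; orphan child annotations (contained in
#'   no parent) raise warnings; two values of one variable on the same record
#'   raise an error.
#' @export
assembleRecords <- function(doc, catalogue = NULL, vocab = NULL,
                            tier_map = defaultTierMap()) {
  stopifnot(inherits(doc, "elanDocument"))
  ann <- doc$annotations
  present <- function(tier) ann[ann$tier_id %in% tier, , drop = FALSE]
  named_tiers <- c(tier_map$communication_tier, tier_map$record_tier)
  missing_tiers <- setdiff(named_tiers, doc$tiers$tier_id)
  if (length(missing_tiers) > 0L && nrow(ann) > 0L)
    stop("tier(s) named in tier map absent from document: ",
         paste(missing_tiers, collapse = ", "))

  comm_ann <- present(tier_map$communication_tier)
  rec_ann <- present(tier_map$record_tier)

  ## attach a child annotation table to parent annotations: by annotation
  ## reference where present, else by shared start time (phase tiers start
  ## with their parent), else by midpoint containment
  linkChildren <- function(children, parents) {
    if (nrow(children) == 0L)
      return(integer(0))
    idx <- match(children$ref, parents$annotation_id)
    for (k in which(is.na(idx))) {
      same_start <- which(!is.na(parents$start_ms) &
                            !is.na(children$start_ms[k]) &
                            parents$start_ms == children$start_ms[k])
      idx[k] <- if (length(same_start) == 1L) same_start
      else containingParent(children$start_ms[k], children$end_ms[k], parents)
    }
    idx
  }
  childValue <- function(tier, parents, what) {
    vals <- rep(NA_character_, nrow(parents))
    if (is.null(tier) || is.na(tier)) return(vals)
    ch <- present(tier)
    if (nrow(ch) == 0L) return(vals)
    idx <- linkChildren(ch, parents)
    orphan <- is.na(idx)
    if (any(orphan))
      warning(sprintf("orphan annotation(s) on tier '%s' contained in no %s: %s",
                      tier, what,
                      paste(ch$annotation_id[orphan], collapse = ", ")))
    dup <- idx[!is.na(idx)][duplicated(idx[!is.na(idx)])]
    if (length(dup) > 0L)
      stop(sprintf("two values of '%s' attached to one %s (annotation(s) %s)",
                   tier, what,
                   paste(parents$annotation_id[unique(dup)], collapse = ", ")))
    vals[idx[!orphan]] <- ch$value[!orphan]
    vals
  }
  childEnd <- function(tier, parents) {
    vals <- rep(NA_integer_, nrow(parents))
    if (is.null(tier) || is.na(tier)) return(vals)
    ch <- present(tier)
    if (nrow(ch) == 0L) return(vals)
    idx <- linkChildren(ch, parents)
    if (anyNA(idx))
      warning(sprintf("orphan phase annotation(s) on tier '%s'", tier))
    dup <- idx[!is.na(idx)][duplicated(idx[!is.na(idx)])]
    if (length(dup) > 0L)
      stop(sprintf("two phase annotations of '%s' on one record", tier))
    vals[idx[!is.na(idx)]] <- ch$end_ms[!is.na(idx)]
    vals
  }

  ## gesture records
  rec <- data.frame(
    record_id = rec_ann$annotation_id,
    gesture_action = rec_ann$value,
    g_start_ms = rec_ann$start_ms,
    g_end_ms = rec_ann$end_ms,
    stringsAsFactors = FALSE)
  rid <- childValue(tier_map$record_id_tier, rec_ann, "gesture record")
  rec$record_id[!is.na(rid)] <- rid[!is.na(rid)]
  rec$mau_end_ms <- childEnd(tier_map$mau_tier, rec_ann)
  rec$ga_end_ms <- childEnd(tier_map$ga_tier, rec_ann)
  for (var in names(tier_map$modifier_tiers))
    rec[[var]] <- childValue(tier_map$modifier_tiers[[var]], rec_ann,
                             "gesture record")
  for (var in names(tier_map$record_field_tiers)) {
    v <- childValue(tier_map$record_field_tiers[[var]], rec_ann,
                    "gesture record")
    rec[[var]] <- if (var %in% INTENTIONALITY_FLAGS) as.logical(v) else v
  }

  ## communications
  comm <- data.frame(communication_id = comm_ann$value, stringsAsFactors = FALSE)
  if (nrow(comm) > 0L && anyDuplicated(comm$communication_id))
    stop("duplicate communication annotation value(s)")
  for (var in names(tier_map$comm_field_tiers))
    comm[[var]] <- childValue(tier_map$comm_field_tiers[[var]], comm_ann,
                              "communication")
  out_ann <- present(tier_map$outcome_time_tier)
  comm$outcome_ms <- NA_integer_
  if (nrow(out_ann) > 0L && nrow(comm_ann) > 0L) {
    idx <- linkChildren(out_ann, comm_ann)
    if (any(is.na(idx)))
      warning("orphan outcome-time annotation(s)")
    comm$outcome_ms[idx[!is.na(idx)]] <- out_ann$start_ms[!is.na(idx)]
  }

  ## attach records to communications by containment
  if (nrow(rec) > 0L) {
    idx <- vapply(seq_len(nrow(rec)), function(k)
      containingParent(rec$g_start_ms[k], rec$g_end_ms[k], comm_ann),
      integer(1))
    rec$communication_id <- comm$communication_id[idx]
    lone <- is.na(idx)
    if (any(lone)) {
      warning(sprintf("gesture record(s) contained in no communication: %s",
                      paste(rec$record_id[lone], collapse = ", ")))
      rec$communication_id[lone] <- paste0("comm_", rec$record_id[lone])
      extra <- data.frame(communication_id = rec$communication_id[lone],
                          stringsAsFactors = FALSE)
      comm <- merge(comm, extra, all = TRUE, sort = FALSE)
    }
  } else {
    rec$communication_id <- character()
  }

  cs <- CommunicationSet(comm, rec)
  if (!is.null(catalogue)) {
    viol <- rbind(validateRecords(cs, catalogue, vocab),
                  validateCommunications(cs))
    attr(cs, "violations") <- viol
  }
  cs
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a CommunicationSet as an ELAN EAF file
#'
#' Emits an EAF document under the GestureKit template: one alignable
#' communication tier, one alignable gesture-record tier (annotation value =
#' gesture action), alignable child tiers whose annotation ends mark the MAU
#' and gesture-action phase ends, and reference-annotation child tiers for
#' record ids, modifiers, intentionality flags and communication-level
#' variables. Unknown (`NA`) values and time points are simply not annotated.
#' Controlled vocabularies, when supplied, are embedded in the document so
#' coding tools can constrain entry.
#'
#' The output round-trips: `assembleRecords(parseEAF(writeEAF(x)))` restores
#' `x`.
#'
#' @param x a [CommunicationSet-class].
#' @param path output file path.
#' @param vocab optional [VocabularySet-class] to embed.
#' @param tier_map tier map, default [defaultTierMap()].
#' @param media_url media URL written to the header.
#' @return `path`, invisibly.
#' @seealso [writeTemplateEAF()], [parseEAF()]
#' @export
writeEAF <- function(x, path, vocab = NULL, tier_map = defaultTierMap(),
                     media_url = "unknown://media") {
  stopifnot(is(x, "CommunicationSet"))
  comms <- communications(x)
  recs <- records(x)

  slot_env <- new.env(parent = emptyenv())
  slot_env$n <- 0L
  slot_env$rows <- character()
  newSlot <- function(ms) {
    slot_env$n <- slot_env$n + 1L
    id <- sprintf("ts%d", slot_env$n)
    slot_env$rows <- c(slot_env$rows, sprintf(
      '        <TIME_SLOT TIME_SLOT_ID="%s"%s/>', id,
      if (is.na(ms)) "" else sprintf(' TIME_VALUE="%d"', ms)))
    id
  }
  ann_env <- new.env(parent = emptyenv())
  ann_env$n <- 0L
  newAnnId <- function() {
    ann_env$n <- ann_env$n + 1L
    sprintf("a%d", ann_env$n)
  }
  alignable <- function(id, t1, t2, value) sprintf(
    '            <ANNOTATION>\n                <ALIGNABLE_ANNOTATION ANNOTATION_ID="%s" TIME_SLOT_REF1="%s" TIME_SLOT_REF2="%s">\n                    <ANNOTATION_VALUE>%s</ANNOTATION_VALUE>\n                </ALIGNABLE_ANNOTATION>\n            </ANNOTATION>',
    id, newSlot(t1), newSlot(t2), xmlEscape(value))
  refAnn <- function(id, ref, value) sprintf(
    '            <ANNOTATION>\n                <REF_ANNOTATION ANNOTATION_ID="%s" ANNOTATION_REF="%s">\n                    <ANNOTATION_VALUE>%s</ANNOTATION_VALUE>\n                </REF_ANNOTATION>\n            </ANNOTATION>',
    id, ref, xmlEscape(value))

  ## communication spans cover their records and outcome
  comm_span <- lapply(seq_len(nrow(comms)), function(i) {
    cid <- comms$communication_id[i]
    rr <- recs[recs$communication_id == cid, , drop = FALSE]
    tm <- c(unlist(rr[RECORD_TIME_COLS], use.names = FALSE), comms$outcome_ms[i])
    tm <- tm[!is.na(tm)]
    if (length(tm) == 0L) c(NA_integer_, NA_integer_)
    else c(min(tm), max(tm) + 1L)
  })

  comm_ids <- character(nrow(comms))
  tier_rows <- list()
  addTier <- function(tier_id, parent, type, body) {
    tier_rows[[length(tier_rows) + 1L]] <<- sprintf(
      '    <TIER TIER_ID="%s"%s LINGUISTIC_TYPE_REF="%s">\n%s\n    </TIER>',
      tier_id,
      if (is.null(parent)) "" else sprintf(' PARENT_REF="%s"', parent),
      type,
      paste(body, collapse = "\n"))
  }

  comm_body <- character()
  for (i in seq_len(nrow(comms))) {
    comm_ids[i] <- newAnnId()
    sp <- comm_span[[i]]
    comm_body <- c(comm_body, alignable(comm_ids[i], sp[1], sp[2],
                                        comms$communication_id[i]))
  }
  addTier(tier_map$communication_tier, NULL, "communication-lt", comm_body)

  rec_ids <- character(nrow(recs))
  rec_body <- character()
  for (i in seq_len(nrow(recs))) {
    rec_ids[i] <- newAnnId()
    rec_body <- c(rec_body, alignable(rec_ids[i], recs$g_start_ms[i],
                                      recs$g_end_ms[i], recs$gesture_action[i]))
  }
  addTier(tier_map$record_tier, NULL, "phase-lt", rec_body)

  phaseTier <- function(tier, end_col) {
    body <- character()
    for (i in seq_len(nrow(recs))) {
      if (is.na(recs[[end_col]][i])) next
      body <- c(body, alignable(newAnnId(), recs$g_start_ms[i],
                                recs[[end_col]][i], ""))
    }
    if (length(body) > 0L)
      addTier(tier, tier_map$record_tier, "phase-lt", body)
    else addTier(tier, tier_map$record_tier, "phase-lt", character())
  }
  phaseTier(tier_map$mau_tier, "mau_end_ms")
  phaseTier(tier_map$ga_tier, "ga_end_ms")

  refTier <- function(tier, values, parent_ids, parent_tier) {
    keep <- !is.na(values)
    body <- character()
    for (i in which(keep))
      body <- c(body, refAnn(newAnnId(), parent_ids[i], as.character(values[i])))
    addTier(tier, parent_tier, "ref-lt", body)
  }
  refTier(tier_map$record_id_tier, recs$record_id, rec_ids, tier_map$record_tier)
  for (var in names(tier_map$modifier_tiers))
    refTier(tier_map$modifier_tiers[[var]], recs[[var]], rec_ids,
            tier_map$record_tier)
  for (var in names(tier_map$record_field_tiers))
    refTier(tier_map$record_field_tiers[[var]], recs[[var]], rec_ids,
            tier_map$record_tier)
  for (var in names(tier_map$comm_field_tiers))
    refTier(tier_map$comm_field_tiers[[var]], comms[[var]], comm_ids,
            tier_map$communication_tier)

  out_body <- character()
  for (i in seq_len(nrow(comms))) {
    if (is.na(comms$outcome_ms[i])) next
    out_body <- c(out_body, alignable(newAnnId(), comms$outcome_ms[i],
                                      comms$outcome_ms[i], "outcome"))
  }
  addTier(tier_map$outcome_time_tier, tier_map$communication_tier,
          "phase-lt", out_body)

  cv_block <- ""
  cv_refs <- ""
  if (!is.null(vocab)) {
    stopifnot(is(vocab, "VocabularySet"))
    vv <- vocab@values
    cvs <- vapply(unique(vv$variable), function(v) {
      entries <- vapply(vv$value[vv$variable == v], function(val) sprintf(
        '        <CV_ENTRY_ML CVE_ID="cve_%s"><CVE_VALUE LANG_REF="und">%s</CVE_VALUE></CV_ENTRY_ML>',
        xmlEscape(gsub("[^A-Za-z0-9]", "_", paste(v, val, sep = "_"))),
        xmlEscape(val)), character(1))
      sprintf('    <CONTROLLED_VOCABULARY CV_ID="%s">\n%s\n    </CONTROLLED_VOCABULARY>',
              xmlEscape(v), paste(entries, collapse = "\n"))
    }, character(1))
    cv_block <- paste(cvs, collapse = "\n")
  }

  ling_types <- paste(
    '    <LINGUISTIC_TYPE LINGUISTIC_TYPE_ID="communication-lt" TIME_ALIGNABLE="true" GRAPHIC_REFERENCES="false"/>',
    '    <LINGUISTIC_TYPE LINGUISTIC_TYPE_ID="phase-lt" TIME_ALIGNABLE="true" GRAPHIC_REFERENCES="false" CONSTRAINTS="Included_In"/>',
    '    <LINGUISTIC_TYPE LINGUISTIC_TYPE_ID="ref-lt" TIME_ALIGNABLE="false" GRAPHIC_REFERENCES="false" CONSTRAINTS="Symbolic_Association"/>',
    '    <CONSTRAINT STEREOTYPE="Included_In"/>',
    '    <CONSTRAINT STEREOTYPE="Symbolic_Association"/>',
    sep = "\n")

  doc <- paste(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<ANNOTATION_DOCUMENT AUTHOR="GestureKit" DATE="%s" FORMAT="3.0" VERSION="3.0">',
            format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    '    <HEADER MEDIA_FILE="" TIME_UNITS="milliseconds">',
    sprintf('        <MEDIA_DESCRIPTOR MEDIA_URL="%s" MIME_TYPE="video/mp4"/>',
            xmlEscape(media_url)),
    '    </HEADER>',
    '    <TIME_ORDER>',
    paste(slot_env$rows, collapse = "\n"),
    '    </TIME_ORDER>',
    paste(unlist(tier_rows), collapse = "\n"),
    ling_types,
    cv_block,
    '</ANNOTATION_DOCUMENT>',
    sep = "\n")
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

#' Write an empty EAF coding template
#'
#' Produces a valid EAF with the full tier structure (communication tier,
#' gesture-record tier, linked phase and modifier child tiers) but no
#' annotations, and with one embedded controlled-vocabulary entry per
#' vocabulary value, ready to be filled in by coders.
#'
#' @param catalogue a [GestureCatalogue-class]; the gesture-action names are
#'   embedded as the controlled vocabulary of the record tier.
#' @param vocab a [VocabularySet-class].
#' @param path output file path.
#' @param tier_map tier map, default [defaultTierMap()].
#' @return `path`, invisibly.
#' @export
writeTemplateEAF <- function(catalogue, vocab, path,
                             tier_map = defaultTierMap()) {
  stopifnot(is(catalogue, "GestureCatalogue"), is(vocab, "VocabularySet"))
  full_vocab <- VocabularySet(
    rbind(data.frame(variable = "gesture_action",
                     value = actions(catalogue)$action,
                     stringsAsFactors = FALSE),
          vocab@values),
    free_text = vocab@free_text)
  empty <- CommunicationSet(
    communications = data.frame(communication_id = character()),
    records = data.frame(record_id = character(),
                         communication_id = character(),
                         gesture_action = character()))
  writeEAF(empty, path, vocab = full_vocab, tier_map = tier_map)
}

#' Write and read the tidy long-format CSV
#'
#' One row per gesture record with the communication-level columns repeated,
#' prefixed `comm_` (except the shared key `communication_id`). The pair
#' round-trips: `readTidyCSV(writeTidyCSV(x, f))` restores `x`.
#'
#' @param x a [CommunicationSet-class].
#' @param path CSV path.
#' @return `writeTidyCSV`: `path`, invisibly. `readTidyCSV`: a
#'   [CommunicationSet-class]. Communications without records are preserved
#'   as rows with empty record fields.
#' @export
writeTidyCSV <- function(x, path) {
  stopifnot(is(x, "CommunicationSet"))
  comms <- communications(x)
  recs <- records(x)
  names(comms)[-1] <- paste0("comm_", names(comms)[-1])
  ## keep record-less communications as record-empty rows
  lone <- setdiff(comms$communication_id, recs$communication_id)
  if (length(lone) > 0L) {
    pad <- fillColumns(
      data.frame(record_id = NA_character_, communication_id = lone,
                 gesture_action = NA_character_, stringsAsFactors = FALSE),
      RECORD_COLS, numeric_cols = RECORD_TIME_COLS,
      logical_cols = INTENTIONALITY_FLAGS)
    recs <- rbind(recs, pad[, names(recs)])
  }
  tidy <- merge(recs, comms, by = "communication_id", sort = FALSE)
  tidy <- tidy[, c(RECORD_COLS, paste0("comm_", COMMUNICATION_COLS[-1]))]
  utils::write.csv(tidy, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname writeTidyCSV
#' @export
readTidyCSV <- function(path) {
  tidy <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                          encoding = "UTF-8")
  miss <- setdiff(c("record_id", "communication_id", "gesture_action"),
                  names(tidy))
  if (length(miss) > 0L)
    stop("tidy CSV is missing required column(s): ", paste(miss, collapse = ", "))
  comm_cols <- grep("^comm_", names(tidy), value = TRUE)
  comms <- unique(tidy[, c("communication_id", comm_cols), drop = FALSE])
  names(comms) <- sub("^comm_", "", names(comms))
  recs <- tidy[!is.na(tidy$record_id),
               setdiff(names(tidy), comm_cols), drop = FALSE]
  for (flag in intersect(INTENTIONALITY_FLAGS, names(recs)))
    recs[[flag]] <- as.logical(recs[[flag]])
  CommunicationSet(comms, recs)
}
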