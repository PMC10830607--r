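#' Configuration for the synthetic communication generator
#'
#' Defines the statistical structure of simulated gestural communications.
#' Durations are log-normal (positive and right-skewed, so that medians fall
#' below means, as observed duration data do); inter-gesture gaps are a
#' mixture of short within-sequence gaps (below the segmentation cutoff) and
#' long response-waiting gaps (at or above it), giving every simulated
#' stream a known, planted sequence structure. The outcome time of a
#' successful communication is planted at a known latency after the chosen
#' anchor end point of the final gesture, so latency computations can be
#' checked against ground truth.
#'
#' The default scale (250 communications, 37 signallers) mirrors a
#' field-realistic single-species latency dataset.
#'
#' @param seed integer; mandatory, the single pseudorandom stream for the
#'   dataset.
#' @param n_communications number of communications.
#' @param n_signallers size of the signaller pool.
#' @param species,group labels stamped on every communication.
#' @param catalogue [GestureCatalogue-class] supplying the actions.
#' @param action_probs named numeric vector of sampling weights over
#'   catalogue actions (default uniform).
#' @param mau_meanlog,mau_sdlog log-normal parameters of the MAU duration in
#'   seconds (median `exp(mau_meanlog)`).
#' @param p_hold probability that a variable-action instance is continued
#'   (uses its optional hold/repetition phase).
#' @param hold_meanlog,hold_sdlog log-normal hold duration (seconds).
#' @param recovery_meanlog,recovery_sdlog log-normal recovery duration.
#' @param n_gesture_probs probabilities of 1, 2, ... gestures per
#'   communication.
#' @param p_split probability that a gap is a response-waiting gap (at or
#'   above `cutoff`).
#' @param cutoff segmentation cutoff (seconds) the gap mixture is planted
#'   around.
#' @param within_gap_range range (seconds) of within-sequence gaps; must lie
#'   below `cutoff`.
#' @param split_gap_meanlog,split_gap_sdlog log-normal excess (seconds) of
#'   response-waiting gaps above `cutoff`.
#' @param p_success probability a communication is successful (has a known
#'   outcome time).
#' @param latency_meanlog,latency_sdlog log-normal outcome latency (seconds)
#'   from the anchor end point of the final gesture.
#' @param latency_anchor `"MAU_end"` or `"GA_end"`: the end point the planted
#'   outcome latency is measured from.
#' @param vocab [VocabularySet-class] supplying modifier values.
#' @return a validated list of class `"simConfig"`.
#' @seealso [generateDataset()]
#' @export
simConfig <- function(seed,
                      n_communications = 250L,
                      n_signallers = 37L,
                      species = "SpeciesA",
                      group = "Group1",
                      catalogue = defaultCatalogue(),
                      action_probs = NULL,
                      mau_meanlog = log(0.8), mau_sdlog = 0.4,
                      p_hold = 0.5,
                      hold_meanlog = log(1.0), hold_sdlog = 0.8,
                      recovery_meanlog = log(0.25), recovery_sdlog = 0.3,
                      n_gesture_probs = c(0.5, 0.25, 0.15, 0.1),
                      p_split = 0.3,
                      cutoff = 1.0,
                      within_gap_range = c(0.05, 0.9),
                      split_gap_meanlog = log(1.5), split_gap_sdlog = 0.8,
                      p_success = 0.8,
                      latency_meanlog = log(1.5), latency_sdlog = 1.0,
                      latency_anchor = c("MAU_end", "GA_end"),
                      vocab = defaultVocabulary()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is mandatory")
  latency_anchor <- match.arg(latency_anchor)
  acts <- actions(catalogue)
  if (is.null(action_probs))
    action_probs <- stats::setNames(rep(1, nrow(acts)), acts$action)
  if (!all(names(action_probs) %in% acts$action))
    stop("action_probs names unknown actions")
  probs <- c(p_hold, p_split, p_success)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (any(n_gesture_probs < 0) || sum(n_gesture_probs) <= 0)
    stop("invalid n_gesture_probs")
  if (n_signallers < 2L) stop("need at least 2 individuals")
  if (any(c(mau_sdlog, hold_sdlog, recovery_sdlog, split_gap_sdlog,
            latency_sdlog) < 0))
    stop("sdlog parameters must be non-negative")
  if (within_gap_range[1] < 0 || within_gap_range[2] >= cutoff ||
      within_gap_range[1] > within_gap_range[2])
    stop("within_gap_range must lie within [0, cutoff)")
  structure(as.list(environment()), class = "simConfig")
}

secToMs <- function(s) as.integer(pmax(1, round(s * 1000)))

#' Generate a synthetic communication dataset
#'
#' Simulates communications under a [simConfig()]: per communication a
#' signaller and recipient, a gesture count, per-gesture action draws with
#' log-normal MAU durations, optional hold phases for variable action types
#' (stable types always end their gesture action with the MAU), recoveries,
#' a gap structure planted relative to the gesture-action end, modifier
#' values drawn per the catalogue's action attributes, and for successful
#' communications an outcome time planted at a known latency after the
#' anchor end point of the final gesture.
#'
#' Reproducible from the seed; every generated record passes
#' [validateRecords()] with zero errors.
#'
#' @param config a [simConfig()].
#' @return a [CommunicationSet-class] with attribute `"ground_truth"`: a list
#'   with `records` (per-record planted hold, continued flag, unit index of
#'   the planted segmentation, morph key at full resolution) and
#'   `communications` (planted latency in seconds, anchor, final record id,
#'   success flag).
#' @examples
#' cs <- generateDataset(simConfig(seed = 1, n_communications = 5))
#' nCommunications(cs)
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  acts <- actions(config$catalogue)
  vv <- config$vocab@values
  pickVal <- function(var) {
    vals <- vv$value[vv$variable == var]
    vals <- setdiff(vals, "Unknown")
    if (length(vals) == 0L) NA_character_ else sample(vals, 1L)
  }
  signallers <- sprintf("S%02d", seq_len(config$n_signallers))
  act_w <- config$action_probs[acts$action]
  act_w[is.na(act_w)] <- 0

  comm_rows <- vector("list", config$n_communications)
  rec_rows <- vector("list", config$n_communications)
  gt_rec <- vector("list", config$n_communications)
  gt_comm <- vector("list", config$n_communications)

  clock <- 0L  # communications laid out sequentially, as on continuous video
  for (ci in seq_len(config$n_communications)) {
    cid <- sprintf("c%04d", ci)
    sig <- sample(signallers, 1L)
    rcp <- sample(setdiff(signallers, sig), 1L)
    n_g <- sample(seq_along(config$n_gesture_probs), 1L,
                  prob = config$n_gesture_probs)
    t <- clock + as.integer(round(stats::runif(1, 2000, 10000)))
    rows <- vector("list", n_g)
    unit <- 1L
    units <- integer(n_g)
    holds_ms <- integer(n_g)
    continued <- logical(n_g)
    for (gi in seq_len(n_g)) {
      if (gi > 1L) {
        split <- stats::runif(1) < config$p_split
        gap_s <- if (split)
          config$cutoff + stats::rlnorm(1, config$split_gap_meanlog,
                                        config$split_gap_sdlog)
        else stats::runif(1, config$within_gap_range[1],
                          config$within_gap_range[2])
        ## gaps are planted relative to the GA end of the previous gesture;
        ## an exact-cutoff gap counts as a split (>= rule)
        gap_ms <- secToMs(gap_s)
        if (split && gap_ms < secToMs(config$cutoff))
          gap_ms <- secToMs(config$cutoff)
        t <- t + gap_ms
        if (split) unit <- unit + 1L
      }
      units[gi] <- unit
      act_i <- sample(seq_len(nrow(acts)), 1L, prob = act_w)
      def <- acts[act_i, ]
      g_start <- t
      mau_ms <- secToMs(stats::rlnorm(1, config$mau_meanlog, config$mau_sdlog))
      hold_ms <- 0L
      if (def$phase_class == "variable" && stats::runif(1) < config$p_hold)
        hold_ms <- secToMs(stats::rlnorm(1, config$hold_meanlog,
                                         config$hold_sdlog))
      rec_ms <- secToMs(stats::rlnorm(1, config$recovery_meanlog,
                                      config$recovery_sdlog))
      mau_end <- g_start + mau_ms
      ga_end <- mau_end + hold_ms
      g_end <- ga_end + rec_ms
      holds_ms[gi] <- hold_ms
      continued[gi] <- hold_ms > 0L
      rows[[gi]] <- data.frame(
        record_id = sprintf("%s_r%02d", cid, gi), communication_id = cid,
        signaller_id = sig, recipient_id = rcp,
        gesture_action = def$action,
        g_start_ms = g_start, mau_end_ms = mau_end, ga_end_ms = ga_end,
        g_end_ms = g_end,
        body_part = pickVal("body_part"),
        laterality = pickVal("laterality"),
        object_used = "None",
        flexion = if (def$free_limb) pickVal("flexion") else NA_character_,
        orientation = if (def$free_limb) pickVal("orientation") else NA_character_,
        repetition_count = if (def$repetition)
          as.character(sample(2:8, 1L)) else NA_character_,
        body_part_contact = if (def$contact) pickVal("body_part_contact")
          else NA_character_,
        audibility = pickVal("audibility"),
        directionality = pickVal("directionality"),
        audience_checking = stats::runif(1) < 0.9,
        response_waiting = stats::runif(1) < 0.8,
        goal_persistence = n_g > 1L,
        stringsAsFactors = FALSE)
      t <- ga_end  # next gap measured from this GA end
    }
    rr <- do.call(rbind, rows)
    success <- stats::runif(1) < config$p_success
    latency_ms <- NA_integer_
    outcome_ms <- NA_integer_
    anchor_col <- if (config$latency_anchor == "MAU_end") "mau_end_ms"
                  else "ga_end_ms"
    final_id <- rr$record_id[which.max(rr[[anchor_col]])]
    if (success) {
      latency_ms <- secToMs(stats::rlnorm(1, config$latency_meanlog,
                                          config$latency_sdlog))
      outcome_ms <- max(rr[[anchor_col]]) + latency_ms
    }
    comm_rows[[ci]] <- data.frame(
      communication_id = cid, species = config$species, group = config$group,
      signaller_id = sig, recipient_id = rcp,
      context_pre = pickVal("context"), context_post = pickVal("context"),
      goal = pickVal("goal"),
      outcome_status = if (success) "success" else "failure",
      outcome_ms = outcome_ms, stringsAsFactors = FALSE)
    rec_rows[[ci]] <- rr
    clock <- max(rr$g_end_ms, outcome_ms, na.rm = TRUE)
    gt_rec[[ci]] <- data.frame(
      record_id = rr$record_id, communication_id = cid,
      hold_ms = holds_ms, continued = continued, unit = units,
      stringsAsFactors = FALSE)
    gt_comm[[ci]] <- data.frame(
      communication_id = cid, success = success,
      latency_s = if (success) latency_ms / 1000 else NA_real_,
      anchor = config$latency_anchor, final_record_id = final_id,
      stringsAsFactors = FALSE)
  }

  recs <- do.call(rbind, rec_rows)
  gt_records <- do.call(rbind, gt_rec)
  gt_records$morph <- morphKey(recs, MODIFIER_VARIABLES, config$catalogue)
  cs <- CommunicationSet(do.call(rbind, comm_rows), recs)
  attr(cs, "ground_truth") <- list(
    records = gt_records,
    communications = do.call(rbind, gt_comm),
    config = config)
  cs
}

#' Ground truth of a generated dataset
#'
#' @param x a [CommunicationSet-class] produced by [generateDataset()].
#' @return the `"ground_truth"` attribute (see [generateDataset()]).
#' @export
groundTruth <- function(x) attr(x, "ground_truth")

#' Emit a generated dataset as an EAF file
#'
#' Writes the simulated communications under the standard template so that
#' the full pipeline (parse, assemble, metrics) can be exercised end to end;
#' the output round-trips through [parseEAF()] + [assembleRecords()].
#'
#' @param x a [CommunicationSet-class].
#' @param path output EAF path.
#' @param vocab vocabulary to embed, default [defaultVocabulary()].
#' @return `path`, invisibly.
#' @export
emitEAF <- function(x, path, vocab = defaultVocabulary()) {
  writeEAF(x, path, vocab = vocab)
}
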