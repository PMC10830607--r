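# Fixtures and independent oracles shared across the suite.
# All fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# minimal CommunicationSet builder: comms inferred from the records
makeCS <- function(records, comms = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(comms))
    comms <- data.frame(communication_id = unique(records$communication_id),
                        stringsAsFactors = FALSE)
  CommunicationSet(comms, records)
}

# the worked reach instance: arm, right, elbow flexion, side orientation
reachRecord <- function(record_id = "r1", communication_id = "c1",
                        g_start = 0L, mau_end = 740L, ga_end = 740L,
                        g_end = 1000L) {
  data.frame(record_id = record_id, communication_id = communication_id,
             signaller_id = "S01", recipient_id = "S02",
             gesture_action = "Reach",
             g_start_ms = g_start, mau_end_ms = mau_end, ga_end_ms = ga_end,
             g_end_ms = g_end,
             body_part = "Arm", laterality = "Right", object_used = "None",
             flexion = "Elbow", orientation = "Side",
             repetition_count = NA_character_, body_part_contact = NA_character_,
             audibility = "Silent", directionality = "Present",
             stringsAsFactors = FALSE)
}

# independent ICC(2,1) oracle: mean squares from stats::aov on long data
oracleICC2 <- function(m) {
  m <- as.matrix(m)
  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                     rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  # aov warns on essentially perfect fits; only the mean squares are needed
  tab <- suppressWarnings(stats::anova(stats::aov(y ~ subject + rater,
                                                  data = long)))
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# brute-force segmentation oracle: classify every adjacent pair on its own
oracleSegment <- function(cs, endpoint, cutoff, strict = FALSE) {
  recs <- records(cs)
  sig <- ifelse(is.na(recs$signaller_id), "<NA>", recs$signaller_id)
  stream <- paste(recs$communication_id, sig, sep = "\r")
  unlist(lapply(unique(stream), function(key) {
    rr <- recs[stream == key, , drop = FALSE]
    n <- nrow(rr)
    if (n == 1L) return(1L)
    splits <- vapply(seq_len(n - 1L), function(i) {
      iv <- interGestureInterval(rr[i, ], rr[i + 1L, ], endpoint)
      if (is.na(iv)) TRUE
      else if (strict) iv > cutoff else iv >= cutoff
    }, logical(1))
    cumsum(c(1L, as.integer(splits)))
  }), use.names = FALSE)
}

# brute-force grouped summary oracle over raw values
oracleSummary <- function(values, groups) {
  do.call(rbind, lapply(sort(unique(groups)), function(g) {
    v <- values[groups == g & !is.na(values)]
    data.frame(group = g, n = length(v), median = stats::median(v),
               mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
}

smallConfig <- function(seed, n = 40L, ...) {
  simConfig(seed = seed, n_communications = n, n_signallers = 8L, ...)
}
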