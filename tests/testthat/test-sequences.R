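pairCS <- function(mau1 = 4000L, ga1 = 5000L, start2 = 5500L) {
  makeCS(rbind(
    reachRecord("g1", g_start = 0L, mau_end = mau1, ga_end = ga1, g_end = ga1 + 200L),
    reachRecord("g2", g_start = start2, mau_end = start2 + 500L,
                ga_end = start2 + 500L, g_end = start2 + 800L)))
}

test_that("the same stream segments differently under the two end points", {
  cs <- pairCS()  # GA-end interval 0.5 s; MAU-end interval 1.5 s
  expect_identical(segmentSequences(cs, "GA_end", cutoff = 1)$unit, c(1L, 1L))
  expect_identical(segmentSequences(cs, "MAU_end", cutoff = 1)$unit, c(1L, 2L))
})

test_that("the cutoff boundary is >= by default and > under strict", {
  cs <- pairCS(start2 = 6000L)  # GA-end interval exactly 1.0 s
  expect_identical(segmentSequences(cs, "GA_end", cutoff = 1)$unit, c(1L, 2L))
  expect_identical(segmentSequences(cs, "GA_end", cutoff = 1, strict = TRUE)$unit,
                   c(1L, 1L))
})

test_that("single gestures and undecidable boundaries", {
  seg1 <- segmentSequences(makeCS(reachRecord()), "GA_end")
  expect_identical(seg1$unit, 1L)

  cs <- pairCS()
  recs <- records(cs); recs$ga_end_ms[1] <- NA_integer_
  seg <- segmentSequences(CommunicationSet(communications(cs), recs), "GA_end")
  expect_identical(seg$unit, c(1L, 2L))  # conservative split
  expect_true(seg$undecidable[2])
})

test_that("segmentation equals the brute-force adjacent-pair oracle", {
  for (seed in c(2, 9, 31)) {
    cs <- generateDataset(smallConfig(seed = seed, n = 50L))
    for (ep in c("MAU_end", "GA_end")) {
      seg <- segmentSequences(cs, ep, cutoff = 1)
      expect_identical(seg$unit, oracleSegment(cs, ep, cutoff = 1),
                       info = sprintf("seed %d endpoint %s", seed, ep))
    }
  }
})

test_that("raising the cutoff never increases the number of units", {
  cs <- generateDataset(smallConfig(seed = 17, n = 60L))
  cuts <- c(0.2, 0.5, 1, 2, 5)
  n_units <- vapply(cuts, function(ct)
    sum(sequenceUnitCounts(segmentSequences(cs, "GA_end", ct))$n_units),
    numeric(1))
  expect_true(all(diff(n_units) <= 0))
})

test_that("measuring from the MAU end never decreases intervals or unit count", {
  cs <- generateDataset(smallConfig(seed = 23, n = 60L))
  iv_ga <- gestureIntervals(cs, "GA_end")$interval
  iv_mau <- gestureIntervals(cs, "MAU_end")$interval
  ok <- !is.na(iv_ga) & !is.na(iv_mau)
  expect_true(all(iv_mau[ok] >= iv_ga[ok]))  # MAU end <= GA end
  n_ga <- sum(sequenceUnitCounts(segmentSequences(cs, "GA_end"))$n_units)
  n_mau <- sum(sequenceUnitCounts(segmentSequences(cs, "MAU_end"))$n_units)
  expect_gte(n_mau, n_ga)
})

test_that("concatenating far-apart communications unions their segmentations", {
  cs1 <- generateDataset(smallConfig(seed = 41, n = 10L))
  seg_parts <- segmentSequences(cs1, "GA_end")
  # merge all communications into one, shifting each far beyond the cutoff
  recs <- records(cs1)
  comms <- communications(cs1)
  offset <- 0L
  shifted <- lapply(comms$communication_id, function(cid) {
    rr <- recs[recs$communication_id == cid, , drop = FALSE]
    for (col in c("g_start_ms", "mau_end_ms", "ga_end_ms", "g_end_ms"))
      rr[[col]] <- rr[[col]] + offset
    offset <<- max(rr$g_end_ms) + 60000L  # one minute apart
    rr$communication_id <- "merged"
    rr
  })
  merged <- CommunicationSet(data.frame(communication_id = "merged"),
                             do.call(rbind, shifted))
  seg_merged <- segmentSequences(merged, "GA_end")
  # same signaller's far-apart blocks must not fuse: per-stream unit counts add up
  for (sig in unique(seg_merged$signaller_id)) {
    expect_identical(
      max(seg_merged$unit[seg_merged$signaller_id == sig]),
      sum(vapply(split(seg_parts[seg_parts$signaller_id == sig, ],
                       seg_parts$communication_id[seg_parts$signaller_id == sig]),
                 function(s) max(s$unit), integer(1))))
  }
})

test_that("follow-up classification depends on morph resolution", {
  expect_identical(classifyFollowup("Reach", "Reach"), "persistence")
  expect_identical(classifyFollowup("Reach", "Beckon"),
                   "persistence_with_elaboration")

  left <- reachRecord("L"); right <- reachRecord("R"); right$laterality <- "Left"
  k_action <- morphKey(rbind(left, right), character())
  k_full <- morphKey(rbind(left, right), c("body_part", "laterality"))
  expect_identical(classifyFollowup(k_action[1], k_action[2]), "persistence")
  expect_identical(classifyFollowup(k_full[1], k_full[2]),
                   "persistence_with_elaboration")
})
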