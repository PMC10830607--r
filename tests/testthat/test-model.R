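cat9 <- defaultCatalogue()
voc <- defaultVocabulary()

test_that("a fully coded reach instance validates cleanly", {
  cs <- makeCS(reachRecord())
  expect_identical(nrow(validateRecords(cs, cat9, voc)), 0L)
})

test_that("stable actions must end their gesture action with the MAU", {
  r <- reachRecord()
  r$gesture_action <- "Beckon"
  r$flexion <- NA; r$orientation <- NA  # beckon is free-limb; keep it clean
  r$ga_end_ms <- 900L                   # != mau_end
  v <- validateRecords(makeCS(r), cat9, voc)
  expect_true("stable_action_ends_with_mau" %in% v$rule)
  expect_identical(v$severity[v$rule == "stable_action_ends_with_mau"], "error")
})

test_that("time-point ordering violations are reported per offending pair", {
  r <- reachRecord(mau_end = 740L)
  r$g_start_ms <- 800L  # start after MAU end
  v <- validateRecords(makeCS(r), cat9, voc)
  expect_true(any(v$rule == "time_ordering" & v$severity == "error"))
})

test_that("modifier gating follows the action's attributes", {
  r <- reachRecord()
  r$gesture_action <- "Push"           # contact action, not free-limb
  r$flexion <- "Elbow"                 # meaningless for non-free-limb
  r$repetition_count <- "3"            # push is not a repetition action
  v <- validateRecords(makeCS(r), cat9, voc)
  expect_true(any(v$rule == "free_limb_only" & v$field == "flexion"))
  expect_true(any(v$rule == "repetition_actions_only"))
  expect_true(all(v$severity[v$rule %in%
    c("free_limb_only", "repetition_actions_only")] == "warning"))

  r2 <- reachRecord()
  r2$body_part_contact <- "Back"       # reach is not a contact action
  v2 <- validateRecords(makeCS(r2), cat9, voc)
  expect_true(any(v2$rule == "contact_actions_only"))
})

test_that("vocabulary violations and unknown actions are errors", {
  r <- reachRecord()
  r$laterality <- "Ambidextrous"
  v <- validateRecords(makeCS(r), cat9, voc)
  expect_true(any(v$rule == "vocabulary" & v$field == "laterality" &
                    v$severity == "error"))
  r2 <- reachRecord()
  r2$gesture_action <- "Levitate"
  v2 <- validateRecords(makeCS(r2), cat9, voc)
  expect_true(any(v2$rule == "action_in_catalogue"))
})

test_that("validation is idempotent and pure", {
  cs <- generateDataset(smallConfig(seed = 11))
  v1 <- validateRecords(cs, cat9, voc)
  v2 <- validateRecords(cs, cat9, voc)
  expect_identical(v1, v2)
})

test_that("communication-level checks: outcome consistency and ordering", {
  # success without an outcome time is flagged as a warning, not an error
  cs <- makeCS(reachRecord(),
               comms = data.frame(communication_id = "c1",
                                  outcome_status = "success"))
  v <- validateCommunications(cs)
  expect_true(any(v$rule == "success_has_outcome_time" & v$severity == "warning"))
  expect_match(v$message[v$rule == "success_has_outcome_time"],
               "successful outcome lacks time")

  # outcome after the gesture: clean
  cs2 <- makeCS(reachRecord(),
                comms = data.frame(communication_id = "c1",
                                   outcome_status = "success",
                                   outcome_ms = 3450L))
  expect_identical(nrow(validateCommunications(cs2)), 0L)

  # outcome before the first gesture start: error
  cs3 <- makeCS(reachRecord(g_start = 1000L, mau_end = 1700L,
                            ga_end = 1700L, g_end = 2000L),
                comms = data.frame(communication_id = "c1",
                                   outcome_status = "success",
                                   outcome_ms = 500L))
  v3 <- validateCommunications(cs3)
  expect_true(any(v3$rule == "outcome_after_first_gesture" &
                    v3$severity == "error"))

  # records out of temporal order (bypassing the ordering constructor)
  r <- rbind(reachRecord("r1", g_start = 5000L, mau_end = 5700L,
                         ga_end = 5700L, g_end = 6000L),
             reachRecord("r2", g_start = 0L))
  cs4 <- makeCS(r)
  raw <- new("CommunicationSet", communications = communications(cs4),
             records = records(cs4)[c(2, 1), ])
  v4 <- validateCommunications(raw)
  expect_true(any(v4$rule == "record_ordering"))
  expect_match(v4$message[v4$rule == "record_ordering"][1], "r1")
})

test_that("the constructor orders records and normalises time columns", {
  r <- rbind(reachRecord("r2", g_start = 2000L, mau_end = 2700L,
                         ga_end = 2700L, g_end = 3000L),
             reachRecord("r1"))
  cs <- makeCS(r)
  expect_identical(records(cs)$record_id, c("r1", "r2"))
  expect_true(is.integer(records(cs)$g_start_ms))

  # unknown is NA, never a sentinel; negative times are structural errors
  expect_error(makeCS(reachRecord(g_start = -5L)), ">= 0")
  # fractional milliseconds are rejected (ELAN codes whole ms)
  r3 <- reachRecord(); r3$g_start_ms <- 0.25
  expect_error(makeCS(r3), "whole milliseconds")
})

test_that("records accepted with zero errors are computable by every metric", {
  cs <- generateDataset(smallConfig(seed = 3))
  v <- validateRecords(cs, cat9, voc)
  expect_identical(sum(v$severity == "error"), 0L)
  expect_silent(phaseDurations(cs))
  expect_silent(responseLatency(cs, "MAU_end"))
  expect_silent(segmentSequences(cs, "GA_end"))
  expect_silent(buildRepertoire(cs, c("body_part", "laterality")))
})
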