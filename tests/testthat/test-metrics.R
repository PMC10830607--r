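cat9 <- defaultCatalogue()

test_that("phase durations are end-point differences in seconds", {
  pd <- phaseDurations(makeCS(reachRecord(g_start = 0L, mau_end = 740L,
                                          ga_end = 740L, g_end = 1000L)))
  expect_equal(pd$mau_duration, 0.74)
  expect_equal(pd$ga_duration, 0.74)
  expect_equal(pd$hold_duration, 0)
  expect_equal(pd$full_duration, 1.00)
  expect_equal(pd$recovery_duration, 0.26)
})

test_that("durations touching an unknown end point are undefined", {
  r <- reachRecord(); r$mau_end_ms <- NA_integer_
  pd <- phaseDurations(makeCS(r))
  expect_true(is.na(pd$mau_duration) && is.na(pd$hold_duration))
  expect_equal(pd$ga_duration, 0.74)   # its own end points are known
  expect_equal(pd$full_duration, 1.00)
})

test_that("instances classify as continued/minimised per hold use", {
  rec <- rbind(
    reachRecord("a", g_start = 0L, mau_end = 700L, ga_end = 2800L, g_end = 3000L),
    reachRecord("b", g_start = 4000L, mau_end = 4700L, ga_end = 4700L, g_end = 5000L))
  cs <- makeCS(rec)
  expect_identical(classifyInstance(cs, cat9), c("continued", "minimised"))

  # stable actions are minimised whatever the timings
  r <- reachRecord(); r$gesture_action <- "Beckon"
  r$flexion <- NA; r$orientation <- NA
  expect_identical(classifyInstance(makeCS(r), cat9), "minimised")

  # undefined hold -> unknown
  r2 <- reachRecord(); r2$ga_end_ms <- NA_integer_
  expect_identical(classifyInstance(makeCS(r2), cat9), "unknown")

  # tolerance moves the continued boundary
  r3 <- reachRecord(g_start = 0L, mau_end = 700L, ga_end = 750L, g_end = 1000L)
  expect_identical(classifyInstance(makeCS(r3), cat9), "continued")
  expect_identical(classifyInstance(makeCS(r3), cat9, zero_hold_tolerance = 0.1),
                   "minimised")
})

test_that("response latency measures final gesture end point to outcome", {
  cs <- makeCS(reachRecord(g_start = 0L, mau_end = 1000L, ga_end = 1800L,
                           g_end = 2000L),
               comms = data.frame(communication_id = "c1",
                                  outcome_status = "success",
                                  outcome_ms = 3450L))
  expect_equal(responseLatency(cs, "MAU_end")$latency, 2.45)
  expect_equal(responseLatency(cs, "GA_end")$latency, 1.65)

  # negative latency: recipient responded before the phase completed
  cs2 <- makeCS(reachRecord(g_start = 0L, mau_end = 1000L, ga_end = 1000L,
                            g_end = 1200L),
                comms = data.frame(communication_id = "c1",
                                   outcome_status = "success",
                                   outcome_ms = 800L))
  expect_equal(responseLatency(cs2, "MAU_end")$latency, -0.20)
})

test_that("the final gesture is the one whose end point is closest to the outcome", {
  rec <- rbind(
    reachRecord("r1", g_start = 0L, mau_end = 700L, ga_end = 700L, g_end = 900L),
    reachRecord("r2", g_start = 2000L, mau_end = 2700L, ga_end = 2700L,
                g_end = 2900L))
  cs <- makeCS(rec, comms = data.frame(communication_id = "c1",
                                       outcome_status = "success",
                                       outcome_ms = 4000L))
  lat <- responseLatency(cs, "MAU_end")
  expect_identical(lat$final_record_id, "r2")
  expect_equal(lat$latency, 1.3)
  expect_false(lat$fallback)

  # unknown end point on the last record: fall back to the latest known, flag
  rec$mau_end_ms[2] <- NA_integer_
  cs2 <- makeCS(rec, comms = data.frame(communication_id = "c1",
                                        outcome_status = "success",
                                        outcome_ms = 4000L))
  lat2 <- responseLatency(cs2, "MAU_end")
  expect_identical(lat2$final_record_id, "r1")
  expect_true(lat2$fallback)
  expect_equal(lat2$latency, 3.3)

  # unknown outcome: undefined latency, not an error
  cs3 <- makeCS(rec)
  expect_true(is.na(responseLatency(cs3, "MAU_end")$latency))
})

test_that("inter-gesture intervals depend on the chosen end point", {
  g1 <- reachRecord("g1", g_start = 0L, mau_end = 4000L, ga_end = 5000L,
                    g_end = 5200L)
  g2 <- reachRecord("g2", g_start = 5500L, mau_end = 6000L, ga_end = 6000L,
                    g_end = 6300L)
  expect_equal(interGestureInterval(g1, g2, "GA_end"), 0.5)
  expect_equal(interGestureInterval(g1, g2, "MAU_end"), 1.5)

  # overlapping production gives a negative interval
  g3 <- reachRecord("g3", g_start = 4800L, mau_end = 5600L, ga_end = 5600L,
                    g_end = 5900L)
  expect_lt(interGestureInterval(g1, g3, "GA_end"), 0)

  g4 <- reachRecord("g4", communication_id = "c2", g_start = 9000L,
                    mau_end = 9700L, ga_end = 9700L, g_end = 9900L)
  expect_error(interGestureInterval(g1, g4), "different communications")
  g5 <- g2; g5$signaller_id <- "S09"
  expect_error(interGestureInterval(g1, g5), "different signallers")
})

test_that("grouped summaries agree with a brute-force oracle", {
  cs <- generateDataset(smallConfig(seed = 21, n = 60L))
  pd <- phaseDurations(cs)
  got <- summariseBy(pd, "ga_duration", "gesture_action")
  want <- oracleSummary(pd$ga_duration, pd$gesture_action)
  expect_equal(got$n, want$n)
  expect_equal(got$median, want$median)
  expect_equal(got$mean, want$mean)
  expect_equal(got$sd, want$sd)
  expect_equal(got$min, want$min)
  expect_equal(got$max, want$max)

  # single-value group: median = mean = value, SD undefined
  s1 <- summariseBy(data.frame(g = "a", v = 2.5), "v", "g")
  expect_equal(s1$median, 2.5)
  expect_equal(s1$mean, 2.5)
  expect_true(is.na(s1$sd))

  # group whose values are all undefined: n = 0, statistics NA
  s0 <- summariseBy(data.frame(g = c("a", "b"), v = c(1, NA)), "v", "g")
  expect_identical(s0$n[s0$g == "b"], 0L)
  expect_identical(s0$n_excluded[s0$g == "b"], 1L)
  expect_true(is.na(s0$median[s0$g == "b"]))
})

test_that("phase ordering and non-negative hold/recovery hold on generated data", {
  cs <- generateDataset(smallConfig(seed = 5, n = 80L))
  pd <- phaseDurations(cs)
  expect_true(all(pd$mau_duration <= pd$ga_duration))
  expect_true(all(pd$ga_duration <= pd$full_duration))
  expect_true(all(pd$hold_duration >= 0))
  expect_true(all(pd$recovery_duration >= 0))
  # stable actions: hold exactly zero
  stable <- classifyActionPhase(pd$gesture_action, cat9) == "stable"
  expect_true(all(pd$hold_duration[stable] == 0))
})

test_that("GA-end latency is invariant to extending the recovery phase", {
  cs <- generateDataset(smallConfig(seed = 13))
  base <- responseLatency(cs, "GA_end")
  recs <- records(cs)
  recs$g_end_ms <- recs$g_end_ms + 5000L  # stretch every recovery
  pert <- responseLatency(CommunicationSet(communications(cs), recs), "GA_end")
  expect_equal(pert$latency, base$latency)
})
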