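fixtureCS <- function(seed = 1, n = 8L) generateDataset(smallConfig(seed, n))

test_that("EAF documents parse to resolved tiers and millisecond times", {
  cs <- fixtureCS()
  f <- withr::local_tempfile(fileext = ".eaf")
  writeEAF(cs, f, vocab = defaultVocabulary())
  doc <- parseEAF(f)
  tm <- defaultTierMap()
  expect_true(all(c(tm$communication_tier, tm$record_tier, tm$mau_tier,
                    tm$ga_tier, tm$modifier_tiers) %in% doc$tiers$tier_id))
  # modifier tiers are children of the gesture-record tier
  expect_identical(
    unique(doc$tiers$parent_tier_id[doc$tiers$tier_id %in% tm$modifier_tiers]),
    tm$record_tier)
  rec_ann <- doc$annotations[doc$annotations$tier_id == tm$record_tier, ]
  expect_identical(nrow(rec_ann), nRecords(cs))
  expect_true(is.integer(rec_ann$start_ms))
  # reference annotations inherit their parent's times
  bp <- doc$annotations[doc$annotations$tier_id == tm$modifier_tiers[["body_part"]], ]
  expect_true(all(!is.na(bp$ref)))
  expect_identical(bp$start_ms,
                   rec_ann$start_ms[match(bp$ref, rec_ann$annotation_id)])
})

test_that("dangling references are reported with the offending id", {
  bad <- withr::local_tempfile(fileext = ".eaf")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT AUTHOR="x" DATE="d" FORMAT="3.0" VERSION="3.0">',
    '<HEADER TIME_UNITS="milliseconds"/>',
    '<TIME_ORDER><TIME_SLOT TIME_SLOT_ID="ts1" TIME_VALUE="0"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts2" TIME_VALUE="500"/></TIME_ORDER>',
    '<TIER TIER_ID="Gesture_record" LINGUISTIC_TYPE_REF="a">',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a1" TIME_SLOT_REF1="ts1" TIME_SLOT_REF2="ts2">',
    '<ANNOTATION_VALUE>Reach</ANNOTATION_VALUE></ALIGNABLE_ANNOTATION></ANNOTATION></TIER>',
    '<TIER TIER_ID="Body_part" PARENT_REF="Gesture_record" LINGUISTIC_TYPE_REF="r">',
    '<ANNOTATION><REF_ANNOTATION ANNOTATION_ID="a2" ANNOTATION_REF="a99">',
    '<ANNOTATION_VALUE>Arm</ANNOTATION_VALUE></REF_ANNOTATION></ANNOTATION></TIER>',
    '</ANNOTATION_DOCUMENT>'), bad)
  expect_error(parseEAF(bad), "a99")

  bad2 <- withr::local_tempfile(fileext = ".eaf")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT AUTHOR="x" DATE="d" FORMAT="3.0" VERSION="3.0">',
    '<HEADER TIME_UNITS="milliseconds"/>',
    '<TIME_ORDER><TIME_SLOT TIME_SLOT_ID="ts1" TIME_VALUE="0"/></TIME_ORDER>',
    '<TIER TIER_ID="Gesture_record" LINGUISTIC_TYPE_REF="a">',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a1" TIME_SLOT_REF1="ts1" TIME_SLOT_REF2="ts9">',
    '<ANNOTATION_VALUE>Reach</ANNOTATION_VALUE></ALIGNABLE_ANNOTATION></ANNOTATION></TIER>',
    '</ANNOTATION_DOCUMENT>'), bad2)
  expect_error(parseEAF(bad2), "ts9")
})

test_that("the coding template round-trips its tier structure and embeds vocabularies", {
  f <- withr::local_tempfile(fileext = ".eaf")
  voc <- defaultVocabulary()
  cat9 <- defaultCatalogue()
  writeTemplateEAF(cat9, voc, f)
  doc <- parseEAF(f)
  tm <- defaultTierMap()
  expect_true(all(c(tm$communication_tier, tm$record_tier, tm$mau_tier,
                    tm$ga_tier, tm$modifier_tiers, tm$record_field_tiers,
                    tm$comm_field_tiers) %in% doc$tiers$tier_id))
  expect_identical(nrow(doc$annotations), 0L)
  # one controlled-vocabulary entry per vocabulary value (+ gesture actions)
  x <- xml2::read_xml(f)
  entries <- xml2::xml_find_all(x, ".//CONTROLLED_VOCABULARY/CV_ENTRY_ML")
  expect_identical(length(entries),
                   nrow(voc@values) + nrow(actions(cat9)))
  # re-parsing the re-written structure is stable
  doc2 <- parseEAF(f)
  expect_identical(doc2$tiers, doc$tiers)
})

test_that("tab exports parse to the same times and values as the source EAF", {
  cs <- fixtureCS(seed = 4)
  f <- withr::local_tempfile(fileext = ".eaf")
  writeEAF(cs, f)
  doc <- parseEAF(f)
  tab <- withr::local_tempfile(fileext = ".txt")
  writeTabExport(doc, tab)
  doc2 <- parseTabExport(tab)
  a1 <- doc$annotations[order(doc$annotations$tier_id, doc$annotations$start_ms,
                              doc$annotations$value), ]
  a2 <- doc2$annotations[order(doc2$annotations$tier_id, doc2$annotations$start_ms,
                               doc2$annotations$value), ]
  expect_identical(a2$tier_id, a1$tier_id)
  expect_identical(a2$start_ms, a1$start_ms)
  expect_identical(a2$end_ms, a1$end_ms)
  expect_identical(a2$value, a1$value)
})

test_that("tab-export parsing rejects malformed rows and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tier\tstart_ms\tend_ms\tvalue", "Gesture_record\t500\t100\tReach"), f)
  expect_error(parseTabExport(f), "row")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("tier\tstart_ms\tend_ms\tvalue", f2)
  expect_warning(doc <- parseTabExport(f2), "empty export")
  expect_identical(nrow(doc$annotations), 0L)

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tier\tvalue", "Gesture_record\tReach"), f3)
  expect_error(parseTabExport(f3), "missing")
})

test_that("assembly groups records into communications and tolerates unknowns", {
  cs <- fixtureCS(seed = 6, n = 10L)
  # blank out one MAU end: assembles to an unknown time point, no error
  recs <- records(cs)
  recs$mau_end_ms[3] <- NA_integer_
  cs <- CommunicationSet(communications(cs), recs)
  f <- withr::local_tempfile(fileext = ".eaf")
  writeEAF(cs, f)
  cs2 <- assembleRecords(parseEAF(f))
  expect_identical(records(cs2), records(cs))
  expect_true(is.na(records(cs2)$mau_end_ms[3]))
  # records within each communication are ordered by start
  for (cid in communications(cs2)$communication_id) {
    st <- records(cs2)$g_start_ms[records(cs2)$communication_id == cid]
    expect_true(!is.unsorted(st))
  }
})

test_that("assembly flags orphans and duplicated child values", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "tier\tstart_ms\tend_ms\tvalue",
    "Communication\t0\t3000\tc1",
    "Gesture_record\t100\t1100\tReach",
    "Record_ID\t100\t1100\tr1",
    "Body_part\t100\t1100\tArm",
    "Body_part\t5000\t5400\tHand"), f)  # second body part floats outside
  expect_warning(cs <- assembleRecords(parseTabExport(f)), "orphan")
  expect_identical(records(cs)$body_part, "Arm")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "tier\tstart_ms\tend_ms\tvalue",
    "Communication\t0\t3000\tc1",
    "Gesture_record\t100\t1100\tReach",
    "Body_part\t100\t1100\tArm",
    "Body_part\t100\t1100\tHand"), f2)  # two body parts on one record
  expect_error(assembleRecords(parseTabExport(f2)), "two values")

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "tier\tstart_ms\tend_ms\tvalue",
    "Communication\t0\t3000\tc1",
    "Gesture_record\t100\t1100\tReach",
    "Gesture_record\t9000\t9400\tBeckon"), f3)  # beckon outside every comm
  expect_warning(cs3 <- assembleRecords(parseTabExport(f3)),
                 "no communication")
  expect_identical(nCommunications(cs3), 2L)
})

test_that("EAF and tidy CSV round-trip generated datasets identically", {
  for (seed in 1:3) {
    cs <- fixtureCS(seed = seed, n = 12L)
    f <- withr::local_tempfile(fileext = ".eaf")
    writeEAF(cs, f)
    cs_eaf <- assembleRecords(parseEAF(f))
    expect_identical(records(cs_eaf), records(cs))
    c1 <- communications(cs)
    c2 <- communications(cs_eaf)
    c2 <- c2[match(c1$communication_id, c2$communication_id), ]
    rownames(c2) <- NULL
    expect_identical(c2, c1)

    g <- withr::local_tempfile(fileext = ".csv")
    writeTidyCSV(cs, g)
    cs_csv <- readTidyCSV(g)
    expect_identical(records(cs_csv), records(cs))
    c3 <- communications(cs_csv)
    c3 <- c3[match(c1$communication_id, c3$communication_id), ]
    rownames(c3) <- NULL
    expect_identical(c3, c1)
  }
  # empty set: header-only CSV
  empty <- CommunicationSet(data.frame(communication_id = character()),
                            data.frame(record_id = character(),
                                       communication_id = character(),
                                       gesture_action = character()))
  g0 <- withr::local_tempfile(fileext = ".csv")
  writeTidyCSV(empty, g0)
  expect_identical(length(readLines(g0)), 1L)
})
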