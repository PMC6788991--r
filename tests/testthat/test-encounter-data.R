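# photo-record ingestion, the 0.5-h independence rule, and encounter arrays

test_that("readPhotoRecords validates, filters and sorts", {
  design <- toyDesign()
  # empty file with header -> empty table
  empty <- rec(character(0), character(0), character(0))
  expect_equal(nrow(recordsWithTimestamps(empty, design)), 0)

  df <- rbind(
    rec("S1", "2016-06-03T10:00:00", "left", left_id = "L1"),
    rec("S1", "2016-06-02T09:00:00", "right", right_id = "R1"),
    rec("S9", "2016-06-02T09:30:00", "right", right_id = "R2"))
  expect_warning(out <- recordsWithTimestamps(df, design),
                 "stations not in the design")
  expect_equal(nrow(out), 2)
  expect_true(!is.unsorted(out$timestamp))

  # records outside the occasion windows are dropped with a message
  late <- rbind(df[1:2, ], rec("S2", "2017-01-01T00:00:00", "left",
                               left_id = "L2"))
  expect_message(out2 <- recordsWithTimestamps(late, design),
                 "outside the occasion windows")
  expect_equal(nrow(out2), 2)

  # missing column -> format error naming it
  p <- writeRecords(df[, setdiff(names(df), "side")])
  expect_error(readPhotoRecords(p, design), "side")
})

test_that("collapseDetections applies the pairwise 0.5-h rule", {
  design <- toyDesign()
  mk <- function(times, station = "S2", id = "R07") {
    recordsWithTimestamps(
      rec(station, times, "right", right_id = id), design)
  }
  # three photos 10 min apart -> one record, the earliest kept
  r3 <- mk(paste0("2016-06-01T10:", c("00", "10", "20"), ":00"))
  out <- collapseDetections(r3)
  expect_equal(nrow(out), 1)
  expect_equal(format(out$timestamp, "%H:%M"), "10:00")

  # a 1-h gap stays two records
  expect_equal(nrow(collapseDetections(mk(c("2016-06-01T10:00:00",
                                            "2016-06-01T11:00:00")))), 2)

  # chained gaps of 25 min collapse to one record
  chain <- mk(c("2016-06-01T10:00:00", "2016-06-01T10:25:00",
                "2016-06-01T10:50:00"))
  expect_equal(nrow(collapseDetections(chain)), 1)

  # different stations or individuals are untouched
  two <- rbind(mk("2016-06-01T10:00:00"),
               mk("2016-06-01T10:05:00", station = "S1"),
               mk("2016-06-01T10:06:00", id = "R08"))
  expect_equal(nrow(collapseDetections(two)), 3)

  expect_error(collapseDetections(r3, -1), "window")
})

test_that("collapseDetections is idempotent", {
  set.seed(11)
  paths <- makeFixture("tiny", tempfile(), seed = 11)
  design <- readDesign(paths["design"], paths["occasions"])
  recs <- suppressMessages(readPhotoRecords(paths["records"], design))
  once <- collapseDetections(recs)
  twice <- collapseDetections(once)
  expect_equal(twice, once)
})

test_that("buildEncounterArray applies the coding rules", {
  design <- toyDesign()
  # one side=both photo -> code 4
  df <- rec("S1", "2016-06-01T10:00:00", "both", left_id = "L1",
            right_id = "R1")
  arr <- buildEncounterArray(recordsWithTimestamps(df, design), design)
  expect_equal(arr@codes[1, 1, 1], 4L)
  expect_equal(historyKind(arr), "known")

  # known pair seen on both flanks in one interval, different photos -> code 3
  df3 <- rbind(rec("S1", "2016-06-01T10:00:00", "left", left_id = "L1"),
               rec("S1", "2016-06-01T14:00:00", "right", right_id = "R1"))
  kp <- data.frame(left_id = "L1", right_id = "R1")
  arr3 <- buildEncounterArray(recordsWithTimestamps(df3, design), design, kp)
  expect_equal(nHistories(arr3), 1)
  expect_equal(arr3@codes[1, 1, 1], 3L)

  # without the known pair, the same records give two single-flank histories
  arr2 <- buildEncounterArray(recordsWithTimestamps(df3, design), design)
  expect_equal(sort(historyKind(arr2)), c("left", "right"))
  expect_true(all(arr2@codes %in% c(0L, 1L, 2L)))

  # a left id in two known pairs is a data error
  bad <- data.frame(left_id = c("L1", "L1"), right_id = c("R1", "R2"))
  expect_error(buildEncounterArray(recordsWithTimestamps(df3, design),
                                   design, bad), "two known pairs")

  # cubs are excluded
  dfc <- rbind(df, rec("S2", "2016-06-01T11:00:00", "right",
                       right_id = "R1C1", age = "cub", mother_id = "R1"))
  arrc <- buildEncounterArray(recordsWithTimestamps(dfc, design), design)
  expect_equal(nHistories(arrc), 1)
})

test_that("buildEncounterArray reproduces the simulator's truth coding", {
  for (seed in c(3, 17)) {
    paths <- makeFixture("tiny", tempfile(), seed = seed)
    sim <- attr(paths, "survey")
    design <- readDesign(paths["design"], paths["occasions"])
    recs <- suppressMessages(readPhotoRecords(paths["records"], design))
    kp <- read.csv(paths["known_pairs"], colClasses = "character")
    arr <- buildEncounterArray(collapseDetections(recs), design, kp)
    truth <- sim$data
    expect_equal(nHistories(arr), nHistories(truth))
    # match histories by id label
    tid <- truth@historyIds
    aid <- arr@historyIds
    aid[arr@kind == "known"] <- paste0("L", substring(
      aid[arr@kind == "known"], 2), "|", aid[arr@kind == "known"])
    idx <- match(tid, aid)
    expect_false(anyNA(idx))
    expect_equal(arr@codes[idx, , , drop = FALSE], truth@codes)
    expect_equal(arr@kind[idx], truth@kind)
  }
})

test_that("encounter arrays conserve detections", {
  set.seed(21)
  sim <- simulateSurvey(simulationConfig(N_true = 15, trap_rows = 3,
                                         trap_cols = 3, T = 4,
                                         buffer_km = 2), seed = 21)
  # every true encounter appears in exactly one observed cell, except code-3
  # cells of unknown individuals which split into a left and a right cell
  trueCells <- sum(sim$truth$trueCodes > 0)
  splitCells <- sum(sim$truth$trueCodes[!sim$truth$known, , ] == 3)
  expect_equal(sum(sim$data@codes > 0), trueCells + splitCells)
  # with all identities known, M_obs equals the number of detected individuals
  sim2 <- simulateSurvey(simulationConfig(N_true = 15, trap_rows = 3,
                                          trap_cols = 3, T = 4, buffer_km = 2,
                                          known_both_fraction = 1), seed = 5)
  detected <- sum(apply(sim2$truth$trueCodes > 0, 1, any))
  expect_equal(nHistories(sim2$data), detected)
})

test_that("encounter arrays round-trip through the long CSV + sidecar", {
  set.seed(23)
  sim <- simulateSurvey(simulationConfig(N_true = 10, trap_rows = 3,
                                         trap_cols = 3, T = 4,
                                         buffer_km = 2), seed = 23)
  p <- tempfile(fileext = ".csv")
  writeEncounterArray(sim$data, p)
  back <- readEncounterArray(p, sim$design)
  expect_equal(back@codes, sim$data@codes)
  expect_equal(back@kind, sim$data@kind)
  expect_equal(knownFlag(back), knownFlag(sim$data))
  expect_equal(back@sex, sim$data@sex)
})

test_that("summarizeCounts tallies flank-specific individuals and sex", {
  expect_equal(summarizeCounts(rec(character(0), character(0),
                                   character(0)))$pictures, 0L)
  design <- toyDesign()
  df <- rbind(
    rec("S1", "2016-06-01T10:00:00", "both", "L1", "R1", sex = "M"),
    rec("S1", "2016-06-01T10:05:00", "both", "L1", "R1", sex = "M"),
    rec("S2", "2016-06-02T10:00:00", "right", right_id = "R2", sex = "F"),
    rec("S2", "2016-06-03T10:00:00", "left", left_id = "L3"),
    rec("S2", "2016-06-03T12:00:00", "right", right_id = "R2C1", age = "cub",
        mother_id = "R2"))
  s <- summarizeCounts(recordsWithTimestamps(df, design))
  expect_equal(s$pictures, 5L)
  expect_equal(s$detections, 4L)  # the duplicate both-photo collapses
  expect_equal(s$right_individuals, 2L)
  expect_equal(s$left_individuals, 2L)
  expect_equal(s$known_individuals, 1L)
  expect_equal(unname(s$sex), c(1L, 1L, 0L))
  expect_equal(s$families, 1L)
  expect_equal(s$cubs, 1L)
})
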