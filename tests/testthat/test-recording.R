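test_that("loader maps a clean file onto the 20-s grid", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,map_mmhg,hpi",
               "0,70,10", "20,64,12", "40,64,14"), f)
  rec <- load_recording(f)
  expect_equal(n_samples(rec), 3L)
  expect_equal(rec$map, c(70, 64, 64))
  expect_equal(rec$index, c(10, 12, 14))
  expect_true(all(rec$valid))
})

test_that("loader fills grid gaps with invalid samples", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,map_mmhg,hpi",
               "0,70,10", "20,64,12", "60,66,14"), f)
  rec <- load_recording(f)
  expect_equal(n_samples(rec), 4L)
  expect_equal(rec$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_true(is.na(rec$map[3]))
})

test_that("loader rejects bad inputs with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,map_mmhg,hpi", "0,70,10", "20,64,101"), f)
  expect_error(load_recording(f), "out of \\[0, 100\\]")

  writeLines(c("time_s,map_mmhg,hpi", "0,70,10", "0,64,12"), f)
  expect_error(load_recording(f), "strictly increasing")

  writeLines(c("time_s,bp,hpi", "0,70,10"), f)
  expect_error(load_recording(f), "missing column")

  writeLines(c("time_s,map_mmhg,hpi", "0,70,10", "13,64,12"), f)
  expect_error(load_recording(f), "grid")
})

test_that("loader decimates an exact sub-grid by last value", {
  f <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 115, by = 5)
  writeLines(c("time_s,map_mmhg,hpi",
               paste(t, 60 + seq_along(t), 5, sep = ",")), f)
  rec <- load_recording(f)
  expect_equal(n_samples(rec), 6L)
  # last 5-s sample of each 20-s bin: offsets 15, 35, 55, ...
  expect_equal(rec$map, 60 + c(4, 8, 12, 16, 20, 24))
})

test_that("write/load round-trips valid samples bit-identically", {
  set.seed(42)
  rec <- make_rec(map = 70 + rnorm(50) * pi, index = runif(50) * 100,
                  recording_id = "rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, f)
  back <- load_recording(f, recording_id = "rt")
  expect_identical(back$map[back$valid], rec$map[rec$valid])
  expect_identical(back$index[back$valid], rec$index[rec$valid])
})

test_that("default censor rules fire on range, jump, flatline, missing index", {
  # plausible flat-ish trace below the flatline run length: untouched
  rec <- make_rec(rep(75, 10))
  expect_true(all(censor_artifacts(rec)$valid))

  # out-of-range sample censored alone (jump rule dropped from the set)
  rec <- make_rec(c(75, 75, 250, 75, 75))
  cen <- censor_artifacts(rec, censor_rules()[c("map_range", "flatline",
                                               "missing_index")])
  expect_equal(cen$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(cen$map, rec$map)  # values preserved, mask only

  # hand-applied jump rule on a 5-sample trace: 80 -> 120 censors both
  rec <- make_rec(c(80, 80, 120, 80, 80))
  cen <- censor_artifacts(rec)
  expect_equal(cen$valid, c(TRUE, FALSE, FALSE, FALSE, TRUE))

  # flatline: 16 identical values censored, 15 kept
  rec <- make_rec(c(70, rep(80, 16), 70))
  expect_equal(sum(!censor_artifacts(rec)$valid), 16)
  rec <- make_rec(c(70, rep(80, 15), 70))
  expect_true(all(censor_artifacts(rec)$valid))

  # missing index
  rec <- recording(map = rep(75, 4), index = c(10, NA, 10, 10))
  expect_equal(censor_artifacts(rec)$valid, c(TRUE, FALSE, TRUE, TRUE))

  expect_error(censor_artifacts(rec, list(bogus = list())), "unknown")
})

test_that("censoring is idempotent and never revalidates samples", {
  for (seed in 1:5) {
    rec <- random_recording(200, seed)
    rec$map[sample(200, 3)] <- 240            # artifacts
    rec$valid[sample(200, 10)] <- FALSE       # pre-masked samples
    once <- censor_artifacts(rec)
    twice <- censor_artifacts(once)
    expect_identical(once$valid, twice$valid)
    expect_true(all(once$valid[!rec$valid] == FALSE))
  }
})

test_that("analysis blocks are maximal valid runs with a length gate", {
  rec <- make_rec(rep(75, 100))
  bl <- analysis_blocks(rec)
  expect_equal(bl$start, 1L)
  expect_equal(bl$end, 101L)

  rec$valid[11] <- FALSE
  bl <- analysis_blocks(rec)
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$start, c(1L, 12L))
  expect_equal(bl$end, c(11L, 101L))

  rec <- make_rec(rep(75, 21))
  rec$valid[11] <- FALSE  # two 10-sample runs
  expect_equal(nrow(analysis_blocks(rec, min_block = 220)), 0L)
  expect_error(analysis_blocks(rec, min_block = 30), "multiple of 20")
})

test_that("segment accounting matches the valid mask and the hour identity", {
  expect_equal(segment_count(data.frame(start = 1, end = 181)), 180L)
  expect_equal(segment_count(data.frame(start = integer(),
                                        end = integer())), 0L)
  # 3130 monitored hours correspond to 563,400 twenty-second segments
  expect_identical(3130 * 180, 563400)
  for (seed in 1:5) {
    rec <- random_recording(300, seed)
    rec$valid[sample(300, 40)] <- FALSE
    expect_equal(segment_count(analysis_blocks(rec, 0)), sum(rec$valid))
  }
})
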