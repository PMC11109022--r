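test_that("expression table parses values, missingness and errors", {
  header <- paste(c("participant_id", "frame_index", channels),
                  collapse = ",")
  lines <- c(header,
             paste("a", 0:2, "0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5", sep = ","),
             paste("b", 0:2, "0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5", sep = ","))
  tracks <- read_expression_table(I(paste(lines, collapse = "\n")))
  expect_named(tracks, c("a", "b"))
  expect_true(all(tracks$a$valid_mask))
  expect_true(all(tracks$a$intensities == 0.5))

  # empty happy cell invalidates the whole frame
  lines2 <- c(header,
              "a,0,0.5,,0.5,0.5,0.5,0.5,0.5,0.5",
              "a,1,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5")
  tr <- read_expression_table(I(paste(lines2, collapse = "\n")))$a
  expect_equal(tr$valid_mask, c(FALSE, TRUE))
  expect_true(all(is.na(tr$intensities[1, ])))

  # out-of-bound value names the row
  lines3 <- c(header, "a,0,0.5,0.5,0.5,1.2,0.5,0.5,0.5,0.5")
  expect_error(read_expression_table(I(paste(lines3, collapse = "\n"))),
               "angry.*row 1")

  # duplicate frame
  lines4 <- c(header,
              "a,0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5",
              "a,0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5")
  expect_error(read_expression_table(I(paste(lines4, collapse = "\n"))),
               "duplicated")

  # non-contiguous frames
  lines5 <- c(header,
              "a,0,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5",
              "a,2,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5")
  expect_error(read_expression_table(I(paste(lines5, collapse = "\n"))),
               "non-contiguous")
})

test_that("expression tables round-trip at full precision", {
  for (seed in 1:3) {
    rec <- make_random_recording(3, 40, seed, missing_frac = 0.2)
    path <- withr::local_tempfile(fileext = ".csv")
    write_expression_table(rec$tracks, path)
    back <- read_expression_table(path)
    expect_equal(names(back), participant_ids(rec))
    for (id in names(back)) {
      expect_identical(back[[id]]$intensities, rec$tracks[[id]]$intensities)
      expect_identical(back[[id]]$valid_mask, rec$tracks[[id]]$valid_mask)
    }
  }
  # one missing frame becomes one row of empty cells
  tr <- make_track("a", seq(0, 1, length.out = 5), drop_frames = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(list(tr), path)
  raw <- readLines(path)
  expect_equal(sum(grepl(",{8}$", raw)), 1L)
  # empty list writes a header-only file
  write_expression_table(list(), path)
  expect_length(readLines(path), 1L)
})

test_that("valid_mask is a pure function of missingness", {
  m <- matrix(runif(80), 10, 8, dimnames = list(NULL, channels))
  m[3, 5] <- NA
  m[7, ] <- NA
  tr <- expression_track("a", m)
  expect_equal(tr$valid_mask, !(seq_len(10) %in% c(3, 7)))
  expect_true(all(is.na(tr$intensities[3, ])))  # frame is atomic
})

test_that("engagement scripts validate contiguity and score range", {
  s <- engagement_script(c(0, 60), c(60, 120), c(2, 3))
  expect_equal(script_duration(s), 120)
  expect_error(engagement_script(c(0, 70), c(60, 120), c(2, 3)), "gap")
  expect_error(engagement_script(c(0, 50), c(60, 120), c(2, 3)), "verlap")
  expect_error(engagement_script(0, 60, 4), "score")
  path <- withr::local_tempfile(fileext = ".csv")
  write_engagement_script(s, path)
  expect_equal(read_engagement_script(path), s)
})

test_that("participant tables validate and round-trip", {
  info <- participant_table(c("a", "b"), row = c(0, 0), seat = c(0, 1),
                            age = c(20, NA), gender = c("female", "other"),
                            empathy_total = c(30, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_participant_table(info, path)
  expect_equal(read_participant_table(path), info)
  expect_error(participant_table("a", 0, 0, empathy_total = 50,
                                 empathy_scale = "EQ-short"), "range")
  expect_error(participant_table(c("a", "b"), c(0, 0), c(1, 1)),
               "duplicate seat")
  # QCAE range is wider
  expect_silent(participant_table("a", 0, 0, empathy_total = 100,
                                  empathy_scale = "QCAE"))
})

test_that("validate_recording reports findings instead of throwing", {
  rec <- make_random_recording(3, 20, 1)
  expect_equal(nrow(validate_recording(rec)), 0L)

  # duplicate seat: bypass the constructor to inspect findings
  broken <- rec
  broken$info$seat[2] <- broken$info$seat[1]
  broken$info$row[2] <- broken$info$row[1]
  f <- validate_recording(broken)
  expect_true("duplicate_seat" %in% f$rule)

  # unequal lengths
  broken2 <- rec
  broken2$tracks[[2]] <- make_track("p02", runif(19))
  f2 <- validate_recording(broken2)
  expect_true("unequal_track_length" %in% f2$rule)
  expect_error(audience_recording("x", broken2$tracks, rec$info),
               "track length")
})
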