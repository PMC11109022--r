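test_that("validity fraction counts valid frames", {
  tr <- make_track("a", runif(100), drop_frames = 1:10)
  expect_equal(validity_fraction(tr), 0.9)
  expect_equal(validity_fraction(make_track("b", runif(10))), 1.0)
  tr0 <- make_track("c", runif(100), drop_frames = 1:100)
  expect_equal(validity_fraction(tr0), 0.0)
})

test_that("inclusion applies the strict >90% and >1 survivor rules", {
  mk <- function(valid_frac) {
    ids <- c("a", "b", "c")[seq_along(valid_frac)]
    tracks <- lapply(seq_along(valid_frac), function(i) {
      make_track(ids[i], runif(100),
                 drop_frames = seq_len(round((1 - valid_frac[i]) * 100)))
    })
    audience_recording(
      "perf", tracks,
      participant_table(ids, row = rep(0, length(ids)),
                        seat = seq_along(ids) - 1))
  }
  kept <- apply_inclusion(mk(c(0.95, 0.91, 0.89)))
  expect_equal(sort(participant_ids(kept)), c("a", "b"))

  # a lone survivor triggers whole-performance exclusion
  excluded <- apply_inclusion(mk(c(0.95, 0.80)))
  expect_equal(n_participants(excluded), 0L)
  expect_equal(nrow(attr(excluded, "exclusion_log")), 2L)

  # exactly at threshold is excluded (strict inequality)
  at <- apply_inclusion(mk(c(0.95, 0.95, 0.90)))
  expect_equal(sort(participant_ids(at)), c("a", "b"))

  # idempotence
  twice <- apply_inclusion(kept)
  expect_equal(participant_ids(twice), participant_ids(kept))

  # questionnaire requirement
  rec <- mk(c(0.95, 0.95, 0.95))
  rec$info$questionnaires_complete[2] <- FALSE
  kept_q <- apply_inclusion(rec)
  expect_equal(sort(participant_ids(kept_q)), c("a", "c"))
  expect_equal(sort(participant_ids(
    apply_inclusion(rec, require_questionnaires = FALSE))),
    c("a", "b", "c"))
})

test_that("expression summaries use valid frames and sample SD", {
  tr <- make_track("a", rep(0.68, 50))
  s <- expression_summary(tr)
  expect_equal(s$mean, rep(0.68, 8))
  expect_equal(s$sd, rep(0, 8))

  # alternating 0/1 over 4 valid frames; invalid frames carry extremes
  m <- matrix(rep(c(0, 1), 4), nrow = 8, ncol = 8)
  m[5:8, ] <- 1  # would shift the mean if masking leaked
  m[5:8, 1] <- NA  # invalidates frames 5-8 entirely
  tr2 <- expression_track("b", m)
  s2 <- expression_summary(tr2)
  expect_equal(s2$mean, rep(0.5, 8))
  expect_equal(s2$sd, rep(sqrt(1 / 3), 8), tolerance = 1e-12)

  expect_error(expression_summary(make_track("c", runif(3),
                                             drop_frames = 1:2)),
               "2 valid")
})

test_that("between-expression matrices capture exact dependencies", {
  nf <- 200
  base <- 0.5 + 0.3 * sin(seq_len(nf) / 7)
  m <- matrix(runif(nf * 8), nf, 8, dimnames = list(NULL, channels))
  m[, "happy"] <- base
  m[, "sad"] <- base          # identical
  m[, "fear"] <- 1 - base     # perfect complement
  m[, "contempt"] <- 0.4      # zero variance
  cm <- between_expression_matrix(expression_track("a", m))
  expect_equal(cm["happy", "sad"], 1)
  expect_equal(cm["happy", "fear"], -1)
  expect_true(all(is.na(cm["contempt", ])))
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(cm["neutral", "neutral"], 1)

  # independent channels stay near zero at large n
  set.seed(9)
  big <- matrix(runif(10000 * 8), 10000, 8, dimnames = list(NULL, channels))
  cb <- between_expression_matrix(expression_track("b", big))
  expect_lt(max(abs(cb[upper.tri(cb)])), 0.05)
})

test_that("individual-vs-rest matrices are directed and exact", {
  nf <- 300
  base <- 0.5 + 0.3 * sin(seq_len(nf) / 9)
  mk <- function(id, happy) {
    m <- matrix(rep(base, 8), nf, 8, dimnames = list(NULL, channels))
    m[, "happy"] <- happy
    expression_track(id, m)
  }
  rec <- audience_recording(
    "r", list(mk("a", base), mk("b", base), mk("c", base)),
    participant_table(c("a", "b", "c"), row = 0, seat = 0:2))
  cm <- individual_vs_rest_matrix(rec, "a")
  expect_true(all(abs(diag(unclass(cm)) - 1) < 1e-12))

  # one participant mirrored against the others
  rec2 <- audience_recording(
    "r2", list(mk("a", 1 - base), mk("b", base), mk("c", base)),
    participant_table(c("a", "b", "c"), row = 0, seat = 0:2))
  cm2 <- individual_vs_rest_matrix(rec2, "a")
  expect_equal(cm2["happy", "happy"], -1)

  expect_error(individual_vs_rest_matrix(
    audience_recording("one", list(mk("a", base)),
                       participant_table("a", 0, 0)), "a"),
    "audience of 1")

  # independent audience: entries near zero
  set.seed(21)
  recn <- make_random_recording(10, 10000, 22, missing_frac = 0)
  cmn <- individual_vs_rest_matrix(recn, "p01")
  expect_lt(mean(abs(cmn)), 0.05)
})

test_that("within/between contrast works on transformed values", {
  m <- matrix(0, 8, 8, dimnames = list(channels, channels))
  diag(m) <- 0.5
  cm <- structure(m, class = c("cross_expression_matrix", "matrix", "array"),
                  type = "individual_vs_rest", participant_id = "a")
  wb <- within_between_contrast(list(cm))
  expect_equal(wb$individual$on_z, atanh(0.5), tolerance = 1e-12)
  expect_equal(wb$individual$off_z, 0)
  expect_equal(wb$individual$contrast, atanh(0.5), tolerance = 1e-12)
  expect_equal(nrow(wb$per_expression), 8L)

  # equal diagonal and off-diagonal: zero contrast
  m2 <- matrix(0.3, 8, 8, dimnames = list(channels, channels))
  cm2 <- structure(m2, class = c("cross_expression_matrix", "matrix",
                                 "array"),
                   type = "individual_vs_rest", participant_id = "b")
  wb2 <- within_between_contrast(list(cm2))
  expect_equal(wb2$individual$contrast, 0, tolerance = 1e-12)

  m3 <- matrix(NA_real_, 8, 8, dimnames = list(channels, channels))
  cm3 <- structure(m3, class = c("cross_expression_matrix", "matrix",
                                 "array"), type = "individual_vs_rest")
  expect_error(within_between_contrast(list(cm3)), "undefined")
})
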