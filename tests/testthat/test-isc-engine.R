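test_that("window arithmetic follows the count formula", {
  spec <- window_spec(3000, 100)
  s <- window_starts(9000, spec)
  expect_length(s, 61)
  expect_equal(s[1], 0)
  expect_equal(s[61], 6000)
  expect_equal(window_starts(3000, spec), 0)             # exactly one window
  expect_length(window_starts(3099, spec), 1)            # partial dropped
  expect_error(window_starts(2999, spec), "shorter")
  expect_error(window_spec(step = 0), "step")
})

test_that("fisher transform matches closed forms and round-trips", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(-0.9), -1.472219, tolerance = 1e-6)
  r <- seq(-0.999, 0.999, length.out = 1999)
  expect_lt(max(abs(r - fisher_z_inv(fisher_z(r)))), 1e-12)
  # odd and strictly increasing
  expect_equal(fisher_z(r), -fisher_z(-r))
  expect_true(all(diff(fisher_z(r)) > 0))
  # clipping keeps perfect correlations finite
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.5), "outside")
})

test_that("windowed pair correlation honors Pearson invariances", {
  nf <- 500
  base <- 0.5 + 0.4 * sin(seq_len(nf) / 20)
  a <- make_track("a", base)
  b <- make_track("b", 0.2 + 0.5 * base)  # affine image of a
  spec <- window_spec(100, 50)
  w <- windowed_pair_correlation(a, b, "happy", spec)
  expect_true(all(abs(w$r - 1) < 1e-12))
  # symmetry is exact
  w2 <- windowed_pair_correlation(b, a, "happy", spec)
  expect_identical(w$r, w2$r)
  expect_error(windowed_pair_correlation(a, b, "joy", spec), "unknown")
})

test_that("windowed correlations match the brute-force oracle", {
  for (seed in 1:8) {
    set.seed(seed + 100)
    n <- sample(2:6, 1)
    nf <- sample(150:600, 1)
    rec <- make_random_recording(n, nf, seed + 200, missing_frac = 0.15)
    wl <- sample(c(60, 100, 150), 1)
    st <- sample(c(20, 50), 1)
    spec <- window_spec(wl, st, min_valid_fraction = 0.5)
    ch <- sample(channels, 1)
    ids <- participant_ids(rec)
    for (pair in list(c(1, 2), c(1, n))) {
      got <- windowed_pair_correlation(rec$tracks[[pair[1]]],
                                       rec$tracks[[pair[2]]], ch, spec)
      ref <- naive_windowed_r(rec$tracks[[pair[1]]],
                              rec$tracks[[pair[2]]], ch, wl, st, 0.5)
      expect_equal(is.na(got$r), is.na(ref))
      expect_lt(max(abs(got$r - ref), na.rm = TRUE), 1e-10)
    }
  }
})

test_that("sliding-window ISC averages defined pairs only", {
  nf <- 300
  base <- 0.5 + 0.3 * sin(seq_len(nf) / 10)
  rec <- audience_recording(
    "toy",
    list(make_track("a", base), make_track("b", base),
         make_track("c", rep(0.4, nf))),  # constant: undefined pairs
    participant_table(c("a", "b", "c"), row = c(0, 0, 0), seat = 0:2))
  isc <- sliding_window_isc(rec, window_spec(100, 100))
  happy <- isc[isc$expression == "happy", ]
  expect_true(all(abs(happy$mean_r - 1) < 1e-12))
  expect_true(all(happy$n_pairs == 1L))  # only the (a, b) pair is defined

  # three identical tracks: mean 1 over all three pairs
  rec3 <- audience_recording(
    "toy3",
    list(make_track("a", base), make_track("b", base),
         make_track("c", base)),
    participant_table(c("a", "b", "c"), row = c(0, 0, 0), seat = 0:2))
  isc3 <- sliding_window_isc(rec3, window_spec(100, 100))
  expect_true(all(abs(isc3$mean_r - 1) < 1e-12))
  expect_true(all(isc3$n_pairs == 3L))
})

test_that("sliding-window ISC is invariant to participant order", {
  rec <- make_random_recording(5, 400, 31, missing_frac = 0.1)
  spec <- window_spec(150, 50)
  isc1 <- sliding_window_isc(rec, spec)
  perm <- c(4, 2, 5, 1, 3)
  rec2 <- audience_recording(rec$performance_id, rec$tracks[perm],
                             rec$info)
  isc2 <- sliding_window_isc(rec2, spec)
  expect_equal(isc1$mean_r, isc2$mean_r, tolerance = 1e-12)
  expect_equal(isc1$n_pairs, isc2$n_pairs)
})

test_that("pair-level ISC table has one clipped-z row per pair", {
  nf <- 300
  base <- 0.5 + 0.3 * sin(seq_len(nf) / 10)
  rec <- audience_recording(
    "pair",
    list(make_track("a", base), make_track("b", base)),
    participant_table(c("a", "b"), row = c(0, 0), seat = c(0, 1)))
  pt <- pairwise_isc(rec)
  expect_equal(nrow(pt), 8L)  # one pair x 8 expressions
  expect_true(all(abs(pt$r - 1) < 1e-12))
  expect_equal(pt$z, rep(atanh(1 - 1e-7), 8))  # ~ 8.39, finite
  expect_true(all(pt$seat_distance == 1))

  # whole-series equals the single full-length window
  rec2 <- make_random_recording(4, 200, 77, missing_frac = 0.1)
  whole <- pairwise_isc(rec2)
  windowed <- pairwise_isc(rec2, mode = "window_mean",
                           spec = window_spec(200, 200))
  expect_equal(whole$r, windowed$r, tolerance = 1e-12)
  # z is always the transform of r
  expect_equal(whole$z, fisher_z(whole$r))
})

test_that("null audiences give near-zero ISC time courses", {
  means <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_participants = 6, n_frames = 1500,
                             dropout = 0, seed = seed)
    rec <- simulate_null_recording(cfg)
    isc <- sliding_window_isc(rec, window_spec(500, 250))
    mean(isc$mean_r, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(means), -0.03)
  expect_lt(mean(means), 0.03)
})
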