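test_that("generator is a pure function of (config, seed)", {
  cfg <- simulation_config(n_participants = 4, n_frames = 1500, seed = 11)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  for (id in participant_ids(a$recording)) {
    expect_identical(a$recording$tracks[[id]]$intensities,
                     b$recording$tracks[[id]]$intensities)
  }
  expect_identical(a$truth$coupling_weight, b$truth$coupling_weight)
  expect_identical(a$recording$info, b$recording$info)
})

test_that("noise-free fully shared audience is perfectly synchronized", {
  # two participants, no noise, no dropout, near-infinite spatial
  # correlation, no trait modulation: tracks must correlate at ~1
  cfg <- simulation_config(
    n_participants = 2, n_frames = 1500, grid = c(1, 2), noise_sd = 0,
    dropout = 0, spatial_length = 1e6, beta_age = 0, beta_empathy = 0,
    beta_gender = 0, seed = 5)
  rec <- simulate_recording(cfg)$recording
  for (ch in channels) {
    x <- rec$tracks[[1]]$intensities[, ch]
    y <- rec$tracks[[2]]$intensities[, ch]
    if (sd(x) > 0 && sd(y) > 0) expect_gt(cor(x, y), 0.999)
  }
})

test_that("uncoupled audiences are uncorrelated on average", {
  rs <- vapply(1:50, function(seed) {
    cfg <- simulation_config(n_participants = 3, n_frames = 800,
                             coupling = 0, noise_sd = 0.05, dropout = 0,
                             seed = seed)
    rec <- simulate_recording(cfg)$recording
    x <- sapply(rec$tracks, function(t) t$intensities[, "happy"])
    mean(cor(x)[upper.tri(diag(3))])
  }, numeric(1))
  expect_gt(mean(rs), -0.05)
  expect_lt(mean(rs), 0.05)
})

test_that("dropout produces the exact validity fraction", {
  cfg <- simulation_config(n_participants = 3, n_frames = 1000,
                           dropout = 0.2, seed = 3)
  rec <- simulate_recording(cfg)$recording
  for (tr in rec$tracks) {
    expect_equal(validity_fraction(tr), 1 - ceiling(0.2 * 1000) / 1000)
  }
  # null recordings share the machinery and the determinism
  null1 <- simulate_null_recording(cfg)
  null2 <- simulate_null_recording(cfg)
  expect_identical(null1$tracks[[1]]$intensities,
                   null2$tracks[[1]]$intensities)
  expect_true(all(vapply(null1$tracks, function(t) {
    v <- t$intensities[t$valid_mask, ]
    all(v >= 0 & v <= 1)
  }, logical(1))))
})

test_that("spatial_field matches its exponential covariance", {
  seats <- data.frame(row = c(0, 0), seat = c(0, 2))  # distance 2
  f <- spatial_field(seats, lambda = 2, n_blocks = 2000, seed = 42)
  expect_equal(dim(f), c(2000, 2))
  expect_equal(cor(f[, 1], f[, 2]), exp(-1), tolerance = 0.05 / exp(-1))

  # lambda -> 0: independence
  f0 <- spatial_field(seats, lambda = 1e-6, n_blocks = 2000, seed = 43)
  expect_lt(abs(cor(f0[, 1], f0[, 2])), 0.07)

  # lambda -> Inf: all seats tied together
  seats3 <- data.frame(row = c(0, 1, 3), seat = c(0, 2, 1))
  f1 <- spatial_field(seats3, lambda = 1e6, n_blocks = 500, seed = 44)
  cm <- cor(f1)
  expect_true(all(cm[upper.tri(cm)] > 0.95))

  expect_error(spatial_field(seats, lambda = 0, n_blocks = 10), "> 0")
})

test_that("make_engagement_script builds contiguous scripts", {
  s <- make_engagement_script(c(60, 60), c(1, 3))
  expect_equal(s$start_s, c(0, 60))
  expect_equal(s$end_s, c(60, 120))
  s1 <- make_engagement_script(30, 2)
  expect_equal(script_duration(s1), 30)
  expect_error(make_engagement_script(10, 5), "score")
  expect_error(make_engagement_script(numeric(0), integer(0)), "non-empty")
})

test_that("infeasible grids are rejected", {
  expect_error(simulation_config(n_participants = 10, grid = c(3, 3)),
               "cannot seat")
})

test_that("mean pairwise ISC increases with the coupling gain", {
  mean_isc <- function(kappa) {
    mean(vapply(1:30, function(seed) {
      cfg <- simulation_config(n_participants = 6, n_frames = 1200,
                               coupling = kappa, dropout = 0, seed = seed)
      rec <- simulate_recording(cfg)$recording
      x <- sapply(rec$tracks, function(t) t$intensities[, "happy"])
      mean(cor(x)[upper.tri(diag(6))])
    }, numeric(1)))
  }
  m <- vapply(c(0, 1, 2), mean_isc, numeric(1))
  expect_lt(m[1], m[2])
  expect_lt(m[2], m[3])
})

test_that("close pairs are more synchronized than distant ones", {
  # one long row so seat distance spans 1..9
  diffs <- vapply(1:30, function(seed) {
    cfg <- simulation_config(n_participants = 10, n_frames = 1200,
                             grid = c(1, 10), spatial_length = 3,
                             dropout = 0, seed = seed)
    rec <- simulate_recording(cfg)$recording
    pt <- pairwise_isc(rec)
    happy <- pt[pt$expression == "happy", ]
    mean(happy$r[happy$seat_distance == 1]) -
      mean(happy$r[happy$seat_distance >= 5])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("high-empathy pairs are more synchronized when beta_empathy > 0", {
  diffs <- vapply(1:30, function(seed) {
    cfg <- simulation_config(n_participants = 10, n_frames = 1200,
                             beta_empathy = 1, beta_age = 0,
                             beta_gender = 0, dropout = 0, seed = seed)
    rec <- simulate_recording(cfg)$recording
    pt <- pairwise_isc(rec)
    happy <- pt[pt$expression == "happy", ]
    hi <- happy$total_empathy > median(happy$total_empathy)
    mean(happy$r[hi]) - mean(happy$r[!hi])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
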