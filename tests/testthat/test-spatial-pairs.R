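test_that("seat distance is the Euclidean metric on the seat grid", {
  expect_equal(seat_distance(c(0, 0), c(0, 1)), 1.0)
  expect_equal(seat_distance(c(0, 0), c(1, 1)), sqrt(2))
  expect_equal(seat_distance(c(2, 3), c(2, 3)), 0)
  # metric properties on random triples
  set.seed(12)
  for (i in 1:20) {
    a <- sample(0:9, 2); b <- sample(0:9, 2); c <- sample(0:9, 2)
    expect_equal(seat_distance(a, b), seat_distance(b, a))
    expect_lte(seat_distance(a, c),
               seat_distance(a, b) + seat_distance(b, c) + 1e-12)
  }
})

test_that("pair features implement the grouping definitions", {
  f <- pair_features(list(age = 20, gender = "female", empathy_total = 30),
                     list(age = 30, gender = "male", empathy_total = 10))
  expect_equal(f$total_age, 50)
  expect_equal(f$total_empathy, 40)
  expect_equal(f$gender_group, "different")
  expect_equal(f$age_group, "different")

  f2 <- pair_features(list(age = 20, gender = "female", empathy_total = 3),
                      list(age = 22, gender = "female", empathy_total = 4))
  expect_equal(f2$gender_group, "female")
  expect_equal(f2$age_group, "young")

  f3 <- pair_features(list(age = 30, gender = "other", empathy_total = NA),
                      list(age = 40, gender = "male", empathy_total = 10))
  expect_equal(f3$gender_group, "excluded")
  expect_true(is.na(f3$total_empathy))

  # age exactly 25 defeats both strict inequalities
  f4 <- pair_features(list(age = 25, gender = "male", empathy_total = 1),
                      list(age = 30, gender = "male", empathy_total = 1))
  expect_equal(f4$age_group, "different")
  # missing age propagates
  f5 <- pair_features(list(age = NA, gender = "male", empathy_total = 1),
                      list(age = 30, gender = "male", empathy_total = 1))
  expect_true(is.na(f5$total_age))
  expect_true(is.na(f5$age_group))
})

test_that("proximity correlation handles exact and degenerate tables", {
  d <- c(1, 2, 3, 4, 5, 6)
  tab <- make_pair_table(tibble::tibble(
    participant_a = letters[1:6], participant_b = LETTERS[1:6],
    expression = "happy", r = tanh(-sqrt(d)), seat_distance = d))
  expect_equal(proximity_correlation(tab, "happy"), -1, tolerance = 1e-12)

  flat <- make_pair_table(tibble::tibble(
    participant_a = letters[1:6], participant_b = LETTERS[1:6],
    expression = "happy", r = rep(0.5, 6), seat_distance = d))
  expect_warning(expect_true(is.na(proximity_correlation(flat, "happy"))),
                 "zero variance")
  expect_error(proximity_correlation(tab, "sad"), "at least 4")
})

test_that("permutation test counts extreme draws reproducibly", {
  set.seed(3)
  d <- rep(1:5, each = 4)
  tab <- make_pair_table(tibble::tibble(
    participant_a = sprintf("a%02d", 1:20),
    participant_b = sprintf("b%02d", 1:20),
    expression = "happy", r = tanh(-sqrt(d)), seat_distance = d))
  # observed r = -1 is more extreme than any non-identity permutation
  res <- permutation_test_proximity(tab, "happy", n_perm = 500, seed = 4)
  expect_equal(res$r_obs, -1, tolerance = 1e-12)
  expect_equal(res$p, 0)
  res1 <- permutation_test_proximity(tab, "happy", n_perm = 500, seed = 4,
                                     p_rule = "add_one")
  expect_equal(res1$p, 1 / 501)
  # the literal greater-or-equal rule counts the other tail for a negative r_obs
  res2 <- permutation_test_proximity(tab, "happy", n_perm = 500, seed = 4,
                                     p_rule = "ge_observed")
  expect_equal(res2$p, 1)

  # determinism
  ra <- permutation_test_proximity(tab, "happy", n_perm = 300, seed = 9)
  rb <- permutation_test_proximity(tab, "happy", n_perm = 300, seed = 9)
  expect_identical(ra$p, rb$p)
  expect_warning(permutation_test_proximity(tab, "happy", n_perm = 50,
                                            seed = 1), "n_perm")
  # tidy() round trip
  expect_equal(tidy(ra)$p, ra$p)
})

test_that("feature associations recover exact linear relations", {
  n <- 30
  set.seed(6)
  age <- runif(n, 40, 120)
  tab <- make_pair_table(tibble::tibble(
    participant_a = sprintf("a%02d", 1:n),
    participant_b = sprintf("b%02d", 1:n),
    expression = "happy", r = tanh(1 - 0.01 * age),
    seat_distance = 1, total_age = age,
    total_empathy = runif(n, 10, 60)))
  fa <- feature_association(tab, "total_age", "happy")
  expect_equal(fa$correlation$r, -1, tolerance = 1e-9)
  expect_equal(fa$models$model[1], "total_age")
  expect_gt(fa$correlation$bf10, 100)  # negative direction is favored

  const <- make_pair_table(tibble::tibble(
    participant_a = sprintf("a%02d", 1:n),
    participant_b = sprintf("b%02d", 1:n),
    expression = "happy", r = tanh(rnorm(n, 0, 0.1)),
    seat_distance = 1, total_age = rep(50, n),
    total_empathy = runif(n, 10, 60)))
  expect_warning(fc <- feature_association(const, "total_age", "happy"),
                 "zero variance")
  expect_true(is.na(fc$correlation$r))

  missing_all <- make_pair_table(tibble::tibble(
    participant_a = "a", participant_b = "b", expression = "happy",
    r = 0.2, seat_distance = 1, total_age = NA_real_,
    total_empathy = NA_real_))
  expect_error(feature_association(missing_all, "total_age", "happy"),
               "missing")
})

test_that("group contrasts score gender structure against an age null", {
  build <- function(shift, seed) {
    set.seed(seed)
    n <- 60
    gg <- rep(c("female", "male", "different"), each = n / 3)
    ag <- rep(c("young", "old"), n / 2)
    z <- rnorm(n, 0.2, 0.1) + ifelse(gg == "female", shift, 0)
    make_pair_table(tibble::tibble(
      participant_a = sprintf("a%02d", 1:n),
      participant_b = sprintf("b%02d", 1:n),
      expression = "happy", r = tanh(z), seat_distance = 1,
      total_age = 50, total_empathy = 30,
      gender_group = gg, age_group = ag))
  }
  gc_eff <- group_contrast(build(0.2, 1), "happy")
  expect_true(gc_eff$models$model[1] != "age")
  expect_equal(nrow(gc_eff$cell_means), 6L)

  # calibration: with no gender effect the age-only null wins mostly
  wins <- vapply(1:50, function(seed) {
    group_contrast(build(0, seed), "happy")$models$model[1] == "age"
  }, logical(1))
  expect_gte(mean(wins), 0.8)

  single <- make_pair_table(tibble::tibble(
    participant_a = sprintf("a%02d", 1:10),
    participant_b = sprintf("b%02d", 1:10),
    expression = "happy", r = runif(10, 0, 0.5), seat_distance = 1,
    total_age = 50, total_empathy = 30,
    gender_group = "female", age_group = "old"))
  expect_error(group_contrast(single, "happy"), "2 gender groups")
})
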