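# Programmatic fixtures; nothing is stored on disk.

channels <- expression_channels()

# A track whose channels all equal `values` (a vector or frames x 8
# matrix); drop_frames are marked invalid.
make_track <- function(id, values, frame_rate = 50, drop_frames = integer(0)) {
  if (!is.matrix(values)) {
    values <- matrix(rep(values, 8), ncol = 8)
  }
  colnames(values) <- channels
  if (length(drop_frames)) values[drop_frames, ] <- NA_real_
  expression_track(id, values, frame_rate = frame_rate)
}

# Random audience of independent uniform tracks with optional random
# missing frames, plus a row-major seat grid and complete metadata.
make_random_recording <- function(n, nf, seed, missing_frac = 0.1,
                                  frame_rate = 50) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(n))
  tracks <- lapply(ids, function(id) {
    m <- matrix(runif(nf * 8), nf, 8)
    if (missing_frac > 0) {
      drop <- sample.int(nf, round(missing_frac * nf))
      m[drop, ] <- NA_real_
    }
    colnames(m) <- channels
    expression_track(id, m, frame_rate)
  })
  side <- ceiling(sqrt(n))
  info <- participant_table(
    ids,
    row = (seq_len(n) - 1) %/% side,
    seat = (seq_len(n) - 1) %% side,
    age = runif(n, 18, 80),
    gender = sample(c("female", "male"), n, replace = TRUE),
    empathy_total = runif(n, 0, 44),
    empathy_scale = "EQ-short",
    questionnaires_complete = TRUE)
  audience_recording(sprintf("fixture-%d", seed), tracks, info)
}

# Hand-built pair ISC table for the pair-analysis units.
make_pair_table <- function(df) {
  df$expression <- factor(df$expression, levels = channels)
  needed <- c("participant_a", "participant_b", "expression", "n_joint",
              "r", "z", "seat_distance", "total_age", "total_empathy",
              "gender_group", "age_group")
  for (col in setdiff(needed, names(df))) {
    df[[col]] <- switch(col,
                        n_joint = 1000L,
                        z = fisher_z(df$r),
                        total_age = NA_real_, total_empathy = NA_real_,
                        gender_group = "different", age_group = "different",
                        NA)
  }
  structure(tibble::as_tibble(df[, needed]),
            class = c("pair_isc_table", class(tibble::tibble())),
            mode = "constructed", window_spec = window_spec())
}

# Fake windowed objects for regression unit tests: an isc_timecourse and
# an engagement_course sharing one window grid.
make_fake_windows <- function(isc_matrix, engagement, frame_rate = 50,
                              step = 100, window_len = 3000) {
  stopifnot(ncol(isc_matrix) == 8)
  colnames(isc_matrix) <- channels
  n_win <- nrow(isc_matrix)
  starts <- seq(0, by = step, length.out = n_win)
  nf <- max(starts) + window_len
  spec <- window_spec(window_len, step)
  isc <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(window_start_frame = starts),
                     tibble::as_tibble(isc_matrix)),
    -"window_start_frame", names_to = "expression", values_to = "mean_r")
  isc$window_start_s <- isc$window_start_frame / frame_rate
  isc$n_pairs <- 1L
  isc$expression <- factor(isc$expression, levels = channels)
  isc <- structure(
    isc[, c("window_start_frame", "window_start_s", "expression",
            "mean_r", "n_pairs")],
    class = c("isc_timecourse", class(tibble::tibble())),
    window_spec = spec, frame_rate = frame_rate, n_frames = nf)
  course <- structure(
    tibble::tibble(window_start_frame = starts,
                   window_start_s = starts / frame_rate,
                   engagement = engagement),
    class = c("engagement_course", class(tibble::tibble())),
    window_spec = spec, frame_rate = frame_rate, n_frames = nf)
  list(isc = isc, course = course)
}
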