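# Fixed amplitude of the coupled (shared + spatial) component, relative to
# the [0,1] intensity scale. Kept constant so that coupling gains are
# comparable across configurations.
.signal_amplitude <- 0.1

# Default per-channel baselines: neutral dominates, emotional channels
# are sparse, mirroring what automated classification typically reports
# for seated audiences.
.default_baseline <- function() {
  stats::setNames(c(0.55, 0.25, 0.2, 0.2, 0.15, 0.15, 0.15, 0.2),
                  .channels())
}

#' Build an engagement script from scene lengths
#'
#' @param scene_lengths_s Scene durations in whole seconds.
#' @param scores Scores in `{1, 2, 3}`, same length.
#' @return An [engagement_script()] starting at 0.
#' @export
#' @examples
#' make_engagement_script(c(60, 60), c(1, 3))
make_engagement_script <- function(scene_lengths_s, scores) {
  if (length(scene_lengths_s) == 0L || length(scores) == 0L) {
    stop("scene lengths and scores must be non-empty", call. = FALSE)
  }
  if (length(scene_lengths_s) != length(scores)) {
    stop("scene lengths and scores must have equal length", call. = FALSE)
  }
  ends <- cumsum(scene_lengths_s)
  engagement_script(c(0, ends[-length(ends)]), ends, scores)
}

#' Configuration for the synthetic-audience generator
#'
#' Defines the generative model's knobs: audience size and seating grid,
#' recording length, the engagement script gating the shared signal,
#' per-channel baselines and coupling gains, the engagement exponent, the
#' spatial correlation length of the local coupling field, trait slopes
#' entering each participant's coupling weight, noise level, latent-signal
#' smoothing, and frame dropout.
#'
#' @param n_participants Audience size (must fit the grid).
#' @param n_frames Recording length in frames.
#' @param frame_rate Frames per second (default 50).
#' @param grid `c(rows, seats_per_row)` of the seating grid.
#' @param script An [engagement_script()] whose duration equals
#'   `n_frames / frame_rate`; by default a deterministic script of 30 s
#'   scenes cycling through scores 1, 2, 3 is built.
#' @param baseline Named per-channel baseline intensities in \[0, 1\].
#' @param coupling Named per-channel coupling gains (>= 0; default 0.3,
#'   calibrated so windowed ISCs land in the 0.01-0.1 range reported for
#'   real audiences).
#' @param engagement_exponent Exponent `gamma >= 0`: the shared-signal
#'   gain in a frame with scene score e is `(e/3)^gamma`.
#' @param spatial_length Correlation length `lambda > 0` in seat units of
#'   the exponentially decaying local coupling field.
#' @param spatial_weight Amplitude `omega >= 0` of the local spatial
#'   field relative to the globally shared signal (default 2: local
#'   coupling dominates, as emotional contagion between neighbours
#'   suggests).
#' @param beta_age,beta_empathy,beta_gender Trait slopes (per standardized
#'   unit; gender slope applies to the female indicator) in each
#'   participant's logistic coupling weight.
#' @param noise_sd Per-frame Gaussian noise SD (default 0.15).
#' @param smooth_frames Moving-average length (frames) of latent signals,
#'   also the coarse block length of the spatial field.
#' @param dropout Fraction of frames marked invalid per participant, in
#'   \[0, 1).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @param empathy_scale `"EQ-short"` or `"QCAE"` for simulated empathy
#'   totals.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 20,
                              n_frames = 6000,
                              frame_rate = 50,
                              grid = NULL,
                              script = NULL,
                              baseline = .default_baseline(),
                              coupling = 0.3,
                              engagement_exponent = 1,
                              spatial_length = 3,
                              spatial_weight = 2,
                              beta_age = -0.5,
                              beta_empathy = 0.5,
                              beta_gender = 0.5,
                              noise_sd = 0.15,
                              smooth_frames = 50,
                              dropout = 0.05,
                              seed = 1L,
                              empathy_scale = "EQ-short") {
  if (is.null(grid)) {
    side <- ceiling(sqrt(n_participants))
    grid <- c(side, side)
  }
  stopifnot(n_participants >= 1, n_frames >= 2, frame_rate > 0,
            length(grid) == 2, all(grid >= 1),
            engagement_exponent >= 0, spatial_length > 0,
            spatial_weight >= 0,
            noise_sd >= 0, smooth_frames >= 1,
            dropout >= 0, dropout < 1)
  if (n_participants > grid[1] * grid[2]) {
    stop(sprintf("grid %dx%d cannot seat %d participants",
                 grid[1], grid[2], n_participants), call. = FALSE)
  }
  if (length(coupling) == 1L) coupling <- rep(coupling, .n_channels)
  coupling <- stats::setNames(as.numeric(coupling), .channels())
  if (any(coupling < 0)) stop("coupling gains must be >= 0", call. = FALSE)
  baseline <- stats::setNames(as.numeric(baseline), .channels())
  if (any(baseline < 0 | baseline > 1)) {
    stop("baselines must be in [0,1]", call. = FALSE)
  }
  if (is.null(script)) {
    dur <- n_frames / frame_rate
    if (dur != round(dur)) {
      stop("default script needs a whole-second duration; supply a script",
           call. = FALSE)
    }
    n_scenes <- max(1L, floor(dur / 30))
    lens <- rep(floor(dur / n_scenes), n_scenes)
    lens[n_scenes] <- dur - sum(lens[-n_scenes])
    script <- make_engagement_script(lens, rep_len(c(1L, 3L, 2L), n_scenes))
  }
  if (abs(script_duration(script) - n_frames / frame_rate) > 1e-9) {
    stop("script duration must equal n_frames / frame_rate", call. = FALSE)
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_frames = as.integer(n_frames), frame_rate = frame_rate,
    grid = as.integer(grid), script = script, baseline = baseline,
    coupling = coupling, engagement_exponent = engagement_exponent,
    spatial_length = spatial_length, spatial_weight = spatial_weight,
    beta_age = beta_age,
    beta_empathy = beta_empathy, beta_gender = beta_gender,
    noise_sd = noise_sd, smooth_frames = as.integer(smooth_frames),
    dropout = dropout, seed = as.integer(seed),
    empathy_scale = empathy_scale), class = "simulation_config")
}

# Standardize a vector; constant input maps to zeros.
.standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Standardized moving average (length L) of unit-normal noise: the latent
# shared signal for one channel.
.smooth_noise <- function(n, L) {
  e <- stats::rnorm(n + L - 1L)
  s <- as.numeric(stats::filter(e, rep(1 / L, L), sides = 1))[L:(n + L - 1L)]
  .standardize(s)
}

#' Draw a spatially correlated field over the audience
#'
#' Each row is an independent draw from a zero-mean multivariate normal
#' over participants with covariance `exp(-d_ij / lambda)`, where `d_ij`
#' is the Euclidean seat distance. Realized through a symmetric
#' eigendecomposition root of the covariance with a small diagonal jitter
#' for conditioning.
#'
#' @param seat_map Data frame with columns `row` and `seat` (one row per
#'   participant).
#' @param lambda Correlation length in seat units (> 0).
#' @param n_blocks Number of independent draws (rows).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside the generator).
#' @return `n_blocks` x participants numeric matrix.
#' @export
spatial_field <- function(seat_map, lambda, n_blocks, seed = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("spatial correlation length must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  coords <- as.matrix(seat_map[, c("row", "seat")])
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  sigma <- exp(-d / lambda) + diag(1e-8, n)
  eg <- eigen(sigma, symmetric = TRUE)
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  z <- matrix(stats::rnorm(n_blocks * n), n_blocks, n)
  z %*% root
}

# Exact-count contiguous dropout: mark m = ceiling(delta * n) frames
# invalid as up to 3 non-overlapping contiguous runs at random offsets.
.dropout_frames <- function(n, delta) {
  m <- ceiling(delta * n)
  if (m == 0L) return(integer(0))
  if (m >= n) return(seq_len(n))
  k <- max(1L, min(3L, m %/% 50L))
  lens <- rep(m %/% k, k)
  lens[1] <- lens[1] + m %% k
  offsets <- sort(sample.int(n - m + 1L, k, replace = TRUE) - 1L)
  starts <- offsets + c(0L, cumsum(lens[-k]))
  unlist(purrr::map2(starts, lens, function(s, l) (s + 1L):(s + l)))
}

#' Simulate an audience recording with known ground truth
#'
#' The generative model, in draw order (one seeded RNG stream):
#' \enumerate{
#'   \item Traits: age ~ Uniform(18, 80); empathy ~ Normal truncated to
#'     the declared scale's range; gender ~ Bernoulli(1/2) female/male.
#'     Seats fill the grid row-major (deterministic).
#'   \item Per-frame engagement `e(t)` is the scene score; the gain is
#'     `g(t) = (e(t)/3)^gamma`.
#'   \item Per channel c, a shared signal `s_c(t)`: standardized moving
#'     average (length `smooth_frames`) of unit-normal noise.
#'   \item Per channel, a spatially correlated local field `u_ic(t)`:
#'     independent multivariate-normal draws with covariance
#'     `exp(-d_ij/lambda)` at each coarse block of `smooth_frames`
#'     frames, upsampled by repetition and standardized per participant.
#'   \item Coupling weight `w_i = logistic(beta_age z(age) +
#'     beta_empathy z(empathy) + beta_gender 1[female])`, with z the
#'     within-audience standardization.
#'   \item Intensity `x_ic(t) = clip(mu_c + kappa_c g(t) w_i
#'     (s_c(t) + u_ic(t)) a + sigma eps, 0, 1)` with fixed amplitude
#'     `a = 0.1` and i.i.d. unit-normal noise.
#'   \item Dropout: `ceiling(dropout * n_frames)` frames per participant
#'     are marked invalid as contiguous runs at random positions.
#' }
#'
#' @param config A [simulation_config()].
#' @return List with elements `recording` (an [audience_recording()]) and
#'   `truth` (class `audience_ground_truth`: per-frame engagement and
#'   gain, the frames x 8 shared-signal matrix, per-participant coupling
#'   weights, and the config).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_participants; nf <- config$n_frames
  ids <- sprintf("p%02d", seq_len(n))

  # seats: row-major fill (deterministic)
  seat_row <- (seq_len(n) - 1L) %/% config$grid[2]
  seat_col <- (seq_len(n) - 1L) %% config$grid[2]

  # traits
  age <- stats::runif(n, 18, 80)
  rng <- .empathy_range(config$empathy_scale)
  mu_e <- mean(rng); sd_e <- diff(rng) / 6
  empathy <- stats::qnorm(
    stats::runif(n,
                 stats::pnorm(rng[1], mu_e, sd_e),
                 stats::pnorm(rng[2], mu_e, sd_e)), mu_e, sd_e)
  female <- stats::runif(n) < 0.5
  gender <- ifelse(female, "female", "male")

  info <- participant_table(
    ids, seat_row, seat_col, age = age, gender = gender,
    empathy_total = empathy, empathy_scale = config$empathy_scale,
    questionnaires_complete = TRUE)

  e <- engagement_frame_series(config$script, config$frame_rate, nf)
  g <- (e / 3)^config$engagement_exponent

  shared <- vapply(.channels(),
                   function(ch) .smooth_noise(nf, config$smooth_frames),
                   numeric(nf))

  n_blocks <- ceiling(nf / config$smooth_frames)
  local_fields <- purrr::map(.channels(), function(ch) {
    blocks <- spatial_field(info, config$spatial_length, n_blocks)
    u <- blocks[rep(seq_len(n_blocks), each = config$smooth_frames), ,
                drop = FALSE][seq_len(nf), , drop = FALSE]
    mu <- colMeans(u)
    sdv <- sqrt(colMeans(u * u) - mu^2) * sqrt(nf / (nf - 1))
    sdv[sdv == 0] <- 1
    (u - rep(mu, each = nf)) / rep(sdv, each = nf)
  })
  names(local_fields) <- .channels()

  w <- stats::plogis(config$beta_age * .standardize(age) +
                       config$beta_empathy * .standardize(empathy) +
                       config$beta_gender * as.numeric(female))

  intensities <- purrr::map(.channels(), function(ch) {
    signal <- (shared[, ch] +
                 config$spatial_weight * local_fields[[ch]]) * g
    x <- config$baseline[ch] +
      config$coupling[ch] * .signal_amplitude *
        signal * rep(w, each = nf) +
      config$noise_sd * stats::rnorm(nf * n)
    pmin(pmax(x, 0), 1)
  })
  names(intensities) <- .channels()

  tracks <- purrr::map(seq_len(n), function(i) {
    m <- vapply(.channels(), function(ch) intensities[[ch]][, i],
                numeric(nf))
    drop_idx <- .dropout_frames(nf, config$dropout)
    if (length(drop_idx)) m[drop_idx, ] <- NA_real_
    expression_track(ids[i], m, config$frame_rate)
  })

  recording <- audience_recording(
    sprintf("sim-seed%d", config$seed), tracks, info)
  truth <- structure(
    list(engagement = e, gain = g, shared = shared, coupling_weight = w,
         config = config), class = "audience_ground_truth")
  list(recording = recording, truth = truth)
}

#' Simulate a null audience: mutually independent tracks
#'
#' Equivalent to [simulate_recording()] with every coupling gain set to
#' zero: no shared and no spatial component enters any track, so all
#' participants are mutually independent. Used for calibration tests of
#' the inferential stages.
#'
#' @param config A [simulation_config()]; its `coupling` is overridden.
#' @return An [audience_recording()].
#' @export
simulate_null_recording <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  config$coupling[] <- 0
  simulate_recording(config)$recording
}
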