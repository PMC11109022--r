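#' Sliding-window specification
#'
#' Defaults follow the field convention for audience recordings sampled at
#' 50 frames/s: a 60 s window (3000 frames) advanced in 2 s steps
#' (100 frames). `min_valid_fraction` is the fraction of jointly valid
#' frames a pair must contribute inside a window for its correlation to be
#' defined; windows below it are missing, not zero, to avoid biasing ISC
#' toward zero during occlusions.
#'
#' @param window_len Window length in frames (default 3000).
#' @param step Step between window starts in frames (default 100).
#' @param min_valid_fraction Required joint-valid fraction in (0, 1\]
#'   (default 0.5).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(window_len = 3000, step = 100,
                        min_valid_fraction = 0.5) {
  stopifnot(is.numeric(window_len), window_len >= 1,
            is.numeric(step), step >= 1, step <= window_len,
            is.numeric(min_valid_fraction),
            min_valid_fraction > 0, min_valid_fraction <= 1)
  structure(list(window_len = as.integer(window_len), step = as.integer(step),
                 min_valid_fraction = min_valid_fraction),
            class = "window_spec")
}

#' Window start frames
#'
#' 0-based start frames `0, step, 2*step, ...` up to the largest start for
#' which a full window fits; the trailing partial window is dropped. The
#' count is `floor((n_frames - window_len)/step) + 1`.
#'
#' @param n_frames Total frame count (must be at least `window_len`).
#' @param spec A [window_spec()].
#' @return Integer vector of 0-based start frames.
#' @export
#' @examples
#' length(window_starts(9000, window_spec(3000, 100)))  # 61
window_starts <- function(n_frames, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  if (n_frames < spec$window_len) {
    stop(sprintf("n_frames (%d) shorter than window_len (%d)",
                 n_frames, spec$window_len), call. = FALSE)
  }
  seq.int(0L, n_frames - spec$window_len, by = spec$step)
}

#' Fisher r-to-z transform and its inverse
#'
#' `fisher_z()` is `atanh(r)` after clipping `r` into
#' `[-(1 - 1e-7), 1 - 1e-7]` so that perfect correlations map to a finite
#' z; `fisher_z_inv()` is `tanh(z)`. Both are vectorized.
#'
#' @param r Correlations in \[-1, 1\] (`NA` passes through).
#' @param z Fisher-z values.
#' @return Numeric vector.
#' @export
#' @examples
#' fisher_z(0.5)          # 0.549306
#' fisher_z_inv(fisher_z(0.3))
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlation outside [-1, 1]", call. = FALSE)
  }
  eps <- 1e-7
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

# Pairwise-complete Pearson correlations of the columns of x over every
# window [s, s + len), computed from masked crossprod prefix sums so the
# work is O(channels^2 * frames) across all windows combined. x carries NA
# exactly at invalid frames; entries based on < max(min_n, 3) joint frames
# or a zero-variance series are NA. Returns a list with one element per
# window: list(r = p x p matrix, n = joint-count matrix).
.window_cor_all <- function(x, valid, starts, len, min_n) {
  p <- ncol(x)
  m <- x
  m[!valid] <- 0
  v <- valid + 0
  bounds <- sort(unique(c(starts, starts + len)))
  nb <- length(bounds)
  zero <- matrix(0, p, p)
  cum_n <- cum_sxy <- cum_sxv <- cum_qxv <- vector("list", nb)
  cum_n[[1]] <- cum_sxy[[1]] <- cum_sxv[[1]] <- cum_qxv[[1]] <- zero
  for (i in 2:nb) {
    idx <- (bounds[i - 1] + 1L):bounds[i]
    ms <- m[idx, , drop = FALSE]
    vs <- v[idx, , drop = FALSE]
    cum_n[[i]] <- cum_n[[i - 1]] + crossprod(vs)
    cum_sxy[[i]] <- cum_sxy[[i - 1]] + crossprod(ms)
    cum_sxv[[i]] <- cum_sxv[[i - 1]] + crossprod(ms, vs)
    cum_qxv[[i]] <- cum_qxv[[i - 1]] + crossprod(ms * ms, vs)
  }
  lo <- match(starts, bounds)
  hi <- match(starts + len, bounds)
  min_joint <- max(min_n, 3)
  purrr::map(seq_along(starts), function(w) {
    nj <- cum_n[[hi[w]]] - cum_n[[lo[w]]]
    sxy <- cum_sxy[[hi[w]]] - cum_sxy[[lo[w]]]
    sxv <- cum_sxv[[hi[w]]] - cum_sxv[[lo[w]]]
    qxv <- cum_qxv[[hi[w]]] - cum_qxv[[lo[w]]]
    num <- nj * sxy - sxv * t(sxv)
    vx <- nj * qxv - sxv^2          # row series' variance over joint frames
    vy <- t(vx)
    den <- vx * vy
    # relative guard: exact-constant series cancel to ~machine-eps residue
    tiny <- 1e-9 * pmax(nj * qxv, .Machine$double.xmin) *
      pmax(nj * t(qxv), .Machine$double.xmin)
    r <- matrix(NA_real_, p, p)
    ok <- den > tiny & nj >= min_joint
    r[ok] <- num[ok] / sqrt(den[ok])
    r[which(r > 1)] <- 1
    r[which(r < -1)] <- -1
    list(r = r, n = nj)
  })
}

# Single-window convenience wrapper.
.window_cor <- function(x, valid, start, len, min_n) {
  .window_cor_all(x, valid, start, len, min_n)[[1]]
}

#' Sliding-window correlation between two participants' tracks
#'
#' For one expression channel, computes the Pearson correlation between
#' two tracks inside each sliding window, over the frames jointly valid
#' for both participants. A window's value is missing when the joint-valid
#' fraction falls below `spec$min_valid_fraction` or either series has
#' zero variance in-window.
#'
#' @param track_a,track_b [expression_track()] objects of equal length.
#' @param expression One of [expression_channels()].
#' @param spec A [window_spec()].
#' @return Tibble with columns `window_start_frame`, `n_joint`, `r`.
#' @export
windowed_pair_correlation <- function(track_a, track_b, expression,
                                      spec = window_spec()) {
  expression <- .match_channel(expression)
  stopifnot(inherits(track_a, "expression_track"),
            inherits(track_b, "expression_track"))
  if (n_frames(track_a) != n_frames(track_b)) {
    stop("tracks must have equal length", call. = FALSE)
  }
  starts <- window_starts(n_frames(track_a), spec)
  x <- cbind(track_a$intensities[, expression],
             track_b$intensities[, expression])
  valid <- cbind(track_a$valid_mask, track_b$valid_mask)
  min_n <- spec$min_valid_fraction * spec$window_len
  res <- .window_cor_all(x, valid, starts, spec$window_len, min_n)
  m <- do.call(rbind, purrr::map(res, function(w) c(w$n[1, 2], w$r[1, 2])))
  tibble::tibble(window_start_frame = starts,
                 n_joint = as.integer(m[, 1]), r = m[, 2])
}

#' Sliding-window inter-subject correlation time course
#'
#' The core synchrony measure: for every expression channel and every
#' sliding window, each participant's series is correlated with the same
#' channel of every other participant (happy with happy, sad with sad,
#' ...) over their jointly valid frames, and the raw r values of all
#' defined pairs are averaged. Fisher transformation is deliberately not
#' applied here — it is reserved for the inferential stages.
#'
#' @param recording An [audience_recording()] with at least 2 participants.
#' @param spec A [window_spec()].
#' @return Tibble of class `isc_timecourse` with columns
#'   `window_start_frame`, `window_start_s`, `expression`, `mean_r`,
#'   `n_pairs`; attributes `window_spec`, `frame_rate`, `n_frames`.
#' @export
sliding_window_isc <- function(recording, spec = window_spec()) {
  stopifnot(inherits(recording, "audience_recording"))
  n <- n_participants(recording)
  if (n < 2L) stop("ISC needs at least 2 participants", call. = FALSE)
  nf <- n_frames(recording$tracks[[1]])
  starts <- window_starts(nf, spec)
  valid <- .valid_matrix(recording)
  min_n <- spec$min_valid_fraction * spec$window_len
  ut <- upper.tri(matrix(0, n, n))
  frame_rate <- recording$tracks[[1]]$frame_rate
  per_channel <- purrr::map(.channels(), function(ch) {
    x <- .expression_matrix(recording, ch)
    wins <- .window_cor_all(x, valid, starts, spec$window_len, min_n)
    m <- vapply(wins, function(w) {
      r <- w$r[ut]
      k <- sum(!is.na(r))
      c(if (k > 0L) mean(r, na.rm = TRUE) else NA_real_, k)
    }, numeric(2))
    tibble::tibble(window_start_frame = starts,
                   window_start_s = starts / frame_rate,
                   expression = ch, mean_r = m[1, ],
                   n_pairs = as.integer(m[2, ]))
  })
  out <- dplyr::bind_rows(per_channel)
  out$expression <- .channel_factor(out$expression)
  structure(out,
            class = c("isc_timecourse", class(tibble::tibble())),
            window_spec = spec, frame_rate = frame_rate, n_frames = nf)
}

#' Pair-level inter-subject correlations
#'
#' One synchrony value per unordered participant pair per expression, used
#' as the outcome of the proximity and pair-characteristic analyses. Two
#' aggregation modes are provided because the granularity at which
#' pair-level synchrony should be summarized is a genuine modelling
#' choice: `"whole_series"` correlates the full jointly valid series,
#' `"window_mean"` averages per-window Fisher-z values and back-transforms.
#' Each row also carries the pair's seat distance and combined
#' characteristics (total age, total empathy, gender and age grouping; see
#' [pair_features()]).
#'
#' @param recording An [audience_recording()] with at least 2 participants.
#' @param mode `"whole_series"` (default) or `"window_mean"`.
#' @param spec [window_spec()] (used by `"window_mean"`).
#' @return Tibble of class `pair_isc_table`: one row per pair x
#'   expression with columns `participant_a`, `participant_b`,
#'   `expression`, `n_joint`, `r`, `z`, `seat_distance`, `total_age`,
#'   `total_empathy`, `gender_group`, `age_group`. `participant_a` sorts
#'   before `participant_b`; `z = atanh(r)` with `r` clipped to
#'   `1 - 1e-7` in magnitude first. Pairs with fewer than 3 joint frames
#'   get a missing `r`.
#' @export
pairwise_isc <- function(recording, mode = c("whole_series", "window_mean"),
                         spec = window_spec()) {
  mode <- match.arg(mode)
  stopifnot(inherits(recording, "audience_recording"))
  n <- n_participants(recording)
  if (n < 2L) stop("pair ISC needs at least 2 participants", call. = FALSE)
  ids <- participant_ids(recording)
  nf <- n_frames(recording$tracks[[1]])
  valid <- .valid_matrix(recording)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  per_channel <- purrr::map(.channels(), function(ch) {
    x <- .expression_matrix(recording, ch)
    if (mode == "whole_series") {
      w <- .window_cor(x, valid, 0L, nf, 3)
      r_mat <- w$r; n_mat <- w$n
    } else {
      starts <- window_starts(nf, spec)
      min_n <- spec$min_valid_fraction * spec$window_len
      zsum <- matrix(0, n, n); zcnt <- matrix(0L, n, n)
      for (w in .window_cor_all(x, valid, starts, spec$window_len, min_n)) {
        ok <- !is.na(w$r)
        zsum[ok] <- zsum[ok] + fisher_z(w$r[ok])
        zcnt <- zcnt + ok
      }
      r_mat <- ifelse(zcnt > 0, tanh(zsum / pmax(zcnt, 1L)), NA_real_)
      n_mat <- crossprod(valid)  # joint frames over the whole series
    }
    tibble::tibble(
      i = pair_idx[, 1], j = pair_idx[, 2],
      expression = ch,
      n_joint = as.integer(n_mat[pair_idx]),
      r = r_mat[pair_idx])
  })
  out <- dplyr::bind_rows(per_channel)
  # order ids within pair
  id_i <- ids[out$i]; id_j <- ids[out$j]
  swap <- id_i > id_j
  out$participant_a <- ifelse(swap, id_j, id_i)
  out$participant_b <- ifelse(swap, id_i, id_j)
  out$z <- fisher_z(out$r)
  out$expression <- .channel_factor(out$expression)

  info <- recording$info
  meta <- function(col) stats::setNames(info[[col]], info$participant_id)
  ra <- meta("row")[out$participant_a]; sa <- meta("seat")[out$participant_a]
  rb <- meta("row")[out$participant_b]; sb <- meta("seat")[out$participant_b]
  out$seat_distance <- seat_distance(cbind(ra, sa), cbind(rb, sb))
  feats <- pair_features_table(
    age_a = meta("age")[out$participant_a],
    age_b = meta("age")[out$participant_b],
    empathy_a = meta("empathy_total")[out$participant_a],
    empathy_b = meta("empathy_total")[out$participant_b],
    gender_a = meta("gender")[out$participant_a],
    gender_b = meta("gender")[out$participant_b])
  out <- dplyr::bind_cols(
    out[, c("participant_a", "participant_b", "expression", "n_joint",
            "r", "z", "seat_distance")],
    feats)
  out <- dplyr::arrange(out, .data$expression, .data$participant_a,
                        .data$participant_b)
  structure(out, class = c("pair_isc_table", class(tibble::tibble())),
            mode = mode, window_spec = spec)
}
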