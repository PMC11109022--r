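#' Per-frame engagement series from a scene script
#'
#' Expands the dramaturge's scene scores to the frame grid: frame t (time
#' `t / frame_rate`) receives the score of the scene whose half-open
#' interval `[start_s, end_s)` contains that time, so a frame exactly on a
#' boundary second belongs to the later scene.
#'
#' @param script An [engagement_script()] whose duration equals
#'   `n_frames / frame_rate`.
#' @param frame_rate Frames per second.
#' @param n_frames Number of frames.
#' @return Numeric vector of length `n_frames` with values in `{1, 2, 3}`.
#' @export
engagement_frame_series <- function(script, frame_rate, n_frames) {
  stopifnot(inherits(script, "engagement_script"))
  if (abs(script_duration(script) - n_frames / frame_rate) > 1e-9) {
    stop(sprintf("script duration (%g s) != n_frames/frame_rate (%g s)",
                 script_duration(script), n_frames / frame_rate),
         call. = FALSE)
  }
  t_s <- (seq_len(n_frames) - 1L) / frame_rate
  idx <- findInterval(t_s, script$start_s)  # half-open [start, end)
  as.numeric(script$score[idx])
}

#' Resample an engagement script onto the ISC window grid
#'
#' Applies the same sliding-window scheme as the ISC computation to the
#' per-frame engagement series: each window's value is the arithmetic mean
#' of the frame scores it covers, which slightly smooths scene
#' transitions. A window lying wholly inside one scene reproduces that
#' scene's score exactly.
#'
#' @param script An [engagement_script()].
#' @param spec A [window_spec()] (must match the ISC's).
#' @param frame_rate Frames per second.
#' @param n_frames Number of frames.
#' @return Tibble of class `engagement_course` with columns
#'   `window_start_frame`, `window_start_s`, `engagement`.
#' @export
resample_engagement <- function(script, spec, frame_rate, n_frames) {
  e <- engagement_frame_series(script, frame_rate, n_frames)
  starts <- window_starts(n_frames, spec)
  eng <- vapply(starts,
                function(s) mean(e[(s + 1L):(s + spec$window_len)]),
                numeric(1))
  structure(
    tibble::tibble(window_start_frame = starts,
                   window_start_s = starts / frame_rate,
                   engagement = eng),
    class = c("engagement_course", class(tibble::tibble())),
    window_spec = spec, frame_rate = frame_rate, n_frames = n_frames)
}

# Wide windows x expressions matrix from an isc_timecourse, plus the
# aligned engagement vector; grids must match exactly.
.align_isc_engagement <- function(isc, course) {
  stopifnot(inherits(isc, "isc_timecourse"),
            inherits(course, "engagement_course"))
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(isc)[, c("window_start_frame", "expression", "mean_r")],
    names_from = "expression", values_from = "mean_r")
  if (!identical(as.integer(wide$window_start_frame),
                 as.integer(course$window_start_frame))) {
    stop("ISC and engagement window grids do not match", call. = FALSE)
  }
  list(isc = as.matrix(wide[, .channels()]), engagement = course$engagement,
       starts = wide$window_start_frame)
}

#' Correlate expression ISC time courses with predicted engagement
#'
#' Pearson correlation, per expression channel, between the windowed ISC
#' trace and the window-resampled engagement course, over windows where
#' both are defined, with a JZS-style Bayes factor under the
#' positive-truncated Cauchy prior. Overlapping windows make successive
#' values autocorrelated; no correction is applied (flagged in the
#' `autocorrelation_note` attribute), matching common practice for this
#' design.
#'
#' @param isc An [sliding_window_isc()] result.
#' @param course A [resample_engagement()] result on the same grid.
#' @param bayes A [bayes_spec()].
#' @return Tibble with columns `expression`, `n_windows`, `r`, `z`,
#'   `bf10`. Channels with zero variance in either series give missing
#'   `r` with a warning.
#' @export
isc_engagement_correlation <- function(isc, course, bayes = bayes_spec()) {
  al <- .align_isc_engagement(isc, course)
  rows <- purrr::map(.channels(), function(ch) {
    x <- al$isc[, ch]; y <- al$engagement
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 4L) {
      warning("fewer than 4 paired windows for '", ch, "'", call. = FALSE)
      return(tibble::tibble(expression = ch, n_windows = n, r = NA_real_,
                            z = NA_real_, bf10 = NA_real_))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("zero variance for '", ch, "': correlation undefined",
              call. = FALSE)
      return(tibble::tibble(expression = ch, n_windows = n, r = NA_real_,
                            z = NA_real_, bf10 = NA_real_))
    }
    r <- stats::cor(x[ok], y[ok])
    # perfect correlations are clipped like fisher_z before the BF
    bf <- bf_correlation(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7), n, bayes)
    tibble::tibble(expression = ch, n_windows = n, r = r, z = fisher_z(r),
                   bf10 = bf$bf10)
  })
  out <- dplyr::bind_rows(rows)
  out$expression <- .channel_factor(out$expression)
  attr(out, "autocorrelation_note") <-
    "overlapping windows induce autocorrelation; no correction applied"
  out
}

#' All-subsets regression of engagement on expression ISCs
#'
#' Exhaustively fits every subset of the eight expression-ISC predictors
#' (2^8 models, windows with any missing value dropped listwise) by least
#' squares, and ranks models by a BIC-based posterior-probability proxy
#' with a uniform model prior (see [bic_model_scores()]). Zero-variance
#' predictors are dropped with a warning before enumeration.
#'
#' @param isc An [sliding_window_isc()] result.
#' @param course A [resample_engagement()] result on the same grid
#'   (>= 10 complete windows required).
#' @return Object of class `engagement_fit`: list with `models` (tibble:
#'   `model`, `k`, `r_squared`, `bic`, `post_prob`, `rank`),
#'   `best_model`, `best_r_squared`, `n_windows`, `predictors`.
#' @export
engagement_regression <- function(isc, course) {
  al <- .align_isc_engagement(isc, course)
  ok <- stats::complete.cases(al$isc) & !is.na(al$engagement)
  X <- al$isc[ok, , drop = FALSE]
  y <- al$engagement[ok]
  n <- length(y)
  if (n < 10L) stop("need at least 10 complete windows", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("engagement course is constant: nothing to predict", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance predictors: ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  preds <- colnames(X)
  p <- length(preds)
  tss <- sum((y - mean(y))^2)
  subsets <- purrr::map(0:(2^p - 1), function(bits) {
    which(bitwAnd(bits, 2^(seq_len(p) - 1)) > 0)
  })
  fits <- purrr::map(subsets, function(sel) {
    if (length(sel) == 0L) {
      rss <- tss; k <- 1L
    } else {
      fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
      rss <- sum(fit$residuals^2)
      k <- length(sel) + 1L
    }
    tibble::tibble(
      model = if (length(sel)) paste(preds[sel], collapse = " + ")
              else "(null)",
      k = k, rss = rss, r_squared = 1 - rss / tss)
  })
  models <- dplyr::bind_rows(fits)
  # perfect fits give RSS = 0; floor so the BIC proxy stays finite
  scores <- bic_model_scores(
    dplyr::mutate(models, rss = pmax(.data$rss, 1e-12 * tss)), n)
  models <- dplyr::bind_cols(
    models[, c("model", "k", "r_squared")],
    scores[, c("bic", "post_prob", "rank")])
  models <- dplyr::arrange(models, .data$rank)
  structure(
    list(models = models,
         best_model = models$model[1],
         best_r_squared = models$r_squared[1],
         n_windows = n, predictors = preds),
    class = "engagement_fit")
}

#' @export
print.engagement_fit <- function(x, ...) {
  cat(sprintf(
    "<engagement_fit> %d windows, %d models; best: %s (R^2 = %.3f, post prob = %.3f)\n",
    x$n_windows, nrow(x$models), x$best_model, x$best_r_squared,
    x$models$post_prob[1]))
  invisible(x)
}
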