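#' Fraction of valid frames in a track
#'
#' @param track An [expression_track()].
#' @return Fraction in \[0, 1\].
#' @export
validity_fraction <- function(track) {
  stopifnot(inherits(track, "expression_track"))
  if (n_frames(track) == 0L) stop("zero-length track", call. = FALSE)
  mean(track$valid_mask)
}

#' Apply the inclusion criteria
#'
#' Retains participants whose facial expressions could be modelled for
#' strictly more than `min_valid` of the performance and (optionally) who
#' completed all questionnaires. If fewer than `min_audience` participants
#' survive, the whole performance is excluded: the result is an empty
#' recording. The exclusion log is attached as attribute
#' `"exclusion_log"` (a tibble with `participant_id` and `reason`).
#'
#' @param recording An [audience_recording()].
#' @param min_valid Strict lower bound on [validity_fraction()]
#'   (default 0.9).
#' @param require_questionnaires Require `questionnaires_complete`
#'   (default `TRUE`).
#' @param min_audience Minimum surviving audience size for the
#'   performance to be analyzable (default 2: "more than one individual").
#' @return An [audience_recording()] (possibly with zero tracks).
#' @export
apply_inclusion <- function(recording, min_valid = 0.9,
                            require_questionnaires = TRUE,
                            min_audience = 2L) {
  stopifnot(inherits(recording, "audience_recording"))
  if (n_participants(recording) == 0L) return(recording)
  keep <- logical(n_participants(recording))
  reasons <- character(0); dropped <- character(0)
  qc <- stats::setNames(recording$info$questionnaires_complete,
                        recording$info$participant_id)
  for (i in seq_along(recording$tracks)) {
    tr <- recording$tracks[[i]]
    vf <- validity_fraction(tr)
    if (vf <= min_valid) {
      dropped <- c(dropped, tr$participant_id)
      reasons <- c(reasons, sprintf("validity %.3f <= %.3f", vf, min_valid))
    } else if (require_questionnaires && !isTRUE(qc[[tr$participant_id]])) {
      dropped <- c(dropped, tr$participant_id)
      reasons <- c(reasons, "questionnaires incomplete")
    } else {
      keep[i] <- TRUE
    }
  }
  if (sum(keep) < min_audience) {
    dropped <- c(dropped, names(recording$tracks)[keep])
    reasons <- c(reasons, rep(
      sprintf("performance excluded: fewer than %d eligible participants",
              min_audience), sum(keep)))
    keep[] <- FALSE
  }
  kept_ids <- names(recording$tracks)[keep]
  info <- recording$info[recording$info$participant_id %in% kept_ids, ,
                         drop = FALSE]
  out <- audience_recording(recording$performance_id,
                            recording$tracks[keep], info,
                            allow_empty = TRUE)
  attr(out, "exclusion_log") <-
    tibble::tibble(participant_id = dropped, reason = reasons)
  out
}

#' Per-channel mean and SD of a track
#'
#' Summarizes each expression channel over the track's valid frames only
#' (sample SD, n - 1 denominator). Values stored at invalid frames never
#' influence the result.
#'
#' @param track An [expression_track()] with at least 2 valid frames.
#' @return Tibble with columns `expression`, `mean`, `sd`.
#' @export
expression_summary <- function(track) {
  stopifnot(inherits(track, "expression_track"))
  v <- track$valid_mask
  if (sum(v) < 2L) stop("need at least 2 valid frames", call. = FALSE)
  x <- track$intensities[v, , drop = FALSE]
  tibble::tibble(expression = .channel_factor(.channels()),
                 mean = unname(colMeans(x)),
                 sd = unname(apply(x, 2, stats::sd)))
}

# Mark zero-variance channels NA in a correlation matrix computed over
# complete rows x.
.na_zero_var <- function(cmat, x) {
  sds <- apply(x, 2, stats::sd)
  bad <- !is.finite(sds) | sds == 0
  cmat[bad, ] <- NA_real_
  cmat[, bad] <- NA_real_
  cmat
}

#' Within-individual between-expression correlation matrix
#'
#' Pearson correlations between every pair of the eight channels over one
#' participant's valid frames. A frame is atomic, so valid frames have all
#' eight channels present. Zero-variance channels yield missing entries;
#' the diagonal is 1 where defined.
#'
#' @param track An [expression_track()] with at least 3 valid frames.
#' @return 8 x 8 symmetric matrix of class `cross_expression_matrix`
#'   (attribute `type = "within"`).
#' @export
between_expression_matrix <- function(track) {
  stopifnot(inherits(track, "expression_track"))
  v <- track$valid_mask
  if (sum(v) < 3L) stop("need at least 3 valid frames", call. = FALSE)
  x <- track$intensities[v, , drop = FALSE]
  cmat <- suppressWarnings(stats::cor(x))
  cmat <- .na_zero_var(cmat, x)
  d <- diag(cmat)
  d[apply(x, 2, stats::sd) > 0] <- 1
  diag(cmat) <- d
  structure(cmat, class = c("cross_expression_matrix", "matrix", "array"),
            type = "within", participant_id = track$participant_id)
}

#' Individual versus rest-of-audience correlation matrix
#'
#' For one participant, correlates each of their eight channels with the
#' frame-wise average of each channel over the rest of the audience
#' ("audience n-1"): entry (i, j) is the Pearson correlation between the
#' participant's channel i and the rest-average channel j, over frames
#' valid for both sides. Frames where no other participant is valid are
#' excluded.
#'
#' @param recording An [audience_recording()] with at least 2 participants.
#' @param participant_id The focal participant.
#' @return 8 x 8 directed matrix of class `cross_expression_matrix`
#'   (rows: individual, columns: rest of audience;
#'   attribute `type = "individual_vs_rest"`).
#' @export
individual_vs_rest_matrix <- function(recording, participant_id) {
  stopifnot(inherits(recording, "audience_recording"))
  if (n_participants(recording) < 2L) {
    stop("audience of 1: no rest-of-audience signal", call. = FALSE)
  }
  if (!participant_id %in% participant_ids(recording)) {
    stop("unknown participant '", participant_id, "'", call. = FALSE)
  }
  focal <- recording$tracks[[participant_id]]
  others <- recording$tracks[names(recording$tracks) != participant_id]
  nf <- n_frames(focal)
  rest <- vapply(.channels(), function(ch) {
    m <- vapply(others, function(tr) tr$intensities[, ch], numeric(nf))
    if (!is.matrix(m)) m <- matrix(m, ncol = 1)
    rowMeans(m, na.rm = TRUE)
  }, numeric(nf))
  rest[is.nan(rest)] <- NA_real_
  cmat <- suppressWarnings(
    stats::cor(focal$intensities, rest, use = "pairwise.complete.obs"))
  dimnames(cmat) <- list(.channels(), .channels())
  structure(cmat, class = c("cross_expression_matrix", "matrix", "array"),
            type = "individual_vs_rest", participant_id = participant_id)
}

#' Within- versus between-expression synchrony contrast
#'
#' Takes the individual-versus-rest matrices of an audience and contrasts
#' on-diagonal (within-expression) against off-diagonal
#' (between-expression) synchrony. All r values are Fisher-transformed
#' before averaging. Undefined entries are excluded from means, never
#' coerced to zero.
#'
#' @param matrices List of directed [individual_vs_rest_matrix()] results
#'   (one per individual).
#' @return Object of class `within_between_contrast`: list with
#'   `individual` (tibble: `participant_id`, `on_z`, `off_z`,
#'   `contrast = on_z - off_z`) and `per_expression` (tibble:
#'   `participant_id`, `expression`, `on_z`, `off_row_z`). The
#'   per-individual `contrast` column is the paired-difference vector
#'   handed to [bf_paired_ttest()].
#' @export
within_between_contrast <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  per_ind <- purrr::imap(matrices, function(m, i) {
    stopifnot(inherits(m, "cross_expression_matrix"))
    z <- fisher_z(unclass(m))
    dg <- diag(z); off <- z[row(z) != col(z)]
    if (all(is.na(dg)) && all(is.na(off))) {
      stop("matrix with all entries undefined", call. = FALSE)
    }
    pid <- attr(m, "participant_id")
    if (is.null(pid)) pid <- as.character(i)
    tibble::tibble(
      participant_id = pid,
      on_z = mean(dg, na.rm = TRUE),
      off_z = mean(off, na.rm = TRUE),
      per_expr = list(tibble::tibble(
        expression = .channel_factor(.channels()),
        on_z = dg,
        off_row_z = vapply(seq_len(.n_channels), function(k) {
          mean(z[k, -k], na.rm = TRUE)
        }, numeric(1)))))
  })
  ind <- dplyr::bind_rows(per_ind)
  per_expr <- tidyr::unnest(
    ind[, c("participant_id", "per_expr")], "per_expr")
  ind <- dplyr::mutate(ind[, c("participant_id", "on_z", "off_z")],
                       contrast = .data$on_z - .data$off_z)
  structure(list(individual = ind, per_expression = per_expr),
            class = "within_between_contrast")
}

#' @export
print.within_between_contrast <- function(x, ...) {
  cat(sprintf(
    "<within_between_contrast> %d individuals; mean on-diag z = %.3f, mean off-diag z = %.3f\n",
    nrow(x$individual), mean(x$individual$on_z), mean(x$individual$off_z)))
  invisible(x)
}
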