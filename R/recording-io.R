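#' Construct an expression track
#'
#' An expression track is one participant's per-frame facial-expression
#' intensity series: a frames x 8 matrix of intensities in \[0, 1\] with a
#' per-frame validity mask. A frame is atomic: automated face-model fitting
#' fails for a whole frame, so if any channel is missing the frame is
#' invalid and all eight values are treated as missing.
#'
#' @param participant_id Single string identifying the participant.
#' @param intensities Numeric matrix (frames x 8) or data frame with the
#'   eight channel columns in the order of [expression_channels()]. `NA`
#'   marks missing values.
#' @param frame_rate Frames per second (positive; field data use 50).
#'
#' @return An object of class `expression_track`: a list with elements
#'   `participant_id`, `frame_rate`, `intensities` (frames x 8 matrix,
#'   invalid frames all-`NA`) and `valid_mask` (logical per frame, `TRUE`
#'   iff all 8 channels are present).
#' @export
#' @examples
#' m <- matrix(runif(40), 5, 8, dimnames = list(NULL, expression_channels()))
#' tr <- expression_track("p1", m)
#' tr$valid_mask
expression_track <- function(participant_id, intensities, frame_rate = 50) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            nzchar(participant_id))
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("frame_rate must be a positive number", call. = FALSE)
  }
  if (is.data.frame(intensities)) {
    intensities <- as.matrix(intensities[, .channels(), drop = FALSE])
  }
  if (!is.matrix(intensities) || ncol(intensities) != .n_channels) {
    stop("intensities must be a frames x 8 matrix", call. = FALSE)
  }
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- list(NULL, .channels())
  bad <- which(!is.na(intensities) &
                 (intensities < 0 | intensities > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "intensity outside [0,1] for participant '%s' at frame %d, channel '%s'",
      participant_id, bad[1, 1] - 1L, .channels()[bad[1, 2]]), call. = FALSE)
  }
  valid_mask <- stats::complete.cases(intensities)
  intensities[!valid_mask, ] <- NA_real_
  structure(
    list(participant_id = participant_id,
         frame_rate = frame_rate,
         intensities = intensities,
         valid_mask = valid_mask),
    class = "expression_track")
}

#' @export
print.expression_track <- function(x, ...) {
  cat(sprintf("<expression_track> participant '%s': %d frames at %g fps, %.1f%% valid\n",
              x$participant_id, nrow(x$intensities), x$frame_rate,
              100 * mean(x$valid_mask)))
  invisible(x)
}

n_frames <- function(track) nrow(track$intensities)

#' Read a long-format expression table
#'
#' Reads a CSV with header
#' `participant_id,frame_index,neutral,happy,sad,angry,surprise,fear,disgust,contempt`
#' — one row per frame per participant, 0-based contiguous `frame_index`
#' per participant, empty cells marking missing values — and returns one
#' [expression_track()] per participant.
#'
#' @param file Path or connection understood by [readr::read_csv()].
#' @param frame_rate Frames per second to stamp on each track.
#' @return Named list of `expression_track` objects (by participant id,
#'   in order of first appearance).
#' @export
read_expression_table <- function(file, frame_rate = 50) {
  expected <- c("participant_id", "frame_index", .channels())
  # base read.csv: its double parser is correctly rounded, so %.17g
  # values written by write_expression_table() round-trip bit-exactly
  df <- if (is.character(file) && length(file) == 1L &&
            grepl("\n", file, fixed = TRUE)) {
    utils::read.csv(text = file, na.strings = c("", "NA"),
                    check.names = FALSE)
  } else {
    utils::read.csv(file, na.strings = c("", "NA"), check.names = FALSE)
  }
  if (!identical(names(df), expected)) {
    stop("expression table must have header: ",
         paste(expected, collapse = ","), call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  df$frame_index <- as.integer(df$frame_index)
  for (ch in .channels()) df[[ch]] <- as.numeric(df[[ch]])
  dup <- duplicated(df[, c("participant_id", "frame_index")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicated (participant, frame): ('%s', %d) at row %d",
                 df$participant_id[i], df$frame_index[i], i), call. = FALSE)
  }
  out_of_range <- vapply(.channels(), function(ch) {
    v <- df[[ch]]
    w <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  if (any(!is.na(out_of_range))) {
    ch <- names(which(!is.na(out_of_range)))[1]
    stop(sprintf("value outside [0,1] in channel '%s' at row %d",
                 ch, out_of_range[[ch]]), call. = FALSE)
  }
  ids <- unique(df$participant_id)
  tracks <- lapply(ids, function(id) {
    sub <- df[df$participant_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame_index), , drop = FALSE]
    if (!identical(sub$frame_index, seq_len(nrow(sub)) - 1L)) {
      stop(sprintf("non-contiguous frame_index for participant '%s'", id),
           call. = FALSE)
    }
    expression_track(id, as.matrix(sub[, .channels()]), frame_rate)
  })
  stats::setNames(tracks, ids)
}

#' Write expression tracks to a long-format CSV
#'
#' Inverse of [read_expression_table()]: values round-trip at full
#' precision, invalid frames are written as rows with eight empty cells,
#' and an empty track list produces a header-only file.
#'
#' @param tracks List of [expression_track()] objects.
#' @param file Path or connection.
#' @export
write_expression_table <- function(tracks, file) {
  stopifnot(is.list(tracks))
  rows <- purrr::map(tracks, function(tr) {
    if (!inherits(tr, "expression_track")) {
      stop("tracks must be expression_track objects", call. = FALSE)
    }
    vals <- tibble::as_tibble(tr$intensities)
    # %.17g guarantees the doubles survive the text round trip exactly
    vals <- dplyr::mutate(vals, dplyr::across(
      dplyr::everything(),
      function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
    dplyr::bind_cols(
      tibble::tibble(participant_id = tr$participant_id,
                     frame_index = seq_len(n_frames(tr)) - 1L),
      vals)
  })
  df <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::as_tibble(stats::setNames(
      c(list(character(0), integer(0)), rep(list(double(0)), .n_channels)),
      c("participant_id", "frame_index", .channels())))
  readr::write_csv(df, file, na = "", progress = FALSE)
  invisible(file)
}

#' Construct an engagement script
#'
#' An engagement script is the dramaturge's scene-by-scene prediction of
#' audience engagement: an ordered, contiguous partition of the
#' performance into scenes with whole-second boundaries, each scored on a
#' 1-3 Likert scale (1 = low, 3 = high engagement).
#'
#' @param start_s,end_s Scene boundaries in seconds (whole numbers; each
#'   start must equal the previous end; first start must be 0).
#' @param score Integer scores in `{1, 2, 3}`.
#' @return Tibble of class `engagement_script` with columns `start_s`,
#'   `end_s`, `score`.
#' @export
#' @examples
#' engagement_script(c(0, 60), c(60, 120), c(2, 3))
engagement_script <- function(start_s, end_s, score) {
  stopifnot(length(start_s) == length(end_s),
            length(start_s) == length(score))
  if (length(start_s) == 0L) stop("script needs at least one scene", call. = FALSE)
  if (any(!score %in% c(1, 2, 3))) {
    stop("engagement score outside {1,2,3}", call. = FALSE)
  }
  if (any(end_s <= start_s)) stop("scene with non-positive duration", call. = FALSE)
  if (start_s[1] != 0) stop("first scene must start at 0 s", call. = FALSE)
  if (length(start_s) > 1L) {
    d <- start_s[-1] - end_s[-length(end_s)]
    if (any(d > 0)) stop("gap between scenes", call. = FALSE)
    if (any(d < 0)) stop("overlapping scenes", call. = FALSE)
  }
  structure(
    tibble::tibble(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   score = as.integer(score)),
    class = c("engagement_script", class(tibble::tibble())))
}

#' Total duration of an engagement script, in seconds
#' @param script An [engagement_script()].
#' @return Number of seconds.
#' @export
script_duration <- function(script) {
  stopifnot(inherits(script, "engagement_script"))
  script$end_s[nrow(script)]
}

#' Read an engagement script CSV
#'
#' @param file CSV with columns `start_s,end_s,score`.
#' @return A validated [engagement_script()].
#' @export
read_engagement_script <- function(file) {
  df <- readr::read_csv(file, col_types = "ddi", progress = FALSE,
                        show_col_types = FALSE)
  if (!identical(names(df), c("start_s", "end_s", "score"))) {
    stop("engagement script must have header start_s,end_s,score",
         call. = FALSE)
  }
  engagement_script(df$start_s, df$end_s, df$score)
}

#' Write an engagement script CSV
#' @param script An [engagement_script()].
#' @param file Path or connection.
#' @export
write_engagement_script <- function(script, file) {
  stopifnot(inherits(script, "engagement_script"))
  readr::write_csv(tibble::as_tibble(unclass(script))[
    , c("start_s", "end_s", "score")], file, progress = FALSE)
  invisible(file)
}

# ---- seat map + participant metadata -------------------------------------

.empathy_range <- function(scale) {
  switch(scale,
         "EQ-short" = c(0, 44),
         "QCAE" = c(4, 124),
         stop("unknown empathy scale: ", scale, call. = FALSE))
}

#' Build the seat/metadata table
#'
#' One row per participant: seat coordinates (integer `row`, `seat`;
#' adjacent seats and adjacent rows are both 1 seat unit apart), plus
#' metadata used by the pair analyses — age in years, gender
#' (`"female"`, `"male"`, or `"other"`), empathy questionnaire total
#' (EQ-short range 0-44 or QCAE range 4-124) and a questionnaire
#' completeness flag.
#'
#' @param participant_id Character vector of unique ids.
#' @param row,seat Non-negative integer seat coordinates (unique pairs).
#' @param age Age in years (`NA` allowed).
#' @param gender `"female"`, `"male"` or `"other"`.
#' @param empathy_total Empathy questionnaire total (`NA` allowed).
#' @param empathy_scale `"EQ-short"` or `"QCAE"` (recycled if length 1).
#' @param questionnaires_complete Logical.
#' @return Tibble of class `participant_table`.
#' @export
participant_table <- function(participant_id, row, seat,
                              age = NA_real_, gender = "other",
                              empathy_total = NA_real_,
                              empathy_scale = "EQ-short",
                              questionnaires_complete = TRUE) {
  n <- length(participant_id)
  df <- tibble::tibble(
    participant_id = as.character(participant_id),
    row = as.integer(row), seat = as.integer(seat),
    age = rep_len(as.numeric(age), n),
    gender = rep_len(as.character(gender), n),
    empathy_total = rep_len(as.numeric(empathy_total), n),
    empathy_scale = rep_len(as.character(empathy_scale), n),
    questionnaires_complete = rep_len(as.logical(questionnaires_complete), n))
  if (anyDuplicated(df$participant_id)) {
    stop("duplicate participant_id in metadata", call. = FALSE)
  }
  if (any(df$row < 0 | df$seat < 0, na.rm = TRUE)) {
    stop("seat coordinates must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(df[, c("row", "seat")])) {
    stop("duplicate seat assignment", call. = FALSE)
  }
  bad_gender <- !df$gender %in% c("female", "male", "other")
  if (any(bad_gender, na.rm = TRUE)) {
    stop("gender must be 'female', 'male' or 'other'", call. = FALSE)
  }
  for (i in seq_len(n)) {
    if (!is.na(df$empathy_total[i])) {
      rng <- .empathy_range(df$empathy_scale[i])
      if (df$empathy_total[i] < rng[1] || df$empathy_total[i] > rng[2]) {
        stop(sprintf("empathy_total %g outside %s range [%g, %g] for '%s'",
                     df$empathy_total[i], df$empathy_scale[i], rng[1], rng[2],
                     df$participant_id[i]), call. = FALSE)
      }
    }
    if (!is.na(df$age[i]) && df$age[i] < 0) {
      stop("negative age for '", df$participant_id[i], "'", call. = FALSE)
    }
  }
  structure(df, class = c("participant_table", class(tibble::tibble())))
}

#' Read the seat/metadata CSV
#' @param file CSV with header
#'   `participant_id,row,seat,age,gender,empathy_total,empathy_scale,questionnaires_complete`.
#' @return A validated [participant_table()].
#' @export
read_participant_table <- function(file) {
  df <- readr::read_csv(file, col_types = "ciidcdcl", na = c("", "NA"),
                        progress = FALSE, show_col_types = FALSE)
  expected <- c("participant_id", "row", "seat", "age", "gender",
                "empathy_total", "empathy_scale", "questionnaires_complete")
  if (!identical(names(df), expected)) {
    stop("participant table must have header: ",
         paste(expected, collapse = ","), call. = FALSE)
  }
  participant_table(df$participant_id, df$row, df$seat, df$age, df$gender,
                    df$empathy_total, df$empathy_scale,
                    df$questionnaires_complete)
}

#' Write the seat/metadata CSV
#' @param info A [participant_table()].
#' @param file Path or connection.
#' @export
write_participant_table <- function(info, file) {
  stopifnot(inherits(info, "participant_table"))
  readr::write_csv(tibble::as_tibble(unclass(info)), file, na = "",
                   progress = FALSE)
  invisible(file)
}

# ---- the recording container ---------------------------------------------

#' Assemble an audience recording
#'
#' The central container: every expression track of one performance plus
#' the seat map and participant metadata. All tracks must share one frame
#' count and frame rate, and every track must have a metadata row.
#'
#' @param performance_id Single string.
#' @param tracks List of [expression_track()] objects.
#' @param info A [participant_table()] covering every track's participant.
#' @param allow_empty Allow zero tracks (used to represent a
#'   whole-performance exclusion); default `FALSE`.
#' @return Object of class `audience_recording`.
#' @export
audience_recording <- function(performance_id, tracks, info,
                               allow_empty = FALSE) {
  stopifnot(is.character(performance_id), length(performance_id) == 1L,
            is.list(tracks), inherits(info, "participant_table"))
  if (length(tracks) == 0L && !allow_empty) {
    stop("recording needs at least one track", call. = FALSE)
  }
  ids <- vapply(tracks, function(t) t$participant_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate participant ids", call. = FALSE)
  names(tracks) <- ids
  rec <- structure(
    list(performance_id = performance_id, tracks = tracks, info = info),
    class = "audience_recording")
  findings <- validate_recording(rec)
  hard <- findings$rule %in% c("unequal_track_length", "frame_rate_mismatch",
                               "missing_metadata")
  if (any(hard)) {
    stop("invalid recording: ", findings$message[which(hard)[1]],
         call. = FALSE)
  }
  rec
}

#' @export
print.audience_recording <- function(x, ...) {
  nf <- if (length(x$tracks)) n_frames(x$tracks[[1]]) else 0L
  cat(sprintf("<audience_recording> '%s': %d participants, %d frames\n",
              x$performance_id, length(x$tracks), nf))
  invisible(x)
}

#' Number of participants in a recording
#' @param recording An [audience_recording()].
#' @return Integer count.
#' @export
n_participants <- function(recording) length(recording$tracks)

#' Participant ids of a recording
#' @param recording An [audience_recording()].
#' @return Character vector.
#' @export
participant_ids <- function(recording) names(recording$tracks)

#' Validate an audience recording
#'
#' Checks every container invariant and returns findings rather than
#' throwing: an empty result means the recording is consistent.
#'
#' @param recording An [audience_recording()] (or a structurally similar
#'   list, so that broken objects can still be inspected).
#' @return Tibble with columns `rule`, `participant_id`, `message`; zero
#'   rows iff all invariants hold.
#' @export
validate_recording <- function(recording) {
  findings <- list()
  add <- function(rule, pid, msg) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(rule = rule, participant_id = pid, message = msg)
  }
  tracks <- recording$tracks
  info <- recording$info
  if (length(tracks) == 0L) {
    add("empty_recording", NA_character_, "recording has no tracks")
  }
  if (length(tracks) > 1L) {
    lens <- vapply(tracks, n_frames, integer(1))
    if (length(unique(lens)) > 1L) {
      add("unequal_track_length", NA_character_,
          sprintf("track lengths differ: %s",
                  paste(unique(lens), collapse = ", ")))
    }
    rates <- vapply(tracks, function(t) t$frame_rate, numeric(1))
    if (length(unique(rates)) > 1L) {
      add("frame_rate_mismatch", NA_character_, "frame rates differ")
    }
  }
  ids <- names(tracks)
  missing_meta <- setdiff(ids, info$participant_id)
  for (id in missing_meta) {
    add("missing_metadata", id,
        sprintf("participant '%s' has no seat/metadata row", id))
  }
  dup_seat <- duplicated(info[, c("row", "seat")])
  for (i in which(dup_seat)) {
    add("duplicate_seat", info$participant_id[i],
        sprintf("seat (%d, %d) assigned more than once",
                info$row[i], info$seat[i]))
  }
  if (length(findings)) dplyr::bind_rows(findings) else
    tibble::tibble(rule = character(0), participant_id = character(0),
                   message = character(0))
}

# Frames x participants matrix for one channel; NA at invalid frames.
.expression_matrix <- function(recording, expression) {
  expression <- .match_channel(expression)
  vapply(recording$tracks, function(tr) tr$intensities[, expression],
         numeric(n_frames(recording$tracks[[1]])))
}

# Validity matrix (frames x participants).
.valid_matrix <- function(recording) {
  vapply(recording$tracks, function(tr) tr$valid_mask,
         logical(n_frames(recording$tracks[[1]])))
}
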