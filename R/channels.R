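#' Expression channel names
#'
#' The eight expression-intensity channels emitted by automated facial
#' expression classification, in the fixed order used throughout the
#' package: neutral, happy, sad, angry, surprise, fear, disgust, contempt.
#' Every intensity is in \[0, 1\] (0 = expression not detected, 1 = fully
#' present).
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' expression_channels()
expression_channels <- function() {
  c("neutral", "happy", "sad", "angry", "surprise", "fear", "disgust",
    "contempt")
}

# Internal shorthand used pervasively.
.channels <- function() expression_channels()
.n_channels <- 8L

# Coerce a channel name, validating against the fixed set.
.match_channel <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L ||
      !(expression %in% .channels())) {
    stop("unknown expression channel: ",
         paste(utils::head(expression, 3), collapse = ", "),
         " (must be one of: ", paste(.channels(), collapse = ", "), ")",
         call. = FALSE)
  }
  expression
}

# Channel factor with fixed level order, for tidy outputs.
.channel_factor <- function(x) factor(x, levels = .channels())
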