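#' Default channel alphabets for the five healthcare utilization channels
#'
#' Each channel records an annual ordinal utilization level, position 0
#' always meaning no utilization. The default alphabets are:
#'
#' * `ambulatory`: none / low / medium / high (number of physician visits),
#' * `emergency`: none / one / multiple emergency consultations,
#' * `hospital`: none / one / multiple overnight hospital stays,
#' * `homecare`: none / temporary / regular professional home care,
#' * `nursinghome`: none / temporary / permanent nursing home stay.
#'
#' The exact count-to-category cutoffs behind each label are a survey design
#' choice, not part of the method; any alternative alphabet with unique
#' labels and a "none" level at position 0 can be supplied wherever a
#' `specs` argument is accepted.
#'
#' @return A tibble with columns `channel`, `level` (state label) and
#'   `position` (ordinal position, 0-based); one row per channel level.
#' @examples
#' default_channel_specs()
#' @export
default_channel_specs <- function() {
  tibble::tibble(
    channel = rep(
      c("ambulatory", "emergency", "hospital", "homecare", "nursinghome"),
      times = c(4L, 3L, 3L, 3L, 3L)
    ),
    level = c(
      "none", "low", "medium", "high",
      "none", "one", "multiple",
      "none", "one", "multiple",
      "none", "temporary", "regular",
      "none", "temporary", "permanent"
    ),
    position = c(0:3, 0:2, 0:2, 0:2, 0:2)
  )
}

#' Validate a channel specification table
#'
#' @param specs A tibble like [default_channel_specs()]: columns `channel`,
#'   `level`, `position`.
#' @return `specs`, invisibly, if valid; otherwise an error.
#' @export
validate_channel_specs <- function(specs) {
  stopifnot(is.data.frame(specs),
            all(c("channel", "level", "position") %in% names(specs)))
  for (ch in unique(specs$channel)) {
    sub <- specs[specs$channel == ch, ]
    if (nrow(sub) < 2) {
      stop("channel '", ch, "' needs at least 2 levels", call. = FALSE)
    }
    if (anyDuplicated(sub$level)) {
      stop("channel '", ch, "' has duplicated level labels", call. = FALSE)
    }
    if (!identical(sort(sub$position), seq(0L, nrow(sub) - 1L))) {
      stop("channel '", ch, "' positions must be 0..K-1", call. = FALSE)
    }
    if (any(sub$level %in% OVERLAY_STATES)) {
      stop("channel '", ch, "' reuses a reserved overlay code", call. = FALSE)
    }
  }
  invisible(specs)
}

#' Channel names of a specification table, in first-appearance order
#' @param specs A channel specification tibble.
#' @return Character vector of channel names.
#' @export
channel_names <- function(specs) unique(specs$channel)

# levels of one channel ordered by position
channel_levels <- function(specs, channel) {
  sub <- specs[specs$channel == channel, ]
  sub$level[order(sub$position)]
}

# extended alphabet: ordinal levels then the shared overlay states
extended_alphabet <- function(specs, channel) {
  c(channel_levels(specs, channel), OVERLAY_STATES)
}
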