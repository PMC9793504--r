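#' Assemble a cohort from trajectory states and baseline covariates
#'
#' A cohort couples a rectangular trajectory table (one row per individual
#' and wave, one column per channel) with an optional baseline covariate
#' table. All invariants are checked on construction:
#'
#' * every individual has one row for each wave `1..T`;
#' * every cell holds either a channel level or an overlay code
#'   (`"NR"`, `"INCAP"`, `"DEAD"`);
#' * overlay states apply to all channels of a person-wave at once;
#' * `"DEAD"` is absorbing: once dead, always dead.
#'
#' @param states Tibble with columns `id`, `wave` and one character column
#'   per channel in `specs`.
#' @param covariates Optional tibble of baseline covariates, one row per
#'   individual, with an `id` column.
#' @param specs Channel specification tibble; see [default_channel_specs()].
#' @return An object of class `cohort`: a list with elements `states`,
#'   `covariates` and `specs`.
#' @examples
#' states <- tidyr::expand_grid(id = "a", wave = 1:11)
#' for (ch in channel_names(default_channel_specs())) states[[ch]] <- "none"
#' cohort(states)
#' @export
cohort <- function(states, covariates = NULL, specs = default_channel_specs()) {
  validate_channel_specs(specs)
  states <- tibble::as_tibble(states)
  states$id <- as.character(states$id)
  states$wave <- as.integer(states$wave)
  states <- dplyr::arrange(states, .data$id, .data$wave)
  validate_cohort_states(states, specs)
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    covariates$id <- as.character(covariates$id)
    if (anyDuplicated(covariates$id)) {
      stop("covariate table has duplicated ids", call. = FALSE)
    }
    missing_cov <- setdiff(unique(states$id), covariates$id)
    if (length(missing_cov) > 0) {
      stop("individuals without covariate row: ",
           paste(head(missing_cov, 5), collapse = ", "), call. = FALSE)
    }
    covariates <- covariates[match(unique(states$id), covariates$id), ]
  }
  structure(list(states = states, covariates = covariates, specs = specs),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(unique(x$states$id))
  waves <- sort(unique(x$states$wave))
  cat("<cohort> ", n, " individuals x ", length(waves), " waves x ",
      length(channel_names(x$specs)), " channels\n", sep = "")
  if (!is.null(x$covariates)) {
    cat("covariates: ",
        paste(setdiff(names(x$covariates), "id"), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
as_tibble.cohort <- function(x, ...) x$states

# Extract the states tibble whether given a cohort object or a bare tibble.
cohort_states <- function(x) {
  if (inherits(x, "cohort")) x$states else tibble::as_tibble(x)
}

cohort_specs <- function(x, specs = NULL) {
  if (!is.null(specs)) return(specs)
  if (inherits(x, "cohort")) x$specs else default_channel_specs()
}

validate_cohort_states <- function(states, specs) {
  chans <- channel_names(specs)
  need <- c("id", "wave", chans)
  miss <- setdiff(need, names(states))
  if (length(miss) > 0) {
    stop("trajectory table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  waves <- sort(unique(states$wave))
  if (!identical(waves, seq_along(waves))) {
    stop("waves must be 1..T without gaps", call. = FALSE)
  }
  counts <- table(states$id)
  if (any(counts != length(waves)) ||
      anyDuplicated(states[c("id", "wave")]) > 0) {
    bad <- names(counts)[counts != length(waves)][1]
    stop("individual '", bad, "' does not have exactly one row per wave",
         call. = FALSE)
  }
  for (ch in chans) {
    ok <- states[[ch]] %in% extended_alphabet(specs, ch)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("unknown state '", states[[ch]][i], "' for channel '", ch,
           "' (individual ", states$id[i], ", wave ", states$wave[i], ")",
           call. = FALSE)
    }
  }
  # overlay consistency: a person-wave is entirely in one overlay state or
  # entirely in channel levels
  ov <- vapply(chans, function(ch) {
    ifelse(states[[ch]] %in% OVERLAY_STATES, states[[ch]], "")
  }, character(nrow(states)))
  ov <- matrix(ov, nrow = nrow(states))
  n_distinct_ov <- apply(ov, 1, function(r) length(unique(r)))
  if (any(n_distinct_ov > 1)) {
    i <- which(n_distinct_ov > 1)[1]
    stop("overlay inconsistency at individual ", states$id[i], ", wave ",
         states$wave[i], ": channels mix overlay and level states",
         call. = FALSE)
  }
  # DEAD absorbing (states sorted by id, wave)
  dead <- ov[, 1] == "DEAD"
  if (any(dead)) {
    per_id <- split(dead, states$id)
    for (id in names(per_id)) {
      d <- per_id[[id]]
      if (any(d) && any(!d[seq(which(d)[1], length(d))])) {
        w <- which(d)[1] + which(!d[seq(which(d)[1], length(d))])[1] - 1
        stop("individual ", id, " leaves the DEAD state at wave ", w,
             " (DEAD must be absorbing)", call. = FALSE)
      }
    }
  }
  invisible(states)
}

#' Read a cohort from trajectory and covariate CSV files
#'
#' The trajectory file may be in long form (columns `id`, `wave`,
#' `channel`, `state`) or wide form (columns `id`, `wave`, then one column
#' per channel); the dialect is detected from the header. State codes are
#' channel level labels or the overlay codes `NR` / `INCAP` / `DEAD`.
#' Both dialects produce identical cohorts.
#'
#' @param trajectory_path Path to the trajectory CSV (UTF-8, header row).
#' @param covariate_path Optional path to a covariate CSV (`id` plus one
#'   column per covariate; empty cells are read as missing).
#' @inheritParams cohort
#' @return A [cohort()] object.
#' @export
read_cohort <- function(trajectory_path, covariate_path = NULL,
                        specs = default_channel_specs()) {
  raw <- readr::read_csv(trajectory_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  chans <- channel_names(specs)
  if (all(c("id", "wave", "channel", "state") %in% names(raw))) {
    bad <- which(!raw$channel %in% chans)
    if (length(bad) > 0) {
      stop("line ", bad[1] + 1L, " of ", trajectory_path,
           ": unknown channel '", raw$channel[bad[1]], "'", call. = FALSE)
    }
    if (anyDuplicated(raw[c("id", "wave", "channel")]) > 0) {
      i <- anyDuplicated(raw[c("id", "wave", "channel")])
      stop("line ", i + 1L, " of ", trajectory_path,
           ": duplicate (id, wave, channel) cell", call. = FALSE)
    }
    states <- tidyr::pivot_wider(raw, names_from = "channel",
                                 values_from = "state")
  } else if (all(c("id", "wave", chans) %in% names(raw))) {
    states <- raw[c("id", "wave", chans)]
  } else {
    stop("unrecognized trajectory header in ", trajectory_path,
         ": need long (id, wave, channel, state) or wide (id, wave, ",
         paste(chans, collapse = ", "), ")", call. = FALSE)
  }
  states$wave <- suppressWarnings(as.integer(states$wave))
  if (anyNA(states$wave)) {
    stop("non-integer wave value in ", trajectory_path, call. = FALSE)
  }
  covariates <- NULL
  if (!is.null(covariate_path)) {
    # read as character and convert only unambiguously numeric columns:
    # category labels like "no"/"yes" must never be guessed as logicals
    covariates <- readr::read_csv(covariate_path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
    for (cov in setdiff(names(covariates), "id")) {
      x <- covariates[[cov]]
      numeric_like <- grepl("^[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?$", x)
      if (all(numeric_like | is.na(x)) && any(numeric_like)) {
        covariates[[cov]] <- as.numeric(x)
      }
    }
  }
  cohort(states, covariates, specs)
}

#' Write a cohort to CSV
#'
#' @param x A [cohort()] object.
#' @param trajectory_path Output path for the trajectory table.
#' @param covariate_path Optional output path for the covariate table.
#' @param format `"wide"` (default) or `"long"` trajectory dialect.
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, trajectory_path, covariate_path = NULL,
                         format = c("wide", "long")) {
  format <- match.arg(format)
  states <- cohort_states(x)
  if (format == "long") {
    states <- tidyr::pivot_longer(states, -c("id", "wave"),
                                  names_to = "channel", values_to = "state")
  }
  readr::write_csv(states, trajectory_path, progress = FALSE)
  if (!is.null(covariate_path) && !is.null(x$covariates)) {
    readr::write_csv(x$covariates, covariate_path, na = "", progress = FALSE)
  }
  invisible(x)
}

#' Keep individuals with enough observed waves
#'
#' Applies the study-inclusion rule: an individual is retained when at
#' least `min_obs` of their waves are in a known state. A wave counts as
#' known when it carries a channel level, `"INCAP"` or `"DEAD"`;
#' `"NR"` (nonresponse) waves are unknown. Confirmed deaths therefore
#' count as observations, so individuals dying early are retained rather
#' than discarded as attrition.
#'
#' @param x A [cohort()] object or a trajectory states tibble.
#' @param min_obs Minimum number of known waves (default 6).
#' @param specs Channel specification; defaults to the cohort's own.
#' @return The filtered object (same type as `x`), with attributes
#'   `retained_ids` and `excluded_ids`.
#' @export
filter_min_observations <- function(x, min_obs = 6L, specs = NULL) {
  states <- cohort_states(x)
  specs <- cohort_specs(x, specs)
  waves <- sort(unique(states$wave))
  stopifnot(min_obs >= 1, min_obs <= length(waves))
  ch1 <- channel_names(specs)[1]
  known <- states[[ch1]] != "NR"  # overlay consistency: one channel suffices
  n_known <- tapply(known, states$id, sum)
  retained <- names(n_known)[n_known >= min_obs]
  excluded <- setdiff(names(n_known), retained)
  out_states <- states[states$id %in% retained, ]
  if (inherits(x, "cohort")) {
    covs <- x$covariates
    if (!is.null(covs)) covs <- covs[covs$id %in% retained, ]
    out <- cohort(out_states, covs, specs)
  } else {
    out <- out_states
  }
  attr(out, "retained_ids") <- retained
  attr(out, "excluded_ids") <- excluded
  out
}
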