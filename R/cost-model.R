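#' Build the substitution/indel cost model over the extended alphabets
#'
#' For every channel the substitution matrix is defined over the extended
#' alphabet: the ordinal utilization levels `0..K-1`, then `NR`, `INCAP`
#' and `DEAD`. The default ordinal scheme places
#'
#' * `INCAP` at position `K-1` (too unwell to participate is treated as
#'   equivalent to the highest utilization level),
#' * `DEAD` at extended position `K` (death is the furthest state from no
#'   utilization),
#'
#' and sets `s(a, b) = 2 * |pos(a) - pos(b)| / K`, so the maximum
#' substitution cost (`DEAD` vs `none`) is 2 on every channel and the
#' indel cost — half the maximum substitution cost, giving equal weight to
#' timing and sequencing — is 1. `NR` (random nonresponse) costs exactly
#' the indel cost against every other state, the unique equidistant value
#' that keeps the matrix metric. Because all channels share the same
#' normalized indel cost, equal channel weights (the default) already give
#' each channel the same leverage in the pooled multichannel distance.
#'
#' @param specs Channel specification tibble; see [default_channel_specs()].
#' @param weights Optional named numeric vector of channel weights
#'   (default 1 for every channel).
#' @param substitution Optional named list of full substitution-matrix
#'   overrides (one per channel, rows/columns named by the extended
#'   alphabet). Overrides must be symmetric, nonnegative, with a zero
#'   diagonal; the indel cost is recomputed as half their maximum.
#' @return An object of class `cost_model`: per channel the substitution
#'   matrix, indel cost and weight.
#' @examples
#' cm <- build_cost_model(default_channel_specs())
#' cm$channels$homecare$sub["none", "DEAD"]  # 2: furthest from no use
#' @export
build_cost_model <- function(specs = default_channel_specs(), weights = NULL,
                             substitution = NULL) {
  validate_channel_specs(specs)
  chans <- channel_names(specs)
  if (is.null(weights)) weights <- setNames(rep(1, length(chans)), chans)
  stopifnot(all(chans %in% names(weights)), all(weights >= 0))
  channels <- lapply(chans, function(ch) {
    alphabet <- extended_alphabet(specs, ch)
    K <- length(channel_levels(specs, ch))
    if (!is.null(substitution) && !is.null(substitution[[ch]])) {
      sub <- substitution[[ch]]
      if (!is.matrix(sub) || nrow(sub) != length(alphabet) ||
          is.null(dimnames(sub)) ||
          !identical(sort(rownames(sub)), sort(alphabet))) {
        stop("substitution override for '", ch, "' must be a ",
             length(alphabet), "x", length(alphabet),
             " matrix named by the extended alphabet", call. = FALSE)
      }
      sub <- sub[alphabet, alphabet]
      if (any(sub < 0) || any(diag(sub) != 0) || !isSymmetric(unname(sub))) {
        stop("substitution override for '", ch, "' must be symmetric, ",
             "nonnegative, with a zero diagonal", call. = FALSE)
      }
    } else {
      # positions: levels 0..K-1, INCAP shares K-1, DEAD at K; NR filled after
      pos <- c(seq_len(K) - 1, NA, K - 1, K)
      sub <- 2 * abs(outer(pos, pos, "-")) / K
      gamma <- max(sub, na.rm = TRUE) / 2
      nr <- which(alphabet == "NR")
      sub[nr, ] <- gamma
      sub[, nr] <- gamma
      sub[nr, nr] <- 0
      dimnames(sub) <- list(alphabet, alphabet)
    }
    list(alphabet = alphabet, sub = sub, indel = max(sub) / 2,
         weight = unname(weights[ch]))
  })
  names(channels) <- chans
  structure(list(channels = channels, specs = specs), class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("<cost_model> over", length(x$channels), "channels\n")
  for (ch in names(x$channels)) {
    m <- x$channels[[ch]]
    cat(sprintf("  %-12s K=%d  indel=%.3g  weight=%.3g\n", ch,
                length(m$alphabet) - 3L, m$indel, m$weight))
  }
  invisible(x)
}

# pooled indel cost over channels
pooled_indel <- function(cm) {
  sum(vapply(cm$channels, function(m) m$weight * m$indel, numeric(1)))
}
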