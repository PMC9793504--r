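#' Optimal Matching distance between two single-channel sequences
#'
#' The minimum total cost of transforming one sequence into the other by
#' substitutions and single-state insertions/deletions (indels), computed
#' by the classic edit-distance dynamic programme. Sequences of unequal
#' length are supported.
#'
#' @param a,b Character vectors of states (must appear in the row names of
#'   `sub`), or integer vectors of 1-based indices into `sub`.
#' @param sub Symmetric substitution-cost matrix with zero diagonal.
#' @param indel Indel cost; defaults to half the maximum substitution cost.
#' @return A single nonnegative number.
#' @examples
#' cm <- build_cost_model()
#' hc <- cm$channels$homecare
#' om_distance(c("none", "none"), c("none", "regular"), hc$sub, hc$indel)
#' @export
om_distance <- function(a, b, sub, indel = max(sub) / 2) {
  ai <- state_indices(a, sub)
  bi <- state_indices(b, sub)
  om_dist_cpp(ai - 1L, bi - 1L, sub, indel)
}

state_indices <- function(x, sub) {
  if (is.character(x) || is.factor(x)) {
    idx <- match(as.character(x), rownames(sub))
    if (anyNA(idx)) {
      stop("unknown state '", as.character(x)[which(is.na(idx))[1]], "'",
           call. = FALSE)
    }
    idx
  } else {
    idx <- as.integer(x)
    if (anyNA(idx) || any(idx < 1) || any(idx > nrow(sub))) {
      stop("state index out of range", call. = FALSE)
    }
    idx
  }
}

#' Multichannel Optimal Matching distance between two individuals
#'
#' Runs a single dynamic programme on the vector-valued states, with the
#' pooled substitution cost `S(x_t, y_u) = sum_c w_c * s_c(x_t[c], y_u[c])`
#' and the pooled indel cost `sum_c w_c * indel_c` (local interdependence:
#' channels are compared and their costs added at each aligned time
#' point). With a single channel of weight 1 this reduces exactly to
#' [om_distance()].
#'
#' @param x,y Data frames (or matrices) of states with one column per
#'   channel of the cost model and one row per wave.
#' @param cost_model A [build_cost_model()] object.
#' @return A single nonnegative number.
#' @export
multichannel_distance <- function(x, y, cost_model) {
  chans <- names(cost_model$channels)
  x <- as.data.frame(x)
  y <- as.data.frame(y)
  if (!all(chans %in% names(x)) || !all(chans %in% names(y))) {
    stop("x and y must both have the cost model's channel columns: ",
         paste(chans, collapse = ", "), call. = FALSE)
  }
  both <- rbind(x[chans], y[chans])
  enc <- encode_profiles(both, cost_model)
  nx <- nrow(x)
  om_dist_cpp(enc$pidx[seq_len(nx)] - 1L,
              enc$pidx[nx + seq_len(nrow(y))] - 1L,
              enc$S, pooled_indel(cost_model))
}

# Map each multichannel state vector (row) to a profile index and build the
# pooled substitution matrix over the distinct profiles.
encode_profiles <- function(states, cost_model) {
  chans <- names(cost_model$channels)
  key <- do.call(paste, c(states[chans], list(sep = "\r")))
  uk <- unique(key)
  pidx <- match(key, uk)
  comp <- states[match(uk, key), chans, drop = FALSE]
  P <- length(uk)
  S <- matrix(0, P, P)
  for (ch in chans) {
    m <- cost_model$channels[[ch]]
    ci <- state_indices(comp[[ch]], m$sub)
    S <- S + m$weight * m$sub[ci, ci, drop = FALSE]
  }
  dimnames(S) <- NULL
  list(pidx = pidx, S = S)
}

#' Pairwise multichannel OM distance matrix for a cohort
#'
#' Computes the full symmetric matrix of multichannel Optimal Matching
#' distances between all retained individuals. Distinct multichannel
#' person-wave profiles are pooled once, so the dynamic programme runs on
#' compact integer sequences; each unordered pair is computed once.
#'
#' @param x A [cohort()] object or trajectory states tibble.
#' @param cost_model A [build_cost_model()] object; defaults to the model
#'   built from the cohort's channel specification.
#' @param verbose Print a progress line (default `FALSE`).
#' @return A symmetric numeric matrix with zero diagonal, row and column
#'   names set to the individual ids.
#' @export
pairwise_distance_matrix <- function(x, cost_model = NULL, verbose = FALSE) {
  states <- cohort_states(x)
  if (is.null(cost_model)) cost_model <- build_cost_model(cohort_specs(x))
  states <- dplyr::arrange(states, .data$id, .data$wave)
  ids <- unique(states$id)
  waves <- sort(unique(states$wave))
  enc <- encode_profiles(states, cost_model)
  seqs <- matrix(enc$pidx - 1L, nrow = length(ids), ncol = length(waves),
                 byrow = TRUE)
  if (verbose) {
    message("pairwise OM over ", length(ids), " individuals (",
            nrow(enc$S), " distinct profiles)")
  }
  D <- pairwise_om_cpp(seqs, enc$S, pooled_indel(cost_model))
  dimnames(D) <- list(ids, ids)
  D
}
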