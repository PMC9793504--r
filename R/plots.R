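state_factor <- function(x, specs, channel) {
  levels <- c(channel_levels(specs, channel), OVERLAY_STATES)
  factor(x, levels = levels)
}

#' Per-wave state distribution of a cohort
#'
#' The data behind a state distribution plot: for each channel and wave
#' (and optionally each cluster), the share of individuals in every
#' state. Shares sum to 1 within each channel-wave (-cluster) cell.
#'
#' @param x A [cohort()] object or trajectory states tibble.
#' @param labels Optional cluster labels (tibble `id`/`cluster` or a
#'   `cluster_solution`) for per-cluster distributions.
#' @param specs Channel specification; defaults to the cohort's own.
#' @return A tibble: `channel`, `wave`, `state`, `n`, `prop` and, when
#'   labels are given, `cluster`.
#' @export
state_distribution <- function(x, labels = NULL, specs = NULL) {
  states <- cohort_states(x)
  specs <- cohort_specs(x, specs)
  chans <- channel_names(specs)
  long <- tidyr::pivot_longer(states, dplyr::all_of(chans),
                              names_to = "channel", values_to = "state")
  grouping <- c("channel", "wave", "state")
  if (!is.null(labels)) {
    if (inherits(labels, "cluster_solution")) labels <- labels$labels
    long$cluster <- labels$cluster[match(long$id, labels$id)]
    grouping <- c("cluster", grouping)
  }
  out <- dplyr::count(long, dplyr::across(dplyr::all_of(grouping)))
  out <- dplyr::mutate(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(setdiff(grouping, "state")))),
    prop = .data$n / sum(.data$n)
  )
  dplyr::ungroup(out)
}

#' State distribution plot
#'
#' Stacked per-wave state proportions, one panel per channel (and per
#' cluster when labels are given) — the standard exploratory display of a
#' set of categorical sequences. Every plotted quantity is available from
#' [state_distribution()], so the figure content is testable without
#' image parsing.
#'
#' @inheritParams state_distribution
#' @return A ggplot object.
#' @export
plot_state_distribution <- function(x, labels = NULL, specs = NULL) {
  specs <- cohort_specs(x, specs)
  data <- state_distribution(x, labels, specs)
  all_states <- c(unique(specs$level), OVERLAY_STATES)
  data$state <- factor(data$state, levels = unique(all_states))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$wave, y = .data$prop,
                                          fill = .data$state)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_x_continuous(breaks = scales_breaks(data$wave)) +
    ggplot2::labs(x = "years since entry", y = "share of individuals",
                  fill = "state") +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    p + ggplot2::facet_grid(cluster ~ channel)
  } else {
    p + ggplot2::facet_wrap(~channel, nrow = 1)
  }
}

scales_breaks <- function(waves) {
  w <- sort(unique(waves))
  w[seq(1, length(w), by = 2)]
}

#' Most frequent single-channel sequences
#'
#' @param x A [cohort()] object or trajectory states tibble.
#' @param channel Channel name.
#' @param top Number of sequences to keep (default 10).
#' @return A tibble `sequence` (states joined by `-`), `n`, `share`,
#'   sorted by decreasing frequency.
#' @export
sequence_frequencies <- function(x, channel, top = 10) {
  states <- cohort_states(x)
  states <- dplyr::arrange(states, .data$id, .data$wave)
  seqs <- tapply(states[[channel]], states$id, paste, collapse = "-")
  tab <- sort(table(seqs), decreasing = TRUE)
  tibble::tibble(
    sequence = names(tab),
    n = as.integer(tab),
    share = as.numeric(tab) / length(seqs)
  )[seq_len(min(top, length(tab))), ]
}

#' Sequence frequency plot for one channel
#'
#' Horizontal bars of the `top` most frequent sequences of one channel
#' with their cohort shares; data from [sequence_frequencies()].
#'
#' @inheritParams sequence_frequencies
#' @return A ggplot object.
#' @export
plot_sequence_frequency <- function(x, channel, top = 10) {
  freq <- sequence_frequencies(x, channel, top)
  freq$sequence <- factor(freq$sequence, levels = rev(freq$sequence))
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$share, y = .data$sequence)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "share of individuals", y = NULL,
                  title = paste0(channel, ": ", top,
                                 " most frequent sequences")) +
    ggplot2::theme_minimal()
}

#' Sequence index plot for one channel
#'
#' One row per individual, waves on the x axis, tile colour = state.
#' When cluster labels and the distance matrix are supplied, rows are
#' sorted by cluster and, within cluster, by distance to the cluster
#' medoid (the member minimizing total within-cluster distance); the row
#' order is a presentation choice only.
#'
#' @param x A [cohort()] object or trajectory states tibble.
#' @param channel Channel name.
#' @param labels Optional cluster labels.
#' @param D Optional distance matrix for medoid-distance ordering.
#' @param specs Channel specification; defaults to the cohort's own.
#' @return A ggplot object.
#' @export
plot_sequence_index <- function(x, channel, labels = NULL, D = NULL,
                                specs = NULL) {
  states <- cohort_states(x)
  specs <- cohort_specs(x, specs)
  ids <- unique(states$id)
  ord <- ids
  if (!is.null(labels)) {
    if (inherits(labels, "cluster_solution")) labels <- labels$labels
    cl <- labels$cluster[match(ids, labels$id)]
    key <- rep(0, length(ids))
    if (!is.null(D)) {
      for (c in unique(cl)) {
        members <- ids[cl == c]
        sub <- D[members, members, drop = FALSE]
        medoid <- members[which.min(rowSums(sub))]
        key[match(members, ids)] <- D[members, medoid]
      }
    }
    ord <- ids[order(cl, key)]
  }
  data <- states[, c("id", "wave", channel)]
  names(data)[3] <- "state"
  data$state <- state_factor(data$state, specs, channel)
  data$id <- factor(data$id, levels = rev(ord))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$wave, y = .data$id,
                                     fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "years since entry", y = NULL, fill = "state",
                  title = paste0(channel, ": individual sequences")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
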