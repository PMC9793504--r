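# Shared fixtures, built in code.

# A rectangular states tibble where every channel is "none" everywhere,
# which individual edits can then perturb.
all_none_states <- function(ids = "a", waves = 11,
                            specs = default_channel_specs()) {
  out <- tidyr::expand_grid(id = ids, wave = seq_len(waves))
  for (ch in channel_names(specs)) out[[ch]] <- "none"
  out
}

# Set one person-wave to an overlay state across all channels.
set_overlay <- function(states, id, waves, overlay,
                        specs = default_channel_specs()) {
  rows <- states$id == id & states$wave %in% waves
  for (ch in channel_names(specs)) states[[ch]][rows] <- overlay
  states
}

# Independent brute-force OM oracle: enumerate all monotone alignments
# (pairs of equal-size increasing index subsets); unmatched positions pay
# the indel cost, matched pairs the substitution cost. Never uses the
# dynamic programme.
om_bruteforce <- function(a, b, sub, indel) {
  m <- length(a)
  n <- length(b)
  ai <- match(a, rownames(sub))
  bi <- match(b, rownames(sub))
  best <- (m + n) * indel  # empty alignment
  for (j in seq_len(min(m, n))) {
    IA <- utils::combn(m, j, simplify = FALSE)
    IB <- utils::combn(n, j, simplify = FALSE)
    for (I in IA) {
      for (J in IB) {
        cost <- sum(sub[cbind(ai[I], bi[J])]) + (m - j + n - j) * indel
        if (cost < best) best <- cost
      }
    }
  }
  best
}

# A small generator configuration (fewer individuals simulated by the
# caller; the config itself is the shipped default).
tiny_config <- function() default_generator_config()

# Naive silhouette computed point by point, as an independent check.
naive_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}
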