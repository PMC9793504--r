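#' Default configuration of the synthetic cohort generator
#'
#' Reads and validates the generator configuration shipped with the
#' package (`inst/extdata/archetypes.yaml`): six latent trajectory
#' archetypes with their prevalences, per-channel phase-wise Markov
#' kernels, per-wave death/incapacity hazards, dropout and nonresponse
#' rates, and the cluster-conditional covariate model. All numeric
#' defaults live in that file; pass an edited copy through `path` to
#' change the study conditions.
#'
#' @param path Optional path to an alternative YAML configuration.
#' @return A validated configuration list.
#' @export
default_generator_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "archetypes.yaml", package = "caretraj")
  }
  config <- yaml::read_yaml(path)
  validate_generator_config(config)
}

validate_generator_config <- function(config) {
  stopifnot(config$n_raw >= 1, config$waves >= 1,
            length(config$dropout_hazard) %in% c(1L, config$waves),
            all(config$dropout_hazard >= 0), all(config$dropout_hazard <= 1),
            config$nonresponse_rate >= 0, config$nonresponse_rate <= 1)
  prev <- vapply(config$archetypes, function(a) a$prevalence, numeric(1))
  if (abs(sum(prev) - 1) > 1e-6) {
    stop("archetype prevalences must sum to 1 (got ", sum(prev), ")",
         call. = FALSE)
  }
  specs <- default_channel_specs()
  for (an in names(config$archetypes)) {
    a <- config$archetypes[[an]]
    for (hz in list(a$death_hazard, a$incap_hazard)) {
      if (length(hz) != config$waves || any(hz < 0) || any(hz > 1)) {
        stop("archetype ", an, ": hazards must be length ", config$waves,
             " probabilities", call. = FALSE)
      }
    }
    for (ch in names(a$channels)) {
      K <- length(channel_levels(specs, ch))
      cc <- a$channels[[ch]]
      stopifnot(cc$stickiness >= 0, cc$stickiness <= 1)
      for (tg in cc$targets) {
        if (length(tg) != K || any(tg < 0) || abs(sum(tg) - 1) > 1e-6) {
          stop("archetype ", an, ", channel ", ch,
               ": each target must be a length-", K,
               " probability vector", call. = FALSE)
        }
      }
    }
  }
  config
}

# phase index (1..3) of each wave
phase_of_waves <- function(config) {
  out <- integer(config$waves)
  for (p in seq_along(config$phases)) {
    rng <- config$phases[[p]]
    out[rng[1]:rng[2]] <- p
  }
  out
}

#' Simulate a synthetic cohort with latent trajectory archetypes
#'
#' Each individual is assigned one of six archetypes (multinomial draw
#' with the configured prevalences) and their five utilization channels
#' evolve wave by wave under the archetype's phase-wise Markov kernels.
#' Incapacity and death hazards then overlay the person-wave states
#' (death is absorbing and overrides everything); permanent dropout turns
#' all subsequent waves into nonresponse, and transient nonresponse hits
#' remaining waves independently. Wave 1 is always observed (individuals
#' were recruited then). Covariates are drawn from the cluster-conditional
#' model. The result is deterministic given `seed`.
#'
#' @param config Generator configuration; see [default_generator_config()].
#' @param n_raw Number of individuals to simulate (default: the
#'   configuration's `n_raw`, 3053).
#' @param seed Integer seed.
#' @return A [cohort()] object with an extra element `latent`: a tibble
#'   (`id`, `archetype`) of the latent labels, for evaluation only.
#' @examples
#' sim <- simulate_cohort(n_raw = 50, seed = 1)
#' table(sim$latent$archetype)
#' @export
simulate_cohort <- function(config = default_generator_config(),
                            n_raw = NULL, seed = 1L) {
  validate_generator_config(config)
  set.seed(seed)
  n <- if (is.null(n_raw)) config$n_raw else n_raw
  T <- config$waves
  specs <- default_channel_specs()
  chans <- channel_names(specs)
  arch_names <- names(config$archetypes)
  prev <- vapply(config$archetypes, function(a) a$prevalence, numeric(1))
  labels <- sample(arch_names, n, replace = TRUE, prob = prev)
  phase <- phase_of_waves(config)

  # underlying utilization levels, simulated per archetype and channel
  levels_int <- lapply(chans, function(ch) matrix(1L, n, T))
  names(levels_int) <- chans
  for (an in arch_names) {
    rows <- which(labels == an)
    if (length(rows) == 0) next
    a <- config$archetypes[[an]]
    for (ch in chans) {
      cc <- a$channels[[ch]]
      K <- length(cc$targets[[1]])
      m <- matrix(0L, length(rows), T)
      m[, 1] <- sample.int(K, length(rows), replace = TRUE,
                           prob = cc$targets[[phase[1]]])
      for (t in 2:T) {
        stay <- stats::runif(length(rows)) < cc$stickiness
        draw <- sample.int(K, length(rows), replace = TRUE,
                           prob = cc$targets[[phase[t]]])
        m[, t] <- ifelse(stay, m[, t - 1], draw)
      }
      levels_int[[ch]][rows, ] <- m
    }
  }

  # death (absorbing) and incapacity overlays from per-wave hazards
  death_hz <- t(vapply(labels, function(a) {
    as.numeric(config$archetypes[[a]]$death_hazard)
  }, numeric(T)))
  incap_hz <- t(vapply(labels, function(a) {
    as.numeric(config$archetypes[[a]]$incap_hazard)
  }, numeric(T)))
  death_draw <- matrix(stats::runif(n * T), n, T) < death_hz
  death_wave <- apply(death_draw, 1, function(d) {
    w <- which(d)
    if (length(w) == 0) Inf else w[1]
  })
  incap <- matrix(stats::runif(n * T), n, T) < incap_hz

  # permanent dropout (first nonresponse wave, from wave 2 on) and
  # transient nonresponse; the dropout hazard may be a scalar or a
  # per-wave vector (hazard of dropping out AT that wave; wave 1 ignored)
  drop_hz <- config$dropout_hazard
  if (length(drop_hz) == 1) drop_hz <- c(0, rep(drop_hz, T - 1))
  drop_draw <- sweep(matrix(stats::runif(n * (T - 1)), n, T - 1), 2,
                     drop_hz[-1], "<")
  dropout_wave <- apply(drop_draw, 1, function(d) {
    w <- which(d)
    if (length(w) == 0) Inf else w[1] + 1
  })
  # transient nonresponse: at most one missed questionnaire per
  # individual (repeat nonresponse is what the permanent-dropout process
  # models), with probability chosen so the expected per-wave rate
  # equals nonresponse_rate
  q <- min(1, config$nonresponse_rate * (T - 1))
  has_nr <- stats::runif(n) < q
  transient <- matrix(FALSE, n, T)
  if (any(has_nr)) {
    w1 <- sample(2:T, sum(has_nr), replace = TRUE)
    transient[cbind(which(has_nr), w1)] <- TRUE
  }

  # dropout means withdrawal from follow-up: a death occurring after the
  # dropout wave is never observed, so those waves remain nonresponse;
  # a death while under follow-up is recorded and absorbing
  wave_idx <- matrix(rep(seq_len(T), each = n), n, T)
  death_observed <- death_wave < dropout_wave
  is_dead <- wave_idx >= death_wave & death_observed
  is_nr <- !is_dead & (wave_idx >= dropout_wave | transient)
  is_incap <- !is_dead & !is_nr & incap

  ids <- sprintf("id%05d", seq_len(n))
  states <- tibble::tibble(
    id = rep(ids, each = T),
    wave = rep(seq_len(T), times = n)
  )
  for (ch in chans) {
    lab <- channel_levels(specs, ch)[levels_int[[ch]]]
    lab[is_dead] <- "DEAD"
    lab[is_incap] <- "INCAP"
    lab[is_nr] <- "NR"
    states[[ch]] <- as.vector(t(matrix(lab, n, T)))
  }

  covariates <- simulate_covariates(labels, config$covariates, ids = ids)
  out <- cohort(states, covariates, specs)
  out$latent <- tibble::tibble(id = ids, archetype = labels)
  out
}

#' Draw baseline covariates conditional on latent archetypes
#'
#' Categorical covariates are drawn independently per individual from the
#' archetype-conditional category probabilities; a drawn `"missing"`
#' category becomes an `NA` cell. Age is uniform on 65..70 years shifted
#' to the archetype's configured mean.
#'
#' @param archetypes Character vector of latent archetype labels.
#' @param model Covariate model (the `covariates` element of a generator
#'   configuration).
#' @param ids Optional individual ids (default `id00001`, ...).
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return A tibble with `id`, `age` and one column per covariate.
#' @export
simulate_covariates <- function(archetypes, model, ids = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(archetypes)
  if (is.null(ids)) ids <- sprintf("id%05d", seq_len(n))
  order <- model$archetype_order
  bad <- setdiff(unique(archetypes), order)
  if (length(bad) > 0) {
    stop("unknown archetype label: ", bad[1], call. = FALSE)
  }
  ai <- match(archetypes, order)
  out <- tibble::tibble(id = ids)
  out$age <- sample(65:70, n, replace = TRUE) +
    (unlist(model$age$mean)[ai] - 67.5)
  for (cov in names(model$categorical)) {
    cm <- model$categorical[[cov]]
    lev <- as.character(unlist(cm$levels))
    val <- character(n)
    for (a in order) {
      rows <- which(archetypes == a)
      if (length(rows) == 0) next
      p <- as.numeric(unlist(cm$probs[[a]]))
      p <- p / sum(p)
      val[rows] <- sample(lev, length(rows), replace = TRUE, prob = p)
    }
    val[val == "missing"] <- NA_character_
    out[[cov]] <- val
  }
  out
}

#' Kernel-implied marginal state distribution of one archetype channel
#'
#' Chains the phase-wise kernels analytically: with kernel
#' `rho * I + (1 - rho) * 1 t(target)` the wave-to-wave update of the
#' marginal is `mu' = rho * mu + (1 - rho) * target`. Useful to check the
#' generator against its own configuration.
#'
#' @param config Generator configuration.
#' @param archetype Archetype name.
#' @param channel Channel name.
#' @return A `waves x K` matrix of marginal level probabilities.
#' @export
archetype_marginals <- function(config, archetype, channel) {
  a <- config$archetypes[[archetype]]
  if (is.null(a)) stop("unknown archetype '", archetype, "'", call. = FALSE)
  cc <- a$channels[[channel]]
  phase <- phase_of_waves(config)
  K <- length(cc$targets[[1]])
  mu <- matrix(0, config$waves, K)
  mu[1, ] <- as.numeric(cc$targets[[phase[1]]])
  for (t in 2:config$waves) {
    tg <- as.numeric(cc$targets[[phase[t]]])
    mu[t, ] <- cc$stickiness * mu[t - 1, ] + (1 - cc$stickiness) * tg
  }
  mu
}

#' Summary statistics of a cohort
#'
#' @param x A [cohort()] object or trajectory states tibble.
#' @param specs Channel specification; defaults to the cohort's own.
#' @return A list with elements:
#' * `n_individuals`, `n_waves`;
#' * `nonresponse_share`: share of person-wave cells in the `NR` state;
#' * `never_use`: tibble of the share of individuals whose channel never
#'   leaves ordinal position 0 (overlay waves ignored);
#' * `state_distribution`: tibble of per-wave state shares per channel;
#' * `deaths_by_wave`: tibble of newly dead individuals per wave.
#' @export
summarize_cohort <- function(x, specs = NULL) {
  states <- cohort_states(x)
  specs <- cohort_specs(x, specs)
  chans <- channel_names(specs)
  ids <- unique(states$id)
  ch1 <- states[[chans[1]]]
  nr_share <- mean(ch1 == "NR")
  never_use <- purrr::map_dfr(chans, function(ch) {
    sub <- specs[specs$channel == ch, ]
    pos <- sub$position[match(states[[ch]], sub$level)]  # NA for overlays
    used <- tapply(!is.na(pos) & pos > 0, states$id, any)
    tibble::tibble(channel = ch, share_never_use = mean(!used))
  })
  dist <- tidyr::pivot_longer(states, dplyr::all_of(chans),
                              names_to = "channel", values_to = "state")
  dist <- dplyr::count(dist, .data$channel, .data$wave, .data$state)
  dist <- dplyr::mutate(dplyr::group_by(dist, .data$channel, .data$wave),
                        share = .data$n / sum(.data$n))
  dist <- dplyr::ungroup(dist)
  dead <- states[ch1 == "DEAD", c("id", "wave")]
  first_dead <- if (nrow(dead) > 0) {
    stats::aggregate(wave ~ id, dead, min)
  } else {
    data.frame(id = character(), wave = integer())
  }
  deaths_by_wave <- dplyr::count(tibble::as_tibble(first_dead), .data$wave,
                                 name = "deaths")
  list(
    n_individuals = length(ids),
    n_waves = length(unique(states$wave)),
    nonresponse_share = nr_share,
    never_use = never_use,
    state_distribution = dist,
    deaths_by_wave = deaths_by_wave
  )
}
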