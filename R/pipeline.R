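#' Run the full trajectory-typology pipeline
#'
#' Chains the analysis stages on a cohort: study-inclusion filter (at
#' least `min_obs` known waves), cost model, pairwise multichannel
#' Optimal Matching distances, clustering with silhouette/minimum-size
#' model selection (or a fixed `k`), and cluster characterization
#' (bivariate screen at `alpha`, then multinomial regression with
#' backward stepwise AIC). Deterministic given the cohort and settings.
#'
#' @param x A [cohort()] object (with covariates for the
#'   characterization stage to run).
#' @param min_obs Minimum known waves for inclusion (default 6).
#' @param cost_model Optional [build_cost_model()] override.
#' @param method Clustering procedure: `"complete"`, `"ward"` or `"pam"`.
#' @param k Fixed number of clusters; `NULL` (default) selects it by the
#'   silhouette/minimum-size rule over `k_range`.
#' @param k_range,min_frac Model-selection settings; see
#'   [select_solution()].
#' @param alpha Bivariate significance level gating entry into the
#'   multivariable model (default 0.05).
#' @param missing_threshold Covariate missingness threshold; see
#'   [prepare_covariates()].
#' @param characterize Run the characterization stage (default `TRUE`
#'   when covariates are present).
#' @param verbose Log stage progress.
#' @return An object of class `caretraj_run`: the filtered cohort,
#'   distance matrix, `solution` (a `cluster_solution`), `bivariate`
#'   test table, `stepwise` selection result, and settings. Use
#'   [glance()] for a one-row summary and [run_report()] for a
#'   machine-readable report.
#' @export
run_pipeline <- function(x, min_obs = 6L, cost_model = NULL,
                         method = c("complete", "ward", "pam"), k = NULL,
                         k_range = 2:10, min_frac = 0.011, alpha = 0.05,
                         missing_threshold = 0.005,
                         characterize = !is.null(x$covariates),
                         verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(x, "cohort"))
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  say("filter: requiring >= ", min_obs, " known waves")
  filtered <- filter_min_observations(x, min_obs)
  n <- length(unique(filtered$states$id))
  say("retained ", n, " of ", length(unique(x$states$id)), " individuals")
  if (is.null(cost_model)) cost_model <- build_cost_model(x$specs)
  say("distance: pairwise multichannel OM over ", n, " individuals")
  D <- pairwise_distance_matrix(filtered, cost_model, verbose = verbose)
  say("clustering: ", method)
  if (method == "pam") {
    if (is.null(k)) stop("PAM needs an explicit k", call. = FALSE)
    solution <- pam_clusters(D, k)
    sil <- silhouette_width(D, solution$labels)
    solution$asw <- sil$asw
  } else {
    tree <- agglomerate(D, linkage = method)
    if (is.null(k)) {
      solution <- select_solution(tree, D, k_range = k_range,
                                  min_frac = min_frac)
    } else {
      solution <- cut_clusters(tree, k)
      solution$asw <- silhouette_width(D, solution$labels)$asw
    }
  }
  say("solution: k = ", solution$k, ", sizes ",
      paste(solution$sizes, collapse = "/"))
  bivariate <- NULL
  stepwise <- NULL
  prepared <- NULL
  if (characterize && !is.null(filtered$covariates)) {
    say("characterization: coding covariates")
    prepared <- prepare_covariates(filtered$covariates, missing_threshold)
    lab <- solution$labels[solution$labels$id %in% prepared$data$id, ]
    bivariate <- bivariate_tests(prepared$data, lab)
    initial <- bivariate$covariate[bivariate$p_value < alpha]
    say("stepwise multinomial model over ", length(initial), " covariates")
    stepwise <- backward_stepwise_aic(prepared$data, lab, initial)
  }
  structure(list(
    cohort = filtered, n_retained = n,
    n_excluded = length(attr(filtered, "excluded_ids")),
    cost_model = cost_model, distance = D, solution = solution,
    prepared = prepared, bivariate = bivariate, stepwise = stepwise,
    settings = list(min_obs = min_obs, method = method, k = k,
                    k_range = k_range, min_frac = min_frac, alpha = alpha,
                    missing_threshold = missing_threshold)
  ), class = "caretraj_run")
}

#' @export
print.caretraj_run <- function(x, ...) {
  cat("<caretraj_run>\n")
  cat("  retained:", x$n_retained, "individuals (",
      x$n_excluded, "excluded by the inclusion filter)\n")
  cat("  clustering:", x$settings$method, "with k =", x$solution$k, "\n")
  cat("  cluster sizes:", paste(x$solution$sizes, collapse = ", "), "\n")
  if (!is.na(x$solution$asw)) {
    cat(sprintf("  average silhouette width: %.3f\n", x$solution$asw))
  }
  if (!is.null(x$stepwise)) {
    cat("  selected covariates:",
        paste(x$stepwise$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.caretraj_run <- function(x, ...) {
  tibble::tibble(
    n_retained = x$n_retained, n_excluded = x$n_excluded,
    method = x$settings$method, k = x$solution$k,
    largest_share = max(x$solution$sizes) / sum(x$solution$sizes),
    asw = x$solution$asw,
    n_selected_covariates =
      if (is.null(x$stepwise)) NA_integer_ else length(x$stepwise$selected)
  )
}

#' Machine-readable report of a pipeline run
#'
#' @param run A `caretraj_run` object.
#' @param path Optional path; when given, the report is written as JSON.
#' @return The report list, invisibly when written to `path`.
#' @export
run_report <- function(run, path = NULL) {
  report <- list(
    n_retained = run$n_retained,
    n_excluded = run$n_excluded,
    method = run$settings$method,
    k = run$solution$k,
    sizes = run$solution$sizes,
    shares = round(run$solution$sizes / sum(run$solution$sizes), 5),
    asw = run$solution$asw,
    asw_curve = if (!is.null(run$solution$curve)) run$solution$curve,
    selected_covariates =
      if (!is.null(run$stepwise)) run$stepwise$selected,
    aic_trace = if (!is.null(run$stepwise)) run$stepwise$trace,
    settings = run$settings[c("min_obs", "method", "min_frac", "alpha",
                              "missing_threshold")]
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(report))
  }
  report
}

#' Match recovered clusters to latent archetypes by majority label
#'
#' For a simulated cohort with known latent archetypes, assigns each
#' recovered cluster the archetype held by the majority of its members,
#' and reports the share of retained individuals per archetype-matched
#' cluster (clusters matched to the same archetype are pooled).
#'
#' @param solution A `cluster_solution`.
#' @param latent Tibble (`id`, `archetype`) of latent labels.
#' @return A list with `matching` (tibble `cluster`, `archetype`,
#'   `size`) and `shares` (named vector: share of individuals in the
#'   cluster(s) matched to each archetype; 0 when unmatched).
#' @export
match_clusters_to_archetypes <- function(solution, latent) {
  labs <- solution$labels
  arch <- latent$archetype[match(labs$id, latent$id)]
  if (anyNA(arch)) stop("latent labels missing for some ids", call. = FALSE)
  matching <- purrr::map_dfr(seq_len(solution$k), function(cl) {
    sub <- arch[labs$cluster == cl]
    tab <- sort(table(sub), decreasing = TRUE)
    tibble::tibble(cluster = cl, archetype = names(tab)[1],
                   size = length(sub))
  })
  n <- nrow(labs)
  shares <- vapply(unique(latent$archetype), function(a) {
    sum(matching$size[matching$archetype == a]) / n
  }, numeric(1))
  list(matching = matching, shares = shares)
}
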