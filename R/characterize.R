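#' Code baseline covariates for modelling, applying the missingness rule
#'
#' Categorical covariates with more than `missing_threshold` of their
#' values missing gain an explicit `"missing"` category (so the
#' missingness itself enters the model); covariates with rarer missing
#' values instead drop the affected individuals from the model sample.
#' Numeric covariates with missing values always drop the affected rows.
#' Categorical covariates become factors whose first observed category is
#' the reference level; `"missing"` is always the last level.
#'
#' @param covariates Tibble with an `id` column plus covariate columns
#'   (character/factor = categorical, numeric = continuous).
#' @param missing_threshold Share of missing values above which an
#'   explicit category is added (default 0.005).
#' @return A list with `data` (coded tibble restricted to retained rows),
#'   `retained_ids`, `dropped_ids` and `coding` (tibble `covariate`,
#'   `type`, `n_missing`, `policy`).
#' @export
prepare_covariates <- function(covariates, missing_threshold = 0.005) {
  stopifnot("id" %in% names(covariates))
  data <- tibble::as_tibble(covariates)
  covs <- setdiff(names(data), "id")
  drop <- rep(FALSE, nrow(data))
  coding <- list()
  for (cov in covs) {
    x <- data[[cov]]
    if (is.numeric(x)) {
      miss <- is.na(x)
      policy <- if (any(miss)) "drop_rows" else "complete"
      drop <- drop | miss
      coding[[cov]] <- tibble::tibble(covariate = cov, type = "numeric",
                                      n_missing = sum(miss), policy = policy)
      next
    }
    x <- as.character(x)
    miss <- is.na(x) | x == ""
    lev <- unique(x[!miss])
    if (length(lev) < 2 && !any(miss)) {
      stop("covariate '", cov, "' has a single category", call. = FALSE)
    }
    if (mean(miss) > missing_threshold && any(miss)) {
      x[miss] <- "missing"
      data[[cov]] <- factor(x, levels = c(lev, "missing"))
      policy <- "missing_category"
    } else {
      drop <- drop | miss
      data[[cov]] <- factor(x, levels = lev)
      policy <- if (any(miss)) "drop_rows" else "complete"
    }
    coding[[cov]] <- tibble::tibble(covariate = cov, type = "categorical",
                                    n_missing = sum(miss), policy = policy)
  }
  retained <- data$id[!drop]
  out <- data[!drop, ]
  for (cov in covs) {
    if (is.factor(out[[cov]]) && nlevels(droplevels(out[[cov]])) < 2) {
      stop("covariate '", cov, "' has a single category after coding",
           call. = FALSE)
    }
  }
  list(data = out, retained_ids = retained, dropped_ids = data$id[drop],
       coding = dplyr::bind_rows(coding))
}

#' Pearson chi-squared test of independence on a contingency table
#'
#' Plain Pearson statistic without continuity correction (the tables of
#' interest here are `k x c` with `k` clusters, where no correction
#' applies).
#'
#' @param counts Matrix of observed counts.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
chi_squared_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  fit <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(test = "chi_squared",
                 statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = unname(fit$p.value))
}

#' One-way fixed-effects ANOVA F test
#'
#' @param groups List of numeric vectors, one per group.
#' @return A one-row tibble: `test`, `statistic`, `df` (between), `df2`
#'   (within), `p_value`.
#' @export
anova_f <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) < 2) {
    stop("ANOVA needs at least two distinct values", call. = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  tibble::tibble(test = "anova_f",
                 statistic = unname(fit$statistic),
                 df = unname(fit$parameter[1]),
                 df2 = unname(fit$parameter[2]),
                 p_value = unname(fit$p.value))
}

#' Bivariate association of every covariate with cluster membership
#'
#' Categorical covariates are tested with Pearson chi-squared tests on
#' the covariate-by-cluster contingency table; numeric covariates (age)
#' with one-way ANOVA across clusters.
#'
#' @param data Coded covariate tibble (see [prepare_covariates()]) with an
#'   `id` column.
#' @param labels Cluster labels: tibble (`id`, `cluster`) or vector
#'   aligned with `data`.
#' @return A tibble with one row per covariate: `covariate`, `test`,
#'   `statistic`, `df`, `df2`, `p_value`.
#' @export
bivariate_tests <- function(data, labels) {
  cl <- align_labels(labels, data$id)
  covs <- setdiff(names(data), "id")
  purrr::map_dfr(covs, function(cov) {
    x <- data[[cov]]
    if (is.numeric(x)) {
      res <- anova_f(split(x, cl))
    } else {
      res <- chi_squared_test(table(droplevels(factor(x)), cl))
      res$df2 <- NA_real_
    }
    dplyr::bind_cols(tibble::tibble(covariate = cov), res)
  })
}

align_labels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    if (!all(ids %in% labels$id)) {
      stop("labels are missing some individuals", call. = FALSE)
    }
    labels$cluster[match(ids, labels$id)]
  } else if (inherits(labels, "cluster_solution")) {
    align_labels(labels$labels, ids)
  } else {
    if (length(labels) != length(ids)) {
      stop("labels do not align with the data", call. = FALSE)
    }
    as.integer(labels)
  }
}

#' Multinomial logistic regression by Newton-Raphson
#'
#' Maximum-likelihood multinomial logit of cluster membership on baseline
#' covariates, with the largest cluster (cluster 1) as the reference
#' outcome. Fitting uses full Newton iterations on the joint coefficient
#' vector with step halving; convergence is declared when the
#' log-likelihood improves by less than `tol`. Standard errors come from
#' the observed information matrix; odds ratios are `exp(beta)` with Wald
#' confidence intervals. Quasi-complete separation — a covariate category
#' with zero observations in some cluster — is detected from the
#' category-by-cluster crosstabs and the affected odds ratios are flagged
#' non-estimable instead of reporting a diverged value.
#'
#' @param data Coded covariate tibble with an `id` column (see
#'   [prepare_covariates()]).
#' @param labels Cluster labels (tibble `id`/`cluster`, vector, or a
#'   `cluster_solution`).
#' @param covariates Covariate columns to include (default: all except
#'   `id`). May be empty for an intercept-only model.
#' @param max_iter,tol Newton iteration cap (default 200) and
#'   log-likelihood convergence tolerance (default 1e-8).
#' @return An object of class `multinom_fit` with coefficient and
#'   standard-error matrices, log-likelihood, AIC and separation flags.
#'   Use [tidy()] for the odds-ratio table and [glance()] for fit
#'   statistics.
#' @export
fit_multinomial <- function(data, labels, covariates = NULL,
                            max_iter = 200L, tol = 1e-8) {
  cl <- align_labels(labels, data$id)
  if (is.null(covariates)) covariates <- setdiff(names(data), "id")
  classes <- sort(unique(cl))
  K <- length(classes)
  if (K < 2) stop("need at least two clusters", call. = FALSE)
  y <- match(cl, classes)               # 1 = reference (largest cluster)
  mf <- as.data.frame(data[, covariates, drop = FALSE])
  mf <- droplevels(mf)
  X <- if (length(covariates) == 0) {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., mf)
  }
  n <- nrow(X)
  p <- ncol(X)
  npar <- p * (K - 1)

  Y <- matrix(0, n, K - 1)
  for (k in 2:K) Y[, k - 1] <- as.numeric(y == k)

  B <- matrix(0, p, K - 1)
  loglik <- function(B) {
    eta <- X %*% B                       # n x (K-1)
    m <- pmax(apply(eta, 1, max), 0)
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum((eta * Y)) - sum(lse)
  }
  probs <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    exp(eta - m) / denom                 # n x (K-1), non-reference classes
  }
  ll <- loglik(B)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    P <- probs(B)
    grad <- as.vector(crossprod(X, Y - P))
    H <- matrix(0, npar, npar)
    for (k in seq_len(K - 1)) {
      for (l in seq_len(k)) {
        w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        blk <- crossprod(X, X * w)
        ri <- (k - 1) * p + seq_len(p)
        ci <- (l - 1) * p + seq_len(p)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(H, grad),
                     error = function(e) solve(H + diag(1e-8, npar), grad))
    new_B <- B
    alpha <- 1
    repeat {
      cand <- B + alpha * matrix(step, p, K - 1)
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        new_B <- cand
        break
      }
      alpha <- alpha / 2
      if (alpha < 1e-10) {
        ll_new <- ll
        break
      }
    }
    delta <- ll_new - ll
    B <- new_B
    ll <- ll_new
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("multinomial fit did not converge in ", max_iter,
         " iterations (last log-likelihood ", format(ll), ")", call. = FALSE)
  }

  P <- probs(B)
  H <- matrix(0, npar, npar)
  for (k in seq_len(K - 1)) {
    for (l in seq_len(k)) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      blk <- crossprod(X, X * w)
      ri <- (k - 1) * p + seq_len(p)
      ci <- (l - 1) * p + seq_len(p)
      H[ri, ci] <- blk
      H[ci, ri] <- t(blk)
    }
  }
  cov_B <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  SE <- matrix(sqrt(pmax(diag(cov_B), 0)), p, K - 1)
  dimnames(B) <- dimnames(SE) <-
    list(colnames(X), paste0("cluster", classes[-1]))

  separation <- detect_separation(mf, cl, classes)
  aic <- -2 * ll + 2 * npar
  structure(list(
    coefficients = B, se = SE, logLik = ll, AIC = aic, n = n,
    classes = classes, reference = classes[1], covariates = covariates,
    xlevels = lapply(Filter(is.factor, mf), levels),
    separation = separation, iter = iter, converged = converged
  ), class = "multinom_fit")
}

# zero (cluster, category) cells make the corresponding log odds diverge
detect_separation <- function(mf, cl, classes) {
  flags <- list()
  for (cov in names(mf)) {
    if (!is.factor(mf[[cov]])) next
    tab <- table(mf[[cov]], factor(cl, levels = classes))
    zero <- which(tab == 0, arr.ind = TRUE)
    if (nrow(zero) > 0) {
      flags[[cov]] <- tibble::tibble(
        covariate = cov,
        category = rownames(tab)[zero[, 1]],
        cluster = classes[zero[, 2]],
        term = paste0(cov, rownames(tab)[zero[, 1]])
      )
    }
  }
  if (length(flags) == 0) {
    tibble::tibble(covariate = character(), category = character(),
                   cluster = integer(), term = character())
  } else {
    dplyr::bind_rows(flags)
  }
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("<multinom_fit> ", length(x$classes), " clusters (reference: cluster ",
      x$reference, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("logLik = %.3f, AIC = %.3f, %d Newton iterations\n",
              x$logLik, x$AIC, x$iter))
  if (nrow(x$separation) > 0) {
    cat("quasi-complete separation flagged for ", nrow(x$separation),
        " (cluster, category) cells\n", sep = "")
  }
  invisible(x)
}

#' @rdname fit_multinomial
#' @param x A `multinom_fit` object.
#' @param conf_level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @export
tidy.multinom_fit <- function(x, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- purrr::map_dfr(seq_along(colnames(x$coefficients)), function(j) {
    cl <- x$classes[-1][j]
    tibble::tibble(
      cluster = cl,
      term = rownames(x$coefficients),
      estimate = x$coefficients[, j],
      std.error = x$se[, j]
    )
  })
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * pnorm(-abs(out$statistic))
  out$or <- exp(out$estimate)
  out$conf.low <- exp(out$estimate - z * out$std.error)
  out$conf.high <- exp(out$estimate + z * out$std.error)
  flagged <- rep(FALSE, nrow(out))
  for (r in seq_len(nrow(x$separation))) {
    cov <- x$separation$covariate[r]
    cat <- x$separation$category[r]
    cl <- x$separation$cluster[r]
    cov_terms <- paste0(cov, x$xlevels[[cov]])
    if (cl == x$reference) {
      # empty cell in the reference cluster: the category's log odds
      # diverge for every contrast
      flagged <- flagged | out$term == paste0(cov, cat)
    } else if (cat == x$xlevels[[cov]][1]) {
      # reference category empty in this cluster: the whole covariate
      # block for this cluster diverges
      flagged <- flagged | (out$cluster == cl & out$term %in% cov_terms)
    } else {
      flagged <- flagged | (out$cluster == cl & out$term == paste0(cov, cat))
    }
  }
  out$nonestimable <- flagged
  out[flagged, c("estimate", "std.error", "statistic", "p.value",
                 "or", "conf.low", "conf.high")] <- NA_real_
  out
}

#' @rdname fit_multinomial
#' @export
glance.multinom_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, k = length(x$classes),
    npar = length(x$coefficients),
    logLik = x$logLik, AIC = x$AIC,
    iter = x$iter, converged = x$converged
  )
}

#' Backward stepwise covariate selection by AIC
#'
#' Starting from the supplied covariates (conventionally those
#' significant at `p < 0.05` in the bivariate screen), repeatedly refits
#' the multinomial model dropping each remaining covariate in turn — a
#' covariate leaves with all of its dummy columns at once — and removes
#' the covariate whose deletion gives the lowest AIC, as long as that
#' improves on the current model's AIC. Stops when no removal improves
#' the criterion. Deterministic.
#'
#' @inheritParams fit_multinomial
#' @param covariates Initial covariate set; an empty set returns the
#'   intercept-only model.
#' @return A list with `model` (the final `multinom_fit`), `selected`
#'   (retained covariates) and `trace` (tibble of AIC per step).
#' @export
backward_stepwise_aic <- function(data, labels, covariates,
                                  max_iter = 200L, tol = 1e-8) {
  current <- covariates
  model <- fit_multinomial(data, labels, current, max_iter, tol)
  trace <- tibble::tibble(step = 0L, action = "initial",
                          covariate = NA_character_, AIC = model$AIC)
  step <- 0L
  while (length(current) > 0) {
    fits <- purrr::map(current, function(cov) {
      fit_multinomial(data, labels, setdiff(current, cov), max_iter, tol)
    })
    aics <- vapply(fits, function(f) f$AIC, numeric(1))
    best <- which.min(aics)
    if (aics[best] < model$AIC) {
      step <- step + 1L
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step, action = "drop", covariate = current[best],
        AIC = aics[best]
      ))
      current <- setdiff(current, current[best])
      model <- fits[[best]]
    } else {
      break
    }
  }
  list(model = model, selected = current, trace = trace)
}
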