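test_that("covariate coding applies the 0.5% missingness rule", {
  n <- 1000
  covs <- tibble::tibble(
    id = as.character(1:n),
    frequent_missing = c(rep(NA, 30), rep(c("yes", "no"), length.out = n - 30)),
    rare_missing = c(rep(NA, 2), rep(c("a", "b"), length.out = n - 2)),
    age = stats::runif(n, 65, 70)
  )
  prep <- prepare_covariates(covs, missing_threshold = 0.005)
  # 3% missing -> explicit category, no rows dropped for it
  expect_true("missing" %in% levels(prep$data$frequent_missing))
  # 0.2% missing -> those rows excluded
  expect_equal(length(prep$dropped_ids), 2)
  expect_false("missing" %in% levels(prep$data$rare_missing))
  expect_equal(nrow(prep$data), n - 2)

  # no missing anywhere: identity passthrough of rows
  clean <- tibble::tibble(id = as.character(1:20),
                          sex = rep(c("f", "m"), 10))
  prep2 <- prepare_covariates(clean)
  expect_equal(nrow(prep2$data), 20)
  expect_equal(length(prep2$dropped_ids), 0)

  # degenerate covariate
  bad <- tibble::tibble(id = as.character(1:10), cst = rep("x", 10))
  expect_error(prepare_covariates(bad), "single category")
})

test_that("chi-squared test matches the closed form on a 2x2 table", {
  res <- chi_squared_test(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, stats::pchisq(20, 1, lower.tail = FALSE))

  # independence: identical rows
  flat <- chi_squared_test(matrix(c(5, 10, 5, 10), 2, byrow = TRUE))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # Pearson statistic scales linearly with counts
  a <- chi_squared_test(matrix(c(12, 7, 9, 14), 2))$statistic
  b <- chi_squared_test(10 * matrix(c(12, 7, 9, 14), 2))$statistic
  expect_equal(b, 10 * a)

  expect_error(chi_squared_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero marginal")
})

test_that("one-way ANOVA matches the hand-computed toy", {
  res <- anova_f(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df, 1)
  expect_equal(res$df2, 4)

  # equal group means
  expect_lt(anova_f(list(c(1, 3), c(2, 2)))$statistic, 1e-12)

  # permuting values within groups leaves F unchanged
  g <- list(c(3, 1, 2), c(6, 4, 5))
  expect_equal(anova_f(g)$statistic, 13.5)

  expect_error(anova_f(list(c(1, 1), c(1, 1))), "distinct")
})

test_that("bivariate screen dispatches on covariate type", {
  set.seed(1)
  n <- 300
  dat <- tibble::tibble(
    id = as.character(1:n),
    sex = sample(c("f", "m"), n, TRUE),
    age = stats::rnorm(n, 68)
  )
  labels <- tibble::tibble(id = dat$id, cluster = sample(1:3, n, TRUE))
  res <- bivariate_tests(dat, labels)
  expect_equal(res$test[res$covariate == "sex"], "chi_squared")
  expect_equal(res$test[res$covariate == "age"], "anova_f")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("intercept-only multinomial recovers log count ratios exactly", {
  labs <- rep(1:3, times = c(80, 15, 5))
  dat <- tibble::tibble(id = as.character(seq_along(labs)))
  fit <- fit_multinomial(dat, labs, covariates = character(0))
  expect_equal(unname(fit$coefficients[1, ]),
               c(log(15 / 80), log(5 / 80)), tolerance = 1e-8)
  # predicted shares at the MLE equal observed shares
  g <- glance(fit)
  expect_true(g$converged)
  p2 <- exp(fit$coefficients[1, 1]) /
    (1 + sum(exp(fit$coefficients[1, ])))
  expect_equal(p2, 15 / 100, tolerance = 1e-8)
})

test_that("two-cluster multinomial reduces to binary logistic regression", {
  set.seed(6)
  n <- 500
  x <- stats::rnorm(n)
  grp <- sample(c("a", "b"), n, TRUE)
  eta <- -0.5 + 1.2 * x + 0.8 * (grp == "b")
  y <- stats::rbinom(n, 1, stats::plogis(eta)) + 1L
  dat <- tibble::tibble(id = as.character(1:n), x = x, grp = grp)
  fit <- fit_multinomial(dat, y, tol = 1e-12)
  ref <- stats::glm(I(y == 2) ~ x + grp, family = stats::binomial(),
                    control = list(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients[, 1]), unname(stats::coef(ref)),
               tolerance = 1e-6)
  # standard errors from the observed information agree too
  expect_equal(unname(fit$se[, 1]),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("multinomial fit agrees with an independent nnet fit", {
  set.seed(13)
  n <- 600
  x <- stats::rnorm(n)
  sexf <- sample(c(0, 1), n, TRUE)
  lp2 <- -1.5 + 0.9 * x
  lp3 <- -2 + 1.5 * sexf
  den <- 1 + exp(lp2) + exp(lp3)
  u <- stats::runif(n)
  y <- ifelse(u < exp(lp2) / den, 2, ifelse(u < (exp(lp2) + exp(lp3)) / den,
                                            3, 1))
  dat <- tibble::tibble(id = as.character(1:n), x = x,
                        sex = ifelse(sexf == 1, "f", "m"))
  fit <- fit_multinomial(dat, y)
  ref <- nnet::multinom(factor(y) ~ x + sex, data = dat, trace = FALSE,
                        reltol = 1e-12, maxit = 500)
  expect_equal(unname(fit$coefficients),
               unname(t(stats::coef(ref))), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(fit$AIC, stats::AIC(ref), tolerance = 1e-5)
})

test_that("fitted class probabilities sum to one for every individual", {
  set.seed(9)
  n <- 200
  dat <- tibble::tibble(id = as.character(1:n), x = stats::rnorm(n))
  y <- sample(1:3, n, TRUE)
  fit <- fit_multinomial(dat, y)
  eta <- cbind(1, dat$x) %*% fit$coefficients
  p <- cbind(1, exp(eta)) / (1 + rowSums(exp(eta)))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
})

test_that("quasi-complete separation is flagged non-estimable", {
  set.seed(4)
  n <- 300
  grp <- sample(c("low", "high"), n, TRUE)
  y <- ifelse(grp == "high", sample(c(1, 2), n, TRUE),
              sample(c(1, 2, 3), n, TRUE))
  # cluster 3 never occurs with grp == "high": zero cell
  dat <- tibble::tibble(id = as.character(1:n),
                        grp = factor(grp, levels = c("low", "high")))
  fit <- fit_multinomial(dat, y)
  expect_gt(nrow(fit$separation), 0)
  td <- tidy(fit)
  flagged <- td[td$nonestimable, ]
  expect_gt(nrow(flagged), 0)
  expect_true(all(is.na(flagged$or)))
  # unflagged rows carry finite odds ratios and Wald intervals
  okrows <- td[!td$nonestimable, ]
  expect_true(all(is.finite(okrows$or)))
  expect_true(all(okrows$conf.low <= okrows$or & okrows$or <= okrows$conf.high))
})

test_that("backward stepwise drops noise and keeps signal", {
  set.seed(27)
  n <- 2000
  strong <- sample(c("no", "yes"), n, TRUE)
  noise <- sample(c("u", "v"), n, TRUE)
  lp2 <- -2.2 + log(5) * (strong == "yes")
  den <- 1 + exp(lp2)
  y <- ifelse(stats::runif(n) < exp(lp2) / den, 2, 1)
  dat <- tibble::tibble(id = as.character(1:n), strong = strong, noise = noise)
  res <- backward_stepwise_aic(dat, y, c("strong", "noise"))
  expect_true("strong" %in% res$selected)
  expect_false("noise" %in% res$selected)
  expect_lte(res$model$AIC, res$trace$AIC[1])

  # empty initial set: intercept-only model
  res0 <- backward_stepwise_aic(dat, y, character(0))
  expect_equal(nrow(res0$model$coefficients), 1)
})

test_that("synthetic covariates reproduce the published association signs", {
  set.seed(33)
  cfg <- default_generator_config()
  arch <- sample(names(cfg$archetypes), 4000, replace = TRUE,
                 prob = c(0.7, 0.06, 0.06, 0.06, 0.06, 0.06))
  covs <- simulate_covariates(arch, cfg$covariates)
  dat <- tibble::tibble(id = covs$id,
                        sex = factor(covs$sex, levels = c("female", "male")))
  labels <- match(arch, c("LHU", "IHU", "LHD", "AC2NH", "EFE", "HAC"))
  fit <- fit_multinomial(dat, labels)
  td <- tidy(fit)
  # reference category is female: male lowers the odds of the
  # high-ambulatory cluster (6) and raises those of the early-death
  # cluster (5)
  expect_lt(td$estimate[td$cluster == 6 & td$term == "sexmale"], 0)
  expect_gt(td$estimate[td$cluster == 5 & td$term == "sexmale"], 0)
})
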