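test_that("default cost model encodes the missing-state conventions", {
  cm <- build_cost_model()
  hc <- cm$channels$homecare
  # death furthest from no utilization; normalized maximum 2
  expect_equal(hc$sub["none", "DEAD"], 2)
  expect_equal(max(hc$sub), 2)
  # incapacity equivalent to the highest utilization level
  expect_equal(hc$sub["regular", "INCAP"], 0)
  expect_equal(hc$sub["none", "INCAP"], hc$sub["none", "regular"])
  # ordinal costs 2|dpos|/K
  expect_equal(hc$sub["none", "temporary"], 2 / 3)
  expect_equal(hc$sub["none", "regular"], 4 / 3)
  # indel = half the maximum substitution cost
  expect_equal(hc$indel, 1)
  # nonresponse equidistant at the indel cost
  nr <- hc$sub["NR", setdiff(colnames(hc$sub), "NR")]
  expect_true(all(nr == hc$indel))
  # symmetry, zero diagonal on every channel
  for (m in cm$channels) {
    expect_true(isSymmetric(unname(m$sub)))
    expect_true(all(diag(m$sub) == 0))
    expect_equal(m$indel, max(m$sub) / 2)
  }
})

test_that("user substitution overrides are validated", {
  specs <- default_channel_specs()
  cm <- build_cost_model(specs)
  bad <- cm$channels$homecare$sub
  bad[1, 2] <- 5  # breaks symmetry
  expect_error(build_cost_model(specs, substitution = list(homecare = bad)),
               "symmetric")
  ok <- cm$channels$homecare$sub * 3
  cm2 <- build_cost_model(specs, substitution = list(homecare = ok))
  expect_equal(cm2$channels$homecare$indel, 3)
})

test_that("om_distance reproduces hand-derived values", {
  cm <- build_cost_model()
  hc <- cm$channels$homecare
  lv <- c("none", "temporary", "regular")

  expect_equal(om_distance(lv, lv, hc$sub), 0)
  expect_equal(om_distance(character(0), rep("none", 5), hc$sub, indel = 1), 5)
  # single substitution beats delete+insert
  expect_equal(om_distance(c("none", "none", "none"),
                           c("none", "none", "regular"), hc$sub), 4 / 3)
  # one deletion + one insertion realigns an alternating pair
  expect_equal(om_distance(c("none", "regular", "none", "regular", "none"),
                           c("regular", "none", "regular", "none", "regular"),
                           hc$sub), 2)
  expect_error(om_distance(c("none", "never"), lv, hc$sub), "unknown state")
})

test_that("om_distance agrees with the brute-force alignment oracle", {
  cm <- build_cost_model()
  sub <- cm$channels$ambulatory$sub[1:4, 1:4]  # 4 ordinal levels
  lv <- rownames(sub)
  set.seed(31)
  for (i in 1:300) {
    a <- sample(lv, sample(1:4, 1), replace = TRUE)
    b <- sample(lv, sample(1:4, 1), replace = TRUE)
    expect_equal(om_distance(a, b, sub, 1), om_bruteforce(a, b, sub, 1))
  }
})

test_that("om_distance is symmetric and bounded by pure indels", {
  cm <- build_cost_model()
  sub <- cm$channels$emergency$sub
  lv <- rownames(sub)
  set.seed(7)
  for (i in 1:50) {
    a <- sample(lv, sample(2:8, 1), replace = TRUE)
    b <- sample(lv, sample(2:8, 1), replace = TRUE)
    d <- om_distance(a, b, sub, 1)
    expect_equal(d, om_distance(b, a, sub, 1))
    expect_lte(d, (length(a) + length(b)) * 1)
    expect_gte(d, 0)
  }
})

test_that("raising a substitution cost never shrinks a distance", {
  cm <- build_cost_model()
  sub <- cm$channels$homecare$sub
  lv <- rownames(sub)[1:3]
  set.seed(12)
  for (i in 1:30) {
    a <- sample(lv, 6, replace = TRUE)
    b <- sample(lv, 6, replace = TRUE)
    sub2 <- sub
    sub2["none", "temporary"] <- sub2["temporary", "none"] <- 1.1
    expect_gte(om_distance(a, b, sub2, 1), om_distance(a, b, sub, 1) - 1e-12)
  }
})

test_that("multichannel distance pools channels and reduces to one channel", {
  specs2 <- tibble::tibble(
    channel = rep(c("c1", "c2"), each = 3),
    level = rep(c("none", "mid", "top"), 2),
    position = rep(0:2, 2)
  )
  cm2 <- build_cost_model(specs2)
  x <- data.frame(c1 = rep("none", 3), c2 = rep("none", 3))
  expect_equal(multichannel_distance(x, x, cm2), 0)
  # both channels jump two ordinal steps at one position:
  # pooled substitution 4/3 + 4/3 beats pooled indel pair 2 + 2
  y <- x
  y$c1[2] <- "top"
  y$c2[2] <- "top"
  expect_equal(multichannel_distance(x, y, cm2), 8 / 3)

  # single-channel reduction: identical to om_distance
  cm <- build_cost_model()
  specs1 <- default_channel_specs()
  specs1 <- specs1[specs1$channel == "homecare", ]
  cm1 <- build_cost_model(specs1)
  hc <- cm$channels$homecare
  lv <- rownames(hc$sub)
  set.seed(3)
  for (i in 1:200) {
    a <- sample(lv, 5, replace = TRUE)
    b <- sample(lv, 5, replace = TRUE)
    # overlay consistency not required for the arithmetic check
    expect_equal(
      multichannel_distance(data.frame(homecare = a),
                            data.frame(homecare = b), cm1),
      om_distance(a, b, hc$sub, hc$indel)
    )
  }
})

test_that("doubling all channel weights doubles all distances", {
  sim <- simulate_cohort(n_raw = 40, seed = 21)
  f <- filter_min_observations(sim)
  specs <- default_channel_specs()
  w1 <- setNames(rep(1, 5), channel_names(specs))
  D1 <- pairwise_distance_matrix(f, build_cost_model(specs, weights = w1))
  D2 <- pairwise_distance_matrix(f, build_cost_model(specs, weights = 2 * w1))
  expect_equal(D2, 2 * D1)
})

test_that("pairwise matrix is symmetric, zero-diagonal and matches per-pair DP", {
  sim <- simulate_cohort(n_raw = 60, seed = 14)
  f <- filter_min_observations(sim)
  cm <- build_cost_model()
  D <- pairwise_distance_matrix(f, cm)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  # spot-check against the two-sequence entry point
  st <- dplyr::arrange(f$states, id, wave)
  ids <- rownames(D)
  set.seed(2)
  for (i in 1:10) {
    pair <- sample(ids, 2)
    x <- st[st$id == pair[1], ]
    y <- st[st$id == pair[2], ]
    expect_equal(D[pair[1], pair[2]], multichannel_distance(x, y, cm))
  }
  # 1x1 case
  one <- cohort(f$states[f$states$id == ids[1], ])
  expect_equal(unname(pairwise_distance_matrix(one, cm)), matrix(0, 1, 1))
})
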