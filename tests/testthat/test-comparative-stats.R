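test_that("randomization p matches exact enumeration at n = 4", {
  # full enumeration of the 24 permutations gives p = 11/24 for these data
  x <- c(1.3, 0.2, -0.7, 2.1)
  y <- c(0.5, 1.1, -0.2, 0.9)
  exact <- 11 / 24
  res <- randomization_correlation(x, y, B = 20000, seed = 1)
  mc_se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(res$p - exact), 4 * mc_se)
  expect_equal(res$statistic, cor(x, y))
})

test_that("a perfect monotone association reaches the attainable minimum", {
  x <- 1:10
  res <- randomization_correlation(x, x, B = 10000, seed = 2)
  # only the identity and the reversal give |r| = 1 among 10! orderings
  expect_lt(res$p, 0.005)
  expect_gte(res$p, 1 / 10001)
})

test_that("randomization p-values respect their invariants", {
  set.seed(5)
  x <- rnorm(8); y <- rnorm(8)
  r1 <- randomization_correlation(x, y, B = 500, seed = 10)
  r2 <- randomization_correlation(x, y, B = 500, seed = 10)
  expect_identical(r1$p, r2$p)          # same seed, same p
  expect_gte(r1$p, 1 / 501)
  expect_lte(r1$p, 1)
  # a different seed moves p only within binomial MC error
  r3 <- randomization_correlation(x, y, B = 5000, seed = 11)
  r4 <- randomization_correlation(x, y, B = 5000, seed = 12)
  se <- sqrt(r3$p * (1 - r3$p) / 5000)
  expect_lt(abs(r3$p - r4$p), 6 * se + 2 / 5000)
  expect_error(randomization_correlation(x, rep(1, 8), B = 10, seed = 1),
               "zero variance")
  expect_error(randomization_correlation(x, y, B = 10), "seed")
})

test_that("two-stage guard reduces to plain randomization for equal GSIs", {
  set.seed(6)
  growth <- exp(rnorm(10, 3, 0.5))
  mort <- runif(10)
  gsi <- rep(0.2, 10)
  ts <- two_stage_randomization(growth, mort, gsi, B = 3000, seed = 30)
  pl <- randomization_correlation(1 / growth, mort, B = 3000, seed = 30)
  expect_equal(ts$statistic, pl$statistic, tolerance = 1e-12)
  # same null distribution (the guard permutes growth, the plain test
  # permutes mortality): p-values agree within Monte Carlo error
  se <- sqrt(pl$p * (1 - pl$p) / 3000)
  expect_lt(abs(ts$p - pl$p), 5 * se)
})

test_that("two-stage guard detects coupling beyond the growth artifact", {
  # gsi rises with mortality on top of the 1/growth artifact: the guard
  # must reject often at this effect size
  set.seed(7)
  hits <- 0
  for (s in 1:20) {
    mort <- seq(0.05, 0.4, length.out = 10)
    growth <- exp(4 - 3 * mort + rnorm(10, 0, 0.2))
    gsi <- 0.1 + 0.5 * mort + rnorm(10, 0, 0.01)
    ts <- two_stage_randomization(growth, mort, gsi, B = 1000, seed = s)
    if (ts$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits, 12)
})

test_that("standard major axis has the closed-form slope", {
  x <- c(1, 2, 3, 4, 5)
  fit <- sma_fit(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r, 1)

  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, -0.5 * x)
    fit <- sma_fit(x, y)
    expect_equal(abs(fit$slope), sd(y) / sd(x), tolerance = 1e-12)
    expect_equal(sign(fit$slope), sign(cor(x, y)))
    # |SMA| >= |OLS| whenever |r| < 1
    ols <- cor(x, y) * sd(y) / sd(x)
    expect_gte(abs(fit$slope), abs(ols))
    # symmetric up to inversion on standardized axes
    xs <- scale(x)[, 1]; ys <- scale(y)[, 1]
    expect_equal(abs(sma_fit(xs, ys)$slope),
                 1 / abs(sma_fit(ys, xs)$slope), tolerance = 1e-10)
  }
  expect_error(sma_fit(x, rep(3, 12)), "zero variance")
})

test_that("regression through the origin matches the sum formulas", {
  x <- c(1, 2, 3)
  res <- regression_through_origin(x, 3 * x)
  expect_equal(res$slope, 3)
  expect_equal(res$df, 2)
  expect_true(is.infinite(res$t))

  # df = n - 1: nine contrast pairs give t with 8 df
  set.seed(9)
  x9 <- rnorm(9); y9 <- rnorm(9)
  res9 <- regression_through_origin(x9, y9)
  expect_equal(res9$df, 8)
  # independent oracle: R's no-intercept lm
  lmfit <- summary(lm(y9 ~ x9 - 1))
  expect_equal(res9$slope, unname(coef(lmfit)[1, 1]), tolerance = 1e-10)
  expect_equal(res9$t, unname(coef(lmfit)[1, 3]), tolerance = 1e-10)
  expect_equal(res9$p, unname(coef(lmfit)[1, 4]), tolerance = 1e-10)
  expect_error(regression_through_origin(rep(0, 5), rnorm(5)), "sum")
})

test_that("plasticity F-test reports the joint risk-slope test", {
  set.seed(14)
  # 10 groups x 10 sites, no true risk effect -> numerator df = 10
  st <- expand.grid(group = paste0("g", 1:10), site = paste0("s", 1:10),
                    stringsAsFactors = FALSE)
  st$risk <- runif(nrow(st))
  st$mean_growth <- rnorm(nrow(st), 20 + as.integer(factor(st$group)))
  res <- plasticity_test(st)
  expect_equal(res$df1, 10)
  expect_equal(res$df2, nrow(st) - 2 * 10)
  expect_gt(res$p, 1e-4)

  # a genuine within-group decline with risk is detected
  st2 <- st
  st2$mean_growth <- 25 - 12 * st2$risk + rnorm(nrow(st2), 0, 0.5)
  expect_lt(plasticity_test(st2)$p, 1e-6)

  # single-site groups are dropped with a warning
  st3 <- rbind(st, data.frame(group = "lonely", site = "s1", risk = 0.2,
                              mean_growth = 11))
  expect_warning(res3 <- plasticity_test(st3), "lonely")
  expect_false("lonely" %in% res3$groups)
})

test_that("site-level growth-risk table uses dominant prevalence as risk", {
  w <- generate_world(default_world_config(n_per_site = 60), seed = 27)
  dat <- apply_filters(prepare_growth_data(w$records))$records
  st <- site_growth_risk(dat, w$config$hierarchy)
  expect_true(all(c("group", "site", "mean_growth", "risk") %in% names(st)))
  expect_true(all(st$risk >= 0 & st$risk <= 1))
  # the top-ranked species has no dominants: its local risk is zero
  expect_true(all(st$risk[st$group == "hima"] == 0))
  # uninfected snails: risk is overall trematode prevalence, positive here
  expect_true(all(st$risk[st$group %in% c("male", "female")] > 0))
})
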