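test_that("group effects equal log mean ratios (Poisson GLM identity)", {
  rec <- make_growth_records(group = rep(c("a", "b"), each = 30),
                             growth = rep(c(2, 8), each = 30),
                             initial_volume = 500)
  fit <- fit_growth(rec)
  expect_equal(unname(coef(fit$glm)[["groupb"]]), log(4), tolerance = 1e-8)
  expect_equal(unname(coef(fit$glm)[["(Intercept)"]]), log(2),
               tolerance = 1e-8)
  # residual-free fit: dispersion collapses to zero
  expect_lt(fit$dispersion, 1e-12)
})

test_that("an intercept-only fit returns log of the constant response", {
  rec <- make_growth_records(group = rep("a", 20),
                             growth = rep(7, 20), initial_volume = 500)
  fit <- fit_growth(rec)
  expect_equal(unname(coef(fit$glm)[["(Intercept)"]]), log(7),
               tolerance = 1e-10)
})

test_that("ten groups yield a species term with 9 degrees of freedom", {
  set.seed(30)
  groups <- c(paste0("sp", 1:8), "male", "female")
  rec <- make_growth_records(group = rep(groups, each = 25),
                             growth = rpois(250, 12),
                             initial_volume = runif(250, 100, 2000))
  fit <- fit_growth(rec)
  expect_equal(fit$terms$df[fit$terms$term == "group"], 9)
  expect_equal(fit$terms$df[fit$terms$term == "group:initial_volume"], 9)
})

test_that("quasi-Poisson point estimates equal plain Poisson ML", {
  w <- generate_world(default_world_config(n_per_site = 30), seed = 17)
  dat <- apply_filters(prepare_growth_data(w$records))$records
  fq <- fit_growth(dat, family = "quasipoisson")
  # growth recomputed from rounded shell measurements is non-integer;
  # the Poisson refit is only used for the coefficient-identity check
  fp <- suppressWarnings(fit_growth(dat, family = "poisson"))
  expect_equal(coef(fq$glm), coef(fp$glm), tolerance = 1e-10)
  # only the uncertainties scale, by sqrt(dispersion)
  expect_gt(fq$dispersion, 1)
  se_q <- sqrt(diag(vcov(fq$glm)))
  se_p <- sqrt(diag(vcov(fp$glm)))
  est <- !is.na(se_q) & !is.na(se_p)   # aliased nesting dummies excluded
  expect_equal(unname(se_q[est] / se_p[est]),
               rep(sqrt(fq$dispersion), sum(est)), tolerance = 1e-5)
})

test_that("dispersion estimates track the generating factor", {
  for (phi in c(1, 4)) {
    cfg <- recovery_config(phi = phi, n_per_site = 2000, seed = 31 + phi)
    w <- generate_world(cfg)
    fit <- fit_growth(prepare_growth_data(w$records))
    expect_equal(fit$dispersion, phi, tolerance = 0.15)
  }
})

test_that("growth curves respect slope sign and sampled domains", {
  # exact exp-linear data: the two-parameter fit recovers it exactly
  v <- seq(100, 2000, length.out = 60)
  rec <- make_growth_records(group = rep("a", 60),
                             growth = exp(3.5 - 6e-4 * v),
                             initial_volume = v)
  fit <- fit_growth(rec)
  cu <- growth_curve(fit, "a")
  expect_equal(cu$f(705), exp(3.5 - 6e-4 * 705), tolerance = 1e-6)
  # negative size slope: monotonically decreasing curve
  grid <- cu$f(seq(150, 1900, length.out = 20))
  expect_true(all(diff(grid) < 0))
  expect_error(cu$f(5000), "pooled sampled range")
  expect_error(growth_curve(fit, "nope"), "not present")

  # flat group: constant curve equal to exp(intercept)
  rec2 <- make_growth_records(group = rep("b", 40), growth = rep(11, 40),
                              initial_volume = seq(100, 2000, length.out = 40))
  fit2 <- fit_growth(rec2)
  cu2 <- growth_curve(fit2, "b")
  expect_equal(cu2$f(400), 11, tolerance = 1e-6)
  expect_equal(cu2$f(1500), cu2$f(300), tolerance = 1e-6)
  expect_equal(growth_at_mean_size(fit2, "b", 800), cu2$f(800))
})

test_that("total growth allocation matches closed-form integrals", {
  # constant curve c on [a, b] integrates to c (b - a)
  rec <- make_growth_records(group = rep("b", 40), growth = rep(11, 40),
                             initial_volume = seq(100, 2000, length.out = 40))
  cu <- growth_curve(fit_growth(rec), "b")
  expect_equal(total_growth_allocation(cu, 200, 1200), 11 * 1000,
               tolerance = 1e-6)

  # exp-linear curve vs the analytic antiderivative
  v <- seq(100, 2000, length.out = 60)
  rec2 <- make_growth_records(group = rep("a", 60),
                              growth = exp(3.5 - 6e-4 * v),
                              initial_volume = v)
  cu2 <- growth_curve(fit_growth(rec2), "a")
  a <- 3.5; b <- -6e-4
  analytic <- (exp(a + b * 1800) - exp(a + b * 200)) / b
  expect_equal(total_growth_allocation(cu2, 200, 1800), analytic,
               tolerance = 1e-5)
  expect_error(total_growth_allocation(cu2, 1800, 200), "inverted")
})

test_that("synthetic growth coefficients are recovered within their CIs", {
  cfg <- recovery_config(phi = 4, n_per_site = 1500, seed = 40)
  w <- generate_world(cfg)
  fit <- fit_growth(prepare_growth_data(w$records))
  co <- coef(fit$glm)
  se <- sqrt(diag(vcov(fit$glm)))
  gp <- cfg$growth_params
  int <- setNames(gp$intercept, gp$group)
  slo <- setNames(gp$slope, gp$group)
  truth <- c("(Intercept)" = unname(int["female"]),
             "groupmale" = unname(int["male"] - int["female"]),
             "groupsp1" = unname(int["sp1"] - int["female"]),
             "initial_volume" = unname(slo["female"]),
             "groupmale:initial_volume" = unname(slo["male"] - slo["female"]),
             "groupsp1:initial_volume" = unname(slo["sp1"] - slo["female"]))
  z <- abs(co[names(truth)] - truth) / se[names(truth)]
  expect_true(all(z < 3.5))
})

test_that("pairwise contrasts count C(k,2) and control the FDR", {
  set.seed(50)
  groups <- c(paste0("sp", 1:8), "male", "female")
  mu <- setNames(seq(5, 50, length.out = 10), groups)
  g <- rep(groups, each = 40)
  rec <- make_growth_records(group = g, growth = rpois(400, mu[g]),
                             initial_volume = runif(400, 100, 2000))
  fit <- fit_growth(rec)
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 45)
  expect_true(all(ct$p_bh >= ct$p))
  expect_identical(ct$significant_fdr, ct$p_bh <= 0.05)
  # extreme mean difference must survive FDR control
  row <- ct$group1 == "sp1" & ct$group2 == "sp8" |
    ct$group1 == "sp8" & ct$group2 == "sp1"
  expect_true(ct$significant_fdr[row])
})

test_that("identical groups give a near-zero contrast with p near 1", {
  rec <- make_growth_records(group = rep(c("a", "b"), each = 50),
                             growth = rep(c(9, 9), each = 50),
                             initial_volume = 500)
  # add tiny jitter so dispersion is non-degenerate
  set.seed(3)
  rec$growth <- rpois(100, 9)
  fit <- fit_growth(rec)
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), 1)
  expect_lt(abs(ct$log_difference), 0.5)
  expect_gt(ct$p, 0.05)
})

test_that("degenerate inputs are rejected with clear messages", {
  rec <- make_growth_records(group = rep("a", 10), growth = rep(0, 10),
                             initial_volume = 500)
  expect_error(fit_growth(rec), "all-zero growth")
  expect_error(fit_growth(rec[0, ]), "no usable")
})
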