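test_that("site mortality follows the prevalence-transfer arithmetic", {
  h <- dominance_hierarchy(data.frame(killer = "D", victim = "S"))
  # 100 snails: 38 single-D, 2 S+D co-infections (40 carrying the
  # dominant), 12 S among the 60 dominant-free -> p = 0.2, E = 8,
  # K = 8 - 2 = 6, R = 12 + 8 = 20 -> 0.30
  tab <- make_site_table("x", c("D" = 38, "S+D" = 2, "S" = 12),
                         uninf_male = 24, uninf_female = 24)
  expect_equal(site_mortality(tab, h, "S"), 0.30)

  # ten observed co-infections instead: K = -2 -> facilitation, -0.10
  tab2 <- make_site_table("x", c("D" = 30, "S+D" = 10, "S" = 12),
                          uninf_male = 24, uninf_female = 24)
  expect_equal(site_mortality(tab2, h, "S"), -0.10)

  # no dominants present: estimated kill count is zero
  tab3 <- make_site_table("x", c("S" = 12), uninf_male = 44,
                          uninf_female = 44)
  expect_equal(site_mortality(tab3, h, "S"), 0)

  # the top-ranked species has no dominants anywhere
  expect_equal(site_mortality(tab, h, "D"), 0)
})

test_that("unusable sites are skipped with a warning", {
  h <- dominance_hierarchy(data.frame(killer = "D", victim = "S"))
  tab <- make_site_table("y", c("D" = 50))
  expect_warning(v <- site_mortality(tab, h, "S"), "dominant-free")
  expect_true(is.na(v))
})

test_that("pooling weights site estimates by observed focal prevalence", {
  h <- dominance_hierarchy(data.frame(killer = "D", victim = "S"))
  # two sites with equal focal prevalence (14/100): plain mean.
  # site a: p = 12/60, E = 8, K = 8 - 2 = 6, R = 20 -> 0.30
  t1 <- make_site_table("a", c("D" = 38, "S+D" = 2, "S" = 12),
                        uninf_male = 24, uninf_female = 24)
  # site b: p = 6/60, E = 4, K = 4 - 8 = -4, R = 10 -> -0.40
  t2 <- make_site_table("b", c("D" = 32, "S+D" = 8, "S" = 6),
                        uninf_male = 24, uninf_female = 30)
  expect_equal(site_mortality(t2, h, "S"), -0.40)
  est <- pooled_mortality(list(t1, t2), h, "S")
  expect_equal(est$pooled, mean(c(0.30, -0.40)))
  expect_equal(est$n_sites, 2)

  # single site: returns that value
  expect_equal(pooled_mortality(list(t1), h, "S")$pooled, 0.30)

  # a site with no focal infections contributes nothing
  t3 <- make_site_table("c", c("D" = 40), uninf_male = 30,
                        uninf_female = 30)
  expect_equal(pooled_mortality(list(t1, t3), h, "S")$pooled, 0.30)
  expect_error(pooled_mortality(list(t3), h, "S"), "no site")
})

test_that("unequal prevalence weights follow weighted-mean arithmetic", {
  h <- dominance_hierarchy(data.frame(killer = "D", victim = "S"))
  # site a: mortality 0.30, focal prevalence 14/100
  t1 <- make_site_table("a", c("D" = 38, "S+D" = 2, "S" = 12),
                        uninf_male = 24, uninf_female = 24)
  # site b: mortality -0.10, focal prevalence 22/100
  t2 <- make_site_table("b", c("D" = 30, "S+D" = 10, "S" = 12),
                        uninf_male = 24, uninf_female = 24)
  expect_equal(site_mortality(t2, h, "S"), -0.10)
  est <- pooled_mortality(list(t1, t2), h, "S")
  expect_equal(est$pooled,
               (0.30 * 0.14 + (-0.10) * 0.22) / (0.14 + 0.22))
})

test_that("the pooled estimator recovers the latent kill fraction", {
  cfg <- two_species_config(n_per_site = 2500, prev_d = 0.5, prev_s = 0.3,
                            seed = 77)
  w <- generate_world(cfg)
  est <- pooled_mortality(build_site_tables(w$records),
                          cfg$hierarchy, "subo")
  truth <- w$true_mortality[["subo"]]
  recruits <- sum(w$latent_infections[, "subo"])
  mc_se <- sqrt(truth * (1 - truth) / recruits)
  expect_lt(abs(est$pooled - truth), 3 * mc_se + 0.01)
})

test_that("estimates stay within [-1, 1] on randomized tables", {
  h <- dominance_hierarchy(data.frame(killer = "D", victim = "S"))
  set.seed(99)
  for (i in 1:50) {
    counts <- c("D" = rpois(1, 20), "S+D" = rpois(1, 5), "S" = rpois(1, 8))
    counts <- counts[counts > 0]
    if (!any(grepl("S", names(counts)))) next
    tab <- make_site_table("z", counts, uninf_male = rpois(1, 20),
                           uninf_female = rpois(1, 20))
    v <- suppressWarnings(site_mortality(tab, h, "S"))
    if (!is.na(v)) expect_true(v >= -1 && v <= 1)
  }
})

test_that("a species confined to dominant-free sites shows zero mortality", {
  # the spatial-refuge pattern: subordinate present only where no
  # dominant occurs
  h <- dominance_hierarchy(data.frame(killer = "D", victim = "S"))
  t1 <- make_site_table("refuge1", c("S" = 30), uninf_male = 35,
                        uninf_female = 35)
  t2 <- make_site_table("refuge2", c("S" = 20), uninf_male = 40,
                        uninf_female = 40)
  t3 <- make_site_table("dominated", c("D" = 50), uninf_male = 25,
                        uninf_female = 25)
  est <- pooled_mortality(list(t1, t2, t3), h, "S")
  expect_equal(est$pooled, 0)
})

test_that("castration risk averages gender-specific prevalence", {
  rec <- rbind(
    data.frame(site = "a", gender = "female",
               infection = rep(c("D", "none"), c(2, 8))),
    data.frame(site = "b", gender = "female",
               infection = rep(c("D", "none"), c(4, 6))))
  expect_equal(castration_risk(rec, "female"), 0.3)

  rec0 <- data.frame(site = c("a", "b"), gender = "male",
                     infection = "none")
  expect_equal(castration_risk(rec0, "male"), 0)
  expect_error(castration_risk(rec0, "female"), "no snails")

  # sample-size weighting is available but not the default
  recw <- rbind(
    data.frame(site = "a", gender = "male",
               infection = rep(c("D", "none"), c(1, 9))),
    data.frame(site = "b", gender = "male",
               infection = rep(c("D", "none"), c(30, 10))))
  expect_equal(castration_risk(recw, "male"), mean(c(0.1, 0.75)))
  expect_equal(castration_risk(recw, "male", weighted = TRUE), 31 / 50)
})

test_that("castration risk recovers configured recruitment", {
  cfg <- two_species_config(n_per_site = 3000, prev_d = 0.2, prev_s = 0.2,
                            seed = 3)
  w <- generate_world(cfg)
  # overall infection probability per snail: 1 - (1-.2)^2 = 0.36
  risk <- castration_risk(w$records, "female")
  expect_equal(risk, 1 - 0.8^2, tolerance = 0.03)
})

test_that("gender susceptibility test has df 1 and recovers direction", {
  cfg <- two_species_config(n_per_site = 1500, seed = 15)
  cfg$male_susceptibility <- 2
  w <- generate_world(cfg)
  res <- gender_susceptibility_test(w$records)
  expect_equal(res$df, 1)
  expect_gt(res$coefficient, 0)   # males more susceptible
  expect_lt(res$p, 0.05)

  # null world: no gender difference, p should not be extreme
  w0 <- generate_world(two_species_config(n_per_site = 1500, seed = 16))
  res0 <- gender_susceptibility_test(w0$records)
  expect_gt(res0$p, 0.001)
})

test_that("mortality_table assembles per-group estimates", {
  w <- generate_world(default_world_config(n_per_site = 60), seed = 11)
  mt <- mortality_table(w$records, w$config$hierarchy)
  expect_true(all(c("male", "female") %in% mt$group))
  expect_true(all(mt$differential_mortality >= -1 &
                    mt$differential_mortality <= 1))
  # top-ranked species has nothing above it
  expect_equal(mt$differential_mortality[mt$group == "hima"], 0)
})
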