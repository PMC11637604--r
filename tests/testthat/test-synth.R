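two_channel_g <- function() {
  G0 <- matrix(c(0.3, 0.1, 0.1, 0.2), 2, 2)
  dimnames(G0) <- list(c("lat_sing:direct", "lat_sing:indirect"),
                       c("lat_sing:direct", "lat_sing:indirect"))
  genetic_covariance(G0)
}

test_that("a zero G gives exactly zero breeding values", {
  ped <- build_half_sib_design(2, 2, 3, 0, 0.5, seed = 1)
  G0 <- matrix(0, 1, 1, dimnames = list("testis:direct", "testis:direct"))
  bv <- sample_breeding_values(ped, genetic_covariance(G0), seed = 4)
  expect_true(all(bv == 0))
})

test_that("non-PSD G is rejected at construction", {
  G0 <- matrix(c(1, 2, 2, 1), 2, 2,
               dimnames = list(c("testis:direct", "mandible:direct"),
                               c("testis:direct", "mandible:direct")))
  expect_error(genetic_covariance(G0), class = "ige_not_psd")
})

test_that("parent-offspring breeding-value covariance matches A", {
  ped <- pedigree(c("S", "D", "X"), c("0", "0", "S"), c("0", "0", "D"),
                  c("M", "F", "M"))
  G0 <- matrix(1, 1, 1, dimnames = list("testis:direct", "testis:direct"))
  g <- genetic_covariance(G0)
  reps <- t(vapply(1:2000, function(r) sample_breeding_values(ped, g, seed = r)[, 1],
                   numeric(3)))
  emp <- cov(reps[, "S"], reps[, "X"])
  se <- sd(reps[, "S"] * reps[, "X"]) / sqrt(nrow(reps))
  expect_lt(abs(emp - 0.5), 3 * se)
  # offspring variance stays 1
  se_v <- sd(reps[, "X"]^2) / sqrt(nrow(reps))
  expect_lt(abs(var(reps[, "X"]) - 1), 3 * se_v)
})

test_that("breeding values are deterministic given the seed", {
  ped <- build_half_sib_design(3, 2, 4, 0, 0.5, seed = 2)
  g <- two_channel_g()
  expect_identical(sample_breeding_values(ped, g, seed = 11),
                   sample_breeding_values(ped, g, seed = 11))
  expect_false(identical(sample_breeding_values(ped, g, seed = 11),
                         sample_breeding_values(ped, g, seed = 12)))
})

test_that("with all variances zero the trait is exactly its fixed part", {
  pre <- study_scale_preset(n_sires = 2)
  G0 <- pre$g$G0 * 0
  g <- genetic_covariance(G0)
  env <- environment_config(
    pe = setNames(rep(0, length(pre$env$pe)), names(pre$env$pe)),
    resid = setNames(rep(1e-12, length(pre$env$resid)), names(pre$env$resid)),
    beta = list(intercept = c(lat_sing = 5), order = c(lat_sing = 0.5),
                shelf = c(lat_sing = 2)))
  ped <- build_half_sib_design(2, 2, 8, 0, 0.5, seed = 1)
  bv <- sample_breeding_values(ped, g, seed = 1)
  sim <- simulate_trials(ped, bv, env, assay_design(), seed = 3)
  expected <- 5 + 0.5 * sim$trials$order + 2 * (sim$trials$shelf == "upper")
  expect_equal(sim$trials$lat_sing, expected, tolerance = 1e-5)
})

test_that("trial values decompose exactly into their simulated parts when noiseless", {
  pre <- study_scale_preset(n_sires = 2)
  env <- pre$env
  env$pe[] <- 0
  env$resid[] <- 1e-12
  ped <- build_half_sib_design(2, 2, 8, 0, 0.5, seed = 2)
  bv <- sample_breeding_values(ped, pre$g, seed = 2)
  sim <- simulate_trials(ped, bv, env, assay_design(), seed = 4)
  tr <- sim$trials
  pred <- beta <- pre$env$beta
  expected <- beta$intercept["lat_sing"] + beta$order["lat_sing"] * tr$order +
    beta$shelf["lat_sing"] * (tr$shelf == "upper") +
    bv[tr$male_id, "lat_sing:direct"] + bv[tr$female_id, "lat_sing:indirect"]
  expect_equal(tr$lat_sing, unname(expected), tolerance = 1e-5)
})

test_that("simulated trials are deterministic given the seed", {
  pre <- study_scale_preset(n_sires = 3)
  d1 <- simulate_dataset(pre, seed = 21)
  d2 <- simulate_dataset(pre, seed = 21)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$morph, d2$morph)
})

test_that("partner reuse can be forbidden, raising a design error", {
  pre <- study_scale_preset(n_sires = 2)
  ped <- build_half_sib_design(2, 2, 10, 0, 0.2, seed = 5) # few females
  bv <- sample_breeding_values(ped, pre$g, seed = 5)
  design <- assay_design(target_assays = NULL, trial_probs = c(0, 0, 1),
                         allow_reuse = FALSE)
  expect_error(simulate_trials(ped, bv, pre$env, design, seed = 6),
               class = "ige_design_infeasible")
})

test_that("the study-scale preset reproduces the realised design counts", {
  pre <- study_scale_preset()
  expect_equal(pre$pedigree_pars$n_sires, 35)
  expect_equal(pre$pedigree_pars$dams_per_sire, 2)
  expect_equal(pre$design$target_assays, 826)
  # ~16 offspring per family: (310 + 747) / 66 rounds to 16
  expect_equal(pre$pedigree_pars$offspring_per_family, 16)
  dat <- simulate_dataset(pre, seed = 42)
  expect_equal(nrow(dat$trials), 826)
  expect_true(abs(n_families(dat$ped) - 66) <= 5)
  n_m <- length(unique(dat$trials$male_id))
  n_f <- length(unique(dat$trials$female_id))
  expect_true(abs(n_m - 310) / 310 < 0.1)
  expect_true(abs(n_f - 747) / 747 < 0.1)
  # 1-3 trials per male, order incrementing from 1
  per_male <- table(dat$trials$male_id)
  expect_true(all(per_male >= 1 & per_male <= 3))
  ord <- tapply(dat$trials$order, dat$trials$male_id,
                function(x) identical(sort(x), seq_along(x)))
  expect_true(all(ord))
})

test_that("guarding distance carries no additive variance in the preset", {
  pre <- study_scale_preset()
  expect_equal(pre$g$G0["guard_dist:direct", "guard_dist:direct"], 0)
  expect_equal(pre$g$G0["guard_dist:indirect", "guard_dist:indirect"], 0)
})
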