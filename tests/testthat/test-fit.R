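# Properties of the REML optimiser: restart stability, nesting of
# constrained fits, the balanced-design ANOVA limit, and recovery when the
# data contain no genetic signal.

balanced_half_sib_fit <- function(seed_ped = 3, seed_bv = 11, seed_e = 21,
                                  v_a = 0.4, v_e = 0.6) {
  # 20 sires x 10 dams x 1 offspring: 10 paternal half-sibs per sire
  ped <- build_half_sib_design(20, 10, 1, 0, 0.5, seed = seed_ped)
  G0 <- matrix(v_a, 1, 1, dimnames = list("testis:direct", "testis:direct"))
  bv <- sample_breeding_values(ped, genetic_covariance(G0), seed = seed_bv)
  off <- ped$id[!ped$founder]
  set.seed(seed_e)
  y <- 2 + bv[off, 1] + rnorm(length(off), sd = sqrt(v_e))
  morph <- data.frame(id = off, trait = "testis", value = y, occasion = 1L)
  trials <- data.frame(male_id = character(), female_id = character(),
                       order = integer(), shelf = character())
  mm <- build_mixed_model(trials, morph, ped, model_spec("testis"))
  list(mm = mm, y = y, sire = ped$sire[match(off, ped$id)])
}

test_that("REML matches the ANOVA sire estimator on a balanced half-sib design", {
  bal <- balanced_half_sib_fit()
  f <- fit(bal$mm, seed = 1, n_restarts = 3)
  a <- anova(aov(bal$y ~ factor(bal$sire)))
  s2_sire <- (a[["Mean Sq"]][1] - a[["Mean Sq"]][2]) / 10
  expect_gt(s2_sire, 0) # interior case
  expect_equal(unname(f$vc$G[1, 1]), 4 * s2_sire, tolerance = 1e-6)
})

test_that("refits from different seeds land on the same likelihood", {
  dat <- small_dataset(n_sires = 3, seed = 5)
  mm <- build_mixed_model(dat$trials, dat$morph, dat$ped, model_spec("lat_sing"))
  lls <- vapply(1:3, function(s) fit(mm, seed = s, n_restarts = 2)$logL, 0)
  expect_lt(max(lls) - min(lls), 1e-6)
})

test_that("constrained fits never beat the full fit (nesting)", {
  dat <- small_dataset(n_sires = 3, seed = 6)
  mm <- build_mixed_model(dat$trials, dat$morph, dat$ped, model_spec("lat_sing"))
  full <- fit(mm, seed = 1, n_restarts = 2)
  for (constr in list(list(zero_var = "lat_sing:indirect"),
                      list(zero_cov = list(c("lat_sing:direct",
                                             "lat_sing:indirect"))))) {
    red <- fit_constrained(mm, constr, init = full, seed = 2)
    expect_lte(red$logL, full$logL + 1e-6)
  }
})

test_that("constraining everything reproduces the fixed-effects-only REML", {
  dat <- small_dataset(n_sires = 2, seed = 7)
  mm <- build_mixed_model(dat$trials, dat$morph, dat$ped, model_spec("lat_sing"))
  red <- fit_constrained(
    mm, list(zero_var = c("lat_sing:direct", "lat_sing:indirect",
                          "pe:lat_sing:direct", "pe:lat_sing:indirect")),
    seed = 1)
  # closed form: OLS residual variance, REML-profiled
  n <- mm$n; p <- ncol(mm$X)
  rss <- sum(qr.resid(qr(mm$X), mm$y)^2)
  s2 <- rss / (n - p)
  expect_equal(red$logL, -0.5 * (n - p) * (log(2 * pi * s2) + 1),
               tolerance = 1e-6)
  expect_equal(unname(red$vc$resid), s2, tolerance = 1e-4)
})

test_that("pure-noise data yield near-zero channel variances", {
  # all genetic and PE variances zero in the generator; phenotype is noise
  pre <- study_scale_preset(n_sires = 15)
  g0 <- pre$g$G0 * 0
  pre$g <- genetic_covariance(g0)
  pre$env$pe[] <- 0
  dat <- simulate_dataset(pre, seed = 31)
  mm <- build_mixed_model(dat$trials, dat$morph, dat$ped, model_spec("lat_sing"))
  f <- fit(mm, seed = 1, n_restarts = 2)
  expect_lt(f$vc$G["lat_sing:direct", "lat_sing:direct"], 0.06)
  expect_lt(f$vc$G["lat_sing:indirect", "lat_sing:indirect"], 0.06)
  # the total fitted variance matches the simulated noise variance even when
  # slices of it drift between the PE and residual components
  total <- sum(diag(f$vc$G)) + sum(f$vc$pe) + f$vc$resid
  expect_lt(abs(total - 0.6), 0.12)
})

test_that("boundary estimates are flagged", {
  pre <- study_scale_preset(n_sires = 6)
  g0 <- pre$g$G0 * 0
  pre$g <- genetic_covariance(g0)
  pre$env$pe[] <- 0
  dat <- simulate_dataset(pre, seed = 32)
  mm <- build_mixed_model(dat$trials, dat$morph, dat$ped, model_spec("lat_sing"))
  f <- fit(mm, seed = 1, n_restarts = 1)
  expect_true(length(f$boundary$variances) > 0)
})

test_that("too few records is rejected", {
  dat <- small_dataset(n_sires = 2, seed = 8)
  suppressWarnings(
    mm <- build_mixed_model(dat$trials[1:2, ], dat$morph, dat$ped,
                            model_spec("lat_sing")))
  expect_error(fit(mm), class = "ige_too_few_records")
})
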