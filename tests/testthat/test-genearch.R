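test_that("total heritable variance follows the dyadic formula", {
  expect_equal(total_heritable_variance(1, 1, 0), 2)
  expect_equal(total_heritable_variance(0.2, 0.1, 0.05), 0.4)
  # perfect negative covariance cancels the heritable variance entirely
  expect_equal(total_heritable_variance(0.1, 0.1, -0.1), 0)
  expect_error(total_heritable_variance(0.1, 0.1, 0.2),
               class = "ige_inadmissible")
  expect_error(total_heritable_variance(-0.1, 0.1, 0),
               class = "ige_inadmissible")
  # linear in each argument; reduces to the sum without covariance
  expect_equal(total_heritable_variance(0.3, 0.2, 0),
               total_heritable_variance(0.3, 0, 0) +
                 total_heritable_variance(0, 0.2, 0))
  expect_equal(total_heritable_variance(0.4, 0.2, 0.1),
               2 * total_heritable_variance(0.2, 0.1, 0.05))
})

test_that("genetic correlations match an independent covariance-to-correlation oracle", {
  labs <- c("a:direct", "a:indirect", "b:direct", "c:direct")
  set.seed(42)
  B <- matrix(rnorm(16), 4)
  G0 <- crossprod(B)
  dimnames(G0) <- list(labs, labs)
  g <- genetic_covariance(G0)
  Cor <- cov2cor(G0) # oracle
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(genetic_correlation(g, labs[i], labs[j]), Cor[i, j],
                 tolerance = 1e-12)
  expect_equal(genetic_correlation(g, labs[1], labs[1]), 1)
  # degenerate cases
  G1 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(labs[1:2], labs[1:2]))
  expect_equal(genetic_correlation(genetic_covariance(G1), labs[1], labs[2]), 0)
  v <- 0.3
  G2 <- matrix(v, 2, 2, dimnames = list(labs[1:2], labs[1:2]))
  expect_equal(genetic_correlation(genetic_covariance(G2), labs[1], labs[2]), 1)
  G3 <- diag(c(0.5, 0)); dimnames(G3) <- list(labs[1:2], labs[1:2])
  expect_error(genetic_correlation(genetic_covariance(G3), labs[1], labs[2]),
               class = "ige_undefined_correlation")
})

test_that("LRT p-values follow the two reference-distribution conventions", {
  # variance tested on its boundary: 50:50 mixture of chi2_0 and chi2_1
  expect_equal(lrt(10, 10 - 2.706 / 2, "variance")$p, 0.05, tolerance = 1e-3)
  expect_equal(lrt(5, 5, "variance")$p, 0.5) # point mass at statistic 0
  # covariance/correlation: plain chi-square, 1 df
  expect_equal(lrt(0, -4.33 / 2, "covariance_or_correlation")$p,
               pchisq(4.33, 1, lower.tail = FALSE))
  r <- lrt(0, -4.33 / 2, "covariance_or_correlation")
  expect_equal(r$statistic, 4.33)
  expect_equal(r$convention, "chi2_df1")
})

test_that("LRT p decreases strictly as the statistic grows, both conventions", {
  stats <- seq(0.1, 12, by = 0.4)
  for (kind in c("variance", "covariance_or_correlation")) {
    ps <- vapply(stats, function(s) lrt(s / 2, 0, kind)$p, 0)
    expect_true(all(diff(ps) < 0))
  }
})

test_that("negative LRT statistics are clipped or rejected", {
  expect_warning(r <- lrt(5, 5 + 4e-7, "variance"), "clipped")
  expect_equal(r$statistic, 0)
  expect_error(lrt(5, 6, "variance"), class = "ige_lrt_negative")
})

test_that("psi recovers the responsiveness coefficients from G components", {
  # identity direct matrix: psi equals the covariance block itself
  C <- matrix(c(0.2, -0.1, 0.05, 0.3), 2, 2)
  expect_equal(psi_matrix(C, diag(2)), C)
  # scalar case
  expect_equal(psi_matrix(matrix(0.3), matrix(0.6)), matrix(0.5))
  # random 3x3: psi %*% G_D returns C_ID
  set.seed(7)
  B <- matrix(rnorm(9), 3)
  G_D <- crossprod(B) + diag(3) * 0.1
  C_ID <- matrix(rnorm(9, sd = 0.3), 3)
  Psi <- psi_matrix(C_ID, G_D)
  expect_lt(max(abs(Psi %*% G_D - C_ID)), 1e-10)
  # singular direct matrix is refused
  G_sing <- matrix(1, 2, 2)
  expect_error(psi_matrix(matrix(0.1, 2, 2), G_sing), class = "ige_singular")
})

test_that("reverse scoring negates, is an involution, and flips covariances", {
  expect_equal(reverse_score(c(3, -1, 0)), c(-3, 1, 0))
  x <- rnorm(10)
  expect_equal(reverse_score(reverse_score(x)), x)
})

test_that("reverse-scoring a latency flips its cross-trait genetic covariances", {
  dat <- small_dataset(n_sires = 3, seed = 17)
  spec <- model_spec(c("lat_sing", "testis"))
  mm1 <- build_mixed_model(dat$trials, dat$morph, dat$ped, spec)
  rev_trials <- dat$trials
  rev_trials$lat_sing <- reverse_score(rev_trials$lat_sing)
  mm2 <- build_mixed_model(rev_trials, dat$morph, dat$ped, spec)
  f1 <- fit(mm1, seed = 1, n_restarts = 2)
  # negating the latency maps each admissible G to the one with latency
  # cross-trait covariances negated; the restricted likelihood is invariant
  vc_flip <- f1$vc
  for (ch in c("lat_sing:direct", "lat_sing:indirect")) {
    vc_flip$G[ch, "testis:direct"] <- -vc_flip$G[ch, "testis:direct"]
    vc_flip$G["testis:direct", ch] <- -vc_flip$G["testis:direct", ch]
  }
  expect_equal(reml_loglik(mm2, vc_flip), f1$logL, tolerance = 1e-8)
  # and refitting the reversed data from the mapped optimum stays there,
  # with the cross-trait covariances sign-flipped
  f2 <- fit(mm2, init = vc_flip, seed = 1, n_restarts = 1)
  expect_gte(f2$logL, f1$logL - 1e-4)
  for (ch in c("lat_sing:direct", "lat_sing:indirect")) {
    if (abs(f1$vc$G[ch, "testis:direct"]) > 0.02)
      expect_equal(sign(f2$vc$G[ch, "testis:direct"]),
                   -sign(f1$vc$G[ch, "testis:direct"]))
  }
})
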