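# The restricted likelihood is checked against the error-contrast oracle
# (orthonormal null-space basis of X', plain MVN density) with V assembled
# naively from A, and for its defining invariances.

test_that("reml_loglik equals the error-contrast oracle on small instances", {
  dat <- small_dataset(n_sires = 2, seed = 9)
  sub <- dat$trials[seq_len(30), ]
  mm <- build_mixed_model(sub, dat$morph, dat$ped, model_spec("lat_sing"))
  for (s in 1:5) {
    vc <- random_vc(mm, seed = s)
    expect_equal(reml_loglik(mm, vc), ec_reml_oracle(mm, vc), tolerance = 1e-10)
  }
})

test_that("the likelihood is invariant to translations along the fixed effects", {
  dat <- small_dataset(n_sires = 2, seed = 10)
  mm <- build_mixed_model(dat$trials[1:40, ], dat$morph, dat$ped,
                          model_spec("lat_sing"))
  vc <- random_vc(mm, seed = 3)
  base <- reml_loglik(mm, vc)
  set.seed(1)
  for (k in 1:3) {
    mm2 <- mm
    mm2$y <- mm$y + as.vector(mm$X %*% rnorm(ncol(mm$X), sd = 10))
    expect_lt(abs(reml_loglik(mm2, vc) - base), 1e-8)
  }
})

test_that("with no genetic or PE variance and V_R = 1 an exact fit leaves only the constant", {
  dat <- small_dataset(n_sires = 2, seed = 11)
  mm <- build_mixed_model(dat$trials[1:20, ], dat$morph, dat$ped,
                          model_spec("lat_sing"))
  b <- c(2, 0.3, -1)
  mm$y <- as.vector(mm$X %*% b) # residual-free response
  k <- length(mm$g_labels)
  G <- matrix(0, k, k, dimnames = list(mm$g_labels, mm$g_labels))
  vc <- variance_components(G, pe = setNames(rep(0, length(mm$pe_labels)),
                                             mm$pe_labels),
                            resid = c(lat_sing = 1))
  # V = I: logL reduces to -(n-p)/2 log(2 pi), all determinant terms cancel
  expect_equal(reml_loglik(mm, vc),
               -0.5 * (mm$n - ncol(mm$X)) * log(2 * pi), tolerance = 1e-10)
})

test_that("inadmissible components are rejected, never silent NaN", {
  dat <- small_dataset(n_sires = 2, seed = 12)
  mm <- build_mixed_model(dat$trials[1:25, ], dat$morph, dat$ped,
                          model_spec("lat_sing"))
  G <- matrix(c(0.1, 0.5, 0.5, 0.1), 2, 2,
              dimnames = list(mm$g_labels, mm$g_labels))
  expect_error(
    reml_loglik(mm, variance_components(G, resid = c(lat_sing = 0.5))),
    class = "ige_inadmissible")
  G2 <- diag(c(0.1, 0.1)); dimnames(G2) <- dimnames(G)
  expect_error(
    reml_loglik(mm, variance_components(G2, resid = c(lat_sing = 0))),
    class = "ige_inadmissible")
})

test_that("model assembly produces the documented structure", {
  dat <- small_dataset(n_sires = 2, seed = 13)
  mm <- build_mixed_model(dat$trials, dat$morph, dat$ped, model_spec("lat_sing"))
  expect_equal(colnames(mm$X), c("intercept", "order", "shelf_upper"))
  expect_equal(mm$g_labels, c("lat_sing:direct", "lat_sing:indirect"))
  expect_equal(mm$pe_labels, c("lat_sing:direct", "lat_sing:indirect"))
  # once-measured morphology: one genetic channel, no PE channel
  mm2 <- build_mixed_model(dat$trials, dat$morph, dat$ped, model_spec("testis"))
  expect_equal(mm2$g_labels, "testis:direct")
  expect_length(mm2$pe_labels, 0)
  expect_equal(colnames(mm2$X), "intercept")
  # bivariate: trait-specific intercepts only
  mm3 <- build_mixed_model(dat$trials, dat$morph, dat$ped,
                           model_spec(c("lat_sing", "testis")))
  expect_equal(colnames(mm3$X), c("intercept_lat_sing", "intercept_testis"))
  expect_equal(mm3$resid_cov_mode, "zero") # never observed on the same record
  # two behaviours scored on the same trials can share residuals
  mm4 <- build_mixed_model(dat$trials, dat$morph, dat$ped,
                           model_spec(c("lat_sing", "lat_mount")))
  expect_equal(mm4$resid_cov_mode, "estimate")
  expect_gt(nrow(mm4$same_trial), 0)
})

test_that("unknown individuals and missing responses raise errors", {
  dat <- small_dataset(n_sires = 2, seed = 14)
  bad <- dat$trials
  bad$male_id[1] <- "GHOST"
  expect_error(build_mixed_model(bad, dat$morph, dat$ped, model_spec("lat_sing")),
               class = "ige_unknown_individual")
  empty <- dat$trials
  empty$lat_sing <- NA_real_
  expect_error(build_mixed_model(empty, dat$morph, dat$ped, model_spec("lat_sing")),
               class = "ige_no_response")
})
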