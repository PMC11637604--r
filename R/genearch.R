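# Derived quantitative-genetic quantities and significance machinery.

#' Total heritable variance of a dyadic trait
#'
#' For a trait expressed in male-female dyads (group size 2), the variance
#' in total breeding value combines the direct and indirect additive
#' variances and twice their covariance:
#' `V_TBV = V_Am + V_Af + 2 COV_Am,Af`.
#'
#' @param v_am direct additive genetic variance (males, for a
#'   male-expressed trait).
#' @param v_af indirect additive genetic variance (partner females).
#' @param cov_amaf additive covariance between the direct and indirect
#'   effects; must satisfy `|cov| <= sqrt(v_am v_af)`.
#' @return the total heritable variance (non-negative for any admissible
#'   input).
#' @export
total_heritable_variance <- function(v_am, v_af, cov_amaf) {
  if (v_am < 0 || v_af < 0)
    ige_error("ige_inadmissible", "variances must be non-negative")
  if (cov_amaf^2 > v_am * v_af * (1 + 1e-10))
    ige_error("ige_inadmissible",
              "covariance exceeds the bound sqrt(v_am * v_af)")
  v_am + v_af + 2 * cov_amaf
}

#' Likelihood-ratio test for a variance component or correlation
#'
#' Computes `max(0, 2 (logL_full - logL_reduced))` and its p-value under
#' the applicable reference distribution. Testing a variance pinned at its
#' boundary (zero) uses the 50:50 mixture of a point mass at zero and a
#' chi-square with 1 df: `p = 0.5 P(chi2_1 >= LRT)` for a positive
#' statistic and `p = 0.5` at exactly zero (the df = 0 component is a point
#' mass, handled with strict inequality). Testing a covariance or
#' correlation (an interior null) uses a plain chi-square with 1 df.
#'
#' @param logL_full restricted log-likelihood of the full model.
#' @param logL_reduced restricted log-likelihood of the model with the
#'   focal component removed/constrained to zero.
#' @param component_kind `"variance"` (boundary mixture) or
#'   `"covariance_or_correlation"` (chi-square, 1 df).
#' @param tol small negative statistics up to `-tol` are clipped to zero
#'   with a warning; anything more negative raises an error, since it means
#'   the "full" model was out-optimised by its own submodel.
#' @return object of class `lrt_result`: `statistic`, `convention`, `p`.
#' @export
lrt <- function(logL_full, logL_reduced,
                component_kind = c("variance", "covariance_or_correlation"),
                tol = 1e-6) {
  component_kind <- match.arg(component_kind)
  stat <- 2 * (logL_full - logL_reduced)
  if (stat < -2 * tol)
    ige_error("ige_lrt_negative",
              sprintf("reduced model beats full model (2*diff = %.3g); refit the full model",
                      stat))
  if (stat < 0) {
    warning("small negative LRT statistic clipped to 0")
    stat <- 0
  }
  if (component_kind == "variance") {
    p <- if (stat > 0) 0.5 * pchisq(stat, df = 1, lower.tail = FALSE) else 0.5
    convention <- "mixture_half_chi2"
  } else {
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    convention <- "chi2_df1"
  }
  structure(list(statistic = stat, convention = convention, p = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT = %.3f (%s), p = %.4g\n", x$statistic, x$convention, x$p))
  invisible(x)
}

#' Genetic-level responsiveness matrix Psi
#'
#' The interaction (responsiveness) coefficients linking partner breeding
#' values to focal trait expression, recovered from variance components as
#' the product of the IGE-DGE covariance matrix and the inverse of the DGE
#' (co)variance matrix: `Psi = C_ID %*% solve(G_D)`.
#'
#' @param c_id matrix of covariances between indirect channels (rows) and
#'   direct channels (columns).
#' @param g_d symmetric positive-definite matrix of direct-effect
#'   (co)variances.
#' @return the Psi matrix, `c_id %*% solve(g_d)`.
#' @export
psi_matrix <- function(c_id, g_d) {
  c_id <- as.matrix(c_id); g_d <- as.matrix(g_d)
  if (nrow(g_d) != ncol(g_d) || max(abs(g_d - t(g_d))) > 1e-8)
    ige_error("ige_bad_input", "g_d must be a symmetric square matrix")
  if (ncol(c_id) != nrow(g_d))
    ige_error("ige_bad_input", "c_id and g_d are not conformable")
  if (rcond(g_d) < 1e-12)
    ige_error("ige_singular", "direct genetic covariance matrix is singular")
  t(solve(g_d, t(c_id)))
}

# ---------------------------------------------------------------------------
# LRT orchestration over fitted models: refit with one component pinned,
# warm-starting from the full fit. If the reduced model nevertheless beats
# the full one (optimiser noise), the full model is refit warm-started from
# the reduced solution so the nesting inequality holds before the test.

#' Likelihood-ratio test of one variance or covariance component of a fit
#'
#' Refits the model with the focal component constrained to zero
#' (warm-started from the full fit) and applies the appropriate reference
#' distribution: boundary mixture for variances, chi-square 1 df for
#' covariances/correlations.
#'
#' @param mm the `model_matrices` the full model was fitted on.
#' @param fit_full an `ige_fit` of the full model.
#' @param component either a channel label (variance test) or a 2-vector of
#'   channel labels (covariance/correlation test).
#' @param seed seed for the constrained refit.
#' @param n_restarts restarts for the constrained refit.
#' @return list with `lrt` (an `lrt_result`), `fit_reduced`, and possibly
#'   an improved `fit_full`.
#' @export
lrt_component <- function(mm, fit_full, component, seed = 1L, n_restarts = 2L) {
  is_var <- length(component) == 1
  constraints <- if (is_var) list(zero_var = component)
  else list(zero_cov = list(component))
  red <- fit_constrained(mm, constraints, init = fit_full, seed = seed,
                         n_restarts = n_restarts, compute_se = FALSE)
  if (red$logL > fit_full$logL + 1e-8) {
    # out-optimised full model: refit it warm-started from the reduced optimum
    refit <- fit(mm, init = red, seed = seed + 1L, n_restarts = 1L)
    if (refit$logL > fit_full$logL) fit_full <- refit
  }
  res <- lrt(max(fit_full$logL, red$logL), red$logL,
             if (is_var) "variance" else "covariance_or_correlation")
  list(lrt = res, fit_reduced = red, fit_full = fit_full)
}
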