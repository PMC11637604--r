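# Restricted likelihood of a variance-component configuration.
#
# Convention: the value is the log density of the error contrasts K'y for
# any orthonormal basis K of the null space of X', i.e.
#   logL = -1/2 [ log|V| + log|X'V^-1 X| - log|X'X| + y'Py + (n-p) log 2pi ]
# with P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1. This is invariant to the
# choice of basis and to translations y -> y + Xc.

#' Variance components for a fitted or evaluated model
#'
#' @param G symmetric matrix of additive (co)variances over the model's
#'   genetic channels (dimnames = channel labels). Channels constrained to
#'   zero variance appear as zero rows/columns.
#' @param pe named vector of permanent-environment variances.
#' @param resid named per-trait residual variances (all > 0).
#' @param resid_cov cross-trait residual covariance for same-trial
#'   bivariate records (ignored unless the model estimates it).
#' @return object of class `variance_components`.
#' @export
variance_components <- function(G, pe = numeric(), resid, resid_cov = 0) {
  G <- as.matrix(G)
  structure(list(G = G, pe = pe, resid = resid, resid_cov = resid_cov),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("genetic (co)variances:\n")
  print(round(x$G, 4))
  if (length(x$pe)) { cat("permanent environment:\n"); print(round(x$pe, 4)) }
  cat("residual:\n"); print(round(x$resid, 4))
  if (!is.null(x$resid_cov) && x$resid_cov != 0)
    cat("residual covariance:", round(x$resid_cov, 4), "\n")
  invisible(x)
}

# Admissibility: PSD genetic block, non-negative PE, positive residuals,
# PSD 2x2 residual block when a cross-trait covariance is present.
check_admissible <- function(mm, vc) {
  if (!is_psd(vc$G, tol = 1e-7))
    ige_error("ige_inadmissible", "genetic covariance block is not PSD")
  if (any(vc$pe < 0))
    ige_error("ige_inadmissible", "negative permanent-environment variance")
  if (any(vc$resid <= 0))
    ige_error("ige_inadmissible", "residual variances must be positive")
  if (mm$resid_cov_mode == "estimate") {
    r <- vc$resid
    if (vc$resid_cov^2 > prod(r[mm$traits]) * (1 + 1e-10))
      ige_error("ige_inadmissible", "residual covariance exceeds its bound")
  }
  invisible(TRUE)
}

# V = sum_cd G[c,d] Zc A Zd' + sum_c pe_c Zc Zc' + R
build_V <- function(mm, vc) {
  n <- mm$n
  rv <- vc$resid[mm$traits]
  V <- diag(rv[mm$tix], n)
  if (mm$resid_cov_mode == "estimate" && !is.null(mm$same_trial) &&
      nrow(mm$same_trial) && vc$resid_cov != 0) {
    V[mm$same_trial] <- V[mm$same_trial] + vc$resid_cov
    V[mm$same_trial[, c(2, 1), drop = FALSE]] <-
      V[mm$same_trial[, c(2, 1), drop = FALSE]] + vc$resid_cov
  }
  for (i in seq_along(mm$g_labels)) for (j in i:length(mm$g_labels)) {
    gij <- vc$G[mm$g_labels[i], mm$g_labels[j]]
    if (gij == 0) next
    V <- V + gij * mm$K[[paste(mm$g_labels[i], mm$g_labels[j], sep = "|")]]
  }
  for (lab in mm$pe_labels) {
    p <- if (lab %in% names(vc$pe)) vc$pe[[lab]] else 0
    if (!is.na(p) && p != 0) V <- V + p * mm$PE[[lab]]
  }
  V
}

#' Restricted log-likelihood of variance components
#'
#' Evaluates the REML log-likelihood (error-contrast convention, including
#' the `(n-p)/2 log 2pi` constant) for a given set of variance components.
#' The value is invariant, to numerical precision, to replacing `y` by
#' `y + X c` for any coefficient vector `c`.
#'
#' @param mm a `model_matrices` object from [build_mixed_model()].
#' @param vc a `variance_components` object (admissible: PSD genetic block,
#'   positive residuals).
#' @return scalar restricted log-likelihood.
#' @export
reml_loglik <- function(mm, vc) {
  check_admissible(mm, vc)
  V <- build_V(mm, vc)
  ch <- tryCatch(chol(V), error = function(e)
    ige_error("ige_inadmissible", "V is not positive definite"))
  logdetV <- 2 * sum(log(diag(ch)))
  ViX <- backsolve(ch, forwardsolve(t(ch), mm$X))
  Viy <- backsolve(ch, forwardsolve(t(ch), mm$y))
  XtViX <- crossprod(mm$X, ViX)
  chx <- chol(XtViX)
  logdetXtViX <- 2 * sum(log(diag(chx)))
  b <- backsolve(chx, forwardsolve(t(chx), crossprod(mm$X, Viy)))
  yPy <- sum(mm$y * Viy) - sum(crossprod(mm$X, Viy) * b)
  p <- ncol(mm$X)
  -0.5 * (logdetV + logdetXtViX - mm$logdetXtX + yPy +
            (mm$n - p) * log(2 * pi))
}

# Generalised least-squares fixed-effect solutions at given components.
gls_fixef <- function(mm, vc) {
  V <- build_V(mm, vc)
  ch <- chol(V)
  ViX <- backsolve(ch, forwardsolve(t(ch), mm$X))
  Viy <- backsolve(ch, forwardsolve(t(ch), mm$y))
  XtViX <- crossprod(mm$X, ViX)
  setNames(as.vector(solve(XtViX, crossprod(mm$X, Viy))), colnames(mm$X))
}
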