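# REML fitting.
#
# Parameterisation: each active genetic variance is optimised as a
# log-variance, each free genetic covariance as a scale-free coefficient z
# with G_ij = z_ij sqrt(G_ii G_jj) (so z is the genetic correlation itself),
# permanent-environment and residual variances as log-variances, and the
# cross-trait residual covariance (when estimated) as a correlation-like z.
# Positive semidefiniteness of the genetic block with arbitrary constraint
# patterns is enforced by a smooth eigenvalue penalty; for two channels the
# box |z| <= 1 is exact and the penalty never activates.
#
# Search: Nelder-Mead warm start, then a bounded quasi-Newton (PORT) polish,
# repeated from seed-jittered starting points; the best restricted
# likelihood wins.

LOG_V_FLOOR <- log(1e-9)
LOG_V_CEIL <- log(1e3)

# paste0 recycles a zero-length vector against a scalar prefix to the bare
# prefix; every label-prefix operation must instead stay zero-length
prefix_each <- function(prefix, x) {
  if (length(x)) paste0(prefix, x) else character(0)
}

# --- parameter packing -------------------------------------------------------

make_param_map <- function(mm) {
  spec <- mm$spec
  zero_var <- spec$constraints$zero_var
  active_g <- setdiff(mm$g_labels, zero_var)
  pinned <- vapply(spec$constraints$zero_cov, function(pr)
    paste(sort(pr), collapse = "|"), "")
  free_cov <- list()
  if (length(active_g) > 1) {
    for (i in 1:(length(active_g) - 1)) for (j in (i + 1):length(active_g)) {
      key <- paste(sort(c(active_g[i], active_g[j])), collapse = "|")
      if (!key %in% pinned)
        free_cov[[length(free_cov) + 1]] <- c(active_g[i], active_g[j])
    }
  }
  # PE channels share labels with genetic channels; constraints target a PE
  # variance via the "pe:" prefix, so plain labels only drop genetic channels
  active_pe <- mm$pe_labels[!prefix_each("pe:", mm$pe_labels) %in% zero_var]
  nm <- c(prefix_each("lv:", active_g),
          vapply(free_cov, function(pr) paste0("z:", pr[1], "~", pr[2]), ""),
          prefix_each("lpe:", active_pe),
          prefix_each("lr:", mm$traits),
          if (mm$resid_cov_mode == "estimate") "zr:resid")
  list(active_g = active_g, free_cov = free_cov, active_pe = active_pe,
       names = nm,
       idx_lv = seq_along(active_g),
       idx_z = length(active_g) + seq_along(free_cov),
       idx_lpe = length(active_g) + length(free_cov) + seq_along(active_pe),
       idx_lr = length(active_g) + length(free_cov) + length(active_pe) +
         seq_along(mm$traits),
       idx_zr = if (mm$resid_cov_mode == "estimate")
         length(active_g) + length(free_cov) + length(active_pe) +
         length(mm$traits) + 1L else integer(0))
}

# Map packed parameters to variance_components. Returns the components plus
# the minimum eigenvalue of the implied genetic correlation matrix (used as
# a PSD penalty when more than two channels are active).
unpack_params <- function(mm, map, par) {
  gl <- mm$g_labels
  G <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
  v <- exp(pmin(pmax(par[map$idx_lv], LOG_V_FLOOR), LOG_V_CEIL))
  diag(G)[match(map$active_g, gl)] <- v
  for (k in seq_along(map$free_cov)) {
    pr <- map$free_cov[[k]]
    z <- par[map$idx_z[k]]
    G[pr[1], pr[2]] <- G[pr[2], pr[1]] <- z * sqrt(G[pr[1], pr[1]] * G[pr[2], pr[2]])
  }
  min_eig <- 0
  if (length(map$active_g) > 1) {
    Ga <- G[map$active_g, map$active_g]
    Ca <- stats::cov2cor(Ga)
    min_eig <- min(eigen(Ca, symmetric = TRUE, only.values = TRUE)$values)
  }
  pe <- setNames(exp(pmin(pmax(par[map$idx_lpe], LOG_V_FLOOR), LOG_V_CEIL)),
                 map$active_pe)
  resid <- setNames(exp(pmin(pmax(par[map$idx_lr], LOG_V_FLOOR), LOG_V_CEIL)),
                    mm$traits)
  rc <- if (length(map$idx_zr)) par[map$idx_zr] * sqrt(prod(resid)) else 0
  list(vc = variance_components(G, pe, resid, rc), min_eig = min_eig)
}

pack_init <- function(mm, map, init) {
  if (inherits(init, "ige_fit")) init <- init$vc
  if (identical(init, "AUTO") || is.null(init)) {
    par <- numeric(length(map$names))
    for (t in seq_along(mm$traits)) {
      yt <- mm$y[mm$tix == t]
      vp <- var(yt)
      tr <- mm$traits[t]
      chs <- c(grep(paste0("^lv:", tr, ":"), map$names),
               grep(paste0("^lpe:", tr, ":"), map$names),
               grep(paste0("^lr:", tr, "$"), map$names))
      par[chs] <- log(vp / length(chs))
    }
    return(par)
  }
  stopifnot(inherits(init, "variance_components"))
  par <- numeric(length(map$names))
  for (k in seq_along(map$active_g)) {
    lab <- map$active_g[k]
    par[map$idx_lv[k]] <- log(max(init$G[lab, lab], 1e-8))
  }
  for (k in seq_along(map$free_cov)) {
    pr <- map$free_cov[[k]]
    vv <- init$G[pr[1], pr[1]] * init$G[pr[2], pr[2]]
    par[map$idx_z[k]] <- if (vv > 0)
      max(min(init$G[pr[1], pr[2]] / sqrt(vv), 0.99), -0.99) else 0
  }
  for (k in seq_along(map$active_pe)) {
    lab <- map$active_pe[k]
    pv <- if (lab %in% names(init$pe)) init$pe[[lab]] else 0.05
    par[map$idx_lpe[k]] <- log(max(pv, 1e-8))
  }
  for (k in seq_along(mm$traits))
    par[map$idx_lr[k]] <- log(max(init$resid[[mm$traits[k]]], 1e-8))
  if (length(map$idx_zr)) {
    rr <- prod(vapply(mm$traits, function(tr) max(init$resid[[tr]], 1e-8), 0))
    par[map$idx_zr] <- max(min(init$resid_cov / sqrt(rr), 0.99), -0.99)
  }
  par
}

# --- fitting -----------------------------------------------------------------

#' Fit an animal model by restricted maximum likelihood
#'
#' Maximises [reml_loglik()] over the admissible variance components of a
#' model, from several seed-jittered starting values (Nelder-Mead warm
#' start, bounded quasi-Newton polish); the best likelihood is kept.
#' Components constrained in the model specification are excluded from the
#' parameterisation: a variance fixed at zero drops its channel, a pinned
#' covariance stays exactly zero.
#'
#' @param mm a `model_matrices` from [build_mixed_model()].
#' @param init `"AUTO"` (phenotypic variance split equally over active
#'   channels), a `variance_components` object, or a previous `ige_fit`
#'   to warm-start from.
#' @param seed integer seed controlling the jittered restarts.
#' @param n_restarts number of starting points (the first is unjittered).
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param compute_se compute curvature-based standard errors at the
#'   optimum (skip in replicate simulation loops where they are unused).
#' @return object of class `ige_fit`: variance components (`vc`), restricted
#'   log-likelihood (`logL`), fixed-effect solutions (`fixef`), `converged`,
#'   per-component `boundary` flags (variance within `1e-6` of zero or
#'   correlation within `1e-4` of +/-1), approximate standard errors (`se`,
#'   from the observed curvature at the optimum via the delta method), and
#'   the optimiser trace.
#' @export
fit <- function(mm, init = "AUTO", seed = 1L, n_restarts = 3L, reltol = 1e-10,
                compute_se = TRUE) {
  stopifnot(inherits(mm, "model_matrices"))
  if (mm$n < ncol(mm$X) + 1)
    ige_error("ige_too_few_records", "fewer records than fixed effects + 1")
  map <- make_param_map(mm)
  npar <- length(map$names)
  penalty_scale <- 1e7

  objective <- function(par) {
    up <- unpack_params(mm, map, par)
    if (up$min_eig < -1e-10)
      return(penalty_scale * (1 - up$min_eig))
    ll <- tryCatch(reml_loglik(mm, up$vc), igemate_error = function(e) NA_real_)
    if (!is.finite(ll)) return(penalty_scale)
    -ll
  }

  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  lower[c(map$idx_lv, map$idx_lpe, map$idx_lr)] <- LOG_V_FLOOR
  upper[c(map$idx_lv, map$idx_lpe, map$idx_lr)] <- LOG_V_CEIL
  lower[c(map$idx_z, map$idx_zr)] <- -1
  upper[c(map$idx_z, map$idx_zr)] <- 1

  par0 <- pack_init(mm, map, init)
  best <- NULL
  trace <- list()
  with_seed(seed, {
    for (r in seq_len(max(1L, n_restarts))) {
      p0 <- if (r == 1L) par0 else par0 + rnorm(npar, sd = 0.3)
      p0 <- pmin(pmax(p0, lower), upper)
      # simplex warm start on the first pass only; jittered restarts go
      # straight to the quasi-Newton stage, which does the precision work
      nm <- if (r == 1L && npar > 1)
        optim(p0, objective, method = "Nelder-Mead",
              control = list(maxit = 200L * npar, reltol = 1e-8))
      else list(par = p0, value = objective(p0))
      pn <- tryCatch(
        nlminb(nm$par, objective, lower = lower, upper = upper,
               control = list(rel.tol = reltol, iter.max = 500L)),
        error = function(e) NULL)
      cand <- if (!is.null(pn) && is.finite(pn$objective) &&
                  pn$objective <= nm$value)
        list(par = pn$par, value = pn$objective,
             converged = isTRUE(pn$convergence == 0))
      else list(par = nm$par, value = nm$value,
                converged = isTRUE(nm$convergence == 0))
      trace[[r]] <- c(restart = r, negLogL = cand$value)
      if (is.null(best) || cand$value < best$value) best <- cand
    }
  })
  if (!is.finite(best$value) || best$value >= penalty_scale / 2)
    return(structure(list(spec = mm$spec, map = map, vc = NULL,
                          logL = -Inf, fixef = NULL, converged = FALSE,
                          boundary = list(), se = NULL, par = best$par,
                          trace = trace),
                     class = "ige_fit"))
  up <- unpack_params(mm, map, best$par)
  vc <- up$vc
  logL <- -best$value

  # boundary flags
  boundary <- list(
    variances = names(which(c(setNames(diag(vc$G)[map$active_g], map$active_g),
                              setNames(vc$pe, prefix_each("pe:", names(vc$pe)))) < 1e-6)),
    correlations = vapply(map$free_cov, function(pr)
      paste(pr, collapse = "~"), "")[
        vapply(seq_along(map$free_cov), function(k)
          abs(best$par[map$idx_z[k]]) > 1 - 1e-4, TRUE)]
  )

  se <- if (compute_se)
    tryCatch(curvature_se(mm, map, best$par, objective, lower, upper),
             error = function(e) NULL)
  else NULL
  structure(list(spec = mm$spec, map = map, vc = vc, logL = logL,
                 fixef = gls_fixef(mm, vc),
                 converged = isTRUE(best$converged),
                 boundary = boundary, se = se, par = best$par, trace = trace),
            class = "ige_fit")
}

#' Fit an animal model with additional components constrained
#'
#' Same optimiser as [fit()], with the listed components removed from the
#' parameterisation: a variance constrained to zero drops its channel and
#' every covariance involving it; a covariance constrained to zero is
#' pinned exactly. The returned likelihood can never exceed the
#' unconstrained one beyond numerical slack.
#'
#' @param mm a `model_matrices`.
#' @param constraints list with `zero_var` (channel labels) and/or
#'   `zero_cov` (list of label pairs).
#' @inheritParams fit
#' @return an `ige_fit`.
#' @export
fit_constrained <- function(mm, constraints, init = "AUTO", seed = 1L,
                            n_restarts = 3L, compute_se = TRUE) {
  spec2 <- constrain(mm$spec,
                     zero_var = constraints$zero_var %||% character(0),
                     zero_cov = constraints$zero_cov %||% list())
  mm2 <- mm
  mm2$spec <- spec2
  fit(mm2, init = init, seed = seed, n_restarts = n_restarts,
      compute_se = compute_se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Approximate standard errors from the observed curvature of the restricted
# likelihood at the optimum, delta-mapped from the transformed scale.
# Parameters pinned at a box bound (e.g. a variance at its floor) carry no
# curvature information; they are excluded and reported as NA.
curvature_se <- function(mm, map, par, objective, lower, upper) {
  interior <- which(par > lower + 1e-5 & par < upper - 1e-5)
  if (!length(interior)) return(NULL)
  obj_sub <- function(p_sub) {
    p <- par
    p[interior] <- p_sub
    objective(p)
  }
  H <- optimHess(par[interior], obj_sub)
  cov_sub <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov_sub) || any(!is.finite(cov_sub))) return(NULL)
  npar <- length(par)
  cov_t <- matrix(NA_real_, npar, npar)
  cov_t[interior, interior] <- cov_sub
  d <- diag(cov_t)
  d[!is.na(d) & d < 0] <- NA_real_
  se_t <- sqrt(d)
  up <- unpack_params(mm, map, par)
  vc <- up$vc
  se_var <- setNames(se_t[map$idx_lv] * diag(vc$G)[map$active_g], map$active_g)
  se_cor <- setNames(se_t[map$idx_z],
                     vapply(map$free_cov, function(pr) paste(pr, collapse = "~"), ""))
  se_pe <- setNames(se_t[map$idx_lpe] * vc$pe[map$active_pe], map$active_pe)
  se_resid <- setNames(se_t[map$idx_lr] * vc$resid[mm$traits], mm$traits)
  # covariance SE by the delta method from (z, log v_i, log v_j)
  se_cov <- rep(NA_real_, length(map$free_cov))
  for (k in seq_along(map$free_cov)) {
    pr <- map$free_cov[[k]]
    i <- map$idx_lv[match(pr[1], map$active_g)]
    j <- map$idx_lv[match(pr[2], map$active_g)]
    z <- map$idx_z[k]
    gij <- vc$G[pr[1], pr[2]]
    grad <- c(sqrt(vc$G[pr[1], pr[1]] * vc$G[pr[2], pr[2]]), gij / 2, gij / 2)
    idx <- c(z, i, j)
    block <- cov_t[idx, idx]
    vv <- if (any(is.na(block))) NA_real_
    else as.numeric(t(grad) %*% block %*% grad)
    se_cov[k] <- if (!is.na(vv) && vv >= 0) sqrt(vv) else NA_real_
  }
  names(se_cov) <- names(se_cor)
  list(variances = se_var, correlations = se_cor, covariances = se_cov,
       pe = se_pe, resid = se_resid)
}

#' @export
print.ige_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s): logL = %.4f, converged = %s\n",
              paste(x$spec$traits, collapse = " + "), x$logL, x$converged))
  if (!is.null(x$vc)) print(x$vc)
  if (length(x$boundary$variances) || length(x$boundary$correlations))
    cat("boundary:", paste(unlist(x$boundary), collapse = ", "), "\n")
  invisible(x)
}
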