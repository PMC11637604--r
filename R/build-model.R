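# Assembly of the mixed-model structures: response vector, fixed-effect
# matrix, per-channel incidence, and the precomputed n x n covariance
# kernels that make repeated likelihood evaluations cheap.
#
# For a genetic channel c whose record-to-individual map is ids_c, the
# contribution of the channel pair (c, d) to V is G[c,d] * Zc A Zd', and
# Zc A Zd' is just A indexed by (ids_c, ids_d). These kernels depend only
# on the data, so they are computed once per model and reused by every
# likelihood evaluation during optimisation.

# Records for one trait: response, focal (direct) individual, partner
# (indirect) individual or NA, covariates.
trait_records <- function(trials, morph, trait) {
  info <- trait_info(trait)
  if (info$kind == "once") {
    m <- morph[morph$trait == trait & !is.na(morph$value), , drop = FALSE]
    if (!nrow(m)) ige_error("ige_no_response", paste("no records for trait", trait))
    data.frame(y = m$value, direct_id = m$id, indirect_id = NA_character_,
               order = NA_real_, shelf = NA_character_,
               trial_key = NA_character_, stringsAsFactors = FALSE)
  } else {
    if (is.null(trials[[trait]]))
      ige_error("ige_no_response", paste("trait column missing from trials:", trait))
    t2 <- trials[!is.na(trials[[trait]]), , drop = FALSE]
    if (!nrow(t2)) ige_error("ige_no_response", paste("no records for trait", trait))
    foc <- if (info$expresser == "M") t2$male_id else t2$female_id
    par <- if (info$expresser == "M") t2$female_id else t2$male_id
    if (info$kind != "dyadic") par <- rep(NA_character_, nrow(t2))
    data.frame(y = t2[[trait]], direct_id = foc, indirect_id = par,
               order = as.numeric(t2$order), shelf = t2$shelf,
               trial_key = paste(t2$male_id, t2$female_id, t2$order),
               stringsAsFactors = FALSE)
  }
}

#' Build the mixed-model matrices for a model specification
#'
#' Assembles the stacked response, the full-rank fixed-effect matrix
#' (redundant columns dropped with a warning), one incidence map per active
#' genetic or permanent-environment channel, and dense covariance kernels
#' `Zc A Zd'` (genetic) and `Zc Zc'` (PE) used by [reml_loglik()].
#'
#' @param trials trial table (`male_id`, `female_id`, `order`, `shelf`, one
#'   column per behavioural/mass trait), already on the analysis scale.
#' @param morph morphology table (`id`, `trait`, `value`, `occasion`).
#' @param ped a `pedigree` covering every individual referenced.
#' @param spec a `model_spec`.
#' @return object of class `model_matrices`.
#' @export
build_mixed_model <- function(trials, morph, ped, spec) {
  stopifnot(inherits(spec, "model_spec"))
  rm_ <- relationship_matrix(ped)
  A <- rm_$A
  recs <- lapply(spec$traits, function(tr) trait_records(trials, morph, tr))
  names(recs) <- spec$traits
  ids_used <- unique(unlist(lapply(recs, function(r) c(r$direct_id, r$indirect_id))))
  ids_used <- ids_used[!is.na(ids_used)]
  unknown <- setdiff(ids_used, ped$id)
  if (length(unknown))
    ige_error("ige_unknown_individual",
              paste("individual(s) not in pedigree:",
                    paste(utils::head(unknown, 5), collapse = ", ")))
  n_per <- vapply(recs, nrow, 0L)
  n <- sum(n_per)
  tix <- rep(seq_along(spec$traits), n_per)
  y <- unlist(lapply(recs, `[[`, "y"), use.names = FALSE)

  # ---- fixed effects -------------------------------------------------------
  if (spec$bivariate) {
    X <- sapply(seq_along(spec$traits), function(t) as.numeric(tix == t))
    colnames(X) <- paste0("intercept_", spec$traits)
  } else {
    r <- recs[[1]]
    X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    trial_based <- trait_info(spec$traits)$kind != "once"
    if (trial_based && "order" %in% spec$fixed)
      X <- cbind(X, order = r$order - mean(r$order))
    if (trial_based && "shelf" %in% spec$fixed)
      X <- cbind(X, shelf_upper = as.numeric(r$shelf == "upper"))
  }
  qrX <- qr(X)
  if (qrX$rank == 0) ige_error("ige_rank_zero", "fixed-effect matrix has rank 0")
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    warning(sprintf("dropping %d rank-deficient fixed-effect column(s): %s",
                    length(drop), paste(colnames(X)[drop], collapse = ", ")))
    X <- X[, -drop, drop = FALSE]
  }

  # ---- channel incidence ---------------------------------------------------
  channel_ids <- function(tr, role) {
    out <- rep(NA_character_, n)
    r <- recs[[tr]]
    rows <- which(tix == match(tr, spec$traits))
    out[rows] <- if (role == "direct") r$direct_id else r$indirect_id
    out
  }
  g_labels <- spec$g_channels$label
  g_ids <- lapply(seq_len(nrow(spec$g_channels)), function(i)
    channel_ids(spec$g_channels$trait[i], spec$g_channels$role[i]))
  names(g_ids) <- g_labels
  pe_labels <- if (is.null(spec$pe_channels)) character(0) else spec$pe_channels$label
  pe_ids <- lapply(seq_along(pe_labels), function(i)
    channel_ids(spec$pe_channels$trait[i], spec$pe_channels$role[i]))
  names(pe_ids) <- pe_labels

  # ---- dense kernels -------------------------------------------------------
  K <- list()
  for (i in seq_along(g_labels)) for (j in i:length(g_labels)) {
    ci <- g_ids[[i]]; cj <- g_ids[[j]]
    ai <- which(!is.na(ci)); aj <- which(!is.na(cj))
    M <- matrix(0, n, n)
    if (length(ai) && length(aj))
      M[ai, aj] <- A[ci[ai], cj[aj]]
    # off-diagonal channel pairs enter V as G_ij (Zi A Zj' + Zj A Zi');
    # store the symmetrised kernel so likelihood evaluations skip the t()
    if (i != j) M <- M + t(M)
    K[[paste(g_labels[i], g_labels[j], sep = "|")]] <- M
  }
  PE <- lapply(pe_ids, function(ci) {
    a <- which(!is.na(ci))
    M <- matrix(0, n, n)
    if (length(a)) M[a, a] <- outer(ci[a], ci[a], "==") + 0
    M
  })

  # ---- residual structure --------------------------------------------------
  same_trial <- NULL
  resid_cov_mode <- spec$resid_cov
  if (spec$bivariate) {
    k1 <- recs[[1]]$trial_key; k2 <- recs[[2]]$trial_key
    shared <- !all(is.na(k1)) && !all(is.na(k2)) && length(intersect(k1, k2)) > 0
    if (resid_cov_mode == "auto")
      resid_cov_mode <- if (shared) "estimate" else "zero"
    if (resid_cov_mode == "estimate") {
      if (!shared)
        ige_error("ige_resid_cov",
                  "cross-trait residual covariance requested but the traits share no trials")
      i1 <- which(tix == 1); i2 <- which(tix == 2)
      m <- match(k1, k2)
      ok <- which(!is.na(m))
      same_trial <- cbind(i1[ok], i2[m[ok]])
    }
  } else resid_cov_mode <- "zero"

  structure(list(y = y, X = X, n = n, tix = tix, traits = spec$traits,
                 spec = spec, K = K, PE = PE,
                 g_ids = g_ids, pe_ids = pe_ids, A = A,
                 g_labels = g_labels, pe_labels = pe_labels,
                 resid_cov_mode = resid_cov_mode, same_trial = same_trial,
                 logdetXtX = as.numeric(determinant(crossprod(X))$modulus)),
            class = "model_matrices")
}

#' @export
print.model_matrices <- function(x, ...) {
  cat(sprintf("model_matrices: %d records (%s), %d fixed-effect column(s),\n  genetic channels: %s\n  PE channels: %s\n",
              x$n, paste(x$traits, collapse = " + "), ncol(x$X),
              paste(x$g_labels, collapse = ", "),
              if (length(x$pe_labels)) paste(x$pe_labels, collapse = ", ") else "none"))
  invisible(x)
}
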