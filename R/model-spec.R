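# Model specification: which trait(s) are analysed, which genetic and
# permanent-environment channels are active, which fixed effects enter, and
# which components are constrained.

#' Specify an animal model for one or two traits
#'
#' Channel activation follows the trait registry: dyadic behaviours carry
#' direct and indirect genetic channels plus direct and indirect
#' permanent-environment (PE) channels; repeatedly measured morphology
#' carries direct genetic and direct PE channels only (the partner's
#' identity cannot influence a morphological trait); once-measured
#' morphology carries a direct genetic channel only, because a PE variance
#' is not identifiable from a single measurement per individual.
#'
#' Univariate models of trial-based traits include testing order (a centred
#' numeric covariate) and shelf (an upper-vs-lower contrast) as fixed
#' effects; once-measured traits get an intercept only. Bivariate models
#' are intercept-only (one intercept per trait), which eases convergence of
#' the constrained refits the likelihood-ratio tests require.
#'
#' @param traits one or two trait names from [trait_registry()].
#' @param fixed fixed effects for univariate trial-based models; any subset
#'   of `c("order", "shelf")`. Ignored (forced empty) for bivariate models.
#' @param constraints list with elements `zero_var` (channel labels whose
#'   variance is fixed to 0, dropping the channel) and `zero_cov` (list of
#'   2-vectors of channel labels whose genetic covariance is pinned to 0).
#' @param resid_cov `"auto"` fixes the cross-trait residual covariance to 0
#'   unless the two traits are observed on the same trials, in which case it
#'   is estimated; `"zero"` and `"estimate"` force either choice.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(traits, fixed = c("order", "shelf"),
                       constraints = list(), resid_cov = "auto") {
  stopifnot(length(traits) %in% 1:2)
  reg <- trait_registry()
  if (!all(traits %in% reg$trait))
    ige_error("ige_unknown_trait",
              paste("unknown trait(s):", paste(setdiff(traits, reg$trait), collapse = ", ")))
  bivariate <- length(traits) == 2
  if (bivariate) fixed <- character(0)
  fixed <- intersect(fixed, c("order", "shelf"))
  gch <- do.call(rbind, lapply(traits, trait_channels))
  pe_ch <- do.call(rbind, lapply(traits, function(tr) {
    info <- trait_info(tr)
    if (info$kind == "dyadic") trait_channels(tr)
    else if (info$kind == "repeated") trait_channels(tr)[1, , drop = FALSE]
    else NULL
  }))
  constraints <- modifyList(list(zero_var = character(0), zero_cov = list()),
                            constraints)
  pe_ok <- if (is.null(pe_ch)) character(0) else paste0("pe:", pe_ch$label)
  bad <- setdiff(constraints$zero_var, c(gch$label, pe_ok))
  if (length(bad))
    ige_error("ige_bad_constraint",
              paste("constraint references unknown channel(s):", paste(bad, collapse = ", ")))
  for (pr in constraints$zero_cov)
    if (!all(pr %in% gch$label))
      ige_error("ige_bad_constraint",
                paste("covariance constraint references unknown channel(s):",
                      paste(pr, collapse = ", ")))
  structure(list(traits = traits, bivariate = bivariate, fixed = fixed,
                 g_channels = gch, pe_channels = pe_ch,
                 constraints = constraints, resid_cov = resid_cov),
            class = "model_spec")
}

#' Add constraints to an existing model specification
#'
#' @param spec a `model_spec`.
#' @param zero_var channel labels whose variance is additionally fixed to 0.
#' @param zero_cov list of channel-label pairs whose covariance is
#'   additionally pinned to 0.
#' @return the modified `model_spec`.
#' @export
constrain <- function(spec, zero_var = character(0), zero_cov = list()) {
  spec$constraints$zero_var <- union(spec$constraints$zero_var, zero_var)
  spec$constraints$zero_cov <- c(spec$constraints$zero_cov, zero_cov)
  spec
}
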