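# Genetic channels and the additive (co)variance matrix G0 over them.
#
# A "channel" is one axis of the genetic architecture: a trait together with
# the role its carrier plays in a dyad -- `direct` (the expresser's own
# genotype, a DGE) or `indirect` (the partner's genotype, an IGE). All G
# matrices in the package are indexed by channel labels "trait:role".

#' Built-in trait registry
#'
#' The seven traits of a sequential mate-choice assay: three behaviours
#' scored per trial (male latency to sing and guarding distance expressed by
#' the male, latency to mount expressed by the female), per-trial body mass
#' of both sexes, and two once-dissected male morphologies.
#'
#' @return data.frame with columns `trait`, `expresser` (`"M"`/`"F"`),
#'   `kind` (`dyadic`, `repeated`, `once`). Dyadic traits carry direct and
#'   indirect channels; `repeated` traits carry a direct genetic and a
#'   direct permanent-environment channel; `once` traits carry only a direct
#'   genetic channel (no permanent environment is identifiable from a single
#'   measurement).
#' @export
trait_registry <- function() {
  data.frame(
    trait = c("lat_sing", "lat_mount", "guard_dist",
              "male_mass", "female_mass", "mandible", "testis"),
    expresser = c("M", "F", "M", "M", "F", "M", "M"),
    kind = c("dyadic", "dyadic", "dyadic",
             "repeated", "repeated", "once", "once"),
    stringsAsFactors = FALSE
  )
}

trait_info <- function(trait) {
  reg <- trait_registry()
  i <- match(trait, reg$trait)
  if (is.na(i)) ige_error("ige_unknown_trait", paste("unknown trait:", trait))
  reg[i, ]
}

channel_label <- function(trait, role) paste(trait, role, sep = ":")

# Channels a trait contributes to the genetic architecture.
trait_channels <- function(trait) {
  info <- trait_info(trait)
  if (info$kind == "dyadic") {
    data.frame(trait = trait, role = c("direct", "indirect"),
               label = channel_label(trait, c("direct", "indirect")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(trait = trait, role = "direct",
               label = channel_label(trait, "direct"),
               stringsAsFactors = FALSE)
  }
}

#' Additive genetic covariance over a set of channels
#'
#' @param G0 symmetric positive-semidefinite matrix of additive
#'   (co)variances on the z-score scale, with dimnames equal to channel
#'   labels (`"trait:direct"` / `"trait:indirect"`).
#' @return object of class `genetic_covariance` with elements `channels`
#'   (data.frame trait/role/label) and `G0`.
#' @export
genetic_covariance <- function(G0) {
  G0 <- as.matrix(G0)
  labs <- rownames(G0)
  if (is.null(labs) || is.null(colnames(G0)) || !identical(labs, colnames(G0)))
    ige_error("ige_bad_channels", "G0 must have identical row/col channel labels")
  if (anyDuplicated(labs))
    ige_error("ige_bad_channels", "duplicate channel labels")
  if (max(abs(G0 - t(G0))) > 1e-10)
    ige_error("ige_not_symmetric", "G0 must be symmetric")
  if (any(diag(G0) < 0) || !is_psd(G0))
    ige_error("ige_not_psd", "G0 must be positive semidefinite")
  parts <- strsplit(labs, ":", fixed = TRUE)
  channels <- data.frame(trait = vapply(parts, `[`, "", 1),
                         role = vapply(parts, `[`, "", 2),
                         label = labs, stringsAsFactors = FALSE)
  if (!all(channels$role %in% c("direct", "indirect")))
    ige_error("ige_bad_channels", "channel roles must be 'direct' or 'indirect'")
  structure(list(channels = channels, G0 = G0), class = "genetic_covariance")
}

#' Genetic correlation between two channels
#'
#' r = G_ij / sqrt(G_ii G_jj). A channel with zero additive variance has no
#' defined correlation; this mirrors the situation where a trait shows no
#' genetic variance and its correlations cannot be estimated.
#'
#' @param g a `genetic_covariance`, or any symmetric matrix with channel
#'   dimnames.
#' @param i,j channel labels (or indices).
#' @return the correlation, a scalar in `[-1, 1]`.
#' @export
genetic_correlation <- function(g, i, j) {
  G <- if (inherits(g, "genetic_covariance")) g$G0 else as.matrix(g)
  vi <- G[i, i]; vj <- G[j, j]
  if (vi <= 0 || vj <= 0)
    ige_error("ige_undefined_correlation",
              "correlation undefined: a channel has zero additive variance")
  G[i, j] / sqrt(vi * vj)
}
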