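#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq rnorm runif rbinom optim nlminb optimHess sd var
#'   aov qnorm setNames complete.cases
#' @importFrom utils read.csv write.csv modifyList
NULL

# Run expr with a local RNG state seeded at `seed`, restoring the caller's
# stream afterwards so library code never clobbers user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Structured condition constructor: all igemate errors carry a subclass so
# callers can distinguish validation failures programmatically.
ige_error <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    list(message = message, call = call),
    class = c(subclass, "igemate_error", "error", "condition")
  ))
}

#' Standardise a numeric vector to zero mean and unit variance
#'
#' Trait scores are placed on the z-score scale before variance partitioning
#' so that variance components are comparable across traits. Missing values
#' are ignored when computing the centre and scale.
#'
#' @param x numeric vector.
#' @return numeric vector with mean 0 and standard deviation 1 (attributes
#'   `center` and `scale` record the transformation).
#' @export
z_transform <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    ige_error("ige_degenerate_trait", "trait has zero variance; cannot z-transform")
  out <- (x - m) / s
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Reverse-score a trait vector
#'
#' Latency-type traits are multiplied by -1 so that higher scores reflect
#' greater mating motivation (for the expresser) or greater attractiveness
#' (for the partner driving the indirect effect). Applying the function twice
#' returns the original values.
#'
#' @param values numeric vector of trait scores.
#' @return the elementwise negation of `values`.
#' @export
reverse_score <- function(values) -values

# Symmetric PSD square root used wherever a covariance matrix may be
# singular (e.g. an all-zero G); plain chol() would fail there.
psd_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -tol * max(abs(lam), 1))
    ige_error("ige_not_psd", "covariance matrix is not positive semidefinite")
  e$vectors %*% (sqrt(pmax(lam, 0)) * t(e$vectors))
}

is_psd <- function(S, tol = 1e-8) {
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(lam) >= -tol * max(abs(lam), 1)
}
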