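# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: kinship is computed by naive recursion, the
# restricted likelihood by the error-contrast definition, and V by direct
# record-by-record assembly from A.

# Brute-force kinship by recursion with memoisation; A = 2 * kinship.
# Independent of the tabular method in relationship_matrix().
kinship_oracle_A <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  f <- matrix(NA_real_, n, n)
  kin <- function(i, j) {
    if (!is.na(f[i, j])) return(f[i, j])
    v <- if (i == j) {
      0.5 * (1 + if (!is.na(s[i]) && !is.na(d[i])) kin(s[i], d[i]) else 0)
    } else {
      a <- max(i, j); b <- min(i, j) # a is the later individual
      out <- 0
      if (!is.na(s[a])) out <- out + 0.5 * kin(s[a], b)
      if (!is.na(d[a])) out <- out + 0.5 * kin(d[a], b)
      out
    }
    f[i, j] <<- v
    f[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in i:n) kin(i, j)
  A <- 2 * f
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# Random multi-generation pedigree: founders plus individuals whose parents
# are drawn from earlier generations, occasionally unknown.
random_pedigree <- function(n = 40, n_founders = 8, seed = 1,
                            p_unknown = 0.1) {
  set.seed(seed)
  n_founders <- max(n_founders, 2)
  id <- sprintf("I%03d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F") # both sexes among founders
  sire <- dam <- rep(NA_character_, n)
  pick <- function(pool) if (length(pool)) id[pool[sample.int(length(pool), 1)]] else NA_character_
  for (i in seq(n_founders + 1, n)) {
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (runif(1) > p_unknown) sire[i] <- pick(males)
    if (runif(1) > p_unknown) dam[i] <- pick(females)
  }
  pedigree(id, sire, dam, sex)
}

# V assembled record by record from A and the incidence maps, independent
# of the kernel bookkeeping inside the package.
naive_V <- function(mm, vc) {
  n <- mm$n
  A <- mm$A
  V <- matrix(0, n, n)
  for (r in seq_len(n)) for (s in seq_len(n)) {
    v <- 0
    for (ci in mm$g_labels) for (cj in mm$g_labels) {
      ir <- mm$g_ids[[ci]][r]; js <- mm$g_ids[[cj]][s]
      if (!is.na(ir) && !is.na(js))
        v <- v + vc$G[ci, cj] * A[ir, js]
    }
    for (cp in mm$pe_labels) {
      ir <- mm$pe_ids[[cp]][r]; js <- mm$pe_ids[[cp]][s]
      pvar <- if (cp %in% names(vc$pe)) vc$pe[[cp]] else 0
      if (!is.na(ir) && !is.na(js) && ir == js) v <- v + pvar
    }
    if (r == s) v <- v + vc$resid[[mm$traits[mm$tix[r]]]]
    V[r, s] <- v
  }
  V
}

# Restricted likelihood by the error-contrast definition: project y onto an
# orthonormal basis of the null space of X' and evaluate the plain
# multivariate-normal density of the contrasts.
ec_reml_oracle <- function(mm, vc, V = NULL) {
  if (is.null(V)) V <- naive_V(mm, vc)
  X <- mm$X
  n <- mm$n
  p <- ncol(X)
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  w <- crossprod(K, mm$y)
  M <- crossprod(K, V %*% K)
  as.numeric(-0.5 * (determinant(M)$modulus + t(w) %*% solve(M, w) +
                       (n - p) * log(2 * pi)))
}

# Random admissible variance components for a model's channel structure.
random_vc <- function(mm, seed = 1) {
  set.seed(seed)
  k <- length(mm$g_labels)
  B <- matrix(rnorm(k * k, sd = 0.4), k)
  G <- crossprod(B)
  dimnames(G) <- list(mm$g_labels, mm$g_labels)
  pe <- setNames(runif(length(mm$pe_labels), 0.02, 0.3), mm$pe_labels)
  resid <- setNames(runif(length(mm$traits), 0.3, 1), mm$traits)
  variance_components(G, pe, resid)
}

# A small dyadic data set (pedigree + trials + morphology) for model tests.
small_dataset <- function(n_sires = 3, seed = 5) {
  pre <- study_scale_preset(n_sires = n_sires)
  simulate_dataset(pre, seed = seed)
}
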