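# Synthetic-data generator.
#
# Emulates the statistical structure the animal model assumes: multivariate
# breeding values flowing down a half-sib pedigree, sequential male-female
# mating trials in which each behavioural score receives direct (expresser)
# and indirect (partner) genetic and permanent-environment contributions,
# repeated body-mass measures, and once-dissected morphology.

#' Permanent-environment and residual configuration
#'
#' @param pe named numeric vector of permanent-environment variances, one
#'   per channel label (`"trait:role"`); channels absent from the vector get
#'   variance 0. Once-measured traits must not carry PE variance.
#' @param resid named numeric vector of residual variances, one per trait.
#' @param beta list with elements `intercept`, `order`, `shelf`: named
#'   per-trait fixed-effect coefficients (testing order enters as the raw
#'   1-3 covariate; shelf as an upper-vs-lower contrast). Traits absent from
#'   a component get coefficient 0 (intercept included).
#' @param resid_trial_cor correlation between the residuals of behavioural
#'   traits observed on the same trial (default 0: independent residuals).
#' @return object of class `environment_config`.
#' @export
environment_config <- function(pe = numeric(), resid, beta = list(),
                               resid_trial_cor = 0) {
  stopifnot(all(pe >= 0), all(resid > 0),
            resid_trial_cor >= 0, resid_trial_cor < 1)
  once <- trait_registry()$trait[trait_registry()$kind == "once"]
  bad <- intersect(names(pe), channel_label(once, "direct"))
  if (length(bad) && any(pe[bad] > 0))
    ige_error("ige_bad_pe", "once-measured traits cannot have permanent-environment variance")
  structure(list(pe = pe, resid = resid, beta = beta,
                 resid_trial_cor = resid_trial_cor),
            class = "environment_config")
}

#' Design of the sequential mating assays
#'
#' Each focal male is paired with 1-3 distinct females, one trial per day;
#' trial order within a male increments 1, 2, 3. Partners are drawn without
#' replacement from the pool of unmated females until the pool is exhausted,
#' after which reuse is allowed (never pairing the same dyad twice).
#'
#' @param target_assays total number of trials to realise; the per-male
#'   trial counts drawn from `trial_probs` are adjusted (trials trimmed from
#'   or added to randomly chosen males) to hit the target exactly when it is
#'   feasible, i.e. between 1 and 3 trials per male.
#' @param trial_probs probabilities of a male receiving 1, 2 or 3 trials.
#' @param allow_reuse logical; if `FALSE` and the design needs more partners
#'   than the pedigree supplies, an error is raised.
#' @return object of class `assay_design`.
#' @export
assay_design <- function(target_assays = NULL,
                         trial_probs = c(0.06, 0.215, 0.725),
                         allow_reuse = TRUE) {
  stopifnot(length(trial_probs) == 3, all(trial_probs >= 0))
  structure(list(target_assays = target_assays,
                 trial_probs = trial_probs / sum(trial_probs),
                 allow_reuse = allow_reuse),
            class = "assay_design")
}

#' Sample breeding values down a pedigree
#'
#' Founders receive i.i.d. multivariate-normal vectors with covariance
#' `G0`; each offspring receives the parental average plus an independent
#' Mendelian-sampling deviation with covariance
#' `(0.5 - 0.25 (F_sire + F_dam)) * G0` (0.75 or 1 times G0 with one or both
#' parents unknown). Marginally every pair satisfies
#' `cov(a_i[c], a_j[d]) = A_ij * G0[c, d]`.
#'
#' @param ped a `pedigree`.
#' @param g a `genetic_covariance`.
#' @param seed integer seed.
#' @return numeric matrix (individuals x channels) with pedigree ids as row
#'   names and channel labels as column names.
#' @export
sample_breeding_values <- function(ped, g, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"), inherits(g, "genetic_covariance"))
  k <- nrow(g$G0)
  L <- psd_sqrt(g$G0)
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  Fi <- relationship_matrix(ped)$F[ped$id] # exact, so inbred pedigrees work too
  bv <- matrix(0, n, k, dimnames = list(ped$id, rownames(g$G0)))
  with_seed(seed, {
    for (i in seq_len(n)) {
      par <- c(s[i], d[i]); par <- par[!is.na(par)]
      z <- rnorm(k)
      if (length(par) == 0) {
        bv[i, ] <- as.vector(L %*% z)
      } else {
        mid <- colSums(bv[par, , drop = FALSE]) / 2
        dvar <- mendelian_variance(Fi[par])
        bv[i, ] <- mid + sqrt(dvar) * as.vector(L %*% z)
      }
    }
  })
  bv
}

# Draw permanent-environment values: one value per individual per PE channel.
sample_pe_values <- function(ids, pe_var) {
  out <- lapply(names(pe_var), function(lab) {
    setNames(rnorm(length(ids), sd = sqrt(pe_var[[lab]])), ids)
  })
  names(out) <- names(pe_var)
  out
}

beta_of <- function(beta, comp, trait) {
  v <- beta[[comp]]
  if (is.null(v) || is.na(v[trait]) || is.null(v[trait])) 0 else unname(v[trait])
}

#' Simulate sequential mating trials and morphology
#'
#' Generates the dyadic trial table and the once-measured morphology table
#' implied by a pedigree, a table of breeding values, an environment
#' configuration and an assay design. For a male-expressed behavioural
#' trait in a trial pairing male m with female f,
#' `y = b0 + b_order * order + b_shelf * [shelf = upper] + a_direct(m) +
#' a_indirect(f) + pe_direct(m) + pe_indirect(f) + e`; female-expressed
#' traits swap the roles. Body mass is simulated per trial from direct
#' genetic plus permanent-environment plus residual components; mandible
#' and testis size once per male with no permanent-environment term.
#'
#' @param ped a `pedigree`.
#' @param bv breeding-value matrix from [sample_breeding_values()]; must
#'   contain every channel demanded by `env`/the trait registry.
#' @param env an `environment_config`.
#' @param design an `assay_design`.
#' @param seed integer seed; output is deterministic given the seed.
#' @param traits character vector of traits to simulate (default: all seven
#'   registry traits whose channels appear in `bv`).
#' @return list with `trials` (data.frame `male_id, female_id, order, shelf,
#'   <behaviour columns>, male_mass, female_mass`) and `morph` (data.frame
#'   `id, trait, value, occasion`).
#' @export
simulate_trials <- function(ped, bv, env, design, seed = 1L, traits = NULL) {
  reg <- trait_registry()
  if (is.null(traits)) {
    traits <- reg$trait[vapply(reg$trait, function(tr)
      all(trait_channels(tr)$label %in% colnames(bv)), TRUE)]
  }
  missing_ch <- setdiff(unlist(lapply(traits, function(tr) trait_channels(tr)$label)),
                        colnames(bv))
  if (length(missing_ch))
    ige_error("ige_missing_channel",
              paste("breeding values lack channel(s):", paste(missing_ch, collapse = ", ")))
  males <- ped$id[!ped$founder & ped$sex == "M"]
  females <- ped$id[!ped$founder & ped$sex == "F"]
  if (!length(males) || !length(females))
    ige_error("ige_design_infeasible", "pedigree supplies no non-founder males or females")

  with_seed(seed, {
    # -- per-male trial counts, adjusted to the target assay total ----------
    n_trials <- sample(1:3, length(males), replace = TRUE, prob = design$trial_probs)
    if (!is.null(design$target_assays)) {
      target <- design$target_assays
      if (target < length(males)) {
        keep <- sort(sample(seq_along(males), target))
        males <- males[keep]
        n_trials <- rep(1L, target)
      } else {
        # a target beyond 3 trials per available male is unreachable;
        # realise the closest feasible schedule instead
        target <- min(target, 3L * length(males))
        while (sum(n_trials) > target) {
          i <- sample(which(n_trials > 1L), 1)
          n_trials[i] <- n_trials[i] - 1L
        }
        while (sum(n_trials) < target) {
          i <- sample(which(n_trials < 3L), 1)
          n_trials[i] <- n_trials[i] + 1L
        }
      }
    }
    n_assay <- sum(n_trials)
    if (!design$allow_reuse && n_assay > length(females))
      ige_error("ige_design_infeasible",
                sprintf("design needs %d partners but only %d females exist and reuse is disabled",
                        n_assay, length(females)))
    # -- partner assignment: a shuffled queue, reuse after exhaustion -------
    queue <- sample(females)
    used <- list()
    pick_partner <- function(m) {
      if (length(queue)) {
        f <- queue[1]; queue <<- queue[-1]
      } else {
        avoid <- used[[m]]
        pool <- setdiff(females, avoid)
        if (!length(pool)) pool <- females
        f <- sample(pool, 1)
      }
      used[[m]] <<- c(used[[m]], f)
      f
    }
    rows <- vector("list", n_assay)
    k <- 0L
    for (mi in seq_along(males)) {
      for (ord in seq_len(n_trials[mi])) {
        k <- k + 1L
        rows[[k]] <- data.frame(male_id = males[mi],
                                female_id = pick_partner(males[mi]),
                                order = ord,
                                shelf = sample(c("lower", "upper"), 1),
                                stringsAsFactors = FALSE)
      }
    }
    trials <- do.call(rbind, rows)

    # -- permanent-environment draws ---------------------------------------
    pe_vals <- sample_pe_values(ped$id, as.list(env$pe))
    pe_of <- function(lab, ids) {
      if (lab %in% names(pe_vals)) pe_vals[[lab]][ids] else rep(0, length(ids))
    }
    n <- nrow(trials)
    shelf_up <- as.numeric(trials$shelf == "upper")
    rho <- env$resid_trial_cor
    trial_shock <- if (rho > 0) rnorm(n) else numeric(n)

    trial_traits <- traits[reg$kind[match(traits, reg$trait)] != "once"]
    for (tr in trial_traits) {
      info <- trait_info(tr)
      if (info$expresser == "M") { foc <- trials$male_id; par <- trials$female_id }
      else { foc <- trials$female_id; par <- trials$male_id }
      y <- beta_of(env$beta, "intercept", tr) +
        beta_of(env$beta, "order", tr) * trials$order +
        beta_of(env$beta, "shelf", tr) * shelf_up +
        bv[foc, channel_label(tr, "direct")] +
        pe_of(channel_label(tr, "direct"), foc)
      if (info$kind == "dyadic") {
        y <- y + bv[par, channel_label(tr, "indirect")] +
          pe_of(channel_label(tr, "indirect"), par)
      }
      vr <- env$resid[[tr]]
      eps <- if (rho > 0)
        sqrt(vr) * (sqrt(rho) * trial_shock + sqrt(1 - rho) * rnorm(n))
      else rnorm(n, sd = sqrt(vr))
      trials[[tr]] <- as.numeric(y + eps)
    }

    # -- once-measured morphology ------------------------------------------
    once_traits <- traits[reg$kind[match(traits, reg$trait)] == "once"]
    morph <- do.call(rbind, lapply(once_traits, function(tr) {
      info <- trait_info(tr)
      ids <- if (info$expresser == "M") males else unique(trials$female_id)
      data.frame(id = ids, trait = tr,
                 value = as.numeric(
                   beta_of(env$beta, "intercept", tr) +
                     bv[ids, channel_label(tr, "direct")] +
                     rnorm(length(ids), sd = sqrt(env$resid[[tr]]))),
                 occasion = 1L, stringsAsFactors = FALSE)
    }))
    if (is.null(morph)) morph <- data.frame(id = character(), trait = character(),
                                            value = numeric(), occasion = integer())
    list(trials = trials, morph = morph)
  })
}

#' Study-scale simulation preset
#'
#' Parameters emulating the realised breeding design and assay schedule the
#' analysis is built for: 35 sires each mated to 2 dams with a family
#' failure rate leaving about 66 full-sib families, roughly 16 offspring per
#' family with a female-biased tested sex ratio giving about 310 phenotyped
#' males and 747 phenotyped females, and 826 sequential mating assays with
#' 1-3 trials per male. Genetic defaults place moderate additive variance in
#' each behavioural channel (direct 0.15, indirect 0.10, direct-indirect
#' covariance 0.05), strong direct variance in morphology, and zero genetic
#' variance in guarding distance; permanent-environment variances are 0.10
#' per behavioural channel and residual variances 0.60.
#'
#' @param n_sires number of sires; scale the whole design down by lowering
#'   it (dams, families, offspring and assay targets shrink proportionally).
#' @return list with elements `pedigree_pars`, `design`, `g`
#'   (`genetic_covariance`), `env` (`environment_config`), `traits`.
#' @export
study_scale_preset <- function(n_sires = 35) {
  scale <- n_sires / 35
  reg <- trait_registry()
  labs <- unlist(lapply(reg$trait, function(tr) trait_channels(tr)$label))
  G0 <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (tr in c("lat_sing", "lat_mount")) {
    dl <- channel_label(tr, "direct"); il <- channel_label(tr, "indirect")
    G0[dl, dl] <- 0.15; G0[il, il] <- 0.10
    G0[dl, il] <- G0[il, dl] <- 0.05
  }
  # guarding distance: no additive variance in either channel
  for (lab in c("male_mass:direct", "female_mass:direct"))
    G0[lab, lab] <- 0.30
  G0["mandible:direct", "mandible:direct"] <- 0.40
  G0["testis:direct", "testis:direct"] <- 0.40
  pe <- c("lat_sing:direct" = 0.10, "lat_sing:indirect" = 0.10,
          "lat_mount:direct" = 0.10, "lat_mount:indirect" = 0.10,
          "guard_dist:direct" = 0.10, "guard_dist:indirect" = 0.10,
          "male_mass:direct" = 0.20, "female_mass:direct" = 0.20)
  resid <- c(lat_sing = 0.60, lat_mount = 0.60, guard_dist = 0.80,
             male_mass = 0.50, female_mass = 0.50,
             mandible = 0.60, testis = 0.60)
  beta <- list(intercept = c(lat_sing = 0, lat_mount = 0, guard_dist = 0,
                             male_mass = 0, female_mass = 0,
                             mandible = 0, testis = 0),
               order = c(lat_sing = 0.10, lat_mount = 0.10, guard_dist = 0.10),
               shelf = c(lat_sing = 0.20, lat_mount = 0.20, guard_dist = 0.20))
  list(
    pedigree_pars = list(n_sires = n_sires, dams_per_sire = 2,
                         offspring_per_family = 16,
                         family_failure_rate = 0.057, prop_female = 0.707),
    design = assay_design(target_assays = round(826 * scale)),
    g = genetic_covariance(G0),
    env = environment_config(pe = pe, resid = resid, beta = beta),
    traits = reg$trait
  )
}

#' Simulate a complete data set from a preset
#'
#' Convenience wrapper: builds the half-sib pedigree, samples breeding
#' values, and simulates trials and morphology, all from one preset and one
#' seed (sub-seeds for the three stages are derived from it).
#'
#' @param preset a list as returned by [study_scale_preset()].
#' @param seed integer master seed.
#' @return list with `ped`, `bv`, `trials`, `morph`.
#' @export
simulate_dataset <- function(preset, seed = 1L) {
  pp <- preset$pedigree_pars
  ped <- build_half_sib_design(pp$n_sires, pp$dams_per_sire,
                               pp$offspring_per_family,
                               pp$family_failure_rate, pp$prop_female,
                               seed = seed)
  bv <- sample_breeding_values(ped, preset$g, seed = seed + 1000L)
  sim <- simulate_trials(ped, bv, preset$env, preset$design,
                         seed = seed + 2000L, traits = preset$traits)
  c(list(ped = ped, bv = bv), sim)
}
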