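# Configuration-driven orchestration: simulate (or load) data, standardise
# and reverse-score, fit the univariate suite with variance LRTs and total
# heritable variances, select channel pairs, fit the bivariate suite, and
# write a correlation report with full seed provenance.

#' Prepare trial and morphology tables for variance partitioning
#'
#' z-transforms every trait column and (optionally) reverse-scores the two
#' latency traits so that higher scores reflect greater mating motivation /
#' attractiveness. Variance components are invariant to the sign flip; the
#' signs of covariances involving a latency channel flip with it.
#'
#' @param trials trial table.
#' @param morph morphology table.
#' @param reverse_latencies logical; reverse-score `lat_sing`, `lat_mount`.
#' @return list with transformed `trials` and `morph`.
#' @export
prep_tables <- function(trials, morph, reverse_latencies = TRUE) {
  reg <- trait_registry()
  for (tr in intersect(reg$trait, names(trials))) {
    x <- z_transform(trials[[tr]])
    if (reverse_latencies && tr %in% c("lat_sing", "lat_mount")) x <- reverse_score(x)
    trials[[tr]] <- as.numeric(x)
  }
  if (nrow(morph)) {
    for (tr in unique(morph$trait)) {
      i <- morph$trait == tr
      morph$value[i] <- as.numeric(z_transform(morph$value[i]))
    }
  }
  list(trials = trials, morph = morph)
}

#' Univariate variance partitioning of one trait
#'
#' Fits the univariate animal model for a trait (direct + indirect genetic
#' and permanent-environment channels for dyadic behaviours; direct-only
#' for morphology; no PE for once-measured traits), then likelihood-ratio
#' tests every genetic variance (boundary mixture convention) and, for
#' dyadic traits, the direct-indirect covariance (chi-square 1 df), and
#' computes the total heritable variance.
#'
#' @param trials,morph prepared tables (see [prep_tables()]).
#' @param ped a `pedigree`.
#' @param trait trait name.
#' @param seed integer seed for optimiser restarts.
#' @param n_restarts restarts for the full fit.
#' @param zero_channels genetic channel labels constrained to zero variance
#'   throughout (e.g. both guarding channels when its additive variance is
#'   taken as null); constrained channels are reported as 0 with no test.
#' @return list with `fit`, `components` (data.frame: component, estimate,
#'   se, lrt, convention, p, boundary), `v_tbv` (dyadic traits; `NA`
#'   otherwise).
#' @export
fit_univariate <- function(trials, morph, ped, trait, seed = 1L,
                           n_restarts = 2L, zero_channels = character(0)) {
  dlab <- channel_label(trait, "direct")
  ilab <- channel_label(trait, "indirect")
  my_zero <- intersect(zero_channels, c(dlab, ilab))
  spec <- model_spec(trait, constraints = list(zero_var = my_zero))
  mm <- build_mixed_model(trials, morph, ped, spec)
  full <- fit(mm, seed = seed, n_restarts = n_restarts)
  info <- trait_info(trait)
  rows <- list()
  add_row <- function(component, estimate, se, lrt_res, boundary) {
    rows[[length(rows) + 1]] <<- data.frame(
      trait = trait, component = component, estimate = estimate,
      se = if (is.null(se) || is.na(se)) NA_real_ else se,
      lrt = if (is.null(lrt_res)) NA_real_ else lrt_res$statistic,
      convention = if (is.null(lrt_res)) NA_character_ else lrt_res$convention,
      p = if (is.null(lrt_res)) NA_real_ else lrt_res$p,
      boundary = boundary, stringsAsFactors = FALSE)
  }
  se_of <- function(field, lab) {
    if (is.null(full$se)) NA_real_
    else {
      v <- full$se[[field]][lab]
      if (is.null(v)) NA_real_ else unname(v)
    }
  }
  # direct genetic variance
  if (dlab %in% my_zero) {
    add_row("V_A_direct", 0, NA_real_, NULL, TRUE)
  } else {
    t1 <- lrt_component(mm, full, dlab, seed = seed)
    full <- t1$fit_full
    add_row("V_A_direct", full$vc$G[dlab, dlab], se_of("variances", dlab),
            t1$lrt, dlab %in% full$boundary$variances)
  }
  v_tbv <- NA_real_
  if (info$kind == "dyadic") {
    if (ilab %in% my_zero) {
      add_row("V_A_indirect", 0, NA_real_, NULL, TRUE)
    } else {
      t2 <- lrt_component(mm, full, ilab, seed = seed + 1L)
      full <- t2$fit_full
      add_row("V_A_indirect", full$vc$G[ilab, ilab], se_of("variances", ilab),
              t2$lrt, ilab %in% full$boundary$variances)
    }
    if (!length(my_zero)) {
      t3 <- lrt_component(mm, full, c(dlab, ilab), seed = seed + 2L)
      full <- t3$fit_full
      add_row("COV_A_direct_indirect", full$vc$G[dlab, ilab],
              se_of("covariances", paste(dlab, ilab, sep = "~")), t3$lrt,
              paste(dlab, ilab, sep = "~") %in% full$boundary$correlations)
    } else {
      add_row("COV_A_direct_indirect", 0, NA_real_, NULL, TRUE)
    }
    v_tbv <- total_heritable_variance(full$vc$G[dlab, dlab],
                                      full$vc$G[ilab, ilab],
                                      full$vc$G[dlab, ilab])
    add_row("V_TBV", v_tbv, NA_real_, NULL, FALSE)
  }
  for (lab in mm$pe_labels)
    add_row(paste0("V_PE_", sub(".*:", "", lab)), full$vc$pe[[lab]],
            se_of("pe", lab), NULL, lab %in% full$boundary$variances)
  add_row("V_R", full$vc$resid[[trait]], se_of("resid", trait), NULL, FALSE)
  list(fit = full, components = do.call(rbind, rows), v_tbv = v_tbv, mm = mm)
}

#' Univariate suite over several traits
#'
#' @inheritParams fit_univariate
#' @param traits trait names (default: every registry trait present in the
#'   data).
#' @return named list of [fit_univariate()] results.
#' @export
fit_univariate_suite <- function(trials, morph, ped, traits = NULL,
                                 seed = 1L, n_restarts = 2L,
                                 zero_channels = character(0)) {
  reg <- trait_registry()
  if (is.null(traits))
    traits <- reg$trait[reg$trait %in% c(names(trials), unique(morph$trait))]
  res <- list()
  for (i in seq_along(traits)) {
    res[[traits[i]]] <- fit_univariate(trials, morph, ped, traits[i],
                                       seed = seed + 10L * i,
                                       n_restarts = n_restarts,
                                       zero_channels = zero_channels)
  }
  res
}

# p-value of the variance LRT for one channel, from a univariate suite.
channel_variance_p <- function(uni, label) {
  trait <- sub(":.*", "", label)
  role <- sub(".*:", "", label)
  comp <- paste0("V_A_", role)
  u <- uni[[trait]]
  if (is.null(u)) return(NA_real_)
  tab <- u$components
  p <- tab$p[tab$component == comp]
  if (length(p)) p[1] else NA_real_
}

#' Select channel pairs for bivariate estimation
#'
#' The default policy mirrors restricting bivariate models to traits that
#' both showed significant additive genetic effects: a declared channel
#' pair is kept only when the variance LRT of each member channel is
#' significant at `alpha` in the univariate suite. `"all"` keeps every
#' declared pair.
#'
#' @param uni a univariate suite from [fit_univariate_suite()].
#' @param pairs list of 2-vectors of channel labels.
#' @param policy `"significant_both"` or `"all"`.
#' @param alpha significance gate (default 0.05).
#' @return the retained subset of `pairs`.
#' @export
select_pairs <- function(uni, pairs, policy = c("significant_both", "all"),
                         alpha = 0.05) {
  policy <- match.arg(policy)
  if (policy == "all") return(pairs)
  keep <- vapply(pairs, function(pr) {
    p1 <- channel_variance_p(uni, pr[1])
    p2 <- channel_variance_p(uni, pr[2])
    isTRUE(p1 < alpha) && isTRUE(p2 < alpha)
  }, TRUE)
  pairs[keep]
}

#' Genetic correlation between two channels from a bivariate fit
#'
#' For channels of two different traits, fits the intercept-only bivariate
#' animal model of both traits and extracts the focal correlation, its
#' curvature-based standard error, and the chi-square (1 df)
#' likelihood-ratio test of the focal covariance. For two channels of the
#' same trait the univariate fit already contains the correlation and is
#' reused. A channel whose additive variance is at the zero boundary gets
#' `r = NA` with a flag instead of a number.
#'
#' @param trials,morph prepared tables.
#' @param ped a `pedigree`.
#' @param pair 2-vector of channel labels.
#' @param uni optional univariate suite (needed for same-trait pairs).
#' @param seed,n_restarts optimiser controls.
#' @param zero_channels genetic channels constrained to zero variance; a
#'   pair touching one is unestimable and reported `NA` with a flag.
#' @return one-row data.frame: `pair_label, r, se, lrt, df_convention, p,
#'   significant, boundary`.
#' @export
fit_bivariate_pair <- function(trials, morph, ped, pair, uni = NULL,
                               seed = 1L, n_restarts = 2L,
                               zero_channels = character(0)) {
  traits <- unique(sub(":.*", "", pair))
  pair_label <- paste(pair, collapse = " ~ ")
  if (any(pair %in% zero_channels))
    return(data.frame(pair_label = pair_label, r = NA_real_, se = NA_real_,
                      lrt = NA_real_, df_convention = "chi2_df1",
                      p = NA_real_, significant = FALSE, boundary = TRUE,
                      stringsAsFactors = FALSE))
  if (length(traits) == 1) {
    if (is.null(uni) || is.null(uni[[traits]]))
      ige_error("ige_bad_input",
                "same-trait channel pair needs the univariate suite")
    u <- uni[[traits]]
    full <- u$fit
    mm <- u$mm
  } else {
    spec <- model_spec(traits)
    mm <- build_mixed_model(trials, morph, ped, spec)
    full <- fit(mm, seed = seed, n_restarts = n_restarts)
  }
  out <- data.frame(pair_label = pair_label, r = NA_real_, se = NA_real_,
                    lrt = NA_real_, df_convention = "chi2_df1", p = NA_real_,
                    significant = FALSE, boundary = TRUE,
                    stringsAsFactors = FALSE)
  if (is.null(full$vc)) return(out)
  v1 <- full$vc$G[pair[1], pair[1]]
  v2 <- full$vc$G[pair[2], pair[2]]
  at_boundary <- pair[1] %in% full$boundary$variances ||
    pair[2] %in% full$boundary$variances || v1 <= 1e-6 || v2 <= 1e-6
  if (at_boundary) return(out)
  tt <- lrt_component(mm, full, pair, seed = seed + 5L)
  full <- tt$fit_full
  key <- paste(pair, collapse = "~")
  key_rev <- paste(rev(pair), collapse = "~")
  se <- NA_real_
  if (!is.null(full$se)) {
    se <- full$se$correlations[key]
    if (is.na(se) || is.null(se)) se <- full$se$correlations[key_rev]
  }
  data.frame(pair_label = pair_label,
             r = genetic_correlation(full$vc$G, pair[1], pair[2]),
             se = unname(se), lrt = tt$lrt$statistic,
             df_convention = tt$lrt$convention, p = tt$lrt$p,
             significant = tt$lrt$p < 0.05,
             boundary = key %in% full$boundary$correlations ||
               key_rev %in% full$boundary$correlations,
             stringsAsFactors = FALSE)
}

#' Bivariate suite over a list of channel pairs
#'
#' @inheritParams fit_bivariate_pair
#' @param pairs list of channel-label pairs (after [select_pairs()]).
#' @return data.frame with one row per pair (non-converged pairs are
#'   reported flagged, never fatal).
#' @export
fit_bivariate_suite <- function(trials, morph, ped, pairs, uni = NULL,
                                seed = 1L, n_restarts = 2L,
                                zero_channels = character(0)) {
  rows <- lapply(seq_along(pairs), function(i) {
    tryCatch(
      fit_bivariate_pair(trials, morph, ped, pairs[[i]], uni = uni,
                         seed = seed + 100L * i, n_restarts = n_restarts,
                         zero_channels = zero_channels),
      igemate_error = function(e)
        data.frame(pair_label = paste(pairs[[i]], collapse = " ~ "),
                   r = NA_real_, se = NA_real_, lrt = NA_real_,
                   df_convention = "chi2_df1", p = NA_real_,
                   significant = FALSE, boundary = TRUE,
                   stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

default_pairs <- function() {
  list(c("lat_sing:indirect", "testis:direct"),
       c("lat_sing:indirect", "lat_sing:direct"),
       c("lat_sing:indirect", "male_mass:direct"),
       c("lat_sing:direct", "lat_mount:indirect"),
       c("lat_sing:indirect", "lat_mount:indirect"),
       c("male_mass:direct", "testis:direct"),
       c("guard_dist:direct", "testis:direct"))
}

#' Default pipeline configuration
#'
#' @param preset `"study"`: simulate from [study_scale_preset()].
#' @param n_sires design scale (35 = full study scale).
#' @param seed master seed; every stochastic step derives its stream from
#'   it.
#' @param outdir output directory.
#' @param pair_policy `"significant_both"` or `"all"` (see [select_pairs()]).
#' @param n_restarts optimiser restarts used throughout.
#' @param traits traits to analyse (default: all seven).
#' @param pairs declared channel pairs for the bivariate suite.
#' @param zero_var_traits traits whose genetic variances are constrained to
#'   zero in every model (reported as 0 without a test, and any declared
#'   pair touching them flagged `NA`).
#' @return a named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(preset = "study", n_sires = 35, seed = 1L,
                            outdir = "igemate_run", pair_policy = "significant_both",
                            n_restarts = 2L, traits = NULL, pairs = NULL,
                            zero_var_traits = character(0)) {
  list(preset = preset, n_sires = n_sires, seed = as.integer(seed),
       outdir = outdir, pair_policy = pair_policy,
       n_restarts = as.integer(n_restarts),
       traits = traits %||% trait_registry()$trait,
       pairs = pairs %||% default_pairs(),
       zero_var_traits = zero_var_traits,
       reverse_latencies = TRUE)
}

write_config <- function(cfg, path) {
  cfg_out <- cfg
  cfg_out$outdir <- NULL # a runtime location, not part of the analysis
  cfg_out$pairs <- lapply(cfg_out$pairs, as.list)
  yaml::write_yaml(cfg_out, path)
  path
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$pairs)) cfg$pairs <- lapply(cfg$pairs, unlist)
  base <- pipeline_config()
  # flat field-by-field override; modifyList would merge the unnamed
  # pairs list elementwise with the defaults
  for (nm in intersect(names(cfg), names(base))) base[[nm]] <- cfg[[nm]]
  base
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a data set, z-transform and reverse-score, fit the
#' univariate suite with variance LRTs and total heritable variances,
#' select channel pairs, fit the bivariate suite, and write: the input
#' tables, `univariate.csv`, `report.csv` (pair_label, r, se, lrt,
#' df_convention, p, significant), a machine-readable `manifest.json`
#' (config hash, seeds, versions) and `run.log`. Rerunning with the same
#' configuration reproduces every numeric output byte for byte. A
#' non-converged pair is reported flagged, not fatal.
#'
#' @param cfg configuration list from [pipeline_config()] or
#'   [read_config()].
#' @return (invisibly) the output directory; the full results are attached
#'   as attribute `results`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$outdir, "run.log")
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  say("igemate pipeline, seed %d, preset %s (n_sires = %d)",
      cfg$seed, cfg$preset, cfg$n_sires)
  preset <- study_scale_preset(n_sires = cfg$n_sires)
  dat <- simulate_dataset(preset, seed = cfg$seed)
  write_pedigree(dat$ped, file.path(cfg$outdir, "pedigree.csv"))
  write.csv(dat$trials, file.path(cfg$outdir, "trials.csv"), row.names = FALSE)
  write.csv(dat$morph, file.path(cfg$outdir, "morphology.csv"), row.names = FALSE)
  say("simulated %d assays, %d males, %d females, %d families",
      nrow(dat$trials), length(unique(dat$trials$male_id)),
      length(unique(dat$trials$female_id)), n_families(dat$ped))

  prep <- prep_tables(dat$trials, dat$morph,
                      reverse_latencies = isTRUE(cfg$reverse_latencies))
  traits <- intersect(cfg$traits,
                      c(names(prep$trials), unique(prep$morph$trait)))
  zero_channels <- unlist(lapply(cfg$zero_var_traits, function(tr)
    trait_channels(tr)$label))
  if (is.null(zero_channels)) zero_channels <- character(0)
  uni <- fit_univariate_suite(prep$trials, prep$morph, dat$ped, traits,
                              seed = cfg$seed + 1L, n_restarts = cfg$n_restarts,
                              zero_channels = zero_channels)
  uni_tab <- do.call(rbind, lapply(uni, `[[`, "components"))
  rownames(uni_tab) <- NULL
  write.csv(uni_tab, file.path(cfg$outdir, "univariate.csv"), row.names = FALSE)
  for (tr in names(uni))
    say("univariate %s: logL = %.4f, converged = %s", tr,
        uni[[tr]]$fit$logL, uni[[tr]]$fit$converged)

  pairs <- select_pairs(uni, cfg$pairs, policy = cfg$pair_policy)
  say("bivariate pairs: %d declared, %d retained by policy '%s'",
      length(cfg$pairs), length(pairs), cfg$pair_policy)
  report <- if (length(pairs))
    fit_bivariate_suite(prep$trials, prep$morph, dat$ped, pairs, uni = uni,
                        seed = cfg$seed + 2L, n_restarts = cfg$n_restarts,
                        zero_channels = zero_channels)
  else data.frame(pair_label = character(), r = numeric(), se = numeric(),
                  lrt = numeric(), df_convention = character(), p = numeric(),
                  significant = logical(), boundary = logical())
  write.csv(report, file.path(cfg$outdir, "report.csv"), row.names = FALSE)

  cfg_path <- write_config(cfg, file.path(cfg$outdir, "config.yaml"))
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("igemate")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_assays = nrow(dat$trials), n_families = n_families(dat$ped),
    n_pairs_fit = length(pairs))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, logf)
  structure(invisible(cfg$outdir),
            results = list(uni = uni, report = report, data = dat))
}
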