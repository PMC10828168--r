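#' Simulation configuration for synthetic methylation cohorts
#'
#' Describes a synthetic cross-species methylation study: how many CpGs, a
#' per-species sample plan (size, age range, tissues), how many CpGs drift
#' up/down with age and how strongly, per-tissue and per-species baseline
#' offsets, observation noise, and how the PRC2-like annotation set overlaps
#' the positively drifting CpGs.
#'
#' Defaults emulate the structure of a two-frog-species array study: ~4000
#' usable CpGs, 300 CpGs gaining and 200 losing methylation with age, a
#' maximum drift of 0.35 beta units over each species' (transformed) age
#' range, beta noise sd 0.03, tissue offsets sd 0.02, species baseline shifts
#' sd 0.05, and 80% of positive-drift CpGs carrying the PRC2 flag against a
#' 10% background rate.
#'
#' @param n_cpgs Number of CpGs.
#' @param plan Tibble with columns `species`, `cohort`, `n`, `age_lo`,
#'   `age_hi`, `tissues` (list-column of tissue labels).
#' @param n_positive,n_negative Planted counts of CpGs drifting up/down with age.
#' @param effect_scale Maximum methylation drift (beta units) over the
#'   transformed age range.
#' @param noise_sd Per-observation Gaussian sd before bounding to \[0,1\].
#' @param tissue_offset_sd Sd of per-tissue, per-CpG baseline offsets.
#' @param species_offset_sd Sd of per-species, per-CpG baseline shifts.
#' @param frac_prc2 Probability a planted positive CpG is flagged PRC2.
#' @param prc2_background_rate PRC2 flag rate among all other CpGs.
#' @param registry Species registry supplying the age-transform parameters.
#' @param seed Default random seed used by [generate_cohort()].
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_cpgs = 4000,
                              plan = default_plan_table(),
                              n_positive = 300,
                              n_negative = 200,
                              effect_scale = 0.35,
                              noise_sd = 0.03,
                              tissue_offset_sd = 0.02,
                              species_offset_sd = 0.05,
                              frac_prc2 = 0.8,
                              prc2_background_rate = 0.1,
                              registry = default_species_registry(),
                              seed = 1L) {
  plan <- tibble::as_tibble(plan)
  need <- c("species", "cohort", "n", "age_lo", "age_hi", "tissues")
  miss <- setdiff(need, names(plan))
  if (length(miss)) stop_config(paste0("plan is missing columns: ", toString(miss)))
  if (any(plan$n <= 0)) stop_config("plan sample sizes must be positive")
  if (any(plan$age_hi <= plan$age_lo) || any(plan$age_lo < 0)) {
    stop_config("plan requires 0 <= age_lo < age_hi")
  }
  if (n_positive + n_negative > n_cpgs) {
    stop_config("n_positive + n_negative must not exceed n_cpgs")
  }
  sds <- c(noise_sd, tissue_offset_sd, species_offset_sd)
  if (any(sds < 0)) stop_config("all sds must be >= 0")
  if (frac_prc2 < 0 || frac_prc2 > 1 || prc2_background_rate < 0 ||
      prc2_background_rate > 1) {
    stop_config("PRC2 rates must lie in [0,1]")
  }
  registry <- validate_species_registry(registry)
  missing_sp <- setdiff(plan$species, registry$species)
  if (length(missing_sp)) {
    stop_config(paste0("plan species not in registry: ", toString(missing_sp)))
  }
  structure(
    list(n_cpgs = as.integer(n_cpgs), plan = plan,
         n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
         effect_scale = effect_scale, noise_sd = noise_sd,
         tissue_offset_sd = tissue_offset_sd, species_offset_sd = species_offset_sd,
         frac_prc2 = frac_prc2, prc2_background_rate = prc2_background_rate,
         registry = registry, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# the per-species sample plan of the emulated study design
default_plan_table <- function(n_human = 200) {
  frog_tissues <- c("blood", "brain", "liver", "muscle", "skin", "toe", "whole")
  tibble::tibble(
    species = c("laevis", "tropicalis", "human"),
    cohort = c("frog", "frog", "human"),
    n = c(35L, 30L, as.integer(n_human)),
    age_lo = c(0.005, 0.005, 0),
    age_hi = c(19, 8, 101),
    tissues = list(frog_tissues, frog_tissues, "blood")
  )
}

#' Default synthetic study plan
#'
#' The study-design configuration used throughout: 35 *X. laevis* samples
#' (ages 0.005–19 y) and 30 *X. tropicalis* samples (ages 0.005–8 y) across
#' six tissues plus whole-animal samples — 65 frog samples in total — and a
#' human cohort (default n = 200, ages 0–101 y) for the dual-species clocks.
#'
#' @param n_human Human cohort size.
#' @param ... Further arguments passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_study_plan <- function(n_human = 200, ...) {
  simulation_config(plan = default_plan_table(n_human), ...)
}

#' Generate a synthetic methylation cohort
#'
#' Simulates a cohort under the generative model
#' `beta = clip01(baseline + species_offset + tissue_offset +
#' direction * effect * g(age) + noise)`, where `g` is the species'
#' log-linear age transform rescaled to \[0,1\] over that species' planned age
#' range — so the planted signal is monotone but nonlinear in chronological
#' age, as methylation clocks assume. Ages are drawn log-uniformly (shifted
#' by the species' transform offset so a lower bound of 0 is valid), which
#' over-represents embryos and juveniles the way an aging-cohort design does.
#'
#' Baselines mix low/intermediate/high methylation to mimic the bimodality of
#' array betas; planted positive (negative) CpGs start low (high) so drift
#' rarely clips. Each planted CpG's effect size is scaled per species by a
#' modest uniform factor, reflecting species-varying effect sizes. The PRC2
#' annotation set is assembled by flagging planted positive CpGs with
#' probability `frac_prc2` and all other CpGs at the background rate; a PRC1
#' set is drawn entirely at the background rate as a negative control.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   config + seed yields identical output.
#' @return A list with elements `cohort` (a `methyl_cohort`), `annotations`
#'   (an [annotation_sets()] with sets `PRC2` and `PRC1`), and `truth` (a
#'   list: `cpgs` tibble with per-CpG `direction`, `effect`, `baseline`,
#'   `prc2`; `samples` tibble of generating ages; `clip_rate`, the fraction
#'   of values clipped into \[0,1\]).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "simulation_config")) {
    stop_config("`config` must be a simulation_config")
  }
  withr::with_seed(as.integer(seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  reg <- config$registry
  plan <- config$plan
  n_cpgs <- config$n_cpgs
  cpg_ids <- sprintf("cg%08d", seq_len(n_cpgs))

  # --- samples: ages shifted-log-uniform per species, tissues cycled ---
  samples <- purrr::pmap_dfr(plan, function(species, cohort, n, age_lo, age_hi,
                                            tissues) {
    p <- species_params(reg, species)
    k <- p$maturity_years / 5 # same offset the log-linear transform uses
    u <- runif(n)
    ages <- exp(log(age_lo + k) + u * (log(age_hi + k) - log(age_lo + k))) - k
    ages <- pmax(ages, age_lo)
    tibble::tibble(
      sample_id = sprintf("%s_%03d", substr(species, 1, 3), seq_len(n)),
      species = species,
      tissue = rep_len(unlist(tissues), n),
      age_years = ages,
      sex = sample(c("female", "male", "unknown"), n, replace = TRUE),
      cohort = cohort
    )
  })

  # --- per-CpG truth: direction, effect, baseline ---
  direction <- rep("0", n_cpgs)
  planted <- sample.int(n_cpgs, config$n_positive + config$n_negative)
  pos_idx <- planted[seq_len(config$n_positive)]
  neg_idx <- setdiff(planted, pos_idx)
  direction[pos_idx] <- "+"
  direction[neg_idx] <- "-"
  effect <- numeric(n_cpgs)
  effect[planted] <- runif(length(planted), 0.5, 1) * config$effect_scale

  baseline <- numeric(n_cpgs)
  null_idx <- which(direction == "0")
  comp <- sample(c("lo", "mid", "hi"), length(null_idx), replace = TRUE,
                 prob = c(0.4, 0.2, 0.4))
  baseline[null_idx] <- ifelse(comp == "lo", rbeta(length(null_idx), 2, 8),
                        ifelse(comp == "mid", rbeta(length(null_idx), 2, 2),
                               rbeta(length(null_idx), 8, 2)))
  baseline[pos_idx] <- runif(length(pos_idx), 0.15, 0.5)
  baseline[neg_idx] <- runif(length(neg_idx), 0.5, 0.85)

  # --- structured offsets ---
  sp_levels <- plan$species
  ti_levels <- unique(unlist(plan$tissues))
  sp_off <- matrix(rnorm(n_cpgs * length(sp_levels), 0, config$species_offset_sd),
                   n_cpgs, dimnames = list(NULL, sp_levels))
  ti_off <- matrix(rnorm(n_cpgs * length(ti_levels), 0, config$tissue_offset_sd),
                   n_cpgs, dimnames = list(NULL, ti_levels))
  # per-species effect modulation for planted CpGs
  eff_mod <- matrix(runif(n_cpgs * length(sp_levels), 0.8, 1.2),
                    n_cpgs, dimnames = list(NULL, sp_levels))

  # --- age signal: species log-linear transform rescaled to [0,1] over plan ---
  tr <- age_transform("loglinear", reg)
  g_range <- purrr::pmap(plan, function(species, age_lo, age_hi, ...) {
    f <- transform_age(tr, c(age_lo, age_hi), c(species, species))
    list(lo = f[1], span = f[2] - f[1])
  })
  names(g_range) <- plan$species
  f_sample <- transform_age(tr, samples$age_years, samples$species)
  g_sample <- purrr::map2_dbl(f_sample, samples$species, function(f, sp) {
    (f - g_range[[sp]]$lo) / g_range[[sp]]$span
  })

  dir_num <- c("+" = 1, "-" = -1, "0" = 0)[direction]
  n_samples <- nrow(samples)
  signal <- (dir_num * effect * eff_mod[, samples$species, drop = FALSE]) *
    rep(g_sample, each = n_cpgs)
  raw <- baseline +
    sp_off[, samples$species, drop = FALSE] +
    ti_off[, samples$tissue, drop = FALSE] +
    signal +
    matrix(rnorm(n_cpgs * n_samples, 0, config$noise_sd), n_cpgs)
  clip_rate <- mean(raw < 0 | raw > 1)
  beta <- clip01(raw)
  dimnames(beta) <- list(cpg_ids, samples$sample_id)

  # --- annotation sets ---
  prc2 <- runif(n_cpgs) < ifelse(direction == "+", config$frac_prc2,
                                 config$prc2_background_rate)
  prc1 <- runif(n_cpgs) < config$prc2_background_rate
  annotations <- annotation_sets(
    cpg_ids,
    list(PRC2 = cpg_ids[prc2], PRC1 = cpg_ids[prc1])
  )

  truth <- list(
    cpgs = tibble::tibble(cpg_id = cpg_ids, direction = direction,
                          effect = effect, baseline = baseline, prc2 = prc2),
    samples = dplyr::select(samples, "sample_id", "species", "age_years"),
    clip_rate = clip_rate
  )

  list(cohort = assemble_cohort(beta, samples),
       annotations = annotations,
       truth = truth)
}
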