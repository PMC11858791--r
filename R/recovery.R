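#' Default study designs for the simulation validation studies
#'
#' Pre-set [sim_config()]s for the two replicate studies shipped with the
#' package: `"transition"` (coverage of the transition coefficients) and
#' `"siring"` / `"matechoice"` (credible-sign recovery of the qualitative
#' effect structure: guard siring advantage, negative frequency dependence,
#' assortative guarding with a sneaker rank-lag). Population sizes are kept
#' moderate so that a full 20-replicate study runs on a single CPU in
#' minutes; the mate-choice design amplifies the tactic-specific
#' assortativity interaction so that it is detectable at this scale while
#' keeping the direction structure of the study system.
#'
#' @param study One of `"transition"`, `"siring"`, `"matechoice"`.
#' @param seed Seed stored in the config.
#' @return A [sim_config()].
#' @export
study_config <- function(study = c("transition", "siring", "matechoice"),
                         seed = 1L) {
  study <- match.arg(study)
  switch(study,
    transition = sim_config(n_groups = 6, females_per_group = c(2, 5),
                            n_events_per_group = 6, seed = seed),
    siring = sim_config(n_groups = 10, females_per_group = c(2, 5),
                        n_events_per_group = 12, litter_prob = 1,
                        true_transition_params = default_transition_params(
                          sigma_male = 0.2, sigma_group = 0.1,
                          sigma_event = 0.1),
                        seed = seed),
    matechoice = {
      cfg <- sim_config(n_groups = 4, females_per_group = c(5, 6),
                        n_events_per_group = 6, days_per_event = c(1, 3),
                        seed = seed)
      cfg$true_matechoice_params["rank_product"] <- 0.01
      cfg$true_matechoice_params["guard_rank_product"] <- 0.18
      cfg
    })
}

#' Reduced chain settings for the replicate studies
#'
#' Three chains with 2,000 retained post-burn-in draws each (thin 1), a
#' short burn-in and adaptation: the settings used per replicate fit in the
#' parameter-recovery study.
#'
#' @param seed Seed for the fit.
#' @param iterations Post-burn-in iterations per chain.
#' @return An [mcmc_config()].
#' @export
study_mcmc <- function(seed = 1L, iterations = 2000) {
  mcmc_config(chains = 3, iterations = iterations, burnin = 300, thin = 1,
              adapt = 200, seed = seed)
}

# lean derivations for the replicate studies: only the tables the fitted
# model needs (skips weight imputation and unused tables)
lean_transitions <- function(ds, tie_rule = "sneaker") {
  h <- derive_tactic_histories(ds, tie_rule)
  build_transitions(h, derive_covariates(ds, h))
}

lean_siring_trials <- function(ds) {
  h <- derive_tactic_histories(ds)
  links <- link_litters(ds$litters, ds$events, ds$demography)
  build_siring_trials(links, ds$litters, ds$focals,
                      h[, c("event_id", "male_id", "tactic")])
}

lean_dyads <- function(ds) {
  h <- derive_tactic_histories(ds)
  live <- h[h$tactic != "dead", , drop = FALSE]
  demo <- ds$demography
  birth <- stats::setNames(demo$birth_date, demo$individual_id)
  ev_start <- stats::setNames(ds$events$start_date, ds$events$event_id)
  ev_group <- stats::setNames(ds$events$group_id, ds$events$event_id)
  male_ranks <- do.call(rbind, lapply(split(live, live$event_id), function(g) {
    age <- as.numeric(ev_start[g$event_id[1]] - birth[g$male_id])
    data.frame(event_id = g$event_id[1], male_id = g$male_id,
               age_rank = unname(assign_age_ranks(
                 stats::setNames(age, g$male_id))),
               stringsAsFactors = FALSE)
  }))
  female_ranks <- do.call(rbind, lapply(unique(live$event_id), function(e) {
    fem <- demo[demo$group_id == ev_group[e] & demo$sex == "F", , drop = FALSE]
    age <- as.numeric(ev_start[e] - fem$birth_date)
    sel <- age >= 365 & (is.na(fem$death_date) | fem$death_date > ev_start[e])
    if (!any(sel)) return(NULL)
    data.frame(event_id = e, female_id = fem$individual_id[sel],
               age_rank = unname(assign_age_ranks(
                 stats::setNames(age[sel], fem$individual_id[sel]))),
               stringsAsFactors = FALSE)
  }))
  build_dyad_table(ds$focals, male_ranks, female_ranks, ds$relatedness)
}

#' Transition-coefficient recovery study
#'
#' Simulates `n_reps` replicate populations from known transition
#' coefficients, runs the full pipeline (generation, preprocessing with
#' imputation, model fitting) on each, and records whether each raw-scale
#' coefficient's 95% credible interval covers the generating value. With a
#' well-calibrated model about 95% of intervals should cover.
#'
#' @param n_reps Number of replicate populations.
#' @param config Generating [sim_config()] (the replicate index is folded
#'   into its seed).
#' @param mcmc_iterations Post-burn-in draws per chain for each fit.
#' @param seed Base seed.
#' @return Data frame with one row per replicate x coefficient: `rep`,
#'   `parameter`, `truth`, `mean`, `lci`, `hci`, `covered`, `max_rhat`.
#'   Attribute `"coverage"` holds the overall coverage proportion.
#' @export
transition_recovery_study <- function(n_reps = 20,
                                      config = study_config("transition"),
                                      mcmc_iterations = 2000, seed = 1L) {
  truth_beta <- config$true_transition_params$beta
  coefs <- dimnames(truth_beta)$coef
  out <- list()
  for (rep in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- (seed * 1013L + rep) %% 2000000L
    ds <- generate_population(cfg)
    transitions <- lean_transitions(ds)
    fit <- fit_transition_model(transitions,
                                mcmc = study_mcmc(seed = cfg$seed + 7L,
                                                  iterations = mcmc_iterations),
                                interactions = FALSE)
    sm <- fit$summary
    max_rhat <- max(sm$rhat, na.rm = TRUE)
    for (from in LIVE_STATES) for (to in LIVE_STATES[-1]) for (k in coefs) {
      par <- sprintf("beta_raw[%s->%s:%s]", from, to, k)
      row <- sm[sm$parameter == par, , drop = FALSE]
      tr <- truth_beta[from, to, k]
      out[[length(out) + 1L]] <- data.frame(
        rep = rep, parameter = par, truth = tr, mean = row$mean,
        lci = row$lci, hci = row$hci,
        covered = tr >= row$lci & tr <= row$hci, max_rhat = max_rhat,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "coverage") <- mean(out$covered)
  out
}

#' Qualitative sign-recovery study for the outcome models
#'
#' Simulates `n_reps` replicate populations under the qualitative effect
#' structure of the study system (guard siring advantage, negative
#' frequency dependence of siring success, assortative guarding with a
#' sneaker rank-lag), fits the siring and mate-choice models to each, and
#' records whether the key effects come out credible with the generating
#' sign: the guard siring advantage (> 0), the proportion-same-tactic
#' effect (< 0), the tactic difference in assortativity (> 0), and the
#' guards' overall assortativity (> 0, from the summed rank-product draws).
#'
#' @param n_reps Number of replicate populations.
#' @param siring_config,matechoice_config Generating configs.
#' @param mcmc_iterations Post-burn-in draws per chain for each fit.
#' @param seed Base seed.
#' @return Data frame with one row per replicate and one logical column per
#'   key effect; attribute `"successes"` gives the per-effect count of
#'   credible-with-correct-sign replicates.
#' @export
sign_recovery_study <- function(n_reps = 20,
                                siring_config = study_config("siring"),
                                matechoice_config = study_config("matechoice"),
                                mcmc_iterations = 800, seed = 1L) {
  out <- list()
  for (rep in seq_len(n_reps)) {
    scfg <- siring_config
    scfg$seed <- (seed * 2027L + rep) %% 2000000L
    sds <- generate_population(scfg)
    strials <- lean_siring_trials(sds)
    screen_mcmc <- function(s)
      mcmc_config(chains = 2, iterations = mcmc_iterations, burnin = 250,
                  thin = 1, adapt = 150, seed = s)
    sfit <- fit_siring(strials, mcmc = screen_mcmc(scfg$seed + 3L),
                       interactions = FALSE)
    ssm <- sfit$summary
    row_g <- ssm[ssm$parameter == "guard", ]
    row_p <- ssm[ssm$parameter == "prop_same_tactic", ]

    mcfg <- matechoice_config
    mcfg$seed <- (seed * 3041L + rep) %% 2000000L
    mds <- generate_population(mcfg)
    mdyads <- lean_dyads(mds)
    mfit <- fit_matechoice(mdyads, mcmc = screen_mcmc(mcfg$seed + 5L),
                           interactions = FALSE)
    msm <- mfit$summary
    row_3 <- msm[msm$parameter == "guard_rank_product", ]
    dm <- combined_draws(mfit)
    assort <- credibility(dm[, "rank_product"] + dm[, "guard_rank_product"])

    out[[length(out) + 1L]] <- data.frame(
      rep = rep,
      guard_advantage = row_g$credible && row_g$mean > 0,
      negative_freq_dependence = row_p$credible && row_p$mean < 0,
      sneaker_rank_lag = row_3$credible && row_3$mean > 0,
      guard_assortativity = assort$credible && assort$p_positive >= 0.5,
      n_trials = nrow(strials), n_dyads = nrow(mdyads))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  checks <- c("guard_advantage", "negative_freq_dependence",
              "sneaker_rank_lag", "guard_assortativity")
  attr(out, "successes") <- vapply(out[checks], sum, numeric(1))
  out
}
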