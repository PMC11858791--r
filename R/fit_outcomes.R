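# a constant covariate is collinear with the intercept; centring it (to an
# all-zero column) leaves its coefficient at the prior and keeps the
# prediction scale consistent through the recorded offset
centre_constant_columns <- function(std) {
  meta <- attr(std, "scaling")
  for (v in names(std)) {
    s <- stats::sd(std[[v]])
    if (is.finite(s) && s == 0) {
      meta$mean[meta$variable == v] <- std[[v]][1]
      std[[v]] <- 0
    }
  }
  attr(std, "scaling") <- meta
  std
}

glmm_model_string <- function(family = c("bernoulli", "gaussian"),
                              re_tags = c("m", "g", "e"),
                              re_names = c("male", "group", "event")) {
  family <- match.arg(family)
  blocks <- Map(re_block, rep(TRUE, length(re_tags)), re_names, re_tags)
  terms <- paste(vapply(blocks, `[[`, character(1), "term"), collapse = "")
  defs <- paste(vapply(blocks, `[[`, character(1), "def"), collapse = "")
  lik <- if (family == "bernoulli") {
    sprintf("    y[r] ~ dbern(p[r])
    logit(p[r]) <- inprod(beta[1:K], X[r, 1:K])%s", terms)
  } else {
    sprintf("    y[r] ~ dnorm(mu[r], tau_resid)
    mu[r] <- inprod(beta[1:K], X[r, 1:K])%s", terms)
  }
  resid <- if (family == "gaussian")
    "  tau_resid <- pow(sigma_resid, -2)\n  sigma_resid ~ dnorm(0, 0.04) T(0,)\n"
  else ""
  sprintf("model {
  for (r in 1:N) {
%s
  }
  for (k in 1:K) { beta[k] ~ dnorm(0, 0.01) }
%s%s}", lik, resid, defs)
}

fit_glmm <- function(X, y, re_index, family, mcmc, type, scaling, data,
                     random_effects = TRUE, extra = list()) {
  stopifnot(nrow(X) == length(y))
  re_names <- names(re_index)
  tags <- substr(re_names, 1, 1)
  if (!random_effects) { re_index <- list(); re_names <- character(0); tags <- character(0) }
  dat <- list(N = nrow(X), K = ncol(X), X = unname(as.matrix(X)),
              y = as.numeric(y))
  for (i in seq_along(re_index)) {
    dat[[re_names[i]]] <- re_index[[i]]
    dat[[paste0("N", tags[i])]] <- max(re_index[[i]])
  }
  model <- if (length(re_index))
    glmm_model_string(family, re_tags = tags, re_names = re_names)
  else glmm_model_string(family, re_tags = character(0),
                         re_names = character(0))
  monitor <- c("beta", if (family == "gaussian") "sigma_resid",
               if (length(tags)) paste0("sigma_", tags))
  inits <- lapply(seq_len(mcmc$chains), function(ch)
    list(beta = rep(0, ncol(X))))
  draws <- run_mcmc(model, dat, monitor, config = mcmc, inits = inits,
                    glm_module = FALSE)
  labels <- c(colnames(X), if (family == "gaussian") "sigma_resid",
              if (length(tags)) paste0("sigma_", re_names))
  for (ch in seq_along(draws)) {
    cn <- colnames(draws[[ch]])
    beta_idx <- grepl("^beta\\[", cn)
    cn[beta_idx] <- colnames(X)[as.integer(sub("^beta\\[(\\d+)\\]$", "\\1",
                                               cn[beta_idx]))]
    for (i in seq_along(tags))
      cn[cn == paste0("sigma_", tags[i])] <- paste0("sigma_", re_names[i])
    colnames(draws[[ch]]) <- cn
  }
  structure(c(list(type = type, draws = draws,
                   summary = summarize_draws(draws), scaling = scaling,
                   coef_names = colnames(X), config = mcmc, data = data,
                   family = family, random_effects = random_effects,
                   dropped_interactions = character(0)), extra),
            class = "art_fit")
}

#' Fit the Gaussian oestrus weight-loss model
#'
#' Hierarchical Gaussian model of the percentage weight change over an
#' oestrus event: a mean per tactic (subordinate, sneaker, guard) plus
#' crossed random effects for male, group and oestrus event. Reports the
#' per-tactic means and all pairwise tactic contrasts with the 97.5%
#' credibility rule. Imputed weights never enter this model because
#' [derive_weight_changes()] only uses directly observed weights.
#'
#' @param weight_changes Table from [derive_weight_changes()] (columns
#'   `pct_change`, `tactic`, `male_id`, `group_id`, `event_id`).
#' @param mcmc An [mcmc_config()]; defaults to 3 chains, 50,000 iterations,
#'   thin 100, burn-in 5,000.
#' @param random_effects Include the crossed random effects.
#' @return An `art_fit` with parameters `mean_pct[<tactic>]`,
#'   `contrast[...]`, `sigma_resid` and the random-effect SDs.
#' @export
fit_weightloss <- function(weight_changes,
                           mcmc = mcmc_config(iterations = 50000,
                                              burnin = 5000, thin = 100),
                           random_effects = TRUE) {
  wc <- weight_changes
  stopifnot(all(is.finite(wc$pct_change)))
  tac <- factor(wc$tactic, levels = LIVE_STATES)
  present <- levels(tac)[tabulate(tac, 3) > 0]
  if (length(present) < 2L)
    stop("fewer than two tactics represented: contrast undefined")
  X <- stats::model.matrix(~ 0 + tac)
  colnames(X) <- sprintf("mean_pct[%s]", LIVE_STATES)
  X <- X[, colSums(X) > 0, drop = FALSE]
  re_index <- list(male = as.integer(factor(wc$male_id)),
                   group = as.integer(factor(wc$group_id)),
                   event = as.integer(factor(wc$event_id)))
  fit <- fit_glmm(X, wc$pct_change, re_index, "gaussian", mcmc, "weightloss",
                  scaling = NULL, data = wc, random_effects = random_effects)
  # pairwise tactic contrasts, recomputed from the saved draws
  combos <- utils::combn(colnames(X), 2, simplify = FALSE)
  for (ch in seq_along(fit$draws)) {
    m <- as.matrix(fit$draws[[ch]])
    extra <- vapply(combos, function(cp) m[, cp[2]] - m[, cp[1]],
                    numeric(nrow(m)))
    colnames(extra) <- vapply(combos, function(cp)
      sprintf("contrast[%s-%s]", gsub("^mean_pct\\[|\\]$", "", cp[2]),
              gsub("^mean_pct\\[|\\]$", "", cp[1])), character(1))
    fit$draws[[ch]] <- coda::mcmc(cbind(m, extra),
                                  start = stats::start(fit$draws[[ch]]),
                                  thin = coda::thin(fit$draws[[ch]]))
  }
  fit$summary <- summarize_draws(fit$draws)
  fit
}

#' Fit the Bernoulli siring-success model
#'
#' Hierarchical logistic model of whether a male sired the litter of a
#' female he interacted with over an oestrus event, regressed on his tactic
#' (guard = 1, sneaker = 0), the number of male competitors interacting with
#' the female (standardized) and the proportion of his competitors adopting
#' the same tactic, with crossed random effects for female, male and oestrus
#' event. The tactic x proportion-same interaction is fitted first and
#' dropped when not credible.
#'
#' @param trials Table from [build_siring_trials()].
#' @param mcmc An [mcmc_config()]; defaults to 3 chains, 100,000 iterations,
#'   thin 100, burn-in 10,000.
#' @param interactions Fit and credibility-screen the tactic x
#'   proportion-same interaction.
#' @param random_effects Include the crossed random effects.
#' @return An `art_fit`.
#' @export
fit_siring <- function(trials,
                       mcmc = mcmc_config(iterations = 100000,
                                          burnin = 10000, thin = 100),
                       interactions = TRUE, random_effects = TRUE) {
  stopifnot(nrow(trials) > 0)
  if (length(unique(trials$sired)) == 1L)
    warning("all trials share one outcome: complete separation likely")
  std <- standardize_covariates(
    trials[, c("n_competitors", "prop_same_tactic"), drop = FALSE])
  scaling <- attr(std, "scaling")
  guard <- as.numeric(trials$tactic == "guard")
  X <- cbind(intercept = 1, guard = guard,
             n_competitors = std$n_competitors,
             prop_same_tactic = std$prop_same_tactic)
  if (interactions)
    X <- cbind(X, guard_x_prop_same = guard * std$prop_same_tactic)
  re_index <- list(female = as.integer(factor(trials$female_id)),
                   male = as.integer(factor(trials$male_id)),
                   event = as.integer(factor(trials$event_id)))
  fit <- fit_glmm(X, trials$sired, re_index, "bernoulli", mcmc, "siring",
                  scaling, trials, random_effects)
  if (interactions &&
      !fit$summary$credible[fit$summary$parameter == "guard_x_prop_same"]) {
    X <- X[, colnames(X) != "guard_x_prop_same", drop = FALSE]
    fit <- fit_glmm(X, trials$sired, re_index, "bernoulli", mcmc, "siring",
                    scaling, trials, random_effects)
    fit$dropped_interactions <- "guard_x_prop_same"
  }
  fit
}

#' Fit the Bernoulli mate-choice model
#'
#' Hierarchical logistic model of whether an active male pursued a given
#' adult female on a given day, regressed on group-centred relatedness, male
#' and female age rank with their interaction (assortative mating), the
#' tactic (guard = 1, sneaker = 0) with its two- and three-way rank
#' interactions (tactic-specific mate preferences), the number of adult
#' females present, and crossed random effects for male, female and oestrus
#' event. The relatedness x tactic interaction is fitted first and dropped
#' when not credible. Numeric covariates are standardized with the shared
#' rule before interaction terms are formed.
#'
#' @param dyads Table from [build_dyad_table()].
#' @param mcmc An [mcmc_config()]; defaults to 3 chains, 20,000 iterations,
#'   thin 100, burn-in 2,000.
#' @param interactions Fit and credibility-screen the relatedness x tactic
#'   interaction.
#' @param random_effects Include the crossed random effects.
#' @param unit Model each male-day (default, one Bernoulli per female
#'   present per interaction day) or collapse to male-events.
#' @return An `art_fit`.
#' @export
fit_matechoice <- function(dyads,
                           mcmc = mcmc_config(iterations = 20000,
                                              burnin = 2000, thin = 100),
                           interactions = TRUE, random_effects = TRUE,
                           unit = c("day", "event")) {
  unit <- match.arg(unit)
  stopifnot(nrow(dyads) > 0)
  if (length(unique(dyads$female_id)) < 2L)
    stop("a single female across the data: rank interactions unidentifiable")
  d <- dyads
  if (unit == "event") {
    key <- paste(d$event_id, d$male_id, d$female_id)
    agg <- lapply(split(seq_len(nrow(d)), key), function(idx) {
      row <- d[idx[1], , drop = FALSE]
      row$interacted <- any(d$interacted[idx])
      row$tactic <- if (any(d$tactic[idx] == "guard")) "guard" else "sneaker"
      row
    })
    d <- do.call(rbind, agg)
  }
  std <- centre_constant_columns(suppressWarnings(standardize_covariates(
    d[, c("male_age_rank", "female_age_rank", "group_centred_relatedness",
          "n_adult_females"), drop = FALSE])))
  scaling <- attr(std, "scaling")
  guard <- as.numeric(d$tactic == "guard")
  X <- cbind(intercept = 1,
             relatedness = std$group_centred_relatedness,
             male_rank = std$male_age_rank,
             female_rank = std$female_age_rank,
             rank_product = std$male_age_rank * std$female_age_rank,
             guard = guard,
             guard_male_rank = guard * std$male_age_rank,
             guard_female_rank = guard * std$female_age_rank,
             guard_rank_product = guard * std$male_age_rank *
               std$female_age_rank,
             n_adult_females = std$n_adult_females)
  if (interactions)
    X <- cbind(X, relatedness_guard = std$group_centred_relatedness * guard)
  re_index <- list(male = as.integer(factor(d$male_id)),
                   female = as.integer(factor(d$female_id)),
                   event = as.integer(factor(d$event_id)))
  fit <- fit_glmm(X, d$interacted, re_index, "bernoulli", mcmc, "matechoice",
                  scaling, d, random_effects)
  if (interactions &&
      !fit$summary$credible[fit$summary$parameter == "relatedness_guard"]) {
    X <- X[, colnames(X) != "relatedness_guard", drop = FALSE]
    fit <- fit_glmm(X, d$interacted, re_index, "bernoulli", mcmc,
                    "matechoice", scaling, d, random_effects)
    fit$dropped_interactions <- "relatedness_guard"
  }
  fit
}

build_design <- function(fit, newdata) {
  std_val <- function(var, raw) standardize_value(raw, fit$scaling, var)
  if (fit$type == "siring") {
    guard <- as.numeric(newdata$tactic == "guard")
    X <- cbind(intercept = 1, guard = guard,
               n_competitors = std_val("n_competitors", newdata$n_competitors),
               prop_same_tactic = std_val("prop_same_tactic",
                                          newdata$prop_same_tactic))
    if ("guard_x_prop_same" %in% fit$coef_names)
      X <- cbind(X, guard_x_prop_same = guard * X[, "prop_same_tactic"])
  } else if (fit$type == "matechoice") {
    guard <- as.numeric(newdata$tactic == "guard")
    mr <- std_val("male_age_rank", newdata$male_age_rank)
    fr <- std_val("female_age_rank", newdata$female_age_rank)
    rel <- std_val("group_centred_relatedness",
                   newdata$group_centred_relatedness)
    X <- cbind(intercept = 1, relatedness = rel, male_rank = mr,
               female_rank = fr, rank_product = mr * fr, guard = guard,
               guard_male_rank = guard * mr, guard_female_rank = guard * fr,
               guard_rank_product = guard * mr * fr,
               n_adult_females = std_val("n_adult_females",
                                         newdata$n_adult_females))
    if ("relatedness_guard" %in% fit$coef_names)
      X <- cbind(X, relatedness_guard = rel * guard)
  } else stop("prediction implemented for siring and mate-choice fits")
  X[, fit$coef_names, drop = FALSE]
}

#' Posterior predicted probabilities from a Bernoulli fit
#'
#' Evaluates, per posterior draw, the predicted probability for new
#' raw-scale scenarios (random effects at zero) and summarizes the result.
#'
#' @param fit A `"siring"` or `"matechoice"` `art_fit`.
#' @param newdata Data frame of scenarios. For siring: `tactic`,
#'   `n_competitors`, `prop_same_tactic`. For mate choice: `tactic`,
#'   `male_age_rank`, `female_age_rank`, `group_centred_relatedness`,
#'   `n_adult_females`.
#' @return `newdata` with added `mean`, `lci`, `hci` of the predicted
#'   probability.
#' @export
predict_probability <- function(fit, newdata) {
  stopifnot(inherits(fit, "art_fit"), fit$family == "bernoulli")
  X <- build_design(fit, newdata)
  dm <- combined_draws(fit)[, fit$coef_names, drop = FALSE]
  out <- newdata
  out$mean <- NA_real_; out$lci <- NA_real_; out$hci <- NA_real_
  for (i in seq_len(nrow(X))) {
    p <- stats::plogis(as.numeric(dm %*% X[i, ]))
    qs <- stats::quantile(p, c(0.025, 0.975), names = FALSE)
    out$mean[i] <- mean(p); out$lci[i] <- qs[1]; out$hci[i] <- qs[2]
  }
  out
}

#' Maximum a posteriori estimate for a random-effect-free fit
#'
#' Direct numerical maximization of the log-posterior (Bernoulli or Gaussian
#' likelihood with the package's Normal(0, 10^2) coefficient priors) of a
#' fit built with `random_effects = FALSE`. Used to check that the MCMC fits
#' reduce to ordinary logistic/linear regression when the hierarchy is
#' switched off.
#'
#' @param fit An `art_fit` fitted with `random_effects = FALSE`.
#' @return Named vector of MAP coefficient estimates.
#' @export
map_estimate <- function(fit) {
  stopifnot(inherits(fit, "art_fit"), !fit$random_effects)
  X <- build_design_from_data(fit)
  y <- fit_response(fit)
  nll <- if (fit$family == "bernoulli") {
    function(b) {
      eta <- as.numeric(X %*% b)
      -sum(y * eta - log1p(exp(eta))) + sum(b^2) / 200
    }
  } else {
    function(b) {
      r <- y - as.numeric(X %*% b)
      sum(r^2) / (2 * stats::var(y)) + sum(b^2) / 200
    }
  }
  start <- fit$summary$mean[match(fit$coef_names, fit$summary$parameter)]
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  stats::setNames(opt$par, fit$coef_names)
}

build_design_from_data <- function(fit) {
  if (fit$type == "siring") {
    build_design(fit, data.frame(
      tactic = fit$data$tactic, n_competitors = fit$data$n_competitors,
      prop_same_tactic = fit$data$prop_same_tactic))
  } else if (fit$type == "matechoice") {
    build_design(fit, data.frame(
      tactic = fit$data$tactic, male_age_rank = fit$data$male_age_rank,
      female_age_rank = fit$data$female_age_rank,
      group_centred_relatedness = fit$data$group_centred_relatedness,
      n_adult_females = fit$data$n_adult_females))
  } else stop("unsupported fit type")
}

fit_response <- function(fit) {
  switch(fit$type,
         siring = as.numeric(fit$data$sired),
         matechoice = as.numeric(fit$data$interacted),
         weightloss = fit$data$pct_change,
         stop("unsupported fit type"))
}
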