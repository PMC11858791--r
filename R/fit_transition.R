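# Random-effect blocks use the non-centred parameterization
# (u = sigma * z with z ~ N(0, 1)): identical model, far better mixing for
# the slice samplers when the data only weakly pin the SD.
re_block <- function(use, name, tag) {
  if (!use) return(list(def = "", term = ""))
  list(def = sprintf(
    "  for (j in 1:N%s) { z_%s[j] ~ dnorm(0, 1) }
  sigma_%s ~ dnorm(0, 0.04) T(0,)\n", tag, tag, tag),
    term = sprintf(" + sigma_%s * z_%s[%s[r]]", tag, tag, name))
}

transition_model_string <- function(random_effects = TRUE,
                                    coef_prior_sd = 2.5) {
  rem <- re_block(random_effects, "male", "m")
  reg <- re_block(random_effects, "group", "g")
  ree <- re_block(random_effects, "event", "e")
  prec <- format(1 / coef_prior_sd^2, digits = 10)
  sprintf("model {
  for (r in 1:N) {
    phi[r, 1] <- 1
    for (m in 1:2) {
      log(phi[r, m + 1]) <- inprod(b[from[r], m, 1:K], X[r, 1:K])%s%s%s
    }
    denom[r] <- phi[r, 1] + phi[r, 2] + phi[r, 3]
    for (m in 1:3) { p[r, m] <- s[from[r]] * phi[r, m] / denom[r] }
    p[r, 4] <- 1 - s[from[r]]
    to[r] ~ dcat(p[r, 1:4])
  }
  for (n in 1:3) {
    for (m in 1:2) { for (k in 1:K) { b[n, m, k] ~ dnorm(0, %s) } }
    logit(s[n]) <- ls[n]
    ls[n] ~ dlogis(0, 1)
  }
%s%s%s}", rem$term, reg$term, ree$term, prec, rem$def, reg$def, ree$def)
}

rename_transition_draws <- function(draws, coef_names) {
  relabel <- function(nm) {
    m_b <- regmatches(nm, regexec("^b\\[(\\d+),(\\d+),(\\d+)\\]$", nm))[[1]]
    if (length(m_b) == 4) {
      return(sprintf("beta[%s->%s:%s]", LIVE_STATES[as.integer(m_b[2])],
                     LIVE_STATES[as.integer(m_b[3]) + 1L],
                     coef_names[as.integer(m_b[4])]))
    }
    m_s <- regmatches(nm, regexec("^s\\[(\\d+)\\]$", nm))[[1]]
    if (length(m_s) == 2)
      return(sprintf("survival[%s]", LIVE_STATES[as.integer(m_s[2])]))
    switch(nm, sigma_m = "sigma_male", sigma_g = "sigma_group",
           sigma_e = "sigma_event", nm)
  }
  for (ch in seq_along(draws))
    colnames(draws[[ch]]) <- vapply(colnames(draws[[ch]]), relabel,
                                    character(1))
  draws
}

# raw-scale back-transform of the multinomial-logit betas (main effects only)
add_raw_scale_betas <- function(draws, scaling, coef_names) {
  covs <- coef_names[-1]
  mu <- stats::setNames(scaling$mean[match(covs, scaling$variable)], covs)
  sd_ <- stats::setNames(scaling$sd[match(covs, scaling$variable)], covs)
  for (ch in seq_along(draws)) {
    m <- as.matrix(draws[[ch]])
    extra <- list()
    for (n in LIVE_STATES) for (to in LIVE_STATES[-1]) {
      cols <- sprintf("beta[%s->%s:%s]", n, to, coef_names)
      raw <- m[, cols[-1], drop = FALSE]
      raw <- sweep(raw, 2, sd_, "/")
      int <- m[, cols[1]] - raw %*% mu
      block <- cbind(int, raw)
      colnames(block) <- sprintf("beta_raw[%s->%s:%s]", n, to, coef_names)
      extra[[length(extra) + 1L]] <- block
    }
    draws[[ch]] <- coda::mcmc(cbind(m, do.call(cbind, extra)),
                              start = stats::start(draws[[ch]]),
                              thin = coda::thin(draws[[ch]]))
  }
  draws
}

#' Fit the Bayesian multi-state tactic-transition model
#'
#' Models the probability that a male in tactic `n` at one oestrus event is
#' in state `m` at the next: destination probabilities are a per-origin
#' multinomial logit over the live states (reference destination
#' `"subordinate"`) scaled by a status-specific survival probability, with
#' the complement going to the absorbing dead state. Covariates (age rank,
#' group-centred weight, group sex ratio) are standardized with the shared
#' rule, and crossed random effects for male, group and oestrus event enter
#' the non-reference destination predictors. Coefficient priors are
#' weakly-informative Normal(0, 2.5^2) on the standardized scale (the
#' standard default for logistic-family regressions, which also counters the
#' away-from-zero small-sample bias of multinomial-logit estimates;
#' adjustable via `coef_prior_sd`), random-effect SDs half-Normal(0, 5^2),
#' and survival has a flat prior on the probability scale (logistic on the
#' logit scale).
#'
#' When `interactions = TRUE` the model is first fitted with the sex ratio x
#' age rank and sex ratio x weight interaction terms; any interaction with
#' no credible cell (97.5% rule) is then dropped and the model refitted.
#'
#' @param transitions Transition table from [build_transitions()] (columns
#'   `from`, `to`, `age_rank`, `group_centred_weight`, `sex_ratio`,
#'   `male_id`, `group_id`, `event_id`).
#' @param mcmc An [mcmc_config()]; the study's printed settings
#'   (3 chains, 20,000 iterations, thin 100, burn-in 2,500) are the default.
#' @param interactions Fit (and credibility-screen) sex-ratio interactions.
#' @param random_effects Include the crossed random effects (disable only
#'   for reduction checks against plain multinomial regression).
#' @param coef_prior_sd Prior SD of the (standardized-scale) regression
#'   coefficients.
#' @return An `art_fit` object: posterior draws (including raw-covariate
#'   -scale betas `beta_raw[...]` when `interactions = FALSE`), a summary
#'   table with means, 95% CIs, split R-hat and credibility flags, the
#'   scaling metadata and the data used.
#' @export
fit_transition_model <- function(transitions, mcmc = mcmc_config(),
                                 interactions = FALSE,
                                 random_effects = TRUE,
                                 coef_prior_sd = 2.5) {
  stopifnot(is.data.frame(transitions), nrow(transitions) > 0)
  if (any(transitions$from == "dead"))
    stop("invalid history: transitions out of the dead state")
  base_covs <- TRANSITION_COVARIATES
  std <- standardize_covariates(transitions[, base_covs, drop = FALSE])
  scaling <- attr(std, "scaling")
  coef_names <- c("intercept", base_covs)
  X <- cbind(intercept = 1, as.matrix(std))
  if (interactions) {
    X <- cbind(X, sex_ratio_x_age_rank = std$sex_ratio * std$age_rank,
               sex_ratio_x_group_centred_weight =
                 std$sex_ratio * std$group_centred_weight)
    coef_names <- colnames(X)
  }
  fit1 <- fit_transition_jags(transitions, X, coef_names, scaling, mcmc,
                              random_effects, coef_prior_sd)
  if (!interactions) return(fit1)
  inter <- c("sex_ratio_x_age_rank", "sex_ratio_x_group_centred_weight")
  keep <- vapply(inter, function(term) {
    rows <- grepl(paste0(":", term, "\\]$"), fit1$summary$parameter)
    any(fit1$summary$credible[rows])
  }, logical(1))
  if (all(keep)) return(fit1)
  X2 <- X[, c("intercept", base_covs, inter[keep]), drop = FALSE]
  fit2 <- fit_transition_jags(transitions, X2, colnames(X2), scaling, mcmc,
                              random_effects, coef_prior_sd)
  fit2$dropped_interactions <- inter[!keep]
  fit2
}

fit_transition_jags <- function(transitions, X, coef_names, scaling, mcmc,
                                random_effects, coef_prior_sd = 2.5) {
  from <- match(transitions$from, LIVE_STATES)
  to <- match(transitions$to, ART_STATES)
  if (anyNA(from) || anyNA(to)) stop("unknown state in transitions table")
  male <- as.integer(factor(transitions$male_id))
  group <- as.integer(factor(transitions$group_id))
  event <- as.integer(factor(transitions$event_id))
  K <- ncol(X)
  data <- list(N = nrow(X), K = K, X = unname(X), from = from, to = to)
  monitor <- c("b", "s", "ls")
  if (random_effects) {
    data <- c(data, list(male = male, group = group, event = event,
                         Nm = max(male), Ng = max(group), Ne = max(event)))
    monitor <- c(monitor, "sigma_m", "sigma_g", "sigma_e")
  }
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(mcmc$seed * 131L + ch)
    # over-dispersed but deterministic starts so R-hat is an honest check
    list(b = array(stats::rnorm(3 * 2 * K, 0, 0.2 * ch), c(3, 2, K)),
         ls = rep(2, 3))
  })
  draws <- run_mcmc(transition_model_string(random_effects, coef_prior_sd),
                    data, monitor,
                    config = mcmc, inits = inits)
  draws <- rename_transition_draws(draws, coef_names)
  # drop the redundant logit-scale survival nodes from the reported draws
  keep_cols <- !grepl("^ls\\[", colnames(draws[[1]]))
  for (ch in seq_along(draws))
    draws[[ch]] <- draws[[ch]][, keep_cols, drop = FALSE]
  main_only <- identical(coef_names, c("intercept", TRANSITION_COVARIATES))
  if (main_only) draws <- add_raw_scale_betas(draws, scaling, coef_names)
  structure(list(type = "transition", draws = draws,
                 summary = summarize_draws(draws), scaling = scaling,
                 coef_names = coef_names, config = mcmc,
                 data = transitions, random_effects = random_effects,
                 dropped_interactions = character(0)),
            class = "art_fit")
}

#' @export
print.art_fit <- function(x, ...) {
  cat("Bayesian", x$type, "model fit (", x$config$chains, "chains x",
      floor(x$config$iterations / x$config$thin), "draws )\n")
  bad <- sum(x$summary$rhat >= 1.1, na.rm = TRUE)
  cat(if (bad == 0) "All split R-hat < 1.1\n" else
    paste0(bad, " parameter(s) with R-hat >= 1.1 - inspect convergence\n"))
  if (length(x$dropped_interactions))
    cat("Dropped non-credible interaction(s):",
        paste(x$dropped_interactions, collapse = ", "), "\n")
  print(utils::head(x$summary, 20), row.names = FALSE)
  if (nrow(x$summary) > 20) cat("...", nrow(x$summary) - 20, "more rows\n")
  invisible(x)
}

combined_draws <- function(fit) do.call(rbind, lapply(fit$draws, as.matrix))

#' Posterior transition curves over a covariate grid
#'
#' Evaluates, draw by draw, the one-step transition probabilities while one
#' covariate moves over a grid (raw scale) and the others are held at
#' reference values, returning pointwise posterior means and 95% credible
#' intervals. Random effects are set to zero (a typical male in a typical
#' group and event).
#'
#' @param fit A transition-model `art_fit` (main-effects parameterization).
#' @param covariate One of `"age_rank"`, `"group_centred_weight"`,
#'   `"sex_ratio"`.
#' @param grid Numeric vector of raw-scale covariate values.
#' @param at Named list/vector of raw-scale values for the remaining
#'   covariates; defaults to their data means.
#' @param origins Origin states for which to compute curves.
#' @return Data frame `origin`, `destination`, `covariate`, `value`, `mean`,
#'   `lci`, `hci`.
#' @export
posterior_transition_curves <- function(fit, covariate, grid, at = NULL,
                                        origins = LIVE_STATES) {
  stopifnot(inherits(fit, "art_fit"), fit$type == "transition")
  covariate <- match.arg(covariate, TRANSITION_COVARIATES)
  if (!identical(fit$coef_names, c("intercept", TRANSITION_COVARIATES)))
    stop("curves require a main-effects transition fit")
  dm <- combined_draws(fit)
  if (nrow(dm) == 0L) stop("no posterior draws")
  others <- setdiff(TRANSITION_COVARIATES, covariate)
  x_other <- vapply(others, function(v) {
    raw <- if (!is.null(at) && v %in% names(at)) at[[v]] else
      mean(fit$data[[v]], na.rm = TRUE)
    standardize_value(raw, fit$scaling, v)
  }, numeric(1))
  out <- list()
  for (origin in origins) {
    surv <- dm[, sprintf("survival[%s]", origin)]
    bcols <- lapply(LIVE_STATES[-1], function(to)
      dm[, sprintf("beta[%s->%s:%s]", origin, to,
                   c("intercept", TRANSITION_COVARIATES)), drop = FALSE])
    for (g in grid) {
      x <- c(intercept = 1,
             stats::setNames(standardize_value(g, fit$scaling, covariate),
                             covariate), x_other)
      x <- x[c("intercept", TRANSITION_COVARIATES)]
      eta_live <- vapply(bcols, function(B) as.numeric(B %*% x),
                         numeric(nrow(dm)))
      if (!is.matrix(eta_live)) eta_live <- matrix(eta_live, nrow = 1)
      eta <- cbind(0, eta_live)
      eta <- eta - apply(eta, 1, max)
      soft <- exp(eta) / rowSums(exp(eta))
      probs <- cbind(soft * surv, 1 - surv)
      colnames(probs) <- ART_STATES
      for (dest in ART_STATES) {
        qs <- stats::quantile(probs[, dest], c(0.025, 0.975), names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          origin = origin, destination = dest, covariate = covariate,
          value = g, mean = mean(probs[, dest]), lci = qs[1], hci = qs[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior summary of the transition matrix at reference covariates
#'
#' The nine live-to-live transition probabilities plus the three death
#' probabilities, evaluated at reference covariate values (data means by
#' default) for a typical male (random effects zero), with posterior means
#' and 95% credible intervals.
#'
#' @param fit A transition-model `art_fit`.
#' @param at Optional named raw-scale covariate values.
#' @return Data frame `from`, `to`, `mean`, `lci`, `hci`.
#' @export
transition_matrix_summary <- function(fit, at = NULL) {
  grids <- lapply(TRANSITION_COVARIATES, function(v)
    if (!is.null(at) && v %in% names(at)) at[[v]] else
      mean(fit$data[[v]], na.rm = TRUE))
  names(grids) <- TRANSITION_COVARIATES
  curves <- posterior_transition_curves(fit, "age_rank",
                                        grid = grids$age_rank,
                                        at = grids[-1])
  out <- curves[, c("origin", "destination", "mean", "lci", "hci")]
  names(out)[1:2] <- c("from", "to")
  rownames(out) <- NULL
  out
}
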