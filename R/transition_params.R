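TRANSITION_COVARIATES <- c("age_rank", "group_centred_weight", "sex_ratio")

#' Parameters of the tactic-transition process
#'
#' Bundles everything that defines the four-dimensional transition array: the
#' multinomial-logit regression coefficients for moves between the three live
#' states, the status-specific survival probabilities that feed the absorbing
#' dead state, and the standard deviations of the crossed random effects
#' (male, group, oestrus event).
#'
#' The linear predictor for a move from live state `n` to live state `m` is
#' `sum(beta[n, m, ] * c(1, covariates)) + u_male + u_group + u_event`, with
#' `"subordinate"` as the reference destination (`beta[n, "subordinate", ]`
#' fixed at zero, and the random-effect sum entering only the non-reference
#' destinations). Destination probabilities are
#' `survival[n] * softmax(linear predictors)` for the live states and
#' `1 - survival[n]` for death. Once dead, the probability of remaining dead
#' is 1.
#'
#' @param beta Numeric array `3 x 3 x (1 + length(covariates))`
#'   (origin state, destination state, coefficient); the reference
#'   destination slice must be zero. Coefficient order is `"intercept"`
#'   followed by `covariates`.
#' @param survival Numeric vector of length 3 in (0, 1]: per-origin-state
#'   probability of surviving to the next oestrus event.
#' @param sigma_male,sigma_group,sigma_event Random-effect standard
#'   deviations (>= 0).
#' @param covariates Character vector of covariate names (defaults to age
#'   rank, group-centred weight and group sex ratio).
#' @return Object of class `transition_params`.
#' @export
#' @examples
#' p <- default_transition_params()
#' transition_probs(p, c(age_rank = 3, group_centred_weight = 50,
#'                       sex_ratio = 2.2), origin = "subordinate")
transition_params <- function(beta, survival,
                              sigma_male = 0, sigma_group = 0, sigma_event = 0,
                              covariates = TRANSITION_COVARIATES) {
  coef_names <- c("intercept", covariates)
  if (is.null(dim(beta)) || !all(dim(beta) == c(3, 3, length(coef_names))))
    stop("`beta` must be a 3 x 3 x ", length(coef_names), " array")
  dimnames(beta) <- list(from = LIVE_STATES, to = LIVE_STATES, coef = coef_names)
  if (any(beta[, "subordinate", ] != 0))
    stop("reference destination 'subordinate' must have zero coefficients")
  stopifnot(length(survival) == 3, all(survival > 0), all(survival <= 1),
            sigma_male >= 0, sigma_group >= 0, sigma_event >= 0)
  names(survival) <- LIVE_STATES
  structure(list(beta = beta, survival = survival,
                 sigma_male = sigma_male, sigma_group = sigma_group,
                 sigma_event = sigma_event, covariates = covariates),
            class = "transition_params")
}

#' Default generating parameters for the tactic-transition process
#'
#' A parameter set on the raw covariate scale (age rank in rank units,
#' group-centred weight in grams, sex ratio in males per female) that
#' reproduces the qualitative transition structure reported for banded
#' mongoose groups: most males stay reproductively inactive, guarding is
#' gained with old age rank (small rank number) and high relative weight,
#' sneaking is rarer, is also reached from guarding, and declines as males
#' grow old and heavy; biased sex ratios have no effect. Survival per
#' oestrus-event step is high. Intercepts are expressed at the covariate
#' reference point (age rank 6, centred weight 0 g, sex ratio 2.2).
#'
#' @param sigma_male,sigma_group,sigma_event Random-effect SDs.
#' @return A [transition_params()] object.
#' @export
default_transition_params <- function(sigma_male = 0.3, sigma_group = 0.2,
                                      sigma_event = 0.2) {
  beta <- array(0, c(3, 3, 4))
  dimnames(beta) <- list(from = LIVE_STATES, to = LIVE_STATES,
                         coef = c("intercept", TRANSITION_COVARIATES))
  ref <- c(age_rank = 6, group_centred_weight = 0, sex_ratio = 2.2)
  # raw-scale slopes; intercept_at_ref is the linear predictor at `ref`
  set_dest <- function(from, to, intercept_at_ref, age_rank, weight, sexr) {
    beta[from, to, ] <<- c(intercept_at_ref -
                             sum(c(age_rank, weight, sexr) * ref),
                           age_rank, weight, sexr)
  }
  # from subordinate: guarding favoured by old rank/high weight, sneaking flat-ish
  set_dest("subordinate", "sneaker", -1.8, -0.05, 0.0000, 0)
  set_dest("subordinate", "guard",   -1.4, -0.18, 0.0030, 0)
  # from sneaker: tactic unstable, mostly drops to subordinate or gains guard
  set_dest("sneaker", "sneaker", -1.0, -0.08, -0.0015, 0)
  set_dest("sneaker", "guard",   -0.3, -0.15,  0.0030, 0)
  # from guard: retention vs displacement driven by rank and weight
  set_dest("guard", "sneaker", -1.2, -0.08, -0.0015, 0)
  set_dest("guard", "guard",    0.0, -0.20,  0.0035, 0)
  transition_params(beta, survival = c(0.96, 0.94, 0.95),
                    sigma_male = sigma_male, sigma_group = sigma_group,
                    sigma_event = sigma_event)
}

#' One-step transition probabilities
#'
#' Evaluates the transition-probability row for a male in a given origin
#' state: the probability of dying before the next oestrus event is
#' `1 - survival[origin]`, and the live destinations share the remaining mass
#' according to a multinomial logit (softmax) over the linear predictors. The
#' dead origin returns the absorbing row `(0, 0, 0, 1)`.
#'
#' @param params A [transition_params()] object.
#' @param covariates Named numeric vector holding `params$covariates`
#'   (no intercept entry).
#' @param origin Origin state name.
#' @param re Total random-effect contribution (scalar; sum of the male, group
#'   and event effects), added to each non-reference destination predictor.
#' @return Named numeric vector of length 4 summing to 1.
#' @export
transition_probs <- function(params, covariates, origin, re = 0) {
  stopifnot(inherits(params, "transition_params"))
  origin <- match.arg(origin, ART_STATES)
  if (origin == "dead")
    return(stats::setNames(c(0, 0, 0, 1), ART_STATES))
  x <- c(intercept = 1, covariates[params$covariates])
  if (anyNA(x)) stop("missing covariate value(s): ",
                     paste(params$covariates[is.na(covariates[params$covariates])],
                           collapse = ", "))
  eta <- vapply(LIVE_STATES, function(to) {
    lp <- sum(params$beta[origin, to, ] * x)
    if (to != "subordinate") lp <- lp + re
    lp
  }, numeric(1))
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  eta <- eta - max(eta)
  soft <- exp(eta) / sum(exp(eta))
  s <- params$survival[origin]
  stats::setNames(c(s * soft, 1 - s), ART_STATES)
}

#' Log-likelihood of observed tactic histories
#'
#' Sums the log transition probabilities over all consecutive event pairs in
#' a table of observed transitions. The result is additive over males and
#' invariant to the ordering of rows.
#'
#' @param params A [transition_params()] object.
#' @param transitions Data frame with columns `from`, `to` and the covariate
#'   columns named in `params$covariates` (covariates measured at the origin
#'   event). A `re` column may supply per-row random-effect sums.
#' @return Scalar log-likelihood.
#' @export
transition_loglik <- function(params, transitions) {
  stopifnot(inherits(params, "transition_params"), is.data.frame(transitions))
  needed <- c("from", "to", params$covariates)
  missing_cols <- setdiff(needed, names(transitions))
  if (length(missing_cols))
    stop("transitions table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(transitions$from == "dead" & transitions$to != "dead"))
    stop("invalid history: live state following dead")
  re <- if ("re" %in% names(transitions)) transitions$re else rep(0, nrow(transitions))
  ll <- 0
  for (i in seq_len(nrow(transitions))) {
    p <- transition_probs(params,
                          unlist(transitions[i, params$covariates]),
                          transitions$from[i], re = re[i])
    ll <- ll + log(p[transitions$to[i]])
  }
  unname(ll)
}

#' Forward-simulate a tactic sequence
#'
#' Simulates one male's tactic history across a sequence of oestrus events.
#' The sequence starts in the initial state (by default `"subordinate"`,
#' the state in which males enter the study population), each step is drawn
#' from the transition-probability row for the current state, and death is
#' absorbing.
#'
#' @param params A [transition_params()] object.
#' @param covariates Data frame with one row per oestrus event (in order) and
#'   the covariate columns named in `params$covariates`. Row `t` drives the
#'   transition from event `t` to event `t + 1`; an optional `re` column
#'   supplies per-event random-effect sums.
#' @param init Initial state (default `"subordinate"`).
#' @return Character vector of states, one per event (`nrow(covariates)`).
#'   Uses the R random number generator; seed with [set.seed()].
#' @export
simulate_tactic_sequence <- function(params, covariates, init = "subordinate") {
  stopifnot(inherits(params, "transition_params"), is.data.frame(covariates),
            nrow(covariates) >= 1)
  init <- match.arg(init, ART_STATES)
  re <- if ("re" %in% names(covariates)) covariates$re else rep(0, nrow(covariates))
  states <- character(nrow(covariates))
  states[1] <- init
  if (nrow(covariates) > 1) {
    for (t in seq_len(nrow(covariates) - 1L)) {
      p <- transition_probs(params, unlist(covariates[t, params$covariates]),
                            states[t], re = re[t])
      states[t + 1L] <- sample(ART_STATES, 1L, prob = p)
    }
  }
  states
}
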