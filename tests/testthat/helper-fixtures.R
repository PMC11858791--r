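# shared fixtures and short chain settings for the test suite

quick_mcmc <- function(seed = 1L, iterations = 600, chains = 3) {
  mcmc_config(chains = chains, iterations = iterations, burnin = 200,
              thin = 1, adapt = 150, seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

# small synthetic population reused across test files
tiny_dataset <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- generate_population(
      sim_config(n_groups = 3, n_events_per_group = 6, seed = 4242))
  }
  .fixture_cache$tiny
}

tiny_preprocessed <- function() {
  if (is.null(.fixture_cache$tiny_pp)) {
    .fixture_cache$tiny_pp <- preprocess_dataset(tiny_dataset())
  }
  .fixture_cache$tiny_pp
}

# arbitrary (but fixed) transition parameters for oracle checks
random_transition_params <- function(seed, survival = NULL) {
  set.seed(seed)
  beta <- array(0, c(3, 3, 4))
  beta[, 2:3, ] <- rnorm(3 * 2 * 4, sd = 0.6)
  if (is.null(survival)) survival <- runif(3, 0.7, 1)
  transition_params(beta, survival)
}

random_covariates <- function(n, seed) {
  set.seed(seed)
  data.frame(age_rank = sample(1:15, n, replace = TRUE),
             group_centred_weight = rnorm(n, 0, 150),
             sex_ratio = runif(n, 0.5, 4))
}

# independent arithmetic oracle for one transition-probability row
oracle_transition_row <- function(params, covs, origin, re = 0) {
  if (origin == "dead") return(c(subordinate = 0, sneaker = 0, guard = 0, dead = 1))
  x <- c(1, covs[["age_rank"]], covs[["group_centred_weight"]],
         covs[["sex_ratio"]])
  eta <- numeric(3)
  for (m in 1:3) {
    eta[m] <- sum(params$beta[origin, m, ] * x) + if (m > 1) re else 0
  }
  num <- exp(eta - max(eta))   # stabilized softmax, same mathematical value
  s <- params$survival[[origin]]
  out <- c(s * num / sum(num), 1 - s)
  names(out) <- c("subordinate", "sneaker", "guard", "dead")
  out
}

# direct simulation of transition records from known parameters (no
# population structure; used for fitter checks that need speed)
simulate_transition_records <- function(params, n_males, n_events, seed,
                                        n_groups = 4) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_males)) {
    covs <- random_covariates(n_events, seed * 1000 + i)
    state <- "subordinate"
    grp <- sprintf("G%d", 1 + (i %% n_groups))
    for (t in seq_len(n_events - 1)) {
      p <- transition_probs(params, unlist(covs[t, ]), state)
      nxt <- sample(art_states(), 1, prob = p)
      out[[length(out) + 1L]] <- data.frame(
        male_id = sprintf("M%d", i), group_id = grp,
        event_id = sprintf("%s_E%d", grp, t), from = state, to = nxt,
        covs[t, , drop = FALSE], stringsAsFactors = FALSE)
      if (nxt == "dead") break
      state <- nxt
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Bernoulli siring trials generated straight from the regression model
simulate_siring_trials <- function(beta, n, seed) {
  set.seed(seed)
  tactic <- sample(c("guard", "sneaker"), n, replace = TRUE)
  ncomp <- sample(2:6, n, replace = TRUE)
  propsame <- round(runif(n), 2)
  eta <- beta["intercept"] + beta["guard"] * (tactic == "guard") +
    beta["n_competitors"] * ncomp + beta["prop_same_tactic"] * propsame
  data.frame(litter_id = sprintf("L%d", seq_len(n)),
             event_id = sprintf("E%d", sample(1:40, n, replace = TRUE)),
             female_id = sprintf("F%d", sample(1:30, n, replace = TRUE)),
             male_id = sprintf("M%d", sample(1:60, n, replace = TRUE)),
             tactic = tactic, n_competitors = ncomp,
             prop_same_tactic = propsame,
             sired = runif(n) < plogis(eta), stringsAsFactors = FALSE)
}

# Bernoulli mate-choice dyads generated straight from the regression model
simulate_dyads <- function(beta, n, seed) {
  set.seed(seed)
  mrank <- sample(1:12, n, replace = TRUE)
  frank <- sample(1:6, n, replace = TRUE)
  rel <- sample(c(-0.2, -0.1, 0, 0.1, 0.3), n, replace = TRUE)
  tactic <- sample(c("guard", "sneaker"), n, replace = TRUE)
  nf <- sample(2:6, n, replace = TRUE)
  guard <- as.numeric(tactic == "guard")
  eta <- beta["intercept"] + beta["relatedness"] * rel +
    beta["male_rank"] * mrank + beta["female_rank"] * frank +
    beta["rank_product"] * mrank * frank +
    beta["guard"] * guard +
    beta["guard_rank_product"] * guard * mrank * frank +
    beta["n_adult_females"] * nf
  data.frame(event_id = sprintf("E%d", sample(1:50, n, replace = TRUE)),
             date = as.Date("2010-01-01") + sample(1:300, n, replace = TRUE),
             male_id = sprintf("M%d", sample(1:50, n, replace = TRUE)),
             female_id = sprintf("F%d", sample(1:30, n, replace = TRUE)),
             interacted = runif(n) < plogis(eta), tactic = tactic,
             male_age_rank = mrank, female_age_rank = frank,
             group_centred_relatedness = rel, n_adult_females = nf,
             stringsAsFactors = FALSE)
}
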