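test_that("the dead state is absorbing with probability one", {
  p <- random_transition_params(41)
  covs <- random_covariates(1, 42)
  row <- transition_probs(p, unlist(covs[1, ]), "dead")
  expect_identical(unname(row), c(0, 0, 0, 1))
})

test_that("transition rows match a hand-computed softmax-survival oracle", {
  set.seed(43)
  for (i in 1:60) {
    p <- random_transition_params(1000 + i)
    covs <- unlist(random_covariates(1, 2000 + i))
    re <- rnorm(1, 0, 0.5)
    for (origin in art_states(live = TRUE)) {
      got <- transition_probs(p, covs, origin, re = re)
      expect_equal(got, oracle_transition_row(p, covs, origin, re),
                   tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-12)
      expect_true(all(got >= 0 & got <= 1))
    }
  }
})

state_dimnames <- function(beta) {
  dimnames(beta) <- list(c("subordinate", "sneaker", "guard"),
                         c("subordinate", "sneaker", "guard"),
                         c("intercept", "age_rank", "group_centred_weight",
                           "sex_ratio"))
  beta
}

test_that("a positive beta increases its destination probability", {
  beta <- state_dimnames(array(0, c(3, 3, 4)))
  beta["subordinate", "guard", 2] <- 0.5  # age-rank slope toward guarding
  p <- transition_params(beta, survival = c(0.9, 0.9, 0.9))
  base <- c(age_rank = 2, group_centred_weight = 0, sex_ratio = 2)
  up <- base; up["age_rank"] <- 5
  expect_gt(transition_probs(p, up, "subordinate")[["guard"]],
            transition_probs(p, base, "subordinate")[["guard"]])
})

test_that("the transition log-likelihood matches a brute-force oracle", {
  # survival 0.5 with symmetric logits: P(dead) = 0.5 exactly
  beta <- array(0, c(3, 3, 4))
  p5 <- transition_params(beta, survival = c(0.5, 0.5, 0.5))
  one <- data.frame(from = "subordinate", to = "dead", age_rank = 1,
                    group_centred_weight = 0, sex_ratio = 2)
  expect_equal(transition_loglik(p5, one), log(0.5), tolerance = 1e-12)
  # randomized tables against an independent per-row product
  set.seed(44)
  for (i in 1:60) {
    p <- random_transition_params(3000 + i)
    tr <- simulate_transition_records(p, n_males = 4, n_events = 5,
                                      seed = 4000 + i)
    got <- transition_loglik(p, tr)
    oracle <- 0
    for (r in seq_len(nrow(tr))) {
      row <- oracle_transition_row(p, unlist(tr[r, c("age_rank",
                                                     "group_centred_weight",
                                                     "sex_ratio")]),
                                   tr$from[r])
      oracle <- oracle + log(row[[tr$to[r]]])
    }
    expect_equal(got, oracle, tolerance = 1e-10)
    # invariant to row order
    expect_equal(transition_loglik(p, tr[sample(nrow(tr)), ]), got,
                 tolerance = 1e-10)
  }
})

test_that("probability-one transitions leave the log-likelihood unchanged", {
  p <- random_transition_params(45)
  tr <- simulate_transition_records(p, n_males = 3, n_events = 4, seed = 46)
  base <- transition_loglik(p, tr)
  # dead -> dead happens with probability one
  extra <- data.frame(male_id = "M1", group_id = "G1", event_id = "X",
                      from = "dead", to = "dead", age_rank = 3,
                      group_centred_weight = 0, sex_ratio = 2)
  expect_equal(transition_loglik(p, rbind(tr, extra)), base, tolerance = 1e-12)
  # a live state after dead is an invalid history
  bad <- extra; bad$to <- "guard"
  expect_error(transition_loglik(p, rbind(tr, bad)), "invalid history")
})

test_that("the fitted model recovers a strong age-rank effect", {
  beta <- state_dimnames(array(0, c(3, 3, 4)))
  beta[, "sneaker", 1] <- -1
  beta[, "guard", 1] <- 1.5
  beta["subordinate", "guard", 2] <- -0.35   # old ranks guard more
  truth <- transition_params(beta, survival = c(0.95, 0.95, 0.95))
  tr <- simulate_transition_records(truth, n_males = 60, n_events = 8,
                                    seed = 47)
  fit <- fit_transition_model(tr, mcmc = quick_mcmc(seed = 48,
                                                    iterations = 1000),
                              random_effects = FALSE)
  sm <- fit$summary
  row <- sm[sm$parameter == "beta_raw[subordinate->guard:age_rank]", ]
  expect_lt(row$mean, 0)
  expect_true(row$credible)
  expect_true(row$lci <= -0.35 & -0.35 <= row$hci)
  # survival estimates sit near the truth
  srow <- sm[sm$parameter == "survival[subordinate]", ]
  expect_equal(srow$mean, 0.95, tolerance = 0.04)
})

test_that("all-subordinate immortal histories fit without error", {
  tr <- data.frame(male_id = rep(sprintf("M%d", 1:20), each = 3),
                   group_id = "G1",
                   event_id = rep(sprintf("E%d", 1:3), 20),
                   from = "subordinate", to = "subordinate",
                   age_rank = sample(1:10, 60, replace = TRUE),
                   group_centred_weight = rnorm(60, 0, 100),
                   sex_ratio = runif(60, 1, 3))
  fit <- fit_transition_model(tr, mcmc = quick_mcmc(seed = 49,
                                                    iterations = 500),
                              random_effects = FALSE)
  sm <- fit$summary
  # intercepts toward ever observing sneaking/guarding are strongly negative
  expect_lt(sm$mean[sm$parameter == "beta[subordinate->sneaker:intercept]"], -1)
  expect_lt(sm$mean[sm$parameter == "beta[subordinate->guard:intercept]"], -1)
})

test_that("posterior means agree with an independent multinomial-logit fit", {
  skip_if_not_installed("nnet")
  p <- random_transition_params(50, survival = rep(1, 3))
  tr <- simulate_transition_records(p, n_males = 80, n_events = 7, seed = 51)
  fit <- fit_transition_model(tr, mcmc = quick_mcmc(seed = 52,
                                                    iterations = 1200),
                              random_effects = FALSE)
  sm <- fit$summary
  std <- standardize_covariates(tr[, c("age_rank", "group_centred_weight",
                                       "sex_ratio")])
  for (origin in art_states(live = TRUE)) {
    sel <- tr$from == origin
    if (length(unique(tr$to[sel])) < 3) next
    d <- cbind(to = factor(tr$to[sel], levels = art_states(live = TRUE)),
               std[sel, ])
    mle <- nnet::multinom(to ~ age_rank + group_centred_weight + sex_ratio,
                          data = d, trace = FALSE)
    co <- coef(mle); se <- summary(mle)$standard.errors
    for (dest in rownames(co)) {
      for (k in c("age_rank", "group_centred_weight", "sex_ratio")) {
        bayes <- sm$mean[sm$parameter ==
                           sprintf("beta[%s->%s:%s]", origin, dest, k)]
        expect_lt(abs(bayes - co[dest, k]), 3 * se[dest, k] + 0.05)
      }
    }
  }
})

test_that("interaction screening drops non-credible sex-ratio interactions", {
  p <- random_transition_params(53, survival = rep(0.95, 3))
  tr <- simulate_transition_records(p, n_males = 40, n_events = 6, seed = 54)
  fit <- fit_transition_model(tr, mcmc = quick_mcmc(seed = 55,
                                                    iterations = 500),
                              interactions = TRUE, random_effects = FALSE)
  # the generator has no sex-ratio interactions, so screening removes them
  expect_true(length(fit$dropped_interactions) >= 1)
  expect_false(any(grepl("sex_ratio_x", fit$summary$parameter[
    fit$summary$parameter %in% fit$coef_names])))
})

test_that("posterior transition curves conserve probability", {
  p <- random_transition_params(56)
  tr <- simulate_transition_records(p, n_males = 30, n_events = 6, seed = 57)
  fit <- fit_transition_model(tr, mcmc = quick_mcmc(seed = 58,
                                                    iterations = 400,
                                                    chains = 2),
                              random_effects = FALSE)
  grid <- c(1, 4, 8)
  curves <- posterior_transition_curves(fit, "age_rank", grid)
  sums <- aggregate(mean ~ origin + value, data = curves, FUN = sum)
  expect_equal(sums$mean, rep(1, nrow(sums)), tolerance = 1e-9)
  expect_true(all(curves$lci <= curves$mean & curves$mean <= curves$hci))

  # a single retained draw reproduces that draw's transition row exactly
  single <- fit
  single$draws <- lapply(fit$draws[1], function(m) m[1, , drop = FALSE])
  dm <- single$draws[[1]]
  cv <- posterior_transition_curves(single, "age_rank", 4)
  x <- c(1, standardize_value(4, fit$scaling, "age_rank"),
         standardize_value(mean(tr$group_centred_weight), fit$scaling,
                           "group_centred_weight"),
         standardize_value(mean(tr$sex_ratio), fit$scaling, "sex_ratio"))
  for (origin in art_states(live = TRUE)) {
    eta <- c(0, vapply(c("sneaker", "guard"), function(to)
      sum(dm[1, sprintf("beta[%s->%s:%s]", origin, to,
                        c("intercept", "age_rank", "group_centred_weight",
                          "sex_ratio"))] * x), numeric(1)))
    soft <- exp(eta - max(eta)) / sum(exp(eta - max(eta)))
    s <- dm[1, sprintf("survival[%s]", origin)]
    expected <- c(soft * s, 1 - s)
    got <- cv$mean[cv$origin == origin]
    expect_equal(got, unname(expected), tolerance = 1e-10)
  }
})

test_that("the reference transition matrix mirrors the fitted nine cells", {
  p <- random_transition_params(59)
  tr <- simulate_transition_records(p, n_males = 25, n_events = 5, seed = 60)
  fit <- fit_transition_model(tr, mcmc = quick_mcmc(seed = 61,
                                                    iterations = 400,
                                                    chains = 2),
                              random_effects = FALSE)
  tm <- transition_matrix_summary(fit)
  expect_equal(nrow(tm), 12)  # 3 origins x 4 destinations
  expect_equal(aggregate(mean ~ from, tm, sum)$mean, rep(1, 3),
               tolerance = 1e-9)
})
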