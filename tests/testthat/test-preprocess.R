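test_that("tactic summarization follows the any/majority/tie rules", {
  expect_equal(as.character(summarize_tactic(c("guard", "guard", "sneak"))),
               "guard")
  expect_equal(as.character(summarize_tactic(c("none", "none"))), "subordinate")
  expect_equal(as.character(summarize_tactic(c("sneak", "none", "none"))),
               "sneaker")
  # equal guard and sneak days: main tie rule says sneaker, flagged
  tie <- summarize_tactic(c("guard", "sneak"))
  expect_equal(as.character(tie), "sneaker")
  expect_true(attr(tie, "tie"))
  expect_equal(as.character(summarize_tactic(c("guard", "sneak"),
                                             tie_rule = "guard")), "guard")
  expect_error(summarize_tactic(character(0)), "not present")
})

test_that("tactic summarization is invariant to day order", {
  set.seed(11)
  for (i in 1:50) {
    days <- sample(c("guard", "sneak", "none"), sample(1:7, 1), replace = TRUE)
    expect_identical(as.character(summarize_tactic(days)),
                     as.character(summarize_tactic(sample(days))))
  }
})

test_that("age ranks use minimum-rank ties with gaps", {
  # one oldest male, three equal-aged males, one younger -> 1,2,2,2,5
  ranks <- assign_age_ranks(c(a = 3000, b = 2000, c = 2000, d = 2000, e = 900))
  expect_equal(unname(ranks), c(1L, 2L, 2L, 2L, 5L))
  # no ties: ranks are exactly 1..n
  set.seed(12)
  ages <- setNames(sample(200:4000, 8), letters[1:8])
  expect_setequal(assign_age_ranks(ages), 1:8)
  expect_equal(unname(assign_age_ranks(sort(ages, decreasing = TRUE))), 1:8)
})

test_that("age ranks match the strictly-older-count oracle on random input", {
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    ages <- sample(180:2000, n, replace = TRUE)
    names(ages) <- paste0("m", seq_len(n))
    got <- assign_age_ranks(ages)
    oracle <- vapply(ages, function(a) sum(ages > a) + 1L, integer(1))
    expect_identical(unname(got), unname(oracle))
  }
})

test_that("oestrus weights average the +/-60 day window", {
  ev <- as.Date(c("2010-06-01", "2010-06-03"))
  w <- data.frame(date = ev[1] + c(-10, 12), grams = c(1000, 1100))
  expect_equal(oestrus_weight(w, ev[1], ev[2]), 1050)
  # a single weight just outside the window is ignored
  w2 <- data.frame(date = ev[1] - 61, grams = 900)
  expect_true(is.na(oestrus_weight(w2, ev[1], ev[2])))
  expect_equal(oestrus_weight(rbind(w, w2), ev[1], ev[2]), 1050)
})

test_that("oestrus weights equal a brute-force filter-and-mean oracle", {
  set.seed(14)
  for (i in 1:200) {
    start <- as.Date("2010-01-01") + sample(0:300, 1)
    end <- start + sample(0:6, 1)
    w <- data.frame(date = start + sample(-120:120, 20, replace = TRUE),
                    grams = runif(20, 800, 2000))
    w <- w[order(w$date), ]
    inside <- w$grams[w$date >= start - 60 & w$date <= end + 60]
    expected <- if (length(inside)) mean(inside) else NA_real_
    expect_equal(oestrus_weight(w, start, end), expected)
  }
})

test_that("weight centring is exact and conserves zero mean", {
  expect_equal(unname(centre_weights(c(a = 1000, b = 1200))), c(-100, 100))
  expect_equal(unname(centre_weights(c(a = 1500))), 0)
  set.seed(15)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    w <- setNames(runif(n, 900, 2000), paste0("m", seq_len(n)))
    expect_equal(sum(centre_weights(w)), 0, tolerance = 1e-9)
  }
  # NA values pass through and do not move the observed mean
  ctr <- centre_weights(c(a = 1000, b = NA, c = 1200))
  expect_true(is.na(ctr[["b"]]))
  expect_equal(sum(ctr, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_error(centre_weights(c(a = NA_real_)), "impute or drop")
})

test_that("imputation reproduces a perfectly linear growth history", {
  demo <- data.frame(individual_id = "m1", birth_date = as.Date("2008-01-01"))
  dates <- as.Date("2009-01-01") + seq(0, 300, by = 30)
  age <- as.numeric(dates - demo$birth_date)
  w <- data.frame(individual_id = "m1", date = dates, grams = 500 + 0.8 * age)
  tgt <- data.frame(individual_id = "m1", event_id = "e9",
                    event_start = as.Date("2009-06-10"),
                    event_end = as.Date("2009-06-14"))
  imp <- impute_missing_weights(w, demo, tgt)
  mid_age <- as.numeric(as.Date("2009-06-12") - demo$birth_date)
  expect_equal(imp$grams, 500 + 0.8 * mid_age, tolerance = 1e-8)
  expect_true(imp$imputed)
})

test_that("imputation error stays within twice the measurement noise", {
  ds <- tiny_dataset()
  pp <- tiny_preprocessed()
  noise_sd <- ds$truth$config$weight_noise_sd
  cov <- pp$covariates[pp$covariates$imputed & !is.na(pp$covariates$oestrus_weight), ]
  expect_gt(nrow(cov), 0)
  # compare imputed oestrus weights against the noiseless growth-curve truth
  birth <- setNames(ds$demography$birth_date, ds$demography$individual_id)
  events <- ds$events
  errs <- vapply(seq_len(nrow(cov)), function(i) {
    ev <- events[events$event_id == cov$event_id[i], ]
    mid <- ev$start_date + as.numeric(ev$end_date - ev$start_date) / 2
    age <- as.numeric(mid - birth[cov$male_id[i]])
    truth <- arttrans:::growth_curve(age, ds$truth$w_inf[cov$male_id[i]])
    cov$oestrus_weight[i] - truth
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 2 * noise_sd)
  # imputed fraction close to the configured missingness rate
  expect_equal(mean(pp$covariates$imputed),
               ds$truth$config$weight_missing_frac, tolerance = 0.04)
})

test_that("weight change uses the 60-day prior mean and <= 9 day post weight", {
  start <- as.Date("2011-03-01"); end <- as.Date("2011-03-04")
  w <- data.frame(date = c(start - c(30, 10), end + 2),
                  grams = c(990, 1010, 980))
  wc <- extract_weight_change(w, start, end)
  expect_equal(wc$prior_weight, 1000)
  expect_equal(wc$post_weight, 980)
  expect_equal(wc$pct_change, -2)
  expect_equal(wc$days_to_post, 2)
  # post weight only at +10 days -> no record
  w10 <- data.frame(date = c(start - 10, end + 10), grams = c(1000, 950))
  expect_null(extract_weight_change(w10, start, end))
  # day 9 is inside the boundary
  w9 <- data.frame(date = c(start - 10, end + 9), grams = c(1000, 950))
  expect_equal(extract_weight_change(w9, start, end)$days_to_post, 9)
})

test_that("weight change matches a brute-force oracle on random fixtures", {
  set.seed(16)
  for (i in 1:200) {
    start <- as.Date("2010-01-01") + sample(0:200, 1)
    end <- start + sample(0:6, 1)
    w <- data.frame(date = start + sample(-90:30, 15, replace = TRUE),
                    grams = runif(15, 800, 2000))
    got <- extract_weight_change(w, start, end)
    prior <- w$grams[w$date >= start - 60 & w$date < start]
    post <- w[w$date > end & w$date <= end + 9, ]
    if (!length(prior) || !nrow(post)) {
      expect_null(got)
    } else {
      nearest <- min(as.numeric(post$date - end))
      expected_post <- mean(post$grams[as.numeric(post$date - end) == nearest])
      expect_equal(got$pct_change,
                   100 * (expected_post - mean(prior)) / mean(prior),
                   tolerance = 1e-10)
    }
  }
})

test_that("group-centred relatedness averages to zero and drops unknowns", {
  expect_equal(unname(group_centred_relatedness(c(f1 = 0.5, f2 = 0))),
               c(0.25, -0.25), ignore_attr = TRUE)
  expect_equal(unname(group_centred_relatedness(c(f1 = .25, f2 = .25, f3 = .25))),
               c(0, 0, 0), ignore_attr = TRUE)
  set.seed(17)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    r <- setNames(sample(c(0, .125, .25, .5), n, replace = TRUE),
                  paste0("f", seq_len(n)))
    expect_equal(mean(group_centred_relatedness(r)), 0, tolerance = 1e-12)
  }
  out <- group_centred_relatedness(c(f1 = 0.5, f2 = NA, f3 = 0))
  expect_equal(attr(out, "dropped"), "f2")
  expect_equal(length(out), 2)
})

test_that("litters link to events ending 44-74 days before birth", {
  demo <- data.frame(individual_id = "fA", group_id = "G1")
  events <- data.frame(event_id = c("e1", "e2"), group_id = "G1",
                       end_date = as.Date(c("2012-01-10", "2012-04-10")))
  litters <- data.frame(litter_id = c("L1", "L2"),
                        mother_id = "fA",
                        birth_date = as.Date(c("2012-03-09", "2012-04-30")))
  links <- link_litters(litters, events, demo)
  expect_equal(links$event_id, c("e1", NA))       # 59 d before vs 20 d before
  expect_equal(links$gestation_days, c(59, NA))
})

test_that("litter links recover the generating events", {
  ds <- tiny_dataset()
  pp <- tiny_preprocessed()
  truth <- ds$truth$litter_events
  got <- pp$litter_links
  m <- match(truth$litter_id, got$litter_id)
  agree <- mean(got$event_id[m] == truth$event_id, na.rm = TRUE)
  expect_gte(agree, 0.99)
})

test_that("sex ratio counts one-year-olds only", {
  roster <- data.frame(sex = c(rep("M", 6), rep("F", 3)),
                       age_days = c(rep(600, 6), rep(800, 3)))
  expect_equal(compute_sex_ratio(roster), 2)
  # an 11-month female drops out of the denominator
  roster$age_days[7] <- 330
  expect_equal(compute_sex_ratio(roster), 3)
  roster$sex <- "M"
  expect_warning(out <- compute_sex_ratio(roster), "no adult females")
  expect_true(is.na(out))
})

test_that("dyad records cover every adult female on interaction days", {
  focals <- data.frame(
    date = as.Date("2010-05-01"), event_id = "e1", group_id = "G1",
    male_id = c("m1", "m2"), female_id = c("fA", NA),
    behaviour = c("guard", "none"), stringsAsFactors = FALSE)
  male_ranks <- data.frame(event_id = "e1", male_id = c("m1", "m2"),
                           age_rank = c(1L, 2L))
  female_ranks <- data.frame(event_id = "e1",
                             female_id = c("fA", "fB", "fC"),
                             age_rank = c(1L, 2L, 3L))
  rel <- data.frame(id_a = c("m1", "m1", "m1"), id_b = c("fA", "fB", "fC"),
                    r = c(0.5, 0, 0.25))
  dy <- build_dyad_table(focals, male_ranks, female_ranks, rel)
  # one record per female present, only for the interacting male
  expect_equal(nrow(dy), 3)
  expect_setequal(dy$female_id, c("fA", "fB", "fC"))
  expect_equal(dy$interacted, dy$female_id == "fA")
  expect_true(all(dy$n_adult_females == 3))
  expect_equal(sum(dy$group_centred_relatedness), 0, tolerance = 1e-12)
  # unknown relatedness drops the dyad
  rel2 <- rel[rel$id_b != "fC", ]
  dy2 <- build_dyad_table(focals, male_ranks, female_ranks, rel2)
  expect_equal(nrow(dy2), 2)
  expect_equal(attr(dy2, "dropped"), 1L)
})

test_that("dyad counts follow the counting oracle on a synthetic population", {
  ds <- tiny_dataset()
  pp <- tiny_preprocessed()
  f <- ds$focals
  active <- unique(f[f$behaviour != "none",
                     c("event_id", "date", "male_id")])
  # adult females present per event
  demo <- ds$demography
  ev <- ds$events
  nf <- vapply(active$event_id, function(e) {
    e_row <- ev[ev$event_id == e, ]
    fem <- demo[demo$group_id == e_row$group_id & demo$sex == "F", ]
    sum(as.numeric(e_row$start_date - fem$birth_date) >= 365)
  }, numeric(1))
  # all synthetic dyads have known relatedness, so nothing is dropped
  expect_equal(nrow(pp$dyads), sum(nf))
  expect_equal(attr(pp$dyads, "dropped"), 0L)
})

test_that("siring trials compute competitor counts and same-tactic shares", {
  litters <- data.frame(litter_id = "L1", mother_id = "fA",
                        birth_date = as.Date("2012-03-09"),
                        sire_ids = "m2", stringsAsFactors = FALSE)
  links <- data.frame(litter_id = "L1", event_id = "e1",
                      gestation_days = 59)
  focals <- data.frame(
    date = as.Date("2012-01-08"), event_id = "e1", group_id = "G1",
    male_id = c("m1", "m2", "m3"), female_id = "fA",
    behaviour = c("guard", "sneak", "sneak"), stringsAsFactors = FALSE)
  tactics <- data.frame(event_id = "e1", male_id = c("m1", "m2", "m3"),
                        tactic = c("guard", "sneaker", "sneaker"))
  tr <- build_siring_trials(links, litters, focals, tactics)
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$n_competitors == 3))
  # 1 guard + 2 sneakers: guard shares with nobody, each sneaker with one of two
  expect_equal(tr$prop_same_tactic[tr$male_id == "m1"], 0)
  expect_equal(tr$prop_same_tactic[tr$male_id %in% c("m2", "m3")], c(0.5, 0.5))
  expect_equal(tr$sired, tr$male_id == "m2")
  # females pursued only by guards are excluded
  tactics2 <- data.frame(event_id = "e1", male_id = c("m1", "m2", "m3"),
                         tactic = "guard")
  expect_equal(nrow(build_siring_trials(links, litters, focals, tactics2)), 0)
  # a sire who never interacted with the mother voids the litter
  litters3 <- litters; litters3$sire_ids <- "m9"
  tr3 <- build_siring_trials(links, litters3, focals, tactics)
  expect_equal(nrow(tr3), 0)
  expect_equal(attr(tr3, "orphaned"), 1L)
})

test_that("multiple-paternity litters yield several successful trials", {
  litters <- data.frame(litter_id = "L1", mother_id = "fA",
                        birth_date = as.Date("2012-03-09"),
                        sire_ids = "m1;m2", stringsAsFactors = FALSE)
  links <- data.frame(litter_id = "L1", event_id = "e1", gestation_days = 59)
  focals <- data.frame(
    date = as.Date("2012-01-08"), event_id = "e1", group_id = "G1",
    male_id = c("m1", "m2"), female_id = "fA",
    behaviour = c("guard", "sneak"), stringsAsFactors = FALSE)
  tactics <- data.frame(event_id = "e1", male_id = c("m1", "m2"),
                        tactic = c("guard", "sneaker"))
  tr <- build_siring_trials(links, litters, focals, tactics)
  expect_equal(sum(tr$sired), 2)
})

test_that("males under 180 days never enter derived tables", {
  ds <- tiny_dataset()
  pp <- tiny_preprocessed()
  birth <- setNames(ds$demography$birth_date, ds$demography$individual_id)
  ev_start <- setNames(ds$events$start_date, ds$events$event_id)
  age_at <- as.numeric(ev_start[pp$covariates$event_id] -
                       birth[pp$covariates$male_id])
  expect_true(all(age_at >= 180))
})
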