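#' Derive per-event tactic histories
#'
#' Summarizes each male's daily behaviours into one tactic per oestrus event
#' attended (males under 180 days are excluded), orders events by date, and
#' appends an absorbing `"dead"` state at the first event of the male's
#' group following his death.
#'
#' @param dataset An `art_dataset`.
#' @param tie_rule Passed to [summarize_tactic()].
#' @return Data frame `male_id`, `group_id`, `event_id`, `event_index`
#'   (order within the male's history), `tactic`, `tie`.
#' @export
derive_tactic_histories <- function(dataset, tie_rule = c("sneaker", "guard")) {
  tie_rule <- match.arg(tie_rule)
  demo <- dataset$demography
  events <- dataset$events[order(dataset$events$group_id,
                                 dataset$events$start_date), , drop = FALSE]
  birth <- stats::setNames(demo$birth_date, demo$individual_id)
  death <- stats::setNames(demo$death_date, demo$individual_id)
  f <- dataset$focals
  out <- list()
  for (male in unique(f$male_id)) {
    fm <- f[f$male_id == male, , drop = FALSE]
    grp <- fm$group_id[1]
    ev <- events[events$group_id == grp, , drop = FALSE]
    attended <- ev[ev$event_id %in% fm$event_id &
                   as.numeric(ev$start_date - birth[male]) >= 180, ,
                   drop = FALSE]
    if (nrow(attended) == 0L) next
    summaries <- lapply(attended$event_id, function(e)
      summarize_tactic(fm$behaviour[fm$event_id == e], tie_rule = tie_rule))
    tactics <- vapply(summaries, as.character, character(1))
    ties <- vapply(summaries, function(s) attr(s, "tie"), logical(1))
    hist <- data.frame(male_id = male, group_id = grp,
                       event_id = attended$event_id,
                       event_index = seq_len(nrow(attended)),
                       tactic = unname(tactics), tie = unname(ties),
                       stringsAsFactors = FALSE)
    # absorbing death: one dead record at the group's next event after death
    if (!is.na(death[male])) {
      later <- ev[ev$start_date > death[male], , drop = FALSE]
      if (nrow(later) > 0L)
        hist <- rbind(hist, data.frame(
          male_id = male, group_id = grp, event_id = later$event_id[1],
          event_index = nrow(hist) + 1L, tactic = "dead", tie = FALSE,
          stringsAsFactors = FALSE))
    }
    out[[length(out) + 1L]] <- hist
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Derive per-male-per-event covariates
#'
#' Builds the covariate table of the transition model: age in days, within
#' group-event age rank, oestrus-window weight (imputed from the
#' individual's age-weight relationship where missing, and flagged), group
#' -centred weight, and group sex ratio.
#'
#' @param dataset An `art_dataset`.
#' @param histories Output of [derive_tactic_histories()]; covariates are
#'   built for every live male-event it contains.
#' @return Data frame `male_id`, `group_id`, `event_id`, `age_days`,
#'   `age_rank`, `oestrus_weight`, `group_centred_weight`, `sex_ratio`,
#'   `imputed`.
#' @export
derive_covariates <- function(dataset, histories) {
  demo <- dataset$demography
  events <- dataset$events
  birth <- stats::setNames(demo$birth_date, demo$individual_id)
  live <- histories[histories$tactic != "dead", , drop = FALSE]
  out <- list()
  for (e in unique(live$event_id)) {
    ev <- events[events$event_id == e, , drop = FALSE]
    males <- live$male_id[live$event_id == e]
    age <- as.numeric(ev$start_date - birth[males])
    ranks <- assign_age_ranks(stats::setNames(age, males))
    ow <- vapply(males, function(m)
      oestrus_weight(dataset$weights[dataset$weights$individual_id == m, ,
                                     drop = FALSE],
                     ev$start_date, ev$end_date), numeric(1))
    fem <- demo[demo$group_id == ev$group_id & demo$sex == "F", , drop = FALSE]
    fem_alive <- is.na(fem$death_date) | fem$death_date > ev$start_date
    roster <- data.frame(
      sex = c(rep("M", length(males)), rep("F", sum(fem_alive))),
      age_days = c(age, as.numeric(ev$start_date - fem$birth_date[fem_alive])))
    sexr <- compute_sex_ratio(roster)
    out[[length(out) + 1L]] <- data.frame(
      male_id = males, group_id = ev$group_id, event_id = e, age_days = age,
      age_rank = unname(ranks), oestrus_weight = unname(ow),
      sex_ratio = sexr, imputed = FALSE, stringsAsFactors = FALSE)
  }
  cov <- do.call(rbind, out)
  rownames(cov) <- NULL
  # impute missing oestrus weights, then centre within group-event
  miss <- cov[is.na(cov$oestrus_weight), , drop = FALSE]
  if (nrow(miss) > 0L) {
    tgt <- merge(miss[, c("male_id", "event_id")],
                 events[, c("event_id", "start_date", "end_date")],
                 by = "event_id")
    tgt <- data.frame(individual_id = tgt$male_id, event_id = tgt$event_id,
                      event_start = tgt$start_date, event_end = tgt$end_date,
                      stringsAsFactors = FALSE)
    imp <- impute_missing_weights(dataset$weights, demo, tgt)
    key <- paste(cov$male_id, cov$event_id)
    ikey <- paste(imp$individual_id, imp$event_id)
    cov$oestrus_weight[match(ikey, key)] <- imp$grams
    cov$imputed[match(ikey, key)] <- TRUE
  }
  cov$group_centred_weight <- NA_real_
  for (e in unique(cov$event_id)) {
    sel <- cov$event_id == e
    w <- cov$oestrus_weight[sel]
    obs_mean <- mean(w[!cov$imputed[sel]], na.rm = TRUE)
    if (is.nan(obs_mean)) obs_mean <- mean(w, na.rm = TRUE)
    cov$group_centred_weight[sel] <- w - obs_mean
  }
  cov
}

#' Build the transition table
#'
#' Joins consecutive pairs of a male's per-event tactics with the covariates
#' measured at the origin event; this is the modelling table consumed by
#' [fit_transition_model()] and [transition_loglik()].
#'
#' @param histories Output of [derive_tactic_histories()].
#' @param covariates Output of [derive_covariates()].
#' @return Data frame with `male_id`, `group_id`, `event_id` (origin event),
#'   `from`, `to`, `age_rank`, `group_centred_weight`, `sex_ratio`,
#'   `imputed`.
#' @export
build_transitions <- function(histories, covariates) {
  ck <- paste(covariates$male_id, covariates$event_id)
  out <- list()
  for (male in unique(histories$male_id)) {
    h <- histories[histories$male_id == male, , drop = FALSE]
    h <- h[order(h$event_index), , drop = FALSE]
    if (nrow(h) < 2L) next
    idx <- seq_len(nrow(h) - 1L)
    cr <- match(paste(male, h$event_id[idx]), ck)
    out[[length(out) + 1L]] <- data.frame(
      male_id = male, group_id = h$group_id[1], event_id = h$event_id[idx],
      from = h$tactic[idx], to = h$tactic[idx + 1L],
      age_rank = covariates$age_rank[cr],
      group_centred_weight = covariates$group_centred_weight[cr],
      sex_ratio = covariates$sex_ratio[cr],
      imputed = covariates$imputed[cr], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  # males whose weight could not even be imputed are excluded downstream
  ok <- stats::complete.cases(out[, c("age_rank", "group_centred_weight",
                                      "sex_ratio")])
  out[ok, , drop = FALSE]
}

#' Derive weight changes over oestrus events
#'
#' Extracts the percentage weight change over each male-event with a known
#' tactic, using observed weights only (the prior 60-day average and the
#' nearest post-event weight within 9 days; see [extract_weight_change()]).
#'
#' @param dataset An `art_dataset`.
#' @param histories Output of [derive_tactic_histories()].
#' @return Data frame `male_id`, `group_id`, `event_id`, `tactic`,
#'   `prior_weight`, `post_weight`, `days_to_post`, `pct_change`.
#' @export
derive_weight_changes <- function(dataset, histories) {
  live <- histories[histories$tactic != "dead", , drop = FALSE]
  events <- dataset$events
  out <- list()
  for (i in seq_len(nrow(live))) {
    ev <- events[events$event_id == live$event_id[i], , drop = FALSE]
    w <- dataset$weights[dataset$weights$individual_id == live$male_id[i], ,
                         drop = FALSE]
    wc <- extract_weight_change(w, ev$start_date, ev$end_date)
    if (is.null(wc)) next
    out[[length(out) + 1L]] <- cbind(
      data.frame(male_id = live$male_id[i], group_id = live$group_id[i],
                 event_id = live$event_id[i], tactic = live$tactic[i],
                 stringsAsFactors = FALSE), wc)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Preprocess a dataset into modelling tables
#'
#' Runs the full derivation pipeline: per-event tactic histories (with the
#' absorbing dead state), covariates (age ranks, imputed and group-centred
#' oestrus weights, sex ratios), the transition table, weight changes, the
#' male-female dyad table, litter-event links and siring trials.
#'
#' @param dataset An `art_dataset` from [generate_population()] or
#'   [read_dataset()].
#' @param tie_rule Tie rule for [summarize_tactic()].
#' @return Object of class `art_data`: list of data frames `histories`,
#'   `covariates`, `transitions`, `weight_changes`, `dyads`,
#'   `litter_links`, `siring_trials`, plus `events`.
#' @export
preprocess_dataset <- function(dataset, tie_rule = c("sneaker", "guard")) {
  tie_rule <- match.arg(tie_rule)
  histories <- derive_tactic_histories(dataset, tie_rule)
  covariates <- derive_covariates(dataset, histories)
  transitions <- build_transitions(histories, covariates)
  weight_changes <- derive_weight_changes(dataset, histories)

  demo <- dataset$demography
  birth <- stats::setNames(demo$birth_date, demo$individual_id)
  events <- dataset$events
  male_ranks <- data.frame(event_id = covariates$event_id,
                           male_id = covariates$male_id,
                           age_rank = covariates$age_rank,
                           stringsAsFactors = FALSE)
  female_ranks <- list()
  for (e in unique(covariates$event_id)) {
    ev <- events[events$event_id == e, , drop = FALSE]
    fem <- demo[demo$group_id == ev$group_id & demo$sex == "F", , drop = FALSE]
    age <- as.numeric(ev$start_date - fem$birth_date)
    alive <- is.na(fem$death_date) | fem$death_date > ev$start_date
    sel <- alive & age >= 365
    if (!any(sel)) next
    rk <- assign_age_ranks(stats::setNames(age[sel], fem$individual_id[sel]))
    female_ranks[[length(female_ranks) + 1L]] <- data.frame(
      event_id = e, female_id = names(rk), age_rank = unname(rk),
      stringsAsFactors = FALSE)
  }
  female_ranks <- do.call(rbind, female_ranks)
  dyads <- build_dyad_table(dataset$focals, male_ranks, female_ranks,
                            dataset$relatedness)
  litter_links <- link_litters(dataset$litters, events, demo)
  tactics <- histories[, c("event_id", "male_id", "tactic")]
  siring_trials <- build_siring_trials(litter_links, dataset$litters,
                                       dataset$focals, tactics)
  structure(list(histories = histories, covariates = covariates,
                 transitions = transitions, weight_changes = weight_changes,
                 dyads = dyads, litter_links = litter_links,
                 siring_trials = siring_trials, events = events),
            class = "art_data")
}
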