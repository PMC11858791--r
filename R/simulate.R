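#' Configuration for the synthetic-population generator
#'
#' Bundles the demographic structure and the true parameter values from which
#' [generate_population()] forward-simulates a complete study dataset. The
#' defaults emulate the banded mongoose study system: groups holding several
#' adult males per breeding female (target 2.2 males per female), roughly
#' four oestrus events per year lasting 1-7 days (mean about 3), 6.6% of
#' oestrus-weight windows missing, and tactic transitions following the
#' covariate-dependent multinomial-logit process of
#' [default_transition_params()].
#'
#' @param n_groups Number of social groups.
#' @param males_per_group Length-2 range for initial males per group (the
#'   realized number also depends on `sex_ratio_target`).
#' @param females_per_group Length-2 range for adult females per group.
#' @param n_events_per_group Oestrus events per group.
#' @param days_per_event Length-2 range (within 1-7) of observation days per
#'   event; days are drawn uniformly, the default `c(1, 5)` giving mean 3.
#' @param event_interval_days Days between successive event starts
#'   (default 91, about four events per year).
#' @param true_transition_params A [transition_params()] object on the raw
#'   covariate scale (ranks, grams, males per female).
#' @param true_siring_params Named vector `intercept`, `guard`,
#'   `n_competitors`, `prop_same_tactic`: logits from which litter sires are
#'   sampled among a female's suitors. Defaults derive from the reported
#'   posterior siring probabilities (guard 0.40 vs sneaker 0.12; lone-tactic
#'   0.48 vs shared-tactic 0.26 among three suitors).
#' @param true_matechoice_params Named vector of mate-choice logit
#'   coefficients (see Details).
#' @param true_weightloss_params List with `mean` (named per-tactic mean
#'   percentage weight change over an oestrus event; defaults are the
#'   reported estimates 0.32, -2.30, -2.31) and `sd` (between-male-event SD
#'   of that percentage).
#' @param weight_missing_frac Fraction of male-event oestrus-weight windows
#'   deleted completely at random (default 0.066).
#' @param sex_ratio_target Adult males per adult female (default 2.2).
#' @param adult_weight_mean,adult_weight_sd Individual asymptotic weights
#'   (grams) are drawn from this normal distribution.
#' @param weight_noise_sd Measurement noise SD on each weight record (grams).
#' @param litter_prob Probability a pursued female produces a litter.
#' @param multiple_paternity_prob Probability a litter has two sires.
#' @param behav_swap_prob Probability an active male shows the opposite
#'   behaviour on one day of a multi-day event (observation inconsistency;
#'   never enough days to overturn the majority tactic).
#' @param start_date First event date (Date or string).
#' @param seed Integer seed; the whole dataset is deterministic given the
#'   config.
#'
#' @details
#' `true_matechoice_params` drives which adult females an active male
#' pursues each day, through per-dyad Bernoulli draws on the logit scale
#' (guards, who follow a single female, pick one female with probability
#' proportional to the exponentiated logit). Male and female age ranks enter
#' centred within the group-event. Elements: `intercept`, `relatedness`
#' (group-centred relatedness), `male_rank`, `female_rank`, `rank_product`
#' (assortative term: positive values make old males favour old females),
#' `guard`, `guard_male_rank`, `guard_female_rank`, `guard_rank_product`
#' (tactic differences; a positive `guard_rank_product` makes guards more
#' assortative than sneakers, the "sneaker rank-lag"), `relatedness_guard`,
#' and `n_adult_females`.
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_groups = 6,
                       males_per_group = c(3, 25),
                       females_per_group = c(2, 6),
                       n_events_per_group = 10,
                       days_per_event = c(1, 5),
                       event_interval_days = 91,
                       true_transition_params = default_transition_params(),
                       true_siring_params = c(intercept = -0.2, guard = 1.6,
                                              n_competitors = -0.45,
                                              prop_same_tactic = -1.9),
                       true_matechoice_params = c(intercept = -0.6,
                                                  relatedness = -0.7,
                                                  male_rank = -0.05,
                                                  female_rank = -0.10,
                                                  rank_product = 0.01,
                                                  guard = 0,
                                                  guard_male_rank = 0,
                                                  guard_female_rank = 0,
                                                  guard_rank_product = 0.03,
                                                  relatedness_guard = 0,
                                                  n_adult_females = -0.25),
                       true_weightloss_params = list(
                         mean = c(subordinate = 0.32, sneaker = -2.30,
                                  guard = -2.31),
                         sd = 2.5),
                       weight_missing_frac = 0.066,
                       sex_ratio_target = 2.2,
                       adult_weight_mean = 1800,
                       adult_weight_sd = 120,
                       weight_noise_sd = 30,
                       litter_prob = 0.55,
                       multiple_paternity_prob = 0.05,
                       behav_swap_prob = 0.15,
                       start_date = "2010-01-01",
                       seed = 1L) {
  stopifnot(n_groups >= 1, n_events_per_group >= 1,
            length(males_per_group) == 2, length(females_per_group) == 2,
            males_per_group[1] >= 1, females_per_group[1] >= 1,
            length(days_per_event) == 2,
            days_per_event[1] >= 1, days_per_event[2] <= 7,
            weight_missing_frac >= 0, weight_missing_frac <= 1,
            litter_prob >= 0, litter_prob <= 1,
            multiple_paternity_prob >= 0, multiple_paternity_prob <= 1,
            behav_swap_prob >= 0, behav_swap_prob <= 1,
            sex_ratio_target > 0,
            inherits(true_transition_params, "transition_params"))
  structure(list(n_groups = n_groups, males_per_group = males_per_group,
                 females_per_group = females_per_group,
                 n_events_per_group = n_events_per_group,
                 days_per_event = days_per_event,
                 event_interval_days = event_interval_days,
                 true_transition_params = true_transition_params,
                 true_siring_params = true_siring_params,
                 true_matechoice_params = true_matechoice_params,
                 true_weightloss_params = true_weightloss_params,
                 weight_missing_frac = weight_missing_frac,
                 sex_ratio_target = sex_ratio_target,
                 adult_weight_mean = adult_weight_mean,
                 adult_weight_sd = adult_weight_sd,
                 weight_noise_sd = weight_noise_sd,
                 litter_prob = litter_prob,
                 multiple_paternity_prob = multiple_paternity_prob,
                 behav_swap_prob = behav_swap_prob,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# logistic-style growth to an individual asymptote
growth_curve <- function(age_days, w_inf) {
  w_inf / (1 + exp(-(age_days - 100) / 250))
}

#' Generate a synthetic study population
#'
#' Forward-simulates a complete dataset from known true parameters: group
#' rosters and demography, oestrus events, per-event tactic sequences driven
#' by [transition_probs()] with an absorbing dead state, daily focal
#' observations (including which females each active male pursued), weight
#' records following individual growth curves plus tactic-specific
#' post-oestrus weight loss and measurement noise, pairwise pedigree
#' relatedness drawn from a kin-structure mixture over
#' \{0, 0.125, 0.25, 0.5\}, and litters whose sires are sampled from the
#' true siring logits among the mother's suitors.
#'
#' @param config A [sim_config()].
#' @return Object of class `art_dataset`: list with data frames `focals`,
#'   `weights`, `demography`, `relatedness`, `litters`, `events`, and a
#'   `truth` list holding every generating parameter plus the true state
#'   matrix (`truth$states`) and litter-event map (`truth$litter_events`).
#' @export
#' @examples
#' \donttest{
#' ds <- generate_population(sim_config(n_groups = 2, n_events_per_group = 4,
#'                                      seed = 42))
#' head(ds$focals)
#' }
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tp <- config$true_transition_params
  mc <- config$true_matechoice_params
  sp <- config$true_siring_params
  wl <- config$true_weightloss_params
  origin <- config$start_date
  span <- config$n_events_per_group * config$event_interval_days

  demography <- list(); events <- list(); relatedness <- list()
  male_meta <- list()
  id_counter <- c(M = 0L, F = 0L)

  for (g in seq_len(config$n_groups)) {
    gid <- sprintf("G%02d", g)
    n_f <- sample(seq(config$females_per_group[1],
                      config$females_per_group[2]), 1)
    n_m0 <- round(n_f * config$sex_ratio_target)
    n_m0 <- max(config$males_per_group[1],
                min(config$males_per_group[2], n_m0))
    fem_ids <- sprintf("F%03d", id_counter["F"] + seq_len(n_f))
    id_counter["F"] <- id_counter["F"] + n_f
    fem_birth <- origin - sample(500:3000, n_f, replace = TRUE)
    # initial males (some litter-mates share a birth date -> age-rank ties)
    m_birth <- origin - sample(200:2800, n_m0, replace = TRUE)
    if (n_m0 >= 2) {
      for (j in 2:n_m0) if (stats::runif(1) < 0.3) m_birth[j] <- m_birth[j - 1]
    }
    # recruits maturing during the study keep numbers up as males die
    n_rec <- ceiling(0.4 * n_m0)
    r_birth <- origin + sample(-170:max(-160, span - 300), n_rec, replace = TRUE)
    male_birth <- c(m_birth, r_birth)
    male_ids <- sprintf("M%03d", id_counter["M"] + seq_along(male_birth))
    id_counter["M"] <- id_counter["M"] + length(male_birth)

    demography[[g]] <- data.frame(
      individual_id = c(male_ids, fem_ids),
      sex = c(rep("M", length(male_ids)), rep("F", n_f)),
      birth_date = c(male_birth, fem_birth),
      death_date = as.Date(NA),
      group_id = gid,
      entry_date = c(male_birth, fem_birth),
      exit_date = as.Date(NA), stringsAsFactors = FALSE)

    starts <- origin + (seq_len(config$n_events_per_group) - 1L) *
      config$event_interval_days + sample(0:6, config$n_events_per_group,
                                          replace = TRUE)
    durs <- sample(seq(config$days_per_event[1], config$days_per_event[2]),
                   config$n_events_per_group, replace = TRUE)
    events[[g]] <- data.frame(
      event_id = sprintf("E%02d_%02d", g, seq_len(config$n_events_per_group)),
      group_id = gid, start_date = starts, end_date = starts + durs - 1L,
      stringsAsFactors = FALSE)

    relatedness[[g]] <- data.frame(
      id_a = rep(male_ids, each = n_f), id_b = rep(fem_ids, length(male_ids)),
      r = sample(c(0, 0.125, 0.25, 0.5), length(male_ids) * n_f,
                 replace = TRUE, prob = c(0.45, 0.2, 0.2, 0.15)),
      stringsAsFactors = FALSE)

    male_meta[[g]] <- data.frame(
      male_id = male_ids, group_id = gid, birth_date = male_birth,
      w_inf = stats::rnorm(length(male_ids), config$adult_weight_mean,
                           config$adult_weight_sd),
      u_male = stats::rnorm(length(male_ids), 0, tp$sigma_male),
      stringsAsFactors = FALSE)
  }
  demography <- do.call(rbind, demography)
  events_all <- do.call(rbind, events)
  relatedness <- do.call(rbind, relatedness)
  male_meta <- do.call(rbind, male_meta)
  rownames(demography) <- rownames(events_all) <- rownames(male_meta) <- NULL

  u_group <- stats::setNames(stats::rnorm(config$n_groups, 0, tp$sigma_group),
                             unique(events_all$group_id))
  u_event <- stats::setNames(stats::rnorm(nrow(events_all), 0, tp$sigma_event),
                             events_all$event_id)

  rel_mat <- stats::setNames(relatedness$r,
                             paste(relatedness$id_a, relatedness$id_b))

  focals <- list(); litters <- list(); states <- list()
  litter_events <- list()
  wl_shift <- list()   # per male-event percentage shifts applied to weights
  study_end <- max(events_all$end_date)

  for (g in seq_len(config$n_groups)) {
    gid <- unique(events[[g]]$group_id)
    ev <- events[[g]]
    mm <- male_meta[male_meta$group_id == gid, , drop = FALSE]
    fem <- demography[demography$group_id == gid & demography$sex == "F", ,
                      drop = FALSE]
    state <- stats::setNames(rep(NA_character_, nrow(mm)), mm$male_id)
    death <- stats::setNames(rep(as.Date(NA), nrow(mm)), mm$male_id)

    for (k in seq_len(nrow(ev))) {
      ev_start <- ev$start_date[k]; ev_end <- ev$end_date[k]
      age_m <- as.numeric(ev_start - mm$birth_date)
      present <- age_m >= 180 & (is.na(death) | death > ev_start)
      if (!any(present)) next
      ids <- mm$male_id[present]
      # newly entering males start as subordinates
      state[ids][is.na(state[ids])] <- "subordinate"

      ranks <- assign_age_ranks(stats::setNames(age_m[present], ids))
      w_true <- growth_curve(age_m[present], mm$w_inf[present])
      gc_w <- w_true - mean(w_true)
      age_f <- as.numeric(ev_start - fem$birth_date)
      adult_f <- fem$individual_id[age_f >= 365]
      n_males_adult <- sum(age_m[present] >= 365)
      sexr <- if (length(adult_f)) n_males_adult / length(adult_f) else NA_real_
      f_ranks <- assign_age_ranks(stats::setNames(age_f[age_f >= 365], adult_f))

      states[[length(states) + 1L]] <- data.frame(
        male_id = ids, event_id = ev$event_id[k], tactic = unname(state[ids]),
        stringsAsFactors = FALSE)

      # ---- daily focal observations -------------------------------------
      days <- seq(ev_start, ev_end, by = 1)
      mr_c <- ranks - mean(ranks)
      fr_c <- f_ranks - mean(f_ranks)
      for (mi in seq_along(ids)) {
        id <- ids[mi]; tac <- state[id]
        if (tac == "subordinate" || length(adult_f) == 0L) {
          focals[[length(focals) + 1L]] <- data.frame(
            date = days, event_id = ev$event_id[k], group_id = gid,
            male_id = id, female_id = NA_character_, behaviour = "none",
            stringsAsFactors = FALSE)
          next
        }
        r_f <- rel_mat[paste(id, adult_f)]
        gcr <- r_f - mean(r_f)
        is_guard <- as.numeric(tac == "guard")
        eta <- mc["intercept"] + mc["relatedness"] * gcr +
          mc["male_rank"] * mr_c[mi] + mc["female_rank"] * fr_c +
          mc["rank_product"] * mr_c[mi] * fr_c +
          is_guard * (mc["guard"] + mc["guard_male_rank"] * mr_c[mi] +
                      mc["guard_female_rank"] * fr_c +
                      mc["guard_rank_product"] * mr_c[mi] * fr_c) +
          mc["relatedness_guard"] * gcr * is_guard +
          mc["n_adult_females"] * length(adult_f)
        day_rows <- lapply(days, function(d) {
          if (tac == "guard") {
            f_sel <- adult_f[sample.int(length(adult_f), 1,
                                        prob = exp(eta - max(eta)))]
          } else {
            hit <- stats::runif(length(adult_f)) < stats::plogis(eta)
            if (!any(hit)) hit[which.max(eta)] <- TRUE
            f_sel <- adult_f[hit]
          }
          data.frame(date = d, event_id = ev$event_id[k], group_id = gid,
                     male_id = id, female_id = f_sel,
                     behaviour = if (tac == "guard") "guard" else "sneak",
                     stringsAsFactors = FALSE)
        })
        # occasional opposite-behaviour day (kept to a minority of days)
        if (length(days) >= 3 && stats::runif(1) < config$behav_swap_prob) {
          d_swap <- sample.int(length(days), 1)
          rows <- day_rows[[d_swap]]
          if (tac == "guard") {
            rows$behaviour <- "sneak"
          } else {
            rows <- rows[1, , drop = FALSE]
            rows$behaviour <- "guard"
          }
          day_rows[[d_swap]] <- rows
        }
        focals[[length(focals) + 1L]] <- do.call(rbind, day_rows)
      }

      # ---- per male-event weight-loss shifts ----------------------------
      shift <- stats::rnorm(length(ids), wl$mean[state[ids]], wl$sd)
      wl_shift[[length(wl_shift) + 1L]] <- data.frame(
        male_id = ids, start = ev_end, end = ev_end + 14,
        pct = shift, stringsAsFactors = FALSE)

      # ---- litters ------------------------------------------------------
      ev_focs <- do.call(rbind, focals[vapply(focals, function(x)
        x$event_id[1] == ev$event_id[k], logical(1))])
      act <- ev_focs[ev_focs$behaviour %in% c("guard", "sneak"), , drop = FALSE]
      for (f in unique(act$female_id)) {
        suitors <- unique(act$male_id[act$female_id == f])
        if (length(suitors) == 0L || stats::runif(1) > config$litter_prob) next
        stac <- state[suitors]
        n_s <- length(suitors)
        same <- vapply(seq_len(n_s), function(j)
          if (n_s == 1) 0 else (sum(stac == stac[j]) - 1) / (n_s - 1),
          numeric(1))
        eta_s <- sp["intercept"] + sp["guard"] * (stac == "guard") +
          sp["n_competitors"] * n_s + sp["prop_same_tactic"] * same
        sire <- suitors[sample.int(n_s, 1, prob = exp(eta_s - max(eta_s)))]
        sires <- sire
        if (n_s >= 2 && stats::runif(1) < config$multiple_paternity_prob) {
          rest <- setdiff(suitors, sire)
          w <- exp(eta_s - max(eta_s))[match(rest, suitors)]
          sires <- c(sire, rest[sample.int(length(rest), 1, prob = w)])
        }
        birth <- ev_end + max(45, min(73, round(stats::rnorm(1, 59, 7))))
        lid <- sprintf("L%02d_%02d_%s", g, k, f)
        litters[[length(litters) + 1L]] <- data.frame(
          litter_id = lid, mother_id = f, birth_date = birth,
          sire_ids = paste(sires, collapse = ";"), stringsAsFactors = FALSE)
        litter_events[[length(litter_events) + 1L]] <- data.frame(
          litter_id = lid, event_id = ev$event_id[k], stringsAsFactors = FALSE)
      }

      # ---- transition to the next event ---------------------------------
      if (k < nrow(ev)) {
        nxt <- ev$start_date[k + 1]
        for (mi in seq_along(ids)) {
          id <- ids[mi]
          covs <- c(age_rank = unname(ranks[mi]),
                    group_centred_weight = gc_w[mi], sex_ratio = sexr)
          re <- mm$u_male[mm$male_id == id] + u_group[gid] +
            u_event[ev$event_id[k]]
          p <- transition_probs(tp, covs, state[id], re = re)
          nxt_state <- sample(ART_STATES, 1, prob = p)
          if (nxt_state == "dead") {
            gap <- as.numeric(nxt - ev_end)
            death[id] <- ev_end + sample.int(max(1, gap - 1), 1)
            state[id] <- "dead"
          } else {
            state[id] <- nxt_state
          }
        }
      }
    }
    demography$death_date[match(names(death), demography$individual_id)] <- death
    demography$exit_date[match(names(death), demography$individual_id)] <- death
  }

  focals <- do.call(rbind, focals)
  litters <- if (length(litters)) do.call(rbind, litters) else
    data.frame(litter_id = character(0), mother_id = character(0),
               birth_date = as.Date(character(0)), sire_ids = character(0))
  states <- do.call(rbind, states)
  litter_events <- if (length(litter_events)) do.call(rbind, litter_events) else
    data.frame(litter_id = character(0), event_id = character(0))
  wl_shift <- do.call(rbind, wl_shift)
  rownames(focals) <- rownames(litters) <- rownames(states) <- NULL

  if (!any(demography$sex == "M") || !any(demography$sex == "F") ||
      nrow(states) == 0L)
    stop("degenerate demography: no males and females alive at any event")

  # ---- weight records ----------------------------------------------------
  weights <- list()
  for (i in seq_len(nrow(male_meta))) {
    id <- male_meta$male_id[i]
    birth <- male_meta$birth_date[i]
    last <- demography$death_date[demography$individual_id == id]
    if (is.na(last)) last <- study_end
    d <- birth + 180
    dates <- as.Date(character(0))
    while (d <= last) {
      dates <- c(dates, d)
      d <- d + sample(6:14, 1)
    }
    if (length(dates) == 0L) next
    age <- as.numeric(dates - birth)
    grams <- growth_curve(age, male_meta$w_inf[i]) +
      stats::rnorm(length(dates), 0, config$weight_noise_sd)
    sh <- wl_shift[wl_shift$male_id == id, , drop = FALSE]
    for (j in seq_len(nrow(sh))) {
      sel <- dates > sh$start[j] & dates <= sh$end[j]
      grams[sel] <- grams[sel] * (1 + sh$pct[j] / 100)
    }
    weights[[length(weights) + 1L]] <- data.frame(
      individual_id = id, date = dates, grams = grams, stringsAsFactors = FALSE)
  }
  weights <- do.call(rbind, weights)

  # ---- missing oestrus-weight windows (completely at random) -------------
  windows <- merge(states[states$tactic != "dead", c("male_id", "event_id")],
                   events_all[, c("event_id", "start_date", "end_date")],
                   by = "event_id")
  drop_win <- stats::runif(nrow(windows)) < config$weight_missing_frac
  for (j in which(drop_win)) {
    sel <- weights$individual_id == windows$male_id[j] &
      weights$date >= windows$start_date[j] - 60 &
      weights$date <= windows$end_date[j] + 60
    weights <- weights[!sel, , drop = FALSE]
  }
  rownames(weights) <- NULL

  structure(list(
    focals = focals, weights = weights, demography = demography,
    relatedness = relatedness, litters = litters, events = events_all,
    truth = list(transition_params = tp, siring_params = sp,
                 matechoice_params = mc, weightloss_params = wl,
                 u_group = u_group, u_event = u_event,
                 u_male = stats::setNames(male_meta$u_male, male_meta$male_id),
                 w_inf = stats::setNames(male_meta$w_inf, male_meta$male_id),
                 states = states, litter_events = litter_events,
                 missing_windows = windows$event_id[drop_win],
                 config = config)),
    class = "art_dataset")
}

#' Check dataset invariants
#'
#' Validates the structural invariants of an `art_dataset`: every individual
#' referenced anywhere exists in the demography table, no record of any kind
#' postdates an individual's death, and relatedness is stored once per
#' unordered pair with no self-pairs.
#'
#' @param dataset An `art_dataset`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_dataset <- function(dataset) {
  ids <- dataset$demography$individual_id
  ref <- c(dataset$focals$male_id, dataset$focals$female_id,
           dataset$weights$individual_id, dataset$litters$mother_id,
           unlist(strsplit(dataset$litters$sire_ids, ";", fixed = TRUE)))
  ref <- ref[!is.na(ref)]
  if (!all(ref %in% ids)) stop("individual referenced but absent from demography")
  death <- stats::setNames(dataset$demography$death_date, ids)
  dd <- death[dataset$focals$male_id]
  if (any(!is.na(dd) & dataset$focals$date > dd))
    stop("focal record after the male's death")
  dw <- death[dataset$weights$individual_id]
  if (any(!is.na(dw) & dataset$weights$date > dw))
    stop("weight record after the individual's death")
  if (any(dataset$relatedness$id_a == dataset$relatedness$id_b))
    stop("self-pair in relatedness table")
  key <- paste(pmin(dataset$relatedness$id_a, dataset$relatedness$id_b),
               pmax(dataset$relatedness$id_a, dataset$relatedness$id_b))
  if (anyDuplicated(key)) stop("duplicate relatedness pair")
  invisible(TRUE)
}
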