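#' Summarize daily behaviours into one per-oestrus tactic
#'
#' Collapses a male's daily focal behaviours over one oestrus event into a
#' single tactic. A male that guarded on any day and never sneaked is a
#' guard; one that sneaked and never guarded is a sneaker; a male expressing
#' both is assigned the behaviour shown on more days, with ties resolved by
#' `tie_rule` (default `"sneaker"`); a male inactive on every day is a
#' subordinate. The result is invariant to the order of days.
#'
#' @param behaviours Character vector of per-day behaviours for one male over
#'   one oestrus event; values in `c("guard", "sneak", "none")`.
#' @param tie_rule Tactic assigned when a male guarded and sneaked on equally
#'   many days: `"sneaker"` (default) or `"guard"`.
#' @return One of `"guard"`, `"sneaker"`, `"subordinate"`, with attribute
#'   `"tie"` set to `TRUE` when the tie rule decided the outcome.
#' @export
#' @examples
#' summarize_tactic(c("guard", "guard", "sneak"))  # guard
#' summarize_tactic(c("none", "none"))             # subordinate
#' summarize_tactic(c("guard", "sneak"))           # sneaker (tie rule)
summarize_tactic <- function(behaviours, tie_rule = c("sneaker", "guard")) {
  tie_rule <- match.arg(tie_rule)
  if (length(behaviours) == 0L)
    stop("no daily observations: male not present at this oestrus event")
  bad <- setdiff(unique(behaviours), BEHAVIOURS)
  if (length(bad)) stop("unknown behaviour(s): ", paste(bad, collapse = ", "))
  g <- sum(behaviours == "guard")
  s <- sum(behaviours == "sneak")
  tie <- FALSE
  tactic <- if (g == 0 && s == 0) {
    "subordinate"
  } else if (g > s) {
    "guard"
  } else if (s > g) {
    "sneaker"
  } else {
    tie <- TRUE
    tie_rule
  }
  attr(tactic, "tie") <- tie
  tactic
}

#' Within-group age ranks
#'
#' Ranks males (or females) by age within one group-event: the oldest
#' individual gets rank 1, ties share the minimum rank, and the next-younger
#' individual's rank skips by the size of the tie group (so ranks after one
#' oldest male and three equal-aged males run 1, 2, 2, 2, 5).
#'
#' @param age_days Named numeric vector of ages in days (names are
#'   individual ids).
#' @return Named integer vector of ranks.
#' @export
#' @examples
#' assign_age_ranks(c(a = 2000, b = 1500, c = 1500, d = 1500, e = 900))
assign_age_ranks <- function(age_days) {
  if (length(age_days) == 0L) stop("no individuals to rank")
  stats::setNames(as.integer(rank(-age_days, ties.method = "min")),
                  names(age_days))
}

#' Oestrus-window weight
#'
#' Averages an individual's weights over the window spanning 60 days before
#' the event start to 60 days after the event end (dates inclusive). Returns
#' `NA` when no weight falls in the window; missing values are filled later
#' by [impute_missing_weights()].
#'
#' @param weights Data frame with columns `date` (Date) and `grams`.
#' @param event_start,event_end Event start and end dates.
#' @param days_before,days_after Window half-widths in days (default 60).
#' @return Mean weight in grams, or `NA_real_`.
#' @export
oestrus_weight <- function(weights, event_start, event_end,
                           days_before = 60, days_after = 60) {
  event_start <- as.Date(event_start); event_end <- as.Date(event_end)
  sel <- weights$date >= event_start - days_before &
         weights$date <= event_end + days_after
  if (!any(sel)) return(NA_real_)
  mean(weights$grams[sel])
}

#' Group-centre oestrus weights
#'
#' Subtracts the group-event mean (over males with observed weights) from
#' each male's oestrus weight, so observed centred values sum to zero
#' exactly. `NA` entries are preserved.
#'
#' @param oestrus_weights Named numeric vector of oestrus weights (grams) for
#'   the males of one group-event; may contain `NA`.
#' @return Named numeric vector of group-centred weights.
#' @export
#' @examples
#' centre_weights(c(a = 1000, b = 1200))  # -100, +100
centre_weights <- function(oestrus_weights) {
  if (all(is.na(oestrus_weights)))
    stop("no observed weights in this group-event: impute or drop first")
  oestrus_weights - mean(oestrus_weights, na.rm = TRUE)
}

#' Impute missing oestrus weights from individual growth
#'
#' Fills missing oestrus-window weights using each individual's own age-weight
#' relationship: a per-individual linear regression of weight on age when the
#' individual has at least three weights at distinct ages, otherwise a pooled
#' fallback (population-level slope plus an individual intercept offset).
#' Because growth is decelerating, the per-individual regression is local:
#' when enough records exist near the target window (within
#' `local_window` days of its midpoint) only those are used, which removes
#' most of the curvature bias of a lifetime-wide straight line.
#' Individuals with no weights at all are left missing. Imputed values are
#' flagged and must never enter weight-loss analyses.
#'
#' @param weights Data frame with columns `individual_id`, `date`, `grams`.
#' @param demography Data frame with columns `individual_id`, `birth_date`.
#' @param targets Data frame of windows needing values, with columns
#'   `individual_id`, `event_id`, `event_start`, `event_end`.
#' @param local_window Half-width (days around the window midpoint) of the
#'   preferred local regression window.
#' @return `targets` with added columns `grams` (imputed value, possibly
#'   `NA`) and `imputed = TRUE`.
#' @export
impute_missing_weights <- function(weights, demography, targets,
                                   local_window = 300) {
  if (nrow(targets) == 0L)
    return(cbind(targets, grams = numeric(0), imputed = logical(0)))
  birth <- stats::setNames(as.Date(demography$birth_date), demography$individual_id)
  w <- weights
  w$age <- as.numeric(as.Date(w$date) - birth[w$individual_id])
  # pooled fallback: common slope, individual intercepts via offsets
  pooled_slope <- if (nrow(w) >= 2 && stats::sd(w$age) > 0)
    unname(coef(stats::lm(grams ~ age, data = w))[2]) else 0
  mid_age <- as.numeric((as.Date(targets$event_start) +
                         (as.Date(targets$event_end) -
                          as.Date(targets$event_start)) / 2) -
                        birth[targets$individual_id])
  grams <- rep(NA_real_, nrow(targets))
  for (i in seq_len(nrow(targets))) {
    wi <- w[w$individual_id == targets$individual_id[i], , drop = FALSE]
    if (nrow(wi) == 0L) next
    near <- wi[abs(wi$age - mid_age[i]) <= local_window, , drop = FALSE]
    if (nrow(near) >= 3 && length(unique(near$age)) >= 3) wi <- near
    if (nrow(wi) >= 3 && length(unique(wi$age)) >= 3) {
      fit <- stats::lm(grams ~ age, data = wi)
      grams[i] <- unname(predict(fit, data.frame(age = mid_age[i])))
    } else {
      # pooled slope anchored at the individual's own mean weight/age
      grams[i] <- mean(wi$grams) + pooled_slope * (mid_age[i] - mean(wi$age))
    }
  }
  cbind(targets, grams = grams, imputed = TRUE)
}

#' Extract a weight change over an oestrus event
#'
#' Computes the percentage weight change over one oestrus event from directly
#' observed weights only: the prior weight is the average over the 60 days
#' before the event start, the post weight is the single nearest weight
#' recorded after the event end, restricted to at most 9 days after (day 9
#' inclusive). Returns `NULL` when either piece is unavailable.
#'
#' @param weights Data frame with columns `date`, `grams` for one individual.
#' @param event_start,event_end Event dates.
#' @param max_days_post Latest usable post-event weight, in days after the
#'   event end (default 9).
#' @return One-row data frame with `prior_weight`, `post_weight`,
#'   `days_to_post`, `pct_change`, or `NULL`.
#' @export
extract_weight_change <- function(weights, event_start, event_end,
                                  max_days_post = 9) {
  event_start <- as.Date(event_start); event_end <- as.Date(event_end)
  prior_sel <- weights$date >= event_start - 60 & weights$date < event_start
  if (!any(prior_sel)) return(NULL)
  post_sel <- weights$date > event_end &
              weights$date <= event_end + max_days_post
  if (!any(post_sel)) return(NULL)
  post_dates <- weights$date[post_sel]
  nearest <- which.min(as.numeric(post_dates - event_end))
  prior <- mean(weights$grams[prior_sel])
  post_rows <- which(post_sel)[post_dates == post_dates[nearest]]
  post <- mean(weights$grams[post_rows])  # average if several same-day weights
  data.frame(prior_weight = prior, post_weight = post,
             days_to_post = as.numeric(post_dates[nearest] - event_end),
             pct_change = 100 * (post - prior) / prior)
}

#' Group-centred relatedness
#'
#' Centres a male's pairwise pedigree relatedness to each adult female
#' present on his mean relatedness over those females, so his centred values
#' average to zero. Females with unknown relatedness are excluded (and
#' reported via attribute `"dropped"`).
#'
#' @param r Named numeric vector: the male's pedigree relatedness to each
#'   adult female present (names are female ids); may contain `NA`.
#' @return Named numeric vector of centred relatedness over the females with
#'   known values; attribute `"dropped"` lists excluded females.
#' @export
#' @examples
#' group_centred_relatedness(c(f1 = 0.5, f2 = 0))  # +0.25, -0.25
group_centred_relatedness <- function(r) {
  dropped <- names(r)[is.na(r)]
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("no known relatedness values for this male")
  out <- r - mean(r)
  attr(out, "dropped") <- dropped
  out
}

#' Link litters to the oestrus events that produced them
#'
#' Attaches each litter to the oestrus event of the mother's group whose end
#' date falls 44-74 days before the litter's birth date (the gestation
#' window, 59 +/- 15 days). When two events fall in the window the one whose
#' end date is nearest to birth minus 59 days wins. Litters with no candidate
#' event are left unlinked.
#'
#' @param litters Data frame with columns `litter_id`, `mother_id`,
#'   `birth_date`.
#' @param events Data frame with columns `event_id`, `group_id`, `end_date`.
#' @param demography Data frame with `individual_id`, `group_id` used to find
#'   each mother's group.
#' @return Data frame `litter_id`, `event_id` (`NA` when unlinked),
#'   `gestation_days`; attribute `"ambiguous"` counts multi-candidate cases.
#' @export
link_litters <- function(litters, events, demography) {
  if (nrow(litters) == 0L) {
    out <- data.frame(litter_id = character(0), event_id = character(0),
                      gestation_days = numeric(0), stringsAsFactors = FALSE)
    attr(out, "ambiguous") <- 0L
    return(out)
  }
  mother_group <- stats::setNames(demography$group_id, demography$individual_id)
  out <- data.frame(litter_id = litters$litter_id,
                    event_id = NA_character_,
                    gestation_days = NA_real_, stringsAsFactors = FALSE)
  n_ambiguous <- 0L
  for (i in seq_len(nrow(litters))) {
    birth <- as.Date(litters$birth_date[i])
    grp <- mother_group[litters$mother_id[i]]
    cand <- events[events$group_id %in% grp, , drop = FALSE]
    gest <- as.numeric(birth - as.Date(cand$end_date))
    cand <- cand[gest >= 44 & gest <= 74, , drop = FALSE]
    gest <- gest[gest >= 44 & gest <= 74]
    if (nrow(cand) == 0L) next
    if (nrow(cand) > 1L) n_ambiguous <- n_ambiguous + 1L
    pick <- which.min(abs(gest - 59))
    out$event_id[i] <- cand$event_id[pick]
    out$gestation_days[i] <- gest[pick]
  }
  attr(out, "ambiguous") <- n_ambiguous
  out
}

#' Group sex ratio at an oestrus event
#'
#' Number of males at least one year old per female at least one year old.
#'
#' @param roster Data frame for one group-event with columns `sex`
#'   (`"M"`/`"F"`) and `age_days`.
#' @return Males per adult female, or `NA` (with a warning) when the group
#'   holds no adult female.
#' @export
#' @examples
#' compute_sex_ratio(data.frame(sex = c("M","M","M","F"),
#'                              age_days = c(400, 700, 900, 800)))
compute_sex_ratio <- function(roster) {
  n_m <- sum(roster$sex == "M" & roster$age_days >= 365)
  n_f <- sum(roster$sex == "F" & roster$age_days >= 365)
  if (n_f == 0L) {
    warning("no adult females in group-event; sex ratio undefined")
    return(NA_real_)
  }
  n_m / n_f
}

#' Build the male-female dyad table for the mate-choice model
#'
#' For every day on which a male interacted (guarded or sneaked), emits one
#' record per adult female present in the group, marking which female(s) the
#' male pursued. Attaches male and female age ranks, group-centred
#' relatedness and the number of adult females present. Dyads with unknown
#' relatedness are dropped (count reported via attribute `"dropped"`).
#' Inactive male-days emit no records.
#'
#' @param focals Daily focal table (`date`, `event_id`, `group_id`,
#'   `male_id`, `female_id`, `behaviour`).
#' @param male_ranks Data frame `event_id`, `male_id`, `age_rank` (from
#'   [assign_age_ranks()] over the males of each event).
#' @param female_ranks Data frame `event_id`, `female_id`, `age_rank` over
#'   the adult females of each event.
#' @param relatedness Data frame `id_a`, `id_b`, `r` of pairwise pedigree
#'   relatedness (unordered pairs).
#' @return Data frame of dyad records (`event_id`, `date`, `male_id`,
#'   `female_id`, `interacted`, `tactic`, `male_age_rank`,
#'   `female_age_rank`, `group_centred_relatedness`, `n_adult_females`).
#' @export
build_dyad_table <- function(focals, male_ranks, female_ranks, relatedness) {
  rel_key <- c(stats::setNames(relatedness$r,
                               paste(relatedness$id_a, relatedness$id_b)),
               stats::setNames(relatedness$r,
                               paste(relatedness$id_b, relatedness$id_a)))
  active <- focals[focals$behaviour %in% c("guard", "sneak"), , drop = FALSE]
  if (nrow(active) == 0L)
    return(data.frame())
  out <- vector("list", 0L)
  n_dropped <- 0L
  active$day_key <- paste(active$event_id, active$date, active$male_id)
  for (key in unique(active$day_key)) {
    rows <- active[active$day_key == key, , drop = FALSE]
    ev <- rows$event_id[1]; male <- rows$male_id[1]; date <- rows$date[1]
    fem <- female_ranks[female_ranks$event_id == ev, , drop = FALSE]
    if (nrow(fem) == 0L) next
    # day tactic: guard dominates if both behaviours appear on the same day
    tactic <- if (any(rows$behaviour == "guard")) "guard" else "sneaker"
    r <- rel_key[paste(male, fem$female_id)]
    known <- !is.na(r)
    n_dropped <- n_dropped + sum(!known)
    if (!any(known)) next
    gcr <- r[known] - mean(r[known])
    mrank <- male_ranks$age_rank[male_ranks$event_id == ev &
                                 male_ranks$male_id == male]
    if (length(mrank) != 1L) next
    out[[length(out) + 1L]] <- data.frame(
      event_id = ev, date = date, male_id = male,
      female_id = fem$female_id[known],
      interacted = fem$female_id[known] %in% rows$female_id,
      tactic = tactic, male_age_rank = mrank,
      female_age_rank = fem$age_rank[known],
      group_centred_relatedness = unname(gcr),
      n_adult_females = nrow(fem), stringsAsFactors = FALSE)
  }
  out <- if (length(out)) do.call(rbind, out) else data.frame()
  attr(out, "dropped") <- n_dropped
  out
}

#' Build siring trials from linked litters
#'
#' For each litter linked to an oestrus event, emits one Bernoulli trial per
#' male who interacted with the mother during that event (her "suitors"),
#' with `sired = TRUE` for assigned sires. Only litters whose mother received
#' attention from at least one guard and at least one sneaker are used, and
#' litters whose sire never interacted with the mother are excluded
#' (count via attribute `"orphaned"`). Each trial carries the number of
#' competitors (all suitors of that female over the event) and the
#' proportion of the male's competitors sharing his tactic
#' (excluding himself).
#'
#' @param litter_links Output of [link_litters()] (only linked rows used).
#' @param litters Litter table (`litter_id`, `mother_id`, `birth_date`,
#'   `sire_ids`; multiple sires separated by `";"`).
#' @param focals Daily focal table.
#' @param tactics Data frame `event_id`, `male_id`, `tactic` of per-event
#'   summarized tactics.
#' @return Data frame of trials (`litter_id`, `event_id`, `female_id`,
#'   `male_id`, `tactic`, `n_competitors`, `prop_same_tactic`, `sired`).
#' @export
build_siring_trials <- function(litter_links, litters, focals, tactics) {
  links <- litter_links[!is.na(litter_links$event_id), , drop = FALSE]
  out <- vector("list", 0L)
  n_orphaned <- 0L
  tac_key <- stats::setNames(tactics$tactic,
                             paste(tactics$event_id, tactics$male_id))
  for (i in seq_len(nrow(links))) {
    lit <- litters[litters$litter_id == links$litter_id[i], , drop = FALSE]
    ev <- links$event_id[i]
    mother <- lit$mother_id
    suitors <- unique(focals$male_id[focals$event_id == ev &
                                     focals$behaviour %in% c("guard", "sneak") &
                                     !is.na(focals$female_id) &
                                     focals$female_id == mother])
    if (length(suitors) < 2L) next
    stac <- tac_key[paste(ev, suitors)]
    # a suitor's per-event tactic can be subordinate-free by construction;
    # classify by behaviour toward this female if the event tactic is absent
    stac[is.na(stac)] <- "sneaker"
    if (!any(stac == "guard") || !any(stac == "sneaker")) next
    sires <- strsplit(lit$sire_ids, ";", fixed = TRUE)[[1]]
    if (!any(sires %in% suitors)) { n_orphaned <- n_orphaned + 1L; next }
    n <- length(suitors)
    same <- vapply(seq_along(suitors),
                   function(j) (sum(stac == stac[j]) - 1) / (n - 1),
                   numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      litter_id = lit$litter_id, event_id = ev, female_id = mother,
      male_id = suitors, tactic = unname(stac), n_competitors = n,
      prop_same_tactic = same, sired = suitors %in% sires,
      stringsAsFactors = FALSE)
  }
  out <- if (length(out)) do.call(rbind, out) else data.frame()
  attr(out, "orphaned") <- n_orphaned
  out
}
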