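#' Write a dataset to CSV tables
#'
#' Writes the five study tables to a directory using fixed schemas:
#' `focals.csv` (date, event_id, group_id, male_id, female_id, behaviour),
#' `weights.csv` (individual_id, date, grams), `demography.csv`
#' (individual_id, sex, birth_date, death_date, group_id, entry_date,
#' exit_date), `relatedness.csv` (id_a, id_b, r) and `litters.csv`
#' (litter_id, mother_id, birth_date, sire_ids). For synthetic datasets the
#' generating parameters are also written to `truth.json`.
#'
#' @param dataset An `art_dataset` (or a bare list of the five tables).
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$focals[, c("date", "event_id", "group_id",
                                      "male_id", "female_id", "behaviour")],
                   file.path(dir, "focals.csv"), row.names = FALSE)
  utils::write.csv(dataset$weights[, c("individual_id", "date", "grams")],
                   file.path(dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(dataset$demography[, c("individual_id", "sex", "birth_date",
                                          "death_date", "group_id",
                                          "entry_date", "exit_date")],
                   file.path(dir, "demography.csv"), row.names = FALSE)
  utils::write.csv(dataset$relatedness[, c("id_a", "id_b", "r")],
                   file.path(dir, "relatedness.csv"), row.names = FALSE)
  utils::write.csv(dataset$litters[, c("litter_id", "mother_id", "birth_date",
                                       "sire_ids")],
                   file.path(dir, "litters.csv"), row.names = FALSE)
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    out <- list(
      transition_beta = truth$transition_params$beta,
      transition_survival = truth$transition_params$survival,
      transition_sigmas = c(male = truth$transition_params$sigma_male,
                            group = truth$transition_params$sigma_group,
                            event = truth$transition_params$sigma_event),
      siring_params = truth$siring_params,
      matechoice_params = truth$matechoice_params,
      weightloss_params = truth$weightloss_params)
    jsonlite::write_json(out, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a dataset from CSV tables
#'
#' Reads the tables written by [write_dataset()] (or equivalently formatted
#' field data) and rebuilds an `art_dataset`. Event start and end dates are
#' derived from the focal table (first and last observation day per event).
#'
#' @param dir Directory holding the CSV tables.
#' @return An `art_dataset` (without a `truth` element unless regenerated).
#' @export
read_dataset <- function(dir) {
  focals <- utils::read.csv(file.path(dir, "focals.csv"),
                            stringsAsFactors = FALSE)
  focals$date <- as.Date(focals$date)
  focals$female_id[focals$female_id %in% c("", "NA")] <- NA_character_
  weights <- utils::read.csv(file.path(dir, "weights.csv"),
                             stringsAsFactors = FALSE)
  weights$date <- as.Date(weights$date)
  demography <- utils::read.csv(file.path(dir, "demography.csv"),
                                stringsAsFactors = FALSE)
  for (col in c("birth_date", "death_date", "entry_date", "exit_date"))
    demography[[col]] <- as.Date(demography[[col]])
  relatedness <- utils::read.csv(file.path(dir, "relatedness.csv"),
                                 stringsAsFactors = FALSE)
  litters <- utils::read.csv(file.path(dir, "litters.csv"),
                             stringsAsFactors = FALSE)
  litters$birth_date <- as.Date(litters$birth_date)
  events <- derive_events(focals)
  structure(list(focals = focals, weights = weights, demography = demography,
                 relatedness = relatedness, litters = litters,
                 events = events, truth = NULL),
            class = "art_dataset")
}

derive_events <- function(focals) {
  agg_min <- aggregate(date ~ event_id + group_id, data = focals, FUN = min)
  agg_max <- aggregate(date ~ event_id + group_id, data = focals, FUN = max)
  out <- merge(agg_min, agg_max, by = c("event_id", "group_id"),
               suffixes = c("_start", "_end"))
  names(out) <- c("event_id", "group_id", "start_date", "end_date")
  out[order(out$group_id, out$start_date), , drop = FALSE]
}
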