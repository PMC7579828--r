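#' Assign an age classification from age in days
#'
#' Age class `n` covers ages from `(n * 365) - 90` days (inclusive) up to
#' `((n + 1) * 365) - 90` days (exclusive), mirroring the age-of-dam
#' window system used in beef-cattle evaluation. The lower bound of the
#' first class, 275 days, coincides with the minimum age at which records
#' are retained; younger animals are flagged for removal rather than
#' classified.
#'
#' @param age_days age at scoring, in days.
#' @return A list with `age_days`, `class_n` (integer class, `NA` when
#'   flagged), `four_class` ("1","2","3","other"), `bif_class` (yearling,
#'   2, 3, 4, 5-9, 10, 11, 12, 13+) and `remove` (TRUE when younger than
#'   275 days).
#' @export
assign_age_class <- function(age_days) {
  stopifnot(length(age_days) == 1L, is.finite(age_days))
  if (age_days < 275) {
    return(list(age_days = age_days, class_n = NA_integer_,
                four_class = NA_character_, bif_class = NA_character_,
                remove = TRUE))
  }
  n <- as.integer(floor((age_days + 90) / 365))
  four <- if (n >= 4L) "other" else as.character(n)
  bif <- if (n == 1L) "yearling"
         else if (n <= 4L) as.character(n)
         else if (n <= 9L) "5-9"
         else if (n <= 12L) as.character(n)
         else "13+"
  list(age_days = age_days, class_n = n, four_class = four,
       bif_class = bif, remove = FALSE)
}

#' Filter score records against pedigree metadata
#'
#' Applies the record-level validity rules: the record's reported sex must
#' match the pedigree sex and only female records are retained; records
#' from animals younger than 275 days are removed; and records whose
#' breeder-reported age differs from the calculated age classification by
#' more than 2 years are removed. Every input record lands either in
#' `kept` or in `removal_log` with the rule that triggered it.
#'
#' @param records score-record `data.frame` with at least `animal_id`,
#'   `date`, `birth_date`, `sex`, and optionally `breeder_reported_age`.
#' @param pedigree_metadata optional `data.frame` (`animal`, `sex`,
#'   `birth_date`) used to cross-check the record's own fields.
#' @return A list with `kept` (records plus `age_days`, `class_n`,
#'   `age_four_class` columns) and `removal_log` (`row`, `animal_id`,
#'   `reason`).
#' @export
validate_records <- function(records, pedigree_metadata = NULL) {
  rec <- records
  n <- nrow(rec)
  reason <- rep(NA_character_, n)
  ped_sex <- rec$sex
  birth <- as.Date(rec$birth_date)
  if (!is.null(pedigree_metadata)) {
    k <- match(rec$animal_id, pedigree_metadata$animal)
    ped_sex <- ifelse(is.na(k), rec$sex, pedigree_metadata$sex[k])
    if (!is.null(pedigree_metadata$birth_date))
      birth <- as.Date(ifelse(is.na(k), as.character(birth),
                              as.character(pedigree_metadata$birth_date[k])))
    mismatch <- !is.na(k) & !is.na(rec$sex) & rec$sex != ped_sex
    reason[is.na(reason) & mismatch] <- "sex_mismatch"
  }
  reason[is.na(reason) & ped_sex != "F"] <- "not_female"

  age_days <- as.integer(as.Date(rec$date) - birth)
  reason[is.na(reason) & age_days < 275L] <- "under_275_days"

  class_n <- ifelse(age_days >= 275L,
                    as.integer(floor((age_days + 90) / 365)), NA_integer_)
  if (!is.null(rec$breeder_reported_age)) {
    mism <- !is.na(rec$breeder_reported_age) & !is.na(class_n) &
      abs(rec$breeder_reported_age - class_n) > 2
    reason[is.na(reason) & mism] <- "age_mismatch_gt2y"
  }

  rec$age_days <- age_days
  rec$class_n <- class_n
  rec$age_four_class <- ifelse(is.na(class_n), NA_character_,
                               ifelse(class_n >= 4L, "other",
                                      as.character(class_n)))
  kept <- rec[is.na(reason), , drop = FALSE]
  removal_log <- data.frame(row = which(!is.na(reason)),
                            animal_id = rec$animal_id[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE)
  list(kept = kept, removal_log = removal_log)
}

#' Average scores recorded on the same animal and day
#'
#' When several technicians score the same animal on the same day the
#' records collapse to one with the arithmetic mean score; all other
#' fields are taken from the first record of the pair.
#'
#' @param records score-record `data.frame` with `animal_id`, `date`,
#'   `score`.
#' @return The deduplicated `data.frame`, one row per animal-date.
#' @export
average_same_day_scores <- function(records) {
  key <- paste(records$animal_id, as.character(records$date), sep = "|")
  if (!anyDuplicated(key)) return(records)
  mean_by <- tapply(records$score, key, mean)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  out$score <- unname(mean_by[key[first]])
  rownames(out) <- NULL
  out
}

# month -> calving season; configurable cut: months 1..6 spring, 7..12 fall
month_to_season <- function(month, spring_months = 1:6) {
  ifelse(month %in% spring_months, "spring", "fall")
}

#' Impute missing calving season
#'
#' A record with missing calving season takes the season of the most
#' recent natural-birth calving date before the score date; when the
#' animal has no natural calvings on file, her own birth date is used.
#'
#' @param records score-record `data.frame` (needs `animal_id`, `date`,
#'   `calving_season`, `birth_date`).
#' @param calving_history optional `data.frame` (`animal_id`,
#'   `calving_date`, `natural` logical).
#' @param spring_months months mapped to "spring"; the rest are "fall".
#' @return `records` with `calving_season` filled in.
#' @export
impute_calving_season <- function(records, calving_history = NULL,
                                  spring_months = 1:6) {
  season <- as.character(records$calving_season)
  missing_season <- is.na(season) | season == ""
  if (!any(missing_season)) return(records)
  for (i in which(missing_season)) {
    src_date <- NA
    if (!is.null(calving_history)) {
      h <- calving_history[calving_history$animal_id == records$animal_id[i] &
                             calving_history$natural &
                             as.Date(calving_history$calving_date) <
                               as.Date(records$date[i]), , drop = FALSE]
      if (nrow(h)) src_date <- max(as.Date(h$calving_date))
    }
    if (is.na(src_date)) src_date <- as.Date(records$birth_date[i])
    season[i] <- month_to_season(as.integer(format(src_date, "%m")),
                                 spring_months)
  }
  records$calving_season <- season
  records
}

#' Score groups from a 7-day sliding window
#'
#' Within a farm-year, scoring dates are grouped greedily: the earliest
#' unassigned date opens a window, every date within 6 days of it joins
#' the same group (a 7-calendar-day span), and the process repeats. The
#' greedy-by-earliest rule is deterministic and near-optimal when scoring
#' days cluster, which is the purpose of the window: keeping contemporary
#' groups as large as possible.
#'
#' @param dates a `Date` vector (records sharing a farm and year).
#' @return Integer group labels, one per input date.
#' @export
build_score_groups <- function(dates) {
  dates <- as.Date(dates)
  ud <- sort(unique(dates))
  grp <- integer(length(ud))
  g <- 0L
  i <- 1L
  while (i <= length(ud)) {
    g <- g + 1L
    in_win <- ud <= ud[i] + 6 & grp == 0L
    grp[in_win] <- g
    i <- which(grp == 0L)[1]
    if (is.na(i)) break
  }
  grp[match(dates, ud)]
}

#' Assemble contemporary groups and drop uninformative ones
#'
#' Builds the six-part contemporary-group key (farm, year scored, calving
#' season, fescue grazing status, four-level age group, score group) and
#' drops groups with fewer than `min_size` animals or no score variation,
#' logging the records they carried.
#'
#' @param records prepared records with `farm_id`, `date`,
#'   `calving_season`, `fescue_status`, `age_four_class`, `score`.
#' @param min_size minimum group size (default 5).
#' @return A list with `kept` (records gaining `score_group` and `cg_id`
#'   columns), `groups` (per-group summary) and `removal_log`.
#' @export
assemble_contemporary_groups <- function(records, min_size = 5L) {
  rec <- records
  rec$year <- format(as.Date(rec$date), "%Y")
  fy <- paste(rec$farm_id, rec$year, sep = "|")
  rec$score_group <- NA_integer_
  for (k in unique(fy)) {
    idx <- fy == k
    rec$score_group[idx] <- build_score_groups(rec$date[idx])
  }
  rec$cg_id <- paste(rec$farm_id, rec$year, rec$calving_season,
                     rec$fescue_status, rec$age_four_class,
                     rec$score_group, sep = "_")
  size <- table(rec$cg_id)
  v <- tapply(rec$score, rec$cg_id, function(s) var(s) > 0 && length(s) > 1)
  bad_small <- names(size)[size < min_size]
  bad_flat <- names(v)[!v]
  drop <- rec$cg_id %in% union(bad_small, bad_flat)
  reason <- ifelse(rec$cg_id %in% bad_small, "cg_too_small",
                   "cg_no_variation")
  removal_log <- data.frame(row = which(drop),
                            animal_id = rec$animal_id[drop],
                            reason = reason[drop],
                            cg_id = rec$cg_id[drop],
                            stringsAsFactors = FALSE)
  kept <- rec[!drop, , drop = FALSE]
  tab <- table(kept$cg_id)
  groups <- data.frame(cg_id = names(tab),
                       n_records = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(kept = kept, groups = groups, removal_log = removal_log)
}

#' Full phenotype preparation pipeline
#'
#' Chains the record filters in the order they are meant to run:
#' same-day averaging, validity filters, calving-season imputation,
#' score-group construction and contemporary-group assembly. The steps
#' are idempotent: running the pipeline on its own output changes
#' nothing.
#'
#' @inheritParams validate_records
#' @inheritParams impute_calving_season
#' @param min_cg_size minimum contemporary-group size.
#' @return A list with `records` (analysis-ready, with `cg_id`),
#'   `removal_log` and `groups`.
#' @export
prep_records <- function(records, pedigree_metadata = NULL,
                         calving_history = NULL, min_cg_size = 5L) {
  step0 <- average_same_day_scores(records)
  step1 <- validate_records(step0, pedigree_metadata)
  step2 <- impute_calving_season(step1$kept, calving_history)
  step3 <- assemble_contemporary_groups(step2, min_size = min_cg_size)
  tag <- function(log, stage) {
    out <- log[, c("animal_id", "reason"), drop = FALSE]
    out$stage <- rep(stage, nrow(out))
    out
  }
  removal_log <- rbind(tag(step1$removal_log, "validate"),
                       tag(step3$removal_log, "cg"))
  list(records = step3$kept, removal_log = removal_log,
       groups = step3$groups)
}
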