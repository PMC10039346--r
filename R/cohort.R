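#' @name cohort
#' @title Matched case-control cohort construction
#'
#' @description
#' Cases are persons with an index diagnosis (first ICD-10 I63 episode by
#' default); controls are drawn from an exclusion-screened pool, matched on
#' sex and nearest birth year. Each matched group shares the case's index
#' date; measurement windows and minimum-panel filters are applied per group,
#' and five analysis sub-groups (all / men / women / young / old) are derived
#' by transferring whole matched groups.
NULL

#' Default control exclusion policy
#'
#' Diagnosis prefixes I60-I64 (haemorrhagic and unspecified stroke plus the
#' index diagnosis itself) and medication prefixes B01 (antithrombotics),
#' M01A (NSAIDs), M01BA03, N02BA (salicylates).
#'
#' @return List with `diagnosis_prefixes` and `medication_prefixes`.
#' @export
default_exclusion_policy <- function() {
  list(diagnosis_prefixes = c("I60", "I61", "I62", "I63", "I64"),
       medication_prefixes = c("B01", "M01A", "M01BA03", "N02BA"))
}

#' First event matching a code prefix
#'
#' Earliest date among a person's events whose code starts with `prefix`
#' (ICD-10 block-prefix matching: "I63" matches "I63" and "I63.9").
#'
#' @param events data.frame of one person's events (columns `code`, `date`).
#' @param prefix Code prefix.
#' @return The earliest matching `Date`, or `NA` if none matches.
#' @export
first_event <- function(events, prefix) {
  hit <- icd10_prefix_match(events$code, prefix)
  if (!any(hit)) return(as.Date(NA))
  min(events$date[hit])
}

#' Control eligibility under an exclusion policy
#'
#' A person is control-eligible iff no event of theirs, at any date, matches
#' any policy prefix (diagnoses are checked against ICD10 events, medications
#' against ATC events).
#'
#' @param events data.frame of one person's events (columns `code_type`,
#'   `code`, `date`); may have zero rows.
#' @param policy Exclusion policy (see [default_exclusion_policy()]).
#' @param before_date Optional `Date`: only events strictly before this date
#'   are considered (default `NULL`: any date, the stricter reading of
#'   "no mention of").
#' @return Logical scalar.
#' @export
eligible_control <- function(events, policy = default_exclusion_policy(),
                             before_date = NULL) {
  if (nrow(events) == 0L) return(TRUE)
  ev <- events
  if (!is.null(before_date)) ev <- ev[ev$date < before_date, , drop = FALSE]
  if (nrow(ev) == 0L) return(TRUE)
  dx <- ev$code_type == "ICD10"
  bad_dx <- any(icd10_prefix_match(ev$code[dx], policy$diagnosis_prefixes))
  bad_rx <- any(icd10_prefix_match(ev$code[!dx], policy$medication_prefixes))
  !(bad_dx || bad_rx)
}

#' Match controls to cases by sex and nearest birth year
#'
#' Greedy assignment in a seeded random case order: each case receives
#' `ratio` unused same-sex controls minimising the absolute birth-year
#' difference, ties broken by smaller `person_id`. Controls are used at most
#' once. A case for which fewer than `ratio` same-sex candidates remain is
#' dropped with a warning.
#'
#' @param cases data.frame with `person_id`, `sex`, `birth_year`,
#'   `index_date`.
#' @param pool data.frame with `person_id`, `sex`, `birth_year`
#'   (pre-filtered by [eligible_control()]).
#' @param ratio Controls per case (default 4).
#' @param seed Integer seed for the case order.
#' @return A cohort data.frame with columns `person_id`, `role`
#'   (`case`/`control`), `group_id`, `index_date`, `sex`, `birth_year`, plus
#'   attribute `dropped_cases` (character vector of dropped case ids).
#' @export
match_controls <- function(cases, pool, ratio = 4, seed = 1) {
  stopifnot(all(c("person_id", "sex", "birth_year", "index_date") %in%
                  names(cases)),
            all(c("person_id", "sex", "birth_year") %in% names(pool)))
  pool <- pool[order(pool$person_id), ]
  used <- rep(FALSE, nrow(pool))
  order_cases <- with_seed(seed, sample.int(nrow(cases)))
  entries <- vector("list", nrow(cases))
  dropped <- character(0)
  for (g in seq_along(order_cases)) {
    cs <- cases[order_cases[g], ]
    cand <- which(!used & pool$sex == cs$sex)
    if (length(cand) < ratio) {
      dropped <- c(dropped, cs$person_id)
      next
    }
    d <- abs(pool$birth_year[cand] - cs$birth_year)
    # stable: order by |year diff| then person_id (pool is id-sorted)
    pick <- cand[order(d)][seq_len(ratio)]
    used[pick] <- TRUE
    entries[[g]] <- data.frame(
      person_id = c(cs$person_id, pool$person_id[pick]),
      role = c("case", rep("control", ratio)),
      group_id = cs$person_id,
      index_date = cs$index_date,
      sex = cs$sex,
      birth_year = c(cs$birth_year, pool$birth_year[pick]),
      stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0)
    warning(length(dropped), " case(s) dropped: fewer than ", ratio,
            " same-sex controls remained (",
            paste(utils::head(dropped, 5), collapse = ", "), ")")
  out <- do.call(rbind, entries[!vapply(entries, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(person_id = character(), role = character(),
                      group_id = character(), index_date = as.Date(character()),
                      sex = character(), birth_year = integer(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$group_id, out$role != "case", out$person_id), ]
  rownames(out) <- NULL
  attr(out, "dropped_cases") <- dropped
  out
}

#' Build a cohort from simulation or io tables
#'
#' Identifies cases by their first index-prefix event, screens the remaining
#' persons with the exclusion policy, and matches controls.
#'
#' @param persons,events io-schema data.frames.
#' @param index_prefix Diagnosis prefix defining the event (default "I63").
#' @param policy Exclusion policy.
#' @param ratio Controls per case.
#' @param seed Integer seed.
#' @return Cohort data.frame (see [match_controls()]).
#' @export
build_cohort <- function(persons, events, index_prefix = "I63",
                         policy = default_exclusion_policy(), ratio = 4,
                         seed = 1) {
  ev_split <- split(events, events$person_id)
  empty <- events[0, , drop = FALSE]
  idx <- lapply(persons$person_id, function(id) {
    ev <- ev_split[[id]]
    if (is.null(ev)) ev <- empty
    first_event(ev[ev$code_type == "ICD10", , drop = FALSE], index_prefix)
  })
  idx <- do.call(c, idx)
  is_case <- !is.na(idx)
  cases <- persons[is_case, , drop = FALSE]
  cases$index_date <- idx[is_case]
  pool <- persons[!is_case, , drop = FALSE]
  ok <- vapply(pool$person_id, function(id) {
    ev <- ev_split[[id]]
    if (is.null(ev)) ev <- empty
    eligible_control(ev, policy)
  }, logical(1))
  match_controls(cases, pool[ok, , drop = FALSE], ratio = ratio, seed = seed)
}

#' Restrict measurements to the pre-index window
#'
#' A measurement is retained iff `0 < index_date - date <= window_days`,
#' using the matched group's index date for controls. Index-date measurements
#' are excluded (strictly before the event).
#'
#' @param measurements io-schema measurements data.frame.
#' @param cohort Cohort data.frame.
#' @param window_days Window length in days (default 1000).
#' @return Filtered measurements with extra columns `role`, `group_id`,
#'   `index_date`, `days_before` (positive days before index).
#' @export
window_filter <- function(measurements, cohort, window_days = 1000) {
  m <- match(measurements$person_id, cohort$person_id)
  keep <- !is.na(m)
  meas <- measurements[keep, , drop = FALSE]
  m <- m[keep]
  db <- as.numeric(cohort$index_date[m] - meas$date)
  sel <- db > 0 & db <= window_days
  out <- meas[sel, , drop = FALSE]
  out$role <- cohort$role[m][sel]
  out$group_id <- cohort$group_id[m][sel]
  out$index_date <- cohort$index_date[m][sel]
  out$days_before <- db[sel]
  rownames(out) <- NULL
  out
}

#' Drop persons with too few distinct analytes
#'
#' Persons with fewer than `min_codes` distinct analyte codes among the
#' windowed measurements are removed. A matched group losing its case is
#' dropped entirely; a group losing controls keeps the remaining controls.
#'
#' @param cohort Cohort data.frame.
#' @param windowed Output of [window_filter()].
#' @param min_codes Minimum distinct analyte codes (default 10).
#' @return Reduced cohort, with attribute `reduced_groups` (ids of groups
#'   that lost at least one control but were kept).
#' @export
min_cp_filter <- function(cohort, windowed, min_codes = 10) {
  if (nrow(cohort) == 0L) return(cohort)
  n_codes <- tapply(windowed$analyte_code, windowed$person_id,
                    function(x) length(unique(x)))
  cnt <- ifelse(cohort$person_id %in% names(n_codes),
                n_codes[cohort$person_id], 0L)
  keep_person <- cnt >= min_codes
  lost_case <- unique(cohort$group_id[cohort$role == "case" & !keep_person])
  out <- cohort[keep_person & !(cohort$group_id %in% lost_case), , drop = FALSE]
  before <- table(cohort$group_id[cohort$role == "control"])
  after <- table(out$group_id[out$role == "control"])
  kept_groups <- unique(out$group_id)
  reduced <- kept_groups[
    before[kept_groups] > ifelse(is.na(after[kept_groups]), 0,
                                 after[kept_groups])]
  rownames(out) <- NULL
  attr(out, "reduced_groups") <- as.character(reduced[!is.na(reduced)])
  out
}

#' Derive the five analysis sub-groups
#'
#' Whole matched groups are transferred by the case's sex and the case's age
#' at index: `all`, `men`, `women`, `young` (age <= 60), `old` (age > 60).
#' Age at index is `floor((index_date - Jan 1 of birth_year) / 365.25)`.
#'
#' @param cohort Cohort data.frame.
#' @return Named list of five cohort data.frames.
#' @export
cohort_subgroups <- function(cohort) {
  cases <- cohort[cohort$role == "case", , drop = FALSE]
  jan1 <- as.Date(paste0(cases$birth_year, "-01-01"))
  age <- floor(as.numeric(cases$index_date - jan1) / 365.25)
  grp_sex <- stats::setNames(cases$sex, cases$group_id)
  grp_age <- stats::setNames(age, cases$group_id)
  pick <- function(gids) {
    out <- cohort[cohort$group_id %in% gids, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(
    all = pick(cases$group_id),
    men = pick(cases$group_id[grp_sex[cases$group_id] == "male"]),
    women = pick(cases$group_id[grp_sex[cases$group_id] == "female"]),
    young = pick(cases$group_id[grp_age[cases$group_id] <= 60]),
    old = pick(cases$group_id[grp_age[cases$group_id] > 60])
  )
}

#' Age of each cohort member at the group's index date
#'
#' @param cohort Cohort data.frame.
#' @return Integer ages, `floor((index_date - Jan 1 of birth_year)/365.25)`.
#' @export
age_at_index <- function(cohort) {
  jan1 <- as.Date(paste0(cohort$birth_year, "-01-01"))
  as.integer(floor(as.numeric(cohort$index_date - jan1) / 365.25))
}
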