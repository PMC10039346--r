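#' @name synthetic_data
#' @title Seeded synthetic-EHR generator
#'
#' @description
#' Real pre-event screening studies run on access-restricted EHR data, so the
#' package ships a generator that produces populations, diagnosis/medication
#' events and longitudinal laboratory measurements with the statistical
#' structure every downstream stage assumes:
#'
#' * sex/age-dependent analyte baselines with Gaussian noise,
#' * planted pre-event z-score drifts in cases, starting a configurable number
#'   of days before the index date,
#' * case-enriched measurement frequency (informative missingness) as a
#'   per-analyte rate multiplier,
#' * multiple units per analyte and per-"lab" perturbed reference ranges,
#' * exclusion diagnoses/medications and comorbidity codes in the control
#'   pool.
#'
#' Every generator is deterministic given its seed, and returns the ground
#' truth (`truth`) used to plant signals so that recovery can be scored.
NULL

.exclusion_diagnoses <- c("I60", "I61", "I62", "I63", "I64")
.exclusion_medications <- c("B01", "M01A", "M01BA03", "N02BA")
.comorbidity_codes <- c("E11", "I10", "E78", "J45", "K21", "N18", "F32",
                        "M54", "J06", "K29", "E66", "I48")

#' Default analyte panel specification
#'
#' One row per (analyte, unit). Columns: `analyte_code`, `unit`,
#' `unit_weight` (sampling probability of this unit within the analyte),
#' `intercept`, `sex_effect` (added for males), `age_slope` (per year),
#' `noise_sd`, `rate` (mean measurements per person-year for the analyte).
#' Two analytes carry a minority second unit on a different scale, mirroring
#' multi-unit laboratory feeds that must be analysed as separate series.
#'
#' @param n_analytes Number of analytes (default 20).
#' @return data.frame panel specification.
#' @export
default_panel <- function(n_analytes = 20) {
  i <- seq_len(n_analytes)
  code <- sprintf("%d-%d", 1000 + 7 * i, (i %% 9) + 1)
  panel <- data.frame(
    analyte_code = code,
    unit = rep("U/L", n_analytes),
    unit_weight = 1,
    intercept = 50 + 5 * i,
    sex_effect = rep(c(4, -3, 0, 2), length.out = n_analytes),
    age_slope = rep(c(0.15, -0.1, 0.05, 0), length.out = n_analytes),
    noise_sd = 4 + (i %% 5),
    rate = 0.6,
    stringsAsFactors = FALSE
  )
  if (n_analytes >= 2) {
    # minority second unit for the first two analytes, on a x10 scale
    alt <- panel[1:2, ]
    alt$unit <- "mg/dL"
    alt$unit_weight <- 0.15
    alt$intercept <- alt$intercept * 10
    alt$sex_effect <- alt$sex_effect * 10
    alt$age_slope <- alt$age_slope * 10
    alt$noise_sd <- alt$noise_sd * 10
    panel$unit_weight[1:2] <- 0.85
    panel <- rbind(panel, alt)
  }
  panel
}

#' Default planted trend specification
#'
#' Signed pre-index drifts in z-units per 1000 days applied to cases only,
#' with onsets 1000-3000 days before the index date (most at 2000), the
#' range where pre-event laboratory trends are typically reported.
#'
#' @param panel Panel the trends refer to.
#' @return data.frame with `analyte_code`, `onset` (days before index),
#'   `slope_z` (z-units per 1000 days).
#' @export
default_trends <- function(panel = default_panel()) {
  codes <- unique(panel$analyte_code)
  k <- min(6L, length(codes))
  data.frame(
    analyte_code = codes[seq_len(k)],
    onset = c(1000L, 2000L, 1500L, 2000L, 2500L, 3000L)[seq_len(k)],
    slope_z = c(0.3, 0.3, -0.3, 0.5, -0.5, 0.2)[seq_len(k)],
    stringsAsFactors = FALSE
  )
}

#' Default informative-missingness specification
#'
#' Cases are measured more often than controls for half the panel
#' (multiplier 3), emulating measurement frequency driven by comorbidity.
#'
#' @param panel Panel the multipliers refer to.
#' @return data.frame with `analyte_code`, `case_multiplier`.
#' @export
default_missingness <- function(panel = default_panel()) {
  codes <- unique(panel$analyte_code)
  mult <- rep(1, length(codes))
  if (length(codes) >= 11) mult[11:length(codes)] <- 3
  data.frame(analyte_code = codes, case_multiplier = mult,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic population with events
#'
#' Cases receive exactly one index diagnosis (ICD-10 I63) at an anchor date
#' drawn within the last year of the study period. A configurable fraction of
#' the control pool carries exclusion diagnoses or medications; everyone may
#' carry comorbidity diagnoses.
#'
#' @param n_cases Number of cases.
#' @param n_pool Size of the control candidate pool (must be at least
#'   4 x `n_cases` so that matching is feasible).
#' @param sex_ratio Probability that a person is male (default 0.405, the
#'   male fraction typical of elderly stroke cohorts).
#' @param age_mean,age_sd Age-at-index distribution (default 71.3 / 12.8).
#' @param exclusion_frac Fraction of the pool planted with an exclusion
#'   diagnosis or medication (default 0.15).
#' @param comorbidity_mean Mean number of comorbidity diagnoses per person
#'   (Poisson; default 1).
#' @param study_end Last day of the study period (default "2018-01-01").
#' @param seed Integer seed.
#' @return List with `persons`, `events` (io-schema data.frames) and
#'   `anchors` (person_id, role, anchor_date): the case's index date, or the
#'   pool member's observation-stop anchor.
#' @export
sim_population <- function(n_cases, n_pool, sex_ratio = 0.405,
                           age_mean = 71.3, age_sd = 12.8,
                           exclusion_frac = 0.15, comorbidity_mean = 1,
                           study_end = as.Date("2018-01-01"), seed = 1) {
  if (n_pool < 4 * n_cases)
    stop("control pool must be at least 4x the number of cases")
  if (sex_ratio <= 0 || sex_ratio >= 1)
    stop("infeasible sex configuration: sex_ratio must be in (0, 1)")
  if (age_sd <= 0) stop("infeasible age configuration: age_sd must be > 0")
  study_end <- as.Date(study_end)
  with_seed(seed, {
    n <- n_cases + n_pool
    id <- c(sprintf("case%04d", seq_len(n_cases)),
            sprintf("pool%05d", seq_len(n_pool)))
    role <- c(rep("case", n_cases), rep("pool", n_pool))
    sex <- ifelse(stats::runif(n) < sex_ratio, "male", "female")
    age <- pmin(pmax(stats::rnorm(n, age_mean, age_sd), 25), 99)
    anchor <- study_end - sample.int(365L, n, replace = TRUE)
    birth_year <- as.integer(format(anchor, "%Y")) - as.integer(round(age))
    persons <- data.frame(person_id = id, sex = sex, birth_year = birth_year,
                          stringsAsFactors = FALSE)
    anchors <- data.frame(person_id = id, role = role, anchor_date = anchor,
                          stringsAsFactors = FALSE)

    ev <- list()
    # index diagnosis for every case
    ev[[1]] <- data.frame(person_id = id[role == "case"], code_type = "ICD10",
                          code = "I63", date = anchor[role == "case"],
                          stringsAsFactors = FALSE)
    # exclusion codes for a fraction of the pool
    pool_idx <- which(role == "pool")
    n_excl <- round(exclusion_frac * length(pool_idx))
    if (n_excl > 0) {
      who <- sample(pool_idx, n_excl)
      # the index diagnosis itself is never planted in the pool: a pool
      # member with I63 would be a case, not an ineligible control
      codes <- sample(c(setdiff(.exclusion_diagnoses, "I63"),
                        .exclusion_medications),
                      n_excl, replace = TRUE)
      ev[[2]] <- data.frame(
        person_id = id[who],
        code_type = ifelse(codes %in% .exclusion_diagnoses, "ICD10", "ATC"),
        code = codes,
        date = anchor[who] - sample.int(2000L, n_excl, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    # comorbidity diagnoses for everyone
    n_com <- stats::rpois(n, comorbidity_mean)
    if (sum(n_com) > 0) {
      who <- rep(seq_len(n), n_com)
      ev[[3]] <- data.frame(
        person_id = id[who],
        code_type = "ICD10",
        code = sample(.comorbidity_codes, sum(n_com), replace = TRUE),
        date = anchor[who] - sample.int(3000L, sum(n_com), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
    rownames(events) <- NULL
    list(persons = persons, events = events, anchors = anchors)
  })
}

#' Generate longitudinal measurements with planted trends
#'
#' Measurement times per (person, analyte) follow a Poisson process at the
#' panel rate, multiplied for cases by the analyte's informative-missingness
#' multiplier. Values follow the linear sex/age baseline plus Gaussian noise;
#' for cases, a linear drift of `slope_z` z-units per 1000 days (converted to
#' native units through the noise sd) is added from the trend onset to the
#' index date. Reference ranges are the unit baseline at age 70 +/- 1.5 noise
#' sd, perturbed by one of three simulated laboratories.
#'
#' @param pop Population list from [sim_population()].
#' @param panel Panel specification (see [default_panel()]).
#' @param trends Trend specification (see [default_trends()]); may have zero
#'   rows.
#' @param missingness Missingness specification (see [default_missingness()]).
#' @param horizon_days Length of the pre-anchor observation window in days;
#'   must cover every trend onset.
#' @param seed Integer seed.
#' @return List with `measurements` (io-schema data.frame) and `truth`
#'   (the planted trends, missingness, panel and role assignment).
#' @export
sim_measurements <- function(pop, panel = default_panel(),
                             trends = default_trends(panel),
                             missingness = default_missingness(panel),
                             horizon_days = 3650, seed = 1) {
  bad <- setdiff(trends$analyte_code, panel$analyte_code)
  if (length(bad) > 0)
    stop("trend refers to unknown analyte(s): ", paste(bad, collapse = ", "))
  if (nrow(trends) > 0 && any(trends$onset > horizon_days))
    stop("horizon_days must cover every trend onset")
  if (nrow(trends) > 0 && any(trends$onset < 0 | trends$onset > 3650))
    stop("trend onset must lie in [0, 3650] days")
  an <- pop$anchors
  per <- pop$persons
  stopifnot(identical(an$person_id, per$person_id))
  analytes <- unique(panel$analyte_code)
  mult <- stats::setNames(rep(1, length(analytes)), analytes)
  m_idx <- match(missingness$analyte_code, analytes)
  mult[m_idx[!is.na(m_idx)]] <- missingness$case_multiplier[!is.na(m_idx)]
  rate <- stats::setNames(panel$rate[match(analytes, panel$analyte_code)],
                          analytes)
  onset <- stats::setNames(rep(NA_real_, length(analytes)), analytes)
  slope <- stats::setNames(rep(0, length(analytes)), analytes)
  if (nrow(trends) > 0) {
    onset[trends$analyte_code] <- trends$onset
    slope[trends$analyte_code] <- trends$slope_z
  }
  lab_shift <- c(-0.3, 0, 0.3)  # per-lab reference-range offsets, in sd units

  with_seed(seed, {
    n <- nrow(per)
    is_case <- an$role == "case"
    age_anchor <- as.integer(format(an$anchor_date, "%Y")) - per$birth_year
    out <- vector("list", length(analytes))
    for (k in seq_along(analytes)) {
      a <- analytes[k]
      lam <- rate[a] * horizon_days / 365.25 * ifelse(is_case, mult[a], 1)
      cnt <- stats::rpois(n, lam)
      tot <- sum(cnt)
      if (tot == 0) next
      pid <- rep(seq_len(n), cnt)
      days_before <- sample.int(horizon_days, tot, replace = TRUE)
      rows <- panel[panel$analyte_code == a, , drop = FALSE]
      u <- if (nrow(rows) == 1) rep(1L, tot) else
        sample.int(nrow(rows), tot, replace = TRUE, prob = rows$unit_weight)
      age_rec <- age_anchor[pid] - days_before / 365.25
      male <- as.numeric(per$sex[pid] == "male")
      base <- rows$intercept[u] + rows$sex_effect[u] * male +
        rows$age_slope[u] * age_rec
      val <- base + stats::rnorm(tot, 0, rows$noise_sd[u])
      if (!is.na(onset[a]) && slope[a] != 0) {
        since <- pmax(0, onset[a] - days_before)
        val <- val + is_case[pid] * slope[a] * since / 1000 * rows$noise_sd[u]
      }
      mid <- rows$intercept[u] + rows$sex_effect[u] * 0.5 +
        rows$age_slope[u] * 70
      lab <- sample.int(3L, tot, replace = TRUE)
      lo <- mid - (1.5 - lab_shift[lab]) * rows$noise_sd[u]
      hi <- mid + (1.5 + lab_shift[lab]) * rows$noise_sd[u]
      out[[k]] <- data.frame(
        person_id = per$person_id[pid],
        analyte_code = a,
        value = val,
        unit = rows$unit[u],
        date = an$anchor_date[pid] - days_before,
        ref_low = lo, ref_high = hi,
        stringsAsFactors = FALSE)
    }
    meas <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(meas)) {
      meas <- data.frame(person_id = character(), analyte_code = character(),
                         value = numeric(), unit = character(),
                         date = as.Date(character()), ref_low = numeric(),
                         ref_high = numeric(), stringsAsFactors = FALSE)
    } else {
      meas <- meas[order(meas$person_id, meas$analyte_code, meas$date), ]
      rownames(meas) <- NULL
    }
    truth <- list(trends = trends, missingness = missingness, panel = panel,
                  roles = an[, c("person_id", "role")],
                  horizon_days = horizon_days)
    list(measurements = meas, truth = truth)
  })
}

#' Generate transactions with a planted item-pair association
#'
#' Two items with fixed marginal probabilities and a controllable joint
#' probability (a Bernoulli copula): `p_joint = p_a * p_b` gives independent
#' items; larger values plant a co-occurrence excess. This is the pairwise
#' correlation knob used to validate the rule-mining stage.
#'
#' @param n Number of transactions.
#' @param p_a,p_b Marginal probabilities of items `a` and `b`.
#' @param p_joint Joint probability (must satisfy
#'   `max(0, p_a + p_b - 1) <= p_joint <= min(p_a, p_b)`).
#' @param items Item labels (length 2).
#' @param seed Integer seed.
#' @return List of `n` character vectors (possibly empty transactions).
#' @export
sim_transactions <- function(n, p_a, p_b, p_joint,
                             items = c("A_HIGH", "B_LOW"), seed = 1) {
  if (p_joint > min(p_a, p_b) + 1e-12 || p_joint < max(0, p_a + p_b - 1) - 1e-12)
    stop("infeasible joint probability for the given marginals")
  ra <- (p_a - p_joint) / (1 - p_joint)  # a-only rate given "not both"
  rb <- (p_b - p_joint) / (1 - p_joint)
  if (ra + rb > 1 + 1e-12)
    stop("infeasible joint probability: p_a + p_b - p_joint exceeds 1")
  with_seed(seed, {
    both <- stats::runif(n) < p_joint
    # exclusive residual branches keep the joint probability exact
    u <- stats::runif(n)
    a <- both | (!both & u < ra)
    b <- both | (!both & u >= ra & u < ra + rb)
    lapply(seq_len(n), function(i) {
      c(if (a[i]) items[1], if (b[i]) items[2])
    })
  })
}

#' Generate a stratified survival validation scenario
#'
#' Exponential event times with per-stratum hazard `baseline_rate * hr`,
#' censored at a fixed horizon. Used to validate the Cox and Kaplan-Meier
#' stages against known hazard ratios.
#'
#' @param n Total subjects, split evenly (remainder to the first strata).
#' @param hr Named or unnamed vector of hazard ratios, one per stratum.
#' @param baseline_rate Baseline hazard (events per day).
#' @param censor_time Administrative censoring horizon (days).
#' @param seed Integer seed.
#' @return data.frame with `stratum`, `time`, `event` (1 = event, 0 =
#'   censored).
#' @export
sim_survival_scenario <- function(n, hr, baseline_rate = 1 / 2000,
                                  censor_time = 2000, seed = 1) {
  if (any(hr <= 0)) stop("hazard ratios must be positive")
  k <- length(hr)
  strata <- names(hr)
  if (is.null(strata)) strata <- paste0("s", seq_len(k))
  with_seed(seed, {
    grp <- rep(seq_len(k), length.out = n)[sample.int(n)]
    t_event <- stats::rexp(n, rate = baseline_rate * hr[grp])
    event <- as.integer(t_event <= censor_time)
    time <- pmin(t_event, censor_time)
    data.frame(stratum = strata[grp], time = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Generate the default end-to-end scenario
#'
#' Convenience wrapper combining [sim_population()] and [sim_measurements()]
#' under the package's default panel, trends and informative missingness.
#'
#' @param n_cases,n_pool Population sizes (defaults 200 / 1400).
#' @param seed Integer seed.
#' @param ... Passed to [sim_population()].
#' @return List with `persons`, `events`, `anchors`, `measurements`, `truth`.
#' @export
sim_scenario <- function(n_cases = 200, n_pool = 1400, seed = 1, ...) {
  pop <- sim_population(n_cases, n_pool, seed = seed, ...)
  ms <- sim_measurements(pop, seed = seed + 1L)
  c(pop, ms)
}
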