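#' @name stats_module
#' @title Per-analyte logistic and Cox proportional-hazards analyses
#'
#' @description
#' Logistic regression of case status on the (rank-inverse-normal
#' transformed) latest value, adjusted for sex and age, with Bonferroni
#' control across the analyte family. Cox proportional hazards on z-score
#' strata (-Inf,-1), [-1,1], (1,Inf) with the middle stratum as reference,
#' Kaplan-Meier curves per stratum, and an operational middle-curve
#' proportionality check: the mid stratum's survival must lie weakly between
#' the low and high strata's at every evaluated time.
NULL

#' Rank-based inverse-normal transform
#'
#' Blom-offset rank-inverse-normal transform with mid-ranks for ties:
#' `qnorm((rank - 3/8) / (n + 1/4))`. Monotone, bounded, and maps any
#' continuous distribution to approximate normality, removing outliers.
#'
#' @param values Numeric vector (length >= 10, non-constant).
#' @return Transformed numeric vector.
#' @export
transform_for_lr <- function(values) {
  if (length(values) < 10) stop("transform requires at least 10 values")
  if (length(unique(values)) == 1L) stop("constant input cannot be transformed")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

#' Per-analyte logistic association
#'
#' Maximum-likelihood logistic fit of case status on the transformed latest
#' value, sex (optional) and age; two-sided Wald p-value for the value
#' coefficient. Separation / non-convergence is flagged so the result can be
#' excluded from the Bonferroni family.
#'
#' @param value Transformed latest value per person.
#' @param is_case Logical or 0/1 case indicator.
#' @param sex Character or factor sex per person.
#' @param age Numeric age per person.
#' @param adjust_sex Include the sex term (default TRUE; set FALSE for
#'   single-sex sub-groups).
#' @return List: `effect` (value coefficient), `se`, `p`, `n`, `converged`.
#' @export
logistic_assoc <- function(value, is_case, sex, age, adjust_sex = TRUE) {
  y <- as.integer(is_case)
  if (length(unique(y)) < 2L) stop("both classes required")
  dat <- data.frame(y = y, value = value, age = age)
  form <- y ~ value + age
  if (adjust_sex) {
    dat$sex <- factor(sex)
    form <- y ~ value + sex + age
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = dat))
  co <- summary(fit)$coefficients
  converged <- isTRUE(fit$converged) &&
    all(is.finite(co["value", ])) && co["value", "Std. Error"] < 50
  list(effect = unname(co["value", "Estimate"]),
       se = unname(co["value", "Std. Error"]),
       p = unname(co["value", "Pr(>|z|)"]),
       n = nrow(dat), converged = converged)
}

#' Bonferroni significance flags
#'
#' Flags p-values strictly below `alpha / m`.
#'
#' @param p Numeric vector of p-values.
#' @param m Family size (defaults to `length(p)`; must be at least that).
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector.
#' @export
bonferroni_flags <- function(p, m = length(p), alpha = 0.05) {
  stopifnot(m >= length(p))
  p < alpha / m
}

#' z-score strata
#'
#' low = (-Inf, -1), mid = \[-1, 1\] (closed), high = (1, Inf).
#'
#' @param z Numeric z-scores.
#' @return Factor with levels `low`, `mid`, `high` (mid first as reference
#'   would be set by the caller; levels ordered low/mid/high).
#' @export
zscore_strata <- function(z) {
  out <- ifelse(z < -1, "low", ifelse(z > 1, "high", "mid"))
  factor(out, levels = c("mid", "low", "high"))
}

#' Cox proportional-hazards fit on z-score strata
#'
#' Partial-likelihood Cox model (Efron ties) with `mid` as the reference
#' stratum. Time axis: days from each person's latest measurement to the
#' event (cases) or to index-date censoring (controls).
#'
#' @param strata Factor from [zscore_strata()] (reference level first).
#' @param time Positive follow-up times (days).
#' @param event 1 = event, 0 = censored.
#' @return List: `contrasts` data.frame (one row per non-reference stratum
#'   present: `stratum`, `hr`, `p`), `fit` (the `coxph` object), and `n`.
#'   Strata with zero members are omitted and recorded in `omitted`.
#' @export
cox_fit <- function(strata, time, event) {
  stopifnot(length(strata) == length(time), length(time) == length(event))
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (sum(event) == 0) stop("no events observed")
  strata <- droplevels(strata)
  omitted <- setdiff(c("low", "high"), levels(strata))
  dat <- data.frame(time = time, event = event, stratum = strata)
  fit <- survival::coxph(survival::Surv(time, event) ~ stratum, data = dat,
                         ties = "efron")
  co <- summary(fit)$coefficients
  lab <- sub("^stratum", "", rownames(co))
  contrasts <- data.frame(stratum = lab, hr = unname(co[, "exp(coef)"]),
                          p = unname(co[, "Pr(>|z|)"]),
                          stringsAsFactors = FALSE)
  list(contrasts = contrasts, fit = fit, n = nrow(dat), omitted = omitted)
}

#' Kaplan-Meier survival curves per stratum
#'
#' Product-limit estimates with risk sets at event times.
#'
#' @inheritParams cox_fit
#' @return Named list of data.frames (`time`, `surv`, `n_risk`), one per
#'   stratum, each starting implicitly at survival 1.
#' @export
km_curves <- function(strata, time, event) {
  strata <- droplevels(strata)
  dat <- data.frame(time = time, event = event, stratum = strata)
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = dat)
  if (is.null(fit$strata)) {
    out <- list(data.frame(time = fit$time, surv = fit$surv,
                           n_risk = fit$n.risk))
    names(out) <- levels(strata)[1]
    return(out)
  }
  lab <- sub("^stratum=", "", names(fit$strata))
  idx <- rep(seq_along(fit$strata), fit$strata)
  out <- lapply(seq_along(lab), function(k) {
    sel <- idx == k
    data.frame(time = fit$time[sel], surv = fit$surv[sel],
               n_risk = fit$n.risk[sel])
  })
  stats::setNames(out, lab)
}

# step-function evaluation of a K-M curve at time t (right-continuous)
.km_at <- function(curve, t) {
  i <- findInterval(t, curve$time)
  c(1, curve$surv)[i + 1]
}

# number at risk just before time t
.km_risk_at <- function(curve, t, n0) {
  i <- findInterval(t, curve$time, left.open = TRUE)
  if (i == 0) n0 else curve$n_risk[i]
}

#' Middle-curve proportionality check
#'
#' Operationalises the visual check that the mid stratum's Kaplan-Meier
#' curve runs between the low and high strata's: at every evaluation time
#' (deciles of the observed event times) where each stratum still has at
#' least `min_risk` subjects at risk, `surv(mid)` must lie weakly between
#' `surv(low)` and `surv(high)`.
#'
#' @param curves Named list from [km_curves()] with entries `low`, `mid`,
#'   `high`.
#' @param n0 Named vector of initial stratum sizes (same names).
#' @param event_times Observed event times (used for the decile grid).
#' @param min_risk Minimum risk-set size per stratum (default 10).
#' @return Logical: `TRUE` when the mid curve is weakly between at all
#'   evaluated times. Errors when fewer than 3 strata are available.
#' @export
proportionality_check <- function(curves, n0, event_times, min_risk = 10) {
  need <- c("low", "mid", "high")
  if (!all(need %in% names(curves)))
    stop("proportionality undefined: need all three strata, have ",
         paste(names(curves), collapse = ", "))
  ts <- unique(stats::quantile(event_times, probs = seq(0.1, 0.9, by = 0.1),
                               names = FALSE, type = 1))
  ok <- TRUE
  for (t in ts) {
    risks <- vapply(need, function(s) .km_risk_at(curves[[s]], t, n0[[s]]), 0)
    if (any(risks < min_risk)) next
    s <- vapply(need, function(nm) .km_at(curves[[nm]], t), 0)
    lo <- min(s[["low"]], s[["high"]])
    hi <- max(s[["low"]], s[["high"]])
    if (s[["mid"]] < lo || s[["mid"]] > hi) {
      ok <- FALSE
      break
    }
  }
  ok
}
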