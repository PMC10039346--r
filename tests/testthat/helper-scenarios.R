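# Shared scenario builders and independent oracles for the test-suite.

# exhaustive frequent-itemset enumeration: the independent oracle for the
# FP-Growth miner
brute_force_itemsets <- function(transactions, min_count, max_size = Inf) {
  tx <- lapply(transactions, unique)
  items <- sort(unique(unlist(tx, use.names = FALSE)))
  if (length(items) == 0L)
    return(data.frame(items = character(), size = integer(),
                      count = numeric(), stringsAsFactors = FALSE))
  m <- vapply(items, function(it) vapply(tx, function(t) it %in% t,
                                         logical(1)),
              logical(length(tx)))
  m <- matrix(m, nrow = length(tx))
  rows <- list()
  for (s in seq_len(min(length(items), max_size))) {
    sets <- utils::combn(length(items), s)
    for (j in seq_len(ncol(sets))) {
      idx <- sets[, j]
      cnt <- sum(rowSums(m[, idx, drop = FALSE]) == s)
      if (cnt >= min_count) {
        rows[[length(rows) + 1L]] <- data.frame(
          items = paste(items[idx], collapse = ","), size = s, count = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(items = character(), size = integer(),
                      count = numeric(), stringsAsFactors = FALSE))
  out <- out[order(out$size, out$items), ]
  rownames(out) <- NULL
  out
}

# random transaction set for property tests
random_transactions <- function(n_tx, n_items, seed) {
  with_seed(seed, {
    items <- LETTERS[seq_len(n_items)]
    lapply(seq_len(n_tx), function(i) {
      k <- sample.int(n_items, 1) - 1L
      if (k == 0L) character(0) else sample(items, k)
    })
  })
}

# trajectory scenario for the trend stage: values are z-scores (flat
# baseline, noise sd 0.05); a drift of `drift` z-units accumulates over the
# final `onset` days before the index date. Observed within a window of
# `horizon` days; ~`points_per_arm` measurements per arm.
make_trend_scenario <- function(seed, drift = 0.3, onset = 1000L,
                                horizon = 1000, n_arm = 100,
                                points_per_arm = 3000) {
  noise <- 0.05
  rate <- points_per_arm / n_arm / (horizon / 365.25)
  panel <- data.frame(analyte_code = "T1", unit = "z", unit_weight = 1,
                      intercept = 0, sex_effect = 0, age_slope = 0,
                      noise_sd = noise, rate = rate, stringsAsFactors = FALSE)
  trends <- if (drift == 0) {
    data.frame(analyte_code = character(), onset = integer(),
               slope_z = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(analyte_code = "T1", onset = onset, slope_z = drift / noise,
               stringsAsFactors = FALSE)
  }
  miss <- data.frame(analyte_code = "T1", case_multiplier = 1,
                     stringsAsFactors = FALSE)
  pop <- sim_population(n_arm, 4 * n_arm, seed = seed)
  ms <- sim_measurements(pop, panel, trends, miss, horizon_days = horizon,
                         seed = seed + 1L)
  m <- ms$measurements
  roles <- stats::setNames(ms$truth$roles$role, ms$truth$roles$person_id)
  m$role <- ifelse(roles[m$person_id] == "case", "case", "control")
  ctl <- unique(m$person_id[m$role == "control"])
  m <- m[m$role == "case" | m$person_id %in% ctl[seq_len(min(n_arm, length(ctl)))], ,
         drop = FALSE]
  anch <- stats::setNames(pop$anchors$anchor_date, pop$anchors$person_id)
  m$days_before <- as.numeric(anch[m$person_id] - m$date)
  m$z <- m$value  # the panel is expressed directly in z-units
  m
}

# direct tricube weighted-least-squares evaluation of a non-robust local
# linear fit at one target point (Cleveland's definition)
lowess_wls_oracle <- function(x, y, x0, span = 2 / 3) {
  n <- length(x)
  ns <- max(2, min(n, floor(n * span + 1e-7)))
  d <- abs(x - x0)
  h <- sort(d)[ns]
  w <- pmax(0, (1 - pmin(1, d / h)^3))^3
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  sum(fit$coefficients * c(1, x0))
}

# tiny valid tables for io round-trips
random_persons_table <- function(n, seed) {
  with_seed(seed, data.frame(
    person_id = sprintf("p%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    birth_year = sample(1920:2000, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

random_measurements_table <- function(n, seed) {
  with_seed(seed, {
    lo <- round(stats::runif(n, 1, 5), 3)
    data.frame(
      person_id = sprintf("p%04d", sample.int(max(2, n %/% 2), n, TRUE)),
      analyte_code = sample(c("1007-2", "1014-3", "1021-4"), n, TRUE),
      value = round(stats::rnorm(n, 10, 3), 6),
      unit = sample(c("U/L", "mg/dL"), n, TRUE),
      date = as.Date("2015-01-01") + sample.int(1000, n, TRUE),
      ref_low = lo,
      ref_high = lo + round(stats::runif(n, 0.5, 10), 3),
      stringsAsFactors = FALSE)
  })
}

random_events_table <- function(n, seed) {
  with_seed(seed, data.frame(
    person_id = sprintf("p%04d", sample.int(max(2, n %/% 2), n, TRUE)),
    code_type = sample(c("ICD10", "ATC"), n, TRUE),
    code = sample(c("I63", "I63.9", "E11", "I10", "B01AC06", "N02BA01"),
                  n, TRUE),
    date = as.Date("2010-01-01") + sample.int(3000, n, TRUE),
    stringsAsFactors = FALSE))
}
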