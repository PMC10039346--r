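#' @name pipeline
#' @title End-to-end screening pipeline
#'
#' @description
#' `run_pipeline()` chains the full procedure on synthetic data: simulate ->
#' match cohort -> window + minimum-panel filters -> per-(analyte, unit)
#' sex/age z-score adjustment -> association-rule mining with the
#' control-resampling null -> lowess trend classification -> per-analyte
#' logistic and Cox analyses -> the five-representation ML benchmark, and
#' writes every result as a TSV. Fully deterministic given the seed.
NULL

#' Adjust all windowed series to z-scores
#'
#' Applies [window_filter()], [attach_demographics()], [split_by_unit()] and
#' [adjust_zscore()] and binds the surviving series back together with a
#' `key` column.
#'
#' @param measurements Measurements data.frame.
#' @param cohort Cohort data.frame.
#' @param persons Persons data.frame.
#' @param window_days Window length (default 1000).
#' @param adjust_sex Include the sex term (default TRUE).
#' @param min_n Minimum observations per series (default 10).
#' @return Adjusted measurements with `key` and `z` columns (zero rows if no
#'   series qualifies).
#' @export
prepare_adjusted <- function(measurements, cohort, persons,
                             window_days = 1000, adjust_sex = TRUE,
                             min_n = 10) {
  w <- window_filter(measurements, cohort, window_days)
  w <- attach_demographics(w, persons)
  series <- split_by_unit(w)
  out <- vector("list", length(series))
  for (i in seq_along(series)) {
    s <- adjust_zscore(series[[i]], adjust_sex = adjust_sex, min_n = min_n)
    if (!is.null(s)) {
      s$key <- names(series)[i]
      out[[i]] <- s
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- w[0, , drop = FALSE]
    res$z <- numeric(0)
    res$key <- character(0)
  }
  rownames(res) <- NULL
  res
}

#' Run the full screening pipeline on synthetic data
#'
#' @param seed Integer master seed.
#' @param out_dir Directory for the result TSVs (created if needed);
#'   `NULL` skips writing.
#' @param n_cases,n_pool Simulation sizes (defaults 200 / 1400).
#' @param ratio Controls per case (default 4).
#' @param window_days Analysis window for ARM/LR/CPH/benchmark
#'   (default 1000).
#' @param trend_window_days Window for the lowess stage, which pools all
#'   measurements (default 3650).
#' @param min_codes Minimum distinct analytes per person (default 10).
#' @return Invisible list with `cohort`, `rules`, `trends`, `logistic`,
#'   `cox`, `bench` data.frames and the simulation `truth`.
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL, n_cases = 200,
                         n_pool = 1400, ratio = 4, window_days = 1000,
                         trend_window_days = 3650, min_codes = 10) {
  sim <- sim_scenario(n_cases = n_cases, n_pool = n_pool, seed = seed)
  cohort <- build_cohort(sim$persons, sim$events, ratio = ratio,
                         seed = seed + 1L)
  adj <- prepare_adjusted(sim$measurements, cohort, sim$persons,
                          window_days = window_days)
  cohort <- min_cp_filter(cohort, adj, min_codes = min_codes)
  adj <- adj[adj$person_id %in% cohort$person_id, , drop = FALSE]

  # --- association rules on latest adjusted values
  latest <- latest_per_person_by_key(adj)
  tx_all <- discretize_items(
    data.frame(person_id = latest$person_id, key = latest$key, z = latest$z,
               stringsAsFactors = FALSE),
    persons = cohort$person_id)
  case_ids <- cohort$person_id[cohort$role == "case"]
  ctrl_ids <- cohort$person_id[cohort$role == "control"]
  rules <- resampling_null(tx_all[case_ids], tx_all[ctrl_ids],
                           seed = seed + 2L)
  rules_final <- filter_rules(rules, tx_all[case_ids], seed = seed + 3L)

  # --- lowess trends over the full horizon
  adj_long <- prepare_adjusted(sim$measurements, cohort, sim$persons,
                               window_days = trend_window_days)
  trends <- lapply(split(adj_long, adj_long$key), trend_for_series)
  trends <- trends[!vapply(trends, is.null, logical(1))]
  trend_tab <- data.frame(
    key = names(trends),
    start_time = vapply(trends, function(t) t$start_time, 0),
    direction = vapply(trends, function(t) t$direction, ""),
    significant = vapply(trends, function(t) t$significant, logical(1)),
    confidence = vapply(trends, function(t) t$confidence, ""),
    delta_z = vapply(trends, function(t) t$delta_z, 0),
    stringsAsFactors = FALSE)
  rownames(trend_tab) <- NULL

  # --- per-analyte logistic regression and Cox PH on the 1000-day window
  persons_idx <- match(latest$person_id, cohort$person_id)
  latest$is_case <- cohort$role[persons_idx] == "case"
  latest$age_idx <- age_at_index(cohort)[persons_idx]
  lr_rows <- list()
  cox_rows <- list()
  for (k in sort(unique(latest$key))) {
    s <- latest[latest$key == k, , drop = FALSE]
    if (nrow(s) < 10 || length(unique(s$is_case)) < 2) next
    if (length(unique(s$value)) < 2) next
    lr <- logistic_assoc(transform_for_lr(s$value), s$is_case, s$sex,
                         s$age_idx)
    lr_rows[[k]] <- data.frame(key = k, effect = lr$effect, p = lr$p,
                               n = lr$n, converged = lr$converged,
                               stringsAsFactors = FALSE)
    st <- zscore_strata(s$z)
    if (sum(s$is_case) > 0 && all(table(st) > 0)) {
      cf <- tryCatch(cox_fit(st, s$days_before, as.integer(s$is_case)),
                     error = function(e) NULL)
      if (!is.null(cf)) {
        km <- km_curves(st, s$days_before, as.integer(s$is_case))
        prop <- if (all(c("low", "mid", "high") %in% names(km)))
          proportionality_check(km, table(st)[names(km)],
                                s$days_before[s$is_case]) else NA
        cc <- cf$contrasts
        cox_rows[[k]] <- data.frame(key = k, stratum = cc$stratum,
                                    hr = cc$hr, p = cc$p,
                                    proportional = prop,
                                    stringsAsFactors = FALSE)
      }
    }
  }
  lr_tab <- do.call(rbind, lr_rows)
  if (is.null(lr_tab))
    lr_tab <- data.frame(key = character(), effect = numeric(),
                         p = numeric(), n = integer(), converged = logical())
  fam <- lr_tab[lr_tab$converged, , drop = FALSE]
  lr_tab$bonferroni_significant <- FALSE
  lr_tab$bonferroni_significant[lr_tab$converged] <-
    bonferroni_flags(fam$p, m = nrow(fam))
  rownames(lr_tab) <- NULL
  cox_tab <- do.call(rbind, cox_rows)
  if (is.null(cox_tab))
    cox_tab <- data.frame(key = character(), stratum = character(),
                          hr = numeric(), p = numeric(),
                          proportional = logical())
  rownames(cox_tab) <- NULL

  # --- five-representation benchmark (individual-based)
  tab <- tabularize(adj, cohort, mode = "individual")
  schemes <- c("binary", "balanced_binary", "reference_category", "raw",
               "zscore")
  bench_rows <- list()
  base <- baseline_model(tab$sex, tab$age, tab$label, seed = seed + 4L)
  bench_rows[["baseline"]] <- data.frame(
    encoding = "baseline", model = "RF", accuracy = base$accuracy,
    precision = base$precision, auc = base$auc, stringsAsFactors = FALSE)
  for (sc in schemes) {
    enc <- encode_table(tab, sc, seed = seed + 5L)
    for (mdl in c("LR", "KNN", "RF")) {
      r <- train_eval(mdl, enc, seed = seed + 6L)
      bench_rows[[paste(sc, mdl)]] <- data.frame(
        encoding = sc, model = mdl, accuracy = r$accuracy,
        precision = r$precision, auc = r$auc, stringsAsFactors = FALSE)
    }
  }
  bench_tab <- do.call(rbind, bench_rows)
  rownames(bench_tab) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    cohort_out <- cohort
    write_results(cohort_out, file.path(out_dir, "cohort.tsv"))
    write_results(rules_final, file.path(out_dir, "rules.tsv"))
    write_results(trend_tab, file.path(out_dir, "trends.tsv"))
    write_results(lr_tab, file.path(out_dir, "logistic.tsv"))
    write_results(cox_tab, file.path(out_dir, "cox.tsv"))
    write_results(bench_tab, file.path(out_dir, "bench.tsv"))
  }
  invisible(list(cohort = cohort, rules = rules_final, trends = trend_tab,
                 logistic = lr_tab, cox = cox_tab, bench = bench_tab,
                 truth = sim$truth))
}
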