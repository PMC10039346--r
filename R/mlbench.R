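#' @name mlbench
#' @title Five-way input-representation benchmark
#'
#' @description
#' The windowed, filtered cohort is tabularised one person per row
#' (individual-based: latest value per analyte) or one measurement per row
#' (measurement-based: the row's own measurement plus the person's latest
#' values carried forward for the other analytes), then encoded under one of
#' five schemes:
#'
#' 1. `binary` — 1/0 statement whether the analyte was ever measured;
#' 2. `balanced_binary` — binary with positive indicators randomly masked in
#'    the class with the higher measurement rate until class rates differ by
#'    less than 1% (never flips a 0 to a 1);
#' 3. `reference_category` — below / within / above the laboratory reference
#'    range (plus unknown / missing);
#' 4. `raw` — raw latest values, training-median imputed;
#' 5. `zscore` — sex/age-adjusted z-scores, training-median imputed.
#'
#' Logistic regression, k-nearest-neighbours (Euclidean) and random forest
#' are trained against a sex+age-only baseline; feature importance is
#' available as Gini (mean impurity decrease) or permutation (held-out AUC
#' drop).
NULL

#' Tabularise windowed measurements
#'
#' @param windowed_adj Adjusted windowed measurements carrying `person_id`,
#'   `key` (analyte|unit), `value`, `z`, `date`, `ref_low`, `ref_high`,
#'   `days_before`.
#' @param cohort Cohort data.frame (defines rows/labels; persons without
#'   measurements keep all-missing rows in individual mode).
#' @param mode `"individual"` (one row per person, latest value per analyte)
#'   or `"measurement"` (one row per measurement, other analytes carried
#'   forward from the person's latest values).
#' @return List: `cells` (list of per-column vectors: `value`, `z`,
#'   `category` data.frames keyed by analyte), `person_id`, `label` (1 =
#'   case), `sex`, `age`, `mode`.
#' @export
tabularize <- function(windowed_adj, cohort, mode = c("individual",
                                                      "measurement")) {
  mode <- match.arg(mode)
  keys <- sort(unique(windowed_adj$key))
  latest <- latest_per_person_by_key(windowed_adj)
  # person-level lookup matrices of latest values / z / category
  persons <- cohort$person_id
  np <- length(persons)
  mk <- function(fill) {
    m <- matrix(fill, nrow = np, ncol = length(keys),
                dimnames = list(persons, keys))
    m
  }
  val <- mk(NA_real_)
  zz <- mk(NA_real_)
  cat_m <- mk(NA_character_)
  ri <- match(latest$person_id, persons)
  ci <- match(latest$key, keys)
  keep <- !is.na(ri)
  val[cbind(ri[keep], ci[keep])] <- latest$value[keep]
  zz[cbind(ri[keep], ci[keep])] <- latest$z[keep]
  cat_m[cbind(ri[keep], ci[keep])] <-
    categorize_reference(latest$value[keep], latest$ref_low[keep],
                         latest$ref_high[keep])
  lab <- as.integer(cohort$role == "case")
  age <- age_at_index(cohort)
  if (mode == "individual") {
    return(list(value = val, z = zz, category = cat_m, keys = keys,
                person_id = persons, label = lab, sex = cohort$sex,
                age = age, mode = mode))
  }
  # measurement-based: one row per measurement, LOCF for the other columns
  w <- windowed_adj[windowed_adj$person_id %in% persons, , drop = FALSE]
  ri <- match(w$person_id, persons)
  v2 <- val[ri, , drop = FALSE]
  z2 <- zz[ri, , drop = FALSE]
  c2 <- cat_m[ri, , drop = FALSE]
  ci <- match(w$key, keys)
  v2[cbind(seq_len(nrow(w)), ci)] <- w$value
  z2[cbind(seq_len(nrow(w)), ci)] <- w$z
  c2[cbind(seq_len(nrow(w)), ci)] <-
    categorize_reference(w$value, w$ref_low, w$ref_high)
  list(value = v2, z = z2, category = c2, keys = keys,
       person_id = w$person_id, label = lab[ri], sex = cohort$sex[ri],
       age = age[ri], mode = mode)
}

#' Latest observation per (person, key)
#'
#' @param windowed_adj Measurements with `person_id`, `key`, `date`.
#' @return One row per (person, key), ties on date broken by row ordinal.
#' @export
latest_per_person_by_key <- function(windowed_adj) {
  ord <- order(windowed_adj$person_id, windowed_adj$key, windowed_adj$date,
               seq_len(nrow(windowed_adj)))
  s <- windowed_adj[ord, , drop = FALSE]
  id <- paste(s$person_id, s$key, sep = "\r")
  out <- s[!duplicated(id, fromLast = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Encode a tabularised dataset under one of the five schemes
#'
#' @param tab Output of [tabularize()].
#' @param scheme One of `"binary"`, `"balanced_binary"`,
#'   `"reference_category"`, `"raw"`, `"zscore"`.
#' @param seed Seed for the balancing mask (`balanced_binary` only).
#' @return List: `features` (numeric matrix or character matrix for the
#'   categorical scheme), `categorical` flag, plus the `person_id`, `label`,
#'   `sex`, `age`, `mode` carried through.
#' @export
encode_table <- function(tab, scheme = c("binary", "balanced_binary",
                                         "reference_category", "raw",
                                         "zscore"), seed = 1) {
  scheme <- match.arg(scheme)
  measured <- !is.na(tab$value)
  feats <- switch(scheme,
    binary = ,
    balanced_binary = {
      x <- matrix(as.numeric(measured), nrow = nrow(tab$value),
                  dimnames = dimnames(tab$value))
      if (scheme == "balanced_binary") x <- .balance_binary(x, tab$label, seed)
      x
    },
    reference_category = {
      x <- tab$category
      x[is.na(x)] <- "missing"
      x
    },
    raw = tab$value,
    zscore = tab$z)
  list(features = feats, categorical = scheme == "reference_category",
      scheme = scheme, person_id = tab$person_id, label = tab$label,
      sex = tab$sex, age = tab$age, mode = tab$mode)
}

# mask positive indicators in the class with the higher per-column rate until
# class rates differ by < 1%; never flips a 0 to 1
.balance_binary <- function(x, label, seed) {
  with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      for (swap in 1:2) {
        hi <- if (swap == 1) label == 1L else label == 0L
        lo <- !hi
        r_hi <- mean(x[hi, j])
        r_lo <- mean(x[lo, j])
        if (r_hi - r_lo >= 0.01) {
          n_hi <- sum(hi)
          k <- floor((r_hi - r_lo - 0.01) * n_hi) + 1L
          ones <- which(hi & x[, j] == 1)
          k <- min(k, length(ones))
          x[sample(ones, k), j] <- 0
        }
      }
    }
    x
  })
}

#' Add one-hot ICD-10 block features
#'
#' One indicator column per retained 3-character ICD-10 block among events
#' dated strictly before the person's index date. Excluded prefixes (the
#' index and related diagnoses) are removed before encoding. The column
#' schema can be fixed (e.g. on the training split) via `blocks`.
#'
#' @param enc Encoded table from [encode_table()].
#' @param events Events data.frame.
#' @param cohort Cohort data.frame (for index dates).
#' @param excluded Excluded code prefixes (default I60-I64).
#' @param blocks Optional fixed character vector of blocks (column schema).
#' @return `enc` with an added numeric matrix `icd10` (and `icd10_blocks`).
#' @export
add_icd10_features <- function(enc, events, cohort,
                               excluded = c("I60", "I61", "I62", "I63", "I64"),
                               blocks = NULL) {
  ev <- events[events$code_type == "ICD10", , drop = FALSE]
  m <- match(ev$person_id, cohort$person_id)
  keep <- !is.na(m) & ev$date < cohort$index_date[m]
  ev <- ev[keep, , drop = FALSE]
  blk <- substr(ev$code, 1, 3)
  drop <- icd10_prefix_match(blk, excluded)
  ev <- ev[!drop, , drop = FALSE]
  blk <- blk[!drop]
  if (is.null(blocks)) blocks <- sort(unique(blk))
  x <- matrix(0, nrow = length(enc$person_id), ncol = length(blocks),
              dimnames = list(NULL, paste0("ICD10_", blocks)))
  if (length(blocks) > 0 && nrow(ev) > 0) {
    ri <- match(ev$person_id, enc$person_id)
    # measurement mode repeats persons; mark every row of the person
    per_block <- split(ev$person_id, factor(blk, levels = blocks))
    for (b in seq_along(blocks)) {
      x[enc$person_id %in% per_block[[b]], b] <- 1
    }
  }
  enc$icd10 <- x
  enc$icd10_blocks <- blocks
  enc
}

# build numeric model frame: analyte features (+ optional one-hot), sex/age,
# imputing numeric NAs with training medians computed on train rows only
.model_frames <- function(enc, train, test, onehot) {
  f <- enc$features
  if (enc$categorical) {
    lv <- c("below", "within", "above", "unknown", "missing")
    if (onehot) {
      cols <- list()
      for (j in seq_len(ncol(f))) {
        for (l in lv[-length(lv)]) {
          cols[[paste0(colnames(f)[j], "=", l)]] <- as.numeric(f[, j] == l)
        }
      }
      X <- do.call(cbind, cols)
    } else {
      X <- as.data.frame(f, stringsAsFactors = FALSE, optional = TRUE)
      for (j in seq_along(X)) X[[j]] <- factor(X[[j]], levels = lv)
      names(X) <- make.names(colnames(f))
    }
  } else {
    X <- f
    med <- apply(X[train, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- med[j]
    }
  }
  sexn <- as.numeric(enc$sex == "male")
  if (is.data.frame(X)) {
    X$sex <- sexn
    X$age <- enc$age
    if (!is.null(enc$icd10)) X <- cbind(X, as.data.frame(enc$icd10))
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
  } else {
    X <- cbind(X, sex = sexn, age = enc$age)
    if (!is.null(enc$icd10)) X <- cbind(X, enc$icd10)
    colnames(X) <- make.names(colnames(X), unique = TRUE)
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
  }
  list(train = Xtr, test = Xte)
}

# grouped, label-stratified person-level split
.person_split <- function(enc, train_frac, seed) {
  ids <- unique(enc$person_id)
  lab <- enc$label[match(ids, enc$person_id)]
  with_seed(seed, {
    tr_ids <- character(0)
    for (l in unique(lab)) {
      g <- ids[lab == l]
      n_tr <- max(1L, round(train_frac * length(g)))
      n_tr <- min(n_tr, length(g) - 1L)
      tr_ids <- c(tr_ids, sample(g, n_tr))
    }
    train <- which(enc$person_id %in% tr_ids)
    test <- setdiff(seq_along(enc$person_id), train)
    list(train = train, test = test)
  })
}

.metrics <- function(label, score) {
  pred <- as.integer(score >= 0.5)
  acc <- mean(pred == label)
  prec <- if (sum(pred) == 0) NA_real_ else
    sum(pred == 1 & label == 1) / sum(pred == 1)
  list(accuracy = acc, precision = prec,
       auc = auc_rank(label, score))
}

# fit one model and return test-set case probabilities
.fit_predict <- function(model, Xtr, ytr, Xte, k = 15, ntree = 500,
                         mtry = NULL, nodesize = 1, seed = 1) {
  with_seed(seed, {
    if (model == "LR") {
      dtr <- as.data.frame(Xtr)
      dte <- as.data.frame(Xte)
      names(dte) <- names(dtr) <- make.names(names(dtr), unique = TRUE)
      dtr$.y <- ytr
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dtr,
                                         family = stats::binomial()))
      list(score = suppressWarnings(
             unname(stats::predict(fit, newdata = dte, type = "response"))),
           fit = fit)
    } else if (model == "KNN") {
      Xtr <- as.matrix(as.data.frame(lapply(as.data.frame(Xtr), as.numeric)))
      Xte <- as.matrix(as.data.frame(lapply(as.data.frame(Xte), as.numeric)))
      pr <- class::knn(Xtr, Xte, factor(ytr, levels = c(0, 1)), k = k,
                       prob = TRUE)
      p_win <- attr(pr, "prob")
      score <- ifelse(pr == "1", p_win, 1 - p_win)
      list(score = score, fit = NULL)
    } else if (model == "RF") {
      ytrf <- factor(ytr, levels = c(0, 1))
      if (is.matrix(Xtr)) {
        Xtr <- as.data.frame(Xtr)
        Xte <- as.data.frame(Xte)
      }
      args <- list(x = Xtr, y = ytrf, ntree = ntree, nodesize = nodesize)
      if (!is.null(mtry)) args$mtry <- mtry
      fit <- do.call(randomForest::randomForest, args)
      list(score = unname(stats::predict(fit, Xte, type = "prob")[, "1"]),
           fit = fit)
    } else stop("unknown model: ", model)
  })
}

#' Sex+age-only baseline model
#'
#' Random forest on sex and age alone, evaluated on a held-out split.
#'
#' @param sex,age,label Per-row vectors.
#' @param train_frac Training fraction (default 0.95).
#' @param seed Integer seed.
#' @return List with `accuracy`, `precision`, `auc`, `model = "RF"`,
#'   `encoding = "baseline"`.
#' @export
baseline_model <- function(sex, age, label, train_frac = 0.95, seed = 1) {
  enc <- list(features = matrix(numeric(0), nrow = length(label), ncol = 0),
              categorical = FALSE, person_id = as.character(seq_along(label)),
              label = label, sex = sex, age = age, mode = "individual")
  sp <- .person_split(enc, train_frac, seed)
  if (length(unique(label[sp$train])) < 2 ||
      length(unique(label[sp$test])) < 2)
    stop("degenerate split: both classes required in train and test")
  mf <- .model_frames(enc, sp$train, sp$test, onehot = TRUE)
  r <- .fit_predict("RF", mf$train, label[sp$train], mf$test, seed = seed)
  c(.metrics(label[sp$test], r$score),
    list(model = "RF", encoding = "baseline"))
}

#' Train and evaluate one model on an encoded table
#'
#' Person-level label-stratified split (grouped, so measurement-based rows of
#' one person never span train and test), training-median imputation for
#' numeric encodings, one-hot expansion of the categorical encoding for
#' LR/KNN, all randomness seeded.
#'
#' @param model `"LR"`, `"KNN"` or `"RF"`.
#' @param enc Encoded table from [encode_table()] (optionally with ICD-10
#'   features).
#' @param train_frac Training fraction (default 0.95).
#' @param seed Integer seed.
#' @param k KNN neighbours (default 15).
#' @param ntree RF trees (default 500).
#' @param mtry,nodesize Optional RF hyperparameters.
#' @return List: `accuracy`, `precision`, `auc`, `model`, `encoding`,
#'   `fit`, `split`, `test_label`, `test_score`, plus the model frames for
#'   importance computation.
#' @export
train_eval <- function(model = c("LR", "KNN", "RF"), enc, train_frac = 0.95,
                       seed = 1, k = 15, ntree = 500, mtry = NULL,
                       nodesize = 1) {
  model <- match.arg(model)
  sp <- .person_split(enc, train_frac, seed)
  ytr <- enc$label[sp$train]
  yte <- enc$label[sp$test]
  if (length(unique(ytr)) < 2)
    stop("degenerate split: single-class training partition")
  mf <- .model_frames(enc, sp$train, sp$test, onehot = model != "RF")
  r <- .fit_predict(model, mf$train, ytr, mf$test, k = k, ntree = ntree,
                    mtry = mtry, nodesize = nodesize, seed = seed + 1L)
  c(.metrics(yte, r$score),
    list(model = model, encoding = enc$scheme, fit = r$fit, split = sp,
         test_label = yte, test_score = r$score, frames = mf, k = k,
         ntree = ntree, mtry = mtry, nodesize = nodesize, seed = seed))
}

#' Grid search with stratified k-fold cross-validation
#'
#' Hyperparameters are selected on the training partition only (default 90%
#' of persons) by stratified k-fold cross-validated AUC; the best point is
#' refit on the full training partition and evaluated once on the held-out
#' rows.
#'
#' @param model `"LR"`, `"KNN"` or `"RF"`.
#' @param enc Encoded table.
#' @param grid data.frame of hyperparameter combinations (columns among
#'   `k`, `ntree`, `mtry`, `nodesize`); must be non-empty.
#' @param folds Number of folds (default 10).
#' @param train_frac Training partition fraction (default 0.9).
#' @param seed Integer seed.
#' @return List: `best` (grid row), `cv` (grid with `mean_auc`, `sd_auc`),
#'   `test` (final held-out metrics).
#' @export
cross_validate_grid <- function(model, enc, grid, folds = 10,
                                train_frac = 0.9, seed = 1) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")
  stopifnot(folds >= 2)
  sp <- .person_split(enc, train_frac, seed)
  tr_ids <- unique(enc$person_id[sp$train])
  tr_lab <- enc$label[match(tr_ids, enc$person_id)]
  fold_of <- with_seed(seed + 1L, {
    f <- integer(length(tr_ids))
    for (l in unique(tr_lab)) {
      g <- which(tr_lab == l)
      f[g[sample.int(length(g))]] <- rep_len(seq_len(folds), length(g))
    }
    f
  })
  args_of <- function(row) {
    a <- as.list(grid[row, , drop = FALSE])
    a[vapply(a, function(v) !is.na(v), logical(1))]
  }
  cv_mean <- cv_sd <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    aucs <- numeric(folds)
    for (fd in seq_len(folds)) {
      va_ids <- tr_ids[fold_of == fd]
      tr2 <- which(enc$person_id %in% setdiff(tr_ids, va_ids))
      va <- which(enc$person_id %in% va_ids)
      mf <- .model_frames(enc, tr2, va, onehot = model != "RF")
      a <- args_of(gi)
      r <- do.call(.fit_predict,
                   c(list(model = model, Xtr = mf$train,
                          ytr = enc$label[tr2], Xte = mf$test,
                          seed = seed + 10L + fd), a))
      aucs[fd] <- auc_rank(enc$label[va], r$score)
    }
    cv_mean[gi] <- mean(aucs)
    cv_sd[gi] <- stats::sd(aucs)
  }
  best_i <- which.max(cv_mean)
  mf <- .model_frames(enc, sp$train, sp$test, onehot = model != "RF")
  r <- do.call(.fit_predict,
               c(list(model = model, Xtr = mf$train,
                      ytr = enc$label[sp$train], Xte = mf$test,
                      seed = seed + 99L), args_of(best_i)))
  cv <- cbind(grid, mean_auc = cv_mean, sd_auc = cv_sd)
  list(best = grid[best_i, , drop = FALSE], cv = cv,
       test = c(.metrics(enc$label[sp$test], r$score),
                list(model = model, fit = r$fit)))
}

#' Feature importance for a fitted benchmark model
#'
#' `gini`: mean decrease in node impurity (random forest only).
#' `permutation`: mean held-out AUC drop over `r` shuffles per feature.
#'
#' @param result A [train_eval()] result.
#' @param method `"gini"` or `"permutation"`.
#' @param r Shuffles per feature for permutation (default 10).
#' @param seed Integer seed.
#' @return data.frame `feature`, `score`, sorted descending.
#' @export
feature_importance <- function(result, method = c("gini", "permutation"),
                               r = 10, seed = 1) {
  method <- match.arg(method)
  if (method == "gini") {
    if (!inherits(result$fit, "randomForest"))
      stop("gini importance requires a random-forest fit")
    imp <- randomForest::importance(result$fit, type = 2)
    out <- data.frame(feature = rownames(imp), score = unname(imp[, 1]),
                      stringsAsFactors = FALSE)
  } else {
    Xte <- result$frames$test
    yte <- result$test_label
    base <- auc_rank(yte, result$test_score)
    feats <- colnames(Xte)
    score <- numeric(length(feats))
    with_seed(seed, {
      for (j in seq_along(feats)) {
        drops <- numeric(r)
        for (b in seq_len(r)) {
          Xp <- Xte
          if (is.data.frame(Xp)) Xp[[j]] <- sample(Xp[[j]])
          else Xp[, j] <- sample(Xp[, j])
          sc <- .refit_score(result, Xp)
          drops[b] <- base - auc_rank(yte, sc)
        }
        score[j] <- mean(drops)
      }
    })
    out <- data.frame(feature = feats, score = score, stringsAsFactors = FALSE)
  }
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}

# score permuted held-out rows with the already-fitted model
.refit_score <- function(result, Xp) {
  if (result$model == "RF") {
    unname(stats::predict(result$fit, as.data.frame(Xp),
                          type = "prob")[, "1"])
  } else if (result$model == "LR") {
    d <- as.data.frame(Xp)
    names(d) <- make.names(names(d), unique = TRUE)
    suppressWarnings(unname(stats::predict(result$fit, newdata = d,
                                           type = "response")))
  } else {
    stop("permutation importance requires a persistent fit (LR or RF)")
  }
}
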