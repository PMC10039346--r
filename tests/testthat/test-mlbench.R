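# small adjusted+windowed scenario reused across benchmark tests
bench_fixture <- function(seed = 31, n_cases = 120, n_pool = 800) {
  sim <- sim_scenario(n_cases = n_cases, n_pool = n_pool, seed = seed)
  coh <- suppressWarnings(build_cohort(sim$persons, sim$events, ratio = 4,
                                       seed = seed + 1))
  adj <- prepare_adjusted(sim$measurements, coh, sim$persons,
                          window_days = 1000)
  coh <- min_cp_filter(coh, adj)
  adj <- adj[adj$person_id %in% coh$person_id, ]
  list(sim = sim, cohort = coh, adj = adj)
}

fx <- bench_fixture()

test_that("tabularisation agrees with latest-per-person and row semantics", {
  tab_i <- tabularize(fx$adj, fx$cohort, "individual")
  expect_equal(length(tab_i$person_id), nrow(fx$cohort))
  latest <- latest_per_person_by_key(fx$adj)
  # every cell equals the latest observation for that (person, analyte)
  for (i in with_seed(1, sample(seq_len(nrow(latest)), 50))) {
    expect_equal(tab_i$value[latest$person_id[i], latest$key[i]],
                 latest$value[i])
  }
  # unmeasured cells are absent
  expect_true(anyNA(tab_i$value))
  tab_m <- tabularize(fx$adj, fx$cohort, "measurement")
  n_in_cohort <- sum(fx$adj$person_id %in% fx$cohort$person_id)
  expect_equal(length(tab_m$person_id), n_in_cohort)
  # one person with k measurements of one analyte contributes k rows
  p1 <- fx$adj$person_id[1]
  expect_equal(sum(tab_m$person_id == p1), sum(fx$adj$person_id == p1))
})

test_that("encodings implement the five schemes", {
  tab <- tabularize(fx$adj, fx$cohort, "individual")
  bin <- encode_table(tab, "binary")
  expect_true(all(bin$features %in% c(0, 1)))
  expect_equal(unname(bin$features[!is.na(tab$value)][1]), 1)
  raw <- encode_table(tab, "raw")
  expect_equal(raw$features, tab$value)
  zs <- encode_table(tab, "zscore")
  expect_equal(zs$features, tab$z)
  rc <- encode_table(tab, "reference_category")
  expect_true(all(rc$features %in% c("below", "within", "above", "unknown",
                                     "missing")))
  expect_true(rc$categorical)
})

test_that("balanced binary equalises class rates and never flips 0 to 1", {
  tab <- tabularize(fx$adj, fx$cohort, "individual")
  bin <- encode_table(tab, "binary")
  bal <- encode_table(tab, "balanced_binary", seed = 5)
  expect_true(all(bal$features <= bin$features))  # only 1 -> 0 masking
  for (j in seq_len(ncol(bal$features))) {
    r1 <- mean(bal$features[tab$label == 1, j])
    r0 <- mean(bal$features[tab$label == 0, j])
    expect_lt(abs(r1 - r0), 0.01)
  }
})

test_that("ICD-10 features exclude index-related codes and mark comorbidities", {
  tab <- tabularize(fx$adj, fx$cohort, "individual")
  enc <- encode_table(tab, "binary")
  enc <- add_icd10_features(enc, fx$sim$events, fx$cohort)
  expect_false(any(grepl("I6[0-4]", colnames(enc$icd10))))
  # a person with a pre-index E11 event gets a 1 in the E11 block
  evs <- fx$sim$events
  m <- match(evs$person_id, fx$cohort$person_id)
  pre <- evs[!is.na(m) & evs$code == "E11" &
               evs$date < fx$cohort$index_date[m], ]
  if (nrow(pre) > 0 && "ICD10_E11" %in% colnames(enc$icd10)) {
    rows <- which(enc$person_id %in% pre$person_id)
    expect_true(all(enc$icd10[rows, "ICD10_E11"] == 1))
  }
  # schema can be fixed externally (train-defined columns)
  enc2 <- add_icd10_features(encode_table(tab, "binary"), fx$sim$events,
                             fx$cohort, blocks = c("E11", "ZZZ"))
  expect_equal(colnames(enc2$icd10), c("ICD10_E11", "ICD10_ZZZ"))
  expect_true(all(enc2$icd10[, "ICD10_ZZZ"] == 0))
})

test_that("baseline behaves at chance on independent labels and separates on age", {
  with_seed(7, {
    n <- 3000
    sex <- sample(c("male", "female"), n, TRUE)
    age <- stats::runif(n, 40, 90)
    y <- stats::rbinom(n, 1, 0.3)
  })
  r <- baseline_model(sex, age, y, seed = 8)
  expect_gt(r$auc, 0.42)
  expect_lt(r$auc, 0.58)
  y2 <- as.integer(age > 65)
  r2 <- baseline_model(sex, age, y2, seed = 9)
  expect_gte(r2$auc, 0.99)
})

test_that("training is deterministic given the seed and leak-free on medians", {
  tab <- tabularize(fx$adj, fx$cohort, "individual")
  enc <- encode_table(tab, "raw")
  a <- train_eval("RF", enc, seed = 11, ntree = 150)
  b <- train_eval("RF", enc, seed = 11, ntree = 150)
  expect_equal(a[c("accuracy", "precision", "auc")],
               b[c("accuracy", "precision", "auc")])
  # imputation medians computed on the training rows only
  sp <- a$split
  med_train <- apply(enc$features[sp$train, , drop = FALSE], 2,
                     stats::median, na.rm = TRUE)
  j <- 1
  nas_te <- which(is.na(enc$features[sp$test, j]))
  if (length(nas_te) > 0) {
    expect_true(all(a$frames$test[nas_te, j] == med_train[j]))
  }
})

test_that("shuffled labels yield chance-level test AUC", {
  tab <- tabularize(fx$adj, fx$cohort, "individual")
  enc <- encode_table(tab, "binary")
  enc$label <- with_seed(13, sample(enc$label))
  r <- train_eval("RF", enc, seed = 14, ntree = 200)
  expect_gt(r$auc, 0.3)
  expect_lt(r$auc, 0.7)
})

test_that("informative missingness makes binary features predictive over baseline", {
  tab <- tabularize(fx$adj, fx$cohort, "individual")
  enc <- encode_table(tab, "binary")
  r <- train_eval("RF", enc, seed = 15)
  b <- baseline_model(tab$sex, tab$age, tab$label, seed = 15)
  expect_gte(r$auc - b$auc, 0.1)
})

test_that("grid search selects the argmax and is fold-reproducible", {
  tab <- tabularize(fx$adj, fx$cohort, "individual")
  enc <- encode_table(tab, "binary")
  grid1 <- data.frame(ntree = 100)
  g1 <- cross_validate_grid("RF", enc, grid1, folds = 3, seed = 21)
  expect_equal(g1$best$ntree, 100)
  grid2 <- data.frame(ntree = c(50, 150))
  g2 <- cross_validate_grid("RF", enc, grid2, folds = 3, seed = 21)
  expect_equal(g2$best$ntree,
               grid2$ntree[which.max(g2$cv$mean_auc)])
  g3 <- cross_validate_grid("RF", enc, grid2, folds = 3, seed = 21)
  expect_equal(g2$cv, g3$cv)
  expect_error(cross_validate_grid("RF", enc, data.frame(), folds = 3,
                                   seed = 1), "empty")
})

test_that("feature importance ranks a planted signal first under both methods", {
  with_seed(41, {
    n <- 1200
    x <- matrix(stats::rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- stats::rbinom(n, 1, stats::plogis(2 * x[, 3]))
  })
  enc <- list(features = x, categorical = FALSE, scheme = "raw",
              person_id = as.character(seq_len(n)), label = y,
              sex = rep(c("male", "female"), length.out = n),
              age = rep(60, n), mode = "individual")
  r <- train_eval("RF", enc, train_frac = 0.8, seed = 42, ntree = 200)
  gini <- feature_importance(r, "gini")
  expect_equal(gini$feature[1], "f3")
  perm <- feature_importance(r, "permutation", seed = 43)
  expect_equal(perm$feature[1], "f3")
  expect_equal(nrow(perm), ncol(r$frames$test))
  # pure-noise features have near-zero permutation importance
  noise <- perm$score[!perm$feature %in% c("f3")]
  expect_lt(max(abs(noise)), 0.05)
  expect_error(feature_importance(train_eval("KNN", enc, train_frac = 0.8,
                                             seed = 44), "gini"),
               "random-forest")
})

test_that("rank AUC agrees with pROC", {
  with_seed(51, {
    y <- stats::rbinom(200, 1, 0.4)
    s <- stats::rnorm(200) + y
  })
  expect_equal(auc_rank(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})
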