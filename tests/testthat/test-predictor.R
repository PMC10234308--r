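test_that("split plan partitions ids with stratified, reproducible test sets", {
  set.seed(2)
  ids <- sprintf("id%04d", 1:1000)
  labels <- c(rep(1L, 300), rep(0L, 700))[sample(1000)]
  names(labels) <- NULL
  plan <- make_split_plan(ids, labels, n_iter = 10, seed = 77)

  tests <- split(plan$sno_id[plan$set == "test"],
                 plan$iteration[plan$set == "test"])
  expect_equal(length(tests), 10)
  expect_true(all(lengths(tests) == 100))
  # disjoint and covering (set-algebra oracle)
  expect_equal(sort(unlist(tests, use.names = FALSE)), sort(ids))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(length(intersect(tests[[i]], tests[[j]])), 0)
  }
  # stratification: 30 +/- 1 positives per test set
  pos_per_set <- vapply(tests, function(s) sum(labels[match(s, ids)]), numeric(1))
  expect_true(all(abs(pos_per_set - 30) <= 1))
  # within an iteration the three sets are disjoint and cover all ids
  for (i in c(1, 5, 10)) {
    it <- plan[plan$iteration == i, ]
    expect_equal(sort(it$sno_id), sort(ids))
    expect_equal(anyDuplicated(it$sno_id), 0)
  }
  # tuning/training fractions roughly 10/80
  expect_equal(sum(plan$set == "tuning" & plan$iteration == 1), 100,
               tolerance = 0.05)

  # deterministic regeneration
  plan2 <- make_split_plan(ids, labels, n_iter = 10, seed = 77)
  expect_identical(plan, plan2)
  plan3 <- make_split_plan(ids, labels, n_iter = 10, seed = 78)
  expect_false(identical(plan, plan3))
})

test_that("tiny cohorts still yield singleton-style stratified plans", {
  ids <- letters[1:10]
  labels <- rep(c(0L, 1L), 5)
  expect_warning(plan <- make_split_plan(ids, labels, n_iter = 10, seed = 1),
                 "fewer than")
  tests <- split(plan$sno_id[plan$set == "test"],
                 plan$iteration[plan$set == "test"])
  expect_true(all(lengths(tests) == 1))
  expect_equal(sort(unlist(tests, use.names = FALSE)), sort(ids))
})

test_that("grid tuning picks separating hyperparameters and matches re-evaluation", {
  toy <- toy_classif(n = 60, seed = 10)
  # single-point grid returns that point
  one <- tune_model("knn", tibble::tibble(k = 5L), toy$x, toy$y, seed = 3)
  expect_equal(one$params$k, 5L)

  # a local neighbourhood separates the clouds; voting over (almost) the
  # whole training fold cannot do better than the majority class
  toy2 <- toy_classif(n = 90, seed = 17)
  grid <- tibble::tibble(k = c(59L, 3L))
  tn <- tune_model("knn", grid, toy2$x, toy2$y, seed = 3)
  expect_equal(tn$params$k, 3L)

  # ties resolve to the earlier grid row: on separable data every ridge
  # strength classifies perfectly, so the first lambda must be returned
  lgrid <- tibble::tibble(lambda = c(1e4, 1e-3))
  tl <- tune_model("logistic_regression", lgrid, toy$x, toy$y, seed = 3)
  expect_equal(tl$grid_accuracy, c(1, 1))
  expect_equal(tl$params$lambda, 1e4)

  # brute-force re-evaluation of every grid point with the same folds
  fold <- stratified_folds(toy2$y, 3, snostatus:::derive_seed(3, 7L))
  manual <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(1:3, function(f) {
      tr <- fold != f
      m <- snostatus:::fit_family("knn", grid[g, ],
                                  toy2$x[tr, ], toy2$y[tr],
                                  snostatus:::derive_seed(3, 13L * g + f))
      mean(predict_status(m, toy2$x[!tr, ]) == toy2$y[!tr])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(tn$grid_accuracy, manual)
})

test_that("model families are deterministic under a fixed seed and fit separable data", {
  toy <- toy_classif(n = 80, seed = 4)
  for (fam in c("logistic_regression", "svm", "random_forest",
                "knn", "gradient_boosting")) {
    params <- model_specs()[[fam]][1, ]
    m1 <- snostatus:::fit_family(fam, params, toy$x, toy$y, seed = 9)
    m2 <- snostatus:::fit_family(fam, params, toy$x, toy$y, seed = 9)
    expect_identical(predict_scores(m1, toy$x), predict_scores(m2, toy$x))
    expect_gte(mean(predict_status(m1, toy$x) == toy$y), 0.95)
  }
  # logistic family: training accuracy 100% on separable data
  ml <- snostatus:::fit_family("logistic_regression",
                               tibble::tibble(lambda = 1e-4), toy$x, toy$y, 1)
  expect_equal(mean(predict_status(ml, toy$x) == toy$y), 1)
  # duplicating every row leaves the (deterministic) logistic fit unchanged
  md <- snostatus:::fit_family("logistic_regression",
                               tibble::tibble(lambda = 1e-4),
                               rbind(toy$x, toy$x), c(toy$y, toy$y), 1)
  expect_equal(predict_scores(md, toy$x), predict_scores(ml, toy$x),
               tolerance = 1e-6)
})

test_that("ensemble vote is the majority over exactly three models", {
  combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  got <- ensemble_vote(as.matrix(combos))
  oracle <- as.integer(rowSums(combos) >= 2)
  expect_equal(got, oracle)
  expect_error(ensemble_vote(as.matrix(combos[, 1:2])), "three votes")
  # the ensemble disagrees with a model only when the other two agree against it
  for (r in seq_len(nrow(combos))) {
    v <- as.integer(combos[r, ])
    for (k in 1:3) {
      if (got[r] != v[k]) expect_true(all(v[-k] == got[r]))
    }
  }
})

test_that("metrics identities hold and AUC matches the concordance oracle", {
  # perfect scores
  perfect <- tibble::tibble(truth = c(1, 1, 0, 0),
                            ensemble_status = c(1, 1, 0, 0),
                            ensemble_score = c(0.9, 0.8, 0.2, 0.1))
  m <- confusion_and_metrics(perfect)
  expect_equal(m$auc, 1)
  expect_equal(m$accuracy, 1)

  # label-independent scores: AUC ~ 0.5 at n = 10,000
  set.seed(6)
  null <- tibble::tibble(truth = rbinom(10000, 1, 0.4),
                         ensemble_status = rbinom(10000, 1, 0.5),
                         ensemble_score = runif(10000))
  expect_equal(confusion_and_metrics(null)$auc, 0.5, tolerance = 0.02)

  # small record set: trapezoid AUC equals the Mann-Whitney identity
  set.seed(16)
  small <- tibble::tibble(truth = rbinom(40, 1, 0.5),
                          ensemble_score = round(runif(40), 1))  # forces ties
  small$ensemble_status <- as.integer(small$ensemble_score > 0.5)
  ms <- confusion_and_metrics(small)
  expect_equal(ms$auc, oracle_auc(small$ensemble_score, small$truth))

  # count identities
  cc <- ms$counts
  expect_equal(ms$accuracy, unname((cc["TP"] + cc["TN"]) / 40))
  expect_equal(ms$sensitivity, unname(cc["TP"] / (cc["TP"] + cc["FN"])))
  expect_equal(ms$specificity, unname(cc["TN"] / (cc["TN"] + cc["FP"])))

  # single-class truth: AUC undefined
  mono <- tibble::tibble(truth = c(1, 1), ensemble_status = c(1, 0),
                         ensemble_score = c(0.6, 0.4))
  expect_true(is.na(confusion_and_metrics(mono)$auc))
})

test_that("cross-species prediction reuses human scaling and reproduces in-sample calls", {
  toy <- toy_classif(n = 100, seed = 13)
  human <- tibble::tibble(sno_id = sprintf("h%03d", 1:100), label = toy$y,
                          f1 = toy$x[, 1], f2 = toy$x[, 2])
  stats <- fit_scaler(human)
  scaled <- apply_scaler(stats, human)
  x <- snostatus:::features_matrix(scaled)
  model <- snostatus:::fit_family("logistic_regression",
                                  tibble::tibble(lambda = 0.01),
                                  x, human$label, seed = 42)
  insample <- as.integer(predict_scores(model, x) > 0.5)

  # species table identical to the human rows: identical predictions
  species <- human |> dplyr::select(-"label")
  res <- cross_species_predict(model, stats, species)
  expect_equal(res$predictions$status, insample)
  expect_equal(res$proportion_expressed, mean(insample))

  expect_error(cross_species_predict(model, stats,
                                     species |> dplyr::rename(zz = "f1")),
               "do not match")

  # proportions anti-ordered with totals give a negative correlation
  summ <- tibble::tibble(n_annotated = c(100, 500, 2000),
                         proportion_expressed = c(0.5, 0.3, 0.1))
  expect_lt(proportion_count_correlation(summ), 0)
})

test_that("tune/train splits for species transfer are stratified and seeded", {
  ids <- sprintf("h%03d", 1:300)
  labels <- rep(c(0L, 1L), c(200, 100))
  sp <- make_tune_train_split(ids, labels, tune_frac = 0.1, seed = 42)
  expect_equal(sort(sp$sno_id), sort(ids))
  expect_equal(sum(sp$set == "tuning"), 30)
  tune_pos <- sum(labels[match(sp$sno_id[sp$set == "tuning"], ids)])
  expect_lte(abs(tune_pos - 10), 1)
  expect_identical(sp, make_tune_train_split(ids, labels, seed = 42))
})

test_that("every snoRNA is predicted exactly once across iterations", {
  toy <- toy_classif(n = 120, seed = 21)
  enc <- tibble::tibble(sno_id = sprintf("s%03d", 1:120), label = toy$y,
                        f1 = toy$x[, 1], f2 = toy$x[, 2],
                        f3 = rnorm(120))
  fit <- fit_expression_models(enc, n_iter = 10,
                               families = c("logistic_regression", "svm",
                                            "random_forest"),
                               seed = 31)
  expect_equal(sort(fit$predictions$sno_id), sort(enc$sno_id))
  expect_equal(anyDuplicated(fit$predictions$sno_id), 0)
  # confusion category consistent with (ensemble, truth)
  with(fit$predictions, {
    expect_true(all(confusion[ensemble_status == 1 & truth == 1] == "TP"))
    expect_true(all(confusion[ensemble_status == 0 & truth == 0] == "TN"))
  })
  # byte-identical reproduction under the same seed
  fit2 <- fit_expression_models(enc, n_iter = 10,
                                families = c("logistic_regression", "svm",
                                             "random_forest"),
                                seed = 31)
  expect_identical(fit$predictions, fit2$predictions)
  # glance/tidy accessors
  g <- glance(fit)
  expect_equal(g$n, 120)
  expect_gte(g$accuracy, 0.9)
  expect_equal(nrow(tidy(fit)), 120)
})
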