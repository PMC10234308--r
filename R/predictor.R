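# Stratified multi-iteration ensemble classification of expression status.
#
# Ten stratified splits (tuning/training/test = 10/80/10%) whose test sets
# partition all snoRNAs, so every snoRNA is predicted exactly once. Five
# classifier families are tuned (grid search, stratified 3-fold CV),
# trained and tested per iteration; the final call is the majority vote of
# logistic regression, support vector machine and random forest (k-nearest
# neighbours and gradient boosting overfit and are excluded by default).

ENSEMBLE_FAMILIES <- c("logistic_regression", "svm", "random_forest")
ALL_FAMILIES <- c(ENSEMBLE_FAMILIES, "knn", "gradient_boosting")

#' Default hyperparameter grids per model family
#'
#' Modest, fully user-overridable defaults: ridge strength over 5
#' log-spaced values for logistic regression; kernel x cost for the SVM;
#' tree count x node size (3x3) for the random forest; k in {3, 5, 11} for
#' kNN; rounds x depth (3x3) for gradient boosting.
#'
#' @return named list: per family a tibble grid (one row per point, scanned
#'   in order; ties in tuning resolve to the earlier row).
#' @export
model_specs <- function() {
  list(
    logistic_regression = tibble(lambda = 10^seq(-4, 0, length.out = 5)),
    svm = tidyr::expand_grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10)),
    random_forest = tidyr::expand_grid(ntree = c(100L, 300L, 500L),
                                       nodesize = c(1L, 5L, 10L)),
    knn = tibble(k = c(3L, 5L, 11L)),
    gradient_boosting = tidyr::expand_grid(nrounds = c(50L, 100L, 150L),
                                           max_depth = c(2L, 3L, 4L))
  )
}

#' Stratified split plan over multiple iterations
#'
#' Shuffles ids within each class under `seed` and chops each class into
#' `n_iter` near-equal chunks: chunk i is the test set of iteration i, so
#' the test sets are disjoint and partition all ids. The remaining ids of
#' each iteration are split, again stratified, into tuning and training
#' sets at `fractions[1] : fractions[2]`.
#'
#' @param ids character vector of snoRNA ids.
#' @param labels 0/1 vector aligned with `ids`.
#' @param n_iter number of iterations (default 10).
#' @param fractions tuning/training/test fractions; the test fraction must
#'   equal 1/n_iter.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return tibble: `iteration`, `sno_id`, `set` in
#'   {"tuning", "training", "test"}.
#' @export
make_split_plan <- function(ids, labels, n_iter = 10L,
                            fractions = c(0.1, 0.8, 0.1), seed = 42L) {
  abort_if(abs(n_iter * fractions[3] - 1) > 1e-9,
           "n_iter x test fraction must equal 1")
  abort_if(length(unique(labels)) < 2, "both classes must be present")
  counts <- table(labels)
  if (any(counts < n_iter)) {
    warning(sprintf("a class has fewer than %d members; some test sets will miss it",
                    n_iter), call. = FALSE)
  }
  chunk_sizes <- function(n, k) {
    sz <- rep(n %/% k, k)
    if (n %% k > 0) sz[seq_len(n %% k)] <- sz[seq_len(n %% k)] + 1L
    sz
  }
  set.seed(derive_seed(seed, 1L))
  test_sets <- vector("list", n_iter)
  rot <- 0L  # rotate remainder chunks between classes to even out set sizes
  for (cls in sort(unique(labels))) {
    cl_ids <- sample(ids[labels == cls])
    sz <- chunk_sizes(length(cl_ids), n_iter)
    sz <- sz[((seq_len(n_iter) - 1L - rot) %% n_iter) + 1L]
    rot <- (rot + length(cl_ids) %% n_iter) %% n_iter
    brk <- cumsum(c(0L, sz))
    for (i in seq_len(n_iter)) {
      if (sz[i] > 0L) {
        test_sets[[i]] <- c(test_sets[[i]], cl_ids[(brk[i] + 1L):brk[i + 1L]])
      }
    }
  }
  tune_frac <- fractions[1] / (fractions[1] + fractions[2])
  purrr::map_dfr(seq_len(n_iter), function(i) {
    rest <- setdiff(ids, test_sets[[i]])
    rest_lab <- labels[match(rest, ids)]
    set.seed(derive_seed(seed, 100L + i))
    tune_ids <- unlist(lapply(sort(unique(rest_lab)), function(cls) {
      pool <- sample(rest[rest_lab == cls])
      pool[seq_len(max(1L, round(length(pool) * tune_frac)))]
    }))
    bind_rows(
      tibble(iteration = i, sno_id = test_sets[[i]], set = "test"),
      tibble(iteration = i, sno_id = tune_ids, set = "tuning"),
      tibble(iteration = i, sno_id = setdiff(rest, tune_ids), set = "training")
    )
  })
}

#' Stratified tuning/training split for cross-species transfer
#'
#' For applying a model to an external test set (another species), the
#' source snoRNAs are split into tuning and training sets only, stratified
#' by label (default 10% / 90%).
#'
#' @param ids,labels id vector and 0/1 labels.
#' @param tune_frac tuning fraction (default 0.1).
#' @param seed integer seed (42 is the documented default for selecting
#'   the cross-species model iteration).
#' @return tibble: `sno_id`, `set` in {"tuning", "training"}.
#' @export
make_tune_train_split <- function(ids, labels, tune_frac = 0.1, seed = 42L) {
  abort_if(length(unique(labels)) < 2, "both classes must be present")
  set.seed(derive_seed(seed, 5L))
  tune_ids <- unlist(lapply(sort(unique(labels)), function(cls) {
    pool <- sample(ids[labels == cls])
    pool[seq_len(max(1L, round(length(pool) * tune_frac)))]
  }))
  tibble(sno_id = ids,
         set = ifelse(ids %in% tune_ids, "tuning", "training"))
}

features_matrix <- function(tbl) {
  cols <- setdiff(names(tbl), c("sno_id", "label"))
  m <- as.matrix(tbl[cols])
  abort_if(!is.numeric(m), "feature table must be fully numeric (encode first)")
  rownames(m) <- tbl$sno_id
  m
}

# Fit one classifier family. Scores are always monotone in the probability
# of the expressed (positive = 1) class and mapped into [0, 1].
fit_family <- function(family, params, x, y, seed) {
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(
    family,
    # ridge logistic: fit a descending lambda path ending at the requested
    # strength (single-lambda glmnet fits are unreliable), predict at s
    # small-fold refits trip glmnet's sample-size warning routinely in
    # cross-validation; those warnings are expected and silenced
    logistic_regression = suppressWarnings(glmnet::glmnet(
      x, yf, family = "binomial", alpha = 0,
      lambda = unique(params$lambda * 10^seq(4, 0, length.out = 25)))),
    svm = e1071::svm(x, yf, kernel = params$kernel, cost = params$cost,
                     scale = FALSE),
    random_forest = randomForest::randomForest(x, yf, ntree = params$ntree,
                                               nodesize = params$nodesize),
    knn = list(train = x, cl = yf, k = params$k),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds),
    stop("unknown model family: ", family)
  )
  structure(list(family = family, params = params, fit = fit,
                 feature_names = colnames(x), seed = seed),
            class = "sno_model")
}

#' Positive-class score of a fitted model
#'
#' @param model a `sno_model` from the training protocol.
#' @param x numeric feature matrix with the model's feature columns.
#' @return numeric vector in [0, 1], monotone in P(expressed).
#' @export
predict_scores <- function(model, x) {
  x <- x[, model$feature_names, drop = FALSE]
  if (mean(abs(colMeans(x))) > 5) {
    warning("features look unscaled (|column mean| > 5)", call. = FALSE)
  }
  switch(
    model$family,
    logistic_regression = as.numeric(predict(model$fit, x, type = "response",
                                             s = model$params$lambda)),
    svm = {
      dv <- attr(predict(model$fit, x, decision.values = TRUE),
                 "decision.values")
      # decision values are oriented toward the first level in the colname
      flip <- startsWith(colnames(dv)[1], "1")
      stats::plogis(if (flip) dv[, 1] else -dv[, 1])
    },
    random_forest = unname(predict(model$fit, x, type = "prob")[, "1"]),
    knn = {
      set.seed(model$seed)
      pr <- class::knn(model$fit$train, x, model$fit$cl, k = model$fit$k,
                       prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    gradient_boosting = as.numeric(predict(
      model$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  )
}

#' Predicted expression status (0/1) of a fitted model
#' @inheritParams predict_scores
#' @return integer vector of 0/1 statuses (1 = expressed).
#' @export
predict_status <- function(model, x) {
  as.integer(predict_scores(model, x) > 0.5)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class under the seed and deals its members to folds in
#' round-robin order, keeping fold class ratios near the global ratio.
#'
#' @param y 0/1 label vector.
#' @param k fold count.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k) per element of `y`.
#' @export
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustive evaluation of the family's grid by mean accuracy over a
#' stratified 3-fold cross-validation of the tuning set; ties resolve to
#' the earlier grid row. With fewer than 2 members in the minority class
#' the first grid point is returned with a warning; the fold count never
#' exceeds the minority-class size.
#'
#' @param family model family name.
#' @param grid tibble of hyperparameter combinations.
#' @param x,y tuning-set feature matrix and 0/1 labels.
#' @param seed integer seed.
#' @param k_folds desired fold count (default 3).
#' @return list: `params` (best row), `cv_accuracy`, `grid_accuracy`.
#' @export
tune_model <- function(family, grid, x, y, seed, k_folds = 3L) {
  abort_if(length(unique(y)) < 2, "tuning set must contain both classes")
  k <- min(k_folds, min(table(y)))
  if (k < 2) {
    warning("tuning set too small for cross-validation; using first grid point",
            call. = FALSE)
    return(list(params = grid[1, ], cv_accuracy = NA_real_,
                grid_accuracy = rep(NA_real_, nrow(grid))))
  }
  fold <- stratified_folds(y, k, derive_seed(seed, 7L))
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      # some families need >= 2 members per class to fit at all
      if (length(unique(y[tr])) < 2 || min(table(y[tr])) < 2) return(NA_real_)
      m <- fit_family(family, grid[g, ], x[tr, , drop = FALSE], y[tr],
                      derive_seed(seed, 13L * g + f))
      mean(predict_status(m, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))
  if (!any(is.finite(acc))) {
    warning("tuning folds degenerate; using first grid point", call. = FALSE)
    return(list(params = grid[1, ], cv_accuracy = NA_real_,
                grid_accuracy = acc))
  }
  best <- which.max(acc)  # first maximum = earliest grid row
  list(params = grid[best, ], cv_accuracy = acc[best], grid_accuracy = acc)
}

#' Majority vote over the selected model families
#'
#' @param statuses integer matrix (rows = snoRNAs, one column per voting
#'   model; exactly three columns) of 0/1 statuses.
#' @return integer vector of 0/1 ensemble calls.
#' @export
ensemble_vote <- function(statuses) {
  statuses <- as.matrix(statuses)
  abort_if(ncol(statuses) != 3L, "ensemble_vote expects exactly three votes")
  as.integer(rowSums(statuses) >= 2L)
}

confusion_category <- function(predicted, truth) {
  dplyr::case_when(
    predicted == 1 & truth == 1 ~ "TP",
    predicted == 0 & truth == 0 ~ "TN",
    predicted == 1 & truth == 0 ~ "FP",
    TRUE ~ "FN"
  )
}

#' ROC curve points by threshold sweep
#'
#' @param scores numeric scores (higher = more likely expressed).
#' @param truth 0/1 truth vector.
#' @return tibble: `threshold`, `fpr`, `tpr`, starting at (0, 0).
#' @export
roc_points <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t); fp <- cumsum(1 - t)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(threshold = c(Inf, s[last]),
         fpr = c(0, fp[last] / max(sum(1 - truth), 1)),
         tpr = c(0, tp[last] / max(sum(truth), 1)))
}

#' Confusion counts and performance metrics
#'
#' Accuracy, sensitivity TP/(TP+FN), specificity TN/(TN+FP), confusion
#' counts, ROC points and trapezoidal AUC. The positive class is
#' `expressed`. AUC is NA when the truth contains a single class.
#'
#' @param predictions tibble with columns `truth` (0/1), a status column
#'   and a score column.
#' @param status_col,score_col column names (defaults: ensemble columns).
#' @return list: `counts`, `accuracy`, `sensitivity`, `specificity`,
#'   `roc` (tibble), `auc`.
#' @export
confusion_and_metrics <- function(predictions, status_col = "ensemble_status",
                                  score_col = "ensemble_score") {
  truth <- predictions$truth
  st <- predictions[[status_col]]
  conf <- confusion_category(st, truth)
  counts <- c(TP = sum(conf == "TP"), TN = sum(conf == "TN"),
              FP = sum(conf == "FP"), FN = sum(conf == "FN"))
  roc <- NULL; auc <- NA_real_
  if (length(unique(truth)) == 2 && !is.null(predictions[[score_col]])) {
    roc <- roc_points(predictions[[score_col]], truth)
    auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  }
  list(counts = counts,
       accuracy = unname((counts["TP"] + counts["TN"]) / length(truth)),
       sensitivity = unname(counts["TP"] / (counts["TP"] + counts["FN"])),
       specificity = unname(counts["TN"] / (counts["TN"] + counts["FP"])),
       roc = roc, auc = auc)
}

#' Run the full tuning/training/testing protocol
#'
#' For each iteration of the split plan: standardisation is fit on the
#' training rows and applied to all three sets, every requested family is
#' grid-tuned on the tuning set, trained on the training set and evaluated
#' on the test set. The ensemble call is the majority vote of the three
#' selected families; the ensemble score is the unweighted mean of their
#' positive-class scores.
#'
#' @param encoded one-hot encoded feature table with `sno_id` and `label`.
#' @param n_iter number of split iterations (default 10).
#' @param families families to fit (default all five).
#' @param ensemble_families the three voting families.
#' @param specs hyperparameter grids, see [model_specs()].
#' @param seed master seed; all per-iteration seeds derive from it.
#' @return a `sno_ensemble_fit`: list with `predictions` (one row per
#'   snoRNA: truth, per-family status/score, ensemble status/score,
#'   confusion), `models`, `scalers`, `tuned`, `split_plan`, `set_accuracy`
#'   (per family/iteration/set), and the call parameters.
#' @export
fit_expression_models <- function(encoded, n_iter = 10L,
                                  families = ALL_FAMILIES,
                                  ensemble_families = ENSEMBLE_FAMILIES,
                                  specs = model_specs(), seed = 42L) {
  abort_if(!all(c("sno_id", "label") %in% names(encoded)),
           "encoded table needs sno_id and label columns")
  plan <- make_split_plan(encoded$sno_id, encoded$label, n_iter = n_iter,
                          seed = seed)
  models <- list(); scalers <- list(); tuned <- list()
  preds <- list(); accs <- list()
  for (i in seq_len(n_iter)) {
    sets <- lapply(c(tuning = "tuning", training = "training", test = "test"),
                   function(s) {
                     ids <- plan$sno_id[plan$iteration == i & plan$set == s]
                     encoded[match(ids, encoded$sno_id), , drop = FALSE]
                   })
    sc <- fit_scaler(sets$training)
    scaled <- lapply(sets, function(tb) apply_scaler(sc, tb))
    xs <- lapply(scaled, features_matrix)
    scalers[[i]] <- sc
    it_status <- list(); it_score <- list()
    for (fam in families) {
      tn <- tune_model(fam, specs[[fam]], xs$tuning, sets$tuning$label,
                       seed = derive_seed(seed, 1000L * i + match(fam, ALL_FAMILIES)))
      m <- fit_family(fam, tn$params, xs$training, sets$training$label,
                      seed = derive_seed(seed, 2000L * i + match(fam, ALL_FAMILIES)))
      models[[paste(i, fam, sep = ".")]] <- m
      tuned[[paste(i, fam, sep = ".")]] <- tn$params
      it_score[[fam]] <- predict_scores(m, xs$test)
      it_status[[fam]] <- as.integer(it_score[[fam]] > 0.5)
      accs[[paste(i, fam, sep = ".")]] <- tibble(
        iteration = i, family = fam,
        set = c("tuning", "training", "test"),
        accuracy = vapply(c("tuning", "training", "test"), function(s) {
          mean(predict_status(m, xs[[s]]) == sets[[s]]$label)
        }, numeric(1)))
    }
    vote <- ensemble_vote(do.call(cbind, it_status[ensemble_families]))
    esc <- rowMeans(do.call(cbind, it_score[ensemble_families]))
    pr <- tibble(sno_id = sets$test$sno_id, iteration = i,
                 truth = sets$test$label)
    for (fam in families) {
      pr[[paste0(fam, "_status")]] <- it_status[[fam]]
      pr[[paste0(fam, "_score")]] <- it_score[[fam]]
    }
    pr$ensemble_status <- vote
    pr$ensemble_score <- esc
    pr$confusion <- confusion_category(vote, pr$truth)
    preds[[i]] <- pr
  }
  structure(list(predictions = bind_rows(preds) |> arrange(.data$sno_id),
                 models = models, scalers = scalers, tuned = tuned,
                 split_plan = plan, set_accuracy = bind_rows(accs),
                 families = families, ensemble_families = ensemble_families,
                 n_iter = n_iter, seed = seed),
            class = "sno_ensemble_fit")
}

#' @export
print.sno_ensemble_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sno_ensemble_fit> %d snoRNAs, %d iterations, families: %s\n",
    nrow(x$predictions), x$n_iter, paste(x$families, collapse = ", ")))
  cat(sprintf(
    "  ensemble accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %s\n",
    g$accuracy, g$sensitivity, g$specificity,
    ifelse(is.na(g$auc), "NA", sprintf("%.3f", g$auc))))
  invisible(x)
}

#' Predict expression status across species with a human-trained model
#'
#' Scales the species rows with the HUMAN training statistics and applies
#' the trained model; the species feature table must carry exactly the
#' model's feature columns (plus `sno_id`).
#'
#' @param model a `sno_model` (typically the logistic-regression model of
#'   the iteration seeded with 42).
#' @param scaling_stats the human training-set scaler from [fit_scaler()].
#' @param species_features encoded feature table of the species' snoRNAs.
#' @return list: `predictions` (tibble `sno_id`, `score`, `status`),
#'   `proportion_expressed`.
#' @export
cross_species_predict <- function(model, scaling_stats, species_features) {
  feat_cols <- setdiff(names(species_features), c("sno_id", "label"))
  abort_if(!setequal(feat_cols, model$feature_names),
           paste("species table columns do not match the model:",
                 paste(symdiff_chr(feat_cols, model$feature_names), collapse = ",")))
  scaled <- apply_scaler(scaling_stats, species_features)
  x <- features_matrix(scaled)[, model$feature_names, drop = FALSE]
  sc <- predict_scores(model, x)
  tibble(sno_id = species_features$sno_id, score = sc,
         status = as.integer(sc > 0.5)) -> pred
  list(predictions = pred, proportion_expressed = mean(pred$status))
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' Correlation of annotated snoRNA count with predicted expressed proportion
#'
#' Pearson correlation across species between the total number of annotated
#' snoRNAs and the (predicted) proportion that are expressed.
#'
#' @param species_summary tibble with columns `n_annotated` and
#'   `proportion_expressed` (one row per species).
#' @return Pearson correlation coefficient.
#' @export
proportion_count_correlation <- function(species_summary) {
  stats::cor(species_summary$n_annotated, species_summary$proportion_expressed,
             method = "pearson")
}
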