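fit_toy_model <- function(family, n = 80, seed = 2, p_extra = 0) {
  toy <- toy_classif(n = n, seed = seed)
  x <- toy$x
  if (p_extra > 0) {
    set.seed(seed + 1)
    extra <- matrix(rnorm(n * p_extra), n,
                    dimnames = list(NULL, paste0("z", seq_len(p_extra))))
    x <- cbind(x, extra)
  }
  params <- model_specs()[[family]][1, ]
  list(model = snostatus:::fit_family(family, params, x, toy$y, seed = 5),
       x = x, y = toy$y)
}

test_that("linear attributions follow the closed form w_j (x_j - mean bg_j)", {
  tm <- fit_toy_model("logistic_regression")
  bg <- tm$x[1:40, ]
  rows <- tm$x[41:50, ]
  at <- attribute(tm$model, rows, bg)
  w <- as.numeric(glmnet::coef.glmnet(tm$model$fit,
                                      s = tm$model$params$lambda))[-1]
  manual <- sweep(rows, 2, colMeans(bg)) %*% diag(w)
  expect_equal(unname(as.matrix(at$values)), unname(manual), tolerance = 1e-9)
  # additivity on the link scale
  link <- function(x) as.numeric(predict(tm$model$fit, x, type = "link",
                                         s = tm$model$params$lambda))
  expect_equal(at$baseline + rowSums(at$values), link(rows), tolerance = 1e-9)
  # a row equal to the background mean gets zero contributions
  mu <- matrix(colMeans(bg), 1, dimnames = list(NULL, colnames(bg)))
  at0 <- attribute(tm$model, mu, bg)
  expect_equal(unname(as.numeric(at0$values)), c(0, 0), tolerance = 1e-9)
  expect_equal(at0$output[1], at0$baseline, tolerance = 1e-9)
})

test_that("exact Shapley matches permutation enumeration and handles edge models", {
  # 3-feature model on an 8-point background grid
  f <- function(m) m[, 1] * 2 + m[, 2] * m[, 3] - 0.5 * m[, 3]
  grid <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  x_row <- matrix(c(1, 1, 1), 1, dimnames = list(NULL, c("a", "b", "c")))
  got <- shap_exact(f, x_row, grid)
  orc <- oracle_shapley_perms(f, x_row, grid)
  expect_equal(got$values, orc, tolerance = 1e-9)
  expect_equal(got$baseline + sum(got$values), got$output, tolerance = 1e-9)

  # constant model: all contributions zero
  cst <- shap_exact(function(m) rep(3.14, nrow(m)), x_row, grid)
  expect_equal(unname(cst$values), c(0, 0, 0))

  # symmetry: identical feature columns share credit equally
  fsym <- function(m) m[, 1] + m[, 2]
  xs <- matrix(c(1, 1, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  sym <- shap_exact(fsym, xs, grid[, c(1, 1, 3)] |>
                      `colnames<-`(c("a", "b", "c")))
  expect_equal(sym$values[["a"]], sym$values[["b"]], tolerance = 1e-9)
})

test_that("nonlinear model attributions are exact for few features and additive always", {
  tm <- fit_toy_model("random_forest")
  bg <- tm$x[1:30, ]
  rows <- tm$x[31:40, ]
  # p = 2 <= exact_max: full coalition enumeration inside attribute()
  at <- attribute(tm$model, rows, bg)
  f <- function(m) predict_scores(tm$model, m)
  for (i in 1:3) {
    orc <- oracle_shapley_perms(f, rows[i, , drop = FALSE], bg)
    expect_equal(unname(as.numeric(at$values[i, ])), unname(orc),
                 tolerance = 1e-9)
  }
  expect_equal(at$baseline + rowSums(at$values), f(rows), tolerance = 1e-6)

  # sampling mode (many features): additivity still holds exactly
  tm2 <- fit_toy_model("random_forest", p_extra = 10)
  bg2 <- tm2$x[1:25, ]
  rows2 <- tm2$x[26:31, ]
  at2 <- attribute(tm2$model, rows2, bg2, n_perm = 4, seed = 8)
  f2 <- function(m) predict_scores(tm2$model, m)
  expect_equal(at2$baseline + rowSums(at2$values), f2(rows2), tolerance = 1e-6)
  # deterministic given the seed
  at2b <- attribute(tm2$model, rows2, bg2, n_perm = 4, seed = 8)
  expect_identical(at2$values, at2b$values)
})

test_that("rank tables are per-iteration permutations ordered by mean |value|", {
  set.seed(14)
  long <- tidyr::expand_grid(family = c("m1", "m2"), iteration = 1:3,
                             sno_id = paste0("s", 1:20),
                             feature = c("f1", "f2", "f3")) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  rk <- rank_features(long)
  # ranks are a permutation of 1..3 in every block
  blocks <- split(rk$rank, paste(rk$family, rk$iteration))
  expect_true(all(vapply(blocks, function(r) all(sort(r) == 1:3), logical(1))))
  # argsort oracle on one block
  b11 <- long |> dplyr::filter(family == "m1", iteration == 1) |>
    dplyr::group_by(feature) |>
    dplyr::summarise(m = mean(abs(value)))
  want <- b11$feature[order(-b11$m)]
  got <- rk |> dplyr::filter(family == "m1", iteration == 1) |>
    dplyr::arrange(rank) |> dplyr::pull(feature)
  expect_equal(got, want)
  # invariant to input row order
  rk2 <- rank_features(long[sample(nrow(long)), ])
  expect_equal(dplyr::arrange(rk, family, iteration, feature),
               dplyr::arrange(rk2, family, iteration, feature))
  # ties break by feature name order
  tied <- tibble::tibble(family = "m", iteration = 1L,
                         sno_id = rep(paste0("s", 1:4), each = 2),
                         feature = rep(c("beta", "alpha"), 4),
                         value = rep(c(1, -1), 4))
  rkt <- rank_features(tied)
  expect_equal(rkt$feature[rkt$rank == 1], "alpha")
})

test_that("decision traces order features by |contribution| and sum to the output", {
  tm <- fit_toy_model("svm", p_extra = 1)
  bg <- tm$x[1:30, ]
  tr <- decision_trace(tm$model, tm$x[31, , drop = FALSE], bg)
  expect_equal(tr$value, tr$value[order(-abs(tr$value))])
  expect_equal(attr(tr, "baseline") + sum(tr$value), attr(tr, "output"),
               tolerance = 1e-6)
  expect_true(attr(tr, "status") %in% c(0L, 1L))

  # single-feature model: the lone contribution is output - baseline
  x1 <- tm$x[, 1, drop = FALSE]
  m1 <- snostatus:::fit_family("random_forest",
                               model_specs()$random_forest[1, ], x1, tm$y, 3)
  tr1 <- decision_trace(m1, x1[5, , drop = FALSE], x1[1:20, , drop = FALSE])
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$value, attr(tr1, "output") - attr(tr1, "baseline"),
               tolerance = 1e-9)
})

test_that("logo statistics recover frequencies, entropies and found proportions", {
  # identical instances: zero cumulative entropy
  same <- motif_logo_stats(rep("AUGAUGA", 25), n_total = 50)
  expect_equal(same$cumulative_entropy, 0)
  expect_equal(same$proportion_found, 0.5)
  expect_equal(colSums(same$pfm), rep(1, 7))

  # uniform random positions approach 2 bits per position (14 for a 7-mer)
  set.seed(18)
  inst <- replicate(10000, random_rna_seq(7))
  uni <- motif_logo_stats(inst)
  expect_equal(uni$cumulative_entropy, 14, tolerance = 0.2)

  # fixed instance set equals a direct -sum(p log2 p) recomputation
  fixed <- c("AUGA", "AUGG", "ACGA", "AUGA")
  got <- motif_logo_stats(fixed)
  mat <- do.call(rbind, strsplit(fixed, ""))
  manual <- vapply(1:4, function(j) {
    p <- table(mat[, j]) / 4
    -sum(p * log2(p))
  }, numeric(1))
  expect_equal(unname(got$entropy), manual, tolerance = 1e-12)

  expect_error(motif_logo_stats(c("AUG", "AUGA")), "same length")

  # KS utility runs over frequency vectors
  ks <- ks_logo_test(c(0.9, 0.8, 0.95, 0.85), c(0.4, 0.5, 0.3, 0.45))
  expect_true(ks$p.value >= 0 && ks$p.value <= 1)
})
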