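# Shapley-additive interpretation of the classifiers.
#
# Per-feature signed contributions that, together with a baseline (the
# expected model output over a background set), sum exactly to the model
# output for each snoRNA. Contributions are computed on the model's
# decision score: the linear link for logistic regression (closed form),
# the positive-class score for the other families (permutation sampling,
# which preserves the additivity identity exactly because every sampled
# permutation telescopes).

# Decision-score function used for attribution, per family.
attribution_output <- function(model) {
  if (model$family == "logistic_regression") {
    function(x) {
      as.numeric(predict(model$fit, x[, model$feature_names, drop = FALSE],
                         type = "link", s = model$params$lambda))
    }
  } else {
    function(x) predict_scores(model, x)
  }
}

#' Exact Shapley values by full coalition enumeration
#'
#' Reference implementation: enumerates all 2^p coalitions, valuing a
#' coalition S as the mean model output with features in S taken from the
#' explained row and the rest from each background row. Exponential in the
#' number of features — intended for small models and as a test oracle.
#'
#' @param f function mapping a feature matrix to a numeric output vector.
#' @param x_row single-row feature matrix (the instance to explain).
#' @param background feature matrix of background rows.
#' @return list: `values` (named numeric contributions), `baseline`
#'   (mean output over the background), `output` (f at `x_row`).
#' @export
shap_exact <- function(f, x_row, background) {
  p <- ncol(background)
  feats <- colnames(background)
  vcache <- numeric(2^p)
  for (code in 0:(2^p - 1)) {
    inS <- as.logical(bitwAnd(code, 2^(0:(p - 1))))
    M <- background
    if (any(inS)) M[, inS] <- matrix(x_row[1, inS], nrow(background),
                                     sum(inS), byrow = TRUE)
    vcache[code + 1] <- mean(f(M))
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (code in 0:(2^(p - 1) - 1)) {
      inS <- as.logical(bitwAnd(code, 2^(0:(p - 2))))
      S <- others[inS]
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      code_S <- sum(2^(S - 1))
      code_Sj <- code_S + 2^(j - 1)
      phi[j] <- phi[j] + w * (vcache[code_Sj + 1] - vcache[code_S + 1])
    }
  }
  list(values = setNames(phi, feats), baseline = vcache[1],
       output = unname(f(x_row)[1]))
}

# Permutation-sampling Shapley for a batch of rows: antithetic permutation
# pairs; every model evaluation is collected into one matrix per chunk so
# the underlying predict is called O(1) times.
shap_sampling <- function(f, rows, background, n_perm = 6L, seed = 1L,
                          chunk = 50L) {
  p <- ncol(background)
  feats <- colnames(background)
  K <- nrow(background)
  set.seed(seed)
  half <- max(1L, n_perm %/% 2L)
  perms <- list()
  for (r in seq_len(half)) {
    pi1 <- sample.int(p)
    perms[[2 * r - 1]] <- pi1
    perms[[2 * r]] <- rev(pi1)
  }
  n_perm <- length(perms)
  n <- nrow(rows)
  values <- matrix(0, n, p, dimnames = list(rownames(rows), feats))
  baseline <- mean(f(background))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # stacked masked matrices: for each row, perm, step t in 0..p
    blocks <- vector("list", length(idx) * n_perm)
    b <- 0L
    for (ri in idx) {
      x <- rows[ri, , drop = FALSE]
      for (pm in seq_len(n_perm)) {
        ord <- perms[[pm]]
        M <- background[rep(seq_len(K), p + 1L), , drop = FALSE]
        for (t in seq_len(p)) {
          sel <- (t * K + 1L):((p + 1L) * K)
          M[sel, ord[t]] <- x[1, ord[t]]
        }
        b <- b + 1L
        blocks[[b]] <- M
      }
    }
    big <- do.call(rbind, blocks)
    out <- f(big)
    b <- 0L
    for (ri in idx) {
      for (pm in seq_len(n_perm)) {
        ord <- perms[[pm]]
        off <- b * (p + 1L) * K
        v <- vapply(0:p, function(t) mean(out[(off + t * K + 1L):(off + (t + 1L) * K)]),
                    numeric(1))
        values[ri, ord] <- values[ri, ord] + diff(v) / n_perm
        b <- b + 1L
      }
    }
  }
  list(values = values, baseline = baseline, output = f(rows))
}

#' Shapley-additive attributions for a fitted model
#'
#' Closed-form (exact) contributions on the link scale for the
#' logistic-regression family; exact coalition enumeration for other
#' families with at most `exact_max` features; antithetic permutation
#' sampling otherwise. In every mode the additivity identity
#' `baseline + sum(contributions) == output` holds to numerical precision.
#'
#' @param model a `sno_model`.
#' @param rows scaled feature matrix of the instances to explain.
#' @param background scaled feature matrix of background rows (typically
#'   the model's training rows, capped at 100).
#' @param n_perm permutations for the sampling mode (rounded to even).
#' @param seed integer seed for the sampling mode.
#' @param exact_max maximum feature count for exact enumeration (default 8).
#' @return list: `values` (rows x features matrix of signed contributions),
#'   `baseline` (scalar expected output), `output` (per-row model output).
#' @export
attribute <- function(model, rows, background, n_perm = 6L, seed = 1L,
                      exact_max = 8L) {
  abort_if(!setequal(colnames(rows), model$feature_names),
           "feature mismatch between rows and model")
  rows <- rows[, model$feature_names, drop = FALSE]
  background <- background[, model$feature_names, drop = FALSE]
  f <- attribution_output(model)
  if (model$family == "logistic_regression") {
    w <- as.numeric(glmnet::coef.glmnet(model$fit,
                                        s = model$params$lambda))[-1]
    mu <- colMeans(background)
    values <- sweep(rows, 2, mu) * matrix(w, nrow(rows), ncol(rows), byrow = TRUE)
    baseline <- f(matrix(mu, 1, dimnames = list(NULL, model$feature_names)))
    return(list(values = values, baseline = baseline, output = f(rows)))
  }
  if (ncol(rows) <= exact_max) {
    res <- lapply(seq_len(nrow(rows)), function(i)
      shap_exact(f, rows[i, , drop = FALSE], background))
    values <- do.call(rbind, lapply(res, `[[`, "values"))
    rownames(values) <- rownames(rows)
    return(list(values = values, baseline = res[[1]]$baseline,
                output = vapply(res, `[[`, numeric(1), "output")))
  }
  shap_sampling(f, rows, background, n_perm = n_perm, seed = seed)
}

#' Attributions across all iterations of an ensemble fit
#'
#' For each (family, iteration), explains the iteration's test rows against
#' a background of its training rows (sampled down to `background_cap` with
#' the fit's master seed) and returns all contributions in long form.
#'
#' @param fit a `sno_ensemble_fit`.
#' @param encoded the encoded feature table the fit was trained on.
#' @param families families to attribute (default: the ensemble families).
#' @param background_cap maximum background rows (default 100).
#' @param n_perm,seed sampling-mode parameters (seed defaults to the fit's).
#' @return tibble: `family`, `iteration`, `sno_id`, `feature`, `value`,
#'   plus per-row `baseline` and `output`.
#' @export
attribute_fit <- function(fit, encoded, families = fit$ensemble_families,
                          background_cap = 100L, n_perm = 6L, seed = NULL) {
  seed <- seed %||% fit$seed
  plan <- fit$split_plan
  out <- list()
  for (i in seq_len(fit$n_iter)) {
    tr_ids <- plan$sno_id[plan$iteration == i & plan$set == "training"]
    te_ids <- plan$sno_id[plan$iteration == i & plan$set == "test"]
    sc <- fit$scalers[[i]]
    tr <- features_matrix(apply_scaler(sc, encoded[match(tr_ids, encoded$sno_id), ]))
    te <- features_matrix(apply_scaler(sc, encoded[match(te_ids, encoded$sno_id), ]))
    if (nrow(tr) > background_cap) {
      set.seed(derive_seed(seed, 3000L + i))
      tr <- tr[sample(nrow(tr), background_cap), , drop = FALSE]
    }
    for (fam in families) {
      m <- fit$models[[paste(i, fam, sep = ".")]]
      at <- attribute(m, te, tr, n_perm = n_perm,
                      seed = derive_seed(seed, 4000L + 17L * i + match(fam, ALL_FAMILIES)))
      long <- as_tibble(at$values) |>
        mutate(sno_id = te_ids, baseline = at$baseline, output = at$output,
               family = fam, iteration = i) |>
        tidyr::pivot_longer(cols = dplyr::all_of(colnames(at$values)),
                            names_to = "feature", values_to = "value")
      out[[paste(i, fam)]] <- long
    }
  }
  bind_rows(out) |>
    select("family", "iteration", "sno_id", "feature", "value",
           "baseline", "output")
}

#' Predictive ranks from attribution values
#'
#' Within each (family, iteration) the features are ranked by the mean of
#' their absolute contributions, rank 1 being the largest mean (ties broken
#' by feature name order). Supplying the matrices in any order gives the
#' same table.
#'
#' One-hot encoding splits a categorical feature into complementary
#' indicator columns that dilute each other's apparent importance; passing
#' `groups` (see [feature_groups()]) first sums each snoRNA's signed
#' contributions within a group — the Shapley value of the grouped feature
#' — and ranks the groups instead.
#'
#' @param attributions long tibble from [attribute_fit()] (needs `family`,
#'   `iteration`, `sno_id`, `feature`, `value`).
#' @param groups optional named character vector mapping feature columns
#'   to group names.
#' @return tibble: `family`, `iteration`, `feature`, `mean_abs_shap`,
#'   `rank` (a permutation of 1..n_features within each family/iteration).
#' @export
rank_features <- function(attributions, groups = NULL) {
  if (!is.null(groups)) {
    attributions <- attributions |>
      mutate(feature = unname(groups[.data$feature])) |>
      group_by(.data$family, .data$iteration, .data$sno_id, .data$feature) |>
      summarise(value = sum(.data$value), .groups = "drop")
  }
  attributions |>
    group_by(.data$family, .data$iteration, .data$feature) |>
    summarise(mean_abs_shap = mean(abs(.data$value)), .groups = "drop_last") |>
    arrange(dplyr::desc(.data$mean_abs_shap), .data$feature, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    arrange(.data$family, .data$iteration, .data$rank)
}

#' Aggregate rank distribution per feature
#'
#' Plot-ready summary across all models and iterations: per feature the
#' median, mean, min and max predictive rank.
#'
#' @param rank_table tibble from [rank_features()].
#' @return tibble sorted by median rank.
#' @export
summarise_ranks <- function(rank_table) {
  rank_table |>
    group_by(.data$feature) |>
    summarise(median_rank = stats::median(.data$rank),
              mean_rank = mean(.data$rank),
              min_rank = min(.data$rank), max_rank = max(.data$rank),
              .groups = "drop") |>
    arrange(.data$median_rank, .data$mean_rank, .data$feature)
}

#' Per-snoRNA decision trace
#'
#' The instance's signed contributions ordered by decreasing magnitude,
#' with the baseline and final output — the tabular form of a decision
#' plot line converging to "expressed" or "not expressed".
#'
#' @param model a `sno_model`.
#' @param row single-row scaled feature matrix.
#' @param background scaled background matrix.
#' @param ... passed to [attribute()].
#' @return tibble: `feature`, `value` (|value|-descending), with
#'   attributes `baseline`, `output` and `status` (0/1).
#' @export
decision_trace <- function(model, row, background, ...) {
  at <- attribute(model, row, background, ...)
  tr <- tibble(feature = colnames(at$values), value = as.numeric(at$values[1, ])) |>
    arrange(dplyr::desc(abs(.data$value)))
  attr(tr, "baseline") <- at$baseline
  attr(tr, "output") <- at$output[1]
  attr(tr, "status") <- as.integer(predict_scores(
    model, row[, model$feature_names, drop = FALSE]) > 0.5)
  tr
}

#' Position frequency matrix and Shannon entropy of aligned motifs
#'
#' @param instances character vector of equal-length motif strings over
#'   {A, C, G, U}.
#' @param n_total total number of snoRNAs searched (for the
#'   proportion-found statistic); defaults to `length(instances)`.
#' @return list: `pfm` (4 x L frequency matrix, columns sum to 1),
#'   `entropy` (per-position Shannon entropy, bits), `cumulative_entropy`
#'   (their sum), `n` (instances used), `proportion_found`.
#' @export
motif_logo_stats <- function(instances, n_total = length(instances)) {
  instances <- dna_to_rna(instances)
  lens <- unique(nchar(instances))
  abort_if(length(lens) != 1, "motif instances must all have the same length")
  L <- lens
  mat <- do.call(rbind, strsplit(instances, "", fixed = TRUE))
  pfm <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "U")))
    as.numeric(tab) / length(instances)
  }, numeric(4))
  rownames(pfm) <- c("A", "C", "G", "U")
  ent <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  list(pfm = pfm, entropy = ent, cumulative_entropy = sum(ent),
       n = length(instances), proportion_found = length(instances) / n_total)
}

#' Kolmogorov-Smirnov comparison of two logo position-frequency vectors
#'
#' Utility over per-position frequency vectors (e.g. the frequency of the
#' consensus nucleotide at each motif position in two snoRNA groups).
#'
#' @param freq_a,freq_b numeric frequency vectors.
#' @return the `ks.test` result.
#' @export
ks_logo_test <- function(freq_a, freq_b) {
  suppressWarnings(stats::ks.test(freq_a, freq_b))
}
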