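# Assembly of the model-ready feature matrix.
#
# Categorical and numerical features are merged into one table per snoRNA,
# categoricals are one-hot encoded (with the repeatedly generated
# "intergenic" indicator kept only once), and numeric standardisation is
# fit on training rows only and applied to every other set — including
# other species, which are scaled with the human training statistics.

#' Merge all per-snoRNA feature sources into one table
#'
#' Every source must carry `sno_id` and cover exactly the same ids; a
#' mismatch raises an error listing the offending ids. Intron-context
#' features that are structurally missing (intergenic or exonic snoRNAs)
#' are imputed with raw zeros (`impute = "zero"`, the default) or with the
#' column median over intronic snoRNAs (`impute = "median"`); the genomic
#' context indicator columns carry the distinction either way.
#'
#' @param snornas tibble from [load_snornas()] (uses `sno_id`, `length`).
#' @param box_scores tibble from [score_boxes()].
#' @param global_folds tibble from [fold_global()].
#' @param stems tibble from [stem_features()].
#' @param context tibble from [derive_intron_context()].
#' @param bp_dist tibble from [branchpoint_distance()].
#' @param host_status tibble from [host_expression_status()].
#' @param assignments tibble from [assign_host()].
#' @param metadata tibble with `sno_id`, `sno_type`, `target`,
#'   `host_function`, `promoter`, `nmd`.
#' @param labels tibble from [label_expression()] on the snoRNA abundance
#'   table (`gene_id` matched to `sno_id`), or NULL to omit the label
#'   column (e.g. for other species).
#' @param impute `"zero"` or `"median"`.
#' @return tibble, one row per snoRNA: `sno_id`, `label` (1 = expressed;
#'   absent when `labels` is NULL), numeric features and categorical
#'   columns (still un-encoded).
#' @export
assemble_features <- function(snornas, box_scores, global_folds, stems,
                              context, bp_dist, host_status, assignments,
                              metadata, labels = NULL,
                              impute = c("zero", "median")) {
  impute <- match.arg(impute)
  sources <- list(box_scores = box_scores, global_folds = global_folds,
                  stems = stems, context = context, bp_dist = bp_dist,
                  host_status = host_status, assignments = assignments,
                  metadata = metadata)
  ids <- snornas$sno_id
  for (nm in names(sources)) {
    extra <- setdiff(sources[[nm]]$sno_id, ids)
    miss <- setdiff(ids, sources[[nm]]$sno_id)
    abort_if(length(extra) + length(miss) > 0,
             sprintf("id mismatch in %s (missing: %s; extra: %s)", nm,
                     paste(head(miss, 5), collapse = ","),
                     paste(head(extra, 5), collapse = ",")))
  }
  tbl <- tibble(sno_id = ids, sno_length = snornas$length) |>
    left_join(box_scores |> select("sno_id", "box_score"), by = "sno_id") |>
    left_join(global_folds |> select("sno_id", "sno_stability"), by = "sno_id") |>
    left_join(stems |> select("sno_id", "terminal_stem_stability",
                              "terminal_stem_length_score"), by = "sno_id") |>
    left_join(context |> select("sno_id", "total_introns", "intron_length",
                                "rank_5p", "rank_3p", "relative_rank_3p",
                                "dist_upstream_exon", "dist_downstream_exon"),
              by = "sno_id") |>
    left_join(bp_dist, by = "sno_id") |>
    left_join(host_status, by = "sno_id") |>
    left_join(assignments |> select("sno_id", "host_biotype"), by = "sno_id") |>
    left_join(metadata |> select("sno_id", "sno_type", "target",
                                 "host_function", "promoter", "nmd"),
              by = "sno_id")
  intron_cols <- c("total_introns", "intron_length", "rank_5p", "rank_3p",
                   "relative_rank_3p", "dist_upstream_exon",
                   "dist_downstream_exon", "dist_branchpoint")
  for (cl in intron_cols) {
    v <- tbl[[cl]]
    fill <- if (impute == "zero") 0 else stats::median(v, na.rm = TRUE)
    if (all(is.na(v))) fill <- 0
    tbl[[cl]][is.na(v)] <- fill
  }
  if (!is.null(labels)) {
    lab <- labels |> select(sno_id = "gene_id", "status")
    tbl <- tbl |> left_join(lab, by = "sno_id") |>
      mutate(label = as.integer(.data$status == "expressed")) |>
      select(-"status")
    abort_if(anyNA(tbl$label), "snoRNA ids missing from the label table")
    tbl <- tbl |> select("sno_id", "label", dplyr::everything())
  }
  tbl
}

#' Category levels of a feature table (one-hot encoder fit)
#'
#' @param table feature table with character categorical columns.
#' @param cols categorical column names; defaults to all character columns
#'   except `sno_id`.
#' @return named list of sorted level vectors.
#' @export
one_hot_levels <- function(table, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(table)[vapply(table, is.character, logical(1))], "sno_id")
  }
  setNames(lapply(cols, function(cl) sort(unique(table[[cl]]))), cols)
}

# Shared naming scheme for encoded columns: bare level names, disambiguated
# by parent on clashes; the collapsed "intergenic" indicator is a single
# shared column.
encoded_column_map <- function(levels, base_cols) {
  all_levels <- unlist(lapply(names(levels), function(cl)
    setdiff(levels[[cl]], "intergenic")), use.names = FALSE)
  dup <- unique(all_levels[duplicated(all_levels)])
  purrr::map_dfr(names(levels), function(cl) {
    purrr::map_dfr(levels[[cl]], function(lv) {
      nm <- if (lv == "intergenic") "intergenic"
      else if (lv %in% dup || lv %in% base_cols) paste(cl, lv, sep = "_")
      else lv
      tibble(parent = cl, level = lv, column = nm)
    })
  })
}

#' Map encoded feature columns to their parent features
#'
#' One-hot encoding splits a categorical feature into complementary
#' indicator columns that share the underlying signal; this map groups
#' them back. Numeric columns map to themselves; indicator columns map to
#' their parent categorical; the shared `intergenic` indicator maps to the
#' host-expression parent (intergenic being one of the host-expression
#' states) when present, else to its first parent.
#'
#' @param table the UN-encoded feature table (as fed to
#'   [one_hot_encode()]).
#' @param levels encoder from [one_hot_levels()]; fit from `table` when
#'   NULL.
#' @return named character vector: encoded column -> group name.
#' @export
feature_groups <- function(table, levels = NULL) {
  if (is.null(levels)) levels <- one_hot_levels(table)
  map <- encoded_column_map(levels, names(table))
  grp <- setNames(map$parent, map$column)
  if ("intergenic" %in% names(grp)) {
    parents_of_intergenic <- map$parent[map$column == "intergenic"]
    grp["intergenic"] <- if ("host_expression" %in% parents_of_intergenic)
      "host_expression" else parents_of_intergenic[1]
  }
  numeric_cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                          c("label"))
  c(setNames(numeric_cols, numeric_cols), grp[!duplicated(names(grp))])
}

#' One-hot encode categorical columns
#'
#' Each category becomes a binary column. Any category named `intergenic` —
#' generated by every host-related parent column — is collapsed into a
#' single `intergenic` indicator. Binary columns are named after the bare
#' category when that is unambiguous, otherwise `parent_category`. The
#' encoder (`levels`) is fit on the full table before any data split; a
#' category unseen by the encoder raises an error.
#'
#' @param table feature table (e.g. from [assemble_features()]).
#' @param levels encoder from [one_hot_levels()]; fit from `table` when NULL.
#' @return tibble with categorical columns replaced by binary columns.
#' @export
one_hot_encode <- function(table, levels = NULL) {
  if (is.null(levels)) levels <- one_hot_levels(table)
  for (cl in names(levels)) {
    unseen <- setdiff(unique(table[[cl]]), levels[[cl]])
    abort_if(length(unseen) > 0,
             sprintf("unseen categories in %s: %s", cl, paste(unseen, collapse = ",")))
  }
  map <- encoded_column_map(levels, names(table))
  out <- table
  for (k in seq_len(nrow(map))) {
    if (!map$column[k] %in% names(out)) {
      out[[map$column[k]]] <- as.integer(table[[map$parent[k]]] == map$level[k])
    }
  }
  out <- out[, setdiff(names(out), names(levels)), drop = FALSE]
  abort_if(anyDuplicated(names(out)) > 0, "duplicated column names after encoding")
  out
}

#' Fit standardisation statistics on training rows
#'
#' Population convention (variance divisor n). Binary one-hot columns are
#' standardised like any other column.
#'
#' @param train feature table rows (training set only).
#' @param cols columns to scale; defaults to all numeric columns except
#'   `label`.
#' @return tibble of scaling stats: `column`, `mean`, `var`.
#' @export
fit_scaler <- function(train, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(train)[vapply(train, is.numeric, logical(1))], "label")
  }
  abort_if(nrow(train) < 2, "need at least 2 training rows to fit a scaler")
  tibble(
    column = cols,
    mean = vapply(cols, function(cl) mean(train[[cl]]), numeric(1),
                  USE.NAMES = FALSE),
    var = vapply(cols, function(cl) mean((train[[cl]] - mean(train[[cl]]))^2),
                 numeric(1), USE.NAMES = FALSE)
  )
}

#' Apply standardisation statistics
#'
#' z = (x - mean) / sd with sd from the stored population variance;
#' zero-variance columns scale to 0. Rows from tuning/test sets or from
#' other species must be scaled with the TRAINING statistics.
#'
#' @param stats tibble from [fit_scaler()].
#' @param rows feature table rows to scale.
#' @return the rows with scaled columns.
#' @export
apply_scaler <- function(stats, rows) {
  abort_if(!all(stats$column %in% names(rows)),
           paste("columns missing from rows:",
                 paste(setdiff(stats$column, names(rows)), collapse = ",")))
  for (k in seq_len(nrow(stats))) {
    cl <- stats$column[k]
    s <- sqrt(stats$var[k])
    rows[[cl]] <- if (s > 0) (rows[[cl]] - stats$mean[k]) / s else rep(0, nrow(rows))
  }
  rows
}

#' Filter snoRNAs redundant on the key feature set
#'
#' snoRNAs sharing exactly the same values of the key features (default:
#' the cross-species top-4) are collapsed to one representative — the first
#' in `sno_id` order — to limit bias from large identical copy families.
#'
#' @param table feature table with a `sno_id` column.
#' @param key_features character vector of key column names.
#' @return list: `table` (deduplicated, original row order), `mapping`
#'   (tibble `removed`, `kept`).
#' @export
filter_redundant <- function(table,
                             key_features = c("box_score", "sno_stability",
                                              "terminal_stem_stability",
                                              "host_expressed")) {
  abort_if(!all(key_features %in% names(table)),
           paste("key features missing:",
                 paste(setdiff(key_features, names(table)), collapse = ",")))
  key <- do.call(paste, c(lapply(key_features, function(cl) table[[cl]]),
                          sep = "\r"))
  ord <- order(table$sno_id)
  first_of_key <- tapply(ord, key[ord], function(ix) ix[1])
  keep_idx <- sort(unname(unlist(first_of_key)))
  kept_for <- table$sno_id[unname(first_of_key)[match(key, names(first_of_key))]]
  removed_idx <- setdiff(seq_len(nrow(table)), keep_idx)
  list(
    table = table[keep_idx, , drop = FALSE],
    mapping = tibble(removed = table$sno_id[removed_idx],
                     kept = kept_for[removed_idx])
  )
}
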