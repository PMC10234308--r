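# End-to-end orchestration: files in, feature table, ensemble fit,
# attribution ranks, TSV artefacts out.

#' Assemble the full snoRNA feature table from input files
#'
#' Runs every feature module: annotation + genome ingestion, host
#' assignment, intron context, branchpoint distances, flank extraction,
#' box scores, global folding, terminal-stem features, expression labels
#' (snoRNA and host level), and merges them with the categorical metadata.
#'
#' @param gtf,fasta paths to annotation and genome.
#' @param branchpoints path to the branchpoint TSV (chrom, pos, strand,
#'   intron_id, probability, source), or NULL.
#' @param metadata path to the categorical metadata TSV (sno_id, sno_type,
#'   target, host_function, promoter, nmd).
#' @param sno_tpm,host_tpm,design paths to the TPM tables and the
#'   sample-to-tissue design TSV; `sno_tpm = NULL` omits labels.
#' @param threshold expression TPM threshold (default 1).
#' @param engine folding engine.
#' @param impute intron-feature imputation mode, see [assemble_features()].
#' @return list: `features` (un-encoded assembled table), `snornas`,
#'   `annotation`, `assignments`, `context`, plus the intermediate
#'   tibbles (`box_scores`, `stems`, `global_folds`).
#' @export
sno_feature_table <- function(gtf, fasta, branchpoints = NULL, metadata,
                              sno_tpm = NULL, host_tpm = NULL, design = NULL,
                              threshold = 1.0, engine = default_engine(),
                              impute = "zero") {
  genome <- read_genome(fasta)
  anno <- read_annotation(gtf)
  snos <- load_snornas(anno, genome)
  meta <- readr::read_tsv(metadata, show_col_types = FALSE)
  snos_typed <- snos |> left_join(meta |> select("sno_id", "sno_type"),
                                  by = "sno_id")
  assignments <- assign_host(snos, anno$genes)
  context <- derive_intron_context(snos, assignments, anno)
  bp_tbl <- if (is.null(branchpoints)) {
    tibble(chrom = character(), pos = integer(), strand = character(),
           intron_id = character(), probability = numeric(),
           source = character())
  } else {
    readr::read_tsv(branchpoints, show_col_types = FALSE)
  }
  bp_dist <- branchpoint_distance(snos, context, bp_tbl)
  flanks <- extract_flanks(snos, genome)
  folds <- fold_global(snos, engine = engine)
  boxes <- score_boxes(snos_typed |>
                         left_join(folds |> select("sno_id", "structure"),
                                   by = "sno_id"),
                       engine = engine)
  stems <- stem_features(snos_typed |> left_join(flanks, by = "sno_id"),
                         engine = engine)
  labels <- NULL
  host_status <- if (!is.null(host_tpm) && !is.null(design)) {
    des <- readr::read_tsv(design, show_col_types = FALSE)
    host_tab <- readr::read_tsv(host_tpm, show_col_types = FALSE)
    host_labels <- label_expression(average_by_tissue(host_tab, des), threshold)
    host_expression_status(assignments, host_labels)
  } else {
    assignments |>
      mutate(host_expression = ifelse(is.na(.data$host_id), "intergenic",
                                      "host_not_expressed")) |>
      select("sno_id", "host_expression")
  }
  if (!is.null(sno_tpm) && !is.null(design)) {
    des <- readr::read_tsv(design, show_col_types = FALSE)
    sno_tab <- readr::read_tsv(sno_tpm, show_col_types = FALSE)
    labels <- label_expression(average_by_tissue(sno_tab, des), threshold)
  }
  features <- assemble_features(
    snornas = snos, box_scores = boxes, global_folds = folds, stems = stems,
    context = context, bp_dist = bp_dist, host_status = host_status,
    assignments = assignments, metadata = meta, labels = labels,
    impute = impute)
  list(features = features, snornas = snos, annotation = anno,
       assignments = assignments, context = context, box_scores = boxes,
       stems = stems, global_folds = folds)
}

#' Run the complete analysis on a generated cohort directory
#'
#' Reads the standard cohort files (as written by [generate_cohort()]),
#' assembles and encodes features, fits the stratified multi-iteration
#' ensemble, computes Shapley attributions and predictive ranks, and
#' writes `predictions.tsv` and `ranks.tsv` under `outdir`. The whole run
#' is deterministic given `seed`.
#'
#' @param cohort_dir directory holding the cohort files.
#' @param outdir output directory for the TSV artefacts (created).
#' @param seed master seed.
#' @param n_iter split iterations (default 10).
#' @param families model families to fit.
#' @param n_perm permutations for sampling-mode attribution.
#' @param engine folding engine.
#' @return list: `fit` (`sno_ensemble_fit`), `attributions`, `ranks`,
#'   `rank_summary`, `encoded`, `paths`.
#' @export
run_cohort_pipeline <- function(cohort_dir, outdir, seed = 42L, n_iter = 10L,
                                families = ENSEMBLE_FAMILIES, n_perm = 4L,
                                engine = default_engine()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cohort_dir, f)
  ft <- sno_feature_table(
    gtf = p("annotation.gtf"), fasta = p("genome.fa"),
    branchpoints = p("branchpoints.tsv"), metadata = p("metadata.tsv"),
    sno_tpm = p("sno_tpm.tsv"), host_tpm = p("host_tpm.tsv"),
    design = p("design.tsv"), engine = engine)
  encoded <- one_hot_encode(ft$features)
  fit <- fit_expression_models(encoded, n_iter = n_iter, families = families,
                               ensemble_families = intersect(ENSEMBLE_FAMILIES,
                                                             families),
                               seed = seed)
  attr_long <- attribute_fit(fit, encoded, n_perm = n_perm, seed = seed)
  ranks <- rank_features(attr_long)
  paths <- list(predictions = file.path(outdir, "predictions.tsv"),
                ranks = file.path(outdir, "ranks.tsv"))
  readr::write_tsv(fit$predictions, paths$predictions)
  readr::write_tsv(ranks, paths$ranks)
  list(fit = fit, attributions = attr_long, ranks = ranks,
       rank_summary = summarise_ranks(ranks), encoded = encoded,
       features = ft, paths = paths)
}
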