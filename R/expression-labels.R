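# Binary expression status from replicate TPM tables.
#
# A gene is expressed when its tissue-averaged abundance (mean of biological
# replicates) exceeds 1 TPM in at least one tissue, and not expressed
# otherwise. The same rule applies to snoRNAs and to host genes.

#' Average replicate TPM columns by tissue
#'
#' @param tpm data frame: first column `gene_id`, remaining columns one per
#'   sample, values in TPM.
#' @param design data frame mapping `sample` to `tissue`; every TPM sample
#'   column must appear exactly once.
#' @return tibble: `gene_id` plus one mean-TPM column per tissue.
#' @export
average_by_tissue <- function(tpm, design) {
  samples <- setdiff(names(tpm), "gene_id")
  missing <- setdiff(samples, design$sample)
  abort_if(length(missing) > 0,
           paste("samples with no tissue mapping:", paste(missing, collapse = ", ")))
  abort_if(any(tpm[samples] < 0, na.rm = TRUE), "TPM values must be non-negative")
  out <- tpm |>
    tidyr::pivot_longer(dplyr::all_of(samples), names_to = "sample",
                        values_to = "tpm") |>
    left_join(design, by = "sample") |>
    group_by(.data$gene_id, .data$tissue) |>
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "mean_tpm")
  out[match(tpm$gene_id, out$gene_id), , drop = FALSE]
}

#' Label expression status from tissue means
#'
#' A gene is `expressed` iff its mean abundance is strictly greater than
#' `threshold` (default 1 TPM) in at least one tissue.
#'
#' @param tissue_means tibble from [average_by_tissue()].
#' @param threshold TPM threshold (strict inequality), default 1.
#' @return tibble: `gene_id`, `status` (`expressed`/`not_expressed`),
#'   `max_tissue_mean`.
#' @export
label_expression <- function(tissue_means, threshold = 1.0) {
  abort_if(threshold <= 0, "threshold must be positive")
  mat <- as.matrix(tissue_means[setdiff(names(tissue_means), "gene_id")])
  mx <- apply(mat, 1, max)
  tibble(gene_id = tissue_means$gene_id,
         status = ifelse(mx > threshold, "expressed", "not_expressed"),
         max_tissue_mean = unname(mx))
}

#' Host-gene expression status per snoRNA
#'
#' Intergenic snoRNAs get `intergenic`; hosted snoRNAs inherit their host's
#' label (`host_expressed` / `host_not_expressed`). A host absent from the
#' abundance-derived labels is treated as not detected, hence
#' `host_not_expressed`, with a warning.
#'
#' @param assignments tibble from [assign_host()].
#' @param host_labels tibble from [label_expression()] computed on a
#'   host-level abundance table (which may come from a different study than
#'   the snoRNA table).
#' @return tibble: `sno_id`, `host_expression` in
#'   {`host_expressed`, `host_not_expressed`, `intergenic`}.
#' @export
host_expression_status <- function(assignments, host_labels) {
  out <- assignments |>
    left_join(host_labels |> select(host_id = "gene_id", "status"), by = "host_id")
  absent <- !is.na(out$host_id) & is.na(out$status)
  if (any(absent)) {
    warning(sprintf("%d host gene(s) absent from abundance table; labelled not expressed",
                    sum(absent)), call. = FALSE)
  }
  out |>
    mutate(host_expression = dplyr::case_when(
      is.na(.data$host_id) ~ "intergenic",
      !is.na(.data$status) & .data$status == "expressed" ~ "host_expressed",
      TRUE ~ "host_not_expressed"
    )) |>
    select("sno_id", "host_expression")
}
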