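# Genome and annotation ingestion; genomic-context features.
#
# Internal coordinates are 0-based half-open throughout; GTF input/output
# converts at the boundary (GTF is 1-based inclusive). This removes any
# off-by-one ambiguity from the distance arithmetic below.

#' Read a genome FASTA
#'
#' @param fasta_path path to a FASTA file.
#' @return named character vector of uppercase chromosome sequences.
#' @export
read_genome <- function(fasta_path) {
  abort_if(!file.exists(fasta_path), paste("no such file:", fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Read gene/transcript/exon annotation from a GTF file
#'
#' Parses an Ensembl-dialect GTF (via rtracklayer) into tibbles of genes,
#' transcripts, exons and derived introns, with coordinates converted from
#' 1-based inclusive to 0-based half-open. Transcripts without exons are
#' retained with zero introns.
#'
#' @param gtf_path path to the GTF file.
#' @return list of tibbles: `genes` (chrom, start, end, strand, gene_id,
#'   gene_biotype), `transcripts` (+ transcript_id), `exons`, and `introns`
#'   (per-transcript, with `intron_rank5p` counted from the transcript 5'
#'   end and `total_introns`).
#' @export
read_annotation <- function(gtf_path) {
  abort_if(!file.exists(gtf_path), paste("no such file:", gtf_path))
  raw <- readLines(gtf_path)
  body <- !startsWith(raw, "#") & nzchar(raw)
  nf <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1]]
    stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields",
                 bad, gtf_path), call. = FALSE)
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  df <- df |>
    mutate(chrom = as.character(.data$seqnames),
           strand = as.character(.data$strand),
           start0 = .data$start - 1L,   # 1-based inclusive -> 0-based half-open
           end0 = .data$end)
  pick <- function(ty, cols) {
    out <- df |> filter(.data$type == ty)
    out <- out[, intersect(c("chrom", "start0", "end0", "strand", cols), names(out))]
    out |> rename(start = "start0", end = "end0")
  }
  genes <- pick("gene", c("gene_id", "gene_biotype"))
  transcripts <- pick("transcript", c("gene_id", "transcript_id"))
  exons <- pick("exon", c("gene_id", "transcript_id"))
  # validate exons against their transcript bounds
  if (nrow(exons) > 0 && nrow(transcripts) > 0) {
    chk <- exons |>
      inner_join(transcripts |> select("transcript_id", tx_start = "start", tx_end = "end"),
                 by = "transcript_id") |>
      filter(.data$start < .data$tx_start | .data$end > .data$tx_end)
    abort_if(nrow(chk) > 0,
             paste("exon outside transcript bounds for:",
                   paste(unique(chk$transcript_id), collapse = ", ")))
  }
  introns <- derive_introns(exons)
  list(genes = genes, transcripts = transcripts, exons = exons, introns = introns)
}

# Introns between consecutive exons of each transcript; rank 1 = closest to
# the transcript 5' end (strand-aware).
derive_introns <- function(exons) {
  if (nrow(exons) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), gene_id = character(),
                  transcript_id = character(), intron_rank5p = integer(),
                  total_introns = integer()))
  }
  exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              gene_id = .data$gene_id[1],
              istart = list(utils::head(.data$end, -1L)),
              iend = list(utils::tail(.data$start, -1L)),
              .groups = "drop") |>
    tidyr::unnest(c("istart", "iend")) |>
    filter(.data$iend > .data$istart) |>
    group_by(.data$transcript_id) |>
    mutate(total_introns = dplyr::n(),
           intron_rank5p = if (.data$strand[1] == "+") row_number()
                           else rev(row_number())) |>
    ungroup() |>
    select("chrom", start = "istart", end = "iend", "strand",
           "gene_id", "transcript_id", "intron_rank5p", "total_introns")
}

#' Convert internal 0-based half-open coordinates back to GTF convention
#'
#' @param tbl tibble with `start`/`end` in internal coordinates.
#' @return the tibble with 1-based inclusive `start`/`end`.
#' @export
to_gtf_coords <- function(tbl) {
  tbl |> mutate(start = .data$start + 1L)
}

#' Load snoRNA records from annotation plus genome
#'
#' snoRNAs are the genes with `gene_biotype == "snoRNA"`. Sequences are
#' strand-corrected (reverse-complemented for minus-strand records) and
#' reported 5'->3' in the DNA alphabet.
#'
#' @param annotation result of [read_annotation()].
#' @param genome named character vector from [read_genome()].
#' @return tibble: `sno_id`, `chrom`, `start`, `end`, `strand`, `sequence`,
#'   `length`.
#' @export
load_snornas <- function(annotation, genome) {
  snos <- annotation$genes |> filter(.data$gene_biotype == "snoRNA")
  seqs <- vapply(seq_len(nrow(snos)), function(i) {
    s <- substr(genome[[snos$chrom[i]]], snos$start[i] + 1L, snos$end[i])
    if (snos$strand[i] == "-") revcomp(s) else s
  }, character(1))
  tibble(sno_id = snos$gene_id, chrom = snos$chrom, start = snos$start,
         end = snos$end, strand = snos$strand, sequence = seqs,
         length = snos$end - snos$start)
}

#' Assign snoRNAs to host genes
#'
#' A host gene overlaps the snoRNA on the same strand (and is not the snoRNA
#' gene itself). When several candidates overlap, the smallest gene fully
#' containing the snoRNA wins; failing full containment, the smallest
#' overlapping gene (a warning notes the ambiguity). snoRNAs with no
#' candidate are intergenic.
#'
#' @param snornas tibble from [load_snornas()].
#' @param genes gene tibble from [read_annotation()].
#' @return tibble: `sno_id`, `host_id` (NA when intergenic), `host_biotype`
#'   (`protein_coding`, `noncoding` or `intergenic`).
#' @export
assign_host <- function(snornas, genes) {
  cand_pool <- genes |> filter(.data$gene_biotype != "snoRNA")
  purrr::map_dfr(seq_len(nrow(snornas)), function(i) {
    s <- snornas[i, ]
    cand <- cand_pool |>
      filter(.data$chrom == s$chrom, .data$strand == s$strand,
             .data$start < s$end, .data$end > s$start,
             .data$gene_id != s$sno_id)
    if (nrow(cand) == 0) {
      return(tibble(sno_id = s$sno_id, host_id = NA_character_,
                    host_biotype = "intergenic"))
    }
    if (nrow(cand) > 1) {
      warning(sprintf("snoRNA %s overlaps %d candidate hosts; choosing smallest",
                      s$sno_id, nrow(cand)), call. = FALSE)
    }
    containing <- cand |> filter(.data$start <= s$start, .data$end >= s$end)
    pool <- if (nrow(containing) > 0) containing else cand
    pool <- pool |> mutate(size = .data$end - .data$start) |>
      arrange(.data$size, .data$gene_id)
    host <- pool[1, ]
    tibble(sno_id = s$sno_id, host_id = host$gene_id,
           host_biotype = if (host$gene_biotype == "protein_coding")
             "protein_coding" else "noncoding")
  })
}

#' Intron context of hosted snoRNAs
#'
#' For each snoRNA with a host, finds the host transcript whose intron fully
#' contains the snoRNA (smallest containing intron; ties broken by
#' transcript id) and derives the intron-context features. snoRNAs that
#' overlap an exon are flagged `exonic`; those in no intron, `missing`;
#' intergenic snoRNAs, `intergenic` — all with NA features.
#'
#' Distances are computed on the coding strand: `dist_upstream_exon` is the
#' gap between the snoRNA and the exon toward the host 5' end.
#'
#' @param snornas tibble from [load_snornas()].
#' @param assignments tibble from [assign_host()].
#' @param annotation result of [read_annotation()].
#' @return tibble: `sno_id`, `context_status`, `transcript_id`,
#'   `intron_start`, `intron_end`, `total_introns`, `intron_length`,
#'   `rank_5p`, `rank_3p`, `relative_rank_3p`, `dist_upstream_exon`,
#'   `dist_downstream_exon`.
#' @export
derive_intron_context <- function(snornas, assignments, annotation) {
  na_row <- function(sno_id, status) {
    tibble(sno_id = sno_id, context_status = status,
           transcript_id = NA_character_, intron_start = NA_integer_,
           intron_end = NA_integer_, total_introns = NA_integer_,
           intron_length = NA_integer_, rank_5p = NA_integer_,
           rank_3p = NA_integer_, relative_rank_3p = NA_real_,
           dist_upstream_exon = NA_integer_, dist_downstream_exon = NA_integer_)
  }
  joined <- snornas |> left_join(assignments, by = "sno_id")
  purrr::map_dfr(seq_len(nrow(joined)), function(i) {
    s <- joined[i, ]
    if (is.na(s$host_id)) return(na_row(s$sno_id, "intergenic"))
    host_tx <- annotation$transcripts |> filter(.data$gene_id == s$host_id)
    host_introns <- annotation$introns |>
      filter(.data$transcript_id %in% host_tx$transcript_id,
             .data$start <= s$start, .data$end >= s$end)
    if (nrow(host_introns) == 0) {
      host_exons <- annotation$exons |>
        filter(.data$transcript_id %in% host_tx$transcript_id,
               .data$start < s$end, .data$end > s$start)
      status <- if (nrow(host_exons) > 0) "exonic" else "missing"
      return(na_row(s$sno_id, status))
    }
    it <- host_introns |>
      mutate(ilen = .data$end - .data$start) |>
      arrange(.data$ilen, .data$transcript_id)
    it <- it[1, ]
    rank_3p <- it$total_introns - it$intron_rank5p + 1L
    dist_up <- if (s$strand == "+") s$start - it$start else it$end - s$end
    dist_down <- it$ilen - (s$end - s$start) - dist_up
    tibble(sno_id = s$sno_id, context_status = "intronic",
           transcript_id = it$transcript_id, intron_start = it$start,
           intron_end = it$end, total_introns = it$total_introns,
           intron_length = it$ilen, rank_5p = it$intron_rank5p,
           rank_3p = rank_3p,
           relative_rank_3p = rank_3p / it$total_introns,
           dist_upstream_exon = as.integer(dist_up),
           dist_downstream_exon = as.integer(dist_down))
  })
}

#' Distance from a snoRNA 3' end to the best branchpoint
#'
#' Among the supplied branchpoints the one with the highest probability is
#' selected (probability ties resolve to the nearer branchpoint); the
#' distance is the non-negative magnitude between its position and the
#' snoRNA 3' end. Returns NA for an empty branchpoint set.
#'
#' @param sno_3p 0-based genomic position of the snoRNA 3'-end nucleotide.
#' @param bp_pos integer vector of 0-based branchpoint positions.
#' @param bp_prob numeric vector of branchpoint probabilities.
#' @return non-negative integer distance, or NA.
#' @export
distance_to_branchpoint <- function(sno_3p, bp_pos, bp_prob) {
  if (length(bp_pos) == 0) return(NA_integer_)
  d <- abs(bp_pos - sno_3p)
  ord <- order(-bp_prob, d)
  as.integer(d[ord[1]])
}

#' Branchpoint distances for a snoRNA context table
#'
#' Restricts the branchpoint table to each snoRNA's intron (same chromosome
#' and strand, position inside the intron) and applies
#' [distance_to_branchpoint()].
#'
#' @param snornas tibble from [load_snornas()].
#' @param context tibble from [derive_intron_context()].
#' @param branchpoints tibble with columns `chrom`, `pos` (1-based),
#'   `strand`, `intron_id`, `probability`, `source`.
#' @return tibble: `sno_id`, `dist_branchpoint` (NA when no branchpoint or
#'   not intronic).
#' @export
branchpoint_distance <- function(snornas, context, branchpoints) {
  joined <- snornas |> left_join(context, by = "sno_id")
  purrr::map_dfr(seq_len(nrow(joined)), function(i) {
    s <- joined[i, ]
    if (is.na(s$context_status) || s$context_status != "intronic") {
      return(tibble(sno_id = s$sno_id, dist_branchpoint = NA_integer_))
    }
    bp <- branchpoints |>
      filter(.data$chrom == s$chrom, .data$strand == s$strand,
             .data$pos - 1L >= s$intron_start, .data$pos - 1L < s$intron_end)
    sno_3p <- if (s$strand == "+") s$end - 1L else s$start
    tibble(sno_id = s$sno_id,
           dist_branchpoint = distance_to_branchpoint(sno_3p, bp$pos - 1L,
                                                      bp$probability))
  })
}

#' Extract the flanking sequences of snoRNAs
#'
#' Returns the `up_len` nt genomically upstream of the snoRNA 5' end and the
#' `down_len` nt downstream of its 3' end, both 5'->3' in snoRNA orientation
#' (reverse-complemented and swapped on the minus strand). Flanks running
#' past a chromosome edge are truncated with a warning.
#'
#' @param snornas tibble from [load_snornas()].
#' @param genome named character vector from [read_genome()].
#' @param up_len,down_len flank lengths in nt (default 15).
#' @return tibble: `sno_id`, `flank_up`, `flank_down`.
#' @export
extract_flanks <- function(snornas, genome, up_len = 15L, down_len = 15L) {
  purrr::map_dfr(seq_len(nrow(snornas)), function(i) {
    s <- snornas[i, ]
    chrom_seq <- genome[[s$chrom]]
    abort_if(is.null(chrom_seq), paste("chromosome absent from genome:", s$chrom))
    clen <- nchar(chrom_seq)
    slice <- function(a, b) {  # 0-based half-open, truncated to bounds
      a2 <- max(a, 0L); b2 <- min(b, clen)
      if (a2 != a || b2 != b) {
        warning(sprintf("flank of %s truncated at chromosome edge", s$sno_id),
                call. = FALSE)
      }
      if (b2 <= a2) "" else substr(chrom_seq, a2 + 1L, b2)
    }
    if (s$strand == "+") {
      up <- slice(s$start - up_len, s$start)
      down <- slice(s$end, s$end + down_len)
    } else {
      up <- revcomp(slice(s$end, s$end + up_len))
      down <- revcomp(slice(s$start - down_len, s$start))
    }
    tibble(sno_id = s$sno_id, flank_up = up, flank_down = down)
  })
}
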