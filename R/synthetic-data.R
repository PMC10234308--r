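# Self-contained synthetic cohorts: genome FASTA, GTF with host genes and
# embedded snoRNAs, branchpoints, replicate TPM tables, categorical
# metadata and a truth manifest.
#
# Expression status is generated from MEASURED features — the pipeline is
# run on the emitted files and a logistic model links box score, global
# stability, terminal-stem stability and host expression to the label — so
# imperfect motif planting cannot silently decouple features from labels.

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the pipeline assumes: a majority
#' C/D cohort with a quarter of snoRNAs intergenic, motif degeneration
#' drawn per motif from a truncated geometric distribution, engineered
#' complementary flank blocks of 0-15 nt, seven tissues in biological
#' triplicate, and a logistic expression model over the four driver
#' features with directionality matching the biology (degenerate boxes and
#' unstable stems suppress expression; an expressed host promotes it).
#'
#' @param n_snornas cohort size.
#' @param cd_fraction fraction of C/D box snoRNAs.
#' @param intergenic_fraction fraction without a host gene.
#' @param degeneration_p geometric parameter: mutations per motif
#'   ~ min(rgeom(p), motif length).
#' @param stem_block_max maximal engineered complementary block (nt);
#'   block length is uniform on 0..max.
#' @param host_expressed_prob probability a host gene is expressed.
#' @param protein_coding_prob probability a host is protein-coding.
#' @param dual_promoter_prob,nmd_prob host promoter/NMD flag probabilities.
#' @param beta named coefficients of the expression model, in per-standard-
#'   deviation units of the measured features: `box_score`, `sno_stability`,
#'   `terminal_stem_stability`, `host_expressed`. Signs encode the biology:
#'   degenerate boxes and unstable stems/structures suppress expression, an
#'   expressed host promotes it.
#' @param signal_scale steepness of the logistic link (multiplies `beta`);
#'   the default makes expression nearly deterministic in the features,
#'   giving cohorts whose discriminability sits in the high-0.8 AUC range.
#' @param target_expressed_fraction the intercept is solved so the mean
#'   expression probability equals this.
#' @param label_noise probability of flipping a sampled label (in [0, 0.5)).
#' @param n_tissues,n_replicates design of the TPM tables.
#' @param tpm_meanlog,tpm_sdlog lognormal tissue-mean TPM of expressed genes.
#' @param seed master seed.
#' @return a `sno_synth_config` list.
#' @export
synthetic_config <- function(n_snornas = 50L, cd_fraction = 0.7,
                             intergenic_fraction = 0.25,
                             degeneration_p = 0.5, stem_block_max = 15L,
                             host_expressed_prob = 0.6,
                             protein_coding_prob = 0.6,
                             dual_promoter_prob = 0.5, nmd_prob = 0.4,
                             beta = c(box_score = -0.8,
                                      sno_stability = -0.3,
                                      terminal_stem_stability = -0.5,
                                      host_expressed = 1.5),
                             signal_scale = 2,
                             target_expressed_fraction = 0.35,
                             label_noise = 0.05,
                             n_tissues = 7L, n_replicates = 3L,
                             tpm_meanlog = 2, tpm_sdlog = 1, seed = 42L) {
  abort_if(label_noise < 0 || label_noise >= 0.5, "label_noise must be in [0, 0.5)")
  abort_if(intergenic_fraction >= 1 && beta[["host_expressed"]] != 0,
           "intergenic fraction 1 is incompatible with a host-dependent beta")
  structure(as.list(environment()), class = "sno_synth_config")
}

mutate_motif <- function(motif, d) {
  if (d == 0) return(motif)
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), min(d, length(ch)))
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

trunc_geom <- function(n, p, cap) pmin(stats::rgeom(n, p), cap)

#' Generate one synthetic snoRNA sequence with planted motifs
#'
#' Motifs are planted at canonical positions (C box at offset 3-6, D box
#' ending 3-6 nt before the 3' end, internal D'/C' pair for C/D snoRNAs;
#' mid-sequence H box and ACA 3 nt from the 3' end for H/ACA) and then
#' mutated at the requested number of random positions. The background
#' composition is C/U-rich to limit accidental motifs.
#'
#' @param sno_type "CD" or "HACA".
#' @param degeneration named integer vector of mutations per motif (names
#'   from C, D, Dprime, Cprime, H, ACA as applicable).
#' @return list: `sequence` (RNA alphabet), `planted` (tibble kind,
#'   offset, mutations).
#' @export
generate_snorna <- function(sno_type, degeneration) {
  bg <- c(A = 0.12, C = 0.36, G = 0.12, U = 0.40)
  len <- if (sno_type == "CD") sample(60:120, 1) else sample(120:160, 1)
  ch <- sample(names(bg), len, replace = TRUE, prob = bg)
  plant <- function(offset0, motif) {
    ch[(offset0 + 1):(offset0 + nchar(motif))] <<-
      strsplit(motif, "", fixed = TRUE)[[1]]
  }
  planted <- list()
  d_of <- function(kind) {
    d <- degeneration[[kind]]
    if (is.null(d) || is.na(d)) 0L else as.integer(d)
  }
  if (sno_type == "CD") {
    c_off <- sample(3:6, 1)
    c_mot <- mutate_motif(paste0(sample(c("A", "G"), 1), "UGAUGA"), d_of("C"))
    plant(c_off, c_mot)
    d_end_gap <- sample(3:6, 1)
    d_off <- len - 4L - d_end_gap
    d_mot <- mutate_motif("CUGA", d_of("D"))
    plant(d_off, d_mot)
    # internal D' upstream of C'
    mid <- 20L + ((len - 40L) %/% 2L)
    dp_off <- max(21L, mid - 10L)
    cp_off <- min(len - 28L, mid + 4L)
    if (cp_off >= dp_off + 4L && cp_off + 7L <= len - 20L) {
      plant(dp_off, mutate_motif("CUGA", d_of("Dprime")))
      plant(cp_off, mutate_motif(paste0(sample(c("A", "G"), 1), "UGAUGA"),
                                 d_of("Cprime")))
      planted <- c(planted, list(
        tibble(kind = "Dprime", offset = dp_off, mutations = d_of("Dprime")),
        tibble(kind = "Cprime", offset = cp_off, mutations = d_of("Cprime"))))
    }
    planted <- c(planted, list(
      tibble(kind = "C", offset = c_off, mutations = d_of("C")),
      tibble(kind = "D", offset = d_off, mutations = d_of("D"))))
  } else {
    h_off <- sample((len %/% 2 - 10):(len %/% 2 + 10), 1)
    h_core <- paste0("A", sample(c("A","C","G","U"), 1), "A",
                     sample(c("A","C","G","U"), 1), sample(c("A","C","G","U"), 1), "A")
    plant(h_off, mutate_motif(h_core, d_of("H")))
    aca_off <- len - 6L
    plant(aca_off, mutate_motif("ACA", d_of("ACA")))
    planted <- c(planted, list(
      tibble(kind = "H", offset = h_off, mutations = d_of("H")),
      tibble(kind = "ACA", offset = aca_off, mutations = d_of("ACA"))))
  }
  list(sequence = paste(ch, collapse = ""), planted = bind_rows(planted))
}

random_dna <- function(len, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a genomic locus around one snoRNA
#'
#' Builds a chromosome segment in transcription orientation — optionally
#' reverse-complemented onto the minus strand — containing either a host
#' gene whose sampled intron embeds the snoRNA or a bare intergenic
#' snoRNA. The downstream flank's first `stem_block_len` nt are the
#' reverse complement of the upstream flank's last `stem_block_len` nt,
#' and a branchpoint adenosine is planted 18-44 nt upstream of the 3'
#' splice site of the hosting intron.
#'
#' @param sno list from [generate_snorna()] plus an id.
#' @param sno_id snoRNA identifier.
#' @param chrom chromosome name for this locus.
#' @param stem_block_len engineered complementary block length (0-15).
#' @param host NULL for an intergenic locus, else a list with `host_id`,
#'   `biotype` ("protein_coding"/"noncoding").
#' @return list: `seq` (chromosome DNA), `gtf` (tibble of GTF fields,
#'   1-based), `branchpoints` (tibble, possibly empty), `truth` (planted
#'   context values).
#' @export
generate_locus <- function(sno, sno_id, chrom, stem_block_len, host = NULL) {
  abort_if(stem_block_len > FLANK_LEN, "stem block cannot exceed the flank length")
  sno_dna <- chartr("U", "T", sno$sequence)
  sno_len <- nchar(sno_dna)
  flank_up <- random_dna(FLANK_LEN)
  rest <- if (stem_block_len < FLANK_LEN) random_dna(FLANK_LEN - stem_block_len) else ""
  block <- if (stem_block_len > 0) {
    revcomp(substr(flank_up, FLANK_LEN - stem_block_len + 1L, FLANK_LEN))
  } else ""
  flank_down <- paste0(block, rest)
  strand <- sample(c("+", "-"), 1)
  gtf_row <- function(type, start0, end0, gene_id, biotype, tx = NA) {
    tibble(chrom = chrom, source = "snostatus_synth", type = type,
           start = start0 + 1L, end = end0, score = ".", strand = strand,
           frame = ".", gene_id = gene_id, gene_biotype = biotype,
           transcript_id = tx)
  }
  flip <- function(start0, end0, L) c(L - end0, L - start0)
  if (is.null(host)) {
    pad <- 60L
    seq_plus <- paste0(random_dna(pad), flank_up, sno_dna, flank_down, random_dna(pad))
    L <- nchar(seq_plus)
    s0 <- pad + FLANK_LEN; e0 <- s0 + sno_len
    if (strand == "-") { seq_out <- revcomp(seq_plus); se <- flip(s0, e0, L) }
    else { seq_out <- seq_plus; se <- c(s0, e0) }
    return(list(
      seq = seq_out,
      gtf = gtf_row("gene", se[1], se[2], sno_id, "snoRNA"),
      branchpoints = tibble(chrom = character(), pos = integer(),
                            strand = character(), intron_id = character(),
                            probability = numeric(), source = character()),
      truth = tibble(sno_id = sno_id, strand = strand, host_id = NA_character_,
                     total_introns = NA_integer_, sno_intron = NA_integer_,
                     intron_length = NA_integer_, dist_up = NA_integer_,
                     dist_down = NA_integer_, bp_offset = NA_integer_,
                     stem_block_len = stem_block_len)))
  }
  total_introns <- sample(2:8, 1)
  k <- sample(seq_len(total_introns), 1)          # hosting intron (5'->3' rank)
  exon_lens <- sample(80:200, total_introns + 1L, replace = TRUE)
  intron_lens <- sample(150:400, total_introns, replace = TRUE)
  dist_up <- sample(20:250, 1)
  dist_down <- sample(50:250, 1)
  intron_lens[k] <- dist_up + sno_len + dist_down
  pad <- 60L
  pieces <- character(0)
  # transcription-orientation assembly with exact coordinates
  pos <- pad
  exon_bounds <- matrix(0L, total_introns + 1L, 2)
  intron_bounds <- matrix(0L, total_introns, 2)
  for (e in seq_len(total_introns + 1L)) {
    exon_bounds[e, ] <- c(pos, pos + exon_lens[e])
    pos <- pos + exon_lens[e]
    if (e <= total_introns) {
      intron_bounds[e, ] <- c(pos, pos + intron_lens[e])
      pos <- pos + intron_lens[e]
    }
  }
  L <- pos + pad
  sno_s0 <- intron_bounds[k, 1] + dist_up
  sno_e0 <- sno_s0 + sno_len
  bp_offset <- sample(18:44, 1)    # nt upstream of the last intron nucleotide
  bp0 <- intron_bounds[k, 2] - 1L - bp_offset
  # build sequence
  chseq <- strsplit(random_dna(L), "", fixed = TRUE)[[1]]
  ins <- function(at0, s) {
    if (nchar(s) > 0)
      chseq[(at0 + 1):(at0 + nchar(s))] <<- strsplit(s, "", fixed = TRUE)[[1]]
  }
  ins(sno_s0 - FLANK_LEN, flank_up)
  ins(sno_s0, sno_dna)
  ins(sno_e0, flank_down)
  chseq[bp0 + 1] <- "A"
  seq_plus <- paste(chseq, collapse = "")
  gene_s0 <- exon_bounds[1, 1]; gene_e0 <- exon_bounds[total_introns + 1L, 2]
  if (strand == "-") {
    seq_out <- revcomp(seq_plus)
    conv <- function(b) flip(b[1], b[2], L)
    bp_pos0 <- L - bp0 - 1L
  } else {
    seq_out <- seq_plus
    conv <- function(b) b
    bp_pos0 <- bp0
  }
  ge <- conv(c(gene_s0, gene_e0)); se <- conv(c(sno_s0, sno_e0))
  tx_id <- paste0(host$host_id, ".t1")
  gtf <- bind_rows(
    gtf_row("gene", ge[1], ge[2], host$host_id, host$biotype),
    gtf_row("transcript", ge[1], ge[2], host$host_id, host$biotype, tx_id),
    purrr::map_dfr(seq_len(total_introns + 1L), function(e) {
      eb <- conv(exon_bounds[e, ])
      gtf_row("exon", eb[1], eb[2], host$host_id, host$biotype, tx_id)
    }),
    gtf_row("gene", se[1], se[2], sno_id, "snoRNA")
  )
  list(
    seq = seq_out,
    gtf = gtf,
    branchpoints = tibble(chrom = chrom, pos = bp_pos0 + 1L, strand = strand,
                          intron_id = paste0(tx_id, ".i", k),
                          probability = round(runif(1, 0.5, 1), 3),
                          source = "synthetic"),
    truth = tibble(sno_id = sno_id, strand = strand, host_id = host$host_id,
                   total_introns = total_introns, sno_intron = k,
                   intron_length = intron_lens[k], dist_up = dist_up,
                   dist_down = dist_down, bp_offset = bp_offset,
                   stem_block_len = stem_block_len)
  )
}

#' Generate labels and replicate TPM tables from measured features
#'
#' P(expressed) = logistic(signal_scale x beta . z + intercept), where z
#' are the measured driver features standardised within the cohort
#' (population convention), so the coefficients are per-SD effects; the
#' intercept is solved so the mean probability matches the configured
#' expressed fraction; labels are sampled and flipped at the noise rate.
#' Expressed genes draw lognormal tissue means conditioned on exceeding
#' 1 TPM in at least one tissue; non-expressed genes draw uniform tissue
#' means below 1 TPM. Replicates are tissue mean times lognormal noise
#' renormalised so the replicate mean recovers the tissue mean exactly.
#'
#' @param features tibble with `sno_id`, `box_score`, `sno_stability`,
#'   `terminal_stem_stability`, `host_expressed` (0/1).
#' @param config a [synthetic_config()].
#' @return list: `labels` (sno_id, probability, label), `tissue_means`,
#'   `tpm` (replicate TPM tibble, first column `gene_id`), `design`.
#' @export
generate_labels_and_tpm <- function(features, config) {
  b <- config$beta
  zscore <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  }
  eta0 <- config$signal_scale *
    (b[["box_score"]] * zscore(features$box_score) +
       b[["sno_stability"]] * zscore(features$sno_stability) +
       b[["terminal_stem_stability"]] * zscore(features$terminal_stem_stability) +
       b[["host_expressed"]] * zscore(features$host_expressed))
  intercept <- uniroot(function(a) mean(stats::plogis(eta0 + a)) -
                         config$target_expressed_fraction,
                       interval = c(-200, 200))$root
  prob <- stats::plogis(eta0 + intercept)
  label <- rbinom(length(prob), 1L, prob)
  flip <- rbinom(length(prob), 1L, config$label_noise) == 1L
  label[flip] <- 1L - label[flip]
  tp <- sample_tpm(features$sno_id, label, config)
  list(labels = tibble(sno_id = features$sno_id, probability = prob,
                       label = label, intercept = intercept),
       tissue_means = tp$tissue_means, tpm = tp$tpm, design = tp$design)
}

# Replicate TPM tables consistent with a 0/1 label vector.
sample_tpm <- function(gene_ids, label, config) {
  Tn <- config$n_tissues; R <- config$n_replicates
  tissues <- paste0("tissue", seq_len(Tn))
  means <- t(vapply(label, function(l) {
    if (l == 1L) {
      repeat {
        m <- rlnorm(Tn, config$tpm_meanlog, config$tpm_sdlog)
        if (max(m) > 1) break
      }
    } else {
      m <- runif(Tn, 0, 0.99)
    }
    m
  }, numeric(Tn)))
  reps <- matrix(0, length(gene_ids), Tn * R)
  cn <- character(Tn * R)
  for (t in seq_len(Tn)) for (r in seq_len(R)) cn[(t - 1) * R + r] <-
      paste0(tissues[t], "_rep", r)
  for (g in seq_along(gene_ids)) {
    for (t in seq_len(Tn)) {
      eps <- rlnorm(R, 0, 0.1)
      eps <- eps / mean(eps)              # replicate mean == tissue mean
      reps[g, (t - 1) * R + seq_len(R)] <- means[g, t] * eps
    }
  }
  colnames(reps) <- cn
  tm <- as_tibble(means, .name_repair = "minimal")
  names(tm) <- tissues
  list(tissue_means = bind_cols(tibble(gene_id = gene_ids), tm),
       tpm = bind_cols(tibble(gene_id = gene_ids), as_tibble(reps)),
       design = tibble(sample = cn, tissue = rep(tissues, each = R)))
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

write_gtf <- function(gtf, path) {
  attrs <- sprintf('gene_id "%s"; gene_biotype "%s";', gtf$gene_id, gtf$gene_biotype)
  has_tx <- !is.na(gtf$transcript_id)
  attrs[has_tx] <- sprintf('%s transcript_id "%s";', attrs[has_tx],
                           gtf$transcript_id[has_tx])
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   gtf$chrom, gtf$source, gtf$type, gtf$start, gtf$end,
                   gtf$score, gtf$strand, gtf$frame, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a full synthetic cohort on disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `branchpoints.tsv`, `metadata.tsv`,
#' `sno_tpm.tsv`, `host_tpm.tsv`, `design.tsv` and `manifest.json` under
#' `outdir`. The pipeline is run on the emitted files to measure the four
#' driver features, from which labels and TPM tables are generated. A
#' fixed seed yields byte-identical files.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created if needed).
#' @param engine folding engine for the measured features.
#' @return invisibly, a list with the file `paths` and the `manifest`.
#' @export
generate_cohort <- function(config, outdir, engine = default_engine()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  n <- config$n_snornas
  set.seed(derive_seed(config$seed, 11L))
  sno_type <- ifelse(runif(n) < config$cd_fraction, "CD", "HACA")
  hosted <- runif(n) >= config$intergenic_fraction
  host_expressed <- hosted & (runif(n) < config$host_expressed_prob)
  biotype <- ifelse(runif(n) < config$protein_coding_prob,
                    "protein_coding", "noncoding")
  seqs <- list(); gtf <- list(); bps <- list(); truth <- list(); planted <- list()
  for (i in seq_len(n)) {
    id <- sprintf("SNO%04d", i)
    motifs <- if (sno_type[i] == "CD") c("C", "D", "Dprime", "Cprime") else c("H", "ACA")
    deg <- setNames(trunc_geom(length(motifs), config$degeneration_p,
                               c(C = 7, D = 4, Dprime = 4, Cprime = 7,
                                 H = 6, ACA = 3)[motifs]), motifs)
    sno <- generate_snorna(sno_type[i], deg)
    host <- if (hosted[i]) list(host_id = sprintf("HOST%04d", i),
                                biotype = biotype[i]) else NULL
    loc <- generate_locus(sno, id, sprintf("chr%d", i),
                          stem_block_len = sample(0:config$stem_block_max, 1),
                          host = host)
    seqs[[sprintf("chr%d", i)]] <- loc$seq
    gtf[[i]] <- loc$gtf
    bps[[i]] <- loc$branchpoints
    truth[[i]] <- loc$truth |> mutate(sno_type = sno_type[i],
                                      host_expressed_truth = host_expressed[i])
    planted[[i]] <- sno$planted |> mutate(sno_id = id)
  }
  gtf <- bind_rows(gtf); bps <- bind_rows(bps); truth <- bind_rows(truth)
  # categorical metadata
  set.seed(derive_seed(config$seed, 12L))
  hosted_fun <- c("ribosomal_protein", "ribosome_biogenesis", "RNA_processing",
                  "functional_ncRNA", "nonfunctional_ncRNA", "other",
                  "poorly_characterized")
  metadata <- tibble(
    sno_id = truth$sno_id, sno_type = sno_type,
    target = sample(c("rRNA", "snRNA", "orphan"), n, replace = TRUE,
                    prob = c(0.5, 0.2, 0.3)),
    host_function = ifelse(hosted, sample(hosted_fun, n, replace = TRUE),
                           "intergenic"),
    promoter = ifelse(hosted,
                      ifelse(runif(n) < config$dual_promoter_prob,
                             "dual_initiation", "single_initiation"),
                      "intergenic"),
    nmd = ifelse(hosted, ifelse(runif(n) < config$nmd_prob,
                                "NMD_sensitive", "NMD_insensitive"),
                 "intergenic")
  )
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gtf = file.path(outdir, "annotation.gtf"),
    branchpoints = file.path(outdir, "branchpoints.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    sno_tpm = file.path(outdir, "sno_tpm.tsv"),
    host_tpm = file.path(outdir, "host_tpm.tsv"),
    design = file.path(outdir, "design.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_fasta(seqs, paths$genome)
  write_gtf(gtf, paths$gtf)
  readr::write_tsv(bps, paths$branchpoints)
  readr::write_tsv(metadata, paths$metadata)
  # measure the driver features from the emitted files
  genome <- read_genome(paths$genome)
  anno <- read_annotation(paths$gtf)
  snos <- load_snornas(anno, genome)
  boxes <- score_boxes(snos |> left_join(metadata |> select("sno_id", "sno_type"),
                                         by = "sno_id"),
                       engine = engine)
  flanks <- extract_flanks(snos, genome)
  stems <- stem_features(snos |>
                           left_join(metadata |> select("sno_id", "sno_type"), by = "sno_id") |>
                           left_join(flanks, by = "sno_id"),
                         engine = engine)
  measured <- tibble(sno_id = snos$sno_id) |>
    left_join(metadata |> select("sno_id", "sno_type"), by = "sno_id") |>
    left_join(boxes |> select("sno_id", "box_score"), by = "sno_id") |>
    left_join(fold_global(snos, engine = engine) |>
                select("sno_id", "sno_stability"), by = "sno_id") |>
    left_join(stems |> select("sno_id", "terminal_stem_stability"), by = "sno_id") |>
    left_join(truth |> select("sno_id", host_expressed = "host_expressed_truth"),
              by = "sno_id") |>
    mutate(host_expressed = as.integer(.data$host_expressed))
  set.seed(derive_seed(config$seed, 13L))
  gen <- generate_labels_and_tpm(measured, config)
  readr::write_tsv(gen$tpm, paths$sno_tpm)
  readr::write_tsv(gen$design, paths$design)
  # host-level TPM table consistent with the host_expressed truth
  host_rows <- truth |> filter(!is.na(.data$host_id))
  set.seed(derive_seed(config$seed, 14L))
  host_tp <- sample_tpm(host_rows$host_id,
                        as.integer(host_rows$host_expressed_truth), config)
  readr::write_tsv(host_tp$tpm, paths$host_tpm)
  manifest <- list(
    config = config[setdiff(names(config), "beta")],
    beta = as.list(config$beta),
    truth = truth |> left_join(gen$labels, by = "sno_id") |>
      left_join(measured |> select("sno_id", "box_score", "sno_stability",
                                   "terminal_stem_stability", "host_expressed"),
                by = "sno_id"),
    planted_motifs = bind_rows(planted)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = 10)
  invisible(list(paths = paths, manifest = manifest))
}
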