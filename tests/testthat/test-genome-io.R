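write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

toy_gene <- function() {
  a <- 'gene_id "g1"; gene_biotype "protein_coding";'
  t <- paste(a, 'transcript_id "g1.t1";')
  c(paste("chr1\tsrc\tgene\t100\t200\t.\t+\t.", a, sep = "\t"),
    paste("chr1\tsrc\ttranscript\t100\t200\t.\t+\t.", t, sep = "\t"),
    paste("chr1\tsrc\texon\t100\t120\t.\t+\t.", t, sep = "\t"),
    paste("chr1\tsrc\texon\t180\t200\t.\t+\t.", t, sep = "\t"))
}

test_that("GTF ingestion converts coordinates and derives introns", {
  anno <- read_annotation(write_toy_gtf(toy_gene()))
  expect_equal(anno$genes$start, 99L)     # 1-based 100 -> 0-based 99
  expect_equal(anno$genes$end, 200L)
  expect_equal(nrow(anno$introns), 1)
  expect_equal(anno$introns$start, 120L)  # internal coords [120, 179)
  expect_equal(anno$introns$end, 179L)
  expect_equal(anno$introns$intron_rank5p, 1L)
  # round trip back to GTF convention
  back <- to_gtf_coords(anno$genes)
  expect_equal(back$start, 100L)
  expect_equal(back$end, 200L)
})

test_that("exonless transcripts are retained with zero introns and bad lines are located", {
  lines <- toy_gene()
  extra <- gsub("g1", "g2", lines[2], fixed = TRUE)
  anno <- read_annotation(write_toy_gtf(c(lines, extra)))
  expect_true("g2.t1" %in% anno$transcripts$transcript_id)
  expect_false("g2.t1" %in% anno$introns$transcript_id)

  bad <- write_toy_gtf(c(lines[1:2], "chr1\tonly\tthree"))
  expect_error(read_annotation(bad), "line 3")
})

test_that("host assignment is same-strand, smallest-containing, else intergenic", {
  genes <- tibble::tibble(
    chrom = "chr1", start = c(100L, 50L, 140L), end = c(500L, 800L, 260L),
    strand = c("+", "+", "+"),
    gene_id = c("big", "bigger", "small"),
    gene_biotype = c("protein_coding", "protein_coding", "noncoding"))
  sno <- tibble::tibble(sno_id = "s1", chrom = "chr1", start = 150L, end = 230L,
                        strand = "+")
  expect_warning(a <- assign_host(sno, genes), "candidate hosts")
  expect_equal(a$host_id, "small")      # smallest fully containing gene
  expect_equal(a$host_biotype, "noncoding")

  # brute-force overlap scan agrees on the candidate set
  cand <- genes$gene_id[genes$start < sno$end & genes$end > sno$start &
                          genes$strand == sno$strand]
  expect_true(a$host_id %in% cand)

  # opposite strand only: intergenic
  sno_m <- sno |> dplyr::mutate(strand = "-")
  am <- assign_host(sno_m, genes)
  expect_true(is.na(am$host_id))
  expect_equal(am$host_biotype, "intergenic")
})

test_that("intron context ranks and distances satisfy their identities", {
  # host with 4 introns on +, snoRNA inside the 3rd from the 5' end
  a <- 'gene_id "h"; gene_biotype "protein_coding";'
  t <- paste(a, 'transcript_id "h.t1";')
  ex <- c("100\t150", "250\t300", "400\t450", "550\t600", "700\t750")
  lines <- c(paste("chr1\tsrc\tgene\t100\t750\t.\t+\t.", a, sep = "\t"),
             paste("chr1\tsrc\ttranscript\t100\t750\t.\t+\t.", t, sep = "\t"),
             vapply(ex, function(e) paste0("chr1\tsrc\texon\t", e, "\t.\t+\t.\t", t),
                    character(1)))
  anno <- read_annotation(write_toy_gtf(lines))
  sno <- tibble::tibble(sno_id = "s", chrom = "chr1", start = 480L, end = 520L,
                        strand = "+")
  asg <- tibble::tibble(sno_id = "s", host_id = "h", host_biotype = "protein_coding")
  ctx <- derive_intron_context(sno, asg, anno)
  expect_equal(ctx$context_status, "intronic")
  expect_equal(ctx$total_introns, 4L)
  expect_equal(ctx$rank_5p, 3L)
  expect_equal(ctx$rank_3p, 2L)
  expect_equal(ctx$relative_rank_3p, 0.5)
  expect_equal(ctx$rank_5p + ctx$rank_3p, ctx$total_introns + 1L)
  expect_equal(ctx$dist_upstream_exon + (sno$end - sno$start) +
                 ctx$dist_downstream_exon, ctx$intron_length)
  expect_equal(ctx$dist_upstream_exon, 480L - 450L)

  # snoRNA overlapping an exon is flagged exonic with missing features
  sno_ex <- tibble::tibble(sno_id = "s", chrom = "chr1", start = 430L,
                           end = 470L, strand = "+")
  ctx_ex <- derive_intron_context(sno_ex, asg, anno)
  expect_equal(ctx_ex$context_status, "exonic")
  expect_true(is.na(ctx_ex$intron_length))
})

test_that("single-intron hosts give rank 1 and relative rank 1", {
  anno <- read_annotation(write_toy_gtf(toy_gene()))
  sno <- tibble::tibble(sno_id = "s", chrom = "chr1", start = 130L, end = 170L,
                        strand = "+")
  asg <- tibble::tibble(sno_id = "s", host_id = "g1", host_biotype = "protein_coding")
  ctx <- derive_intron_context(sno, asg, anno)
  expect_equal(ctx$rank_5p, 1L)
  expect_equal(ctx$rank_3p, 1L)
  expect_equal(ctx$relative_rank_3p, 1.0)
})

test_that("branchpoint selection takes highest probability, ties to nearer", {
  expect_equal(distance_to_branchpoint(1000L, c(1040L, 1100L), c(0.9, 0.3)), 40L)
  expect_equal(distance_to_branchpoint(1000L, c(1040L, 1020L), c(0.5, 0.5)), 20L)
  expect_true(is.na(distance_to_branchpoint(1000L, integer(0), numeric(0))))

  set.seed(21)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    pos <- sample(500:2000, k)
    pr <- round(runif(k), 3)
    sno3p <- sample(500:2000, 1)
    got <- distance_to_branchpoint(sno3p, pos, pr)
    # brute-force argmax-then-subtract oracle
    cand <- which(pr == max(pr))
    exp_d <- min(abs(pos[cand] - sno3p))
    expect_equal(got, exp_d)
  }
})

test_that("flank extraction is strand-symmetric and matches a slicing oracle", {
  set.seed(3)
  chrom <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  genome <- c(chr1 = chrom)
  sno <- tibble::tibble(sno_id = "p", chrom = "chr1", start = 100L, end = 180L,
                        strand = "+")
  fl <- extract_flanks(sno, genome)
  expect_equal(fl$flank_up, substr(chrom, 86, 100))     # genome[85:100) 0-based
  expect_equal(fl$flank_down, substr(chrom, 181, 195))

  # minus strand: reverse complement of the mirrored windows
  sno_m <- sno |> dplyr::mutate(strand = "-")
  flm <- extract_flanks(sno_m, genome)
  expect_equal(flm$flank_up, revcomp(substr(chrom, 181, 195)))
  expect_equal(flm$flank_down, revcomp(substr(chrom, 86, 100)))

  # extracting from the reverse-complemented genome at mirrored coordinates
  # reproduces the plus-strand flanks
  L <- nchar(chrom)
  genome_rc <- c(chr1 = revcomp(chrom))
  sno_rc <- tibble::tibble(sno_id = "p", chrom = "chr1",
                           start = L - 180L, end = L - 100L, strand = "-")
  fl_rc <- extract_flanks(sno_rc, genome_rc)
  expect_equal(fl_rc$flank_up, fl$flank_up)
  expect_equal(fl_rc$flank_down, fl$flank_down)

  # random loci vs an independent Biostrings oracle
  bs <- Biostrings::DNAString(chrom)
  for (i in 1:25) {
    s0 <- sample(50:300, 1); e0 <- s0 + sample(20:60, 1)
    st <- sample(c("+", "-"), 1)
    got <- extract_flanks(tibble::tibble(sno_id = "r", chrom = "chr1",
                                         start = s0, end = e0, strand = st),
                          genome)
    if (st == "+") {
      expect_equal(got$flank_up,
                   as.character(Biostrings::subseq(bs, s0 - 14, s0)))
      expect_equal(got$flank_down,
                   as.character(Biostrings::subseq(bs, e0 + 1, e0 + 15)))
    } else {
      expect_equal(got$flank_up,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::subseq(bs, e0 + 1, e0 + 15))))
      expect_equal(got$flank_down,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::subseq(bs, s0 - 14, s0))))
    }
  }

  # chromosome edge: truncated with a warning
  edge <- tibble::tibble(sno_id = "e", chrom = "chr1", start = 5L, end = 40L,
                         strand = "+")
  expect_warning(fe <- extract_flanks(edge, genome), "truncated")
  expect_equal(nchar(fe$flank_up), 5L)
})
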