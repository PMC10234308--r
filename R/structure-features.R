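# Global folding stability and the terminal stem.
#
# The terminal stem is the duplex formed by the regions flanking a snoRNA:
# 15 genomic nt on each side, extended into the snoRNA body by 5 nt at the
# 5' end and by 5 (C/D) or 3 (H/ACA) nt at the 3' end. Its co-fold free
# energy is the stem stability; the stem length score approximates stem
# length as intermolecular paired nucleotides minus gap nucleotides.

FLANK_LEN <- 15L
STEM_EXT <- list(CD = c(ext5 = 5L, ext3 = 5L), HACA = c(ext5 = 5L, ext3 = 3L))

#' Global folding stability of snoRNA sequences
#'
#' Runs the folding engine on each sequence and reports the minimum free
#' energy structure. The MFE (kcal/mol) is the `sno_stability` feature.
#'
#' @param snornas data frame with columns `sno_id` and `sequence`.
#' @param engine folding engine; see [default_engine()].
#' @return tibble: `sno_id`, `structure` (dot-bracket), `sno_stability`.
#' @export
fold_global <- function(snornas, engine = default_engine()) {
  stopifnot(all(c("sno_id", "sequence") %in% names(snornas)))
  abort_if(any(nchar(snornas$sequence) == 0), "empty sequence supplied")
  res <- engine$fold(snornas$sequence)
  tibble(sno_id = snornas$sno_id, structure = res$structure,
         sno_stability = res$mfe)
}

#' Build the two terminal-stem strands
#'
#' The 5' strand is the upstream flank plus the first 5 snoRNA nucleotides;
#' the 3' strand is the last 5 (C/D) or last 3 (H/ACA) snoRNA nucleotides
#' plus the downstream flank. The ACA motif, sitting 3 nt from the H/ACA 3'
#' end, is assumed not to participate in stem pairing, hence the shorter
#' 3' extension for that type.
#'
#' @param sequence snoRNA sequence (5'->3').
#' @param upstream,downstream flanking sequences from [extract_flanks()],
#'   both 5'->3' in snoRNA orientation.
#' @param sno_type "CD" or "HACA".
#' @return list with `strand5` and `strand3`.
#' @export
build_stem_strands <- function(sequence, upstream, downstream, sno_type) {
  abort_if(!sno_type %in% names(STEM_EXT), paste("unknown sno_type:", sno_type))
  ext <- STEM_EXT[[sno_type]]
  min_len <- ext["ext5"] + ext["ext3"]
  abort_if(nchar(sequence) < min_len,
           sprintf("snoRNA too short for stem strands: need >= %d nt", min_len))
  n <- nchar(sequence)
  list(
    strand5 = paste0(upstream, substr(sequence, 1L, ext["ext5"])),
    strand3 = paste0(substr(sequence, n - ext["ext3"] + 1L, n), downstream)
  )
}

#' Parse a co-fold dot-bracket structure into a pair map
#'
#' The structure string contains `&` separating the two strands. Pairs are
#' recovered with a bracket stack over the concatenated structure; a pair is
#' intermolecular when its partners sit on different strands.
#'
#' @param structure dot-bracket string with a single `&` separator.
#' @return list: `pairs` (tibble `i`, `j`, `intermolecular`; positions are
#'   1-based in the concatenation of the two strands), `n5`, `n3`,
#'   `state` (character vector of per-position symbols without the `&`).
#' @export
parse_cofold_pairs <- function(structure) {
  amp <- regexpr("&", structure, fixed = TRUE)[1]
  abort_if(amp < 0, "co-fold structure must contain '&'")
  flat <- sub("&", "", structure, fixed = TRUE)
  n5 <- amp - 1L
  ch <- strsplit(flat, "", fixed = TRUE)[[1]]
  n <- length(ch)
  stack <- integer(0)
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(n)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      abort_if(length(stack) == 0L, "unbalanced brackets in structure")
      ii <- c(ii, stack[length(stack)])
      jj <- c(jj, k)
      stack <- stack[-length(stack)]
    }
  }
  abort_if(length(stack) != 0L, "unbalanced brackets in structure")
  pairs <- tibble(i = ii, j = jj) |>
    mutate(intermolecular = .data$i <= n5 & .data$j > n5) |>
    arrange(.data$i)
  list(pairs = pairs, n5 = n5, n3 = n - n5, state = ch)
}

#' Co-fold the two terminal-stem strands
#'
#' @param strand5,strand3 the strands from [build_stem_strands()].
#' @param engine folding engine.
#' @return a `sno_duplex` object: list with `strand5`, `strand3`,
#'   `structure`, `mfe` (the `terminal_stem_stability` feature) and the
#'   parsed pair map (`pairs`, `n5`, `n3`, `state`).
#' @export
cofold_stem <- function(strand5, strand3, engine = default_engine()) {
  abort_if(nchar(strand5) == 0 || nchar(strand3) == 0,
           "both stem strands must be non-empty")
  res <- engine$cofold(strand5, strand3)
  parsed <- parse_cofold_pairs(res$structure[1])
  structure(
    c(list(strand5 = strand5, strand3 = strand3,
           structure = res$structure[1], mfe = res$mfe[1]),
      parsed),
    class = "sno_duplex"
  )
}

#' Terminal stem length score
#'
#' Counts nucleotides engaged in intermolecular pairs (2 per pair in the
#' default `"nucleotides"` mode, 1 in `"pairs"` mode) minus gap nucleotides:
#' unpaired positions lying strictly between the outermost and innermost
#' intermolecular pair on each strand. Zero intermolecular pairs score 0.
#'
#' @param duplex a `sno_duplex` from [cofold_stem()].
#' @param mode `"nucleotides"` (default) or `"pairs"`.
#' @return integer score.
#' @export
stem_length_score <- function(duplex, mode = c("nucleotides", "pairs")) {
  mode <- match.arg(mode)
  inter <- duplex$pairs |> filter(.data$intermolecular)
  if (nrow(inter) == 0L) return(0L)
  paired_nt <- if (mode == "nucleotides") 2L * nrow(inter) else nrow(inter)
  gap_on <- function(pos) {
    if (length(pos) < 2L) return(0L)
    span <- (min(pos) + 1L):(max(pos) - 1L)
    span <- setdiff(span, pos)
    sum(duplex$state[span] == ".")
  }
  gaps <- gap_on(inter$i) + gap_on(inter$j)
  as.integer(paired_nt - gaps)
}

#' Terminal-stem features for a table of snoRNAs
#'
#' Builds the stem strands, co-folds them in one engine batch and derives
#' stability and length score per snoRNA.
#'
#' @param snornas data frame with columns `sno_id`, `sequence`, `sno_type`,
#'   `flank_up`, `flank_down`.
#' @param engine folding engine.
#' @param mode length-score counting mode, see [stem_length_score()].
#' @return tibble: `sno_id`, `strand5`, `strand3`, `stem_structure`,
#'   `terminal_stem_stability`, `terminal_stem_length_score`,
#'   `n_intermolecular_pairs`.
#' @export
stem_features <- function(snornas, engine = default_engine(),
                          mode = c("nucleotides", "pairs")) {
  mode <- match.arg(mode)
  stopifnot(all(c("sno_id", "sequence", "sno_type", "flank_up", "flank_down")
                %in% names(snornas)))
  strands <- purrr::pmap(
    list(snornas$sequence, snornas$flank_up, snornas$flank_down, snornas$sno_type),
    function(s, u, d, t) build_stem_strands(s, u, d, t)
  )
  s5 <- vapply(strands, `[[`, character(1), "strand5")
  s3 <- vapply(strands, `[[`, character(1), "strand3")
  res <- engine$cofold(s5, s3)
  scored <- purrr::map2(res$structure, seq_along(s5), function(st, k) {
    parsed <- parse_cofold_pairs(st)
    dup <- structure(c(list(strand5 = s5[k], strand3 = s3[k],
                            structure = st, mfe = res$mfe[k]), parsed),
                     class = "sno_duplex")
    tibble(terminal_stem_length_score = stem_length_score(dup, mode),
           n_intermolecular_pairs = sum(parsed$pairs$intermolecular))
  })
  bind_cols(
    tibble(sno_id = snornas$sno_id, strand5 = s5, strand3 = s3,
           stem_structure = res$structure, terminal_stem_stability = res$mfe),
    bind_rows(scored)
  )
}
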