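# Box motif detection and the per-snoRNA box score.
#
# C/D box snoRNAs carry C (RUGAUGA) and D (CUGA) boxes near their 5' and 3'
# ends plus internal C'/D' copies; H/ACA box snoRNAs carry an H box (ANANNA)
# in the unpaired hinge and an ACA motif near the 3' end. Each motif found is
# scored by its Hamming distance to the consensus; a motif that cannot be
# identified contributes its full length, so the box score ranges over
# [0, 22] for C/D (7 + 4 + 7 + 4) and {0, 3, 6, 9} for H/ACA (6 + 3).

MOTIFS <- list(
  C      = list(consensus = "RUGAUGA", len = 7L, max_mismatch = 3L),
  D      = list(consensus = "CUGA",    len = 4L, max_mismatch = 2L),
  Cprime = list(consensus = "RUGAUGA", len = 7L, max_mismatch = NA_integer_),
  Dprime = list(consensus = "CUGA",    len = 4L, max_mismatch = NA_integer_),
  H      = list(consensus = "ANANNA",  len = 6L, max_mismatch = 0L),
  ACA    = list(consensus = "ACA",     len = 3L, max_mismatch = 0L)
)

TERMINAL_SEARCH_WINDOW <- 20L  # C and D boxes confined to terminal 20 nt

motif_miss <- function(kind) {
  tibble(kind = kind, start = NA_integer_, observed = NA_character_,
         hamming = MOTIFS[[kind]]$len, found = FALSE)
}

motif_hit <- function(kind, start0, seq) {
  m <- MOTIFS[[kind]]
  obs <- substr(seq, start0 + 1L, start0 + m$len)
  tibble(kind = kind, start = as.integer(start0), observed = obs,
         hamming = hamming(obs, m$consensus), found = TRUE)
}

# Shared terminal-window search: candidate start offsets (0-based) are those
# placing the whole motif inside the window; exact consensus wins, otherwise
# the minimum-Hamming candidate under the mismatch cap, ties resolved toward
# the relevant terminus (5' for C, 3' for D).
search_window <- function(seq, kind, window_starts, prefer_3p) {
  m <- MOTIFS[[kind]]
  if (length(window_starts) == 0L) return(motif_miss(kind))
  prof <- hamming_profile(seq, m$consensus)
  cand <- window_starts[window_starts + 1L <= length(prof)]
  if (length(cand) == 0L) return(motif_miss(kind))
  h <- prof[cand + 1L]
  keep <- h <= m$max_mismatch
  if (!any(keep)) return(motif_miss(kind))
  cand <- cand[keep]; h <- h[keep]
  best <- which(h == min(h))
  pick <- if (prefer_3p) best[length(best)] else best[1L]
  motif_hit(kind, cand[pick], seq)
}

#' Locate the C box (RUGAUGA) in the first 20 nt of a snoRNA
#'
#' Exact consensus matches take priority; otherwise up to 3 mismatches are
#' tolerated and no motif is returned beyond that. Equal-Hamming candidates
#' resolve to the one nearest the 5' end.
#'
#' @param seq snoRNA sequence (RNA alphabet, 5'->3').
#' @return one-row tibble: kind, start (0-based, NA if absent), observed,
#'   hamming (full motif length when absent), found.
#' @export
find_c_box <- function(seq) {
  seq <- dna_to_rna(seq)
  n <- nchar(seq)
  if (n < MOTIFS$C$len) return(motif_miss("C"))
  last_start <- min(TERMINAL_SEARCH_WINDOW, n) - MOTIFS$C$len
  if (last_start < 0L) return(motif_miss("C"))
  search_window(seq, "C", 0:last_start, prefer_3p = FALSE)
}

#' Locate the D box (CUGA) in the last 20 nt of a snoRNA
#'
#' Up to 2 mismatches tolerated; equal-Hamming ties resolve to the candidate
#' nearest the 3' end.
#'
#' @inheritParams find_c_box
#' @return one-row tibble as in [find_c_box()].
#' @export
find_d_box <- function(seq) {
  seq <- dna_to_rna(seq)
  n <- nchar(seq)
  if (n < MOTIFS$D$len) return(motif_miss("D"))
  win_lo <- max(0L, n - TERMINAL_SEARCH_WINDOW)
  starts <- win_lo:(n - MOTIFS$D$len)
  search_window(seq, "D", starts, prefer_3p = TRUE)
}

#' Locate the best C'/D' pair in the snoRNA interior
#'
#' The pair minimising hamming(D' vs CUGA) + hamming(C' vs RUGAUGA) is chosen
#' over the region between the 21st and 21st-to-last nucleotide, with the D'
#' box strictly upstream of (non-overlapping with) the C' box. No mismatch cap
#' applies; a pair is always returned when the region admits one (>= 11 nt).
#' Ties resolve to the smallest D' offset, then the smallest C' offset.
#'
#' @inheritParams find_c_box
#' @return two-row tibble (Dprime then Cprime rows) as in [find_c_box()].
#' @export
find_cprime_dprime <- function(seq) {
  seq <- dna_to_rna(seq)
  n <- nchar(seq)
  lo <- TERMINAL_SEARCH_WINDOW                 # 0-based region start (21st nt)
  hi <- n - TERMINAL_SEARCH_WINDOW - 1L        # 0-based region end (21st-to-last)
  region_len <- hi - lo + 1L
  need <- MOTIFS$Dprime$len + MOTIFS$Cprime$len
  if (region_len < need) {
    return(bind_rows(motif_miss("Dprime"), motif_miss("Cprime")))
  }
  region <- substr(seq, lo + 1L, hi + 1L)
  ham_d <- hamming_profile(region, MOTIFS$Dprime$consensus)
  ham_c <- hamming_profile(region, MOTIFS$Cprime$consensus)
  nc <- length(ham_c)
  # suffix argmin over C' profile, ties to the smallest offset
  suf_val <- rep(Inf, nc + 1L)
  suf_idx <- rep(NA_integer_, nc + 1L)
  for (i in nc:1L) {
    if (ham_c[i] <= suf_val[i + 1L]) {
      suf_val[i] <- ham_c[i]; suf_idx[i] <- i
    } else {
      suf_val[i] <- suf_val[i + 1L]; suf_idx[i] <- suf_idx[i + 1L]
    }
  }
  best_total <- Inf; best_d <- NA_integer_; best_c <- NA_integer_
  for (p in seq_along(ham_d)) {
    cpos <- p + MOTIFS$Dprime$len              # first C' start after D' ends
    if (cpos > nc) break
    tot <- ham_d[p] + suf_val[cpos]
    if (tot < best_total) {
      best_total <- tot; best_d <- p; best_c <- suf_idx[cpos]
    }
  }
  if (!is.finite(best_total)) {
    return(bind_rows(motif_miss("Dprime"), motif_miss("Cprime")))
  }
  bind_rows(
    motif_hit("Dprime", lo + best_d - 1L, seq),
    motif_hit("Cprime", lo + best_c - 1L, seq)
  )
}

#' Locate the H box (ANANNA) in unpaired hinge regions
#'
#' Exact matches only; the first occurrence (5'->3') whose six positions are
#' all unpaired ('.') in the supplied secondary structure is returned. When no
#' structure is given the search falls back to the interior region (positions
#' 21 to 21st-to-last) with a warning.
#'
#' @inheritParams find_c_box
#' @param structure dot-bracket string of the same length as `seq`, or NULL.
#' @return one-row tibble as in [find_c_box()].
#' @export
find_h_box <- function(seq, structure = NULL) {
  seq <- dna_to_rna(seq)
  n <- nchar(seq)
  m <- MOTIFS$H
  if (n < m$len) return(motif_miss("H"))
  prof <- hamming_profile(seq, m$consensus)
  starts0 <- which(prof == 0L) - 1L
  if (is.null(structure)) {
    warning("no structure supplied; H box searched in interior positions only",
            call. = FALSE)
    lo <- TERMINAL_SEARCH_WINDOW
    hi <- n - TERMINAL_SEARCH_WINDOW - 1L
    starts0 <- starts0[starts0 >= lo & (starts0 + m$len - 1L) <= hi]
  } else {
    abort_if(nchar(structure) != n, "structure length must equal sequence length")
    dots <- strsplit(structure, "", fixed = TRUE)[[1]] == "."
    unp <- vapply(starts0, function(s) all(dots[(s + 1L):(s + m$len)]), logical(1))
    starts0 <- starts0[unp]
  }
  if (length(starts0) == 0L) return(motif_miss("H"))
  motif_hit("H", starts0[1L], seq)
}

#' Locate the ACA motif in the last 10 nt of a snoRNA
#'
#' Exact matches only; when several occur the 3'-most is returned (the
#' canonical position is 3 nt from the 3' end).
#'
#' @inheritParams find_c_box
#' @return one-row tibble as in [find_c_box()].
#' @export
find_aca_box <- function(seq) {
  seq <- dna_to_rna(seq)
  n <- nchar(seq)
  m <- MOTIFS$ACA
  if (n < m$len) return(motif_miss("ACA"))
  prof <- hamming_profile(seq, m$consensus)
  lo <- max(0L, n - 10L)
  starts0 <- which(prof == 0L) - 1L
  starts0 <- starts0[starts0 >= lo]
  if (length(starts0) == 0L) return(motif_miss("ACA"))
  motif_hit("ACA", starts0[length(starts0)], seq)
}

#' Box score of a snoRNA
#'
#' Sums the Hamming distances of the type's expected motifs: C + D + C' + D'
#' for C/D box snoRNAs (range 0-22), H + ACA for H/ACA box snoRNAs
#' (0, 3, 6 or 9). Unidentifiable motifs contribute their full length.
#'
#' @param seq snoRNA sequence.
#' @param sno_type "CD" or "HACA".
#' @param structure dot-bracket string for the H-box hinge search
#'   (see [find_h_box()]); ignored for C/D snoRNAs.
#' @return list with `hits` (tibble of per-motif hits) and `total`.
#' @export
box_score <- function(seq, sno_type, structure = NULL) {
  abort_if(!sno_type %in% c("CD", "HACA"), paste("unknown sno_type:", sno_type))
  hits <- if (sno_type == "CD") {
    bind_rows(find_c_box(seq), find_d_box(seq), find_cprime_dprime(seq))
  } else {
    bind_rows(find_h_box(seq, structure), find_aca_box(seq))
  }
  list(hits = hits, total = sum(hits$hamming))
}

#' Box scores for a table of snoRNAs
#'
#' Data-frame-first wrapper over [box_score()]. Structures for the H-box
#' hinge search are computed with the folding engine when not supplied.
#'
#' @param snornas data frame with columns `sno_id`, `sequence`, `sno_type`
#'   and optionally `structure`.
#' @param engine folding engine (used only for H/ACA rows lacking a
#'   `structure` column); see [default_engine()].
#' @return tibble with one row per snoRNA: `sno_id`, per-motif Hamming
#'   distances and offsets, and the total `box_score`.
#' @export
score_boxes <- function(snornas, engine = default_engine()) {
  stopifnot(all(c("sno_id", "sequence", "sno_type") %in% names(snornas)))
  snornas <- as_tibble(snornas)
  if (!"structure" %in% names(snornas)) snornas$structure <- NA_character_
  need <- snornas$sno_type == "HACA" & is.na(snornas$structure)
  if (any(need)) {
    snornas$structure[need] <- engine$fold(snornas$sequence[need])$structure
  }
  kinds <- c("C", "D", "Dprime", "Cprime", "H", "ACA")
  rows <- lapply(seq_len(nrow(snornas)), function(i) {
    row <- snornas[i, ]
    bs <- box_score(row$sequence, row$sno_type,
                    structure = if (is.na(row$structure)) NULL else row$structure)
    out <- list(sno_id = row$sno_id)
    for (k in kinds) {
      hit <- bs$hits[bs$hits$kind == k, ]
      out[[paste0(k, "_start")]] <- if (nrow(hit)) hit$start else NA_integer_
      out[[paste0(k, "_hamming")]] <- if (nrow(hit)) hit$hamming else NA_integer_
    }
    out$box_score <- bs$total
    tibble::as_tibble_row(out)
  })
  bind_rows(rows)
}
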