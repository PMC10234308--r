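# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain loops, scalar arithmetic.

# One folding engine per test run (ViennaRNA when available).
ENG <- snostatus::default_engine()

oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  d <- 0L
  for (k in seq_along(vb)) {
    ok <- va[k] == vb[k] || vb[k] == "N" ||
      (vb[k] == "R" && va[k] %in% c("A", "G"))
    if (!ok) d <- d + 1L
  }
  d
}

# Exhaustive sliding-window motif search with the windowed, capped,
# tie-toward-terminus rules.
oracle_terminal_box <- function(seq, consensus, window, cap, from_3p) {
  n <- nchar(seq)
  m <- nchar(consensus)
  if (n < m) return(list(found = FALSE, start = NA, hamming = m))
  if (from_3p) {
    starts <- seq(max(0L, n - window), n - m)
  } else {
    starts <- seq(0L, min(window, n) - m)
    if (min(window, n) - m < 0) return(list(found = FALSE, start = NA, hamming = m))
  }
  best <- NULL
  for (s in starts) {
    h <- oracle_hamming(substr(seq, s + 1, s + m), consensus)
    if (h > cap) next
    # toward 5': first (smallest s) equal-Hamming candidate wins, so only
    # strict improvement replaces; toward 3': a later candidate wins ties
    if (is.null(best) || h < best$hamming || (h == best$hamming && from_3p))
      best <- list(found = TRUE, start = s, hamming = h)
  }
  if (is.null(best)) list(found = FALSE, start = NA, hamming = m) else best
}

# O(n^2) enumeration of all ordered non-overlapping D'/C' position pairs.
oracle_cprime_dprime <- function(seq) {
  n <- nchar(seq)
  lo <- 20L; hi <- n - 21L
  if (hi - lo + 1L < 11L) {
    return(list(found = FALSE, dp = NA, cp = NA, total = 11L))
  }
  dp_starts <- lo:(hi - 3L)
  best <- NULL
  for (dp in dp_starts) {
    hd <- oracle_hamming(substr(seq, dp + 1, dp + 4), "CUGA")
    if (dp + 4L > hi - 6L) next
    for (cp in (dp + 4L):(hi - 6L)) {
      hc <- oracle_hamming(substr(seq, cp + 1, cp + 7), "RUGAUGA")
      tot <- hd + hc
      if (is.null(best) || tot < best$total) {
        best <- list(found = TRUE, dp = dp, cp = cp, total = tot,
                     hd = hd, hc = hc)
      }
    }
  }
  if (is.null(best)) list(found = FALSE, dp = NA, cp = NA, total = 11L) else best
}

# Dot-bracket pair recovery by scalar stack walk (co-fold aware).
oracle_parse_pairs <- function(structure) {
  amp <- as.integer(regexpr("&", structure, fixed = TRUE))
  flat <- sub("&", "", structure, fixed = TRUE)
  ch <- strsplit(flat, "")[[1]]
  stack <- c(); pairs <- list()
  for (k in seq_along(ch)) {
    if (ch[k] == "(") stack <- c(stack, k)
    if (ch[k] == ")") {
      pairs[[length(pairs) + 1]] <- c(stack[length(stack)], k)
      stack <- stack[-length(stack)]
    }
  }
  list(pairs = pairs, n5 = amp - 1L, ch = ch)
}

# Independent stem length recount from the dot-bracket string.
oracle_stem_score <- function(structure) {
  pp <- oracle_parse_pairs(structure)
  inter <- Filter(function(p) p[1] <= pp$n5 && p[2] > pp$n5, pp$pairs)
  if (length(inter) == 0) return(0L)
  i5 <- sort(vapply(inter, `[`, numeric(1), 1))
  i3 <- sort(vapply(inter, `[`, numeric(1), 2))
  gap <- function(pos) {
    if (length(pos) < 2) return(0L)
    g <- 0L
    for (k in (min(pos) + 1):(max(pos) - 1)) {
      if (!(k %in% pos) && pp$ch[k] == ".") g <- g + 1L
    }
    g
  }
  as.integer(2L * length(inter) - gap(i5) - gap(i3))
}

# Shapley values by full enumeration of feature permutations (independent
# of the package's coalition-weighted enumeration and sampling schemes).
oracle_shapley_perms <- function(f, x_row, background) {
  p <- ncol(background)
  perms <- gtools_permutations(p)
  phi <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    M <- background
    v_prev <- mean(f(M))
    for (t in seq_len(p)) {
      j <- perms[r, t]
      M[, j] <- x_row[1, j]
      v <- mean(f(M))
      phi[j] <- phi[j] + (v - v_prev)
      v_prev <- v
    }
  }
  setNames(phi / nrow(perms), colnames(background))
}

gtools_permutations <- function(p) {
  if (p == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(p - 1)
  out <- NULL
  for (j in seq_len(p)) {
    rest <- setdiff(seq_len(p), j)
    out <- rbind(out, cbind(j, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Pairwise-concordance AUC (Mann-Whitney identity).
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

random_rna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Small labelled toy data: two well-separated gaussian clouds.
toy_classif <- function(n = 60, seed = 1, sep = 4) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(f1 = rnorm(n) + sep * y, f2 = rnorm(n) - sep * y)
  list(x = x, y = y)
}
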