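#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols rename n row_number across
#' @importFrom stats predict rnorm runif rbinom rlnorm sd var uniroot setNames
#' @importFrom utils head tail
NULL

# Nucleotide helpers ----------------------------------------------------------

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

#' Reverse-complement a DNA/RNA string
#'
#' Operates on plain character vectors; the complement of U is A and the
#' output alphabet follows the input (T in, T out; U in, U out).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    is_rna <- any(ch == "U")
    comp <- unname(DNA_COMPLEMENT[ch])
    comp[is.na(comp)] <- "N"
    if (is_rna) comp[comp == "T"] <- "U"
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert DNA to RNA alphabet (T to U, uppercased)
#' @param x character vector.
#' @return character vector in the RNA alphabet.
#' @export
dna_to_rna <- function(x) {
  chartr("tT", "uU", toupper(chartr("uU", "tT", x)))
}

#' Hamming distance between two equal-length strings
#'
#' Consensus symbols are honoured: `R` matches A or G, `N` matches anything.
#' The first argument is the observed string, the second the consensus.
#'
#' @param observed,consensus equal-length nucleotide strings.
#' @return integer mismatch count.
#' @export
hamming <- function(observed, consensus) {
  stopifnot(nchar(observed) == nchar(consensus))
  a <- strsplit(observed, "", fixed = TRUE)[[1]]
  b <- strsplit(consensus, "", fixed = TRUE)[[1]]
  ok <- a == b | b == "N" | (b == "R" & (a == "A" | a == "G"))
  sum(!ok)
}

# Vectorised Hamming profile of a consensus along a sequence: returns the
# mismatch count of consensus placed at every start offset 1..(n-m+1).
hamming_profile <- function(seq, consensus) {
  n <- nchar(seq)
  m <- nchar(consensus)
  if (n < m) return(integer(0))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  k <- n - m + 1L
  mism <- integer(k)
  for (j in seq_len(m)) {
    s <- ch[j:(j + k - 1L)]
    cj <- cons[j]
    ok <- s == cj | cj == "N" | (cj == "R" & (s == "A" | s == "G"))
    mism <- mism + !ok
  }
  mism
}

random_rna <- function(n, len, rng_probs = c(0.25, 0.25, 0.25, 0.25)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len[min(i, length(len))],
                 replace = TRUE, prob = rng_probs), collapse = "")
  }, character(1))
}

# Seed derivation: a single master seed drives every stochastic step through
# fixed offsets, keeping derived seeds within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}
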