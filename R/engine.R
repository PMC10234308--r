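# RNA folding engines.
#
# All structure/energy computation in the package goes through an engine
# object: a list with `name`, `fold(seqs)` and `cofold(seq5, seq3)` members.
# The default engine shells out to the ViennaRNA command-line programs
# (RNAfold / RNAcofold) in batch; a built-in maximum-complementarity scorer
# is available as a clearly labelled NON-thermodynamic substitute.

#' Thermodynamic folding engine (ViennaRNA command line)
#'
#' Batches sequences through `RNAfold --noPS` / `RNAcofold --noPS`.
#' Deterministic for a fixed engine version; energies in kcal/mol.
#'
#' @return an engine object (list with `name`, `fold`, `cofold`).
#' @export
vienna_engine <- function() {
  abort_if(Sys.which("RNAfold") == "" || Sys.which("RNAcofold") == "",
           paste("ViennaRNA executables (RNAfold/RNAcofold) not found on PATH;",
                 "install ViennaRNA or select complementarity_engine()"))
  run <- function(prog, lines) {
    out <- suppressWarnings(system2(prog, "--noPS", stdout = TRUE,
                                    stderr = FALSE, input = lines))
    abort_if(!is.null(attr(out, "status")) && attr(out, "status") != 0,
             paste(prog, "failed on input:", paste(head(lines, 4), collapse = " ")))
    out
  }
  parse_out <- function(out, n) {
    # output triplets: >name / sequence / structure ( energy )
    hits <- grep("^>", out)
    abort_if(length(hits) != n, "unexpected folding engine output")
    struct_lines <- out[hits + 2L]
    m <- regmatches(struct_lines,
                    regexec("^(\\S+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", struct_lines))
    abort_if(any(lengths(m) != 3L), "could not parse folding engine output")
    tibble(
      structure = vapply(m, `[`, character(1), 2L),
      mfe = as.numeric(vapply(m, `[`, character(1), 3L))
    )
  }
  list(
    name = "vienna",
    fold = function(seqs) {
      if (length(seqs) == 0) return(tibble(structure = character(), mfe = numeric()))
      lines <- as.vector(rbind(paste0(">s", seq_along(seqs)), dna_to_rna(seqs)))
      parse_out(run("RNAfold", lines), length(seqs))
    },
    cofold = function(seq5, seq3) {
      stopifnot(length(seq5) == length(seq3))
      if (length(seq5) == 0) return(tibble(structure = character(), mfe = numeric()))
      lines <- as.vector(rbind(paste0(">d", seq_along(seq5)),
                               paste0(dna_to_rna(seq5), "&", dna_to_rna(seq3))))
      parse_out(run("RNAcofold", lines), length(seq5))
    }
  )
}

# Pair weight for the complementarity scorer: GC=3, AU=2, GU=1, else 0.
pair_weight_matrix <- function() {
  w <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  w["G", "C"] <- w["C", "G"] <- 3
  w["A", "U"] <- w["U", "A"] <- 2
  w["G", "U"] <- w["U", "G"] <- 1
  w
}

# Nussinov-style maximum-weight pairing with a 3-nt minimum hairpin loop.
# `cut` (0 = none) marks a strand boundary across which the loop constraint
# does not apply (co-folding two strands joined at the cut).
nussinov_fold <- function(seq, cut = 0L) {
  ch <- strsplit(dna_to_rna(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  w <- pair_weight_matrix()
  idx <- match(ch, rownames(w))
  M <- matrix(0, n, n)
  allowed <- function(i, j) (j - i > 3L) || (cut > 0L && i <= cut && j > cut)
  if (n >= 2) {
    for (span in 1:(n - 1L)) {
      for (i in 1:(n - span)) {
        j <- i + span
        best <- M[i, j - 1L]
        ks <- i:(j - 1L)
        ks <- ks[vapply(ks, function(k) allowed(k, j), logical(1))]
        if (length(ks)) {
          pw <- w[cbind(idx[ks], idx[j])]
          ks <- ks[pw > 0]
          pw <- pw[pw > 0]
          if (length(ks)) {
            left <- vapply(seq_along(ks), function(t) if (ks[t] > i) M[i, ks[t] - 1L] else 0, numeric(1))
            inner <- vapply(seq_along(ks), function(t) if (ks[t] + 1L <= j - 1L) M[ks[t] + 1L, j - 1L] else 0, numeric(1))
            cand <- left + inner + pw
            best <- max(best, max(cand))
          }
        }
        M[i, j] <- best
      }
    }
  }
  # traceback
  dots <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (j > i) {
      if (M[i, j] == M[i, j - 1L]) { j <- j - 1L; next }
      done <- FALSE
      for (k in i:(j - 1L)) {
        if (!allowed(k, j)) next
        pw <- w[idx[k], idx[j]]
        if (pw == 0) next
        left <- if (k > i) M[i, k - 1L] else 0
        inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0
        if (abs(M[i, j] - (left + inner + pw)) < 1e-9) {
          dots[k] <- "("; dots[j] <- ")"
          if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          if (k > i) { j <- k - 1L } else { done <- TRUE }
          break
        }
      }
      if (done) break
      if (j <= i) break
    }
  }
  score <- if (n >= 2) M[1, n] else 0
  list(structure = paste(dots, collapse = ""), mfe = -score / 2)
}

#' Maximum-complementarity folding engine (non-thermodynamic)
#'
#' A built-in substitute scorer that maximises summed pair weights
#' (GC = 3, AU = 2, GU = 1) under a 3-nt minimum loop, reporting
#' energy = -total weight / 2 in pseudo kcal/mol. It is NOT a thermodynamic
#' model: magnitudes are not comparable with ViennaRNA energies and should
#' only be used where no thermodynamic engine is available.
#'
#' @return an engine object (list with `name`, `fold`, `cofold`).
#' @export
complementarity_engine <- function() {
  list(
    name = "complementarity",
    fold = function(seqs) {
      res <- lapply(seqs, nussinov_fold)
      tibble(structure = vapply(res, `[[`, character(1), "structure"),
             mfe = vapply(res, `[[`, numeric(1), "mfe"))
    },
    cofold = function(seq5, seq3) {
      stopifnot(length(seq5) == length(seq3))
      res <- lapply(seq_along(seq5), function(i) {
        cut <- nchar(seq5[i])
        r <- nussinov_fold(paste0(seq5[i], seq3[i]), cut = cut)
        r$structure <- paste0(substr(r$structure, 1, cut), "&",
                              substr(r$structure, cut + 1L, nchar(seq5[i]) + nchar(seq3[i])))
        r
      })
      tibble(structure = vapply(res, `[[`, character(1), "structure"),
             mfe = vapply(res, `[[`, numeric(1), "mfe"))
    }
  )
}

#' Default folding engine
#'
#' Returns the ViennaRNA engine when its executables are on the PATH,
#' otherwise the (non-thermodynamic) complementarity engine with a warning.
#' Override globally with `options(snostatus.engine = <engine>)`.
#'
#' @return an engine object.
#' @export
default_engine <- function() {
  opt <- getOption("snostatus.engine", NULL)
  if (!is.null(opt)) return(opt)
  if (Sys.which("RNAfold") != "" && Sys.which("RNAcofold") != "") {
    vienna_engine()
  } else {
    warning("ViennaRNA not found; using the non-thermodynamic complementarity engine",
            call. = FALSE)
    complementarity_engine()
  }
}
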