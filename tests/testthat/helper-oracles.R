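# Independent oracles used across the suite. Each is deliberately written as
# plain enumeration / textbook recursion, not by calling the package's own
# code paths.

.b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# brute-force Smith-Waterman with affine gaps (gap of length L costs open + L*ext)
oracle_sw_score <- function(x, y, open = 11, ext = 1) {
  X <- strsplit(x, "")[[1]]
  Y <- strsplit(y, "")[[1]]
  n <- length(X); m <- length(Y)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      sc <- .b62[X[i], Y[j]]
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + sc)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# breadth-first connected components; returns list of sorted member vectors,
# sorted by (size desc, smallest member)
oracle_components <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    a <- edges$a[k]; b <- edges$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  comps <- list()
  for (root in ids) {
    if (seen[[root]]) next
    queue <- root
    seen[[root]] <- TRUE
    members <- character(0)
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      members <- c(members, v)
      for (w in adj[[v]]) {
        if (!seen[[w]]) {
          seen[[w]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  mins <- vapply(comps, `[`, character(1), 1)
  comps[order(-lengths(comps), mins)]
}

# six-frame ORF enumeration by walking each frame codon by codon; start
# codons outside the windows are invisible to the scan (a start is only
# "opened" when its codon lies inside a window)
oracle_orfs <- function(sequence, starts = c("ATG", "GTG", "TTG"),
                        min_len_aa = 20, max_len_aa = Inf, windows = NULL) {
  n <- nchar(sequence)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    w <- windows
    if (!is.null(windows) && strand == "-") {
      w <- data.frame(start = n - windows$end, end = n - windows$start)
    }
    for (f in 0:2) {
      i <- 1 + f
      open_at <- NA_integer_
      while (i + 2 <= n) {
        cod <- substr(s, i, i + 2)
        visible <- is.null(w) || any(i - 1L >= w$start & i + 2L <= w$end)
        if (is.na(open_at) && cod %in% starts && visible) open_at <- i
        if (cod %in% stops) {
          if (!is.na(open_at)) {
            len_aa <- (i - open_at) / 3
            span <- substr(s, open_at, i + 2)
            if (len_aa >= min_len_aa && len_aa <= max_len_aa &&
                !grepl("N", span, fixed = TRUE)) {
              # local (strand) coords, 0-based half-open incl stop
              a0 <- open_at - 1L
              b0 <- i + 2L
              if (strand == "-") {
                tmp <- n - b0
                b0 <- n - a0
                a0 <- tmp
              }
              out[[length(out) + 1L]] <- data.frame(
                start = a0, end = b0, strand = strand,
                length_aa = len_aa, stringsAsFactors = FALSE)
            }
          }
          open_at <- NA_integer_
        }
        i <- i + 3
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length_aa = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exhaustive maximal-tandem-array enumeration with primitive units and
# leftmost-phase collapsing
oracle_repeats <- function(pep, min_period = 2, max_period = 6, min_copies = 2) {
  s <- strsplit(pep, "")[[1]]
  n <- length(s)
  rows <- list()
  for (p in min_period:max_period) {
    if (n < 2 * p) next
    for (st in 1:(n - 2 * p + 1)) {
      unit <- paste(s[st:(st + p - 1)], collapse = "")
      k <- 1
      while (st + (k + 1) * p - 1 <= n &&
             paste(s[(st + k * p):(st + (k + 1) * p - 1)], collapse = "") == unit) {
        k <- k + 1
      }
      if (k < min_copies) next
      if (st - p >= 1 &&
          paste(s[(st - p):(st - 1)], collapse = "") == unit) next # left-extendable
      prim <- TRUE
      for (d in seq_len(p - 1)) {
        if (p %% d == 0 && strrep(substr(unit, 1, d), p / d) == unit) prim <- FALSE
      }
      if (!prim) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = st - 1L, unit = unit, period = p, copies = k, span = p * k,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), unit = character(0),
                      period = integer(0), copies = integer(0),
                      span = integer(0), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, rows)
  h <- h[order(h$period, h$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1]) {
    prev <- max(which(keep[seq_len(i - 1)] & h$period[seq_len(i - 1)] == h$period[i]),
                -Inf)
    if (is.finite(prev) && h$start[i] - h$start[prev] < h$period[i]) keep[i] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start, h$period), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# published monoisotopic residue masses (independent of the package's
# elemental-composition route)
REF_RESIDUE_MASS <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047679, W = 186.079313, Y = 163.063329, V = 99.068414
)
REF_WATER <- 18.010565

oracle_peptide_mass <- function(seq_) {
  sum(REF_RESIDUE_MASS[strsplit(seq_, "")[[1]]]) + REF_WATER
}

random_peptide <- function(min_len = 5, max_len = 30) {
  paste(sample(names(REF_RESIDUE_MASS), sample(min_len:max_len, 1), TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}
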