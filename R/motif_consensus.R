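# Conserved-core evidence for precursor candidates: progressive multiple
# alignment with per-column conservation, exact tandem-repeat detection, and
# residue-class pattern matching.

#' Progressive multiple alignment of candidate peptides
#'
#' Guide tree by single linkage on pairwise percent identity (global
#' alignments, BLOSUM62, gap open 10 / extend 0.5); profiles merged by
#' profile-profile Needleman-Wunsch with affine gaps under the same scoring.
#' Deterministic: ties in the guide tree are broken by input order.
#'
#' @param peptides character vector (>= 2) of amino-acid sequences, or a
#'   data frame with `peptide_id`/`peptide` columns.
#' @param gap_open,gap_extend affine gap penalties (defaults 10 and 0.5).
#' @param consensus_threshold minimum column conservation for a consensus
#'   letter (default 0.8; below it the consensus shows `.`).
#' @return An `msa_result`: list with `ids`, `aligned` (equal-length rows, gap
#'   `-`), `conservation` (per column, fraction of non-gap residues equal to
#'   the modal residue; all-gap columns score 0), and `consensus`.
#' @export
align_peptides <- function(peptides, gap_open = 10, gap_extend = 0.5,
                           consensus_threshold = 0.8) {
  if (is.data.frame(peptides)) {
    ids <- peptides$peptide_id
    seqs <- peptides$peptide
  } else {
    seqs <- as.character(peptides)
    ids <- if (!is.null(names(peptides))) names(peptides) else
      paste0("p", seq_along(seqs))
  }
  if (length(seqs) < 2) stop("need at least 2 peptides to align", call. = FALSE)
  seqs <- toupper(seqs)
  n <- length(seqs)
  mat <- .blosum62()
  # pairwise identities for the guide tree
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[i]), Biostrings::AAString(seqs[j]),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = gap_open, gapExtension = gap_extend)
      cols <- nchar(as.character(Biostrings::pattern(aln)))
      sim[i, j] <- sim[j, i] <- if (cols > 0) 100 * Biostrings::nmatch(aln) / cols else 0
    }
  }
  # single-linkage agglomeration; each cluster holds member indices + profile
  clusters <- lapply(seq_len(n), function(i) list(members = i, rows = seqs[i]))
  while (length(clusters) > 1) {
    best <- c(NA_integer_, NA_integer_)
    best_sim <- -Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        s <- max(sim[clusters[[i]]$members, clusters[[j]]$members])
        if (s > best_sim + 1e-12) {
          best_sim <- s
          best <- c(i, j)
        }
      }
    }
    merged <- .pp_align(clusters[[best[1]]]$rows, clusters[[best[2]]]$rows,
                        mat, gap_open, gap_extend)
    clusters[[best[1]]] <- list(
      members = c(clusters[[best[1]]]$members, clusters[[best[2]]]$members),
      rows = c(merged$A, merged$B))
    clusters[[best[2]]] <- NULL
  }
  rows <- clusters[[1]]$rows
  ord <- order(clusters[[1]]$members)
  rows <- rows[ord]
  cons <- .column_conservation(rows)
  structure(list(
    ids = ids,
    aligned = stats::setNames(rows, ids),
    conservation = cons$conservation,
    modal = cons$modal,
    consensus = .consensus_string(cons, consensus_threshold),
    threshold = consensus_threshold
  ), class = "msa_result")
}

#' @export
print.msa_result <- function(x, ...) {
  cat(sprintf("<msa_result> %d sequences x %d columns; consensus: %s\n",
              length(x$aligned), nchar(x$aligned[[1]]), x$consensus))
  invisible(x)
}

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# profile-profile global alignment (Gotoh affine) between two sets of aligned
# rows; column score = f_A' M f_B with frequencies over rows (gaps excluded).
.pp_align <- function(A, B, mat, open, ext) {
  letters_ <- .PROTEIN_ALPHABET
  prof <- function(rows) {
    m <- do.call(rbind, strsplit(rows, ""))
    L <- ncol(m)
    f <- matrix(0, nrow = length(letters_), ncol = L, dimnames = list(letters_, NULL))
    for (j in seq_len(L)) {
      tab <- table(factor(m[, j], levels = letters_))
      f[, j] <- as.numeric(tab) / nrow(m)
    }
    f
  }
  FA <- prof(A)
  FB <- prof(B)
  S <- t(FA) %*% mat[letters_, letters_] %*% FB
  La <- ncol(FA); Lb <- ncol(FB)
  NEG <- -1e9
  M <- matrix(NEG, La + 1, Lb + 1)
  Ix <- matrix(NEG, La + 1, Lb + 1) # gap in B (consume A column)
  Iy <- matrix(NEG, La + 1, Lb + 1) # gap in A (consume B column)
  M[1, 1] <- 0
  for (i in seq_len(La)) Ix[i + 1, 1] <- -open - ext * i
  for (j in seq_len(Lb)) Iy[1, j + 1] <- -open - ext * j
  for (i in seq_len(La)) {
    for (j in seq_len(Lb)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + S[i, j]
    }
  }
  # traceback from the best terminal state (ties prefer M, then Ix, then Iy)
  tol <- 1e-9
  argmax3 <- function(v) which(v >= max(v) - tol)[1]
  i <- La; j <- Lb
  state <- argmax3(c(M[La + 1, Lb + 1], Ix[La + 1, Lb + 1], Iy[La + 1, Lb + 1]))
  opsA <- character(La + Lb); opsB <- character(La + Lb)
  t <- La + Lb + 1L
  push <- function(a, b) {
    t <<- t - 1L
    opsA[t] <<- a
    opsB[t] <<- b
  }
  while (i > 0 || j > 0) {
    if (i == 0) state <- 3L
    if (j == 0) state <- 2L
    if (state == 1L) {
      push("c", "c")
      state <- argmax3(c(M[i, j], Ix[i, j], Iy[i, j]))
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      push("c", "g")
      from_m <- M[i, j + 1] - open - ext >= Ix[i, j + 1] - ext - tol
      i <- i - 1
      state <- if (from_m) 1L else 2L
    } else {
      push("g", "c")
      from_m <- M[i + 1, j] - open - ext >= Iy[i + 1, j] - ext - tol
      j <- j - 1
      state <- if (from_m) 1L else 3L
    }
  }
  opsA <- opsA[t:(La + Lb)]
  opsB <- opsB[t:(La + Lb)]
  expand <- function(rows, ops) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      out <- character(length(ops))
      k <- 0L
      for (t in seq_along(ops)) {
        if (ops[t] == "c") {
          k <- k + 1L
          out[t] <- ch[k]
        } else {
          out[t] <- "-"
        }
      }
      paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  list(A = expand(A, opsA), B = expand(B, opsB))
}

.column_conservation <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(m)
  conservation <- numeric(L)
  modal <- character(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    res <- col[col != "-"]
    if (!length(res)) {
      conservation[j] <- 0
      modal[j] <- "-"
    } else {
      tab <- sort(table(res), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      modal[j] <- sort(top)[1]
      conservation[j] <- max(tab) / length(res)
    }
  }
  list(conservation = conservation, modal = modal)
}

.consensus_string <- function(cons, threshold) {
  paste(ifelse(cons$conservation >= threshold & cons$modal != "-",
               cons$modal, "."), collapse = "")
}

#' Find maximal exact tandem repeats in a peptide
#'
#' Reports every maximal exact tandem array whose period lies in
#' `[min_period, max_period]` with at least `min_copies` full copies. Units
#' are primitive (a unit that is itself a tandem of a shorter unit, e.g.
#' `DCDC`, is reported through its shorter period only) and rotated phases of
#' the same array collapse to the leftmost start. Starts are 0-based.
#'
#' @param peptide amino-acid string.
#' @param min_period,max_period unit-length range (defaults 2 and 6).
#' @param min_copies minimum number of full copies (default 2).
#' @return Data frame `start` (0-based), `unit`, `period`, `copies`, `span`
#'   (`period * copies`), sorted by `(start, period)`.
#' @export
find_tandem_repeats <- function(peptide, min_period = 2L, max_period = 6L,
                                min_copies = 2L) {
  if (!nzchar(peptide)) stop("peptide must be non-empty", call. = FALSE)
  s <- strsplit(toupper(peptide), "")[[1]]
  n <- length(s)
  hits <- list()
  for (p in seq.int(min_period, max_period)) {
    if (n < 2L * p) next
    eq <- s[seq_len(n - p)] == s[seq_len(n - p) + p]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts_run <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths + p >= 2L * p)) {
      i0 <- starts_run[k]              # 1-based start of the array
      total <- r$lengths[k] + p        # length of the periodic region
      copies <- total %/% p
      if (copies < min_copies) next
      unit <- paste(s[i0:(i0 + p - 1L)], collapse = "")
      if (!.is_primitive(unit)) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = i0 - 1L, unit = unit, period = p, copies = copies,
        span = p * copies, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), unit = character(0),
                      period = integer(0), copies = integer(0),
                      span = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.is_primitive <- function(unit) {
  p <- nchar(unit)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        identical(strrep(substr(unit, 1L, d), p %/% d), unit)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Define a residue-class motif pattern
#'
#' @param name pattern name.
#' @param elements list of residue classes: each a character vector of 1-letter
#'   codes, or `NULL` for the `Xaa` wildcard.
#' @param min_copies minimum copies for repeat-style use (metadata; default 1).
#' @return A `motif_pattern`.
#' @export
motif_pattern <- function(name, elements, min_copies = 1L) {
  if (!length(elements)) stop("pattern needs at least one element", call. = FALSE)
  for (e in elements) {
    if (!is.null(e) && !length(e)) stop("empty residue class", call. = FALSE)
  }
  structure(list(name = name, elements = elements,
                 min_copies = as.integer(min_copies)),
            class = "motif_pattern")
}

#' Built-in motif patterns
#'
#' The residue-class motifs recurrent in rSAM-associated precursor peptides:
#' `aro_xxn` (Aro-Xaa-Xaa-Asn with Aro = Trp/Tyr by default; set
#' `aro_includes_phe` to add Phe), `asp_cys` (the Asp-Cys dipeptide),
#' `ynr_hnr2` (Tyr-Asn-Arg-Xaa followed by two His-Asn-Arg copies) and
#' `his_x_ser` (His-Xaa-Ser).
#'
#' @param aro_includes_phe include F in the aromatic class (default FALSE).
#' @return Named list of [motif_pattern] objects.
#' @export
motif_patterns <- function(aro_includes_phe = FALSE) {
  aro <- if (aro_includes_phe) c("W", "Y", "F") else c("W", "Y")
  list(
    aro_xxn = motif_pattern("aro_xxn", list(aro, NULL, NULL, "N"), min_copies = 2L),
    asp_cys = motif_pattern("asp_cys", list("D", "C"), min_copies = 2L),
    ynr_hnr2 = motif_pattern("ynr_hnr2",
                             list("Y", "N", "R", NULL, "H", "N", "R", "H", "N", "R")),
    his_x_ser = motif_pattern("his_x_ser", list("H", NULL, "S"))
  )
}

#' Match a residue-class pattern against a peptide
#'
#' Every position where each residue belongs to its class (`Xaa` matches any
#' residue) is reported; overlapping matches are all returned. Starts are
#' 0-based.
#'
#' @param peptide amino-acid string.
#' @param pattern a [motif_pattern].
#' @return Data frame `start` (0-based), `match` (the substring), `name`.
#' @export
match_pattern <- function(peptide, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  s <- strsplit(toupper(peptide), "")[[1]]
  L <- length(pattern$elements)
  n <- length(s)
  starts <- integer(0)
  if (n >= L) {
    for (i in seq_len(n - L + 1L)) {
      ok <- TRUE
      for (k in seq_len(L)) {
        cls <- pattern$elements[[k]]
        if (!is.null(cls) && !(s[i + k - 1L] %in% cls)) {
          ok <- FALSE
          break
        }
      }
      if (ok) starts <- c(starts, i)
    }
  }
  data.frame(
    start = starts - 1L,
    match = vapply(starts, function(i) paste(s[i:(i + L - 1L)], collapse = ""),
                   character(1)),
    name = rep(pattern$name, length(starts)),
    stringsAsFactors = FALSE
  )
}

#' Score and rank precursor candidates by conserved-core evidence
#'
#' `score = w1 * consensus-support term + w2 * min(max repeat copies,
#' copies_cap) + w3 * pattern hit count`. The support term averages, over the
#' candidate's non-gap columns, column conservation multiplied by column
#' occupancy (fraction of pool rows non-gap there) and by whether the
#' candidate itself carries the column's modal residue: a column private to
#' one candidate, or a residue disagreeing with the consensus, carries no
#' consensus evidence. Deterministic; ties broken by peptide id.
#'
#' @param msa an `msa_result` over the candidates (or `NULL` for a single
#'   candidate, whose conservation term is then 1).
#' @param repeats named list (by peptide id) of [find_tandem_repeats()] hits.
#' @param patterns named list (by peptide id) of [match_pattern()] hits
#'   (row-bound over patterns).
#' @param weights numeric triple `(w1, w2, w3)`; default `c(1, 0.25, 0.5)`.
#' @param copies_cap cap on the repeat-copies term (default 6).
#' @return Data frame ranked by decreasing `score`: `peptide_id`, `score`,
#'   `conservation`, `max_copies`, `n_pattern_hits`.
#' @export
score_precursor <- function(msa = NULL, repeats = list(), patterns = list(),
                            weights = c(1, 0.25, 0.5), copies_cap = 6L) {
  ids <- unique(c(if (!is.null(msa)) msa$ids, names(repeats), names(patterns)))
  if (!length(ids)) stop("need at least one candidate", call. = FALSE)
  occupancy <- NULL
  if (!is.null(msa)) {
    mat <- do.call(rbind, strsplit(unname(msa$aligned), ""))
    occupancy <- colMeans(mat != "-")
  }
  rows <- lapply(ids, function(id) {
    cons <- 1
    if (!is.null(msa) && id %in% msa$ids) {
      row <- strsplit(msa$aligned[[id]], "")[[1]]
      core <- which(row != "-")
      agrees <- if (is.null(msa$modal)) 1 else (row[core] == msa$modal[core])
      cons <- if (length(core)) {
        mean(msa$conservation[core] * occupancy[core] * agrees)
      } else 0
    }
    reps <- repeats[[id]]
    max_copies <- if (!is.null(reps) && nrow(reps)) max(reps$copies) else 0L
    pats <- patterns[[id]]
    n_hits <- if (!is.null(pats)) nrow(pats) else 0L
    data.frame(
      peptide_id = id,
      score = weights[1] * cons + weights[2] * min(max_copies, copies_cap) +
        weights[3] * n_hits,
      conservation = cons, max_copies = max_copies, n_pattern_hits = n_hits,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$peptide_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
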