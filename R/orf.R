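# Six-frame open-reading-frame enumeration.
#
# An ORF is a start codon followed by the first in-frame stop; the reported
# genomic interval is 0-based half-open and includes the stop codon. Nested
# ORFs sharing a stop collapse to the longest (earliest in-frame start).
# When a window restriction is given, start codons outside the windows do
# not exist for the scan — the collapse happens among in-window starts, the
# way a scanner handed only the window subsequence would behave. Codons
# containing N never act as start or stop, and an ORF whose span contains N
# is dropped (its translation is undefined).

#' Enumerate open reading frames in a DNA sequence
#'
#' Scans all six frames for ORFs with a recognized start codon and an in-frame
#' stop. When `windows` is given, only start codons lying entirely within one
#' of the windows are considered (the ORF itself may extend beyond the
#' window); this is the rule used by [scan_flanks()].
#'
#' @param sequence DNA string over `ACGTN`.
#' @param starts accepted start codons (default bacterial `ATG`, `GTG`, `TTG`).
#' @param min_len_aa,max_len_aa bounds on peptide length (start codon included,
#'   stop excluded).
#' @param windows optional data frame with columns `start`, `end` (0-based
#'   half-open genomic intervals) restricting where start codons may lie.
#' @return Data frame with columns `start`, `end` (0-based half-open, stop
#'   codon included), `strand`, `start_codon`, `length_aa`, `nt_sequence`,
#'   `aa_sequence` (initiator translated as M, stop removed), sorted by
#'   genomic `start` then `strand`.
#' @export
find_orfs <- function(sequence, starts = c("ATG", "GTG", "TTG"),
                      min_len_aa = 20L, max_len_aa = Inf, windows = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else .revcomp(sequence)
    w_local <- windows
    if (!is.null(windows) && strand == "-") {
      w_local <- data.frame(start = n - windows$end, end = n - windows$start)
    }
    hits <- .orfs_one_strand(s, starts, min_len_aa, max_len_aa, w_local)
    if (!nrow(hits)) next
    if (strand == "-") {
      g_start <- n - hits$end
      g_end <- n - hits$start
      hits$start <- g_start
      hits$end <- g_end
    }
    hits$strand <- strand
    out[[strand]] <- hits
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), start_codon = character(0),
               length_aa = integer(0), nt_sequence = character(0),
               aa_sequence = character(0), strand = character(0),
               stringsAsFactors = FALSE)
  res <- res[order(res$start, res$strand, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("start", "end", "strand", "start_codon", "length_aa",
          "nt_sequence", "aa_sequence")]
}

# ORFs on the forward strand of `s`; coordinates 0-based half-open in `s`.
# `windows` (already strand-local) filters the start codons BEFORE nested
# collapse: invisible starts cannot swallow an in-window ORF.
.orfs_one_strand <- function(s, starts, min_len_aa, max_len_aa, windows = NULL) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      start_codon = character(0), length_aa = integer(0),
                      nt_sequence = character(0), aa_sequence = character(0),
                      stringsAsFactors = FALSE)
  n <- nchar(s)
  if (n < 6) return(empty)
  pos <- seq_len(n - 2L) # 1-based codon start positions
  cod <- substring(s, pos, pos + 2L)
  is_start <- cod %in% starts
  is_stop <- cod %in% .STOP_CODONS
  rows <- list()
  for (f in 0:2) {
    idx <- seq.int(1L + f, n - 2L, by = 3L)
    st <- idx[is_start[idx]]
    if (!is.null(windows) && length(st)) {
      keep <- vapply(st, function(p) {
        any(p - 1L >= windows$start & p + 2L <= windows$end)
      }, logical(1))
      st <- st[keep]
    }
    sp <- idx[is_stop[idx]]
    if (!length(st) || !length(sp)) next
    j <- findInterval(st, sp) + 1L # first stop strictly after the start
    ok <- j <= length(sp)
    st <- st[ok]
    stop_pos <- sp[j[ok]]
    if (!length(st)) next
    # collapse nested ORFs sharing a stop (the longest visible one is "the"
    # ORF), then apply the length bounds
    first <- !duplicated(stop_pos) # st ascending within frame
    st <- st[first]; stop_pos <- stop_pos[first]
    len_aa <- (stop_pos - st) %/% 3L
    keep <- len_aa >= min_len_aa & len_aa <= max_len_aa
    st <- st[keep]; stop_pos <- stop_pos[keep]; len_aa <- len_aa[keep]
    if (!length(st)) next
    rows[[length(rows) + 1L]] <- data.frame(
      st = st, stop_pos = stop_pos, length_aa = len_aa,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  d <- do.call(rbind, rows)
  nt <- substring(s, d$st, d$stop_pos + 2L)
  aa <- vapply(nt, function(x) {
    t <- .translate_nt(x, init_met = TRUE)
    if (is.na(t)) NA_character_ else substr(t, 1L, nchar(t) - 1L)
  }, character(1), USE.NAMES = FALSE)
  ok <- !is.na(aa) # N within the span: candidate dropped
  d <- d[ok, , drop = FALSE]; nt <- nt[ok]; aa <- aa[ok]
  data.frame(
    start = d$st - 1L,
    end = d$stop_pos + 2L,
    start_codon = substring(nt, 1L, 3L),
    length_aa = d$length_aa,
    nt_sequence = nt,
    aa_sequence = aa,
    stringsAsFactors = FALSE
  )
}
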