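# Precursor peptide discovery: annotated small CDS within the neighborhood,
# plus six-frame ORF scanning of the 1000 bp windows flanking the candidate
# gene cluster (the OrfFinder step, re-implemented offline).

#' Annotated small peptides within a neighborhood
#'
#' CDS features in the context whose translation is at most `max_len` residues
#' long, excluding the anchor, reported as precursor candidates with
#' `source = "annotated"`.
#'
#' @param nb a `neighborhood` from [extract_neighborhood()].
#' @param max_len maximum peptide length (default 120).
#' @return Data frame of candidates: `genome_id`, `start`, `end`, `strand`,
#'   `source`, `peptide`.
#' @export
find_annotated_peptides <- function(nb, max_len = 120L) {
  ctx <- nb$context
  sel <- ctx$feature_id != nb$anchor_id &
    !is.na(ctx$translation) &
    nchar(ctx$translation) <= max_len
  ctx <- ctx[sel, , drop = FALSE]
  data.frame(
    genome_id = rep(nb$genome_id, nrow(ctx)),
    start = ctx$start, end = ctx$end, strand = ctx$strand,
    source = rep("annotated", nrow(ctx)),
    peptide = ctx$translation,
    stringsAsFactors = FALSE
  )
}

#' Scan the flanking windows of a cluster for unannotated ORFs
#'
#' Scans the two windows `[span.start - window_bp, span.start)` and
#' `[span.end, span.end + window_bp)` (clipped to the contig) in all six
#' frames. An ORF must have its start codon inside a window but may run past
#' the window boundary (a precursor straddling the edge is not lost); nested
#' ORFs sharing a stop report only the longest.
#'
#' @param genome a [genome_record].
#' @param nb a `neighborhood` delimiting the cluster span.
#' @param window_bp window width (default 1000).
#' @param min_len_aa,max_len_aa peptide length bounds (defaults 20 and 120).
#' @param starts accepted start codons (default `ATG`, `GTG`, `TTG`,
#'   bacterial translation table 11).
#' @return Data frame of ORF candidates (columns as in [find_orfs()] plus
#'   `genome_id` and `source = "orf_scan"`), sorted by genomic start.
#' @export
scan_flanks <- function(genome, nb, window_bp = 1000L, min_len_aa = 20L,
                        max_len_aa = 120L, starts = c("ATG", "GTG", "TTG")) {
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  n <- nchar(genome$sequence)
  span <- nb$cluster_span
  windows <- data.frame(
    start = c(max(0L, span[["start"]] - window_bp), min(n, span[["end"]])),
    end = c(max(0L, span[["start"]]), min(n, span[["end"]] + window_bp))
  )
  windows <- windows[windows$end > windows$start, , drop = FALSE]
  orfs <- find_orfs(genome$sequence, starts = starts, min_len_aa = min_len_aa,
                    max_len_aa = max_len_aa, windows = windows)
  if (nrow(orfs)) {
    orfs$genome_id <- genome$id
    orfs$source <- "orf_scan"
  } else {
    orfs$genome_id <- character(0)
    orfs$source <- character(0)
  }
  orfs
}

#' Pool precursor candidates across the genomes of one SSN cluster
#'
#' Exact duplicate peptides are deduplicated with provenance kept; when an
#' annotated candidate and an ORF-scan candidate cover the same interval of
#' the same genome, the annotated source wins.
#'
#' @param per_genome list of data frames of candidates (each with columns
#'   `genome_id`, `start`, `end`, `strand`, `source`, and `peptide` or
#'   `aa_sequence`).
#' @param cluster_id SSN cluster id to tag the pool with.
#' @return List with `peptides` (unique peptides: `peptide_id`, `peptide`,
#'   `source`, `n_genomes`, `cluster_id`) and `provenance` (one row per
#'   original observation). A zero-candidate pool is returned empty with a
#'   warning.
#' @export
pool_candidates <- function(per_genome, cluster_id) {
  rows <- list()
  for (cand in per_genome) {
    if (is.null(cand) || !nrow(cand)) next
    pep <- if ("peptide" %in% names(cand)) cand$peptide else cand$aa_sequence
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = cand$genome_id, start = cand$start, end = cand$end,
      strand = cand$strand, source = cand$source, peptide = pep,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    warning("no precursor candidates pooled for cluster ", cluster_id, call. = FALSE)
    return(list(
      peptides = data.frame(peptide_id = character(0), peptide = character(0),
                            source = character(0), n_genomes = integer(0),
                            cluster_id = character(0), stringsAsFactors = FALSE),
      provenance = data.frame(peptide_id = character(0), genome_id = character(0),
                              start = integer(0), end = integer(0),
                              strand = character(0), source = character(0),
                              stringsAsFactors = FALSE)
    ))
  }
  prov <- do.call(rbind, rows)
  # same genome + interval + strand observed as both annotated and orf_scan:
  # keep the annotated row only
  key <- paste(prov$genome_id, prov$start, prov$end, prov$strand)
  ord <- order(key, match(prov$source, c("annotated", "orf_scan")))
  prov <- prov[ord, , drop = FALSE]
  prov <- prov[!duplicated(paste(prov$genome_id, prov$start, prov$end, prov$strand)), ,
               drop = FALSE]
  upep <- unique(prov$peptide)
  pid <- stats::setNames(sprintf("c%s_p%02d", cluster_id, seq_along(upep)), upep)
  prov$peptide_id <- unname(pid[prov$peptide])
  prov <- prov[order(prov$peptide_id, prov$genome_id, prov$start), , drop = FALSE]
  rownames(prov) <- NULL
  peptides <- do.call(rbind, lapply(upep, function(p) {
    sub <- prov[prov$peptide == p, , drop = FALSE]
    data.frame(
      peptide_id = pid[[p]], peptide = p,
      source = if (any(sub$source == "annotated")) "annotated" else "orf_scan",
      n_genomes = length(unique(sub$genome_id)),
      cluster_id = as.character(cluster_id), stringsAsFactors = FALSE
    )
  }))
  peptides <- peptides[order(peptides$peptide_id), , drop = FALSE]
  rownames(peptides) <- NULL
  list(peptides = peptides,
       provenance = prov[, c("peptide_id", "genome_id", "start", "end",
                             "strand", "source", "peptide")])
}
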