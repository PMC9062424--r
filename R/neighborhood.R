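# Gene-context extraction around an anchor gene.
#
# "±k genes" counts CDS features only, by genomic order, ignoring strand
# (matching genome-neighborhood diagrams, which draw both strands); the
# cluster span is the permissive [min start, max end) envelope of the context
# handed on to the flank scanner.

#' Extract the ±k gene context around an anchor CDS
#'
#' @param genome a [genome_record].
#' @param anchor_id feature id of the anchor; must exist and be a CDS.
#' @param k number of CDS features to take on each side (default 10);
#'   truncated silently at contig ends.
#' @return A `neighborhood`: list with `genome_id`, `anchor_id`, `context`
#'   (feature data frame, sorted by start, with translations filled in from
#'   the genome where missing), `k`, and `cluster_span` (`c(start, end)`,
#'   0-based half-open).
#' @export
extract_neighborhood <- function(genome, anchor_id, k = 10L) {
  f <- genome$features
  cds <- f[f$kind == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start, cds$end), , drop = FALSE]
  pos <- which(cds$feature_id == anchor_id)
  if (!length(pos)) {
    stop("anchor CDS not found: ", anchor_id, call. = FALSE)
  }
  pos <- pos[1]
  lo <- max(1L, pos - k)
  hi <- min(nrow(cds), pos + k)
  ctx <- cds[lo:hi, , drop = FALSE]
  # fill translations from the genome where annotation lacks them
  miss <- which(is.na(ctx$translation))
  for (i in miss) {
    nt <- substr(genome$sequence, ctx$start[i] + 1L, ctx$end[i])
    if (ctx$strand[i] == "-") nt <- .revcomp(nt)
    if (nchar(nt) %% 3L == 0L) {
      # literal translation (no initiator-Met forcing: annotation slop aside,
      # the translation of an annotated CDS should reproduce its protein)
      aa <- .translate_nt(nt, init_met = FALSE)
      if (!is.na(aa)) ctx$translation[i] <- sub("\\*$", "", aa)
    }
  }
  rownames(ctx) <- NULL
  structure(list(
    genome_id = genome$id,
    anchor_id = anchor_id,
    context = ctx,
    k = as.integer(k),
    cluster_span = c(start = min(ctx$start), end = max(ctx$end))
  ), class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood> %s anchor=%s: %d CDS, span [%d, %d)\n",
              x$genome_id, x$anchor_id, nrow(x$context),
              x$cluster_span[["start"]], x$cluster_span[["end"]]))
  invisible(x)
}

#' Locate anchor genes in a genome
#'
#' CDS features whose translation exactly matches one of the family member
#' sequences are returned; if none match, CDS whose product annotation
#' matches a keyword list (default `"radical SAM"`, case-insensitive) are
#' returned instead. Exact-sequence matches always take precedence.
#'
#' @param genome a [genome_record].
#' @param family_members character vector of protein sequences (or a
#'   [protein_set], whose `sequence` column is used).
#' @param keywords product keywords used as fallback.
#' @return Character vector of feature ids in genomic order (possibly empty).
#' @export
find_anchors <- function(genome, family_members = character(0),
                         keywords = "radical SAM") {
  f <- genome$features
  cds <- f[f$kind == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start, cds$end), , drop = FALSE]
  if (!nrow(cds)) return(character(0))
  if (is.data.frame(family_members)) family_members <- family_members$sequence
  tr <- cds$translation
  tr_met <- cds$translation # variant with a forced initiator Met
  miss <- which(is.na(tr))
  for (i in miss) {
    nt <- substr(genome$sequence, cds$start[i] + 1L, cds$end[i])
    if (cds$strand[i] == "-") nt <- .revcomp(nt)
    if (nchar(nt) %% 3L == 0L) {
      aa <- .translate_nt(nt, init_met = FALSE)
      aa_met <- .translate_nt(nt, init_met = TRUE)
      if (!is.na(aa)) tr[i] <- sub("\\*$", "", aa)
      if (!is.na(aa_met)) tr_met[i] <- sub("\\*$", "", aa_met)
    }
  }
  exact <- which((!is.na(tr) & tr %in% family_members) |
                   (!is.na(tr_met) & tr_met %in% family_members))
  if (length(exact)) return(cds$feature_id[exact])
  if (length(keywords)) {
    pat <- paste(keywords, collapse = "|")
    kw <- which(grepl(pat, cds$product, ignore.case = TRUE))
    return(cds$feature_id[kw])
  }
  character(0)
}
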