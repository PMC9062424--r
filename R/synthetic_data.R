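# Seeded generators for protein families with block-structured identity,
# genomes carrying an anchor gene plus neighbors and a planted precursor ORF,
# and fragment ladders with planted -2 Da shifts. Every generator records its
# ground truth (`planted_truth`) so downstream stages can be tested without
# any external data.

#' Generate a protein family with block-structured pairwise identity
#'
#' Members of a block are derived from a common block ancestor by independent
#' per-site substitutions at rate `1 - sqrt(target/100)`, so the expected
#' pairwise within-block identity equals the target; block ancestors are
#' independent (between-identity at the random baseline) unless the
#' between-identity target exceeds 5, in which case they are derived from a
#' shared root the same way. Substitutions only — identity, not phylogeny, is
#' the controlled variable.
#'
#' @param blocks list of triples `(size, within_identity, between_identity)`
#'   (or a 3-column matrix/data frame); identities in percent.
#' @param seq_length_range `(min, max)` residue lengths; one length is drawn
#'   per block (the substitution-only model preserves length within a block).
#' @param seed integer seed; identical seeds give identical output.
#' @return List with `records` (a [protein_set]) and `truth` (list with
#'   `family_blocks`: block id, member ids, target identity).
#' @export
make_family <- function(blocks, seq_length_range = c(340L, 450L), seed = 1L) {
  if (is.data.frame(blocks) || is.matrix(blocks)) {
    blocks <- lapply(seq_len(nrow(blocks)), function(i) as.numeric(blocks[i, ]))
  }
  for (b in blocks) {
    if (length(b) != 3) stop("each block needs (size, within, between)", call. = FALSE)
    if (b[1] < 1) stop("block size must be >= 1", call. = FALSE)
    if (b[2] <= b[3]) {
      stop("infeasible identity targets: within must exceed between", call. = FALSE)
    }
    if (b[2] <= 0 || b[2] > 100) stop("within identity must be in (0, 100]", call. = FALSE)
  }
  .seeded(seed, function() {
    lmin <- seq_length_range[1]; lmax <- seq_length_range[2]
    betweens <- vapply(blocks, `[`, numeric(1), 3)
    use_root <- max(betweens) > 5
    root <- if (use_root) .random_protein(lmax, start_met = FALSE) else NULL
    ids <- character(0); seqs <- character(0)
    truth_blocks <- list()
    for (bi in seq_along(blocks)) {
      size <- blocks[[bi]][1]
      within <- blocks[[bi]][2]
      between <- blocks[[bi]][3]
      len <- sample(lmin:lmax, 1L)
      anc <- if (use_root) {
        m_b <- 1 - sqrt(max(between, 0) / 100)
        substr(.mutate_protein(root, m_b), 1L, len)
      } else {
        .random_protein(len, start_met = FALSE)
      }
      m_w <- 1 - sqrt(within / 100)
      member_ids <- sprintf("blk%d_s%d", bi, seq_len(size))
      members <- vapply(member_ids, function(id) .mutate_protein(anc, m_w),
                        character(1))
      ids <- c(ids, member_ids)
      seqs <- c(seqs, unname(members))
      truth_blocks[[bi]] <- list(block_id = bi, member_ids = member_ids,
                                 target_within_identity = within)
    }
    list(records = protein_set(ids, seqs,
                               description = "synthetic family member"),
         truth = list(family_blocks = truth_blocks, seed = seed))
  })
}

.mutate_protein <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(.AA20, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a genome containing an anchor gene, neighbors, and a precursor
#'
#' The anchor protein is back-translated (standard code, uniform codon
#' choice); neighbors are random proteins placed on both sides with 50-200 bp
#' intergenic gaps and random strands. The precursor is either annotated as a
#' CDS inside the cluster (next to the anchor) or planted unannotated,
#' starting `flank_offset_bp` beyond the outermost cluster gene on the plus
#' strand. Flanking DNA is guaranteed to contain no spurious ORF of at least
#' `scan_min_len_aa` residues starting in the flanks (constructive repair of
#' start codons, bounded at 1000 rounds; see the methods vignette for why
#' blind rejection sampling cannot terminate here).
#'
#' @param anchor a single-row [protein_set] slice, or list with `id` and
#'   `sequence`.
#' @param n_neighbors total number of neighbor genes (split across the two
#'   sides).
#' @param precursor precursor peptide string (>= 10 aa, starting with M).
#' @param hidden logical; plant the precursor unannotated in the flank?
#' @param flank_offset_bp offset of the hidden precursor past the cluster
#'   edge; `flank_offset_bp + 3*len + 3` must stay within 1000 bp.
#' @param seed integer seed.
#' @param scan_min_len_aa the ORF-scan minimum length the flanks are cleaned
#'   against (default 20, matching [scan_flanks()]).
#' @return List with `genome` (a [genome_record]) and `truth` (anchor,
#'   neighbor and precursor intervals, strand, hidden flag).
#' @export
make_genome <- function(anchor, n_neighbors = 4L, precursor,
                        hidden = TRUE, flank_offset_bp = 200L, seed = 1L,
                        scan_min_len_aa = 20L) {
  a <- .as_protein(anchor, "anchor")
  if (nchar(precursor) < 10) stop("precursor must be >= 10 aa", call. = FALSE)
  if (substr(precursor, 1, 1) != "M") {
    stop("precursor peptide must start with M (ATG start codon)", call. = FALSE)
  }
  prec_nt_len <- 3L * nchar(precursor) + 3L
  if (hidden && flank_offset_bp + prec_nt_len > 1000L) {
    stop("hidden precursor does not fit: flank_offset_bp + 3*len + 3 > 1000",
         call. = FALSE)
  }
  .seeded(seed, function() {
    flank_pad <- 1000L + 3L * 120L + 60L # window + allowed overrun + slack
    left_n <- n_neighbors %/% 2L
    right_n <- n_neighbors - left_n
    assemble <- function() {
      genes <- list()
      add_gene <- function(id, aa, product, strand) {
        nt <- .back_translate(aa, stop_codon = TRUE)
        genes[[length(genes) + 1L]] <<- list(id = id, aa = aa, nt = nt,
                                             product = product, strand = strand)
      }
      for (i in seq_len(left_n)) {
        add_gene(sprintf("nbrL%d", i), .random_protein(sample(120:250, 1L)),
                 "hypothetical protein", sample(c("+", "-"), 1L))
      }
      add_gene("anchor", a$sequence, "radical SAM enzyme", "+")
      if (!hidden) {
        add_gene("precursor", precursor, "hypothetical peptide", "+")
      }
      for (i in seq_len(right_n)) {
        add_gene(sprintf("nbrR%d", i), .random_protein(sample(120:250, 1L)),
                 "hypothetical protein", sample(c("+", "-"), 1L))
      }
      # left flank, genes with 50-200 bp gaps, right flank (with the hidden
      # precursor at its offset)
      pieces <- character(0)
      feats <- list()
      pos <- 0L
      emit <- function(x) {
        pieces[[length(pieces) + 1L]] <<- x
        pos <<- pos + nchar(x)
      }
      emit(.random_dna(flank_pad))
      for (gi in seq_along(genes)) {
        if (gi > 1) emit(.random_dna(sample(50:200, 1L)))
        g <- genes[[gi]]
        nt <- if (g$strand == "-") .revcomp(g$nt) else g$nt
        feats[[length(feats) + 1L]] <- data.frame(
          feature_id = g$id, start = pos, end = pos + nchar(nt), strand = g$strand,
          kind = "CDS", product = g$product, translation = g$aa,
          stringsAsFactors = FALSE)
        emit(nt)
      }
      cluster_start <- min(vapply(feats, function(f) f$start, numeric(1)))
      cluster_end <- max(vapply(feats, function(f) f$end, numeric(1)))
      prec_truth <- NULL
      if (hidden) {
        emit(.random_dna(flank_offset_bp))
        prec_nt <- .back_translate(precursor, stop_codon = TRUE)
        prec_truth <- list(start = pos, end = pos + nchar(prec_nt), strand = "+",
                           hidden = TRUE, peptide = precursor)
        emit(prec_nt)
        emit(.random_dna(flank_pad - flank_offset_bp - nchar(prec_nt)))
      } else {
        fp <- feats[[which(vapply(feats, function(f) f$feature_id, character(1)) == "precursor")]]
        prec_truth <- list(start = fp$start, end = fp$end, strand = "+",
                           hidden = FALSE, peptide = precursor)
        emit(.random_dna(flank_pad))
      }
      seq_ <- paste(pieces, collapse = "")
      features <- do.call(rbind, feats)
      protected <- data.frame(start = features$start, end = features$end)
      if (hidden) {
        protected <- rbind(protected,
                           data.frame(start = prec_truth$start, end = prec_truth$end))
      }
      flanks <- data.frame(start = c(0L, cluster_end),
                           end = c(cluster_start, nchar(seq_)))
      planted <- if (hidden) c(prec_truth$start, prec_truth$end) else NULL
      seq_ <- .scrub_flank_orfs(seq_, flanks, protected, planted,
                                min_len_aa = scan_min_len_aa)
      if (is.null(seq_)) return(NULL) # unrepairable layout: redraw everything
      list(seq_ = seq_, features = features, prec_truth = prec_truth)
    }
    asm <- NULL
    for (try in seq_len(50L)) {
      asm <- assemble()
      if (!is.null(asm)) break
    }
    if (is.null(asm)) {
      stop("generation error: no spurious-ORF-free layout in 50 restarts",
           call. = FALSE)
    }
    features <- asm$features
    prec_truth <- asm$prec_truth
    genome <- genome_record(sprintf("syn_%s", a$id), asm$seq_, features)
    anchor_feat <- features[features$feature_id == "anchor", ]
    truth <- list(
      genome_id = genome$id,
      anchor = list(feature_id = "anchor", start = anchor_feat$start,
                    end = anchor_feat$end, strand = anchor_feat$strand),
      neighbors = features[!(features$feature_id %in% c("anchor")),
                           c("feature_id", "start", "end", "strand")],
      precursor = prec_truth,
      seed = seed
    )
    list(genome = genome, truth = truth)
  })
}

# Remove every ORF of >= min_len_aa residues whose start codon lies in the
# flank regions, except the planted precursor. Start codons outside protected
# intervals are disabled by a middle-base substitution; ORFs starting inside
# the protected precursor (alternate frames/strands) get an early in-frame
# stop planted at the first codon position clear of all protected intervals.
.scrub_flank_orfs <- function(seq_, flanks, protected, planted,
                              min_len_aa = 20L, max_iter = 1000L) {
  ch <- strsplit(seq_, "")[[1]]
  # repair stops planted in earlier rounds become protected themselves, so
  # repairs for overlapping ORFs in other frames cannot clobber them
  for (iter in seq_len(max_iter)) {
    orfs <- find_orfs(paste(ch, collapse = ""), min_len_aa = min_len_aa,
                      max_len_aa = Inf, windows = flanks)
    if (!is.null(planted)) {
      spurious <- orfs[!(orfs$start == planted[1] & orfs$end == planted[2] &
                           orfs$strand == "+"), , drop = FALSE]
    } else {
      spurious <- orfs
    }
    if (!nrow(spurious)) return(paste(ch, collapse = ""))
    for (i in seq_len(nrow(spurious))) {
      o <- spurious[i, ]
      cs <- if (o$strand == "+") o$start else o$end - 3L # codon start, 0-based
      in_protected <- any(cs >= protected$start & cs + 3L <= protected$end)
      if (!in_protected) {
        # disable the start codon: middle base -> C (plus) / G (minus)
        mid <- cs + 1L
        ch[mid + 1L] <- if (o$strand == "+") "C" else "G"
      } else {
        # plant an early stop at the first in-frame codon outside protection
        placed <- FALSE
        n_cod <- (o$end - o$start) %/% 3L
        for (k in seq_len(n_cod - 1L)) {
          cod0 <- if (o$strand == "+") o$start + 3L * k else o$end - 3L * (k + 1L)
          clear <- !any(cod0 < protected$end & cod0 + 3L > protected$start)
          if (clear) {
            stop_nt <- if (o$strand == "+") c("T", "A", "A") else c("T", "T", "A")
            ch[(cod0 + 1L):(cod0 + 3L)] <- stop_nt
            protected <- rbind(protected,
                               data.frame(start = cod0, end = cod0 + 3L))
            placed <- TRUE
            break
          }
        }
        if (!placed) return(NULL) # ORF buried in the precursor: force a redraw
      }
    }
  }
  stop("generation error: no spurious-ORF-free flanks in ", max_iter, " tries",
       call. = FALSE)
}

#' Generate a fragment ladder with planted -2 Da shifts
#'
#' Theoretical fragment m/z from the mass engine, shifted by `-2 m_H / z` for
#' every fragment containing a modified Val, then perturbed by Gaussian ppm
#' noise under the seed.
#'
#' @param p a [peptide].
#' @param mod_sites planted modified Val positions (1-based; must be Val).
#' @param series `"b"` or `"y"` (or `"internal"`).
#' @param noise_ppm Gaussian noise s.d. in ppm (0 = exact).
#' @param seed integer seed.
#' @param z charge (default 1).
#' @return Data frame as [fragment_ladder()] plus `mz_observed`; the planted
#'   sites are attached as `attr(, "mod_sites")`.
#' @export
make_ladder <- function(p, mod_sites, series = "y", noise_ppm = 0, seed = 1L,
                        z = 1L) {
  .check_mod_sites(p, mod_sites)
  lad <- fragment_ladder(p, mod_sites, series = series, z = z)
  obs <- .seeded(seed, function() {
    lad$mz * (1 + stats::rnorm(nrow(lad), 0, noise_ppm) * 1e-6)
  })
  lad$mz_observed <- obs
  attr(lad, "mod_sites") <- mod_sites
  lad
}
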