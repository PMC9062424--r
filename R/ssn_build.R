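# Sequence similarity network construction, clustering, and cluster selection.
#
# Pairwise scores come from Smith-Waterman local alignment (BLOSUM62, affine
# gaps open 11 / extend 1, so a gap of length L costs 11 + L). E-values use
# the Karlin-Altschul formula with gapped BLOSUM62 constants and a per-pair
# m*n search space; absolute values therefore differ from any particular
# BLAST release, which is why the thresholds are parameters rather than
# constants.

#' SSN construction parameters
#'
#' @param evalue_max maximum pairwise E-value for an edge (default `1e-80`).
#' @param pid_min minimum percent identity (identities over alignment columns,
#'   gaps included) for an edge (default 40).
#' @param len_min,len_max residue-length window for retained nodes (defaults
#'   340 and 450).
#' @param karlin_lambda,karlin_k Karlin-Altschul constants for gapped BLOSUM62
#'   (defaults 0.267 and 0.041).
#' @param gap_open,gap_extend affine gap penalties (defaults 11 and 1).
#' @return A list of class `ssn_params`.
#' @export
ssn_params <- function(evalue_max = 1e-80, pid_min = 40,
                       len_min = 340L, len_max = 450L,
                       karlin_lambda = 0.267, karlin_k = 0.041,
                       gap_open = 11, gap_extend = 1) {
  if (len_min > len_max) stop("len_min must be <= len_max", call. = FALSE)
  if (evalue_max <= 0 || pid_min < 0 || pid_min > 100) {
    stop("invalid thresholds", call. = FALSE)
  }
  structure(list(evalue_max = evalue_max, pid_min = pid_min,
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "ssn_params")
}

#' Align a pair of protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps. Percent
#' identity uses alignment columns (gaps included) as the denominator; the bit
#' score is \eqn{(\lambda s - \ln K)/\ln 2} and the E-value \eqn{m n
#' 2^{-bits}} with `m`, `n` the full sequence lengths.
#'
#' @param x,y protein sequences (character) or single rows of a
#'   [protein_set]; ids default to `"x"`/`"y"` for bare strings.
#' @param params an [ssn_params] supplying gap penalties and Karlin constants.
#' @return One-row data frame (`similarity_edge`): `a`, `b`, `score_raw`,
#'   `bitscore`, `evalue`, `pct_identity`, `aln_length`.
#' @export
align_pair <- function(x, y, params = ssn_params()) {
  gx <- .as_protein(x, "x")
  gy <- .as_protein(y, "y")
  .check_protein_seq(gx$sequence, gx$id)
  .check_protein_seq(gy$sequence, gy$id)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gx$sequence), Biostrings::AAString(gy$sequence),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  raw <- Biostrings::score(aln)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  pid <- if (cols > 0) 100 * Biostrings::nmatch(aln) / cols else 0
  bits <- (params$karlin_lambda * raw - log(params$karlin_k)) / log(2)
  ev <- nchar(gx$sequence) * nchar(gy$sequence) * 2^(-bits)
  data.frame(a = gx$id, b = gy$id, score_raw = raw, bitscore = bits,
             evalue = ev, pct_identity = pid, aln_length = cols,
             stringsAsFactors = FALSE)
}

.as_protein <- function(x, default_id) {
  if (is.character(x) && length(x) == 1L) {
    list(id = default_id, sequence = toupper(x))
  } else if (is.data.frame(x) && nrow(x) == 1L) {
    list(id = x$id, sequence = x$sequence)
  } else if (is.list(x) && !is.null(x$sequence)) {
    list(id = if (is.null(x$id)) default_id else x$id, sequence = x$sequence)
  } else {
    stop("cannot interpret input as a protein record", call. = FALSE)
  }
}

#' Build a sequence similarity network
#'
#' Applies the length filter to the records, aligns every retained pair, and
#' keeps an edge when `evalue <= evalue_max` and `pct_identity >= pid_min`.
#'
#' @param records a [protein_set].
#' @param params an [ssn_params].
#' @return An `ssn_graph`: list with `nodes` (id, length), `edges`
#'   (similarity edges surviving the thresholds), and `params`.
#' @export
build_ssn <- function(records, params = ssn_params()) {
  if (!is.data.frame(records) || nrow(records) < 1) {
    stop("need at least one record", call. = FALSE)
  }
  keep <- records$length >= params$len_min & records$length <= params$len_max
  recs <- records[keep, , drop = FALSE]
  nodes <- data.frame(id = recs$id, length = recs$length, stringsAsFactors = FALSE)
  edges <- .empty_edges()
  edges$score_raw <- numeric(0)
  edges$aln_length <- integer(0)
  if (nrow(recs) >= 2) {
    pairs <- utils::combn(nrow(recs), 2)
    rows <- vector("list", ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      rows[[k]] <- align_pair(recs[i, ], recs[j, ], params)
    }
    all_edges <- do.call(rbind, rows)
    sel <- all_edges$evalue <= params$evalue_max &
      all_edges$pct_identity >= params$pid_min
    edges <- all_edges[sel, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "ssn_graph")
}

#' @export
print.ssn_graph <- function(x, ...) {
  cat(sprintf("<ssn_graph> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Cluster an SSN into connected components
#'
#' Clusters are the connected components of the thresholded network (isolated
#' nodes become singletons), ranked by member count descending with ties
#' broken by the lexicographically smallest member id. The representative is
#' the medoid: the member maximizing summed percent identity over its incident
#' within-cluster edges (ties to the smallest id).
#'
#' @param graph an `ssn_graph`.
#' @param node_weights optional named vector giving the number of underlying
#'   sequences per node (defaults to 1 each); summed into `n_sequences`.
#' @return Data frame with columns `cluster_id` (rank), `size`,
#'   `n_sequences`, `representative`, and list-column `members`.
#' @export
cluster_ssn <- function(graph, node_weights = NULL) {
  ids <- graph$nodes$id
  if (!length(ids)) {
    return(data.frame(cluster_id = integer(0), size = integer(0),
                      n_sequences = integer(0), representative = character(0)))
  }
  if (is.null(node_weights)) node_weights <- stats::setNames(rep(1L, length(ids)), ids)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("a", "b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[ids]
  groups <- split(ids, membership)
  min_id <- vapply(groups, function(m) min(m), character(1))
  sizes <- lengths(groups)
  ord <- order(-sizes, min_id)
  groups <- groups[ord]
  # medoid per cluster from edge pct identities
  e <- graph$edges
  reps <- vapply(groups, function(members) {
    if (length(members) == 1L) return(members)
    sums <- stats::setNames(numeric(length(members)), sort(members))
    sel <- e$a %in% members & e$b %in% members
    if (any(sel)) {
      for (k in which(sel)) {
        sums[e$a[k]] <- sums[e$a[k]] + e$pct_identity[k]
        sums[e$b[k]] <- sums[e$b[k]] + e$pct_identity[k]
      }
    }
    names(sums)[which.max(sums)] # names sorted: ties -> smallest id
  }, character(1))
  out <- data.frame(
    cluster_id = seq_along(groups),
    size = unname(lengths(groups)),
    n_sequences = vapply(groups, function(m) sum(node_weights[m]), numeric(1)),
    representative = unname(reps),
    stringsAsFactors = FALSE
  )
  out$members <- unname(groups)
  out
}

#' Select clusters for downstream gene-context analysis
#'
#' Keeps clusters with rank at most `max_rank` that contain multiple nodes and
#' more than three sequences total (read strictly: at least `min_sequences`).
#'
#' @param clusters output of [cluster_ssn()].
#' @param min_nodes minimum member count (default 2, "multiple nodes").
#' @param min_sequences minimum total sequences (default 4).
#' @param max_rank highest rank retained (default 118).
#' @return The filtered cluster table, order preserved.
#' @export
select_analysis_clusters <- function(clusters, min_nodes = 2L,
                                     min_sequences = 4L, max_rank = 118L) {
  sel <- clusters$cluster_id <= max_rank &
    clusters$size >= min_nodes &
    clusters$n_sequences >= min_sequences
  out <- clusters[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
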