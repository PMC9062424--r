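# End-to-end orchestration: family FASTA + annotated genomes -> SSN ->
# clusters -> neighborhoods -> precursor candidates -> motif evidence; and
# peptide definition + observed m/z -> modification / localization report.
# Runs are deterministic and every applied threshold is logged.

.default_mine_params <- function() {
  list(evalue_max = 1e-80, pid_min = 40, len_min = 340L, len_max = 450L,
       k = 10L, window_bp = 1000L, min_len_aa = 20L, max_len_aa = 120L,
       min_nodes = 2L, min_sequences = 4L, max_rank = 118L)
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config error: file not found: ", config, call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config error: expected a list or JSON path", call. = FALSE)
  config
}

#' Run the genome-mining pipeline
#'
#' Reads the protein family and the annotated genomes named in the config,
#' builds and clusters the SSN, extracts the gene neighborhood around every
#' anchor, collects annotated small peptides and flank-scan ORFs, pools and
#' aligns them per cluster, and scores motif evidence. All thresholds default
#' to the standard analysis values (E <= 1e-80, identity >= 40, lengths
#' 340-450, k = 10, 1000 bp windows).
#'
#' @param config path to a JSON config, or an equivalent list, with fields
#'   `family_fasta`, `genomes` (data frame / list of records with
#'   `genome_fasta` + `gff3`, or `genbank`), optional `out_dir`, `params`
#'   (overrides of the defaults), and `seed`.
#' @return A `mine_report`: list with `clusters`, `selected`, `per_cluster`
#'   (candidates, provenance, msa, repeats, patterns, scores per cluster),
#'   `params`, `log`, and `files` (paths written when `out_dir` is set).
#' @export
run_mining <- function(config) {
  cfg <- .read_config(config)
  if (is.null(cfg$family_fasta)) stop("config error: missing family_fasta", call. = FALSE)
  if (is.null(cfg$genomes)) stop("config error: missing genomes", call. = FALSE)
  if (!file.exists(cfg$family_fasta)) {
    stop("config error: family_fasta not found: ", cfg$family_fasta, call. = FALSE)
  }
  genome_specs <- cfg$genomes
  if (is.data.frame(genome_specs)) {
    genome_specs <- lapply(seq_len(nrow(genome_specs)),
                           function(i) as.list(genome_specs[i, ]))
  }
  for (gs in genome_specs) {
    p <- if (!is.null(gs$genbank)) gs$genbank else c(gs$genome_fasta, gs$gff3)
    if (any(!file.exists(unlist(p)))) {
      stop("config error: genome input not found: ",
           paste(unlist(p)[!file.exists(unlist(p))], collapse = ","), call. = FALSE)
    }
  }
  params <- utils::modifyList(.default_mine_params(), as.list(cfg$params %||% list()))
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message("[mine] ", line)
  }

  family <- read_fasta(cfg$family_fasta, type = "protein")
  say("family: %d records from %s", nrow(family), cfg$family_fasta)

  sp <- ssn_params(evalue_max = params$evalue_max, pid_min = params$pid_min,
                   len_min = params$len_min, len_max = params$len_max)
  graph <- build_ssn(family, sp)
  say("ssn: E<=%g pid>=%g len[%d,%d] -> %d nodes, %d edges",
      sp$evalue_max, sp$pid_min, sp$len_min, sp$len_max,
      nrow(graph$nodes), nrow(graph$edges))

  clusters <- cluster_ssn(graph)
  selected <- select_analysis_clusters(clusters, params$min_nodes,
                                       params$min_sequences, params$max_rank)
  say("clusters: %d total, %d selected (min_nodes=%d min_sequences=%d max_rank=%d)",
      nrow(clusters), nrow(selected), params$min_nodes, params$min_sequences,
      params$max_rank)

  genomes <- lapply(genome_specs, function(gs) {
    if (!is.null(gs$genbank)) {
      read_annotations(gs$genbank, dialect = "genbank")
    } else {
      read_annotations(gs$gff3, dialect = "gff3", genome_fasta = gs$genome_fasta)
    }
  })
  say("genomes: %d loaded", length(genomes))

  pats <- motif_patterns()
  per_cluster <- list()
  for (ci in seq_len(nrow(selected))) {
    cl <- selected[ci, ]
    member_seqs <- family$sequence[family$id %in% cl$members[[1]]]
    cands <- list()
    neighborhoods <- list()
    for (g in genomes) {
      # exact-sequence matches only: the keyword fallback would attach every
      # rSAM-annotated genome to every cluster
      anchors <- find_anchors(g, member_seqs, keywords = character(0))
      for (aid in anchors) {
        nb <- extract_neighborhood(g, aid, k = params$k)
        neighborhoods[[length(neighborhoods) + 1L]] <- nb
        ann <- find_annotated_peptides(nb, max_len = params$max_len_aa)
        orf <- scan_flanks(g, nb, window_bp = params$window_bp,
                           min_len_aa = params$min_len_aa,
                           max_len_aa = params$max_len_aa)
        cands[[length(cands) + 1L]] <- ann
        cands[[length(cands) + 1L]] <- orf
      }
    }
    pool <- suppressWarnings(pool_candidates(cands, cl$cluster_id))
    say("cluster %d: %d anchors, %d unique candidate peptides",
        cl$cluster_id, length(neighborhoods), nrow(pool$peptides))
    msa <- NULL
    if (nrow(pool$peptides) >= 2) {
      msa <- align_peptides(pool$peptides)
    }
    reps <- stats::setNames(
      lapply(pool$peptides$peptide, find_tandem_repeats),
      pool$peptides$peptide_id)
    pat_hits <- stats::setNames(
      lapply(pool$peptides$peptide, function(pep) {
        do.call(rbind, lapply(pats, function(p) match_pattern(pep, p)))
      }),
      pool$peptides$peptide_id)
    scores <- if (nrow(pool$peptides)) {
      score_precursor(msa, reps, pat_hits)
    } else {
      NULL
    }
    per_cluster[[as.character(cl$cluster_id)]] <- list(
      cluster_id = cl$cluster_id, candidates = pool$peptides,
      provenance = pool$provenance, neighborhoods = neighborhoods,
      msa = msa, repeats = reps, patterns = pat_hits, scores = scores)
  }

  report <- structure(list(clusters = clusters, selected = selected,
                           graph = graph, per_cluster = per_cluster,
                           params = params, log = log, files = character(0)),
                      class = "mine_report")
  if (!is.null(cfg$out_dir)) {
    report$files <- .write_mine_outputs(report, cfg)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_mine_outputs <- function(report, cfg) {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  cl <- report$clusters
  cl$members <- vapply(cl$members, paste, character(1), collapse = ",")
  f <- file.path(out, "clusters.tsv")
  utils::write.table(cl, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out, "network.tsv")
  write_network(report$graph, f, dialect = "edgelist")
  files <- c(files, f)
  cand_rows <- list()
  evid_rows <- list()
  for (pc in report$per_cluster) {
    for (nb in pc$neighborhoods) {
      fn <- file.path(out, sprintf("cluster_%d_%s_neighborhood.tsv",
                                   pc$cluster_id, nb$genome_id))
      utils::write.table(
        nb$context[, c("feature_id", "start", "end", "strand", "product")],
        fn, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, fn)
    }
    if (nrow(pc$candidates)) {
      cand_rows[[length(cand_rows) + 1L]] <- pc$candidates
      for (pid in pc$candidates$peptide_id) {
        r <- pc$repeats[[pid]]
        top_unit <- if (!is.null(r) && nrow(r)) r$unit[which.max(r$copies)] else ""
        top_copies <- if (!is.null(r) && nrow(r)) max(r$copies) else 0L
        sc <- pc$scores[pc$scores$peptide_id == pid, ]
        evid_rows[[length(evid_rows) + 1L]] <- data.frame(
          cluster_id = pc$cluster_id, peptide_id = pid,
          score = sc$score, conservation = sc$conservation,
          repeat_unit = top_unit, repeat_copies = top_copies,
          n_pattern_hits = sc$n_pattern_hits, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand_rows)) {
    cands <- do.call(rbind, cand_rows)
    f <- file.path(out, "candidates.fasta")
    write_fasta(stats::setNames(cands$peptide,
                                paste(cands$peptide_id, cands$source)), f)
    files <- c(files, f)
  }
  if (length(evid_rows)) {
    f <- file.path(out, "motif_evidence.tsv")
    utils::write.table(do.call(rbind, evid_rows), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  inputs <- c(cfg$family_fasta,
              unlist(lapply(cfg$genomes, function(g) unlist(g)), use.names = FALSE))
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(params = report$params, seed = cfg$seed %||% NA,
                   input_md5 = as.list(tools::md5sum(inputs)))
  f <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, f)
  files
}

#' @export
print.mine_report <- function(x, ...) {
  cat(sprintf("<mine_report> %d clusters (%d selected), %d analyzed\n",
              nrow(x$clusters), nrow(x$selected), length(x$per_cluster)))
  invisible(x)
}

#' Verify observed masses against the predicted modification series
#'
#' Computes the predicted `[M+zH]^z+` series for 0..n_max ring modifications
#' (from an explicit base m/z, or from a peptide definition) and matches each
#' observed m/z to its nearest prediction within `tol_ppm`, reporting the
#' truncated-one-decimal ppm error and the inferred modification counts.
#' When the config carries fragment-ion observations, localization is run as
#' well.
#'
#' @param peptide_config path to a JSON file (or list) with either `base_mz`
#'   or `peptide` (`sequence`, `c_terminus`, optional `val_13c15n` flag),
#'   plus `z`, `n_max`, optional `tol_ppm` (default 10) and optional
#'   `fragments` (data frame of observed ions for localization).
#' @param observed numeric vector of observed m/z values, or a path to a text
#'   file with one value per line.
#' @return An `ms_report`: list with `series` (prediction/match table),
#'   `inferred_counts`, `unmatched`, and optional `localization`.
#' @export
run_ms_verify <- function(peptide_config, observed = NULL) {
  cfg <- .read_config(peptide_config)
  if (is.null(cfg$z) || is.null(cfg$n_max)) {
    stop("config error: need z and n_max", call. = FALSE)
  }
  tol <- cfg$tol_ppm %||% 10
  pep <- NULL
  if (!is.null(cfg$base_mz)) {
    base <- cfg$base_mz
  } else if (!is.null(cfg$peptide)) {
    pd <- cfg$peptide
    pep <- peptide(pd$sequence, c_terminus = pd$c_terminus %||% "free_acid")
    if (isTRUE(pd$val_13c15n)) {
      pep <- peptide(pd$sequence, c_terminus = pd$c_terminus %||% "free_acid",
                     labels = val_13c15n_labels(pep))
    }
    base <- mz(monoisotopic_mass(pep), cfg$z)
  } else {
    stop("config error: need base_mz or peptide", call. = FALSE)
  }
  if (is.character(observed)) {
    observed <- as.numeric(readLines(observed, warn = FALSE))
  }
  series <- modification_series(base, cfg$z, cfg$n_max)
  series$observed <- NA_real_
  series$dppm <- NA_real_
  series$matched <- FALSE
  unmatched <- numeric(0)
  for (o in observed %||% numeric(0)) {
    i <- which.min(abs(series$mz - o))
    e <- ppm_error(o, series$mz[i])
    if (e$full <= tol) {
      series$observed[i] <- o
      series$dppm[i] <- e$reported
      series$matched[i] <- TRUE
    } else {
      unmatched <- c(unmatched, o)
    }
  }
  if (length(unmatched)) {
    message("[ms-verify] unmatched observations: ",
            paste(format(unmatched), collapse = ", "))
  }
  loc <- NULL
  if (!is.null(cfg$fragments) && !is.null(pep)) {
    loc <- localize_modifications(pep, as.data.frame(cfg$fragments),
                                  tol_ppm = tol)
  }
  structure(list(series = series,
                 inferred_counts = series$n_mods[series$matched],
                 unmatched = unmatched, localization = loc,
                 base_mz = base, z = cfg$z, tol_ppm = tol),
            class = "ms_report")
}

#' @export
print.ms_report <- function(x, ...) {
  cat(sprintf("<ms_report> base m/z %.4f (z=%d), %d/%d series entries matched\n",
              x$base_mz, x$z, sum(x$series$matched), nrow(x$series)))
  print(x$series, digits = 8)
  invisible(x)
}

#' Simulate a full mining bundle with planted ground truth
#'
#' Writes a synthetic protein family (block-structured identity), one
#' annotated genome per family member carrying that member as the anchor
#' gene, and per-block planted precursor peptides: a tandem `TVGG` x4 core
#' (hidden in the downstream flank), an Asp-Cys x6 repeat (annotated CDS),
#' and an Aro-Xaa-Xaa-Asn twin motif (hidden). Emits the family FASTA, per
#' genome GFF3 + FASTA, `truth.json`, and a ready-to-run `config.json`.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_blocks number of family blocks (1-3 get distinct planted motifs;
#'   default 3).
#' @param block_size genomes (= members) per block (default 5).
#' @param n_neighbors neighbor genes per genome (default 4).
#' @return List with `config` (path), `truth` (list), and `files`.
#' @export
simulate_bundle <- function(out_dir, seed = 1L, n_blocks = 3L, block_size = 5L,
                            n_neighbors = 4L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fam <- make_family(
    blocks = lapply(seq_len(n_blocks), function(i) c(block_size, 90, 20)),
    seq_length_range = c(360L, 430L), seed = seed)
  fam_path <- file.path(out_dir, "family.fasta")
  write_fasta(fam$records, fam_path)
  variable_aa <- c("K", "R", "N", "S", "T", "E", "Q", "A", "L", "G")
  block_precursor <- function(block, member) {
    v <- variable_aa[(member - 1L) %% length(variable_aa) + 1L]
    switch(((block - 1L) %% 3L) + 1L,
           paste0("MA", v, "KW", strrep("TVGG", 4L)),          # 21 aa, repeat core
           paste0("M", v, "GAL", strrep("DC", 6L), "AKL"),     # 20 aa, Asp-Cys
           paste0("M", v, "LKG", "WAANYAAN", "GKAVETS"))       # 20 aa, Aro-Xaa-Xaa-Asn
  }
  block_hidden <- function(block) ((block - 1L) %% 3L) + 1L != 2L
  block_offset <- function(block) c(200L, 0L, 350L)[((block - 1L) %% 3L) + 1L]
  genomes <- list()
  truth_genomes <- list()
  gi <- 0L
  for (b in seq_len(n_blocks)) {
    ids <- sprintf("blk%d_s%d", b, seq_len(block_size))
    for (m in seq_len(block_size)) {
      gi <- gi + 1L
      rec <- fam$records[fam$records$id == ids[m], ]
      g <- make_genome(rec, n_neighbors = n_neighbors,
                       precursor = block_precursor(b, m),
                       hidden = block_hidden(b),
                       flank_offset_bp = block_offset(b),
                       seed = seed * 1000L + gi)
      gp <- file.path(out_dir, sprintf("genome_%s.fasta", rec$id))
      ap <- file.path(out_dir, sprintf("genome_%s.gff3", rec$id))
      write_gff3(g$genome, ap, fasta_path = gp)
      genomes[[gi]] <- list(genome_fasta = gp, gff3 = ap)
      g$truth$block <- b
      truth_genomes[[gi]] <- g$truth
    }
  }
  truth <- list(family = fam$truth, genomes = truth_genomes, seed = seed)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  config <- list(
    family_fasta = fam_path,
    genomes = genomes,
    out_dir = file.path(out_dir, "report"),
    params = list(k = 10L, min_sequences = 2L),
    seed = seed
  )
  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(config = config_path, truth = truth, truth_path = truth_path,
       files = c(fam_path, unlist(genomes, use.names = FALSE)))
}
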