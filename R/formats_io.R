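# File formats and coordinate conventions.
#
# Every genomic interval inside the package is 0-based half-open; GFF3 and
# GenBank coordinates (1-based inclusive) are converted at the I/O boundary.

#' Construct a protein set
#'
#' A `protein_set` is a data frame with one row per protein record and columns
#' `id`, `sequence`, `description`, `length`. Sequences are uppercase strings
#' over the 20 canonical amino-acid letters plus `X`; ids must be unique.
#'
#' @param id character vector of unique record ids.
#' @param sequence character vector of amino-acid sequences.
#' @param description optional character vector of free-text descriptions.
#' @return A `protein_set` data frame.
#' @export
protein_set <- function(id, sequence, description = "") {
  sequence <- toupper(gsub("[\\s-]", "", sequence, perl = TRUE))
  if (length(id) != length(sequence)) stop("id/sequence length mismatch", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate id: ", id[duplicated(id)][1], call. = FALSE)
  }
  if (any(!nzchar(sequence))) stop("empty sequence not allowed", call. = FALSE)
  mapply(.check_protein_seq, sequence, id)
  out <- data.frame(
    id = as.character(id),
    sequence = sequence,
    description = rep_len(as.character(description), length(id)),
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Construct an annotated genome record
#'
#' @param id contig/genome id.
#' @param sequence uppercase DNA string over `ACGTN`.
#' @param features data frame of gene features with columns `feature_id`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `kind`
#'   (`CDS`/`other`), `product`, `translation` (`NA` when absent). A CDS whose
#'   span is not divisible by 3 and that carries no translation is flagged in
#'   the logical `phase_ok` column (with a warning) but kept, allowing for
#'   annotation slop.
#' @return A `genome_record` (list with elements `id`, `sequence`, `features`).
#' @export
genome_record <- function(id, sequence, features = NULL) {
  sequence <- unname(toupper(gsub("\\s", "", sequence)))
  .check_dna_seq(sequence, id)
  n <- nchar(sequence)
  if (is.null(features) || nrow(features) == 0) {
    features <- data.frame(
      feature_id = character(0), start = integer(0), end = integer(0),
      strand = character(0), kind = character(0), product = character(0),
      translation = character(0), phase_ok = logical(0),
      stringsAsFactors = FALSE
    )
  } else {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    needed <- c("feature_id", "start", "end", "strand", "kind")
    missing_cols <- setdiff(needed, names(features))
    if (length(missing_cols)) {
      stop("features missing columns: ", paste(missing_cols, collapse = ","), call. = FALSE)
    }
    if (!("product" %in% names(features))) features$product <- ""
    if (!("translation" %in% names(features))) features$translation <- NA_character_
    if (any(features$start < 0 | features$end > n | features$start >= features$end)) {
      stop("feature interval outside sequence bounds [0, ", n, ")", call. = FALSE)
    }
    if (any(!(features$strand %in% c("+", "-")))) {
      stop("unknown strand symbol: ",
           features$strand[!(features$strand %in% c("+", "-"))][1], call. = FALSE)
    }
    features$phase_ok <- !(features$kind == "CDS" &
                             is.na(features$translation) &
                             (features$end - features$start) %% 3L != 0L)
    if (any(!features$phase_ok)) {
      warning("CDS without translation has span not divisible by 3: ",
              paste(features$feature_id[!features$phase_ok], collapse = ","),
              call. = FALSE)
    }
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = as.character(id), sequence = sequence, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d features\n",
              x$id, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Convert between GFF3 and internal coordinates
#'
#' Internal coordinates are 0-based half-open; GFF3 (and GenBank) are 1-based
#' inclusive. The two functions are mutual inverses.
#'
#' @param start,end interval bounds in the source convention.
#' @return A list with converted `start` and `end`.
#' @export
gff3_to_internal <- function(start, end) list(start = start - 1L, end = end)

#' @rdname gff3_to_internal
#' @export
internal_to_gff3 <- function(start, end) list(start = start + 1L, end = end)

#' Read a FASTA file
#'
#' Reads protein or nucleotide FASTA. Sequences are uppercased and
#' whitespace/gap characters are stripped; molecule type is inferred from the
#' alphabet (every sequence over `ACGTN` implies DNA) unless forced.
#'
#' @param path FASTA file path.
#' @param type `"auto"`, `"protein"`, or `"dna"`.
#' @return For protein input, a [protein_set]; for DNA input a list of
#'   [genome_record] objects (one per contig, no features).
#' @export
read_fasta <- function(path, type = c("auto", "protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("FASTA format error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0) stop("FASTA format error: no records in ", path, call. = FALSE)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate id in ", path, ": ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- toupper(gsub("[\\s*-]", "", as.character(x), perl = TRUE))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id: ", ids[!nzchar(seqs)][1], call. = FALSE)
  }
  if (type == "auto") {
    type <- if (all(vapply(seqs, .is_dna_seq, logical(1)))) "dna" else "protein"
  }
  if (type == "protein") {
    protein_set(ids, seqs, desc)
  } else {
    mapply(.check_dna_seq, seqs, ids)
    lapply(seq_along(ids), function(i) genome_record(ids[i], seqs[i]))
  }
}

#' Write sequences as FASTA (wrapped at 60 columns)
#'
#' @param x a [protein_set], a [genome_record], a list of genome records, or a
#'   named character vector.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "protein_set")) {
    nm <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
    set <- Biostrings::BStringSet(stats::setNames(x$sequence, nm))
  } else if (inherits(x, "genome_record")) {
    set <- Biostrings::BStringSet(stats::setNames(x$sequence, x$id))
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "genome_record"))) {
    set <- Biostrings::BStringSet(stats::setNames(
      vapply(x, `[[`, character(1), "sequence"),
      vapply(x, `[[`, character(1), "id")))
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("character input must be named", call. = FALSE)
    set <- Biostrings::BStringSet(x)
  } else {
    stop("unsupported input for write_fasta", call. = FALSE)
  }
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an annotated genome
#'
#' Supported dialects: `"gff3"` (requires the companion genome FASTA) and
#' `"genbank"` (flat file with an ORIGIN sequence block; simple `a..b` and
#' `complement(a..b)` CDS locations only). 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"genbank"`.
#' @param genome_fasta genome FASTA path (gff3 dialect only).
#' @return A [genome_record].
#' @export
read_annotations <- function(path, dialect = c("gff3", "genbank"),
                             genome_fasta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "gff3") {
    if (is.null(genome_fasta)) {
      stop("gff3 dialect requires `genome_fasta`", call. = FALSE)
    }
    genomes <- read_fasta(genome_fasta, type = "dna")
    if (length(genomes) != 1) stop("expected a single contig in ", genome_fasta, call. = FALSE)
    g <- genomes[[1]]
    gr <- rtracklayer::import(path)
    if (length(gr) == 0) return(g)
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
    ids[is.na(ids) | !nzchar(ids)] <- paste0("feat_", which(is.na(ids) | !nzchar(ids)))
    prod <- if ("product" %in% names(md)) as.character(md$product) else rep("", length(gr))
    prod[is.na(prod)] <- ""
    strand_chr <- as.character(BiocGenerics::strand(gr))
    if (any(strand_chr == "*")) stop("unknown strand symbol '*' in ", path, call. = FALSE)
    conv <- gff3_to_internal(BiocGenerics::start(gr), BiocGenerics::end(gr))
    feats <- data.frame(
      feature_id = ids,
      start = conv$start,
      end = conv$end,
      strand = strand_chr,
      kind = ifelse(as.character(md$type) == "CDS", "CDS", "other"),
      product = prod,
      translation = NA_character_,
      stringsAsFactors = FALSE
    )
    genome_record(g$id, g$sequence, feats)
  } else {
    .read_genbank(path)
  }
}

# Minimal GenBank flat-file reader: LOCUS id, CDS features with a..b /
# complement(a..b) locations, /product /locus_tag /translation qualifiers,
# ORIGIN sequence block. join() locations are not supported.
.read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  gid <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1] else "genbank"
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank file lacks ORIGIN block: ", path, call. = FALSE)
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_start <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1] + 1L):(ori[1] - 1L)]
    key_idx <- grep("^\\s{5}\\S", block)
    for (i in seq_along(key_idx)) {
      from <- key_idx[i]
      to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(block)
      head_line <- block[from]
      key <- strsplit(trimws(head_line), "\\s+")[[1]][1]
      loc <- strsplit(trimws(head_line), "\\s+")[[1]][2]
      body <- paste(c(loc, trimws(block[seq.int(from + 1L, length.out = max(0L, to - from))])),
                    collapse = " ")
      if (grepl("join|order", body)) {
        stop("unsupported compound location in GenBank feature: ", key, call. = FALSE)
      }
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) < 2) next
      conv <- gff3_to_internal(as.integer(nums[1]), as.integer(nums[2]))
      qual <- function(name) {
        m <- regmatches(body, regexpr(sprintf('/%s="[^"]*"', name), body))
        if (length(m)) sub(sprintf('^/%s="', name), "", sub('"$', "", m)) else NA_character_
      }
      translation <- qual("translation")
      if (!is.na(translation)) translation <- gsub("\\s", "", translation)
      fid <- qual("locus_tag")
      if (is.na(fid)) fid <- paste0("feat_", length(feats) + 1L)
      prod <- qual("product")
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = fid, start = conv$start, end = conv$end, strand = strand,
        kind = if (identical(key, "CDS")) "CDS" else "other",
        product = if (is.na(prod)) "" else prod,
        translation = translation, stringsAsFactors = FALSE
      )
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  genome_record(gid, sequence, features)
}

#' Write a genome record as GFF3 (optionally with its FASTA)
#'
#' @param genome a [genome_record].
#' @param gff_path output GFF3 path.
#' @param fasta_path optional output FASTA path for the sequence.
#' @return `gff_path`, invisibly.
#' @export
write_gff3 <- function(genome, gff_path, fasta_path = NULL) {
  f <- genome$features
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d", genome$id, nchar(genome$sequence)))
  rows <- character(0)
  if (nrow(f)) {
    conv <- internal_to_gff3(f$start, f$end)
    attrs <- sprintf("ID=%s%s", f$feature_id,
                     ifelse(nzchar(f$product), paste0(";product=", f$product), ""))
    rows <- sprintf("%s\trippmine\t%s\t%d\t%d\t.\t%s\t0\t%s",
                    genome$id, ifelse(f$kind == "CDS", "CDS", "region"),
                    conv$start, conv$end, f$strand, attrs)
  }
  writeLines(c(header, rows), gff_path)
  if (!is.null(fasta_path)) write_fasta(genome, fasta_path)
  invisible(gff_path)
}

#' Write / read a sequence similarity network
#'
#' Two dialects: a TSV edge list (columns `source`, `target`, `pct_identity`,
#' `bitscore`, `evalue`; isolated nodes are carried in `## node` comment lines
#' so that read(write(g)) reproduces the node set), and a GraphML-like XML for
#' network viewers. Edge attributes round-trip to at least 6 significant
#' digits.
#'
#' @param graph an `ssn_graph` as produced by [build_ssn()].
#' @param path output file.
#' @param dialect `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, dialect = c("edgelist", "graphml")) {
  dialect <- match.arg(dialect)
  nodes <- graph$nodes
  edges <- graph$edges
  fmt <- function(x) formatC(x, digits = 10, format = "g")
  if (dialect == "edgelist") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(nodes))) {
      writeLines(sprintf("## node\t%s\t%d", nodes$id[i], nodes$length[i]), con)
    }
    writeLines("source\ttarget\tpct_identity\tbitscore\tevalue", con)
    if (nrow(edges)) {
      writeLines(sprintf("%s\t%s\t%s\t%s\t%s", edges$a, edges$b,
                         fmt(edges$pct_identity), fmt(edges$bitscore),
                         fmt(edges$evalue)), con)
    }
  } else {
    doc <- xml2::xml_new_root("graphml")
    gr <- xml2::xml_add_child(doc, "graph", id = "ssn", edgedefault = "undirected")
    for (i in seq_len(nrow(nodes))) {
      xml2::xml_add_child(gr, "node", id = nodes$id[i], length = as.character(nodes$length[i]))
    }
    for (i in seq_len(nrow(edges))) {
      xml2::xml_add_child(gr, "edge",
                          source = edges$a[i], target = edges$b[i],
                          pct_identity = fmt(edges$pct_identity[i]),
                          bitscore = fmt(edges$bitscore[i]),
                          evalue = fmt(edges$evalue[i]))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, dialect = c("edgelist", "graphml")) {
  dialect <- match.arg(dialect)
  if (dialect == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    node_lines <- grep("^## node\t", lines, value = TRUE)
    parts <- strsplit(node_lines, "\t")
    nodes <- data.frame(
      id = vapply(parts, `[`, character(1), 2),
      length = as.integer(vapply(parts, `[`, character(1), 3)),
      stringsAsFactors = FALSE
    )
    body <- lines[!grepl("^##", lines)]
    if (length(body) > 1) {
      df <- utils::read.delim(text = paste(body, collapse = "\n"),
                              stringsAsFactors = FALSE)
      edges <- data.frame(a = as.character(df$source), b = as.character(df$target),
                          pct_identity = df$pct_identity, bitscore = df$bitscore,
                          evalue = df$evalue, stringsAsFactors = FALSE)
    } else {
      edges <- .empty_edges()
    }
  } else {
    doc <- xml2::read_xml(path)
    nset <- xml2::xml_find_all(doc, ".//node")
    eset <- xml2::xml_find_all(doc, ".//edge")
    nodes <- data.frame(
      id = xml2::xml_attr(nset, "id"),
      length = as.integer(xml2::xml_attr(nset, "length")),
      stringsAsFactors = FALSE
    )
    if (length(eset)) {
      edges <- data.frame(
        a = xml2::xml_attr(eset, "source"),
        b = xml2::xml_attr(eset, "target"),
        pct_identity = as.numeric(xml2::xml_attr(eset, "pct_identity")),
        bitscore = as.numeric(xml2::xml_attr(eset, "bitscore")),
        evalue = as.numeric(xml2::xml_attr(eset, "evalue")),
        stringsAsFactors = FALSE
      )
    } else {
      edges <- .empty_edges()
    }
  }
  structure(list(nodes = nodes, edges = edges, params = NULL), class = "ssn_graph")
}

.empty_edges <- function() {
  data.frame(a = character(0), b = character(0), pct_identity = numeric(0),
             bitscore = numeric(0), evalue = numeric(0), stringsAsFactors = FALSE)
}
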