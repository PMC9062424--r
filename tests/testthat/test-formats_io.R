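# formats_io: FASTA, GFF3, GenBank, network serialization, coordinates

test_that("read_fasta parses, normalizes, and validates protein records", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "TVGG"), f)
  ps <- read_fasta(f)
  expect_s3_class(ps, "protein_set")
  expect_equal(ps$id, "a")
  expect_equal(ps$length, 4L)

  writeLines(c(">a desc one", "acDE", ">b", "ghKl", ">c", "MNPQ"), f)
  ps <- read_fasta(f)
  expect_equal(nrow(ps), 3L)
  expect_equal(ps$sequence, c("ACDE", "GHKL", "MNPQ"))
  expect_equal(ps$description[1], "desc one")
  expect_equal(ps$length, rep(4L, 3))

  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate id.*a")

  writeLines(c(">a", "AC1DE"), f)
  expect_error(read_fasta(f, type = "protein"), "illegal character '1' at position 3")

  file.create(f2 <- tempfile())
  expect_error(read_fasta(f2), "format error")
})

test_that("FASTA output wraps at 60 columns and round-trips", {
  ps <- protein_set(c("x", "y"), c(strrep("ACDEFGHIKL", 13), "MW"),
                    c("long one", ""))
  f <- tempfile(fileext = ".fasta")
  write_fasta(ps, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(f, type = "protein")
  expect_equal(back$id, ps$id)
  expect_equal(back$sequence, ps$sequence)
})

test_that("coordinate conversion is an involution", {
  for (st in c(1L, 7L, 100L)) {
    en <- st + 8L
    inner <- gff3_to_internal(st, en)
    expect_equal(internal_to_gff3(inner$start, inner$end), list(start = st, end = en))
  }
  # spec anchor: GFF3 start=1,end=9 -> internal [0, 9)
  expect_equal(gff3_to_internal(1L, 9L), list(start = 0L, end = 9L))
})

test_that("read_annotations handles GFF3 with coordinate conversion and bounds", {
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(">ctg", strrep("ACGT", 30)), fa)
  writeLines(c("##gff-version 3",
               "ctg\tsrc\tCDS\t1\t9\t.\t+\t0\tID=g1;product=thing",
               "ctg\tsrc\tCDS\t10\t30\t.\t-\t0\tID=g2"), gff)
  g <- read_annotations(gff, "gff3", genome_fasta = fa)
  expect_equal(g$features$start, c(0L, 9L))
  expect_equal(g$features$end, c(9L, 30L))
  expect_equal(g$features$strand, c("+", "-"))
  expect_equal(g$features$product[1], "thing")

  writeLines(c("##gff-version 3",
               "ctg\tsrc\tCDS\t100\t200\t.\t+\t0\tID=g1"), gff)
  expect_error(read_annotations(gff, "gff3", genome_fasta = fa), "bounds")
})

test_that("GenBank dialect parses complement locations and qualifiers", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       testrec                  30 bp    DNA     linear",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(4..9)",
    '                     /locus_tag="gene1"',
    '                     /product="demo protein"',
    '                     /translation="MK"',
    "     CDS             10..18",
    '                     /locus_tag="gene2"',
    "ORIGIN",
    "        1 atgcatgcat gcatgcatgc atgcatgcat",
    "//"), gb)
  g <- read_annotations(gb, "genbank")
  expect_equal(g$id, "testrec")
  expect_equal(nchar(g$sequence), 30L)
  f1 <- g$features[g$features$feature_id == "gene1", ]
  expect_equal(f1$start, 3L)       # complement(4..9) -> [3, 9) on minus
  expect_equal(f1$end, 9L)
  expect_equal(f1$strand, "-")
  expect_equal(f1$product, "demo protein")
  expect_equal(f1$translation, "MK")
})

test_that("genome_record enforces bounds, strand symbols, and phase flag", {
  feat <- data.frame(feature_id = "f", start = 0L, end = 50L, strand = "+",
                     kind = "CDS", product = "", translation = NA_character_)
  expect_error(genome_record("g", "ACGT", feat), "bounds")
  feat$end <- 4L
  feat$strand <- "?"
  expect_error(genome_record("g", "ACGTACGT", feat), "unknown strand")
  feat$strand <- "+"
  expect_warning(genome_record("g", "ACGTACGT", feat), "not divisible by 3")
  feat$end <- 3L
  g <- genome_record("g", "ACGTACGT", feat)
  expect_true(g$features$phase_ok)
})

test_that("network serialization round-trips node ids, edges, and attributes", {
  for (dialect in c("edgelist", "graphml")) {
    # empty graph
    g0 <- structure(list(nodes = data.frame(id = character(0), length = integer(0)),
                         edges = rippmine:::.empty_edges(), params = NULL),
                    class = "ssn_graph")
    f <- tempfile()
    write_network(g0, f, dialect)
    b0 <- read_network(f, dialect)
    expect_equal(nrow(b0$nodes), 0L)
    expect_equal(nrow(b0$edges), 0L)

    # 2-node 1-edge graph
    g1 <- structure(list(
      nodes = data.frame(id = c("a", "b"), length = c(400L, 410L)),
      edges = data.frame(a = "a", b = "b", pct_identity = 87.654321,
                         bitscore = 123.456789, evalue = 3.21e-99),
      params = NULL), class = "ssn_graph")
    write_network(g1, f, dialect)
    b1 <- read_network(f, dialect)
    expect_equal(b1$nodes$id, c("a", "b"))
    expect_equal(signif(b1$edges$pct_identity, 6), signif(87.654321, 6))
    expect_equal(signif(b1$edges$evalue, 6), signif(3.21e-99, 6))

    # many-cluster synthetic graph with isolated nodes
    set.seed(20)
    n <- 250
    ids <- sprintf("n%03d", seq_len(n))
    # ~118 pair-clusters plus singletons
    pairs <- matrix(ids[1:236], ncol = 2, byrow = TRUE)
    edges <- data.frame(a = pairs[, 1], b = pairs[, 2],
                        pct_identity = runif(118, 40, 100),
                        bitscore = runif(118, 100, 900),
                        evalue = 10^runif(118, -200, -80))
    gg <- structure(list(nodes = data.frame(id = ids, length = rep(400L, n)),
                         edges = edges, params = NULL), class = "ssn_graph")
    write_network(gg, f, dialect)
    bb <- read_network(f, dialect)
    expect_equal(bb$nodes$id, ids)
    expect_equal(paste(bb$edges$a, bb$edges$b), paste(edges$a, edges$b))
    expect_equal(signif(bb$edges$pct_identity, 6), signif(edges$pct_identity, 6))
    expect_equal(signif(bb$edges$bitscore, 6), signif(edges$bitscore, 6))
    expect_equal(signif(bb$edges$evalue, 6), signif(edges$evalue, 6))
  }
})

test_that("genome write/read GFF3 round-trip preserves records", {
  fam <- make_family(list(c(1, 100, 0)), c(50, 60), seed = 4)
  g <- make_genome(fam$records[1, ], n_neighbors = 2,
                   precursor = "MAKWTVGGTVGGTVGGTVGG", hidden = FALSE,
                   seed = 5)$genome
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fasta")
  write_gff3(g, gff, fasta_path = fa)
  back <- read_annotations(gff, "gff3", genome_fasta = fa)
  expect_equal(back$sequence, g$sequence)
  expect_equal(back$features$feature_id, g$features$feature_id)
  expect_equal(back$features$start, g$features$start)
  expect_equal(back$features$end, g$features$end)
  expect_equal(back$features$strand, g$features$strand)
})
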