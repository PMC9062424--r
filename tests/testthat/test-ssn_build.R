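# ssn_build: pairwise alignment, network thresholds, clustering, selection

test_that("align_pair reproduces forced identities and is symmetric", {
  x <- strrep("ACDEFGHIKL", 10)
  e <- align_pair(x, x)
  expect_equal(e$pct_identity, 100)

  # one substitution mid-sequence, ungapped optimum
  a <- "ARNDCQEGHK"
  b <- "ARNDVQEGHK"
  e <- align_pair(a, b)
  expect_equal(e$pct_identity, 90)
  expect_equal(e$aln_length, 10L)

  e2 <- align_pair(b, a)
  expect_equal(e2$score_raw, e$score_raw)
  expect_equal(e2$bitscore, e$bitscore)
  expect_equal(e2$pct_identity, e$pct_identity)

  expect_error(align_pair("AC9T", a), "illegal character")
})

test_that("align_pair raw scores match the brute-force DP oracle", {
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (t in 1:15) {
    x <- paste(sample(aas, sample(15:50, 1), TRUE), collapse = "")
    y <- if (t %% 3 == 0) {
      z <- strsplit(x, "")[[1]]
      i <- sample(length(z), 3)
      z[i] <- sample(aas, 3, TRUE)
      paste(z, collapse = "")
    } else {
      paste(sample(aas, sample(15:50, 1), TRUE), collapse = "")
    }
    expect_equal(align_pair(x, y)$score_raw, oracle_sw_score(x, y),
                 info = paste("pair", t))
  }
})

test_that("between-block pairs fail the E-value threshold", {
  fam <- make_family(list(c(2, 90, 20), c(2, 90, 20)), c(340, 380), seed = 21)
  r <- fam$records
  cross <- align_pair(r[r$id == "blk1_s1", ], r[r$id == "blk2_s1", ])
  expect_gt(cross$evalue, 1e-80)
  within <- align_pair(r[r$id == "blk1_s1", ], r[r$id == "blk1_s2", ])
  expect_lt(within$evalue, 1e-80)
})

test_that("build_ssn applies length and threshold filters", {
  x400 <- strrep("ACDEFGHIKL", 40)
  ps <- protein_set(c("a", "b", "c"), rep(x400, 3))
  g <- build_ssn(ps)
  expect_equal(nrow(g$edges), 3L) # triangle
  expect_setequal(g$nodes$id, c("a", "b", "c"))

  ps2 <- protein_set(c("a", "b", "short"), c(x400, x400, strrep("ACDEFGHIKL", 30)))
  g2 <- build_ssn(ps2)
  expect_false("short" %in% g2$nodes$id)
  expect_equal(nrow(g2$edges), 1L)
})

test_that("planted family blocks are recovered as SSN clusters", {
  fam <- make_family(list(c(4, 90, 20), c(3, 90, 20), c(2, 90, 20)),
                     c(340, 400), seed = 31)
  g <- build_ssn(fam$records)
  # every edge stays within a block
  blk <- function(id) sub("_.*", "", id)
  expect_true(all(blk(g$edges$a) == blk(g$edges$b)))
  cl <- cluster_ssn(g)
  got <- lapply(cl$members, sort)
  want <- lapply(fam$truth$family_blocks, function(b) sort(b$member_ids))
  expect_setequal(got, want)
  # rank by size: 4, 3, 2
  expect_equal(cl$size, c(4L, 3L, 2L))
})

test_that("realized within-block identity is near its target", {
  fam <- make_family(list(c(4, 90, 20)), c(340, 380), seed = 41)
  r <- fam$records
  pids <- combn(4, 2, function(ij) {
    align_pair(r[ij[1], ], r[ij[2], ])$pct_identity
  })
  expect_lt(abs(mean(pids) - 90), 5)
})

test_that("cluster_ssn matches trivial structure and handles isolates", {
  nodes <- data.frame(id = sprintf("n%d", 1:7), length = rep(400L, 7))
  edges <- data.frame(a = c("n1", "n2", "n1", "n4", "n5", "n4"),
                      b = c("n2", "n3", "n3", "n5", "n6", "n6"),
                      pct_identity = c(90, 80, 70, 95, 85, 75),
                      bitscore = 1, evalue = 1e-100)
  g <- structure(list(nodes = nodes, edges = edges, params = NULL),
                 class = "ssn_graph")
  cl <- cluster_ssn(g)
  expect_equal(cl$size, c(3L, 3L, 1L))
  expect_equal(sort(cl$members[[3]]), "n7")
  # medoid of {n1,n2,n3}: n1 has 90+70=160, n2 170, n3 150 -> n2
  expect_equal(cl$representative[cl$cluster_id == 1], "n2")

  # empty edge set -> n singletons
  g0 <- structure(list(nodes = nodes, edges = rippmine:::.empty_edges(),
                       params = NULL), class = "ssn_graph")
  cl0 <- cluster_ssn(g0)
  expect_equal(nrow(cl0), 7L)
  expect_true(all(cl0$size == 1L))
})

test_that("components equal the BFS oracle on random graphs", {
  set.seed(51)
  for (t in 1:10) {
    n <- sample(20:120, 1)
    ids <- sprintf("v%03d", seq_len(n))
    ne <- sample(0:(2 * n), 1)
    edges <- data.frame(a = sample(ids, ne, TRUE), b = sample(ids, ne, TRUE))
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    edges$pct_identity <- runif(nrow(edges), 40, 100)
    edges$bitscore <- 1
    edges$evalue <- 1e-100
    g <- structure(list(nodes = data.frame(id = ids, length = 400L),
                        edges = edges, params = NULL), class = "ssn_graph")
    got <- lapply(cluster_ssn(g)$members, sort)
    expect_equal(got, oracle_components(ids, edges), info = paste("graph", t))
  }
})

test_that("tightening thresholds never adds edges and never merges components", {
  fam <- make_family(list(c(4, 85, 20), c(4, 70, 20)), c(340, 380), seed = 61)
  loose <- build_ssn(fam$records, ssn_params(evalue_max = 1e-20, pid_min = 30))
  for (p in list(ssn_params(evalue_max = 1e-20, pid_min = 60),
                 ssn_params(evalue_max = 1e-120, pid_min = 30))) {
    tight <- build_ssn(fam$records, p)
    key <- function(e) paste(e$a, e$b)
    expect_true(all(key(tight$edges) %in% key(loose$edges)))
    expect_gte(nrow(cluster_ssn(tight)), nrow(cluster_ssn(loose)))
  }
})

test_that("select_analysis_clusters applies the rank/size/sequence rules", {
  cl <- data.frame(
    cluster_id = 1:5,
    size = c(5L, 2L, 1L, 3L, 2L),
    n_sequences = c(5L, 4L, 1L, 3L, 4L),
    representative = letters[1:5]
  )
  cl$members <- replicate(5, "x", simplify = FALSE)
  sel <- select_analysis_clusters(cl)
  # size 1 excluded ("multiple nodes"); n_sequences 3 excluded (>3 means >=4)
  expect_equal(sel$cluster_id, c(1L, 2L, 5L))
  # max_rank truncation
  sel2 <- select_analysis_clusters(cl, max_rank = 2L)
  expect_equal(sel2$cluster_id, c(1L, 2L))
})
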