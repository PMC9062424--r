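# motif_consensus: MSA + conservation, tandem repeats, patterns, scoring

test_that("align_peptides handles identical and near-identical inputs", {
  m <- align_peptides(c("MAKWTVGG", "MAKWTVGG"))
  expect_equal(unname(nchar(m$aligned)), c(8L, 8L))
  expect_false(any(grepl("-", m$aligned)))
  expect_equal(m$conservation, rep(1, 8))
  expect_equal(m$consensus, "MAKWTVGG")

  m2 <- align_peptides(c("TVGGTVGG", "TVGGAVGG"))
  expect_equal(sum(m2$conservation == 0.5), 1L)
  expect_equal(sum(m2$conservation == 1), 7L)

  expect_error(align_peptides("TVGG"), "at least 2")
})

test_that("alignment of length-variant peptides places gaps, not mismatches", {
  m <- align_peptides(c("MAKWTVGGTVGG", "MAWTVGGTVGG", "MAKWTVGGTVGG"))
  expect_equal(length(unique(nchar(m$aligned))), 1L)
  # the deletion shows up as exactly one gap in the short row; conservation
  # (over non-gap residues) stays 1 everywhere and the consensus is the
  # full-length peptide
  expect_equal(sum(strsplit(m$aligned[[2]], "")[[1]] == "-"), 1L)
  expect_equal(m$conservation, rep(1, 12))
  expect_equal(m$consensus, "MAKWTVGGTVGG")
})

test_that("consensus of planted-motif candidates contains the planted unit", {
  set.seed(91)
  peps <- vapply(1:10, function(i) {
    paste0("M", sample(LETTERS[LETTERS %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]], 1),
           "KW", strrep("TVGG", 4))
  }, character(1))
  m <- align_peptides(peps)
  expect_match(m$consensus, "TVGGTVGGTVGGTVGG")
})

test_that("find_tandem_repeats reproduces the canonical examples", {
  h <- find_tandem_repeats(paste0("W", strrep("TVGG", 4)))
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1L)
  expect_equal(h$unit, "TVGG")
  expect_equal(h$copies, 4L)
  expect_equal(h$span, 16L)

  h2 <- find_tandem_repeats("DCDCDCDCDCDC")
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$unit, "DC")
  expect_equal(h2$copies, 6L)

  expect_equal(nrow(find_tandem_repeats("ACDEFGHIKL")), 0L)
  expect_error(find_tandem_repeats(""), "non-empty")
})

test_that("repeat detection is translation-invariant", {
  base <- paste0(strrep("TVGG", 3), "DCDCDC")
  h0 <- find_tandem_repeats(base)
  h1 <- find_tandem_repeats(paste0("A", base))
  expect_equal(h1$start, h0$start + 1L)
  expect_equal(h1$unit, h0$unit)
  expect_equal(h1$copies, h0$copies)
})

test_that("find_tandem_repeats equals the brute-force oracle exhaustively (TVG, len <= 8)", {
  alpha <- c("T", "V", "G")
  for (len in 2:8) {
    grid <- do.call(expand.grid, rep(list(alpha), len))
    strs <- apply(grid, 1, paste, collapse = "")
    for (s in strs) {
      got <- find_tandem_repeats(s)
      want <- oracle_repeats(s)
      if (!isTRUE(all.equal(got, want))) {
        fail(sprintf("mismatch on '%s'", s))
      }
    }
  }
  succeed()
})

test_that("find_tandem_repeats equals the oracle on 200 random peptides", {
  set.seed(101)
  for (t in 1:200) {
    s <- paste(sample(c("T", "V", "G", "D", "C", "A"), sample(8:40, 1), TRUE),
               collapse = "")
    got <- find_tandem_repeats(s)
    want <- oracle_repeats(s)
    expect_equal(got, want, info = s)
  }
})

test_that("match_pattern applies residue classes and wildcards", {
  pats <- motif_patterns()
  m <- match_pattern("WAANYAAN", pats$aro_xxn)
  expect_equal(m$start, c(0L, 4L))
  expect_equal(m$match, c("WAAN", "YAAN"))

  # Aro = {W, Y}: F does not match unless the flag widens the class
  expect_equal(nrow(match_pattern("FAAN", pats$aro_xxn)), 0L)
  wide <- motif_patterns(aro_includes_phe = TRUE)
  expect_equal(nrow(match_pattern("FAAN", wide$aro_xxn)), 1L)

  expect_equal(match_pattern("HAS", pats$his_x_ser)$start, 0L)
  m2 <- match_pattern("YNRAHNRHNR", pats$ynr_hnr2)
  expect_equal(m2$start, 0L)

  # overlapping matches are all reported
  m3 <- match_pattern("DCDCDC", pats$asp_cys)
  expect_equal(m3$start, c(0L, 2L, 4L))
})

test_that("score_precursor ranks planted candidates above decoys on seeded pools", {
  set.seed(111)
  # decoy alphabet avoids V (would seed TVGG-like repeats) and the motif
  # class anchors N/C/S so decoy evidence comes from chance repeats only
  aas <- strsplit("ADEFGHIKLMPQRTWY", "")[[1]]
  leaders <- c("K", "R", "N", "S", "T", "E")
  for (trial in 1:20) {
    planted <- paste0("M", leaders, "W", strrep("TVGG", 4))
    decoys <- vapply(1:4, function(i) {
      paste(sample(aas, 19, TRUE), collapse = "")
    }, character(1))
    pool <- data.frame(
      peptide_id = c(sprintf("planted%d", seq_along(planted)),
                     sprintf("decoy%d", seq_along(decoys))),
      peptide = c(planted, decoys))
    msa <- align_peptides(pool)
    reps <- stats::setNames(lapply(pool$peptide, find_tandem_repeats),
                            pool$peptide_id)
    pats <- motif_patterns()
    hits <- stats::setNames(lapply(pool$peptide, function(p) {
      do.call(rbind, lapply(pats, function(q) match_pattern(p, q)))
    }), pool$peptide_id)
    sc <- score_precursor(msa, reps, hits)
    expect_match(sc$peptide_id[1], "^planted", info = paste("trial", trial))
  }
})

test_that("single candidate and degenerate cores are handled", {
  sc <- score_precursor(repeats = list(solo = find_tandem_repeats("MKWTVGGTVGG")))
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$max_copies, 2L)

  # an all-gap row contributes conservation 0
  msa <- structure(list(
    ids = c("a", "b"),
    aligned = c(a = "----", b = "MKWT"),
    conservation = c(1, 1, 1, 1),
    modal = c("M", "K", "W", "T"),
    consensus = "MKWT", threshold = 0.8), class = "msa_result")
  sc2 <- score_precursor(msa)
  expect_equal(sc2$conservation[sc2$peptide_id == "a"], 0)
})
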