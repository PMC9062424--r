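# Internal sequence helpers shared by the generator and the scanners.

# Run fn() with a locally-set RNG seed, restoring the caller's RNG state.
.seeded <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# genetic code (standard table); initiator codons are handled by callers
.GENETIC_CODE <- Biostrings::GENETIC_CODE

.codon_table_by_aa <- function() {
  split(names(.GENETIC_CODE), unname(.GENETIC_CODE))
}

# Translate an in-frame nucleotide string. Returns NA_character_ when a codon
# contains N. init_met forces the first residue to M (bacterial table 11
# treatment of GTG/TTG initiators).
.translate_nt <- function(nt, init_met = TRUE) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("nucleotide length not divisible by 3", call. = FALSE)
  cod <- substring(nt, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  if (any(grepl("N", cod, fixed = TRUE))) return(NA_character_)
  aa <- unname(.GENETIC_CODE[cod])
  if (anyNA(aa)) return(NA_character_)
  if (init_met && length(aa)) aa[1L] <- "M"
  paste(aa, collapse = "")
}

# Back-translate a peptide with uniformly drawn synonymous codons (RNG must be
# seeded by the caller). The initial M is always ATG.
.back_translate <- function(aa, stop_codon = TRUE) {
  tab <- .codon_table_by_aa()
  letters_ <- strsplit(aa, "")[[1]]
  if (!all(letters_ %in% .AA20)) {
    stop("back-translation requires canonical residues, got: ",
         paste(setdiff(letters_, .AA20), collapse = ","), call. = FALSE)
  }
  codons <- vapply(letters_, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  if (stop_codon) codons <- c(codons, .STOP_CODONS[sample.int(3L, 1L)])
  paste(codons, collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_protein <- function(n, start_met = TRUE) {
  body <- sample(.AA20, n - as.integer(start_met), replace = TRUE)
  paste0(if (start_met) "M" else "", paste(body, collapse = ""))
}

.is_dna_seq <- function(s) {
  chars <- unique(strsplit(s, "")[[1]])
  length(chars) > 0 && all(chars %in% .DNA_ALPHABET)
}

.check_protein_seq <- function(s, id = "<sequence>") {
  chars <- strsplit(s, "")[[1]]
  bad <- which(!(chars %in% .PROTEIN_ALPHABET))
  if (length(bad)) {
    stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                 chars[bad[1]], bad[1], id), call. = FALSE)
  }
  invisible(TRUE)
}

.check_dna_seq <- function(s, id = "<sequence>") {
  chars <- strsplit(s, "")[[1]]
  bad <- which(!(chars %in% .DNA_ALPHABET))
  if (length(bad)) {
    stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                 chars[bad[1]], bad[1], id), call. = FALSE)
  }
  invisible(TRUE)
}
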