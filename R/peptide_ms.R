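# Peptide monoisotopic mass engine: terminal amidation, isotope labels,
# cyclopropylglycine ring events (neutral loss of two hydrogen atoms per
# ring), b/y/internal fragment ladders, ppm errors, and modification-site
# localization from shifted ladders.
#
# Residue positions are 1-based, consistent with b_i / y_j nomenclature.

#' Define a peptide
#'
#' @param residues 1-letter amino-acid chain (canonical 20 letters).
#' @param c_terminus `"free_acid"` or `"amide"` (C-terminal amidation swaps
#'   OH for NH2, -0.98402 Da).
#' @param labels optional isotope labels: data frame with columns `position`
#'   (1-based residue index), `c13` (number of 13C atoms), `n15` (number of
#'   15N atoms).
#' @param name optional display name.
#' @return A `peptide` object.
#' @export
peptide <- function(residues, c_terminus = c("free_acid", "amide"),
                    labels = NULL, name = "") {
  c_terminus <- match.arg(c_terminus)
  residues <- toupper(gsub("\\s", "", residues))
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!(chars %in% .AA20))
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (!all(c("position", "c13", "n15") %in% names(labels))) {
      stop("labels need columns position, c13, n15", call. = FALSE)
    }
    if (any(labels$position < 1 | labels$position > length(chars))) {
      stop("label position outside peptide", call. = FALSE)
    }
  }
  structure(list(residues = residues, c_terminus = c_terminus,
                 labels = labels, name = name),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s%s (%d aa, %s)\n",
              if (nzchar(x$name)) paste0(x$name, ": ") else "", x$residues,
              nchar(x$residues), x$c_terminus))
  invisible(x)
}

#' 13C5,15N labels on every Val residue
#'
#' Convenience constructor for uniformly labeled valine (5 carbons, 1
#' nitrogen per residue), as used for isotope-assisted NMR/MS work.
#'
#' @param p a [peptide].
#' @return A labels data frame suitable for [peptide()].
#' @export
val_13c15n_labels <- function(p) {
  pos <- which(strsplit(p$residues, "")[[1]] == "V")
  data.frame(position = pos, c13 = 5L, n15 = 1L)
}

.label_delta_per_pos <- function(p) {
  n <- nchar(p$residues)
  d <- numeric(n)
  if (!is.null(p$labels) && nrow(p$labels)) {
    d[p$labels$position] <- p$labels$c13 * .MASS_C13_DELTA +
      p$labels$n15 * .MASS_N15_DELTA
  }
  d
}

.check_mod_sites <- function(p, mod_sites) {
  if (!length(mod_sites)) return(invisible(TRUE))
  chars <- strsplit(p$residues, "")[[1]]
  if (any(mod_sites < 1 | mod_sites > length(chars))) {
    stop("modification site outside peptide", call. = FALSE)
  }
  bad <- mod_sites[chars[mod_sites] != "V"]
  if (length(bad)) {
    stop("cyclopropane modification site is not Val at position ",
         bad[1], call. = FALSE)
  }
  if (anyDuplicated(mod_sites)) stop("duplicate modification site", call. = FALSE)
  invisible(TRUE)
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue masses plus water, the amide adjustment when the C-terminus
#' is amidated, all isotope-label deltas, and one -2 H-atom delta per
#' cyclopropane ring.
#'
#' @param p a [peptide].
#' @param mod_sites integer vector of modified Val positions (1-based).
#' @return Neutral mass in Da.
#' @export
monoisotopic_mass <- function(p, mod_sites = integer(0)) {
  .check_mod_sites(p, mod_sites)
  chars <- strsplit(p$residues, "")[[1]]
  m <- sum(.RESIDUE_MASS[chars]) + .WATER_MASS +
    if (p$c_terminus == "amide") .AMIDE_DELTA else 0
  m + sum(.label_delta_per_pos(p)) + length(mod_sites) * .RING_DELTA
}

#' m/z of a neutral mass at charge z
#'
#' `(M + z * proton) / z`, protons as the only charge carrier.
#'
#' @param neutral_mass neutral mass in Da.
#' @param z positive integer charge.
#' @return m/z.
#' @export
mz <- function(neutral_mass, z) {
  if (any(z < 1)) stop("z must be >= 1", call. = FALSE)
  (neutral_mass + z * .PROTON_MASS) / z
}

#' Predicted m/z series for 0..n_max ring modifications
#'
#' Each modification removes two hydrogen atoms, so entry `n` is
#' `base_mz - n * 2 * m_H / z`; the series is strictly decreasing.
#'
#' @param base_mz observed or predicted m/z of the unmodified species.
#' @param z charge.
#' @param n_max maximum number of modifications.
#' @return Data frame `n_mods`, `mz`.
#' @export
modification_series <- function(base_mz, z, n_max) {
  if (z < 1) stop("z must be >= 1", call. = FALSE)
  if (n_max < 0) stop("n_max must be >= 0", call. = FALSE)
  n <- 0:n_max
  data.frame(n_mods = n, mz = base_mz - n * (2 * .ATOMIC_MASS[["H"]]) / z)
}

#' Relative mass error in ppm
#'
#' `|observed - predicted| / predicted * 1e6`. The reported value is
#' truncated (not rounded) to one decimal, the convention that reproduces
#' instrument-software output; full precision is also returned.
#'
#' @param observed,predicted m/z values (`predicted > 0`).
#' @return List with `reported` (one decimal, truncated) and `full`.
#' @export
ppm_error <- function(observed, predicted) {
  if (any(predicted <= 0)) stop("predicted must be positive", call. = FALSE)
  full <- abs(observed - predicted) / predicted * 1e6
  list(reported = trunc(full * 10) / 10, full = full)
}

#' b/y/internal fragment ladder
#'
#' `b_i` covers residues 1..i (plus one proton per charge); `y_j` covers the
#' last j residues plus water and, when the peptide is amidated, the amide
#' adjustment; internal b/y-type fragments are bare contiguous residue sums
#' plus proton(s). A ring modification or isotope label is included exactly
#' when its residue position lies inside the fragment.
#'
#' @param p a [peptide].
#' @param mod_sites modified Val positions (1-based).
#' @param series `"b"`, `"y"`, or `"internal"`.
#' @param z charge (default 1).
#' @return Data frame `series`, `index` (fragment length; `NA` for internal),
#'   `start`, `end` (1-based residue bounds), `z`, `n_mods`, `mz`, sorted by
#'   index (internal: by `start`, `end`).
#' @export
fragment_ladder <- function(p, mod_sites = integer(0),
                            series = c("b", "y", "internal"), z = 1L) {
  series <- match.arg(series)
  .check_mod_sites(p, mod_sites)
  chars <- strsplit(p$residues, "")[[1]]
  n <- length(chars)
  res_mass <- .RESIDUE_MASS[chars] + .label_delta_per_pos(p)
  mod_mass <- numeric(n)
  mod_mass[mod_sites] <- .RING_DELTA
  total <- res_mass + mod_mass
  csum <- cumsum(total)
  seg_sum <- function(a, b) csum[b] - if (a > 1) csum[a - 1] else 0
  seg_mods <- function(a, b) sum(mod_sites >= a & mod_sites <= b)
  amide <- if (p$c_terminus == "amide") .AMIDE_DELTA else 0
  if (series == "b") {
    idx <- seq_len(n)
    out <- data.frame(series = "b", index = idx, start = 1L, end = idx, z = z,
                      n_mods = vapply(idx, function(i) seg_mods(1L, i), numeric(1)),
                      mz = (csum[idx] + z * .PROTON_MASS) / z,
                      stringsAsFactors = FALSE)
  } else if (series == "y") {
    idx <- seq_len(n)
    a <- n - idx + 1L
    sums <- vapply(a, function(ai) seg_sum(ai, n), numeric(1))
    out <- data.frame(series = "y", index = idx, start = a, end = n, z = z,
                      n_mods = vapply(a, function(ai) seg_mods(ai, n), numeric(1)),
                      mz = (sums + .WATER_MASS + amide + z * .PROTON_MASS) / z,
                      stringsAsFactors = FALSE)
  } else {
    combos <- list()
    for (a in 2:(n - 1)) {
      for (b in a:(n - 1)) {
        combos[[length(combos) + 1L]] <- c(a, b)
      }
    }
    ab <- do.call(rbind, combos)
    sums <- vapply(seq_len(nrow(ab)), function(k) seg_sum(ab[k, 1], ab[k, 2]),
                   numeric(1))
    out <- data.frame(series = "internal", index = NA_integer_,
                      start = ab[, 1], end = ab[, 2], z = z,
                      n_mods = vapply(seq_len(nrow(ab)),
                                      function(k) seg_mods(ab[k, 1], ab[k, 2]),
                                      numeric(1)),
                      mz = (sums + z * .PROTON_MASS) / z,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Localize ring modifications from an observed fragment ladder
#'
#' Enumerates every assignment of rings to the peptide's Val positions,
#' predicts the shifted ladder for each, and compares with the observed ions
#' at `tol_ppm`. Two tiers are reported: `consistent` assignments explain
#' every observed ion; `best` assignments maximize the number of matched
#' ions (robust to isolated noise-broken ions). The nonprocessivity
#' (`mixture`) flag is raised when no single assignment is consistent but
#' every ion is explained by some assignment — the observed ions then require
#' at least two distinct modification states jointly.
#'
#' @param p a [peptide].
#' @param observed data frame with columns `series` (`b`/`y`/`internal`),
#'   `index` (for b/y) or `start`,`end` (for internal), `z`, `mz`.
#' @param tol_ppm match tolerance in ppm (default 10).
#' @return List: `val_sites`, `consistent` (list of integer site vectors),
#'   `best` (assignments maximizing matched ions), `n_matched_best`,
#'   `mixture` (logical), `conflict` (first ion matched by no assignment, or
#'   `NULL`), `table` (per-assignment match counts).
#' @export
localize_modifications <- function(p, observed, tol_ppm = 10) {
  chars <- strsplit(p$residues, "")[[1]]
  val_sites <- which(chars == "V")
  if (length(val_sites) > 14) stop("too many Val sites to enumerate", call. = FALSE)
  observed <- as.data.frame(observed)
  n_obs <- nrow(observed)
  if (!n_obs) stop("no observed ions", call. = FALSE)
  subsets <- .all_subsets(val_sites)
  match_mat <- matrix(FALSE, nrow = n_obs, ncol = length(subsets))
  for (s in seq_along(subsets)) {
    pred <- .predict_ions(p, subsets[[s]], observed)
    ppm <- abs(observed$mz - pred) / pred * 1e6
    match_mat[, s] <- !is.na(ppm) & ppm <= tol_ppm
  }
  n_matched <- colSums(match_mat)
  consistent <- subsets[n_matched == n_obs]
  best_idx <- which(n_matched == max(n_matched))
  best <- subsets[best_idx]
  ion_explained <- rowSums(match_mat) > 0
  conflict <- if (all(ion_explained)) NULL else observed[which(!ion_explained)[1], ]
  mixture <- length(consistent) == 0 && all(ion_explained)
  list(
    val_sites = val_sites,
    consistent = consistent,
    best = best,
    n_matched_best = max(n_matched),
    n_observed = n_obs,
    mixture = mixture,
    conflict = conflict,
    table = data.frame(
      assignment = vapply(subsets, function(x) paste(x, collapse = "+"), character(1)),
      n_sites = lengths(subsets),
      n_matched = n_matched
    )
  )
}

.all_subsets <- function(x) {
  out <- list(integer(0))
  for (v in x) {
    out <- c(out, lapply(out, function(s) c(s, v)))
  }
  out
}

# predicted m/z for the ion specs in `observed` under a given assignment
.predict_ions <- function(p, mod_sites, observed) {
  pred <- rep(NA_real_, nrow(observed))
  for (ser in unique(observed$series)) {
    rows <- which(observed$series == ser)
    for (zz in unique(observed$z[rows])) {
      rz <- rows[observed$z[rows] == zz]
      lad <- fragment_ladder(p, mod_sites, series = ser, z = zz)
      if (ser == "internal") {
        key_l <- paste(lad$start, lad$end)
        key_o <- paste(observed$start[rz], observed$end[rz])
        pred[rz] <- lad$mz[match(key_o, key_l)]
      } else {
        pred[rz] <- lad$mz[match(observed$index[rz], lad$index)]
      }
    }
  }
  pred
}
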