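# peptide_ms: masses, series, ppm, ladders, localization

H_ATOM <- 1.0078250319
PROTON <- 1.0072764669

test_that("monoisotopic masses match frozen elemental sums", {
  expect_equal(monoisotopic_mass(peptide("GG")), 132.0535, tolerance = 1e-4)
  # amidation replaces OH with NH2
  p_acid <- peptide("WTVGG")
  p_amide <- peptide("WTVGG", c_terminus = "amide")
  expect_equal(monoisotopic_mass(p_amide) - monoisotopic_mass(p_acid),
               -0.98402, tolerance = 1e-5)
  # one ring = exactly two hydrogen atoms
  pv <- peptide("GVG")
  expect_equal(monoisotopic_mass(pv) - monoisotopic_mass(pv, 2L),
               2 * H_ATOM, tolerance = 1e-9)
  expect_error(monoisotopic_mass(pv, 1L), "not Val")
  # 13C5 15N Val label
  pl <- peptide("GVG", labels = data.frame(position = 2, c13 = 5, n15 = 1))
  expect_equal(monoisotopic_mass(pl) - monoisotopic_mass(pv),
               6.013810, tolerance = 1e-5)
})

test_that("residue masses reproduce standard values to 1e-4", {
  rm <- mass_constants()$residue_mass
  expect_equal(rm[names(REF_RESIDUE_MASS)], REF_RESIDUE_MASS,
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("peptide masses agree with the independent residue-table oracle", {
  set.seed(121)
  for (t in 1:100) {
    s <- random_peptide()
    expect_equal(monoisotopic_mass(peptide(s)), oracle_peptide_mass(s),
                 tolerance = 1e-4, info = s)
  }
})

test_that("mass additivity over concatenation", {
  set.seed(131)
  for (t in 1:10) {
    a <- random_peptide(3, 10)
    b <- random_peptide(3, 10)
    expect_equal(monoisotopic_mass(peptide(paste0(a, b))),
                 monoisotopic_mass(peptide(a)) + monoisotopic_mass(peptide(b)) -
                   mass_constants()$water_mass,
                 tolerance = 1e-9)
  }
})

test_that("mz follows (M + z*proton)/z", {
  expect_equal(mz(0, 1), PROTON, tolerance = 1e-7)
  M <- 2434.2383
  expect_equal(mz(M, 2), (M + 2 * PROTON) / 2, tolerance = 1e-9)
  expect_true(all(diff(mz(M, 1:4)) < 0)) # strictly decreasing in z
  expect_error(mz(100, 0), "z must be")
})

test_that("modification_series steps by exactly 2*mH/z and hits the printed values", {
  s <- modification_series(1218.1337, 2, 3)
  expect_equal(s$mz[1], 1218.1337)
  expect_equal(s$mz[2], 1217.1259, tolerance = 2e-4)
  expect_equal(s$mz[3], 1216.1180, tolerance = 2e-4)
  expect_equal(s$mz[4], 1215.1102, tolerance = 2e-4)
  expect_equal(unique(round(diff(s$mz), 7)), round(-2 * H_ATOM / 2, 7))
  # n = 0 leaves the base unchanged at any charge
  expect_equal(modification_series(500.5, 1, 0)$mz, 500.5)
})

test_that("ppm_error truncates to one decimal and scales invariantly", {
  expect_equal(ppm_error(1218.1376, 1218.1337)$reported, 3.2)
  expect_equal(ppm_error(1217.1238, 1217.1259)$reported, 1.7)
  expect_equal(ppm_error(1216.1166, 1216.1180)$reported, 1.1)
  expect_equal(ppm_error(1215.1069, 1215.1102)$reported, 2.7)
  expect_equal(ppm_error(500, 500)$reported, 0)
  e1 <- ppm_error(1001, 1000)
  e2 <- ppm_error(2002, 2000)
  expect_equal(e1$full, e2$full)
})

test_that("fragment ladders telescope and respect mods and labels", {
  p <- peptide(paste0("W", strrep("TVGG", 4)), c_terminus = "amide")
  n <- 17
  b <- fragment_ladder(p)
  y <- fragment_ladder(p)
  y <- fragment_ladder(p, series = "y")
  # b1 of a Gly-initial peptide
  expect_equal(fragment_ladder(peptide("GVK"))$mz[1], 58.0287, tolerance = 1e-4)
  # telescoping: b_i + y_(n-i) = mz(M,1) + proton
  M <- monoisotopic_mass(p)
  for (i in 1:(n - 1)) {
    expect_equal(b$mz[i] + y$mz[n - i], mz(M, 1) + PROTON, tolerance = 1e-4)
  }
  # full y_n equals the precursor ion
  expect_equal(y$mz[n], mz(M, 1), tolerance = 1e-9)

  # a modified Val shifts exactly the fragments containing it
  y1 <- fragment_ladder(p, mod_sites = 7L, series = "y")
  shifted <- y$mz - y1$mz
  contains <- (n - y$index + 1) <= 7
  expect_equal(shifted[contains], rep(2 * H_ATOM, sum(contains)))
  expect_equal(shifted[!contains], rep(0, sum(!contains)))
  b1 <- fragment_ladder(p, mod_sites = 7L, series = "b")
  expect_equal(b$mz - b1$mz, ifelse(b$index >= 7, 2 * H_ATOM, 0))

  # labels shift masses but not the ladder structure
  pl <- peptide(p$residues, c_terminus = "amide",
                labels = val_13c15n_labels(p))
  yl <- fragment_ladder(pl, series = "y")
  expect_equal(yl$index, y$index)
  expect_true(all(yl$mz >= y$mz))

  # internal fragments: only those containing the site move
  int0 <- fragment_ladder(p, series = "internal")
  int1 <- fragment_ladder(p, mod_sites = 7L, series = "internal")
  inside <- int0$start <= 7 & int0$end >= 7
  expect_equal((int0$mz - int1$mz)[inside], rep(2 * H_ATOM, sum(inside)))
  expect_equal((int0$mz - int1$mz)[!inside], rep(0, sum(!inside)))
})

test_that("noiseless ladders localize the planted site uniquely", {
  p <- peptide(paste0("W", strrep("TVGG", 4)), c_terminus = "amide")
  for (site in c(3L, 7L, 11L, 15L)) {
    ly <- make_ladder(p, site, series = "y", noise_ppm = 0, seed = 1)
    lb <- make_ladder(p, site, series = "b", noise_ppm = 0, seed = 1)
    obs <- rbind(
      data.frame(series = "y", index = ly$index, z = 1, mz = ly$mz_observed),
      data.frame(series = "b", index = lb$index, z = 1, mz = lb$mz_observed))
    loc <- localize_modifications(p, obs)
    expect_equal(loc$consistent, list(site))
    expect_false(loc$mixture)
  }
})

test_that("mixed shifted/unshifted ions over one Val raise the mixture flag", {
  p <- peptide(paste0("W", strrep("TVGG", 4)), c_terminus = "amide")
  un <- fragment_ladder(p, series = "y")
  sh <- fragment_ladder(p, 15L, series = "y")
  obs <- rbind(data.frame(series = "y", index = un$index, z = 1, mz = un$mz),
               data.frame(series = "y", index = 6, z = 1, mz = sh$mz[6]))
  loc <- localize_modifications(p, obs)
  expect_true(loc$mixture)
  expect_equal(loc$consistent, list())
})

test_that("an inexplicable ion yields a conflict diagnostic", {
  p <- peptide(paste0("W", strrep("TVGG", 4)), c_terminus = "amide")
  un <- fragment_ladder(p, series = "y")
  obs <- data.frame(series = "y", index = un$index, z = 1, mz = un$mz)
  obs$mz[5] <- obs$mz[5] + 0.5 # half a Dalton off anything predictable
  loc <- localize_modifications(p, obs)
  expect_equal(loc$consistent, list())
  expect_false(loc$mixture)
  expect_equal(loc$conflict$index, 5)
})
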