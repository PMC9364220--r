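test_that("parser handles ether alternatives, sphingoid splits, and errors", {
  x <- parse_lipid_name("PE(O-36:5)|PE(P-36:4)")
  expect_length(x$alternatives, 2)
  expect_identical(x$alternatives[[1]]$ether, "O")
  expect_identical(x$alternatives[[2]]$ether, "P")
  expect_equal(x$alternatives[[1]]$carbons, 36)
  expect_equal(x$alternatives[[1]]$double_bonds, 5)
  expect_equal(x$alternatives[[2]]$double_bonds, 4)

  st <- parse_lipid_name("ST(d18:1/24:1)")
  expect_identical(st$class, "ST")
  expect_identical(st$sphingoid, "d")
  expect_length(st$alternatives[[1]]$chains, 2)
  expect_equal(st$carbons, 42)
  expect_equal(st$double_bonds, 2)

  fmc <- parse_lipid_name("FMC-6(d18:1/22:0(2-OH))")
  expect_identical(fmc$class, "FMC")
  expect_equal(fmc$alternatives[[1]]$hydroxyls, 1)

  expect_error(parse_lipid_name("PC(35:3"), "parse error")
  expect_error(parse_lipid_name("QQ(34:1)"), "unknown lipid class")
  expect_error(parse_lipid_name("PC(x:1)"), "parse error")
})

test_that("format(parse(s)) round-trips every bundled annotated species", {
  species <- readLines(system.file("extdata", "annotated_species.txt",
                                   package = "lipidmsi"))
  expect_gte(length(species), 39)
  for (s in species)
    expect_identical(format(parse_lipid_name(s)), s)
})

test_that("closed-form class formulas match reference chemistry", {
  expect_identical(format_formula(lipid_formula("FA(22:6)")), "C22H32O2")
  expect_identical(format_formula(lipid_formula("CAR(16:0)")), "C23H45NO4")
  expect_identical(format_formula(lipid_formula("PC(34:1)")), "C42H82NO8P")
  # one double bond removes exactly H2
  f0 <- lipid_formula("PC(36:0)"); f1 <- lipid_formula("PC(36:1)")
  expect_equal(f0[["H"]] - f1[["H"]], 2)
  expect_equal(f0[["C"]], f1[["C"]])
  # O- ether = diacyl - O + H2; P- = diacyl - O
  d <- lipid_formula("PE(36:2)")
  o <- lipid_formula("PE(O-36:2)")
  p <- lipid_formula("PE(P-36:2)")
  expect_equal(d[["O"]] - o[["O"]], 1)
  expect_equal(o[["H"]] - d[["H"]], 2)
  expect_equal(d[["O"]] - p[["O"]], 1)
  expect_equal(p[["H"]], d[["H"]])
  # O-/P- alternatives of an ambiguous name are isomeric
  expect_identical(format_formula(lipid_formula("PE(O-36:5)|PE(P-36:4)")),
                   format_formula(lipid_formula("PE(O-36:5)")))
})

test_that("lookup classes resolve from the bundled table; unsupported error", {
  expect_identical(format_formula(lipid_formula("CDP-DG(40:7)")),
                   "C52H83N3O15P2")
  expect_identical(format_formula(lipid_formula("ST(d18:1/24:1)")),
                   "C48H91NO11S")
  expect_error(lipid_formula("WE(60:0)"), "not in the bundled lookup")
})

test_that("monoisotopic masses and adduct m/z match independent values", {
  expect_equal(monoisotopic_mass(make_formula()), 0)
  expect_equal(adduct_mz(monoisotopic_mass(lipid_formula("FA(22:6)")),
                         "[M-H]-"), 327.2330, tolerance = 5e-4)
  expect_equal(adduct_mz(monoisotopic_mass(lipid_formula("PC(34:1)")),
                         "[M+H]+"), 760.5851, tolerance = 5e-4)
  expect_error(adduct_mz(700, "[M+NH4]+"), "unknown adduct")
})

test_that("formula builder reproduces the bundled reference table", {
  ref <- lipid_reference()
  expect_gte(nrow(ref), 10)
  for (i in seq_len(nrow(ref))) {
    f <- lipid_formula(ref$name[i])
    expect_identical(format_formula(f), ref$formula[i])
    expect_lt(abs(monoisotopic_mass(f) - ref$monoisotopic_mass[i]), 5e-4)
    expect_lt(abs(adduct_mz(monoisotopic_mass(f), ref$adduct[i]) -
                  ref$adduct_mz[i]), 5e-4)
  }
})

test_that("peak matching enforces the ppm tolerance boundary", {
  db <- data.frame(name = "PC(34:1)", adduct = "[M+H]+",
                   mz = 760.5851, mode = "pos")
  exact <- match_peaks(760.5851, db, tol_ppm = 10)
  expect_equal(nrow(exact), 1)
  expect_equal(exact$ppm_error, 0, tolerance = 1e-9)
  inside <- match_peaks(760.5851 * (1 + 9.9e-6), db, tol_ppm = 10)
  expect_equal(nrow(inside), 1)
  outside <- match_peaks(760.5851 * (1 + 10.1e-6), db, tol_ppm = 10)
  expect_equal(nrow(outside), 0)
  # mode separation: a negative-mode peak never matches a positive entry
  expect_equal(nrow(match_peaks(760.5851, db, mode = "neg")), 0)
})

test_that("decoy peaks at least 20 ppm away never match", {
  ref <- lipid_reference()
  db <- data.frame(name = ref$name, adduct = ref$adduct, mz = ref$adduct_mz,
                   mode = ref$mode)
  set.seed(12)
  decoys <- vapply(seq_len(50), function(i) {
    repeat {
      m <- runif(1, 300, 900)
      if (all(abs(1e6 * (db$mz - m) / m) >= 20)) return(m)
    }
  }, numeric(1))
  expect_equal(nrow(match_peaks(decoys, db, tol_ppm = 10)), 0)
})

test_that("matching tolerance is symmetric between peak and theoretical", {
  set.seed(13)
  theo <- sort(runif(30, 300, 900))
  db <- data.frame(name = paste0("x", 1:30), adduct = "[M-H]-", mz = theo,
                   mode = "neg")
  peaks <- theo * (1 + runif(30, -1.2e-5, 1.2e-5))
  hits <- match_peaks(peaks, db, tol_ppm = 10)
  for (i in seq_along(peaks)) {
    fwd <- any(hits$peak_mz == peaks[i] & hits$theo_mz == theo[i])
    rev_ppm <- abs(1e6 * (theo[i] - peaks[i]) / peaks[i])
    expect_equal(fwd, rev_ppm <= 10 + 1e-4)
  }
})

test_that("even-chain preference resolves ties; lone odd chains are kept", {
  mz35 <- adduct_mz(monoisotopic_mass(lipid_formula("PC(35:3)")), "[M+H]+")
  mz36 <- adduct_mz(monoisotopic_mass(lipid_formula("PC(36:3)")), "[M+H]+")
  cands <- data.frame(
    peak_mz = c(760.0, 760.0), name = c("PC(35:3)", "PC(36:3)"),
    adduct = "[M+H]+", theo_mz = c(mz35, mz36),
    ppm_error = c(0.5, 2.0), mode = "pos", stringsAsFactors = FALSE)
  ann <- filter_candidates(cands)
  expect_equal(nrow(ann), 1)
  expect_identical(ann$annotation, "PC(36:3)")
  expect_true(ann$parity_preferred)
  rej <- attr(ann, "rejections")
  expect_true("PC(35:3)" %in% rej$name)
  expect_identical(rej$rule[rej$name == "PC(35:3)"], "odd_chain_disfavored")
  # a lone odd-chain candidate survives, flagged
  ann2 <- filter_candidates(cands[1, ])
  expect_identical(ann2$annotation, "PC(35:3)")
  expect_false(ann2$parity_preferred)
})

test_that("isomeric O-/P- candidates merge into an ambiguous annotation", {
  mz <- adduct_mz(monoisotopic_mass(lipid_formula("PE(O-36:5)")), "[M-H]-")
  cands <- data.frame(
    peak_mz = mz, name = c("PE(P-36:4)", "PE(O-36:5)"),
    adduct = "[M-H]-", theo_mz = mz, ppm_error = 0, mode = "neg",
    stringsAsFactors = FALSE)
  ann <- filter_candidates(cands)
  expect_equal(nrow(ann), 1)
  expect_identical(ann$annotation, "PE(O-36:5)|PE(P-36:4)")
})

test_that("adduct-class consistency and isotope checks reject impostors", {
  # a choline-bearing PC proposed in negative mode is rejected
  cands <- data.frame(peak_mz = 760, name = "PC(34:1)", adduct = "[M-H]-",
                      theo_mz = 760, ppm_error = 0, mode = "neg",
                      stringsAsFactors = FALSE)
  ann <- filter_candidates(cands)
  expect_equal(nrow(ann), 0)
  expect_identical(attr(ann, "rejections")$rule, "adduct_class_consistency")

  # C40 lipid with observed (M+1)/M = 0.43: predicted 0.428 -> accepted
  mzpi <- 800
  c40 <- data.frame(peak_mz = mzpi, name = "PI(31:0)", adduct = "[M-H]-",
                    theo_mz = mzpi, ppm_error = 0, mode = "neg",
                    stringsAsFactors = FALSE)  # PI(31:0) has C40
  expect_equal(lipid_formula("PI(31:0)")[["C"]], 40)
  env <- data.frame(peak_mz = mzpi, ratio_m1 = 0.43)
  ann_ok <- filter_candidates(c40, envelopes = env)
  expect_equal(nrow(ann_ok), 1)
  expect_true(ann_ok$isotope_ok)
  # far-off ratio -> rejected by the isotope rule
  env_bad <- data.frame(peak_mz = mzpi, ratio_m1 = 0.20)
  ann_bad <- filter_candidates(c40, envelopes = env_bad)
  expect_equal(nrow(ann_bad), 0)
  expect_identical(attr(ann_bad, "rejections")$rule, "isotope_pattern")

  # chain window: a 60-carbon "diacyl" is implausible
  big <- data.frame(peak_mz = 1200, name = "PC(60:1)", adduct = "[M+H]+",
                    theo_mz = 1200, ppm_error = 0, mode = "pos",
                    stringsAsFactors = FALSE)
  ann3 <- filter_candidates(big)
  expect_equal(nrow(ann3), 0)
  expect_identical(attr(ann3, "rejections")$rule, "chain_length")
})

test_that("isotope ratio prediction follows the 13C/15N expansion", {
  expect_equal(isotope_ratio_m1(make_formula(C = 40)), 0.428)
  expect_equal(isotope_ratio_m1("C10N2"), 0.107 + 0.0074)
})
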