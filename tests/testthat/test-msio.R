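test_that("global-max normalization rescales by the dataset-wide maximum", {
  d <- tiny_dataset(matrix(c(2, 4, 6, 0, 10, 40, 20, 0), ncol = 2))
  nd <- normalize_global_max(d)
  expect_equal(max(nd$sections[[1]]$intensities), 1)
  expect_equal(nd$sections[[1]]$intensities, d$sections[[1]]$intensities / 40)
  # idempotence on an already-normalized dataset
  nd2 <- normalize_global_max(nd)
  expect_equal(nd2$sections[[1]]$intensities, nd$sections[[1]]$intensities)
})

test_that("normalization synchronizes across sections (cross-section maximum)", {
  # two sections with maxima 10 and 40: both divided by 40
  s1 <- matrix(c(1, 2, 10, 0), ncol = 1)
  s2 <- matrix(c(4, 40, 8, 0), ncol = 1)
  d <- tiny_dataset(s1, n_sections = 2, section_values = list(s1, s2))
  nd <- normalize_global_max(d)
  expect_equal(nd$sections[[1]]$intensities, s1 / 40)
  expect_equal(nd$sections[[2]]$intensities, s2 / 40)
  expect_equal(unname(attr(nd, "norm_constant")["pos"]), 40)
})

test_that("normalization is per ionization mode and all-zero data errors", {
  s_pos <- list(meta = list(section_id = "p1", animal = "a", age = 7,
                            treatment = "CTL", mode = "pos"),
                intensities = matrix(c(0, 5, 0, 0), ncol = 1))
  s_neg <- list(meta = list(section_id = "n1", animal = "a", age = 7,
                            treatment = "CTL", mode = "neg"),
                intensities = matrix(c(0, 20, 0, 0), ncol = 1))
  d <- msi_dataset(list(s_pos, s_neg), feature_mz = 500, dims = c(2L, 2L))
  nd <- normalize_global_max(d)
  expect_equal(max(nd$sections[[1]]$intensities), 1)  # pos scaled by 5
  expect_equal(max(nd$sections[[2]]$intensities), 1)  # neg scaled by 20
  zero <- tiny_dataset(matrix(0, 4, 1))
  expect_error(normalize_global_max(zero), "no positive intensity")
})

test_that("roi_average computes hand-checked per-region and whole means", {
  # 2x2 grid, labels [A, A, B, bg], intensities [2, 4, 6, 1]
  d <- tiny_dataset(matrix(c(2, 4, 6, 1), ncol = 1))
  fm <- roi_average(d, tiny_atlas())
  expect_equal(unname(fm$values[fm$samples$region == "A", 1]), 3)
  expect_equal(unname(fm$values[fm$samples$region == "B", 1]), 6)
  expect_equal(unname(fm$values[fm$samples$region == "whole", 1]), 4)
})

test_that("roi_average on the default atlas yields 13 region rows + whole", {
  fx <- small_sim(n_features = 6, n_identified = 3)
  fm <- roi_average(fx$sim$datasets$pos, fx$atlas)
  per_section <- table(fm$samples$section_id)
  expect_true(all(per_section == 14))
  expect_setequal(unique(fm$samples$region),
                  c("OA", "vST", "ST", "CTX", "HIP", "HYP", "TH", "MB",
                    "HB", "CBX", "AV", "FO", "CC", "whole"))
  # uniform intensity 1 -> every ROI mean 1
  u <- fx$sim$datasets$pos
  lv <- as.vector(fx$atlas$labels)
  u$sections <- lapply(u$sections[1], function(s) {
    s$intensities[] <- 0; s$intensities[lv > 0, ] <- 1; s
  })
  fmu <- roi_average(u, fx$atlas)
  expect_true(all(abs(fmu$values - 1) < 1e-12))
})

test_that("empty ROI is an explicit error unless na_empty", {
  atl <- tiny_atlas()
  atl$names <- c(atl$names, `3` = "C")  # C never occurs in the grid
  d <- tiny_dataset(matrix(c(2, 4, 6, 1), ncol = 1))
  expect_error(roi_average(d, atl), "empty ROI.*C")
  fm <- roi_average(d, atl, na_empty = TRUE)
  expect_true(all(is.na(fm$values[fm$samples$region == "C", ])))
})

test_that("roi_average commutes with normalization up to the same scalar", {
  fx <- small_sim(n_features = 6, n_identified = 3)
  d <- fx$sim$datasets$pos
  fm_raw <- roi_average(d, fx$atlas)
  nd <- normalize_global_max(d)
  fm_norm <- roi_average(nd, fx$atlas)
  const <- unname(attr(nd, "norm_constant")["pos"])
  expect_equal(fm_norm$values, fm_raw$values / const, tolerance = 1e-12)
})

test_that("whole-section mean is the size-weighted mean of region means", {
  fx <- small_sim(n_features = 4, n_identified = 2)
  fm <- roi_average(fx$sim$datasets$pos, fx$atlas)
  sizes <- table(factor(as.vector(fx$atlas$labels), levels = 1:13))
  s1 <- fm$samples$section_id == fm$samples$section_id[1]
  regions <- fm$values[s1 & fm$samples$region != "whole", ]
  whole <- fm$values[s1 & fm$samples$region == "whole", ]
  expect_equal(unname(colSums(regions * as.numeric(sizes)) / sum(sizes)),
               unname(whole), tolerance = 1e-12)
})

test_that("columnar text round trip preserves intensities and metadata", {
  fx <- small_sim(n_features = 5, n_identified = 3)
  d <- fx$sim$datasets$pos
  d$sections <- d$sections[1:3]
  dir <- tempfile("msiio")
  write_msi_dataset(d, dir)
  d2 <- read_msi_dataset(dir)
  expect_equal(d2$feature_mz, d$feature_mz)
  expect_identical(d2$dims, as.integer(d$dims))
  for (i in 1:3) {
    expect_equal(d2$sections[[i]]$intensities,
                 d$sections[[i]]$intensities, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_identical(d2$sections[[i]]$meta$animal, d$sections[[i]]$meta$animal)
    expect_identical(d2$sections[[i]]$meta$treatment,
                     d$sections[[i]]$meta$treatment)
  }
  unlink(dir, recursive = TRUE)
})

test_that("feature matrix TSV and atlas files round-trip", {
  fm <- sim_feature_matrix(n_features = 4)
  path <- tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path, norm_constant = c(pos = 40))
  fm2 <- read_feature_matrix(path)
  expect_equal(fm2$values, fm$values, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(fm2$feature_mz, fm$feature_mz, tolerance = 1e-6)
  expect_identical(fm2$samples$treatment, fm$samples$treatment)
  unlink(path)

  atl <- make_atlas(48, 32, seed = 4)
  pre <- tempfile("atl")
  write_atlas(atl, pre)
  atl2 <- read_atlas(pre)
  expect_identical(atl2$labels, atl$labels)
  expect_identical(unname(unlist(atl2$names)), unname(atl$names))
})
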