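test_that("constant responses yield zero effect and p = 1 by convention", {
  fm <- sim_feature_matrix(n_features = 3)
  fm$values[, 2] <- 5
  g <- fit_feature_glms(fm)
  expect_equal(g$stats$estimate[2], 0)
  expect_equal(g$stats$p_treatment[2], 1)
  expect_equal(g$stats$p_age[2], 1)
  expect_equal(g$stats$p_interaction[2], 1)
})

test_that("swapping group labels negates the estimate and maps p to 1 - p", {
  fm <- sim_feature_matrix(n_features = 5, shift = rep(0.4, 5), seed = 3)
  g1 <- fit_feature_glms(fm)
  fm2 <- fm
  fm2$samples$treatment <- ifelse(fm$samples$treatment == "CTL", "PL", "CTL")
  g2 <- fit_feature_glms(fm2)
  expect_equal(g2$stats$estimate, -g1$stats$estimate, tolerance = 1e-10)
  expect_equal(g2$stats$p_treatment, 1 - g1$stats$p_treatment,
               tolerance = 1e-10)
})

test_that("F tests and one-sided p agree with the lm/anova oracle", {
  fm <- sim_feature_matrix(n_features = 6, shift = c(0, 0, 0.5, 1, 0, 0.2),
                           seed = 5)
  g <- fit_feature_glms(fm)
  treatment <- relevel(factor(fm$samples$treatment), "CTL")
  age <- factor(fm$samples$age)
  for (j in seq_len(6)) {
    y <- fm$values[, j]
    an <- anova(lm(y ~ treatment * age))
    expect_equal(g$stats$F_treatment[j], an["treatment", "F value"],
                 tolerance = 1e-8)
    expect_equal(g$stats$F_age[j], an["age", "F value"], tolerance = 1e-8)
    expect_equal(g$stats$F_interaction[j], an["treatment:age", "F value"],
                 tolerance = 1e-8)
    expect_equal(g$stats$p_interaction[j], an["treatment:age", "Pr(>F)"],
                 tolerance = 1e-8)
    sm <- summary(lm(y ~ treatment + age))$coefficients
    expect_equal(g$stats$estimate[j], sm["treatmentPL", "Estimate"],
                 tolerance = 1e-8)
    expect_equal(g$stats$p_treatment[j],
                 pt(sm["treatmentPL", "t value"], 32 - 5,
                    lower.tail = FALSE), tolerance = 1e-10)
  }
  # two-sided option matches lm's reported p
  g2 <- fit_feature_glms(fm, two_sided = TRUE)
  y <- fm$values[, 3]
  sm <- summary(lm(y ~ treatment + age))$coefficients
  expect_equal(g2$stats$p_treatment[3], sm["treatmentPL", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("one-sided p agrees with a 10,000-draw permutation oracle", {
  # balanced 2 x 4 design, n = 4 per cell, planted +1 shift, sd 0.5
  fm <- sim_feature_matrix(n_features = 2, shift = c(1, 0), sd = 0.5,
                           seed = 17)
  g <- fit_feature_glms(fm)
  treatment <- relevel(factor(fm$samples$treatment), "CTL")
  age <- factor(fm$samples$age)
  Xage <- model.matrix(~age)
  perm_p <- function(y, n_draws = 10000) {
    tstat <- function(trt) {
      X <- cbind(Xage, PL = as.numeric(trt == "PL"))
      q <- qr(X)
      res <- qr.resid(q, y)
      df <- length(y) - ncol(X)
      s2 <- sum(res^2) / df
      xtxinv <- chol2inv(qr.R(q))
      co <- qr.coef(q, y)[["PL"]]
      co / sqrt(xtxinv[ncol(X), ncol(X)] * s2)
    }
    obs <- tstat(treatment)
    set.seed(99)
    hits <- 0
    ages <- unique(fm$samples$age)
    for (i in seq_len(n_draws)) {
      trt <- as.character(treatment)
      for (a in ages) {               # permute labels within each age
        idx <- which(fm$samples$age == a)
        trt[idx] <- sample(trt[idx])
      }
      if (tstat(trt) >= obs) hits <- hits + 1
    }
    hits / n_draws
  }
  for (j in 1:2) {
    p_perm <- perm_p(fm$values[, j])
    mc_err <- 3 * sqrt(max(p_perm, 1e-4) * (1 - p_perm) / 10000)
    expect_lt(abs(g$stats$p_treatment[j] - p_perm), mc_err + 0.01)
  }
})

test_that("decile selection keeps the ceiling(0.6 n) smallest p per m/z decile", {
  # 10 significant features with hand-assigned p across 2 deciles
  stats <- data.frame(
    feature_id = paste0("f", 1:10),
    mz = c(100, 110, 120, 130, 140, 500, 510, 520, 530, 540),
    p_treatment = c(0.04, 0.01, 0.03, 0.02, 0.045,
                    0.002, 0.049, 0.001, 0.03, 0.02))
  sel <- select_pl_up(stats, alpha = 0.05, n_deciles = 2,
                      keep_fraction = 0.6)
  # brute-force oracle: sort each half by p, keep ceiling(0.6 * 5) = 3
  lower <- c("f2", "f4", "f3")
  upper <- c("f8", "f6", "f10")
  expect_setequal(sel$retained, c(lower, upper))
  expect_length(sel$significant, 10)
})

test_that("selection handles edge cases and ties deterministically", {
  # no significant features -> empty result, not an error
  stats <- data.frame(feature_id = "a", mz = 100, p_treatment = 0.2)
  sel <- select_pl_up(stats)
  expect_length(sel$retained, 0)
  # tie on p broken by smaller m/z
  stats2 <- data.frame(feature_id = c("lo", "hi"), mz = c(100, 200),
                       p_treatment = c(0.01, 0.01))
  sel2 <- select_pl_up(stats2, n_deciles = 1, keep_fraction = 0.5)
  expect_identical(sel2$retained, "lo")
})

test_that("selection is invariant to monotone rescaling of m/z", {
  set.seed(31)
  stats <- data.frame(feature_id = sprintf("f%03d", 1:80),
                      mz = sort(runif(80, 100, 1000)),
                      p_treatment = runif(80, 0, 0.049))
  s1 <- select_pl_up(stats)
  stats2 <- stats
  stats2$mz <- stats$mz^3 / 1e5   # strictly monotone transform
  s2 <- select_pl_up(stats2)
  expect_setequal(s1$retained, s2$retained)
})

test_that("singular designs raise an error naming the empty cell", {
  fm <- sim_feature_matrix(n_features = 2)
  drop <- !(fm$samples$treatment == "PL" & fm$samples$age == 21)
  expect_error(fit_feature_glms(fm_subset(fm, drop)),
               "empty cell treatment=PL x age=21")
})

test_that("ROI model reports a 13-level region F test and sane conventions", {
  fx <- small_sim(n_features = 12, n_identified = 5)
  fm <- roi_average(fx$sim$datasets$pos, fx$atlas)
  pm <- preprocess(fm_subset(fm, fm$samples$region != "whole"))
  g <- fit_roi_glms(pm)
  expect_length(g$region_levels, 13)
  expect_true(all(c("F_roi", "p_roi") %in% names(g$stats)))
  expect_true(all(g$stats$p_roi >= 0 & g$stats$p_roi <= 1))
  # oracle agreement for one feature
  treatment <- relevel(factor(pm$samples$treatment), "CTL")
  age <- factor(pm$samples$age)
  region <- factor(pm$samples$region)
  y <- pm$values[, 1]
  an <- anova(lm(y ~ treatment + age + region + treatment:age))
  expect_equal(g$stats$F_roi[1], an["region", "F value"], tolerance = 1e-8)
  expect_equal(g$stats$p_roi[1], an["region", "Pr(>F)"], tolerance = 1e-8)
})

test_that("region-uniform responses give ROI p = 1 without breaking the treatment test", {
  fm <- sim_feature_matrix(n_features = 2, shift = c(0.8, 0), seed = 41)
  regions <- c("OA", "CTX", "TH")
  samples <- do.call(rbind, lapply(regions, function(r) {
    s <- fm$samples; s$region <- r; s
  }))
  samples$section_id <- paste(samples$animal, samples$age,
                              samples$treatment)
  values <- do.call(rbind, replicate(3, fm$values, simplify = FALSE))
  fmr <- feature_matrix(values, samples, fm$feature_mz)
  g <- fit_roi_glms(fmr)
  expect_equal(g$stats$F_roi, c(0, 0))
  expect_equal(g$stats$p_roi, c(1, 1))
  expect_lt(g$stats$p_treatment[1], 0.01)
})

test_that("planted region-only signal: ROI p small, treatment p null-uniform", {
  # animal_sd = 0 so region rows are independent given the design; with an
  # animal random intercept the per-ROI rows of one section are correlated
  # and the fixed-effects treatment test is anti-conservative (see vignette)
  fx <- small_sim(n_features = 30, n_identified = 10, effect_fraction = 0,
                  animal_sd = 0, seed = 55)
  fm <- roi_average(fx$sim$datasets$pos, fx$atlas)
  pm <- preprocess(fm_subset(fm, fm$samples$region != "whole"))
  g <- fit_roi_glms(pm)
  # region profiles are planted for most features
  has_region <- fx$sim$truth$region_type != "uniform"
  expect_gt(mean(g$stats$p_roi[has_region] < 0.01), 0.9)
  # no treatment effect anywhere: one-sided p roughly uniform
  expect_lt(mean(g$stats$p_treatment < 0.05), 0.25)
  expect_gt(mean(g$stats$p_treatment), 0.3)
})
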