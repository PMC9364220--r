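# Per-feature linear models for treatment and development effects, and the
# decile-stratified selection of supplement-elevated peaks.
#
# "GLM" here is ordinary least squares with Gaussian errors and identity
# link: the response is a preprocessed z-score, and the factors are treatment
# (2 levels), age (4 levels), optionally ROI (13 levels), with the treatment
# x age interaction. Because the design is shared across features, all
# features are fitted at once through one QR decomposition per nested model;
# F statistics come from sequential sums of squares (which, in the balanced
# designs this pipeline produces, coincide with the usual two-way ANOVA
# main-effect tests).

# residual sums of squares per feature for a fixed design matrix
.rss_cols <- function(X, Y) {
  q <- qr(X)
  colSums(qr.resid(q, Y)^2)
}

.check_cells <- function(samples) {
  tab <- table(samples$treatment, samples$age)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("singular design: empty cell treatment=",
         rownames(tab)[empty[1]], " x age=", colnames(tab)[empty[2]])
  }
  if (any(tab < 2))
    stop("design needs at least 2 samples per treatment x age cell")
}

.fit_glms <- function(pm, with_roi, two_sided) {
  stopifnot(inherits(pm, "feature_matrix"))
  samples <- pm$samples
  if ("region" %in% names(samples)) {
    keep <- if (with_roi) samples$region != "whole"
            else samples$region == "whole"
    pm <- fm_subset(pm, keep)
    samples <- pm$samples
  } else if (with_roi) {
    stop("ROI model requested but the matrix has no region column")
  }
  .check_cells(samples)
  treatment <- factor(samples$treatment)
  if ("CTL" %in% levels(treatment))
    treatment <- stats::relevel(treatment, "CTL")
  age <- factor(samples$age)
  Y <- pm$values
  n <- nrow(Y)

  if (with_roi) {
    region <- factor(samples$region)
    per_section <- table(samples$section_id)
    if (length(unique(per_section)) != 1)
      stop("region rows must be present for all sections")
    X0 <- stats::model.matrix(~1, data.frame(treatment))
    X1 <- stats::model.matrix(~treatment)
    X2 <- stats::model.matrix(~treatment + age)
    X3 <- stats::model.matrix(~treatment + age + region)
    X4 <- stats::model.matrix(~treatment + age + region + treatment:age)
    Xmain <- X3
  } else {
    X0 <- stats::model.matrix(~1, data.frame(treatment))
    X1 <- stats::model.matrix(~treatment)
    X2 <- stats::model.matrix(~treatment + age)
    X4 <- stats::model.matrix(~treatment * age)
    X3 <- NULL
    Xmain <- X2
  }

  rss <- lapply(Filter(Negate(is.null), list(X0, X1, X2, X3, X4)),
                .rss_cols, Y = Y)
  nm <- length(rss)
  rss_full <- rss[[nm]]
  df_res <- n - qr(if (with_roi) X4 else X4)$rank
  ss_trt <- rss[[1]] - rss[[2]]
  ss_age <- rss[[2]] - rss[[3]]
  ss_int <- rss[[nm - 1]] - rss[[nm]]
  df_age <- nlevels(age) - 1
  df_int <- df_age  # treatment has 1 df
  mse <- pmax(rss_full / df_res, .Machine$double.xmin)

  total_ss <- rss[[1]]
  degenerate <- total_ss < 1e-18

  f_of <- function(ss, df) {
    f <- (ss / df) / mse
    f[degenerate] <- 0
    pmax(f, 0)
  }
  F_trt <- f_of(ss_trt, 1)
  F_age <- f_of(ss_age, df_age)
  F_int <- f_of(ss_int, df_int)
  p_trt_F <- stats::pf(F_trt, 1, df_res, lower.tail = FALSE)
  p_age <- stats::pf(F_age, df_age, df_res, lower.tail = FALSE)
  p_int <- stats::pf(F_int, df_int, df_res, lower.tail = FALSE)

  # one-sided treatment test from the main-effects model t statistic
  qmain <- qr(Xmain)
  coefs <- qr.coef(qmain, Y)
  trt_col <- grep("^treatment", colnames(Xmain), value = TRUE)[1]
  est <- coefs[trt_col, ]
  df_main <- n - qmain$rank
  sigma2 <- pmax(.rss_cols(Xmain, Y) / df_main, .Machine$double.xmin)
  xtxinv <- chol2inv(qr.R(qmain))
  ii <- which(colnames(Xmain) == trt_col)
  tstat <- est / sqrt(xtxinv[ii, ii] * sigma2)
  p_one <- stats::pt(tstat, df_main, lower.tail = FALSE)
  p_two <- 2 * stats::pt(abs(tstat), df_main, lower.tail = FALSE)
  est[degenerate] <- 0
  tstat[degenerate] <- 0
  p_one[degenerate] <- 1
  p_two[degenerate] <- 1

  stats_df <- data.frame(
    feature_id = pm$feature_id, mz = pm$feature_mz,
    estimate = unname(est), t = unname(tstat),
    p_treatment = unname(if (two_sided) p_two else p_one),
    F_treatment = unname(F_trt), p_treatment_F = unname(p_trt_F),
    F_age = unname(F_age), p_age = unname(p_age),
    F_interaction = unname(F_int), p_interaction = unname(p_int),
    stringsAsFactors = FALSE)

  if (with_roi) {
    ss_roi <- rss[[3]] - rss[[4]]
    df_roi <- nlevels(region) - 1
    F_roi <- f_of(ss_roi, df_roi)
    stats_df$F_roi <- unname(F_roi)
    stats_df$p_roi <- unname(stats::pf(F_roi, df_roi, df_res,
                                       lower.tail = FALSE))
    stats_df$p_roi[degenerate] <- 1
  }
  stats_df$p_age[degenerate] <- 1
  stats_df$p_interaction[degenerate] <- 1
  stats_df$p_treatment_F[degenerate] <- 1

  structure(list(stats = stats_df, two_sided = two_sided,
                 with_roi = with_roi, n = n, df_residual = df_res,
                 df_main = df_main,
                 treatment_levels = levels(treatment),
                 age_levels = levels(age),
                 region_levels = if (with_roi) levels(region) else NULL),
            class = "msi_glm")
}

#' Per-feature treatment x development linear models
#'
#' Fits, for every feature, a Gaussian identity-link linear model of the
#' preprocessed (z-score) response on treatment (2 levels), age (4 levels),
#' and their interaction; reports main-effect and interaction F tests, and a
#' treatment p-value from the t statistic of the supplemented-group
#' coefficient in the main-effects model. By default the treatment test is
#' one-sided (supplemented greater than control), matching a selection aimed
#' at supplement-elevated peaks; set \code{two_sided = TRUE} for the
#' two-sided version.
#'
#' If the matrix has a \code{region} column only the "whole"-section rows are
#' used; see \code{\link{fit_roi_glms}} for the per-ROI variant.
#'
#' @param pm a \code{preprocessed_matrix} (or any \code{feature_matrix}).
#' @param two_sided report a two-sided treatment p instead.
#' @return an object of class \code{msi_glm}; \code{$stats} holds one row per
#'   feature (estimate = supplemented minus control in z-score units,
#'   one-sided p, F and p for age and interaction).
#' @export
fit_feature_glms <- function(pm, two_sided = FALSE) {
  .fit_glms(pm, with_roi = FALSE, two_sided = two_sided)
}

#' Per-feature models with ROI as an additional factor
#'
#' Same as \code{\link{fit_feature_glms}} but fitted on the per-region rows
#' with region (13 levels) as an additional main-effect factor; the
#' per-feature ROI F test is reported alongside the treatment and age
#' effects.
#'
#' @inheritParams fit_feature_glms
#' @return an \code{msi_glm} whose stats include \code{F_roi}, \code{p_roi}.
#' @export
fit_roi_glms <- function(pm, two_sided = FALSE) {
  .fit_glms(pm, with_roi = TRUE, two_sided = two_sided)
}

#' @export
print.msi_glm <- function(x, ...) {
  cat("Per-feature linear models:", nrow(x$stats), "features,",
      x$n, "samples", if (x$with_roi) "(ROI model)" else "(whole-section)",
      "\n")
  cat("treatment test:", if (x$two_sided) "two-sided" else
      "one-sided (supplemented > control)", "| residual df", x$df_residual,
      "\n")
  invisible(x)
}

#' @export
summary.msi_glm <- function(object, alpha = 0.05, ...) {
  s <- object$stats
  out <- list(
    n_features = nrow(s),
    n_treatment_sig = sum(s$p_treatment < alpha),
    n_age_sig = sum(s$p_age < alpha),
    n_interaction_sig = sum(s$p_interaction < alpha),
    alpha = alpha)
  cat("Features:", out$n_features, "\n")
  cat(sprintf("treatment p < %.3g: %d | age: %d | interaction: %d\n",
              alpha, out$n_treatment_sig, out$n_age_sig,
              out$n_interaction_sig))
  invisible(out)
}

#' @export
coef.msi_glm <- function(object, ...) {
  stats::setNames(object$stats$estimate, object$stats$feature_id)
}

#' Decile-stratified selection of supplement-elevated peaks
#'
#' Features whose treatment p-value is below \code{alpha} are grouped by the
#' deciles of increasing m/z (rank-based, computed on the significant set),
#' and within each decile the \code{ceiling(keep_fraction * n_decile)}
#' features with the smallest p-values are retained (ties broken by smaller
#' m/z), so the selection spans the whole m/z range instead of clumping where
#' power is highest.
#'
#' @param stats an \code{msi_glm}, or a data frame with columns
#'   \code{feature_id}, \code{p_treatment} (and \code{mz} unless given
#'   separately).
#' @param mz optional m/z vector aligned with \code{stats}.
#' @param alpha significance threshold on the treatment p.
#' @param n_deciles number of m/z strata.
#' @param keep_fraction fraction of each stratum retained.
#' @return an object of class \code{selection_result}: \code{significant}
#'   and \code{retained} feature ids, decile \code{boundaries} (m/z),
#'   per-decile membership, and the parameters.
#' @export
select_pl_up <- function(stats, mz = NULL, alpha = 0.05, n_deciles = 10,
                         keep_fraction = 0.6) {
  if (inherits(stats, "msi_glm")) stats <- stats$stats
  stats <- as.data.frame(stats)
  if (is.null(mz)) mz <- stats$mz
  if (is.null(mz) || length(mz) != nrow(stats))
    stop("stats and mz are not aligned")
  p <- stats$p_treatment
  sig <- which(!is.na(p) & p < alpha)
  if (!length(sig)) {
    return(structure(list(significant = character(0),
                          retained = character(0),
                          boundaries = numeric(0), per_decile = list(),
                          alpha = alpha, n_deciles = n_deciles,
                          keep_fraction = keep_fraction),
                     class = "selection_result"))
  }
  ids <- stats$feature_id[sig]
  pz <- p[sig]; mzs <- mz[sig]
  ord <- order(mzs)
  bin <- integer(length(sig))
  bin[ord] <- ceiling(n_deciles * seq_along(ord) / length(ord))
  per_decile <- list(); retained <- character(0)
  for (d in sort(unique(bin))) {
    in_d <- which(bin == d)
    keep_n <- ceiling(keep_fraction * length(in_d))
    o <- in_d[order(pz[in_d], mzs[in_d])]
    kept <- ids[o[seq_len(keep_n)]]
    per_decile[[as.character(d)]] <- list(members = ids[in_d],
                                          retained = kept)
    retained <- c(retained, kept)
  }
  boundaries <- stats::quantile(mzs, probs = seq(0, 1,
                                                 length.out = n_deciles + 1),
                                names = FALSE)
  structure(list(significant = ids, retained = retained,
                 boundaries = boundaries, per_decile = per_decile,
                 alpha = alpha, n_deciles = n_deciles,
                 keep_fraction = keep_fraction),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Decile-stratified selection:", length(x$significant),
      "significant (p <", x$alpha, "),", length(x$retained),
      sprintf("retained (%.0f%% smallest p per m/z decile)\n",
              100 * x$keep_fraction))
  invisible(x)
}

#' Write per-feature statistics / selection results as TSV
#'
#' @param x an \code{msi_glm} or \code{selection_result}.
#' @param path output path.
#' @export
write_stats <- function(x, path) {
  if (inherits(x, "msi_glm")) {
    data.table::fwrite(x$stats, path, sep = "\t")
  } else if (inherits(x, "selection_result")) {
    tab <- data.frame(feature_id = x$significant,
                      retained = x$significant %in% x$retained)
    data.table::fwrite(tab, path, sep = "\t")
  } else stop("unsupported object")
  invisible(path)
}
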