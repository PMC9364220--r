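# Three-step preprocessing of feature matrices: log-transform (peak
# intensities are log-normally distributed), per-feature z-scoring (equal
# weight to all peaks regardless of abundance), and 5% winsorization per tail
# (robustness to individual outliers). The order is fixed: log -> z -> winsor.

#' Log-transform a feature matrix
#'
#' Natural log of \code{value + offset}, per feature. The offset is 0 when
#' the feature has no zeros, half the smallest positive value when zeros are
#' present, and 1 for an all-zero feature (flagged). This avoids -Inf without
#' a global pseudo-count; the log base is immaterial because downstream
#' z-scoring absorbs constant factors.
#'
#' @param fm a \code{feature_matrix} with nonnegative values.
#' @return the transformed \code{feature_matrix}; per-feature offsets in
#'   \code{attr(, "log_offsets")}, all-zero features in
#'   \code{attr(, "all_zero_features")}.
#' @export
log_transform <- function(fm) {
  v <- fm$values
  if (any(v < 0, na.rm = TRUE)) stop("negative intensities: cannot log-transform")
  offsets <- apply(v, 2, function(x) {
    if (all(x == 0)) return(1)
    if (any(x == 0)) return(min(x[x > 0]) / 2)
    0
  })
  all_zero <- colnames(v)[apply(v, 2, function(x) all(x == 0))]
  fm$values <- log(sweep(v, 2, offsets, `+`))
  attr(fm, "log_offsets") <- offsets
  attr(fm, "all_zero_features") <- all_zero
  fm
}

#' Standardize each feature to z-scores
#'
#' Per feature: subtract the sample mean and divide by the sample standard
#' deviation (denominator n - 1). Constant features map to all-zero and are
#' flagged rather than producing NaN.
#'
#' @param fm a \code{feature_matrix} with at least 2 samples.
#' @return the standardized matrix; means/sds in attributes, constant
#'   features in \code{attr(, "constant_features")}.
#' @export
zscore <- function(fm) {
  v <- fm$values
  if (nrow(v) < 2) stop("z-scoring needs at least 2 samples per feature")
  mu <- colMeans(v)
  sd_ <- apply(v, 2, stats::sd)
  const <- sd_ < 1e-12 | !is.finite(sd_)
  sd_safe <- ifelse(const, 1, sd_)
  fm$values <- sweep(sweep(v, 2, mu, `-`), 2, sd_safe, `/`)
  fm$values[, const] <- 0
  attr(fm, "feature_means") <- mu
  attr(fm, "feature_sds") <- sd_
  attr(fm, "constant_features") <- colnames(v)[const]
  fm
}

#' Winsorize each feature
#'
#' Per feature, the lowest \code{floor(tail_fraction * n)} values are
#' replaced by the smallest unreplaced value, and symmetrically at the top.
#' Sample count and rank order are preserved; winsorization never increases
#' variance and is idempotent at fixed bounds.
#'
#' @param fm a \code{feature_matrix} (normally already log-transformed and
#'   z-scored).
#' @param tail_fraction fraction clipped per tail, in [0, 0.5); default 0.05
#'   ("5% winsorized" read as 5% per tail, the usual winsorization-limits
#'   convention).
#' @return a \code{preprocessed_matrix} (inherits \code{feature_matrix});
#'   per-feature winsor bounds in \code{attr(, "winsor_bounds")}.
#' @export
winsorize <- function(fm, tail_fraction = 0.05) {
  if (tail_fraction < 0 || tail_fraction >= 0.5)
    stop("tail_fraction must be in [0, 0.5)")
  v <- fm$values
  n <- nrow(v)
  k <- floor(tail_fraction * n)
  bounds <- matrix(NA_real_, ncol(v), 2,
                   dimnames = list(colnames(v), c("lo", "hi")))
  if (k > 0) {
    for (j in seq_len(ncol(v))) {
      srt <- sort(v[, j])
      lo <- srt[k + 1]; hi <- srt[n - k]
      v[v[, j] < lo, j] <- lo
      v[v[, j] > hi, j] <- hi
      bounds[j, ] <- c(lo, hi)
    }
  } else {
    bounds[, 1] <- apply(v, 2, min)
    bounds[, 2] <- apply(v, 2, max)
  }
  fm$values <- v
  attr(fm, "winsor_bounds") <- bounds
  attr(fm, "tail_fraction") <- tail_fraction
  class(fm) <- unique(c("preprocessed_matrix", class(fm)))
  fm
}

#' Full preprocessing pipeline
#'
#' Applies, in this order: (1) log transform, (2) z-scoring, (3)
#' winsorization. Returns a \code{preprocessed_matrix} carrying all recorded
#' per-feature parameters (offsets, means, sds, winsor bounds) so a run can
#' be reproduced exactly.
#'
#' @param fm a raw \code{feature_matrix}.
#' @param tail_fraction winsorization fraction per tail.
#' @return a \code{preprocessed_matrix}.
#' @examples
#' fm <- feature_matrix(matrix(rexp(40), 10), data.frame(mode = rep("pos", 10)),
#'                      feature_mz = c(400, 500, 600, 700))
#' pm <- preprocess(fm)
#' round(colMeans(pm$values), 10)
#' @export
preprocess <- function(fm, tail_fraction = 0.05) {
  lt <- log_transform(fm)
  zs <- zscore(lt)
  out <- winsorize(zs, tail_fraction)
  attr(out, "log_offsets") <- attr(lt, "log_offsets")
  attr(out, "all_zero_features") <- attr(lt, "all_zero_features")
  attr(out, "feature_means") <- attr(zs, "feature_means")
  attr(out, "feature_sds") <- attr(zs, "feature_sds")
  attr(out, "constant_features") <- attr(zs, "constant_features")
  out
}

#' Write preprocessing parameters to a JSON sidecar
#'
#' @param pm a \code{preprocessed_matrix}.
#' @param path output JSON path.
#' @export
write_prep_params <- function(pm, path) {
  jsonlite::write_json(
    list(log_offsets = as.list(attr(pm, "log_offsets")),
         feature_means = as.list(attr(pm, "feature_means")),
         feature_sds = as.list(attr(pm, "feature_sds")),
         winsor_bounds = as.data.frame(attr(pm, "winsor_bounds")),
         tail_fraction = attr(pm, "tail_fraction"),
         constant_features = attr(pm, "constant_features"),
         all_zero_features = attr(pm, "all_zero_features")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
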