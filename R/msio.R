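# MSI dataset container, global-maximum normalization, ROI aggregation and
# the columnar text I/O dialect.

#' MSI dataset container
#'
#' A set of sections sharing one feature axis. Each section holds per-pixel
#' feature intensities as an \code{n_pixels x n_features} matrix; pixels are
#' stored in column-major order of the label grid (the pixel at 0-based
#' coordinate (x, y) is row \code{x * height + y + 1}), matching the atlas
#' coordinate frame: 0-based (x, y), y increasing downward.
#'
#' @param sections list of sections, each \code{list(meta, intensities)};
#'   \code{meta} must carry \code{section_id}, \code{animal}, \code{age},
#'   \code{treatment}, \code{mode}.
#' @param feature_mz per-feature m/z, strictly increasing.
#' @param feature_id per-feature identifier.
#' @param dims grid dimensions \code{c(height, width)}.
#' @return object of class \code{msi_dataset}.
#' @export
msi_dataset <- function(sections, feature_mz, feature_id = NULL, dims) {
  if (is.unsorted(feature_mz, strictly = TRUE))
    stop("feature m/z must be strictly increasing")
  if (is.null(feature_id))
    feature_id <- sprintf("F%04d", seq_along(feature_mz))
  n_pix <- prod(dims)
  for (s in sections) {
    if (nrow(s$intensities) != n_pix ||
        ncol(s$intensities) != length(feature_mz))
      stop("section ", s$meta$section_id,
           " does not match the grid/feature dimensions")
    if (any(s$intensities < 0))
      stop("negative intensity in section ", s$meta$section_id)
  }
  structure(list(sections = sections, feature_mz = feature_mz,
                 feature_id = feature_id, dims = dims),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  modes <- unique(vapply(x$sections, function(s) s$meta$mode, character(1)))
  cat("MSI dataset:", length(x$sections), "sections,",
      length(x$feature_mz), "features, grid",
      x$dims[2], "x", x$dims[1], "px, mode(s):",
      paste(modes, collapse = ","), "\n")
  invisible(x)
}

section_meta <- function(data) {
  do.call(rbind, lapply(data$sections, function(s)
    data.frame(section_id = s$meta$section_id, animal = s$meta$animal,
               age = s$meta$age, treatment = s$meta$treatment,
               mode = s$meta$mode, stringsAsFactors = FALSE)))
}

#' Normalize intensities to the maximum pixel across the dataset
#'
#' All images of one ionization mode are synchronized by dividing every pixel
#' intensity by the single maximum pixel intensity observed across all
#' sections and features of that mode, so the maximum of the output is 1.
#' Modes are normalized separately: positive and negative acquisitions are
#' separate experiments with incomparable intensity scales.
#'
#' @param data an \code{msi_dataset}.
#' @return the dataset rescaled, with the per-mode constants in
#'   \code{attr(, "norm_constant")}.
#' @export
normalize_global_max <- function(data) {
  stopifnot(inherits(data, "msi_dataset"))
  modes <- vapply(data$sections, function(s) s$meta$mode, character(1))
  consts <- stats::setNames(numeric(0), character(0))
  for (m in unique(modes)) {
    mx <- max(vapply(data$sections[modes == m],
                     function(s) max(s$intensities), numeric(1)))
    if (mx <= 0)
      stop("normalization error: no positive intensity in mode ", m)
    consts[m] <- mx
  }
  data$sections <- lapply(data$sections, function(s) {
    s$intensities <- s$intensities / consts[[s$meta$mode]]
    s
  })
  attr(data, "norm_constant") <- consts
  data
}

#' Aggregate pixel intensities into a per-ROI sample x feature matrix
#'
#' For every section, the mean intensity of each feature is computed over the
#' pixels of each atlas region, plus a "whole" row over all non-background
#' pixels. A named region with no pixels in the grid is an error unless
#' \code{na_empty = TRUE}, in which case its rows are NA.
#'
#' @param data an \code{msi_dataset}.
#' @param atlas an \code{msi_atlas} on the same grid.
#' @param na_empty emit NA rows for empty regions instead of erroring.
#' @return a \code{feature_matrix} with one row per section x (region +
#'   whole).
#' @export
roi_average <- function(data, atlas, na_empty = FALSE) {
  stopifnot(inherits(data, "msi_dataset"), inherits(atlas, "msi_atlas"))
  if (!identical(dim(atlas$labels), as.integer(data$dims)) &&
      !identical(dim(atlas$labels), data$dims))
    stop("atlas grid dimensions do not match section grids")
  lv <- as.vector(atlas$labels)
  region_codes <- unname(atlas$names)
  labels_int <- as.integer(names(atlas$names))
  counts <- vapply(labels_int, function(l) sum(lv == l), integer(1))
  if (any(counts == 0) && !na_empty)
    stop("empty ROI: region(s) ",
         paste(region_codes[counts == 0], collapse = ", "),
         " have no pixels in the atlas grid")
  tissue <- lv > 0

  rows <- NULL; values <- NULL
  for (s in data$sections) {
    means <- matrix(NA_real_, nrow = length(labels_int),
                    ncol = ncol(s$intensities))
    for (i in seq_along(labels_int)) {
      if (counts[i] > 0)
        means[i, ] <- colMeans(s$intensities[lv == labels_int[i], ,
                                             drop = FALSE])
    }
    whole <- colMeans(s$intensities[tissue, , drop = FALSE])
    values <- rbind(values, means, whole)
    rows <- rbind(rows, data.frame(
      section_id = s$meta$section_id, animal = s$meta$animal,
      age = s$meta$age, treatment = s$meta$treatment, mode = s$meta$mode,
      region = c(region_codes, "whole"), stringsAsFactors = FALSE))
  }
  feature_matrix(values, rows, data$feature_mz, data$feature_id)
}

#' Sample x feature matrix
#'
#' @param values numeric matrix, samples in rows.
#' @param samples data frame of row descriptors (animal, age, treatment,
#'   mode, region).
#' @param feature_mz per-column m/z.
#' @param feature_id per-column id.
#' @return object of class \code{feature_matrix}.
#' @export
feature_matrix <- function(values, samples, feature_mz, feature_id = NULL) {
  values <- as.matrix(values)
  rownames(values) <- NULL
  if (ncol(values) != length(feature_mz))
    stop("values and feature_mz are not aligned")
  if (is.null(feature_id))
    feature_id <- sprintf("F%04d", seq_along(feature_mz))
  colnames(values) <- feature_id
  structure(list(values = values, samples = samples,
                 feature_mz = feature_mz, feature_id = feature_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "samples x", ncol(x$values),
      "features")
  if ("region" %in% names(x$samples))
    cat(";", length(unique(x$samples$region)), "region levels")
  cat("\n")
  invisible(x)
}

#' Subset a feature matrix by sample descriptors
#'
#' @param fm a \code{feature_matrix}.
#' @param keep logical vector over rows, or an expression on the samples
#'   table evaluated with \code{subset} semantics is not supported -- pass a
#'   logical.
#' @return the subsetted \code{feature_matrix}.
#' @export
fm_subset <- function(fm, keep) {
  fm$values <- fm$values[keep, , drop = FALSE]
  fm$samples <- fm$samples[keep, , drop = FALSE]
  rownames(fm$samples) <- NULL
  fm
}

#' Write / read a feature matrix as TSV with a header block
#'
#' Header lines starting with \code{#} record the mode(s) and, when the
#' source dataset was normalized, the normalization constant(s).
#'
#' @param fm a \code{feature_matrix}.
#' @param path file path.
#' @param norm_constant optional named per-mode normalization constants.
#' @export
write_feature_matrix <- function(fm, path, norm_constant = NULL) {
  hdr <- c(sprintf("# modes: %s",
                   paste(unique(fm$samples$mode), collapse = ",")))
  if (!is.null(norm_constant))
    hdr <- c(hdr, sprintf("# normalization: %s",
                          paste(sprintf("%s=%.10g", names(norm_constant),
                                        norm_constant), collapse = ",")))
  hdr <- c(hdr, sprintf("# feature_mz: %s",
                        paste(sprintf("%.6f", fm$feature_mz),
                              collapse = ",")))
  writeLines(hdr, path)
  tab <- cbind(fm$samples, as.data.frame(fm$values))
  data.table::fwrite(tab, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  hdr <- character(0)
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  tab <- data.table::fread(path, sep = "\t", skip = length(hdr),
                           header = TRUE, data.table = FALSE)
  mz_line <- sub("^# feature_mz: ", "", grep("^# feature_mz",
                                             hdr, value = TRUE))
  mz <- as.numeric(strsplit(mz_line, ",")[[1]])
  meta_cols <- intersect(c("section_id", "animal", "age", "treatment",
                           "mode", "region"), names(tab))
  feature_matrix(as.matrix(tab[, setdiff(names(tab), meta_cols),
                               drop = FALSE]),
                 tab[, meta_cols, drop = FALSE], mz,
                 setdiff(names(tab), meta_cols))
}

#' Write / read an MSI dataset in the gzipped columnar text dialect
#'
#' One gzipped TSV per section with columns \code{x}, \code{y},
#' \code{feature_id}, \code{intensity} (tissue pixels only; background pixels
#' are implicitly zero), plus \code{features.tsv}, \code{sections.tsv} and
#' \code{dataset.json} describing the grid. Coordinates are 0-based (x, y)
#' with y increasing downward.
#'
#' @param data an \code{msi_dataset}.
#' @param dir output directory, created if needed.
#' @export
write_msi_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- data$dims[1]; w <- data$dims[2]
  pix <- data.frame(x = rep(0:(w - 1), each = h),
                    y = rep(0:(h - 1), times = w))
  data.table::fwrite(data.frame(feature_id = data$feature_id,
                                mz = data$feature_mz),
                     file.path(dir, "features.tsv"), sep = "\t")
  data.table::fwrite(section_meta(data), file.path(dir, "sections.tsv"),
                     sep = "\t")
  jsonlite::write_json(list(height = h, width = w,
                            n_features = length(data$feature_mz),
                            coordinates = "0-based (x, y), y downward"),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)
  for (s in data$sections) {
    nz <- which(rowSums(s$intensities) > 0)
    long <- data.table::data.table(
      x = rep(pix$x[nz], times = ncol(s$intensities)),
      y = rep(pix$y[nz], times = ncol(s$intensities)),
      feature_id = rep(data$feature_id, each = length(nz)),
      intensity = as.vector(s$intensities[nz, , drop = FALSE]))
    data.table::fwrite(long,
                       file.path(dir, paste0(s$meta$section_id, ".tsv.gz")),
                       sep = "\t", compress = "gzip")
  }
  invisible(dir)
}

#' @rdname write_msi_dataset
#' @export
read_msi_dataset <- function(dir) {
  feat <- data.table::fread(file.path(dir, "features.tsv"),
                            data.table = FALSE)
  meta <- data.table::fread(file.path(dir, "sections.tsv"),
                            data.table = FALSE)
  info <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  h <- info$height; w <- info$width
  sections <- lapply(seq_len(nrow(meta)), function(i) {
    con <- gzfile(file.path(dir, paste0(meta$section_id[i], ".tsv.gz")))
    long <- utils::read.delim(con, stringsAsFactors = FALSE)
    intens <- matrix(0, nrow = h * w, ncol = nrow(feat))
    colnames(intens) <- feat$feature_id
    fidx <- match(long$feature_id, feat$feature_id)
    pidx <- long$x * h + long$y + 1
    intens[cbind(pidx, fidx)] <- long$intensity
    list(meta = as.list(meta[i, ]), intensities = intens)
  })
  msi_dataset(sections, feature_mz = feat$mz, feature_id = feat$feature_id,
              dims = c(h, w))
}
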