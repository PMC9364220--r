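# ROI atlas: a stylized sagittal rat-brain parcellation used both by the
# simulator and by ROI aggregation.

# The 13 regions, ordered rostral -> caudal along the x axis, with the fiber
# tracts last. Each region carries a coarse spatial class used by the
# simulator to grade developmental trajectories.
BRAIN_REGIONS <- data.frame(
  code  = c("OA", "vST", "ST", "CTX", "HIP", "HYP", "TH", "MB", "HB", "CBX",
            "AV", "FO", "CC"),
  name  = c("olfactory area", "ventral striatum", "striatum",
            "cerebral cortex", "hippocampus", "hypothalamus", "thalamus",
            "midbrain", "hindbrain", "cerebellar cortex", "arbor vitae",
            "fornix", "corpus callosum"),
  class = c("rostral", "rostral", "rostral", "rostral", "rostral",
            "caudal", "caudal", "caudal", "caudal", "caudal",
            "fiber", "fiber", "fiber"),
  stringsAsFactors = FALSE
)

#' Build a stylized brain-region atlas
#'
#' Lays out the 13 sagittal rat-brain regions (olfactory area through corpus
#' callosum) as contiguous bands along the rostral--caudal (x) axis inside an
#' elliptical tissue mask. Pixels outside the ellipse are background. The
#' geometry is stylized: bands stand in for anatomical parcels so that every
#' region is present, disjoint, and orderable along the x axis; anatomical
#' realism is a non-goal.
#'
#' Coordinates are 0-based, \code{(x, y)} with y increasing downward; the
#' label grid is stored as a matrix with \code{height} rows and \code{width}
#' columns, so \code{labels[y + 1, x + 1]} is the label at pixel (x, y).
#'
#' @param width,height grid dimensions in pixels; both must be at least 32 so
#'   that 13 bands of usable size fit.
#' @param seed integer seed controlling the (small) jitter of band boundaries.
#' @return An object of class \code{msi_atlas}: list with \code{labels}
#'   (integer matrix, 0 = background), \code{names} (label -> region code),
#'   \code{region_class} (region code -> rostral/caudal/fiber),
#'   \code{background} (0L).
#' @examples
#' atl <- make_atlas(64, 40, seed = 1)
#' table(atl$labels)[-1]  # pixel count per region
#' @export
make_atlas <- function(width, height, seed = 1L) {
  if (width < 32 || height < 32)
    stop("atlas dimensions too small to place 13 regions: need width and ",
         "height >= 32, got ", width, " x ", height)
  set.seed(seed)
  labels <- matrix(0L, nrow = height, ncol = width)
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  rx <- width / 2 - 1; ry <- height / 2 - 1
  xs <- matrix(rep(0:(width - 1), each = height), nrow = height)
  ys <- matrix(rep(0:(height - 1), times = width), nrow = height)
  inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1

  # band boundaries along x over the ellipse extent, with seeded jitter
  x_in <- range(xs[inside])
  span <- x_in[2] - x_in[1] + 1
  base <- seq(x_in[1], x_in[2] + 1, length.out = 14)
  jit <- stats::runif(12, -span / 80, span / 80)
  bounds <- base
  bounds[2:13] <- base[2:13] + jit
  bounds <- sort(bounds)
  band <- findInterval(xs[inside], bounds, rightmost.closed = TRUE)
  band[band < 1] <- 1L; band[band > 13] <- 13L
  labels[inside] <- as.integer(band)

  nm <- BRAIN_REGIONS$code
  names(nm) <- as.character(1:13)
  atlas <- structure(
    list(labels = labels, names = nm,
         region_class = stats::setNames(BRAIN_REGIONS$class,
                                        BRAIN_REGIONS$code),
         background = 0L),
    class = "msi_atlas")
  missing <- setdiff(1:13, unique(as.vector(labels)))
  if (length(missing))
    stop("atlas dimensions too small: region(s) ",
         paste(nm[as.character(missing)], collapse = ", "),
         " received no pixels")
  atlas
}

#' @export
print.msi_atlas <- function(x, ...) {
  cat("MSI atlas:", ncol(x$labels), "x", nrow(x$labels), "pixels,",
      length(x$names), "regions + background\n")
  cat("regions:", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' Write / read an atlas as plain text
#'
#' The label grid goes to \code{<prefix>_labels.tsv} (integers, one grid row
#' per line) and the label -> region map plus region classes to
#' \code{<prefix>_names.json}.
#'
#' @param atlas an \code{msi_atlas}.
#' @param prefix file path prefix.
#' @return \code{write_atlas} returns the two file paths invisibly;
#'   \code{read_atlas} returns the reconstructed \code{msi_atlas}.
#' @export
write_atlas <- function(atlas, prefix) {
  lab_path <- paste0(prefix, "_labels.tsv")
  meta_path <- paste0(prefix, "_names.json")
  utils::write.table(atlas$labels, lab_path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(names = as.list(atlas$names),
         region_class = as.list(atlas$region_class),
         background = atlas$background,
         coordinate_note = "0-based (x, y), y increasing downward"),
    meta_path, auto_unbox = TRUE)
  invisible(c(lab_path, meta_path))
}

#' @rdname write_atlas
#' @export
read_atlas <- function(prefix) {
  lab <- as.matrix(utils::read.table(paste0(prefix, "_labels.tsv"),
                                     sep = "\t"))
  dimnames(lab) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, "_names.json"),
                              simplifyVector = TRUE)
  structure(list(labels = matrix(as.integer(lab), nrow = nrow(lab)),
                 names = meta$names,
                 region_class = meta$region_class,
                 background = as.integer(meta$background)),
            class = "msi_atlas")
}
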