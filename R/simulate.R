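# Synthetic MSI study generator.
#
# Emulates the statistical and spatial structure of a two-arm developmental
# brain MSI study: 2 treatments x 4 ages x 4 animals per cell, sagittal
# sections rasterized on a stylized 13-region atlas, hundreds of m/z features
# per ionization mode, log-normal pixel noise, a per-animal random intercept,
# three developmental feature clusters (increasing / flat / decreasing with
# age), region-graded spatial profiles, and a multiplicative treatment effect
# on a configured subset of features. Ground truth is returned for recovery
# tests.

#' Study design descriptor
#'
#' @param ages postnatal days sampled; strictly increasing.
#' @param treatments group labels; first level is the reference (control).
#' @param animals_per_cell animals per treatment x age cell.
#' @param modes ionization modes acquired.
#' @param pixel_size_um pixel edge length in micrometers.
#' @param mz_range acquisition window (low, high) in Th.
#' @return object of class \code{study_design}.
#' @examples
#' study_design()  # the default: PND 7/14/21/50, CTL vs PL, n = 4, two modes
#' @export
study_design <- function(ages = c(7, 14, 21, 50),
                         treatments = c("CTL", "PL"),
                         animals_per_cell = 4L,
                         modes = c("pos", "neg"),
                         pixel_size_um = 125,
                         mz_range = c(50, 2000)) {
  if (is.unsorted(ages, strictly = TRUE))
    stop("ages must be strictly increasing")
  if (animals_per_cell < 1) stop("animals_per_cell must be >= 1")
  if (length(mz_range) != 2 || mz_range[1] >= mz_range[2])
    stop("mz_range must be (low, high) with low < high")
  if (length(treatments) != 2)
    stop("exactly two treatment groups are supported")
  structure(list(ages = ages, treatments = treatments,
                 animals_per_cell = as.integer(animals_per_cell),
                 modes = modes, pixel_size_um = pixel_size_um,
                 mz_range = mz_range),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("MSI study design: ages PND", paste(x$ages, collapse = "/"),
      "| groups", paste(x$treatments, collapse = " vs "),
      "| n =", x$animals_per_cell, "per cell | modes",
      paste(x$modes, collapse = ","), "\n")
  cat("pixel size", x$pixel_size_um, "um; m/z",
      x$mz_range[1], "-", x$mz_range[2], "Th\n")
  invisible(x)
}

# class -> default ionization mode and adduct for panel construction
PANEL_CLASS_MODES <- data.frame(
  class  = c("SM", "PC", "LPC", "CAR", "PE", "PS", "PI", "PA", "PG", "LPA",
             "FA"),
  mode   = c("pos", "pos", "pos", "pos", "neg", "neg", "neg", "neg", "neg",
             "neg", "neg"),
  adduct = c("[M+H]+", "[M+H]+", "[M+H]+", "[M+H]+", "[M-H]-", "[M-H]-",
             "[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-", "[M-H]-"),
  # weights for the five majors follow the composition of a milk polar-lipid
  # extract (g / 100 g: SM 14.6, PC 14.5, PE 5.5, PS 1.1, PI 1.1); the minor
  # classes get small weights so annotation exercises them too.
  weight = c(14.6, 14.5, 1.5, 1.5, 5.5, 1.1, 1.1, 1.0, 1.0, 0.8, 1.2),
  stringsAsFactors = FALSE
)

#' Build a species panel with ground-truth identities and decoys
#'
#' Draws lipid species (class weighted toward sphingomyelin and
#' phosphatidylcholine, matching a milk polar-lipid extract), computes their
#' molecular formulas and adduct m/z, and pads each ionization mode to
#' \code{n_features} features with identity-free decoy m/z values. Decoys are
#' kept more than 10 ppm away from every panel m/z so annotation has an
#' unambiguous negative set.
#'
#' @param design a \code{study_design}.
#' @param n_features features per ionization mode.
#' @param n_identified of those, how many carry a true lipid identity.
#' @param seed integer seed.
#' @return object of class \code{species_panel}: \code{entries} (name,
#'   formula, adduct, mz, mode), \code{decoys} (mz, mode) and \code{features}
#'   (per-mode table merged and sorted by m/z, decoys with NA identity).
#' @export
default_species_panel <- function(design = study_design(),
                                  n_features = 500L,
                                  n_identified = 120L,
                                  seed = 1L) {
  stopifnot(n_identified <= n_features, n_identified >= 1)
  set.seed(seed)
  entries <- NULL
  for (mode in design$modes) {
    cls_tab <- PANEL_CLASS_MODES[PANEL_CLASS_MODES$mode == mode, ]
    got <- data.frame(name = character(), formula = character(),
                      adduct = character(), mz = numeric(),
                      stringsAsFactors = FALSE)
    guard <- 0
    while (nrow(got) < n_identified && guard < 50 * n_identified) {
      guard <- guard + 1
      cls <- sample(cls_tab$class, 1, prob = cls_tab$weight)
      win <- default_chain_windows()[[chain_category(cls)]]
      carbons <- sample(seq(win[1], win[2]), 1)
      if (stats::runif(1) < 0.85 && carbons %% 2 == 1)
        carbons <- carbons + ifelse(carbons < win[2], 1, -1)
      db <- sample(0:6, 1)
      nm <- if (cls %in% c("SM")) sprintf("%s(d%d:%d)", cls, carbons, db)
            else sprintf("%s(%d:%d)", cls, carbons, db)
      f <- tryCatch(lipid_formula(parse_lipid_name(nm)),
                    error = function(e) NULL)
      if (is.null(f)) next
      adduct <- cls_tab$adduct[cls_tab$class == cls]
      mz <- adduct_mz(monoisotopic_mass(f), adduct)
      if (mz < design$mz_range[1] || mz > design$mz_range[2]) next
      if (nrow(got) && any(abs(1e6 * (got$mz - mz) / mz) <= 1)) next
      got <- rbind(got, data.frame(name = nm, formula = format_formula(f),
                                   adduct = adduct, mz = mz,
                                   stringsAsFactors = FALSE))
    }
    if (nrow(got) < n_identified)
      stop("could not place ", n_identified, " unique species in mode ", mode)
    got$mode <- mode
    entries <- rbind(entries, got)
  }

  decoys <- NULL
  for (mode in design$modes) {
    emz <- entries$mz[entries$mode == mode]
    need <- n_features - n_identified
    dmz <- numeric(0)
    lo <- max(design$mz_range[1], 300); hi <- min(design$mz_range[2], 1900)
    while (length(dmz) < need) {
      cand <- stats::runif(2 * need, lo, hi)
      ok <- vapply(cand, function(m)
        all(abs(1e6 * (emz - m) / m) > 10) &&
          (!length(dmz) || all(abs(1e6 * (dmz - m) / m) > 10)),
        logical(1))
      dmz <- c(dmz, cand[ok])[seq_len(min(need, length(dmz) + sum(ok)))]
    }
    decoys <- rbind(decoys, data.frame(mz = dmz, mode = mode,
                                       stringsAsFactors = FALSE))
  }

  features <- lapply(stats::setNames(design$modes, design$modes),
                     function(mode) {
    e <- entries[entries$mode == mode, c("name", "formula", "adduct", "mz")]
    d <- data.frame(name = NA_character_, formula = NA_character_,
                    adduct = NA_character_,
                    mz = decoys$mz[decoys$mode == mode],
                    stringsAsFactors = FALSE)
    tab <- rbind(e, d)
    tab <- tab[order(tab$mz), ]
    tab$feature_id <- sprintf("%s_%04d", mode, seq_len(nrow(tab)))
    rownames(tab) <- NULL
    tab[, c("feature_id", "mz", "name", "formula", "adduct")]
  })

  structure(list(entries = entries, decoys = decoys, features = features,
                 mz_range = design$mz_range),
            class = "species_panel")
}

#' @export
print.species_panel <- function(x, ...) {
  cat("Species panel:", nrow(x$entries), "identified entries,",
      nrow(x$decoys), "decoys, modes:",
      paste(names(x$features), collapse = ","), "\n")
  invisible(x)
}

#' Ground-truth trajectory model for the simulator
#'
#' Assigns each feature a developmental cluster (increasing / flat /
#' decreasing with age), a spatial profile graded along the rostral--caudal
#' axis or concentrated in fiber tracts, and -- for exactly
#' \code{round(effect_fraction * n)} features per mode -- a log-scale
#' treatment effect.
#'
#' @param panel a \code{species_panel}; the model is aligned to its per-mode
#'   feature order.
#' @param cluster_probs probabilities of the increasing / flat / decreasing
#'   clusters (defaults 0.46 / 0.28 / 0.26, the approximate proportions seen
#'   in developing rat brain).
#' @param effect_fraction fraction of features with a nonzero treatment
#'   effect.
#' @param effect_size log-scale treatment shift applied to affected features.
#' @param age_amplitude total log-scale change of the increasing/decreasing
#'   clusters across the age range.
#' @param seed integer seed.
#' @return object of class \code{trajectory_model}: one component per mode
#'   with \code{age_cluster}, \code{region_log} (feature x region log
#'   effects), \code{treatment_log_effect}, plus the shared parameters.
#' @export
make_trajectory_model <- function(panel,
                                  cluster_probs = c(increasing = 0.46,
                                                    flat = 0.28,
                                                    decreasing = 0.26),
                                  effect_fraction = 0.10,
                                  effect_size = 0.30,
                                  age_amplitude = 1.0,
                                  seed = 1L) {
  set.seed(seed)
  regions <- BRAIN_REGIONS$code
  rclass <- BRAIN_REGIONS$class
  profile_log <- function(type) {
    switch(type,
           rostral = ifelse(rclass == "rostral", 0.3, -0.3),
           caudal  = ifelse(rclass == "caudal", 0.3, -0.3),
           fiber   = ifelse(rclass == "fiber", 0.5, -0.1),
           uniform = rep(0, length(rclass)))
  }
  per_mode <- lapply(panel$features, function(feat) {
    n <- nrow(feat)
    cl <- sample(names(cluster_probs), n, replace = TRUE,
                 prob = cluster_probs)
    rtype <- sample(c("rostral", "caudal", "fiber", "uniform"), n,
                    replace = TRUE)
    region_log <- t(vapply(rtype, profile_log, numeric(length(regions))))
    colnames(region_log) <- regions
    delta <- rep(0, n)
    n_eff <- round(effect_fraction * n)
    if (n_eff > 0) delta[sample.int(n, n_eff)] <- effect_size
    list(age_cluster = cl, region_type = rtype, region_log = region_log,
         treatment_log_effect = delta)
  })
  structure(c(per_mode,
              list(params = list(cluster_probs = cluster_probs,
                                 effect_fraction = effect_fraction,
                                 effect_size = effect_size,
                                 age_amplitude = age_amplitude,
                                 seed = seed))),
            class = "trajectory_model")
}

age_trend <- function(cluster, age, ages, amplitude) {
  u <- (log(age) - log(min(ages))) / (log(max(ages)) - log(min(ages)))
  amplitude * u * (cluster == "increasing") -
    amplitude * u * (cluster == "decreasing")
}

#' Simulate an MSI study
#'
#' Generates one section per animal x age x treatment x mode. The log pixel
#' intensity of a tissue pixel in region r is
#' \deqn{\log I = b_f + a_f(age) + r_{f,r} + \delta_f [PL] + u + \epsilon,}
#' with feature baseline \eqn{b_f \sim N(4, 1)}, developmental trend
#' \eqn{a_f}, region log-multiplier \eqn{r_{f,r}}, treatment log-effect
#' \eqn{\delta_f}, per-animal random intercept \eqn{u \sim N(0,
#' \code{animal_sd}^2)} and pixel noise \eqn{\epsilon \sim N(0,
#' \code{noise_sd}^2)}. Background pixels are zero.
#'
#' @param design a \code{study_design}.
#' @param atlas an \code{msi_atlas}.
#' @param panel a \code{species_panel}.
#' @param model a \code{trajectory_model} aligned with \code{panel}.
#' @param noise_sd log-scale pixel noise SD.
#' @param animal_sd log-scale SD of the per-animal random intercept.
#' @param seed integer seed; the whole study is reproducible from it.
#' @return list with \code{datasets} (named list of \code{msi_dataset}, one
#'   per mode) and \code{truth} (a \code{ground_truth} data frame).
#' @export
simulate_dataset <- function(design, atlas, panel, model,
                             noise_sd = 0.3, animal_sd = 0.2, seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(atlas, "msi_atlas"),
            inherits(panel, "species_panel"),
            inherits(model, "trajectory_model"))
  if (noise_sd < 0 || animal_sd < 0) stop("noise_sd/animal_sd must be >= 0")
  if (!nrow(panel$entries)) stop("panel must be nonempty")
  set.seed(seed)
  lv <- as.vector(atlas$labels)
  tissue <- which(lv > 0)
  reg_idx <- lv[tissue]                       # 1..13 row index into region_log
  n_pix <- length(lv)
  amp <- model$params$age_amplitude

  datasets <- list(); truth <- NULL
  for (mode in design$modes) {
    feat <- panel$features[[mode]]
    mm <- model[[mode]]
    if (is.null(mm) || length(mm$age_cluster) != nrow(feat))
      stop("trajectory model is not aligned with the panel for mode ", mode)
    nfeat <- nrow(feat)
    base <- stats::rnorm(nfeat, mean = 4, sd = 1)
    sections <- list()
    for (age in design$ages) {
      trend <- base +
        age_trend(mm$age_cluster, age, design$ages, amp)
      for (trt in design$treatments) {
        is_pl <- trt == design$treatments[2]
        for (a in seq_len(design$animals_per_cell)) {
          animal <- sprintf("PND%02d_%s_%d", age, trt, a)
          u <- stats::rnorm(nfeat, 0, animal_sd)
          # 13 x nfeat matrix of region-level log means
          mu <- t(mm$region_log) +
            matrix(trend + mm$treatment_log_effect * is_pl + u,
                   nrow = ncol(mm$region_log), ncol = nfeat, byrow = TRUE)
          logI <- mu[reg_idx, , drop = FALSE]
          if (noise_sd > 0)
            logI <- logI + matrix(stats::rnorm(length(logI), 0, noise_sd),
                                  nrow = nrow(logI))
          intens <- matrix(0, nrow = n_pix, ncol = nfeat)
          intens[tissue, ] <- exp(logI)
          sections[[length(sections) + 1]] <- list(
            meta = list(section_id = sprintf("%s_%s", mode, animal),
                        animal = animal, age = age, treatment = trt,
                        mode = mode),
            intensities = intens)
        }
      }
    }
    datasets[[mode]] <- msi_dataset(sections, feature_mz = feat$mz,
                                    feature_id = feat$feature_id,
                                    dims = dim(atlas$labels))
    truth <- rbind(truth, data.frame(
      feature_id = feat$feature_id, mode = mode, mz = feat$mz,
      identity = feat$name, age_cluster = mm$age_cluster,
      region_type = mm$region_type,
      treatment_log_effect = mm$treatment_log_effect,
      stringsAsFactors = FALSE))
  }
  class(truth) <- c("ground_truth", "data.frame")
  list(datasets = datasets, truth = truth)
}

#' Ground-truth accessors
#'
#' @param truth a \code{ground_truth} table from \code{simulate_dataset}.
#' @return \code{true_effect_features}: feature ids with a nonzero treatment
#'   effect.
#' @export
true_effect_features <- function(truth) {
  truth$feature_id[truth$treatment_log_effect != 0]
}

#' Write study inputs as TSV
#'
#' @param truth a \code{ground_truth} table.
#' @param panel a \code{species_panel}.
#' @param path output file path.
#' @export
write_ground_truth <- function(truth, path) {
  data.table::fwrite(as.data.frame(truth), path, sep = "\t")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
write_panel <- function(panel, path) {
  tab <- do.call(rbind, lapply(names(panel$features), function(m)
    cbind(mode = m, panel$features[[m]])))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
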