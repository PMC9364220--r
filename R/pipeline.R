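# End-to-end orchestration: simulate -> normalize -> aggregate -> preprocess
# -> per-feature GLMs and decile selection -> annotate -> enrich -> explore,
# with one config object, per-stage logging, and a summary report with
# ground-truth recovery metrics.

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline in one object that
#' round-trips losslessly through JSON. All randomness is funneled through
#' \code{seed}: each stage derives its own sub-seed deterministically.
#'
#' @param out_dir output directory for all intermediates and the report.
#' @param seed master integer seed.
#' @param ages,treatments,animals_per_cell,modes,pixel_size_um,mz_range study
#'   design (see \code{\link{study_design}}).
#' @param atlas_width,atlas_height atlas grid in pixels.
#' @param n_features,n_identified features per mode and how many carry a
#'   true identity.
#' @param cluster_probs,effect_fraction,effect_size,age_amplitude trajectory
#'   model (see \code{\link{make_trajectory_model}}).
#' @param noise_sd,animal_sd log-scale pixel and animal noise.
#' @param tail_fraction winsorization fraction per tail.
#' @param alpha,n_deciles,keep_fraction,two_sided selection parameters.
#' @param tol_ppm annotation mass tolerance.
#' @param adjust_method "holm" or "BH".
#' @param n_clusters clusters for the species HCA.
#' @param write_pixels also write pixel-level sections (large; off by
#'   default).
#' @return object of class \code{msi_config}.
#' @export
msi_config <- function(out_dir = tempfile("msirun"),
                       seed = 1L,
                       ages = c(7, 14, 21, 50),
                       treatments = c("CTL", "PL"),
                       animals_per_cell = 4L,
                       modes = c("pos", "neg"),
                       pixel_size_um = 125,
                       mz_range = c(50, 2000),
                       atlas_width = 64L,
                       atlas_height = 40L,
                       n_features = 500L,
                       n_identified = 120L,
                       cluster_probs = c(increasing = 0.46, flat = 0.28,
                                         decreasing = 0.26),
                       effect_fraction = 0.10,
                       effect_size = 0.30,
                       age_amplitude = 1.0,
                       noise_sd = 0.3,
                       animal_sd = 0.2,
                       tail_fraction = 0.05,
                       alpha = 0.05,
                       n_deciles = 10L,
                       keep_fraction = 0.6,
                       two_sided = FALSE,
                       tol_ppm = 10,
                       adjust_method = "holm",
                       n_clusters = 5L,
                       write_pixels = FALSE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), ages = ages,
              treatments = treatments,
              animals_per_cell = as.integer(animals_per_cell),
              modes = modes, pixel_size_um = pixel_size_um,
              mz_range = mz_range, atlas_width = as.integer(atlas_width),
              atlas_height = as.integer(atlas_height),
              n_features = as.integer(n_features),
              n_identified = as.integer(n_identified),
              cluster_probs = cluster_probs,
              effect_fraction = effect_fraction,
              effect_size = effect_size, age_amplitude = age_amplitude,
              noise_sd = noise_sd, animal_sd = animal_sd,
              tail_fraction = tail_fraction, alpha = alpha,
              n_deciles = as.integer(n_deciles),
              keep_fraction = keep_fraction, two_sided = two_sided,
              tol_ppm = tol_ppm, adjust_method = adjust_method,
              n_clusters = as.integer(n_clusters),
              write_pixels = write_pixels)
  class(cfg) <- "msi_config"
  cfg
}

#' @export
print.msi_config <- function(x, ...) {
  cat("MSI pipeline config: seed", x$seed, "|", x$n_features,
      "features/mode | modes", paste(x$modes, collapse = ","),
      "| out:", x$out_dir, "\n")
  invisible(x)
}

#' Write / read a config as JSON
#'
#' @param cfg an \code{msi_config}.
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$cluster_probs <- as.list(out$cluster_probs)  # keep names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$cluster_probs <- unlist(raw$cluster_probs)
  # JSON has no integer/double distinction; restore numeric storage
  for (f in c("ages", "pixel_size_um", "mz_range", "effect_fraction",
              "effect_size", "age_amplitude", "noise_sd", "animal_sd",
              "tail_fraction", "alpha", "keep_fraction", "tol_ppm"))
    raw[[f]] <- as.numeric(raw[[f]])
  do.call(msi_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort_stage(name, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes all stages in acquisition-to-interpretation order: simulate,
#' normalize (per mode, global maximum pixel), aggregate (13 ROIs + whole),
#' preprocess (log, z-score, winsorize), per-feature GLMs with
#' decile-stratified selection (plus the per-ROI GLM variant), annotation of
#' the retained peaks, class and pathway over-representation, and PCA / HCA
#' exploration. Every intermediate is written under \code{cfg$out_dir};
#' rerunning with the same config reproduces all outputs bit-identically.
#'
#' @param cfg an \code{msi_config}.
#' @return an \code{msi_report}: per-stage counts and numeric fingerprints,
#'   all parameters, and ground-truth recovery metrics (sensitivity and
#'   false discovery rate of the significance and selection steps, and
#'   annotation accuracy).
#' @export
msi_run_all <- function(cfg) {
  stopifnot(inherits(cfg, "msi_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(cfg), stages = list())
  log_stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
  }

  design <- .stage("design", study_design(
    ages = cfg$ages, treatments = cfg$treatments,
    animals_per_cell = cfg$animals_per_cell, modes = cfg$modes,
    pixel_size_um = cfg$pixel_size_um, mz_range = cfg$mz_range))

  atlas <- .stage("atlas", make_atlas(cfg$atlas_width, cfg$atlas_height,
                                      seed = derive_seed(cfg$seed, 1)))
  write_atlas(atlas, file.path(cfg$out_dir, "atlas"))

  panel <- .stage("panel", default_species_panel(
    design, n_features = cfg$n_features, n_identified = cfg$n_identified,
    seed = derive_seed(cfg$seed, 2)))
  write_panel(panel, file.path(cfg$out_dir, "panel.tsv"))

  model <- .stage("trajectory_model", make_trajectory_model(
    panel, cluster_probs = cfg$cluster_probs,
    effect_fraction = cfg$effect_fraction, effect_size = cfg$effect_size,
    age_amplitude = cfg$age_amplitude, seed = derive_seed(cfg$seed, 3)))

  sim <- .stage("simulate", simulate_dataset(
    design, atlas, panel, model, noise_sd = cfg$noise_sd,
    animal_sd = cfg$animal_sd, seed = derive_seed(cfg$seed, 4)))
  truth <- sim$truth
  write_ground_truth(truth, file.path(cfg$out_dir, "ground_truth.tsv"))
  log_stage("simulate",
            n_sections = sum(vapply(sim$datasets, function(d)
              length(d$sections), integer(1))),
            n_features_per_mode = vapply(sim$datasets, function(d)
              length(d$feature_mz), integer(1)))

  per_mode <- list()
  ann_all <- NULL
  roi_profiles <- list()
  for (mode in cfg$modes) {
    data <- sim$datasets[[mode]]
    if (cfg$write_pixels)
      write_msi_dataset(data, file.path(cfg$out_dir, paste0("pixels_",
                                                            mode)))
    data <- .stage("normalize", normalize_global_max(data))
    nc <- attr(data, "norm_constant")
    fm <- .stage("aggregate", roi_average(data, atlas))
    write_feature_matrix(fm, file.path(cfg$out_dir,
                                       paste0("roi_matrix_", mode, ".tsv")),
                         norm_constant = nc)
    log_stage(paste0("aggregate_", mode),
              n_rows = nrow(fm$values),
              n_regions = length(setdiff(unique(fm$samples$region),
                                         "whole")),
              fingerprint = num_fingerprint(fm$values))

    fm_whole <- fm_subset(fm, fm$samples$region == "whole")
    fm_roi <- fm_subset(fm, fm$samples$region != "whole")
    pm_whole <- .stage("preprocess", preprocess(fm_whole,
                                                cfg$tail_fraction))
    pm_roi <- .stage("preprocess", preprocess(fm_roi, cfg$tail_fraction))
    write_prep_params(pm_whole,
                      file.path(cfg$out_dir,
                                paste0("prep_params_", mode, ".json")))

    glm_w <- .stage("glm", fit_feature_glms(pm_whole,
                                            two_sided = cfg$two_sided))
    write_stats(glm_w, file.path(cfg$out_dir,
                                 paste0("glm_whole_", mode, ".tsv")))
    glm_r <- .stage("glm_roi", fit_roi_glms(pm_roi,
                                            two_sided = cfg$two_sided))
    write_stats(glm_r, file.path(cfg$out_dir,
                                 paste0("glm_roi_", mode, ".tsv")))

    sel <- .stage("select", select_pl_up(
      glm_w, alpha = cfg$alpha, n_deciles = cfg$n_deciles,
      keep_fraction = cfg$keep_fraction))
    write_stats(sel, file.path(cfg$out_dir,
                               paste0("selection_", mode, ".tsv")))
    log_stage(paste0("select_", mode),
              n_significant = length(sel$significant),
              n_retained = length(sel$retained))

    db <- panel$entries[panel$entries$mode == mode,
                        c("name", "adduct", "mz", "mode")]
    retained_mz <- glm_w$stats$mz[match(sel$retained,
                                        glm_w$stats$feature_id)]
    ann <- .stage("annotate", annotate_peaks(retained_mz, db,
                                             tol_ppm = cfg$tol_ppm,
                                             mode = mode))
    if (nrow(ann)) {
      ann$feature_id <- sel$retained[match(ann$peak_mz, retained_mz)]
      data.table::fwrite(ann, file.path(cfg$out_dir,
                                        paste0("annotations_", mode,
                                               ".tsv")),
                         sep = "\t")
      ann_all <- rbind(ann_all, ann)
    }
    log_stage(paste0("annotate_", mode), n_annotated = nrow(ann))

    # species profiles over treatment x age x region for the HCA stage
    if (nrow(ann)) {
      key <- interaction(pm_roi$samples$treatment, pm_roi$samples$age,
                         pm_roi$samples$region, drop = TRUE, sep = ":")
      idx <- match(ann$feature_id, pm_roi$feature_id)
      prof <- t(vapply(idx, function(j)
        tapply(pm_roi$values[, j], key, mean),
        numeric(nlevels(key))))
      rownames(prof) <- ann$annotation
      roi_profiles[[mode]] <- prof
    }

    per_mode[[mode]] <- list(glm_whole = glm_w, glm_roi = glm_r,
                             selection = sel, annotations = ann,
                             pm_whole = pm_whole, pm_roi = pm_roi)
  }

  # ---- recovery against ground truth ----
  recovery <- list()
  for (mode in cfg$modes) {
    tr <- truth[truth$mode == mode, ]
    true_eff <- tr$feature_id[tr$treatment_log_effect != 0]
    null_f <- tr$feature_id[tr$treatment_log_effect == 0]
    sel <- per_mode[[mode]]$selection
    sig <- sel$significant
    recovery[[mode]] <- list(
      sensitivity_significance =
        if (length(true_eff)) mean(true_eff %in% sig) else NA,
      null_positive_rate =
        if (length(null_f)) mean(null_f %in% sig) else NA,
      fdr_significance =
        if (length(sig)) mean(!(sig %in% true_eff)) else NA,
      sensitivity_retained =
        if (length(true_eff)) mean(true_eff %in% sel$retained) else NA)
    ann <- per_mode[[mode]]$annotations
    if (!is.null(ann) && nrow(ann)) {
      ids <- tr$identity[match(ann$feature_id, tr$feature_id)]
      has_id <- !is.na(ids)
      correct <- vapply(which(has_id), function(i)
        ids[i] %in% strsplit(ann$annotation[i], "|", fixed = TRUE)[[1]],
        logical(1))
      recovery[[mode]]$annotation_accuracy <-
        if (any(has_id)) mean(correct) else NA
    }
  }

  # ---- enrichment over all annotated species ----
  enrichment <- NULL
  if (!is.null(ann_all) && nrow(ann_all)) {
    universe_tab <- panel$entries
    universe_tab$class <- vapply(universe_tab$name, function(n)
      parse_lipid_name(n)$class, character(1))
    universe <- universe_tab$name
    selected <- unique(unlist(lapply(ann_all$annotation, function(a)
      strsplit(a, "|", fixed = TRUE)[[1]])))
    selected <- intersect(selected, universe)
    class_sets <- split(universe_tab$name, universe_tab$class)
    cls_en <- .stage("enrich", enrich_sets(selected, universe, class_sets,
                                           method = cfg$adjust_method))
    pmap <- pathway_map()
    pw_sets <- lapply(split(pmap$class, pmap$pathway), function(cls)
      unlist(class_sets[intersect(cls, names(class_sets))],
             use.names = FALSE))
    pw_sets <- pw_sets[vapply(pw_sets, length, integer(1)) > 0]
    pw_en <- .stage("enrich", enrich_sets(selected, universe, pw_sets,
                                          method = cfg$adjust_method))
    # topology impact at the class level
    graphs <- pathway_graphs()
    sel_classes <- unique(universe_tab$class[universe_tab$name %in%
                                             selected])
    pw_en$impact <- vapply(pw_en$set, function(pw) {
      if (!pw %in% names(graphs)) return(NA_real_)
      g <- graphs[[pw]]
      nodes <- unique(c(g$from, g$to))
      topology_impact(g, intersect(sel_classes, nodes))
    }, numeric(1))
    data.table::fwrite(cls_en, file.path(cfg$out_dir,
                                         "enrichment_classes.tsv"),
                       sep = "\t")
    data.table::fwrite(pw_en, file.path(cfg$out_dir,
                                        "enrichment_pathways.tsv"),
                       sep = "\t")
    enrichment <- list(classes = cls_en, pathways = pw_en)
    log_stage("enrich", n_class_sets = nrow(cls_en),
              n_pathway_sets = nrow(pw_en),
              n_sig_pathways = sum(pw_en$p_adjusted < 0.05))
  }

  # ---- exploration ----
  explore_out <- list()
  for (mode in cfg$modes) {
    pca <- .stage("explore", pca_biplot(per_mode[[mode]]$pm_whole,
                                        average_by = c("treatment",
                                                       "age")))
    data.table::fwrite(pca$condition_scores,
                       file.path(cfg$out_dir,
                                 paste0("pca_scores_", mode, ".tsv")),
                       sep = "\t")
    explore_out[[mode]]$pca_var <- pca$var_fraction[1:3]
  }
  if (length(roi_profiles)) {
    prof <- do.call(rbind, roi_profiles)
    k <- min(cfg$n_clusters, nrow(prof) - 1)
    if (nrow(prof) >= 3 && k >= 2) {
      cl <- .stage("explore", hca_clusters(prof, k = k))
      data.table::fwrite(data.frame(species = names(cl$labels),
                                    cluster = cl$labels),
                         file.path(cfg$out_dir, "hca_clusters.tsv"),
                         sep = "\t")
      oc <- ordered_cor_matrix(prof, cl)
      data.table::fwrite(data.frame(species = rownames(oc), oc,
                                    check.names = FALSE),
                         file.path(cfg$out_dir, "hca_cor_matrix.tsv"),
                         sep = "\t")
      explore_out$hca_n_species <- nrow(prof)
      explore_out$hca_k <- k
    }
  }

  report$stages <- report$stages
  report$recovery <- recovery
  report$enrichment_summary <- if (!is.null(enrichment)) list(
    n_sig_pathways = sum(enrichment$pathways$p_adjusted < 0.05),
    top_pathways = utils::head(enrichment$pathways$set, 3)) else NULL
  report$explore <- explore_out
  report$counts <- list(
    modes = length(cfg$modes),
    features_per_mode = cfg$n_features,
    significant = vapply(per_mode, function(m)
      length(m$selection$significant), integer(1)),
    retained = vapply(per_mode, function(m)
      length(m$selection$retained), integer(1)),
    annotated = vapply(per_mode, function(m)
      if (is.null(m$annotations)) 0L else nrow(m$annotations),
      integer(1)))
  report$results <- list(per_mode = per_mode, enrichment = enrichment)
  class(report) <- "msi_report"
  # JSON report (without the bulky fitted objects)
  slim <- report[c("config", "stages", "recovery", "enrichment_summary",
                   "explore", "counts")]
  jsonlite::write_json(slim, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_config(cfg, file.path(cfg$out_dir, "config.json"))
  report
}

#' @export
print.msi_report <- function(x, ...) {
  cat("MSI pipeline report\n")
  cat("  modes processed:", x$counts$modes, "\n")
  cat("  features/mode:", x$counts$features_per_mode, "\n")
  cat("  significant:", paste(sprintf("%s=%d", names(x$counts$significant),
                                      x$counts$significant),
                              collapse = " "), "\n")
  cat("  retained:", paste(sprintf("%s=%d", names(x$counts$retained),
                                   x$counts$retained), collapse = " "),
      "\n")
  cat("  annotated:", paste(sprintf("%s=%d", names(x$counts$annotated),
                                    x$counts$annotated), collapse = " "),
      "\n")
  for (m in names(x$recovery)) {
    r <- x$recovery[[m]]
    cat(sprintf("  recovery %s: sensitivity %.3f | null rate %.3f\n", m,
                r$sensitivity_significance, r$null_positive_rate))
  }
  if (!is.null(x$enrichment_summary))
    cat("  significant pathways:", x$enrichment_summary$n_sig_pathways,
        "(top:", paste(x$enrichment_summary$top_pathways, collapse = ", "),
        ")\n")
  invisible(x)
}
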