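# Shared fixtures, built in code.

# a small two-region atlas on a 2 x 2 grid for hand-computed aggregation
tiny_atlas <- function() {
  labels <- matrix(c(1L, 1L, 2L, 0L), nrow = 2)  # column-major: A A B bg
  structure(list(labels = labels,
                 names = c(`1` = "A", `2` = "B"),
                 region_class = c(A = "rostral", B = "caudal"),
                 background = 0L),
            class = "msi_atlas")
}

# dataset with one section on the tiny atlas; intensities given per pixel
# (column-major over the 2 x 2 grid) and per feature
tiny_dataset <- function(values, mz = NULL, mode = "pos", n_sections = 1,
                         section_values = NULL) {
  values <- as.matrix(values)
  if (is.null(mz)) mz <- 100 + seq_len(ncol(values))
  sections <- lapply(seq_len(n_sections), function(i) {
    v <- if (is.null(section_values)) values else section_values[[i]]
    list(meta = list(section_id = paste0(mode, "_S", i),
                     animal = paste0("A", i), age = 7, treatment = "CTL",
                     mode = mode),
         intensities = as.matrix(v))
  })
  msi_dataset(sections, feature_mz = mz, dims = c(2L, 2L))
}

# a balanced whole-brain feature matrix with known structure:
# 2 treatments x 4 ages x n animals, optional planted PL shift per feature
sim_feature_matrix <- function(n_features = 20, n_animals = 4,
                               shift = numeric(n_features), sd = 0.5,
                               seed = 1) {
  set.seed(seed)
  ages <- c(7, 14, 21, 50)
  samples <- expand.grid(animal = seq_len(n_animals), age = ages,
                         treatment = c("CTL", "PL"),
                         stringsAsFactors = FALSE)
  samples$mode <- "pos"
  samples$region <- "whole"
  n <- nrow(samples)
  values <- matrix(rnorm(n * n_features, sd = sd), n, n_features)
  values <- values + outer(as.numeric(samples$treatment == "PL"), shift)
  feature_matrix(values, samples, feature_mz = 300 + seq_len(n_features))
}

# small simulated study shared by several tests
small_sim <- function(noise_sd = 0.3, animal_sd = 0.2, n_features = 40,
                      n_identified = 15, modes = "pos", seed = 11,
                      effect_size = 0.3, effect_fraction = 0.1) {
  des <- study_design(modes = modes)
  atl <- make_atlas(48, 32, seed = seed)
  pan <- default_species_panel(des, n_features = n_features,
                               n_identified = n_identified,
                               seed = seed + 1)
  mod <- make_trajectory_model(pan, effect_fraction = effect_fraction,
                               effect_size = effect_size, seed = seed + 2)
  sim <- simulate_dataset(des, atl, pan, mod, noise_sd = noise_sd,
                          animal_sd = animal_sd, seed = seed + 3)
  list(design = des, atlas = atl, panel = pan, model = mod, sim = sim)
}
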