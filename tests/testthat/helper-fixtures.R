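# Small, fast fixtures shared across test files. Grids are coarse versions of
# the full acquisition grid so matrix shapes stay tiny.

coarse_grid <- function(n_points = 200, step = 40) {
  default_grid(start = 4000, step = step, n_points = n_points)
}

# a labelled toy set with k classes on a coarse grid
toy_spectra <- function(n_classes = 3, samples_per_class = 10, seed = 7,
                        separation = 0.05, noise_sd = 0.003,
                        n_points = 200, step = 40, ...) {
  simulate_spectra(sim_config(
    n_classes = n_classes, samples_per_class = samples_per_class,
    grid = coarse_grid(n_points, step), class_separation = separation,
    noise_sd = noise_sd, seed = seed, ...))
}

# deterministic unlabelled set from an explicit matrix
matrix_spectra <- function(m, step = 10) {
  nir_spectra(m, default_grid(step = step, n_points = ncol(m)))
}
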