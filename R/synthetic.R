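#' Default wavenumber grid for synthetic NIR spectra
#'
#' Mirrors a typical FT-NIR diffuse-reflectance acquisition: 2074 points from
#' 4000 cm^-1 at 3.857 cm^-1 spacing (the top end falls just short of
#' 12,000 cm^-1).
#'
#' @param start first wavenumber (cm^-1).
#' @param step grid spacing (cm^-1).
#' @param n_points number of grid points.
#' @return Numeric wavenumber vector.
#' @export
default_grid <- function(start = 4000, step = 3.857, n_points = 2074) {
  stopifnot(step > 0, n_points >= 2)
  start + step * (seq_len(n_points) - 1)
}

# Characteristic NIR peaks shared by polyethylene-based packaging materials:
# methylene combination/overtone bands plus ester (plasticizer) bands.
pe_peak_positions <- c(4250, 4323, 5245, 5338, 5390, 5440, 5700, 5773,
                       5940, 7010, 7230, 7340, 7378)
# extra ester band inside the 5160-5500 cm^-1 second-overtone window
ester_band_position <- 5300

#' Class band profiles for the synthetic generator
#'
#' Every class shares the same 14 Gaussian bands (13 methylene/ester
#' characteristic peaks plus one additional ester band near 5300 cm^-1);
#' classes differ only by small per-band relative amplitude perturbations,
#' emulating packaging films whose base polymer is identical but whose
#' plasticizer/auxiliary content varies slightly.
#'
#' @param n_classes number of classes (>= 2).
#' @param separation scale of the per-class relative amplitude perturbations
#'   (standard deviation of the multiplicative offsets). 0 makes all classes
#'   identical.
#' @param seed integer seed; fully determines the profiles.
#' @return A list of `n_classes` profiles, each a list with `class_name`,
#'   `bands` (tibble: center, width, amplitude) and `band_perturbation`.
#' @export
default_profiles <- function(n_classes, separation = 0.02, seed = 1) {
  if (n_classes < 2) rlang::abort("`n_classes` must be at least 2.")
  stopifnot(separation >= 0)
  centers <- c(pe_peak_positions, ester_band_position)
  nb <- length(centers)
  withr_seed(seed, {
    # widths drawn once, shared across classes, so class differences are
    # amplitude-only; 15-40 cm^-1 makes adjacent peaks partially overlap
    widths <- stats::runif(nb, 15, 40)
    amps <- stats::runif(nb, 0.2, 1.0)
    lapply(seq_len(n_classes), function(i) {
      list(
        class_name = paste0("C", i),
        bands = tibble::tibble(center = centers, width = widths, amplitude = amps),
        band_perturbation = stats::rnorm(nb, 0, separation)
      )
    })
  })
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# deterministic sub-seed derivation (keeps values < 2^31)
substream <- function(seed, stage) {
  (seed * 7919 + stage * 104729) %% 2147483647L
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic spectra generator. The defaults emulate
#' a 10-class, 75-samples-per-class NIR study on the standard 2074-point grid,
#' with moderate between-class overlap.
#'
#' @param n_classes number of classes.
#' @param samples_per_class samples per class (scalar or one count per class).
#' @param grid numeric wavenumber vector, see [default_grid()].
#' @param noise_sd standard deviation of additive i.i.d. noise (absorbance).
#' @param baseline_poly_degree degree of the random polynomial baseline.
#' @param baseline_scale scale of the random baseline coefficients (absorbance).
#' @param scatter_gain_sd sd of the per-sample multiplicative gain about 1.
#' @param scatter_offset_sd sd of the per-sample additive offset (absorbance).
#' @param class_separation scale of between-class band-amplitude differences.
#' @param outlier_fraction fraction of samples replaced by injected outliers
#'   when the config is run through [simulate_study()].
#' @param seed integer root seed; fully determines the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_classes = 10, samples_per_class = 75,
                       grid = default_grid(), noise_sd = 0.01,
                       baseline_poly_degree = 2, baseline_scale = 0.01,
                       scatter_gain_sd = 0.05, scatter_offset_sd = 0.01,
                       class_separation = 0.02, outlier_fraction = 0,
                       seed = 1) {
  stopifnot(n_classes >= 2, all(samples_per_class >= 1),
            noise_sd >= 0, baseline_scale >= 0, scatter_gain_sd >= 0,
            scatter_offset_sd >= 0, class_separation >= 0,
            outlier_fraction >= 0, outlier_fraction < 1)
  if (length(samples_per_class) == 1) {
    samples_per_class <- rep(samples_per_class, n_classes)
  }
  stopifnot(length(samples_per_class) == n_classes)
  structure(list(
    n_classes = n_classes, samples_per_class = as.integer(samples_per_class),
    grid = grid, noise_sd = noise_sd,
    baseline_poly_degree = baseline_poly_degree,
    baseline_scale = baseline_scale, scatter_gain_sd = scatter_gain_sd,
    scatter_offset_sd = scatter_offset_sd,
    class_separation = class_separation,
    outlier_fraction = outlier_fraction, seed = as.integer(seed)
  ), class = "sim_config")
}

# pure (noise-free, scatter-free) spectrum of one class profile
profile_signal <- function(profile, grid) {
  b <- profile$bands
  amp <- b$amplitude * (1 + profile$band_perturbation)
  sig <- numeric(length(grid))
  for (j in seq_len(nrow(b))) {
    sig <- sig + amp[j] * exp(-(grid - b$center[j])^2 / (2 * b$width[j]^2))
  }
  sig
}

#' Simulate class-structured NIR spectra
#'
#' Each spectrum is its class's Gaussian band sum scaled by a per-sample
#' multiplicative gain `1 + N(0, scatter_gain_sd)`, shifted by a per-sample
#' additive offset, plus a random low-degree polynomial baseline and i.i.d.
#' Gaussian noise. The class band sums come from `profiles`; the whole draw is
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param profiles list of class profiles of length `cfg$n_classes`; defaults
#'   to [default_profiles()] drawn from a sub-seed of `cfg$seed` with
#'   `cfg$class_separation`.
#' @return An `nir_spectra` tibble with labels.
#' @export
simulate_spectra <- function(cfg, profiles = NULL) {
  if (is.null(profiles)) {
    profiles <- default_profiles(cfg$n_classes, cfg$class_separation,
                                 seed = substream(cfg$seed, 1))
  }
  if (length(profiles) != cfg$n_classes) {
    rlang::abort("Need one profile per class.")
  }
  grid <- cfg$grid
  n <- sum(cfg$samples_per_class)
  labels <- rep(vapply(profiles, `[[`, "", "class_name"),
                times = cfg$samples_per_class)
  pure <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    matrix(profile_signal(profiles[[i]], grid), nrow = cfg$samples_per_class[i],
           ncol = length(grid), byrow = TRUE)
  }))
  # normalised abscissa keeps baseline coefficients comparable across degrees
  u <- seq(-1, 1, length.out = length(grid))
  withr_seed(substream(cfg$seed, 2), {
    gain <- 1 + stats::rnorm(n, 0, cfg$scatter_gain_sd)
    offset <- stats::rnorm(n, 0, cfg$scatter_offset_sd)
    base_coef <- matrix(stats::rnorm(n * (cfg$baseline_poly_degree + 1),
                                     0, cfg$baseline_scale),
                        nrow = n)
    basis <- outer(u, 0:cfg$baseline_poly_degree, `^`)
    baseline <- base_coef %*% t(basis)
    noise <- matrix(stats::rnorm(n * length(grid), 0, cfg$noise_sd), nrow = n)
    m <- pure * gain + offset + baseline + noise
    nir_spectra(m, grid,
                sample_ids = sprintf("%s_%02d", labels,
                                     stats::ave(seq_len(n), labels, FUN = seq_along)),
                labels = labels)
  })
}

#' Inject synthetic outlier spectra
#'
#' Corrupts a seeded random subset of spectra in one of three ways:
#' `"shifted-baseline"` adds a large constant offset, `"alien-band"` adds a
#' Gaussian band at a wavenumber where no class has signal (drives up the
#' orthogonal distance), and `"extreme-leverage"` inflates a spectrum's
#' deviation from the set mean along the dominant principal direction (drives
#' up the score distance).
#'
#' @param s an `nir_spectra` tibble.
#' @param fraction fraction of samples to corrupt, in `[0, 1)`; `fraction * n`
#'   must be at least 1 when positive.
#' @param mode corruption mode, see above.
#' @param seed integer seed selecting the victims and corruption magnitudes.
#' @param magnitude corruption strength relative to the set's signal scale.
#' @return A list with `spectra` (modified copy) and `injected_ids`.
#' @export
inject_outliers <- function(s, fraction,
                            mode = c("alien-band", "shifted-baseline",
                                     "extreme-leverage"),
                            seed = 1, magnitude = 5) {
  mode <- match.arg(mode)
  if (nrow(s) == 0) rlang::abort("Empty spectra set.")
  if (fraction == 0) {
    return(list(spectra = s, injected_ids = character(0)))
  }
  n_out <- floor(fraction * nrow(s))
  if (n_out < 1) rlang::abort("`fraction * n` must be at least 1.")
  m <- spectra_matrix(s)
  w <- wavenumbers(s)
  withr_seed(seed, {
    idx <- sample(nrow(s), n_out)
    scale <- stats::median(apply(m, 1, stats::sd))
    for (i in idx) {
      m[i, ] <- switch(mode,
        "shifted-baseline" = m[i, ] + magnitude * scale,
        "alien-band" = {
          # place the band in the upper, signal-free part of the grid; keep
          # it resolved by at least a few grid points
          center <- stats::quantile(w, 0.85) + stats::runif(1, -50, 50)
          width <- max(30, 3 * stats::median(diff(w)))
          m[i, ] + magnitude * scale * exp(-(w - center)^2 / (2 * width^2))
        },
        "extreme-leverage" = {
          # move the sample to `magnitude` score-standard-deviations along
          # the dominant principal direction of the set
          ctr <- colMeans(m)
          v1 <- svd(sweep(m, 2, ctr), nu = 0, nv = 1)$v[, 1]
          proj <- sum((m[i, ] - ctr) * v1)
          spread <- stats::sd(sweep(m, 2, ctr) %*% v1)
          m[i, ] + (sign(proj + (proj == 0)) * magnitude * spread - proj) * v1
        })
    }
    list(spectra = set_spectra_matrix(s, m),
         injected_ids = s$sample_id[sort(idx)])
  })
}

#' Simulate a full study data set, outliers included
#'
#' Convenience wrapper: draws clean spectra with [simulate_spectra()] and, if
#' `cfg$outlier_fraction > 0`, corrupts that fraction with [inject_outliers()].
#'
#' @param cfg a [sim_config()].
#' @param outlier_mode passed to [inject_outliers()].
#' @return A list with `spectra` and `injected_ids`.
#' @export
simulate_study <- function(cfg, outlier_mode = "alien-band") {
  s <- simulate_spectra(cfg)
  if (cfg$outlier_fraction > 0) {
    inject_outliers(s, cfg$outlier_fraction, mode = outlier_mode,
                    seed = substream(cfg$seed, 3))
  } else {
    list(spectra = s, injected_ids = character(0))
  }
}
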