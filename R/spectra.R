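#' Labelled NIR spectra on a uniform wavenumber grid
#'
#' An `nir_spectra` object is a wide tibble: a `sample_id` column, an optional
#' `label` column, and one numeric column per wavenumber, named by its value in
#' cm^-1. The wavenumber grid must be uniform (constant spacing) and is stored
#' ascending. All spectral operations in this package take and return this
#' shape, so calls chain with the pipe.
#'
#' @param absorbance numeric matrix, samples in rows, wavenumbers in columns.
#' @param wavenumbers numeric vector of column wavenumbers (cm^-1), uniform
#'   spacing; may be descending (normalised to ascending).
#' @param sample_ids character vector of unique sample identifiers; defaults to
#'   `"s1", "s2", ...`.
#' @param labels optional character vector of class labels, one per sample.
#'
#' @return A tibble of class `nir_spectra`.
#' @export
#' @examples
#' s <- nir_spectra(matrix(rnorm(10), 2, 5), seq(4000, by = 3.857, length.out = 5))
#' wavenumbers(s)
nir_spectra <- function(absorbance, wavenumbers, sample_ids = NULL,
                        labels = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers)) {
    rlang::abort("`absorbance` must have one column per wavenumber.")
  }
  check_uniform_grid(wavenumbers)
  if (is.unsorted(wavenumbers)) {
    ord <- order(wavenumbers)
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
  }
  n <- nrow(absorbance)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    rlang::abort("`sample_ids` must have one entry per spectrum.")
  }
  if (anyDuplicated(sample_ids)) {
    rlang::abort("`sample_ids` must be unique.")
  }
  out <- tibble::tibble(sample_id = sample_ids)
  if (!is.null(labels)) {
    if (length(labels) != n) rlang::abort("`labels` must have one entry per sample.")
    out$label <- as.character(labels)
  }
  spec <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(spec) <- format_wavenumber(wavenumbers)
  out <- dplyr::bind_cols(out, spec)
  class(out) <- c("nir_spectra", class(tibble::tibble()))
  out
}

format_wavenumber <- function(w) {
  format(w, digits = 12, trim = TRUE, scientific = FALSE)
}

# spacing must be constant to 0.1% relative tolerance
check_uniform_grid <- function(w, tol = 1e-3) {
  if (length(w) < 2) rlang::abort("Grid needs at least 2 points.")
  d <- diff(w)
  if (any(d == 0)) rlang::abort("non-uniform grid: repeated wavenumbers.")
  step <- stats::median(d)
  if (any(abs(d - step) > tol * abs(step))) {
    rlang::abort("non-uniform grid: spacing varies by more than the tolerance.")
  }
  invisible(step)
}

meta_cols <- function(s) intersect(c("sample_id", "label"), names(s))

spectral_cols <- function(s) setdiff(names(s), c("sample_id", "label"))

#' Extract the wavenumber grid of an `nir_spectra` tibble
#'
#' @param s an `nir_spectra` tibble (or any data frame whose spectral columns
#'   are named by wavenumber).
#' @return Numeric vector of wavenumbers in cm^-1, ascending.
#' @export
wavenumbers <- function(s) {
  as.numeric(spectral_cols(s))
}

#' Grid spacing in cm^-1
#' @inheritParams wavenumbers
#' @return Median spacing between consecutive grid points.
#' @export
grid_step <- function(s) {
  stats::median(diff(wavenumbers(s)))
}

#' Absorbance matrix of an `nir_spectra` tibble
#'
#' @inheritParams wavenumbers
#' @return Numeric matrix (samples x wavenumbers) with `sample_id` row names.
#' @export
spectra_matrix <- function(s) {
  m <- as.matrix(s[spectral_cols(s)])
  rownames(m) <- s$sample_id
  m
}

# rebuild an nir_spectra from a template's metadata and a new matrix
set_spectra_matrix <- function(s, m) {
  nir_spectra(m, wavenumbers(s), sample_ids = s$sample_id,
              labels = if ("label" %in% names(s)) s$label else NULL)
}

#' Read labelled spectra from delimited text
#'
#' Expects a header row `sample_id[,label],<wavenumber...>` with one spectrum
#' per row. Lines starting with `#` are comments. Columns listed in descending
#' wavenumber order are normalised to ascending. Grid uniformity is verified to
#' a 0.1% relative tolerance.
#'
#' @param path file path to a CSV written by [write_spectra()] or compatible.
#' @param delim field delimiter, default `","`.
#' @return An `nir_spectra` tibble.
#' @export
read_spectra <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df)) {
    rlang::abort("File must contain a `sample_id` column.")
  }
  has_label <- "label" %in% names(df)
  spec_names <- setdiff(names(df), c("sample_id", "label"))
  w <- suppressWarnings(as.numeric(spec_names))
  if (anyNA(w)) rlang::abort("Header wavenumbers must be numeric.")
  m <- as.matrix(df[spec_names])
  if (!is.numeric(m)) rlang::abort("Spectral cells must all be numeric.")
  nir_spectra(m, w, sample_ids = as.character(df$sample_id),
              labels = if (has_label) df$label else NULL)
}

#' Write spectra as delimited text
#'
#' Serialises with 15 significant digits so that
#' `read_spectra(write_spectra(s))` round-trips to working precision.
#'
#' @param s an `nir_spectra` tibble.
#' @param path output file path.
#' @param delim field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, delim = ",") {
  stopifnot(is.data.frame(s))
  m <- spectra_matrix(s)
  header <- c(meta_cols(s), spectral_cols(s))
  body <- cbind(
    sample_id = s$sample_id,
    if ("label" %in% names(s)) s$label,
    matrix(sprintf("%.15g", m), nrow = nrow(m))
  )
  lines <- c(paste(header, collapse = delim),
             apply(body, 1, paste, collapse = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Mean spectrum, overall or per class
#'
#' @param s an `nir_spectra` tibble with at least one sample.
#' @param by_label if `TRUE`, one mean spectrum per class (requires labels),
#'   in first-appearance order; otherwise a single overall mean.
#' @return An `nir_spectra` tibble with one row per group.
#' @export
mean_spectrum <- function(s, by_label = FALSE) {
  if (nrow(s) == 0) rlang::abort("Cannot average an empty spectra set.")
  m <- spectra_matrix(s)
  w <- wavenumbers(s)
  if (by_label) {
    if (!"label" %in% names(s)) rlang::abort("`by_label = TRUE` requires labels.")
    classes <- unique(s$label)
    means <- do.call(rbind, lapply(classes, function(cl) {
      colMeans(m[s$label == cl, , drop = FALSE])
    }))
    nir_spectra(means, w, sample_ids = paste0("mean_", classes), labels = classes)
  } else {
    nir_spectra(matrix(colMeans(m), nrow = 1), w, sample_ids = "mean")
  }
}

#' Class labels in first-appearance order
#' @inheritParams wavenumbers
#' @return Character vector of unique labels.
#' @export
class_levels <- function(s) {
  if (!"label" %in% names(s)) rlang::abort("Spectra set has no labels.")
  unique(s$label)
}

#' @export
print.nir_spectra <- function(x, ...) {
  w <- wavenumbers(x)
  cat(sprintf("<nir_spectra> %d sample(s) x %d points, %.6g-%.6g cm^-1 (step %.6g)\n",
              nrow(x), length(w), min(w), max(w), stats::median(diff(w))))
  if ("label" %in% names(x)) {
    tab <- table(factor(x$label, levels = unique(x$label)))
    cat("classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  }
  NextMethod()
}

#' Plot spectra coloured by class
#'
#' @param object an `nir_spectra` tibble.
#' @param max_samples cap on the number of spectra drawn (random thinning is
#'   not used; the first rows win).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nir_spectra <- function(object, max_samples = 50, ...) {
  s <- utils::head(object, max_samples)
  long <- tidyr::pivot_longer(s, cols = dplyr::all_of(spectral_cols(s)),
                              names_to = "wavenumber", values_to = "absorbance")
  long$wavenumber <- as.numeric(long$wavenumber)
  aes <- if ("label" %in% names(long)) {
    ggplot2::aes(.data$wavenumber, .data$absorbance,
                 group = .data$sample_id, colour = .data$label)
  } else {
    ggplot2::aes(.data$wavenumber, .data$absorbance, group = .data$sample_id)
  }
  ggplot2::ggplot(long, aes) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance") +
    ggplot2::theme_minimal()
}
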