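#' Savitzky-Golay smoothing and derivatives
#'
#' Per-row local polynomial filtering via [signal::sgolayfilt()]. Boundary
#' points are handled by the filter's own polynomial edge rows, so the number
#' of grid points is unchanged. Derivatives are returned in physical units
#' (per cm^-1 for order 1, per cm^-2 for order 2) by scaling with the grid
#' step.
#'
#' @param s an `nir_spectra` tibble.
#' @param window filter window length in points; odd, greater than `polyorder`,
#'   at most the number of grid points.
#' @param polyorder polynomial order of the local fit.
#' @param deriv_order derivative order, 0 (smoothing), 1 or 2; must not exceed
#'   `polyorder`.
#' @return An `nir_spectra` tibble on the same grid.
#' @export
sg_filter <- function(s, window, polyorder = 2, deriv_order = 0) {
  if (window %% 2 == 0) rlang::abort("`window` must be odd.")
  if (window <= polyorder) rlang::abort("`window` must exceed `polyorder`.")
  if (deriv_order > polyorder) rlang::abort("`deriv_order` must not exceed `polyorder`.")
  m <- spectra_matrix(s)
  if (window > ncol(m)) rlang::abort("`window` larger than the spectrum.")
  step <- grid_step(s)
  out <- t(apply(m, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = deriv_order, ts = step))
  set_spectra_matrix(s, out)
}

#' Standard normal variate transformation
#'
#' Centers each spectrum to mean 0 and scales it to unit standard deviation
#' (n - 1 denominator), removing per-sample multiplicative scatter and offset.
#'
#' @param s an `nir_spectra` tibble; no row may be constant.
#' @return An `nir_spectra` tibble.
#' @export
snv <- function(s) {
  m <- spectra_matrix(s)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- s$sample_id[sds == 0][1]
    rlang::abort(sprintf("Constant spectrum cannot be SNV-scaled: sample '%s'.", bad))
  }
  out <- (m - rowMeans(m)) / sds
  set_spectra_matrix(s, out)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a * ref + b`, and
#' returns `(x - b) / a`. The reference defaults to the mean spectrum of `s`
#' itself; pass the training-set reference at prediction time to avoid
#' information leakage.
#'
#' @param s an `nir_spectra` tibble.
#' @param reference optional numeric reference spectrum (same grid length);
#'   defaults to the column mean of `s` (which then needs >= 2 samples).
#' @return An `nir_spectra` tibble.
#' @export
msc <- function(s, reference = NULL) {
  m <- spectra_matrix(s)
  if (is.null(reference)) {
    if (nrow(m) < 2) rlang::abort("MSC needs >= 2 samples to form a mean reference.")
    reference <- colMeans(m)
  }
  stopifnot(length(reference) == ncol(m))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom == 0) rlang::abort("Zero-variance MSC reference.")
  a <- as.vector(m %*% rc) / denom           # slope of x ~ a*ref + b
  b <- rowMeans(m) - a * mean(reference)
  out <- (m - b) / a
  set_spectra_matrix(s, out)
}

#' Parse a pretreatment pipeline name
#'
#' Understands the compact naming convention used for comparing pretreatments,
#' e.g. `"SNV+SG-17+2D"`. Tokens: `SNV`, `MSC`, `SG-w` (smoothing, window `w`
#' points), `1D`/`2D` (first/second derivative with the minimal legal window),
#' `1D-w`/`2D-w` (derivative with window `w`). An `SG-w` immediately followed
#' by `1D`/`2D` fuses into a single derivative step with window `w`.
#'
#' @param name pipeline name string.
#' @return A list of class `preprocess_pipeline` with elements `name` and
#'   `steps` (list of step descriptors).
#' @export
parse_pipeline_name <- function(name) {
  if (is.null(name) || !nzchar(name) || toupper(name) == "NONE") {
    return(structure(list(name = "none", steps = list()),
                     class = "preprocess_pipeline"))
  }
  tokens <- strsplit(name, "+", fixed = TRUE)[[1]]
  steps <- list()
  i <- 1
  while (i <= length(tokens)) {
    tok <- toupper(trimws(tokens[i]))
    if (tok == "SNV") {
      steps <- c(steps, list(list(kind = "snv")))
    } else if (tok == "MSC") {
      steps <- c(steps, list(list(kind = "msc")))
    } else if (grepl("^SG-[0-9]+$", tok)) {
      w <- as.integer(sub("^SG-", "", tok))
      if (w %% 2 == 0) rlang::abort(sprintf("Even SG window in '%s'.", tok))
      nxt <- if (i < length(tokens)) toupper(trimws(tokens[i + 1])) else ""
      if (nxt %in% c("1D", "2D")) {
        d <- as.integer(substr(nxt, 1, 1))
        steps <- c(steps, list(list(kind = "sg-derivative", window = w,
                                    polyorder = max(2L, d), deriv_order = d)))
        i <- i + 1
      } else {
        steps <- c(steps, list(list(kind = "sg-smooth", window = w,
                                    polyorder = 2L, deriv_order = 0L)))
      }
    } else if (grepl("^[12]D(-[0-9]+)?$", tok)) {
      d <- as.integer(substr(tok, 1, 1))
      w <- if (grepl("-", tok)) as.integer(sub("^[12]D-", "", tok)) else {
        # minimal legal odd window for the default polyorder
        as.integer(max(2L, d) + 1 + (max(2L, d) %% 2))
      }
      if (w %% 2 == 0) rlang::abort(sprintf("Even derivative window in '%s'.", tok))
      steps <- c(steps, list(list(kind = "sg-derivative", window = w,
                                  polyorder = max(2L, d), deriv_order = d)))
    } else {
      rlang::abort(sprintf("Unknown pretreatment token '%s'.", tokens[i]))
    }
    i <- i + 1
  }
  structure(list(name = format_pipeline_steps(steps), steps = steps),
            class = "preprocess_pipeline")
}

format_pipeline_steps <- function(steps) {
  if (length(steps) == 0) return("none")
  paste(vapply(steps, function(st) {
    switch(st$kind,
           "snv" = "SNV",
           "msc" = "MSC",
           "sg-smooth" = sprintf("SG-%d", st$window),
           "sg-derivative" = {
             d <- sprintf("%dD", st$deriv_order)
             mw <- max(2L, st$deriv_order) + 1 + (max(2L, st$deriv_order) %% 2)
             if (st$window == mw) d else sprintf("SG-%d+%s", st$window, d)
           })
  }, ""), collapse = "+")
}

#' @export
format.preprocess_pipeline <- function(x, ...) x$name

#' @export
print.preprocess_pipeline <- function(x, ...) {
  cat("<preprocess_pipeline>", x$name, "\n")
  invisible(x)
}

#' Apply a pretreatment pipeline
#'
#' Applies the steps of a pipeline in order. MSC references are learned from
#' `fit_context` when supplied (the training set, pretreated through the same
#' preceding steps) so that test spectra are corrected against the training
#' reference.
#'
#' @param s an `nir_spectra` tibble to transform.
#' @param pipeline a `preprocess_pipeline` or a pipeline name string.
#' @param fit_context optional `nir_spectra` training set providing the MSC
#'   reference.
#' @return An `nir_spectra` tibble.
#' @export
apply_pipeline <- function(s, pipeline, fit_context = NULL) {
  if (is.character(pipeline)) pipeline <- parse_pipeline_name(pipeline)
  ctx <- fit_context
  for (k in seq_along(pipeline$steps)) {
    st <- pipeline$steps[[k]]
    res <- tryCatch(
      switch(st$kind,
        "snv" = {
          if (!is.null(ctx)) ctx <- snv(ctx)
          snv(s)
        },
        "msc" = {
          ref <- if (!is.null(ctx)) colMeans(spectra_matrix(ctx)) else NULL
          if (!is.null(ctx)) ctx <- msc(ctx)
          msc(s, reference = ref)
        },
        {
          if (!is.null(ctx)) {
            ctx <- sg_filter(ctx, st$window, st$polyorder, st$deriv_order)
          }
          sg_filter(s, st$window, st$polyorder, st$deriv_order)
        }),
      error = function(e) {
        rlang::abort(sprintf("Pipeline step %d (%s) failed: %s",
                             k, st$kind, conditionMessage(e)))
      })
    s <- res
  }
  s
}

#' The fifteen standard pretreatment variants
#'
#' The usual comparison grid for NIR pretreatment selection: Savitzky-Golay
#' smoothing alone, derivatives at low and high smoothing, smoothing-derivative
#' fusions, and SNV/MSC alone and combined with smoothed derivatives. Window
#' lengths are in points and must be odd; conventional even or sub-minimal
#' choices are bumped to the nearest legal odd window.
#'
#' @return Character vector of pipeline names, parseable by
#'   [parse_pipeline_name()].
#' @export
standard_pipelines <- function() {
  c("SG-17", "1D-3", "1D-13", "2D-5", "2D-21",
    "SG-5+1D", "SG-21+1D", "SG-5+2D", "SG-21+2D",
    "SNV", "SNV+SG-25+1D", "SNV+SG-17+2D",
    "MSC", "MSC+SG-9+1D", "MSC+SG-9+2D")
}
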