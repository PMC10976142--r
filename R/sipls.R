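#' Divide a wavenumber axis into equal-width intervals
#'
#' Intervals are equal in wavenumber (cm^-1), contiguous and half-open
#' `[lo, hi)`, the last closed at the top so every grid point belongs to
#' exactly one interval. The span runs from the first grid point to one step
#' past the last (each point owning the cell it starts), or between explicit
#' bounds when `x` is a length-2 numeric range.
#'
#' @param x an `nir_spectra` tibble, a numeric wavenumber vector (> 2 points),
#'   or a numeric length-2 `c(lo, hi)` range.
#' @param k_intervals number of intervals.
#' @return An `interval_grid` tibble: `interval`, `lo`, `hi`, and (when a grid
#'   was given) `n_points`; attribute `width` holds the common width.
#' @export
divide_intervals <- function(x, k_intervals) {
  stopifnot(k_intervals >= 1)
  if (is.data.frame(x)) x <- wavenumbers(x)
  x <- as.numeric(x)
  if (length(x) == 2) {
    lo <- x[1]; hi <- x[2]
    points <- NULL
  } else {
    step <- stats::median(diff(x))
    lo <- x[1]; hi <- x[length(x)] + step
    points <- x
  }
  if (!is.null(points) && k_intervals > length(points)) {
    rlang::abort("More intervals than grid points.")
  }
  width <- (hi - lo) / k_intervals
  bounds <- lo + width * (0:k_intervals)
  out <- tibble::tibble(interval = seq_len(k_intervals),
                        lo = bounds[-(k_intervals + 1)],
                        hi = bounds[-1])
  if (!is.null(points)) {
    idx <- pmin(findInterval(points, bounds, rightmost.closed = TRUE),
                k_intervals)
    out$n_points <- as.integer(tabulate(idx, nbins = k_intervals))
    attr(out, "assignment") <- idx
  }
  attr(out, "width") <- width
  class(out) <- c("interval_grid", class(tibble::tibble()))
  out
}

interval_columns <- function(grid, combo) {
  idx <- attr(grid, "assignment")
  if (is.null(idx)) rlang::abort("Interval grid was built without a point grid.")
  which(idx %in% combo)
}

#' Synergy-interval PLS search
#'
#' Exhaustively evaluates every combination of `j` of the `k` intervals: for
#' each combination a PLS model on the concatenated interval columns is
#' cross-validated and its RMSECV minimised over latent-variable counts up to
#' `lv_max`. The combination with the smallest RMSECV wins; ties go to the
#' lexicographically first combination.
#'
#' @param s an `nir_spectra` tibble (or matrix plus `grid`).
#' @param y numeric response (for PLS-DA tasks, the coded +1/-1 vector).
#' @param k_intervals number of equal-width intervals.
#' @param j number of intervals per combination, `1 <= j <= k_intervals`.
#' @param lv_max largest latent-variable count tried per combination.
#' @param n_folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @param grid optional precomputed `interval_grid`.
#' @param max_combos guard on the exhaustive sweep size.
#' @param keep_scores keep the per-combination score table (can be large).
#' @return An object of class `sipls_result`: `grid`, `j`, `best_combo`,
#'   `best_rmsecv`, `best_lv`, `n_combos`, optionally `scores`.
#' @export
sipls_search <- function(s, y, k_intervals, j, lv_max = 10, n_folds = 5,
                         seed = 1, grid = NULL, max_combos = 1e6,
                         keep_scores = TRUE) {
  stopifnot(j >= 1, j <= k_intervals)
  if (is.null(grid)) grid <- divide_intervals(s, k_intervals)
  X <- as_X(s)
  n_combos <- choose(k_intervals, j)
  if (n_combos > max_combos) {
    rlang::abort(sprintf(
      "C(%d, %d) = %s combinations exceeds the budget; reduce `j` or `k_intervals`.",
      k_intervals, j, format(n_combos, big.mark = ",")))
  }
  combos <- utils::combn(k_intervals, j)
  best <- list(rmsecv = Inf, combo = NULL, lv = NA_integer_)
  scores <- if (keep_scores) vector("list", ncol(combos)) else NULL
  for (ci in seq_len(ncol(combos))) {
    combo <- combos[, ci]
    cols <- interval_columns(grid, combo)
    if (length(cols) < 2) next  # interval(s) empty on this grid
    lv_cap <- min(lv_max, length(cols), nrow(X) - ceiling(nrow(X) / n_folds) - 1)
    errs <- rmsecv(X[, cols, drop = FALSE], y, n_lv = seq_len(lv_cap),
                   n_folds = n_folds, seed = seed)
    lv_best <- which.min(errs)
    if (keep_scores) {
      scores[[ci]] <- tibble::tibble(
        combo = paste(combo, collapse = ","),
        rmsecv = errs[lv_best], n_lv = lv_best)
    }
    if (errs[lv_best] < best$rmsecv) {
      best <- list(rmsecv = errs[lv_best], combo = combo, lv = lv_best)
    }
  }
  if (is.null(best$combo)) rlang::abort("No evaluable interval combination.")
  structure(list(
    grid = grid, j = j, k_intervals = k_intervals,
    best_combo = best$combo, best_rmsecv = best$rmsecv, best_lv = best$lv,
    n_combos = n_combos,
    scores = if (keep_scores) dplyr::bind_rows(scores) else NULL
  ), class = "sipls_result")
}

#' @export
print.sipls_result <- function(x, ...) {
  cat(sprintf("<sipls_result> %d of %d intervals; best {%s}, RMSECV %.5g (%d LV)\n",
              x$j, x$k_intervals, paste(x$best_combo, collapse = ","),
              x$best_rmsecv, x$best_lv))
  invisible(x)
}

#' @export
glance.sipls_result <- function(x, ...) {
  tibble::tibble(k_intervals = x$k_intervals, j = x$j,
                 best_combo = paste(x$best_combo, collapse = ","),
                 best_rmsecv = x$best_rmsecv, best_lv = x$best_lv,
                 n_combos = x$n_combos)
}

#' Interval selection frequency across binary models
#'
#' Counts how often each interval appears in the best combination across a
#' collection of SI-PLS results (one per binary model of a decomposition),
#' the usual way characteristic spectral intervals are identified.
#'
#' @param results list of `sipls_result` objects sharing one interval grid
#'   and one `j`.
#' @return A `frequency_table` tibble: `interval`, `lo`, `hi`, `count`,
#'   `frequency`; attributes `total` (n_models * j) and `top5_share`.
#' @export
selection_frequency <- function(results) {
  stopifnot(length(results) >= 1)
  k <- results[[1]]$k_intervals
  j <- results[[1]]$j
  same <- vapply(results, function(r) {
    r$k_intervals == k && r$j == j &&
      isTRUE(all.equal(r$grid$lo, results[[1]]$grid$lo))
  }, logical(1))
  if (!all(same)) rlang::abort("All results must share one interval grid and j.")
  counts <- tabulate(unlist(lapply(results, `[[`, "best_combo")), nbins = k)
  total <- length(results) * j
  out <- tibble::tibble(interval = seq_len(k),
                        lo = results[[1]]$grid$lo,
                        hi = results[[1]]$grid$hi,
                        count = as.integer(counts),
                        frequency = counts / total)
  attr(out, "total") <- total
  attr(out, "top5_share") <- top_share(counts, total, 5)
  class(out) <- c("frequency_table", class(tibble::tibble()))
  out
}

#' Share of total selections captured by the most-selected intervals
#'
#' @param counts integer selection counts per interval.
#' @param total total number of selections (`n_models * j`).
#' @param top how many top intervals to pool.
#' @return Fraction in `[0, 1]`.
#' @export
top_share <- function(counts, total = sum(counts), top = 5) {
  sum(utils::head(sort(counts, decreasing = TRUE), top)) / total
}

#' @export
autoplot.frequency_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$lo + df$hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$frequency)) +
    ggplot2::geom_col(width = (df$hi - df$lo) * 0.9,
                      fill = "steelblue", colour = "grey30") +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = "Relative selection frequency") +
    ggplot2::theme_minimal()
}
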