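#' Fit a PCA model for outlier diagnostics
#'
#' Principal components of the spectra about a robust (column-wise median)
#' or classical (mean) center, via singular value decomposition. When `p` is
#' not given, the smallest component count whose cumulative explained variance
#' reaches `cumvar_target` is used.
#'
#' @param s an `nir_spectra` tibble or numeric matrix.
#' @param p optional fixed component count.
#' @param cumvar_target cumulative explained-variance fraction in (0, 1] used
#'   to choose `p` automatically.
#' @param center `"median"` (robust, default) or `"mean"`.
#' @return An object of class `spectra_pca`: `center`, `loadings`
#'   (variables x p, orthonormal), `eigenvalues` (score variances,
#'   descending), `p`, `n`, `cumvar`.
#' @export
fit_pca <- function(s, p = NULL, cumvar_target = 0.999,
                    center = c("median", "mean")) {
  center <- match.arg(center)
  X <- as_X(s)
  n <- nrow(X)
  ctr <- if (center == "median") apply(X, 2, stats::median) else colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  # score variances about the chosen center (n - 1 denominator)
  ev <- sv$d^2 / (n - 1)
  pos <- ev > max(ev) * 1e-12
  if (!any(pos)) rlang::abort("Degenerate data: all spectra identical.")
  ev <- ev[pos]
  cumvar <- cumsum(ev) / sum(ev)
  if (is.null(p)) {
    stopifnot(cumvar_target > 0, cumvar_target <= 1)
    p <- which(cumvar >= cumvar_target - 1e-12)[1]
  }
  if (p > length(ev)) rlang::abort("Requested more components than the data rank.")
  if (n < p + 1) rlang::abort("Need n >= p + 1 samples.")
  structure(list(center = ctr,
                 loadings = sv$v[, seq_len(p), drop = FALSE],
                 eigenvalues = ev[seq_len(p)],
                 p = as.integer(p), n = n,
                 cumvar = cumvar[p]),
            class = "spectra_pca")
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat(sprintf("<spectra_pca> %d component(s) from %d samples, cumvar %.4f\n",
              x$p, x$n, x$cumvar))
  invisible(x)
}

#' Score distance
#'
#' Mahalanobis-type distance of each sample to the model center inside the
#' principal-component subspace: `sd_i = sqrt(sum_k t_ik^2 / lambda_k)`.
#'
#' @param m a `spectra_pca` model.
#' @param s an `nir_spectra` tibble or matrix on the model's grid.
#' @return Numeric vector of score distances.
#' @export
score_distance <- function(m, s) {
  X <- as_X(s)
  if (ncol(X) != length(m$center)) rlang::abort("Grid mismatch with the PCA model.")
  if (any(m$eigenvalues <= 0)) rlang::abort("Zero eigenvalue among retained components.")
  Tm <- sweep(X, 2, m$center) %*% m$loadings
  sqrt(rowSums(sweep(Tm^2, 2, m$eigenvalues, `/`)))
}

#' Orthogonal distance
#'
#' Euclidean distance of each sample to its projection on the
#' principal-component subspace:
#' `od_i = || x_i - center - loadings %*% t_i ||`.
#'
#' @inheritParams score_distance
#' @return Numeric vector of orthogonal distances.
#' @export
orthogonal_distance <- function(m, s) {
  X <- as_X(s)
  if (ncol(X) != length(m$center)) rlang::abort("Grid mismatch with the PCA model.")
  Xc <- sweep(X, 2, m$center)
  Tm <- Xc %*% m$loadings
  res <- Xc - Tm %*% t(m$loadings)
  sqrt(rowSums(res^2))
}

#' F-based score-distance cutoff
#'
#' Hotelling T-squared control limit for `p` components and `n` training
#' samples: `T2 = p (n - 1) / (n - p) * F(alpha; p, n - p)`. On the distance
#' scale the cutoff is its square root, to be compared against the score
#' distance directly.
#'
#' @param p number of principal components (>= 1).
#' @param n number of training samples (> p).
#' @param alpha confidence level in (0, 1), default 0.95.
#' @param scale `"distance"` (square root, comparable to [score_distance()])
#'   or `"squared"` (the T-squared limit itself, the scale on which such
#'   cutoffs are conventionally tabulated).
#' @return Numeric threshold.
#' @export
sd_cutoff <- function(p, n, alpha = 0.95, scale = c("distance", "squared")) {
  scale <- match.arg(scale)
  stopifnot(p >= 1, n > p, alpha > 0, alpha < 1)
  t2 <- p * (n - 1) / (n - p) * stats::qf(alpha, p, n - p)
  if (scale == "distance") sqrt(t2) else t2
}

#' F-based orthogonal-distance cutoff
#'
#' Companion limit for the orthogonal distance:
#' `D = p (n - 1) (n + 1) / (n (n - p)) * F(alpha; p, n - p)`, i.e. the
#' score-distance limit inflated by `(n + 1) / n`. Returned on the same scale
#' convention as [sd_cutoff()]; on the `"distance"` scale it is compared
#' against a normalised orthogonal distance (see [screen_outliers()]).
#'
#' @inheritParams sd_cutoff
#' @return Numeric threshold.
#' @export
od_cutoff <- function(p, n, alpha = 0.95, scale = c("distance", "squared")) {
  scale <- match.arg(scale)
  stopifnot(p >= 1, n > p, alpha > 0, alpha < 1)
  d <- p * (n - 1) * (n + 1) / (n * (n - p)) * stats::qf(alpha, p, n - p)
  if (scale == "distance") sqrt(d) else d
}

# Stahel-Donoho outlyingness with the candidate directions taken through the
# data points: o_j = max_d |x_j'd - median(X d)| / mad(X d)
sd_outlyingness <- function(X) {
  ctr <- apply(X, 2, stats::median)
  Xc <- sweep(X, 2, ctr)
  norms <- sqrt(rowSums(Xc^2))
  keep <- norms > 0
  Dirs <- Xc[keep, , drop = FALSE] / norms[keep]
  Z <- X %*% t(Dirs)                       # projections, n x n_dirs
  med <- apply(Z, 2, stats::median)
  madv <- apply(Z, 2, stats::mad)
  ok <- madv > 0
  if (!any(ok)) return(rep(0, nrow(X)))
  dev <- abs(sweep(Z[, ok, drop = FALSE], 2, med[ok]))
  apply(sweep(dev, 2, madv[ok], `/`), 1, max)
}

#' Screen spectra for outliers with robust PCA diagnostics
#'
#' Fits a PCA per class (default) or globally, computes each sample's score
#' distance (SD) and orthogonal distance (OD), compares them against the
#' F-based cutoffs, and assigns the four-way taxonomy:
#'
#' | | low OD | high OD |
#' |---|---|---|
#' | **low SD** | regular | orthogonal-outlier |
#' | **high SD** | good-leverage | bad-leverage |
#'
#' Orthogonal distances are standardised to unit median before comparison
#' against the OD cutoff (the raw OD scale depends on the residual noise
#' level, which the F-based limit does not model). The removal policy
#' `"either"` flags every sample exceeding either cutoff; `"high-od"` flags
#' only the high-OD categories (orthogonal outliers and bad leverage).
#'
#' @param s a labelled `nir_spectra` tibble (labels required for per-class
#'   screening).
#' @param alpha confidence level for both cutoffs.
#' @param policy removal policy, `"either"` (default) or `"high-od"`.
#' @param per_class screen within each class (default) or globally.
#' @param p optional fixed component count passed to [fit_pca()].
#' @param cumvar_target cumulative-variance target for automatic `p`.
#' @param center PCA centering, `"median"` or `"mean"`.
#' @return An `outlier_report` tibble: `sample_id`, `label`, `p`, `n`, `sd`,
#'   `od`, `sd_cutoff`, `od_cutoff`, `category`, `removed`.
#' @export
screen_outliers <- function(s, alpha = 0.95, policy = c("either", "high-od"),
                            per_class = TRUE, p = NULL, cumvar_target = 0.999,
                            center = "median") {
  policy <- match.arg(policy)
  if (per_class && !"label" %in% names(s)) {
    rlang::abort("Per-class screening requires labels.")
  }
  groups <- if (per_class) class_levels(s) else "all"
  rows <- lapply(groups, function(g) {
    sub <- if (per_class) s[s$label == g, , drop = FALSE] else s
    # Robustness step: grossly deviant spectra are excluded from the PCA fit
    # by Stahel-Donoho directional outlyingness (directions through the data
    # points), then every sample is scored against the clean-core model.
    # Fitting on all samples would let a single contaminated spectrum pull
    # the loadings/eigenvalues toward itself and mask its own distances.
    out0 <- sd_outlyingness(spectra_matrix(sub))
    core <- out0 <= stats::median(out0) + 5 * stats::mad(out0)
    min_core <- max(if (is.null(p)) 2 else p + 2, ceiling(nrow(sub) / 2))
    m <- if (sum(core) >= min_core && any(!core)) {
      fit_pca(sub[core, , drop = FALSE], p = p, cumvar_target = cumvar_target,
              center = center)
    } else {
      fit_pca(sub, p = p, cumvar_target = cumvar_target, center = center)
    }
    m$n <- nrow(sub)  # cutoffs refer to the screened population size
    sdv <- score_distance(m, sub)
    odv <- orthogonal_distance(m, sub)
    # express OD on a dimensionless scale so the F-based limit applies
    od_med <- stats::median(odv)
    odn <- if (od_med > 0) odv / od_med else odv
    sc <- sd_cutoff(m$p, m$n, alpha)
    oc <- od_cutoff(m$p, m$n, alpha)
    tibble::tibble(
      sample_id = sub$sample_id,
      label = if ("label" %in% names(sub)) sub$label else NA_character_,
      p = m$p, n = m$n,
      sd = sdv, od = odn,
      sd_cutoff = sc, od_cutoff = oc,
      category = dplyr::case_when(
        sdv <= sc & odn <= oc ~ "regular",
        sdv > sc & odn <= oc ~ "good-leverage",
        sdv <= sc & odn > oc ~ "orthogonal-outlier",
        TRUE ~ "bad-leverage"
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  out$removed <- if (policy == "either") {
    out$category != "regular"
  } else {
    out$category %in% c("orthogonal-outlier", "bad-leverage")
  }
  # restore input sample order
  out <- out[match(s$sample_id, out$sample_id), , drop = FALSE]
  class(out) <- c("outlier_report", class(tibble::tibble()))
  out
}

#' Drop samples flagged by an outlier report
#'
#' @param s the `nir_spectra` tibble the report was computed from.
#' @param report an `outlier_report`.
#' @return `s` without the removed samples.
#' @export
remove_outliers <- function(s, report) {
  keep <- !report$removed[match(s$sample_id, report$sample_id)]
  s[keep, , drop = FALSE]
}

#' @export
autoplot.outlier_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$sd, .data$od,
                                   colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$sd_cutoff),
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$od_cutoff),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Score distance", y = "Orthogonal distance (scaled)") +
    ggplot2::theme_minimal()
}
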