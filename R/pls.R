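#' Fit a mean-centered NIPALS PLS1 model
#'
#' Classic NIPALS partial least squares for a single response: at each step
#' the weight vector is `w = X'y` (normalised), scores `t = Xw`, loadings
#' `p = X't / t't`, response loading `q = y't / t't`, followed by deflation of
#' `X`. Both `X` and `y` are mean-centered, not variance-scaled. Regression
#' coefficients are available for every truncation `1..n_lv`, which makes
#' cross-validation over latent-variable counts cheap. With a coded `+1/-1`
#' response this is a binary PLS-DA model; the decision threshold `threshold_c`
#' (default 0) splits predicted responses into the two classes.
#'
#' @param X numeric matrix (samples x variables) or an `nir_spectra` tibble.
#' @param y numeric response vector (for PLS-DA, coded +1 / -1).
#' @param n_lv number of latent variables, at most `min(n - 1, ncol(X))`.
#' @param threshold_c decision threshold on the predicted response.
#' @return An object of class `pls_binary`.
#' @export
fit_pls <- function(X, y, n_lv, threshold_c = 0) {
  X <- as_X(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_lv >= 1)
  if (n_lv > min(nrow(X) - 1, ncol(X))) {
    rlang::abort("`n_lv` exceeds min(n - 1, n_variables).")
  }
  if (stats::var(y) == 0) rlang::abort("Zero-variance response.")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  p_vars <- ncol(X)
  W <- matrix(0, p_vars, n_lv)   # X weights
  P <- matrix(0, p_vars, n_lv)   # X loadings
  qv <- numeric(n_lv)            # y loadings
  Tm <- matrix(0, nrow(X), n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { # residual exhausted: truncate
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      qv <- qv[seq_len(a - 1)]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      n_lv <- a - 1
      break
    }
    w <- w / nw
    t_sc <- as.vector(E %*% w)
    tt <- sum(t_sc^2)
    p_load <- as.vector(crossprod(E, t_sc)) / tt
    q_load <- sum(f * t_sc) / tt
    E <- E - tcrossprod(t_sc, p_load)
    f <- f - q_load * t_sc
    W[, a] <- w; P[, a] <- p_load; qv[a] <- q_load; Tm[, a] <- t_sc
  }
  if (n_lv == 0) rlang::abort("No latent variable could be extracted.")
  # B_k = W_k (P_k' W_k)^{-1} q_k for every truncation k
  R <- W %*% solve(crossprod(P, W))
  coefs <- sapply(seq_len(n_lv), function(k) {
    as.vector(R[, seq_len(k), drop = FALSE] %*% qv[seq_len(k)])
  })
  coefs <- matrix(coefs, nrow = p_vars)
  structure(list(
    x_mean = x_mean, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = qv, scores = Tm,
    coef = coefs[, n_lv], coef_by_lv = coefs,
    n_lv = n_lv, threshold_c = threshold_c
  ), class = "pls_binary")
}

as_X <- function(X) {
  if (is.data.frame(X)) X <- spectra_matrix(X)
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  m
}

#' Predict responses from a PLS model
#'
#' `y_hat = (X - x_mean) %*% coef + y_mean`, optionally truncated to fewer
#' latent variables than the model was fitted with.
#'
#' @param m a `pls_binary` model.
#' @param X matrix or `nir_spectra` tibble on the model's variable grid.
#' @param n_lv latent-variable count to use (defaults to the fitted count).
#' @return Numeric vector of predicted responses.
#' @export
predict_response <- function(m, X, n_lv = m$n_lv) {
  X <- as_X(X)
  if (ncol(X) != length(m$x_mean)) rlang::abort("Variable count mismatch.")
  stopifnot(n_lv >= 1, n_lv <= m$n_lv)
  b <- m$coef_by_lv[, n_lv]
  as.vector(sweep(X, 2, m$x_mean) %*% b) + m$y_mean
}

#' @export
predict.pls_binary <- function(object, newdata, n_lv = object$n_lv,
                               type = c("response", "class"), ...) {
  type <- match.arg(type)
  p <- predict_response(object, newdata, n_lv)
  if (type == "response") p else ifelse(p >= object$threshold_c, 1, -1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.pls_binary <- function(x, ...) {
  tibble::tibble(
    term = c("(center)", names(x$x_mean) %||% paste0("x", seq_along(x$coef))),
    estimate = c(x$y_mean - sum(x$x_mean * x$coef), x$coef)
  )
}

#' @export
glance.pls_binary <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, threshold_c = x$threshold_c,
                 n_variables = length(x$coef), n_samples = nrow(x$scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Root mean square error of cross-validation
#'
#' Seeded random fold assignment; for each fold the model is refitted on the
#' remainder and held-out responses predicted at `n_lv` latent variables.
#'
#' @param X matrix or `nir_spectra` tibble.
#' @param y numeric response.
#' @param n_lv latent variables for the held-out predictions (a vector is
#'   allowed; one RMSECV per entry is returned).
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed for the fold shuffle.
#' @return Numeric RMSECV, one value per entry of `n_lv`.
#' @export
rmsecv <- function(X, y, n_lv, n_folds = 5, seed = 1) {
  X <- as_X(X)
  y <- as.numeric(y)
  stopifnot(n_folds >= 2, n_folds <= nrow(X))
  max_lv <- max(n_lv)
  folds <- withr_seed(seed, {
    sample(rep_len(seq_len(n_folds), nrow(X)))
  })
  sse <- numeric(length(n_lv))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    # cap by what the training subset can support
    lv_cap <- min(max_lv, sum(tr) - 1, ncol(X))
    m <- fit_pls(X[tr, , drop = FALSE], y[tr], n_lv = lv_cap)
    for (j in seq_along(n_lv)) {
      p <- predict_response(m, X[!tr, , drop = FALSE],
                            n_lv = min(n_lv[j], m$n_lv))
      sse[j] <- sse[j] + sum((y[!tr] - p)^2)
    }
  }
  sqrt(sse / length(y))
}

#' Monte Carlo cross-validation for latent-variable selection
#'
#' Repeated stratified random holdouts. For each candidate latent-variable
#' count the misclassification error rate is the total number of misjudged
#' held-out samples across all splits divided by the total number tested
#' (ERMCCV = sum(M_i) / N); the chosen count minimises that rate, ties going
#' to the smaller count.
#'
#' @param X matrix or `nir_spectra` tibble.
#' @param y coded +1/-1 response (or any two-valued vector; the larger value
#'   is taken as the positive class).
#' @param max_lv largest candidate latent-variable count.
#' @param n_splits number of random holdout splits.
#' @param holdout_fraction fraction of samples held out per split, in (0, 1).
#' @param seed integer seed.
#' @param threshold_c decision threshold.
#' @return An object of class `mccv_result`: tibble of per-LV error rates in
#'   `rates`, `chosen_lv`, `n_splits`, `misjudged` (per split, at the chosen
#'   LV count), `n_tested`.
#' @export
mccv_select_lvs <- function(X, y, max_lv, n_splits = 100,
                            holdout_fraction = 0.2, seed = 1,
                            threshold_c = 0) {
  X <- as_X(X)
  y <- as.numeric(y)
  stopifnot(max_lv >= 1, holdout_fraction > 0, holdout_fraction < 1)
  cls <- sort(unique(y))
  if (length(cls) != 2) rlang::abort("MCCV LV selection expects a binary response.")
  idx_by_cls <- lapply(cls, function(cl) which(y == cl))
  mis <- matrix(0L, n_splits, max_lv)
  n_tested <- 0L
  withr_seed(seed, {
    for (i in seq_len(n_splits)) {
      # stratified holdout keeps both classes present on both sides
      hold <- unlist(lapply(idx_by_cls, function(ix) {
        nh <- max(1L, round(holdout_fraction * length(ix)))
        nh <- min(nh, length(ix) - 1L)
        sample(ix, nh)
      }))
      tr <- setdiff(seq_along(y), hold)
      lv_cap <- min(max_lv, length(tr) - 1, ncol(X))
      m <- fit_pls(X[tr, , drop = FALSE], y[tr], n_lv = lv_cap,
                   threshold_c = threshold_c)
      for (a in seq_len(max_lv)) {
        p <- predict_response(m, X[hold, , drop = FALSE],
                              n_lv = min(a, m$n_lv))
        pred_cls <- ifelse(p >= threshold_c, cls[2], cls[1])
        mis[i, a] <- sum(pred_cls != y[hold])
      }
      n_tested <- n_tested + length(hold)
    }
  })
  rates <- colSums(mis) / n_tested
  chosen <- which.min(rates)  # which.min takes the first (smallest) argmin
  structure(list(
    rates = tibble::tibble(n_lv = seq_len(max_lv), ermccv = rates),
    chosen_lv = as.integer(chosen),
    chosen_ermccv = rates[chosen],
    n_splits = n_splits,
    misjudged = mis[, chosen],
    n_tested = n_tested
  ), class = "mccv_result")
}

#' @export
tidy.mccv_result <- function(x, ...) x$rates

#' @export
glance.mccv_result <- function(x, ...) {
  tibble::tibble(chosen_lv = x$chosen_lv, ermccv = x$chosen_ermccv,
                 n_splits = x$n_splits, n_tested = x$n_tested)
}

#' @export
autoplot.mccv_result <- function(object, ...) {
  ggplot2::ggplot(object$rates, ggplot2::aes(.data$n_lv, .data$ermccv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_lv, linetype = 2) +
    ggplot2::labs(x = "Latent variables", y = "ERMCCV") +
    ggplot2::theme_minimal()
}

#' Classification accuracy
#'
#' The fraction of correctly classified samples, `n_correct / n_total`.
#'
#' @param n_correct number of correctly classified samples.
#' @param n_total number of samples classified (> 0).
#' @return A one-row tibble with `n_correct`, `n_total`, `accuracy`.
#' @export
classification_accuracy <- function(n_correct, n_total) {
  stopifnot(n_total > 0, n_correct >= 0, n_correct <= n_total)
  tibble::tibble(n_correct = n_correct, n_total = n_total,
                 accuracy = n_correct / n_total)
}
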