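#' Multiclass decomposition planners
#'
#' A decomposition plan turns a k-class problem into an ordered list of binary
#' tasks, each naming a positive class group `G_P` (coded +1) and a negative
#' group `G_N` (coded -1).
#'
#' * **OAO** (one-against-one): all unordered class pairs, `k(k-1)/2` tasks.
#' * **OAA** (one-against-all): each class against the union of the rest,
#'   `k` tasks.
#' * **EPHAH** (exhaustive, parallel half-against-half): every balanced
#'   bipartition of the class set. For even `k`, complements describe the same
#'   classifier, so only the half containing the first class is kept:
#'   `C(k, k/2) / 2` tasks. For odd `k` the positive group has
#'   `ceiling(k/2)` classes and all `C(k, ceiling(k/2))` subsets are tasks.
#'
#' @param classes character vector of class names, length >= 2; order fixes
#'   the task enumeration order.
#' @return A `decomposition_plan`: list with `strategy`, `classes` and a
#'   `tasks` tibble (`task`, `positive`, `negative` list-columns).
#' @name decomposition-planners
NULL

new_plan <- function(strategy, classes, pos_list, neg_list) {
  structure(list(
    strategy = strategy,
    classes = classes,
    tasks = tibble::tibble(
      task = seq_along(pos_list),
      positive = pos_list,
      negative = neg_list
    )
  ), class = "decomposition_plan")
}

check_classes <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) < 2) rlang::abort("Need at least 2 classes.")
  if (anyDuplicated(classes)) rlang::abort("Class names must be unique.")
  classes
}

#' @rdname decomposition-planners
#' @export
plan_oao <- function(classes) {
  classes <- check_classes(classes)
  k <- length(classes)
  pairs <- utils::combn(k, 2)
  new_plan("OAO", classes,
           lapply(seq_len(ncol(pairs)), function(j) classes[pairs[1, j]]),
           lapply(seq_len(ncol(pairs)), function(j) classes[pairs[2, j]]))
}

#' @rdname decomposition-planners
#' @export
plan_oaa <- function(classes) {
  classes <- check_classes(classes)
  new_plan("OAA", classes,
           as.list(classes),
           lapply(seq_along(classes), function(i) classes[-i]))
}

#' @rdname decomposition-planners
#' @export
plan_ephah <- function(classes) {
  classes <- check_classes(classes)
  k <- length(classes)
  half <- ceiling(k / 2)
  subs <- utils::combn(k, half)
  keep <- if (k %% 2 == 0) {
    # a subset and its complement define the same classifier; keep the one
    # containing the first class (deterministic, lexicographically first)
    which(subs[1, ] == 1)
  } else {
    seq_len(ncol(subs))
  }
  new_plan("EPHAH", classes,
           lapply(keep, function(j) classes[subs[, j]]),
           lapply(keep, function(j) classes[-subs[, j]]))
}

#' @export
print.decomposition_plan <- function(x, ...) {
  cat(sprintf("<decomposition_plan> %s, %d classes, %d binary task(s)\n",
              x$strategy, length(x$classes), nrow(x$tasks)))
  invisible(x)
}

#' @export
tidy.decomposition_plan <- function(x, ...) {
  dplyr::mutate(x$tasks,
                positive = vapply(.data$positive, paste, "", collapse = "|"),
                negative = vapply(.data$negative, paste, "", collapse = "|"))
}

#' Train a multiclass PLS-DA classifier from a decomposition plan
#'
#' For every binary task of the plan, samples of the task's two class groups
#' are coded +1 (positive group) and -1 (negative group) and a NIPALS PLS-DA
#' model is fitted. For OAO each task sees only its two classes; OAA and
#' EPHAH tasks see every sample. The latent-variable count is chosen per task
#' by Monte Carlo cross-validation, or held fixed with `lv_select = "fixed"`.
#'
#' @param s an `nir_spectra` tibble with labels covering every class in the
#'   plan (additional preprocessing should already have been applied).
#' @param plan a `decomposition_plan`.
#' @param lv_select `"mccv"` (per-task [mccv_select_lvs()]) or `"fixed"`.
#' @param n_lv fixed latent-variable count, or the MCCV candidate maximum.
#' @param mccv list of MCCV settings (`n_splits`, `holdout_fraction`, `seed`).
#' @param threshold_c decision threshold on predicted responses.
#' @return An object of class `multiclass_plsda`.
#' @export
train_decomposition <- function(s, plan, lv_select = c("mccv", "fixed"),
                                n_lv = 10, mccv = list(), threshold_c = 0) {
  lv_select <- match.arg(lv_select)
  stopifnot(inherits(plan, "decomposition_plan"))
  if (!"label" %in% names(s)) rlang::abort("Training spectra need labels.")
  missing_cls <- setdiff(plan$classes, unique(s$label))
  if (length(missing_cls) > 0) {
    rlang::abort(paste("Classes absent from training data:",
                       paste(missing_cls, collapse = ", ")))
  }
  mset <- utils::modifyList(list(n_splits = 30, holdout_fraction = 0.2,
                                 seed = 1), mccv)
  X <- spectra_matrix(s)
  labels <- s$label
  models <- vector("list", nrow(plan$tasks))
  lvs <- integer(nrow(plan$tasks))
  ermccv <- rep(NA_real_, nrow(plan$tasks))
  for (j in seq_len(nrow(plan$tasks))) {
    gp <- plan$tasks$positive[[j]]
    gn <- plan$tasks$negative[[j]]
    in_task <- labels %in% c(gp, gn)
    y <- ifelse(labels[in_task] %in% gp, 1, -1)
    Xt <- X[in_task, , drop = FALSE]
    lv_cap <- min(n_lv, sum(in_task) - 2, ncol(Xt))
    if (lv_select == "mccv") {
      sel <- mccv_select_lvs(Xt, y, max_lv = lv_cap,
                             n_splits = mset$n_splits,
                             holdout_fraction = mset$holdout_fraction,
                             seed = mset$seed + j,
                             threshold_c = threshold_c)
      lvs[j] <- sel$chosen_lv
      ermccv[j] <- sel$chosen_ermccv
    } else {
      lvs[j] <- lv_cap
    }
    models[[j]] <- fit_pls(Xt, y, n_lv = lvs[j], threshold_c = threshold_c)
  }
  structure(list(
    plan = plan,
    models = models,
    classes = plan$classes,
    threshold_c = threshold_c,
    lvs = lvs,
    mean_lv = mean(lvs),
    ermccv = ermccv,
    mean_ermccv = if (all(is.na(ermccv))) NA_real_ else mean(ermccv),
    lv_select = lv_select,
    mccv_settings = mset,
    training = s
  ), class = "multiclass_plsda")
}

#' @export
print.multiclass_plsda <- function(x, ...) {
  cat(sprintf("<multiclass_plsda> %s, %d classes, %d binary model(s), mean LVs %.2f\n",
              x$plan$strategy, length(x$classes), length(x$models), x$mean_lv))
  invisible(x)
}

#' @export
glance.multiclass_plsda <- function(x, ...) {
  tibble::tibble(strategy = x$plan$strategy, k = length(x$classes),
                 n_models = length(x$models), mean_lv = x$mean_lv,
                 mean_ermccv = x$mean_ermccv, threshold_c = x$threshold_c)
}

#' @export
tidy.multiclass_plsda <- function(x, ...) {
  dplyr::mutate(tidy(x$plan), n_lv = x$lvs, ermccv = x$ermccv)
}

#' Vote-based multiclass prediction
#'
#' Aggregates the binary models of a [train_decomposition()] fit:
#'
#' * **OAO** — each pairwise model votes for one of its two classes; the class
#'   with the most votes wins.
#' * **EPHAH** — a response at or above the threshold casts one vote for every
#'   class of the task's positive group, otherwise for every class of the
#'   negative group; maximum-win voting picks the class.
#' * **OAA** — no voting: the class whose model gives the largest response
#'   wins.
#'
#' Vote ties (OAO/EPHAH) are resolved by [resolve_ties()]: a sub-decomposition
#' restricted to the tied classes is trained and re-voted, with a
#' deterministic response-margin fallback.
#'
#' @param model a `multiclass_plsda`.
#' @param s an `nir_spectra` tibble (or matrix) to classify.
#' @param resolve_tie whether to run the recursive tie-breaker (OAO/EPHAH).
#' @return A list with `predictions` (tibble: `sample_id`, `predicted`,
#'   `n_votes`, `tie`) and `votes` (samples x classes count matrix; for OAA,
#'   the response matrix).
#' @export
vote <- function(model, s, resolve_tie = TRUE) {
  stopifnot(inherits(model, "multiclass_plsda"))
  X <- as_X(s)
  ids <- if (is.data.frame(s)) s$sample_id else rownames(X) %||%
    paste0("s", seq_len(nrow(X)))
  k <- length(model$classes)
  n <- nrow(X)
  resp <- vapply(model$models, function(m) predict_response(m, X), numeric(n))
  resp <- matrix(resp, nrow = n)
  votes <- matrix(0, n, k, dimnames = list(ids, model$classes))
  if (model$plan$strategy == "OAA") {
    # maximum-response rule: the votes matrix holds the raw responses
    votes <- resp
    colnames(votes) <- vapply(model$plan$tasks$positive, `[[`, "", 1)
    votes <- votes[, model$classes, drop = FALSE]
    win <- model$classes[apply(votes, 1, which.max)]
    pred <- tibble::tibble(sample_id = ids, predicted = win,
                           n_votes = apply(votes, 1, max), tie = FALSE)
    return(list(predictions = pred, votes = votes))
  }
  for (j in seq_len(nrow(model$plan$tasks))) {
    gp <- model$plan$tasks$positive[[j]]
    gn <- model$plan$tasks$negative[[j]]
    hit <- resp[, j] >= model$threshold_c
    votes[hit, gp] <- votes[hit, gp, drop = FALSE] + 1
    votes[!hit, gn] <- votes[!hit, gn, drop = FALSE] + 1
  }
  top <- apply(votes, 1, max)
  tie <- rowSums(votes == top) > 1
  win <- model$classes[apply(votes, 1, which.max)]
  if (resolve_tie && any(tie)) {
    cache <- new.env(parent = emptyenv())
    for (i in which(tie)) {
      tied <- model$classes[votes[i, ] == top[i]]
      win[i] <- resolve_ties(model, tied, X[i, , drop = FALSE], cache = cache)
    }
  }
  pred <- tibble::tibble(sample_id = ids, predicted = win,
                         n_votes = top, tie = tie)
  list(predictions = pred, votes = votes)
}

#' @export
predict.multiclass_plsda <- function(object, newdata, ...) {
  vote(object, newdata, ...)$predictions
}

#' Resolve a vote tie among classes
#'
#' Trains (lazily, cached per tied-class subset) a sub-decomposition of the
#' same strategy restricted to the tied classes on the stored training data,
#' and re-votes the sample. If the sub-vote ties again the recursion continues
#' to `depth`; a persistent tie falls back to the largest mean response margin
#' in favour of each class, then to class order.
#'
#' @param model a `multiclass_plsda` fitted with training data retained.
#' @param tied_classes character vector of tied class names (length >= 2).
#' @param X_row a single-row matrix, the sample to classify.
#' @param depth remaining recursion depth.
#' @param cache environment used to memoise sub-models.
#' @return The winning class name.
#' @export
resolve_ties <- function(model, tied_classes, X_row, depth = 2,
                         cache = new.env(parent = emptyenv())) {
  stopifnot(length(tied_classes) >= 2)
  if (depth <= 0 || is.null(model$training)) {
    return(margin_fallback(model, tied_classes, X_row))
  }
  if (length(tied_classes) == 2 || model$plan$strategy == "OAA") {
    sub_plan <- plan_oao(tied_classes)
  } else {
    sub_plan <- switch(model$plan$strategy,
                       OAO = plan_oao(tied_classes),
                       EPHAH = plan_ephah(tied_classes))
  }
  key <- paste(sort(tied_classes), collapse = "\r")
  sub <- cache[[key]]
  if (is.null(sub)) {
    tr <- model$training[model$training$label %in% tied_classes, , drop = FALSE]
    sub <- train_decomposition(tr, sub_plan, lv_select = model$lv_select,
                               n_lv = max(model$lvs),
                               mccv = model$mccv_settings,
                               threshold_c = model$threshold_c)
    cache[[key]] <- sub
  }
  v <- vote(sub, X_row, resolve_tie = FALSE)
  top <- max(v$votes[1, ])
  winners <- sub$classes[v$votes[1, ] == top]
  if (length(winners) == 1) return(winners)
  if (length(winners) < length(tied_classes)) {
    return(resolve_ties(model, winners, X_row, depth = depth - 1, cache = cache))
  }
  margin_fallback(model, tied_classes, X_row)
}

# deterministic fallback: mean signed response margin in favour of each class
margin_fallback <- function(model, tied_classes, X_row) {
  resp <- vapply(model$models, function(m) predict_response(m, X_row)[1],
                 numeric(1))
  margins <- vapply(tied_classes, function(cl) {
    vals <- c()
    for (j in seq_len(nrow(model$plan$tasks))) {
      gp <- model$plan$tasks$positive[[j]]
      gn <- model$plan$tasks$negative[[j]]
      if (cl %in% gp) vals <- c(vals, resp[j] - model$threshold_c)
      else if (cl %in% gn) vals <- c(vals, model$threshold_c - resp[j])
    }
    mean(vals)
  }, numeric(1))
  best <- which(margins == max(margins))
  tied_classes[best[1]]  # class order breaks exact margin ties
}

#' Evaluate a multiclass model on labelled spectra
#'
#' @param model a `multiclass_plsda`.
#' @param s labelled `nir_spectra` test set.
#' @return A list of class `classification_eval`: `accuracy` (tibble from
#'   [classification_accuracy()]), `confusion` (truth x predicted counts) and
#'   the per-sample `predictions`.
#' @export
evaluate_model <- function(model, s) {
  if (!"label" %in% names(s)) rlang::abort("Evaluation needs labelled spectra.")
  pred <- vote(model, s)$predictions
  truth <- factor(s$label, levels = model$classes)
  predicted <- factor(pred$predicted, levels = model$classes)
  conf <- table(truth = truth, predicted = predicted)
  acc <- classification_accuracy(sum(pred$predicted == s$label), nrow(s))
  structure(list(accuracy = acc, confusion = conf,
                 predictions = dplyr::mutate(pred, truth = s$label),
                 strategy = model$plan$strategy),
            class = "classification_eval")
}

#' @export
print.classification_eval <- function(x, ...) {
  cat(sprintf("<classification_eval> %s: accuracy %.4f (%d/%d)\n",
              x$strategy, x$accuracy$accuracy, x$accuracy$n_correct,
              x$accuracy$n_total))
  invisible(x)
}

#' @export
glance.classification_eval <- function(x, ...) {
  dplyr::mutate(x$accuracy, strategy = x$strategy, .before = 1)
}

#' @export
tidy.classification_eval <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$confusion, responseName = "n"))
}

#' @export
autoplot.classification_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Predicted class", y = "True class", fill = "Count") +
    ggplot2::theme_minimal()
}
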