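#' Kennard-Stone sample selection
#'
#' Classic max-min Euclidean coverage design: start from the two mutually
#' farthest samples, then repeatedly add the sample whose minimum distance to
#' the already-selected set is largest. Distance ties are broken by the lowest
#' sample index, making the selection deterministic and invariant to row
#' order up to that rule.
#'
#' @param s an `nir_spectra` tibble or numeric matrix.
#' @param n_select number of samples to select, between 2 and `n`.
#' @param dist_matrix optional precomputed distance matrix (used by SPXY).
#' @return Character vector of selected `sample_id`s (row indices as strings
#'   when `s` is a bare matrix).
#' @export
kennard_stone <- function(s, n_select, dist_matrix = NULL) {
  X <- as_X(s)
  ids <- if (is.data.frame(s)) s$sample_id else
    rownames(X) %||% as.character(seq_len(nrow(X)))
  n <- nrow(X)
  if (n_select < 2 || n_select > n) {
    rlang::abort("`n_select` must be between 2 and the number of samples.")
  }
  D <- if (is.null(dist_matrix)) as.matrix(stats::dist(X)) else dist_matrix
  # farthest pair, lowest-index tie-break via row-major which()
  far <- which(D == max(D), arr.ind = TRUE)
  first <- sort(far[1, ])
  sel <- c(first[1], first[2])
  remaining <- setdiff(seq_len(n), sel)
  while (length(sel) < n_select) {
    mind <- apply(D[remaining, sel, drop = FALSE], 1, min)
    pick <- remaining[which.max(mind)]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  ids[sel]
}

new_split <- function(s, train_ids, val_ids, test_ids, method, params = list(),
                      seed = NULL) {
  out <- tibble::tibble(
    sample_id = s$sample_id,
    label = if ("label" %in% names(s)) s$label else NA_character_,
    set = dplyr::case_when(
      s$sample_id %in% train_ids ~ "train",
      s$sample_id %in% val_ids ~ "val",
      TRUE ~ "test"
    )
  )
  attr(out, "method") <- method
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("split_result", class(tibble::tibble()))
  out
}

#' Extract the ids of one partition of a split
#'
#' @param split a `split_result` tibble.
#' @param set one of `"train"`, `"val"`, `"test"`.
#' @return Character vector of sample ids.
#' @export
split_ids <- function(split, set = c("train", "val", "test")) {
  set <- match.arg(set)
  split$sample_id[split$set == set]
}

#' Subset spectra to one partition of a split
#'
#' @param s the `nir_spectra` tibble the split was computed from.
#' @inheritParams split_ids
#' @return An `nir_spectra` tibble.
#' @export
split_spectra <- function(s, split, set = c("train", "val", "test")) {
  s[s$sample_id %in% split_ids(split, set), , drop = FALSE]
}

#' SPXY train/test partitioning
#'
#' Kennard-Stone selection on the joint X-y distance
#' `d(i, j) = d_x(i, j) / max(d_x) + d_y(i, j) / max(d_y)`, both Euclidean;
#' class labels are one-hot encoded for the response distance. Selected
#' samples form the training set.
#'
#' @param s an `nir_spectra` tibble.
#' @param y response values or class labels; defaults to the `label` column.
#' @param train_fraction fraction of samples selected for training, in (0, 1).
#' @param .jitter internal: list(seed, scale) of a multiplicative distance
#'   perturbation, used by [spxy_rounds()].
#' @return A `split_result` tibble (no validation partition).
#' @export
spxy_split <- function(s, y = NULL, train_fraction = 0.7, .jitter = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (is.null(y)) {
    if (!"label" %in% names(s)) rlang::abort("No `y` given and no labels present.")
    y <- s$label
  }
  X <- spectra_matrix(s)
  Dx <- as.matrix(stats::dist(X))
  if (max(Dx) == 0) rlang::abort("All spectra identical: SPXY distance undefined.")
  Y <- if (is.numeric(y)) {
    matrix(y, ncol = 1)
  } else if (length(unique(y)) < 2) {
    matrix(0, nrow(s), 1)  # constant response: the y-distance term vanishes
  } else {
    stats::model.matrix(~ f - 1, data.frame(f = factor(y)))
  }
  Dy <- as.matrix(stats::dist(Y))
  D <- Dx / max(Dx) + if (max(Dy) > 0) Dy / max(Dy) else 0
  if (!is.null(.jitter)) {
    D <- withr_seed(.jitter$seed, {
      J <- matrix(stats::runif(length(D), 1 - .jitter$scale,
                               1 + .jitter$scale), nrow(D))
      D * (J + t(J)) / 2
    })
  }
  n_train <- max(2L, round(train_fraction * nrow(s)))
  train_ids <- kennard_stone(s, n_train, dist_matrix = D)
  new_split(s, train_ids, character(0),
            setdiff(s$sample_id, train_ids),
            method = "spxy", params = list(train_fraction = train_fraction))
}

#' Repeated SPXY partitioning with seeded distance jitter
#'
#' The SPXY selection is deterministic, so repeated "rounds" are generated by
#' perturbing the joint distance matrix with a tiny seeded multiplicative
#' jitter (relative scale `jitter`) before each selection — enough to flip
#' near-ties between candidates while leaving clear-cut selections alone.
#'
#' @inheritParams spxy_split
#' @param rounds number of perturbed repetitions.
#' @param seed integer seed for the jitter stream.
#' @param jitter relative scale of the distance perturbation.
#' @return A list of `split_result` tibbles, one per round.
#' @export
spxy_rounds <- function(s, y = NULL, train_fraction = 0.7, rounds = 100,
                        seed = 1, jitter = 1e-6) {
  lapply(seq_len(rounds), function(r) {
    spxy_split(s, y = y, train_fraction = train_fraction,
               .jitter = list(seed = substream(seed, r), scale = jitter))
  })
}

# per-class 6:2:2 counts: floor for train, remainder split evenly between
# val and test, an odd remainder going to val
stratified_counts <- function(n_c, ratios) {
  n_train <- floor(ratios[1] * n_c)
  rem <- n_c - n_train
  n_val <- ceiling(rem / 2)
  c(train = n_train, val = n_val, test = rem - n_val)
}

#' Stratified DUPLEX partitioning into train / validation / test
#'
#' Within each class the per-set counts follow the floor/even-remainder rule:
#' `n_train = floor(train_ratio * n_c)`, with the remainder split evenly
#' between validation and test (an odd remainder favouring validation). The
#' within-class assignment alternates DUPLEX-style over the three sets in
#' round-robin order: each set is seeded with the most mutually distant
#' remaining pair, then takes the remaining sample farthest from its current
#' members, until its quota is filled.
#'
#' @param s a labelled `nir_spectra` tibble; every class needs >= 3 samples.
#' @param ratios numeric length-3 `(train, val, test)` summing to 1.
#' @return A `split_result` tibble.
#' @export
duplex_stratified <- function(s, ratios = c(0.6, 0.2, 0.2)) {
  stopifnot(length(ratios) == 3, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-8)
  if (!"label" %in% names(s)) rlang::abort("DUPLEX stratification requires labels.")
  sets <- list(train = character(0), val = character(0), test = character(0))
  for (cl in class_levels(s)) {
    sub <- s[s$label == cl, , drop = FALSE]
    if (nrow(sub) < 3) {
      rlang::abort(sprintf("Class '%s' has fewer than 3 samples.", cl))
    }
    quota <- stratified_counts(nrow(sub), ratios)
    D <- as.matrix(stats::dist(spectra_matrix(sub)))
    assigned <- setNames(rep(NA_character_, nrow(sub)), sub$sample_id)
    remaining <- seq_len(nrow(sub))
    members <- list(train = integer(0), val = integer(0), test = integer(0))
    cycle <- c("train", "val", "test")
    repeat {
      done <- TRUE
      for (tgt in cycle) {
        if (length(members[[tgt]]) >= quota[tgt] || length(remaining) == 0) next
        done <- FALSE
        if (length(members[[tgt]]) == 0 && length(remaining) >= 2 &&
            quota[tgt] >= 2) {
          # seed with the most distant remaining pair
          Dr <- D[remaining, remaining, drop = FALSE]
          far <- which(Dr == max(Dr), arr.ind = TRUE)
          pick <- remaining[sort(far[1, ])]
        } else {
          ref <- if (length(members[[tgt]]) > 0) members[[tgt]] else remaining[1]
          mind <- apply(D[remaining, ref, drop = FALSE], 1, min)
          pick <- remaining[which.max(mind)]
        }
        pick <- pick[seq_len(min(length(pick), quota[tgt] - length(members[[tgt]])))]
        members[[tgt]] <- c(members[[tgt]], pick)
        remaining <- setdiff(remaining, pick)
      }
      if (done || length(remaining) == 0) break
    }
    # anything left (quota rounding) goes to train
    members$train <- c(members$train, remaining)
    for (tgt in cycle) {
      sets[[tgt]] <- c(sets[[tgt]], sub$sample_id[members[[tgt]]])
    }
  }
  new_split(s, sets$train, sets$val, sets$test,
            method = "duplex", params = list(ratios = ratios))
}

#' Seeded random partitioning
#'
#' Uniform shuffle then cut, stratified by class label when labels are
#' present.
#'
#' @param s an `nir_spectra` tibble.
#' @param fractions numeric length-3 `(train, val, test)` summing to 1
#'   (entries may be 0).
#' @param seed integer seed.
#' @return A `split_result` tibble.
#' @export
random_split <- function(s, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  strata <- if ("label" %in% names(s)) split(s$sample_id, s$label) else
    list(all = s$sample_id)
  withr_seed(seed, {
    sets <- list(train = character(0), val = character(0), test = character(0))
    for (ids in strata) {
      ids <- sample(ids)
      n <- length(ids)
      n_train <- round(fractions[1] * n)
      n_val <- round(fractions[2] * n)
      n_val <- min(n_val, n - n_train)
      sets$train <- c(sets$train, ids[seq_len(n_train)])
      sets$val <- c(sets$val, ids[seq_len(n_val) + n_train])
      if (n_train + n_val < n) {
        sets$test <- c(sets$test, ids[(n_train + n_val + 1):n])
      }
    }
    new_split(s, sets$train, sets$val, sets$test,
              method = "random", params = list(fractions = fractions),
              seed = seed)
  })
}

#' @export
glance.split_result <- function(x, ...) {
  counts <- table(x$set)
  tibble::tibble(method = attr(x, "method"),
                 n_train = sum(x$set == "train"),
                 n_val = sum(x$set == "val"),
                 n_test = sum(x$set == "test"))
}

#' Per-class partition counts of a split
#'
#' @param split a `split_result` tibble.
#' @return A tibble with one row per class and columns `train`, `val`, `test`.
#' @export
split_counts <- function(split) {
  df <- tibble::as_tibble(split)
  df$label <- factor(df$label, levels = unique(df$label))
  df$set <- factor(df$set, levels = c("train", "val", "test"))
  tidyr::pivot_wider(dplyr::count(df, .data$label, .data$set,
                                  .drop = FALSE),
                     names_from = "set", values_from = "n",
                     values_fill = 0L)
}
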