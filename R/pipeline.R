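#' End-to-end run configuration
#'
#' Bundles every stage's settings for [run_pipeline()]: simulation, outlier
#' screening, partitioning, pretreatment, interval selection, decomposition
#' strategies and latent-variable selection. Fully determines a run together
#' with its root seed (all stage seeds are derived from it).
#'
#' @param simulation a [sim_config()].
#' @param pipeline pretreatment pipeline name (see [parse_pipeline_name()]).
#' @param outlier_alpha confidence level for outlier cutoffs; `NULL` skips
#'   screening.
#' @param outlier_policy removal policy for [screen_outliers()].
#' @param pca_p fixed component count for outlier PCA (`NULL` = automatic).
#' @param split_method `"duplex"`, `"spxy"` or `"random"`.
#' @param split_ratios length-3 ratios for duplex/random splits.
#' @param sipls list with `k`, `j`, `lv_max`, or `NULL` to model the full
#'   spectrum.
#' @param strategies decomposition strategies to train and compare.
#' @param lv_select `"mccv"` or `"fixed"` (see [train_decomposition()]).
#' @param n_lv fixed LV count or MCCV candidate maximum.
#' @param mccv MCCV settings list.
#' @param seed root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(),
                       pipeline = "SNV+SG-17+2D",
                       outlier_alpha = 0.95,
                       outlier_policy = "either",
                       pca_p = NULL,
                       split_method = c("duplex", "spxy", "random"),
                       split_ratios = c(0.6, 0.2, 0.2),
                       sipls = NULL,
                       strategies = c("OAO", "OAA", "EPHAH"),
                       lv_select = "mccv",
                       n_lv = 10,
                       mccv = list(),
                       seed = 1) {
  split_method <- match.arg(split_method)
  strategies <- match.arg(strategies, c("OAO", "OAA", "EPHAH"),
                          several.ok = TRUE)
  structure(list(
    simulation = simulation, pipeline = pipeline,
    outlier_alpha = outlier_alpha, outlier_policy = outlier_policy,
    pca_p = pca_p, split_method = split_method, split_ratios = split_ratios,
    sipls = sipls, strategies = strategies, lv_select = lv_select,
    n_lv = n_lv, mccv = mccv, seed = as.integer(seed)
  ), class = "run_config")
}

planner_for <- function(strategy) {
  switch(strategy, OAO = plan_oao, OAA = plan_oaa, EPHAH = plan_ephah,
         rlang::abort(sprintf("Unknown strategy '%s'.", strategy)))
}

#' Run the full classification workflow on synthetic spectra
#'
#' Stages, in order: simulate spectra (outliers included per the simulation
#' config); screen and remove abnormal samples; partition into train /
#' validation / test; fit the pretreatment pipeline on the training set and
#' apply it to all partitions; optionally restrict to SI-PLS-selected
#' intervals (searched on the training set); train each requested
#' decomposition strategy; evaluate on the test partition.
#'
#' @param cfg a [run_config()].
#' @param spectra optional pre-made labelled `nir_spectra` tibble; when given
#'   the simulation stage is skipped.
#' @param verbose print per-stage progress.
#' @return A list of class `comparison_report`: `results` tibble (one row per
#'   strategy), `evaluations`, `models`, `outliers`, `split`, `intervals`,
#'   `config`.
#' @export
run_pipeline <- function(cfg, spectra = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(spectra)) {
    say("simulating %d spectra", sum(cfg$simulation$samples_per_class))
    spectra <- simulate_study(cfg$simulation)$spectra
  }
  report_outliers <- NULL
  if (!is.null(cfg$outlier_alpha)) {
    say("screening outliers (alpha = %.2f)", cfg$outlier_alpha)
    report_outliers <- screen_outliers(spectra, alpha = cfg$outlier_alpha,
                                       policy = cfg$outlier_policy,
                                       p = cfg$pca_p)
    spectra <- remove_outliers(spectra, report_outliers)
    say("  removed %d of %d samples", sum(report_outliers$removed),
        nrow(report_outliers))
  }
  say("splitting (%s)", cfg$split_method)
  split <- switch(cfg$split_method,
    duplex = duplex_stratified(spectra, cfg$split_ratios),
    spxy = spxy_split(spectra, train_fraction = cfg$split_ratios[1]),
    random = random_split(spectra, cfg$split_ratios,
                          seed = substream(cfg$seed, 11)))
  train <- split_spectra(spectra, split, "train")
  test <- split_spectra(spectra, split, "test")
  if (nrow(test) == 0) rlang::abort("Split produced an empty test set.")
  say("pretreating ('%s')", cfg$pipeline)
  pp <- parse_pipeline_name(cfg$pipeline)
  train_pp <- apply_pipeline(train, pp)
  test_pp <- apply_pipeline(test, pp, fit_context = train)
  intervals <- NULL
  if (!is.null(cfg$sipls)) {
    say("selecting %d of %d intervals", cfg$sipls$j, cfg$sipls$k)
    # search on a one-vs-rest coding of the first class: a single global
    # search keeps the end-to-end run cheap; per-task searches are available
    # through sipls_search() directly
    y <- ifelse(train_pp$label == class_levels(train_pp)[1], 1, -1)
    intervals <- sipls_search(train_pp, y, cfg$sipls$k, cfg$sipls$j,
                              lv_max = cfg$sipls$lv_max %||% 10,
                              seed = substream(cfg$seed, 12))
    cols <- interval_columns(intervals$grid, intervals$best_combo)
    keep <- c(meta_cols(train_pp), spectral_cols(train_pp)[cols])
    train_pp <- train_pp[keep]
    test_pp <- test_pp[keep]
    class(train_pp) <- c("nir_spectra", class(tibble::tibble()))
    class(test_pp) <- c("nir_spectra", class(tibble::tibble()))
  }
  evaluations <- list()
  models <- list()
  for (st in cfg$strategies) {
    say("training %s", st)
    plan <- planner_for(st)(class_levels(train_pp))
    models[[st]] <- train_decomposition(
      train_pp, plan, lv_select = cfg$lv_select, n_lv = cfg$n_lv,
      mccv = utils::modifyList(list(seed = substream(cfg$seed, 13)), cfg$mccv))
    evaluations[[st]] <- evaluate_model(models[[st]], test_pp)
  }
  results <- dplyr::bind_rows(lapply(cfg$strategies, function(st) {
    dplyr::bind_cols(
      glance(evaluations[[st]])[, c("strategy", "n_correct", "n_total",
                                    "accuracy")],
      tibble::tibble(mean_lv = models[[st]]$mean_lv,
                     mean_ermccv = models[[st]]$mean_ermccv,
                     n_models = length(models[[st]]$models))
    )
  }))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(list(results = results, evaluations = evaluations,
                 models = models, outliers = report_outliers,
                 split = split, intervals = intervals, config = cfg),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$results)
  invisible(x)
}

#' @export
tidy.comparison_report <- function(x, ...) x$results

#' Serialise a comparison report
#'
#' @param r a `comparison_report`.
#' @param path output file path.
#' @param format `"json"`, `"tsv"` or `"markdown"`; `"tsv"`/`"markdown"`
#'   write the per-strategy results table, `"json"` additionally includes the
#'   confusion matrices and removed-outlier ids.
#' @return `path`, invisibly.
#' @export
render_report <- function(r, path, format = c("json", "tsv", "markdown")) {
  format <- match.arg(format)
  res <- r$results
  if (format == "json") {
    payload <- list(
      results = res,
      confusion = lapply(r$evaluations, function(e) unclass(e$confusion)),
      removed_outliers = if (!is.null(r$outliers)) {
        r$outliers$sample_id[r$outliers$removed]
      } else character(0),
      intervals = if (!is.null(r$intervals)) glance(r$intervals) else NULL
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (format == "tsv") {
    utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- paste(names(res), collapse = " | ")
    sep <- paste(rep("---", ncol(res)), collapse = " | ")
    rows <- apply(res, 1, function(row) paste(row, collapse = " | "))
    writeLines(c(paste("|", hdr, "|"), paste("|", sep, "|"),
                 paste("|", rows, "|")), path)
  }
  invisible(path)
}
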