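# build a pls_binary stub whose response is an affine function of X
stub_binary <- function(p, coef = rep(0, p), y_mean = 0) {
  structure(list(x_mean = rep(0, p), y_mean = y_mean,
                 coef = coef, coef_by_lv = matrix(coef, ncol = 1),
                 n_lv = 1L, threshold_c = 0,
                 scores = matrix(0, 1, 1)),
            class = "pls_binary")
}

stub_multiclass <- function(plan, p, coefs = NULL, y_means = NULL) {
  nt <- nrow(plan$tasks)
  if (is.null(coefs)) coefs <- replicate(nt, rep(0, p), simplify = FALSE)
  if (is.null(y_means)) y_means <- rep(0, nt)
  structure(list(plan = plan,
                 models = lapply(seq_len(nt), function(j) {
                   stub_binary(p, coefs[[j]], y_means[j])
                 }),
                 classes = plan$classes, threshold_c = 0,
                 lvs = rep(1L, nt), mean_lv = 1, lv_select = "fixed",
                 mccv_settings = list(), training = NULL),
            class = "multiclass_plsda")
}

test_that("task counts follow the combinatorial formulas for k = 2..12", {
  for (k in 2:12) {
    cls <- paste0("C", seq_len(k))
    expect_equal(nrow(plan_oao(cls)$tasks), k * (k - 1) / 2)
    expect_equal(nrow(plan_oaa(cls)$tasks), k)
    expected <- if (k %% 2 == 0) choose(k, k / 2) / 2 else
      choose(k, ceiling(k / 2))
    expect_equal(nrow(plan_ephah(cls)$tasks), expected)
  }
  # the printed large-class-number counts
  cls10 <- paste0("C", 1:10)
  expect_equal(nrow(plan_oao(cls10)$tasks), 45)
  expect_equal(nrow(plan_oaa(cls10)$tasks), 10)
  expect_equal(nrow(plan_ephah(cls10)$tasks), 126)
  expect_equal(nrow(plan_ephah(paste0("C", 1:6))$tasks), 10)
  expect_error(plan_oao("A"), "at least 2")
})

test_that("plans have disjoint, valid groups with no duplicate or complement tasks", {
  for (k in c(3, 4, 6, 7)) {
    cls <- paste0("C", seq_len(k))
    for (plan in list(plan_oao(cls), plan_oaa(cls), plan_ephah(cls))) {
      task_keys <- character(0)
      pos_keys <- character(0)
      for (j in seq_len(nrow(plan$tasks))) {
        gp <- plan$tasks$positive[[j]]
        gn <- plan$tasks$negative[[j]]
        expect_length(intersect(gp, gn), 0)
        expect_true(all(c(gp, gn) %in% cls))
        key <- paste(paste(sort(gp), collapse = ","),
                     paste(sort(gn), collapse = ","), sep = "||")
        expect_false(key %in% task_keys)
        task_keys <- c(task_keys, key)
        if (plan$strategy == "EPHAH") {
          expect_true(abs(length(gp) - length(gn)) <= 1)
          expect_setequal(c(gp, gn), cls)
          if (k %% 2 == 0) {
            # no task's positive group is another's complement
            expect_false(paste(sort(gn), collapse = ",") %in% pos_keys)
          }
          pos_keys <- c(pos_keys, paste(sort(gp), collapse = ","))
        }
      }
    }
  }
  # k = 3 enumerates the three balanced bipartitions
  p3 <- tidy(plan_ephah(c("a", "b", "c")))
  expect_setequal(p3$positive, c("a|b", "a|c", "b|c"))
})

test_that("EPHAH voting with an error-free oracle yields the expected tallies", {
  cls <- paste0("C", 1:6)
  plan <- plan_ephah(cls)
  # an oracle that always decides for the side containing class 1: with the
  # first class pinned to the positive group, every response is +1
  model <- stub_multiclass(plan, p = 4, y_means = rep(1, 10))
  X <- matrix(0, 1, 4)
  v <- vote(model, X, resolve_tie = FALSE)
  expect_equal(unname(v$votes[1, ]), c(10, 4, 4, 4, 4, 4))
  expect_equal(v$predictions$predicted, "C1")

  # oracle favouring class 3: respond +1 exactly when C3 is positive
  y3 <- ifelse(vapply(plan$tasks$positive, function(g) "C3" %in% g,
                      logical(1)), 1, -1)
  m3 <- stub_multiclass(plan, p = 4, y_means = y3)
  v3 <- vote(m3, X, resolve_tie = FALSE)
  expect_equal(unname(v3$votes[1, "C3"]), 10)
  expect_equal(sort(unname(v3$votes[1, ]), decreasing = TRUE),
               c(10, 4, 4, 4, 4, 4))
  expect_equal(v3$predictions$predicted, "C3")
})

test_that("vote tallies match a direct per-definition aggregation oracle", {
  set.seed(11)
  cls <- paste0("C", 1:4)
  p <- 6
  for (plan in list(plan_oao(cls), plan_ephah(cls))) {
    nt <- nrow(plan$tasks)
    coefs <- replicate(nt, rnorm(p), simplify = FALSE)
    y_means <- rnorm(nt, sd = 0.2)
    model <- stub_multiclass(plan, p, coefs, y_means)
    X <- matrix(rnorm(8 * p), 8, p)
    v <- vote(model, X, resolve_tie = FALSE)
    resp <- sapply(seq_len(nt), function(j) X %*% coefs[[j]] + y_means[j])
    expected <- matrix(0, 8, 4, dimnames = list(NULL, cls))
    for (j in seq_len(nt)) {
      gp <- plan$tasks$positive[[j]]
      gn <- plan$tasks$negative[[j]]
      for (i in 1:8) {
        side <- if (resp[i, j] >= 0) gp else gn
        expected[i, side] <- expected[i, side] + 1
      }
    }
    expect_equal(unname(v$votes), unname(expected))
    expect_equal(v$predictions$predicted,
                 cls[apply(expected, 1, which.max)])
  }
})

test_that("trained decompositions separate well-spaced classes and report mean LVs", {
  s <- toy_spectra(n_classes = 3, samples_per_class = 10, separation = 0.2,
                   noise_sd = 0.002, n_points = 80)
  for (planner in list(plan_oao, plan_oaa, plan_ephah)) {
    plan <- planner(class_levels(s))
    m <- train_decomposition(s, plan, lv_select = "fixed", n_lv = 3)
    expect_equal(length(m$models), nrow(plan$tasks))
    expect_equal(m$mean_lv, mean(m$lvs))
    ev <- evaluate_model(m, s)
    expect_equal(ev$accuracy$accuracy, 1)
    # confusion row sums equal per-class counts
    expect_equal(unname(rowSums(ev$confusion)),
                 unname(as.vector(table(factor(s$label, levels = m$classes)))))
  }
  # EPHAH on k = 4 builds 3 tasks, each trained on every sample
  s4 <- toy_spectra(n_classes = 4, samples_per_class = 6, n_points = 60)
  plan4 <- plan_ephah(class_levels(s4))
  expect_equal(nrow(plan4$tasks), 3)
  m4 <- train_decomposition(s4, plan4, lv_select = "fixed", n_lv = 2)
  for (bm in m4$models) expect_equal(nrow(bm$scores), nrow(s4))
})

test_that("predictions are equivariant under class relabeling", {
  s <- toy_spectra(n_classes = 3, samples_per_class = 8, separation = 0.15,
                   noise_sd = 0.003, n_points = 60)
  relab <- c(C1 = "Z", C2 = "Q", C3 = "M")
  s2 <- s
  s2$label <- unname(relab[s$label])
  for (planner in list(plan_oao, plan_oaa, plan_ephah)) {
    m1 <- train_decomposition(s, planner(c("C1", "C2", "C3")),
                              lv_select = "fixed", n_lv = 2)
    m2 <- train_decomposition(s2, planner(c("Z", "Q", "M")),
                              lv_select = "fixed", n_lv = 2)
    p1 <- vote(m1, s)$predictions$predicted
    p2 <- vote(m2, s2)$predictions$predicted
    expect_equal(unname(relab[p1]), p2)
  }
})

test_that("tie resolution is deterministic and a no-op without ties", {
  s <- toy_spectra(n_classes = 4, samples_per_class = 8, separation = 0.1,
                   noise_sd = 0.005, n_points = 60)
  plan <- plan_oao(class_levels(s))
  m <- train_decomposition(s, plan, lv_select = "fixed", n_lv = 2)
  # without ties, resolution leaves winners unchanged
  v0 <- vote(m, s, resolve_tie = FALSE)
  v1 <- vote(m, s, resolve_tie = TRUE)
  no_tie <- !v0$predictions$tie
  expect_equal(v0$predictions$predicted[no_tie],
               v1$predictions$predicted[no_tie])

  # a two-way tie resolves to one of the tied classes, reproducibly
  row <- spectra_matrix(s)[1, , drop = FALSE]
  r1 <- resolve_ties(m, c("C1", "C2"), row)
  r2 <- resolve_ties(m, c("C1", "C2"), row)
  expect_identical(r1, r2)
  expect_true(r1 %in% c("C1", "C2"))
  # three-way ties too
  r3 <- resolve_ties(m, c("C1", "C2", "C3"), row)
  expect_true(r3 %in% c("C1", "C2", "C3"))
})

test_that("accuracy rises from chance to one as class separation grows", {
  accs <- vapply(c(0, 0.3), function(sep) {
    mean(vapply(1:3, function(seed) {
      s <- toy_spectra(n_classes = 4, samples_per_class = 8, separation = sep,
                       noise_sd = 0.01, n_points = 60, seed = seed)
      tr <- duplex_stratified(s, c(0.6, 0.2, 0.2))
      m <- train_decomposition(split_spectra(s, tr, "train"),
                               plan_ephah(class_levels(s)),
                               lv_select = "fixed", n_lv = 2)
      evaluate_model(m, split_spectra(s, tr, "test"))$accuracy$accuracy
    }, numeric(1)))
  }, numeric(1))
  # chance level for 4 classes is 0.25; separable data reaches 1
  expect_lt(accs[1], 0.7)
  expect_equal(accs[2], 1)
})
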