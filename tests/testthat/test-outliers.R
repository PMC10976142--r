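test_that("fit_pca recovers exact low-rank structure and matches an eigen oracle", {
  set.seed(2)
  # points exactly in a 2-plane embedded in 12 dims
  B <- qr.Q(qr(matrix(rnorm(24), 12, 2)))
  scores <- matrix(rnorm(40), 20, 2) %*% diag(c(3, 1))
  X <- scores %*% t(B)
  m <- fit_pca(X, cumvar_target = 0.995, center = "mean")
  expect_equal(m$p, 2)
  expect_lt(max(orthogonal_distance(m, X)), 1e-10)

  # forced p on a full-rank set
  Xr <- matrix(rnorm(15 * 10), 15, 10)
  expect_equal(ncol(fit_pca(Xr, p = 6)$loadings), 6)

  # explained variance fractions match eigen() on the centered covariance
  m2 <- fit_pca(Xr, p = 5, center = "mean")
  ev <- eigen(cov(Xr), symmetric = TRUE)$values
  expect_equal(m2$eigenvalues, ev[1:5], tolerance = 1e-10)
  expect_error(fit_pca(matrix(1, 5, 4)), "Degenerate")
})

test_that("score and orthogonal distances match their defining formulas", {
  set.seed(3)
  X <- matrix(rnorm(30 * 8), 30, 8)
  m <- fit_pca(X, p = 3, center = "mean")

  # model center has sd 0; a point one sd along PC1 has sd 1
  expect_equal(unname(score_distance(m, rbind(m$center))), 0, tolerance = 1e-10)
  pt <- m$center + sqrt(m$eigenvalues[1]) * m$loadings[, 1]
  expect_equal(unname(score_distance(m, rbind(pt))), 1, tolerance = 1e-10)

  # brute-force Mahalanobis distance in score space
  Tm <- sweep(X, 2, m$center) %*% m$loadings
  ref <- sqrt(mahalanobis(Tm, center = rep(0, 3), cov = diag(m$eigenvalues)))
  expect_equal(score_distance(m, X), unname(ref), tolerance = 1e-10)

  # any point inside the PC subspace has od 0; an orthogonal offset of norm
  # 3 has od 3
  inside <- m$center + 2 * m$loadings[, 2]
  expect_equal(unname(orthogonal_distance(m, rbind(inside))), 0,
               tolerance = 1e-10)
  v <- rnorm(8)
  v <- v - m$loadings %*% crossprod(m$loadings, v)
  v <- 3 * v / sqrt(sum(v^2))
  expect_equal(unname(orthogonal_distance(m, rbind(m$center + as.vector(v)))),
               3, tolerance = 1e-10)

  # Pythagoras: od^2 + |projection|^2 = |centered x|^2
  od <- orthogonal_distance(m, X)
  expect_equal(od^2 + rowSums(Tm^2),
               rowSums(sweep(X, 2, m$center)^2), tolerance = 1e-10)
})

test_that("F-based cutoffs reproduce the tabulated control limits", {
  expect_equal(sd_cutoff(6, 75, 0.95, scale = "squared"), 14.35,
               tolerance = 0.05 / 14.35)
  expect_equal(od_cutoff(6, 75, 0.95, scale = "squared"), 14.54,
               tolerance = 0.05 / 14.54)
  expect_equal(sd_cutoff(7, 60, 0.95, scale = "squared"), 17.07,
               tolerance = 0.05 / 17.07)
  expect_equal(od_cutoff(7, 60, 0.95, scale = "squared"), 17.35,
               tolerance = 0.05 / 17.35)

  # algebraic identity between the two limits
  for (p in c(2, 5, 9)) for (n in c(40, 80)) {
    expect_equal(od_cutoff(p, n, scale = "squared") /
                   sd_cutoff(p, n, scale = "squared"), (n + 1) / n)
  }

  # p = 1, large n: the limit approaches the chi-square(1) quantile
  expect_equal(sd_cutoff(1, 1e6, 0.95, scale = "squared"),
               qchisq(0.95, 1), tolerance = 1e-4)
  expect_error(sd_cutoff(10, 10), "n > p")
})

test_that("screening flags injected outliers and is order-invariant", {
  s <- toy_spectra(n_classes = 2, samples_per_class = 25, seed = 7)
  inj <- inject_outliers(s, 0.02, "alien-band", seed = 3)
  rep <- screen_outliers(inj$spectra, p = 4)
  hit <- rep[rep$sample_id %in% inj$injected_ids, ]
  expect_true(all(hit$od > hit$od_cutoff))
  expect_true(all(hit$removed))
  expect_true(all(hit$category %in% c("orthogonal-outlier", "bad-leverage")))

  # extreme leverage drives the score distance up
  inj2 <- inject_outliers(s, 0.02, "extreme-leverage", seed = 4, magnitude = 8)
  rep2 <- screen_outliers(inj2$spectra, p = 4)
  hit2 <- rep2[rep2$sample_id %in% inj2$injected_ids, ]
  expect_true(all(hit2$sd > hit2$sd_cutoff))

  # sample order does not change per-sample results
  perm <- sample(nrow(inj$spectra))
  rep_perm <- screen_outliers(inj$spectra[perm, ], p = 4)
  merged <- merge(as.data.frame(rep), as.data.frame(rep_perm),
                  by = "sample_id")
  expect_equal(merged$sd.x, merged$sd.y, tolerance = 1e-10)
  expect_equal(merged$category.x, merged$category.y)

  # "high-od" policy keeps high-SD/low-OD samples
  rep3 <- screen_outliers(inj2$spectra, p = 4, policy = "high-od")
  gl <- rep3$category == "good-leverage"
  if (any(gl)) expect_false(any(rep3$removed[gl]))
})

test_that("clean data loses only a small fraction at the 95% limits", {
  removed <- vapply(1:8, function(seed) {
    s <- toy_spectra(n_classes = 2, samples_per_class = 25, seed = seed)
    r <- screen_outliers(s, p = 4)
    mean(r$removed)
  }, numeric(1))
  expect_lt(mean(removed), 0.10)  # on the order of the nominal tail mass
  # and the bulk of samples are categorised regular
  s <- toy_spectra(n_classes = 2, samples_per_class = 25, seed = 1)
  expect_gt(mean(screen_outliers(s, p = 4)$category == "regular"), 0.85)
})

test_that("removing flagged samples leaves a set the screen accepts more cleanly", {
  s <- toy_spectra(n_classes = 2, samples_per_class = 25, seed = 12)
  inj <- inject_outliers(s, 0.04, "alien-band", seed = 5)
  r1 <- screen_outliers(inj$spectra, p = 4)
  cleaned <- remove_outliers(inj$spectra, r1)
  r2 <- screen_outliers(cleaned, p = 4)
  expect_lte(sum(r2$category == "bad-leverage"),
             sum(r1$category == "bad-leverage"))
  expect_equal(nrow(cleaned), nrow(inj$spectra) - sum(r1$removed))
})
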