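test_that("Savitzky-Golay reproduces polynomials and their derivatives exactly", {
  w <- default_grid(step = 2, n_points = 101)
  const <- matrix_spectra(matrix(3.5, 1, 101), step = 2)
  expect_equal(spectra_matrix(sg_filter(const, 11, 2, 0)),
               spectra_matrix(const), tolerance = 1e-10)

  # linear ramp: first derivative is the slope everywhere (edges included,
  # since the edge fit is itself polynomial)
  ramp <- nir_spectra(matrix(2 + 0.25 * w, 1), w)
  d1 <- spectra_matrix(sg_filter(ramp, 15, 2, 1))
  expect_equal(unname(d1[1, ]), rep(0.25, 101), tolerance = 1e-8)

  # quadratic: second derivative matches the analytic constant
  quad <- nir_spectra(matrix(1 + 0.1 * w - 0.002 * w^2, 1), w)
  d2 <- spectra_matrix(sg_filter(quad, 15, 2, 2))
  expect_equal(unname(d2[1, ]), rep(-0.004, 101), tolerance = 1e-8)

  expect_error(sg_filter(ramp, 10, 2, 1), "odd")
  expect_error(sg_filter(ramp, 201, 2, 0), "larger")
  expect_error(sg_filter(ramp, 11, 2, 3), "exceed")
})

test_that("fused SG derivative matches the analytic Gaussian derivative", {
  w <- default_grid(step = 4, n_points = 500)
  sig <- exp(-(w - 4800)^2 / (2 * 120^2)) + 0.5 * exp(-(w - 5400)^2 / (2 * 150^2))
  s <- nir_spectra(matrix(sig, 1), w)
  out <- apply_pipeline(s, "SG-17+2D")
  analytic <- (( (w - 4800)^2 / 120^2 - 1) / 120^2) * exp(-(w - 4800)^2 / (2 * 120^2)) +
    0.5 * (((w - 5400)^2 / 150^2 - 1) / 150^2) * exp(-(w - 5400)^2 / (2 * 150^2))
  got <- spectra_matrix(out)[1, ]
  keep <- 10:490  # away from filter edges
  expect_equal(unname(got[keep]), analytic[keep], tolerance = 1e-4)
})

test_that("SNV centers, scales, is affine-invariant and idempotent", {
  s <- matrix_spectra(rbind(c(1, 2, 3)))
  expect_equal(unname(spectra_matrix(snv(s))[1, ]), c(-1, 0, 1))

  set.seed(1)
  x <- rnorm(40)
  two <- matrix_spectra(rbind(x, 3 * x + 7))
  out <- spectra_matrix(snv(two))
  expect_equal(out[2, ], out[1, ], ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(mean(out[1, ]), 0, tolerance = 1e-12)
  expect_equal(sd(out[1, ]), 1, tolerance = 1e-12)

  expect_equal(spectra_matrix(snv(snv(two))), spectra_matrix(snv(two)),
               tolerance = 1e-12)
  expect_error(snv(matrix_spectra(rbind(c(1, 1, 1)))), "Constant")
})

test_that("MSC undoes exact affine scatter and matches normal equations", {
  ref <- sin(seq(0, 3, length.out = 20)) + 2
  s_exact <- matrix_spectra(rbind(2 * ref + 5, ref))
  out <- spectra_matrix(msc(s_exact, reference = ref))
  expect_equal(unname(out[1, ]), ref, tolerance = 1e-10)
  expect_equal(unname(out[2, ]), ref, tolerance = 1e-10)

  # identical rows are left unchanged (a-hat 1, b-hat 0 against their mean)
  same <- matrix_spectra(rbind(ref, ref, ref))
  expect_equal(spectra_matrix(msc(same)), spectra_matrix(same), tolerance = 1e-10)

  # random set: per-row coefficients match an lm() fit on the mean reference
  set.seed(4)
  m <- matrix(rnorm(80), 4, 20)
  s <- matrix_spectra(m)
  ref2 <- colMeans(m)
  out2 <- spectra_matrix(msc(s))
  for (i in 1:4) {
    fit <- lm(m[i, ] ~ ref2)
    expect_equal(unname(out2[i, ]),
                 (m[i, ] - coef(fit)[1]) / coef(fit)[2], tolerance = 1e-10)
  }

  # the mean spectrum itself is a fixed point of MSC against the set mean
  fixed <- msc(matrix_spectra(rbind(ref2, ref2 + 0)), reference = ref2)
  expect_equal(unname(spectra_matrix(fixed)[1, ]), ref2, tolerance = 1e-10)
  expect_error(msc(s, reference = rep(1, 20)), "Zero-variance")
})

test_that("pipeline names parse, fuse, and round-trip", {
  p <- parse_pipeline_name("SNV+SG-17+2D")
  expect_length(p$steps, 2)
  expect_equal(p$steps[[1]]$kind, "snv")
  expect_equal(p$steps[[2]],
               list(kind = "sg-derivative", window = 17L, polyorder = 2L,
                    deriv_order = 2L))

  expect_equal(parse_pipeline_name("SNV")$steps[[1]]$kind, "snv")
  expect_error(parse_pipeline_name("SNV+XYZ"), "Unknown")
  expect_error(parse_pipeline_name("SG-16"), "Even")

  # parse -> format -> parse is the identity on the standard variant names
  for (nm in standard_pipelines()) {
    p1 <- parse_pipeline_name(nm)
    p2 <- parse_pipeline_name(format(p1))
    expect_equal(p2$steps, p1$steps, info = nm)
  }
})

test_that("apply_pipeline composes steps and freezes the MSC training reference", {
  s <- toy_spectra(n_classes = 2, samples_per_class = 4, n_points = 60)
  expect_identical(apply_pipeline(s, parse_pipeline_name("")), s)
  expect_equal(spectra_matrix(apply_pipeline(s, "SNV")),
               spectra_matrix(snv(s)))

  train <- s[1:5, ]
  test <- s[6:8, ]
  out <- apply_pipeline(test, "MSC", fit_context = train)
  ref <- colMeans(spectra_matrix(train))
  expect_equal(spectra_matrix(out),
               spectra_matrix(msc(test, reference = ref)))
  # without context the reference comes from the test set itself: different
  expect_false(isTRUE(all.equal(spectra_matrix(out),
                                spectra_matrix(msc(test)))))
})
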