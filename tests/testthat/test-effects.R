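test_that("adjusted-effect formulas reproduce hand-computed cases", {
  # null-model implied correlations: forward effect 0.130 to 3 dp
  expect_equal(round(beta_forward(0.2401, 0.49, 0.2401), 3), 0.130)
  # no confounding path: raw correlation passes through
  expect_equal(beta_forward(0, 0.3, 0.5), 0.5)
  # numerator vanishes when r_p1y2 = r_p1y1 * r_y1y2
  expect_equal(beta_forward(0.4, 0.5, 0.20), 0)

  expect_equal(beta_reverse(0.5, 0.4, 0), 0.5)
  expect_equal(beta_reverse(0.20, 0.5, 0.4), 0)
  # symmetric triplet: reverse equals forward
  expect_equal(beta_reverse(0.2401, 0.49, 0.2401),
               beta_forward(0.2401, 0.49, 0.2401))

  expect_equal(beta_diff(0.3, 0.49, 0.3), 0)
  expect_equal(beta_diff(0.5, 0.5, 0.5), 0)
  # plug-in of the pooled published correlations (not the pooled per-study
  # estimate, which differs by pooling order)
  expect_equal(round(beta_diff(0.308, 0.582, 0.254), 4), -0.0591)
})

test_that("forward/reverse effects agree with the normal-equations oracle", {
  set.seed(421)
  for (rep in seq_len(1000)) {
    r <- random_psd_triplet()
    expect_equal(beta_forward(r[1], r[2], r[3]),
                 normal_equations_beta(r[1], r[2], r[3], "Y2"),
                 tolerance = 1e-10)
    expect_equal(beta_reverse(r[1], r[2], r[3]),
                 normal_equations_beta(r[1], r[2], r[3], "Y1"),
                 tolerance = 1e-10)
  }
})

test_that("reverse effect is the forward effect with waves exchanged", {
  set.seed(77)
  for (rep in seq_len(50)) {
    r <- random_psd_triplet()
    expect_identical(beta_reverse(r[1], r[2], r[3]),
                     beta_forward(r[3], r[2], r[1]))
  }
})

test_that("difference-score effect carries the sign of the correlation gap", {
  set.seed(9)
  for (rep in seq_len(200)) {
    r <- random_psd_triplet()
    expect_identical(sign(beta_diff(r[1], r[2], r[3])), sign(r[3] - r[1]))
  }
  expect_error(beta_diff(0.3, 1, 0.3), "degenerate autocorrelation")
})

test_that("Fisher z is exact, invertible, monotone and odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  grid <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(inv_fisher_z(fisher_z(grid)), grid, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(grid)) > 0))
  expect_equal(fisher_z(-grid), -fisher_z(grid))
  expect_error(fisher_z(1), "degenerate")
})

test_that("Fisher-z sampling variance is 1/(n-3) with a hard floor", {
  expect_equal(z_sampling_variance(103), 0.01)
  expect_equal(z_sampling_variance(4), 1.0)
  expect_error(z_sampling_variance(3), "n too small")
})

test_that("triplet validation flags degenerate and non-PSD inputs", {
  ok <- tibble::tibble(study_id = "s", effect_id = "e", n = 100,
                       r_p1y1 = 0.3, r_y1y2 = 0.6, r_p1y2 = 0.25)
  expect_identical(validate_triplets(ok), ok)

  bad_psd <- dplyr::mutate(ok, r_p1y1 = 0.9, r_y1y2 = -0.9, r_p1y2 = 0.9)
  # determinant 1 + 2(0.9)(-0.9)(0.9) - 3(0.81) = -2.888
  expect_error(validate_triplets(bad_psd), "non-PSD.*-2\\.888")

  degen <- dplyr::mutate(ok, r_y1y2 = 1.0)
  expect_error(validate_triplets(degen), "degenerate correlation")
  expect_error(validate_triplets(dplyr::mutate(ok, n = 3)), "n too small")
})

test_that("coercion shrinks a non-PSD row onto the PSD boundary", {
  d <- tibble::tibble(study_id = c("s1", "s2"), effect_id = "e1",
                      n = c(100, 100),
                      r_p1y1 = c(0.3, 0.95), r_y1y2 = c(0.6, -0.9),
                      r_p1y2 = c(0.25, 0.92))
  out <- validate_triplets(d, coerce = TRUE)
  expect_identical(out$coerced, c(FALSE, TRUE))
  # valid row untouched, repaired row PSD and barely shrunk past the boundary
  expect_identical(out$r_p1y1[1], 0.3)
  det2 <- 1 + 2 * out$r_p1y1[2] * out$r_y1y2[2] * out$r_p1y2[2] -
    out$r_p1y1[2]^2 - out$r_y1y2[2]^2 - out$r_p1y2[2]^2
  expect_gte(det2, 0)
  s <- out$r_p1y1[2] / 0.95
  det_prev <- 1 + 2 * prod(c(0.95, -0.9, 0.92) * (s + 1e-4)) -
    sum((c(0.95, -0.9, 0.92) * (s + 1e-4))^2)
  expect_lt(det_prev, 0)
})

test_that("derive_effects produces the full per-effect export schema", {
  out <- derive_effects(tiny_triplet_table())
  expect_equal(nrow(out), 4)
  expect_true(all(c("beta_forward", "beta_reverse", "beta_diff",
                    "z_r_p1y1", "z_beta_diff", "v") %in% names(out)))
  expect_equal(out$v, 1 / (out$n - 3))
  expect_equal(out$z_beta_forward, atanh(out$beta_forward))

  # per-record variance override for the beta effects
  with_v <- dplyr::mutate(tiny_triplet_table(), v = 0.02)
  expect_equal(derive_effects(with_v)$v, rep(0.02, 4))
  expect_error(derive_effects(dplyr::mutate(tiny_triplet_table(), v = -1)),
               "positive")
})

test_that("CSV round trip preserves triplets and honours column mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- dplyr::mutate(tiny_triplet_table(), domain = "externalizing")
  readr::write_csv(d, path)
  back <- read_triplets(path)
  expect_equal(back$r_p1y2, d$r_p1y2)
  expect_true("domain" %in% names(back))

  renamed <- dplyr::rename(d, rPY1 = r_p1y1)
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(renamed, path2)
  expect_error(read_triplets(path2), "missing columns")
  mapped <- read_triplets(path2, col_map = c(r_p1y1 = "rPY1"))
  expect_equal(mapped$r_p1y1, d$r_p1y1)
})
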