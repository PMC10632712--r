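test_that("within-study aggregation is inverse-variance weighting", {
  recs <- tibble::tibble(study_id = "s1", effect_id = c("e1", "e2"),
                         z = c(0.3, 0.5), v = c(0.01, 0.01))
  agg <- aggregate_within_study(recs)
  expect_equal(agg$z, 0.4)
  expect_equal(agg$v, 0.005)
  expect_equal(agg$k_effects, 2L)
  expect_equal(agg$effect_id, "e1+e2")

  single <- tibble::tibble(study_id = "s2", effect_id = "e1",
                           z = 0.2, v = 0.02)
  agg1 <- aggregate_within_study(single)
  expect_equal(agg1$z, 0.2)
  expect_equal(agg1$v, 0.02)

  # assumed correlation inflates the combined variance:
  # equal v, m effects -> v * (1 + rho (m - 1)) / m
  agg_rho <- aggregate_within_study(recs, rho = 0.5)
  expect_equal(agg_rho$z, 0.4)
  expect_equal(agg_rho$v, 0.01 * (1 + 0.5) / 2)
  expect_error(aggregate_within_study(recs[0, ]), "empty")
})

test_that("one independent record per study comes out of aggregation", {
  d <- derive_effects(generate_meta_dataset(synth_config(seed = 2)))
  recs <- as_effect_records(d)
  agg <- aggregate_within_study(recs)
  expect_equal(nrow(agg), 6 * length(unique(d$study_id)))
  expect_equal(length(unique(d$study_id)), 58)
})

test_that("degenerate pools: identical effects give zero heterogeneity", {
  recs <- tibble::tibble(z = rep(0.3, 10), v = rep(0.01, 10))
  p <- pool_effects(recs)
  expect_equal(p$estimate_z, 0.3)
  expect_equal(p$estimate, tanh(0.3))
  expect_equal(p$Q, 0)
  expect_equal(p$tau2, 0)
  expect_equal(p$I2, 0)
  expect_error(pool_effects(recs[1, ]), "at least 2")
})

test_that("DerSimonian-Laird pooling matches the closed form by hand", {
  recs <- tibble::tibble(z = c(0.2, 0.4), v = c(0.01, 0.01))
  p <- pool_effects(recs, tau2_method = "DL")
  expect_equal(p$Q, 2.0)
  expect_equal(p$tau2, 0.01)
  expect_equal(p$estimate_z, 0.3)

  set.seed(88)
  for (rep in seq_len(20)) {
    k <- sample(5:40, 1)
    z <- stats::rnorm(k, 0.25, 0.1)
    v <- stats::runif(k, 0.002, 0.05)
    hand <- dl_pool_by_hand(z, v)
    p <- pool_effects(tibble::tibble(z = z, v = v), tau2_method = "DL")
    expect_equal(p$Q, hand$Q, tolerance = 1e-10)
    expect_equal(p$tau2, hand$tau2, tolerance = 1e-10)
    expect_equal(p$estimate_z, hand$estimate_z, tolerance = 1e-10)
    expect_equal(p$se_z, hand$se_z, tolerance = 1e-10)
  }
})

test_that("pooling is order-invariant and back-transform consistent", {
  set.seed(5)
  z <- stats::rnorm(30, 0.3, 0.08)
  v <- stats::runif(30, 0.005, 0.03)
  p1 <- pool_effects(tibble::tibble(z = z, v = v))
  idx <- sample(30)
  p2 <- pool_effects(tibble::tibble(z = z[idx], v = v[idx]))
  expect_equal(p1$estimate_z, p2$estimate_z, tolerance = 1e-10)
  expect_equal(p1$tau2, p2$tau2, tolerance = 1e-8)
  expect_equal(p1$ci95, tanh(p1$ci95_z))
  expect_true(p1$ci95[1] < p1$estimate && p1$estimate < p1$ci95[2])

  # tau2 = 0 forces the random-effects estimate onto the fixed-effect one
  recs0 <- tibble::tibble(z = c(0.30, 0.302, 0.299, 0.301),
                          v = c(0.01, 0.02, 0.015, 0.01))
  p0 <- pool_effects(recs0, tau2_method = "DL")
  expect_equal(p0$tau2, 0)
  w <- 1 / recs0$v
  expect_equal(p0$estimate_z, sum(w * recs0$z) / sum(w), tolerance = 1e-12)
})

test_that("I-squared point estimates and guards follow Higgins-Thompson", {
  expect_equal(i_squared(57, 57)$I2, 0)
  expect_equal(round(i_squared(58, 57)$I2, 2), 1.72)
  expect_equal(i_squared(114, 57)$I2, 50)
  expect_error(i_squared(10, 0), "df")
  expect_error(i_squared(-1, 5), "Q")

  ci <- i_squared(57, 57)
  expect_gte(ci$ci_low, 0)
  expect_lte(ci$ci_high, 100)
  expect_gte(ci$ci_high, ci$I2)

  alt <- i_squared(58, 57, tau2 = 0.01, typical_v = 0.01, method = "tau2")
  expect_equal(alt$I2, 50)
})

test_that("three-level pool degenerates to the two-level fit", {
  set.seed(12)
  recs <- tibble::tibble(study_id = sprintf("s%02d", 1:20),
                         effect_id = "e1",
                         z = stats::rnorm(20, 0.3, 0.05),
                         v = stats::runif(20, 0.005, 0.02))
  p3 <- pool_three_level(recs)
  p2 <- pool_effects(recs)
  expect_equal(p3$estimate_z, p2$estimate_z, tolerance = 1e-8)
  expect_equal(p3$se_z, p2$se_z, tolerance = 1e-8)
  expect_equal(p3$tau2, p2$tau2, tolerance = 1e-6)
  expect_error(pool_three_level(recs[1, ]), "at least 2")
})

test_that("three-level REML recovers both variance components", {
  sim_two_level <- function(seed, tau2_study, tau2_effect) {
    withr::with_seed(seed, {
      k <- 60; m <- 3
      study <- rep(sprintf("s%02d", 1:k), each = m)
      u <- rep(stats::rnorm(k, 0, sqrt(tau2_study)), each = m)
      e <- stats::rnorm(k * m, 0, sqrt(tau2_effect))
      v <- rep(0.01, k * m)
      tibble::tibble(study_id = study,
                     effect_id = rep(paste0("e", 1:m), k),
                     z = 0.3 + u + e + stats::rnorm(k * m, 0, sqrt(v)),
                     v = v)
    })
  }
  fits <- purrr::map(1:200, function(s) {
    p <- pool_three_level(sim_two_level(s, 0.02, 0.01))
    p$tau2_components
  })
  med <- apply(do.call(rbind, fits), 2, stats::median)
  expect_gt(med[["study"]], 0.02 * 0.5)
  expect_lt(med[["study"]], 0.02 * 1.5)
  expect_gt(med[["effect"]], 0.01 * 0.5)
  expect_lt(med[["effect"]], 0.01 * 1.5)

  null_fits <- purrr::map_dbl(1:200, function(s) {
    sum(pool_three_level(sim_two_level(1000 + s, 0, 0))$tau2_components)
  })
  expect_lt(stats::median(null_fits), 0.002)
})

test_that("random-effects CIs cover the true pooled value at k = 58", {
  set.seed(2024)
  covered <- replicate(500, {
    v <- stats::runif(58, 0.002, 0.02)
    z <- stats::rnorm(58, 0.3, sqrt(v))
    p <- pool_effects(tibble::tibble(z = z, v = v))
    p$ci95_z[1] <= 0.3 && 0.3 <= p$ci95_z[2]
  })
  expect_gte(mean(covered), 0.90)
})

test_that("tidy/glance expose the published-table columns", {
  recs <- tibble::tibble(z = c(0.2, 0.3, 0.4), v = rep(0.01, 3))
  p <- pool_effects(recs)
  td <- tidy(p)
  expect_named(td, c("estimate", "ci_low", "ci_high", "estimate_z",
                     "std_error_z", "p_value"))
  gl <- glance(p)
  expect_equal(gl$k, 3L)
  expect_equal(gl$df, 2L)
  expect_output(print(p), "Random-effects pool")
})

test_that("caterpillar export orders effects and appends the diamond", {
  set.seed(3)
  recs <- tibble::tibble(study_id = sprintf("s%d", 1:12),
                         effect_id = "e1",
                         z = stats::rnorm(12, 0.3, 0.1),
                         v = stats::runif(12, 0.005, 0.02))
  p <- pool_effects(recs)
  cat_d <- caterpillar_data(recs, pooled = p)
  expect_equal(nrow(cat_d), 13)
  expect_true(all(diff(cat_d$estimate[!cat_d$pooled]) >= 0))
  expect_equal(cat_d$estimate[cat_d$pooled], p$estimate)
  expect_true(all(cat_d$ci_low < cat_d$estimate &
                    cat_d$estimate < cat_d$ci_high))
})
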