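#' Reshape per-effect derived quantities into effect-size records
#'
#' Converts the wide output of [derive_effects()] into long records, one row
#' per study x effect x parameter, where `parameter` is one of the six pooled
#' quantities (`r_p1y1`, `r_y1y2`, `r_p1y2`, `beta_forward`, `beta_reverse`,
#' `beta_diff`), `z` the Fisher-z value and `v` its sampling variance.
#'
#' @param derived Output of [derive_effects()].
#' @return A tibble with columns `study_id`, `effect_id`, `parameter`, `z`,
#'   `v`.
#' @export
as_effect_records <- function(derived) {
  params <- meta_parameters()
  needed <- c(paste0("z_", params), "v")
  missing_cols <- setdiff(needed, names(derived))
  if (length(missing_cols) > 0) {
    stop("as_effect_records: missing columns: ",
         paste(missing_cols, collapse = ", "),
         "; run derive_effects() first", call. = FALSE)
  }
  derived |>
    dplyr::select("study_id", "effect_id", "v",
                  dplyr::all_of(paste0("z_", params))) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("z_", params)),
                        names_to = "parameter", names_prefix = "z_",
                        values_to = "z") |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = params)) |>
    dplyr::select("study_id", "effect_id", "parameter", "z", "v") |>
    dplyr::arrange(.data$parameter, .data$study_id, .data$effect_id)
}

meta_parameters <- function() {
  c("r_p1y1", "r_y1y2", "r_p1y2",
    "beta_forward", "beta_reverse", "beta_diff")
}

#' Collapse dependent effect sizes within studies
#'
#' Combines a study's multiple effect sizes (for one parameter) into a single
#' independent record by the inverse-variance weighted mean of the Fisher-z
#' values. With `rho = 0` (default) the effects are treated as independent
#' and the combined variance is `1/sum(w)`; a positive `rho` assumes that
#' correlation between every pair of a study's effects (effects from a shared
#' sample typically share participants; `rho = 0.5` is a conventional
#' assumption) and inflates the combined variance accordingly. Single-record
#' studies pass through unchanged.
#'
#' @param records Effect-size records from [as_effect_records()], all rows
#'   sharing one `parameter` label (or carrying a `parameter` column, in which
#'   case aggregation is done per parameter).
#' @param rho Assumed within-study correlation between effect sizes, in
#'   `[0, 1)`.
#' @return A tibble with one row per study (per parameter), columns
#'   `study_id`, `effect_id` (collapsed labels), `parameter`, `z`, `v`,
#'   `k_effects`.
#' @export
aggregate_within_study <- function(records, rho = 0) {
  if (nrow(records) == 0) {
    stop("aggregate_within_study: empty input", call. = FALSE)
  }
  stopifnot(rho >= 0, rho < 1)
  grp <- intersect(c("parameter", "study_id"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      effect_id = paste(.data$effect_id, collapse = "+"),
      k_effects = dplyr::n(),
      z = sum(.data$z / .data$v) / sum(1 / .data$v),
      v = {
        w <- 1 / .data$v
        sw <- sum(w)
        (sw + rho * (sum(sqrt(w))^2 - sw)) / sw^2
      },
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::any_of(c("study_id", "effect_id", "parameter",
                                  "z", "v", "k_effects")))
}

#' Random-effects pooling of Fisher-z effects
#'
#' Pools effect-size records with a random-effects model on the Fisher-z
#' scale: between-unit variance tau^2 by restricted maximum likelihood
#' (default) or the DerSimonian-Laird closed form, pooled estimate with
#' inverse `v + tau^2` weights, Wald 95% CI back-transformed through `tanh`,
#' and heterogeneity via Cochran's Q (fixed-effect `1/v` weights) with the
#' Higgins-Thompson I^2. Fitting is delegated to [metafor::rma.uni()]; if
#' REML fails to converge the DerSimonian-Laird estimator is used with a
#' warning.
#'
#' @param records Tibble with columns `z` and `v` (one parameter's records,
#'   typically after [aggregate_within_study()]).
#' @param tau2_method `"REML"` (default) or `"DL"`.
#' @param level Confidence level (default 0.95).
#' @return A `meta_pool` object; see [tidy.meta_pool()] and
#'   [glance.meta_pool()].
#' @examples
#' recs <- tibble::tibble(z = c(0.2, 0.4), v = c(0.01, 0.01))
#' pool_effects(recs, tau2_method = "DL")
#' @export
pool_effects <- function(records, tau2_method = c("REML", "DL"),
                         level = 0.95) {
  tau2_method <- match.arg(tau2_method)
  if (nrow(records) < 2) {
    stop("pool_effects: need at least 2 records", call. = FALSE)
  }
  if (any(records$v <= 0)) {
    stop("pool_effects: sampling variances must be positive", call. = FALSE)
  }
  fit <- tryCatch(
    metafor::rma.uni(yi = records$z, vi = records$v, method = tau2_method,
                     level = 100 * level, control = list(maxiter = 100)),
    error = function(e) {
      if (tau2_method == "REML") {
        warning("pool_effects: REML did not converge (", conditionMessage(e),
                "); falling back to DerSimonian-Laird", call. = FALSE)
        metafor::rma.uni(yi = records$z, vi = records$v, method = "DL",
                         level = 100 * level)
      } else {
        stop(e)
      }
    }
  )
  new_meta_pool(fit, k = fit$k, level = level,
                tau2_components = c(total = unname(fit$tau2)))
}

new_meta_pool <- function(fit, k, level, tau2_components,
                          model = "two-level") {
  Q <- unname(fit$QE)
  df <- k - 1L
  i2 <- i_squared(Q, df, level = level)
  structure(list(
    k = k,
    estimate_z = unname(fit$beta[1, 1]),
    se_z = unname(fit$se[1]),
    ci95_z = c(unname(fit$ci.lb), unname(fit$ci.ub)),
    estimate = tanh(unname(fit$beta[1, 1])),
    ci95 = tanh(c(unname(fit$ci.lb), unname(fit$ci.ub))),
    pval = unname(fit$pval[1]),
    tau2 = sum(tau2_components),
    tau2_components = tau2_components,
    Q = Q,
    df = df,
    I2 = i2$I2,
    I2_ci = c(i2$ci_low, i2$ci_high),
    level = level,
    model = model,
    method = fit$method,
    fit = fit
  ), class = "meta_pool")
}

#' @export
print.meta_pool <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects pool (%s, %s), k = %d\n",
              x$model, x$method, x$k))
  cat(sprintf("  estimate %0.*f (%d%% CI %0.*f; %0.*f)  [back-transformed]\n",
              digits, x$estimate, round(100 * x$level),
              digits, x$ci95[1], digits, x$ci95[2]))
  cat(sprintf("  tau^2 = %0.4f;  Q = %0.1f (df = %d);  I2 = %0.1f%% (%s; %s)\n",
              x$tau2, x$Q, x$df, x$I2,
              format_pct(x$I2_ci[1]), format_pct(x$I2_ci[2])))
  invisible(x)
}

format_pct <- function(x) if (is.na(x)) "NA" else sprintf("%0.1f", x)

#' Higgins-Thompson I-squared with a test-based interval
#'
#' Point estimate `max(0, 100 * (Q - df) / Q)`: the percentage of variation
#' across effects attributable to heterogeneity rather than sampling error.
#' The confidence interval is test-based, built on the standard error of
#' `ln(H)` with `H^2 = Q/df`. An alternative tau^2-based definition
#' `100 * tau2 / (tau2 + typical_v)` is available via `method = "tau2"`
#' (point estimate only).
#'
#' @param Q Cochran's Q statistic (nonnegative).
#' @param df Degrees of freedom, `k - 1`, at least 1.
#' @param tau2,typical_v Between-unit variance and typical within-unit
#'   variance; only used by `method = "tau2"`.
#' @param method `"higgins"` (default) or `"tau2"`.
#' @param level Confidence level for the interval.
#' @return A one-row tibble with `I2`, `ci_low`, `ci_high` (percent).
#' @examples
#' i_squared(58, 57)
#' @export
i_squared <- function(Q, df, tau2 = NULL, typical_v = NULL,
                      method = c("higgins", "tau2"), level = 0.95) {
  method <- match.arg(method)
  if (df < 1) stop("i_squared: df must be >= 1", call. = FALSE)
  if (Q < 0) stop("i_squared: Q must be >= 0", call. = FALSE)
  if (method == "tau2") {
    if (is.null(tau2) || is.null(typical_v)) {
      stop("i_squared: method 'tau2' needs tau2 and typical_v", call. = FALSE)
    }
    return(tibble::tibble(I2 = 100 * tau2 / (tau2 + typical_v),
                          ci_low = NA_real_, ci_high = NA_real_))
  }
  point <- max(0, 100 * (Q - df) / Q)
  k <- df + 1
  se_lnH <- if (Q > k) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else if (k > 2) {
    sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    NA_real_
  }
  if (is.na(se_lnH)) {
    return(tibble::tibble(I2 = point, ci_low = NA_real_, ci_high = NA_real_))
  }
  zc <- stats::qnorm(1 - (1 - level) / 2)
  lnH <- 0.5 * log(max(Q / df, 1e-300))
  H_bounds <- pmax(exp(lnH + c(-1, 1) * zc * se_lnH), 1)
  i2_bounds <- 100 * (H_bounds^2 - 1) / H_bounds^2
  tibble::tibble(I2 = point, ci_low = i2_bounds[1], ci_high = i2_bounds[2])
}

#' Three-level random-effects pooling
#'
#' Pools all effect sizes for one parameter with random intercepts at the
#' study and the effect level (REML on the marginal likelihood, via
#' [metafor::rma.mv()]), an alternative to collapsing dependent effects with
#' [aggregate_within_study()] first. When every study contributes a single
#' effect the model degenerates to the ordinary two-level random-effects
#' pool.
#'
#' @param records Tibble with columns `study_id`, `effect_id`, `z`, `v` (one
#'   parameter's records).
#' @param level Confidence level.
#' @return A `meta_pool` object whose `tau2_components` element holds the
#'   study-level and effect-level variance components.
#' @export
pool_three_level <- function(records, level = 0.95) {
  if (nrow(records) < 2 || length(unique(records$study_id)) < 2) {
    stop("pool_three_level: need at least 2 studies", call. = FALSE)
  }
  dat <- data.frame(z = records$z, v = records$v,
                    study_id = as.character(records$study_id),
                    effect_id = paste(records$study_id, records$effect_id,
                                      sep = "/"))
  mv_fit <- function(control) {
    metafor::rma.mv(yi = z, V = v, random = ~ 1 | study_id / effect_id,
                    data = dat, method = "REML", level = 100 * level,
                    control = control)
  }
  # boundary fits (variance components near 0) can defeat nlminb; retry with
  # Nelder-Mead before giving up
  fit <- tryCatch(
    mv_fit(list(iter.max = 400)),
    error = function(e) {
      tryCatch(mv_fit(list(optimizer = "optim", optmethod = "Nelder-Mead")),
               error = function(e2) {
                 stop("pool_three_level: REML did not converge (",
                      conditionMessage(e2), ")", call. = FALSE)
               })
    }
  )
  k_studies <- length(unique(dat$study_id))
  new_meta_pool(fit, k = fit$k, level = level,
                tau2_components = c(study = unname(fit$sigma2[1]),
                                    effect = unname(fit$sigma2[2])),
                model = sprintf("three-level (%d studies)", k_studies))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pooled meta-analytic fit
#'
#' @param x A `meta_pool` object.
#' @param ... Unused.
#' @return One-row tibble with the back-transformed pooled estimate and CI
#'   plus the z-scale estimate and standard error.
#' @method tidy meta_pool
#' @export
tidy.meta_pool <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, ci_low = x$ci95[1], ci_high = x$ci95[2],
    estimate_z = x$estimate_z, std_error_z = x$se_z, p_value = x$pval
  )
}

#' Model-level summary of a pooled fit
#'
#' @inheritParams tidy.meta_pool
#' @return One-row tibble with `k`, `tau2`, `Q`, `df`, `I2` and its interval.
#' @method glance meta_pool
#' @export
glance.meta_pool <- function(x, ...) {
  tibble::tibble(
    k = x$k, tau2 = x$tau2, Q = x$Q, df = x$df,
    I2 = x$I2, I2_ci_low = x$I2_ci[1], I2_ci_high = x$I2_ci[2],
    method = x$method, model = x$model
  )
}

#' Pool every parameter of a derived-effects table
#'
#' Runs the full pooling stage for each of the six parameters (three
#' zero-order correlations, three regression effects): reshape to effect-size
#' records, make them independent (study-level aggregation, default) or keep
#' the full nesting (three-level model), pool, and report one row per
#' parameter in the layout of the published summary table.
#'
#' @param derived Output of [derive_effects()].
#' @param aggregation `"study"` (collapse within studies, then two-level
#'   random effects; default) or `"three-level"`.
#' @param tau2_method Passed to [pool_effects()] (study-level path).
#' @param rho Passed to [aggregate_within_study()].
#' @return A tibble with one row per parameter: `parameter`, `k`, `estimate`,
#'   `ci_low`, `ci_high`, `tau2`, `Q`, `df`, `I2`, `I2_ci_low`, `I2_ci_high`,
#'   plus a `pools` list-column of the underlying `meta_pool` objects.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_studies = 20, seed = 7)
#' d <- derive_effects(generate_meta_dataset(cfg))
#' meta_report(d)
#' }
#' @export
meta_report <- function(derived, aggregation = c("study", "three-level"),
                        tau2_method = "REML", rho = 0) {
  aggregation <- match.arg(aggregation)
  records <- as_effect_records(derived)
  if (length(unique(records$study_id)) < 2) {
    warning("meta_report: single study (k = 1); no pooling possible, ",
            "reporting study-level values without CIs", call. = FALSE)
    agg <- aggregate_within_study(records, rho = rho)
    return(dplyr::transmute(
      agg,
      parameter = as.character(.data$parameter), estimate = tanh(.data$z),
      ci_low = NA_real_, ci_high = NA_real_, k = 1L,
      tau2 = NA_real_, Q = NA_real_, df = 0L,
      I2 = NA_real_, I2_ci_low = NA_real_, I2_ci_high = NA_real_,
      pools = list(NULL)
    ))
  }
  pools <- purrr::map(meta_parameters(), function(par) {
    recs <- dplyr::filter(records, .data$parameter == par)
    if (aggregation == "study") {
      pool_effects(aggregate_within_study(recs, rho = rho),
                   tau2_method = tau2_method)
    } else {
      pool_three_level(recs)
    }
  })
  purrr::map2(meta_parameters(), pools, function(par, p) {
    dplyr::bind_cols(tibble::tibble(parameter = par),
                     tidy(p)[c("estimate", "ci_low", "ci_high")],
                     glance(p)[c("k", "tau2", "Q", "df",
                                 "I2", "I2_ci_low", "I2_ci_high")])
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(pools = pools)
}

#' Per-effect data behind a caterpillar plot
#'
#' Orders one parameter's effect sizes by estimate, attaches back-transformed
#' 95% CIs, and appends the pooled estimate as a final `pooled` row (the
#' diamond of a caterpillar display).
#'
#' @param records One parameter's effect-size records (`z`, `v` columns).
#' @param pooled Optional `meta_pool` for the diamond row.
#' @param level Confidence level for per-effect intervals.
#' @return Tibble with `study_id`, `effect_id`, `estimate`, `ci_low`,
#'   `ci_high`, `rank`, `pooled` (logical).
#' @export
caterpillar_data <- function(records, pooled = NULL, level = 0.95) {
  zc <- stats::qnorm(1 - (1 - level) / 2)
  out <- records |>
    dplyr::mutate(
      estimate = tanh(.data$z),
      ci_low = tanh(.data$z - zc * sqrt(.data$v)),
      ci_high = tanh(.data$z + zc * sqrt(.data$v)),
      pooled = FALSE
    ) |>
    dplyr::arrange(.data$estimate) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(dplyr::any_of(c("study_id", "effect_id")),
                  "estimate", "ci_low", "ci_high", "rank", "pooled")
  if (!is.null(pooled)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      study_id = "pooled", effect_id = "pooled",
      estimate = pooled$estimate, ci_low = pooled$ci95[1],
      ci_high = pooled$ci95[2], rank = nrow(out) + 1L, pooled = TRUE
    ))
  }
  out
}
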