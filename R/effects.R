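#' Fisher z transformation and its inverse
#'
#' `fisher_z()` maps a correlation (or a standardized regression effect treated
#' on the correlation scale) to the approximately normal `atanh` scale;
#' `inv_fisher_z()` maps back via `tanh`.
#'
#' @param r Numeric vector of correlations, each strictly inside (-1, 1).
#' @param z Numeric vector of Fisher-z values.
#' @return Numeric vector of the same length.
#' @examples
#' fisher_z(0.5)
#' inv_fisher_z(fisher_z(0.3))
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r) | abs(r) >= 1)) {
    stop("fisher_z: degenerate correlation, |r| must be < 1", call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) {
  if (any(!is.finite(z))) {
    stop("inv_fisher_z: z must be finite", call. = FALSE)
  }
  tanh(z)
}

#' Large-sample variance of a Fisher-z value
#'
#' Returns `1/(n - 3)`, the standard sampling variance of a Fisher-z
#' transformed Pearson correlation. The same rule is applied by default to
#' z-converted standardized regression effects; supply per-record variances
#' to [derive_effects()] to override.
#'
#' @param n Integer vector of sample sizes, each at least 4.
#' @return Numeric vector of variances.
#' @examples
#' z_sampling_variance(103)  # 0.01
#' @export
z_sampling_variance <- function(n) {
  if (any(!is.finite(n) | n < 4)) {
    stop("z_sampling_variance: n too small, need n >= 4", call. = FALSE)
  }
  1 / (n - 3)
}

# Determinant of the 3x3 correlation matrix of (P1, Y1, Y2):
# 1 + 2*r12*r13*r23 - r12^2 - r13^2 - r23^2, with r12 = r(P1,Y1),
# r23 = r(Y1,Y2), r13 = r(P1,Y2). Nonnegative iff the matrix is PSD.
triplet_determinant <- function(r_p1y1, r_y1y2, r_p1y2) {
  1 + 2 * r_p1y1 * r_y1y2 * r_p1y2 - r_p1y1^2 - r_y1y2^2 - r_p1y2^2
}

#' Forward baseline-adjusted cross-lagged effect
#'
#' Standardized coefficient of the time-1 predictor P1 on the time-2 outcome
#' Y2 adjusting for the time-1 outcome Y1, computed from the three zero-order
#' correlations alone:
#' \deqn{\beta_{P1,Y2.Y1} = \frac{r_{P1,Y2} - r_{P1,Y1}\, r_{Y1,Y2}}{1 - r_{P1,Y1}^2}}
#'
#' @param r_p1y1 Correlation between predictor and outcome, both at time 1.
#' @param r_y1y2 Autocorrelation of the outcome across the two waves.
#' @param r_p1y2 Cross-lagged correlation (predictor at time 1, outcome at
#'   time 2).
#' @return Numeric vector of standardized effects.
#' @seealso [beta_reverse()], [beta_diff()], [derive_effects()]
#' @examples
#' beta_forward(0.2401, 0.49, 0.2401)  # ~0.130
#' @export
beta_forward <- function(r_p1y1, r_y1y2, r_p1y2) {
  check_unit_interval(r_p1y1, r_y1y2, r_p1y2)
  (r_p1y2 - r_p1y1 * r_y1y2) / (1 - r_p1y1^2)
}

#' Reverse-time adjusted effect
#'
#' The forward formula with the roles of the two waves exchanged: the effect
#' of P1 on the time-1 outcome Y1 adjusting for the time-2 outcome Y2. Under
#' genuine lagged influence this effect is expected to be negative; a positive
#' value alongside a positive forward effect is the signature of distortion by
#' correlated measurement error and regression to the mean.
#'
#' @inheritParams beta_forward
#' @return Numeric vector of standardized effects.
#' @examples
#' beta_reverse(0.308, 0.582, 0.254)
#' @export
beta_reverse <- function(r_p1y1, r_y1y2, r_p1y2) {
  check_unit_interval(r_p1y1, r_y1y2, r_p1y2)
  (r_p1y1 - r_p1y2 * r_y1y2) / (1 - r_p1y2^2)
}

#' Difference-score effect
#'
#' Standardized effect of P1 on the change score Y2 - Y1 (both waves
#' standardized), without baseline adjustment:
#' \deqn{\beta_{P1,Y2-Y1} = \frac{r_{P1,Y2} - r_{P1,Y1}}{\sqrt{2(1 - r_{Y1,Y2})}}}
#' Its sign equals the sign of `r_p1y2 - r_p1y1`.
#'
#' @inheritParams beta_forward
#' @return Numeric vector of effects on the standardized change score.
#' @examples
#' beta_diff(0.308, 0.582, 0.254)  # ~ -0.0591
#' @export
beta_diff <- function(r_p1y1, r_y1y2, r_p1y2) {
  check_unit_interval(r_p1y1, r_p1y2)
  if (any(r_y1y2 >= 1)) {
    stop("beta_diff: degenerate autocorrelation, r_y1y2 must be < 1",
         call. = FALSE)
  }
  (r_p1y2 - r_p1y1) / sqrt(2 * (1 - r_y1y2))
}

check_unit_interval <- function(...) {
  rs <- c(...)
  if (any(!is.finite(rs) | abs(rs) >= 1)) {
    stop("degenerate correlation: every |r| must be < 1", call. = FALSE)
  }
  invisible(NULL)
}

#' Validate (and optionally repair) correlation triplets
#'
#' Checks each row of a correlation-triplet table: all three correlations
#' strictly inside (-1, 1), sample size `n >= 4`, and the implied 3x3
#' correlation matrix positive semidefinite. With `coerce = TRUE`, a row whose
#' matrix is not PSD is shrunk toward the identity (all three correlations
#' multiplied by `1 - k * step` for the smallest integer `k` that restores
#' PSD); otherwise any violation is a hard error naming the offending rows.
#'
#' @param data A data frame with columns `study_id`, `effect_id`, `n`,
#'   `r_p1y1`, `r_y1y2`, `r_p1y2`. Extra columns (e.g. `domain`) are carried
#'   through untouched.
#' @param coerce Shrink non-PSD rows toward the identity instead of erroring.
#' @param step Shrinkage grid step (default `1e-4`).
#' @return The validated tibble, with a logical `coerced` column when
#'   `coerce = TRUE`.
#' @export
validate_triplets <- function(data, coerce = FALSE, step = 1e-4) {
  required <- c("study_id", "effect_id", "n", "r_p1y1", "r_y1y2", "r_p1y2")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("validate_triplets: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  rs <- data[c("r_p1y1", "r_y1y2", "r_p1y2")]
  bad_r <- !stats::complete.cases(rs) |
    apply(abs(as.matrix(rs)) >= 1, 1, any)
  if (any(bad_r)) {
    stop("degenerate correlation: |r| >= 1 in rows ",
         paste(which(bad_r), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(data$n) | data$n < 4)) {
    stop("n too small: need n >= 4, offending rows ",
         paste(which(!is.finite(data$n) | data$n < 4), collapse = ", "),
         call. = FALSE)
  }
  det3 <- triplet_determinant(data$r_p1y1, data$r_y1y2, data$r_p1y2)
  if (!coerce) {
    if (any(det3 < 0)) {
      i <- which(det3 < 0)
      stop("non-PSD correlation matrix in rows ",
           paste(i, collapse = ", "), " (determinant ",
           paste(signif(det3[i], 4), collapse = ", "), ")", call. = FALSE)
    }
    return(data)
  }
  data$coerced <- det3 < 0
  for (i in which(det3 < 0)) {
    k <- 0L
    repeat {
      k <- k + 1L
      s <- 1 - k * step
      if (s <= 0) stop("validate_triplets: coercion failed", call. = FALSE)
      if (triplet_determinant(data$r_p1y1[i] * s, data$r_y1y2[i] * s,
                              data$r_p1y2[i] * s) >= 0) break
    }
    s <- 1 - k * step
    data$r_p1y1[i] <- data$r_p1y1[i] * s
    data$r_y1y2[i] <- data$r_y1y2[i] * s
    data$r_p1y2[i] <- data$r_p1y2[i] * s
  }
  data
}

#' Per-effect derived quantities
#'
#' Expands each validated correlation triplet into the three diagnostic
#' regression effects (forward, reverse-time, difference-score), their
#' Fisher-z values, and sampling variances. By default every z-scale quantity
#' gets the `1/(n - 3)` variance; a numeric `v` column in `data`, if present,
#' overrides it for the beta effects.
#'
#' @inheritParams validate_triplets
#' @param coerce Passed to [validate_triplets()].
#' @return A tibble with one row per input effect: the input columns plus
#'   `beta_forward`, `beta_reverse`, `beta_diff`, the six `z_*` columns and
#'   the shared variance `v`.
#' @examples
#' d <- tibble::tibble(study_id = "s1", effect_id = "e1", n = 100,
#'                     r_p1y1 = 0.3, r_y1y2 = 0.6, r_p1y2 = 0.25)
#' derive_effects(d)
#' @export
derive_effects <- function(data, coerce = FALSE) {
  override_v <- if ("v" %in% names(data)) data$v else NULL
  data <- validate_triplets(data, coerce = coerce)
  out <- dplyr::mutate(
    data,
    beta_forward = beta_forward(.data$r_p1y1, .data$r_y1y2, .data$r_p1y2),
    beta_reverse = beta_reverse(.data$r_p1y1, .data$r_y1y2, .data$r_p1y2),
    beta_diff    = beta_diff(.data$r_p1y1, .data$r_y1y2, .data$r_p1y2),
    z_r_p1y1 = fisher_z(.data$r_p1y1),
    z_r_y1y2 = fisher_z(.data$r_y1y2),
    z_r_p1y2 = fisher_z(.data$r_p1y2),
    z_beta_forward = fisher_z(.data$beta_forward),
    z_beta_reverse = fisher_z(.data$beta_reverse),
    z_beta_diff    = fisher_z(.data$beta_diff),
    v = z_sampling_variance(.data$n)
  )
  if (!is.null(override_v)) {
    if (any(!is.finite(override_v) | override_v <= 0)) {
      stop("derive_effects: overriding v must be positive", call. = FALSE)
    }
    out$v <- override_v
  }
  out
}

#' Read a correlations CSV
#'
#' Reads the pipeline input schema `study_id,effect_id,n,r_p1y1,r_y1y2,
#' r_p1y2` (optional `domain` and `v` columns carried through), with an
#' optional column mapping for files using other names.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @param col_map Optional named character vector mapping the canonical names
#'   to the file's column names, e.g. `c(r_p1y1 = "rPY1")`.
#' @return A validated tibble of correlation triplets.
#' @export
read_triplets <- function(path, col_map = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(data)) {
        stop("read_triplets: mapped column not found: ", col_map[[canon]],
             call. = FALSE)
      }
      names(data)[names(data) == col_map[[canon]]] <- canon
    }
  }
  validate_triplets(data)
}
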