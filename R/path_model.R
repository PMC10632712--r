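#' Loadings of the common-factor generative model
#'
#' The no-influence null model: a latent peer-group common factor `CF` (e.g.
#' availability of drugs) loads with `g` on peers' and target youths' general
#' behavior levels (`gPSU`, `gYSU`), which load with `h` on the two measured
#' peer scores (`PSU1`, `PSU2`) and with `i` on the two measured youth scores
#' (`YSU1`, `YSU2`). There is no direct path between peer and youth measures,
#' yet for all loadings strictly inside (0, 1) the baseline-adjusted
#' cross-lagged effect of `PSU1` on `YSU2` is strictly positive.
#'
#' @param g Loading of the common factor on the two general levels.
#' @param h Loading of the general peer level on the measured peer scores.
#' @param i Loading of the general youth level on the measured youth scores.
#' @return A `path_params` list with elements `g`, `h`, `i`.
#' @examples
#' path_params(0.7, 0.7, 0.7)
#' @export
path_params <- function(g, h, i) {
  for (val in c(g, h, i)) {
    if (!is.finite(val) || abs(val) > 1) {
      stop("path_params: loadings must be finite with |value| <= 1",
           call. = FALSE)
    }
  }
  if (any(c(g, h, i) <= 0 | c(g, h, i) >= 1)) {
    warning("path_params: loadings outside (0, 1); the positivity argument ",
            "for the spurious cross-lagged effect no longer applies",
            call. = FALSE)
  }
  structure(list(g = g, h = h, i = i), class = "path_params")
}

# Variables as linear maps of 7 independent standard-normal shocks
# (CF, u_gPSU, u_gYSU, e_PSU1, e_PSU2, e_YSU1, e_YSU2); each structural
# variable has unit population variance by construction.
path_loading_matrix <- function(p) {
  g <- p$g; h <- p$h; i <- p$i
  sg <- sqrt(1 - g^2); sh <- sqrt(1 - h^2); si <- sqrt(1 - i^2)
  L <- rbind(
    CF   = c(1,     0,      0,      0,  0,  0,  0),
    gPSU = c(g,     sg,     0,      0,  0,  0,  0),
    gYSU = c(g,     0,      sg,     0,  0,  0,  0),
    PSU1 = c(h * g, h * sg, 0,      sh, 0,  0,  0),
    PSU2 = c(h * g, h * sg, 0,      0,  sh, 0,  0),
    YSU1 = c(i * g, 0,      i * sg, 0,  0,  si, 0),
    YSU2 = c(i * g, 0,      i * sg, 0,  0,  0,  si)
  )
  colnames(L) <- c("CF", "u_gPSU", "u_gYSU",
                   "e_PSU1", "e_PSU2", "e_YSU1", "e_YSU2")
  L
}

#' Exact implied covariance of the common-factor model
#'
#' Returns the population covariance matrix over the seven structural
#' variables (`CF`, `gPSU`, `gYSU`, `PSU1`, `PSU2`, `YSU1`, `YSU2`), all with
#' unit variance. With `include_error_term = TRUE` the matrix is extended by
#' the measurement-error term `D = YSU1 - gYSU` (the error in the first youth
#' measurement), which has variance `2(1 - i)` and
#' `cov(D, X) = cov(YSU1, X) - cov(gYSU, X)`; `D` is deliberately not
#' re-standardized, so regression coefficients on it are on its natural scale.
#'
#' @param p A [path_params()] object.
#' @param include_error_term Append the derived error term `D`?
#' @return A symmetric covariance matrix with named rows and columns.
#' @examples
#' S <- path_covariance(path_params(0.7, 0.7, 0.7))
#' S["PSU1", "YSU2"]  # g^2 * h * i = 0.2401
#' @export
path_covariance <- function(p, include_error_term = TRUE) {
  stopifnot(inherits(p, "path_params"))
  L <- path_loading_matrix(p)
  S <- tcrossprod(L)
  if (include_error_term) {
    d <- S["YSU1", ] - S["gYSU", ]
    dd <- S["YSU1", "YSU1"] + S["gYSU", "gYSU"] - 2 * S["YSU1", "gYSU"]
    S <- rbind(cbind(S, D = d), D = c(d, dd))
  }
  S
}

#' Expected spurious cross-lagged effect under the null model
#'
#' Closed form for the population coefficient of `PSU1` on `YSU2` adjusting
#' for `YSU1` when data are generated by the common-factor model:
#' \deqn{\frac{g^2 h i (1 - i^2)}{1 - (g^2 h i)^2}}
#' obtained by plugging the implied correlations \eqn{g^2 h i} (cross and
#' contemporaneous) and \eqn{i^2} (autocorrelation) into the adjusted-effect
#' formula. Strictly positive for all loadings in (0, 1).
#'
#' @param p A [path_params()] object.
#' @return The expected standardized forward effect.
#' @examples
#' expected_beta(path_params(0.7, 0.7, 0.7))  # ~0.130
#' @export
expected_beta <- function(p) {
  stopifnot(inherits(p, "path_params"))
  a <- p$g^2 * p$h * p$i
  a * (1 - p$i^2) / (1 - a^2)
}

#' Population regression from a covariance matrix
#'
#' Solves the normal equations on a (sub)covariance matrix: coefficients are
#' the exact population values, free of sampling error. This is the analytic
#' oracle behind every arrow of the simulation demonstration.
#'
#' @param sigma Covariance matrix with named rows/columns, e.g. from
#'   [path_covariance()].
#' @param outcome Name of the outcome variable.
#' @param predictors Character vector of predictor names.
#' @return Named numeric vector of regression coefficients.
#' @examples
#' S <- path_covariance(path_params(0.7, 0.7, 0.7))
#' cov_regress(S, "YSU2", c("PSU1", "YSU1"))
#' @export
cov_regress <- function(sigma, outcome, predictors) {
  vars <- c(outcome, predictors)
  missing_vars <- setdiff(vars, rownames(sigma))
  if (length(missing_vars) > 0) {
    stop("cov_regress: unknown variables: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  Sxx <- sigma[predictors, predictors, drop = FALSE]
  sxy <- sigma[predictors, outcome]
  if (abs(det(Sxx)) < 1e-12) {
    stop("cov_regress: singular predictor covariance", call. = FALSE)
  }
  b <- solve(Sxx, sxy)
  stats::setNames(as.numeric(b), predictors)
}

#' Simulate the common-factor model
#'
#' Draws `n` observations of the seven structural variables by the generative
#' recipe: `CF` standard normal, `gPSU = g*CF + sqrt(1-g^2)*u`, `gYSU`
#' likewise with an independent shock, then each measured score as loading
#' times its general level plus independent noise. Every column has unit
#' population variance. The measurement-error term `D = YSU1 - gYSU` is
#' appended.
#'
#' @param p A [path_params()] object.
#' @param n Number of observations.
#' @param seed Optional integer seed; when supplied the draw is fully
#'   reproducible and the global RNG state is left untouched.
#' @return A tibble with columns `CF`, `gPSU`, `gYSU`, `PSU1`, `PSU2`,
#'   `YSU1`, `YSU2`, `D` and attribute `seed`.
#' @examples
#' sim <- simulate_path_model(path_params(0.7, 0.7, 0.7), n = 1000, seed = 1)
#' cor(sim$PSU1, sim$YSU2)
#' @export
simulate_path_model <- function(p, n, seed = NULL) {
  stopifnot(inherits(p, "path_params"), n >= 1)
  draw <- function() {
    shocks <- matrix(stats::rnorm(n * 7), nrow = n)
    X <- shocks %*% t(path_loading_matrix(p))
    out <- tibble::as_tibble(X)
    out$D <- out$YSU1 - out$gYSU
    out
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "seed") <- seed
  out
}

#' Ordinary least squares on a simulated sample
#'
#' Thin wrapper around [stats::lm()] returning only the slope coefficients,
#' the Monte-Carlo companion to the exact [cov_regress()] oracle.
#'
#' @param data Data frame of simulated observations.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor columns.
#' @return Named numeric vector of estimated slopes.
#' @examples
#' sim <- simulate_path_model(path_params(0.7, 0.7, 0.7), n = 2000, seed = 1)
#' fit_ols(sim, "YSU2", c("PSU1", "YSU1"))
#' @export
fit_ols <- function(data, outcome, predictors) {
  if (nrow(data) <= length(predictors)) {
    stop("fit_ols: need more observations than predictors", call. = FALSE)
  }
  # alias the response so regressing a column on itself stays well-posed
  dat <- as.data.frame(data)[predictors]
  dat$.response <- data[[outcome]]
  f <- stats::reformulate(predictors, response = ".response")
  fit <- stats::lm(f, data = dat)
  if (anyNA(stats::coef(fit))) {
    stop("fit_ols: rank-deficient predictor set", call. = FALSE)
  }
  stats::coef(fit)[predictors]
}
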