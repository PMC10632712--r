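#' Configuration for the synthetic meta-dataset generator
#'
#' Describes a population of longitudinal studies, each measuring a peer
#' predictor at wave 1 and a youth outcome at several consecutive waves, from
#' which per-study Pearson correlation triplets are computed. Defaults
#' emulate the scale of the motivating meta-analytic dataset: 58 independent
#' studies contributing ~152 consecutive-wave effect sizes, per-study sample
#' sizes log-uniform on 50-3000 (expected total N around 42,000).
#'
#' @param n_studies Number of studies (default 58).
#' @param effect_rate Each study contributes `1 + Poisson(effect_rate)`
#'   consecutive-wave effects; the default 1.62 puts the expected total at
#'   about 152.
#' @param n_range Per-study sample sizes are drawn log-uniformly on this
#'   range (default `c(50, 3000)`).
#' @param population Either a [path_params()] object (the no-influence null:
#'   every triplet is `(g^2*h*i, i^2, g^2*h*i)`) or a numeric vector
#'   `c(r_p1y1, r_y1y2, r_p1y2)` of explicit population correlations.
#' @param heterogeneity_sd Between-study SD injected on the Fisher-z scale of
#'   the population correlations (default 0: all studies share one
#'   population).
#' @param seed Optional integer seed for [generate_meta_dataset()].
#' @return A `synth_config` list.
#' @examples
#' synth_config(population = path_params(0.7, 0.7, 0.7), seed = 1)
#' @export
synth_config <- function(n_studies = 58, effect_rate = 1.62,
                         n_range = c(50, 3000),
                         population = path_params(0.7, 0.7, 0.7),
                         heterogeneity_sd = 0, seed = NULL) {
  stopifnot(n_studies >= 1, effect_rate >= 0,
            length(n_range) == 2, n_range[1] >= 10, n_range[2] >= n_range[1],
            heterogeneity_sd >= 0)
  if (!inherits(population, "path_params")) {
    population <- as.numeric(population)
    if (length(population) != 3 || any(abs(population) >= 1)) {
      stop("synth_config: explicit population must be three correlations ",
           "strictly inside (-1, 1)", call. = FALSE)
    }
    if (triplet_determinant(population[1], population[2],
                            population[3]) < 0) {
      stop("synth_config: explicit population triplet is not PSD",
           call. = FALSE)
    }
    names(population) <- c("r_p1y1", "r_y1y2", "r_p1y2")
  }
  structure(list(n_studies = n_studies, effect_rate = effect_rate,
                 n_range = n_range, population = population,
                 heterogeneity_sd = heterogeneity_sd, seed = seed),
            class = "synth_config")
}

population_triplet <- function(population) {
  if (inherits(population, "path_params")) {
    a <- population$g^2 * population$h * population$i
    c(r_p1y1 = a, r_y1y2 = population$i^2, r_p1y2 = a)
  } else {
    population
  }
}

# Population correlation matrix over (P1, Y_1, ..., Y_{m+1}) consistent with
# the triplet (a, b, c) on the first consecutive wave pair. Youth waves are
# AR(1) with lag-1 correlation b. The P1 x wave correlation decays
# geometrically, corr(P1, Y_t) = a * (c/a)^(t-1), so every consecutive pair
# shares the same cross/contemporaneous ratio; under a null (path-model)
# population a == c and all waves are exchangeable with corr(P1, Y_t)
# constant.
wave_correlation <- function(triplet, n_waves) {
  a <- triplet[["r_p1y1"]]; b <- triplet[["r_y1y2"]]; c <- triplet[["r_p1y2"]]
  S <- diag(n_waves + 1)
  yy <- outer(seq_len(n_waves), seq_len(n_waves),
              function(t, s) b^abs(t - s))
  S[-1, -1] <- yy
  py <- if (abs(a) > 1e-8) {
    a * (c / a)^(seq_len(n_waves) - 1)
  } else {
    c(0, c * b^(seq_len(n_waves - 1) - 1))[seq_len(n_waves)]
  }
  S[1, -1] <- py
  S[-1, 1] <- py
  dimnames(S) <- list(c("P1", paste0("Y", seq_len(n_waves))),
                      c("P1", paste0("Y", seq_len(n_waves))))
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop("wave_correlation: population wave matrix is not PSD", call. = FALSE)
  }
  S
}

perturb_triplet <- function(triplet, sd, max_attempts = 100) {
  if (sd == 0) return(triplet)
  for (attempt in seq_len(max_attempts)) {
    z <- atanh(triplet) + stats::rnorm(3, 0, sd)
    r <- tanh(z)
    if (triplet_determinant(r[1], r[2], r[3]) >= 0) {
      names(r) <- names(triplet)
      return(r)
    }
  }
  stop("perturb_triplet: no PSD perturbation in ", max_attempts, " attempts",
       call. = FALSE)
}

#' Generate one synthetic study
#'
#' Draws one study's raw multivariate-normal data (peer predictor at wave 1,
#' youth outcome at `m + 1` consecutive waves, `m` = number of effects) under
#' the study's population model and returns the `m` consecutive-wave sample
#' correlation triplets. Because the triplets are sample Pearson correlations
#' from one continuous sample they are automatically jointly consistent
#' (PSD), and a study's effects carry realistic dependence (adjacent triplets
#' share a wave). Uses the current RNG state; seed via
#' [generate_meta_dataset()] or [withr::with_seed()].
#'
#' @param config A [synth_config()].
#' @param study_index Integer study label.
#' @param n,m Optional overrides for the study's sample size and effect
#'   count; drawn from the config's samplers when `NULL`.
#' @return A tibble of `m` correlation-triplet rows plus a `truth` attribute
#'   with the study's population values per effect.
#' @export
generate_study <- function(config, study_index, n = NULL, m = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(n)) {
    n <- round(exp(stats::runif(1, log(config$n_range[1]),
                                log(config$n_range[2]))))
  }
  if (is.null(m)) m <- 1 + stats::rpois(1, config$effect_rate)
  # a perturbed triplet can be PSD as a 3x3 yet break the multi-wave
  # extension (geometric decay pushes later cross correlations out of
  # range); resample the perturbation until the full wave matrix is PSD
  S <- NULL
  for (attempt in seq_len(if (config$heterogeneity_sd > 0) 100L else 1L)) {
    pop <- perturb_triplet(population_triplet(config$population),
                           config$heterogeneity_sd)
    S <- tryCatch(wave_correlation(pop, n_waves = m + 1),
                  error = function(e) NULL)
    if (!is.null(S)) break
  }
  if (is.null(S)) {
    stop("generate_study: no PSD wave structure after 100 perturbation ",
         "attempts", call. = FALSE)
  }
  X <- MASS::mvrnorm(n, mu = rep(0, ncol(S)), Sigma = S)
  colnames(X) <- colnames(S)
  R <- stats::cor(X)
  sid <- sprintf("s%03d", study_index)
  rows <- purrr::map(seq_len(m), function(t) {
    tibble::tibble(
      study_id = sid, effect_id = sprintf("e%d", t), n = n,
      r_p1y1 = R["P1", paste0("Y", t)],
      r_y1y2 = R[paste0("Y", t), paste0("Y", t + 1)],
      r_p1y2 = R["P1", paste0("Y", t + 1)]
    )
  }) |> purrr::list_rbind()
  truth <- purrr::map(seq_len(m), function(t) {
    tibble::tibble(
      study_id = sid, effect_id = sprintf("e%d", t), n = n,
      pop_r_p1y1 = S["P1", paste0("Y", t)],
      pop_r_y1y2 = S[paste0("Y", t), paste0("Y", t + 1)],
      pop_r_p1y2 = S["P1", paste0("Y", t + 1)]
    )
  }) |> purrr::list_rbind()
  attr(rows, "truth") <- truth
  rows
}

#' Generate a full synthetic meta-analytic dataset
#'
#' Draws every study of the configured population and stacks the resulting
#' correlation triplets into the pipeline's input schema. The `truth`
#' attribute records each effect's population correlations (and the config)
#' for parameter-recovery tests.
#'
#' @param config A [synth_config()]; its `seed`, when set, makes the dataset
#'   bit-identical across runs.
#' @return A tibble with columns `study_id`, `effect_id`, `n`, `r_p1y1`,
#'   `r_y1y2`, `r_p1y2`, attributes `truth` (tibble) and `config`.
#' @examples
#' d <- generate_meta_dataset(synth_config(n_studies = 5, seed = 42))
#' head(d)
#' @export
generate_meta_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  gen <- function() {
    studies <- purrr::map(seq_len(config$n_studies),
                          function(i) generate_study(config, i))
    rows <- purrr::list_rbind(studies)
    attr(rows, "truth") <- purrr::list_rbind(purrr::map(studies,
                                                        attr, "truth"))
    rows
  }
  out <- if (is.null(config$seed)) gen() else withr::with_seed(config$seed,
                                                               gen())
  attr(out, "config") <- config
  out
}

#' Write a synthetic dataset and its truth sidecar
#'
#' Writes the input CSV (`correlations.csv`) and a `truth.json` sidecar
#' holding the per-effect population values, the seed, and the config echo.
#'
#' @param dataset Output of [generate_meta_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_meta_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, "correlations.csv")
  readr::write_csv(dataset, csv_path)
  config <- attr(dataset, "config")
  pop <- config$population
  sidecar <- list(
    truth = attr(dataset, "truth"),
    seed = config$seed,
    config = list(
      n_studies = config$n_studies, effect_rate = config$effect_rate,
      n_range = config$n_range, heterogeneity_sd = config$heterogeneity_sd,
      population = if (inherits(pop, "path_params")) {
        list(type = "path_model", g = pop$g, h = pop$h, i = pop$i)
      } else {
        list(type = "explicit", r_p1y1 = pop[["r_p1y1"]],
             r_y1y2 = pop[["r_y1y2"]], r_p1y2 = pop[["r_p1y2"]])
      }
    )
  )
  json_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(correlations = csv_path, truth = json_path))
}
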