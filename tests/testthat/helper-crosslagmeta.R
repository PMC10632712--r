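# Draw a random correlation triplet with a PSD implied 3x3 matrix
# (rejection sampling; correlations kept away from the +/-1 boundary).
random_psd_triplet <- function(max_abs = 0.95) {
  repeat {
    r <- stats::runif(3, -max_abs, max_abs)
    if (1 + 2 * r[1] * r[2] * r[3] - sum(r^2) >= 0) {
      return(r)
    }
  }
}

# Brute-force normal-equations solution for the adjusted effect of P1 on the
# chosen wave: builds the full 3x3 correlation matrix over (P1, Y1, Y2) and
# solves the 2-predictor system directly. Independent of the closed forms.
normal_equations_beta <- function(r_p1y1, r_y1y2, r_p1y2,
                                  outcome = c("Y2", "Y1")) {
  outcome <- match.arg(outcome)
  R <- matrix(c(1,      r_p1y1, r_p1y2,
                r_p1y1, 1,      r_y1y2,
                r_p1y2, r_y1y2, 1), 3, 3,
              dimnames = list(c("P1", "Y1", "Y2"), c("P1", "Y1", "Y2")))
  covariate <- setdiff(c("Y1", "Y2"), outcome)
  b <- solve(R[c("P1", covariate), c("P1", covariate)],
             R[c("P1", covariate), outcome])
  unname(b["P1"])
}

# Hand-rolled DerSimonian-Laird pool (fixed-effect Q, closed-form tau2,
# re-weighted mean), used as an independent oracle for the metafor-backed
# pooling path.
dl_pool_by_hand <- function(z, v) {
  w <- 1 / v
  zbar_fe <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar_fe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (length(z) - 1)) / C)
  ws <- 1 / (v + tau2)
  list(Q = Q, tau2 = tau2,
       estimate_z = sum(ws * z) / sum(ws),
       se_z = sqrt(1 / sum(ws)))
}

tiny_triplet_table <- function() {
  tibble::tibble(
    study_id = c("s1", "s1", "s2", "s3"),
    effect_id = c("e1", "e2", "e1", "e1"),
    n = c(120, 120, 250, 80),
    r_p1y1 = c(0.30, 0.28, 0.35, 0.25),
    r_y1y2 = c(0.60, 0.55, 0.58, 0.62),
    r_p1y2 = c(0.25, 0.24, 0.28, 0.20)
  )
}
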