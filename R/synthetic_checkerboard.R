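#' Hill-type single-drug kill curve
#'
#' Parametric stand-in for a measured single-drug dose response: the fraction
#' of cells killed at dose c is
#' \eqn{kill(c) = E_{max} c^h / (c^h + IC_{50}^h)}, monotone in dose with
#' kill(0) = 0 and kill(Inf) = `max_kill`.
#'
#' @param ic50 dose of half-maximal kill (concentration units, > 0).
#' @param hill_slope Hill coefficient (> 0).
#' @param max_kill maximal kill fraction in \[0, 1\].
#' @return object of class `hill_curve`.
#' @export
hill_curve <- function(ic50, hill_slope = 1, max_kill = 1) {
  stopifnot(ic50 > 0, hill_slope > 0, max_kill >= 0, max_kill <= 1)
  structure(list(ic50 = ic50, hill_slope = hill_slope, max_kill = max_kill),
            class = "hill_curve")
}

#' Kill fraction of a Hill curve at given doses
#' @param curve a [hill_curve()].
#' @param dose numeric vector of non-negative doses.
#' @return kill fractions in \[0, max_kill\].
#' @export
kill_fraction <- function(curve, dose) {
  stopifnot(inherits(curve, "hill_curve"), all(dose >= 0))
  x <- (dose / curve$ic50)^curve$hill_slope
  curve$max_kill * x / (1 + x)
}

# dose on a Hill curve producing kill fraction `effect` (inverse of
# kill_fraction); NA where the curve never reaches the effect
hill_inverse <- function(curve, effect) {
  out <- rep(NA_real_, length(effect))
  ok <- effect >= 0 & effect < curve$max_kill
  r <- effect[ok] / (curve$max_kill - effect[ok])
  out[ok] <- curve$ic50 * r^(1 / curve$hill_slope)
  out[effect == 0] <- 0
  out
}

#' Construct a dose-response surface object
#'
#' Container for a drugs-by-concentrations grid of relative viability
#' (drug-treated over untreated cell number) for one cell line, with the
#' untreated control's population doublings over the assay window.
#'
#' @param drug_names length-2 character vector.
#' @param dose_a,dose_b ascending dose axes, each starting at 0 (the vehicle
#'   row/column).
#' @param relative_viability matrix (length(dose_a) x length(dose_b)) of
#'   positive values; ~1 at the all-zero dose.
#' @param control_doublings untreated population doublings over the assay
#'   window (e.g. 3 for a 24 h doubling time over 72 h).
#' @return object of class `dose_response_surface`.
#' @export
dose_response_surface <- function(drug_names, dose_a, dose_b,
                                  relative_viability, control_doublings = 3) {
  stopifnot(length(drug_names) == 2,
            nrow(relative_viability) == length(dose_a),
            ncol(relative_viability) == length(dose_b))
  if (dose_a[1] != 0 || dose_b[1] != 0)
    stop("dose axes must start at the zero (vehicle) dose")
  if (any(diff(dose_a) <= 0) || any(diff(dose_b) <= 0))
    stop("dose axes must be strictly increasing")
  if (any(c(dose_a[-1], dose_b[-1]) <= 0))
    stop("non-zero doses must be positive")
  if (any(relative_viability < 0))
    stop("relative viability must be non-negative")
  structure(list(drug_names = drug_names, dose_a = dose_a, dose_b = dose_b,
                 relative_viability = relative_viability,
                 control_doublings = control_doublings),
            class = "dose_response_surface")
}

#' @export
print.dose_response_surface <- function(x, ...) {
  cat(sprintf("Dose-response surface: %s x %s (%d x %d doses incl. vehicle)\n",
              x$drug_names[1], x$drug_names[2],
              length(x$dose_a), length(x$dose_b)))
  cat(sprintf("Control doublings: %.2f; viability range %.3g-%.3g\n",
              x$control_doublings, min(x$relative_viability),
              max(x$relative_viability)))
  invisible(x)
}

# combined kill for two Loewe-additive Hill curves at dose pair (ca, cb):
# the effect E satisfying ca/D_a(E) + cb/D_b(E) = 1 (dose equivalence)
loewe_kill <- function(curve_a, curve_b, ca, cb) {
  if (ca == 0 && cb == 0) return(0)
  if (cb == 0) return(kill_fraction(curve_a, ca))
  if (ca == 0) return(kill_fraction(curve_b, cb))
  emax <- min(curve_a$max_kill, curve_b$max_kill)
  g <- function(e) {
    da <- hill_inverse(curve_a, e)
    db <- hill_inverse(curve_b, e)
    ca / da + cb / db - 1
  }
  lo <- 1e-12
  hi <- emax * (1 - 1e-9)
  # g decreases from +Inf (e -> 0); if still positive at the ceiling the
  # doses achieve at least the joint maximal effect
  if (g(hi) >= 0) return(emax)
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Simulate an 11 x 11 drug-drug checkerboard
#'
#' Generates the standard two-drug interaction experiment: each drug spans a
#' log-spaced gradient (default 11 doses covering a 100-fold range centred on
#' its IC50, plus the vehicle dose), and the combined kill at each dose pair
#' follows a configurable interaction rule. Under `bliss`, combined survival
#' is the product of single-drug survivals; under `loewe`, the combination
#' acts by dose equivalence on the constituent curves; `antagonism_factor`
#' interpolates the combined kill between the Bliss expectation (weight
#' `1/antagonism`) and the highest-single-agent kill, weakening the
#' combination while leaving the single-drug margins intact. Multiplicative
#' log-normal noise with coefficient of variation `noise_cv` is applied to
#' the final relative viability.
#'
#' @param curve_a,curve_b [hill_curve()] objects for the two drugs.
#' @param interaction `"bliss"`, `"loewe"` or `"antagonism_factor"`.
#' @param n_doses non-zero doses per axis (default 11).
#' @param fold_range ratio of top to bottom non-zero dose (default 100).
#' @param noise_cv multiplicative noise CV (>= 0; default 0).
#' @param antagonism antagonism strength (> 1 antagonistic) used when
#'   `interaction = "antagonism_factor"`.
#' @param control_doublings untreated doublings over the assay window.
#' @param drug_names names for the two drugs.
#' @param seed integer seed for the noise draw.
#' @return a [dose_response_surface()]; attribute `true_kill` holds the
#'   noise-free kill grid.
#' @export
simulate_checkerboard <- function(curve_a, curve_b,
                                  interaction = c("bliss", "loewe",
                                                  "antagonism_factor"),
                                  n_doses = 11, fold_range = 100,
                                  noise_cv = 0, antagonism = 2,
                                  control_doublings = 3,
                                  drug_names = c("drug_a", "drug_b"),
                                  seed = 1L) {
  interaction <- match.arg(interaction)
  stopifnot(noise_cv >= 0)
  axis <- function(curve) {
    half <- sqrt(fold_range)
    c(0, exp(seq(log(curve$ic50 / half), log(curve$ic50 * half),
                 length.out = n_doses)))
  }
  dose_a <- axis(curve_a)
  dose_b <- axis(curve_b)
  kill <- matrix(0, length(dose_a), length(dose_b))
  for (i in seq_along(dose_a)) {
    for (j in seq_along(dose_b)) {
      ka <- kill_fraction(curve_a, dose_a[i])
      kb <- kill_fraction(curve_b, dose_b[j])
      kill[i, j] <- switch(interaction,
        bliss = 1 - (1 - ka) * (1 - kb),
        loewe = loewe_kill(curve_a, curve_b, dose_a[i], dose_b[j]),
        antagonism_factor = (ka + kb - ka * kb) / antagonism +
          (1 - 1 / antagonism) * max(ka, kb))
    }
  }
  rv <- 1 - kill
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    rv <- rv * matrix(stats::rlnorm(length(rv), -sdlog^2 / 2, sdlog),
                      nrow(rv), ncol(rv))
  }
  out <- dose_response_surface(drug_names, dose_a, dose_b, rv,
                               control_doublings)
  attr(out, "true_kill") <- kill
  out
}

#' Simulate the dose response of a fixed-ratio drug mixture
#'
#' Generates the fixed-ratio (diagonal) design used for higher-order
#' combinations: drugs are mixed at constant weights and the total dose is
#' increased along a gradient. Under `loewe` the mixture acts by dose
#' equivalence on the constituent curves (sham-additive); under `bliss`
#' survival is the product of constituent survivals; `antagonism_factor`
#' divides the dose-equivalent contribution of the first two drugs by
#' `antagonism`, emulating a pairwise antagonistic interaction embedded in
#' the mixture.
#'
#' @param curves list of [hill_curve()] objects.
#' @param weights mixture weights summing to 1; default equipotent at 50%
#'   kill via [design_equipotent_mixture()].
#' @param total_doses ascending positive total doses; default 14 log-spaced
#'   doses spanning 100-fold around the predicted 50%-kill total.
#' @param interaction `"loewe"`, `"bliss"` or `"antagonism_factor"`.
#' @param antagonism antagonism strength for the first drug pair (> 1).
#' @param noise_cv multiplicative log-normal noise CV (default 0).
#' @param n_replicates replicate measurements per dose (default 1).
#' @param seed integer seed for the noise draw.
#' @return data frame with columns `total_dose`, `replicate`,
#'   `relative_viability`; attribute `weights` holds the mixture weights.
#' @export
simulate_mixture_response <- function(curves, weights = NULL,
                                      total_doses = NULL,
                                      interaction = c("loewe", "bliss",
                                                      "antagonism_factor"),
                                      antagonism = 2, noise_cv = 0,
                                      n_replicates = 1, seed = 1L) {
  interaction <- match.arg(interaction)
  stopifnot(all(vapply(curves, inherits, TRUE, "hill_curve")))
  if (is.null(weights)) {
    weights <- design_equipotent_mixture(curves)$weights
  }
  stopifnot(length(weights) == length(curves), all(weights > 0))
  weights <- weights / sum(weights)
  if (is.null(total_doses)) {
    t50 <- mixture_cross_total(curves, weights, 0.5)
    total_doses <- exp(seq(log(t50 / 10), log(t50 * 10), length.out = 14))
  }
  kill <- vapply(total_doses, function(tt)
    mixture_kill(curves, weights, tt, interaction, antagonism), numeric(1))
  rv0 <- 1 - kill
  set.seed(as.integer(seed))
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    rv <- if (sdlog > 0)
      rv0 * stats::rlnorm(length(rv0), -sdlog^2 / 2, sdlog) else rv0
    data.frame(total_dose = total_doses, replicate = r,
               relative_viability = rv)
  }))
  attr(out, "weights") <- weights
  out
}

# combined kill of a fixed-ratio mixture at one total dose
mixture_kill <- function(curves, weights, total, interaction, antagonism = 2) {
  doses <- weights * total
  if (interaction == "bliss") {
    surv <- prod(1 - vapply(seq_along(curves), function(i)
      kill_fraction(curves[[i]], doses[i]), numeric(1)))
    return(1 - surv)
  }
  # Loewe dose equivalence: find E with sum_i c_i / D_i(E) = 1; under
  # antagonism_factor the first two drugs' contributions are divided by
  # `antagonism`
  scale <- rep(1, length(curves))
  if (interaction == "antagonism_factor" && length(curves) >= 2)
    scale[1:2] <- 1 / antagonism
  emax <- min(vapply(curves, function(cv) cv$max_kill, numeric(1)))
  g <- function(e) {
    s <- sum(vapply(seq_along(curves), function(i)
      scale[i] * doses[i] / hill_inverse(curves[[i]], e), numeric(1)))
    s - 1
  }
  hi <- emax * (1 - 1e-9)
  if (g(hi) >= 0) return(emax)
  stats::uniroot(g, c(1e-12, hi), tol = 1e-12)$root
}

# total dose at which a noise-free Loewe mixture crosses `effect`
mixture_cross_total <- function(curves, weights, effect) {
  d <- vapply(curves, function(cv) hill_inverse(cv, effect), numeric(1))
  if (anyNA(d)) stop("a constituent never reaches the reference effect")
  1 / sum(weights / d)
}
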