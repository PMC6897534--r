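#' Design an equipotent fixed-ratio drug mixture
#'
#' Weights each drug in proportion to its single-agent dose at a reference
#' effect (default 50% kill), so that every constituent contributes similarly
#' to cytotoxicity as the total mixture dose is raised. In the resulting
#' potency-scaled units, one unit of any constituent has equal single-agent
#' activity.
#'
#' @param single_curves named list of [hill_curve()] objects, or of data
#'   frames with columns `dose` and `relative_viability` (interpolated in log
#'   dose).
#' @param effect_level reference kill fraction (default 0.5).
#' @return object of class `mixture_design`: list with `drug_names`,
#'   `weights` (positive, summing to 1, in concentration units) and
#'   `ref_doses` (each drug's single-agent dose at the reference effect).
#' @export
design_equipotent_mixture <- function(single_curves, effect_level = 0.5) {
  nm <- names(single_curves)
  if (is.null(nm)) nm <- paste0("drug_", seq_along(single_curves))
  ref <- vapply(seq_along(single_curves), function(i) {
    cv <- single_curves[[i]]
    d <- if (inherits(cv, "hill_curve")) hill_inverse(cv, effect_level)
         else cross_dose(cv$dose, 1 - cv$relative_viability, effect_level,
                         quiet = TRUE)
    if (is.na(d))
      stop(sprintf("drug '%s' never reaches the reference effect (%.0f%% kill)",
                   nm[i], 100 * effect_level))
    d
  }, numeric(1))
  structure(list(drug_names = nm, weights = ref / sum(ref), ref_doses = ref),
            class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat("Equipotent mixture design\n")
  for (i in seq_along(x$drug_names))
    cat(sprintf("  %s: weight %.3f (single-agent reference dose %.4g)\n",
                x$drug_names[i], x$weights[i], x$ref_doses[i]))
  invisible(x)
}

# first level crossing of a monotone-interpolated effect curve, in log10 dose;
# returns NA when the level is never reached
cross_dose <- function(dose, effect, level, quiet = FALSE) {
  keep <- dose > 0
  dose <- dose[keep]; effect <- effect[keep]
  o <- order(dose)
  dose <- dose[o]; effect <- effect[o]
  above <- effect >= level
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(dose[1])
  if (!quiet && any(diff(above[i:length(above)]) < 0))
    warning("non-monotone crossing; using first crossing")
  f <- (level - effect[i - 1]) / (effect[i] - effect[i - 1])
  10^(log10(dose[i - 1]) + f * (log10(dose[i]) - log10(dose[i - 1])))
}

#' Fractional inhibitory concentration of a fixed-ratio mixture
#'
#' At an effect level reached by the mixture at total dose T and by single
#' agents at doses \eqn{A_i}, the fractional inhibitory concentration is
#' \deqn{FIC = \sum_i w_i T / A_i} where \eqn{w_i} are the mixture weights.
#' FIC = 1 indicates Loewe additivity (a drug combined with itself scores
#' exactly 1), FIC < 0.5 is conventional synergy, FIC > 1 antagonism.
#' Crossings are located by monotone piecewise-linear interpolation in log10
#' dose; the first crossing is used (with a warning if the response is
#' non-monotone). When the mixture response has a `replicate` column, a
#' per-replicate FIC is computed and a 95% t-interval reported.
#'
#' @param mixture_response data frame with columns `total_dose`,
#'   `relative_viability` and optionally `replicate` (e.g. from
#'   [simulate_mixture_response()]).
#' @param single_curves named list of [hill_curve()] objects or
#'   dose/relative_viability data frames, one per constituent.
#' @param weights mixture weights (default: taken from the `weights`
#'   attribute of `mixture_response`).
#' @param effect_level kill fraction defining the effect (default 0.5).
#' @return object of class `fic_result`: list with `drug_set`,
#'   `effect_level`, `fic`, `ci95` (NA without replicates), `mixture_dose`
#'   (total dose at the crossing) and `single_doses`.
#' @export
compute_fic <- function(mixture_response, single_curves, weights = NULL,
                        effect_level = 0.5) {
  if (is.null(weights)) weights <- attr(mixture_response, "weights")
  if (is.null(weights))
    stop("mixture weights must be given or attached to mixture_response")
  stopifnot(length(weights) == length(single_curves))
  weights <- weights / sum(weights)
  nm <- names(single_curves)
  if (is.null(nm)) nm <- paste0("drug_", seq_along(single_curves))
  single_doses <- vapply(seq_along(single_curves), function(i) {
    cv <- single_curves[[i]]
    d <- if (inherits(cv, "hill_curve")) hill_inverse(cv, effect_level)
         else cross_dose(cv$dose, 1 - cv$relative_viability, effect_level)
    if (is.na(d))
      stop(sprintf("drug '%s' never reaches the effect level", nm[i]))
    d
  }, numeric(1))
  fic_of <- function(df) {
    agg <- stats::aggregate(relative_viability ~ total_dose, df, mean)
    tt <- cross_dose(agg$total_dose, 1 - agg$relative_viability, effect_level)
    if (is.na(tt)) stop("mixture never reaches the effect level")
    sum(weights * tt / single_doses)
  }
  fic <- fic_of(mixture_response)
  ci95 <- c(NA_real_, NA_real_)
  if (!is.null(mixture_response$replicate) &&
      length(unique(mixture_response$replicate)) > 1) {
    per_rep <- vapply(split(mixture_response, mixture_response$replicate),
                      fic_of, numeric(1))
    se <- stats::sd(per_rep) / sqrt(length(per_rep))
    tq <- stats::qt(0.975, length(per_rep) - 1)
    ci95 <- mean(per_rep) + c(-1, 1) * tq * se
  }
  agg <- stats::aggregate(relative_viability ~ total_dose, mixture_response,
                          mean)
  structure(list(drug_set = nm, effect_level = effect_level, fic = fic,
                 ci95 = ci95,
                 mixture_dose = cross_dose(agg$total_dose,
                                           1 - agg$relative_viability,
                                           effect_level, quiet = TRUE),
                 single_doses = single_doses, weights = weights),
            class = "fic_result")
}

#' @export
print.fic_result <- function(x, ...) {
  cat(sprintf("FIC at %.0f%% kill for %s: %.3f", 100 * x$effect_level,
              paste(x$drug_set, collapse = " + "), x$fic))
  if (!anyNA(x$ci95)) cat(sprintf("  (95%% CI %.3f-%.3f)", x$ci95[1],
                                  x$ci95[2]))
  cat("\n")
  invisible(x)
}

#' Emergent interaction of a higher-order drug combination
#'
#' An N-drug combination can deviate from additivity either because of
#' pairwise/lower-order interactions among its constituents or because of a
#' genuinely emergent N-way interaction. The emergent FIC isolates the
#' latter: the observed N-drug FIC is divided by a dose-additive prediction
#' composed from the measured (N-1)-order FICs. Each (N-1)-subset mixture is
#' treated as a pseudo-drug with potency given by its measured FIC and
#' composed dose-additively with the remaining single agent (equipotent
#' units); the decomposition that best explains the observation (smallest
#' absolute log10 deviation) provides the prediction. Emergent FIC = 1 means
#' no interaction beyond those already present at lower order; > 1 emergent
#' antagonism, < 1 emergent synergy.
#'
#' @param fic_by_subset named numeric vector of FICs; names are drug subsets
#'   joined by "+" (order irrelevant), e.g. `c("A+B" = 1, "A+B+C" = 1.5)`.
#'   Must contain the full set and all its (N-1)-subsets.
#' @param drug_set character vector (length >= 3) of the drugs in the
#'   combination.
#' @return emergent FIC (single number); attribute `prediction` holds the
#'   composed lower-order prediction used.
#' @export
emergent_fic <- function(fic_by_subset, drug_set) {
  n <- length(drug_set)
  if (n < 3) stop("emergent interactions are defined for 3 or more drugs")
  key <- function(set) paste(sort(set), collapse = "+")
  lookup <- stats::setNames(fic_by_subset,
                            vapply(strsplit(names(fic_by_subset), "+",
                                            fixed = TRUE),
                                   key, character(1)))
  need <- c(key(drug_set),
            vapply(seq_len(n), function(i) key(drug_set[-i]), character(1)))
  missing <- setdiff(need, names(lookup))
  if (length(missing))
    stop("missing FIC for subset(s): ", paste(missing, collapse = ", "))
  fic_n <- lookup[[key(drug_set)]]
  preds <- vapply(seq_len(n), function(i) {
    fic_s <- lookup[[key(drug_set[-i])]]
    # pseudo-drug composition in equipotent units: the (N-1)-mixture carries
    # weight (n-1)/n with potency 1/FIC_S, the remaining agent weight 1/n
    1 / (((n - 1) / n) / fic_s + 1 / n)
  }, numeric(1))
  i_best <- which.min(abs(log10(fic_n / preds)))
  out <- fic_n / preds[i_best]
  attr(out, "prediction") <- preds[i_best]
  out
}
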