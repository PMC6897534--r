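#' Theoretical bounds on multi-drug resistance frequency
#'
#' For drugs with single-drug resistance frequencies \eqn{10^{-A}, 10^{-B},
#' \ldots}, the lowest possible frequency of clones resistant to all drugs is
#' the product of the single frequencies (resistance acquired independently),
#' and the highest possible frequency is the smallest single frequency (the
#' rarer resistant set fully nested in the others).
#'
#' @param single_freqs numeric vector of per-drug resistance frequencies, each
#'   in (0, 1]. Counts on a common denominator may be used instead of
#'   frequencies as long as `observed` (in downstream calls) shares the
#'   denominator.
#' @return named numeric vector with elements `min_mdr` (product) and
#'   `max_mdr` (minimum).
#' @seealso [estimate_xi()]
#' @export
mdr_bounds <- function(single_freqs) {
  if (length(single_freqs) == 0) stop("need at least one resistance frequency")
  if (any(!is.finite(single_freqs)) || any(single_freqs <= 0))
    stop("resistance frequencies must be positive and finite")
  c(min_mdr = prod(single_freqs), max_mdr = min(single_freqs))
}

#' Estimate the cross-resistance parameter xi
#'
#' The observed multi-drug resistance (MDR) frequency is modelled as a
#' weighted sum of the two extreme scenarios:
#' \deqn{MDR = \xi \cdot \min_i f_i + (1 - \xi) \prod_i f_i}
#' so that \eqn{\xi = 0} corresponds to independent resistance (MDR at its
#' theoretical minimum) and \eqn{\xi = 1} to maximal overlap. Inputs may be
#' frequencies or counts, provided all share one denominator.
#'
#' @param single_freqs per-drug single-drug resistance frequencies; may be
#'   NULL when `min_mdr` and `max_mdr` are supplied directly.
#' @param observed_mdr observed frequency (or count) of clones/genes resistant
#'   to all drugs in the set.
#' @param drug_set optional character vector naming the drugs.
#' @param min_mdr,max_mdr optional precomputed bounds overriding
#'   [mdr_bounds()]; use these when working on a count scale (e.g. a
#'   predicted minimum of 1 gene and maximum of 132 genes), keeping all
#'   three quantities on one common denominator.
#' @return an object of class `xi_result`: list with `drug_set`,
#'   `single_freqs`, `observed_mdr`, `min_mdr`, `max_mdr`, `xi`,
#'   `out_of_range` (TRUE when the observed value fell outside the
#'   \[min, max\] bracket and xi was clamped to \[0, 1\]).
#' @examples
#' # one gene expected by chance, 132 at maximal overlap, 18 observed
#' estimate_xi(NULL, observed_mdr = 18, min_mdr = 1, max_mdr = 132)
#' @export
estimate_xi <- function(single_freqs, observed_mdr, drug_set = NULL,
                        min_mdr = NULL, max_mdr = NULL) {
  b <- if (is.null(min_mdr) || is.null(max_mdr)) mdr_bounds(single_freqs)
       else c(min_mdr = min_mdr, max_mdr = max_mdr)
  if (b[["min_mdr"]] > b[["max_mdr"]])
    stop("min_mdr exceeds max_mdr")
  if (!is.finite(observed_mdr) || observed_mdr < 0)
    stop("observed_mdr must be a non-negative finite number")
  if (b["min_mdr"] == b["max_mdr"]) {
    xi <- NA_real_
    oor <- FALSE
    warning("min and max MDR coincide; xi is undefined")
  } else {
    xi <- (b[["min_mdr"]] - observed_mdr) / (b[["min_mdr"]] - b[["max_mdr"]])
    oor <- xi < 0 || xi > 1
    xi <- min(max(xi, 0), 1)
  }
  structure(
    list(drug_set = drug_set, single_freqs = single_freqs,
         observed_mdr = observed_mdr,
         min_mdr = b[["min_mdr"]], max_mdr = b[["max_mdr"]],
         xi = xi, out_of_range = oor),
    class = "xi_result")
}

#' @export
print.xi_result <- function(x, ...) {
  if (!is.null(x$drug_set))
    cat("Drug set:", paste(x$drug_set, collapse = " + "), "\n")
  if (!is.null(x$single_freqs))
    cat(sprintf("Single-drug frequencies: %s\n",
                paste(signif(x$single_freqs, 4), collapse = ", ")))
  cat(sprintf("MDR observed %.4g  [min %.4g (xi=0), max %.4g (xi=1)]\n",
              x$observed_mdr, x$min_mdr, x$max_mdr))
  cat(sprintf("Cross-resistance xi = %.3f%s\n", x$xi,
              if (x$out_of_range) " (observed outside bounds; clamped)" else ""))
  invisible(x)
}

#' Expected survivors under the log-kill model
#'
#' The number of cancer cells surviving n drugs with independent (non
#' cross-resistant) surviving fractions is \eqn{P_0 \prod_i f_i}; each drug's
#' log-kills add on the log scale.
#'
#' @param p0 initial cell count (positive).
#' @param f per-drug surviving fraction, each in (0, 1].
#' @return list with `survivors`, `log_kills` (per drug, \eqn{-\log_{10} f_i})
#'   and `total_log_kills`.
#' @examples
#' survivors(1e10, c(0.01, 0.01)) # 1e6 cells survive; 4 log-kills
#' @export
survivors <- function(p0, f) {
  stopifnot(p0 > 0, all(f > 0), all(f <= 1))
  lk <- -log10(f)
  list(survivors = p0 * prod(f), log_kills = lk, total_log_kills = sum(lk))
}

#' Expected clone coverage of a cell sample
#'
#' Fraction of `n_clones` equally abundant clones expected to be represented
#' at least once in a random sample of `n_cells_sampled` cells:
#' \eqn{1 - (1 - 1/n)^m}.
#'
#' @param n_clones number of distinct clones in the pool.
#' @param n_cells_sampled number of cells drawn (with random assortment).
#' @return expected represented fraction in \[0, 1\].
#' @examples
#' clone_coverage(1e6, 12.5e6) # > 0.99999
#' @export
clone_coverage <- function(n_clones, n_cells_sampled) {
  stopifnot(n_clones >= 1, n_cells_sampled >= 0)
  # log-space to stay accurate for large samples
  1 - exp(n_cells_sampled * log1p(-1 / n_clones))
}

#' Fold enrichment of a resistant clone under growth-inhibition selection
#'
#' A clone fully resistant to a drug that inhibits the growth of the rest of
#' the population by a fraction `inhibition` gains a relative-abundance factor
#' of \eqn{(1/(1-inhibition))^{divisions}} over `divisions` population
#' doublings.
#'
#' @param inhibition fractional growth inhibition of sensitive cells in
#'   \[0, 1).
#' @param divisions number of cell divisions during the selection window.
#' @return fold enrichment (>= 1).
#' @examples
#' growth_selection_enrichment(0.2, 13) # ~ 18-fold
#' @export
growth_selection_enrichment <- function(inhibition, divisions) {
  if (inhibition < 0 || inhibition >= 1)
    stop("inhibition must be in [0, 1)")
  (1 / (1 - inhibition))^divisions
}

#' Expected fraction of clones carrying a unique barcode
#'
#' When `n_clones` clones each draw a barcode uniformly from a library of
#' `library_size` barcodes, a given clone's barcode is unique with probability
#' \eqn{(1 - 1/L)^{n-1}}; this is the expected unique fraction.
#'
#' @param n_clones number of barcoded clones.
#' @param library_size number of distinct barcodes in the library.
#' @return expected fraction of clones whose barcode is carried by no other
#'   clone.
#' @examples
#' unique_barcode_fraction(1e6, 7e7) # > 0.98
#' @export
unique_barcode_fraction <- function(n_clones, library_size) {
  stopifnot(library_size >= 1, n_clones >= 1)
  exp((n_clones - 1) * log1p(-1 / library_size))
}
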