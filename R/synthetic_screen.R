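#' Define a pooled CRISPR screen universe with known gene effects
#'
#' Ground truth for a growth-based pooled screen: a library with
#' `sgrnas_per_gene` sgRNAs per gene plus `n_nontargeting` non-targeting
#' controls, per-gene per-drug true rho effects (resistance > 0,
#' hypersensitivity < 0), and per-sgRNA efficacies scaling how much of the
#' gene effect each guide realizes.
#'
#' @param n_genes number of targeted genes.
#' @param drugs character vector of drug arm names.
#' @param true_rho matrix (n_genes x length(drugs)) of true rho effects, or a
#'   single number recycled; default 0 (global null).
#' @param sgrnas_per_gene sgRNAs per gene (10 in the full library, 5 in the
#'   half library).
#' @param n_nontargeting number of non-targeting control sgRNAs (default
#'   4000).
#' @param efficacy_range range of per-sgRNA efficacies, drawn uniformly;
#'   use `c(1, 1)` for fully active guides.
#' @param doublings named per-arm doubling differences between vehicle and
#'   treated populations (recycled; default 7.6).
#' @param gamma_doublings doublings between T0 and the vehicle endpoint
#'   (default 10).
#' @param seed integer seed.
#' @return object of class `screen_universe`.
#' @export
screen_universe <- function(n_genes, drugs, true_rho = 0,
                            sgrnas_per_gene = 10, n_nontargeting = 4000,
                            efficacy_range = c(0.7, 1), doublings = 7.6,
                            gamma_doublings = 10, seed = 1L) {
  stopifnot(n_genes >= 1, length(drugs) >= 1, n_nontargeting >= 1)
  if (!is.matrix(true_rho))
    true_rho <- matrix(true_rho, n_genes, length(drugs))
  stopifnot(nrow(true_rho) == n_genes, ncol(true_rho) == length(drugs))
  colnames(true_rho) <- drugs
  set.seed(as.integer(seed))
  eff <- stats::runif(n_genes * sgrnas_per_gene,
                      efficacy_range[1], efficacy_range[2])
  dbl <- rep_len(doublings, length(drugs))
  names(dbl) <- drugs
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  sg <- data.frame(
    sgrna_id = c(sprintf("%s_sg%02d", rep(genes, each = sgrnas_per_gene),
                         seq_len(sgrnas_per_gene)),
                 sprintf("NTC_sg%05d", seq_len(n_nontargeting))),
    gene = c(rep(genes, each = sgrnas_per_gene),
             rep("non-targeting", n_nontargeting)),
    tss = c(rep("P1", n_genes * sgrnas_per_gene),
            rep(NA_character_, n_nontargeting)),
    targeting = c(rep(TRUE, n_genes * sgrnas_per_gene),
                  rep(FALSE, n_nontargeting)),
    efficacy = c(eff, rep(0, n_nontargeting)),
    stringsAsFactors = FALSE)
  structure(list(n_genes = n_genes, drugs = drugs, true_rho = true_rho,
                 sgrnas_per_gene = sgrnas_per_gene,
                 n_nontargeting = n_nontargeting, sgrnas = sg,
                 doublings = dbl, gamma_doublings = gamma_doublings),
            class = "screen_universe")
}

#' Simulate a pooled CRISPR screen
#'
#' Counts are generated by exponential growth-based selection: each sgRNA's
#' abundance in a treated arm changes, relative to vehicle, by
#' \eqn{2^{\rho_{sg} \Delta d}} where \eqn{\rho_{sg}} = sgRNA efficacy x true
#' gene rho and \eqn{\Delta d} is the arm's doubling difference, so that the
#' rho phenotype recomputed downstream recovers the true effect. T0, vehicle
#' and per-drug treated samples are emitted after multinomial sequencing at
#' `depth` reads each.
#'
#' @param universe a [screen_universe()].
#' @param depth sequencing reads per sample (default 1e7).
#' @param dispersion log-normal CV of per-sgRNA abundance noise applied
#'   before sequencing (default 0.1; 0 disables).
#' @param seed integer seed.
#' @return list with `counts` (a `screen_counts` data frame with columns T0,
#'   vehicle, and one per drug), `doublings` (named per-arm doubling
#'   differences), `gamma_doublings`, and `truth` (the universe).
#' @export
simulate_crispr_screen <- function(universe, depth = 1e7, dispersion = 0.1,
                                   seed = 1L) {
  stopifnot(inherits(universe, "screen_universe"))
  if (universe$n_nontargeting == 0)
    stop("phenotype normalization requires non-targeting sgRNAs")
  set.seed(as.integer(seed))
  sg <- universe$sgrnas
  nsg <- nrow(sg)
  # baseline library abundance: modest log-normal width as after expansion
  base <- stats::rlnorm(nsg, 0, 0.3)
  noisy <- function(w) {
    if (dispersion > 0) {
      sdlog <- sqrt(log(1 + dispersion^2))
      w <- w * stats::rlnorm(nsg, -sdlog^2 / 2, sdlog)
    }
    as.integer(stats::rmultinom(1, depth, w / sum(w)))
  }
  counts <- sg[c("sgrna_id", "gene", "tss", "targeting")]
  counts$T0 <- noisy(base)
  veh <- base * 2^0  # neutral vehicle growth for all sgRNAs
  counts$vehicle <- noisy(veh)
  gene_idx <- match(sg$gene, sprintf("GENE%05d", seq_len(universe$n_genes)))
  for (drug in universe$drugs) {
    rho_sg <- ifelse(sg$targeting,
                     sg$efficacy * universe$true_rho[gene_idx, drug], 0)
    rho_sg[is.na(rho_sg)] <- 0
    treated <- veh * 2^(rho_sg * universe$doublings[[drug]])
    counts[[drug]] <- noisy(treated)
  }
  class(counts) <- c("screen_counts", "data.frame")
  list(counts = counts, doublings = universe$doublings,
       gamma_doublings = universe$gamma_doublings, truth = universe)
}
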