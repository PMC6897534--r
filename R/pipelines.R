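#' End-to-end clone-tracing analysis
#'
#' Runs the full barcode analysis on a count table: floor the pretreatment
#' counts at the 5% quantile, form per-replicate enrichment ratios, aggregate
#' to per-drug geometric-mean scores with vehicle normalization, call
#' resistance at the threshold, and estimate the cross-resistance parameter
#' xi for every drug pair (and, optionally, larger subsets) from the
#' observed single- and multi-drug resistant clone frequencies.
#'
#' @param counts a `barcode_counts` data frame (e.g. from
#'   [read_count_table()] or [simulate_clone_tracing()]).
#' @param pre_sample pretreatment column name.
#' @param vehicle vehicle arm name (NULL to skip vehicle normalization).
#' @param threshold resistance-call enrichment threshold (default 10).
#' @param quantile pretreatment floor quantile (default 0.05).
#' @param drug_map optional named list mapping arms to replicate columns.
#' @param max_subset_size largest drug-subset size for which xi is estimated
#'   (default 2 = all pairs).
#' @return list with `enrichment` (the `enrichment_table`), `calls` (from
#'   [call_resistance()]), `single_freqs` (per-drug resistant fraction of
#'   clones) and `xi` (named list of `xi_result` per drug subset, plus
#'   `xi_mean` / `xi_geomean` summaries across subsets).
#' @export
analyze_clone_tracing <- function(counts, pre_sample = "pretreatment",
                                  vehicle = "DMSO", threshold = 10,
                                  quantile = 0.05, drug_map = NULL,
                                  max_subset_size = 2) {
  floored <- floor_pretreatment(counts, pre_sample, quantile)
  ratios <- replicate_enrichment(floored, pre_sample)
  enr <- aggregate_enrichment(ratios, drug_map = drug_map, vehicle = vehicle)
  calls <- call_resistance(enr, threshold)
  n <- nrow(enr)
  drugs <- attr(enr, "drugs")
  single <- vapply(calls$sets, length, numeric(1)) / n
  xi <- list()
  for (k in 2:max(2, max_subset_size)) {
    if (length(drugs) < k) break
    for (sub in utils::combn(drugs, k, simplify = FALSE)) {
      obs <- length(Reduce(intersect, calls$sets[sub])) / n
      xi[[paste(sub, collapse = "+")]] <-
        estimate_xi(single[sub], obs, drug_set = sub)
    }
  }
  xivals <- vapply(xi, function(x) x$xi, numeric(1))
  list(enrichment = enr, calls = calls, single_freqs = single, xi = xi,
       xi_mean = mean(xivals),
       xi_geomean = exp(mean(log(pmax(xivals, 1e-6)))))
}

#' End-to-end CRISPR screen cross-resistance analysis
#'
#' Computes sgRNA rho phenotypes for each drug arm, scores genes, builds and
#' scores simulated control-gene sets, selects the multi-drug cutoff from
#' the controls, calls cross-resistance (and cross-hypersensitivity), and
#' estimates xi from the counts of single- and double-resistant genes.
#'
#' @param counts a `screen_counts` data frame with a vehicle column and one
#'   column per drug arm.
#' @param doublings named numeric vector: doubling difference (vehicle minus
#'   treated) per drug arm; names select the drug columns.
#' @param vehicle vehicle count column (default "vehicle").
#' @param n_control_sets control-gene sets (default 10).
#' @param k_top,min_observed,min_count,pseudocount passed through to the
#'   scoring functions.
#' @param group_size sgRNAs per pseudo-gene (default 10).
#' @param seed integer seed for control-gene assembly.
#' @return list with `gene_scores` (genes x drugs resistance-score matrix),
#'   `hyper_scores`, `cutoff`, `calls` (from [call_cross_resistance()]),
#'   `xi` (named list of per-pair `xi_result` on gene counts) and `xi_mean`.
#' @export
analyze_crispr_screens <- function(counts, doublings, vehicle = "vehicle",
                                   n_control_sets = 10, k_top = 5,
                                   min_observed = 8, min_count = 25,
                                   pseudocount = 10, group_size = 10,
                                   seed = 1L) {
  drugs <- names(doublings)
  phen <- lapply(drugs, function(d)
    compute_sgrna_phenotypes(counts, treated = d, vehicle = vehicle,
                             doubling_diff = doublings[[d]],
                             min_count = min_count,
                             pseudocount = pseudocount))
  names(phen) <- drugs
  scored <- lapply(phen, score_genes, k_top = k_top,
                   min_observed = min_observed)
  genes <- sort(unique(unlist(lapply(scored, function(s) s$gene))))
  pick <- function(field) {
    m <- vapply(drugs, function(d) {
      s <- scored[[d]]
      s[[field]][match(genes, s$gene)]
    }, numeric(length(genes)))
    rownames(m) <- genes
    m
  }
  res <- pick("resistance_score")
  hyp <- pick("hypersensitivity_score")
  ctrl <- build_control_genes(counts$sgrna_id[!counts$targeting],
                              n_genes = length(genes),
                              group_size = group_size,
                              n_sets = n_control_sets, seed = seed)
  ctrl_scores <- score_control_genes(phen, ctrl, k_top = k_top,
                                     min_observed = min_observed)
  cutoff <- select_cutoff(ctrl_scores)
  calls <- call_cross_resistance(res, cutoff, hypersensitivity_scores = hyp)
  single <- vapply(calls$sets, length, numeric(1))
  xi <- list()
  if (length(drugs) >= 2) {
    for (pair in utils::combn(drugs, 2, simplify = FALSE)) {
      if (any(single[pair] == 0)) next
      obs <- length(intersect(calls$sets[[pair[1]]], calls$sets[[pair[2]]]))
      xi[[paste(pair, collapse = "+")]] <-
        estimate_xi(single[pair] / length(genes), obs / length(genes),
                    drug_set = pair)
    }
  }
  xivals <- vapply(xi, function(x) x$xi, numeric(1))
  list(gene_scores = res, hyper_scores = hyp, phenotypes = phen,
       cutoff = cutoff, calls = calls, single_counts = single, xi = xi,
       xi_mean = if (length(xivals)) mean(xivals) else NA_real_)
}

#' Replicate the published clone-tracing analysis from source data
#'
#' Convenience wrapper: reads a barcode count table exported from the
#' original clone-tracing experiments (barcode column plus pretreatment,
#' per-drug replicate and vehicle columns) and runs
#' [analyze_clone_tracing()] on it. The source-data file is not distributed
#' with this package; download it alongside the original study and point
#' `path` at it.
#'
#' @param path path to the barcode count TSV/CSV.
#' @param ... passed to [analyze_clone_tracing()].
#' @return see [analyze_clone_tracing()].
#' @export
replicate_clone_tracing <- function(path, ...) {
  if (!file.exists(path))
    stop("clone-tracing source data not found at '", path,
         "'; this replication requires the original study's barcode counts")
  analyze_clone_tracing(read_count_table(path, "barcode"), ...)
}

#' Replicate the published CRISPR screen analysis from source data
#'
#' Reads an sgRNA count table exported from the original CRISPRi or CRISPRa
#' screens and runs [analyze_crispr_screens()]. The source-data file is not
#' distributed with this package.
#'
#' @param path path to the sgRNA count TSV/CSV (schema `sgrna`).
#' @param doublings named per-drug doubling differences; defaults to the
#'   measured CRISPRi values (vincristine 7.60, cyclophosphamide 9.34,
#'   doxorubicin 7.41, rituximab 7.53).
#' @param ... passed to [analyze_crispr_screens()].
#' @return see [analyze_crispr_screens()].
#' @export
replicate_crispr_screens <- function(path,
                                     doublings = c(vincristine = 7.60,
                                                   cyclophosphamide = 9.34,
                                                   doxorubicin = 7.41,
                                                   rituximab = 7.53),
                                     ...) {
  if (!file.exists(path))
    stop("CRISPR screen source data not found at '", path,
         "'; this replication requires the original study's sgRNA counts")
  analyze_crispr_screens(read_count_table(path, "sgrna"), doublings, ...)
}
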