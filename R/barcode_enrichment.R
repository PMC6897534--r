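#' Floor pretreatment barcode counts at a low quantile
#'
#' Barcodes that were rare or undetected in the pretreatment reference sample
#' would otherwise score as highly enriched from a handful of reads. Counts
#' in the pretreatment column below its q-quantile are raised to that
#' quantile; other samples are untouched.
#'
#' @param table a `barcode_counts` data frame.
#' @param pre_sample name of the pretreatment column (default
#'   "pretreatment").
#' @param quantile quantile defining the floor (default 0.05).
#' @return the table with the floored pretreatment column; attribute `floor`
#'   records the floor value used.
#' @export
floor_pretreatment <- function(table, pre_sample = "pretreatment",
                               quantile = 0.05) {
  stopifnot(inherits(table, "barcode_counts"))
  if (!pre_sample %in% names(table))
    stop("no pretreatment sample column '", pre_sample, "'")
  pre <- table[[pre_sample]]
  if (all(pre == 0)) stop("pretreatment sample is all zero")
  fl <- stats::quantile(pre, quantile, names = FALSE)
  table[[pre_sample]] <- pmax(pre, fl)
  attr(table, "floor") <- fl
  table
}

#' Per-replicate barcode enrichment ratios
#'
#' Counts are converted to within-sample frequencies (count over column
#' total) and each treated sample's frequency is divided by the pretreatment
#' frequency, giving one enrichment ratio per barcode per sample.
#'
#' @param table a `barcode_counts` data frame, pretreatment counts already
#'   floored via [floor_pretreatment()].
#' @param pre_sample name of the pretreatment column.
#' @param samples treated sample columns (default: every count column other
#'   than the pretreatment).
#' @return data frame with `barcode` plus one ratio column per sample.
#' @export
replicate_enrichment <- function(table, pre_sample = "pretreatment",
                                 samples = NULL) {
  stopifnot(inherits(table, "barcode_counts"))
  if (is.null(samples))
    samples <- setdiff(names(table), c("barcode", pre_sample))
  pre_freq <- table[[pre_sample]] / sum(table[[pre_sample]])
  out <- data.frame(barcode = table$barcode, stringsAsFactors = FALSE)
  for (s in samples) {
    tot <- sum(table[[s]])
    if (tot == 0) {
      warning("sample '", s, "' has zero total counts; ratios set to 0")
      out[[s]] <- 0
    } else {
      out[[s]] <- (table[[s]] / tot) / pre_freq
    }
  }
  out
}

# derive drug -> replicate-column mapping from "<drug>_rep<j>" names
default_drug_map <- function(cols) {
  drugs <- sub("_rep[0-9]+$", "", cols)
  split(cols, factor(drugs, levels = unique(drugs)))
}

# floored geometric mean over replicate columns (each replicate's ratio is
# floored at 1 first, penalizing irreproducible enrichment)
floored_geomean <- function(ratio_df, cols) {
  m <- log(pmax(as.matrix(ratio_df[cols]), 1))
  exp(rowMeans(m))
}

#' Aggregate replicate enrichment into per-drug resistance scores
#'
#' Each replicate's enrichment ratio is floored at 1 (a barcode may be absent
#' from any one flask's inoculum by chance) and the replicates are combined
#' by geometric mean, so stochastic one-off enrichment is strongly penalized
#' while reproducible enrichment is rewarded. To correct for drug-independent
#' fitness differences, each barcode's drug score is divided by its vehicle
#' (DMSO) geometric-mean enrichment, but only when that exceeds 1 — scores
#' are never inflated by a vehicle enrichment below 1.
#'
#' @param ratios data frame from [replicate_enrichment()]; replicate columns
#'   named `<drug>_rep<j>` (or supply `drug_map`).
#' @param drug_map optional named list mapping each drug to its replicate
#'   columns.
#' @param vehicle name of the vehicle arm used for normalization (default
#'   "DMSO"; NULL disables normalization).
#' @param dmso_per_replicate if TRUE, divide each drug replicate ratio by the
#'   matching vehicle replicate ratio (floored at 1) before aggregation,
#'   instead of dividing the aggregated score.
#' @return an `enrichment_table` data frame: `barcode`, one geometric-mean
#'   score column per drug, and `vehicle_enrichment`; attribute `drugs`
#'   names the drug columns.
#' @export
aggregate_enrichment <- function(ratios, drug_map = NULL, vehicle = "DMSO",
                                 dmso_per_replicate = FALSE) {
  cols <- setdiff(names(ratios), "barcode")
  if (is.null(drug_map)) drug_map <- default_drug_map(cols)
  drugs <- setdiff(names(drug_map), vehicle)
  out <- data.frame(barcode = ratios$barcode, stringsAsFactors = FALSE)
  veh_score <- NULL
  if (!is.null(vehicle) && vehicle %in% names(drug_map))
    veh_score <- floored_geomean(ratios, drug_map[[vehicle]])
  for (d in drugs) {
    reps <- drug_map[[d]]
    if (length(reps) < 2)
      warning("drug '", d, "' has fewer than 2 replicates")
    if (dmso_per_replicate && !is.null(veh_score)) {
      vcols <- drug_map[[vehicle]]
      r <- as.matrix(ratios[reps])
      v <- pmax(as.matrix(ratios[rep_len(vcols, length(reps))]), 1)
      sc <- exp(rowMeans(log(pmax(r / v, 1))))
    } else {
      sc <- floored_geomean(ratios, reps)
      if (!is.null(veh_score)) sc <- sc / pmax(veh_score, 1)
    }
    out[[d]] <- sc
  }
  if (!is.null(veh_score)) out$vehicle_enrichment <- veh_score
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "drugs") <- drugs
  out
}

#' Scrambled-label error model and false discovery rate for enrichment
#'
#' Real cross-drug enrichment must be distinguished from coincidental
#' enrichment caused by population bottlenecks and sampling. The null model
#' scrambles barcode identities independently within each replicate column
#' (preserving every column's score distribution exactly, destroying all
#' within-barcode coupling), re-applies the floored geometric-mean
#' aggregation, and counts barcodes exceeding each enrichment threshold in at
#' least 1, 2 or 3 drugs. The FDR at a threshold and multiplicity is the
#' scramble-averaged false count divided by the observed count.
#' `mode = "independent"` draws each column's ratios with replacement
#' instead of permuting, emulating an effectively unlimited number of
#' scrambled replicate sets.
#'
#' @param ratios data frame from [replicate_enrichment()] (drug replicate
#'   columns; vehicle columns are excluded from the null).
#' @param drug_map optional named list mapping drugs to replicate columns.
#' @param vehicle vehicle arm name excluded from the null (default "DMSO").
#' @param n_scrambles number of scrambled replicate sets (default 1000).
#' @param thresholds enrichment thresholds to evaluate (log-spaced grid;
#'   default 2, 5, 10, 20, 50, 100).
#' @param multiplicities drug-multiplicities to tally (default 1:3).
#' @param mode `"permute"` (label permutation) or `"independent"` (bootstrap
#'   resampling of each column).
#' @param seed integer seed.
#' @return an `fdr_curve` data frame: `threshold`, `multiplicity`,
#'   `expected_false`, `observed`, `fdr_raw`, `fdr` (monotone-regularized,
#'   non-increasing in threshold within each multiplicity).
#' @export
scrambled_error_model <- function(ratios, drug_map = NULL, vehicle = "DMSO",
                                  n_scrambles = 1000,
                                  thresholds = c(2, 5, 10, 20, 50, 100),
                                  multiplicities = 1:3, mode = c("permute",
                                                                 "independent"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  if (n_scrambles < 1) stop("n_scrambles must be >= 1")
  cols <- setdiff(names(ratios), "barcode")
  if (is.null(drug_map)) drug_map <- default_drug_map(cols)
  drug_map <- drug_map[setdiff(names(drug_map), vehicle)]
  drugs <- names(drug_map)
  n <- nrow(ratios)
  score_mat <- function(df) {
    vapply(drugs, function(d) floored_geomean(df, drug_map[[d]]), numeric(n))
  }
  tally <- function(S) {
    vapply(thresholds, function(t) {
      hits <- rowSums(S >= t)
      vapply(multiplicities, function(m) sum(hits >= m), numeric(1))
    }, numeric(length(multiplicities)))
  }
  observed <- tally(score_mat(ratios))
  set.seed(as.integer(seed))
  expected <- 0
  scr <- ratios
  for (k in seq_len(n_scrambles)) {
    for (cc in unlist(drug_map))
      scr[[cc]] <- if (mode == "permute") sample(ratios[[cc]]) else
        sample(ratios[[cc]], n, replace = TRUE)
    expected <- expected + tally(score_mat(scr))
  }
  expected <- expected / n_scrambles
  out <- data.frame(
    threshold = rep(thresholds, each = length(multiplicities)),
    multiplicity = rep(multiplicities, length(thresholds)),
    expected_false = as.vector(expected),
    observed = as.vector(observed))
  out$fdr_raw <- pmin(out$expected_false / pmax(out$observed, 1), 1)
  out$fdr <- NA_real_
  for (m in multiplicities) {
    i <- which(out$multiplicity == m)
    i <- i[order(out$threshold[i])]
    out$fdr[i] <- rev(cummax(rev(out$fdr_raw[i])))
  }
  class(out) <- c("fdr_curve", "data.frame")
  out
}

#' Call drug resistance from enrichment scores and tally overlaps
#'
#' A barcode is called resistant to a drug when its geometric-mean enrichment
#' meets the threshold (default 10, where the scrambled-label null puts
#' multi-drug false discovery below a few percent). Returns the per-drug
#' resistant sets and the multi-drug overlap structure.
#'
#' @param table an `enrichment_table` from [aggregate_enrichment()].
#' @param threshold enrichment threshold (default 10).
#' @return list with `sets` (named list of resistant barcode vectors),
#'   `venn` (named counts of barcodes resistant to exactly each drug
#'   subset), and `multiplicity` (counts resistant to >= 1, 2, ... drugs).
#' @export
call_resistance <- function(table, threshold = 10) {
  stopifnot(inherits(table, "enrichment_table"))
  drugs <- attr(table, "drugs")
  sets <- lapply(drugs, function(d) table$barcode[table[[d]] >= threshold])
  names(sets) <- drugs
  c(list(sets = sets), overlap_counts(sets))
}

# exact-region Venn counts and cumulative multiplicity tallies for a named
# list of item sets
overlap_counts <- function(sets) {
  drugs <- names(sets)
  items <- unique(unlist(sets))
  member <- vapply(sets, function(s) items %in% s,
                   logical(length(items)))
  if (length(items) == 0)
    member <- matrix(FALSE, 0, length(sets), dimnames = list(NULL, drugs))
  if (length(items) == 1) member <- matrix(member, 1,
                                           dimnames = list(NULL, drugs))
  region <- apply(member, 1, function(r) paste(drugs[r], collapse = "+"))
  venn <- table(region)
  k <- rowSums(member)
  multiplicity <- vapply(seq_along(drugs), function(m) sum(k >= m),
                         numeric(1))
  names(multiplicity) <- paste0(">=", seq_along(drugs))
  list(venn = venn, multiplicity = multiplicity)
}
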