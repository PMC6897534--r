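#' Compute sgRNA-level selection phenotypes (rho, gamma, tau)
#'
#' The rho phenotype of an sgRNA is the log2 fold change of its frequency
#' between the drug-treated and vehicle samples, centred by subtracting the
#' median log2 fold change of the non-targeting control sgRNAs, and divided
#' by the population-doubling difference between the two arms — so rho = 1
#' is full resistance, 0 parental sensitivity and < 0 hypersensitivity.
#' Gamma (vehicle vs T0) and tau (treated vs T0) are the drug-free and total
#' growth analogues. A pseudocount is added to all counts before forming
#' frequencies; sgRNAs with fewer than `min_count` raw counts in both
#' compared samples are flagged as failing the count filter.
#'
#' @param table a `screen_counts` data frame (columns `sgrna_id`, `gene`,
#'   `tss`, `targeting`, counts per sample).
#' @param treated,vehicle names of the treated and vehicle count columns.
#' @param doubling_diff population doublings lost by the treated arm
#'   relative to vehicle (> 0; measured per screen, e.g. 7.60 for a
#'   vincristine knockdown screen).
#' @param t0 optional T0 column name; enables gamma and tau.
#' @param gamma_doublings doublings between T0 and the vehicle endpoint
#'   (required for gamma/tau).
#' @param min_count count filter (default 25, applied to raw counts).
#' @param pseudocount added to counts; `pseudocount_mode = "all"` adds it to
#'   every count (genome-wide screens, default 10), `"zeros"` only to zero
#'   counts (half-library preset, pseudocount 1).
#' @param pseudocount_mode see `pseudocount`.
#' @return data frame with `sgrna_id`, `gene`, `tss`, `targeting`, `rho`,
#'   `gamma`, `tau` (NA when not computable) and `passed_count_filter`.
#' @export
compute_sgrna_phenotypes <- function(table, treated, vehicle, doubling_diff,
                                     t0 = NULL, gamma_doublings = NULL,
                                     min_count = 25, pseudocount = 10,
                                     pseudocount_mode = c("all", "zeros")) {
  stopifnot(inherits(table, "screen_counts"))
  pseudocount_mode <- match.arg(pseudocount_mode)
  if (doubling_diff <= 0) stop("doubling_diff must be positive")
  nt <- !table$targeting
  if (!any(nt)) stop("no non-targeting sgRNAs; rho normalization undefined")
  adj <- function(x) if (pseudocount_mode == "all") x + pseudocount else
    ifelse(x == 0, x + pseudocount, x)
  freq <- function(col) { a <- adj(table[[col]]); a / sum(a) }
  # centring uses the median over all non-targeting sgRNAs (not just those
  # passing the count filter), so phenotypes are invariant to depth scaling
  centred_lfc <- function(num, den) {
    lfc <- log2(freq(num) / freq(den))
    lfc - stats::median(lfc[nt & is.finite(lfc)])
  }
  pass_rho <- table[[treated]] >= min_count | table[[vehicle]] >= min_count
  rho <- centred_lfc(treated, vehicle) / doubling_diff
  rho[!pass_rho] <- NA_real_
  gamma <- tau <- rep(NA_real_, nrow(table))
  if (!is.null(t0)) {
    if (is.null(gamma_doublings))
      stop("gamma_doublings required when a T0 sample is given")
    pass_g <- table[[vehicle]] >= min_count | table[[t0]] >= min_count
    gamma <- centred_lfc(vehicle, t0) / gamma_doublings
    gamma[!pass_g] <- NA_real_
    pass_t <- table[[treated]] >= min_count | table[[t0]] >= min_count
    tau_doublings <- gamma_doublings - doubling_diff
    if (tau_doublings > 0) {
      tau <- centred_lfc(treated, t0) / tau_doublings
      tau[!pass_t] <- NA_real_
    }
  }
  data.frame(sgrna_id = table$sgrna_id, gene = table$gene, tss = table$tss,
             targeting = table$targeting, rho = rho, gamma = gamma,
             tau = tau, passed_count_filter = pass_rho,
             stringsAsFactors = FALSE)
}

# Mann-Whitney U test of each small sample against one fixed control sample:
# two-sided normal approximation with continuity and tie correction,
# vectorized over genes via a sorted-control lookup.
mw_p_versus_control <- function(values_list, control) {
  control <- control[!is.na(control)]
  n2 <- length(control)
  sc <- sort(control)
  vapply(values_list, function(v) {
    v <- v[!is.na(v)]
    n1 <- length(v)
    if (n1 == 0 || n2 == 0) return(NA_real_)
    less <- findInterval(v, sc, left.open = TRUE)   # controls strictly below
    leq <- findInterval(v, sc)                      # controls <= value
    u <- sum(less) + sum(leq - less) / 2            # ties count half
    mu <- n1 * n2 / 2
    # tie correction over the combined sample (fast path when tie-free)
    comb <- c(v, sc)
    n <- n1 + n2
    sigma2 <- if (anyDuplicated(comb) == 0) n1 * n2 * (n + 1) / 12 else {
      tt <- table(comb)
      n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    }
    if (sigma2 <= 0) return(1)
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-max(z, 0))
  }, numeric(1))
}

#' Gene-level resistance and hypersensitivity scores
#'
#' For every gene (per transcription start site) two statistics are computed
#' from its sgRNA rho phenotypes: the mean of the strongest `k_top`
#' phenotypes by absolute value (signed), and the two-sided Mann-Whitney
#' p-value of all its phenotypes against the non-targeting control sgRNAs.
#' For genes with several TSSs the TSS with the smallest p-value is kept
#' (ties broken by larger |mean phenotype|, then lexicographically). The
#' resistance score is mean-top-rho x (-log10 p); the hypersensitivity score
#' is its negative, so both are positive for their own phenotype direction.
#' Genes with fewer than `min_observed` sgRNA phenotypes are dropped.
#'
#' @param phenotypes data frame from [compute_sgrna_phenotypes()].
#' @param k_top number of strongest phenotypes averaged (default 5).
#' @param min_observed minimum observed sgRNA phenotypes per gene (default 8
#'   for the 10-sgRNA genome-wide library).
#' @return a `gene_scores` data frame: `gene`, `tss`, `n_sgrnas`,
#'   `mean_top_rho`, `mw_p`, `resistance_score`, `hypersensitivity_score`.
#' @export
score_genes <- function(phenotypes, k_top = 5, min_observed = 8) {
  nt_rho <- phenotypes$rho[!phenotypes$targeting &
                             !is.na(phenotypes$rho)]
  if (length(nt_rho) == 0) stop("no non-targeting phenotypes available")
  tg <- phenotypes[phenotypes$targeting & !is.na(phenotypes$rho), ]
  grp <- interaction(tg$gene, tg$tss, drop = TRUE, sep = "\r")
  rho_by <- split(tg$rho, grp)
  keys <- strsplit(names(rho_by), "\r", fixed = TRUE)
  n_obs <- lengths(rho_by)
  keep <- n_obs >= min_observed
  rho_by <- rho_by[keep]
  keys <- keys[keep]
  if (!length(rho_by))
    return(structure(data.frame(gene = character(0), tss = character(0),
                                n_sgrnas = integer(0),
                                mean_top_rho = numeric(0), mw_p = numeric(0),
                                resistance_score = numeric(0),
                                hypersensitivity_score = numeric(0)),
                     class = c("gene_scores", "data.frame")))
  mean_top <- vapply(rho_by, function(v) {
    k <- min(k_top, length(v))
    mean(v[order(abs(v), decreasing = TRUE)][seq_len(k)])
  }, numeric(1))
  mw_p <- mw_p_versus_control(rho_by, nt_rho)
  df <- data.frame(gene = vapply(keys, `[`, "", 1),
                   tss = vapply(keys, `[`, "", 2),
                   n_sgrnas = lengths(rho_by),
                   mean_top_rho = mean_top, mw_p = mw_p,
                   stringsAsFactors = FALSE)
  # per gene keep the TSS with minimal p; ties -> larger |mean|, then lexical
  o <- order(df$gene, df$mw_p, -abs(df$mean_top_rho), df$tss)
  df <- df[o, ]
  df <- df[!duplicated(df$gene), ]
  score <- df$mean_top_rho * (-log10(df$mw_p))
  df$resistance_score <- score
  df$hypersensitivity_score <- -score
  rownames(df) <- NULL
  class(df) <- c("gene_scores", "data.frame")
  df
}

#' Build simulated negative-control genes from non-targeting sgRNAs
#'
#' Pseudo-genes are assembled by randomly grouping non-targeting sgRNAs
#' (`group_size` per pseudo-gene, drawn without replacement within a
#' pseudo-gene; sgRNAs may recur across pseudo-genes). Scored identically to
#' real genes, they measure the technical noise floor of the screen.
#'
#' @param nontargeting_ids character vector of non-targeting sgRNA ids.
#' @param n_genes pseudo-genes per set (match the real gene count).
#' @param group_size sgRNAs per pseudo-gene (10 full library, 5 half).
#' @param n_sets number of independent control sets (default 10).
#' @param seed integer seed.
#' @return list of `n_sets` data frames (`pseudo_gene`, `sgrna_id`).
#' @export
build_control_genes <- function(nontargeting_ids, n_genes, group_size = 10,
                                n_sets = 10, seed = 1L) {
  if (length(nontargeting_ids) < group_size)
    stop("fewer non-targeting sgRNAs than the pseudo-gene group size")
  set.seed(as.integer(seed))
  lapply(seq_len(n_sets), function(s) {
    picks <- replicate(n_genes,
                       sample(nontargeting_ids, group_size, replace = FALSE))
    data.frame(pseudo_gene = rep(sprintf("ctrl%05d", seq_len(n_genes)),
                                 each = group_size),
               sgrna_id = as.vector(picks), stringsAsFactors = FALSE)
  })
}

#' Score control-gene sets across drug arms
#'
#' Applies the gene scoring of [score_genes()] to each pseudo-gene of each
#' control set, for each drug's phenotype table.
#'
#' @param phenotype_list named list (one element per drug) of data frames
#'   from [compute_sgrna_phenotypes()].
#' @param control_sets list from [build_control_genes()].
#' @param k_top,min_observed as in [score_genes()].
#' @return list of matrices (pseudo-gene x drug) of resistance scores, one
#'   per control set.
#' @export
score_control_genes <- function(phenotype_list, control_sets, k_top = 5,
                                min_observed = 8) {
  lapply(control_sets, function(cs) {
    vapply(phenotype_list, function(ph) {
      rho <- ph$rho[match(cs$sgrna_id, ph$sgrna_id)]
      nt_rho <- ph$rho[!ph$targeting & !is.na(ph$rho)]
      rho_by <- split(rho, cs$pseudo_gene)
      rho_by <- lapply(rho_by, function(v) v[!is.na(v)])
      sc <- rep(NA_real_, length(rho_by))
      ok <- lengths(rho_by) >= min_observed
      mean_top <- vapply(rho_by[ok], function(v) {
        k <- min(k_top, length(v))
        mean(v[order(abs(v), decreasing = TRUE)][seq_len(k)])
      }, numeric(1))
      sc[ok] <- mean_top * (-log10(mw_p_versus_control(rho_by[ok], nt_rho)))
      sc
    }, numeric(length(unique(cs$pseudo_gene))))
  })
}

#' Select the cross-resistance score cutoff from control genes
#'
#' Scans score cutoffs upward in fixed increments and returns the smallest
#' cutoff at which, averaged over the control sets, at most `max_false`
#' pseudo-genes exceed the cutoff in two or more drug arms. Being anchored to
#' simulated control genes, the cutoff is lenient for single-drug calls but
#' keeps expected false multi-drug calls below one gene.
#'
#' @param control_scores list of pseudo-gene x drug score matrices from
#'   [score_control_genes()].
#' @param step scan increment (default 0.01).
#' @param max_false tolerated mean count of multi-drug control genes
#'   (default 1).
#' @return the selected cutoff; attribute `control_mean_double` gives the
#'   mean control count at the cutoff.
#' @export
select_cutoff <- function(control_scores, step = 0.01, max_false = 1) {
  n_double <- function(cut) {
    mean(vapply(control_scores, function(m)
      sum(rowSums(m > cut, na.rm = TRUE) >= 2), numeric(1)))
  }
  top <- max(vapply(control_scores, function(m) max(m, na.rm = TRUE),
                    numeric(1)))
  cutoffs <- seq(step, max(top + step, step), by = step)
  for (cut in cutoffs) {
    if (n_double(cut) <= max_false) {
      out <- cut
      attr(out, "control_mean_double") <- n_double(cut)
      return(out)
    }
  }
  stop(sprintf(
    "no cutoff up to %.2f brings mean control double-resistant count below %g (at top: %.2f)",
    max(cutoffs), max_false, n_double(max(cutoffs))))
}

#' Call multi-drug resistance (and hypersensitivity) from gene scores
#'
#' Genes whose resistance score exceeds the cutoff in a drug arm form that
#' drug's resistant set; overlaps across arms are tallied per drug subset.
#' When hypersensitivity scores are supplied the same machinery is applied
#' to them, and collateral-sensitivity pairs (resistant to one drug,
#' hypersensitive to a different drug) are reported.
#'
#' @param resistance_scores matrix or data frame (genes x drugs) of
#'   resistance scores, rownames = genes.
#' @param cutoff score cutoff from [select_cutoff()].
#' @param hypersensitivity_scores optional matrix of the same shape.
#' @return list with `sets`, `venn`, `multiplicity` (as in
#'   [call_resistance()]); plus `hypersensitivity` (same structure) and
#'   `collateral` (data frame of gene, resistant_to, hypersensitive_to) when
#'   hypersensitivity scores are given.
#' @export
call_cross_resistance <- function(resistance_scores, cutoff,
                                  hypersensitivity_scores = NULL) {
  m <- as.matrix(resistance_scores)
  drugs <- colnames(m)
  genes <- rownames(m)
  sets <- lapply(drugs, function(d)
    genes[!is.na(m[, d]) & m[, d] > cutoff])
  names(sets) <- drugs
  out <- c(list(sets = sets), overlap_counts(sets))
  if (!is.null(hypersensitivity_scores)) {
    h <- as.matrix(hypersensitivity_scores)
    hsets <- lapply(drugs, function(d)
      genes[!is.na(h[, d]) & h[, d] > cutoff])
    names(hsets) <- drugs
    out$hypersensitivity <- c(list(sets = hsets), overlap_counts(hsets))
    coll <- do.call(rbind, lapply(drugs, function(dr) {
      do.call(rbind, lapply(setdiff(drugs, dr), function(dh) {
        g <- intersect(sets[[dr]], hsets[[dh]])
        if (length(g)) data.frame(gene = g, resistant_to = dr,
                                  hypersensitive_to = dh,
                                  stringsAsFactors = FALSE)
      }))
    }))
    out$collateral <- if (is.null(coll))
      data.frame(gene = character(0), resistant_to = character(0),
                 hypersensitive_to = character(0)) else coll
  }
  out
}
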