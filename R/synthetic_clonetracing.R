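#' Define a barcoded clone universe with known resistance structure
#'
#' Creates the ground truth for a clone-tracing experiment: `n_clones`
#' uniquely barcoded clones, per-drug resistant subsets at configured marginal
#' frequencies, and a tunable true cross-resistance parameter `true_xi`
#' coupling the resistant sets. The coupling realizes the weighted-sum
#' definition of xi exactly in expectation: for every drug after the first,
#' membership is drawn so that the joint frequency with the first drug's set
#' equals \eqn{\xi \min(f_1, f_k) + (1-\xi) f_1 f_k} while preserving the
#' marginal \eqn{f_k}.
#'
#' @param n_clones number of clones.
#' @param drugs character vector of drug names.
#' @param resistance_freq per-drug marginal resistance frequency (recycled).
#' @param true_xi true cross-resistance in \[0, 1\] between the first drug
#'   and each other drug.
#' @param kill_sensitive per-drug probability that a sensitive cell is killed
#'   by one 72 h drug pulse (recycled; default 0.999).
#' @param surv_resistant survival probability of resistant cells (default 1).
#' @param fitness_sd standard deviation of per-clone log2 growth-rate
#'   multipliers (drug-independent fitness differences; default 0 = neutral).
#' @param seed integer seed.
#' @return object of class `clone_universe`: list with `n_clones`, `drugs`,
#'   `resistant` (named list of clone index vectors), `fitness`,
#'   `kill_sensitive`, `surv_resistant`, `true_xi`.
#' @export
clone_universe <- function(n_clones, drugs, resistance_freq = 1e-3,
                           true_xi = 0, kill_sensitive = 0.999,
                           surv_resistant = 1, fitness_sd = 0, seed = 1L) {
  stopifnot(n_clones >= 1, length(drugs) >= 1,
            all(resistance_freq > 0), all(resistance_freq <= 1),
            true_xi >= 0, true_xi <= 1)
  freq <- rep_len(resistance_freq, length(drugs))
  kill <- rep_len(kill_sensitive, length(drugs))
  names(freq) <- names(kill) <- drugs
  set.seed(as.integer(seed))
  resistant <- vector("list", length(drugs))
  names(resistant) <- drugs
  r1 <- stats::runif(n_clones) < freq[1]
  resistant[[1]] <- which(r1)
  f1 <- freq[1]
  for (k in seq_along(drugs)[-1]) {
    fk <- freq[k]
    joint <- true_xi * min(f1, fk) + (1 - true_xi) * f1 * fk
    p_given_r1 <- min(joint / f1, 1)
    p_given_not <- max((fk - f1 * p_given_r1) / (1 - f1), 0)
    p <- ifelse(r1, p_given_r1, p_given_not)
    resistant[[k]] <- which(stats::runif(n_clones) < p)
  }
  fitness <- if (fitness_sd > 0)
    2^stats::rnorm(n_clones, 0, fitness_sd) else rep(1, n_clones)
  structure(list(n_clones = n_clones, drugs = drugs, freq = freq,
                 resistant = resistant, fitness = fitness,
                 kill_sensitive = kill, surv_resistant = surv_resistant,
                 true_xi = true_xi),
            class = "clone_universe")
}

#' Simulate a barcode clone-tracing selection experiment
#'
#' Emulates the pooled selection design: from a common well-mixed pool of
#' barcoded clones a pretreatment sample is sequenced, and replicate flasks
#' are seeded per drug arm (plus a vehicle arm). Each flask draws a
#' multinomial inoculum from the clone frequencies, kills cells binomially
#' per clone (resistant clones survive at `surv_resistant`, sensitive ones at
#' `1 - kill_sensitive`), regrows deterministically with per-clone fitness
#' multipliers to twice the inoculum, and repeats for `rounds` treatment
#' cycles. Surviving populations are sequenced by multinomial sampling at
#' `depth` reads.
#'
#' @param universe a [clone_universe()].
#' @param n_replicates flasks per drug (default 3).
#' @param inoculum cells seeded per flask (default `12 * n_clones`, i.e.
#'   12-fold clone coverage).
#' @param rounds number of treatment/regrowth cycles (default 2).
#' @param depth sequencing reads per post-treatment sample (default 1e6).
#' @param pre_depth reads for the pretreatment sample (default `20 * depth`,
#'   mirroring deeper sequencing of the reference pool).
#' @param vehicle name of the vehicle arm (default "DMSO"; set NULL to omit).
#' @param seed integer seed.
#' @return list with `counts` (a `barcode_counts` data frame: column
#'   `pretreatment` plus one column per drug x replicate, named
#'   `<drug>_rep<j>`), `sample_sheet` (sample_id, drug, replicate, timepoint),
#'   `truth` (the universe), and `extinct` (names of flasks in which no cell
#'   survived).
#' @export
simulate_clone_tracing <- function(universe, n_replicates = 3,
                                   inoculum = NULL, rounds = 2,
                                   depth = 1e6, pre_depth = NULL,
                                   vehicle = "DMSO", seed = 1L) {
  stopifnot(inherits(universe, "clone_universe"))
  n <- universe$n_clones
  if (is.null(inoculum)) inoculum <- 12 * n
  if (is.null(pre_depth)) pre_depth <- 20 * depth
  set.seed(as.integer(seed))
  pool <- universe$fitness / sum(universe$fitness)  # pool clone frequencies
  barcodes <- sprintf("bc%07d", seq_len(n))
  arms <- c(universe$drugs, vehicle)
  counts <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
  counts$pretreatment <- as.integer(stats::rmultinom(1, pre_depth, pool))
  sheet <- data.frame(sample_id = "pretreatment", drug = NA_character_,
                      replicate = NA_integer_, timepoint = "pretreatment",
                      stringsAsFactors = FALSE)
  extinct <- character(0)
  for (arm in arms) {
    is_drug <- arm %in% universe$drugs
    surv_p <- rep(if (is_drug) 1 - universe$kill_sensitive[[arm]] else 1, n)
    if (is_drug) surv_p[universe$resistant[[arm]]] <- universe$surv_resistant
    for (rep_i in seq_len(n_replicates)) {
      cells <- as.numeric(stats::rmultinom(1, inoculum, pool))
      for (r in seq_len(rounds)) {
        cells <- stats::rbinom(n, size = cells, prob = surv_p)
        if (sum(cells) == 0) break
        # deterministic exponential regrowth to twice the inoculum,
        # fitness-weighted
        w <- cells * universe$fitness
        cells <- w / sum(w) * (2 * inoculum)
        # back to integer cells for the next kill step
        cells <- floor(cells) + stats::rbinom(n, 1, cells - floor(cells))
      }
      nm <- paste0(arm, "_rep", rep_i)
      if (sum(cells) == 0) {
        extinct <- c(extinct, nm)
        counts[[nm]] <- 0L
        warning("all clones extinct in flask ", nm)
      } else {
        counts[[nm]] <- as.integer(
          stats::rmultinom(1, depth, cells / sum(cells)))
      }
      sheet <- rbind(sheet, data.frame(
        sample_id = nm, drug = arm, replicate = rep_i,
        timepoint = "post_treatment", stringsAsFactors = FALSE))
    }
  }
  class(counts) <- c("barcode_counts", "data.frame")
  list(counts = counts, sample_sheet = sheet, truth = universe,
       extinct = extinct)
}
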