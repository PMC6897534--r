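# small screen table builder: one gene's sgRNAs plus non-targeting controls
make_screen <- function(gene_counts_t, gene_counts_v, nt_t, nt_v,
                        gene = "GENE1") {
  ng <- length(gene_counts_t)
  nn <- length(nt_t)
  df <- data.frame(
    sgrna_id = c(sprintf("%s_sg%02d", gene, seq_len(ng)),
                 sprintf("ntc%04d", seq_len(nn))),
    gene = c(rep(gene, ng), rep("non-targeting", nn)),
    tss = c(rep("P1", ng), rep(NA_character_, nn)),
    targeting = c(rep(TRUE, ng), rep(FALSE, nn)),
    treated = as.integer(c(gene_counts_t, nt_t)),
    vehicle = as.integer(c(gene_counts_v, nt_v)),
    stringsAsFactors = FALSE)
  class(df) <- c("screen_counts", "data.frame")
  df
}

test_that("rho evaluates the centred, doubling-normalized log2 fold change", {
  # non-targeting sgRNAs unchanged between arms: their median centres out any
  # depth imbalance, leaving rho = log2(500/100) / 7.6 with pseudocount 10
  tab <- make_screen(490, 90, rep(100, 99), rep(100, 99))
  ph <- compute_sgrna_phenotypes(tab, "treated", "vehicle",
                                 doubling_diff = 7.6)
  expect_equal(ph$rho[1], log2(500 / 100) / 7.6, tolerance = 1e-12)
  # an sgRNA matching the non-targeting median scores exactly zero
  expect_equal(median(ph$rho[!ph$targeting]), 0)
})

test_that("low-count sgRNAs are excluded by the 25-count filter", {
  tab <- make_screen(c(5, 400), c(3, 400), rep(100, 50), rep(100, 50),
                     gene = "G")
  ph <- compute_sgrna_phenotypes(tab, "treated", "vehicle", doubling_diff = 5)
  expect_false(ph$passed_count_filter[1])
  expect_true(is.na(ph$rho[1]))
  expect_true(ph$passed_count_filter[2])
  expect_error(compute_sgrna_phenotypes(tab, "treated", "vehicle",
                                        doubling_diff = 0), "positive")
})

test_that("gamma and tau phenotypes are computed against T0", {
  tab <- make_screen(200, 100, rep(100, 49), rep(100, 49))
  tab$T0 <- as.integer(c(100, rep(100, 49)))
  ph <- compute_sgrna_phenotypes(tab, "treated", "vehicle",
                                 doubling_diff = 4, t0 = "T0",
                                 gamma_doublings = 10)
  expect_false(anyNA(ph$gamma))
  expect_false(anyNA(ph$tau))
  expect_equal(median(ph$gamma[!ph$targeting]), 0)
})

test_that("mean of the strongest five phenotypes keeps the signed values", {
  tab <- make_screen(rep(c(800, 100), each = 5), rep(100, 10),
                     rep(100, 400), rep(100, 400))
  ph <- compute_sgrna_phenotypes(tab, "treated", "vehicle", doubling_diff = 3)
  gs <- score_genes(ph)
  expect_equal(gs$mean_top_rho, log2(810 / 110) / 3, tolerance = 1e-6)
  expect_equal(gs$n_sgrnas, 10)
})

test_that("Mann-Whitney p-values agree with the normal-approximation reference", {
  set.seed(8)
  ph <- data.frame(sgrna_id = sprintf("s%03d", 1:210),
                   gene = c(rep("G", 10), rep("non-targeting", 200)),
                   tss = c(rep("P1", 10), rep(NA, 200)),
                   targeting = c(rep(TRUE, 10), rep(FALSE, 200)),
                   rho = c(rnorm(10, 0.5), rnorm(200)),
                   passed_count_filter = TRUE)
  gs <- score_genes(ph)
  ref <- wilcox.test(ph$rho[1:10], ph$rho[-(1:10)], exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(gs$mw_p, ref, tolerance = 1e-10)
})

test_that("Mann-Whitney p-values match exact enumeration on downsampled controls", {
  set.seed(12)
  for (shift in c(0.2, 0.5, 0.8, 1.2)) {
    gene_rho <- rnorm(10, shift)
    ctrl_rho <- rnorm(50)
    ph <- data.frame(sgrna_id = sprintf("s%03d", 1:60),
                     gene = c(rep("G", 10), rep("non-targeting", 50)),
                     tss = c(rep("P1", 10), rep(NA, 50)),
                     targeting = c(rep(TRUE, 10), rep(FALSE, 50)),
                     rho = c(gene_rho, ctrl_rho),
                     passed_count_filter = TRUE)
    gs <- score_genes(ph)
    exact_p <- wilcox.test(gene_rho, ctrl_rho, exact = TRUE)$p.value
    # tight agreement at moderate p; the normal approximation deviates by
    # design in the far tail, but never by more than ~half a decade here
    if (exact_p > 0.01) {
      expect_lt(abs(gs$mw_p - exact_p), 0.02)
    }
    expect_lt(abs(log10(gs$mw_p) - log10(exact_p)), 0.6)
  }
})

test_that("the lowest-p TSS represents multi-TSS genes", {
  set.seed(3)
  ph <- data.frame(
    sgrna_id = sprintf("s%03d", 1:120),
    gene = c(rep("G", 20), rep("non-targeting", 100)),
    tss = c(rep(c("P1", "P2"), each = 10), rep(NA, 100)),
    targeting = c(rep(TRUE, 20), rep(FALSE, 100)),
    rho = c(rnorm(10, 2), rnorm(10, 0.05), rnorm(100)),
    passed_count_filter = TRUE)
  gs <- score_genes(ph)
  expect_equal(nrow(gs), 1)
  expect_equal(gs$tss, "P1")
  expect_gt(gs$resistance_score, 0)
  expect_equal(gs$hypersensitivity_score, -gs$resistance_score)
})

test_that("genes with too few observed phenotypes are dropped", {
  ph <- data.frame(sgrna_id = sprintf("s%03d", 1:57),
                   gene = c(rep("G", 7), rep("non-targeting", 50)),
                   tss = c(rep("P1", 7), rep(NA, 50)),
                   targeting = c(rep(TRUE, 7), rep(FALSE, 50)),
                   rho = rnorm(57),
                   passed_count_filter = TRUE)
  expect_equal(nrow(score_genes(ph, min_observed = 8)), 0)
})

test_that("control gene sets are reproducible and respect the group size", {
  ids <- sprintf("ntc%04d", 1:100)
  a <- build_control_genes(ids, n_genes = 30, group_size = 10, n_sets = 3,
                           seed = 7)
  b <- build_control_genes(ids, n_genes = 30, group_size = 10, n_sets = 3,
                           seed = 7)
  expect_identical(a, b)
  # no sgRNA repeats within one pseudo-gene
  for (cs in a)
    expect_true(all(tapply(cs$sgrna_id, cs$pseudo_gene,
                           function(x) !anyDuplicated(x))))
  expect_error(build_control_genes(ids[1:5], 10, group_size = 10), "fewer")
})

test_that("control-gene scores are centred on zero with uniform p-values", {
  u <- screen_universe(150, "A", true_rho = 0, n_nontargeting = 800,
                       seed = 61)
  sim <- simulate_crispr_screen(u, depth = 2e6, seed = 62)
  ph <- compute_sgrna_phenotypes(sim$counts, "A", "vehicle",
                                 doubling_diff = 7.6)
  ctrl <- build_control_genes(sim$counts$sgrna_id[!sim$counts$targeting],
                              n_genes = 150, n_sets = 2, seed = 63)
  cs <- score_control_genes(list(A = ph), ctrl)
  allsc <- unlist(cs)
  expect_lt(abs(median(allsc, na.rm = TRUE)), 0.05)
})

test_that("cutoff selection matches a finer brute-force scan and is monotone", {
  set.seed(71)
  mk <- function() {
    m <- matrix(abs(rcauchy(600, 0, 0.05)), 300, 2)  # heavy-tailed null
    colnames(m) <- c("A", "B"); m
  }
  sets <- list(mk(), mk(), mk())
  cut <- select_cutoff(sets, step = 0.01)
  n_double <- function(cutoff) mean(vapply(sets, function(m)
    sum(rowSums(m > cutoff) >= 2), numeric(1)))
  # brute-force oracle at a 10x finer grid
  fine <- seq(0.001, max(unlist(sets)) + 0.001, by = 0.001)
  oracle <- fine[which(vapply(fine, n_double, numeric(1)) <= 1)[1]]
  expect_lte(abs(cut - oracle), 0.01)
  expect_lte(n_double(cut), 1)
  # monotone: raising the cutoff never increases the double count
  grid <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(vapply(grid, n_double, numeric(1))) <= 0))
  # degenerate: all-zero controls accept the smallest scanned cutoff
  zero <- list(matrix(0, 10, 2))
  expect_equal(as.numeric(select_cutoff(zero)), 0.01)
})

test_that("planted dual-resistance genes are recovered across seeds", {
  recovered <- 0
  for (seed in 1:5) {
    tr <- matrix(0, 80, 2, dimnames = list(NULL, c("A", "B")))
    tr[1:5, ] <- 1                                  # 5 dual-resistant genes
    u <- screen_universe(80, c("A", "B"), true_rho = tr,
                         efficacy_range = c(1, 1), n_nontargeting = 400,
                         doublings = 7.6, seed = seed)
    sim <- simulate_crispr_screen(u, depth = 2e6, seed = seed + 100)
    res <- analyze_crispr_screens(sim$counts, c(A = 7.6, B = 7.6),
                                  n_control_sets = 3, seed = seed)
    dual <- Reduce(intersect, res$calls$sets)
    if (all(sprintf("GENE%05d", 1:5) %in% dual)) recovered <- recovered + 1
  }
  expect_gte(recovered, 4)
})

test_that("collateral sensitivity pairs are reported", {
  m <- matrix(c(5, 0, 0, 0), 1, 4,
              dimnames = list("G1", c("A", "B", "C", "D")))
  h <- matrix(c(0, 4, 0, 0), 1, 4,
              dimnames = list("G1", c("A", "B", "C", "D")))
  out <- call_cross_resistance(m, cutoff = 1, hypersensitivity_scores = h)
  expect_equal(out$collateral$gene, "G1")
  expect_equal(out$collateral$resistant_to, "A")
  expect_equal(out$collateral$hypersensitive_to, "B")
  # disjoint resistant sets across drugs -> no overlap
  m2 <- rbind(G1 = c(5, 0), G2 = c(0, 5))
  colnames(m2) <- c("A", "B")
  out2 <- call_cross_resistance(m2, cutoff = 1)
  expect_equal(out2$multiplicity[[">=2"]], 0)
})

test_that("known effect sizes are recovered within 20% at adequate depth", {
  tr <- matrix(c(0.25, 0.5, 1, rep(0, 77)), 80, 1, dimnames = list(NULL, "A"))
  u <- screen_universe(80, "A", true_rho = tr, efficacy_range = c(1, 1),
                       n_nontargeting = 500, doublings = 7.6, seed = 81)
  sim <- simulate_crispr_screen(u, depth = 4e6, dispersion = 0.05, seed = 82)
  ph <- compute_sgrna_phenotypes(sim$counts, "A", "vehicle",
                                 doubling_diff = 7.6)
  gs <- score_genes(ph)
  for (i in 1:3) {
    est <- gs$mean_top_rho[gs$gene == sprintf("GENE%05d", i)]
    expect_lt(abs(est - tr[i, 1]) / tr[i, 1], 0.2)
  }
})

test_that("an all-null screen yields few multi-drug calls at the selected cutoff", {
  u <- screen_universe(150, c("A", "B"), true_rho = 0, n_nontargeting = 600,
                       seed = 91)
  sim <- simulate_crispr_screen(u, depth = 2e6, seed = 92)
  res <- analyze_crispr_screens(sim$counts, c(A = 7.6, B = 7.6),
                                n_control_sets = 5, seed = 93)
  expect_lte(res$calls$multiplicity[[">=2"]], 2)
})
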