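make_surface <- function(rv, d = 3) {
  n <- nrow(rv) - 1
  dose_response_surface(c("a", "b"), c(0, seq_len(n)), c(0, seq_len(ncol(rv) - 1)),
                        rv, control_doublings = d)
}

test_that("GR values hit the identity, stasis and direct-evaluation anchors", {
  rv <- matrix(c(1, 1, 1, 0.02), 2, 2)
  gr <- compute_gr(make_surface(rv, d = 3))$gr
  expect_equal(gr[1, 1], 1)                       # untreated: full growth
  expect_equal(gr[2, 2], log2(0.16) / 3, tolerance = 1e-12)
  expect_equal(round(gr[2, 2], 3), -0.881)
  # final cell count equal to initial: rv = 2^-d  ->  GR = 0 (stasis)
  rv0 <- matrix(c(1, 1, 1, 2^-3), 2, 2)
  expect_equal(compute_gr(make_surface(rv0, d = 3))$gr[2, 2], 0)
  # GR is not floored at -1
  rvdeep <- matrix(c(1, 1, 1, 1e-4), 2, 2)
  expect_lt(compute_gr(make_surface(rvdeep, d = 3))$gr[2, 2], -1)
  bad <- make_surface(rv); bad$control_doublings <- 0
  expect_error(compute_gr(bad), "doublings")
})

test_that("expected kill follows the independence product rule", {
  # two drugs each killing 99% -> 99.99% expected kill (2 + 2 = 4 log-kills)
  rv <- matrix(c(1, 0.01, 0.01, 0.01 * 0.01), 2, 2)
  sc <- excess_over_bliss(make_surface(rv))
  expect_equal(sc$p_expected[2, 2], 0.9999, tolerance = 1e-12)
  expect_equal(sc$eob[2, 2], 0)                   # observed matches expected
})

test_that("EOB measures extra log-kills: 99% expected vs 99.9% observed is 1", {
  rv <- matrix(c(1, 0.1, 0.1, 0.001), 2, 2)       # margins expect 99% kill
  sc <- excess_over_bliss(make_surface(rv))
  expect_equal(sc$p_expected[2, 2], 0.99)
  expect_equal(sc$eob[2, 2], 1.0, tolerance = 1e-12)
})

test_that("noise-free Bliss surfaces recover a null EOB everywhere", {
  for (slopes in list(c(1, 1), c(2, 0.7))) {
    s <- simulate_checkerboard(hill_curve(1, slopes[1]),
                               hill_curve(4, slopes[2], max_kill = 0.98),
                               "bliss", noise_cv = 0)
    expect_lt(max(abs(excess_over_bliss(s)$eob)), 1e-9)
  }
})

test_that("antagonistic surfaces score negative EOB off the margins", {
  s <- simulate_checkerboard(hill_curve(1), hill_curve(1),
                             "antagonism_factor", antagonism = 3,
                             noise_cv = 0)
  eob <- excess_over_bliss(s)$eob
  expect_true(all(eob[-1, -1] < 0))
  expect_true(all(eob[1, ] == 0) && all(eob[, 1] == 0))
})

test_that("median smoothing leaves monotone surfaces alone and removes spikes", {
  mono <- outer(seq(0, 1.4, length.out = 8), seq(0, 0.8, length.out = 9), `+`)
  expect_equal(smooth_surface(mono), mono)
  flat <- matrix(0.5, 7, 7); flat[4, 4] <- 5
  expect_equal(smooth_surface(flat), matrix(0.5, 7, 7))
  set.seed(3)
  rnd <- matrix(runif(121), 11, 11)
  sm <- smooth_surface(rnd)
  orc <- oracle_median_filter(rnd)
  inner <- 2:10
  expect_equal(sm[inner, inner], orc[inner, inner])
  expect_equal(sm[c(1, 11), ], rnd[c(1, 11), ])  # edges pass through
  expect_equal(sm[, c(1, 11)], rnd[, c(1, 11)])
})

test_that("Loewe isoboles are straight lines in linear dose coordinates", {
  cva <- hill_curve(1, 1.2); cvb <- hill_curve(5, 1.2)
  s <- simulate_checkerboard(cva, cvb, "loewe", noise_cv = 0, n_doses = 21)
  iso <- extract_isoboles(s, levels = 0.5, smooth = FALSE)
  pts <- do.call(rbind, iso)
  expect_gt(nrow(pts), 5)
  # additivity line: dose_a / D_a(50%) + dose_b / D_b(50%) = 1
  resid <- pts$dose_a / 1 + pts$dose_b / 5 - 1
  expect_lt(max(abs(resid)), 0.02)
})

test_that("isobole convexity matches the closed-form Bliss crossing", {
  # steep Hill slopes: the Bliss 50%-kill isobole bows away from the origin
  cv <- hill_curve(1, hill_slope = 3)
  s <- simulate_checkerboard(cv, cv, "bliss", noise_cv = 0, n_doses = 41)
  iso <- do.call(rbind, extract_isoboles(s, levels = 0.5, smooth = FALSE))
  near_diag <- iso[which.min(abs(log(iso$dose_a / iso$dose_b))), ]
  # closed form: equal doses d with (1 - k(d))^2 = 0.5
  k_eq <- 1 - sqrt(0.5)
  d_eq <- (k_eq / (1 - k_eq))^(1 / 3)
  expect_equal(near_diag$dose_a, d_eq, tolerance = 0.05)
  expect_gt(near_diag$dose_a + near_diag$dose_b, 1)  # outside the chord
})

test_that("levels beyond the surface range yield a warning and no contours", {
  s <- simulate_checkerboard(hill_curve(1, max_kill = 0.4),
                             hill_curve(1, max_kill = 0.4), "bliss",
                             noise_cv = 0)
  expect_warning(iso <- extract_isoboles(s, levels = 0.9), "outside")
  expect_length(iso, 0)
})

test_that("equipotent designs weight drugs by their equi-effective dose", {
  w <- design_equipotent_mixture(list(a = hill_curve(2), b = hill_curve(2)))
  expect_equal(unname(w$weights), c(0.5, 0.5))
  w2 <- design_equipotent_mixture(list(a = hill_curve(1), b = hill_curve(9)))
  expect_equal(unname(w2$weights), c(0.1, 0.9))
  expect_error(
    design_equipotent_mixture(list(pred = hill_curve(1, max_kill = 0.3))),
    "pred")
})

test_that("each constituent of an equipotent Loewe mixture carries an equal FIC share", {
  curves <- list(a = hill_curve(1, 1.5), b = hill_curve(4, 0.8),
                 c = hill_curve(0.5, 2))
  des <- design_equipotent_mixture(curves)
  mr <- simulate_mixture_response(curves, weights = des$weights,
                                  interaction = "loewe")
  f <- compute_fic(mr, curves)
  shares <- f$weights * f$mixture_dose / f$single_doses
  expect_equal(shares, rep(shares[1], 3), tolerance = 0.02)
  expect_equal(f$fic, 1, tolerance = 0.02)
})

test_that("sham self-combinations score FIC = 1 at every effect level", {
  cv <- hill_curve(3, 1.7, max_kill = 0.97)
  mr <- simulate_mixture_response(list(a = cv, b = cv), weights = c(0.5, 0.5),
                                  interaction = "loewe")
  for (lvl in c(0.3, 0.5, 0.8))
    expect_equal(compute_fic(mr, list(a = cv, b = cv),
                             effect_level = lvl)$fic, 1, tolerance = 0.02)
})

test_that("five-drug Loewe mixtures are additive (FIC = 1) at 50% and 80% kill", {
  curves <- lapply(c(1, 2, 5, 0.3, 9), hill_curve, hill_slope = 1.3)
  names(curves) <- paste0("d", 1:5)
  mr <- simulate_mixture_response(curves, interaction = "loewe")
  for (lvl in c(0.5, 0.8))
    expect_equal(compute_fic(mr, curves, effect_level = lvl)$fic, 1,
                 tolerance = 0.02)
})

test_that("the Bliss-independent pair FIC matches the closed-form crossing", {
  cv <- hill_curve(1)
  mr <- simulate_mixture_response(list(a = cv, b = cv), weights = c(0.5, 0.5),
                                  interaction = "bliss")
  f <- compute_fic(mr, list(a = cv, b = cv))
  # oracle: (1 - k(T/2))^2 = 0.5 with k(d) = d/(1+d)  ->  T = 2(sqrt(2)-1)
  t_oracle <- 2 * (sqrt(2) - 1)
  expect_equal(f$fic, t_oracle / 1, tolerance = 0.02)
})

test_that("FIC replicate confidence intervals cover additivity on noisy data", {
  curves <- lapply(c(1, 2, 5, 0.3, 9), hill_curve)
  names(curves) <- paste0("d", 1:5)
  des <- design_equipotent_mixture(curves)
  t50 <- 1 / sum(des$weights / des$ref_doses)  # additive 50%-kill total dose
  doses <- exp(seq(log(t50 / 6), log(t50 * 6), length.out = 25))
  covered <- 0
  for (seed in 1:100) {
    mr <- simulate_mixture_response(curves, weights = des$weights,
                                    total_doses = doses,
                                    interaction = "loewe",
                                    noise_cv = 0.1, n_replicates = 4,
                                    seed = seed)
    ci <- suppressWarnings(compute_fic(mr, curves)$ci95)
    if (ci[1] <= 1 && 1 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered, 90)
})

test_that("errors are raised when effect levels cannot be located", {
  cv <- hill_curve(1, max_kill = 0.4)
  mr <- simulate_mixture_response(list(a = cv, b = cv),
                                  weights = c(0.5, 0.5),
                                  total_doses = c(0.1, 1, 10),
                                  interaction = "loewe")
  expect_error(compute_fic(mr, list(a = cv, b = cv), effect_level = 0.5),
               "never reaches")
})

test_that("emergent FIC isolates interactions that appear only at higher order", {
  # fully additive system
  fics <- c("A+B" = 1, "A+C" = 1, "B+C" = 1, "A+B+C" = 1)
  expect_equal(as.numeric(emergent_fic(fics, c("A", "B", "C"))), 1)
  # deviation present only at order 3
  fics["A+B+C"] <- 1.5
  expect_equal(as.numeric(emergent_fic(fics, c("A", "B", "C"))), 1.5)
  expect_error(emergent_fic(fics[-1], c("A", "B", "C")), "A\\+B")
})

test_that("a pairwise antagonism embedded in a triple is not scored as emergent", {
  cv <- hill_curve(1, 1.2)
  curves3 <- list(A = cv, B = cv, C = cv)
  w3 <- rep(1 / 3, 3)
  fic_at <- function(curves, w, inter) {
    mr <- simulate_mixture_response(curves, weights = w, interaction = inter,
                                    antagonism = 2)
    compute_fic(mr, curves)$fic
  }
  fics <- c(
    "A+B" = fic_at(curves3[c("A", "B")], c(0.5, 0.5), "antagonism_factor"),
    "A+C" = fic_at(curves3[c("A", "C")], c(0.5, 0.5), "loewe"),
    "B+C" = fic_at(curves3[c("B", "C")], c(0.5, 0.5), "loewe"),
    "A+B+C" = fic_at(curves3, w3, "antagonism_factor"))
  expect_gt(fics[["A+B"]], 1.5)                   # the pair is antagonistic
  em <- emergent_fic(fics, c("A", "B", "C"))
  expect_equal(as.numeric(em), 1, tolerance = 0.05)
})
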