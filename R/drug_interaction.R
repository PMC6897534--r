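#' Convert relative viability to growth-rate (GR) values
#'
#' Relative cell number after treatment confounds cytostasis with killing
#' whenever untreated cells divide during the assay. The GR metric rescales
#' by the untreated growth: with d = control population doublings over the
#' assay window,
#' \deqn{GR = \log_2(\mathrm{relative\ viability} \times 2^d) / d}
#' so GR = 1 means uninhibited growth, GR = 0 complete growth arrest (final
#' cell count equals initial), and GR < 0 net cell killing. No lower
#' asymptote is imposed.
#'
#' @param surface a [dose_response_surface()].
#' @param min_viability relative viabilities below this floor are clipped
#'   before taking logs (keeps GR finite on fully killed wells).
#' @return a `gr_surface` object: the surface fields plus a `gr` matrix.
#' @export
compute_gr <- function(surface, min_viability = 1e-6) {
  stopifnot(inherits(surface, "dose_response_surface"))
  d <- surface$control_doublings
  if (d <= 0) stop("GR is undefined without positive control doublings")
  rv <- pmax(surface$relative_viability, min_viability)
  gr <- log2(rv * 2^d) / d
  out <- unclass(surface)
  out$gr <- gr
  class(out) <- c("gr_surface", "dose_response_surface")
  out
}

#' Score a checkerboard against Bliss independence
#'
#' If drugs a and b alone kill fractions \eqn{p_a} and \eqn{p_b} and deaths
#' are statistically independent, the combination is expected to kill
#' \eqn{p_{exp} = p_a + (1-p_a) p_b}. Deviations are scored on the log scale:
#' \deqn{EOB = \log_{10}(1 - p_{exp}) - \log_{10}(1 - p_{obs})}
#' which counts extra log-kills beyond independence; positive EOB is synergy,
#' negative antagonism. Kill fractions are taken as 1 - relative viability,
#' clipped to \[0, 1 - eps\]; single-drug margins come from the zero-dose
#' row and column of the same surface.
#'
#' @param surface a [dose_response_surface()] whose dose axes include the
#'   zero dose.
#' @param eps clipping guard keeping survival positive (default 1e-12).
#' @return an `interaction_score` object: list with `p_expected`,
#'   `p_observed` and `eob` matrices on the same grid, plus the dose axes.
#' @export
excess_over_bliss <- function(surface, eps = 1e-12) {
  stopifnot(inherits(surface, "dose_response_surface"))
  if (surface$dose_a[1] != 0 || surface$dose_b[1] != 0)
    stop("surface must include zero-dose margins for both drugs")
  p <- pmin(pmax(1 - surface$relative_viability, 0), 1 - eps)
  p_a <- p[, 1]  # margin: drug a alone (dose_b = 0)
  p_b <- p[1, ]  # margin: drug b alone (dose_a = 0)
  p_expected <- outer(p_a, p_b, function(a, b) a + (1 - a) * b)
  eob <- log10(1 - p_expected) - log10(1 - p)
  structure(list(drug_names = surface$drug_names,
                 dose_a = surface$dose_a, dose_b = surface$dose_b,
                 p_expected = p_expected, p_observed = p, eob = eob),
            class = "interaction_score")
}

#' @export
print.interaction_score <- function(x, ...) {
  off <- x$eob[-1, -1]
  cat(sprintf("Excess over Bliss, %s x %s\n", x$drug_names[1],
              x$drug_names[2]))
  cat(sprintf("EOB (log10 kill units) off-margin: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' Nearest-neighbour median smoothing of a response surface
#'
#' Each interior grid cell is replaced by the median of its full 3 x 3
#' neighbourhood; edge and corner cells, which lack a full neighbourhood, are
#' passed through unchanged (an even-sized shrunk window would average its
#' middle pair and perturb even perfectly monotone data). Surfaces monotone
#' in both doses are fixed points; the filter only removes locally
#' non-monotone jaggedness.
#'
#' @param grid numeric matrix.
#' @return smoothed matrix of the same dimensions.
#' @export
smooth_surface <- function(grid) {
  stopifnot(is.matrix(grid))
  nr <- nrow(grid); nc <- ncol(grid)
  out <- grid
  if (nr < 3 || nc < 3) return(out)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      out[i, j] <- stats::median(grid[(i - 1):(i + 1), (j - 1):(j + 1)])
    }
  }
  out
}

#' Extract isoboles (equal-effect contours) from a response surface
#'
#' Contours are computed by linear level-crossing interpolation between grid
#' nodes in log-dose coordinates, over the positive-dose part of the grid.
#' Straight isoboles in linear dose coordinates indicate Loewe additivity;
#' convexity toward the origin indicates synergy, concavity antagonism.
#'
#' @param surface a `gr_surface` (contours of the GR grid) or a
#'   [dose_response_surface()] (contours of the kill-fraction grid).
#' @param levels numeric vector of effect levels to contour.
#' @param smooth apply [smooth_surface()] first (default TRUE).
#' @return list of data frames (`level`, `dose_a`, `dose_b`), one per contour
#'   segment, in original dose units. Levels outside the surface range yield
#'   no contours and a warning.
#' @export
extract_isoboles <- function(surface, levels, smooth = TRUE) {
  stopifnot(inherits(surface, "dose_response_surface"))
  z <- if (inherits(surface, "gr_surface")) surface$gr else
    1 - surface$relative_viability
  z <- z[-1, -1, drop = FALSE]  # positive doses only (log coordinates)
  if (smooth) z <- smooth_surface(z)
  la <- log10(surface$dose_a[-1])
  lb <- log10(surface$dose_b[-1])
  out_of_range <- levels[levels < min(z) | levels > max(z)]
  if (length(out_of_range))
    warning("level(s) outside surface range: ",
            paste(signif(out_of_range, 3), collapse = ", "))
  cl <- grDevices::contourLines(la, lb, z, levels = levels)
  lapply(cl, function(seg)
    data.frame(level = seg$level, dose_a = 10^seg$x, dose_b = 10^seg$y))
}
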