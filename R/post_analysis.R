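#' Concentration weight for one dose combination
#'
#' Weights the synergy delta at a dose combination by how far the single
#' agents are from saturating the response at those doses:
#' \deqn{w = \sqrt{\prod_n \frac{100 - y_n}{100 - l_n}}}
#' where `y_n` is the measured percent-inhibition response of drug `n` at
#' its dose in the cell and `l_n` the lower asymptote of its fitted curve.
#' Each factor is clamped to \[0, 1\] before the product (responses above
#' 100 or below the asymptote would otherwise make the weight undefined or
#' exceed 1), so the weight is 1 when every single agent sits at its
#' baseline and 0 when any single agent reaches full inhibition. Weighting
#' by single-agent response proportions rather than raw doses makes the
#' scheme insensitive to heterogeneous concentration ranges and units.
#'
#' @param y_singles single-agent percent inhibitions at the cell's doses,
#'   one per drug.
#' @param l_asymptotes lower asymptotes `l_n`, one per drug (each < 100).
#' @return weight in \[0, 1\].
#' @examples
#' dose_weight(c(0, 0), c(0, 0))   # 1
#' dose_weight(50, 0)              # sqrt(0.5)
#' dose_weight(c(100, 20), c(0, 0)) # 0
#' @export
dose_weight <- function(y_singles, l_asymptotes) {
  stopifnot(length(y_singles) == length(l_asymptotes), length(y_singles) >= 1)
  if (any(l_asymptotes >= 100 - 1e-9)) {
    stop_synscreen(
      "lower asymptote at or above 100% inhibition: concentration weight undefined",
      "synscreen_degenerate_curves_error")
  }
  f <- clamp((100 - y_singles) / (100 - l_asymptotes), 0, 1)
  sqrt(prod(f))
}

#' Fill the concentration-weight tensor of a synergy surface
#'
#' Computes [dose_weight()] for every all-positive-dose cell from the
#' block's measured (outlier-corrected, if correction was applied)
#' single-agent responses and the fitted curves' lower asymptotes, and
#' stores it in the surface's `weight` slot. [summarize_surface()] then
#' reports `weighted_mean_delta`, the mean of weight x delta over the
#' all-positive cells — an implicit prioritization of synergy observed at
#' low-effect (low-dose) windows. The weighted score is deliberately not
#' renormalized by the mean weight: a block whose synergy sits entirely at
#' saturating doses is meant to score near 0.
#'
#' @param surface a `synergy_surface`.
#' @param block the block it was computed from.
#' @param curves the fitted single-agent curves (providing `l_n`).
#' @return the surface with `weight` filled.
#' @export
weighted_surface <- function(surface, block, curves = fit_block_curves(block)) {
  singles <- single_agent_values(block, curves)
  l <- vapply(curves, `[[`, 0, "l")
  dims <- dim(surface$delta)
  cells <- index_grid(dims)
  w <- array(NA_real_, dim = dims)
  for (r in seq_len(nrow(cells))) {
    ii <- cells[r, ]
    y <- vapply(seq_along(ii), function(k) singles[[k]][ii[k]], 0)
    w[matrix(ii, nrow = 1)] <- dose_weight(y, l)
  }
  surface$weight <- w
  surface
}

# ---------------------------------------------------------------------------
# MuSyC: two-drug mass-action synergy decomposition
# ---------------------------------------------------------------------------

# Steady state of the four-state (unaffected / drug1 / both / drug2)
# mass-action cycle, via the Markov-chain tree theorem (closed form, so the
# surface evaluation is fully vectorized over dose pairs). Rates: forward
# binding d^h, unbinding C^h; the partner drug rescales the effective dose
# by alpha (potency interaction). Cooperativity interactions (gamma) are
# fixed at 1.
#
# Effect scale: normalized inhibition in [0, 1], baseline E0 = 0.
musyc_effect <- function(d1, d2, par) {
  A  <- d1^par$h1                      # U -> A1
  P  <- par$C1^par$h1                  # A1 -> U  (and A12 -> A2)
  B  <- d2^par$h2                      # U -> A2
  Q  <- par$C2^par$h2                  # A2 -> U  (and A12 -> A1)
  A2f <- (par$alpha12 * d2)^par$h2     # A1 -> A12
  A1f <- (par$alpha21 * d1)^par$h1     # A2 -> A12
  # states 1 = U, 2 = A1, 3 = A12, 4 = A2 on the cycle 1-2-3-4-1
  a12 <- A;  a21 <- P
  a23 <- A2f; a32 <- Q
  a34 <- P;  a43 <- A1f
  a41 <- Q;  a14 <- B
  p1 <- a23 * a34 * a41 + a21 * a34 * a41 + a32 * a21 * a41 + a43 * a32 * a21
  p2 <- a34 * a41 * a12 + a32 * a41 * a12 + a43 * a32 * a12 + a14 * a43 * a32
  p3 <- a41 * a12 * a23 + a43 * a12 * a23 + a14 * a43 * a23 + a21 * a14 * a43
  p4 <- a12 * a23 * a34 + a14 * a23 * a34 + a21 * a14 * a34 + a32 * a21 * a14
  tot <- p1 + p2 + p3 + p4
  (p2 * par$E1 + p3 * par$E3 + p4 * par$E2) / tot   # E0 = 0
}

musyc_beta <- function(E1, E2, E3) E3 - max(E1, E2)

#' Fit the MuSyC synergy model to a two-drug block
#'
#' MuSyC models the combination response surface with a mass-action scheme
#' in which each cell population is unaffected, affected by drug 1, by
#' drug 2, or by both. Its parameters separate two modes of synergy:
#' `alpha12` / `alpha21` rescale one drug's effective potency in the
#' presence of the other (potency synergy when their geometric mean exceeds
#' 1), and `beta` is the gain of the combination's maximal effect `E3` over
#' the stronger single-agent maximum on the normalized (0-1 inhibition)
#' effect scale (efficacy synergy when positive). At `alpha = 1` and
#' `beta = 0` the surface reduces to the family's no-interaction null.
#'
#' Responses are normalized internally to \[0, 1\] with baseline `E0 = 0`
#' and fitted by bounded least squares over the whole dose grid. The fit is
#' deterministic: single-agent curve fits seed `E`, `C` and `h`, and a
#' fixed multi-start grid `alpha in (0.1, 1, 10)` (both alphas started at
#' the same value) guards against local minima. Non-sigmoidal monotherapies
#' trigger a quality warning (the model assumes monotone sigmoidal
#' single-agent responses) but the fit proceeds.
#'
#' @param block a two-drug `combination_block` with at least 4 doses per
#'   drug including zero.
#' @param curves optional precomputed single-agent curve fits.
#' @return object of class `musyc_fit` with per-drug `E1`, `E2`, `C1`,
#'   `C2`, `h1`, `h2`, combination `E3`, `alpha12`, `alpha21`, `beta`,
#'   `fit_rss` (percent-inhibition scale) and `quality_warning`.
#' @export
fit_musyc <- function(block, curves = NULL) {
  if (length(block$drugs) != 2) {
    stop_synscreen("MuSyC fitting is defined for two-drug blocks only",
                   "synscreen_domain_error")
  }
  g1 <- block$dose_grid[[1]]; g2 <- block$dose_grid[[2]]
  if (length(g1) < 4 || length(g2) < 4) {
    stop_synscreen("MuSyC needs at least 4 doses (including 0) per drug",
                   "synscreen_insufficient_data_error")
  }
  quality <- FALSE
  if (is.null(curves)) {
    curves <- withCallingHandlers(
      fit_block_curves(block),
      synscreen_poor_fit_warning = function(w) {
        quality <<- TRUE
        invokeRestart("muffleWarning")
      })
  } else {
    quality <- any(vapply(curves, function(cv) isTRUE(cv$poor_fit), TRUE))
  }
  obs <- block$response / 100            # normalized effect scale
  cells <- index_grid(dim(obs))
  d1 <- g1[cells[, 1]]; d2 <- g2[cells[, 2]]
  yv <- obs[cells]
  ok <- is.finite(yv)
  d1 <- d1[ok]; d2 <- d2[ok]; yv <- yv[ok]

  # parameter vector: E1, E2, E3, logC1, logC2, logh1, logh2, la12, la21
  unpack <- function(p) list(
    E1 = p[1], E2 = p[2], E3 = p[3],
    C1 = exp(p[4]), C2 = exp(p[5]), h1 = exp(p[6]), h2 = exp(p[7]),
    alpha12 = 10^p[8], alpha21 = 10^p[9])
  rss_fun <- function(p) {
    par <- unpack(p)
    sum((yv - musyc_effect(d1, d2, par))^2)
  }
  seed_par <- function(a) c(
    clamp((curves[[1]]$u - curves[[1]]$l) / 100, 0.01, 1.5),
    clamp((curves[[2]]$u - curves[[2]]$l) / 100, 0.01, 1.5),
    clamp(max(yv), 0.01, 1.5),
    log(curves[[1]]$ec50), log(curves[[2]]$ec50),
    log(clamp(curves[[1]]$h, 0.1, 10)), log(clamp(curves[[2]]$h, 0.1, 10)),
    log10(a), log10(a))
  lower <- c(0, 0, 0, log(min(g1[g1 > 0]) * 1e-3), log(min(g2[g2 > 0]) * 1e-3),
             log(0.05), log(0.05), -3, -3)
  upper <- c(1.5, 1.5, 1.5, log(max(g1) * 1e3), log(max(g2) * 1e3),
             log(20), log(20), 3, 3)
  best <- NULL
  for (a in c(0.1, 1, 10)) {
    fit <- stats::optim(seed_par(a), rss_fun, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 1000, factr = 1e3))
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  par <- unpack(best$par)
  if (quality) {
    warn_synscreen("monotherapy dose-responses look non-sigmoidal; MuSyC parameters may be unreliable",
                   "synscreen_musyc_quality_warning")
  }
  structure(list(
    block_id = block$block_id, sample_id = block$sample_id,
    drugs = block$drugs,
    E0 = 0, E1 = par$E1, E2 = par$E2, E3 = par$E3,
    C1 = par$C1, C2 = par$C2, h1 = par$h1, h2 = par$h2,
    alpha12 = par$alpha12, alpha21 = par$alpha21,
    beta = musyc_beta(par$E1, par$E2, par$E3),
    fit_rss = best$value * 100^2,        # back to %inh^2
    quality_warning = quality
  ), class = "musyc_fit")
}

#' @export
print.musyc_fit <- function(x, ...) {
  cat(sprintf("<musyc_fit> %s (%s + %s)\n", x$block_id, x$drugs[1], x$drugs[2]))
  cat(sprintf("  E1 %.3f E2 %.3f E3 %.3f | C1 %.4g C2 %.4g | h1 %.2f h2 %.2f\n",
              x$E1, x$E2, x$E3, x$C1, x$C2, x$h1, x$h2))
  cat(sprintf("  alpha12 %.3g alpha21 %.3g beta %.3f (RSS %.3g)\n",
              x$alpha12, x$alpha21, x$beta, x$fit_rss))
  invisible(x)
}

#' Classify the mode of synergy from a MuSyC fit
#'
#' The potency axis compares the geometric mean of `alpha12` and `alpha21`
#' with 1 (on a log10 scale, beyond `alpha_tol`); the efficacy axis
#' compares `beta` with 0 (beyond `beta_tol`). Combinations synergistic on
#' one axis and antagonistic on the other are labelled `mixed`.
#'
#' @param fit a `musyc_fit`.
#' @param alpha_tol dead zone on log10 geometric-mean alpha (default 0.1).
#' @param beta_tol dead zone on beta (default 0.05).
#' @return one of `"potency_synergy"`, `"efficacy_synergy"`, `"both"`,
#'   `"antagonism_potency"`, `"antagonism_efficacy"`, `"mixed"`, `"none"`.
#' @export
classify_synergy_mode <- function(fit, alpha_tol = 0.1, beta_tol = 0.05) {
  la <- log10(geomean(c(fit$alpha12, fit$alpha21)))
  pot <- if (la > alpha_tol) 1L else if (la < -alpha_tol) -1L else 0L
  eff <- if (fit$beta > beta_tol) 1L else if (fit$beta < -beta_tol) -1L else 0L
  if (pot == 1 && eff == 1) return("both")
  if (pot == 1 && eff == 0) return("potency_synergy")
  if (pot == 0 && eff == 1) return("efficacy_synergy")
  if (pot == -1 && eff == 0) return("antagonism_potency")
  if (pot == 0 && eff == -1) return("antagonism_efficacy")
  if (pot == 0 && eff == 0) return("none")
  "mixed"
}

#' Tabulate MuSyC fits
#' @param fits list of `musyc_fit` objects.
#' @param alpha_tol,beta_tol passed to [classify_synergy_mode()].
#' @return one row per fit with parameters and mode label.
#' @export
musyc_table <- function(fits, alpha_tol = 0.1, beta_tol = 0.05) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(block_id = f$block_id, sample_id = f$sample_id,
               drug1 = f$drugs[1], drug2 = f$drugs[2],
               E1 = f$E1, E2 = f$E2, E3 = f$E3, C1 = f$C1, C2 = f$C2,
               h1 = f$h1, h2 = f$h2, alpha12 = f$alpha12, alpha21 = f$alpha21,
               beta = f$beta, fit_rss = f$fit_rss,
               mode = classify_synergy_mode(f, alpha_tol, beta_tol),
               quality_warning = f$quality_warning, stringsAsFactors = FALSE)
  }))
}
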