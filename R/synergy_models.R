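#' Expected combination effect under Bliss independence
#'
#' Bliss assumes independent drug action: survival fractions multiply, so
#' the expected inhibition of `n` drugs with single-agent inhibitions `y_i`
#' is `100 * (1 - prod(1 - y_i/100))`. Inputs are clamped to \[0, 100\]
#' inside the product only — survival fractions outside \[0, 1\] are
#' unphysical and destabilize higher-order products — while raw values are
#' retained everywhere else in the pipeline.
#'
#' @param y numeric vector of single-agent percent inhibitions, one per drug.
#' @return expected percent inhibition.
#' @examples
#' expected_bliss(c(50, 50))     # 75
#' expected_bliss(c(50, 50, 50)) # 87.5
#' @export
expected_bliss <- function(y) {
  if (length(y) == 0) stop_synscreen("empty effect vector", "synscreen_domain_error")
  if (any(!is.finite(y))) stop_synscreen("non-finite effect", "synscreen_domain_error")
  100 * (1 - prod(1 - clamp(y, 0, 100) / 100))
}

#' Expected combination effect under highest single agent (HSA)
#'
#' The expected effect is simply the strongest single-agent effect at the
#' combination's doses. Negative (stimulatory) responses are allowed.
#'
#' @inheritParams expected_bliss
#' @export
expected_hsa <- function(y) {
  if (length(y) == 0) stop_synscreen("empty effect vector", "synscreen_domain_error")
  if (any(!is.finite(y))) stop_synscreen("non-finite effect", "synscreen_domain_error")
  max(y)
}

#' Expected combination effect under Loewe additivity
#'
#' Loewe additivity treats the combination as a dilution of one drug: the
#' expected effect `y*` satisfies the isobole equation
#' `sum_i d_i / D_i(y*) = 1`, where `D_i(y)` is the dose of drug `i` alone
#' producing effect `y` (from its fitted curve). The root is found by
#' bisection on `y` over the overlap of the curves' response ranges,
#' `(max_i l_i, min_i u_i)`, to a tolerance of 1e-6 on the dose-fraction
#' sum. If the sum still exceeds 1 as `y` approaches `min_i u_i`, the
#' combination is saturated and `min_i u_i` is returned.
#'
#' @param curves list of `dose_response_curve`, one per drug.
#' @param doses positive doses, one per drug.
#' @return expected percent inhibition.
#' @export
expected_loewe <- function(curves, doses) {
  stopifnot(length(curves) == length(doses))
  if (any(doses <= 0)) {
    stop_synscreen("Loewe expectation requires strictly positive doses",
                   "synscreen_domain_error")
  }
  lo <- max(vapply(curves, `[[`, 0, "l"))
  hi <- min(vapply(curves, `[[`, 0, "u"))
  if (lo >= hi) {
    stop_synscreen("degenerate curves: single-agent response ranges do not overlap",
                   "synscreen_degenerate_curves_error")
  }
  fsum <- function(y) {
    s <- 0
    for (i in seq_along(curves)) s <- s + doses[i] / inverse_dose(curves[[i]], y)
    s
  }
  span <- hi - lo
  eps <- span * 1e-12
  a <- lo + eps
  b <- hi - eps
  if (fsum(b) - 1 > 1e-6) return(hi)  # saturated: even the max effect is exceeded
  if (fsum(a) - 1 < 0) return(lo)     # doses too small to lift off the baseline
  for (it in 1:200) {
    m <- (a + b) / 2
    fm <- fsum(m) - 1
    if (abs(fm) < 1e-6 || (b - a) < eps) return(m)
    if (fm > 0) a <- m else b <- m    # fsum decreases in y
  }
  m
}

positive_idx <- function(block) {
  lapply(block$dose_grid, function(g) which(g > 0))
}

# Extract the all-positive-dose subtensor of `arr` given a block's grid.
positive_subtensor <- function(block, arr) {
  do.call(`[`, c(list(arr), positive_idx(block), list(drop = FALSE)))
}

new_synergy_surface <- function(block, model, observed, expected, delta,
                                weight = NULL) {
  structure(list(
    block_id = block$block_id, sample_id = block$sample_id,
    drugs = block$drugs, model = model,
    dose_grid_pos = lapply(block$dose_grid, function(g) g[g > 0]),
    observed = observed, expected = expected, delta = delta, weight = weight
  ), class = "synergy_surface")
}

#' @export
print.synergy_surface <- function(x, ...) {
  cat(sprintf("<synergy_surface> %s (%s): %s, mean delta %.3f\n",
              x$block_id, x$model, paste(dim(x$delta), collapse = " x "),
              mean(x$delta, na.rm = TRUE)))
  invisible(x)
}

# Measured single-agent response of drug k at positive-dose position
# (index into the positive grid); falls back to the fitted curve where the
# axis measurement is missing.
single_agent_values <- function(block, curves) {
  lapply(seq_along(block$drugs), function(k) {
    pos <- which(block$dose_grid[[k]] > 0)
    ax <- axis_responses(block, k)[pos]
    miss <- !is.finite(ax)
    if (any(miss)) {
      ax[miss] <- predict_response(curves[[k]], block$dose_grid[[k]][pos][miss])
    }
    ax
  })
}

#' Synergy surface under one reference model
#'
#' Computes the expected-effect tensor and the synergy delta
#' (observed minus expected) over all all-positive-dose combinations of a
#' block. Bliss and HSA expectations use the measured single-agent axis
#' responses (after any outlier correction already applied to the block);
#' Loewe necessarily uses the fitted curves.
#'
#' @param block a `combination_block`.
#' @param model one of `"bliss"`, `"loewe"`, `"hsa"`.
#' @param curves fitted single-agent curves (from [fit_hill()]), one per
#'   drug; defaults to fitting them from the block's axes.
#' @return a `synergy_surface`.
#' @export
synergy_surface <- function(block, model = c("bliss", "loewe", "hsa"),
                            curves = fit_block_curves(block)) {
  model <- match.arg(model)
  pos <- positive_idx(block)
  dims <- unname(lengths(pos))
  singles <- single_agent_values(block, curves)
  cells <- index_grid(dims)
  expected <- array(NA_real_, dim = dims)
  for (r in seq_len(nrow(cells))) {
    ii <- cells[r, ]
    y <- vapply(seq_along(ii), function(k) singles[[k]][ii[k]], 0)
    expected[matrix(ii, nrow = 1)] <- switch(
      model,
      bliss = expected_bliss(y),
      hsa = expected_hsa(y),
      loewe = expected_loewe(
        curves,
        vapply(seq_along(ii), function(k) block$dose_grid[[k]][pos[[k]][ii[k]]], 0))
    )
  }
  observed <- positive_subtensor(block, block$response)
  new_synergy_surface(block, model, observed, expected, observed - expected)
}

#' Bliss/Loewe consensus synergy surface
#'
#' The consensus expected effect is the pointwise maximum of the Bliss,
#' Loewe and HSA expectations at each dose combination, so the consensus
#' delta is the pointwise minimum (most conservative) of the three model
#' deltas. Because the HSA expectation never exceeds Bliss or Loewe for
#' responses in \[0, 100\], this amounts to a Bliss/Loewe consensus. ZIP is
#' excluded by design: it shares Bliss's multiplicative-survival principle
#' and would bias the consensus. Defined for any number of drugs.
#'
#' @inheritParams synergy_surface
#' @return a `synergy_surface` with `model = "consensus"`.
#' @export
consensus_surface <- function(block, curves = fit_block_curves(block)) {
  bliss <- synergy_surface(block, "bliss", curves)
  hsa <- synergy_surface(block, "hsa", curves)
  loewe <- tryCatch(synergy_surface(block, "loewe", curves),
                    synscreen_degenerate_curves_error = identity)
  observed <- bliss$observed
  if (inherits(loewe, "condition")) {
    # the consensus is undefined without Loewe; report missing rather than
    # silently falling back to a Bliss/HSA-only maximum
    warn_synscreen(paste0("consensus undefined: ", conditionMessage(loewe)),
                   "synscreen_consensus_undefined_warning")
    na <- array(NA_real_, dim = dim(observed))
    return(new_synergy_surface(block, "consensus", observed, na, na))
  }
  expected <- pmax(bliss$expected, loewe$expected, hsa$expected)
  new_synergy_surface(block, "consensus", observed, expected, observed - expected)
}

#' ZIP synergy surface (zero interaction potency)
#'
#' For each dose pair of a two-drug block, dose-response curves are refitted
#' conditionally along each row and column (the other drug's dose held
#' fixed) with the zero-dose anchor pinned to the partner drug's fitted
#' single-agent response. The ZIP expectation is the Bliss combination of
#' the two single-agent fitted values, and the ZIP delta is the mean of the
#' two directional differences between the conditional fitted response and
#' that expectation. On a surface that exactly obeys multiplicative
#' survival the delta is 0.
#'
#' @param block a two-drug `combination_block` with at least 3 doses per drug.
#' @param curves fitted single-agent curves.
#' @return a `synergy_surface` with `model = "zip"`.
#' @export
zip_surface <- function(block, curves = fit_block_curves(block)) {
  if (length(block$drugs) != 2) {
    stop_synscreen("ZIP scoring is defined for two-drug blocks only",
                   "synscreen_domain_error")
  }
  g1 <- block$dose_grid[[1]]; g2 <- block$dose_grid[[2]]
  if (length(g1) < 3 || length(g2) < 3) {
    stop_synscreen("ZIP needs at least 3 doses (including 0) per drug",
                   "synscreen_insufficient_data_error")
  }
  resp <- block$response
  p1 <- which(g1 > 0); p2 <- which(g2 > 0)
  y1_fit <- predict_response(curves[[1]], g1)
  y2_fit <- predict_response(curves[[2]], g2)

  # conditional fit along drug 1 for each fixed positive dose of drug 2
  fit_cond <- function(doses, ys, anchor) {
    ok <- is.finite(ys)
    if (sum(ok) < 3) {
      stop_synscreen("conditional ZIP fit needs at least 3 finite responses",
                     "synscreen_insufficient_data_error")
    }
    fit_hill(doses[ok], ys[ok], fix_l = anchor)
  }
  fit_row <- matrix(NA_real_, length(p1), length(p2))
  fit_col <- matrix(NA_real_, length(p1), length(p2))
  for (j in seq_along(p2)) {
    cv <- fit_cond(g1, resp[, p2[j]], y2_fit[p2[j]])
    fit_row[, j] <- predict_response(cv, g1[p1])
  }
  for (i in seq_along(p1)) {
    cv <- fit_cond(g2, resp[p1[i], ], y1_fit[p1[i]])
    fit_col[i, ] <- predict_response(cv, g2[p2])
  }
  expected <- outer(y1_fit[p1], y2_fit[p2], function(a, b)
    100 * (1 - (1 - clamp(a, 0, 100) / 100) * (1 - clamp(b, 0, 100) / 100)))
  delta <- (fit_row + fit_col) / 2 - expected
  observed <- positive_subtensor(block, resp)
  new_synergy_surface(block, "zip", observed, expected, delta)
}

#' Summarize a synergy surface
#'
#' `mean_delta` is the arithmetic mean of the synergy delta over all
#' all-positive-dose cells (zero-dose rows and columns are excluded: their
#' delta is 0 by construction and would dilute the score). `msa_delta` is
#' the most-synergistic-area score: the maximal mean over axis-aligned
#' windows of edge length `msa_window` per dimension (clipped to the grid).
#'
#' @param surface a `synergy_surface`.
#' @param msa_window window edge length per axis (default 3).
#' @return a one-row data frame: block_id, sample_id, model, mean_delta,
#'   msa_delta, weighted_mean_delta (NA unless [weighted_surface()] filled
#'   the weight tensor).
#' @export
summarize_surface <- function(surface, msa_window = 3) {
  delta <- surface$delta
  if (length(delta) == 0) {
    stop_synscreen("empty synergy surface", "synscreen_domain_error")
  }
  dims <- dim(delta)
  w <- pmin(msa_window, dims)
  if (any(w < msa_window)) {
    warn_synscreen(sprintf(
      "most-synergistic-area window %d clipped to grid (%s)",
      msa_window, paste(dims, collapse = " x ")), "synscreen_window_warning")
  }
  starts <- index_grid(dims - w + 1L)
  msa <- -Inf
  for (r in seq_len(nrow(starts))) {
    idx <- lapply(seq_along(dims), function(k) starts[r, k] + seq_len(w[k]) - 1L)
    m <- mean(do.call(`[`, c(list(delta), idx)))
    if (m > msa) msa <- m
  }
  wmd <- NA_real_
  if (!is.null(surface$weight)) {
    wmd <- mean(surface$weight * delta)
  }
  data.frame(block_id = surface$block_id, sample_id = surface$sample_id,
             model = surface$model,
             mean_delta = mean(delta), msa_delta = msa,
             weighted_mean_delta = wmd, stringsAsFactors = FALSE)
}

#' Export a synergy surface as a long-format table
#'
#' One row per all-positive dose combination with the doses, observed and
#' expected responses, synergy delta and (if filled) concentration weight.
#'
#' @param surface a `synergy_surface`.
#' @return data frame.
#' @export
surface_table <- function(surface) {
  dims <- dim(surface$delta)
  cells <- index_grid(dims)
  doses <- as.data.frame(lapply(seq_along(dims), function(k)
    surface$dose_grid_pos[[k]][cells[, k]]))
  names(doses) <- paste0("conc_", surface$drugs)
  out <- cbind(
    data.frame(block_id = surface$block_id, sample_id = surface$sample_id,
               model = surface$model, stringsAsFactors = FALSE),
    doses,
    data.frame(observed = as.vector(surface$observed[cells]),
               expected = as.vector(surface$expected[cells]),
               delta = as.vector(surface$delta[cells]),
               weight = if (is.null(surface$weight)) NA_real_
                        else as.vector(surface$weight[cells])))
  out
}
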