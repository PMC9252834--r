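#' Specification for a simulated combination block
#'
#' Bundles everything needed to generate a combination screen with known
#' ground truth: per-drug Hill parameters, dose grids, the no-interaction
#' null model used for combination cells, an injected synergy delta,
#' measurement noise, and optional injected outliers. The seed fully
#' determines the output.
#'
#' Defaults emulate a typical cell-viability checkerboard: two drugs with
#' complete (u near 100) and partial (u near 80) efficacy, five non-zero
#' doses per drug log-spaced around the EC50, Bliss-null combination cells,
#' and plate-reader noise of 3 percent inhibition (Gaussian on the
#' percent-inhibition scale).
#'
#' @param drugs named list of Hill parameter lists `(l, u, ec50, h)`.
#' @param dose_grid named list of dose vectors (each starting at 0);
#'   defaults to 0 plus 5 doses log-spaced over EC50/10 ... EC50*10.
#' @param null_model combination null: `"bliss"`, `"loewe"`, `"hsa"` or
#'   `"musyc"`.
#' @param injected_delta scalar (or array over the all-positive subgrid)
#'   added to every combination cell on top of the null.
#' @param musyc_params list `(alpha12, alpha21, beta)`; required when
#'   `null_model = "musyc"`.
#' @param noise_sd Gaussian noise standard deviation, percent inhibition.
#' @param outliers list of `list(cell = <positive-subgrid index vector or
#'   full-grid index>, shift = <percent inhibition>)` applied after noise.
#' @param block_id,sample_id identifiers for the generated block.
#' @param seed integer seed.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(
    drugs = list(DrugA = list(l = 0, u = 95, ec50 = 1, h = 1.2),
                 DrugB = list(l = 0, u = 80, ec50 = 5, h = 1.5)),
    dose_grid = NULL,
    null_model = c("bliss", "loewe", "hsa", "musyc"),
    injected_delta = 0,
    musyc_params = NULL,
    noise_sd = 3,
    outliers = list(),
    block_id = "sim_block", sample_id = NA_character_,
    seed = 1L) {
  null_model <- match.arg(null_model)
  if (null_model == "musyc" && is.null(musyc_params)) {
    stop_synscreen("musyc null model requires musyc_params (alpha12, alpha21, beta)",
                   "synscreen_spec_error")
  }
  if (noise_sd < 0) stop_synscreen("noise_sd must be >= 0", "synscreen_spec_error")
  if (is.null(dose_grid)) {
    dose_grid <- lapply(drugs, function(p)
      c(0, p$ec50 * 10^seq(-1, 1, length.out = 5)))
  }
  structure(list(drugs = drugs, dose_grid = dose_grid, null_model = null_model,
                 injected_delta = injected_delta, musyc_params = musyc_params,
                 noise_sd = noise_sd, outliers = outliers,
                 block_id = block_id, sample_id = sample_id,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

true_curve <- function(name, p) {
  structure(list(drug = name, l = p$l, u = p$u, ec50 = p$ec50, h = p$h,
                 rss = 0, n = NA_integer_, poor_fit = FALSE),
            class = "dose_response_curve")
}

#' Simulate one combination block with known ground truth
#'
#' Single-agent axis cells are the drugs' Hill-curve responses; combination
#' cells are the chosen null model applied to the noiseless single-agent
#' values (Loewe and MuSyC use the true curves), plus `injected_delta`,
#' plus Gaussian noise, plus any injected outlier shifts. The returned
#' ground truth retains every noiseless intermediate, so recovery can be
#' checked exactly.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `block` (a `combination_block`) and `truth`
#'   (true curves, noiseless tensor, null expectations, injected delta and
#'   outlier cells).
#' @export
simulate_block <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, simulate_block_impl(spec))
}

simulate_block_impl <- function(spec) {
  drugs <- names(spec$drugs)
  grid <- spec$dose_grid
  dims <- lengths(grid)
  nd <- length(dims)
  curves <- lapply(drugs, function(d) true_curve(d, spec$drugs[[d]]))
  singles <- lapply(seq_len(nd), function(k)
    hill_eval(grid[[k]], curves[[k]]$l, curves[[k]]$u,
              curves[[k]]$ec50, curves[[k]]$h))

  clean <- array(NA_real_, dim = dims)
  cells <- index_grid(dims)
  for (r in seq_len(nrow(cells))) {
    ii <- cells[r, ]
    npos <- sum(ii > 1L)
    y <- vapply(seq_len(nd), function(k) singles[[k]][ii[k]], 0)
    val <- if (npos == 0) {
      0
    } else if (npos == 1) {
      y[which(ii > 1L)]
    } else {
      dd <- vapply(seq_len(nd), function(k) grid[[k]][ii[k]], 0)
      switch(spec$null_model,
        bliss = expected_bliss(y[ii > 1L]),
        hsa = expected_hsa(y[ii > 1L]),
        loewe = expected_loewe(curves[ii > 1L], dd[ii > 1L]),
        musyc = musyc_null_value(spec, curves, dd))
    }
    clean[matrix(ii, nrow = 1)] <- val
  }

  # injected synergy on the all-positive subgrid
  interior <- rowSums(cells > 1L) == nd
  inj <- array(0, dim = dims)
  delta <- spec$injected_delta
  if (length(delta) == 1) {
    inj[cells[interior, , drop = FALSE]] <- delta
  } else {
    pdims <- dims - 1L
    stopifnot(all(dim(delta) == pdims))
    inj[cells[interior, , drop = FALSE]] <-
      delta[cells[interior, , drop = FALSE] - 1L]
  }

  noise <- array(stats::rnorm(prod(dims), 0, spec$noise_sd), dim = dims)
  resp <- clean + inj + noise
  out_cells <- list()
  for (o in spec$outliers) {
    cell <- as.integer(o$cell)
    resp[matrix(cell, nrow = 1)] <- resp[matrix(cell, nrow = 1)] + o$shift
    out_cells[[length(out_cells) + 1]] <- cell
  }
  ctrl <- matrix(1L, 1, nd)
  resp[ctrl] <- 0

  block <- combination_block(drugs, grid, resp,
                             block_id = spec$block_id,
                             sample_id = spec$sample_id)
  list(block = block,
       truth = list(curves = curves, singles = singles, clean = clean,
                    injected = inj, noise_sd = spec$noise_sd,
                    outlier_cells = out_cells, null_model = spec$null_model))
}

# MuSyC surface value on the %inh scale for the simulator; E3 is derived
# from beta (gain over the stronger single agent on the 0-1 scale).
musyc_null_value <- function(spec, curves, dd) {
  p1 <- spec$drugs[[1]]; p2 <- spec$drugs[[2]]
  if (length(dd) != 2) {
    stop_synscreen("musyc null model supports two-drug blocks only",
                   "synscreen_spec_error")
  }
  E1 <- (p1$u - p1$l) / 100; E2 <- (p2$u - p2$l) / 100
  par <- list(E1 = E1, E2 = E2,
              E3 = max(E1, E2) + spec$musyc_params$beta,
              C1 = p1$ec50, C2 = p2$ec50, h1 = p1$h, h2 = p2$h,
              alpha12 = spec$musyc_params$alpha12,
              alpha21 = spec$musyc_params$alpha21)
  100 * musyc_effect(dd[1], dd[2], par)
}

#' Simulate a multi-sample screen
#'
#' Generates `n_samples` blocks from one base spec, perturbing each
#' sample's Hill parameters to emulate between-sample biological
#' heterogeneity: EC50 and slope are jittered log-normally with standard
#' deviation `jitter` (log scale), and the upper asymptote by a Gaussian
#' with standard deviation `20 * jitter` percent inhibition. Per-sample
#' seeds are derived deterministically from the master seed; `jitter = 0`
#' reproduces identical samples (up to their independent noise draws being
#' re-seeded identically).
#'
#' @param spec base [simulation_spec()].
#' @param n_samples number of samples.
#' @param jitter non-negative jitter magnitude.
#' @param sample_ids optional character vector of sample names.
#' @return list of `simulate_block()` results, one per sample.
#' @export
simulate_multisample <- function(spec, n_samples, jitter = 0.1,
                                 sample_ids = sprintf("S%02d", seq_len(n_samples))) {
  stopifnot(inherits(spec, "simulation_spec"), n_samples >= 1, jitter >= 0)
  lapply(seq_len(n_samples), function(i) {
    sspec <- spec
    sspec$seed <- spec$seed + 7919L * i
    sspec$sample_id <- sample_ids[i]
    sspec$block_id <- spec$block_id
    sspec$drugs <- withr::with_seed(spec$seed + 104729L * i, {
      lapply(spec$drugs, function(p) {
        list(l = p$l,
             u = clamp(p$u + stats::rnorm(1, 0, 20 * jitter), 10, 150),
             ec50 = p$ec50 * exp(stats::rnorm(1, 0, jitter)),
             h = clamp(p$h * exp(stats::rnorm(1, 0, jitter / 2)), 0.1, 10))
      })
    })
    # dose grids follow the base spec (fixed plate layout across samples)
    if (is.null(spec$dose_grid)) {
      sspec$dose_grid <- lapply(spec$drugs, function(p)
        c(0, p$ec50 * 10^seq(-1, 1, length.out = 5)))
    }
    simulate_block(sspec)
  })
}

#' Write a simulated block as a long-format input file
#'
#' Serializes a block in the `pairwise` (two drugs) or `multi` input
#' dialect so end-to-end tests can exercise the file reader and the
#' command-line interface on realistic inputs.
#'
#' @param block a `combination_block`.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_block_table <- function(block, path, sep = ",") {
  dims <- dim(block$response)
  cells <- index_grid(dims)
  nd <- length(dims)
  doses <- vapply(seq_len(nd), function(k)
    block$dose_grid[[k]][cells[, k]], numeric(nrow(cells)))
  resp <- block$response[cells]
  keep <- is.finite(resp)
  if (nd == 2) {
    df <- data.frame(block_id = block$block_id,
                     drug_row = block$drugs[1], drug_col = block$drugs[2],
                     conc_r = doses[, 1], conc_c = doses[, 2],
                     response = resp,
                     conc_r_unit = block$dose_units[1],
                     conc_c_unit = block$dose_units[2],
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(block_id = rep(block$block_id, nrow(cells)),
                     stringsAsFactors = FALSE)
    for (k in seq_len(nd)) df[[paste0("drug", k)]] <- block$drugs[k]
    for (k in seq_len(nd)) df[[paste0("conc", k)]] <- doses[, k]
    df$response <- resp
  }
  if (!is.na(block$sample_id)) df$sample <- block$sample_id
  utils::write.table(df[keep, , drop = FALSE], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
}
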