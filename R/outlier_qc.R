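#' Model-based reconstruction of a combination response matrix
#'
#' Predicts every cell of a two-drug response matrix from the rest of the
#' matrix via leave-one-out low-rank reconstruction: the response matrix is
#' shifted to be non-negative (subtracting its minimum), and each cell's
#' prediction is obtained from a rank-2 non-negative matrix factorization
#' fitted with that cell masked, averaged over 5 masked refits from fixed
#' random initializations. Predictions are shifted back to the response
#' scale. Dose-response surfaces are approximately low-rank, so a clean
#' cell is predicted well from its row/column structure while an isolated
#' outlier is not reproduced — the deviation observed - predicted is the
#' outlier statistic.
#'
#' The reconstruction is shift-equivariant: adding a constant to every
#' response adds the same constant to every prediction, so the flag set is
#' unchanged.
#'
#' For blocks with more than 2 drugs, reconstruction operates on each
#' two-drug slice (all other doses fixed); a cell's prediction is averaged
#' over the slices containing it.
#'
#' @param block a `combination_block` with at least 3 doses per drug
#'   (including 0).
#' @return numeric array of predicted responses, same dim as
#'   `block$response`.
#' @export
reconstruct_block <- function(block) {
  dims <- dim(block$response)
  if (any(dims < 3)) {
    stop_synscreen("reconstruction needs at least a 3 x 3 grid including the zero doses",
                   "synscreen_insufficient_data_error")
  }
  nd <- length(dims)
  if (nd == 2) {
    return(reconstruct_matrix(block$response))
  }
  # n-drug: average predictions over every 2-drug slice through each cell
  pred_sum <- array(0, dim = dims)
  pred_n <- array(0, dim = dims)
  pairs <- utils::combn(nd, 2)
  for (p in seq_len(ncol(pairs))) {
    k1 <- pairs[1, p]; k2 <- pairs[2, p]
    others <- setdiff(seq_len(nd), c(k1, k2))
    fixed <- index_grid(dims[others])
    for (r in seq_len(nrow(fixed))) {
      idx <- vector("list", nd)
      idx[[k1]] <- seq_len(dims[k1]); idx[[k2]] <- seq_len(dims[k2])
      for (j in seq_along(others)) idx[[others[j]]] <- fixed[r, j]
      slice <- do.call(`[`, c(list(block$response), idx))
      pm <- reconstruct_matrix(matrix(slice, dims[k1], dims[k2]))
      sub <- do.call(`[`, c(list(pred_sum), idx))
      pred_sum <- do.call(`[<-`, c(list(pred_sum), idx, list(sub + pm)))
      subn <- do.call(`[`, c(list(pred_n), idx))
      pred_n <- do.call(`[<-`, c(list(pred_n), idx, list(subn + 1)))
    }
  }
  pred_sum / pred_n
}

# Leave-one-out predictions for `cells` (matrix of row/col indices) of M,
# optionally masking `extra` cells (k x 2 matrix) as well — used by the
# iterative flagging to keep suspected outliers out of each other's
# reconstructions.
loo_predict_cells <- function(M, cells, extra = NULL,
                              n_refits = 5, rank = 2) {
  shift <- min(M, na.rm = TRUE)
  X <- M - shift
  X[!is.finite(X)] <- 0          # missing axis cells carry no information
  Wbase <- matrix(1, nrow(M), ncol(M))
  Wbase[!is.finite(M)] <- 0
  if (!is.null(extra) && nrow(extra) > 0) Wbase[extra] <- 0
  xmax <- max(X)
  pred <- numeric(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    W <- Wbase
    W[i, j] <- 0
    vals <- vapply(seq_len(n_refits), function(s) {
      fit <- withr::with_seed(1000L + s, nmf_masked(X, W, rank))
      # the masked entry is unconstrained by the objective and can drift
      # in degenerate factorizations; predictions outside the observed
      # data range are meaningless, so clamp before averaging
      clamp(fit[i, j], 0, xmax)
    }, 0)
    pred[r] <- mean(vals) + shift
  }
  pred
}

reconstruct_matrix <- function(M, n_refits = 5, rank = 2) {
  cells <- as.matrix(expand.grid(seq_len(nrow(M)), seq_len(ncol(M))))
  pred <- matrix(NA_real_, nrow(M), ncol(M))
  pred[cells] <- loo_predict_cells(M, cells, n_refits = n_refits, rank = rank)
  pred
}

# Weighted (masked) NMF by multiplicative updates; W is a 0/1 mask.
# A small ridge penalty on both factors removes the masked-entry
# degeneracy: without it a factor component can grow in a direction that
# only changes masked cells, letting their reconstruction drift
# unboundedly while the visible-cell objective is flat. Convergence is
# judged on the reconstruction itself (not the visible-cell objective),
# since the masked cells keep moving after the objective plateaus.
nmf_masked <- function(X, W, rank = 2, maxit = 400, tol = 1e-5) {
  eps <- 1e-12
  n <- nrow(X); m <- ncol(X)
  sc <- sqrt(max(mean(X[W > 0]), eps) / rank)
  A <- matrix(stats::runif(n * rank, 0.5, 1.5) * sc, n, rank)
  H <- matrix(stats::runif(rank * m, 0.5, 1.5) * sc, rank, m)
  WX <- W * X
  scale_ref <- max(X) + eps
  lambda <- 1e-2 * scale_ref
  prev <- NULL
  for (it in seq_len(maxit)) {
    AH <- A %*% H
    A <- A * (WX %*% t(H)) / ((W * AH) %*% t(H) + lambda * A + eps)
    AH <- A %*% H
    H <- H * (t(A) %*% WX) / (t(A) %*% (W * AH) + lambda * H + eps)
    if (it %% 10 == 0) {
      AH <- A %*% H
      if (!is.null(prev) && max(abs(AH - prev)) < tol * scale_ref) break
      prev <- AH
    }
  }
  A %*% H
}

new_outlier_report <- function(block, flags, threshold) {
  structure(list(block_id = block$block_id, sample_id = block$sample_id,
                 drugs = block$drugs, flags = flags, threshold = threshold),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %s: %d flagged cell(s), |deviation| > %g %%inh\n",
              x$block_id, nrow(x$flags), x$threshold))
  invisible(x)
}

empty_flags <- function(nd) {
  data.frame(cell = I(vector("list", 0)),
             observed = numeric(0), predicted = numeric(0),
             deviation = numeric(0), kind = character(0),
             stringsAsFactors = FALSE)[0, ]
}

#' Flag outlier combination measurements
#'
#' Flags all-positive-dose cells whose measured response deviates from the
#' model-based reconstruction by strictly more than `threshold` percent
#' inhibition (default 20, both directions). A deviation of exactly the
#' threshold is not flagged.
#'
#' For two-drug blocks the flag set is refined iteratively: starting from
#' the plain leave-one-out deviations, every candidate cell is re-predicted
#' with all other candidates masked out of the factorization, and the
#' candidate set is updated until it is stable. A genuine outlier left in
#' the matrix contaminates the low-rank reconstruction of its own row and
#' column, which would otherwise produce spurious flags on clean
#' neighbours (and could shield the outlier itself); because that
#' contamination is row/column-local, only cells sharing a row or column
#' with the candidate set are re-predicted between rounds. Blocks with more
#' than two drugs use the single-pass slice-wise reconstruction.
#'
#' @param block a `combination_block`.
#' @param threshold deviation cutoff in percent inhibition (strict `>`).
#' @param predicted optional precomputed [reconstruct_block()] tensor used
#'   for the first pass.
#' @param max_rounds safety cap on refinement rounds.
#' @return an `outlier_report`; `$flags` has one row per flagged cell with
#'   its dose-position index, observed and predicted responses and the
#'   deviation observed - predicted.
#' @export
flag_combination_outliers <- function(block, threshold = 20,
                                      predicted = NULL, max_rounds = 6L) {
  dims <- dim(block$response)
  cells <- index_grid(dims)
  interior <- cells[rowSums(cells > 1L) == length(dims), , drop = FALSE]
  obs <- block$response[interior]

  if (length(dims) != 2) {
    pred_arr <- if (is.null(predicted)) reconstruct_block(block) else predicted
    pred <- pred_arr[interior]
    keep <- is.finite(obs) & abs(obs - pred) > threshold
    return(new_outlier_report(block, interior_flags(interior, obs, pred, keep),
                              threshold))
  }

  work <- block$response
  pred <- if (is.null(predicted)) loo_predict_cells(work, interior)
          else predicted[interior]
  flagged <- logical(nrow(interior))
  for (round in seq_len(max_rounds)) {
    cand <- which(!flagged & is.finite(obs) & abs(obs - pred) > threshold)
    if (length(cand) == 0) break
    if (length(cand) == 1) {
      anchor <- cand
    } else {
      # re-predict every candidate with the other candidates masked: a
      # contamination victim's deviation dissolves, the true outlier's
      # survives (possibly attenuated by the loss of its masked neighbours)
      pred2 <- vapply(cand, function(r) {
        extra <- interior[setdiff(cand, r), , drop = FALSE]
        loo_predict_cells(work, interior[r, , drop = FALSE], extra)
      }, 0)
      dev2 <- abs(obs[cand] - pred2)
      anchor <- cand[which.max(dev2)]
      if (max(dev2) <= threshold / 2) break  # all candidates dissolve
      pred[cand] <- pred2
    }
    flagged[anchor] <- TRUE
    # replace (not mask) the anchor so its row/column keep their signal,
    # then refresh the cells its contamination could have touched
    work[matrix(interior[anchor, ], nrow = 1)] <- pred[anchor]
    touched <- which(!flagged &
                       (interior[, 1] == interior[anchor, 1] |
                        interior[, 2] == interior[anchor, 2]))
    for (r in union(touched, setdiff(cand, anchor))) {
      pred[r] <- loo_predict_cells(work, interior[r, , drop = FALSE])
    }
  }
  new_outlier_report(block, interior_flags(interior, obs, pred, flagged),
                     threshold)
}

interior_flags <- function(interior, obs, pred, keep) {
  nd <- ncol(interior)
  if (!any(keep)) return(empty_flags(nd))
  rows <- lapply(which(keep), function(r) data.frame(
    cell = I(list(interior[r, ])), observed = obs[r], predicted = pred[r],
    deviation = obs[r] - pred[r], kind = "combination",
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Flag outlier single-agent measurements
#'
#' For each drug's single-agent axis, each non-zero-dose point is compared
#' with the prediction of a dose-response curve refitted with that point
#' left out; points deviating by strictly more than `threshold` percent
#' inhibition are flagged. Axes with fewer than 4 dose points (including
#' zero) are skipped with a warning — leave-one-out refitting is not
#' meaningful there.
#'
#' Like the combination scan, the axis scan refines its candidate set: an
#' outlier left in the axis drags the leave-one-out fits of its neighbours
#' and would flag clean points (or shield itself), so candidates are
#' re-predicted with the other candidates excluded, the strongest one is
#' flagged and provisionally replaced, and the remaining points are
#' re-evaluated against the corrected axis.
#'
#' @inheritParams flag_combination_outliers
#' @param curves fitted single-agent curves (used only for bookkeeping of
#'   drug names; the leave-one-out refits are done internally).
#' @param max_rounds safety cap on refinement rounds per axis.
#' @return an `outlier_report` with `kind = "single_agent"` flags; each
#'   flagged cell index is the tensor index of the axis cell.
#' @export
flag_single_agent_outliers <- function(block, curves = NULL, threshold = 20,
                                       max_rounds = 6L) {
  dims <- dim(block$response)
  nd <- length(dims)
  flags <- list()
  quiet_fit <- function(...) withCallingHandlers(
    fit_hill(...),
    synscreen_poor_fit_warning = function(w) invokeRestart("muffleWarning"))
  for (k in seq_len(nd)) {
    g <- block$dose_grid[[k]]
    ax <- axis_responses(block, k)
    usable <- which(is.finite(ax))
    if (length(usable) < 4) {
      warn_synscreen(sprintf(
        "drug '%s': fewer than 4 usable axis points, skipping single-agent outlier scan",
        block$drugs[k]), "synscreen_qc_skip_warning")
      next
    }
    pts <- setdiff(usable, 1L)          # never flag the zero-dose control
    work <- ax
    loo_pred <- function(i, excl = integer(0)) {
      keep <- setdiff(usable, c(i, excl))
      if (length(unique(g[keep])) < 3) return(NA_real_)
      predict_response(quiet_fit(g[keep], work[keep], drug = block$drugs[k]),
                       g[i])
    }
    pred <- setNames(vapply(pts, loo_pred, 0), pts)
    flagged <- integer(0)
    for (round in seq_len(max_rounds)) {
      dev <- ax[pts] - pred
      cand <- pts[!pts %in% flagged & is.finite(dev) & abs(dev) > threshold]
      if (length(cand) == 0) break
      if (length(cand) == 1) {
        anchor <- cand
      } else {
        pred2 <- vapply(cand, function(i) loo_pred(i, setdiff(cand, i)), 0)
        dev2 <- abs(ax[cand] - pred2)
        if (all(!is.finite(dev2)) || max(dev2, na.rm = TRUE) <= threshold / 2) break
        anchor <- cand[which.max(dev2)]
        pred[as.character(cand)] <- pred2
      }
      flagged <- c(flagged, anchor)
      work[anchor] <- pred[as.character(anchor)]
      redo <- setdiff(pts, flagged)
      pred[as.character(redo)] <- vapply(redo, loo_pred, 0)
    }
    for (i in flagged) {
      cell <- rep(1L, nd); cell[k] <- i
      flags[[length(flags) + 1]] <- data.frame(
        cell = I(list(cell)), observed = ax[i],
        predicted = unname(pred[as.character(i)]),
        deviation = ax[i] - unname(pred[as.character(i)]),
        kind = "single_agent", stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else empty_flags(nd)
  new_outlier_report(block, flags, threshold)
}

#' Replace flagged outliers with their model predictions
#'
#' Returns a new block in which every flagged cell is set to its predicted
#' value; the input block is not modified and the provenance of replaced
#' cells is recorded in the result's `$replaced` table. Replacement is
#' opt-in throughout the pipeline.
#'
#' @param block the `combination_block` the report was generated from.
#' @param report an `outlier_report` (possibly rbind of combination and
#'   single-agent reports via [merge_reports()]).
#' @return corrected `combination_block`.
#' @export
replace_outliers <- function(block, report) {
  dims <- dim(block$response)
  out <- block
  if (nrow(report$flags) == 0) return(out)
  for (r in seq_len(nrow(report$flags))) {
    cell <- report$flags$cell[[r]]
    if (length(cell) != length(dims) || any(cell < 1) || any(cell > dims)) {
      stop_synscreen("outlier report does not match this block (stale cell index)",
                     "synscreen_consistency_error")
    }
    out$response[matrix(cell, nrow = 1)] <- report$flags$predicted[r]
  }
  prov <- report$flags
  prov$replaced <- TRUE
  out$replaced <- rbind(out$replaced, prov)
  out
}

#' Combine combination and single-agent outlier reports
#' @param ... `outlier_report` objects for the same block.
#' @return a single `outlier_report`.
#' @export
merge_reports <- function(...) {
  reps <- list(...)
  out <- reps[[1]]
  out$flags <- do.call(rbind, lapply(reps, `[[`, "flags"))
  out
}

#' Export an outlier report as a flat table
#' @param report an `outlier_report`.
#' @param block the block it refers to (for dose lookup).
#' @return data frame with doses, observed, predicted, deviation, kind.
#' @export
outlier_table <- function(report, block) {
  n <- nrow(report$flags)
  doses <- matrix(NA_real_, n, length(block$drugs))
  for (r in seq_len(n)) {
    cell <- report$flags$cell[[r]]
    doses[r, ] <- vapply(seq_along(cell), function(k)
      block$dose_grid[[k]][cell[k]], 0)
  }
  doses <- as.data.frame(doses)
  names(doses) <- paste0("conc_", block$drugs)
  base <- data.frame(block_id = rep(report$block_id, n),
                     sample_id = rep(report$sample_id, n),
                     stringsAsFactors = FALSE)
  cbind(base, doses,
        report$flags[, c("observed", "predicted", "deviation", "kind"),
                     drop = FALSE],
        data.frame(replaced = rep(FALSE, n)))
}
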