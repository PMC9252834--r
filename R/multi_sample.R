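combo_name <- function(drugs) paste(sort(drugs), collapse = " + ")

# Full single-block pipeline: curve fits -> optional outlier QC ->
# surface(s) for one model -> summary row. Returns the summary row plus the
# surface and intermediate objects.
score_block <- function(block, model = "consensus",
                        qc = list(correct = FALSE, threshold = 20),
                        weighted = FALSE, msa_window = 3) {
  curves <- fit_block_curves(block)
  report <- NULL
  if (isTRUE(qc$correct)) {
    thr <- qc$threshold %||% 20
    rep_sa <- flag_single_agent_outliers(block, curves, threshold = thr)
    block <- replace_outliers(block, rep_sa)
    rep_cb <- flag_combination_outliers(block, threshold = thr)
    block <- replace_outliers(block, rep_cb)
    report <- merge_reports(rep_cb, rep_sa)
    curves <- fit_block_curves(block)   # refit on corrected axes
  }
  surface <- switch(model,
    consensus = consensus_surface(block, curves),
    zip = zip_surface(block, curves),
    synergy_surface(block, model, curves))
  if (weighted) surface <- weighted_surface(surface, block, curves)
  summary <- summarize_surface(surface, msa_window = msa_window)
  list(summary = summary, surface = surface, curves = curves,
       report = report, block = block)
}

#' Score a batch of combination blocks across samples
#'
#' Runs the full per-block pipeline (single-agent curve fitting, optional
#' outlier correction, synergy surface, summary score) for every block and
#' assembles a combination x sample score table. Combination identity is
#' the sorted drug-name set, so blocks testing (A, B) and (B, A) in the
#' same sample are recognized as the same combination and averaged with a
#' warning. Failures on individual blocks are recorded as missing cells
#' with a diagnostic message and never abort the batch.
#'
#' @param blocks list of `combination_block` objects.
#' @param model `"bliss"`, `"loewe"`, `"hsa"`, `"zip"` or `"consensus"`.
#' @param score_type `"mean"`, `"msa"` or `"weighted"` summary score.
#' @param qc list: `correct` (logical, apply outlier replacement) and
#'   `threshold` (percent inhibition, default 20).
#' @param msa_window most-synergistic-area window edge length.
#' @return object of class `multi_sample_result`: `$scores` (long table),
#'   `$failures` (diagnostics), plus the chosen model/score type.
#' @export
score_samples <- function(blocks, model = "consensus",
                          score_type = c("mean", "msa", "weighted"),
                          qc = list(correct = FALSE, threshold = 20),
                          msa_window = 3) {
  score_type <- match.arg(score_type)
  stopifnot(length(blocks) >= 1)
  rows <- list(); fails <- list()
  for (b in blocks) {
    res <- tryCatch(
      score_block(b, model = model, qc = qc,
                  weighted = score_type == "weighted",
                  msa_window = msa_window),
      synscreen_error = function(e) e)
    if (inherits(res, "condition")) {
      fails[[length(fails) + 1]] <- data.frame(
        block_id = b$block_id, sample_id = b$sample_id,
        combination = combo_name(b$drugs),
        diagnostic = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    s <- res$summary
    score <- switch(score_type, mean = s$mean_delta, msa = s$msa_delta,
                    weighted = s$weighted_mean_delta)
    if (!is.finite(score)) {
      fails[[length(fails) + 1]] <- data.frame(
        block_id = b$block_id, sample_id = b$sample_id,
        combination = combo_name(b$drugs),
        diagnostic = sprintf("%s %s score is missing for this block",
                             model, score_type), stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      combination = combo_name(b$drugs), sample_id = b$sample_id,
      block_id = b$block_id, model = model, score_type = score_type,
      score = score, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    stop_synscreen(paste0(
      "no block could be scored; diagnostics: ",
      paste(vapply(fails, function(f) f$diagnostic, ""), collapse = " | ")),
      "synscreen_batch_error")
  }
  scores <- do.call(rbind, rows)
  dupkey <- paste(scores$combination, scores$sample_id)
  if (anyDuplicated(dupkey)) {
    warn_synscreen("duplicate (combination, sample) blocks averaged",
                   "synscreen_duplicate_warning")
    scores <- do.call(rbind, lapply(split(scores, dupkey), function(g) {
      g$score[1] <- mean(g$score); g[1, , drop = FALSE]
    }))
  }
  scores <- scores[order(scores$combination, scores$sample_id), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores,
                 failures = if (length(fails)) do.call(rbind, fails) else NULL,
                 model = model, score_type = score_type),
            class = "multi_sample_result")
}

#' @export
print.multi_sample_result <- function(x, ...) {
  cat(sprintf("<multi_sample_result> %d combination(s) x %d sample(s), model %s (%s score)\n",
              length(unique(x$scores$combination)),
              length(unique(x$scores$sample_id)), x$model, x$score_type))
  if (!is.null(x$failures)) cat(sprintf("  %d failed block(s)\n", nrow(x$failures)))
  invisible(x)
}

#' Export combination x sample score matrices (heatmap tables)
#'
#' Produces plot-ready data for a multi-sample synergy heatmap: a wide
#' matrix (rows = combinations sorted by cross-sample mean score,
#' descending, ties by name; columns = samples sorted by name) and the
#' corresponding long table. A combination not tested in a sample is an
#' explicit missing cell, never 0.
#'
#' @param result a `multi_sample_result`.
#' @return list with data frames `wide` and `long`.
#' @export
export_heatmap <- function(result) {
  sc <- result$scores
  if (nrow(sc) == 0) stop_synscreen("empty result", "synscreen_domain_error")
  samples <- sort(unique(sc$sample_id))
  means <- tapply(sc$score, sc$combination, mean, na.rm = TRUE)
  combos <- names(means)[order(-means, names(means))]
  wide <- data.frame(combination = combos, stringsAsFactors = FALSE)
  wide$mean_score <- as.numeric(means[combos])
  for (s in samples) {
    col <- rep(NA_real_, length(combos))
    sub <- sc[sc$sample_id == s, , drop = FALSE]
    col[match(sub$combination, combos)] <- sub$score
    wide[[s]] <- col
  }
  long <- sc[, c("combination", "sample_id", "block_id", "model",
                 "score_type", "score")]
  list(wide = wide, long = long)
}

#' Export a per-sample synergy ranking (waterfall table)
#'
#' Combinations of one sample ranked by score, descending; ties are broken
#' by combination name.
#'
#' @param result a `multi_sample_result`.
#' @param sample_id sample to rank.
#' @return data frame with rank, combination, score.
#' @export
export_waterfall <- function(result, sample_id) {
  sub <- result$scores[result$scores$sample_id %in% sample_id, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop_synscreen(sprintf("unknown sample '%s'", sample_id),
                   "synscreen_lookup_error")
  }
  sub <- sub[order(-sub$score, sub$combination), , drop = FALSE]
  data.frame(rank = seq_len(nrow(sub)), combination = sub$combination,
             sample_id = sub$sample_id, score = sub$score,
             stringsAsFactors = FALSE)
}

#' Cross-sample consistency of combination synergy
#'
#' Per combination: number of samples scored, mean, standard deviation
#' (missing when only one sample), min, max, and the fraction of samples
#' with a positive synergy score — a simple screen for synergies that are
#' consistent versus context-specific across samples.
#'
#' @param result a `multi_sample_result`.
#' @return data frame, one row per combination, sorted by mean descending.
#' @export
consistency_summary <- function(result) {
  sc <- result$scores
  if (nrow(sc) == 0) stop_synscreen("empty result", "synscreen_domain_error")
  out <- do.call(rbind, lapply(split(sc, sc$combination), function(g) {
    data.frame(combination = g$combination[1], n_samples = nrow(g),
               mean = mean(g$score),
               sd = if (nrow(g) >= 2) stats::sd(g$score) else NA_real_,
               min = min(g$score), max = max(g$score),
               fraction_positive = mean(g$score > 0),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$mean, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}
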