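#' Construct a combination block
#'
#' A `combination_block` holds one drug-combination experiment: `n >= 2`
#' drugs, their dose grids (each starting at dose 0), and an n-dimensional
#' response tensor of percent inhibition indexed by dose position. Single
#' agent responses live on the tensor axes (all other doses 0) and the
#' all-zero-dose cell is the untreated control, defined as 0. Responses
#' outside \[0, 100\] are preserved: stimulation (< 0) and super-inhibition
#' (> 100) are real signals that downstream models must see.
#'
#' @param drugs character vector of drug names (length >= 2).
#' @param dose_grid named list, one strictly increasing numeric vector per
#'   drug, each starting at 0.
#' @param response numeric array, `dim == lengths(dose_grid)`, percent
#'   inhibition. `NA` is allowed only on single-agent axis cells, and only if
#'   at least 2 finite non-zero-dose responses remain per drug.
#' @param block_id,sample_id identifiers (sample may be `NA`).
#' @param dose_units optional character vector of unit labels per drug
#'   (labels only; no unit conversion is ever performed).
#' @param replicates optional list of replicate response arrays with the same
#'   dimensions; `response` is then typically their cellwise mean.
#' @return object of class `combination_block`.
#' @export
combination_block <- function(drugs, dose_grid, response,
                              block_id = "block1", sample_id = NA_character_,
                              dose_units = NULL, replicates = NULL) {
  drugs <- as.character(drugs)
  if (length(drugs) < 2) {
    stop_synscreen("a combination block needs at least 2 drugs",
                   "synscreen_format_error")
  }
  if (!is.list(dose_grid) || length(dose_grid) != length(drugs)) {
    stop_synscreen("dose_grid must be a list with one dose vector per drug",
                   "synscreen_format_error")
  }
  names(dose_grid) <- drugs
  for (d in drugs) {
    dg <- dose_grid[[d]]
    if (dg[1] != 0 || any(diff(dg) <= 0)) {
      stop_synscreen(
        sprintf("dose grid for '%s' must start at 0 and be strictly increasing", d),
        "synscreen_format_error")
    }
  }
  dims <- unname(lengths(dose_grid))
  response <- array(as.numeric(response), dim = dims)
  if (any(is.infinite(response))) {
    stop_synscreen("responses must be finite", "synscreen_data_error")
  }
  # control cell is defined 0
  ctrl <- matrix(1L, nrow = 1, ncol = length(dims))
  response[ctrl] <- 0
  na_idx <- which(is.na(response), arr.ind = TRUE)
  if (nrow(na_idx) > 0) {
    on_axis <- rowSums(na_idx > 1L) <= 1L
    if (any(!on_axis)) {
      bad <- na_idx[!on_axis, , drop = FALSE][1, ]
      stop_synscreen(
        sprintf("missing combination response at dose indices (%s)",
                paste(bad, collapse = ", ")),
        "synscreen_missing_data_error")
    }
  }
  for (k in seq_along(drugs)) {
    ax <- axis_responses(list(response = response, dims = dims), k)
    if (sum(is.finite(ax[-1])) < 2) {
      stop_synscreen(
        sprintf("drug '%s' needs at least 2 finite non-zero-dose single-agent responses",
                drugs[k]),
        "synscreen_missing_data_error")
    }
  }
  structure(list(
    block_id = as.character(block_id),
    sample_id = as.character(sample_id),
    drugs = drugs,
    dose_grid = dose_grid,
    dose_units = dose_units %||% rep("", length(drugs)),
    response = response,
    replicates = replicates,
    replaced = NULL
  ), class = "combination_block")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-agent responses of drug k: the tensor axis where all other doses
# are 0. Works for an incomplete "block" list as long as response/dims exist.
axis_responses <- function(block, k) {
  dims <- if (!is.null(block$dims)) block$dims else dim(block$response)
  idx <- matrix(1L, nrow = dims[k], ncol = length(dims))
  idx[, k] <- seq_len(dims[k])
  block$response[idx]
}

# Measured single-agent response of drug k at dose position i (1 = zero dose).
axis_response_at <- function(block, k, i) {
  axis_responses(block, k)[i]
}

#' @export
print.combination_block <- function(x, ...) {
  cat(sprintf("<combination_block> %s%s\n", x$block_id,
              if (!is.na(x$sample_id)) paste0(" [sample ", x$sample_id, "]") else ""))
  cat("  drugs:", paste(x$drugs, collapse = " + "), "\n")
  cat("  grid :", paste(dim(x$response), collapse = " x "),
      sprintf("(%d replicates)\n", length(x$replicates %||% list())))
  invisible(x)
}

#' @export
dim.combination_block <- function(x) dim(x$response)
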