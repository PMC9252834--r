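detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", "\t", ";"), function(s)
    lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))), 0L)
  names(counts)[which.max(counts)]
}

#' Read a long-format combination-screen table
#'
#' Reads delimited text (comma, tab or semicolon; auto-detected) with one
#' row per well into `combination_block` objects, one per
#' `(block_id, sample)` pair. Two dialects are supported:
#'
#' * `"pairwise"`: columns `block_id, drug_row, drug_col, conc_r, conc_c,
#'   response` (or `count`), optional `conc_r_unit, conc_c_unit, sample,
#'   replicate`.
#' * `"multi"`: columns `block_id, drug1..drugN, conc1..concN,
#'   response`/`count`, optional `sample, replicate`; `N` is auto-detected
#'   from the header.
#'
#' Replicate rows at identical doses are averaged into the working tensor
#' (the replicate stack is retained on the block). Raw counts are converted
#' to percent inhibition first (see [normalize_counts()]). Any drug whose
#' grid lacks dose 0 gets it prepended (the untreated control is defined as
#' 0 percent inhibition).
#'
#' @param path delimited text file.
#' @param dialect `"pairwise"` or `"multi"`.
#' @param sep field separator; auto-detected by default.
#' @param count_controls passed to [normalize_counts()] when the table has
#'   a `count` column instead of `response`.
#' @return list of `combination_block` objects.
#' @export
read_long_table <- function(path, dialect = c("pairwise", "multi"),
                            sep = detect_sep(path), count_controls = list()) {
  dialect <- match.arg(dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  has_count <- "count" %in% names(df) && !"response" %in% names(df)
  need <- if (dialect == "pairwise") {
    c("block_id", "drug_row", "drug_col", "conc_r", "conc_c",
      if (has_count) "count" else "response")
  } else {
    c("block_id", if (has_count) "count" else "response")
  }
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_synscreen(sprintf("missing required column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   "synscreen_format_error")
  }
  if (dialect == "multi") {
    drug_cols <- grep("^drug[0-9]+$", names(df), value = TRUE)
    conc_cols <- grep("^conc[0-9]+$", names(df), value = TRUE)
    if (length(drug_cols) < 2 || length(conc_cols) != length(drug_cols)) {
      stop_synscreen("multi dialect needs matched drug1..drugN and conc1..concN columns",
                     "synscreen_format_error")
    }
    drug_cols <- drug_cols[order(as.integer(sub("drug", "", drug_cols)))]
    conc_cols <- conc_cols[order(as.integer(sub("conc", "", conc_cols)))]
  } else {
    drug_cols <- c("drug_row", "drug_col")
    conc_cols <- c("conc_r", "conc_c")
  }
  df$sample <- if ("sample" %in% names(df)) as.character(df$sample) else NA_character_
  df$replicate <- if ("replicate" %in% names(df)) as.integer(df$replicate) else 1L

  if (has_count) {
    df <- normalize_counts(df, conc_cols, count_controls)
  }

  units <- if (dialect == "pairwise" &&
               all(c("conc_r_unit", "conc_c_unit") %in% names(df))) {
    c(as.character(df$conc_r_unit[1]), as.character(df$conc_c_unit[1]))
  } else NULL

  group_key <- paste(df$block_id,
                     ifelse(is.na(df$sample), "", df$sample), sep = "\r")
  groups <- split(df, group_key)
  blocks <- lapply(groups, function(g)
    build_block(g, drug_cols, conc_cols, units))
  names(blocks) <- NULL
  blocks[order(vapply(blocks, function(b)
    paste(b$block_id, b$sample_id), ""))]
}

build_block <- function(g, drug_cols, conc_cols, units) {
  drugs <- vapply(drug_cols, function(cc) as.character(g[[cc]][1]), "")
  grid <- lapply(conc_cols, function(cc) sort(unique(as.numeric(g[[cc]]))))
  grid <- lapply(grid, function(v) if (v[1] == 0) v else c(0, v))
  names(grid) <- drugs
  dims <- lengths(grid)

  pos <- vapply(seq_along(conc_cols), function(k)
    match(as.numeric(g[[conc_cols[k]]]), grid[[k]]), integer(nrow(g)))
  pos <- matrix(pos, nrow = nrow(g))
  key <- apply(pos, 1, paste, collapse = "/")
  dup <- duplicated(data.frame(key, g$replicate))
  if (any(dup)) {
    stop_synscreen(sprintf(
      "duplicate row for dose indices (%s), replicate %s",
      key[dup][1], g$replicate[dup][1]), "synscreen_conflict_error")
  }

  reps <- sort(unique(g$replicate))
  rep_arrays <- lapply(reps, function(rp) {
    arr <- array(NA_real_, dim = dims)
    sel <- g$replicate == rp
    arr[pos[sel, , drop = FALSE]] <- as.numeric(g$response[sel])
    arr
  })
  stacked <- array(unlist(rep_arrays), dim = c(dims, length(reps)))
  mean_arr <- apply(stacked, seq_along(dims), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  mean_arr <- array(mean_arr, dim = dims)

  cells <- index_grid(dims)
  interior <- rowSums(cells > 1L) == length(dims)
  miss <- interior & is.na(mean_arr[cells])
  if (any(miss)) {
    bad <- cells[which(miss)[1], ]
    dose_txt <- paste(vapply(seq_along(bad), function(k)
      format(grid[[k]][bad[k]]), ""), collapse = ", ")
    stop_synscreen(sprintf(
      "block '%s': no measurable response for combination cell at doses (%s)",
      g$block_id[1], dose_txt), "synscreen_missing_data_error")
  }
  combination_block(drugs, grid, mean_arr,
                    block_id = as.character(g$block_id[1]),
                    sample_id = g$sample[1],
                    dose_units = units,
                    replicates = if (length(reps) > 1) rep_arrays else NULL)
}

#' Normalize raw counts to percent inhibition
#'
#' Converts a raw signal (e.g. viable-cell counts) into percent inhibition
#' per block using the negative-control wells (all concentrations 0):
#' `response = 100 * (1 - count / mean(negative controls))`. If positive
#' controls are designated (`controls$positive_value`, the expected count
#' at full inhibition, or rows matching `controls$positive_rows`), the
#' two-point normalization
#' `100 * (mean(neg) - count) / (mean(neg) - mean(pos))` is used instead.
#'
#' By default the count is treated as a surviving-cell signal (inhibition
#' rises as counts fall); set `controls$signal = "killed"` for assays whose
#' count rises with treatment effect, in which case the count is first
#' reflected about the negative-control mean.
#'
#' @param df data frame with a `count` column and concentration columns.
#' @param conc_cols names of the concentration columns.
#' @param controls list with optional entries `positive_value`, `signal`.
#' @return the data frame with a `response` column (percent inhibition) and
#'   the `count` column removed.
#' @export
normalize_counts <- function(df, conc_cols, controls = list()) {
  signal <- controls$signal %||% "surviving"
  out <- lapply(split(df, df$block_id), function(g) {
    conc <- as.matrix(g[, conc_cols, drop = FALSE])
    is_neg <- rowSums(conc != 0) == 0
    if (!any(is_neg)) {
      stop_synscreen(sprintf(
        "block '%s': no negative-control well (all concentrations 0); cannot normalize counts",
        g$block_id[1]), "synscreen_normalization_error")
    }
    counts <- as.numeric(g$count)
    if (signal == "killed") {
      counts <- 2 * mean(counts[is_neg]) - counts
    }
    neg <- mean(counts[is_neg])
    if (!is.null(controls$positive_value)) {
      pos <- controls$positive_value
      if (abs(neg - pos) < 1e-12) {
        stop_synscreen(sprintf(
          "block '%s': negative and positive control means coincide",
          g$block_id[1]), "synscreen_degenerate_control_error")
      }
      g$response <- 100 * (neg - counts) / (neg - pos)
    } else {
      if (abs(neg) < 1e-12) {
        stop_synscreen(sprintf(
          "block '%s': negative-control mean is zero", g$block_id[1]),
          "synscreen_degenerate_control_error")
      }
      g$response <- 100 * (1 - counts / neg)
    }
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$count <- NULL
  res
}

#' Write a result table to CSV or JSON
#'
#' CSV output is written without row names and without quoting; JSON output
#' is a dataframe-oriented array of records. Both round-trip: re-reading
#' reproduces values to within numerical print precision (JSON keeps full
#' double precision).
#'
#' @param results data frame.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}
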