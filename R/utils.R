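#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can branch on failure kind without parsing
# messages. All package errors inherit from "synscreen_error".
stop_synscreen <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "synscreen_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

warn_synscreen <- function(message, class) {
  warning(structure(
    class = c(class, "synscreen_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Clamp values to an interval
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

# expand.grid over index vectors, as an integer matrix (one row per cell).
index_grid <- function(dims) {
  m <- as.matrix(expand.grid(lapply(unname(dims), seq_len),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}
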