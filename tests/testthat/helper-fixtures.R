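# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# A dose-response curve object with known parameters (no fitting).
make_curve <- function(l = 0, u = 100, ec50 = 1, h = 1, drug = "drug") {
  structure(list(drug = drug, l = l, u = u, ec50 = ec50, h = h,
                 rss = 0, n = NA_integer_, poor_fit = FALSE),
            class = "dose_response_curve")
}

hill_y <- function(d, l = 0, u = 100, ec50 = 1, h = 1) {
  ifelse(d == 0, l, l + (u - l) / (1 + (ec50 / d)^h))
}

# Independent brute-force Loewe oracle: scan the effect axis on a fine
# grid and return the y minimizing |sum_i d_i / D_i(y) - 1|.
loewe_grid_oracle <- function(curves, doses, n_grid = 1e6) {
  lo <- max(vapply(curves, `[[`, 0, "l"))
  hi <- min(vapply(curves, `[[`, 0, "u"))
  ys <- seq(lo + (hi - lo) * 1e-9, hi - (hi - lo) * 1e-9, length.out = n_grid)
  s <- rep(0, n_grid)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    d_i <- cv$ec50 * ((ys - cv$l) / (cv$u - ys))^(1 / cv$h)
    s <- s + doses[i] / d_i
  }
  if (s[n_grid] > 1) return(hi)   # saturated
  ys[which.min(abs(s - 1))]
}

# Two-drug block built directly from dose grids and a response matrix.
make_block <- function(response, g1 = NULL, g2 = NULL,
                       drugs = c("A", "B"), block_id = "blk") {
  if (is.null(g1)) g1 <- c(0, 10^seq(-1, 1, length.out = nrow(response) - 1))
  if (is.null(g2)) g2 <- c(0, 10^seq(-1, 1, length.out = ncol(response) - 1))
  combination_block(drugs, setNames(list(g1, g2), drugs), response,
                    block_id = block_id)
}

# Exact Bliss-null block from two Hill curves (noiseless, l = 0).
bliss_null_block <- function(p1 = list(l = 0, u = 95, ec50 = 1, h = 1.2),
                             p2 = list(l = 0, u = 80, ec50 = 5, h = 1.5),
                             n_dose = 5, delta = 0) {
  g1 <- c(0, p1$ec50 * 10^seq(-1, 1, length.out = n_dose))
  g2 <- c(0, p2$ec50 * 10^seq(-1, 1, length.out = n_dose))
  y1 <- hill_y(g1, p1$l, p1$u, p1$ec50, p1$h)
  y2 <- hill_y(g2, p2$l, p2$u, p2$ec50, p2$h)
  M <- outer(y1, y2, function(a, b) 100 * (1 - (1 - a / 100) * (1 - b / 100)))
  M[1, ] <- y2; M[, 1] <- y1; M[1, 1] <- 0
  M[-1, -1] <- M[-1, -1] + delta
  make_block(M, g1, g2)
}

expect_no_synscreen_error <- function(expr) {
  expect_error(expr, NA, class = "synscreen_error")
}
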