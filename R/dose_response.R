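#' Four-parameter log-logistic dose-response fitting
#'
#' Fits the monotone sigmoidal model
#' \deqn{y(d) = l + \frac{u - l}{1 + (EC_{50}/d)^h}}
#' to single-agent percent-inhibition data by bounded least squares. `l` is
#' the lower asymptote (the response at zero dose), `u` the upper asymptote,
#' `EC50` the midpoint dose and `h` the Hill slope. The zero dose is handled
#' by the closed-form limit `y(0) = l`, never by `log(0)`.
#'
#' Optimization is deterministic: a fixed 3 x 3 multi-start grid over
#' starting values `EC50` in (smallest positive dose, geometric mid-range,
#' largest dose) and `h` in (0.5, 1, 3), each start refined with L-BFGS-B
#' under the bounds `l` in \[-50, 150\], `u` in \[l, 200\], `h` in
#' (0.05, 20\]. The best residual sum of squares wins; ties go to the
#' smaller `h`, then the smaller `EC50`.
#'
#' @param doses non-negative numeric vector (>= 3 distinct values).
#' @param responses percent inhibition, same length; `NA` pairs are dropped.
#' @param drug optional drug name stored on the result.
#' @param fix_l optionally pin the lower asymptote to a known value (used by
#'   the ZIP conditional fits, where the zero-dose anchor is the partner
#'   drug's fitted response).
#' @return object of class `dose_response_curve` with fields `drug`, `l`,
#'   `u`, `ec50`, `h`, `rss`, `n`, `poor_fit`.
#' @examples
#' d <- c(0, 10^seq(-2, 2, length.out = 7))
#' y <- 100 / (1 + (1 / pmax(d, 1e-300))^1)
#' fit_hill(d, y)
#' @export
fit_hill <- function(doses, responses, drug = "drug", fix_l = NULL) {
  if (any(is.infinite(responses)) || any(is.infinite(doses))) {
    stop_synscreen("doses and responses must be finite", "synscreen_data_error")
  }
  keep <- !is.na(doses) & !is.na(responses)
  doses <- doses[keep]; responses <- responses[keep]
  if (length(doses) == 0 || any(doses < 0)) {
    stop_synscreen("doses must be non-negative and finite", "synscreen_data_error")
  }
  if (length(unique(doses)) < 3) {
    stop_synscreen("need at least 3 distinct doses to fit a dose-response curve",
                   "synscreen_insufficient_data_error")
  }
  dpos <- sort(unique(doses[doses > 0]))
  ec50_starts <- c(min(dpos), geomean(range(dpos)), max(dpos))
  h_starts <- c(0.5, 1, 3)
  lh_b <- log(c(0.05, 20))
  lec_b <- log(c(min(dpos) * 1e-4, max(dpos) * 1e4))

  free_l <- is.null(fix_l)
  rss_fun <- function(p) {
    if (free_l) {
      l <- p[1]; u <- l + p[2]; lec <- p[3]; lh <- p[4]
    } else {
      l <- fix_l; u <- l + p[1]; lec <- p[2]; lh <- p[3]
    }
    pred <- hill_eval(doses, l, u, exp(lec), exp(lh))
    pen <- if (u > 200) 1e4 * (u - 200)^2 else 0
    sum((responses - pred)^2) + pen
  }

  l0 <- if (free_l) min(responses) else fix_l
  du0 <- max(max(responses) - l0, 0)
  best <- NULL
  for (h0 in h_starts) {
    for (e0 in ec50_starts) {
      par0 <- if (free_l) c(l0, du0, log(e0), log(h0)) else c(du0, log(e0), log(h0))
      lower <- if (free_l) c(-50, 0, lec_b[1], lh_b[1]) else c(0, lec_b[1], lh_b[1])
      upper <- if (free_l) c(150, 250, lec_b[2], lh_b[2]) else c(250, lec_b[2], lh_b[2])
      fit <- stats::optim(par0, rss_fun, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500, factr = 1e3))
      cand <- list(par = fit$par, rss = fit$value, h0 = h0, e0 = e0)
      if (is.null(best) || cand$rss < best$rss - 1e-9 ||
          (abs(cand$rss - best$rss) <= 1e-9 && better_tie(cand, best, free_l))) {
        best <- cand
      }
    }
  }
  p <- best$par
  if (free_l) {
    l <- p[1]; u <- l + p[2]; ec50 <- exp(p[3]); h <- exp(p[4])
  } else {
    l <- fix_l; u <- l + p[1]; ec50 <- exp(p[2]); h <- exp(p[3])
  }
  df <- max(length(doses) - (if (free_l) 4 else 3), 1)
  rss <- sum((responses - hill_eval(doses, l, u, ec50, h))^2)
  poor <- rss / df > 100
  if (poor) {
    warn_synscreen(sprintf("poor dose-response fit for '%s' (RSS/df = %.1f)",
                           drug, rss / df), "synscreen_poor_fit_warning")
  }
  structure(list(drug = drug, l = l, u = u, ec50 = ec50, h = h,
                 rss = rss, n = length(doses), poor_fit = poor),
            class = "dose_response_curve")
}

# tie-break: smaller fitted h, then smaller fitted ec50
better_tie <- function(cand, best, free_l) {
  i <- if (free_l) c(4, 3) else c(3, 2)
  if (cand$par[i[1]] != best$par[i[1]]) return(cand$par[i[1]] < best$par[i[1]])
  cand$par[i[2]] < best$par[i[2]]
}

hill_eval <- function(d, l, u, ec50, h) {
  y <- rep(l, length(d))
  pos <- d > 0
  y[pos] <- l + (u - l) / (1 + (ec50 / d[pos])^h)
  y
}

#' Predict percent inhibition at a dose
#'
#' Closed-form evaluation of a fitted curve; `predict_response(curve, 0)`
#' returns the lower asymptote and `predict_response(curve, ec50)` the
#' midpoint `(l + u) / 2`.
#'
#' @param curve a `dose_response_curve`.
#' @param dose non-negative dose (vectorized).
#' @export
predict_response <- function(curve, dose) {
  if (any(dose < 0)) {
    stop_synscreen("dose must be non-negative", "synscreen_domain_error")
  }
  hill_eval(dose, curve$l, curve$u, curve$ec50, curve$h)
}

#' Invert a dose-response curve
#'
#' Returns the dose producing a given response. For responses at or below
#' the lower asymptote the dose is 0; at or above the upper asymptote the
#' dose is unbounded and `Inf` is returned. These saturation signals (rather
#' than errors) let the Loewe solver handle saturated effect levels.
#'
#' @param curve a `dose_response_curve`.
#' @param response percent inhibition (vectorized).
#' @return dose(s); 0 below the curve range, `Inf` at/above it.
#' @export
inverse_dose <- function(curve, response) {
  out <- numeric(length(response))
  out[response <= curve$l] <- 0
  out[response >= curve$u] <- Inf
  mid <- response > curve$l & response < curve$u
  r <- response[mid]
  out[mid] <- curve$ec50 * ((r - curve$l) / (curve$u - r))^(1 / curve$h)
  out
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf(
    "<dose_response_curve> %s: l = %.3f, u = %.3f, EC50 = %.4g, h = %.3f (RSS %.3g)\n",
    x$drug, x$l, x$u, x$ec50, x$h, x$rss))
  invisible(x)
}

#' Tabulate fitted curve parameters
#'
#' @param curves list of `dose_response_curve` objects.
#' @return data frame with columns drug, l, u, ec50, h, rss.
#' @export
curve_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(drug = cv$drug, l = cv$l, u = cv$u, ec50 = cv$ec50,
               h = cv$h, rss = cv$rss, stringsAsFactors = FALSE)
  }))
}

# Fit one curve per drug from a block's single-agent axes.
fit_block_curves <- function(block) {
  lapply(seq_along(block$drugs), function(k) {
    fit_hill(block$dose_grid[[k]], axis_responses(block, k),
             drug = block$drugs[k])
  })
}
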