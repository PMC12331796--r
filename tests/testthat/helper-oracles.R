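# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the smoother oracle is a per-grid-point tricube
# weighted least squares (neighborhood q = floor(span * n), strict d < d_q
# support), the Bayes-factor oracle a brute-force trapezoid quadrature.

# local polynomial regression of y on x evaluated at each point of `grid`
wls_smooth_oracle <- function(x, y, grid, span = 0.2, degree = 2) {
  n <- length(x)
  q <- max(2L, min(n, floor(span * n)))
  vapply(grid, function(x0) {
    d <- abs(x - x0)
    dq <- sort(d)[q]
    w <- ifelse(d < dq, (1 - (d / dq)^3)^3, 0)
    X <- outer(x - x0, 0:degree, `^`)
    stats::lm.wfit(X, y, w)$coefficients[1]
  }, numeric(1))
}

# restricted curve minimum computed entirely through the oracle smoother;
# mirrors the pipeline's conventions (1-ms rounding, clipping, strict
# rpt > restriction, full-grid evaluation as with surface = "direct")
oracle_restricted_min <- function(rpt, correct, window = c(-200, 1000),
                                  span = 0.2, degree = 2, restriction = 0) {
  b <- pmin(pmax(round(rpt), window[1]), window[2])
  tab_n <- table(b)
  x <- as.numeric(names(tab_n))
  k <- tapply(correct, b, sum)
  ph <- as.numeric(k / tab_n)
  g <- seq(restriction + 1, window[2])
  p <- pmin(1, pmax(0, wls_smooth_oracle(x, ph, g, span, degree)))
  min(p)
}

# exact p-value of the minima-difference test by exhaustive relabeling
oracle_exhaustive_min_diff_p <- function(rpt, correct, n_a, window, span,
                                         degree, restriction, eps = 1e-9) {
  n <- length(rpt)
  idx <- utils::combn(n, n_a)
  stat <- function(sel_a) {
    sel <- logical(n); sel[sel_a] <- TRUE
    oracle_restricted_min(rpt[sel], correct[sel], window, span, degree, restriction) -
      oracle_restricted_min(rpt[!sel], correct[!sel], window, span, degree, restriction)
  }
  obs <- stat(seq_len(n_a))
  null <- apply(idx, 2, stat)
  mean(abs(null) >= abs(obs) - eps)
}

# exact p-value of the minimum-vs-chance test by enumerating all coin vectors
oracle_exhaustive_vs_chance_p <- function(rpt, correct, window, span, degree,
                                          restriction, p0 = 0.5, eps = 1e-9) {
  n <- length(rpt)
  obs <- oracle_restricted_min(rpt, correct, window, span, degree, restriction)
  total <- 0
  hit <- 0
  for (j in seq_len(2^n) - 1L) {
    cc <- as.integer(intToBits(j))[seq_len(n)]
    w <- p0^sum(cc) * (1 - p0)^(n - sum(cc))
    m <- oracle_restricted_min(rpt, cc, window, span, degree, restriction)
    total <- total + w
    if (m <= obs + eps) hit <- hit + w
  }
  hit / total
}

# brute-force trapezoid quadrature for the one-sided proportion Bayes factor,
# on the log-odds scale with the peak factored out
bf_log10_oracle <- function(k, n, side, p0 = 0.5, prior_scale = 0.5,
                            n_grid = 1e6, half_range = 40) {
  mu <- stats::qlogis(p0)
  lim <- if (side == "below") c(mu - half_range, mu) else c(mu, mu + half_range)
  om <- seq(lim[1], lim[2], length.out = n_grid)
  l0 <- stats::dbinom(k, n, p0, log = TRUE)
  lr <- stats::dbinom(k, n, stats::plogis(om), log = TRUE) - l0 +
    stats::dlogis(om, mu, prior_scale, log = TRUE)
  lr[!is.finite(lr)] <- -1e300
  M <- max(lr)
  f <- exp(lr - M)
  dx <- (lim[2] - lim[1]) / (n_grid - 1)
  I <- sum((f[-1] + f[-n_grid]) / 2) * dx
  mass <- 0.5  # symmetric logistic prior, half mass each side of logit(p0)
  (M + log(I) - log(mass)) / log(10)
}

# minimal trial table around given rPTs (gap 0, SOA 0, so rt = rPT)
toy_records <- function(rpt_ms, correct, congruency = "congruent") {
  data.frame(participant = "P01", session = 1L, block = 2L,
             trial_in_block = seq_along(rpt_ms), is_practice = FALSE,
             congruency = congruency, soa_ms = 0, gap_ms = 0,
             fixation_ms = 400, target = "left",
             response = ifelse(correct == 1, "left", "right"),
             rt_ms = rpt_ms, correct = as.integer(correct),
             on_time = 1L)
}

# hand-built full-grid bin table with the given nonempty bins
toy_bins <- function(x, p_hat, n_trials = 5L, window = c(-200, 1000)) {
  grid <- seq(window[1], window[2])
  out <- data.frame(rpt_bin_ms = grid, n_trials = 0L, n_correct = 0L,
                    p_hat = NA_real_, empty = TRUE)
  i <- match(x, grid)
  stopifnot(!anyNA(i))
  out$n_trials[i] <- n_trials
  out$p_hat[i] <- p_hat
  out$n_correct[i] <- round(p_hat * n_trials)
  out$empty[i] <- FALSE
  out
}
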