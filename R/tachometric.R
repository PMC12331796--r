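#' Raw processing time (rPT)
#'
#' The raw processing time is the time the target stimulus was visible before
#' the response: `rPT = RT - gap`, and additionally minus the SOA when the
#' flankers precede the target (`rPT = RT - gap - SOA`). Negative values mean
#' the response was committed before target onset (a guess).
#'
#' @param rt_ms response time from the Go-signal (ms).
#' @param gap_ms gap between Go-signal and target onset (ms).
#' @param soa_ms flanker-to-target SOA (ms), default 0.
#' @return rPT in ms; vectorized.
#' @examples
#' compute_rpt(700, 300)        # 400
#' compute_rpt(700, 300, 120)   # 280
#' @export
compute_rpt <- function(rt_ms, gap_ms, soa_ms = 0) {
  stopifnot(is.numeric(rt_ms), is.numeric(gap_ms), is.numeric(soa_ms))
  rt_ms - gap_ms - soa_ms
}

# rPT column added in place (idempotent)
add_rpt <- function(records) {
  soa <- if ("soa_ms" %in% names(records)) records$soa_ms else 0
  records$rpt_ms <- compute_rpt(records$rt_ms, records$gap_ms, soa)
  records
}

#' Filter trials to the analysis window
#'
#' Keeps non-practice trials with rPT inside the closed analysis window
#' (default \[-200, 1000\] ms; trials beyond 1,000 ms rPT would lie outside
#' the response deadline even at gap 0). Order is preserved. The counts
#' excluded by each rule are attached as attribute `"excluded"` with elements
#' `practice` and `window` (a practice trial outside the window counts as
#' `practice`).
#'
#' @param records trial data.frame with `rt_ms`, `gap_ms` (and optionally
#'   `soa_ms`, `is_practice`); an `rpt_ms` column is computed if absent.
#' @param window_ms closed rPT window, default `c(-200, 1000)`.
#' @return Filtered records with an `rpt_ms` column and an `"excluded"`
#'   attribute.
#' @export
filter_trials <- function(records, window_ms = c(-200, 1000)) {
  stopifnot(length(window_ms) == 2, window_ms[1] < window_ms[2])
  if (!"rpt_ms" %in% names(records)) records <- add_rpt(records)
  practice <- if ("is_practice" %in% names(records)) records$is_practice else
    rep(FALSE, nrow(records))
  in_window <- records$rpt_ms >= window_ms[1] & records$rpt_ms <= window_ms[2]
  keep <- !practice & in_window
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- c(practice = sum(practice),
                             window = sum(!in_window & !practice))
  attr(out, "window_ms") <- window_ms
  out
}

#' Bin accuracy on a 1-ms rPT grid
#'
#' Computes the proportion of correct responses for every 1-ms bin of the rPT
#' window (bin value = rPT rounded to the nearest ms). Bins without trials are
#' flagged `empty` and carry `p_hat = NA`; the total trial count across bins
#' equals the number of input records.
#'
#' @param records filtered trial data.frame with `rpt_ms` and `correct`.
#' @param window_ms integer bin range, default `c(-200, 1000)`.
#' @return data.frame with columns `rpt_bin_ms`, `n_trials`, `n_correct`,
#'   `p_hat`, `empty`.
#' @export
bin_accuracy <- function(records, window_ms = c(-200, 1000)) {
  if (!"rpt_ms" %in% names(records)) records <- add_rpt(records)
  grid <- seq(window_ms[1], window_ms[2])
  b <- round(records$rpt_ms)
  b <- pmin(pmax(b, window_ms[1]), window_ms[2])  # rounding at the window edge
  idx <- b - window_ms[1] + 1L
  n <- tabulate(idx, nbins = length(grid))
  k <- tabulate(idx[records$correct == 1L], nbins = length(grid))
  data.frame(
    rpt_bin_ms = grid,
    n_trials = n,
    n_correct = k,
    p_hat = ifelse(n > 0, k / n, NA_real_),
    empty = n == 0L
  )
}

# neighborhood size used by the local regression, as in loess: q = floor(span*n)
loess_q <- function(span, n) max(2L, min(n, floor(span * n)))

# For each evaluation point, the local bandwidth h = distance to the q-th
# nearest predictor value, and the number of trials whose bins fall strictly
# inside that bandwidth (the trials the local fit is based on).
local_trial_counts <- function(x, n_trials, grid, q) {
  stopifnot(!is.unsorted(x))
  nb <- length(x)
  q <- min(q, nb)
  # windows of q consecutive sorted predictors; bandwidth at g is the smallest
  # max-distance over windows, attained where g is most central
  L <- x[seq_len(nb - q + 1L)]
  R <- x[seq.int(q, nb)]
  mid <- (L + R) / 2
  j <- findInterval(grid, mid)
  j1 <- pmin(pmax(j, 1L), nb - q + 1L)
  j2 <- pmin(j1 + 1L, nb - q + 1L)
  h <- pmin(pmax(grid - L[j1], R[j1] - grid), pmax(grid - L[j2], R[j2] - grid))
  cs <- c(0, cumsum(n_trials))
  # strict |x - g| < h, matching the support of the tricube weights
  lo <- findInterval(grid - h, x)                    # bins with x <= g - h (excluded)
  hi <- findInterval(grid + h, x, left.open = TRUE)  # bins with x <  g + h (included)
  pmax(as.integer(round(cs[hi + 1L] - cs[lo + 1L])), 0L)
}

#' Smooth binned accuracy into a tachometric curve
#'
#' Locally regresses the per-bin proportions on the bin centers (loess, tricube
#' weights, nearest-neighbor bandwidth `span` x number of nonempty bins,
#' default polynomial degree 2) and evaluates the fit on the full 1-ms grid of
#' the window. Empty bins carry no accuracy information and are dropped before
#' the regression; the fit is clipped to \[0, 1\]. Grid points outside the
#' range of nonempty bins are `NA` under the default interpolated surface.
#'
#' `n_local` gives, for each grid point, the number of trials inside the local
#' regression bandwidth — the effective count behind the smoothed value, used
#' by [chance_band()].
#'
#' @param bins output of [bin_accuracy()].
#' @param span smoothing span (fraction of nonempty bins in each local fit),
#'   default 0.2.
#' @param condition label stored with the curve.
#' @param degree local polynomial degree (default 2).
#' @param weighted if `TRUE`, bins are weighted by trial count in the
#'   regression; default `FALSE` (every nonempty bin counts equally).
#' @param surface `"interpolate"` (fast, the loess default) or `"direct"`
#'   (exact local weighted least squares at every grid point).
#' @return A data.frame of class `tachometric_curve` with columns `rpt_ms`,
#'   `p_smooth`, `n_local`, `n_trials_bin`; smoothing settings are attached as
#'   attributes.
#' @export
smooth_curve <- function(bins, span = 0.2, condition = "all", degree = 2,
                         weighted = FALSE, surface = c("interpolate", "direct")) {
  surface <- match.arg(surface)
  nz <- bins[!bins$empty, , drop = FALSE]
  if (nrow(nz) < max(10, ceiling(2 / span)))
    stop(sprintf("too few nonempty bins (%d) for span %g", nrow(nz), span),
         call. = FALSE)
  grid <- bins$rpt_bin_ms
  w <- if (weighted) nz$n_trials else rep(1, nrow(nz))
  fit <- stats::loess(p_hat ~ rpt_bin_ms, data = nz, span = span,
                      degree = degree, weights = w, family = "gaussian",
                      surface = surface)
  p <- as.numeric(stats::predict(fit, data.frame(rpt_bin_ms = grid)))
  q <- loess_q(span, nrow(nz))
  n_local <- local_trial_counts(nz$rpt_bin_ms, nz$n_trials, grid, q)
  out <- data.frame(
    rpt_ms = grid,
    p_smooth = clip01(p),
    n_local = n_local,
    n_trials_bin = bins$n_trials
  )
  structure(out,
            class = c("tachometric_curve", "data.frame"),
            condition = condition, span = span, degree = degree,
            weighted = weighted, surface = surface)
}

#' @export
print.tachometric_curve <- function(x, ...) {
  ok <- !is.na(x$p_smooth)
  cat(sprintf("<tachometric_curve> condition '%s', span %g, degree %d\n",
              attr(x, "condition"), attr(x, "span"), attr(x, "degree")))
  cat(sprintf("  grid %d..%d ms (%d points, %d evaluated), %d trials\n",
              min(x$rpt_ms), max(x$rpt_ms), nrow(x), sum(ok), sum(x$n_trials_bin)))
  if (any(ok))
    cat(sprintf("  p_smooth range: %.3f .. %.3f\n",
                min(x$p_smooth[ok]), max(x$p_smooth[ok])))
  invisible(x)
}

#' Estimate a tachometric curve straight from trial records
#'
#' Convenience wrapper for the canonical estimation path
#' [bin_accuracy()] then [smooth_curve()].
#'
#' @param records filtered trial data.frame (see [filter_trials()]).
#' @param span,condition,window_ms,... passed to [bin_accuracy()] and
#'   [smooth_curve()].
#' @return A `tachometric_curve`.
#' @export
trials_to_curve <- function(records, span = 0.2, condition = "all",
                            window_ms = c(-200, 1000), ...) {
  smooth_curve(bin_accuracy(records, window_ms), span = span,
               condition = condition, ...)
}
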