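#' Restricted minimum of a tachometric curve
#'
#' Returns the minimum of the smoothed curve over grid points with
#' rPT > `restriction_ms` (default 0: negative-rPT responses precede target
#' onset and cannot be stimulus-driven, so the global minimum is not
#' interpretable there). Ties are broken toward the smallest rPT.
#'
#' @param curve a [smooth_curve()] result.
#' @param restriction_ms lower rPT bound (exclusive), default 0.
#' @return An object of class `minimum_stat`: list with `min_value`,
#'   `argmin_rpt_ms`, `restriction_ms`, `condition`.
#' @export
curve_minimum <- function(curve, restriction_ms = 0) {
  sub <- curve[curve$rpt_ms > restriction_ms & !is.na(curve$p_smooth), , drop = FALSE]
  if (nrow(sub) == 0)
    stop("curve has no evaluated points with rPT > restriction_ms", call. = FALSE)
  i <- which.min(sub$p_smooth)
  structure(list(min_value = sub$p_smooth[i],
                 argmin_rpt_ms = sub$rpt_ms[i],
                 restriction_ms = restriction_ms,
                 condition = attr(curve, "condition")),
            class = "minimum_stat")
}

#' @export
print.minimum_stat <- function(x, ...) {
  cat(sprintf("<minimum_stat> %s: min %.4f at rPT %g ms (rPT > %g ms)\n",
              x$condition %||% "", x$min_value, x$argmin_rpt_ms, x$restriction_ms))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# settings bundle for the bin -> smooth -> minimum pipeline used inside
# resampling loops
min_pipeline_opts <- function(span = 0.2, degree = 2,
                              surface = "interpolate",
                              window_ms = c(-200, 1000), restriction_ms = 0,
                              min_bins = NULL) {
  list(span = span, degree = degree, surface = surface, window_ms = window_ms,
       restriction_ms = restriction_ms,
       min_bins = min_bins %||% max(degree + 2, ceiling(2 / span)))
}

# fast bin -> loess -> restricted minimum; ib is the 1-based bin index
# (rounded rPT - window lo + 1), corr a 0/1 vector
fit_restricted_min <- function(ib, corr, opts) {
  nbins <- opts$window_ms[2] - opts$window_ms[1] + 1L
  n <- tabulate(ib, nbins)
  k <- tabulate(ib[corr == 1L], nbins)
  nz <- which(n > 0L)
  if (length(nz) < opts$min_bins) stop("degenerate: too few nonempty bins", call. = FALSE)
  x <- nz + opts$window_ms[1] - 1
  ph <- k[nz] / n[nz]
  # loess may warn about near-singular local fits in sparse resamples; the
  # fitted values are still usable, so keep resampling loops quiet
  fit <- suppressWarnings(
    stats::loess(ph ~ x, span = opts$span, degree = opts$degree,
                 family = "gaussian", surface = opts$surface))
  g <- seq(opts$restriction_ms + 1, opts$window_ms[2])
  if (opts$surface == "interpolate") g <- g[g >= min(x) & g <= max(x)]
  if (length(g) == 0) stop("degenerate: no grid beyond restriction", call. = FALSE)
  p <- clip01(as.numeric(suppressWarnings(stats::predict(fit, data.frame(x = g)))))
  i <- which.min(p)
  c(min = p[i], argmin = g[i])
}

prepare_bins_index <- function(records, window_ms) {
  records <- filter_trials(records, window_ms)
  b <- pmin(pmax(round(records$rpt_ms), window_ms[1]), window_ms[2])
  list(ib = as.integer(b - window_ms[1] + 1L),
       corr = as.integer(records$correct),
       excluded = attr(records, "excluded"))
}

new_permutation_result <- function(observed, null_draws, p_value, sidedness,
                                   seed, exhaustive, n_redrawn = 0L) {
  structure(list(observed = observed, null_draws = null_draws,
                 n_permutations = length(null_draws), p_value = p_value,
                 sidedness = sidedness, seed = seed, exhaustive = exhaustive,
                 n_redrawn = n_redrawn),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.4f, p = %.4g (%s, %d %s draws%s)\n",
              x$observed, x$p_value, x$sidedness, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "random",
              if (x$n_redrawn > 0) sprintf(", %d redrawn", x$n_redrawn) else ""))
  invisible(x)
}

# tolerance guarding exact floating-point ties in p-value counts
.tie_eps <- 1e-9

#' Permutation test for a difference of curve minima between two conditions
#'
#' The statistic is `min_A - min_B`, each restricted minimum computed by the
#' full bin -> smooth -> minimum pipeline. The null distribution relabels the
#' pooled trials into groups of the original sizes and recomputes the
#' statistic; with random relabelings the two-sided p-value uses the add-one
#' convention `p = (1 + #{|null| >= |observed|}) / (1 + n_perm)`. When the
#' number of distinct relabelings is at most `n_perm` the test enumerates all
#' of them and returns the exact p-value (the identity relabeling included).
#'
#' Replicates in which smoothing is infeasible (too few nonempty bins in one
#' group) are flagged and redrawn; the redraw count is recorded.
#'
#' @param records_a,records_b trial data.frames (filtered internally to the
#'   rPT window; practice trials dropped).
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed.
#' @param span,degree,surface,window_ms,restriction_ms pipeline settings as in
#'   [smooth_curve()] and [curve_minimum()].
#' @return A `permutation_result`.
#' @export
perm_test_min_diff <- function(records_a, records_b, n_perm = 1000, seed = 1L,
                               span = 0.2, degree = 2,
                               surface = "interpolate",
                               window_ms = c(-200, 1000), restriction_ms = 0) {
  opts <- min_pipeline_opts(span, degree, surface, window_ms, restriction_ms)
  pa <- prepare_bins_index(records_a, window_ms)
  pb <- prepare_bins_index(records_b, window_ms)
  na <- length(pa$ib); nb <- length(pb$ib)
  if (na == 0 || nb == 0) stop("a record set is empty after filtering", call. = FALSE)
  obs <- fit_restricted_min(pa$ib, pa$corr, opts)[["min"]] -
    fit_restricted_min(pb$ib, pb$corr, opts)[["min"]]
  ib <- c(pa$ib, pb$ib); corr <- c(pa$corr, pb$corr)
  n <- na + nb

  n_distinct <- suppressWarnings(choose(n, na))
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_perm
  local_rng(stage_seed(seed, "permutation"))

  stat_for <- function(idx_a) {
    sel <- logical(n); sel[idx_a] <- TRUE
    fit_restricted_min(ib[sel], corr[sel], opts)[["min"]] -
      fit_restricted_min(ib[!sel], corr[!sel], opts)[["min"]]
  }

  if (exhaustive) {
    combos <- utils::combn(n, na)
    null_draws <- apply(combos, 2, stat_for)
    p <- mean(abs(null_draws) >= abs(obs) - .tie_eps)
  } else {
    null_draws <- numeric(n_perm)
    redrawn <- 0L
    i <- 1L
    while (i <= n_perm) {
      res <- tryCatch(stat_for(sample.int(n, na)), error = function(e) NULL)
      if (is.null(res)) {
        redrawn <- redrawn + 1L
        if (redrawn > 10L * n_perm) stop("too many degenerate replicates", call. = FALSE)
        next
      }
      null_draws[i] <- res
      i <- i + 1L
    }
    p <- (1 + sum(abs(null_draws) >= abs(obs) - .tie_eps)) / (1 + n_perm)
    return(new_permutation_result(obs, null_draws, p, "two-sided", seed,
                                  FALSE, redrawn))
  }
  new_permutation_result(obs, null_draws, p, "two-sided", seed, TRUE)
}

#' Permutation test of a curve minimum against chance level
#'
#' Tests whether the restricted minimum of the tachometric curve lies below
#' chance (0.5). The null keeps every trial's rPT and regenerates its
#' correctness as an independent fair coin, then recomputes the minimum by the
#' full pipeline; the p-value is lower-sided,
#' `p = (1 + #{null <= observed}) / (1 + n_perm)`. When `2^n_trials <= n_perm`
#' all coin assignments are enumerated and the exact (probability-weighted)
#' p-value is returned.
#'
#' @inheritParams perm_test_min_diff
#' @param records trial data.frame.
#' @param p0 chance level, default 0.5.
#' @return A `permutation_result`.
#' @export
perm_test_min_vs_chance <- function(records, n_perm = 1000, seed = 1L, p0 = 0.5,
                                    span = 0.2, degree = 2,
                                    surface = "interpolate",
                                    window_ms = c(-200, 1000),
                                    restriction_ms = 0) {
  opts <- min_pipeline_opts(span, degree, surface, window_ms, restriction_ms)
  pr <- prepare_bins_index(records, window_ms)
  n <- length(pr$ib)
  if (n == 0) stop("no records after filtering", call. = FALSE)
  obs <- fit_restricted_min(pr$ib, pr$corr, opts)[["min"]]

  exhaustive <- n <= 25 && 2^n <= n_perm
  local_rng(stage_seed(seed, "chance_null"))

  if (exhaustive) {
    m <- 2^n
    null_draws <- numeric(m)
    wts <- numeric(m)
    for (j in seq_len(m) - 1L) {
      corr <- as.integer(intToBits(j))[seq_len(n)]
      null_draws[j + 1L] <- fit_restricted_min(pr$ib, corr, opts)[["min"]]
      wts[j + 1L] <- p0^sum(corr) * (1 - p0)^(n - sum(corr))
    }
    p <- sum(wts * (null_draws <= obs + .tie_eps)) / sum(wts)
    return(new_permutation_result(obs, null_draws, p, "lower", seed, TRUE))
  }

  null_draws <- numeric(n_perm)
  redrawn <- 0L
  i <- 1L
  while (i <= n_perm) {
    corr <- stats::rbinom(n, 1L, p0)
    res <- tryCatch(fit_restricted_min(pr$ib, corr, opts)[["min"]],
                    error = function(e) NULL)
    if (is.null(res)) {
      redrawn <- redrawn + 1L
      if (redrawn > 10L * n_perm) stop("too many degenerate replicates", call. = FALSE)
      next
    }
    null_draws[i] <- res
    i <- i + 1L
  }
  p <- (1 + sum(null_draws <= obs + .tie_eps)) / (1 + n_perm)
  new_permutation_result(obs, null_draws, p, "lower", seed, FALSE, redrawn)
}

#' Bootstrap standard error of the restricted curve minimum
#'
#' Resamples trials with replacement, recomputes the restricted minimum by the
#' full pipeline, and returns the standard deviation of the bootstrap minima.
#'
#' @inheritParams perm_test_min_vs_chance
#' @param n_boot number of bootstrap resamples, default 1000.
#' @return Numeric standard error with attributes `minima` (the bootstrap
#'   draws), `n_boot` and `seed`.
#' @export
bootstrap_min_se <- function(records, n_boot = 1000, seed = 1L,
                             span = 0.2, degree = 2,
                             surface = "interpolate",
                             window_ms = c(-200, 1000), restriction_ms = 0) {
  opts <- min_pipeline_opts(span, degree, surface, window_ms, restriction_ms)
  pr <- prepare_bins_index(records, window_ms)
  n <- length(pr$ib)
  if (n == 0) stop("no records after filtering", call. = FALSE)
  local_rng(stage_seed(seed, "bootstrap"))
  minima <- numeric(n_boot)
  redrawn <- 0L
  i <- 1L
  while (i <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(fit_restricted_min(pr$ib[idx], pr$corr[idx], opts)[["min"]],
                    error = function(e) NULL)
    if (is.null(res)) {
      redrawn <- redrawn + 1L
      if (redrawn > 10L * n_boot) stop("too many degenerate resamples", call. = FALSE)
      next
    }
    minima[i] <- res
    i <- i + 1L
  }
  structure(stats::sd(minima), minima = minima, n_boot = n_boot, seed = seed,
            n_redrawn = redrawn)
}

#' Binomial confidence band around chance level
#'
#' Per grid point the half-width is `1.96 * sqrt(p0 (1 - p0) / n)`, with `n`
#' the number of trials the local regression value is based on (`n_local` of
#' the curve). Grid points with `n_local = 0` are flagged undefined.
#'
#' @param curve a [smooth_curve()] result.
#' @param p0 chance probability, default 0.5.
#' @param multiplier normal quantile multiplier, default 1.96 (95%).
#' @return data.frame of class `chance_band` with `rpt_ms`, `n_local`,
#'   `half_width`, `lower`, `upper`, `undefined`.
#' @examples
#' # closed form: n = 100 gives half-width 1.96 * sqrt(0.25 / 100) = 0.098
#' @export
chance_band <- function(curve, p0 = 0.5, multiplier = 1.96) {
  n <- curve$n_local
  hw <- ifelse(n > 0, multiplier * sqrt(p0 * (1 - p0) / n), NA_real_)
  structure(data.frame(rpt_ms = curve$rpt_ms, n_local = n, half_width = hw,
                       lower = p0 - hw, upper = p0 + hw, undefined = n == 0L),
            class = c("chance_band", "data.frame"), p0 = p0, multiplier = multiplier)
}

#' First and last grid points where a curve leaves the chance band
#'
#' @param curve a [smooth_curve()] result.
#' @param band the matching [chance_band()].
#' @return list with components `below` and `above`, each `c(first, last)` in
#'   ms or `NULL` when the curve never leaves the band in that direction.
#' @export
band_exceedance <- function(curve, band = chance_band(curve)) {
  ok <- !is.na(curve$p_smooth) & !band$undefined
  below <- which(ok & curve$p_smooth < band$lower)
  above <- which(ok & curve$p_smooth > band$upper)
  list(
    below = if (length(below)) c(first = curve$rpt_ms[min(below)],
                                 last = curve$rpt_ms[max(below)]) else NULL,
    above = if (length(above)) c(first = curve$rpt_ms[min(above)],
                                 last = curve$rpt_ms[max(above)]) else NULL
  )
}

# log10 Bayes factor for one side, by adaptive quadrature on the log-odds
# scale. H1: logit(p) ~ logistic(logit(p0), scale) truncated to the side;
# H0: p = p0. Works entirely in logs so large n cannot overflow.
log10_bf_one_side <- function(k, n, side = c("below", "above"), p0 = 0.5,
                              prior_scale = 0.5) {
  side <- match.arg(side)
  mu <- stats::qlogis(p0)
  l0 <- stats::dbinom(k, n, p0, log = TRUE)
  h <- function(om) {
    v <- stats::dbinom(k, n, stats::plogis(om), log = TRUE) - l0 +
      stats::dlogis(om, mu, prior_scale, log = TRUE)
    # far tails underflow to -Inf; keep finite for the optimizer
    ifelse(is.finite(v), v, -1e300)
  }
  lim <- if (side == "below") c(mu - 60, mu) else c(mu, mu + 60)
  opt <- stats::optimize(h, interval = lim, maximum = TRUE)
  M <- opt$objective
  mass <- if (side == "below") stats::plogis(mu, mu, prior_scale) else
    stats::plogis(mu, mu, prior_scale, lower.tail = FALSE)
  val <- tryCatch(
    stats::integrate(function(o) exp(h(o) - M), lim[1], lim[2],
                     rel.tol = 1e-10, subdivisions = 500L)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  if (val == 0) return(-Inf)
  (M + log(val) - log(mass)) / log(10)
}

#' Binned binomial-proportion Bayes factors against chance
#'
#' Partitions the rPT window into fixed-width bins (default 100 ms), and for
#' each nonempty bin computes the evidence that accuracy is (a) below versus
#' exactly at chance and (b) above versus exactly at chance. Under the
#' alternative the log-odds of a correct response follow a logistic prior
#' centered at logit(p0) with scale `prior_scale`, truncated to the tested
#' side; the Bayes factor is the marginal likelihood of the bin's successes
#' under that prior divided by the point-null likelihood, computed by adaptive
#' numerical integration. Results are reported as decadal logarithms with
#' infinities preserved as sentinels.
#'
#' @param records trial data.frame (filtered internally).
#' @param bin_width_ms bin width in ms, default 100.
#' @param prior_scale logistic prior scale on the log-odds, default 0.5.
#' @param p0 chance probability, default 0.5.
#' @param window_ms rPT window partitioned into bins, default `c(-200, 1000)`.
#' @return data.frame of class `bf_table` with `bin_start_ms`, `bin_end_ms`,
#'   `n`, `k`, `p_hat`, `log10_bf_below`, `log10_bf_above`, `empty`.
#' @export
bayes_factors <- function(records, bin_width_ms = 100, prior_scale = 0.5,
                          p0 = 0.5, window_ms = c(-200, 1000)) {
  stopifnot((window_ms[2] - window_ms[1]) %% bin_width_ms == 0)
  records <- filter_trials(records, window_ms)
  if (nrow(records) == 0) stop("no records after filtering", call. = FALSE)
  starts <- seq(window_ms[1], window_ms[2] - bin_width_ms, by = bin_width_ms)
  bi <- pmin(floor((records$rpt_ms - window_ms[1]) / bin_width_ms) + 1L,
             length(starts))
  n <- tabulate(bi, nbins = length(starts))
  k <- tabulate(bi[records$correct == 1L], nbins = length(starts))
  below <- above <- rep(NA_real_, length(starts))
  for (i in which(n > 0)) {
    below[i] <- log10_bf_one_side(k[i], n[i], "below", p0, prior_scale)
    above[i] <- log10_bf_one_side(k[i], n[i], "above", p0, prior_scale)
  }
  structure(data.frame(bin_start_ms = starts, bin_end_ms = starts + bin_width_ms,
                       n = n, k = k, p_hat = ifelse(n > 0, k / n, NA_real_),
                       log10_bf_below = below, log10_bf_above = above,
                       empty = n == 0L),
            class = c("bf_table", "data.frame"),
            prior_scale = prior_scale, p0 = p0, bin_width_ms = bin_width_ms)
}
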