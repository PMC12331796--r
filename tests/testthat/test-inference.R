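make_curve <- function(p, grid = seq(-200, 1000), n_local = 100L) {
  structure(data.frame(rpt_ms = grid, p_smooth = p, n_local = n_local,
                       n_trials_bin = 1L),
            class = c("tachometric_curve", "data.frame"),
            condition = "toy", span = 0.2, degree = 2)
}

test_that("restricted minimum ignores negative rPTs and breaks ties leftward", {
  cv <- make_curve(rep(0.5, 1201))
  m <- curve_minimum(cv)
  expect_equal(m$min_value, 0.5)
  expect_equal(m$argmin_rpt_ms, 1)  # tie broken to the smallest positive rPT

  p <- rep(0.6, 1201)
  p[match(-50, cv$rpt_ms)] <- 0.1   # global minimum in the negative range
  p[match(400, cv$rpt_ms)] <- 0.3
  m2 <- curve_minimum(make_curve(p))
  expect_equal(m2$min_value, 0.3)
  expect_equal(m2$argmin_rpt_ms, 400)
  expect_error(curve_minimum(make_curve(rep(NA_real_, 1201))), "no evaluated")
})

test_that("identical groups give a zero minima difference and a large p", {
  set.seed(5)
  rpt <- sample(seq(10, 600), 80)
  rec <- toy_records(rpt, rbinom(80, 1, 0.6))
  res <- perm_test_min_diff(rec, rec, n_perm = 60, seed = 2)
  expect_equal(res$observed, 0)
  expect_gt(res$p_value, 0.5)
})

test_that("minima-difference p equals exhaustive enumeration on a 12-trial toy", {
  rpt_a <- c(10, 20, 30, 40, 50, 60)
  cor_a <- c(1, 1, 0, 1, 0, 1)
  rpt_b <- c(15, 25, 35, 45, 55, 65)
  cor_b <- c(0, 1, 1, 0, 1, 1)
  win <- c(0, 80); span <- 0.75; deg <- 1
  res <- perm_test_min_diff(toy_records(rpt_a, cor_a), toy_records(rpt_b, cor_b),
                            n_perm = 1000, seed = 3, span = span, degree = deg,
                            surface = "direct", window_ms = win)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, choose(12, 6))
  p_oracle <- oracle_exhaustive_min_diff_p(c(rpt_a, rpt_b), c(cor_a, cor_b), 6,
                                           win, span, deg, restriction = 0)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("minimum-vs-chance p equals exhaustive coin enumeration on a 10-trial toy", {
  rpt <- c(5, 12, 19, 26, 33, 40, 47, 54, 61, 68)
  cor <- c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1)
  win <- c(0, 80); span <- 0.6; deg <- 1
  res <- perm_test_min_vs_chance(toy_records(rpt, cor), n_perm = 1024, seed = 4,
                                 span = span, degree = deg, surface = "direct",
                                 window_ms = win)
  expect_true(res$exhaustive)
  p_oracle <- oracle_exhaustive_vs_chance_p(rpt, cor, win, span, deg,
                                            restriction = 0)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("all-correct data cannot be below chance", {
  set.seed(6)
  rec <- toy_records(sample(seq(5, 700), 60), rep(1, 60))
  res <- perm_test_min_vs_chance(rec, n_perm = 60, seed = 7)
  expect_equal(res$observed, 1)
  expect_equal(res$p_value, 1)
})

test_that("bootstrap SE is deterministic, degenerate-safe and shrinks with n", {
  set.seed(8)
  rec <- toy_records(sample(seq(5, 700), 400, replace = TRUE),
                     rbinom(400, 1, 0.7))
  s1 <- bootstrap_min_se(rec, n_boot = 50, seed = 9)
  s2 <- bootstrap_min_se(rec, n_boot = 50, seed = 9)
  expect_identical(as.numeric(s1), as.numeric(s2))

  # every trial correct at a handful of fixed rPTs: the minimum is 1 in every
  # resample, so the bootstrap SE collapses to zero
  degen <- toy_records(rep(seq(10, 120, by = 10), each = 1000),
                       rep(1, 12000))
  expect_equal(as.numeric(bootstrap_min_se(degen, n_boot = 30, seed = 10)), 0)

  big <- toy_records(sample(seq(5, 700), 6400, replace = TRUE),
                     rbinom(6400, 1, 0.7))
  s_small <- as.numeric(bootstrap_min_se(rec, n_boot = 100, seed = 11))
  s_big <- as.numeric(bootstrap_min_se(big, n_boot = 100, seed = 11))
  expect_gt(s_small, 1.3 * s_big)
})

test_that("chance band follows the closed binomial form and its scaling", {
  cv <- make_curve(rep(0.5, 1201), n_local = 100L)
  b <- chance_band(cv)
  expect_equal(unique(b$half_width), 0.098, tolerance = 1e-10)
  b25 <- chance_band(make_curve(rep(0.5, 1201), n_local = 25L))
  expect_equal(unique(b25$half_width), 0.196, tolerance = 1e-10)
  # quadrupling n halves the width
  b400 <- chance_band(make_curve(rep(0.5, 1201), n_local = 400L))
  expect_equal(unique(b400$half_width), unique(b$half_width) / 2)
  # undefined where no local trials
  cv0 <- make_curve(rep(0.5, 1201), n_local = c(0L, rep(100L, 1200)))
  b0 <- chance_band(cv0)
  expect_true(b0$undefined[1] && is.na(b0$half_width[1]))
})

test_that("band exceedance reports first and last crossing per direction", {
  p <- rep(0.5, 1201)
  grid <- seq(-200, 1000)
  p[grid >= 300 & grid <= 350] <- 0.2
  p[grid >= 600] <- 0.9
  cv <- make_curve(p, n_local = 100L)
  ex <- band_exceedance(cv)
  expect_equal(unname(ex$below), c(300, 350))
  expect_equal(unname(ex$above), c(600, 1000))
  expect_null(band_exceedance(make_curve(rep(0.5, 1201)))$below)
})

test_that("Bayes factors match a brute-force quadrature oracle", {
  cases <- list(c(12, 40), c(50, 100), c(190, 200))
  for (cs in cases) {
    k <- cs[1]; n <- cs[2]
    rec <- toy_records(rep(150, n), c(rep(1, k), rep(0, n - k)))
    bf <- bayes_factors(rec, window_ms = c(100, 200), bin_width_ms = 100)
    expect_equal(nrow(bf), 1)
    expect_equal(bf$n, n)
    expect_equal(bf$k, k)
    expect_equal(bf$log10_bf_below, bf_log10_oracle(k, n, "below"),
                 tolerance = 1e-6)
    expect_equal(bf$log10_bf_above, bf_log10_oracle(k, n, "above"),
                 tolerance = 1e-6)
  }
})

test_that("Bayes factors are symmetric at one half and favor the evidence side", {
  rec <- toy_records(rep(50, 100), c(rep(1, 50), rep(0, 50)))
  bf <- bayes_factors(rec, window_ms = c(0, 100))
  expect_equal(bf$log10_bf_below, bf$log10_bf_above, tolerance = 1e-9)

  rec2 <- toy_records(rep(50, 200), rep(1, 200))
  bf2 <- bayes_factors(rec2, window_ms = c(0, 100))
  expect_gt(bf2$log10_bf_above, 5)
  expect_lt(bf2$log10_bf_below, 0)

  # favored-side evidence grows with the departure from 0.5 at fixed n
  above <- sapply(30:60, function(k) {
    r <- toy_records(rep(50, 60), c(rep(1, k), rep(0, 60 - k)))
    bayes_factors(r, window_ms = c(0, 100))$log10_bf_above
  })
  expect_true(all(diff(above) > 0))
})

test_that("Bayes factor bins partition the window and flag empty bins", {
  rec <- toy_records(c(-150, 250, 250, 920), c(1, 1, 0, 1))
  bf <- bayes_factors(rec)
  expect_equal(nrow(bf), 12)
  expect_equal(bf$bin_start_ms, seq(-200, 900, by = 100))
  expect_equal(sum(bf$n), 4)
  expect_true(bf$empty[bf$bin_start_ms == 0])
  expect_true(all(is.na(bf$log10_bf_below[bf$empty])))
})
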