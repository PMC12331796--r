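test_that("rPT arithmetic follows the (SOA-corrected) definition", {
  expect_equal(compute_rpt(700, 300), 400)
  expect_equal(compute_rpt(700, 300, 120), 280)
  expect_equal(compute_rpt(100, 300), -200)
  expect_equal(compute_rpt(c(500, 600), c(100, 0), c(0, 120)), c(400, 480))
})

test_that("window filtering keeps the closed interval and drops practice", {
  rec <- toy_records(c(-201, -200, 0, 500, 1000, 1001), rep(1, 6))
  rec$is_practice[4] <- TRUE
  f <- filter_trials(rec)
  expect_equal(f$rpt_ms, c(-200, 0, 1000))
  ex <- attr(f, "excluded")
  expect_equal(unname(ex["practice"]), 1)
  expect_equal(unname(ex["window"]), 2)
  # conservation: excluded + retained = input
  expect_equal(sum(ex) + nrow(f), nrow(rec))
  # order preserved
  rec2 <- toy_records(c(700, -100, 300), c(1, 0, 1))
  expect_equal(filter_trials(rec2)$rpt_ms, c(700, -100, 300))
})

test_that("1-ms bins partition the window and conserve trials", {
  rec <- toy_records(c(250, 250, 250, 251, -200, 1000), c(1, 1, 0, 0, 1, 1))
  b <- bin_accuracy(filter_trials(rec))
  expect_equal(b$rpt_bin_ms, seq(-200, 1000))
  expect_equal(b$n_trials[b$rpt_bin_ms == 250], 3)
  expect_equal(b$p_hat[b$rpt_bin_ms == 250], 2 / 3)
  expect_equal(sum(b$n_trials), 6)
  expect_true(all(b$empty == (b$n_trials == 0)))
  # all-correct input: every nonempty bin at 1
  bc <- bin_accuracy(filter_trials(toy_records(c(10, 20, 30), c(1, 1, 1))))
  expect_true(all(bc$p_hat[!bc$empty] == 1))
})

test_that("the smoother reproduces constants and straight lines", {
  x <- seq(-150, 950, by = 10)
  const <- toy_bins(x, rep(0.5, length(x)))
  for (surf in c("interpolate", "direct")) {
    cv <- smooth_curve(const, surface = surf)
    expect_lt(max(abs(cv$p_smooth[!is.na(cv$p_smooth)] - 0.5)), 1e-9)
  }
  lin <- toy_bins(x, 0.3 + 0.0004 * (x + 200))
  cv <- smooth_curve(lin, surface = "direct")
  interior <- cv$rpt_ms >= -140 & cv$rpt_ms <= 940
  expect_lt(max(abs(cv$p_smooth[interior] -
                      (0.3 + 0.0004 * (cv$rpt_ms[interior] + 200)))), 1e-6)
})

test_that("direct-surface smoothing equals the per-point tricube WLS oracle", {
  set.seed(31)
  x <- sort(sample(seq(-180, 980, by = 2), 60))
  y <- runif(60, 0.3, 0.7)
  bins <- toy_bins(x, y)
  cv <- smooth_curve(bins, span = 0.2, degree = 2, surface = "direct")
  oracle <- pmin(1, pmax(0, wls_smooth_oracle(x, y, cv$rpt_ms, 0.2, 2)))
  expect_lt(max(abs(cv$p_smooth - oracle)), 1e-8)
  # and for the degree-1 configuration
  cv1 <- smooth_curve(bins, span = 0.3, degree = 1, surface = "direct")
  oracle1 <- pmin(1, pmax(0, wls_smooth_oracle(x, y, cv1$rpt_ms, 0.3, 1)))
  expect_lt(max(abs(cv1$p_smooth - oracle1)), 1e-8)
})

test_that("the smoother is linear in the response for a fixed design", {
  set.seed(17)
  x <- sort(sample(seq(-150, 950), 80))
  y1 <- runif(80, 0.2, 0.8)
  y2 <- runif(80, 0.2, 0.8)
  a <- 0.35
  mix <- a * y1 + (1 - a) * y2
  sm <- function(y) {
    cv <- smooth_curve(toy_bins(x, y), surface = "direct")
    cv$p_smooth
  }
  s1 <- sm(y1); s2 <- sm(y2); s12 <- sm(mix)
  ok <- s1 > 0 & s1 < 1 & s2 > 0 & s2 < 1 & s12 > 0 & s12 < 1  # unclipped
  expect_lt(max(abs(s12[ok] - (a * s1[ok] + (1 - a) * s2[ok]))), 1e-8)
})

test_that("smoothed curves converge on the generative curve with more data", {
  m <- observer_model()
  err <- sapply(c(2, 10), function(nblocks) {
    spec <- design_spec(n_participants = 1, n_sessions = 1,
                        blocks_per_session = nblocks, practice_blocks = 0)
    d <- build_design(spec, seed = 21)
    tr <- simulate_trials(d, m, seed = 22)
    co <- tr[tr$congruency == "congruent", ]
    cv <- trials_to_curve(filter_trials(co), condition = "congruent")
    sel <- cv$rpt_ms >= 50 & cv$rpt_ms <= 800 & !is.na(cv$p_smooth)
    max(abs(cv$p_smooth[sel] - p_correct(m, cv$rpt_ms[sel], "congruent")))
  })
  expect_lt(err[2], err[1])
})

test_that("too few nonempty bins is an estimation error", {
  b <- toy_bins(c(0, 100, 200), c(0.4, 0.5, 0.6))
  expect_error(smooth_curve(b), "too few nonempty bins")
})
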