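test_that("generative accuracy curve has the right limits and shift structure", {
  m <- observer_model()
  # far left of the rise both conditions sit at the guessing floor
  expect_equal(p_correct(m, -150, "congruent"), m$p_floor, tolerance = 0.01)
  expect_equal(p_correct(m, -150, "incongruent"), m$p_floor, tolerance = 0.01)
  # logistic saturation at the asymptote when there is no dip
  expect_equal(p_correct(m, 5000, "congruent"), m$p_asym, tolerance = 1e-6)
  # without a dip the incongruent curve is the congruent curve shifted right
  r <- seq(-200, 1000, by = 1)
  expect_equal(p_correct(m, r, "incongruent"),
               p_correct(m, r - m$congruency_delay_ms, "congruent"),
               tolerance = 1e-12)
})

test_that("no-dip curves are non-decreasing and all curves stay clipped", {
  m <- observer_model(dip_depth = 0, late_decline_per_ms = 0)
  r <- seq(-200, 1000)
  expect_true(all(diff(p_correct(m, r, "incongruent")) >= -1e-12))
  strong <- observer_model(p_floor = 0.1, p_asym = 1, dip_depth = 1,
                           dip_center_ms = 300, dip_width_ms = 50)
  p <- p_correct(strong, r, "incongruent")
  expect_true(all(p >= 0.001 & p <= 0.999))
})

test_that("dip calibration places the generative restricted minimum on target", {
  m <- calibrate_dip_depth(
    observer_model(congruency_delay_ms = 150, dip_center_ms = 400,
                   dip_width_ms = 80, p_asym = 0.93),
    target_min = 0.16)
  expect_equal(min(p_correct(m, seq(1, 1000), "incongruent")), 0.16,
               tolerance = 1e-6)
  expect_error(calibrate_dip_depth(observer_model(p_floor = 0.1), 0.3),
               "already at or below")
})

test_that("simulation is reproducible and matches its generative expectation", {
  spec <- design_spec(n_participants = 1, n_sessions = 1, blocks_per_session = 2,
                      trials_per_block = 132, practice_blocks = 0)
  d <- build_design(spec, seed = 5)
  m <- observer_model()
  t1 <- simulate_trials(d, m, seed = 9)
  t2 <- simulate_trials(d, m, seed = 9)
  expect_identical(t1, t2)

  # large single-cell simulation against the exact generative expectation:
  # guessing below threshold, Bernoulli(p_correct) above
  big <- design_spec(n_participants = 1, n_sessions = 1, blocks_per_session = 1,
                     trials_per_block = 50000, gap_levels_ms = 400,
                     fixation_levels_ms = 400, practice_blocks = 0)
  db <- build_design(big, seed = 6)
  tb <- simulate_trials(db, m, seed = 7)
  inc <- tb[tb$congruency == "incongruent", ]
  rpt <- inc$rt_ms - inc$gap_ms
  p_gen <- ifelse(rpt < m$guess_threshold_ms, 0.5,
                  p_correct(m, pmax(rpt, m$guess_threshold_ms), "incongruent"))
  se <- sqrt(mean(p_gen * (1 - p_gen)) / nrow(inc))
  expect_lt(abs(mean(inc$correct) - mean(p_gen)), 3 * se)

  # RT draws honor the truncation bounds
  expect_true(all(tb$rt_ms >= m$rt_min_ms & tb$rt_ms <= m$rt_max_ms))
  expect_identical(tb$on_time, as.integer(tb$rt_ms <= 1000))
})

test_that("a flat observer produces chance accuracy overall", {
  spec <- design_spec(n_participants = 1, n_sessions = 1, blocks_per_session = 8,
                      trials_per_block = 132, practice_blocks = 0)
  d <- build_design(spec, seed = 2)
  flat <- observer_model(p_floor = 0.5, p_asym = 0.5)
  tr <- simulate_trials(d, flat, seed = 3)
  se <- sqrt(0.25 / nrow(tr))
  expect_lt(abs(mean(tr$correct) - 0.5), 3 * se)
})

test_that("per-SOA observer lists give each SOA condition its own behavior", {
  spec3 <- preset("exp3")$design
  spec3$n_participants <- 1L
  spec3$n_sessions <- 1L
  d <- build_design(spec3, seed = 4)
  obs <- preset("exp3")$observer
  tr <- simulate_trials(d, obs, seed = 5)
  expect_identical(sort(unique(tr$soa_ms)), c(0, 120))
  # the dip model only acts on the 120-SOA incongruent trials: accuracy in the
  # dip window is far lower there
  tr$rpt <- tr$rt_ms - tr$gap_ms - tr$soa_ms
  win <- tr$rpt > 330 & tr$rpt < 470 & tr$congruency == "incongruent"
  acc0 <- mean(tr$correct[win & tr$soa_ms == 0])
  acc120 <- mean(tr$correct[win & tr$soa_ms == 120])
  expect_gt(acc0 - acc120, 0.2)
  expect_error(simulate_trials(d, list("0" = observer_model()), seed = 1),
               "every SOA level")
})

test_that("guessing hand bias shifts responses but not accuracy under balance", {
  d <- build_design(design_spec(n_participants = 1, n_sessions = 1,
                                blocks_per_session = 6, practice_blocks = 0),
                    seed = 8)
  biased <- observer_model(hand_bias = 0.9)
  tr <- simulate_trials(d, biased, seed = 9)
  guess <- (tr$rt_ms - tr$gap_ms) < 0
  skip_if(sum(guess) < 50)
  expect_gt(mean(tr$response[guess] == "right"), 0.8)
  se <- sqrt(0.25 / sum(guess))
  expect_lt(abs(mean(tr$correct[guess]) - 0.5), 4 * se)
})
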