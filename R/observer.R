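#' Parametric observer model for accuracy as a function of processing time
#'
#' The observer's probability of a correct response is a function of the raw
#' processing time rPT (how long the target has been visible when the response
#' is committed):
#'
#' \deqn{p(rPT) = p_{floor} + (p_{asym} - p_{floor}) \, S\!\left(\frac{rPT - m - \delta\,[inc]}{s}\right)
#'   - d \, G(rPT;\, c, w)\,[inc] - \ell \,(rPT - t_0)_+}
#'
#' with `S` a logistic rise from guessing (`p_floor`, nominally 0.5) to the
#' asymptote `p_asym`, an additive rightward shift `congruency_delay_ms` of the
#' rise for incongruent flankers, an optional Gaussian accuracy dip (depth
#' `dip_depth`, center `dip_center_ms`, width `dip_width_ms`) acting on
#' incongruent trials only, and an optional linear late decline. The evaluated
#' probability is clipped to \[0.001, 0.999\].
#'
#' Response times are drawn from a deadline-anchored truncated normal,
#' independent of the gap, so that realized rPT = RT - gap - SOA spans the
#' analysis window across the gap levels.
#'
#' @param p_floor guessing accuracy (default 0.5).
#' @param hand_bias probability of choosing the dominant-hand (right) response
#'   when guessing (rPT below `guess_threshold_ms`); 0.5 = unbiased.
#' @param p_asym asymptotic accuracy.
#' @param rise_mid_ms rPT at half-rise (ms), congruent condition.
#' @param rise_scale_ms logistic rise scale (ms).
#' @param congruency_delay_ms additive shift of the half-rise for incongruent
#'   trials (ms).
#' @param dip_depth amplitude of the below-chance accuracy dip (incongruent
#'   trials only); 0 disables the dip.
#' @param dip_center_ms rPT of the dip center (ms).
#' @param dip_width_ms Gaussian SD of the dip (ms).
#' @param late_decline_per_ms linear accuracy loss per ms beyond
#'   `late_onset_ms` (default 0 = off).
#' @param late_onset_ms rPT where the late decline starts (ms).
#' @param guess_threshold_ms rPT below which the response is a pure guess
#'   governed by `hand_bias` (ms).
#' @param rt_mean_ms,rt_sd_ms mean and SD of the truncated-normal response-time
#'   distribution (ms from Go-signal).
#' @param rt_min_ms,rt_max_ms truncation bounds of the RT distribution (ms).
#' @return An object of class `observer_model`.
#' @seealso [p_correct()], [simulate_trials()], [calibrate_dip_depth()]
#' @export
observer_model <- function(p_floor = 0.5,
                           hand_bias = 0.5,
                           p_asym = 0.95,
                           rise_mid_ms = 350,
                           rise_scale_ms = 60,
                           congruency_delay_ms = 50,
                           dip_depth = 0,
                           dip_center_ms = 400,
                           dip_width_ms = 80,
                           late_decline_per_ms = 0,
                           late_onset_ms = 800,
                           guess_threshold_ms = 0,
                           rt_mean_ms = 800,
                           rt_sd_ms = 150,
                           rt_min_ms = 100,
                           rt_max_ms = 1300) {
  m <- structure(list(
    p_floor = p_floor, hand_bias = hand_bias, p_asym = p_asym,
    rise_mid_ms = rise_mid_ms, rise_scale_ms = rise_scale_ms,
    congruency_delay_ms = congruency_delay_ms,
    dip_depth = dip_depth, dip_center_ms = dip_center_ms,
    dip_width_ms = dip_width_ms,
    late_decline_per_ms = late_decline_per_ms, late_onset_ms = late_onset_ms,
    guess_threshold_ms = guess_threshold_ms,
    rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
    rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms
  ), class = "observer_model")
  validate_observer_model(m)
  m
}

validate_observer_model <- function(m) {
  with(m, {
    if (!(p_floor >= 0 && p_floor <= p_asym && p_asym <= 1))
      stop("need 0 <= p_floor <= p_asym <= 1", call. = FALSE)
    if (dip_depth < 0) stop("dip_depth must be >= 0", call. = FALSE)
    if (hand_bias < 0 || hand_bias > 1) stop("hand_bias must be in [0, 1]", call. = FALSE)
    if (rise_scale_ms <= 0 || dip_width_ms <= 0) stop("scales must be positive", call. = FALSE)
    if (rt_sd_ms <= 0 || rt_min_ms >= rt_max_ms) stop("invalid RT distribution", call. = FALSE)
  })
  invisible(m)
}

#' @export
print.observer_model <- function(x, ...) {
  cat("<observer_model>\n")
  cat(sprintf("  floor %.3g -> asymptote %.3g; half-rise %g ms (scale %g), incongruent +%g ms\n",
              x$p_floor, x$p_asym, x$rise_mid_ms, x$rise_scale_ms, x$congruency_delay_ms))
  if (x$dip_depth > 0)
    cat(sprintf("  dip: depth %.3g at %g ms (width %g ms), incongruent only\n",
                x$dip_depth, x$dip_center_ms, x$dip_width_ms))
  cat(sprintf("  RT ~ truncnorm(%g, %g) on [%g, %g] ms\n",
              x$rt_mean_ms, x$rt_sd_ms, x$rt_min_ms, x$rt_max_ms))
  invisible(x)
}

#' Probability of a correct response at a given raw processing time
#'
#' Evaluates the observer's generative accuracy curve; deterministic in its
#' arguments. See [observer_model()] for the functional form.
#'
#' @param model an [observer_model()].
#' @param rpt_ms raw processing time(s), ms; vectorized.
#' @param congruency `"congruent"` or `"incongruent"` (scalar or vector).
#' @return Probabilities clipped to \[0.001, 0.999\].
#' @examples
#' m <- observer_model()
#' p_correct(m, c(-150, 300, 800), "congruent")
#' @export
p_correct <- function(model, rpt_ms, congruency = "congruent") {
  stopifnot(inherits(model, "observer_model"), all(is.finite(rpt_ms)))
  inc <- as.numeric(congruency == "incongruent")
  mid <- model$rise_mid_ms + model$congruency_delay_ms * inc
  p <- model$p_floor +
    (model$p_asym - model$p_floor) * stats::plogis((rpt_ms - mid) / model$rise_scale_ms)
  if (model$dip_depth > 0)
    p <- p - model$dip_depth * inc *
      exp(-0.5 * ((rpt_ms - model$dip_center_ms) / model$dip_width_ms)^2)
  if (model$late_decline_per_ms > 0)
    p <- p - model$late_decline_per_ms * pmax(0, rpt_ms - model$late_onset_ms)
  clip01(p, 0.001, 0.999)
}

#' Size the accuracy dip so the generative curve bottoms out at a target value
#'
#' Solves for `dip_depth` such that the minimum of the incongruent
#' `p_correct` curve over rPT > `restriction_ms` equals `target_min`,
#' evaluated on a 1-ms grid. Used by the bundled `exp3` asymmetry preset to
#' place the generative minimum at 0.16.
#'
#' @param model an [observer_model()]; its `dip_depth` is ignored.
#' @param target_min desired restricted minimum of the incongruent curve.
#' @param restriction_ms lower rPT bound of the minimum search (default 0).
#' @param grid_ms evaluation grid (default 1-ms steps over (0, 1000\]).
#' @return The input model with `dip_depth` set to the calibrated value.
#' @export
calibrate_dip_depth <- function(model, target_min = 0.16, restriction_ms = 0,
                                grid_ms = seq(restriction_ms + 1, 1000)) {
  stopifnot(target_min > 0.001, target_min < 1)
  f <- function(d) {
    m <- model
    m$dip_depth <- d
    min(p_correct(m, grid_ms, "incongruent")) - target_min
  }
  if (f(0) <= 0)
    stop("curve already at or below target_min without a dip", call. = FALSE)
  sol <- stats::uniroot(f, c(0, 1), tol = 1e-9)
  model$dip_depth <- sol$root
  validate_observer_model(model)
  model
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate trial outcomes from an observer model
#'
#' Fills a design skeleton from [build_design()] with response times,
#' responses, and correctness. RTs are drawn from the model's
#' deadline-anchored truncated normal independent of the gap. For trials whose
#' realized rPT = RT - gap - SOA falls below the model's guessing threshold the
#' response is a guess (dominant-hand response with probability `hand_bias`);
#' otherwise correctness is Bernoulli with probability
#' `p_correct(model, rPT, congruency)` and the response is derived from the
#' target mapping.
#'
#' @param design trial skeleton from [build_design()].
#' @param model an [observer_model()], or a named list of observer models keyed
#'   by SOA level (names = SOA in ms, e.g. `list("0" = m0, "120" = m120)`) to
#'   give each SOA condition its own behavior.
#' @param seed integer seed; same seed, same table.
#' @return The design data.frame with columns `response`, `rt_ms`, `correct`,
#'   `on_time` appended.
#' @examples
#' d <- build_design(design_spec(n_participants = 1, n_sessions = 1), seed = 1)
#' trials <- simulate_trials(d, observer_model(), seed = 2)
#' mean(trials$correct)
#' @export
simulate_trials <- function(design, model, seed = 1L) {
  spec <- attr(design, "spec")
  deadline <- if (!is.null(spec)) spec$deadline_ms else 1000
  models <- if (inherits(model, "observer_model")) {
    soas <- sort(unique(design$soa_ms))
    stats::setNames(rep(list(model), length(soas)), as.character(soas))
  } else {
    stopifnot(is.list(model), all(vapply(model, inherits, TRUE, "observer_model")))
    if (!all(as.character(unique(design$soa_ms)) %in% names(model)))
      stop("model list must name every SOA level in the design", call. = FALSE)
    model
  }
  local_rng(seed)
  n <- nrow(design)
  out <- design

  # RT parameters may differ per SOA model; draw per group to stay reproducible
  out$rt_ms <- NA_real_
  out$correct <- NA_integer_
  out$response <- NA_character_
  for (soa in names(models)) {
    m <- models[[soa]]
    idx <- which(as.character(out$soa_ms) == soa)
    rt <- rtruncnorm(length(idx), m$rt_mean_ms, m$rt_sd_ms, m$rt_min_ms, m$rt_max_ms)
    rpt <- rt - out$gap_ms[idx] - out$soa_ms[idx]
    guess <- rpt < m$guess_threshold_ms
    resp <- character(length(idx))
    corr <- integer(length(idx))
    if (any(guess)) {
      resp[guess] <- ifelse(stats::runif(sum(guess)) < m$hand_bias, "right", "left")
      corr[guess] <- as.integer(resp[guess] == out$target[idx][guess])
    }
    if (any(!guess)) {
      p <- p_correct(m, rpt[!guess], out$congruency[idx][!guess])
      corr[!guess] <- stats::rbinom(sum(!guess), 1L, p)
      tgt <- out$target[idx][!guess]
      resp[!guess] <- ifelse(corr[!guess] == 1L, tgt,
                             ifelse(tgt == "left", "right", "left"))
    }
    out$rt_ms[idx] <- rt
    out$correct[idx] <- corr
    out$response[idx] <- resp
  }
  out$on_time <- as.integer(out$rt_ms <= deadline)
  attr(out, "spec") <- spec
  out
}
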