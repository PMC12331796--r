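#' Analysis configuration
#'
#' Bundles every tunable of the tachometric pipeline. All stages derive their
#' RNG streams from the one master `seed`, so a config determines the full
#' report byte for byte.
#'
#' @param trials a trial data.frame, or a character vector of CSV paths read
#'   with [read_trials()]; mutually exclusive with `preset_name`.
#' @param preset_name simulate the data from a bundled preset instead (see
#'   [preset()]).
#' @param window_ms closed rPT analysis window (ms).
#' @param span loess span.
#' @param degree local polynomial degree.
#' @param surface `"interpolate"` or `"direct"` (see [smooth_curve()]).
#' @param restriction_ms lower rPT bound for minima.
#' @param n_perm permutations per test.
#' @param n_boot bootstrap resamples per minimum.
#' @param bf_bin_width_ms Bayes-factor bin width (ms).
#' @param bf_prior_scale logistic prior scale on the log-odds.
#' @param seed master integer seed.
#' @param out_dir optional output directory for tables, report and figures.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(trials = NULL, preset_name = NULL,
                            window_ms = c(-200, 1000), span = 0.2, degree = 2,
                            surface = "interpolate", restriction_ms = 0,
                            n_perm = 1000, n_boot = 1000,
                            bf_bin_width_ms = 100, bf_prior_scale = 0.5,
                            seed = 1L, out_dir = NULL) {
  if (is.null(trials) && is.null(preset_name))
    stop("provide either trials or preset_name", call. = FALSE)
  stopifnot(span > 0, degree %in% 0:2, n_perm >= 1, n_boot >= 1,
            bf_bin_width_ms > 0, bf_prior_scale > 0,
            restriction_ms >= window_ms[1])
  structure(list(trials = trials, preset_name = preset_name,
                 window_ms = window_ms, span = span, degree = degree,
                 surface = surface, restriction_ms = restriction_ms,
                 n_perm = n_perm, n_boot = n_boot,
                 bf_bin_width_ms = bf_bin_width_ms,
                 bf_prior_scale = bf_prior_scale,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

config_fingerprint <- function(config) {
  keep <- config[setdiff(names(config), c("trials", "out_dir"))]
  keep$n_trials_in <- if (is.data.frame(config$trials)) nrow(config$trials) else
    config$trials
  config_hash(jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA,
                               null = "null"))
}

#' Run the full tachometric analysis
#'
#' Executes, per condition group (congruency, crossed with SOA level when the
#' data contain more than one), the complete scheme: rPT computation and
#' window filtering (the SOA-corrected rPT = RT - gap - SOA throughout),
#' 1-ms binning, loess smoothing, restricted curve minimum with bootstrap SE,
#' permutation test of the minimum against chance, binomial chance band with
#' exceedance intervals, and binned Bayes factors. Between conditions (within
#' each SOA level) the minima difference is tested by relabeling permutation;
#' with two SOA levels the incongruent minima are additionally compared across
#' SOA.
#'
#' @param config an [analysis_config()].
#' @return An `experiment_report`: list with `groups` (per-group results
#'   including the curve), `comparisons`, `excluded`, `provenance`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  trials <- if (!is.null(config$preset_name)) {
    simulate_preset(config$preset_name, seed = config$seed)
  } else if (is.character(config$trials)) {
    do.call(rbind, lapply(config$trials, read_trials))
  } else config$trials
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("no input trials", call. = FALSE)
  for (cc in c("congruency", "gap_ms", "rt_ms", "correct"))
    if (!cc %in% names(trials))
      stop("input trials lack required column: ", cc, call. = FALSE)

  trials <- add_rpt(trials)
  filtered <- filter_trials(trials, config$window_ms)
  excluded <- attr(filtered, "excluded")
  if (nrow(filtered) == 0) stop("no trials left after filtering", call. = FALSE)

  soas <- sort(unique(filtered$soa_ms))
  use_soa <- length(soas) > 1
  conditions <- sort(unique(filtered$congruency))

  groups <- list()
  gi <- 0L
  for (soa in soas) {
    for (cond in conditions) {
      gi <- gi + 1L
      sel <- filtered$congruency == cond & filtered$soa_ms == soa
      recs <- filtered[sel, , drop = FALSE]
      label <- if (use_soa) sprintf("%s_soa%g", cond, soa) else cond
      if (nrow(recs) == 0)
        stop("empty group: ", label, call. = FALSE)
      curve <- trials_to_curve(recs, span = config$span, condition = label,
                               window_ms = config$window_ms,
                               degree = config$degree,
                               surface = config$surface)
      band <- chance_band(curve)
      gseed <- config$seed + 7L * gi
      pos <- curve$rpt_ms > config$restriction_ms
      ex_restricted <- band_exceedance(curve[pos, , drop = FALSE],
                                       band[pos, , drop = FALSE])
      groups[[label]] <- list(
        label = label, condition = cond, soa_ms = soa, n_trials = nrow(recs),
        records = recs, curve = curve, band = band,
        minimum = curve_minimum(curve, config$restriction_ms),
        boot_se = bootstrap_min_se(recs, n_boot = config$n_boot, seed = gseed,
                                   span = config$span, degree = config$degree,
                                   surface = config$surface,
                                   window_ms = config$window_ms,
                                   restriction_ms = config$restriction_ms),
        p_vs_chance = perm_test_min_vs_chance(
          recs, n_perm = config$n_perm, seed = gseed,
          span = config$span, degree = config$degree,
          surface = config$surface, window_ms = config$window_ms,
          restriction_ms = config$restriction_ms),
        exceedance = band_exceedance(curve, band),
        exceedance_restricted = ex_restricted,
        bf = bayes_factors(recs, bin_width_ms = config$bf_bin_width_ms,
                           prior_scale = config$bf_prior_scale,
                           window_ms = config$window_ms)
      )
      g <- groups[[label]]
      # a below-chance dip is called only when the curve leaves the band
      # downward within the interpretable region AND the permutation test
      # agrees; transient band crossings alone are not a dip
      groups[[label]]$dip_detected <-
        !is.null(ex_restricted$below) && g$p_vs_chance$p_value <= 0.05
    }
  }

  comparisons <- list()
  ci <- 0L
  for (soa in soas) {
    if (length(conditions) == 2) {
      ci <- ci + 1L
      a <- groups[[if (use_soa) sprintf("%s_soa%g", conditions[1], soa) else conditions[1]]]
      b <- groups[[if (use_soa) sprintf("%s_soa%g", conditions[2], soa) else conditions[2]]]
      lab <- if (use_soa) sprintf("%s_vs_%s_soa%g", conditions[1], conditions[2], soa) else
        sprintf("%s_vs_%s", conditions[1], conditions[2])
      comparisons[[lab]] <- perm_test_min_diff(
        a$records, b$records, n_perm = config$n_perm,
        seed = config$seed + 131L * ci,
        span = config$span, degree = config$degree, surface = config$surface,
        window_ms = config$window_ms, restriction_ms = config$restriction_ms)
    }
  }
  if (use_soa && "incongruent" %in% conditions && length(soas) >= 2) {
    a <- groups[[sprintf("incongruent_soa%g", soas[1])]]
    b <- groups[[sprintf("incongruent_soa%g", soas[2])]]
    comparisons[[sprintf("incongruent_soa%g_vs_soa%g", soas[1], soas[2])]] <-
      perm_test_min_diff(a$records, b$records, n_perm = config$n_perm,
                         seed = config$seed + 131L * (ci + 1L),
                         span = config$span, degree = config$degree,
                         surface = config$surface,
                         window_ms = config$window_ms,
                         restriction_ms = config$restriction_ms)
  }

  report <- structure(list(
    groups = groups, comparisons = comparisons,
    excluded = as.list(excluded),
    provenance = list(config_hash = config_fingerprint(config),
                      seed = config$seed, n_input = nrow(trials),
                      n_analyzed = nrow(filtered),
                      span = config$span, degree = config$degree,
                      surface = config$surface,
                      restriction_ms = config$restriction_ms,
                      n_perm = config$n_perm, n_boot = config$n_boot)
  ), class = "experiment_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  %d trials analyzed (%d excluded: %d practice, %d window)\n",
              x$provenance$n_analyzed,
              x$excluded$practice + x$excluded$window,
              x$excluded$practice, x$excluded$window))
  for (g in x$groups) {
    ex <- g$exceedance$below
    cat(sprintf("  %-24s n=%6d  min %.3f (SE %.3f) at %4g ms, p(vs chance) %.4g%s\n",
                g$label, g$n_trials, g$minimum$min_value, as.numeric(g$boot_se),
                g$minimum$argmin_rpt_ms, g$p_vs_chance$p_value,
                if (!is.null(ex)) sprintf(", below band %g..%g ms", ex[1], ex[2]) else ""))
  }
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  %-38s diff %+.3f, p = %.4g\n", nm, cmp$observed, cmp$p_value))
  }
  invisible(x)
}

report_tree <- function(report) {
  grp <- lapply(report$groups, function(g) list(
    label = g$label, condition = g$condition, soa_ms = g$soa_ms,
    n_trials = g$n_trials,
    minimum = list(value = g$minimum$min_value,
                   argmin_rpt_ms = g$minimum$argmin_rpt_ms,
                   restriction_ms = g$minimum$restriction_ms,
                   boot_se = as.numeric(g$boot_se)),
    p_vs_chance = list(p = g$p_vs_chance$p_value,
                       observed = g$p_vs_chance$observed,
                       sidedness = g$p_vs_chance$sidedness,
                       n_perm = g$p_vs_chance$n_permutations,
                       seed = g$p_vs_chance$seed),
    band_exceedance = lapply(g$exceedance, function(e)
      if (is.null(e)) NULL else as.list(e)),
    dip_detected = g$dip_detected,
    bayes_factors = g$bf[!g$bf$empty,
                         c("bin_start_ms", "bin_end_ms", "n", "k",
                           "log10_bf_below", "log10_bf_above")]
  ))
  cmp <- lapply(report$comparisons, function(p) list(
    observed_diff = p$observed, p = p$p_value, sidedness = p$sidedness,
    n_perm = p$n_permutations, seed = p$seed))
  list(groups = grp, comparisons = cmp, excluded = report$excluded,
       provenance = report$provenance)
}

#' Write an experiment report to disk
#'
#' Writes `curves.csv` (condition, rpt_ms, p_smooth, n_local, n_trials_bin),
#' `minima.csv`, `bayes_factors.csv` and a machine-readable `report.json`
#' (statistics, seeds, excluded-trial accounting, config hash). Deterministic:
#' the same report writes byte-identical files.
#'
#' @param report an `experiment_report` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curves <- do.call(rbind, lapply(report$groups, function(g) {
    data.frame(condition = g$label, g$curve[, c("rpt_ms", "p_smooth",
                                                "n_local", "n_trials_bin")])
  }))
  utils::write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE,
                   quote = FALSE)
  minima <- do.call(rbind, lapply(report$groups, function(g) {
    data.frame(condition = g$label, n_trials = g$n_trials,
               min_value = g$minimum$min_value,
               argmin_rpt_ms = g$minimum$argmin_rpt_ms,
               boot_se = as.numeric(g$boot_se),
               p_vs_chance = g$p_vs_chance$p_value)
  }))
  utils::write.csv(minima, file.path(dir, "minima.csv"), row.names = FALSE,
                   quote = FALSE)
  bf <- do.call(rbind, lapply(report$groups, function(g) {
    data.frame(condition = g$label, g$bf)
  }))
  utils::write.csv(bf, file.path(dir, "bayes_factors.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(report_tree(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, dataframe = "rows")
  invisible(dir)
}
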