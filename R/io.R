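#' Read and write trial tables
#'
#' Trial tables are comma-separated text with a header row (UTF-8, `.`
#' decimal) and exactly the columns `participant`, `session`, `block`,
#' `trial_in_block`, `is_practice`, `congruency`, `soa_ms`, `gap_ms`,
#' `fixation_ms`, `target`, `response`, `rt_ms`, `correct`, `on_time`.
#' `read_trials()` validates the schema (missing columns are named in the
#' error) and reports malformed rows with their file line numbers;
#' `write_trials()` writes a table that round-trips losslessly.
#'
#' @param path file path.
#' @param records trial data.frame.
#' @return `read_trials()`: the trial data.frame (zero rows for a header-only
#'   file); `write_trials()`: the path, invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols))
    stop("trial table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, trial_columns, drop = FALSE]
  if (nrow(df) == 0) {
    for (cc in names(trial_column_types))
      df[[cc]] <- vector(trial_column_types[[cc]], 0)
    return(df)
  }
  num_cols <- names(trial_column_types)[trial_column_types == "numeric"]
  int_cols <- names(trial_column_types)[trial_column_types == "integer"]
  bad <- rep(FALSE, nrow(df))
  for (cc in c(num_cols, int_cols)) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- bad | is.na(v)
    df[[cc]] <- v
  }
  lg <- tolower(df$is_practice)
  ok_lg <- lg %in% c("true", "false", "t", "f", "0", "1")
  bad <- bad | !ok_lg
  if (any(bad))
    stop("malformed rows in ", path, " at line(s): ",
         paste(utils::head(which(bad) + 1L, 20), collapse = ", "),
         " (header is line 1)", call. = FALSE)
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  df$is_practice <- lg %in% c("true", "t", "1")
  df
}

trial_columns <- c("participant", "session", "block", "trial_in_block",
                   "is_practice", "congruency", "soa_ms", "gap_ms",
                   "fixation_ms", "target", "response", "rt_ms", "correct",
                   "on_time")

trial_column_types <- c(participant = "character", session = "integer",
                        block = "integer", trial_in_block = "integer",
                        is_practice = "logical", congruency = "character",
                        soa_ms = "numeric", gap_ms = "numeric",
                        fixation_ms = "numeric", target = "character",
                        response = "character", rt_ms = "numeric",
                        correct = "integer", on_time = "integer")

#' @rdname read_trials
#' @export
write_trials <- function(records, path) {
  missing_cols <- setdiff(trial_columns, names(records))
  if (length(missing_cols))
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(records[, trial_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundled experiment presets
#'
#' Three presets mirror the study designs of the urgent flanker experiments:
#' `exp1` and `exp2` (5 sessions x 9 blocks x 132 trials; 11 gaps 0-950 ms,
#' SOA 0) and `exp3` (5 sessions x 4 blocks x 264 trials; SOA 0 or 120 ms).
#' Each preset bundles a [design_spec()] and observer behavior: `exp1`/`exp2`
#' use a no-dip observer (congruent and incongruent curves differ only by a
#' rise delay), while `exp3` gives the 120-ms SOA condition a processing
#' asymmetry: an accuracy dip centered at 400 ms rPT whose depth is calibrated
#' so the generative incongruent curve bottoms out at 0.16.
#'
#' @param name `"exp1"`, `"exp2"` or `"exp3"`.
#' @return list with elements `name`, `design` (a `design_spec`) and
#'   `observer` (an `observer_model`, or a named list per SOA level).
#' @examples
#' p <- preset("exp1")
#' p$design
#' @export
preset <- function(name = c("exp1", "exp2", "exp3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "tachometric",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  design <- do.call(design_spec, raw$design)
  build_observer <- function(pars) {
    target_min <- pars$dip_target_min
    pars$dip_target_min <- NULL
    m <- do.call(observer_model, pars)
    if (!is.null(target_min)) m <- calibrate_dip_depth(m, target_min)
    m
  }
  observer <- if (!is.null(raw$observer$soa_models)) {
    lapply(raw$observer$soa_models, build_observer)
  } else {
    build_observer(raw$observer)
  }
  list(name = name, design = design, observer = observer)
}

#' Simulate a full synthetic experiment from a preset
#'
#' Builds the preset's balanced design and simulates every trial from its
#' observer model(s). Design randomization and response generation use seeds
#' derived from the one master seed.
#'
#' @param name preset name, see [preset()].
#' @param seed master integer seed.
#' @param observer optional replacement observer model (or per-SOA list);
#'   default: the preset's.
#' @return Trial data.frame (with the `design_spec` attached as attribute
#'   `"spec"`).
#' @export
simulate_preset <- function(name, seed = 1L, observer = NULL) {
  p <- preset(name)
  d <- build_design(p$design, seed = stage_seed(seed, "design"))
  simulate_trials(d, observer %||% p$observer, seed = stage_seed(seed, "simulate"))
}
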