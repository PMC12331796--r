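#' Experimental design specification for an urgent flanker task
#'
#' A `design_spec` describes one experiment of the urgency paradigm: a fixed
#' response deadline anchored at the Go-signal, a variable gap between
#' Go-signal and target onset (long gaps = high urgency), congruent vs
#' incongruent flankers, two response-mapped targets, and (optionally) a
#' stimulus-onset asynchrony (SOA) between flanker and target onset.
#'
#' Within every block each cell of the factorial
#' gap x congruency x target x SOA (x fixation, when it divides evenly)
#' occurs equally often.
#'
#' @param n_participants number of participants.
#' @param n_sessions sessions per participant.
#' @param blocks_per_session blocks per session.
#' @param trials_per_block trials per block; must be an exact multiple of
#'   `length(gap_levels_ms) * 2 * 2 * length(soa_levels_ms)`.
#' @param gap_levels_ms gap durations (ms), non-negative, strictly increasing.
#' @param fixation_levels_ms fixation durations (ms).
#' @param soa_levels_ms flanker-to-target SOA levels (ms).
#' @param deadline_ms response deadline from the Go-signal (ms).
#' @param practice_blocks number of initial blocks of session 1 flagged as
#'   practice (excluded from analysis).
#'
#' @return An object of class `design_spec`.
#' @seealso [build_design()], [preset()]
#' @examples
#' spec <- design_spec()            # Experiments 1-2 layout
#' spec
#' @export
design_spec <- function(n_participants = 6,
                        n_sessions = 5,
                        blocks_per_session = 9,
                        trials_per_block = 132,
                        gap_levels_ms = c(seq(0, 900, by = 100), 950),
                        fixation_levels_ms = c(350, 400, 500),
                        soa_levels_ms = 0,
                        deadline_ms = 1000,
                        practice_blocks = 1) {
  spec <- structure(list(
    n_participants = as.integer(n_participants),
    n_sessions = as.integer(n_sessions),
    blocks_per_session = as.integer(blocks_per_session),
    trials_per_block = as.integer(trials_per_block),
    gap_levels_ms = as.numeric(gap_levels_ms),
    fixation_levels_ms = as.numeric(fixation_levels_ms),
    soa_levels_ms = as.numeric(soa_levels_ms),
    congruency_levels = c("congruent", "incongruent"),
    target_levels = c("left", "right"),
    deadline_ms = as.numeric(deadline_ms),
    practice_blocks = as.integer(practice_blocks)
  ), class = "design_spec")
  validate_design_spec(spec)
  spec
}

validate_design_spec <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  with(spec, {
    if (any(gap_levels_ms < 0) || is.unsorted(gap_levels_ms, strictly = TRUE))
      stop("gap_levels_ms must be non-negative and strictly increasing", call. = FALSE)
    if (deadline_ms <= 0) stop("deadline_ms must be positive", call. = FALSE)
    if (n_participants < 1 || n_sessions < 1 || blocks_per_session < 1)
      stop("counts must be >= 1", call. = FALSE)
    if (practice_blocks < 0 || practice_blocks > blocks_per_session)
      stop("practice_blocks must lie in [0, blocks_per_session]", call. = FALSE)
  })
  n_core <- n_design_cells(spec, with_fixation = FALSE)
  if (spec$trials_per_block %% n_core != 0L)
    stop(sprintf(
      "design infeasible: trials_per_block (%d) is not a multiple of the %d gap x congruency x target x SOA cells",
      spec$trials_per_block, n_core), call. = FALSE)
  invisible(spec)
}

n_design_cells <- function(spec, with_fixation = TRUE) {
  n <- length(spec$gap_levels_ms) * length(spec$congruency_levels) *
    length(spec$target_levels) * length(spec$soa_levels_ms)
  if (with_fixation) n <- n * length(spec$fixation_levels_ms)
  n
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>\n")
  cat(sprintf("  %d participants x %d sessions x %d blocks x %d trials\n",
              x$n_participants, x$n_sessions, x$blocks_per_session, x$trials_per_block))
  cat(sprintf("  gaps (ms): %s\n", paste(x$gap_levels_ms, collapse = ", ")))
  cat(sprintf("  SOA (ms): %s | fixation (ms): %s\n",
              paste(x$soa_levels_ms, collapse = ", "),
              paste(x$fixation_levels_ms, collapse = ", ")))
  cat(sprintf("  deadline: %g ms | practice blocks: %d\n",
              x$deadline_ms, x$practice_blocks))
  cat(sprintf("  => %d trials per participant, %d total\n",
              x$n_sessions * x$blocks_per_session * x$trials_per_block,
              x$n_participants * x$n_sessions * x$blocks_per_session * x$trials_per_block))
  invisible(x)
}

#' Build a randomized, balanced trial table (design skeleton)
#'
#' Expands a [design_spec()] into one row per trial, balanced within blocks and
#' randomized in presentation order. No responses are filled in; see
#' [simulate_trials()].
#'
#' Within each block the full factorial
#' gap x congruency x target x SOA is replicated an exact integer number of
#' times. When the fixation levels also divide the block evenly (as in all
#' three bundled presets) they are part of the replicated factorial; otherwise
#' fixation durations are assigned by balanced cycling. The first
#' `practice_blocks` blocks of session 1 are flagged `is_practice`.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed; the same seed reproduces the same trial order.
#' @return A data.frame with one row per trial and columns `participant`,
#'   `session`, `block`, `trial_in_block`, `is_practice`, `congruency`,
#'   `soa_ms`, `gap_ms`, `fixation_ms`, `target`; the `design_spec` is attached
#'   as attribute `"spec"`.
#' @examples
#' d <- build_design(design_spec(n_participants = 1, n_sessions = 1), seed = 1)
#' nrow(d)  # blocks_per_session * trials_per_block
#' @export
build_design <- function(spec, seed = 1L) {
  validate_design_spec(spec)
  rng <- local_rng(seed)

  n_full <- n_design_cells(spec, with_fixation = TRUE)
  n_core <- n_design_cells(spec, with_fixation = FALSE)
  use_full <- spec$trials_per_block %% n_full == 0L

  cells <- expand.grid(
    gap_ms = spec$gap_levels_ms,
    congruency = spec$congruency_levels,
    target = spec$target_levels,
    soa_ms = spec$soa_levels_ms,
    fixation_ms = if (use_full) spec$fixation_levels_ms else NA_real_,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  reps <- spec$trials_per_block / nrow(cells)

  one_block <- function() {
    blk <- cells[rep(seq_len(nrow(cells)), reps), , drop = FALSE]
    if (!use_full) {
      # balanced cycling of fixation levels over the shuffled core cells
      blk$fixation_ms <- rep_len(spec$fixation_levels_ms, nrow(blk))
    }
    blk[sample.int(nrow(blk)), , drop = FALSE]
  }

  out <- vector("list", spec$n_participants * spec$n_sessions * spec$blocks_per_session)
  i <- 0L
  for (p in seq_len(spec$n_participants)) {
    for (s in seq_len(spec$n_sessions)) {
      for (b in seq_len(spec$blocks_per_session)) {
        blk <- one_block()
        blk$participant <- sprintf("P%02d", p)
        blk$session <- s
        blk$block <- b
        blk$trial_in_block <- seq_len(nrow(blk))
        blk$is_practice <- s == 1L && b <= spec$practice_blocks
        i <- i + 1L
        out[[i]] <- blk
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[, c("participant", "session", "block", "trial_in_block", "is_practice",
                 "congruency", "soa_ms", "gap_ms", "fixation_ms", "target")]
  attr(out, "spec") <- spec
  out
}
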