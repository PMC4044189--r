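#' Block-design protocol parameters
#'
#' Defaults describe the experiment protocol: four coherence conditions
#' (0%, 33%, 66%, 100%) in 16 s blocks, four counterbalanced sequences per
#' run each followed by a 16 s blank block, a 6 s blank prepended and a
#' 16 s blank appended, TR = 2 s, 12 runs per participant, and the first
#' three volumes of each run censored in the analysis.
#'
#' @param n_conditions Number of stimulus conditions.
#' @param block_duration Block duration (seconds); must be a multiple of
#'   `tr`.
#' @param sequences_per_run Number of condition sequences per run.
#' @param pre_blank Blank period prepended to the run (seconds).
#' @param blank_appended Whether a final blank block is appended.
#' @param tr Repetition time (seconds per volume).
#' @param n_runs Runs per participant.
#' @param censor_volumes_per_run Leading volumes dropped from each run in
#'   the analysis.
#' @return An object of class `block_protocol`.
#' @export
block_protocol <- function(n_conditions = 4, block_duration = 16,
                           sequences_per_run = 4, pre_blank = 6,
                           blank_appended = TRUE, tr = 2, n_runs = 12,
                           censor_volumes_per_run = 3) {
  stopifnot(n_conditions >= 2, tr > 0, n_runs >= 1,
            censor_volumes_per_run >= 0)
  if (block_duration %% tr != 0 || pre_blank %% tr != 0) {
    stop("block and blank durations must be integer multiples of the TR",
         call. = FALSE)
  }
  structure(
    list(n_conditions = as.integer(n_conditions),
         block_duration = block_duration,
         sequences_per_run = as.integer(sequences_per_run),
         pre_blank = pre_blank, blank_appended = isTRUE(blank_appended),
         tr = tr, n_runs = as.integer(n_runs),
         censor_volumes_per_run = as.integer(censor_volumes_per_run)),
    class = "block_protocol")
}

#' Condition labels for a protocol
#'
#' Coherence conditions are labeled `c0`, `c33`, `c66`, `c100` for the
#' default four-level protocol, `c1 ... cn` otherwise.
#'
#' @param protocol A [block_protocol()].
#' @return Character vector of condition labels (excluding `blank`).
#' @export
condition_labels <- function(protocol) {
  if (protocol$n_conditions == 4L) c("c0", "c33", "c66", "c100")
  else paste0("c", seq_len(protocol$n_conditions))
}

#' First-order counterbalanced condition sequences
#'
#' Returns `n_conditions` sequences, each a permutation of all conditions,
#' such that across all within-sequence adjacent pairs every ordered pair
#' of distinct conditions occurs exactly once (a row-complete, Williams-type
#' arrangement): every condition is immediately preceded by every other
#' condition equally often. The arrangement is randomized by uniformly
#' relabeling conditions and shuffling sequence order.
#'
#' @param n_conditions Number of conditions (even; no n-row row-complete
#'   arrangement exists for small odd n).
#' @return A list of `n_conditions` integer vectors (condition indices).
#' @export
counterbalanced_orders <- function(n_conditions) {
  n <- as.integer(n_conditions)
  if (n < 2) stop("need at least 2 conditions", call. = FALSE)
  if (n %% 2 != 0) {
    stop("no single row-complete arrangement of ", n,
         " sequences exists for odd n; use an even condition count",
         call. = FALSE)
  }
  # Williams' construction: base row 1, 2, n, 3, n-1, ... then cyclic shifts
  base <- integer(n)
  base[1] <- 1L
  lo <- 2L; hi <- n
  for (k in 2:n) {
    if (k %% 2 == 0) { base[k] <- lo; lo <- lo + 1L }
    else             { base[k] <- hi; hi <- hi - 1L }
  }
  rows <- lapply(0:(n - 1L), function(s) (base + s - 1L) %% n + 1L)
  relabel <- sample.int(n)
  rows <- lapply(rows, function(r) relabel[r])
  rows[sample.int(n)]
}

#' Build the timeline of one run
#'
#' The run is a prepended blank period, then each condition sequence as
#' stimulus blocks followed by one blank block, then (optionally) a final
#' appended blank block. For the default protocol this gives
#' 6 + 4 x (4 + 1) x 16 + 16 = 342 s, i.e. 171 volumes at TR = 2 s.
#'
#' @param protocol A [block_protocol()].
#' @param orders A list of condition-index sequences, e.g. from
#'   [counterbalanced_orders()]; its length must equal
#'   `protocol$sequences_per_run`.
#' @return An object of class `run_timeline`: a list with `blocks` (data
#'   frame of `onset`, `duration`, `condition`), `total_duration`,
#'   `n_volumes`, `tr`, and `conditions` (the stimulus labels).
#' @export
build_run_timeline <- function(protocol, orders) {
  stopifnot(inherits(protocol, "block_protocol"))
  if (length(orders) != protocol$sequences_per_run) {
    stop("expected ", protocol$sequences_per_run, " sequences, got ",
         length(orders), call. = FALSE)
  }
  labels <- condition_labels(protocol)
  cond_seq <- character(0)
  for (ord in orders) {
    if (length(ord) != protocol$n_conditions || !setequal(ord, seq_along(labels))) {
      stop("each sequence must be a permutation of all conditions",
           call. = FALSE)
    }
    cond_seq <- c(cond_seq, labels[ord], "blank")
  }
  if (protocol$blank_appended) cond_seq <- c(cond_seq, "blank")
  onsets <- protocol$pre_blank +
    protocol$block_duration * (seq_along(cond_seq) - 1)
  total <- protocol$pre_blank + protocol$block_duration * length(cond_seq)
  structure(
    list(blocks = data.frame(onset = onsets,
                             duration = protocol$block_duration,
                             condition = cond_seq),
         total_duration = total,
         n_volumes = as.integer(total / protocol$tr),
         tr = protocol$tr,
         conditions = labels),
    class = "run_timeline")
}

#' @export
print.run_timeline <- function(x, ...) {
  cat(sprintf("Run timeline: %d blocks, %g s (%d volumes at TR = %g s)\n",
              nrow(x$blocks), x$total_duration, x$n_volumes, x$tr))
  print(utils::head(x$blocks, 8))
  if (nrow(x$blocks) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.run_timeline <- function(x, ...) x$blocks

#' Onsets of all blocks of one condition
#'
#' @param timeline A [build_run_timeline()] result.
#' @param condition A condition label present in the timeline's protocol
#'   (`blank` included).
#' @return Numeric vector of onsets (seconds), in order.
#' @export
condition_onsets <- function(timeline, condition) {
  stopifnot(inherits(timeline, "run_timeline"))
  if (!condition %in% c(timeline$conditions, "blank")) {
    stop("unknown condition label: ", condition, call. = FALSE)
  }
  timeline$blocks$onset[timeline$blocks$condition == condition]
}

#' Within-run stimulus block transition counts
#'
#' Counts ordered condition-to-condition adjacencies within each sequence
#' (blank blocks break adjacency chains). For one run of a first-order
#' counterbalanced protocol, every off-diagonal entry is 1 and the
#' diagonal is 0.
#'
#' @param timeline A `run_timeline`.
#' @return Square integer matrix (from-condition rows, to-condition
#'   columns).
#' @export
transition_matrix <- function(timeline) {
  stopifnot(inherits(timeline, "run_timeline"))
  labels <- timeline$conditions
  k <- length(labels)
  tm <- matrix(0L, k, k, dimnames = list(from = labels, to = labels))
  conds <- timeline$blocks$condition
  for (i in seq_len(length(conds) - 1L)) {
    a <- conds[i]; b <- conds[i + 1L]
    if (a != "blank" && b != "blank") {
      tm[a, b] <- tm[a, b] + 1L
    }
  }
  tm
}

#' Write a run timeline as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type`.
#'
#' @param timeline A `run_timeline`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(timeline, path) {
  stopifnot(inherits(timeline, "run_timeline"))
  ev <- data.frame(onset = timeline$blocks$onset,
                   duration = timeline$blocks$duration,
                   trial_type = timeline$blocks$condition)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
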