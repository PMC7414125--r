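#' Stimulus train
#'
#' An ordered set of stimulus onsets with a common pulse duration. The
#' inter-stimulus intervals (ISIs) are the successive onset differences.
#'
#' @param onsets Strictly increasing onset times (ms).
#' @param pulse_dur Pulse duration (ms).
#' @param protocol Optional label describing the generating protocol.
#' @param meta Optional list of protocol parameters (seed, grids, ...).
#' @return An object of class `stimulus_train` with fields `onsets`, `isis`,
#'   `pulse_dur`, `protocol`, `meta`.
#' @export
stimulus_train <- function(onsets, pulse_dur = 10, protocol = "custom",
                           meta = list()) {
  if (length(onsets) < 1) stop("at least one onset required")
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("onsets must be strictly increasing")
  }
  structure(list(onsets = as.numeric(onsets), isis = diff(as.numeric(onsets)),
                 pulse_dur = as.numeric(pulse_dur), protocol = protocol,
                 meta = meta),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("Stimulus train (%s): %d onsets", x$protocol, length(x$onsets)))
  if (length(x$isis)) {
    cat(sprintf(", ISIs %g-%g ms", min(x$isis), max(x$isis)))
  }
  cat("\n")
  invisible(x)
}

#' Isochronous stimulus train
#'
#' @param isi Inter-stimulus interval (ms, > 0).
#' @param n Number of stimuli (>= 1).
#' @param start Onset of the first stimulus (ms).
#' @param pulse_dur Pulse duration (ms).
#' @return A [stimulus_train()].
#' @examples
#' make_isochronous(800, 3, start = 750)$onsets
#' @export
make_isochronous <- function(isi, n, start = 750, pulse_dur = 10) {
  stopifnot(isi > 0, n >= 1)
  stimulus_train(start + isi * (seq_len(n) - 1), pulse_dur,
                 protocol = "isochronous", meta = list(isi = isi, n = n))
}

#' Tracking-task stimulus train
#'
#' Five blocks of twenty ISIs. The first block is fixed at `base_isi`; each
#' later block's ISI is drawn at random (independently, with replacement)
#' from `grid`, a four-value discrete uniform distribution. The result is a
#' sequence of 100 intervals (101 onsets).
#'
#' @param seed RNG seed.
#' @param base_isi First-block ISI (ms).
#' @param grid ISI values for blocks 2-5 (ms).
#' @param n_blocks Number of blocks.
#' @param block_len Intervals per block.
#' @param start First onset (ms).
#' @return A [stimulus_train()] whose `meta` records the block ISIs.
#' @export
make_tracking_blocks <- function(seed = NULL, base_isi = 800,
                                 grid = c(600, 700, 800, 900),
                                 n_blocks = 5, block_len = 20, start = 750) {
  if (!is.null(seed)) set.seed(seed)
  block_isis <- c(base_isi, sample(grid, n_blocks - 1, replace = TRUE))
  isis <- rep(block_isis, each = block_len)
  stimulus_train(start + cumsum(c(0, isis)),
                 protocol = "tracking",
                 meta = list(seed = seed, block_isis = block_isis,
                             block_len = block_len, grid = grid))
}

#' Perturbation stimulus trains
#'
#' Thirty unperturbed ISIs precede each perturbation:
#' * `step`: 30 x 800 ms, then every subsequent ISI is 1000 ms.
#' * `phase_shift`: 30 x 500 ms, a single 600 ms ISI, then 500 ms; all
#'   post-perturbation onsets are shifted by +100 ms relative to the original
#'   grid.
#' * `jitter`: 30 x 500 ms, then 600 ms followed by 400 ms, then 500 ms; the
#'   later stimuli fall back in phase with the original grid.
#'
#' @param kind One of `"step"`, `"phase_shift"`, `"jitter"`.
#' @param n_post Number of ISIs after the perturbation onset.
#' @param start First onset (ms).
#' @return A [stimulus_train()]; `meta$pert_index` is the index (into `isis`)
#'   of the first perturbed interval.
#' @export
make_perturbation <- function(kind = c("step", "phase_shift", "jitter"),
                              n_post = 15, start = 750) {
  kind <- match.arg(kind)
  isis <- switch(kind,
    step = c(rep(800, 30), rep(1000, n_post)),
    phase_shift = c(rep(500, 30), 600, rep(500, n_post - 1)),
    jitter = c(rep(500, 30), 600, 400, rep(500, n_post - 2)))
  stimulus_train(start + cumsum(c(0, isis)),
                 protocol = paste0("perturbation_", kind),
                 meta = list(kind = kind, pert_index = 31L, n_post = n_post))
}

#' Synchronization/continuation stimulus train
#'
#' Three flashes separated by the trial's ISI; the model then runs without
#' stimuli and is allowed to produce `n_continuation` more productions. The
#' ISI grid used across trials is a five-value discrete uniform distribution
#' spanning 550-817 ms (evenly spaced).
#'
#' @param isi Trial ISI (ms).
#' @param n_continuation Number of free productions after the last flash.
#' @param start First onset (ms).
#' @return A list with `train` (a [stimulus_train()]) and `n_continuation`.
#' @export
make_sync_cont <- function(isi, n_continuation = 17, start = 750) {
  stopifnot(isi > 0)
  list(train = stimulus_train(start + isi * 0:2, protocol = "sync_cont",
                              meta = list(isi = isi,
                                          n_continuation = n_continuation)),
       n_continuation = n_continuation)
}

#' ISI grid of the synchronization/continuation task
#'
#' Five evenly spaced values from 550 to 817 ms (rounded to the ms).
#'
#' @return Numeric vector of length 5.
#' @export
sync_cont_grid <- function() round(seq(550, 817, length.out = 5))

#' Read/write stimulus trains as event tables
#'
#' Plain-text, tab-separated tables with header `onset_ms` and
#' `duration_ms`. Values are preserved exactly as written.
#'
#' @param x A [stimulus_train()].
#' @param path File path.
#' @return `read_stimulus_train` returns a [stimulus_train()];
#'   `write_stimulus_train` returns `path` invisibly.
#' @export
write_stimulus_train <- function(x, path) {
  stopifnot(inherits(x, "stimulus_train"))
  df <- data.frame(onset_ms = x$onsets,
                   duration_ms = rep(x$pulse_dur, length(x$onsets)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_train
#' @export
read_stimulus_train <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = TRUE)
  if (!all(c("onset_ms", "duration_ms") %in% names(df))) {
    stop("malformed event table: expected columns onset_ms, duration_ms")
  }
  stimulus_train(df$onset_ms, pulse_dur = df$duration_ms[1],
                 protocol = "from_file", meta = list(path = path))
}
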