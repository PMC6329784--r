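#' Generate a block-randomized trial table
#'
#' Builds the event table of a full scanning session: for each modality
#' (tactile exploration, visual observation) there are \code{n_runs_per_modality}
#' runs, each containing \code{n_blocks} blocks of five trials in which every
#' roughness intensity appears exactly once in randomized order. Onsets follow
#' the session timing: a baseline period opens the run, trials are laid out
#' back to back, and within every trial the 3 s stimulation starts at a
#' modality-specific offset.
#'
#' @param n_runs_per_modality Number of runs per modality (default 3, giving
#'   6 runs and 150 trials under the default timing).
#' @param timing Timing list as produced by [default_timing()].
#' @param seed Integer seed controlling the within-block condition order, or
#'   \code{NULL} to use the current RNG state.
#' @param n_blocks Blocks per run (default 5).
#' @param modalities Character vector of modalities to generate; runs are
#'   numbered consecutively, first modality first.
#' @return A data frame with one row per trial and columns \code{run},
#'   \code{modality}, \code{block}, \code{trial}, \code{condition},
#'   \code{onset} and \code{duration} (seconds). Onsets are strictly
#'   increasing within a run; every block contains each condition once.
#' @examples
#' tt <- generate_trial_table(3, seed = 1)
#' nrow(tt)         # 150 trials: 6 runs x 5 blocks x 5 trials
#' table(tt$run)    # 25 per run
#' @export
generate_trial_table <- function(n_runs_per_modality = 3,
                                 timing = default_timing(),
                                 seed = NULL,
                                 n_blocks = 5,
                                 modalities = c("tactile", "visual")) {
  if (!is.numeric(n_runs_per_modality) || n_runs_per_modality < 1) {
    stop("`n_runs_per_modality` must be a positive integer")
  }
  n_runs_per_modality <- as.integer(n_runs_per_modality)
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 1)
  n_cond <- 5L

  with_seed(seed, {
    rows <- list()
    run_id <- 0L
    for (mod in modalities) {
      offset <- switch(mod,
        tactile = timing$stim_offset_tactile,
        visual = timing$stim_offset_visual,
        stop("unknown modality: ", mod)
      )
      for (r in seq_len(n_runs_per_modality)) {
        run_id <- run_id + 1L
        for (b in seq_len(n_blocks)) {
          order <- sample.int(n_cond)
          trial_in_run <- (b - 1L) * n_cond + seq_len(n_cond)
          rows[[length(rows) + 1L]] <- data.frame(
            run = run_id,
            modality = mod,
            block = b,
            trial = seq_len(n_cond),
            condition = order,
            onset = timing$baseline + (trial_in_run - 1L) * timing$trial + offset,
            duration = timing$stimulation,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "run_length") <- timing$baseline +
      n_blocks * n_cond * timing$trial
    out
  })
}

#' Read or write a BIDS-events-like TSV
#'
#' Trial tables are exchanged as tab-separated files with one row per trial
#' and the columns of [generate_trial_table()].
#'
#' @param trials Trial table data frame.
#' @param path File path.
#' @return `read_events_tsv` returns the trial table data frame;
#'   `write_events_tsv` returns `path` invisibly.
#' @export
write_events_tsv <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
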