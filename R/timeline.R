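#' Generate a block-design stimulus timeline
#'
#' Builds the block/event schedule of a texture-saliency run: stimulus blocks
#' of `block_s` seconds, each followed by a fixation gap of `fix_s` seconds,
#' with `events_per_block` brief texture presentations per block. Each event
#' lasts `stim_ms` and is followed by an inter-stimulus interval drawn
#' uniformly from `isi_choices_ms`; the final interval of every block is
#' truncated or padded so the last event slot ends exactly at the block
#' boundary. Condition order is balanced across blocks and the foreground side
#' is drawn uniformly per event.
#'
#' @param n_blocks Number of stimulus blocks; must be a multiple of
#'   `length(conditions)` (0 gives an empty timeline).
#' @param block_s Block duration in seconds.
#' @param fix_s Fixation gap after each block, seconds.
#' @param stim_ms Stimulus duration, milliseconds.
#' @param isi_choices_ms Vector of candidate inter-stimulus intervals, ms.
#' @param events_per_block Events per block.
#' @param conditions Orientation contrasts in degrees, e.g. `c(90, 15, 0)`.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param paired_tr Paired repetition time of the VASO acquisition, seconds.
#' @return A `stimulus_timeline`: list with `events` (tibble: onset, duration,
#'   isi, condition, side, block), `blocks` (tibble: start, end, condition),
#'   `run_duration` and `paired_tr`.
#' @examples
#' tl <- generate_block_design(6, 30, 15, 200, c(200, 300, 400), 60,
#'                             c(90, 15, 0), seed = 1)
#' tl$run_duration # 270
#' @export
generate_block_design <- function(n_blocks, block_s, fix_s, stim_ms,
                                  isi_choices_ms, events_per_block,
                                  conditions, seed,
                                  paired_tr = 5.02) {
  if (length(conditions) == 0) stop_invalid("conditions must be non-empty")
  if (n_blocks > 0 && (block_s <= 0 || fix_s <= 0 || stim_ms <= 0)) {
    stop_invalid("durations must be positive")
  }
  if (n_blocks %% length(conditions) != 0) {
    stop_invalid("n_blocks (%d) must be a multiple of the number of conditions (%d)",
                 n_blocks, length(conditions))
  }
  set.seed(seed)

  if (n_blocks == 0) {
    return(structure(list(
      events = tibble::tibble(onset = numeric(), duration = numeric(),
                              isi = numeric(), condition = numeric(),
                              side = character(), block = integer()),
      blocks = tibble::tibble(start = numeric(), end = numeric(),
                              condition = numeric()),
      run_duration = 0, paired_tr = paired_tr), class = "stimulus_timeline"))
  }

  # balanced condition order: each condition equally often, order shuffled
  cond_seq <- sample(rep(conditions, n_blocks / length(conditions)))
  block_start <- (seq_len(n_blocks) - 1) * (block_s + fix_s)
  block_end <- block_start + block_s

  ev <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    # balanced shuffle of the ISI menu: each choice appears (nearly) equally
    # often, so the schedule tiles the block when the mean slot length does
    # (60 x (200 + mean{200,300,400}) ms = 30 s); any residual misfit is
    # spread proportionally over the ISIs and the final slot is pinned to the
    # block boundary
    isi <- sample(rep_len(isi_choices_ms, events_per_block)) / 1000
    stim_s <- stim_ms / 1000
    budget <- block_s - events_per_block * stim_s
    if (budget <= 0) stop_invalid("events do not fit the block: %d x %g ms exceeds %g s",
                                  events_per_block, stim_ms, block_s)
    isi <- isi * budget / sum(isi)
    slot <- stim_s + isi
    onset <- block_start[b] + c(0, cumsum(slot[-events_per_block]))
    # pin the final slot end to the block boundary exactly
    isi[events_per_block] <- block_end[b] - onset[events_per_block] - stim_s
    ev[[b]] <- tibble::tibble(
      onset = onset,
      duration = stim_ms / 1000,
      isi = isi,
      condition = cond_seq[b],
      side = sample(c("left", "right"), events_per_block, replace = TRUE),
      block = b
    )
  }

  structure(list(
    events = do.call(rbind, ev),
    blocks = tibble::tibble(start = block_start, end = block_end,
                            condition = cond_seq),
    run_duration = n_blocks * (block_s + fix_s),
    paired_tr = paired_tr
  ), class = "stimulus_timeline")
}

#' @export
print.stimulus_timeline <- function(x, ...) {
  cat(sprintf("<stimulus_timeline> %d blocks, %d events, %.0f s, paired TR %.2f s\n",
              nrow(x$blocks), nrow(x$events), x$run_duration, x$paired_tr))
  invisible(x)
}

# condition label (or NA) for each time point, from block membership
condition_at_time <- function(timeline, times) {
  lab <- rep(NA_real_, length(times))
  for (i in seq_len(nrow(timeline$blocks))) {
    sel <- times >= timeline$blocks$start[i] & times < timeline$blocks$end[i]
    lab[sel] <- timeline$blocks$condition[i]
  }
  lab
}
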