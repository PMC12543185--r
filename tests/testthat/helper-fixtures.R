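# shared fixtures: the standard session timeline and a mid-range observer

std_timeline <- function(seed = 1, isi = c(200, 300, 400)) {
  generate_block_design(6, 30, 15, 200, isi, 60, c(90, 15, 0), seed = seed)
}

std_observer <- list(alpha = 0.05, beta = 3)

# a bare paired run object with chosen values (for unit tests of BOCO)
fake_run <- function(nulled, not_nulled, paired_tr = 5.02) {
  n_pairs <- ncol(nulled)
  structure(list(
    nulled = nulled, not_nulled = not_nulled, paired_tr = paired_tr,
    baseline = rowMeans(nulled),
    t_nulled = (seq_len(n_pairs) - 1) * paired_tr,
    t_not_nulled = (seq_len(n_pairs) - 1) * paired_tr + paired_tr / 2
  ), class = "paired_vaso_run")
}

# a gaze_trace wrapping explicit samples (already clean)
fake_trace <- function(x, y, condition = NA_real_) {
  structure(list(
    samples = tibble::tibble(t = seq_along(x), x = x, y = y, valid = TRUE,
                             condition = condition),
    blink_intervals = tibble::tibble(start = numeric(), end = numeric())
  ), class = "gaze_trace")
}

# independent recursive permutation enumerator (oracle for the max-statistic
# permutation test); distinct implementation from the package's
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}
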