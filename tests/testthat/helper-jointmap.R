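## Shared fixtures and independent oracles for the test suite.

default_seq <- function(...) sequence_params(...)
hr60 <- function(...) cardiac_timing(hr = 60, ...)

## Independent scalar event-list simulator of the 4-heartbeat block.
## Deliberately written as a plain per-pulse loop (no closed-form trains, no
## vectorisation) so it shares no code path with bloch_signals().
oracle_signals <- function(seq, timing, t1, t1rho, m0 = 1,
                           n_blocks = 60) {
  relax1 <- function(mz, dt) m0 + (mz - m0) * exp(-dt / t1)
  td <- timing$trigger_delay
  rr <- rep_len(timing$rr_intervals, 4 * n_blocks)
  tr <- seq$tr_imaging
  inav_len <- seq$n_inav_pulses * tr
  mz <- m0
  sig <- numeric(4)
  k <- 0
  for (b in seq_len(n_blocks)) {
    for (hb in 1:4) {
      k <- k + 1
      p <- seq$prep_pattern[hb]
      if (p == "IR") {
        mz <- relax1(mz, td - seq$ti)
        mz <- -seq$inversion_efficiency * mz
        mz <- relax1(mz, seq$ti - inav_len)
      } else if (p == "T1RHO") {
        mz <- relax1(mz, td - inav_len - seq$tsl)
        mz <- mz * exp(-seq$tsl / t1rho)
      } else {
        mz <- relax1(mz, td - inav_len)
      }
      for (i in seq_len(seq$n_inav_pulses)) {
        mz <- mz * cos(seq$fa_inav * pi / 180)
        mz <- relax1(mz, tr)
      }
      sig[hb] <- mz * sin(seq$fa_imaging * pi / 180)
      for (i in seq_len(seq$n_segments_per_hb)) {
        mz <- mz * cos(seq$fa_imaging * pi / 180)
        mz <- relax1(mz, tr)
      }
      mz <- relax1(mz, rr[k] - td - seq$n_segments_per_hb * tr)
    }
  }
  sig
}

## Exhaustive SSD matcher over all dictionary atoms (independent of the
## compiled inner-product kernel).
brute_force_match <- function(signal, dict) {
  s <- signal / sqrt(sum(signal^2))
  ssd <- colSums((t(dict$atoms) - s)^2)
  i <- which.min(ssd)
  list(t1 = dict$params$t1[i], t1rho = dict$params$t1rho[i],
       ssd = ssd[i], atom = i)
}

## small dictionary covering the test tissues, quick to generate
small_grid <- function() {
  dictionary_grid(t1_values = seq(100, 1500, 20),
                  t1rho_values = seq(10, 150, 4))
}

## complex white gaussian array
crnorm <- function(dims, sd = 1) {
  array(complex(real = stats::rnorm(prod(dims), 0, sd),
                imaginary = stats::rnorm(prod(dims), 0, sd)), dims)
}
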