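# Minimal hand-built networks used across solver tests.

# One segment acting as both root and outlet; a degenerate network for
# closed-form Windkessel checks (anatomical trees require >= 2 outlets, so
# this bypasses the constructor on purpose).
single_segment_tree <- function(length_cm = 1e-4, diameter_cm = 2) {
  df <- tibble::tibble(
    id = "s1", parent_id = NA_character_, name = "MPA",
    length_cm = length_cm, diameter_cm = diameter_cm, generation = 0L
  )
  structure(df, class = c("arterial_tree", class(tibble::tibble())))
}

constant_inflow <- function(Q, period = 1, n = 1000) {
  times <- seq(0, period, length.out = n + 1)[1:n]
  flow_waveform(times, rep(Q, n), period)
}

sinusoidal_inflow <- function(Q0, amp, period = 1, n = 1000) {
  times <- seq(0, period, length.out = n + 1)[1:n]
  flow_waveform(times, Q0 + amp * sin(2 * pi * times / period), period)
}

table2_control_rhc <- function() {
  rhc_record(mPAP = 18.0, sPAP = 28.0, dPAP = 12.0, PAWP = 10.0, CO = 5.20, HR = 75)
}
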