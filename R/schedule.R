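#' Build an intermittent theta-burst stimulation (iTBS) pulse schedule
#'
#' Encodes the canonical iTBS protocol: bursts of 3 pulses at `burst_rate_hz`,
#' bursts repeated at `burst_rep_rate_hz` for `train_duration_s`, trains
#' separated by `inter_train_interval_s`, with train onsets at
#' 0, train_duration + ITI, 2*(train_duration + ITI), ... for as long as the
#' onset does not exceed `session_duration_s`.  The defaults give the standard
#' low-intensity iTBS session: 20 trains of 30 pulses = 600 pulses over 190 s.
#'
#' @param burst_rate_hz Within-burst pulse rate (Hz); 3 pulses per burst.
#' @param burst_rep_rate_hz Burst repetition rate within a train (Hz).
#' @param train_duration_s Duration of each train (s).
#' @param inter_train_interval_s Gap between the end of one train and the
#'   onset of the next (s).
#' @param session_duration_s Latest permitted train onset time (s).
#' @param pulses_per_burst Pulses per burst (default 3, the theta-burst triplet).
#' @return An object of class `itbs_schedule`: a list with `pulse_times_s`
#'   (strictly increasing), `n_pulses`, `n_trains`, `pulses_per_train`, and the
#'   protocol parameters.
#' @examples
#' sched <- itbs_schedule()
#' sched$n_pulses   # 600
#' @export
itbs_schedule <- function(burst_rate_hz = 50,
                          burst_rep_rate_hz = 5,
                          train_duration_s = 2,
                          inter_train_interval_s = 8,
                          session_duration_s = 190,
                          pulses_per_burst = 3L) {
  stopifnot(burst_rate_hz > 0, burst_rep_rate_hz > 0,
            train_duration_s > 0, inter_train_interval_s >= 0,
            session_duration_s >= 0, pulses_per_burst >= 1)
  # a burst of k pulses at burst_rate must fit inside one burst period
  if (burst_rate_hz < pulses_per_burst * burst_rep_rate_hz) {
    stop("infeasible protocol: burst_rate_hz < pulses_per_burst * burst_rep_rate_hz (bursts overlap)")
  }
  period <- train_duration_s + inter_train_interval_s
  train_onsets <- seq(0, session_duration_s, by = period)
  bursts_per_train <- round(train_duration_s * burst_rep_rate_hz)
  burst_offsets <- (seq_len(bursts_per_train) - 1) / burst_rep_rate_hz
  pulse_offsets <- (seq_len(pulses_per_burst) - 1) / burst_rate_hz
  pulse_times <- as.vector(outer(
    pulse_offsets,
    as.vector(outer(burst_offsets, train_onsets, `+`)),
    `+`
  ))
  pulse_times <- sort(pulse_times)
  stopifnot(all(diff(pulse_times) > 0))
  structure(list(
    pulse_times_s = pulse_times,
    n_pulses = length(pulse_times),
    n_trains = length(train_onsets),
    pulses_per_train = bursts_per_train * pulses_per_burst,
    burst_rate_hz = burst_rate_hz,
    burst_rep_rate_hz = burst_rep_rate_hz,
    train_duration_s = train_duration_s,
    inter_train_interval_s = inter_train_interval_s,
    session_duration_s = session_duration_s,
    pulses_per_burst = as.integer(pulses_per_burst)
  ), class = "itbs_schedule")
}

#' @export
print.itbs_schedule <- function(x, ...) {
  cat(sprintf(
    "iTBS schedule: %d pulses (%d trains x %d pulses), %g Hz bursts @ %g Hz, %g s trains, %g s ITI\n",
    x$n_pulses, x$n_trains, x$pulses_per_train,
    x$burst_rate_hz, x$burst_rep_rate_hz, x$train_duration_s,
    x$inter_train_interval_s))
  invisible(x)
}
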