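#' Simulate a plastic theta-neuron network
#'
#' Integrates the coupled phase equations for `duration` time units with
#' the compiled Heun (Stratonovich-consistent) scheme, applying one Euler
#' step of the plasticity rule per time step. Records Kuramoto-Daido order
#' parameters, spike times, weight/phase snapshots and raw phase samples.
#' All randomness (noise increments) is drawn from the R random number
#' stream, so a single `set.seed()` makes a run reproducible.
#'
#' @param state A [network_state()].
#' @param duration Simulated time (in units of the phase equations).
#' @param config A [sim_config()].
#' @param rule A [plasticity_rule()], or `NULL` to freeze the weights.
#' @param schedule A [stimulus_schedule()] or `NULL` for spontaneous
#'   activity. Block times are absolute (compared against the state clock).
#' @param record_every Sampling interval for the order-parameter series;
#'   0 disables the series.
#' @param n_orders Number of Kuramoto-Daido orders recorded.
#' @param snapshot_times Absolute times at which phases + weights are
#'   stored.
#' @param phase_sample_times Absolute times at which raw phase vectors are
#'   stored (cheaper than snapshots).
#' @param record_spikes Whether to keep the spike raster.
#' @return A list of class `theta_sim` with elements `state` (final
#'   [network_state()]), `series` (data frame: time, R1, Psi1, ...),
#'   `raster` (data frame: time, neuron), `snapshots` (list of
#'   time/phases/weights), `phase_samples` (matrix) and
#'   `phase_sample_times`.
#' @export
simulate_network <- function(state, duration, config = sim_config(),
                             rule = NULL, schedule = NULL,
                             record_every = 0.1, n_orders = 2L,
                             snapshot_times = numeric(0),
                             phase_sample_times = numeric(0),
                             record_spikes = TRUE) {
  validate_network_state(state)
  if (duration < 0) stop("`duration` must be >= 0", call. = FALSE)
  if (!is.null(rule) && rule$dale_mode == "unlabelled" &&
      !all(state$types == "unlabelled"))
    stop("unlabelled plasticity requires an unlabelled network", call. = FALSE)
  core_sched <- if (is.null(schedule)) {
    list(blocks = matrix(numeric(0), 0, 3), targets = list())
  } else {
    schedule_to_core(schedule, state$types)
  }
  n_steps <- as.integer(round(duration / config$dt))
  res <- sim_core(state$phases, state$weights, type_sign(state$types),
                  state$excitabilities, config$g, config$dt,
                  sqrt(config$noise_variance), state$time, n_steps,
                  core_sched$blocks, core_sched$targets,
                  kernel_id(rule), rule_mode_id(rule),
                  if (is.null(rule)) 0 else rule$eps_slow,
                  if (is.null(rule)) 0 else rule$eps_fast,
                  if (is.null(rule)) 0.1 else rule$gate_threshold,
                  !is.null(rule),
                  record_every, as.integer(n_orders),
                  sort(as.numeric(snapshot_times)),
                  sort(as.numeric(phase_sample_times)),
                  record_spikes)
  out_state <- state
  out_state$phases <- res$phases
  out_state$weights <- res$weights
  out_state$time <- res$time
  structure(list(
    state = out_state,
    series = series_to_df(res$series),
    raster = data.frame(time = res$spike_times,
                        neuron = res$spike_neuron + 1L),
    snapshots = res$snapshots,
    phase_samples = res$phase_samples,
    phase_sample_times = res$phase_sample_times),
    class = "theta_sim")
}

#' @export
print.theta_sim <- function(x, ...) {
  cat("<theta_sim> N =", length(x$state$phases),
      "ending at t =", format(x$state$time),
      "|", nrow(x$raster), "spikes,",
      nrow(x$series), "series samples\n")
  invisible(x)
}

#' Mean order parameters over a time window
#'
#' Averages the recorded `R_n` moduli over `window[1] <= time <=
#' window[2]`.
#'
#' @param series Series data frame from [simulate_network()].
#' @param window Length-2 numeric time window.
#' @return Named numeric vector of mean `R_n` values.
#' @export
mean_order_parameters <- function(series, window) {
  sel <- series$time >= window[1] & series$time <= window[2]
  if (!any(sel)) stop("no series samples in the window", call. = FALSE)
  rcols <- grep("^R[0-9]+$", names(series), value = TRUE)
  vapply(series[sel, rcols, drop = FALSE], mean, numeric(1))
}
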