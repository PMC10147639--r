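#' Construct a network state
#'
#' Bundles the instantaneous state of a plastic theta-neuron network: the
#' phase of every neuron, the synaptic weight matrix, the neuron type labels,
#' the excitabilities and the simulation clock.
#'
#' @param phases Numeric vector of N phase angles; wrapped to `[-pi, pi)`.
#' @param weights N x N numeric matrix; `weights[i, j]` is the synaptic
#'   weight from pre-synaptic neuron `j` to post-synaptic neuron `i`.
#'   Columns of excitatory neurons must lie in `[0, 1]`, columns of
#'   inhibitory neurons in `[-1, 0]`, columns of unlabelled neurons in
#'   `[-1, 1]`. The diagonal is forced to zero (self-coupling has no effect
#'   on the phase dynamics and is excluded from adaptation).
#' @param types Character vector of N labels among `"excitatory"`,
#'   `"inhibitory"`, `"unlabelled"`.
#' @param excitabilities Numeric vector of N bifurcation parameters
#'   `eta_i`; for constant `eta > 0` an isolated neuron fires periodically
#'   with period `pi / sqrt(eta)`.
#' @param time Simulation time (dimensionless units).
#'
#' @return An object of class `network_state`.
#' @export
network_state <- function(phases, weights, types, excitabilities, time = 0) {
  phases <- wrap_phase(as.numeric(phases))
  N <- length(phases)
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) != N || ncol(weights) != N)
    stop("`weights` must be a numeric ", N, " x ", N, " matrix", call. = FALSE)
  types <- match.arg(as.character(types),
                     c("excitatory", "inhibitory", "unlabelled"),
                     several.ok = TRUE)
  if (length(types) == 1L) types <- rep(types, N)
  if (length(types) != N)
    stop("`types` must have one label per neuron", call. = FALSE)
  excitabilities <- as.numeric(excitabilities)
  if (length(excitabilities) != N)
    stop("`excitabilities` must have length N", call. = FALSE)
  diag(weights) <- 0
  st <- structure(
    list(phases = phases, weights = weights, types = types,
         excitabilities = excitabilities, time = as.numeric(time)[1]),
    class = "network_state")
  validate_network_state(st)
  st
}

#' Validate a network state
#'
#' Checks the structural invariants: phases wrapped, Dale sign constraints
#' on the weight columns, zero diagonal.
#'
#' @param state A `network_state`.
#' @return The state, invisibly; errors if an invariant is violated.
#' @export
validate_network_state <- function(state) {
  stopifnot(inherits(state, "network_state"))
  ph <- state$phases
  if (any(ph < -pi | ph >= pi))
    stop("phases must lie in [-pi, pi)", call. = FALSE)
  if (any(diag(state$weights) != 0))
    stop("self-weights must be zero", call. = FALSE)
  k <- state$weights
  tol <- 1e-12
  for (lab in unique(state$types)) {
    cols <- which(state$types == lab)
    kk <- k[, cols, drop = FALSE]
    ok <- switch(lab,
      excitatory = all(kk >= -tol & kk <= 1 + tol),
      inhibitory = all(kk >= -1 - tol & kk <= tol),
      unlabelled = all(abs(kk) <= 1 + tol))
    if (!ok)
      stop("weight bounds violated for ", lab, " pre-synaptic columns",
           call. = FALSE)
  }
  invisible(state)
}

#' Simulation configuration
#'
#' Global parameters of the phase dynamics. The default values are the
#' standard operating point of the model: coupling strength `g = 1`,
#' integration step `dt = 0.01`, Gaussian background noise of standard
#' deviation 0.1 (variance 0.01), and excitabilities drawn from a normal
#' distribution with mean 1.5 and standard deviation 0.01. At this
#' operating point an unstimulated E/I network relaxes to near-complete
#' phase synchrony (`R1` close to 1), the regime in which entrainment and
#' consolidation operate.
#'
#' @param g Global coupling strength (>= 0).
#' @param dt Integration time step (> 0).
#' @param noise_variance Variance of the Gaussian noise term (>= 0).
#' @param eta_mean,eta_variance Mean and variance of the excitability
#'   distribution.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(g = 1, dt = 0.01, noise_variance = 0.01,
                       eta_mean = 1.5, eta_variance = 1e-4) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (noise_variance < 0) stop("`noise_variance` must be >= 0", call. = FALSE)
  if (g < 0) stop("`g` must be >= 0", call. = FALSE)
  if (eta_variance < 0) stop("`eta_variance` must be >= 0", call. = FALSE)
  structure(list(g = g, dt = dt, noise_variance = noise_variance,
                 eta_mean = eta_mean, eta_variance = eta_variance),
            class = "sim_config")
}

#' Wrap angles to `[-pi, pi)`
#'
#' @param x Numeric vector of angles (radians).
#' @return Wrapped angles.
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi)
  y - pi
}

#' Initialise a random network
#'
#' Draws random initial phases (uniform on `[-pi, pi)`), excitabilities
#' (normal with the configured mean and variance) and synaptic weights:
#' uniform on `[0, 1]` for excitatory pre-synaptic columns, uniform on
#' `[-1, 0]` for inhibitory columns, and uniform on `[-1, 1]` in unlabelled
#' mode. The diagonal is zeroed. In `"ei"` mode the last `n_inhibitory`
#' indices are labelled inhibitory. Consumes the R random number stream, so
#' `set.seed()` gives reproducible networks.
#'
#' @param N Number of neurons.
#' @param n_inhibitory Number of inhibitory neurons (0 <= n_inhibitory <= N).
#' @param mode `"ei"`, `"excitatory_only"` or `"unlabelled"`.
#' @param config A [sim_config()].
#' @return A [network_state()].
#' @export
init_network <- function(N, n_inhibitory = 0,
                         mode = c("ei", "excitatory_only", "unlabelled"),
                         config = sim_config()) {
  mode <- match.arg(mode)
  N <- as.integer(N)
  n_inhibitory <- as.integer(n_inhibitory)
  if (N < 1) stop("`N` must be >= 1", call. = FALSE)
  if (n_inhibitory < 0 || n_inhibitory > N)
    stop("`n_inhibitory` must lie in [0, N]", call. = FALSE)
  if (mode != "ei" && n_inhibitory > 0)
    stop("`n_inhibitory` must be 0 unless mode = \"ei\"", call. = FALSE)
  types <- switch(mode,
    ei = rep(c("excitatory", "inhibitory"), c(N - n_inhibitory, n_inhibitory)),
    excitatory_only = rep("excitatory", N),
    unlabelled = rep("unlabelled", N))
  phases <- stats::runif(N, -pi, pi)
  phases[phases >= pi] <- -pi
  eta <- stats::rnorm(N, config$eta_mean, sqrt(config$eta_variance))
  w <- matrix(stats::runif(N * N), N, N)
  if (mode == "unlabelled") {
    w <- 2 * w - 1
  } else {
    inh <- types == "inhibitory"
    if (any(inh)) w[, inh] <- w[, inh] - 1
  }
  diag(w) <- 0
  network_state(phases, w, types, eta, time = 0)
}

#' Deterministic phase drift
#'
#' Evaluates the noise-free right-hand side of the phase equation,
#' `dtheta_i/dt = (1 - cos theta_i) + (1 + cos theta_i) *
#' (eta_i + (g/N) * sum_j kappa_ij sin(theta_j - theta_i) + I_i)`.
#'
#' @param state A [network_state()].
#' @param currents Numeric vector of N external currents.
#' @param config A [sim_config()].
#' @return Numeric vector of N drift values.
#' @export
phase_drift <- function(state, currents, config = sim_config()) {
  th <- state$phases
  N <- length(th)
  currents <- as.numeric(currents)
  if (length(currents) != N)
    stop("`currents` must have length N = ", N, call. = FALSE)
  ct <- cos(th); st_ <- sin(th)
  coup <- if (config$g != 0 && N > 1) {
    (config$g / N) * (ct * as.numeric(state$weights %*% st_) -
                      st_ * as.numeric(state$weights %*% ct))
  } else {
    numeric(N)
  }
  (1 - ct) + (1 + ct) * (state$excitabilities + coup + currents)
}

#' Advance the network by integration steps
#'
#' Integrates the stochastic phase equations with a Heun
#' predictor-corrector scheme whose averaged multiplicative-noise term is
#' consistent with the Stratonovich interpretation. Optionally applies one
#' Euler step of the plasticity rule per time step (after the phase update,
#' using the updated phases). Spikes are recorded whenever an unwrapped
#' phase increment carries a neuron across `+pi` from below; spike times are
#' linearly interpolated within the step. Noise increments consume the R
#' random number stream (none are drawn when `noise_variance = 0`).
#'
#' @param state A [network_state()].
#' @param currents External current vector, held constant over the steps.
#' @param config A [sim_config()].
#' @param rule Optional [plasticity_rule()]; `NULL` freezes the weights.
#' @param n_steps Number of `dt` steps to take.
#' @return A list with elements `state` (the advanced [network_state()]) and
#'   `spikes` (data frame with columns `time`, `neuron`).
#' @export
step_network <- function(state, currents, config = sim_config(), rule = NULL,
                         n_steps = 1L) {
  validate_network_state(state)
  N <- length(state$phases)
  currents <- as.numeric(currents)
  if (length(currents) != N)
    stop("`currents` must have length N = ", N, call. = FALSE)
  # the compiled core applies one amplitude per block: one block per value
  vals <- unique(currents[currents != 0])
  blocks <- if (length(vals)) {
    do.call(rbind, lapply(vals, function(a) c(-Inf, Inf, a)))
  } else {
    matrix(numeric(0), 0, 3)
  }
  targets <- lapply(vals, function(a) which(currents == a) - 1L)
  res <- sim_core(state$phases, state$weights, type_sign(state$types),
                  state$excitabilities, config$g, config$dt,
                  sqrt(config$noise_variance), state$time, as.integer(n_steps),
                  blocks, targets,
                  kernel_id(rule), rule_mode_id(rule),
                  if (is.null(rule)) 0 else rule$eps_slow,
                  if (is.null(rule)) 0 else rule$eps_fast,
                  if (is.null(rule)) 0.1 else rule$gate_threshold,
                  !is.null(rule),
                  0, 0L, numeric(0), numeric(0), TRUE)
  new_state <- state
  new_state$phases <- res$phases
  new_state$weights <- res$weights
  new_state$time <- res$time
  list(state = new_state,
       spikes = data.frame(time = res$spike_times,
                           neuron = res$spike_neuron + 1L))
}

# integer signs used by the compiled core: +1 E, -1 I, 0 unlabelled
type_sign <- function(types) {
  ifelse(types == "excitatory", 1L, ifelse(types == "inhibitory", -1L, 0L))
}

kernel_id <- function(rule) {
  if (is.null(rule)) return(1L)
  if (rule$kernel == "cosine") 0L else 1L
}

rule_mode_id <- function(rule) {
  if (is.null(rule)) return(0L)
  if (rule$dale_mode == "unlabelled") 1L else 0L
}

#' @export
print.network_state <- function(x, ...) {
  tab <- table(x$types)
  cat("<network_state> N =", length(x$phases),
      paste0("(", paste(names(tab), tab, sep = ": ", collapse = ", "), ")"),
      "at t =", format(x$time), "\n")
  invisible(x)
}
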