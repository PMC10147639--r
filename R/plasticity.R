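#' Hebbian phase-difference plasticity rule
#'
#' Describes how synaptic weights evolve as a function of the instantaneous
#' phase difference between the pre- and post-synaptic neuron. Two learning
#' rates act in parallel: a slow, always-on rate `eps_slow` and a fast rate
#' `eps_fast` that is gated on only while the pre-synaptic neuron receives a
#' sufficiently strong external stimulus (|I| above `gate_threshold`); the
#' fast term applies only to synapses connecting two excitatory neurons.
#'
#' @param kernel `"asymmetric_exponential"` (potentiation lobe with e-fold
#'   width 0.1 rad, depression lobe with width 0.5 rad) or `"cosine"`.
#' @param eps_slow Slow learning rate (default 1e-5).
#' @param eps_fast Fast, stimulus-gated learning rate (default 0.1).
#' @param gate_threshold Stimulus magnitude above which the fast rate is
#'   active (default 0.1).
#' @param dale_mode `"ei"`, `"excitatory_only"` or `"unlabelled"`. The two
#'   Dale-constrained modes use soft bounds that confine excitatory weights
#'   to `[0, 1]` and inhibitory weights to `[-1, 0]`; the unlabelled mode
#'   relaxes each weight towards the kernel value in `[-1, 1]`.
#' @return An object of class `plasticity_rule`.
#' @export
plasticity_rule <- function(kernel = c("asymmetric_exponential", "cosine"),
                            eps_slow = 1e-5, eps_fast = 0.1,
                            gate_threshold = 0.1,
                            dale_mode = c("ei", "excitatory_only", "unlabelled")) {
  kernel <- match.arg(kernel)
  dale_mode <- match.arg(dale_mode)
  if (!(eps_slow > 0 && eps_slow < eps_fast && eps_fast < 1))
    stop("learning rates must satisfy 0 < eps_slow < eps_fast < 1",
         call. = FALSE)
  structure(list(kernel = kernel, eps_slow = eps_slow, eps_fast = eps_fast,
                 gate_threshold = gate_threshold, dale_mode = dale_mode),
            class = "plasticity_rule")
}

#' Cosine plasticity kernel
#'
#' The symmetric Hebbian kernel `cos(dtheta)`: potentiation for phase
#' differences near 0, depression near `+-pi`, with equal-width lobes.
#'
#' @param dtheta Phase difference(s), radians; any real value.
#' @return Kernel value(s).
#' @export
kernel_lambda0 <- function(dtheta) cos(dtheta)

#' Asymmetric exponential plasticity kernel
#'
#' A 2*pi-periodic Hebbian kernel with asymmetric lobes: the potentiation
#' lobe around `dtheta = 0` decays with e-fold width 0.1 rad while the
#' depression lobe around `+-pi` has width 0.5 rad, i.e. depression acts on
#' a window five times longer than potentiation, as observed for cortical
#' spike-timing plasticity. On `[-pi, 0)` the kernel is
#' `exp(dtheta/0.1) - exp(-(dtheta + pi)/0.5)` and on `[0, pi)` it is
#' `exp(-dtheta/0.1) - exp((dtheta - pi)/0.5)`.
#'
#' @param dtheta Phase difference(s), radians; wrapped internally.
#' @return Kernel value(s).
#' @export
kernel_lambda1 <- function(dtheta) {
  d <- wrap_phase(dtheta)
  ifelse(d < 0,
         exp(d / 0.1) - exp(-(d + pi) / 0.5),
         exp(-d / 0.1) - exp((d - pi) / 0.5))
}

#' Kernel function of a plasticity rule
#'
#' @param rule A [plasticity_rule()].
#' @return The kernel as a function of the phase difference.
#' @export
plasticity_kernel <- function(rule) {
  if (rule$kernel == "cosine") kernel_lambda0 else kernel_lambda1
}

#' Tabulate a plasticity kernel
#'
#' Evaluates a kernel on a regular grid of phase differences, e.g. for
#' plotting or for export to delimited text.
#'
#' @param rule A [plasticity_rule()] (or a kernel name).
#' @param n Number of grid points over `[-pi, pi)`.
#' @return Data frame with columns `dtheta` and `lambda`.
#' @export
kernel_table <- function(rule, n = 1001L) {
  fn <- if (inherits(rule, "plasticity_rule")) plasticity_kernel(rule)
        else if (identical(rule, "cosine")) kernel_lambda0
        else kernel_lambda1
  grid <- seq(-pi, pi, length.out = n)
  data.frame(dtheta = grid, lambda = fn(grid))
}

#' Instantaneous weight derivative
#'
#' Evaluates `d kappa / dt` for a single synapse under a plasticity rule.
#' For a synapse between two excitatory neurons the derivative is
#' `[eps_slow + eps_fast * gate] * kappa * (1 - kappa) * Lambda(dtheta)`;
#' when the pre- and/or post-synaptic neuron is inhibitory only the slow
#' rate acts and the soft-bound factor becomes `|kappa| * (1 - |kappa|)`,
#' applied to the signed weight:
#' `d kappa / dt = eps_slow * |kappa| * (1 - |kappa|) * Lambda(dtheta)`.
#' A positive kernel value therefore drives an inhibitory weight towards 0
#' (synchronous partners shed their mutual inhibition) and a negative one
#' drives it towards -1. In unlabelled mode the weight relaxes linearly
#' towards the kernel value:
#' `d kappa / dt = [eps_slow + eps_fast * gate] * (-kappa + Lambda(dtheta))`.
#'
#' @param kappa Current weight, inside the bound interval of `pre_type`.
#' @param dtheta Phase difference `theta_pre - theta_post` (radians).
#' @param pre_type,post_type Neuron type labels.
#' @param pre_stimulated Logical; whether the pre-synaptic neuron currently
#'   receives a stimulus above the gate threshold.
#' @param rule A [plasticity_rule()].
#' @return The derivative `d kappa / dt`.
#' @export
weight_derivative <- function(kappa, dtheta, pre_type = "excitatory",
                              post_type = "excitatory",
                              pre_stimulated = FALSE,
                              rule = plasticity_rule()) {
  lam <- plasticity_kernel(rule)(dtheta)
  if (rule$dale_mode == "unlabelled") {
    if (any(abs(kappa) > 1 + 1e-12))
      stop("`kappa` outside [-1, 1]", call. = FALSE)
    rate <- rule$eps_slow + rule$eps_fast * as.numeric(pre_stimulated)
    return(rate * (-kappa + lam))
  }
  if (pre_type == "excitatory") {
    if (any(kappa < -1e-12 | kappa > 1 + 1e-12))
      stop("`kappa` outside [0, 1] for an excitatory pre-synaptic neuron",
           call. = FALSE)
  } else {
    if (any(kappa > 1e-12 | kappa < -1 - 1e-12))
      stop("`kappa` outside [-1, 0] for an inhibitory pre-synaptic neuron",
           call. = FALSE)
  }
  both_e <- pre_type == "excitatory" && post_type == "excitatory"
  rate <- rule$eps_slow +
    if (both_e) rule$eps_fast * as.numeric(pre_stimulated) else 0
  rate * abs(kappa) * (1 - abs(kappa)) * lam
}

#' One Euler step of the weight dynamics
#'
#' Advances every off-diagonal weight by one Euler step of
#' [weight_derivative()], using the phase differences
#' `dtheta = theta_j - theta_i` of the supplied state and the stimulus gate
#' evaluated from `currents` at the pre-synaptic neuron. Results are
#' clamped so weight magnitudes stay inside `[1e-6, 1 - 1e-6]`: the soft
#' bounds make 0 and 1 absorbing, and a tiny interior clamp prevents an
#' Euler overshoot from freezing a weight at a bound. The diagonal is
#' untouched. This is a vectorised R reference implementation of the update
#' performed inside the compiled integrator.
#'
#' @param state A [network_state()].
#' @param currents External current vector (length N).
#' @param rule A [plasticity_rule()].
#' @param dt Time step.
#' @return The state with updated weights.
#' @export
update_weights <- function(state, currents, rule, dt) {
  th <- state$phases
  N <- length(th)
  currents <- as.numeric(currents)
  if (length(currents) != N)
    stop("`currents` must have length N = ", N, call. = FALSE)
  eps_num <- 1e-6
  dth <- wrap_phase(outer(th, th, function(ti, tj) tj - ti))
  lam <- plasticity_kernel(rule)(dth)
  gate <- abs(currents) > rule$gate_threshold
  k <- state$weights
  if (rule$dale_mode == "unlabelled") {
    rate <- rule$eps_slow +
      rule$eps_fast * matrix(gate, N, N, byrow = TRUE)
    k_new <- k + dt * rate * (-k + lam)
    k_new <- pmin(pmax(k_new, -1 + eps_num), 1 - eps_num)
  } else {
    pre_e <- matrix(state$types == "excitatory", N, N, byrow = TRUE)
    post_e <- matrix(state$types == "excitatory", N, N)
    rate <- rule$eps_slow +
      rule$eps_fast * (pre_e & post_e & matrix(gate, N, N, byrow = TRUE))
    k_new <- k + dt * rate * abs(k) * (1 - abs(k)) * lam
    k_new[pre_e] <- pmin(pmax(k_new[pre_e], eps_num), 1 - eps_num)
    k_new[!pre_e] <- pmin(pmax(k_new[!pre_e], -1 + eps_num), -eps_num)
  }
  diag(k_new) <- diag(k)
  state$weights <- k_new
  state
}

#' @export
print.plasticity_rule <- function(x, ...) {
  cat("<plasticity_rule>", x$kernel, "kernel,",
      "eps_slow =", format(x$eps_slow), "eps_fast =", format(x$eps_fast),
      "mode =", x$dale_mode, "\n")
  invisible(x)
}
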