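#' Consolidation parameters
#'
#' The slow learning rate (1e-5) implies consolidation horizons of order
#' 1e5 time units. For routine runs the slow rate is multiplied by an
#' acceleration factor `rho` and the consolidation duration divided by
#' `rho`, which preserves the number of plasticity e-folds
#' (`eps_slow * duration`) while keeping the separation
#' `eps_slow << eps_fast`. `rho = 1` recovers the literal slow rate.
#'
#' @param rho Acceleration factor (default 100).
#' @param duration Consolidation duration in time units at this `rho`
#'   (default 2000, i.e. 2e5 units at `rho = 1`).
#' @param eps_slow_base Unscaled slow rate (default 1e-5).
#' @return An object of class `consolidation_params` with fields `rho`,
#'   `duration`, `eps_slow` (the scaled rate actually used).
#' @export
consolidation_params <- function(rho = 100, duration = 2000,
                                 eps_slow_base = 1e-5) {
  if (rho <= 0 || duration < 0) stop("invalid consolidation parameters",
                                     call. = FALSE)
  structure(list(rho = rho, duration = duration,
                 eps_slow_base = eps_slow_base,
                 eps_slow = eps_slow_base * rho),
            class = "consolidation_params")
}

# default rule for a mode, with a given slow rate
default_rule <- function(mode, eps_slow = 1e-5, eps_fast = 0.1) {
  plasticity_rule(
    kernel = if (mode == "unlabelled") "cosine" else "asymmetric_exponential",
    eps_slow = eps_slow, eps_fast = eps_fast, dale_mode = mode)
}

#' Run the main entrainment experiment
#'
#' Executes the three-regime protocol: spontaneous rest, a learning phase
#' in which `n_stimuli` groups of excitatory neurons are stimulated in
#' random alternation, and a consolidation phase of spontaneous activity
#' with the (rescaled) slow plasticity rate. Weight/phase snapshots are
#' taken at the regime boundaries T0 (end of rest), T1 (early learning),
#' T2 (end of learning) and T3 (end of consolidation).
#'
#' @param mode `"ei"`, `"excitatory_only"` or `"unlabelled"`.
#' @param n_stimuli Number of stimulated groups (default 2).
#' @param N Network size (default 100).
#' @param n_inhibitory Number of inhibitory neurons (default 20 in `"ei"`
#'   mode, otherwise 0).
#' @param config A [sim_config()].
#' @param rule A [plasticity_rule()]; defaults to the mode's standard rule
#'   (asymmetric kernel under Dale's principle; cosine kernel with the
#'   relaxational rule for unlabelled networks).
#' @param rest Initial rest duration (default 200).
#' @param n_blocks,block_len,amplitude Learning-phase schedule parameters;
#'   the default block count gives every stimulus group the same expected
#'   exposure (25 blocks of 20 time units per group) regardless of how
#'   many stimuli are presented.
#' @param n_hubs Overlap (shared neurons) between the two stimulus groups;
#'   non-zero values switch the schedule to strict alternation with a short
#'   inter-block gap.
#' @param gap Inter-block gap used when `n_hubs > 0` (default 5).
#' @param consolidation A [consolidation_params()].
#' @param seed Optional integer seed (applied via `set.seed`).
#' @param record_spikes Keep the spike raster (default TRUE).
#' @return A list of class `theta_run`: `snapshots` (named T0-T3), `series`,
#'   `raster`, `state` (final), `summary` (final and rest-phase mean order
#'   parameters, structural module count), `params` (configuration echo).
#' @export
run_main_experiment <- function(mode = c("ei", "excitatory_only", "unlabelled"),
                                n_stimuli = 2L, N = 100L,
                                n_inhibitory = if (mode == "ei") 20L else 0L,
                                config = sim_config(), rule = NULL,
                                rest = 200, n_blocks = 25L * n_stimuli,
                                block_len = 20,
                                amplitude = 3, n_hubs = 0L, gap = 5,
                                consolidation = consolidation_params(),
                                seed = NULL, record_spikes = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rule)) rule <- default_rule(mode)
  n_exc <- N - n_inhibitory
  groups <- stimulus_groups(n_exc, n_stimuli, n_hubs)
  state <- init_network(N, n_inhibitory, mode, config)
  strict <- n_hubs > 0L
  sched <- build_learning_schedule(groups, block_len = block_len,
                                   n_blocks = n_blocks, rest_before = rest,
                                   rest_after = 0, amplitude = amplitude,
                                   gap = if (strict) gap else 0,
                                   strict_alternation = strict)
  learn_end <- sched$total_duration
  n_orders <- max(3L, n_stimuli)
  snaps_a <- c(rest, rest + 3 * block_len, learn_end)
  sim_a <- simulate_network(state, learn_end, config, rule, sched,
                            record_every = 0.1, n_orders = n_orders,
                            snapshot_times = snaps_a,
                            record_spikes = record_spikes)
  rule_cons <- plasticity_rule(kernel = rule$kernel,
                               eps_slow = consolidation$eps_slow,
                               eps_fast = rule$eps_fast,
                               gate_threshold = rule$gate_threshold,
                               dale_mode = rule$dale_mode)
  t3 <- learn_end + consolidation$duration
  sim_b <- simulate_network(sim_a$state, consolidation$duration, config,
                            rule_cons, NULL,
                            record_every = 0.1, n_orders = n_orders,
                            snapshot_times = t3,
                            record_spikes = record_spikes)
  snapshots <- c(sim_a$snapshots, sim_b$snapshots)
  names(snapshots) <- c("T0", "T1", "T2", "T3")
  series <- rbind(sim_a$series, sim_b$series[-1, , drop = FALSE])
  raster <- rbind(sim_a$raster, sim_b$raster)
  final_R <- mean_order_parameters(series, c(t3 - 10, t3))
  rest_R <- mean_order_parameters(series, c(rest - 10, rest))
  modules <- if (mode == "unlabelled") NA_integer_ else
    count_structural_modules(sim_b$state$weights, sim_b$state$types)
  structure(list(
    snapshots = snapshots, series = series, raster = raster,
    state = sim_b$state,
    summary = list(final_R = final_R, rest_R = rest_R,
                   structural_modules = modules,
                   boundaries = c(T0 = rest, T1 = rest + 3 * block_len,
                                  T2 = learn_end, T3 = t3)),
    params = list(mode = mode, n_stimuli = n_stimuli, N = N,
                  n_inhibitory = n_inhibitory, n_hubs = n_hubs,
                  rest = rest, n_blocks = n_blocks, block_len = block_len,
                  amplitude = amplitude, seed = seed,
                  groups = groups, config = config, rule = rule,
                  consolidation = consolidation)),
    class = "theta_run")
}

#' @export
print.theta_run <- function(x, ...) {
  s <- x$summary
  cat("<theta_run>", x$params$mode, "mode,", x$params$n_stimuli, "stimuli\n")
  cat("  rest R1 =", round(s$rest_R[["R1"]], 3),
      "| final", paste(names(s$final_R),
                       round(s$final_R, 3), sep = " = ", collapse = ", "), "\n")
  if (!is.na(s$structural_modules))
    cat("  structural modules at T3:", s$structural_modules, "\n")
  invisible(x)
}

#' Spontaneous evolution of a pre-trained network
#'
#' Builds the pre-trained weight matrix for a module layout, softens it to
#' post-learning values, and lets the network evolve spontaneously (no
#' stimuli, slow plasticity only) for the consolidation duration. Survival
#' of the stored modules is then judged jointly on the final weight matrix
#' and on the phase dynamics over the final 50 time units (see
#' [count_surviving_modules()]); survival is assessed over the exclusive
#' cluster members (hubs excluded).
#'
#' @param layout A [module_layout()].
#' @param config A [sim_config()].
#' @param consolidation A [consolidation_params()].
#' @param w_high,w_low Softened saturated/pruned weight magnitudes (see
#'   [soften_pretrained()]).
#' @param eps_fast Fast rate of the rule (inactive without stimuli).
#' @param inhibitory_wiring `"assigned"` keeps the idealised feedforward
#'   inhibitory architecture of the builder (each inhibitory neuron
#'   specialised to its cluster) -- the construction needed to probe
#'   extreme cases such as a single inhibitory neuron per cluster, which
#'   random learning would not produce. `"random"` replaces every
#'   connection involving an inhibitory neuron with a fresh uniform draw,
#'   i.e. the post-learning state in which the slow rate has not yet
#'   specialised the inhibition; cluster survival then also depends on how
#'   fast the inhibition organises during the trial. The default (`"auto"`)
#'   uses `"random"` for layouts with hub neurons -- with pre-specialised
#'   inhibition a bicoupled hub group is ejected to the midpoint between
#'   the clusters and stabilises them at any inhibitory count, whereas the
#'   overlap experiments' merge-or-segregate outcome arises from the race
#'   between hub attraction and inhibitory specialisation -- and
#'   `"assigned"` otherwise.
#' @return A list of class `stability_trial`: `surviving` (module count),
#'   `structural`, `dynamical` (phase-cluster count, modal over the final
#'   window), `intended`, and `state` (final [network_state()]).
#' @export
run_stability_trial <- function(layout, config = sim_config(),
                                consolidation = consolidation_params(),
                                w_high = 0.99, w_low = 0.003,
                                eps_fast = 0.1,
                                inhibitory_wiring = c("auto", "assigned",
                                                      "random")) {
  inhibitory_wiring <- match.arg(inhibitory_wiring)
  if (inhibitory_wiring == "auto")
    inhibitory_wiring <- if (length(layout$hubs)) "random" else "assigned"
  N <- layout$N
  n_inh <- length(layout$inhibitory)
  types <- rep("excitatory", N)
  types[layout$inhibitory] <- "inhibitory"
  k0 <- soften_pretrained(build_pretrained_matrix(N, layout), types,
                          w_high = w_high, w_low = w_low)
  if (inhibitory_wiring == "random" && n_inh > 0) {
    inh <- layout$inhibitory
    exc <- setdiff(seq_len(N), inh)
    k0[, inh] <- -matrix(stats::runif(N * n_inh), N)
    k0[inh, exc] <- matrix(stats::runif(n_inh * length(exc)), n_inh)
    diag(k0) <- 0
  }
  eta <- stats::rnorm(N, config$eta_mean, sqrt(config$eta_variance))
  phases <- stats::runif(N, -pi, pi)
  phases <- wrap_phase(phases)
  state <- network_state(phases, k0, types, eta)
  rule <- plasticity_rule(kernel = "asymmetric_exponential",
                          eps_slow = consolidation$eps_slow,
                          eps_fast = eps_fast,
                          dale_mode = "ei")
  dur <- consolidation$duration
  samp <- seq(max(0, dur - 50), dur, by = 1)
  sim <- simulate_network(state, dur, config, rule, NULL,
                          record_every = 0, n_orders = 0L,
                          phase_sample_times = samp, record_spikes = FALSE)
  members <- setdiff(unlist(layout$clusters), layout$hubs)
  exc_all <- setdiff(seq_len(N), layout$inhibitory)
  structural <- count_structural_modules(sim$state$weights, types,
                                         members = members)
  dyn_counts <- apply(sim$phase_samples[, members, drop = FALSE], 1,
                      count_phase_clusters)
  dynamical <- modal_int(dyn_counts)
  surviving <- count_surviving_modules(sim$state$weights, types,
                                       sim$phase_samples, members = members)
  structure(list(surviving = surviving, structural = structural,
                 dynamical = dynamical,
                 intended = length(layout$clusters),
                 state = sim$state),
            class = "stability_trial")
}

modal_int <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

# run one grid cell with n_seeds replicates; modal surviving count
stability_cell <- function(layout, config, consolidation, n_seeds, w_high,
                           w_low) {
  counts <- vapply(seq_len(n_seeds), function(s) {
    run_stability_trial(layout, config, consolidation,
                        w_high = w_high, w_low = w_low)$surviving
  }, integer(1))
  modal_int(counts)
}

#' Stability map over module count and inhibitory count
#'
#' Sweeps pre-trained networks with `M` modules and `N_I` inhibitory
#' neurons over the supplied grids and records the modal surviving-module
#' count over `n_seeds` replicates per cell. A cell is stable when all `M`
#' intended modules survive. Cells with `M > N - N_I` are infeasible and
#' marked `NA` (non-accessible).
#'
#' @param M_values,NI_values Integer grids.
#' @param N Network size (default 100).
#' @param config,consolidation,w_high,w_low See [run_stability_trial()].
#' @param n_seeds Replicates per cell (default 3).
#' @return A list of class `stability_map` with `axis1` (M), `axis2` (N_I),
#'   `outcome` (matrix of surviving counts, rows = M), `stable` (logical
#'   matrix) and `intended`.
#' @export
stability_map_modules <- function(M_values, NI_values, N = 100L,
                                  config = sim_config(),
                                  consolidation = consolidation_params(),
                                  w_high = 0.99, w_low = 0.003,
                                  n_seeds = 3L) {
  if (!length(M_values) || !length(NI_values))
    stop("grids must be non-empty", call. = FALSE)
  out <- matrix(NA_integer_, length(M_values), length(NI_values),
                dimnames = list(M = M_values, NI = NI_values))
  stable <- matrix(NA, length(M_values), length(NI_values),
                   dimnames = dimnames(out))
  for (a in seq_along(M_values)) {
    for (b in seq_along(NI_values)) {
      M <- M_values[a]; ni <- NI_values[b]
      if (M > N - ni) next  # non-accessible
      layout <- layout_modules(N, M, ni)
      out[a, b] <- stability_cell(layout, config, consolidation, n_seeds,
                                  w_high, w_low)
      stable[a, b] <- out[a, b] == M
    }
  }
  structure(list(axis1 = M_values, axis2 = NI_values, outcome = out,
                 stable = stable, intended = M_values, kind = "modules"),
            class = "stability_map")
}

#' Stability map over hub count and inhibitory count
#'
#' Sweeps pre-trained two-cluster networks sharing `N_H` hub neurons, for
#' varying numbers of inhibitory neurons, and records whether the two
#' clusters remain segregated (outcome 2) or merge (outcome 1). Layouts
#' whose exclusive cluster size would be smaller than the number of hubs
#' are marked unstable by construction (outcome 1, not simulated), and
#' infeasible layouts are `NA`.
#'
#' @param NH_values,NI_values Integer grids.
#' @param N Network size (default 100).
#' @inheritParams stability_map_modules
#' @return A `stability_map` (rows = N_H values, intended count 2).
#' @export
stability_map_hubs <- function(NH_values, NI_values, N = 100L,
                               config = sim_config(),
                               consolidation = consolidation_params(),
                               w_high = 0.99, w_low = 0.003,
                               n_seeds = 3L) {
  if (!length(NH_values) || !length(NI_values))
    stop("grids must be non-empty", call. = FALSE)
  out <- matrix(NA_integer_, length(NH_values), length(NI_values),
                dimnames = list(NH = NH_values, NI = NI_values))
  stable <- matrix(NA, length(NH_values), length(NI_values),
                   dimnames = dimnames(out))
  for (a in seq_along(NH_values)) {
    for (b in seq_along(NI_values)) {
      nh <- NH_values[a]; ni <- NI_values[b]
      n_excl <- N - ni - nh
      if (n_excl < 2L) next  # non-accessible
      if (floor(n_excl / 2) < nh) {  # exclusive members fewer than hubs
        out[a, b] <- 1L
        stable[a, b] <- FALSE
        next
      }
      layout <- layout_hubs(N, nh, ni)
      out[a, b] <- stability_cell(layout, config, consolidation, n_seeds,
                                  w_high, w_low)
      stable[a, b] <- out[a, b] == 2L
    }
  }
  structure(list(axis1 = NH_values, axis2 = NI_values, outcome = out,
                 stable = stable, intended = 2L, kind = "hubs"),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  cat("<stability_map>", x$kind, "sweep\n")
  print(x$outcome)
  invisible(x)
}

#' Memory recall from inhibitory wiring alone
#'
#' Starting from a consolidated E/I network, the excitatory-to-excitatory
#' weights are scrambled (uniform redraw) while every connection involving
#' an inhibitory neuron keeps its learned value. After a rest period each
#' stored pattern is briefly presented; the recall response is the
#' transient anti-phase excursion of the stimulated pattern's excitatory
#' neurons relative to the complementary excitatory neurons, quantified by
#' [recall_score()].
#'
#' @param trained_state A consolidated [network_state()] in E/I mode
#'   (e.g. the final state of [run_main_experiment()] or a softened
#'   pre-trained network).
#' @param patterns List of excitatory index sets (the stored patterns).
#' @param pulse_len Stimulus duration (default 5).
#' @param pulse_amplitude Stimulus current (default 3).
#' @param rest Rest before the first pulse (default 200; the pulse for
#'   pattern p starts at `rest * p`).
#' @param config A [sim_config()].
#' @param rule A [plasticity_rule()] (default: standard E/I rule with the
#'   unscaled slow rate).
#' @param scramble Whether to scramble the excitatory weights first
#'   (default TRUE).
#' @return A list of class `recall_run`: `score` (data frame with `time`
#'   and one score column per pattern), `raster`, `summary` (per pattern:
#'   baseline, peak response, rise), `state`.
#' @export
run_recall_experiment <- function(trained_state, patterns, pulse_len = 5,
                                  pulse_amplitude = 3, rest = 200,
                                  config = sim_config(),
                                  rule = default_rule("ei"),
                                  scramble = TRUE) {
  inh <- which(trained_state$types == "inhibitory")
  for (p in patterns) {
    if (length(intersect(p, inh)))
      stop("patterns must not contain inhibitory indices", call. = FALSE)
  }
  state <- trained_state
  state$time <- 0
  if (scramble) state <- scramble_excitatory_weights(state)
  n_pat <- length(patterns)
  starts <- rest * seq_len(n_pat)
  blocks <- data.frame(t_start = starts, t_end = starts + pulse_len,
                       amplitude = pulse_amplitude)
  blocks$targets <- lapply(patterns, as.integer)
  total <- rest * (n_pat + 1)
  sched <- if (pulse_amplitude != 0) stimulus_schedule(blocks, total) else NULL
  samp <- seq(0, total, by = 0.5)
  sim <- simulate_network(state, total, config, rule, sched,
                          record_every = 0.1, n_orders = 2L,
                          phase_sample_times = samp)
  exc <- setdiff(seq_along(state$types), inh)
  score <- data.frame(time = sim$phase_sample_times)
  summary <- list()
  for (p in seq_len(n_pat)) {
    other <- setdiff(exc, patterns[[p]])
    sc <- apply(sim$phase_samples, 1, function(ph)
      recall_score(ph, patterns[[p]], other))
    score[[paste0("pattern", p)]] <- sc
    pre <- score$time >= starts[p] - 50 & score$time < starts[p]
    post <- score$time >= starts[p] & score$time <= starts[p] + 50
    baseline <- mean(sc[pre])
    peak <- max(sc[post])
    summary[[paste0("pattern", p)]] <-
      c(baseline = baseline, peak = peak, rise = peak - baseline)
  }
  structure(list(score = score, raster = sim$raster, series = sim$series,
                 summary = summary, state = sim$state,
                 pulse_starts = starts),
            class = "recall_run")
}
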