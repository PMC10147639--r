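#' Kuramoto-Daido order parameter
#'
#' Computes `Z_n = (1/N) sum_j exp(i n theta_j)` and returns its modulus
#' `R_n` and argument `Psi_n`. `R_1` close to 1 signals global phase
#' synchrony; `R_1` close to 0 with `R_2` close to 1 signals two anti-phase
#' clusters; more generally `R_M` close to 1 signals M evenly spaced
#' clusters.
#'
#' @param phases Numeric vector of N phases (radians).
#' @param n Order of the parameter (integer >= 1).
#' @return List with elements `R` and `Psi`.
#' @export
kuramoto_daido <- function(phases, n = 1L) {
  if (length(phases) < 1L) stop("`phases` must be non-empty", call. = FALSE)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  z <- mean(exp(1i * n * phases))
  list(R = Mod(z), Psi = Arg(z))
}

#' Count structural modules in the excitatory block
#'
#' Binarises the excitatory-to-excitatory block of the weight matrix at
#' `|kappa| >= strong_threshold`, symmetrises the result by OR, and returns
#' the number of connected components among the excitatory neurons. On a
#' consolidated matrix this equals the number of surviving neural
#' assemblies; on a fully pruned matrix every excitatory neuron is its own
#' singleton component.
#'
#' @param weights N x N weight matrix.
#' @param types Neuron type labels (length N).
#' @param strong_threshold Binarisation threshold (default 0.5, midway
#'   between saturated and pruned weights).
#' @param members Optional subset of excitatory indices to restrict the
#'   count to (e.g. exclusive cluster members, excluding hubs).
#' @return Integer number of connected components.
#' @export
count_structural_modules <- function(weights, types, strong_threshold = 0.5,
                                     members = NULL) {
  exc <- which(types == "excitatory")
  if (!is.null(members)) {
    if (!all(members %in% exc))
      stop("`members` must be excitatory indices", call. = FALSE)
    exc <- members
  }
  if (length(exc) == 0L) return(0L)
  a <- abs(weights[exc, exc, drop = FALSE]) >= strong_threshold
  a <- a | t(a)
  diag(a) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  as.integer(igraph::components(g)$no)
}

#' Count phase clusters on the circle
#'
#' Sorts the phases around the circle and splits clusters at every circular
#' gap larger than `gap_tolerance`. With no gap above tolerance the result
#' is 1.
#'
#' @param phases Numeric vector of phases (radians).
#' @param gap_tolerance Minimal circular gap (radians) separating clusters.
#' @return Integer cluster count.
#' @export
count_phase_clusters <- function(phases, gap_tolerance = 0.5) {
  if (length(phases) < 1L) stop("`phases` must be non-empty", call. = FALSE)
  s <- sort(wrap_phase(phases))
  n <- length(s)
  if (n == 1L) return(1L)
  gaps <- c(diff(s), s[1] + 2 * pi - s[n])
  max(1L, sum(gaps > gap_tolerance))
}

#' Cluster labels from circular gaps
#'
#' Assigns each phase to a cluster using the same circular-gap criterion as
#' [count_phase_clusters()].
#'
#' @inheritParams count_phase_clusters
#' @return Integer vector of cluster labels (1-based, arbitrary order).
#' @export
phase_cluster_labels <- function(phases, gap_tolerance = 0.5) {
  n <- length(phases)
  ph <- wrap_phase(phases)
  ord <- order(ph)
  s <- ph[ord]
  gaps <- c(diff(s), s[1] + 2 * pi - s[n])
  lab_sorted <- cumsum(c(1, as.numeric(gaps[-n] > gap_tolerance)))
  # if the wrap-around gap is small, the first and last runs are one cluster
  if (n > 1 && gaps[n] <= gap_tolerance && max(lab_sorted) > 1)
    lab_sorted[lab_sorted == max(lab_sorted)] <- 1
  labs <- integer(n)
  labs[ord] <- lab_sorted
  match(labs, unique(labs))
}

#' Anti-phase recall score between two neuron groups
#'
#' Measures how far apart the circular mean phases of two groups are:
#' `(1 - cos(dpsi)) / 2`, where `dpsi` is the difference of the circular
#' means. The score is 1 when the groups fire in perfect anti-phase (the
#' stored pattern is recalled) and 0 when they are in phase.
#'
#' @param phases Numeric vector of all N phases.
#' @param cluster_a,cluster_b Disjoint non-empty index sets.
#' @return A number in `[0, 1]`.
#' @export
recall_score <- function(phases, cluster_a, cluster_b) {
  if (length(cluster_a) == 0L || length(cluster_b) == 0L)
    stop("both index sets must be non-empty", call. = FALSE)
  if (length(intersect(cluster_a, cluster_b)) > 0L)
    stop("index sets must be disjoint", call. = FALSE)
  psi_a <- Arg(mean(exp(1i * phases[cluster_a])))
  psi_b <- Arg(mean(exp(1i * phases[cluster_b])))
  (1 - cos(psi_a - psi_b)) / 2
}

#' Count surviving modules from structure and dynamics together
#'
#' A stored assembly has survived only if it is both structurally separate
#' (its strong weights do not bridge to another assembly) and dynamically
#' independent (it does not phase-lock onto another assembly). Two neurons
#' are linked if they are structurally connected at `strong_threshold` or
#' if they co-occur in the same phase cluster in at least a fraction
#' `lock_threshold` of the supplied phase samples; the surviving-module
#' count is the number of connected components of the union graph. Merging through either route
#' (weight regrowth or phase locking) therefore reduces the count, which is
#' the conservative reading of module survival on finite simulation
#' horizons, where phase locking precedes the slow structural fill-in. The
#' co-membership threshold is deliberately strict (`lock_threshold = 0.9`):
#' only pairs locked in phase through essentially the whole window count as
#' dynamically merged, whereas a cluster that merely drifts past another
#' (transient co-location during phase slips) does not. Likewise the gap
#' tolerance used for the dynamical labelling (0.25 rad) sits several times
#' above the internal spread of a synchronised cluster but below the offset
#' at which a distinct assembly can phase-lock behind another one, so only
#' true coalescence -- two populations collapsing into a single phase
#' cluster -- registers as a merge.
#'
#' @param weights Final N x N weight matrix.
#' @param types Neuron type labels.
#' @param phase_samples Matrix (samples x N) of phase snapshots from the
#'   final stretch of the run.
#' @param members Excitatory indices over which survival is judged.
#' @param strong_threshold Structural binarisation threshold.
#' @param gap_tolerance Circular gap tolerance for phase clusters.
#' @param lock_threshold Minimal co-membership fraction for a dynamical
#'   merge.
#' @return Integer number of surviving modules.
#' @export
count_surviving_modules <- function(weights, types, phase_samples,
                                    members = NULL, strong_threshold = 0.5,
                                    gap_tolerance = 0.25,
                                    lock_threshold = 0.9) {
  exc <- which(types == "excitatory")
  if (is.null(members)) members <- exc
  m <- length(members)
  if (m == 0L) return(0L)
  a <- abs(weights[members, members, drop = FALSE]) >= strong_threshold
  a <- a | t(a)
  n_samp <- nrow(phase_samples)
  co <- matrix(0, m, m)
  for (s in seq_len(n_samp)) {
    labs <- phase_cluster_labels(phase_samples[s, members], gap_tolerance)
    co <- co + outer(labs, labs, "==")
  }
  dyn <- co / max(1L, n_samp) > lock_threshold
  g <- igraph::graph_from_adjacency_matrix(a | dyn, mode = "undirected")
  as.integer(igraph::components(g)$no)
}

#' Order parameter series as a data frame
#'
#' @param series Matrix with columns `time, R1, Psi1, ..., Rn, Psin` as
#'   returned by the integrator.
#' @return Data frame with named columns.
#' @export
series_to_df <- function(series) {
  if (is.null(series) || nrow(series) == 0L)
    return(data.frame(time = numeric(0)))
  n_ord <- (ncol(series) - 1L) %/% 2L
  nm <- c("time", as.vector(rbind(paste0("R", seq_len(n_ord)),
                                  paste0("Psi", seq_len(n_ord)))))
  df <- as.data.frame(series)
  names(df) <- nm
  df
}
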