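#' Stimulus schedule
#'
#' A list of timed current blocks. Each block applies a constant external
#' current `amplitude` to the neurons in `targets` between `t_start` and
#' `t_end`. Inhibitory neurons are never stimulated; this is asserted
#' against the state's type vector when a schedule is used in a simulation.
#'
#' @param blocks Data frame with columns `t_start`, `t_end`, `amplitude`
#'   and a list-column `targets` of integer index vectors.
#' @param total_duration Total duration covered by the schedule.
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(blocks, total_duration) {
  stopifnot(is.data.frame(blocks),
            all(c("t_start", "t_end", "amplitude", "targets") %in% names(blocks)))
  if (nrow(blocks) && any(blocks$t_start >= blocks$t_end))
    stop("every block needs t_start < t_end", call. = FALSE)
  if (nrow(blocks) && any(vapply(blocks$targets, length, 1L) == 0L))
    stop("stimulus blocks must target at least one neuron", call. = FALSE)
  structure(list(blocks = blocks, total_duration = as.numeric(total_duration)),
            class = "stimulus_schedule")
}

#' Build an entrainment schedule
#'
#' Constructs the standard three-phase protocol: an initial rest period,
#' a learning phase of `n_blocks` stimulation blocks of length `block_len`
#' each targeting one of the supplied neuron groups, and a final rest
#' (consolidation) period. Block order is uniformly random by default;
#' with `strict_alternation = TRUE` the groups are stimulated in strict
#' round-robin order with an inter-block gap of `gap` time units (used for
#' the overlapping-stimuli protocol). Random group orders consume the R
#' random number stream.
#'
#' @param groups List of integer index vectors (excitatory neurons).
#' @param block_len Length of one stimulation block (default 20).
#' @param n_blocks Number of blocks (default 50).
#' @param rest_before,rest_after Rest durations before/after learning.
#' @param amplitude Stimulus current (default 3).
#' @param gap Inter-block gap, used with `strict_alternation`.
#' @param strict_alternation Round-robin group order instead of random.
#' @return A [stimulus_schedule()].
#' @export
build_learning_schedule <- function(groups, block_len = 20, n_blocks = 50,
                                    rest_before = 200, rest_after = 2000,
                                    amplitude = 3, gap = 0,
                                    strict_alternation = FALSE) {
  if (length(groups) == 0L || any(vapply(groups, length, 1L) == 0L))
    stop("every stimulus group must be non-empty", call. = FALSE)
  if (block_len <= 0) stop("`block_len` must be positive", call. = FALSE)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks > 0) {
    ord <- if (strict_alternation) {
      rep_len(seq_along(groups), n_blocks)
    } else {
      sample.int(length(groups), n_blocks, replace = TRUE)
    }
    starts <- rest_before + (seq_len(n_blocks) - 1) * (block_len + gap)
    blocks <- data.frame(t_start = starts, t_end = starts + block_len,
                         amplitude = amplitude)
    blocks$targets <- lapply(ord, function(g) as.integer(groups[[g]]))
  } else {
    blocks <- data.frame(t_start = numeric(0), t_end = numeric(0),
                         amplitude = numeric(0))
    blocks$targets <- list()
  }
  learn_len <- if (n_blocks > 0) n_blocks * block_len + (n_blocks - 1) * gap else 0
  stimulus_schedule(blocks, rest_before + learn_len + rest_after)
}

#' Partition excitatory neurons into stimulus groups
#'
#' Splits the excitatory indices `1..n_excitatory` into `n_groups`
#' near-equal contiguous groups (the canonical two-stimulus split of 80
#' excitatory neurons is 1-40 and 41-80).
#'
#' @param n_excitatory Number of excitatory neurons.
#' @param n_groups Number of stimulus groups.
#' @param n_hubs Number of shared (hub) neurons between consecutive groups;
#'   with `n_groups = 2` the hubs are the middle `n_hubs` indices, included
#'   in both groups.
#' @return List of integer index vectors.
#' @export
stimulus_groups <- function(n_excitatory, n_groups = 2L, n_hubs = 0L) {
  if (n_hubs == 0L) {
    sizes <- rep(n_excitatory %/% n_groups, n_groups)
    extra <- n_excitatory %% n_groups
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    return(Map(function(a, b) seq.int(a, b), starts, ends))
  }
  if (n_groups != 2L)
    stop("hub groups are defined for two stimuli", call. = FALSE)
  n_excl <- n_excitatory - n_hubs
  if (n_excl < 2L) stop("not enough exclusive neurons", call. = FALSE)
  n1 <- n_excl %/% 2L + n_excl %% 2L
  excl1 <- seq_len(n1)
  hubs <- seq.int(n1 + 1L, n1 + n_hubs)
  excl2 <- seq.int(n1 + n_hubs + 1L, n_excitatory)
  list(c(excl1, hubs), c(hubs, excl2))
}

#' Module layout for pre-trained networks
#'
#' Describes the target modular architecture: a cover of the excitatory
#' indices by M clusters (hub neurons may belong to several), and the
#' assignment of each inhibitory neuron to exactly one cluster.
#'
#' @param clusters List of integer vectors covering all excitatory indices.
#' @param inhibitory_assignment Named or plain integer vector mapping each
#'   inhibitory index to a cluster id (1..M); may be empty.
#' @param inhibitory Integer vector of inhibitory neuron indices.
#' @param N Total number of neurons.
#' @return An object of class `module_layout` with fields `clusters`,
#'   `hubs` (indices in more than one cluster), `inhibitory`,
#'   `inhibitory_assignment` and `N`.
#' @export
module_layout <- function(clusters, inhibitory, inhibitory_assignment, N) {
  all_exc <- sort(unique(unlist(clusters)))
  exc_expected <- setdiff(seq_len(N), inhibitory)
  if (!identical(all_exc, as.integer(exc_expected)) &&
      !identical(as.integer(all_exc), as.integer(exc_expected)))
    stop("clusters must cover all excitatory indices", call. = FALSE)
  if (length(inhibitory_assignment) != length(inhibitory))
    stop("each inhibitory neuron needs exactly one cluster assignment",
         call. = FALSE)
  if (length(inhibitory_assignment) &&
      (any(inhibitory_assignment < 1) ||
       any(inhibitory_assignment > length(clusters))))
    stop("inhibitory neuron assigned to a nonexistent cluster", call. = FALSE)
  counts <- table(unlist(clusters))
  hubs <- as.integer(names(counts)[counts >= 2L])
  structure(list(clusters = lapply(clusters, as.integer),
                 hubs = hubs,
                 inhibitory = as.integer(inhibitory),
                 inhibitory_assignment = as.integer(inhibitory_assignment),
                 N = as.integer(N)),
            class = "module_layout")
}

#' Layout with M non-overlapping clusters
#'
#' Excitatory indices `1..(N - n_inhibitory)` are split into M near-equal
#' clusters; inhibitory indices are the last `n_inhibitory` and are
#' assigned to clusters round-robin (cluster 1, 2, ..., M, 1, ...), so with
#' fewer inhibitory neurons than clusters the trailing clusters have none.
#'
#' @param N Total number of neurons.
#' @param M Number of clusters.
#' @param n_inhibitory Number of inhibitory neurons.
#' @return A [module_layout()].
#' @export
layout_modules <- function(N, M, n_inhibitory) {
  n_exc <- N - n_inhibitory
  if (M < 1 || M > n_exc)
    stop("`M` must lie in [1, N - n_inhibitory]", call. = FALSE)
  clusters <- stimulus_groups(n_exc, M)
  inh <- if (n_inhibitory > 0) seq.int(n_exc + 1L, N) else integer(0)
  assign <- if (n_inhibitory > 0) ((seq_len(n_inhibitory) - 1L) %% M) + 1L
            else integer(0)
  module_layout(clusters, inh, assign, N)
}

#' Layout with two clusters sharing hub neurons
#'
#' Two clusters of excitatory neurons share `n_hubs` hub neurons (members
#' of both); the remaining excitatory neurons are split evenly between the
#' clusters. Inhibitory neurons are assigned round-robin to the two
#' clusters.
#'
#' @param N Total number of neurons.
#' @param n_hubs Number of shared hub neurons.
#' @param n_inhibitory Number of inhibitory neurons.
#' @return A [module_layout()].
#' @export
layout_hubs <- function(N, n_hubs, n_inhibitory) {
  n_exc <- N - n_inhibitory
  groups <- stimulus_groups(n_exc, 2L, n_hubs)
  inh <- if (n_inhibitory > 0) seq.int(n_exc + 1L, N) else integer(0)
  assign <- if (n_inhibitory > 0) ((seq_len(n_inhibitory) - 1L) %% 2L) + 1L
            else integer(0)
  module_layout(groups, inh, assign, N)
}

#' Layout with M clusters all sharing a common hub group
#'
#' Generalises [layout_hubs()]: `n_hubs` excitatory neurons belong to all
#' `M` clusters (they encode every stimulus); the remaining excitatory
#' neurons are split evenly into exclusive groups. Inhibitory neurons are
#' assigned round-robin.
#'
#' @param N Total number of neurons.
#' @param M Number of clusters.
#' @param n_hubs Number of hub neurons shared by all clusters.
#' @param n_inhibitory Number of inhibitory neurons.
#' @return A [module_layout()].
#' @export
layout_hub_modules <- function(N, M, n_hubs, n_inhibitory) {
  n_exc <- N - n_inhibitory
  n_excl <- n_exc - n_hubs
  if (n_excl < M) stop("not enough exclusive neurons", call. = FALSE)
  excl <- stimulus_groups(n_excl, M)
  hubs <- if (n_hubs > 0) seq.int(n_excl + 1L, n_exc) else integer(0)
  clusters <- lapply(excl, function(g) c(g, hubs))
  inh <- if (n_inhibitory > 0) seq.int(n_exc + 1L, N) else integer(0)
  assign <- if (n_inhibitory > 0) ((seq_len(n_inhibitory) - 1L) %% M) + 1L
            else integer(0)
  module_layout(clusters, inh, assign, N)
}

#' Build a pre-trained (consolidated) weight matrix
#'
#' Constructs the idealised consolidated architecture for a module layout:
#' within each cluster all excitatory weights are 1 (including hub links to
#' the members of every cluster the hub belongs to) and 0 across clusters;
#' each inhibitory neuron receives weight-1 excitation from the members of
#' its assigned cluster (hubs included) and nothing else; it inhibits with
#' weight -1 the excitatory neurons exclusive to other clusters and the
#' inhibitory neurons of other clusters, while its own cluster and all hub
#' neurons receive no inhibition. The diagonal is zero.
#'
#' @param N Total number of neurons.
#' @param layout A [module_layout()].
#' @return An N x N matrix with entries in `{-1, 0, 1}`.
#' @export
build_pretrained_matrix <- function(N, layout) {
  stopifnot(inherits(layout, "module_layout"))
  if (layout$N != N) stop("layout is for N = ", layout$N, call. = FALSE)
  M <- length(layout$clusters)
  k <- matrix(0, N, N)
  inh <- layout$inhibitory
  hubs <- layout$hubs
  for (c_id in seq_len(M)) {
    cl <- layout$clusters[[c_id]]
    # intra-cluster excitation
    k[cl, cl] <- 1
    # feedforward excitation onto the cluster's inhibitory neurons
    my_inh <- inh[layout$inhibitory_assignment == c_id]
    if (length(my_inh)) k[my_inh, cl] <- 1
    # inhibition of the other clusters (exclusive members only) and of
    # the other clusters' inhibitory neurons
    if (length(my_inh)) {
      others <- setdiff(seq_len(M), c_id)
      other_exc <- setdiff(unlist(layout$clusters[others]), c(cl, hubs))
      if (length(other_exc)) k[other_exc, my_inh] <- -1
      other_inh <- inh[layout$inhibitory_assignment != c_id]
      if (length(other_inh)) k[other_inh, my_inh] <- -1
    }
  }
  diag(k) <- 0
  k
}

#' Soften a pre-trained matrix to post-learning values
#'
#' Maps the idealised `{-1, 0, 1}` consolidated matrix onto the nearly (but
#' not fully) saturated weights found at the end of a learning phase:
#' saturated entries become `w_high` in magnitude and pruned entries
#' `w_low`, with the sign dictated by the pre-synaptic neuron's type. The
#' soft-bound weight dynamics make exactly-saturated weights nearly
#' immobile, so stability experiments start from these softened matrices.
#'
#' @param weights `{-1, 0, 1}` matrix from [build_pretrained_matrix()].
#' @param types Neuron type labels.
#' @param w_high Magnitude of saturated weights.
#' @param w_low Magnitude of pruned weights.
#' @return Softened weight matrix (zero diagonal).
#' @export
soften_pretrained <- function(weights, types, w_high = 0.99, w_low = 0.01) {
  k <- weights
  sgn <- ifelse(types == "inhibitory", -1, 1)
  sat <- abs(k) >= 0.5
  k[sat] <- sign(k[sat]) * w_high
  low <- matrix(sgn, nrow(k), ncol(k), byrow = TRUE) * w_low
  k[!sat] <- low[!sat]
  diag(k) <- 0
  k
}

#' Redraw the excitatory-to-excitatory weights at random
#'
#' Replaces every weight between two excitatory neurons with a fresh
#' uniform `[0, 1]` draw while leaving every connection involving an
#' inhibitory neuron untouched. This models the volatility of excitatory
#' synapses: the stored pattern survives only in the inhibitory wiring.
#' Consumes the R random number stream.
#'
#' @param state A [network_state()] in E/I mode.
#' @return The state with scrambled excitatory weights (zero diagonal).
#' @export
scramble_excitatory_weights <- function(state) {
  exc <- which(state$types == "excitatory")
  k <- state$weights
  k[exc, exc] <- stats::runif(length(exc)^2)
  diag(k) <- 0
  state$weights <- k
  state
}

#' Currents generated by a schedule at a given time
#'
#' @param schedule A [stimulus_schedule()].
#' @param t Time.
#' @param N Number of neurons.
#' @return Numeric vector of N currents.
#' @export
schedule_currents <- function(schedule, t, N) {
  cur <- numeric(N)
  b <- schedule$blocks
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      if (b$t_start[r] <= t && t < b$t_end[r])
        cur[b$targets[[r]]] <- cur[b$targets[[r]]] + b$amplitude[r]
    }
  }
  cur
}

# internal: convert a schedule to the matrix + target list form used by the
# compiled core, checking that no inhibitory neuron is ever targeted
schedule_to_core <- function(schedule, types) {
  b <- schedule$blocks
  if (!nrow(b))
    return(list(blocks = matrix(numeric(0), 0, 3), targets = list()))
  inh <- which(types == "inhibitory")
  for (tg in b$targets) {
    if (length(intersect(tg, inh)))
      stop("stimulus schedule targets inhibitory neurons", call. = FALSE)
    if (any(tg < 1) || any(tg > length(types)))
      stop("stimulus target index out of range", call. = FALSE)
  }
  list(blocks = cbind(b$t_start, b$t_end, b$amplitude),
       targets = lapply(b$targets, function(tg) as.integer(tg) - 1L))
}
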