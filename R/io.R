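#' Default model parameters
#'
#' The standard operating point of the network: N = 100 neurons, 80
#' excitatory / 20 inhibitory, coupling g = 1, stimulus current 3, slow and
#' fast learning rates 1e-5 and 0.1, integration step 0.01, noise standard
#' deviation 0.1, excitabilities ~ Normal(mean 1.5, sd 0.01).
#'
#' @return Named list of defaults.
#' @export
default_config_values <- function() {
  list(N = 100L, n_inhibitory = 20L, mode = "ei",
       g = 1, dt = 0.01, noise_variance = 0.01,
       eta_mean = 1.5, eta_variance = 1e-4,
       eps_slow = 1e-5, eps_fast = 0.1, gate_threshold = 0.1,
       kernel = "asymmetric_exponential",
       amplitude = 3, block_len = 20, n_blocks = 50L, rest = 200,
       n_stimuli = 2L, n_hubs = 0L,
       rho = 100, consolidation_duration = 2000,
       seed = 1L)
}

#' Load a run configuration
#'
#' Reads a YAML configuration file; missing keys are filled from
#' [default_config_values()], unknown keys raise an error, and basic range
#' checks are applied (`dt > 0`, `eps_slow < eps_fast`, ...). An empty file
#' yields the full defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `values` (full parameter list), `config`
#'   (a [sim_config()]) and `rule` (a [plasticity_rule()]).
#' @export
load_config <- function(path) {
  vals <- default_config_values()
  user <- tryCatch(yaml::read_yaml(path),
                   error = function(e)
                     stop("malformed configuration file: ",
                          conditionMessage(e), call. = FALSE))
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("malformed configuration file", call. = FALSE)
  unknown <- setdiff(names(user), names(vals))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals[names(user)] <- user
  if (vals$dt <= 0)
    stop("configuration error: dt must be positive", call. = FALSE)
  if (vals$noise_variance < 0)
    stop("configuration error: noise_variance must be >= 0", call. = FALSE)
  if (vals$eps_slow >= vals$eps_fast)
    stop("configuration error: eps_slow must be smaller than eps_fast",
         call. = FALSE)
  if (!vals$mode %in% c("ei", "excitatory_only", "unlabelled"))
    stop("configuration error: mode must be ei, excitatory_only or unlabelled",
         call. = FALSE)
  if (vals$mode != "ei" && vals$n_inhibitory != 0)
    stop("configuration error: n_inhibitory must be 0 unless mode = ei",
         call. = FALSE)
  cfg <- sim_config(g = vals$g, dt = vals$dt,
                    noise_variance = vals$noise_variance,
                    eta_mean = vals$eta_mean, eta_variance = vals$eta_variance)
  rule <- plasticity_rule(kernel = vals$kernel, eps_slow = vals$eps_slow,
                          eps_fast = vals$eps_fast,
                          gate_threshold = vals$gate_threshold,
                          dale_mode = vals$mode)
  list(values = vals, config = cfg, rule = rule)
}

#' Write run artifacts to a directory
#'
#' Serialises a [run_main_experiment()] result (or any compatible list) as
#' plain text: weight snapshots as tab-delimited matrices (one row per
#' post-synaptic neuron), the spike raster and order-parameter series as
#' TSV, and a JSON summary plus a manifest listing every file written.
#'
#' @param run A `theta_run` (or a list with the same fields).
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wt <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t",
                       row.names = FALSE, col.names = TRUE, quote = FALSE)
    files <<- c(files, name)
  }
  wm <- function(m, name) {
    utils::write.table(format(m, digits = 17, trim = TRUE),
                       file.path(dir, name), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    files <<- c(files, name)
  }
  for (nm in names(run$snapshots)) {
    snap <- run$snapshots[[nm]]
    wm(snap$weights, paste0("weights_", nm, ".tsv"))
    wt(data.frame(phase = snap$phases), paste0("phases_", nm, ".tsv"))
  }
  wt(run$raster, "raster.tsv")
  wt(run$series, "series.tsv")
  summ <- run$summary
  summ$snapshot_times <- lapply(run$snapshots, `[[`, "time")
  params <- run$params
  params$groups <- NULL
  params$config <- unclass(params$config)
  params$rule <- unclass(params$rule)
  params$consolidation <- unclass(params$consolidation)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "summary.json")
  jsonlite::write_json(params, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "config.json")
  manifest <- list(files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read run artifacts back from a directory
#'
#' Verifies the manifest (every referenced file must exist) and reloads the
#' text artifacts written by [write_run()]. Matrices round-trip to better
#' than 1e-12.
#'
#' @param dir Run directory.
#' @return A list with `snapshots`, `raster`, `series`, `summary`,
#'   `params`.
#' @export
read_run <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop("run directory has no manifest", call. = FALSE)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  missing <- manifest$files[!file.exists(file.path(dir, manifest$files))]
  if (length(missing))
    stop("run integrity error: missing file(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  snaps <- list()
  wfiles <- grep("^weights_", manifest$files, value = TRUE)
  for (wf in wfiles) {
    nm <- sub("^weights_(.*)\\.tsv$", "\\1", wf)
    w <- as.matrix(utils::read.table(file.path(dir, wf), sep = "\t",
                                     header = FALSE))
    dimnames(w) <- NULL
    ph <- utils::read.table(file.path(dir, paste0("phases_", nm, ".tsv")),
                            sep = "\t", header = TRUE)$phase
    snaps[[nm]] <- list(weights = w, phases = ph)
  }
  raster <- utils::read.table(file.path(dir, "raster.tsv"), sep = "\t",
                              header = TRUE)
  series <- utils::read.table(file.path(dir, "series.tsv"), sep = "\t",
                              header = TRUE)
  summary <- jsonlite::read_json(file.path(dir, "summary.json"),
                                 simplifyVector = TRUE)
  params <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  list(snapshots = snaps, raster = raster, series = series,
       summary = summary, params = params)
}
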