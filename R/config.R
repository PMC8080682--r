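# Flat configuration key set: every key maps to exactly one field of the
# nested run configuration. Unknown keys are an error, so typos never pass
# silently.
config_keys <- function() {
  c("topology", "n_nodes", "growth_degree", "triad_probability",
    "grid_side", "grid_neighborhood", "weight_mean", "weight_sd",
    "network_seed",
    "phi", "self_weight", "noise_half_width", "middle_branch_mode",
    "init_mean", "init_sd",
    "max_sweeps", "record_interval", "absorption_tol", "n_realizations",
    "base_seed",
    "intervention_kind", "trigger", "trigger_time", "new_phi",
    "pinned_value", "smoothing_window", "patience",
    "output_dir", "log_level")
}

#' Default run configuration
#'
#' The reference ("standard") conditions: clustered scale-free network of
#' 1089 nodes grown at degree 8 with triad probability 0.5, edge weights
#' Normal(0.5, 0.15), field 0.05, self weight 0.6, noise half-width 0.1,
#' initial behaviours Normal(-0.25, 0.15), 500 realizations.
#'
#' @return A list of class `run_config` with fields `network`
#'   ([network_config()]), `model` ([model_params()]), `schedule`
#'   ([sim_schedule()]), `intervention` (an [intervention_spec()] or
#'   `NULL`), `output_dir`, `log_level`.
#' @export
default_config <- function() {
  structure(list(network = network_config(),
                 model = model_params(),
                 schedule = sim_schedule(),
                 intervention = NULL,
                 output_dir = ".",
                 log_level = "info"),
            class = "run_config")
}

#' Load / write a run configuration
#'
#' Configurations are flat YAML files with the documented key set (see the
#' package vignette); any unknown key is an error. Keys not present keep
#' their defaults, and `write_config(default_config())` followed by
#' `load_config()` reproduces the default configuration exactly.
#'
#' @param path file path.
#' @return `load_config()` returns a validated `run_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config_from_flat(raw)
}

# build a run_config from a flat named list of overrides
config_from_flat <- function(flat) {
  cfg <- default_config()
  pick <- function(key, default) {
    if (!is.null(flat[[key]])) flat[[key]] else default
  }
  cfg$network <- network_config(
    topology = pick("topology", "csf"),
    n_nodes = pick("n_nodes", 1089L),
    growth_degree = pick("growth_degree", 8L),
    triad_probability = pick("triad_probability", 0.5),
    grid_side = pick("grid_side", 13L),
    grid_neighborhood = pick("grid_neighborhood", "degree16"),
    weight_mean = pick("weight_mean", 0.5),
    weight_sd = pick("weight_sd", 0.15),
    seed = pick("network_seed", 1L))
  cfg$model <- model_params(
    phi = pick("phi", 0.05),
    self_weight = pick("self_weight", 0.6),
    noise_half_width = pick("noise_half_width", 0.1),
    middle_branch_mode = pick("middle_branch_mode", "pure_noise"),
    init_mean = pick("init_mean", -0.25),
    init_sd = pick("init_sd", 0.15))
  cfg$schedule <- sim_schedule(
    max_sweeps = pick("max_sweeps", 2000),
    record_interval = pick("record_interval", 1),
    absorption_tol = pick("absorption_tol", 1e-3),
    n_realizations = pick("n_realizations", 500L),
    base_seed = pick("base_seed", 1L))
  kind <- pick("intervention_kind", "none")
  cfg["intervention"] <- list(if (identical(kind, "none")) NULL else
    intervention_spec(
      kind = kind,
      trigger = pick("trigger", "at_polarisation_minimum"),
      trigger_time = pick("trigger_time", 0),
      new_phi = flat[["new_phi"]],
      pinned_value = pick("pinned_value", 1),
      smoothing_window = pick("smoothing_window", 5L),
      patience = pick("patience", 10L)))
  cfg$output_dir <- pick("output_dir", ".")
  cfg$log_level <- pick("log_level", "info")
  if (!cfg$log_level %in% c("quiet", "info", "debug"))
    stop("log_level must be quiet, info or debug", call. = FALSE)
  cfg
}

# flatten a run_config back to the documented key set
config_to_flat <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  nw <- cfg$network; md <- cfg$model; sc <- cfg$schedule
  flat <- list(
    topology = nw$topology, n_nodes = nw$n_nodes,
    growth_degree = nw$growth_degree,
    triad_probability = nw$triad_probability,
    grid_side = nw$grid_side, grid_neighborhood = nw$grid_neighborhood,
    weight_mean = nw$weight_mean, weight_sd = nw$weight_sd,
    network_seed = nw$seed,
    phi = md$phi, self_weight = md$self_weight,
    noise_half_width = md$noise_half_width,
    middle_branch_mode = md$middle_branch_mode,
    init_mean = md$init_mean, init_sd = md$init_sd,
    max_sweeps = sc$max_sweeps, record_interval = sc$record_interval,
    absorption_tol = sc$absorption_tol,
    n_realizations = sc$n_realizations, base_seed = sc$base_seed,
    intervention_kind = if (is.null(cfg$intervention)) "none" else
      cfg$intervention$kind,
    output_dir = cfg$output_dir, log_level = cfg$log_level)
  if (!is.null(cfg$intervention)) {
    iv <- cfg$intervention
    flat$trigger <- iv$trigger
    flat$trigger_time <- iv$trigger_time
    if (!is.null(iv$new_phi)) flat$new_phi <- iv$new_phi
    flat$pinned_value <- iv$pinned_value
    flat$smoothing_window <- iv$smoothing_window
    flat$patience <- iv$patience
  }
  flat
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_flat(config), path)
  invisible(path)
}

#' Write an ensemble result and its provenance to disk
#'
#' Persists the diff-able text outputs: `trajectories.csv` (long format:
#' `realization`, `time_sweeps`, `mean_b`, `sd_b`), `classifications.json`
#' (terminal state, absorption/trigger times, holdouts and seeds per
#' realization), `histogram.csv` (uncapped time x cooperativity counts) and
#' `manifest.json` (flat config plus seeds and package version), from which
#' the run can be regenerated exactly.
#'
#' @param result an `ensemble_result`.
#' @param dir output directory (created if missing).
#' @param config optional `run_config` recorded in the manifest.
#' @param histogram_bins bins for the histogram CSV.
#' @return `dir`, invisibly.
#' @export
write_ensemble_result <- function(result, dir, config = NULL,
                                  histogram_bins = 50L) {
  stopifnot(inherits(result, "ensemble_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_real <- nrow(result$mean_b)
  long <- data.frame(
    realization = rep(seq_len(n_real), each = length(result$time)),
    time_sweeps = rep(result$time, n_real),
    mean_b = as.vector(t(result$mean_b)),
    sd_b = as.vector(t(result$sd_b)))
  utils::write.csv(long, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  cls <- list(classification = result$classification,
              absorb_time_sweeps = result$absorb_time,
              trigger_time_sweeps = result$trigger_time,
              holdouts = result$holdouts,
              seeds = result$seeds,
              network_seeds = result$network_seeds)
  jsonlite::write_json(cls, file.path(dir, "classifications.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  h <- cooperativity_histogram(result, n_bins = histogram_bins)
  hm <- as.data.frame(h$counts)
  names(hm) <- sprintf("t%g", h$time)
  hm <- cbind(bin_lower = h$breaks[-length(h$breaks)], hm)
  utils::write.csv(hm, file.path(dir, "histogram.csv"), row.names = FALSE)
  write_manifest(dir, config = config,
                 extra = list(n_realizations = n_real,
                              base_seed = if (!is.null(result$schedule))
                                result$schedule$base_seed else NA))
  invisible(dir)
}

# manifest: everything needed to regenerate the outputs
write_manifest <- function(dir, config = NULL, extra = list()) {
  man <- c(list(package = "coopnet",
                version = as.character(utils::packageVersion("coopnet")),
                config = if (!is.null(config)) config_to_flat(config)),
           extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
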