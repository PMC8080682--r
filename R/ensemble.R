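#' Run an ensemble of independent realizations
#'
#' Runs `schedule$n_realizations` mutually independent realizations. When
#' `network` is a [network_config()], a fresh network (new topology and new
#' edge weights) is generated for every realization, seeded
#' `base_seed + 1000000 + i`; pass `share_network = TRUE` or a concrete
#' [social_network()] to reuse one graph. Realization `i` itself is seeded
#' `base_seed + i`. Aggregation is by realization index, so the result does
#' not depend on execution order.
#'
#' All series are aligned on the common time grid
#' `seq(0, max_sweeps, record_interval)`; realizations that absorb early are
#' carried forward at their terminal values, so ensemble averages are
#' defined at every time.
#'
#' @param network a [network_config()] or a [social_network()].
#' @param params a [model_params()].
#' @param schedule a [sim_schedule()].
#' @param intervention optional [intervention_spec()] applied per
#'   realization.
#' @param share_network if `TRUE` and `network` is a config, generate one
#'   network (seed `base_seed + 1000000`) and reuse it.
#' @param progress optional function called as `progress(i, trajectory)`
#'   after each realization (used by the CLI for per-realization logging).
#' @return An object of class `ensemble_result`: `time` (grid, sweeps),
#'   matrices `mean_b` and `sd_b` (realization x time), `classification`,
#'   `absorb_time`, `trigger_time`, `pinned_node`, `seeds`,
#'   `network_seeds`, plus the configs used.
#' @export
run_ensemble <- function(network, params, schedule, intervention = NULL,
                         share_network = FALSE, progress = NULL) {
  stopifnot(inherits(params, "model_params"),
            inherits(schedule, "sim_schedule"))
  n_real <- schedule$n_realizations
  times <- seq(0, schedule$max_sweeps, by = schedule$record_interval)
  n_rec <- length(times)
  fresh <- inherits(network, "network_config") && !share_network
  shared_net <- if (inherits(network, "social_network")) {
    network
  } else if (share_network) {
    cfg <- network; cfg$seed <- schedule$base_seed + 1000000L
    generate_network(cfg)
  } else NULL

  mean_b <- matrix(NA_real_, n_real, n_rec)
  sd_b <- matrix(NA_real_, n_real, n_rec)
  classification <- character(n_real)
  holdouts <- rep(NA_integer_, n_real)
  absorb_time <- rep(NA_real_, n_real)
  trigger_time <- rep(NA_real_, n_real)
  pinned_node <- rep(NA_integer_, n_real)
  seeds <- schedule$base_seed + seq_len(n_real)
  network_seeds <- if (fresh) schedule$base_seed + 1000000L + seq_len(n_real)
                   else rep(NA_integer_, n_real)

  for (i in seq_len(n_real)) {
    net_i <- if (fresh) {
      cfg <- network; cfg$seed <- network_seeds[i]
      generate_network(cfg)
    } else shared_net
    tr <- run_realization(net_i, params, schedule, seed = seeds[i],
                          intervention = intervention)
    k <- length(tr$time)
    mean_b[i, seq_len(k)] <- tr$mean_b
    sd_b[i, seq_len(k)] <- tr$sd_b
    if (k < n_rec) {  # absorbed early: carry terminal values forward
      mean_b[i, (k + 1L):n_rec] <- tr$mean_b[k]
      sd_b[i, (k + 1L):n_rec] <- tr$sd_b[k]
    }
    classification[i] <- tr$classification
    holdouts[i] <- tr$holdouts
    absorb_time[i] <- tr$absorb_time
    trigger_time[i] <- tr$trigger_time
    pinned_node[i] <- tr$pinned_node
    if (!is.null(progress)) progress(i, tr)
  }

  new_ensemble_result(times, mean_b, sd_b, classification,
                      holdouts = holdouts,
                      absorb_time = absorb_time,
                      trigger_time = trigger_time,
                      pinned_node = pinned_node, seeds = seeds,
                      network_seeds = network_seeds,
                      params = params, schedule = schedule,
                      intervention = intervention,
                      network = if (inherits(network, "network_config"))
                        network else NULL)
}

#' Low-level ensemble-result constructor
#'
#' Assembles an `ensemble_result` from raw aligned series; used internally
#' by [run_ensemble()] and handy for building small synthetic fixtures.
#'
#' @param time increasing time grid (sweeps).
#' @param mean_b,sd_b numeric matrices, one row per realization, one column
#'   per time point.
#' @param classification character vector of terminal states.
#' @param ... optional fields (`absorb_time`, `seeds`, configs, ...).
#' @return An `ensemble_result`.
#' @export
new_ensemble_result <- function(time, mean_b, sd_b, classification, ...) {
  mean_b <- rbind(mean_b); sd_b <- rbind(sd_b)
  stopifnot(!is.unsorted(time, strictly = TRUE),
            ncol(mean_b) == length(time), ncol(sd_b) == length(time),
            nrow(mean_b) == length(classification))
  structure(c(list(time = time, mean_b = mean_b, sd_b = sd_b,
                   classification = classification), list(...)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  fr <- final_state_fractions(x)
  cat(sprintf(
    "<ensemble_result> %d realizations x %d record points (%.1f sweeps)\n",
    nrow(x$mean_b), length(x$time), max(x$time)))
  cat(sprintf("  terminal: %.0f%% cooperative, %.0f%% defective, %.0f%% unresolved\n",
              100 * fr[["cooperative"]], 100 * fr[["defective"]],
              100 * fr[["unresolved"]]))
  invisible(x)
}

#' Ensemble mean and polarisation trajectories
#'
#' The ensemble mean is the pointwise average over realizations of the
#' per-realization mean cooperativity. The polarisation statistic is the
#' average over realizations of the per-realization SD of cooperativity --
#' never the pooled SD, so between-realization disagreement does not count
#' as polarisation.
#'
#' @param result an `ensemble_result`.
#' @return A data frame with columns `time` and `mean_b` (or `sd_b`).
#' @export
ensemble_mean_trajectory <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  if (nrow(result$mean_b) == 0L) stop("empty ensemble", call. = FALSE)
  data.frame(time = result$time, mean_b = colMeans(result$mean_b))
}

#' @rdname ensemble_mean_trajectory
#' @export
ensemble_sd_trajectory <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  if (nrow(result$sd_b) == 0L) stop("empty ensemble", call. = FALSE)
  data.frame(time = result$time, sd_b = colMeans(result$sd_b))
}

#' Trajectory-density histogram
#'
#' Bins the per-realization mean cooperativity into `n_bins` equal bins on
#' `[-1, 1]` at every recorded time, giving the (time x cooperativity)
#' density of realizations. A capped copy (`pmin(counts, count_cap)`) is
#' provided for contrast-enhanced display; the uncapped matrix conserves
#' the realization count in every column.
#'
#' @param result an `ensemble_result`.
#' @param n_bins number of cooperativity bins (>= 2).
#' @param count_cap cap applied to the display copy (>= 1).
#' @return List of class `cooperativity_histogram` with `counts` and
#'   `capped` (`n_bins` x `length(time)` matrices), `breaks` and `time`.
#' @export
cooperativity_histogram <- function(result, n_bins = 50L, count_cap = 100L) {
  stopifnot(inherits(result, "ensemble_result"), n_bins >= 2L,
            count_cap >= 1L)
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  counts <- vapply(seq_along(result$time), function(k) {
    v <- result$mean_b[, k]
    idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                n_bins)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins))
  counts <- matrix(counts, nrow = n_bins)
  structure(list(counts = counts, capped = pmin(counts, count_cap),
                 breaks = breaks, time = result$time,
                 count_cap = count_cap),
            class = "cooperativity_histogram")
}

#' Terminal-state fractions
#'
#' @param result an `ensemble_result`.
#' @return Named numeric vector over `cooperative`, `defective`,
#'   `unresolved`; sums to 1.
#' @export
final_state_fractions <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  cls <- result$classification
  if (length(cls) == 0L) stop("empty ensemble", call. = FALSE)
  states <- c("cooperative", "defective", "unresolved")
  out <- vapply(states, function(s) mean(cls == s), numeric(1))
  names(out) <- states
  out
}

#' Cooperative fraction under capped-horizon classification
#'
#' Fraction of realizations that either absorbed cooperatively or, if still
#' unresolved at the horizon, ended with positive mean cooperativity. This
#' is the classification used by the tipping-point search, where waiting
#' for full absorption near the critical field would be prohibitively slow.
#'
#' @param result an `ensemble_result`.
#' @return A fraction in `[0, 1]`.
#' @export
cooperative_fraction <- function(result) {
  stopifnot(inherits(result, "ensemble_result"))
  final_mean <- result$mean_b[, ncol(result$mean_b)]
  mean(result$classification == "cooperative" |
         (result$classification == "unresolved" & final_mean > 0))
}
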