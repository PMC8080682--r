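#' Intervention specification
#'
#' Two protocols for steering a run after the transient polarisation stage:
#' `"field_switch"` replaces the external field by `new_phi`, and
#' `"influencer"` pins the highest-degree agent (ties broken toward the
#' lowest node id) at `pinned_value`, turning it into an unyielding
#' cooperator that keeps influencing its neighbours. The trigger is either
#' per-realization detection of the polarisation minimum of the smoothed
#' mean-cooperativity series (default) or a fixed time in sweeps
#' (`trigger_time = 0` applies the intervention before the first event).
#'
#' The online minimum detector smooths the recorded means with a trailing
#' moving average of `smoothing_window` points and fires once no new minimum
#' has appeared for `patience` recorded points, i.e. shortly after the
#' minimum itself, which is when the dynamical crossover to cluster
#' dissolution happens.
#'
#' @param kind `"field_switch"` or `"influencer"`.
#' @param trigger `"at_polarisation_minimum"` or `"at_fixed_time"`.
#' @param trigger_time trigger time in sweeps (fixed-time trigger only).
#' @param new_phi replacement field (field switch only).
#' @param pinned_value behaviour at which the influencer is pinned,
#'   in `[-1, 1]`.
#' @param smoothing_window,patience detector settings in recorded points.
#' @return A validated list of class `intervention_spec`.
#' @export
intervention_spec <- function(kind = c("field_switch", "influencer"),
                              trigger = c("at_polarisation_minimum",
                                          "at_fixed_time"),
                              trigger_time = 0, new_phi = NULL,
                              pinned_value = 1,
                              smoothing_window = 5L, patience = 10L) {
  kind <- match.arg(kind)
  trigger <- match.arg(trigger)
  if (kind == "field_switch" && (is.null(new_phi) || !is.numeric(new_phi)))
    stop("field_switch requires a numeric new_phi", call. = FALSE)
  if (abs(pinned_value) > 1)
    stop("pinned_value must lie in [-1, 1]", call. = FALSE)
  if (trigger_time < 0) stop("trigger_time must be >= 0", call. = FALSE)
  if (smoothing_window < 1L || patience < 1L)
    stop("smoothing_window and patience must be >= 1", call. = FALSE)
  structure(list(kind = kind, trigger = trigger,
                 trigger_time = trigger_time, new_phi = new_phi,
                 pinned_value = pinned_value,
                 smoothing_window = as.integer(smoothing_window),
                 patience = as.integer(patience)),
            class = "intervention_spec")
}

# dispatcher used by run_realization at trigger time
apply_intervention <- function(spec, network, behaviours) {
  if (spec$kind == "influencer") {
    res <- pin_influencer(network, behaviours, spec$pinned_value)
    list(network = res$network, behaviours = res$behaviours,
         pinned_node = res$node)
  } else {
    list(network = network, behaviours = behaviours,
         pinned_node = NA_integer_)
  }
}

#' Pin the highest-degree agent
#'
#' Marks the maximum-degree node (ties broken toward the lowest id) as
#' pinned at `pinned_value` and sets its behaviour accordingly. Pinned
#' agents are still selected for events and still persuade their
#' neighbours, but their own behaviour never changes.
#'
#' @param network a [social_network()].
#' @param behaviours current behaviour vector.
#' @param pinned_value value in `[-1, 1]` (default `+1`, a zealous
#'   cooperator).
#' @return List with the updated `network`, `behaviours` and the pinned
#'   `node` id.
#' @export
pin_influencer <- function(network, behaviours, pinned_value = 1) {
  stopifnot(inherits(network, "social_network"),
            length(behaviours) == network$n_nodes,
            abs(pinned_value) <= 1)
  node <- which.max(node_degrees(network))  # which.max takes the first tie
  network$pinned[node] <- TRUE
  network$pinned_value[node] <- pinned_value
  behaviours[node] <- pinned_value
  list(network = network, behaviours = behaviours, node = node)
}

#' Locate the polarisation minimum of a mean-cooperativity series
#'
#' Smooths the series with a centred moving average of `smoothing_window`
#' points (shrinking symmetrically at the ends) and returns the index of
#' its minimum, ties broken toward the earliest. A series that never
#' decreases yields index 1 with a warning.
#'
#' @param mean_b numeric series of recorded mean cooperativities.
#' @param smoothing_window moving-average width in points.
#' @return Integer index into `mean_b` (1-based).
#' @export
detect_polarisation_minimum <- function(mean_b, smoothing_window = 5L) {
  n <- length(mean_b)
  w <- as.integer(smoothing_window)
  if (n <= w) stop("series shorter than smoothing window", call. = FALSE)
  half <- w %/% 2L
  sm <- vapply(seq_len(n), function(k) {
    lo <- max(1L, k - half); hi <- min(n, k + half)
    mean(mean_b[lo:hi])
  }, numeric(1))
  idx <- which.min(sm)
  if (!is.unsorted(mean_b))
    warning("series is monotone nondecreasing; no polarisation minimum",
            call. = FALSE)
  idx
}

#' Post-polarisation field switch, ensemble protocol
#'
#' Runs an ensemble in which each realization first evolves under the
#' original field of `params`, then -- at its own detected polarisation
#' minimum (default) or at a fixed time -- continues under `new_phi`.
#' Apart from the delayed field change the protocol is identical to
#' [run_ensemble()], and with `new_phi` equal to the original field the
#' result is bit-identical to an unswitched run at matched seeds.
#'
#' @param network a [network_config()] or [social_network()].
#' @param params a [model_params()].
#' @param schedule a [sim_schedule()].
#' @param new_phi field strength after the switch.
#' @param trigger `"at_polarisation_minimum"` or `"at_fixed_time"`.
#' @param trigger_time switch time in sweeps (fixed-time trigger only).
#' @return An `ensemble_result`, see [run_ensemble()]; per-realization
#'   switch times are in its `trigger_time` field.
#' @export
apply_field_switch <- function(network, params, schedule, new_phi,
                               trigger = "at_polarisation_minimum",
                               trigger_time = 0) {
  run_ensemble(network, params, schedule,
               intervention = intervention_spec(
                 kind = "field_switch", trigger = trigger,
                 trigger_time = trigger_time, new_phi = new_phi))
}

#' Ensemble-level polarisation time from a pilot run
#'
#' Runs a small control ensemble and returns the time (sweeps) at which its
#' ensemble mean cooperativity is minimal, i.e. the end of the cluster
#' formation stage. This fixed trigger time lets an intervention be applied
#' at the polarisation minimum itself -- an online per-realization detector
#' can only confirm a minimum in hindsight, after the dynamics have moved
#' on -- so it is the protocol used for intervention rate comparisons.
#'
#' @param network a [network_config()] or [social_network()].
#' @param params a [model_params()].
#' @param n_realizations pilot ensemble size.
#' @param max_sweeps pilot horizon in sweeps.
#' @param base_seed pilot seed block.
#' @param smoothing_window see [detect_polarisation_minimum()].
#' @return Time of the smoothed ensemble-mean minimum, in sweeps.
#' @export
polarisation_time <- function(network, params, n_realizations = 30L,
                              max_sweeps = 300, base_seed = 1L,
                              smoothing_window = 5L) {
  sch <- sim_schedule(max_sweeps = max_sweeps, record_interval = 1,
                      n_realizations = n_realizations,
                      base_seed = base_seed)
  m <- ensemble_mean_trajectory(run_ensemble(network, params, sch))
  m$time[detect_polarisation_minimum(m$mean_b, smoothing_window)]
}
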