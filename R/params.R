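#' Model parameters for the persuasion dynamics
#'
#' Scalars of the interaction rule. Defaults are the reference ("standard")
#' conditions: a weak pro-cooperation external field `phi = 0.05`, agent
#' self-weight (stubbornness) `w_i = 0.6`, interaction-noise half-width
#' 0.1, and initial behaviours drawn i.i.d. Normal(-0.25, 0.15)
#' clipped to `[-1, 1]` (a defector majority).
#'
#' `middle_branch_mode` selects the semantics of the response function
#' between its saturated branches. The default `"pure_noise"` is the
#' published piecewise form, `(r + xi) / 2r`, independent of `x` between the
#' branches: there the outcome is decided by the noise alone, and the field
#' acts through how often the stimulus saturates. The alternative
#' `"ramp_plus_noise"`, `clip((r + x + xi) / 2r, 0, 1)`, joins the saturated
#' branches continuously in expectation; it weakens weak-field cooperation
#' noticeably (a few percent of standard-parameter realizations collapse to
#' full defection), so it is offered for comparison only.
#'
#' @param phi external field strength (positive favours cooperation).
#' @param self_weight resistance to change `w_i`, shared by all agents.
#' @param noise_half_width half-width `r` of the uniform interaction noise
#'   and of the linear response window; must be positive.
#' @param middle_branch_mode `"ramp_plus_noise"` or `"pure_noise"`.
#' @param init_mean,init_sd mean and SD of the initial behaviour draw.
#' @return A validated list of class `model_params`.
#' @export
model_params <- function(phi = 0.05, self_weight = 0.6,
                         noise_half_width = 0.1,
                         middle_branch_mode = "pure_noise",
                         init_mean = -0.25, init_sd = 0.15) {
  if (!is.numeric(noise_half_width) || noise_half_width <= 0)
    stop("noise_half_width must be > 0", call. = FALSE)
  if (!middle_branch_mode %in% c("ramp_plus_noise", "pure_noise"))
    stop("middle_branch_mode must be 'ramp_plus_noise' or 'pure_noise'",
         call. = FALSE)
  if (init_sd < 0) stop("init_sd must be >= 0", call. = FALSE)
  structure(list(phi = phi, self_weight = self_weight,
                 noise_half_width = noise_half_width,
                 middle_branch_mode = middle_branch_mode,
                 init_mean = init_mean, init_sd = init_sd),
            class = "model_params")
}

#' Simulation schedule
#'
#' Time is measured in sweeps: one sweep is `N` persuasion events on an
#' `N`-agent network. A realization runs until absorption (all unpinned
#' behaviours within `absorption_tol` of the same extreme) or `max_sweeps`,
#' recording the network mean and SD of cooperativity every
#' `record_interval` sweeps.
#'
#' @param max_sweeps horizon in sweeps.
#' @param record_interval recording cadence in sweeps.
#' @param absorption_tol absorption tolerance on `|b_i -+ 1|`.
#' @param n_realizations ensemble size for [run_ensemble()].
#' @param base_seed integer; realization `i` is seeded `base_seed + i` and
#'   its fresh network `base_seed + 1000000 + i`.
#' @return A validated list of class `sim_schedule`.
#' @export
sim_schedule <- function(max_sweeps = 2000, record_interval = 1,
                         absorption_tol = 1e-3, n_realizations = 500L,
                         base_seed = 1L) {
  if (record_interval <= 0 || max_sweeps <= 0 ||
      record_interval > max_sweeps)
    stop("need 0 < record_interval <= max_sweeps", call. = FALSE)
  if (absorption_tol <= 0) stop("absorption_tol must be > 0", call. = FALSE)
  if (n_realizations < 1L) stop("n_realizations must be >= 1", call. = FALSE)
  structure(list(max_sweeps = max_sweeps,
                 record_interval = record_interval,
                 absorption_tol = absorption_tol,
                 n_realizations = as.integer(n_realizations),
                 base_seed = as.integer(base_seed)),
            class = "sim_schedule")
}
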