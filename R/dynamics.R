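#' Initial behaviour draw
#'
#' Independent Normal(`init_mean`, `init_sd`) draws, one per agent, clipped
#' to the behaviour range `[-1, 1]`.
#'
#' @param node_count number of agents.
#' @param init_mean,init_sd parameters of the Gaussian.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first, otherwise the current RNG stream is used.
#' @return Numeric vector of behaviours in `[-1, 1]`.
#' @export
draw_initial_behaviours <- function(node_count, init_mean = -0.25,
                                    init_sd = 0.15, seed = NULL) {
  stopifnot(node_count >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pmin(pmax(stats::rnorm(node_count, init_mean, init_sd), -1), 1)
}

#' Response function of the persuaded agent
#'
#' Maps the pooled stimulus `x = w_i b_i + w_ij b_j + phi` to the weight
#' `w+` of a positive behaviour shift: 0 for `x <= -r`, 1 for `x >= r`, and
#' in between either `clip((r + x + xi) / 2r, 0, 1)` (`"ramp_plus_noise"`)
#' or the x-independent `(r + xi) / 2r` (`"pure_noise"`), with noise
#' `xi ~ Uniform(-r, r)`. Vectorised over `x` and `xi`.
#'
#' @param x stimulus value(s).
#' @param noise_half_width the window half-width `r` (> 0).
#' @param xi noise draw(s) in `[-r, r]`.
#' @param middle_branch_mode see [model_params()].
#' @return Value(s) in `[0, 1]`.
#' @export
response_f <- function(x, noise_half_width, xi,
                       middle_branch_mode = "ramp_plus_noise") {
  r <- noise_half_width
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("noise_half_width must be a positive scalar", call. = FALSE)
  if (any(abs(xi) > r))
    stop("xi must lie in [-r, r]", call. = FALSE)
  n <- max(length(x), length(xi))
  x <- rep_len(x, n); xi <- rep_len(xi, n)
  mid <- if (middle_branch_mode == "ramp_plus_noise") {
    pmin(pmax((r + x + xi) / (2 * r), 0), 1)
  } else if (middle_branch_mode == "pure_noise") {
    (r + xi) / (2 * r)
  } else stop("unknown middle_branch_mode", call. = FALSE)
  ifelse(x <= -r, 0, ifelse(x >= r, 1, mid))
}

#' Single persuasion event between two agents
#'
#' Computes the stimulus `x = w_i b_i + w_ij b_j + phi`, evaluates the
#' response `w+ = f(x)`, and moves agent `i` by
#' `delta_b = |b_i - b_j| * (2 f(x) - b_i - 1)`, clipping the result to
#' `[-1, 1]`. This is algebraically identical to the two-weight form
#' `|b_i - b_j| * (w+ (1 - b_i) - w- (1 + b_i))` with `w- = 1 - w+`.
#'
#' @param b_i,b_j behaviours of the persuaded and the persuading agent,
#'   both in `[-1, 1]`.
#' @param self_weight resistance to change `w_i`.
#' @param w_ij interaction weight of the tie.
#' @param params a [model_params()] (its `phi`, `noise_half_width` and
#'   `middle_branch_mode` are used).
#' @param xi optional noise value; drawn as `(2 u - 1) * r` from the current
#'   RNG stream when `NULL`.
#' @return List with `b_i_new` and `trace`, an interaction trace recording
#'   `b_i`, `b_j`, `w_ij`, `x`, `xi`, `w_plus`, `w_minus`, `delta_b`
#'   (pre-clipping) and `b_i_new`.
#' @export
interaction_update <- function(b_i, b_j, self_weight, w_ij, params,
                               xi = NULL) {
  if (abs(b_i) > 1 || abs(b_j) > 1)
    stop("behaviours must lie in [-1, 1]", call. = FALSE)
  r <- params$noise_half_width
  if (is.null(xi)) xi <- (2 * stats::runif(1L) - 1) * r
  x <- self_weight * b_i + w_ij * b_j + params$phi
  w_plus <- response_f(x, r, xi, params$middle_branch_mode)
  delta_b <- abs(b_i - b_j) * (2 * w_plus - b_i - 1)
  b_new <- min(max(b_i + delta_b, -1), 1)
  list(b_i_new = b_new,
       trace = list(b_i = b_i, b_j = b_j, w_ij = w_ij, x = x, xi = xi,
                    w_plus = w_plus, w_minus = 1 - w_plus,
                    delta_b = delta_b, b_i_new = b_new))
}

#' Fresh realization state
#'
#' @param behaviours behaviour vector in `[-1, 1]`.
#' @param seed the seed the realization was started from (bookkeeping).
#' @return List of class `realization_state` with `behaviours`, `events`,
#'   `sweeps_elapsed` (`events / N`), `skipped` (isolated-node no-ops) and
#'   `last_trace`.
#' @export
realization_state <- function(behaviours, seed = NA_integer_) {
  stopifnot(all(abs(behaviours) <= 1))
  structure(list(behaviours = behaviours, events = 0L,
                 sweeps_elapsed = 0, skipped = 0L, seed = seed,
                 last_trace = NULL),
            class = "realization_state")
}

#' One random-sequential update event (reference stepper)
#'
#' Draws, from the current RNG stream and in this fixed order, `u1` (agent
#' `i`, uniform over all nodes), `u2` (neighbour `j`, uniform over `i`'s
#' neighbours in CSR order) and `u3` (noise `xi`), then applies
#' [interaction_update()] to `i` only. Updating the selected agent rather
#' than its neighbour makes high-degree agents more influential (they are
#' chosen as `j` more often). Pinned agents are selected like any other but
#' keep their behaviour; events landing on an isolated node are skipped and
#' counted. The draw order matches the compiled engine used by
#' [run_realization()] bit for bit.
#'
#' @param state a [realization_state()].
#' @param network a [social_network()].
#' @param params a [model_params()].
#' @return The advanced state (events incremented by one, `sweeps_elapsed`
#'   by `1/N`, `last_trace` set for updated events).
#' @export
simulation_step <- function(state, network, params) {
  n <- network$n_nodes
  csr <- network$csr
  u <- stats::runif(3L)
  i <- min(floor(u[1L] * n) + 1L, n)
  deg <- csr$ptr[i + 1L] - csr$ptr[i]
  state$events <- state$events + 1L
  state$sweeps_elapsed <- state$events / n
  state$last_trace <- NULL
  if (deg == 0L) {
    state$skipped <- state$skipped + 1L
    return(state)
  }
  pos <- csr$ptr[i] + min(floor(u[2L] * deg) + 1L, deg)
  if (network$pinned[i]) return(state)
  j <- csr$nbr[pos] + 1L
  xi <- (2 * u[3L] - 1) * params$noise_half_width
  upd <- interaction_update(state$behaviours[i], state$behaviours[j],
                            params$self_weight, csr$w[pos], params, xi = xi)
  state$behaviours[i] <- upd$b_i_new
  upd$trace$i <- i
  upd$trace$j <- j
  state$last_trace <- upd$trace
  state
}

# Terminal-state classification of a behaviour vector.
#
# A realization has reached its cooperative steady state when every unpinned
# agent is within tol of +1, except for structurally frozen dissenters:
# agents at the opposite extreme whose stimulus saturates against change for
# every neighbour, i.e. w_i b_i + max_j |w_ij| + phi <= -r. Such agents can
# never move again no matter which neighbour or noise value is drawn, so the
# state is exactly absorbing; they occur when all of an agent's ties are
# weaker than w_i - phi - r. The defective classification is the mirror
# image. Returns list(class, holdouts).
classify_state <- function(b, network, self_weight, phi, r, tol) {
  free <- !network$pinned
  bf <- if (any(free)) b[free] else b
  maxw <- if (any(free)) network$csr$maxw[free] else network$csr$maxw
  up <- bf >= 1 - tol
  down <- bf <= -1 + tol
  frozen_dn <- down & (self_weight * bf + maxw + phi <= -r)
  frozen_up <- up & (self_weight * bf - maxw + phi >= r)
  coop <- all(up | frozen_dn) && any(up)
  def <- all(down | frozen_up) && any(down)
  if (coop && def) {  # fully frozen polarised state: majority side wins
    if (mean(bf) >= 0) def <- FALSE else coop <- FALSE
  }
  if (coop) list(class = "cooperative", holdouts = sum(frozen_dn & !up))
  else if (def) list(class = "defective", holdouts = sum(frozen_up & !down))
  else list(class = "unresolved", holdouts = NA_integer_)
}

# online polarisation-minimum detector state machine: trailing moving
# average of the recorded means; fires once the smoothed series has not
# made a new minimum for `patience` recorded points.
detector_new <- function(window, patience) {
  list(window = window, patience = patience, sums = numeric(0),
       best = Inf, best_idx = NA_integer_, fired = FALSE)
}

detector_push <- function(det, values, k) {
  if (k < det$window) return(det)
  sm <- mean(values[(k - det$window + 1L):k])
  if (sm < det$best) {
    det$best <- sm
    det$best_idx <- k
  } else if (k - det$best_idx >= det$patience) {
    det$fired <- TRUE
  }
  det
}

#' Run one realization to absorption
#'
#' Seeds the RNG, draws initial behaviours, and advances the dynamics in
#' blocks of `record_interval` sweeps through the compiled event loop,
#' recording the mean and SD of cooperativity at every record point
#' (including `t = 0`). The run stops at absorption or at `max_sweeps`,
#' whichever comes first, and the terminal state is classified as
#' `"cooperative"`, `"defective"` or `"unresolved"`.
#'
#' Absorption means the steady state has been reached: every unpinned agent
#' is within `absorption_tol` of the same extreme, except that agents
#' frozen at the opposite extreme are exempt. An agent at an extreme is
#' frozen when its stimulus saturates against change for every possible
#' neighbour behaviour (all its ties weaker than `w_i - phi - r`); such
#' isolated dissenters are exactly absorbing and their count is reported in
#' `holdouts`. On the reference networks they are rare (roughly one agent
#' per thousand) but make "all agents at +1" unreachable in a fraction of
#' realizations, which is why classification is defined on the mobile
#' agents.
#'
#' All randomness (initial behaviours, then per event the agent, neighbour
#' and noise draws) comes from the single stream started by `seed`; edge
#' weights belong to the network and are untouched.
#'
#' @param network a [social_network()].
#' @param params a [model_params()].
#' @param schedule a [sim_schedule()].
#' @param seed integer seed for this realization.
#' @param intervention optional [intervention_spec()] applied mid-run.
#' @param behaviours optional initial behaviour vector overriding the
#'   Gaussian draw (the RNG stream is then used for events only).
#' @param engine `"cpp"` (default) or `"r"`; the R engine replays the same
#'   stream through [simulation_step()] and is intended for verification on
#'   small problems.
#' @return A list of class `trajectory`: `time` (sweeps), `mean_b`, `sd_b`,
#'   `classification`, `holdouts` (frozen dissenters at absorption),
#'   `absorb_time` (`NA` if unresolved), `trigger_time`
#'   (`NA` without intervention), `pinned_node`, `final_behaviours`, `seed`,
#'   `events`, `skipped`.
#' @export
run_realization <- function(network, params, schedule, seed,
                            intervention = NULL, behaviours = NULL,
                            engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(network, "social_network"),
            inherits(params, "model_params"),
            inherits(schedule, "sim_schedule"))
  n <- network$n_nodes
  set.seed(as.integer(seed))
  b <- if (is.null(behaviours)) {
    draw_initial_behaviours(n, params$init_mean, params$init_sd)
  } else {
    stopifnot(length(behaviours) == n, all(abs(behaviours) <= 1))
    behaviours
  }
  if (any(network$pinned))
    b[network$pinned] <- network$pinned_value[network$pinned]

  phi_now <- params$phi
  pinned_node <- NA_integer_
  trigger_time <- NA_real_
  det <- NULL
  if (!is.null(intervention)) {
    stopifnot(inherits(intervention, "intervention_spec"))
    if (intervention$trigger == "at_polarisation_minimum")
      det <- detector_new(intervention$smoothing_window,
                          intervention$patience)
    if (intervention$trigger == "at_fixed_time" &&
        intervention$trigger_time <= 0) {
      applied <- apply_intervention(intervention, network, b)
      network <- applied$network; b <- applied$behaviours
      if (intervention$kind == "field_switch") phi_now <- intervention$new_phi
      pinned_node <- applied$pinned_node
      trigger_time <- 0
      intervention <- NULL
    }
  }

  times <- seq(0, schedule$max_sweeps, by = schedule$record_interval)
  n_rec <- length(times)
  mean_b <- numeric(n_rec); sd_b <- numeric(n_rec)
  mean_b[1L] <- mean(b); sd_b[1L] <- stats::sd(b)
  events_per_block <- max(1L, as.integer(round(schedule$record_interval * n)))
  events <- 0L; skipped <- 0L
  cls <- classify_state(b, network, params$self_weight, phi_now,
                        params$noise_half_width, schedule$absorption_tol)
  classification <- cls$class
  holdouts <- cls$holdouts
  absorb_time <- if (classification == "unresolved") NA_real_ else 0
  k_last <- 1L
  mode <- if (params$middle_branch_mode == "ramp_plus_noise") 0L else 1L

  if (classification == "unresolved" && n_rec > 1L) {
    for (k in 2L:n_rec) {
      if (engine == "cpp") {
        res <- .run_events_cpp(b, network$csr$ptr, network$csr$nbr,
                               network$csr$w, network$pinned,
                               params$self_weight, phi_now,
                               params$noise_half_width, mode,
                               events_per_block)
        b <- res$behaviours
        skipped <- skipped + res$skipped
      } else {
        st <- realization_state(b)
        p_now <- params; p_now$phi <- phi_now
        for (e in seq_len(events_per_block))
          st <- simulation_step(st, network, p_now)
        b <- st$behaviours
        skipped <- skipped + st$skipped
      }
      events <- events + events_per_block
      mean_b[k] <- mean(b); sd_b[k] <- stats::sd(b)
      k_last <- k

      if (!is.null(intervention)) {
        fire <- FALSE
        if (intervention$trigger == "at_fixed_time") {
          fire <- times[k] >= intervention$trigger_time
        } else {
          det <- detector_push(det, mean_b, k)
          fire <- det$fired
        }
        if (fire) {
          applied <- apply_intervention(intervention, network, b)
          network <- applied$network; b <- applied$behaviours
          if (intervention$kind == "field_switch")
            phi_now <- intervention$new_phi
          pinned_node <- applied$pinned_node
          trigger_time <- times[k]
          intervention <- NULL
        }
      }

      cls <- classify_state(b, network, params$self_weight, phi_now,
                            params$noise_half_width,
                            schedule$absorption_tol)
      if (cls$class != "unresolved") {
        classification <- cls$class
        holdouts <- cls$holdouts
        absorb_time <- times[k]
        break
      }
    }
  }

  structure(list(time = times[seq_len(k_last)],
                 mean_b = mean_b[seq_len(k_last)],
                 sd_b = sd_b[seq_len(k_last)],
                 classification = classification,
                 holdouts = holdouts,
                 absorb_time = absorb_time,
                 trigger_time = trigger_time,
                 pinned_node = pinned_node,
                 final_behaviours = b,
                 seed = as.integer(seed),
                 events = events, skipped = skipped),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d record points over %.1f sweeps, terminal '%s'\n",
    length(x$time), max(x$time), x$classification))
  invisible(x)
}
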