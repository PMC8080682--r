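# Shared fixtures and independent oracles.

# Numeric-integration oracle for E[f(x)] over xi ~ Uniform(-r, r).
# Independent of response_f: integrates the branch definitions directly.
expected_f <- function(x, r, mode = "pure_noise") {
  if (x <= -r) return(0)
  if (x >= r) return(1)
  integrand <- function(xi) {
    f <- if (mode == "ramp_plus_noise") (r + x + xi) / (2 * r)
         else (r + xi) / (2 * r)
    pmin(pmax(f, 0), 1)
  }
  stats::integrate(function(xi) integrand(xi) / (2 * r), -r, r)$value
}

# Closed-form one-event expectation of the updated behaviour of agent i,
# assuming no clipping occurs anywhere in the reachable range.
expected_update <- function(b_i, b_j, w_i, w_ij, phi, r, mode) {
  ef <- expected_f(w_i * b_i + w_ij * b_j + phi, r, mode)
  b_i + abs(b_i - b_j) * (2 * ef - b_i - 1)
}

# small deterministic fixtures
star_network <- function(n_leaves = 4, w = 0.5) {
  social_network(n_leaves + 1L, cbind(1L, 1L + seq_len(n_leaves)),
                 rep(w, n_leaves), topology = "star")
}

pair_network <- function(w = 0.5) {
  social_network(2L, matrix(c(1L, 2L), 1L), w)
}

tiny_csf <- function(n = 30, k0 = 3, seed = 42, wseed = 43) {
  assign_edge_weights(build_holme_kim(n, k0, 0.5, seed = seed),
                      0.5, 0.15, seed = wseed)
}

quick_schedule <- function(max_sweeps = 50, n_realizations = 1L,
                           base_seed = 1L, absorption_tol = 1e-3) {
  sim_schedule(max_sweeps = max_sweeps, record_interval = 1,
               absorption_tol = absorption_tol,
               n_realizations = n_realizations, base_seed = base_seed)
}
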