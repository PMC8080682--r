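#' Social network container
#'
#' An undirected, weighted graph on `n_nodes` agents. Nodes are the integers
#' `1:n_nodes` internally (edge-list files on disk use 0-based ids, see
#' [write_edge_list()]). Each undirected edge carries a single interaction
#' weight `w_ij`, drawn once and used symmetrically; weights may be negative
#' (animosity). Agents can be *pinned*: their behaviour is frozen at a fixed
#' value while they keep influencing neighbours.
#'
#' @param n_nodes number of agents.
#' @param edges integer matrix with two columns, one row per undirected edge,
#'   1-based node ids. Self-loops and duplicate edges are rejected.
#' @param weights numeric vector of edge weights, one per row of `edges`.
#' @param topology optional string recording how the graph was built.
#' @param seed optional integer recording the generator seed.
#' @return An object of class `social_network`: a list with fields
#'   `n_nodes`, `edges`, `weights`, `pinned` (logical per node),
#'   `pinned_value` (numeric per node, `NA` where unpinned), `topology`,
#'   `seed`, and a cached CSR adjacency used by the simulator.
#' @seealso [build_holme_kim()], [build_periodic_grid()],
#'   [assign_edge_weights()], [load_edge_list()]
#' @export
social_network <- function(n_nodes, edges, weights,
                           topology = "custom", seed = NA_integer_) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L)
    stop("n_nodes must be a positive integer", call. = FALSE)
  edges <- matrix(as.integer(edges), ncol = 2L)
  weights <- as.numeric(weights)
  if (nrow(edges) != length(weights))
    stop("need exactly one weight per edge", call. = FALSE)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoints outside 1..n_nodes", call. = FALSE)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed", call. = FALSE)
    if (any(!is.finite(weights)))
      stop("edge weights must be finite", call. = FALSE)
    key <- pmin(edges[, 1L], edges[, 2L]) * (n_nodes + 1) +
      pmax(edges[, 1L], edges[, 2L])
    if (anyDuplicated(key))
      stop("duplicate (parallel) edges are not allowed", call. = FALSE)
  }
  net <- structure(
    list(n_nodes = n_nodes, edges = edges, weights = weights,
         pinned = rep(FALSE, n_nodes),
         pinned_value = rep(NA_real_, n_nodes),
         topology = topology, seed = seed, csr = NULL),
    class = "social_network")
  net$csr <- build_csr(net)
  net
}

# Compressed sparse row adjacency: 0-based ptr/nbr for the C++ core, with
# edge weights aligned to nbr. Neighbour order (sorted by (i, insertion))
# is part of the RNG contract shared by the R and C++ steppers.
build_csr <- function(network) {
  n <- network$n_nodes
  e <- network$edges
  from <- c(e[, 1L], e[, 2L])
  to <- c(e[, 2L], e[, 1L])
  w <- c(network$weights, network$weights)
  ord <- order(from, seq_along(from))
  deg <- tabulate(from, nbins = n)
  maxw <- rep(0, n)
  if (length(from)) {
    agg <- tapply(abs(w), from, max)
    maxw[as.integer(names(agg))] <- agg
  }
  list(ptr = c(0L, cumsum(deg)), nbr = to[ord] - 1L, w = w[ord],
       maxw = maxw)
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network> %d nodes, %d edges (%s)\n",
              x$n_nodes, nrow(x$edges), x$topology))
  cat(sprintf("  mean degree %.3f, weights in [%.3f, %.3f], %d pinned\n",
              mean(node_degrees(x)),
              if (length(x$weights)) min(x$weights) else NA,
              if (length(x$weights)) max(x$weights) else NA,
              sum(x$pinned)))
  invisible(x)
}

#' Node degrees
#' @param network a [social_network()].
#' @return Integer vector of degrees, one per node.
#' @export
node_degrees <- function(network) {
  tabulate(network$edges, nbins = network$n_nodes)
}

#' Convert to an igraph object
#'
#' Useful for inspection (clustering coefficients, components, plotting).
#' The simulator itself never goes through igraph.
#'
#' @param network a [social_network()].
#' @return An undirected `igraph` graph with edge attribute `weight`.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_edgelist(network$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, network$n_nodes - igraph::vcount(g)))
  igraph::E(g)$weight <- network$weights
  g
}

#' Is the network connected?
#' @param network a [social_network()].
#' @return `TRUE` if the graph has a single connected component.
#' @export
is_connected_network <- function(network) {
  igraph::is_connected(as_igraph(network))
}

#' Clustered scale-free network (Holme-Kim growth)
#'
#' Grows a graph by preferential attachment with triad formation: each new
#' node attaches `growth_degree` edges; after a preferential-attachment step,
#' with probability `triad_probability` the next edge instead closes a
#' triangle with a neighbour of the node just linked. `triad_probability = 0`
#' recovers a Barabasi-Albert graph; larger values raise the clustering
#' coefficient at (almost) unchanged degree sequence. The grown graph is
#' connected, with roughly `2 * growth_degree * (1 - growth_degree/n_nodes)`
#' mean degree (15.88 for the default 1089-node, degree-8 growth).
#'
#' All edge weights are initialised to 0.5; call [assign_edge_weights()] (or
#' use [generate_network()]) for the stochastic weight layer.
#'
#' @param n_nodes final number of nodes.
#' @param growth_degree edges added per new node (must be `< n_nodes`).
#' @param triad_probability probability of a triad-formation step.
#' @param seed integer seed; a fixed seed reproduces the edge set exactly.
#' @return A connected [social_network()].
#' @export
build_holme_kim <- function(n_nodes, growth_degree, triad_probability, seed) {
  n <- as.integer(n_nodes)
  m <- as.integer(growth_degree)
  p <- triad_probability
  if (is.na(m) || m < 1L || m >= n)
    stop("growth_degree must satisfy 1 <= growth_degree < n_nodes",
         call. = FALSE)
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("triad_probability must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))

  adj <- vector("list", n)           # adjacency sets for has-edge checks
  e_from <- integer(m * (n - m))
  e_to <- integer(m * (n - m))
  n_edges <- 0L
  # attachment pool: one entry per unit of degree (initial nodes seeded once)
  pool <- integer(2L * m * (n - m) + n)
  pool[seq_len(m)] <- seq_len(m)
  pool_len <- m

  add_edge <- function(u, v) {
    # idempotent: a triad step may pre-empt a later attachment target
    if (v %in% adj[[u]]) return(invisible(FALSE))
    n_edges <<- n_edges + 1L
    e_from[n_edges] <<- u
    e_to[n_edges] <<- v
    adj[[u]] <<- c(adj[[u]], v)
    adj[[v]] <<- c(adj[[v]], u)
    invisible(TRUE)
  }

  for (source in (m + 1L):n) {
    # m distinct targets, degree-proportional (uniform over the pool)
    targets <- integer(m)
    n_targets <- 0L
    while (n_targets < m) {
      cand <- pool[sample.int(pool_len, 1L)]
      if (!(cand %in% targets[seq_len(n_targets)])) {
        n_targets <- n_targets + 1L
        targets[n_targets] <- cand
      }
    }
    t_idx <- 1L
    target <- targets[t_idx]
    add_edge(source, target)
    pool_len <- pool_len + 1L
    pool[pool_len] <- target
    count <- 1L
    while (count < m) {
      hit <- FALSE
      if (stats::runif(1L) < p) {
        nbrs <- setdiff(adj[[target]], c(source, adj[[source]]))
        if (length(nbrs) > 0L) {
          v <- nbrs[sample.int(length(nbrs), 1L)]
          add_edge(source, v)
          pool_len <- pool_len + 1L
          pool[pool_len] <- v
          count <- count + 1L
          hit <- TRUE
        }
      }
      if (!hit) {
        t_idx <- t_idx + 1L
        target <- targets[t_idx]
        add_edge(source, target)
        pool_len <- pool_len + 1L
        pool[pool_len] <- target
        count <- count + 1L
      }
    }
    pool[pool_len + seq_len(m)] <- source
    pool_len <- pool_len + m
  }

  idx <- seq_len(n_edges)
  social_network(n, cbind(e_from[idx], e_to[idx]),
                 rep(0.5, n_edges), topology = "csf",
                 seed = as.integer(seed))
}

# neighbourhood offset tables for periodic grids, by common name
grid_offsets <- function(neighborhood) {
  full <- expand.grid(dr = -2:2, dc = -2:2)
  cheb <- pmax(abs(full$dr), abs(full$dc))
  manh <- abs(full$dr) + abs(full$dc)
  keep <- switch(
    neighborhood,
    von_neumann4 = manh == 1,
    moore8 = cheb == 1,
    manhattan2_12 = manh >= 1 & manh <= 2,
    chebyshev2_24 = cheb >= 1 & cheb <= 2,
    # Moore shell (8) + orthogonal distance 2 (4) + diagonal distance 2 (4)
    degree16 = cheb == 1 | (cheb == 2 & (manh == 2 | manh == 4)),
    stop("unknown grid_neighborhood: ", neighborhood, call. = FALSE))
  full[keep, , drop = FALSE]
}

#' Periodic grid network
#'
#' A `grid_side` x `grid_side` lattice with periodic (toroidal) boundaries
#' and one of five symmetric neighbourhoods: `von_neumann4` (degree 4),
#' `moore8` (8), `manhattan2_12` (12), `degree16` (16, the Moore shell plus
#' the orthogonal and diagonal distance-2 sites) and `chebyshev2_24` (24).
#' The graph is vertex-transitive, so every node has the same degree. Node
#' ids are row-major: node of (row, col), 0-based, is `row * grid_side + col`
#' (plus 1 for the internal 1-based ids).
#'
#' @param grid_side lattice side length; at least 3, and at least 5 for the
#'   neighbourhoods that reach distance 2 (otherwise the neighbourhood wraps
#'   onto itself).
#' @param grid_neighborhood neighbourhood name, see above.
#' @return A connected [social_network()] with `grid_side^2` nodes and all
#'   weights initialised to 0.5.
#' @export
build_periodic_grid <- function(grid_side, grid_neighborhood = "degree16") {
  s <- as.integer(grid_side)
  off <- grid_offsets(grid_neighborhood)
  reach <- max(pmax(abs(off$dr), abs(off$dc)))
  if (is.na(s) || s < 2L * reach + 1L)
    stop(sprintf(
      "grid_side %d too small for neighborhood '%s' (needs >= %d)",
      s, grid_neighborhood, 2L * reach + 1L), call. = FALSE)
  n <- s * s
  cell <- expand.grid(row = 0:(s - 1L), col = 0:(s - 1L))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    r2 <- (cell$row + off$dr[k]) %% s
    c2 <- (cell$col + off$dc[k]) %% s
    from <- c(from, cell$row * s + cell$col + 1L)
    to <- c(to, r2 * s + c2 + 1L)
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  social_network(n, cbind(a[keep], b[keep]),
                 rep(0.5, sum(keep)),
                 topology = sprintf("grid_%s", grid_neighborhood))
}

#' Draw interaction weights for every edge
#'
#' One independent `Normal(weight_mean, weight_sd)` draw per undirected edge,
#' fixed for the lifetime of the network and used in both directions.
#' Negative draws are kept: a negative weight is an antagonistic tie.
#'
#' @param network a [social_network()].
#' @param weight_mean,weight_sd mean and standard deviation of the weight
#'   distribution (`weight_sd = 0` gives identical weights).
#' @param seed integer seed for the draws.
#' @return The network with its `weights` replaced.
#' @export
assign_edge_weights <- function(network, weight_mean = 0.5,
                                weight_sd = 0.15, seed = 1L) {
  stopifnot(inherits(network, "social_network"))
  if (nrow(network$edges) == 0L)
    stop("network has no edges", call. = FALSE)
  if (weight_sd < 0) stop("weight_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  network$weights <- stats::rnorm(nrow(network$edges), weight_mean, weight_sd)
  network$csr <- build_csr(network)
  network
}

#' Generate a network from a configuration
#'
#' Convenience wrapper: builds the topology from `config$seed` and then
#' assigns edge weights from `config$seed + 1`, so one integer reproduces
#' the whole weighted graph.
#'
#' @param config a [network_config()].
#' @return A weighted [social_network()].
#' @export
generate_network <- function(config) {
  config <- validate_network_config(config)
  net <- switch(config$topology,
    csf = build_holme_kim(config$n_nodes, config$growth_degree,
                          config$triad_probability, config$seed),
    grid = build_periodic_grid(config$grid_side, config$grid_neighborhood),
    custom = stop("topology 'custom' requires load_edge_list()",
                  call. = FALSE))
  assign_edge_weights(net, config$weight_mean, config$weight_sd,
                      seed = config$seed + 1L)
}

#' Network configuration
#'
#' Defaults are the reference ("standard") study conditions: a 1089-node
#' clustered scale-free graph grown at degree 8 with triad probability 0.5
#' (mean degree about 16) and edge weights Normal(0.5, 0.15).
#'
#' @param topology `"csf"`, `"grid"` or `"custom"`.
#' @param n_nodes node count for `"csf"` (grids use `grid_side^2`).
#' @param growth_degree Holme-Kim growth degree `k0`.
#' @param triad_probability Holme-Kim triad-formation probability.
#' @param grid_side,grid_neighborhood grid geometry, see
#'   [build_periodic_grid()].
#' @param weight_mean,weight_sd edge-weight distribution.
#' @param seed integer seed for topology (weights use `seed + 1`).
#' @return A validated list of class `network_config`.
#' @export
network_config <- function(topology = "csf", n_nodes = 1089L,
                           growth_degree = 8L, triad_probability = 0.5,
                           grid_side = 13L, grid_neighborhood = "degree16",
                           weight_mean = 0.5, weight_sd = 0.15, seed = 1L) {
  cfg <- structure(list(
    topology = topology, n_nodes = as.integer(n_nodes),
    growth_degree = as.integer(growth_degree),
    triad_probability = triad_probability,
    grid_side = as.integer(grid_side),
    grid_neighborhood = grid_neighborhood,
    weight_mean = weight_mean, weight_sd = weight_sd,
    seed = as.integer(seed)), class = "network_config")
  validate_network_config(cfg)
}

validate_network_config <- function(cfg) {
  if (!cfg$topology %in% c("csf", "grid", "custom"))
    stop("topology must be one of csf, grid, custom", call. = FALSE)
  if (cfg$topology == "csf" && cfg$growth_degree >= cfg$n_nodes)
    stop("growth_degree must be < n_nodes", call. = FALSE)
  if (cfg$triad_probability < 0 || cfg$triad_probability > 1)
    stop("triad_probability must lie in [0, 1]", call. = FALSE)
  if (cfg$weight_sd < 0) stop("weight_sd must be >= 0", call. = FALSE)
  if (cfg$topology == "grid") {
    grid_offsets(cfg$grid_neighborhood)  # validates the name
    cfg$n_nodes <- cfg$grid_side^2
  }
  cfg
}

#' Read / write weighted edge lists
#'
#' Plain-text format: one `u v w` triple per line (whitespace-delimited),
#' 0-based node ids, `#` comment lines ignored. Writing then reading
#' reproduces the same labelled graph and weights.
#'
#' @param path file path.
#' @param n_nodes optional node count (default: `max id + 1`, so trailing
#'   isolated nodes need an explicit count).
#' @return `load_edge_list()` returns a [social_network()];
#'   `write_edge_list()` returns `path` invisibly.
#' @export
load_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no edges in ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  u <- integer(length(keep)); v <- integer(length(keep))
  w <- numeric(length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    p <- parts[[k]]
    if (length(p) != 3L)
      stop(sprintf("line %d: expected 'u v w', got %d fields", ln, length(p)),
           call. = FALSE)
    ui <- suppressWarnings(as.integer(p[1L]))
    vi <- suppressWarnings(as.integer(p[2L]))
    wi <- suppressWarnings(as.numeric(p[3L]))
    if (is.na(ui) || is.na(vi) || is.na(wi))
      stop(sprintf("line %d: non-numeric field in '%s'", ln, lines[ln]),
           call. = FALSE)
    if (ui < 0L || vi < 0L)
      stop(sprintf("line %d: negative node id", ln), call. = FALSE)
    if (ui == vi)
      stop(sprintf("line %d: self-loop %d-%d", ln, ui, vi), call. = FALSE)
    u[k] <- ui; v[k] <- vi; w[k] <- wi
  }
  key <- paste(pmin(u, v), pmax(u, v))
  if (anyDuplicated(key)) {
    ln <- keep[which(duplicated(key))[1L]]
    stop(sprintf("line %d: duplicate edge", ln), call. = FALSE)
  }
  n <- if (is.null(n_nodes)) max(u, v) + 1L else as.integer(n_nodes)
  social_network(n, cbind(u + 1L, v + 1L), w)
}

#' @rdname load_edge_list
#' @param network a [social_network()] to serialise.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "social_network"))
  e <- network$edges
  writeLines(sprintf("%d %d %s", e[, 1L] - 1L, e[, 2L] - 1L,
                     formatC(network$weights, digits = 17, format = "g")),
             path)
  invisible(path)
}
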