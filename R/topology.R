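#' Generate a random degree-regular information-sharing network
#'
#' Draws a simple, connected z-regular graph on `n` nodes by configuration-
#' model stub pairing with rejection: stubs are shuffled and paired, and the
#' draw is rejected and repeated until the realized graph has no self-loops,
#' no duplicate edges and (optionally) a single connected component.
#' Degree-regular ("egalitarian") topologies give every participant the same
#' number of connections, so no node dominates information flow.
#'
#' @param n Number of nodes (participants). Must satisfy `n > z` and
#'   `n * z` even (handshake lemma).
#' @param z Degree: connections per participant.
#' @param seed Integer RNG seed; identical seeds yield identical edge sets.
#' @param connected If `TRUE` (default), reject draws whose graph is not
#'   connected, so every node is reachable and receives a peer signal.
#' @param max_attempts Rejection budget before signalling
#'   `netwisdom_generation_failure`.
#' @return A `regular_network` object: list with `n_nodes`, `degree`, and
#'   `edges`, a tibble with integer columns `node_a < node_b` (0-based ids),
#'   one row per undirected edge (`n * z / 2` rows).
#' @export
#' @examples
#' net <- regular_network(40, 4, seed = 1)
#' nrow(net$edges) # 80
regular_network <- function(n, z, seed = NULL, connected = TRUE,
                            max_attempts = 20000L) {
  check_scalar_number(n, "n", lo = 2)
  check_scalar_number(z, "z", lo = 1)
  n <- as.integer(n)
  z <- as.integer(z)
  if (z >= n || (n * z) %% 2 != 0) {
    abort(
      sprintf("no simple %d-regular graph on %d nodes exists (need z < n and n*z even).", z, n),
      class = "netwisdom_invalid_parameters"
    )
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  for (attempt in seq_len(max_attempts)) {
    stubs <- sample(rep.int(seq_len(n) - 1L, z))
    a <- stubs[c(TRUE, FALSE)]
    b <- stubs[c(FALSE, TRUE)]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    if (any(lo == hi)) next # self-loop
    key <- lo * n + hi
    if (anyDuplicated(key)) next # multi-edge
    if (connected) {
      g <- igraph::graph_from_edgelist(cbind(lo, hi) + 1L, directed = FALSE)
      if (!igraph::is_connected(g)) next
    }
    ord <- order(lo, hi)
    return(new_regular_network(n, z, tibble(node_a = lo[ord], node_b = hi[ord])))
  }
  abort(
    sprintf("failed to realize a simple%s %d-regular graph in %d attempts.",
            if (connected) " connected" else "", z, max_attempts),
    class = "netwisdom_generation_failure"
  )
}

new_regular_network <- function(n, z, edges) {
  structure(
    list(n_nodes = as.integer(n), degree = as.integer(z), edges = edges),
    class = "regular_network"
  )
}

#' @export
print.regular_network <- function(x, ...) {
  cat(sprintf("<regular_network> %d nodes, degree %d, %d edges\n",
              x$n_nodes, x$degree, nrow(x$edges)))
  invisible(x)
}

# Master seed fixing the single topology reused across all networked trials
# of a study (participant networks are fixed; the same realized 40/4 graph
# backs every network trial, with node -> clinician assignment randomized
# per trial).
CANONICAL_TOPOLOGY_SEED <- 723109L

#' The canonical 40-node, degree-4 study topology
#'
#' The experiment reuses one realized random regular topology across all
#' network-condition trials; only the assignment of clinicians to nodes is
#' re-randomized per trial. This returns that canonical graph, produced from
#' a fixed internal master seed (40 nodes, 4 connections each, connected).
#'
#' @param n,z Optional overrides of the 40/4 defaults.
#' @return A [regular_network()] object.
#' @export
canonical_topology <- function(n = 40L, z = 4L) {
  regular_network(n, z, seed = CANONICAL_TOPOLOGY_SEED, connected = TRUE)
}

# Adjacency as a list: element i+1 holds the 0-based neighbor ids of node i.
neighbor_list <- function(topology) {
  stopifnot(inherits(topology, "regular_network"))
  nb <- vector("list", topology$n_nodes)
  e <- topology$edges
  for (i in seq_len(nrow(e))) {
    a <- e$node_a[i]
    b <- e$node_b[i]
    nb[[a + 1L]] <- c(nb[[a + 1L]], b)
    nb[[b + 1L]] <- c(nb[[b + 1L]], a)
  }
  lapply(nb, sort)
}

#' Peer signal: mean risk estimate of a node's network neighbours
#'
#' What a networked participant is shown before revising: the arithmetic
#' mean of their network contacts' current estimates. The focal node's own
#' estimate is excluded.
#'
#' @param topology A [regular_network()].
#' @param estimates Numeric vector of length `n_nodes`; element `i + 1` is
#'   node `i`'s current estimate (0-based node ids).
#' @param nodes 0-based node id(s); defaults to every node.
#' @return Numeric vector of neighbour means, one per requested node.
#' @export
#' @examples
#' net <- regular_network(6, 2, seed = 7)
#' peer_signal(net, estimates = c(10, 20, 30, 40, 50, 60), nodes = 0)
peer_signal <- function(topology, estimates, nodes = seq_len(topology$n_nodes) - 1L) {
  stopifnot(inherits(topology, "regular_network"))
  if (length(estimates) != topology$n_nodes || anyNA(estimates)) {
    abort("`estimates` must be a complete numeric vector, one value per node.",
          class = "netwisdom_invalid_parameters")
  }
  nb <- neighbor_list(topology)
  vapply(nodes, function(v) {
    ids <- nb[[v + 1L]]
    if (length(ids) == 0) {
      abort(sprintf("node %d has no neighbours: no peer signal available.", v),
            class = "netwisdom_no_signal")
    }
    mean(estimates[ids + 1L])
  }, numeric(1))
}

# All-node peer signals as a plain numeric vector, via the adjacency matrix
# (used in the simulator's inner loop; equals peer_signal node by node).
peer_signal_all <- function(neighbors, estimates) {
  vapply(neighbors, function(ids) mean(estimates[ids + 1L]), numeric(1))
}

#' Validate degree-regular topology invariants
#'
#' @param topology A [regular_network()].
#' @return Tibble of violations with columns `rule` and `detail`; zero rows
#'   when the object is a well-formed simple connected z-regular graph.
#' @export
validate_topology <- function(topology) {
  v <- list()
  e <- topology$edges
  if (any(e$node_a == e$node_b)) {
    v <- c(v, list(tibble(rule = "simple", detail = "self-loop present")))
  }
  if (anyDuplicated(paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b)))) {
    v <- c(v, list(tibble(rule = "simple", detail = "duplicate edge present")))
  }
  deg <- tabulate(c(e$node_a, e$node_b) + 1L, nbins = topology$n_nodes)
  if (any(deg != topology$degree)) {
    bad <- which(deg != topology$degree) - 1L
    v <- c(v, list(tibble(
      rule = "degree-regular",
      detail = sprintf("node %d has degree %d, expected %d", bad, deg[bad + 1L], topology$degree)
    )))
  }
  if (nrow(e) != topology$n_nodes * topology$degree / 2) {
    v <- c(v, list(tibble(
      rule = "edge-count",
      detail = sprintf("%d edges, expected %g", nrow(e), topology$n_nodes * topology$degree / 2)
    )))
  }
  g <- igraph::graph_from_edgelist(as.matrix(e) + 1L, directed = FALSE)
  if (igraph::vcount(g) < topology$n_nodes || !igraph::is_connected(g)) {
    v <- c(v, list(tibble(rule = "connected", detail = "graph is not connected")))
  }
  if (length(v) == 0) {
    tibble(rule = character(), detail = character())
  } else {
    bind_rows(v)
  }
}

#' Allocate invited participants to experiment conditions
#'
#' Randomizes invitations to the network and independent-control conditions
#' in a fixed integer ratio (the study design used 2:1). When the invitation
#' count is not divisible by the ratio total, the remainder rounds in favour
#' of the network arm. The id-level assignment is a seeded permutation.
#'
#' @param n_invitations Number of invitations sent.
#' @param ratio_network,ratio_control Positive integer ratio terms
#'   (defaults 2:1).
#' @param seed Optional integer seed for the permutation.
#' @return List with `n_network`, `n_control`, and `assignment`, a tibble
#'   with columns `id` (1..n) and `condition`.
#' @export
#' @examples
#' allocate_conditions(3360, 2, 1, seed = 1)$n_network # 2240
allocate_conditions <- function(n_invitations, ratio_network = 2L,
                                ratio_control = 1L, seed = NULL) {
  check_scalar_number(n_invitations, "n_invitations", lo = 0)
  check_scalar_number(ratio_network, "ratio_network", lo = 1)
  check_scalar_number(ratio_control, "ratio_control", lo = 1)
  n <- as.integer(n_invitations)
  n_network <- as.integer(ceiling(n * ratio_network / (ratio_network + ratio_control)))
  n_control <- n - n_network
  if (!is.null(seed)) set.seed(as.integer(seed))
  cond <- rep(c("network", "control"), c(n_network, n_control))
  assignment <- tibble(
    id = seq_len(n),
    condition = if (n > 0) sample(cond) else character()
  )
  list(n_network = n_network, n_control = n_control, assignment = assignment)
}
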