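# shared graph builders and independent oracles

edges_K <- function(v) t(utils::combn(v, 2L))

net_from <- function(..., class_label = "SYNTHETIC-TEST") {
  ppi_network(do.call(rbind, list(...)), class_label = class_label)
}

# a G(n, p) network with labelled nodes, restricted to simple graphs
random_net <- function(n, p, class_label = "SYNTHETIC-TEST") {
  pairs <- edges_K(sprintf("n%02d", seq_len(n)))
  keep <- stats::runif(nrow(pairs)) < p
  ppi_network(pairs[keep, , drop = FALSE],
              nodes = sprintf("n%02d", seq_len(n)),
              class_label = class_label)
}

# brute-force clique percolation: enumerate every k-clique directly,
# join cliques sharing k-1 nodes, return sorted node unions
cpm_oracle <- function(network, k) {
  nodes <- network$nodes
  if (length(nodes) < k) return(list())
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[network$edges] <- TRUE
  adj[network$edges[, c(2, 1), drop = FALSE]] <- TRUE
  subsets <- utils::combn(nodes, k, simplify = FALSE)
  cliques <- Filter(function(s) all(adj[s, s] | diag(k)), subsets)
  if (!length(cliques)) return(list())
  nc <- length(cliques)
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      if (length(intersect(cliques[[i]], cliques[[j]])) >= k - 1L) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(nc), find, 1L)
  comms <- lapply(split(cliques, roots),
                  function(grp) sort(unique(unlist(grp))))
  unname(comms)
}

# canonical form of a collection of member sets, for set comparison
canon_modules <- function(members) {
  sort(vapply(members, function(m) paste(sort(m), collapse = ";"), ""))
}

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) {
      out[[length(out) + 1L]] <<- a
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive-search modularity optimum (independent of the detectors)
exhaustive_best_q <- function(network) {
  n <- length(network$nodes)
  max(vapply(all_partitions(n), function(p) {
    modularity_q(network, stats::setNames(p, network$nodes))$q_value
  }, numeric(1L)))
}

# hypergeometric upper tail by explicit enumeration of all draws
hyper_oracle <- function(x, set_size, universe_size, module_size) {
  ways <- vapply(0:module_size, function(i) {
    choose(set_size, i) * choose(universe_size - set_size,
                                 module_size - i)
  }, numeric(1L))
  sum(ways[(x:module_size) + 1L]) / choose(universe_size, module_size)
}

# full-partition membership implied by a module set plus leftover
# singletons, for self-consistency checks
full_partition <- function(modules, network) {
  memb <- stats::setNames(rep(NA_integer_, length(network$nodes)),
                          network$nodes)
  for (i in seq_len(nrow(modules))) memb[modules$members[[i]]] <- i
  left <- which(is.na(memb))
  memb[left] <- nrow(modules) + seq_along(left)
  memb
}

# the small structured corpus used for partition-optimality checks
partition_corpus <- function() {
  list(
    bridged_K4s = net_from(edges_K(paste0("a", 1:4)),
                           edges_K(paste0("b", 1:4)),
                           rbind(c("a1", "b1"))),
    K5 = net_from(edges_K(paste0("v", 1:5))),
    two_triangles = net_from(edges_K(c("a", "b", "c")),
                             edges_K(c("d", "e", "f"))),
    path4 = net_from(cbind(c("a", "b", "c"), c("b", "c", "d"))),
    bridged_K3s = net_from(edges_K(c("a", "b", "c")),
                           edges_K(c("d", "e", "f")),
                           rbind(c("a", "d"))),
    shared_node_K3s = net_from(edges_K(c("a", "b", "c")),
                               edges_K(c("c", "d", "e"))),
    cycle6 = net_from(cbind(letters[1:6], letters[c(2:6, 1)])),
    barbell_path = net_from(edges_K(c("a", "b", "c")),
                            cbind(c("c", "g"), c("g", "d")),
                            edges_K(c("d", "e", "f"))))
}
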