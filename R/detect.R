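#' Detection parameters
#'
#' Bundles every tunable of the four detectors. Defaults follow the
#' parameterization used throughout the analysis: MCODE with node score
#' cutoff 0.2, haircut on, fluff off and maximum search depth 100; random
#' walks of length 4; CFinder community selection keeping a representative
#' subset of 5 communities per clique size and discarding communities
#' larger than 200 members.
#'
#' @param k_min smallest clique size considered (>= 2).
#' @param k_max largest clique size considered (`Inf` for unbounded).
#' @param mcode_node_score_cutoff admit neighbors with vertex weight within
#'   this fraction of the seed weight, in \[0,1\].
#' @param mcode_haircut remove members with fewer than 2 intra-module
#'   neighbors (iterated: the module is reduced to its 2-core).
#' @param mcode_fluff expand modules by neighbors whose closed-neighborhood
#'   density exceeds the node score cutoff.
#' @param mcode_max_depth breadth-first growth depth limit (>= 1).
#' @param walktrap_steps random-walk length (>= 1).
#' @param max_community_size communities above this size are discarded
#'   during CFinder selection.
#' @param representative_subset_size communities kept per clique size in
#'   the forward CFinder selection step.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(k_min = 3L, k_max = Inf,
                             mcode_node_score_cutoff = 0.2,
                             mcode_haircut = TRUE,
                             mcode_fluff = FALSE,
                             mcode_max_depth = 100L,
                             walktrap_steps = 4L,
                             max_community_size = 200L,
                             representative_subset_size = 5L) {
  stopifnot(k_min >= 2L, mcode_max_depth >= 1L, walktrap_steps >= 1L,
            mcode_node_score_cutoff >= 0, mcode_node_score_cutoff <= 1)
  structure(list(k_min = as.integer(k_min), k_max = k_max,
                 mcode_node_score_cutoff = mcode_node_score_cutoff,
                 mcode_haircut = isTRUE(mcode_haircut),
                 mcode_fluff = isTRUE(mcode_fluff),
                 mcode_max_depth = as.integer(mcode_max_depth),
                 walktrap_steps = as.integer(walktrap_steps),
                 max_community_size = as.integer(max_community_size),
                 representative_subset_size =
                   as.integer(representative_subset_size)),
            class = "detection_params")
}

#' Clique percolation (CPM) module detection
#'
#' A k-clique community is the node union of a maximal set of k-cliques in
#' which consecutive cliques share k-1 nodes. Communities may overlap;
#' every k-clique of the graph belongs to exactly one community. k = 2
#' (edges) is excluded as uninformative.
#'
#' Implemented through the maximal cliques of the graph: every k-clique is
#' contained in a maximal clique of size >= k, and two k-cliques sharing
#' k-1 nodes keep their percolation connectivity when lifted to maximal
#' cliques, so percolating maximal cliques over >= k-1 overlaps yields the
#' same communities as percolating all k-cliques (the brute-force oracle
#' used in the tests enumerates k-cliques directly).
#'
#' @param network a [ppi_network()].
#' @param k clique size, an integer >= 3.
#' @return a [module_set()] with `method = "CPM"`, `k_param = k` and
#'   `rank_score` equal to the member count; empty when the graph has no
#'   k-clique.
#' @export
detect_cpm <- function(network, k) {
  stopifnot(inherits(network, "ppi_network"))
  k <- as.integer(k)
  if (is.na(k) || k < 3L) stop("CPM requires k >= 3")
  g <- as_igraph(network)
  cl <- igraph::max_cliques(g, min = k)
  comms <- percolate_cliques(lapply(cl, function(v) sort(names(v))), k)
  module_set(comms, method = "CPM", class_label = network$class_label,
             k_param = k)
}

# percolate cliques (each a sorted character vector, size >= k) over
# >= k-1 shared nodes; returns list of node unions, one per component
percolate_cliques <- function(cliques, k) {
  nc <- length(cliques)
  if (nc == 0L) return(list())
  parent <- seq_len(nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # invert node -> clique ids to avoid all-pairs scans on large inputs
  node_ix <- split(rep(seq_len(nc), lengths(cliques)), unlist(cliques))
  cand <- unique(do.call(rbind, lapply(node_ix, function(ids) {
    if (length(ids) < 2L) return(NULL)
    t(utils::combn(sort(ids), 2L))
  })))
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      ri <- find(i); rj <- find(j)
      if (ri != rj &&
          length(intersect(cliques[[i]], cliques[[j]])) >= k - 1L) {
        parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(nc), find, 1L)
  unname(lapply(split(cliques, roots),
                function(grp) sort(unique(unlist(grp)))))
}

# MCODE vertex weight: core number of the closed-neighborhood graph times
# the density of that neighborhood's highest-order core
mcode_weights <- function(g) {
  vs <- igraph::V(g)
  vapply(seq_along(vs), function(i) {
    nb <- c(i, as.integer(igraph::neighbors(g, i)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) return(0)
    hc <- igraph::induced_subgraph(sub, which(core == kmax))
    n <- igraph::vcount(hc)
    dens <- if (n < 2L) 0 else
      2 * igraph::ecount(hc) / (n * (n - 1))
    kmax * dens
  }, numeric(1L))
}

#' MCODE-style molecular complex detection
#'
#' Vertex-weighted core mining: each vertex is weighted by the core number
#' of its closed-neighborhood graph times the density of that
#' neighborhood's highest-order core, seeds are taken in decreasing weight
#' order, and modules grow breadth-first by admitting unvisited neighbors
#' whose weight is within `mcode_node_score_cutoff` of the seed weight.
#' The haircut step reduces each module to its 2-core, so every surviving
#' member has at least 2 intra-module neighbors; the optional fluff step
#' adds boundary neighbors whose closed-neighborhood density exceeds the
#' cutoff. Singleton and pair remnants never form modules.
#'
#' @param network a [ppi_network()].
#' @param params a [detection_params()].
#' @return a [module_set()] with `method = "MCODE"`, `rank_score` equal to
#'   the ratio of intra-module interactions to proteins, and `k_param` the
#'   largest c such that every member keeps >= c intra-module neighbors.
#' @export
detect_mcode <- function(network, params = detection_params()) {
  stopifnot(inherits(network, "ppi_network"),
            inherits(params, "detection_params"))
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(module_set(list(), "MCODE", network$class_label))
  }
  w <- mcode_weights(g)
  nm <- igraph::V(g)$name
  visited <- rep(FALSE, n)
  adj <- igraph::adjacent_vertices(g, seq_len(n))
  raw <- list()
  for (seed in order(-w, nm)) {
    if (visited[seed] || w[seed] <= 0) next
    thr <- (1 - params$mcode_node_score_cutoff) * w[seed]
    memb <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$mcode_max_depth) {
      cand <- unique(unlist(lapply(frontier, function(i) as.integer(adj[[i]]))))
      cand <- cand[!visited[cand] & w[cand] >= thr]
      if (!length(cand)) break
      visited[cand] <- TRUE
      memb <- c(memb, cand)
      frontier <- cand
      depth <- depth + 1L
    }
    if (length(memb) > 1L) raw <- c(raw, list(memb))
  }
  members <- list(); scores <- numeric(); kp <- integer()
  for (memb in raw) {
    # induced_subgraph returns vertices in increasing id order; keep memb
    # sorted so coreness/degree vectors align with it
    memb <- sort(memb)
    if (params$mcode_fluff) {
      nbrs <- setdiff(unique(unlist(lapply(memb, function(i)
        as.integer(adj[[i]])))), memb)
      if (length(nbrs)) {
        nd <- vapply(nbrs, function(i) {
          nb <- c(i, as.integer(adj[[i]]))
          sub <- igraph::induced_subgraph(g, nb)
          nn <- igraph::vcount(sub)
          if (nn < 2L) 0 else 2 * igraph::ecount(sub) / (nn * (nn - 1))
        }, numeric(1L))
        memb <- sort(c(memb, nbrs[nd > params$mcode_node_score_cutoff]))
      }
    }
    if (params$mcode_haircut) {
      sub <- igraph::induced_subgraph(g, memb)
      core <- igraph::coreness(sub)
      memb <- memb[core >= 2L]
    }
    if (length(memb) < 3L) next
    sub <- igraph::induced_subgraph(g, memb)
    deg <- igraph::degree(sub)
    members <- c(members, list(nm[memb]))
    scores <- c(scores, igraph::ecount(sub) / length(memb))
    kp <- c(kp, min(deg))
  }
  module_set(members, method = "MCODE", class_label = network$class_label,
             k_param = kp, rank_score = scores)
}

#' Modularity of a disjoint partition
#'
#' For a partition of the network into N modules, the mixing matrix E has
#' entries e_ij giving the fraction of edge mass connecting module i to
#' module j: e_ii is the fraction l_i/m of edges internal to module i, and
#' e_ij (i != j) splits the cross edges c_ij as c_ij/(2m), so that the
#' entries sum to 1 and the row sums E_i equal d_i/(2m), the share of
#' degree mass in module i. Modularity is
#' Q = Tr\[E\] - sum_i E_i^2 = sum_i ( l_i/m - (d_i/2m)^2 ):
#' the fraction of intra-module edges minus its expectation under a
#' degree-preserving random graph. Q is 0 for the trivial single-module
#' partition, approaches 1 for strong community structure, and is strictly
#' below 1.
#'
#' @param network a [ppi_network()] with at least one edge.
#' @param partition either a named membership vector covering every node,
#'   or a list of disjoint member vectors jointly covering every node.
#' @return an object of class `partition_summary`: list with
#'   `module_count` (N), `mixing_fraction` (the N x N matrix E),
#'   `module_link_share` (E_i), `trace` (Tr\[E\]) and `q_value` (Q).
#' @export
modularity_q <- function(network, partition) {
  stopifnot(inherits(network, "ppi_network"))
  m <- nrow(network$edges)
  if (m == 0L) stop("modularity is undefined on an edgeless network")
  memb <- as_membership(partition, network$nodes)
  mods <- sort(unique(memb))
  N <- length(mods)
  idx <- match(memb, mods)
  names(idx) <- names(memb)
  i <- idx[network$edges[, 1L]]
  j <- idx[network$edges[, 2L]]
  # integer edge counts first, one division at the end: keeps the exact
  # identities Q(single module) = 0 and sum(E) = 1 free of accumulation
  counts <- matrix(0L, N, N, dimnames = list(mods, mods))
  for (r in seq_len(m)) {
    counts[i[r], j[r]] <- counts[i[r], j[r]] + 1L
    if (i[r] != j[r]) counts[j[r], i[r]] <- counts[j[r], i[r]] + 1L
  }
  E <- counts / (2 * m)
  diag(E) <- diag(counts) / m
  d <- 2L * diag(counts) + (rowSums(counts) - diag(counts))
  Ei <- d / (2 * m)
  tr <- sum(diag(counts)) / m
  structure(list(module_count = N, mixing_fraction = E,
                 module_link_share = Ei, trace = tr,
                 q_value = tr - sum(Ei^2)),
            class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat(sprintf("partition of %d module(s): Tr[E] = %.4f, Q = %.4f\n",
              x$module_count, x$trace, x$q_value))
  invisible(x)
}

as_membership <- function(partition, nodes) {
  if (is.list(partition)) {
    flat <- unlist(partition, use.names = FALSE)
    if (anyDuplicated(flat)) stop("partition modules must be disjoint")
    memb <- rep(seq_along(partition), lengths(partition))
    names(memb) <- flat
  } else {
    memb <- partition
  }
  missing <- setdiff(nodes, names(memb))
  if (length(missing)) {
    stop("partition does not cover node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  memb[nodes]
}

partition_modules <- function(memb, method, class_label) {
  groups <- split(names(memb), memb)
  groups <- groups[lengths(groups) >= 2L]  # singletons never form modules
  module_set(unname(groups), method = method, class_label = class_label)
}

#' Greedy modularity maximization (MaxMod)
#'
#' Agglomerative community detection that starts from singleton modules
#' and repeatedly merges the module pair whose amalgamation yields the
#' largest modularity increase, returning the partition of maximal Q
#' encountered along the merge path (the fast greedy algorithm of Clauset,
#' Newman and Moore, via igraph).
#'
#' @param network a [ppi_network()] with at least one edge.
#' @return list with `modules` (a [module_set()], method `"MAXMOD"`,
#'   singleton communities omitted) and `summary` (the
#'   [modularity_q()] of the full returned partition).
#' @export
detect_greedy <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  if (nrow(network$edges) == 0L) stop("greedy merging needs >= 1 edge")
  g <- as_igraph(network)
  cm <- igraph::cluster_fast_greedy(g)
  memb <- best_cut(g, cm)
  list(modules = partition_modules(memb, "MAXMOD", network$class_label),
       summary = modularity_q(network, memb))
}

# walk every cut of the merge dendrogram and keep the partition of
# maximal modularity (membership() can miss it to FP tolerance)
best_cut <- function(g, cm) {
  n <- igraph::vcount(g)
  n_merges <- nrow(igraph::merges(cm))
  best <- NULL; best_q <- -Inf
  for (no in (n - n_merges):n) {
    memb <- igraph::cut_at(cm, no = no)
    q <- igraph::modularity(g, memb)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  stats::setNames(best, igraph::V(g)$name)
}

#' Random-walk (Walktrap) community detection
#'
#' Agglomerative merging by the t-step random-walk distance between nodes
#' and communities (degree-normalized transition probabilities, Ward-style
#' agglomeration), cut at the partition of maximal modularity along the
#' merge tree (Pons-Latapy walktrap, via igraph). Connected components are
#' handled independently; cross-component distances are effectively
#' infinite.
#'
#' @param network a [ppi_network()] with at least one edge.
#' @param steps random-walk length, >= 1 (default 4, the algorithm's
#'   standard value).
#' @return list with `modules` (a [module_set()], method `"WALKTRAP"`) and
#'   `summary` (the [modularity_q()] of the full returned partition).
#' @export
detect_walktrap <- function(network, steps = 4L) {
  stopifnot(inherits(network, "ppi_network"), steps >= 1L)
  if (nrow(network$edges) == 0L) stop("walktrap needs >= 1 edge")
  g <- as_igraph(network)
  cm <- igraph::cluster_walktrap(g, steps = as.integer(steps))
  memb <- best_cut(g, cm)
  list(modules = partition_modules(memb, "WALKTRAP", network$class_label),
       summary = modularity_q(network, memb))
}

#' CFinder-style community selection across clique sizes
#'
#' Reduces the raw CPM output over a range of clique sizes in two steps.
#' Forward, for each k >= 4: discard communities larger than
#' `max_community_size`, then keep at most `representative_subset_size`
#' communities closest to the median community size at that k (ties by
#' distance to the median, then module id). Backward, from the largest k
#' down: keep a community only if its member set is not a subset of an
#' already-selected community, so nested copies surface once at their
#' highest resolution. Communities at k < 4 are not considered.
#'
#' @param modules_by_k list mapping (as names) clique size k to the
#'   [module_set()] detected at that k.
#' @param params a [detection_params()].
#' @return a [module_set()] ordered by decreasing k then decreasing size.
#' @export
select_cfinder_communities <- function(modules_by_k,
                                       params = detection_params()) {
  ks <- as.integer(names(modules_by_k))
  if (any(is.na(ks))) stop("modules_by_k must be named by integer k")
  keep_members <- list(); keep_k <- integer(); keep_id <- character()
  selected <- list()
  for (k in sort(ks[ks >= 4L], decreasing = TRUE)) {
    ms <- modules_by_k[[as.character(k)]]
    if (is.null(ms) || nrow(ms) == 0L) next
    sizes <- lengths(ms$members)
    ok <- sizes <= params$max_community_size
    ms <- ms[ok, , drop = FALSE]; sizes <- sizes[ok]
    if (nrow(ms) == 0L) next
    med <- stats::median(sizes)
    ord <- order(abs(sizes - med), ms$module_id)
    ord <- ord[seq_len(min(params$representative_subset_size, length(ord)))]
    for (i in ord) {
      memb <- ms$members[[i]]
      redundant <- any(vapply(selected, function(s) all(memb %in% s),
                              TRUE))
      if (!redundant) {
        selected <- c(selected, list(memb))
        keep_members <- c(keep_members, list(memb))
        keep_k <- c(keep_k, k)
        keep_id <- c(keep_id, ms$module_id[i])
      }
    }
  }
  if (!length(keep_members)) {
    cls <- if (length(modules_by_k) &&
               nrow(modules_by_k[[1L]])) modules_by_k[[1L]]$class_label[1L]
           else "SYNTHETIC-NA"
    return(module_set(list(), "CPM", cls))
  }
  ord <- order(-keep_k, -lengths(keep_members))
  module_set(keep_members[ord], method = "CPM",
             class_label = modules_by_k[[1L]]$class_label[1L],
             k_param = keep_k[ord],
             rank_score = lengths(keep_members)[ord],
             module_id = make.unique(keep_id[ord], sep = "_"))
}
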