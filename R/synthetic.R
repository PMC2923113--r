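# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Planted-module simulation specification
#'
#' Describes a ground-truth interactome with planted dense modules and the
#' class-specific sampling that emulates evidence sources of different
#' coverage and reliability: a literature-curated class (high retention,
#' little spurious signal), an orthology-transferred class (intermediate)
#' and a high-throughput two-hybrid class (low retention, noisy). The
#' integrated class is their union. Defaults plant 8 modules of 6-12
#' proteins at intra-density 0.9 in a 300-node background of density
#' 0.005, with retention 0.9/0.7/0.4 and spurious-edge rates
#' 0.05/0.10/0.30 for LIT/ORTHO/HTP; half the plants are permanent
#' (co-expressed) and half transient.
#'
#' @param n_plants number of planted modules.
#' @param plant_size_range integer interval of plant sizes.
#' @param intra_density probability of each within-plant edge (must
#'   exceed `background_density`).
#' @param background_nodes size of the protein universe.
#' @param background_density probability of each background edge.
#' @param class_edge_retention named vector: probability that a true edge
#'   is observed in each disaggregated class.
#' @param class_extra_noise named vector: spurious edges added per class,
#'   as a fraction of the true edge count.
#' @param permanent_fraction fraction of plants marked permanent.
#' @param seed integer seed making all generators reproducible.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(n_plants = 8L,
                       plant_size_range = c(6L, 12L),
                       intra_density = 0.9,
                       background_nodes = 300L,
                       background_density = 0.005,
                       class_edge_retention = c(LIT = 0.9, ORTHO = 0.7,
                                                HTP = 0.4),
                       class_extra_noise = c(LIT = 0.05, ORTHO = 0.10,
                                             HTP = 0.30),
                       permanent_fraction = 0.5,
                       seed = 1L) {
  stopifnot(intra_density > background_density,
            all(class_edge_retention >= 0),
            min(plant_size_range) >= 3L,
            permanent_fraction >= 0, permanent_fraction <= 1)
  if (max(plant_size_range) > background_nodes) {
    stop("infeasible spec: plant larger than the node budget")
  }
  structure(list(n_plants = as.integer(n_plants),
                 plant_size_range = as.integer(plant_size_range),
                 intra_density = intra_density,
                 background_nodes = as.integer(background_nodes),
                 background_density = background_density,
                 class_edge_retention = class_edge_retention,
                 class_extra_noise = class_extra_noise,
                 permanent_fraction = permanent_fraction,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

all_pairs <- function(nodes) {
  if (length(nodes) < 2L) return(matrix(character(), ncol = 2L))
  t(utils::combn(sort(nodes), 2L))
}

#' Generate the interactome classes of a planted-module study
#'
#' Builds the ground-truth network (planted dense blocks over a
#' background random graph), then samples each disaggregated class by
#' retaining true edges independently at the class retention rate and
#' adding spurious non-edges at the class noise rate; the integrated
#' class is the union of the disaggregated ones. Plants may pairwise
#' overlap by at most 2 proteins, so clique percolation at k = 4 keeps
#' them separable. Fully reproducible from `spec$seed`.
#'
#' @param spec a [plant_spec()].
#' @return list with `truth` (list: `plants`, `permanence`,
#'   `true_network`) and `classes` (named list of [ppi_network()],
#'   including `INT`).
#' @export
generate_interactome_classes <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    nodes <- sprintf("P%03d", seq_len(spec$background_nodes))
    # plants are sampled disjointly: each protein has one home complex,
    # which keeps the annotation and expression coherence models exact
    plants <- list()
    size_choices <- seq(spec$plant_size_range[1L],
                        spec$plant_size_range[2L])
    pool <- nodes
    for (i in seq_len(spec$n_plants)) {
      size <- size_choices[sample.int(length(size_choices), 1L)]
      if (size > length(pool)) {
        stop("infeasible spec: plants exhaust the node budget")
      }
      cand <- sort(sample(pool, size))
      pool <- setdiff(pool, cand)
      plants[[sprintf("plant_%02d", i)]] <- cand
    }
    n_perm <- round(spec$permanent_fraction * spec$n_plants)
    perm_ids <- sample(names(plants), n_perm)
    permanence <- stats::setNames(
      ifelse(names(plants) %in% perm_ids, "PERMANENT", "TRANSIENT"),
      names(plants))
    # true network: dense plants over sparse background
    intra <- do.call(rbind, lapply(plants, all_pairs))
    intra <- intra[stats::runif(nrow(intra)) < spec$intra_density, ,
                   drop = FALSE]
    bg <- all_pairs(nodes)
    bg <- bg[stats::runif(nrow(bg)) < spec$background_density, ,
             drop = FALSE]
    truth_net <- ppi_network(rbind(intra, bg), nodes = nodes,
                             class_label = "SYNTHETIC-TRUTH")
    true_edges <- truth_net$edges
    edge_key <- paste(true_edges[, 1L], true_edges[, 2L])
    non_edges <- all_pairs(nodes)
    non_edges <- non_edges[!paste(non_edges[, 1L], non_edges[, 2L]) %in%
                             edge_key, , drop = FALSE]
    classes <- list()
    for (cl in names(spec$class_edge_retention)) {
      keep <- stats::runif(nrow(true_edges)) <
        spec$class_edge_retention[[cl]]
      n_noise <- round(spec$class_extra_noise[[cl]] * nrow(true_edges))
      noise <- non_edges[sample(nrow(non_edges), min(n_noise,
                                                     nrow(non_edges))), ,
                         drop = FALSE]
      classes[[cl]] <- ppi_network(rbind(true_edges[keep, , drop = FALSE],
                                         noise),
                                   nodes = nodes, class_label = cl)
    }
    classes$INT <- integrate_networks(classes, class_label = "INT")
    list(truth = list(plants = plants, permanence = permanence,
                      true_network = truth_net),
         classes = classes)
  })
}

# term ids "MF:d.i" for level-d node i; parent = node (i-1)%/%branch + 1
# at level d-1; a complete branch-ary is_a tree per namespace
synthetic_tree <- function(ns, depth, branch = 3L) {
  ids <- character(); parents <- list(); level <- integer()
  for (d in 0:depth) {
    for (i in seq_len(branch^d)) {
      id <- sprintf("%s:%d.%d", ns, d, i)
      ids <- c(ids, id)
      level <- c(level, d)
      parents[[id]] <- if (d == 0L) character() else
        sprintf("%s:%d.%d", ns, d - 1L, (i - 1L) %/% branch + 1L)
    }
  }
  list(ids = ids, parents = parents, leaves = ids[level == depth])
}

#' Generate a synthetic ontology and coherent annotations
#'
#' Builds three complete ternary is_a trees of the given depth (one per
#' namespace MF/BP/CC) and annotates proteins against them: each plant
#' owns a "home" leaf per namespace, plant members receive the home leaf
#' with probability `p_coherent`, a uniformly random leaf with
#' probability `p_noise`, and no annotation otherwise; background
#' proteins each receive one uniformly random leaf per namespace. High
#' `p_coherent` therefore makes within-plant co-annotation similarity
#' approach 1 while random pairs stay low.
#'
#' @param truth the `truth` element of [generate_interactome_classes()].
#' @param depth tree depth (>= 2).
#' @param p_coherent probability of the home-leaf annotation.
#' @param p_noise probability of a random-leaf annotation instead.
#' @param seed integer seed.
#' @return list with `ontology` (an `ontology_dag`) and `annotations`
#'   (an `annotation_map`).
#' @export
generate_annotation_layer <- function(truth, depth = 4L,
                                      p_coherent = 0.9, p_noise = 0.05,
                                      seed = 1L) {
  stopifnot(depth >= 2L, p_coherent + p_noise <= 1)
  with_seed(seed, {
    trees <- lapply(c(MF = "MF", BP = "BP", CC = "CC"), synthetic_tree,
                    depth = depth)
    ids <- unlist(lapply(trees, `[[`, "ids"), use.names = FALSE)
    parents <- do.call(c, lapply(trees, `[[`, "parents"))
    names(parents) <- ids
    ns <- stats::setNames(sub(":.*$", "", ids), ids)
    roots <- ids[lengths(parents) == 0L]
    dag <- structure(list(terms = ids, parents = parents, namespace = ns,
                          roots = stats::setNames(roots, ns[roots])),
                     class = "ontology_dag")
    dag$ancestors <- compute_ancestors(dag)
    nodes <- truth$true_network$nodes
    planted <- unique(unlist(truth$plants))
    # home leaf of the first plant owning the protein
    prot <- character(); term <- character()
    for (namespace in names(trees)) {
      leaves <- trees[[namespace]]$leaves
      home <- stats::setNames(sample(leaves, length(truth$plants),
                                     replace =
                                       length(leaves) <
                                       length(truth$plants)),
                              names(truth$plants))
      owner <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
      for (p in names(truth$plants)) {
        m <- truth$plants[[p]]
        owner[m[is.na(owner[m])]] <- p
      }
      for (v in nodes) {
        if (!is.na(owner[[v]])) {
          u <- stats::runif(1L)
          if (u < p_coherent) {
            prot <- c(prot, v); term <- c(term, home[[owner[[v]]]])
          } else if (u < p_coherent + p_noise) {
            prot <- c(prot, v); term <- c(term, sample(leaves, 1L))
          }
        } else {
          prot <- c(prot, v); term <- c(term, sample(leaves, 1L))
        }
      }
    }
    list(ontology = dag, annotations = annotation_map(prot, term, dag))
  })
}

#' Generate correlated tissue-expression profiles
#'
#' Each plant receives a latent tissue profile; member profiles are
#' `sqrt(rho) * latent + sqrt(1 - rho) * noise` with `rho` set by the
#' plant's permanence class, shifted to a positive log-scale baseline of
#' 8 with unit noise (so pooled means land in the 8-12 range typical of
#' single-platform expression compendia). Background proteins get
#' independent noise around the baseline.
#'
#' @param truth the `truth` element of [generate_interactome_classes()].
#' @param n_tissues number of tissues (>= 10).
#' @param rho_permanent,rho_transient profile correlation for permanent
#'   and transient plants, `0 <= rho_transient < rho_permanent <= 1`.
#' @param seed integer seed.
#' @return numeric matrix, proteins x tissues.
#' @export
generate_expression <- function(truth, n_tissues = 50L,
                                rho_permanent = 0.8,
                                rho_transient = 0.1, seed = 1L) {
  stopifnot(n_tissues >= 10L, rho_transient >= 0,
            rho_transient < rho_permanent, rho_permanent <= 1)
  with_seed(seed, {
    nodes <- truth$true_network$nodes
    m <- matrix(stats::rnorm(length(nodes) * n_tissues), length(nodes),
                n_tissues,
                dimnames = list(nodes,
                                sprintf("tissue_%02d",
                                        seq_len(n_tissues))))
    latent <- lapply(truth$plants, function(p)
      stats::rnorm(n_tissues))
    assigned <- character()
    for (p in names(truth$plants)) {
      rho <- if (truth$permanence[[p]] == "PERMANENT") rho_permanent else
        rho_transient
      for (v in setdiff(truth$plants[[p]], assigned)) {
        m[v, ] <- sqrt(rho) * latent[[p]] + sqrt(1 - rho) * m[v, ]
      }
      assigned <- union(assigned, truth$plants[[p]])
    }
    m + 8
  })
}

#' Generate perturbed complex and pathway catalogs
#'
#' Each reference complex is a plant with members dropped independently
#' at the `dropout` rate and contaminant background proteins added at the
#' `contamination` rate (at least 2 original members are always kept, so
#' catalogs never degenerate); each pathway is the union of 1-3 plants.
#' These synthetic catalogs stand in for curated complex and pathway
#' databases when exercising the validation stage.
#'
#' @param truth the `truth` element of [generate_interactome_classes()].
#' @param dropout,contamination rates in \[0,1).
#' @param seed integer seed.
#' @return list with `complexes` and `pathways`, each a named list of
#'   protein vectors.
#' @export
generate_catalogs <- function(truth, dropout = 0.1, contamination = 0.1,
                              seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, contamination >= 0,
            contamination < 1)
  with_seed(seed, {
    nodes <- truth$true_network$nodes
    planted <- unique(unlist(truth$plants))
    background <- setdiff(nodes, planted)
    complexes <- lapply(truth$plants, function(p) {
      keep <- p[stats::runif(length(p)) >= dropout]
      if (length(keep) < 2L) keep <- sort(sample(p, min(2L, length(p))))
      n_cont <- stats::rbinom(1L, length(p), contamination)
      sort(c(keep, sample(background, min(n_cont, length(background)))))
    })
    names(complexes) <- sub("^plant", "complex", names(truth$plants))
    n_path <- max(3L, length(truth$plants) %/% 2L)
    pathways <- lapply(seq_len(n_path), function(i) {
      picked <- sample(names(truth$plants), sample(1:3, 1L))
      sort(unique(unlist(truth$plants[picked])))
    })
    names(pathways) <- sprintf("pathway_%02d", seq_len(n_path))
    list(complexes = complexes, pathways = pathways)
  })
}

#' Simulate a complete study and write its input files
#'
#' Runs all four generators with seeds derived from `spec$seed` and
#' writes one edge list per interactome class, the ontology OBO, the
#' annotation TSV, the expression TSV, the complex and pathway GMTs and
#' a truth JSON to `outdir`.
#'
#' @param spec a [plant_spec()].
#' @param outdir output directory (created if missing).
#' @param ... passed on to the stage generators
#'   ([generate_annotation_layer()], [generate_expression()],
#'   [generate_catalogs()]).
#' @return invisibly, the list of generated objects (`truth`, `classes`,
#'   `ontology`, `annotations`, `expression`, `complexes`, `pathways`,
#'   `paths`).
#' @export
simulate_study <- function(spec = plant_spec(), outdir = NULL, ...) {
  net <- generate_interactome_classes(spec)
  ann <- generate_annotation_layer(net$truth, seed = spec$seed + 1L, ...)
  expr <- generate_expression(net$truth, seed = spec$seed + 2L)
  cats <- generate_catalogs(net$truth, seed = spec$seed + 3L)
  out <- c(net, ann,
           list(expression = expr, complexes = cats$complexes,
                pathways = cats$pathways))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    for (cl in names(net$classes)) {
      paths[[cl]] <- file.path(outdir, sprintf("edges_%s.tsv",
                                               tolower(cl)))
      write_edgelist(net$classes[[cl]], paths[[cl]])
    }
    write_obo(ann$ontology,
              paths$ontology <- file.path(outdir, "ontology.obo"))
    write_annotations(ann$annotations,
                      paths$annotations <- file.path(outdir,
                                                     "annotations.tsv"))
    write_expression(expr,
                     paths$expression <- file.path(outdir,
                                                   "expression.tsv"))
    write_gmt(cats$complexes,
              paths$complexes <- file.path(outdir, "complexes.gmt"))
    write_gmt(cats$pathways,
              paths$pathways <- file.path(outdir, "pathways.gmt"))
    jsonlite::write_json(list(plants = net$truth$plants,
                              permanence = as.list(net$truth$permanence)),
                         paths$truth <- file.path(outdir, "truth.json"),
                         auto_unbox = TRUE)
    out$paths <- paths
  }
  invisible(out)
}
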