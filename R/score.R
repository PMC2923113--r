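#' Confidence thresholds
#'
#' The GO co-annotation and expression-correlation cutoffs used by
#' [assign_confidence()] and [classify_permanence()]. Both default to 0.5
#' and comparisons are inclusive (>=).
#'
#' @param go_threshold cutoff on `mf_mean`/`bp_mean`/`cc_mean`, in \[0,1\].
#' @param cor_threshold cutoff on `cor_mean`, in \[0,1\].
#' @return list of class `confidence_thresholds`.
#' @export
confidence_thresholds <- function(go_threshold = 0.5,
                                  cor_threshold = 0.5) {
  stopifnot(go_threshold >= 0, go_threshold <= 1,
            cor_threshold >= 0, cor_threshold <= 1)
  structure(list(go_threshold = go_threshold,
                 cor_threshold = cor_threshold),
            class = "confidence_thresholds")
}

#' Assign a confidence label to a module
#'
#' Semi-quantitative tiering of modules from their annotation variables:
#' \describe{
#'   \item{HIGH}{`mf_mean`, `bp_mean` and `cc_mean` all present and >= the
#'     GO threshold}
#'   \item{MEDIUM}{otherwise, `bp_mean` and `cc_mean` >= the GO threshold
#'     and `cor_mean` present and >= the correlation threshold}
#'   \item{LOW}{otherwise, `bp_mean` and `cc_mean` >= the GO threshold
#'     (including the case of an unmeasurable `cor_mean`: a module cannot
#'     earn MEDIUM on a criterion that cannot be evaluated)}
#'   \item{UNASSIGNED}{everything else}
#' }
#' Tiers are mutually exclusive; thresholds are inclusive.
#'
#' @param vars a [module_variables()] result, or any list/one-row
#'   data.frame carrying `mf_mean`, `bp_mean`, `cc_mean`, `cor_mean`.
#' @param thresholds a [confidence_thresholds()].
#' @return one of `"HIGH"`, `"MEDIUM"`, `"LOW"`, `"UNASSIGNED"`.
#' @export
assign_confidence <- function(vars,
                              thresholds = confidence_thresholds()) {
  ok <- function(v, thr) !is.null(v) && !is.na(v) && v >= thr
  gt <- thresholds$go_threshold
  bp_cc <- ok(vars$bp_mean, gt) && ok(vars$cc_mean, gt)
  if (bp_cc && ok(vars$mf_mean, gt)) return("HIGH")
  if (bp_cc && ok(vars$cor_mean, thresholds$cor_threshold)) {
    return("MEDIUM")
  }
  if (bp_cc) return("LOW")
  "UNASSIGNED"
}

#' Gene-set enrichment of a module (hypergeometric test)
#'
#' For each gene set with a nonzero overlap against the module, the
#' upper-tail hypergeometric p-value of drawing at least the observed
#' overlap when `|module|` proteins are sampled from the universe, with
#' `|set n universe|` marked successes. Benjamini-Hochberg q-values are
#' computed across the sets tested for this module.
#'
#' @param members module member proteins (subset of `universe`).
#' @param gene_sets named list mapping set id to protein vector.
#' @param universe character vector of all proteins under consideration.
#' @return data.frame sorted by p-value with columns `set_id`, `overlap`,
#'   `module_size` (the "cluster frequency" pair), `set_size`, `p_value`,
#'   `fdr_q`; zero rows if nothing overlaps.
#' @export
enrich <- function(members, gene_sets, universe) {
  if (length(universe) == 0L) stop("empty universe")
  members <- unique(as.character(members))
  if (!all(members %in% universe)) {
    stop("module members must be contained in the universe")
  }
  N <- length(universe)
  n <- length(members)
  rows <- lapply(names(gene_sets), function(id) {
    K <- intersect(gene_sets[[id]], universe)
    x <- length(intersect(members, K))
    if (x == 0L) return(NULL)
    p <- stats::phyper(x - 1L, length(K), N - length(K), n,
                       lower.tail = FALSE)
    data.frame(set_id = id, overlap = x, module_size = n,
               set_size = length(K), p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(set_id = character(), overlap = integer(),
                      module_size = integer(), set_size = integer(),
                      p_value = numeric(), fdr_q = numeric()))
  }
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set_id), , drop = FALSE]
}

#' Calibration ranking of scored modules
#'
#' Orders modules by their best (minimum) enrichment q-value, ties broken
#' by module id, and reports the confidence-label composition of the
#' top-K prefix — the calibration check that top-ranking modules confirm
#' their pre-assigned confidence levels.
#'
#' @param module_id character vector.
#' @param label confidence labels parallel to `module_id`.
#' @param best_q best enrichment q-value per module.
#' @param top_k prefix size for the composition report (default 5).
#' @return list with `ranking` (data.frame ordered by `best_q`) and
#'   `top_composition` (named counts of labels in the top-K prefix).
#' @export
calibration_rank <- function(module_id, label, best_q, top_k = 5L) {
  stopifnot(length(module_id) == length(label),
            length(module_id) == length(best_q))
  ord <- order(best_q, module_id)
  ranking <- data.frame(rank = seq_along(ord), module_id = module_id[ord],
                        label = label[ord], best_q = best_q[ord],
                        stringsAsFactors = FALSE)
  top <- utils::head(ranking, top_k)
  comp <- table(factor(top$label,
                       levels = c("HIGH", "MEDIUM", "LOW", "UNASSIGNED")))
  list(ranking = ranking, top_composition = comp)
}

#' Overlap scores of a module against reference complexes
#'
#' For each complex with a nonzero intersection, the three canonical
#' set-overlap indices: Jaccard `|MnC|/|MuC|`, Simpson (overlap
#' coefficient) `|MnC|/min(|M|,|C|)` and the geometric score
#' `|MnC|^2/(|M||C|)`. All lie in \[0,1\] and equal 1 when module and
#' complex coincide.
#'
#' @param members module member proteins.
#' @param complexes named list mapping complex name to protein vector.
#' @return data.frame with columns `complex`, `jaccard`, `simpson`,
#'   `geometric`; disjoint complexes are omitted.
#' @export
overlap_scores <- function(members, complexes) {
  members <- unique(as.character(members))
  rows <- lapply(names(complexes), function(nm) {
    C <- unique(complexes[[nm]])
    x <- length(intersect(members, C))
    if (x == 0L) return(NULL)
    data.frame(complex = nm,
               jaccard = x / length(union(members, C)),
               simpson = x / min(length(members), length(C)),
               geometric = x^2 / (length(members) * length(C)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(complex = character(), jaccard = numeric(),
                      simpson = numeric(), geometric = numeric()))
  }
  do.call(rbind, rows)
}

#' Cross-talk score of a module
#'
#' Fraction of the degree mass incident to the module that leaves it:
#' `boundary / (boundary + 2 * internal)`, where `boundary` counts edges
#' with exactly one endpoint in the module and `internal` edges with both.
#' 0 for an isolated clique component (fully self-contained, cohesive
#' dynamics), 1 for a module with no internal edge (purely communicative).
#'
#' @param members module member proteins, all nodes of `network`.
#' @param network a [ppi_network()].
#' @return a number in \[0,1\].
#' @export
crosstalk_score <- function(members, network) {
  stopifnot(inherits(network, "ppi_network"))
  members <- unique(as.character(members))
  if (!all(members %in% network$nodes)) {
    stop("module members must be nodes of the network")
  }
  e <- network$edges
  a <- e[, 1L] %in% members
  b <- e[, 2L] %in% members
  internal <- sum(a & b)
  boundary <- sum(xor(a, b))
  if (boundary + internal == 0L) return(0)
  boundary / (boundary + 2 * internal)
}

#' Permanent versus transient classification
#'
#' Complexes maintained throughout the cell cycle and most conditions
#' (e.g. proteasome, ribosome) show high co-expression of their members,
#' while condition-specific assemblies (e.g. transcription-factor
#' complexes) show low co-expression. A module is `PERMANENT` when its
#' mean pairwise expression correlation reaches the threshold,
#' `TRANSIENT` when it is measurable but below it, `UNKNOWN` when it
#' cannot be measured.
#'
#' @param vars a [module_variables()] result (anything with `cor_mean`).
#' @param cor_threshold correlation cutoff, default 0.5.
#' @return one of `"PERMANENT"`, `"TRANSIENT"`, `"UNKNOWN"`.
#' @export
classify_permanence <- function(vars, cor_threshold = 0.5) {
  v <- vars$cor_mean
  if (is.null(v) || is.na(v)) return("UNKNOWN")
  if (v >= cor_threshold) "PERMANENT" else "TRANSIENT"
}

#' Read and write GMT gene-set catalogs
#'
#' GMT: one set per line, tab-separated `set_id`, `description`, then the
#' member proteins. Reading goes through `fgsea::gmtPathways()` when fgsea
#' is available and falls back to a direct parse otherwise.
#'
#' @param path file path.
#' @param gene_sets named list of protein vectors.
#' @param descriptions optional character vector parallel to `gene_sets`.
#' @return `read_gmt()`: named list of protein vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  toks <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(toks, function(t) t[-(1:2)]),
                  vapply(toks, `[[`, "", 1L))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  writeLines(vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Score a module set end to end
#'
#' Convenience wrapper combining [annotate_modules()],
#' [assign_confidence()], [classify_permanence()], [crosstalk_score()] and
#' the best [enrich()] hit per module into one table.
#'
#' @param modules a [module_set()].
#' @inheritParams module_variables
#' @param gene_sets named list of protein sets used for enrichment
#'   (pathways or complexes); `NULL` to skip.
#' @param thresholds a [confidence_thresholds()].
#' @return data.frame: the [annotate_modules()] columns plus `label`,
#'   `permanence`, `crosstalk`, and when `gene_sets` is given `best_set`
#'   and `best_q`.
#' @export
score_modules <- function(modules, ontology, annotations, expression,
                          network, gene_sets = NULL,
                          thresholds = confidence_thresholds()) {
  vars <- annotate_modules(modules, ontology, annotations, expression,
                           network)
  n <- nrow(vars)
  vars$label <- vapply(seq_len(n), function(i)
    assign_confidence(vars[i, ], thresholds), "")
  vars$permanence <- vapply(seq_len(n), function(i)
    classify_permanence(vars[i, ], thresholds$cor_threshold), "")
  vars$crosstalk <- vapply(seq_len(n), function(i)
    crosstalk_score(modules$members[[i]], network), numeric(1L))
  if (!is.null(gene_sets)) {
    universe <- network$nodes
    best <- lapply(seq_len(n), function(i) {
      er <- enrich(intersect(modules$members[[i]], universe), gene_sets,
                   universe)
      if (nrow(er) == 0L) {
        data.frame(best_set = NA_character_, best_q = NA_real_)
      } else {
        data.frame(best_set = er$set_id[1L], best_q = er$fdr_q[1L])
      }
    })
    vars <- cbind(vars, do.call(rbind, best))
  }
  vars
}
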