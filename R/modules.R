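#' Module sets
#'
#' A `module_set` is the common currency of all detectors: a data.frame
#' with one row per module and columns `module_id`, `method`,
#' `class_label`, `k_param`, `rank_score` and a list column `members`
#' holding the protein identifiers. Module ids take the form
#' `<class>-<ordinal>` (e.g. `"Lit-9"`); ordinals are assigned by
#' decreasing `rank_score`, ties broken by the lexicographic order of the
#' sorted member vectors, so ids are reproducible run to run.
#'
#' @param members list of character vectors, one per module.
#' @param method detector tag: `"CPM"`, `"MCODE"`, `"MAXMOD"` or
#'   `"WALKTRAP"`.
#' @param class_label interactome class the modules came from.
#' @param k_param integer parameter per module (clique size for CPM, core
#'   degree for MCODE) or `NA`.
#' @param rank_score non-negative ordering key per module.
#' @param module_id optional explicit ids; computed when `NULL`.
#' @return a `module_set` data.frame.
#' @export
module_set <- function(members, method, class_label, k_param = NA_integer_,
                       rank_score = NULL, module_id = NULL) {
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  n <- length(members)
  if (n == 0L) {
    out <- data.frame(module_id = character(), method = character(),
                      class_label = character(), k_param = integer(),
                      rank_score = numeric(), stringsAsFactors = FALSE)
    out$members <- list()
    class(out) <- c("module_set", "data.frame")
    return(out)
  }
  if (any(lengths(members) == 0L)) stop("modules must be non-empty")
  if (is.null(rank_score)) rank_score <- lengths(members)
  k_param <- rep_len(as.integer(k_param), n)
  rank_score <- rep_len(as.numeric(rank_score), n)
  if (is.null(module_id)) {
    # ordinals by rank_score descending, ties by lexicographic member order
    key <- vapply(members, paste, "", collapse = ";")
    ord <- order(-rank_score, key)
    members <- members[ord]
    k_param <- k_param[ord]
    rank_score <- rank_score[ord]
    stem <- class_stem(class_label)
    module_id <- sprintf("%s-%d", stem, seq_len(n))
  }
  if (anyDuplicated(module_id)) stop("module ids must be unique")
  out <- data.frame(module_id = module_id,
                    method = rep_len(method, n),
                    class_label = rep_len(class_label, n),
                    k_param = k_param,
                    rank_score = rank_score,
                    stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("module_set", "data.frame")
  out
}

# "LIT" -> "Lit", "ORTHO" -> "Ortho", "SYNTHETIC-X" kept as is
class_stem <- function(class_label) {
  if (grepl("^SYNTHETIC", class_label)) return(class_label)
  paste0(substr(class_label, 1L, 1L),
         tolower(substr(class_label, 2L, nchar(class_label))))
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s)", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(" [%s on %s], sizes %d-%d",
                paste(unique(x$method), collapse = "/"),
                paste(unique(x$class_label), collapse = "/"),
                min(lengths(x$members)), max(lengths(x$members))))
  }
  cat("\n")
  if (nrow(x)) {
    head_n <- utils::head(seq_len(nrow(x)), 10L)
    for (i in head_n) {
      cat(sprintf("  %-12s n=%-3d score=%-8.3g %s%s\n", x$module_id[i],
                  length(x$members[[i]]), x$rank_score[i],
                  paste(utils::head(x$members[[i]], 6L), collapse = " "),
                  if (length(x$members[[i]]) > 6L) " ..." else ""))
    }
    if (nrow(x) > 10L) cat(sprintf("  ... %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' @export
summary.module_set <- function(object, ...) {
  sizes <- lengths(object$members)
  structure(list(n_modules = nrow(object),
                 methods = unique(object$method),
                 classes = unique(object$class_label),
                 size_summary = if (length(sizes)) summary(sizes) else NULL,
                 histogram = size_histogram(object)),
            class = "summary.module_set")
}

#' @export
print.summary.module_set <- function(x, ...) {
  cat(sprintf("%d module(s) from %s on %s\n", x$n_modules,
              paste(x$methods, collapse = "/"),
              paste(x$classes, collapse = "/")))
  if (!is.null(x$size_summary)) {
    cat("module sizes:\n")
    print(x$size_summary)
  }
  invisible(x)
}

#' Write a module table
#'
#' One row per module as tab-delimited text with columns `module_id`,
#' `method`, `class_label`, `k_param`, `rank_score` and the
#' semicolon-joined `members`. Round-trips losslessly through
#' [read_modules()].
#'
#' @param modules a [module_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  df <- as.data.frame(modules[, c("module_id", "method", "class_label",
                                  "k_param", "rank_score")])
  df$members <- vapply(modules$members, paste, "", collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a module table written by [write_modules()]
#'
#' @param path file path.
#' @return a [module_set()].
#' @export
read_modules <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "integer", "numeric",
                                         "character"),
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(module_set(list(), method = character(0),
                      class_label = character(0)))
  }
  module_set(strsplit(df$members, ";", fixed = TRUE),
             method = df$method, class_label = df$class_label[1L],
             k_param = df$k_param, rank_score = df$rank_score,
             module_id = df$module_id)
}

#' Census of module sizes
#'
#' The empirical frequency with which each module size appears; the raw
#' material for the size histograms and power-law fits used to compare the
#' resolution of detectors.
#'
#' @param modules a [module_set()] or a list of member vectors.
#' @return named integer vector mapping size to count (empty for empty
#'   input); counts sum to the number of modules.
#' @export
size_histogram <- function(modules) {
  sizes <- if (inherits(modules, "module_set")) lengths(modules$members)
           else lengths(modules)
  if (length(sizes) == 0L) return(integer(0))
  tab <- table(sizes)
  structure(as.integer(tab), names = names(tab))
}
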