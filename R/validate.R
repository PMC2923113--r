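#' Round half away from zero
#'
#' Printed-value convention for two-decimal tables (0.875 -> 0.88),
#' unlike base R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Matching frequency of a module against a known complex
#'
#' The fraction of the known complex's proteins matched by the predicted
#' module. A complex is deemed well matched at frequency >= 0.5, i.e. when
#' at least fifty per cent of its proteins appear in the module.
#'
#' @param members module member proteins.
#' @param complex non-empty protein vector.
#' @return a number in \[0,1\].
#' @export
match_frequency <- function(members, complex) {
  complex <- unique(as.character(complex))
  if (length(complex) == 0L) stop("empty complex")
  length(intersect(unique(as.character(members)), complex)) /
    length(complex)
}

#' Module-level precision and recall against one complex
#'
#' True positives are module proteins found in the complex, false
#' positives module proteins absent from it, false negatives complex
#' proteins missed by the module; precision `tp/(tp+fp)` and recall
#' `tp/(tp+fn)`. Undefined ratios (zero denominator) are reported `NA`.
#'
#' @param members non-empty module member proteins.
#' @param complex non-empty protein vector.
#' @return list of class `match_counts` with `tp`, `fp`, `fn`,
#'   `precision`, `recall`.
#' @export
module_pr <- function(members, complex) {
  members <- unique(as.character(members))
  complex <- unique(as.character(complex))
  if (length(members) == 0L) stop("empty module")
  if (length(complex) == 0L) stop("empty complex")
  tp <- length(intersect(members, complex))
  fp <- length(setdiff(members, complex))
  fn <- length(setdiff(complex, members))
  match_counts(tp, fp, fn)
}

match_counts <- function(tp, fp, fn) {
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0L) tp / (tp + fp) else
                   NA_real_,
                 recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d  P=%.3f R=%.3f\n", x$tp, x$fp, x$fn,
              x$precision, x$recall))
  invisible(x)
}

#' Class-level precision' and recall' against a complex catalog
#'
#' Per-class bookkeeping across a set of predicted modules. Every module
#' is assigned its best-frequency complex (ties broken by larger
#' intersection, then lexicographic complex name); `MM` counts modules
#' whose best frequency reaches `freq_threshold` (the significantly
#' matched modules), `PM` is the number of predicted modules, `KC` the
#' number of complexes detected with nonzero frequency by any module, and
#' `MC` the sum over modules of the mean of their qualifying (>=
#' threshold) frequencies — the well-matched complex score. Then
#' `precision' = MM/PM` and `recall' = MC/KC`. With `whole_catalog =
#' TRUE`, `KC` is the full catalog size instead of the detected count.
#'
#' @param modules a [module_set()] (or list of member vectors).
#' @param complexes named list mapping complex name to protein vector.
#' @param freq_threshold matching-frequency cutoff, default 0.5.
#' @param whole_catalog use `length(complexes)` as `KC`.
#' @return list of class `class_summary` with `MM`, `PM`, `MC`, `KC`,
#'   `precision_prime`, `recall_prime` and per-module `best` data.frame.
#' @export
class_pr <- function(modules, complexes, freq_threshold = 0.5,
                     whole_catalog = FALSE) {
  members <- if (inherits(modules, "module_set")) modules$members else
    modules
  ids <- if (inherits(modules, "module_set")) modules$module_id else
    as.character(seq_along(members))
  if (length(members) == 0L) stop("empty module collection")
  if (length(complexes) == 0L) stop("empty complex catalog")
  cn <- names(complexes)
  freq <- vapply(members, function(m) {
    vapply(cn, function(nm) match_frequency(m, complexes[[nm]]),
           numeric(1L))
  }, numeric(length(cn)))
  freq <- matrix(freq, nrow = length(cn),
                 dimnames = list(cn, ids))  # complexes x modules
  best <- do.call(rbind, lapply(seq_along(members), function(i) {
    f <- freq[, i]
    inter <- vapply(cn, function(nm)
      length(intersect(members[[i]], complexes[[nm]])), 1L)
    ord <- order(-f, -inter, cn)
    data.frame(module_id = ids[i], complex = cn[ord[1L]],
               frequency = f[ord[1L]], stringsAsFactors = FALSE)
  }))
  MM <- sum(best$frequency >= freq_threshold)
  PM <- length(members)
  KC <- if (whole_catalog) length(complexes) else
    sum(apply(freq, 1L, function(f) any(f > 0)))
  MC <- sum(vapply(seq_along(members), function(i) {
    q <- freq[, i]
    q <- q[q >= freq_threshold]
    if (length(q)) mean(q) else 0
  }, numeric(1L)))
  structure(list(MM = MM, PM = PM, MC = MC, KC = KC,
                 precision_prime = if (PM > 0L) MM / PM else NA_real_,
                 recall_prime = if (KC > 0L) MC / KC else NA_real_,
                 best = best),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("MM=%d PM=%d MC=%.3f KC=%d  P'=%.3f R'=%.3f\n", x$MM, x$PM,
              x$MC, x$KC, x$precision_prime, x$recall_prime))
  invisible(x)
}

#' Protein-level precision and recall
#'
#' Computed over the union of all module members against the union of all
#' complex members: true positives are module proteins matching complex
#' proteins, false positives module proteins without a complex reference,
#' false negatives complex proteins missed by every module.
#'
#' @inheritParams class_pr
#' @return a `match_counts` (see [module_pr()]).
#' @export
protein_pr <- function(modules, complexes) {
  members <- if (inherits(modules, "module_set")) modules$members else
    modules
  pred <- unique(unlist(members))
  known <- unique(unlist(complexes))
  tp <- length(intersect(pred, known))
  match_counts(tp, length(setdiff(pred, known)),
               length(setdiff(known, pred)))
}

# Hurwitz zeta sum_{i=0}^inf (q+i)^-a via partial sum plus
# Euler-Maclaurin tail (ample accuracy for a > 1, q >= 1)
hurwitz_zeta <- function(a, q, K = 1000L) {
  i <- 0:(K - 1L)
  head <- sum((q + i)^(-a))
  t <- q + K
  head + t^(1 - a) / (a - 1) - 0.5 * t^(-a) + a * t^(-a - 1) / 12
}

#' Discrete power-law fit of module sizes
#'
#' Fits `p(x) proportional to x^-alpha` for `x >= x_min` by discrete
#' maximum likelihood, choosing `x_min` to minimize the Kolmogorov-Smirnov
#' distance between the empirical tail distribution and the fitted one
#' (the standard plfit recipe). Module-size distributions of
#' clique-based detectors typically yield scaling exponents between about
#' 2 and 3.
#'
#' @param sizes integer sample (module sizes), all >= 1, with at least 10
#'   observations in the fitted tail and more than one distinct value.
#' @param x_min_candidates candidate lower cutoffs; defaults to the
#'   distinct observed values that leave >= 10 tail observations.
#' @return object of class `power_law_fit`: list with `alpha`, `x_min`,
#'   `ks_distance`, `n_tail`.
#' @export
fit_power_law <- function(sizes, x_min_candidates = NULL) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 1L))
  if (length(unique(sizes)) < 2L) {
    stop("degenerate sample: all sizes equal")
  }
  if (is.null(x_min_candidates)) {
    x_min_candidates <- sort(unique(sizes))
    tail_n <- vapply(x_min_candidates, function(xm) sum(sizes >= xm), 1L)
    x_min_candidates <- x_min_candidates[tail_n >= 10L]
  }
  if (!length(x_min_candidates)) stop("no viable x_min candidate")
  best <- NULL
  for (xm in x_min_candidates) {
    tail <- sizes[sizes >= xm]
    ll <- function(a) {
      -length(tail) * log(hurwitz_zeta(a, xm)) - a * sum(log(tail))
    }
    a_hat <- stats::optimize(ll, c(1.01, 8), maximum = TRUE)$maximum
    # KS distance between empirical and fitted tail CDFs
    xs <- sort(unique(tail))
    z <- hurwitz_zeta(a_hat, xm)
    full <- xm:max(xs)
    cdf_fit <- cumsum(full^(-a_hat) / z)[match(xs, full)]
    cdf_emp <- stats::ecdf(tail)(xs)
    ks <- max(abs(cdf_emp - cdf_fit))
    if (is.null(best) || ks < best$ks_distance) {
      best <- list(alpha = a_hat, x_min = xm, ks_distance = ks,
                   n_tail = length(tail))
    }
  }
  structure(best, class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "discrete power law: alpha = %.3f, x_min = %d, KS = %.4f (n = %d)\n",
    x$alpha, x$x_min, x$ks_distance, x$n_tail))
  invisible(x)
}

#' @export
plot.power_law_fit <- function(x, sizes = NULL, ...) {
  if (is.null(sizes)) stop("supply the fitted sizes to plot")
  tab <- table(sizes)
  xs <- as.integer(names(tab))
  graphics::plot(xs, as.integer(tab) / length(sizes), log = "xy",
                 xlab = "module size", ylab = "frequency",
                 main = sprintf("alpha = %.2f, x_min = %d", x$alpha,
                                x$x_min), ...)
  xx <- seq(x$x_min, max(xs))
  z <- hurwitz_zeta(x$alpha, x$x_min)
  scale <- mean(sizes >= x$x_min)
  graphics::lines(xx, scale * xx^(-x$alpha) / z, col = 2)
  invisible(x)
}

#' Sample from a discrete power law
#'
#' Inverse-CDF sampling of `p(x) proportional to x^-alpha`, `x >= x_min`,
#' truncated at a cap carrying negligible tail mass. Used as the
#' generator oracle when testing [fit_power_law()].
#'
#' @param n sample size.
#' @param alpha scaling exponent (> 1).
#' @param x_min lower cutoff (>= 1).
#' @param cap truncation point.
#' @return integer vector of length `n`.
#' @export
rpower_law <- function(n, alpha, x_min = 1L, cap = 100000L) {
  xs <- x_min:cap
  sample(xs, n, replace = TRUE, prob = xs^(-alpha))
}
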