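#' Packaged confidence-label fixture
#'
#' Published module annotation variables (n, n.ex, ex.mean, cor.mean,
#' mf.mean, bp.mean, cc.mean) for clique-percolation and MCODE modules
#' from a multi-class human-interactome study, packaged verbatim as a
#' label fixture: the `assigned` table carries the expert-assigned
#' High/Medium/Low tier of every selected module, the `residual` table
#' the modules that did not pass the confidence thresholds. Applying
#' [assign_confidence()] to the printed values must reproduce every
#' assigned tier and leave every residual row unassigned.
#'
#' @return list of two data.frames, `assigned` (with a `tier` column) and
#'   `residual`.
#' @export
confidence_fixture <- function() {
  rd <- function(f) {
    utils::read.table(system.file("extdata", f, package = "ppimodules"),
                      sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  }
  list(assigned = rd("confidence_fixture_assigned.tsv"),
       residual = rd("confidence_fixture_residual.tsv"))
}

#' Packaged validation worked example
#'
#' The printed member list of a high-confidence literature-class module
#' (the seven LSM proteins plus SMN1) together with the reference
#' mRNA-degradation complex it maps to (LSM1-LSM7). Module-level
#' precision against this complex is 7/8 (printed 0.88) and recall is 1.
#'
#' @return list with `module` (a one-row [module_set()]) and `complexes`
#'   (named list with one protein vector).
#' @export
worked_example <- function() {
  list(module = read_modules(system.file(
         "extdata", "worked_example_modules.tsv",
         package = "ppimodules")),
       complexes = read_gmt(system.file(
         "extdata", "worked_example_complexes.gmt",
         package = "ppimodules")))
}
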