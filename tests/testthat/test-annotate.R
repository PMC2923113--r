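# tiny three-namespace ontology written and re-read as OBO
local_ontology <- function(env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".obo", .local_envir = env)
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: MF:0", "namespace: molecular_function", "",
    "[Term]", "id: MF:1", "namespace: molecular_function",
    "is_a: MF:0 ! root", "",
    "[Term]", "id: MF:2", "namespace: molecular_function",
    "is_a: MF:1", "",
    "[Term]", "id: MF:3", "namespace: molecular_function",
    "is_a: MF:0", "",
    "[Term]", "id: MF:4", "namespace: molecular_function",
    "is_a: MF:3", "",
    "[Term]", "id: BP:0", "namespace: biological_process", "",
    "[Term]", "id: BP:1", "namespace: biological_process",
    "is_a: BP:0", "",
    "[Term]", "id: CC:0", "namespace: cellular_component", "",
    "[Term]", "id: CC:1", "namespace: cellular_component",
    "is_a: CC:0", "",
    "[Term]", "id: OB:1", "namespace: molecular_function",
    "is_obsolete: true"), f)
  read_obo(f)
}

test_that("OBO parsing keeps ids, namespaces and is_a closure only", {
  ont <- local_ontology()
  expect_length(ont$terms, 9)             # obsolete term dropped
  expect_false("OB:1" %in% ont$terms)
  expect_setequal(unname(ont$roots), c("MF:0", "BP:0", "CC:0"))
  expect_equal(sort(ont$ancestors[["MF:2"]]), c("MF:0", "MF:1"))
  expect_equal(ont$namespace[["BP:1"]], "BP")
})

test_that("ancestor graphs are rootless transitive closures", {
  ont <- local_ontology()
  ann <- annotation_map(c("root_only", "leafy", "leafy"),
                        c("MF:0", "MF:2", "BP:1"), ont)
  # annotated only to the namespace root: excluded, so empty
  expect_equal(ancestor_graph("root_only", "MF", ont, ann), character(0))
  # chain t -> u -> root keeps {t, u}
  expect_setequal(ancestor_graph("leafy", "MF", ont, ann),
                  c("MF:2", "MF:1"))
  # annotation in another namespace does not leak
  expect_setequal(ancestor_graph("leafy", "BP", ont, ann), "BP:1")
  expect_equal(ancestor_graph("unseen", "MF", ont, ann), character(0))
  expect_error(ancestor_graph("leafy", "XX", ont, ann), "namespace")
})

test_that("co-annotation similarity is the ancestor-graph Jaccard", {
  ont <- local_ontology()
  ann <- annotation_map(c("p1", "p2", "p3", "p4"),
                        c("MF:2", "MF:2", "MF:1", "MF:4"), ont)
  expect_equal(coannotation_similarity("p1", "p2", "MF", ont, ann), 1)
  # graphs {MF:2, MF:1} vs {MF:1}
  expect_equal(coannotation_similarity("p1", "p3", "MF", ont, ann), 0.5)
  expect_true(is.na(coannotation_similarity("p1", "nope", "MF", ont,
                                            ann)))
  # symmetry, bounds, disjoint branches
  s12 <- coannotation_similarity("p1", "p4", "MF", ont, ann)
  s21 <- coannotation_similarity("p4", "p1", "MF", ont, ann)
  expect_equal(s12, s21)
  expect_equal(s12, 0)  # MF:1/MF:2 vs MF:3/MF:4 share only the root
})

test_that("shared terms never decrease similarity; disjoint private terms never increase it", {
  ont <- local_ontology()
  base <- annotation_map(c("a", "b"), c("MF:2", "MF:1"), ont)
  s0 <- coannotation_similarity("a", "b", "MF", ont, base)
  # add the same leaf (MF:4, disjoint branch) to both
  shared <- annotation_map(c("a", "a", "b", "b"),
                           c("MF:2", "MF:4", "MF:1", "MF:4"), ont)
  expect_gte(coannotation_similarity("a", "b", "MF", ont, shared), s0)
  # add a private term from a branch disjoint from b's graph to a only
  private <- annotation_map(c("a", "a", "b"),
                            c("MF:2", "MF:4", "MF:1"), ont)
  expect_lte(coannotation_similarity("a", "b", "MF", ont, private), s0)
})

test_that("rank correlation reproduces the worked values", {
  expect_equal(spearman_cor(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(spearman_cor(c(1, 2), c(2, 1))))
  expect_true(is.na(spearman_cor(c(5, 5, 5), c(1, 2, 3))))
  expect_error(spearman_cor(1:3, 1:4), "equal length")
})

test_that("module variables count, average and drop exactly as specified", {
  ont <- local_ontology()
  # module {a, b, c} with intra-module edges a-b and b-c only
  net <- net_from(rbind(c("a", "b"), c("b", "c"), c("c", "x")))
  ann <- annotation_map(c("a", "b", "c"), c("MF:2", "MF:2", "MF:4"), ont)
  expr <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 9))  # identical ranks
  colnames(expr) <- paste0("t", 1:4)

  v <- module_variables(c("a", "b", "c"), ont, ann, expr, net, "m1")
  expect_equal(v$n, 3)
  expect_equal(v$n_ex, 2)           # c missing from the compendium
  expect_equal(v$ex_mean, mean(expr))
  expect_equal(v$cor_mean, 1)       # identical strictly monotone profiles
  # MF mean over the two annotated edges: sim(a,b) = 1, sim(b,c) = 0
  expect_equal(v$mf_mean, 0.5)
  expect_true(is.na(v$bp_mean))     # nobody annotated in BP
  expect_true(is.na(v$cc_mean))

  # a single expressed member leaves the correlation unmeasurable
  v1 <- module_variables(c("a", "c"), ont, ann, expr, net)
  expect_equal(v1$n_ex, 1)
  expect_true(is.na(v1$cor_mean))

  expect_error(module_variables(c("a", "zz"), ont, ann, expr, net),
               "nodes")
})

test_that("annotate_modules returns one consistent row per module", {
  ont <- local_ontology()
  net <- net_from(edges_K(c("a", "b", "c")), rbind(c("c", "d")))
  ann <- annotation_map(c("a", "b"), c("MF:2", "MF:2"), ont)
  expr <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("a", "b", "c"), paste0("t", 1:4)))
  ms <- module_set(list(c("a", "b", "c"), c("c", "d")), "CPM", "LIT",
                   k_param = 3)
  tab <- annotate_modules(ms, ont, ann, expr, net)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$module_id, ms$module_id)
  expect_equal(tab$n, lengths(ms$members))
})
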