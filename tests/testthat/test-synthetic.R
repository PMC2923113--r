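test_that("generators are pure functions of spec and seed", {
  spec <- plant_spec(n_plants = 4, background_nodes = 80, seed = 5)
  a <- generate_interactome_classes(spec)
  b <- generate_interactome_classes(spec)
  expect_identical(a$truth$plants, b$truth$plants)
  expect_identical(lapply(a$classes, `[[`, "edges"),
                   lapply(b$classes, `[[`, "edges"))
  expect_identical(generate_expression(a$truth, seed = 3),
                   generate_expression(b$truth, seed = 3))
  expect_identical(generate_catalogs(a$truth, seed = 3),
                   generate_catalogs(b$truth, seed = 3))
  ann1 <- generate_annotation_layer(a$truth, seed = 3)
  ann2 <- generate_annotation_layer(b$truth, seed = 3)
  expect_identical(unclass(ann1$annotations), unclass(ann2$annotations))
})

test_that("retention and noise extremes bracket the class networks", {
  spec <- plant_spec(n_plants = 3, background_nodes = 60,
                     class_edge_retention = c(LIT = 1, HTP = 1),
                     class_extra_noise = c(LIT = 0, HTP = 0), seed = 2)
  out <- generate_interactome_classes(spec)
  # full retention, no noise: every class equals the true network
  expect_equal(out$classes$LIT$edges, out$truth$true_network$edges)
  expect_equal(out$classes$HTP$edges, out$truth$true_network$edges)
  expect_equal(out$classes$INT$edges, out$truth$true_network$edges)

  spec0 <- plant_spec(n_plants = 3, background_nodes = 60,
                      class_edge_retention = c(LIT = 0),
                      class_extra_noise = c(LIT = 0), seed = 2)
  expect_equal(nrow(generate_interactome_classes(spec0)$classes$LIT$edges),
               0)

  expect_error(plant_spec(plant_size_range = c(10, 50),
                          background_nodes = 40), "node budget")
})

test_that("plants are disjoint, sized in range, and dense in the truth", {
  spec <- plant_spec(seed = 4)
  out <- generate_interactome_classes(spec)
  sizes <- lengths(out$truth$plants)
  expect_true(all(sizes >= 6 & sizes <= 12))
  expect_equal(anyDuplicated(unlist(out$truth$plants)), 0L)
  # planted blocks carry most of their possible edges
  e <- out$truth$true_network$edges
  for (p in out$truth$plants) {
    got <- sum(e[, 1] %in% p & e[, 2] %in% p)
    expect_gt(got / choose(length(p), 2), 0.7)
  }
})

test_that("coherent annotation separates plants from background", {
  spec <- plant_spec(n_plants = 4, background_nodes = 100, seed = 9)
  out <- generate_interactome_classes(spec)
  # fully coherent: within-plant co-annotation is exactly 1
  ann1 <- generate_annotation_layer(out$truth, p_coherent = 1,
                                    p_noise = 0, seed = 1)
  p <- out$truth$plants[[1]]
  expect_equal(coannotation_similarity(p[1], p[2], "MF", ann1$ontology,
                                       ann1$annotations), 1)
  # no annotation at all for plant members
  ann0 <- generate_annotation_layer(out$truth, p_coherent = 0,
                                    p_noise = 0, seed = 1)
  expect_null(ann0$annotations[[p[1]]])
  # defaults: intra-plant similarity beats random background pairs
  annd <- generate_annotation_layer(out$truth, seed = 1)
  intra <- mean(vapply(out$truth$plants, function(pl) {
    prs <- utils::combn(pl, 2)
    mean(vapply(seq_len(ncol(prs)), function(i)
      coannotation_similarity(prs[1, i], prs[2, i], "BP", annd$ontology,
                              annd$annotations), numeric(1)),
      na.rm = TRUE)
  }, numeric(1)))
  bg <- setdiff(out$truth$true_network$nodes,
                unlist(out$truth$plants))
  withr::local_seed(10)
  bg_pairs <- replicate(60, sample(bg, 2))
  inter <- mean(vapply(1:60, function(i)
    coannotation_similarity(bg_pairs[1, i], bg_pairs[2, i], "BP",
                            annd$ontology, annd$annotations),
    numeric(1)), na.rm = TRUE)
  expect_gt(intra, inter)
})

test_that("expression correlation tracks the permanence classes", {
  spec <- plant_spec(n_plants = 6, background_nodes = 120, seed = 21)
  out <- generate_interactome_classes(spec)
  net <- out$truth$true_network
  # perfectly correlated permanent plants reach cor_mean 1 exactly
  e1 <- generate_expression(out$truth, n_tissues = 30,
                            rho_permanent = 1, rho_transient = 0,
                            seed = 2)
  ann <- generate_annotation_layer(out$truth, seed = 2)
  perm <- names(which(out$truth$permanence == "PERMANENT"))
  v <- module_variables(out$truth$plants[[perm[1]]], ann$ontology,
                        ann$annotations, e1, net)
  expect_equal(v$cor_mean, 1)
  # uncorrelated transient plants stay near zero
  vt <- module_variables(
    out$truth$plants[[names(which(out$truth$permanence ==
                                    "TRANSIENT"))[1]]],
    ann$ontology, ann$annotations,
    generate_expression(out$truth, n_tissues = 100, rho_permanent = 1,
                        rho_transient = 0, seed = 3), net)
  expect_lt(abs(vt$cor_mean), 0.1)
  # permanent exceeds transient in almost every replicate
  wins <- vapply(1:10, function(s) {
    ex <- generate_expression(out$truth, n_tissues = 50,
                              rho_permanent = 0.8, rho_transient = 0.1,
                              seed = s)
    cm <- vapply(out$truth$plants, function(pl) {
      module_variables(pl, ann$ontology, ann$annotations, ex,
                       net)$cor_mean
    }, numeric(1))
    min(cm[out$truth$permanence == "PERMANENT"]) >
      max(cm[out$truth$permanence == "TRANSIENT"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("catalog perturbation follows the dropout/contamination model", {
  spec <- plant_spec(n_plants = 5, background_nodes = 120, seed = 31)
  out <- generate_interactome_classes(spec)
  clean <- generate_catalogs(out$truth, dropout = 0, contamination = 0,
                             seed = 1)
  expect_equal(unname(clean$complexes), unname(out$truth$plants))
  # a perfectly recovered plant then validates perfectly
  pr <- module_pr(out$truth$plants[[1]], clean$complexes[[1]])
  expect_equal(c(pr$precision, pr$recall), c(1, 1))
  # every pathway is a union of plants, so it contains whole plants
  for (pw in clean$pathways) {
    covered <- vapply(out$truth$plants, function(p) all(p %in% pw),
                      logical(1))
    expect_equal(sort(unique(unlist(out$truth$plants[covered]))),
                 pw)
  }
  # heavy dropout halves complexes on average (binomial over seeds)
  spec10 <- plant_spec(n_plants = 4, plant_size_range = c(10, 10),
                       background_nodes = 100, seed = 41)
  t10 <- generate_interactome_classes(spec10)$truth
  mean_size <- mean(vapply(1:20, function(s) {
    mean(lengths(generate_catalogs(t10, dropout = 0.5,
                                   contamination = 0,
                                   seed = s)$complexes))
  }, numeric(1)))
  expect_lt(abs(mean_size - 5), 1)
})
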