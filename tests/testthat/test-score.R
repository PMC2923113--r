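test_that("confidence tiers follow the two-of-three and correlation rules", {
  lab <- function(mf, bp, cc, cor) {
    assign_confidence(list(mf_mean = mf, bp_mean = bp, cc_mean = cc,
                           cor_mean = cor))
  }
  expect_equal(lab(0.76, 0.70, 0.70, 0.22), "HIGH")
  expect_equal(lab(0.45, 0.51, 0.70, 0.54), "MEDIUM")
  expect_equal(lab(0.45, 0.73, 0.96, 0.39), "LOW")
  expect_equal(lab(0.46, 0.56, 0.49, 0.60), "UNASSIGNED")
  # thresholds are inclusive: bp exactly at 0.5 still passes
  expect_equal(lab(0.33, 0.50, 0.63, 0.32), "LOW")
  # HIGH does not require a measurable correlation
  expect_equal(lab(0.85, 0.88, 0.84, NA), "HIGH")
  # unmeasurable correlation cannot earn MEDIUM
  expect_equal(lab(0.45, 0.60, 0.60, NA), "LOW")
})

test_that("the packaged label fixture is reproduced without mismatch", {
  fx <- confidence_fixture()
  got <- vapply(seq_len(nrow(fx$assigned)), function(i)
    assign_confidence(as.list(fx$assigned[i, ])), "")
  expect_equal(got, toupper(fx$assigned$tier))
  resid <- vapply(seq_len(nrow(fx$residual)), function(i)
    assign_confidence(as.list(fx$residual[i, ])), "")
  expect_true(all(resid == "UNASSIGNED"))
})

test_that("hypergeometric enrichment matches combinatorial identities", {
  universe <- sprintf("u%02d", 1:20)
  gs <- list(hit = universe[1:5], miss = universe[11:15])
  er <- enrich(universe[1:5], gs, universe)
  # all five drawn from the five-protein set: p = 1 / C(20, 5)
  expect_equal(er$p_value[er$set_id == "hit"], 1 / choose(20, 5))
  expect_equal(er$overlap[er$set_id == "hit"], 5)
  # zero-overlap sets are omitted
  expect_false("miss" %in% er$set_id)
  # single tested set: BH leaves q = p
  expect_equal(er$fdr_q, er$p_value)
  expect_error(enrich("u01", gs, character(0)), "universe")
})

test_that("enrichment p-values agree with brute-force enumeration", {
  withr::local_seed(66)
  for (rep in 1:20) {
    N <- sample(6:15, 1)
    universe <- sprintf("u%02d", seq_len(N))
    set <- sample(universe, sample(2:(N - 1), 1))
    mod <- sample(universe, sample(2:(N - 1), 1))
    x <- length(intersect(mod, set))
    if (x == 0) next
    er <- enrich(mod, list(s = set), universe)
    expect_equal(er$p_value,
                 hyper_oracle(x, length(set), N, length(mod)),
                 tolerance = 1e-12)
  }
})

test_that("BH q-values are monotone nondecreasing in p-rank", {
  withr::local_seed(31)
  universe <- sprintf("u%03d", 1:60)
  gs <- lapply(1:12, function(i) sample(universe, sample(4:20, 1)))
  names(gs) <- sprintf("set%02d", 1:12)
  er <- enrich(sample(universe, 15), gs, universe)
  expect_true(all(diff(er$fdr_q) >= -1e-15))
  expect_true(all(er$p_value <= er$fdr_q + 1e-15))
})

test_that("calibration ranking orders by best q with stable ties", {
  r <- calibration_rank(c("m1", "m2", "m3"),
                        c("HIGH", "LOW", "MEDIUM"),
                        c(1e-3, 1e-8, 0.2))
  expect_equal(r$ranking$module_id, c("m2", "m1", "m3"))
  tie <- calibration_rank(c("b", "a", "c"), rep("HIGH", 3), rep(0.5, 3))
  expect_equal(tie$ranking$module_id, c("a", "b", "c"))
  expect_equal(sum(tie$top_composition), 3)
})

test_that("overlap scores are the canonical index triple", {
  M <- sprintf("p%d", 1:8)
  sc <- overlap_scores(M, list(sub = M[1:7], same = M, far = "zz"))
  expect_equal(sc[sc$complex == "same", -1],
               data.frame(jaccard = 1, simpson = 1, geometric = 1),
               ignore_attr = TRUE)
  row <- sc[sc$complex == "sub", ]
  expect_equal(row$jaccard, 7 / 8)
  expect_equal(row$simpson, 1)
  expect_equal(row$geometric, 49 / 56)
  expect_false("far" %in% sc$complex)
})

test_that("cross-talk measures the boundary share of degree mass", {
  iso <- net_from(edges_K(c("a", "b", "c", "d")))
  expect_equal(crosstalk_score(c("a", "b", "c", "d"), iso), 0)
  star <- net_from(cbind("hub", paste0("l", 1:4)))
  expect_equal(crosstalk_score("hub", star), 1)
  k4out <- net_from(edges_K(letters[1:4]),
                    rbind(c("a", "x"), c("b", "y")))
  expect_equal(crosstalk_score(letters[1:4], k4out), 2 / 14)
})

test_that("permanence classification thresholds the correlation mean", {
  expect_equal(classify_permanence(list(cor_mean = 0.59)), "PERMANENT")
  expect_equal(classify_permanence(list(cor_mean = 0.39)), "TRANSIENT")
  expect_equal(classify_permanence(list(cor_mean = 0.5)), "PERMANENT")
  expect_equal(classify_permanence(list(cor_mean = NA)), "UNKNOWN")
})

test_that("GMT catalogs round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  gs <- list(alpha = c("A", "B", "C"), beta = c("B", "D"))
  write_gmt(gs, f)
  expect_equal(read_gmt(f), gs)
})
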