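test_that("a training compound is its own perfect neighbourhood", {
  sc <- small_scorer()
  smi <- sc$labels$smiles[[1]]
  ca <- compound_applicability(sc, smi, ad_params(k_structural = 1))
  expect_identical(ca$s_fp, 1)
  expect_identical(ca$s_rule, 1)
  expect_identical(ca$compound_score, 1)
  expect_true(ca$in_domain)
})

test_that("compound score is the equal-weight mean of its two components", {
  sc <- small_scorer()
  q <- "O=[N+]([O-])c1ccc(S(N)(=O)=O)cc1"   # outside the training grid
  ca <- compound_applicability(sc, q)
  expect_identical(ca$compound_score, (ca$s_fp + ca$s_rule) / 2)
  expect_true(ca$compound_score >= 0 && ca$compound_score <= 1)
  expect_error(compound_applicability(sc, q,
                                      exclude = sc$labels$smiles),
               "empty training index")
})

test_that("functional-group coverage uses training support and thresholds", {
  sc <- small_scorer()
  smi <- sc$labels$smiles[[1]]
  cov <- functional_group_coverage(sc, smi, ad_params(fg_min_support = 3))
  expect_true(all(cov$covered == (cov$support >= 3)))
  # a molecule with no hetero groups yields an empty map
  cov0 <- functional_group_coverage(sc, "CCCC")
  expect_identical(nrow(cov0), 0L)
  # a group absent from training has support 0 and is not covered
  covq <- functional_group_coverage(sc, "O=S(=O)(N)c1ccccc1")
  sulf <- covq[covq$group_id == "sulfonamide", ]
  expect_identical(sulf$support, 0L)
  expect_false(sulf$covered)
})

test_that("reliability is the mean similarity of the n best rule-compatible neighbours", {
  sc <- small_scorer()
  lbl <- sc$labels
  has_rule <- which(purrr::map_lgl(lbl$triggered, ~ length(.x) > 0))[1]
  smi <- lbl$smiles[[has_rule]]
  rid <- lbl$triggered[[has_rule]][1]
  # brute-force oracle: exhaustive sorted enumeration of candidates
  cand <- lbl[purrr::map_lgl(lbl$triggered, ~ rid %in% .x) &
                lbl$smiles != smi, ]
  sims <- vapply(cand$smiles, function(s) tanimoto(smi, s), numeric(1))
  ord <- order(-sims, cand$smiles)
  for (n in c(1, 3, 5, 20)) {
    got <- reliability_score(sc, smi, rid, n = n)
    want <- mean(sims[ord[seq_len(min(n, length(ord)))]])
    expect_equal(got$reliability, want, tolerance = 1e-12)
    expect_identical(got$low_support, length(ord) < n)
  }
  expect_error(reliability_score(sc, "CCCC", rid), "does not trigger")
})

test_that("reliability is monotone non-increasing in n", {
  sc <- small_scorer()
  lbl <- sc$labels
  idx <- which(purrr::map_lgl(lbl$triggered, ~ length(.x) > 0))[1:5]
  for (i in idx) {
    smi <- lbl$smiles[[i]]
    for (rid in lbl$triggered[[i]]) {
      vals <- vapply(1:8, function(n)
        reliability_score(sc, smi, rid, n = n)$reliability, numeric(1))
      expect_true(all(diff(vals) <= 1e-12),
                  label = paste("monotone for", smi, rid))
    }
  }
})

test_that("leave-one-out never self-matches: injected duplicates are excluded", {
  # training set with an exact duplicate structure under a different id
  pkg <- small_pkg()
  sc <- small_scorer()
  lbl <- sc$labels
  smi <- lbl$smiles[[1]]
  rid <- lbl$triggered[[1]][1]
  rel <- reliability_score(sc, smi, rid, n = 1)
  # the query is itself a training compound yet its own similarity (1.0)
  # must not be used: unless another duplicate exists, top-1 similarity
  # is below 1 or comes from a genuinely different structure
  cand <- lbl[purrr::map_lgl(lbl$triggered, ~ rid %in% .x) &
                lbl$smiles != smi, ]
  best <- max(vapply(cand$smiles, function(s) tanimoto(smi, s), numeric(1)))
  expect_equal(rel$reliability, best, tolerance = 1e-12)
})

test_that("local goodness of fit is a fraction of correct LOO labels", {
  sc <- small_scorer()
  lbl <- sc$labels
  i <- which(purrr::map_lgl(lbl$triggered, ~ length(.x) > 0))[1]
  smi <- lbl$smiles[[i]]
  rid <- lbl$triggered[[i]][1]
  lof <- local_goodness_of_fit(sc, smi, rid, n = 4, threshold = 0.5)
  expect_false(lof$undefined)
  expect_true(lof$local_fit >= 0 && lof$local_fit <= 1)
  expect_true(abs(lof$local_fit * lof$n_candidates -
                    round(lof$local_fit * lof$n_candidates)) < 1e-9)
  # rule with no candidates anywhere: undefined and flagged
  none <- local_goodness_of_fit(sc, "O=[N+]([O-])c1ccncc1",
                                "sulfoxidation", n = 3)
  if (none$n_candidates == 0) {
    expect_true(none$undefined)
    expect_true(is.na(none$local_fit))
  }
})

test_that("all four AD scores stay within [0, 1] on fuzzed queries", {
  sc <- small_scorer()
  frags <- c("O", "N", "Cl", "C#N", "OC", "SC", "C(=O)O", "CO", "NC(C)=O",
             "[N+](=O)[O-]", "C", "CC")
  set.seed(11)
  bad <- 0L
  params <- ad_params(n_neighbors = 3, k_structural = 3)
  for (rep in 1:60) {
    q <- paste0("c1cc(", sample(frags, 1), ")cc(", sample(frags, 1), ")c1")
    ca <- compound_applicability(sc, q, params)
    cov <- functional_group_coverage(sc, q, params)
    vals <- c(ca$s_fp, ca$s_rule, ca$compound_score)
    trig <- triggered_rules(sc$rules, q)$rule_id
    if (length(trig)) {
      rid <- trig[1]
      rel <- reliability_score(sc, q, rid, n = 3)
      lof <- local_goodness_of_fit(sc, q, rid, n = 3)
      vals <- c(vals, rel$reliability,
                if (!lof$undefined) lof$local_fit)
    }
    if (any(vals < 0 | vals > 1) || any(cov$support < 0)) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("pathway annotation covers all nodes and edges consistently", {
  sc <- small_scorer()
  root <- small_pkg()$pathways[[1]]$roots[1]
  pw <- predict_pathway(sc, root, config = prediction_config(
    max_nodes = 15, score_threshold = 0.3))
  ann <- annotate_pathway(pw, sc)
  expect_identical(nrow(ann$nodes), nrow(pw$nodes))
  expect_identical(nrow(ann$edges), nrow(pw$edges))
  expect_true(all(ann$nodes$in_domain ==
                    (ann$nodes$compound_score >= 0.5)))
  ok <- ann$edges$reliability >= 0.5 &
    (is.na(ann$edges$local_fit) | ann$edges$local_fit >= 0.5)
  expect_identical(ann$edges$edge_ok, ok)
  # annotations render into DOT
  dot <- export_dot(pw, ann)
  expect_match(dot, "color=(green|red)")
  # single-node pathway: node annotations only
  solo <- predict_pathway(sc, "c1ccc(Br)cc1",
                          config = prediction_config(max_nodes = 1))
  ann1 <- annotate_pathway(solo, sc)
  expect_identical(nrow(ann1$edges), 0L)
  expect_identical(nrow(ann1$nodes), 1L)
})

test_that("vocabulary mismatch is rejected", {
  sc <- small_scorer()
  pw <- pathway(tibble::tibble(substrate = "A", product = "B",
                               rule_id = "alien_rule"), roots = "A")
  expect_error(annotate_pathway(pw, sc), "outside the scorer vocabulary")
})
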