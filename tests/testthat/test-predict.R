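# A hand-built training package giving a deterministic linear cascade:
# ester -> acid (+ alcohol), acid -> nothing above threshold.
cascade_scorer <- function() {
  if (!is.null(fixture_env$cascade_scorer)) return(fixture_env$cascade_scorer)
  rules <- toy_rules()[toy_rules()$rule_id %in%
                         c("ester_hydrolysis", "alcohol_oxidation"), ]
  compounds <- tibble::tibble(
    compound_id = sprintf("c%d", 1:5),
    smiles = canonicalize_smiles(c("CCOC(C)=O", "CC(=O)O", "CCO",
                                   "CCCOC(C)=O", "CCCO")),
    display_smiles = NA_character_, name = NA_character_
  )
  reactions <- tibble::tibble(
    reaction_id = c("r1", "r2", "r3"),
    substrates = list("CCOC(C)=O", "CCCOC(C)=O", "CCCO"),
    products = list(c("CC(=O)O", "CCO"), c("CC(=O)O", "CCCO"), "CCC(=O)O"),
    rule_id = NA_character_, ec = list(character(0))
  )
  comp <- dplyr::bind_rows(compounds, tibble::tibble(
    compound_id = "c6", smiles = "CCC(=O)O",
    display_smiles = NA_character_, name = NA_character_))
  pkg <- bt_package("cascade", compounds = comp, rules = rules,
                    reactions = reactions)
  fixture_env$cascade_scorer <- suppressMessages(
    train_scorer(pkg, rules, mode = "baseline"))
  fixture_env$cascade_scorer
}

test_that("a root triggering no rules yields a single-node pathway", {
  sc <- cascade_scorer()
  pw <- predict_pathway(sc, "c1ccc(Br)cc1")
  expect_identical(nrow(pw$nodes), 1L)
  expect_identical(nrow(pw$edges), 0L)
  expect_identical(pw$nodes$cumulative_score, c(1))
})

test_that("toy linear chemistry expands into the expected cascade", {
  sc <- cascade_scorer()
  pw <- predict_pathway(sc, "CCOC(C)=O",
                        config = prediction_config(score_threshold = 0.5))
  # ester hydrolysis fires (baseline 1.0): acid + ethanol appear;
  # ethanol oxidizes to acetic acid (already present, gains an edge)
  expect_setequal(pw$nodes$smiles, c("CCOC(C)=O", "CC(=O)O", "CCO"))
  expect_identical(pw$nodes$depth[pw$nodes$smiles == "CC(=O)O"], 1L)
  expect_true(all(pw$edges$score >= 0.5))
  # root cumulative score is 1, others the product of best-path scores
  expect_identical(pw$nodes$cumulative_score[pw$nodes$smiles == "CCOC(C)=O"], 1)
})

test_that("max_nodes = 1 returns only the root regardless of chemistry", {
  sc <- cascade_scorer()
  pw <- predict_pathway(sc, "CCOC(C)=O",
                        config = prediction_config(max_nodes = 1))
  expect_identical(pw$nodes$smiles, canonicalize_smiles("CCOC(C)=O"))
})

test_that("budgets bound node count and depth", {
  sc <- small_scorer()
  roots <- vapply(small_pkg()$pathways[1:3], function(p) p$roots[1], "")
  for (r in roots) {
    pw <- predict_pathway(sc, r, config = prediction_config(
      max_depth = 2, max_nodes = 12, score_threshold = 0.1))
    expect_lte(nrow(pw$nodes), 12L)
    expect_lte(max(pw$nodes$depth), 2L)
  }
})

test_that("prediction is deterministic: byte-identical serializations", {
  sc <- small_scorer()
  root <- small_pkg()$pathways[[1]]$roots[1]
  cfg <- prediction_config(score_threshold = 0.1)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  for (f in c(f1, f2)) {
    pw <- predict_pathway(sc, root, config = cfg)
    pkg <- bt_package(
      "p", compounds = tibble::tibble(
        compound_id = pw$nodes$smiles, smiles = pw$nodes$smiles,
        display_smiles = pw$nodes$smiles, name = NA_character_),
      pathways = list(pw), validate = FALSE)
    save_package(pkg, f)
  }
  expect_identical(readLines(f1), readLines(f2))
})

test_that("raising the threshold never adds predicted nodes", {
  sc <- small_scorer()
  roots <- vapply(small_pkg()$pathways[1:3], function(p) p$roots[1], "")
  for (r in roots) {
    prev <- NULL
    for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      pw <- predict_pathway(sc, r, config = prediction_config(
        score_threshold = th))
      if (!is.null(prev)) {
        expect_true(all(pw$nodes$smiles %in% prev),
                    label = paste("threshold", th, "root", r))
      }
      prev <- pw$nodes$smiles
    }
  }
})

test_that("predicted pathways are acyclic with threshold-respecting edges", {
  sc <- small_scorer()
  root <- small_pkg()$pathways[[2]]$roots[1]
  pw <- predict_pathway(sc, root, config = prediction_config(
    score_threshold = 0.2))
  expect_s3_class(pw, "predicted_pathway")
  expect_true(all(pw$edges$score >= 0.2))
  g <- igraph::graph_from_data_frame(pw$edges[, c("substrate", "product")])
  expect_true(igraph::is_dag(g))
  # cumulative scores multiply along best paths: all in (0, 1]
  expect_true(all(pw$nodes$cumulative_score > 0 &
                    pw$nodes$cumulative_score <= 1))
})
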