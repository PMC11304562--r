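test_that("skipped-intermediate case: B is ignorable and C keeps depth 1", {
  observed <- apw("A>C")
  predicted <- apw(c("A>B", "B>C"))
  m <- match_pathways(predicted, observed)
  expect_identical(m$category[m$smiles == "B"], "intermediate")
  expect_identical(m$category[m$smiles == "C"], "matched")
  expect_identical(m$d_obs[m$smiles == "C"], 1L)
  r <- multi_generation_score(m, eval_params(adjust_intermediates = TRUE))
  expect_identical(r$weighted_tp, 1)
  expect_identical(r$weighted_fp, 0)
  expect_identical(r$weighted_fn, 0)
  expect_identical(r$precision, 1)
  expect_identical(r$recall, 1)
})

test_that("without the adjustment the same prediction is penalized", {
  observed <- apw("A>C")
  predicted <- apw(c("A>B", "B>C"))
  m <- match_pathways(predicted, observed)
  r <- multi_generation_score(m, eval_params(adjust_intermediates = FALSE))
  # B: false positive at depth 1 (weight 1); C credited at predicted depth 2
  expect_identical(r$precision, 0.5 / (0.5 + 1))
  expect_identical(r$recall, 0.5)
})

test_that("identical pathways score perfectly; conventions for empty cases", {
  pw <- apw(c("A>B", "B>C", "A>D"))
  m <- match_pathways(pw, pw)
  expect_true(all(m$category == "matched"))
  for (adj in c(TRUE, FALSE)) {
    r <- multi_generation_score(m, eval_params(adjust_intermediates = adj))
    expect_identical(r$precision, 1)
    expect_identical(r$recall, 1)
  }
  # empty prediction vs observed A->C: precision 1 by 0/0, recall 0
  m2 <- match_pathways(apw(character(0)), apw("A>C"))
  r2 <- multi_generation_score(m2)
  expect_identical(r2$precision, 1)
  expect_identical(r2$recall, 0)
  # root mismatch errors
  expect_error(match_pathways(apw("A>B"), apw("X>Y", roots = "X")),
               "root mismatch")
})

test_that("dead-end predicted-only nodes stay false positives", {
  observed <- apw("A>C")
  predicted <- apw(c("A>B"))
  m <- match_pathways(predicted, observed)
  expect_identical(m$category[m$smiles == "B"], "false_positive")
  expect_identical(m$category[m$smiles == "C"], "false_negative")
})

test_that("categorization equals the brute-force oracle on exhaustive small DAG pairs", {
  dags <- enum_rooted_dags(c("A", "B", "C", "D"))
  expect_gt(length(dags), 20)
  pws <- lapply(dags, apw)
  params_on <- eval_params(adjust_intermediates = TRUE)
  params_off <- eval_params(adjust_intermediates = FALSE)
  n_checked <- 0L
  n_cat_mismatch <- 0L
  n_monotonicity <- 0L
  n_bounds <- 0L
  for (i in seq_along(pws)) {
    for (j in seq_along(pws)) {
      pred <- pws[[i]]
      obs <- pws[[j]]
      m <- match_pathways(pred, obs)
      if (!identical(match_as_list(m), bf_categorize(pred, obs))) {
        n_cat_mismatch <- n_cat_mismatch + 1L
      }
      r_on <- multi_generation_score(m, params_on)
      r_off <- multi_generation_score(m, params_off)
      if (r_on$precision < r_off$precision - 1e-12 ||
          r_on$recall < r_off$recall - 1e-12) {
        n_monotonicity <- n_monotonicity + 1L
      }
      vals <- c(r_on$precision, r_on$recall, r_off$precision, r_off$recall)
      if (any(vals < 0 | vals > 1)) n_bounds <- n_bounds + 1L
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 1000)
  expect_identical(n_cat_mismatch, 0L)
  expect_identical(n_monotonicity, 0L)
  expect_identical(n_bounds, 0L)
})

test_that("adjustment monotonicity and oracle equivalence on random larger pairs", {
  set.seed(7)
  params_on <- eval_params(adjust_intermediates = TRUE)
  params_off <- eval_params(adjust_intermediates = FALSE)
  n_bad <- 0L
  for (rep in 1:300) {
    pred <- apw(random_dag_edges(sample(2:7, 1)))
    obs <- apw(random_dag_edges(sample(2:7, 1)))
    m <- match_pathways(pred, obs)
    r_on <- multi_generation_score(m, params_on)
    r_off <- multi_generation_score(m, params_off)
    if (!identical(match_as_list(m), bf_categorize(pred, obs)) ||
        r_on$precision < r_off$precision - 1e-12 ||
        r_on$recall < r_off$recall - 1e-12) {
      n_bad <- n_bad + 1L
    }
  }
  expect_identical(n_bad, 0L)
})

test_that("multi-generation score is model-agnostic (graphs only)", {
  observed <- apw(c("A>B", "B>C"))
  e1 <- tibble::tibble(substrate = c("A", "B"), product = c("B", "C"),
                       rule_id = c("rule_x", "rule_y"), score = c(0.9, 0.1))
  e2 <- tibble::tibble(substrate = c("A", "B"), product = c("B", "C"),
                       rule_id = c("other_vocabulary_1", "other_vocabulary_2"),
                       score = c(0.2, 0.8))
  p1 <- pathway(e1, roots = "A")
  p2 <- pathway(e2, roots = "A")
  r1 <- multi_generation_score(match_pathways(p1, observed))
  r2 <- multi_generation_score(match_pathways(p2, observed))
  expect_identical(r1, r2)
})

test_that("single-generation evaluation counts rule hits per substrate", {
  pkg <- small_pkg()
  sc <- small_scorer()
  # threshold above every score: no predictions, recall 0, precision 1
  r_hi <- single_generation_score(sc, pkg$reactions, threshold = 1.01)
  expect_identical(r_hi$precision, 1)
  expect_identical(r_hi$recall, 0)
  # threshold 0 predicts every triggered rule: recall is 1 because every
  # observed label is by construction a triggered rule
  r_lo <- single_generation_score(sc, pkg$reactions, threshold = 0)
  expect_identical(r_lo$recall, 1)
  expect_lte(r_lo$precision, 1)
  expect_gte(r_lo$precision, 0)
})

test_that("holdout experiment is deterministic and warns on full overlap", {
  pkg <- small_pkg()
  params <- eval_params(score_thresholds = c(0.2, 0.6))
  c1 <- suppressMessages(holdout_experiment(pkg, n_repeats = 2, seed = 9,
                                            params = params))
  c2 <- suppressMessages(holdout_experiment(pkg, n_repeats = 2, seed = 9,
                                            params = params))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(nrow(c1), 4L)  # 2 modes x 2 thresholds
  expect_true(all(c1$mean_precision >= 0 & c1$mean_precision <= 1))
  expect_true(all(c1$mean_recall >= 0 & c1$mean_recall <= 1))
  expect_warning(
    suppressMessages(holdout_experiment(pkg, n_repeats = 1, seed = 1,
                                        test_fraction = 1,
                                        params = params)),
    "training on the same data"
  )
  expect_error(holdout_experiment(bt_package("x"), toy_rules()),
               "at least 2 pathways")
})

test_that("autoplot on holdout curves returns a ggplot", {
  pkg <- small_pkg()
  c1 <- suppressMessages(holdout_experiment(
    pkg, n_repeats = 2, seed = 9,
    params = eval_params(score_thresholds = c(0.2, 0.6))))
  expect_s3_class(autoplot(c1), "ggplot")
})
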