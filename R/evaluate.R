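# Multi-generation and single-generation evaluation of predicted pathways
# against observed pathways, with depth-weighted scoring and
# intermediate-metabolite adjustment.
#
# Observed environmental pathways frequently omit short-lived, transient
# intermediates, so a several-step process may be reported as one
# multi-step reaction.  The multi-generation score therefore (a) weights
# a node at generation d by base^(d-1), reflecting the decreasing
# detectability of higher-generation transformation products, and (b)
# treats predicted-only compounds lying on a path to an observed
# compound as ignorable intermediates rather than false positives.

#' Evaluation parameters
#'
#' @param depth_weight_base Geometric depth weight base in `(0, 1]`: a
#'   node at effective depth d carries weight `base^(d-1)`; roots are
#'   excluded from scoring.
#' @param adjust_intermediates Ignore predicted-only intermediates and
#'   score matched compounds at their observed depth (default `TRUE`).
#' @param score_thresholds Ascending thresholds for curve sweeps.
#' @return A list of class `eval_params`.
#' @export
eval_params <- function(depth_weight_base = 0.5, adjust_intermediates = TRUE,
                        score_thresholds = seq(0, 0.9, by = 0.1)) {
  stopifnot(depth_weight_base > 0, depth_weight_base <= 1,
            !is.unsorted(score_thresholds))
  structure(list(depth_weight_base = depth_weight_base,
                 adjust_intermediates = adjust_intermediates,
                 score_thresholds = score_thresholds),
            class = "eval_params")
}

#' Match a predicted pathway against an observed pathway
#'
#' Nodes are matched by structure key.  Every predicted non-root node
#' falls into exactly one of three categories: `matched` (present in the
#' observed pathway), `intermediate` (predicted-only, but with at least
#' one matched proper descendant in the predicted DAG -- the situation
#' created when an observed pathway skips a short-lived metabolite), or
#' `false_positive` (predicted-only on a dead-end branch).  Observed
#' non-root nodes absent from the prediction are `false_negative`.
#'
#' @param predicted,observed Two [pathway()] objects rooted at the same
#'   structure key(s); a root mismatch is an error.
#' @return A `pathway_match`: tibble with columns `smiles`, `category`,
#'   `d_pred`, `d_obs` (NA where undefined).
#' @export
match_pathways <- function(predicted, observed) {
  stopifnot(inherits(predicted, "pathway"), inherits(observed, "pathway"))
  if (!setequal(predicted$roots, observed$roots)) {
    rlang::abort(paste0("root mismatch: predicted rooted at {",
                        paste(predicted$roots, collapse = ", "),
                        "}, observed at {",
                        paste(observed$roots, collapse = ", "), "}"))
  }
  roots <- predicted$roots
  dp <- stats::setNames(predicted$nodes$depth, predicted$nodes$smiles)
  do <- stats::setNames(observed$nodes$depth, observed$nodes$smiles)
  pred_nodes <- setdiff(names(dp), roots)
  obs_nodes <- setdiff(names(do), roots)

  matched <- intersect(pred_nodes, obs_nodes)
  pred_only <- setdiff(pred_nodes, obs_nodes)
  fn <- setdiff(obs_nodes, pred_nodes)

  g <- pathway_igraph(predicted)
  is_intermediate <- vapply(pred_only, function(v) {
    desc <- setdiff(names(igraph::subcomponent(g, v, mode = "out")), v)
    any(desc %in% matched)
  }, logical(1))

  tab <- tibble::tibble(
    smiles = c(matched, pred_only, fn),
    category = c(rep("matched", length(matched)),
                 unname(ifelse(is_intermediate, "intermediate",
                               "false_positive")),
                 rep("false_negative", length(fn))),
    d_pred = unname(dp[c(matched, pred_only, fn)]),
    d_obs = unname(do[c(matched, pred_only, fn)])
  )
  tab <- tab[order(tab$category, tab$smiles), ]
  structure(tab, class = c("pathway_match", class(tab)), roots = roots)
}

#' Depth-weighted multi-generation score
#'
#' Scores a [match_pathways()] result with geometric depth weights
#' `base^(d-1)` (roots excluded).  With the intermediate adjustment on,
#' matched compounds are scored at their observed depth, so unobserved
#' intermediates do not deepen a match, and intermediates contribute
#' nothing to any tally.  With the adjustment off, intermediates count as
#' false positives at their predicted depth and matched compounds are
#' credited at their predicted depth (never above their observed weight).
#' Precision is `wTP / (wTP + wFP)` and recall `wTP / (wTP + wFN)`, both
#' defined as 1 when the denominator is 0.
#'
#' @param match A `pathway_match`.
#' @param params An [eval_params()].
#' @return A one-row tibble of class `pathway_eval`: `mode`,
#'   `weighted_tp`, `weighted_fp`, `weighted_fn`, `precision`, `recall`,
#'   plus node-category counts.
#' @export
multi_generation_score <- function(match, params = eval_params()) {
  stopifnot(inherits(match, "pathway_match"), inherits(params, "eval_params"))
  base <- params$depth_weight_base
  w <- function(d) base^(d - 1)
  m <- match[match$category == "matched", ]
  fp <- match[match$category == "false_positive", ]
  im <- match[match$category == "intermediate", ]
  fn <- match[match$category == "false_negative", ]

  if (params$adjust_intermediates) {
    wtp <- sum(w(m$d_obs))
    wfp <- sum(w(fp$d_pred))
    wfn <- sum(w(fn$d_obs))
  } else {
    credit <- pmin(w(m$d_pred), w(m$d_obs))
    wtp <- sum(credit)
    wfp <- sum(w(fp$d_pred)) + sum(w(im$d_pred))
    wfn <- sum(w(fn$d_obs)) + sum(w(m$d_obs) - credit)
  }
  ratio01 <- function(num, den) if (den == 0) 1 else num / den
  tibble::new_tibble(
    tibble::tibble(
      mode = "multi_generation",
      weighted_tp = wtp, weighted_fp = wfp, weighted_fn = wfn,
      precision = ratio01(wtp, wtp + wfp),
      recall = ratio01(wtp, wtp + wfn),
      n_matched = nrow(m), n_intermediate = nrow(im),
      n_false_positive = nrow(fp), n_false_negative = nrow(fn)
    ),
    class = "pathway_eval"
  )
}

#' Single-generation (per-reaction) evaluation
#'
#' For each test substrate, the predicted positives are the triggered
#' rules whose score reaches the threshold; a predicted rule is a true
#' positive when applying it reproduces the (substrate, product multiset)
#' of an observed reaction.  Counts are unweighted and aggregated over
#' substrates.
#'
#' @param scorer A [train_scorer()] model.
#' @param reactions A reactions tibble (single-substrate reactions; see
#'   [bt_package()]).
#' @param threshold Score threshold for a positive prediction.
#' @param rules Rules tibble (default: the scorer's).
#' @return A one-row `pathway_eval` tibble with `mode =
#'   "single_generation"` and unweighted tallies.
#' @export
single_generation_score <- function(scorer, reactions, threshold = 0.2,
                                    rules = scorer$rules) {
  stopifnot(inherits(scorer, "rule_scorer"))
  single <- vapply(reactions$substrates, length, integer(1)) == 1L
  rx <- reactions[single, , drop = FALSE]
  substrates <- sort(unique(unlist(rx$substrates, use.names = FALSE)))
  app <- chem_apply(rules$smirks, substrates)
  obs_sets <- split(
    vapply(rx$products, function(p) paste(sort(p), collapse = "."),
           character(1)),
    unlist(rx$substrates, use.names = FALSE)
  )
  tp <- fp <- fn <- 0L
  for (smi in substrates) {
    observed <- character(0)
    for (j in seq_len(nrow(rules))) {
      sets <- app[[rules$smirks[j]]][[smi]]
      if (length(sets) == 0) next
      sigs <- vapply(sets, function(s) paste(s, collapse = "."), character(1))
      if (any(sigs %in% obs_sets[[smi]])) observed <- c(observed, rules$rule_id[j])
    }
    scores <- score_transformations(scorer, smi)
    predicted <- scores$rule_id[scores$score >= threshold]
    tp <- tp + length(intersect(predicted, observed))
    fp <- fp + length(setdiff(predicted, observed))
    fn <- fn + length(setdiff(observed, predicted))
  }
  ratio01 <- function(num, den) if (den == 0) 1 else num / den
  tibble::new_tibble(
    tibble::tibble(
      mode = "single_generation",
      weighted_tp = as.numeric(tp), weighted_fp = as.numeric(fp),
      weighted_fn = as.numeric(fn),
      precision = ratio01(tp, tp + fp),
      recall = ratio01(tp, tp + fn),
      n_matched = tp, n_intermediate = 0L,
      n_false_positive = fp, n_false_negative = fn
    ),
    class = "pathway_eval"
  )
}

pool_evals <- function(evals, mode) {
  wtp <- sum(vapply(evals, `[[`, numeric(1), "weighted_tp"))
  wfp <- sum(vapply(evals, `[[`, numeric(1), "weighted_fp"))
  wfn <- sum(vapply(evals, `[[`, numeric(1), "weighted_fn"))
  ratio01 <- function(num, den) if (den == 0) 1 else num / den
  tibble::tibble(mode = mode,
                 precision = ratio01(wtp, wtp + wfp),
                 recall = ratio01(wtp, wtp + wfn))
}

#' Repeated-holdout evaluation experiment
#'
#' Repeatedly splits the package's pathways into train and test sets,
#' trains a scorer on the training reactions, predicts each test pathway
#' from its root, and computes single- and multi-generation
#' precision/recall over a threshold sweep.  Tallies are pooled over the
#' test pathways of a repeat; means and standard deviations are taken
#' over repeats.  The experiment is deterministic given `seed`.
#'
#' @param pkg A [bt_package()] with at least two pathways.
#' @param rules Rules tibble.
#' @param params An [eval_params()] (depth weights and threshold sweep).
#' @param n_repeats Number of random splits.
#' @param test_fraction Fraction of pathways held out per repeat.
#' @param seed Integer RNG seed.
#' @param mode,k Scorer mode and neighbourhood size (see
#'   [train_scorer()]).
#' @param config_fn Function mapping a threshold to a
#'   [prediction_config()]; defaults to the standard budgets with
#'   `score_threshold` set to the threshold.
#' @return A tibble of class `holdout_curves`: `mode`, `threshold`,
#'   `mean_precision`, `sd_precision`, `mean_recall`, `sd_recall`.
#' @export
holdout_experiment <- function(pkg, rules = pkg$rules,
                               params = eval_params(),
                               n_repeats = 20L, test_fraction = 0.25,
                               seed = 1L, mode = "knn", k = 5L,
                               config_fn = function(th)
                                 prediction_config(score_threshold = th)) {
  stopifnot(inherits(pkg, "bt_package"))
  n_pw <- length(pkg$pathways)
  if (n_pw < 2) rlang::abort("holdout experiment needs at least 2 pathways")
  n_test <- max(1L, round(test_fraction * n_pw))
  if (n_test >= n_pw) {
    rlang::warn("test fraction covers all pathways; training on the same data")
    n_test <- n_pw
  }
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    test_idx <- withr::with_seed(seed + rep_i - 1L,
                                 sort(sample.int(n_pw, n_test)))
    train_idx <- if (n_test == n_pw) test_idx else setdiff(seq_len(n_pw), test_idx)
    train_pkg <- subset_package(pkg, train_idx)
    test_pws <- pkg$pathways[test_idx]
    test_rx_ids <- unique(unlist(lapply(test_pws, function(p)
      p$edges$reaction_id)))
    test_rx <- pkg$reactions[pkg$reactions$reaction_id %in% test_rx_ids, ]
    scorer <- train_scorer(train_pkg, rules, mode = mode, k = k)
    for (th in params$score_thresholds) {
      sg <- single_generation_score(scorer, test_rx, threshold = th, rules = rules)
      mg <- lapply(test_pws, function(obs) {
        pred <- predict_pathway(scorer, obs$roots[1], config = config_fn(th),
                                rules = rules)
        multi_generation_score(match_pathways(pred, obs), params)
      })
      mg <- pool_evals(mg, "multi_generation")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repeat_id = rep_i, threshold = th,
        mode = c("single_generation", "multi_generation"),
        precision = c(sg$precision, mg$precision),
        recall = c(sg$recall, mg$recall)
      )
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  out <- per_rep |>
    dplyr::group_by(.data$mode, .data$threshold) |>
    dplyr::summarise(
      mean_precision = mean(.data$precision),
      sd_precision = stats::sd(.data$precision),
      mean_recall = mean(.data$recall),
      sd_recall = stats::sd(.data$recall),
      .groups = "drop"
    )
  structure(out, class = c("holdout_curves", class(out)),
            per_repeat = per_rep)
}

# package restricted to the given pathway indices (reactions and
# scenarios filtered accordingly; compounds kept in full).
subset_package <- function(pkg, pathway_idx) {
  pws <- pkg$pathways[pathway_idx]
  rx_ids <- unique(unlist(lapply(pws, function(p) p$edges$reaction_id)))
  bt_package(
    paste0(pkg$id, ":subset"), pkg$name,
    compounds = pkg$compounds,
    rules = pkg$rules,
    reactions = pkg$reactions[pkg$reactions$reaction_id %in% rx_ids, ],
    pathways = pws,
    scenarios = pkg$scenarios,
    validate = FALSE
  )
}

#' @describeIn holdout_experiment Precision-recall curves, one panel per
#'   evaluation mode.
#' @param object A `holdout_curves` tibble.
#' @param ... Unused.
#' @method autoplot holdout_curves
#' @export
autoplot.holdout_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_recall,
                                       y = .data$mean_precision,
                                       colour = .data$mode)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "Evaluation",
                  title = "Precision-recall over score thresholds") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
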