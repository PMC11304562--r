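# Applicability domain: two compound-level assessments (applicability
# score, functional-group coverage) and two transformation-level
# assessments (reliability, local goodness of fit), packaged as an
# annotation layer over predicted pathways.

#' Applicability-domain parameters
#'
#' @param n_neighbors Number of most-similar rule-compatible training
#'   compounds used by the reliability score and local goodness of fit.
#' @param k_structural Number of nearest training compounds for the
#'   compound applicability score.
#' @param fg_min_support Minimum number of training compounds containing
#'   a functional group for it to count as covered.
#' @param compound_threshold,edge_threshold Decision thresholds in
#'   `[0, 1]` for the in-domain flag and the edge flag.
#' @return A list of class `ad_params`.
#' @export
ad_params <- function(n_neighbors = 5L, k_structural = 5L,
                      fg_min_support = 3L, compound_threshold = 0.5,
                      edge_threshold = 0.5) {
  stopifnot(n_neighbors >= 1, k_structural >= 1, fg_min_support >= 1,
            compound_threshold >= 0, compound_threshold <= 1,
            edge_threshold >= 0, edge_threshold <= 1)
  structure(list(n_neighbors = as.integer(n_neighbors),
                 k_structural = as.integer(k_structural),
                 fg_min_support = as.integer(fg_min_support),
                 compound_threshold = compound_threshold,
                 edge_threshold = edge_threshold),
            class = "ad_params")
}

# similarity of a query to every training compound, minus exclusions;
# returns tibble(smiles, sim, idx) sorted for deterministic neighbour
# selection (descending similarity, ties by canonical SMILES).
training_similarities <- function(scorer, smi, exclude = NULL) {
  lbl <- scorer$labels
  keep <- !(lbl$smiles %in% exclude)
  sims <- tanimoto_many(chem_fingerprints(smi)[[1]], scorer$fps[keep])
  out <- tibble::tibble(smiles = lbl$smiles[keep], sim = sims,
                        idx = which(keep))
  out[order(-out$sim, out$smiles), ]
}

#' Compound-level applicability score
#'
#' `score = (S_fp + S_rule) / 2`, where `S_fp` is the mean Tanimoto
#' similarity of the `k_structural` nearest training compounds and
#' `S_rule` is the Jaccard similarity between the query's triggered rule
#' set and the union of the triggered rule sets of those neighbours
#' (defined as 1 when both sets are empty).  The compound is in the
#' domain when the score reaches `compound_threshold`.
#'
#' @param scorer A [train_scorer()] model (the training index).
#' @param smiles A single compound SMILES.
#' @param params An [ad_params()].
#' @param exclude Training compounds to drop (leave-one-out).
#' @return A one-row tibble: `smiles`, `s_fp`, `s_rule`,
#'   `compound_score`, `in_domain`.
#' @export
compound_applicability <- function(scorer, smiles, params = ad_params(),
                                   exclude = NULL) {
  stopifnot(inherits(scorer, "rule_scorer"), length(smiles) == 1L)
  smi <- canonicalize_smiles(smiles)
  nb <- training_similarities(scorer, smi, exclude)
  if (nrow(nb) == 0) rlang::abort("empty training index")
  nb <- nb[seq_len(min(params$k_structural, nrow(nb))), ]
  s_fp <- mean(nb$sim)
  t_q <- triggered_rules(scorer$rules, smi)$rule_id
  t_n <- unique(unlist(scorer$labels$triggered[nb$idx], use.names = FALSE))
  uni <- union(t_q, t_n)
  s_rule <- if (length(uni) == 0) 1 else length(intersect(t_q, t_n)) / length(uni)
  score <- (s_fp + s_rule) / 2
  tibble::tibble(smiles = smi, s_fp = s_fp, s_rule = s_rule,
                 compound_score = score,
                 in_domain = score >= params$compound_threshold)
}

# lazily computed presence of each functional group in each training
# compound, cached on the scorer.
training_fg_support <- function(scorer) {
  cached <- scorer$cache[["__fg_support__"]]
  if (!is.null(cached)) return(cached)
  hits <- find_functional_groups(scorer$labels$smiles)
  support <- hits |>
    dplyr::distinct(.data$smiles, .data$group_id) |>
    dplyr::count(.data$group_id, name = "support")
  out <- stats::setNames(support$support, support$group_id)
  scorer$cache[["__fg_support__"]] <- out
  out
}

#' Functional-group coverage of a compound
#'
#' For each hetero-atom functional group present in the query, reports
#' how many training compounds contain it (`support`) and whether that
#' support reaches `fg_min_support` (`covered`).  A query with no
#' hetero-atom groups yields no rows.
#'
#' @inheritParams compound_applicability
#' @return A tibble: `group_id`, `support`, `covered`.
#' @export
functional_group_coverage <- function(scorer, smiles, params = ad_params()) {
  stopifnot(inherits(scorer, "rule_scorer"), length(smiles) == 1L)
  smi <- canonicalize_smiles(smiles)
  present <- unique(find_functional_groups(smi)$group_id)
  support_map <- training_fg_support(scorer)
  support <- vapply(present, function(g)
    if (g %in% names(support_map)) support_map[[g]] else 0L, integer(1))
  tibble::tibble(group_id = present, support = unname(support),
                 covered = unname(support) >= params$fg_min_support)
}

# shared candidate set for the two transformation-level assessments:
# training compounds on which the rule structurally triggers, query
# excluded (leave-one-out), sorted by similarity.
rule_candidates <- function(scorer, smi, rule_id) {
  nb <- training_similarities(scorer, smi, exclude = smi)
  trig <- purrr::map_lgl(scorer$labels$triggered[nb$idx], ~ rule_id %in% .x)
  nb[trig, ]
}

#' Transformation reliability score
#'
#' The mean Tanimoto similarity of the `n` most similar training
#' compounds on which the same rule structurally triggers (the query
#' itself is excluded if present).  With fewer than `n` such compounds
#' the mean runs over the available ones and the result is flagged low
#' support; with none, the score is 0.
#'
#' @inheritParams compound_applicability
#' @param rule_id A rule that triggers on the query (error otherwise).
#' @param n Neighbourhood size (default from [ad_params()]).
#' @return A one-row tibble: `rule_id`, `reliability`, `n_candidates`,
#'   `low_support`.
#' @export
reliability_score <- function(scorer, smiles, rule_id,
                              n = ad_params()$n_neighbors) {
  stopifnot(inherits(scorer, "rule_scorer"), length(smiles) == 1L)
  smi <- canonicalize_smiles(smiles)
  if (!rule_id %in% triggered_rules(scorer$rules, smi)$rule_id) {
    rlang::abort(paste0("rule ", rule_id, " does not trigger on ", smi,
                        "; reliability is undefined"))
  }
  cand <- rule_candidates(scorer, smi, rule_id)
  taken <- cand[seq_len(min(n, nrow(cand))), , drop = FALSE]
  tibble::tibble(
    rule_id = rule_id,
    reliability = if (nrow(taken) == 0) 0 else mean(taken$sim),
    n_candidates = nrow(taken),
    low_support = nrow(taken) < n
  )
}

#' Local goodness of fit
#'
#' For the same `n` rule-compatible neighbours as [reliability_score()],
#' computes the fraction whose leave-one-out prediction is correct: the
#' neighbour's scorer score for the rule (trained without it) is
#' thresholded into a predicted label and compared with its observed
#' label (whether the rule is realized in at least one of its observed
#' reactions).  Undefined (NA, flagged) when the candidate set is empty.
#'
#' @inheritParams reliability_score
#' @param threshold Score threshold defining a positive predicted label.
#' @return A one-row tibble: `rule_id`, `local_fit`, `n_candidates`,
#'   `undefined`.
#' @export
local_goodness_of_fit <- function(scorer, smiles, rule_id,
                                  n = ad_params()$n_neighbors,
                                  threshold = 0.5) {
  stopifnot(inherits(scorer, "rule_scorer"), length(smiles) == 1L)
  smi <- canonicalize_smiles(smiles)
  cand <- rule_candidates(scorer, smi, rule_id)
  taken <- cand[seq_len(min(n, nrow(cand))), , drop = FALSE]
  if (nrow(taken) == 0) {
    return(tibble::tibble(rule_id = rule_id, local_fit = NA_real_,
                          n_candidates = 0L, undefined = TRUE))
  }
  correct <- vapply(seq_len(nrow(taken)), function(i) {
    c_smi <- taken$smiles[i]
    sc <- score_transformations(scorer, c_smi, exclude = c_smi)
    s <- sc$score[sc$rule_id == rule_id]
    pred_lab <- length(s) > 0 && s[1] >= threshold
    obs_lab <- rule_id %in% scorer$labels$observed[[taken$idx[i]]]
    pred_lab == obs_lab
  }, logical(1))
  tibble::tibble(rule_id = rule_id, local_fit = mean(correct),
                 n_candidates = nrow(taken), undefined = FALSE)
}

#' Annotate a predicted pathway with applicability-domain assessments
#'
#' Every node receives the compound applicability score and
#' functional-group coverage; every edge receives the reliability score
#' and local goodness of fit of its rule on its substrate, and an
#' `edge_ok` flag that requires the reliability and (when defined) the
#' local fit to reach `edge_threshold`.  The pathway must have been
#' predicted with the scorer's rule vocabulary.
#'
#' @param pw A [pathway()], typically a `predicted_pathway`.
#' @param scorer A [train_scorer()] model.
#' @param params An [ad_params()].
#' @return An object of class `ad_assessment` with tibbles `nodes`
#'   (`smiles`, `s_fp`, `s_rule`, `compound_score`, `in_domain`,
#'   `fg_coverage` list column) and `edges` (`substrate`, `product`,
#'   `rule_id`, `reliability`, `local_fit`, `edge_ok`).
#' @export
annotate_pathway <- function(pw, scorer, params = ad_params()) {
  stopifnot(inherits(pw, "pathway"), inherits(scorer, "rule_scorer"))
  edge_rules <- unique(pw$edges$rule_id)
  edge_rules <- edge_rules[!is.na(edge_rules)]
  unknown <- setdiff(edge_rules, scorer$rules$rule_id)
  if (length(unknown)) {
    rlang::abort(paste0("pathway uses rule(s) outside the scorer vocabulary: ",
                        paste(unknown, collapse = ", ")))
  }
  nodes <- purrr::map_dfr(pw$nodes$smiles, function(smi) {
    ca <- compound_applicability(scorer, smi, params)
    ca$fg_coverage <- list(functional_group_coverage(scorer, smi, params))
    ca
  })
  edges <- purrr::map_dfr(seq_len(nrow(pw$edges)), function(i) {
    e <- pw$edges[i, ]
    if (is.na(e$rule_id)) {
      return(tibble::tibble(
        substrate = e$substrate, product = e$product, rule_id = NA_character_,
        reliability = NA_real_, low_support = NA, local_fit = NA_real_,
        edge_ok = NA
      ))
    }
    rel <- reliability_score(scorer, e$substrate, e$rule_id,
                             n = params$n_neighbors)
    lof <- local_goodness_of_fit(scorer, e$substrate, e$rule_id,
                                 n = params$n_neighbors,
                                 threshold = params$edge_threshold)
    tibble::tibble(
      substrate = e$substrate, product = e$product, rule_id = e$rule_id,
      reliability = rel$reliability, low_support = rel$low_support,
      local_fit = lof$local_fit,
      edge_ok = rel$reliability >= params$edge_threshold &&
        (is.na(lof$local_fit) || lof$local_fit >= params$edge_threshold)
    )
  })
  if (nrow(pw$edges) == 0) {
    edges <- tibble::tibble(substrate = character(), product = character(),
                            rule_id = character(), reliability = numeric(),
                            low_support = logical(), local_fit = numeric(),
                            edge_ok = logical())
  }
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "ad_assessment")
}

#' @export
print.ad_assessment <- function(x, ...) {
  cat("<ad_assessment> ", nrow(x$nodes), " compounds (",
      sum(x$nodes$in_domain), " in domain), ", nrow(x$edges), " edges (",
      sum(x$edges$edge_ok), " passing)\n", sep = "")
  invisible(x)
}
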