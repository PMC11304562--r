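# Best-first pathway prediction: iteratively apply scored transformation
# rules to the query compound, expanding the highest-cumulative-score
# compound first, under depth and node-budget limits.
#
# The expansion itself is run without a score threshold: it admits nodes
# in best-first order (cumulative score, ties by lexicographic canonical
# SMILES) up to the budgets, yielding a threshold-independent candidate
# universe.  A predicted pathway at threshold t is the root-reachable
# subgraph of universe edges scoring >= t.  This makes the engine's
# invariants hold by construction: raising the threshold can only shrink
# the node set, and the budgets bound every output.

#' Prediction configuration
#'
#' @param max_depth Maximum generation depth to expand to (>= 1).
#' @param max_nodes Node budget for the predicted pathway (>= 1).
#' @param score_threshold Minimum edge score for a transformation to be
#'   followed, in `[0, 1]`.
#' @return A list of class `prediction_config`.
#' @export
prediction_config <- function(max_depth = 4L, max_nodes = 50L,
                              score_threshold = 0.2) {
  stopifnot(max_depth >= 1, max_nodes >= 1,
            score_threshold >= 0, score_threshold <= 1)
  structure(list(max_depth = as.integer(max_depth),
                 max_nodes = as.integer(max_nodes),
                 score_threshold = score_threshold),
            class = "prediction_config")
}

# does `to` reach `from`? (an edge from->to would close a cycle)
# adj: named list node -> character vector of successors.
reaches <- function(adj, to, from) {
  stack <- to
  seen <- character(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == from) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, adj[[v]])
  }
  FALSE
}

# Threshold-free best-first expansion; memoised on the scorer so that
# threshold sweeps over the same root pay for one expansion.
expand_universe <- function(scorer, root, max_depth, max_nodes, rules) {
  key <- paste("universe", root, max_depth, max_nodes, sep = "\r")
  hit <- scorer$cache[[key]]
  if (!is.null(hit)) return(hit)

  depth <- stats::setNames(0L, root)
  adj <- stats::setNames(list(character(0)), root)
  queue_smiles <- root
  queue_cum <- 1
  expanded <- character(0)
  edges <- list()
  n_reactions <- 0L

  while (length(queue_smiles)) {
    ord <- order(-queue_cum, queue_smiles)
    cur <- queue_smiles[ord[1]]
    cur_cum <- queue_cum[ord[1]]
    queue_smiles <- queue_smiles[-ord[1]]
    queue_cum <- queue_cum[-ord[1]]
    if (cur %in% expanded) next
    expanded <- c(expanded, cur)
    d <- depth[[cur]]
    if (d >= max_depth) next

    scores <- score_transformations(scorer, cur)
    if (nrow(scores) == 0) next
    keep_rules <- rules[match(scores$rule_id, rules$rule_id), , drop = FALSE]
    app <- chem_apply(keep_rules$smirks, cur)

    for (j in seq_len(nrow(scores))) {
      rid <- scores$rule_id[j]
      sc <- scores$score[j]
      sets <- app[[keep_rules$smirks[j]]][[cur]]
      for (set in sets) {
        set <- sort(set)
        new_edges <- list()
        for (p in set) {
          if (p == cur) next                                  # identity
          if (p %in% names(adj) && reaches(adj, p, cur)) next # ancestor
          is_new <- !(p %in% names(depth))
          if (is_new && length(depth) >= max_nodes) next      # budget
          new_edges[[length(new_edges) + 1L]] <- list(p = p, new = is_new)
        }
        # drop duplicate (substrate, product, rule) arcs (symmetric sites)
        dup <- vapply(new_edges, function(ne) any(vapply(edges, function(e)
          e$substrate == cur && e$product == ne$p && e$rule_id == rid,
          logical(1))), logical(1))
        new_edges <- new_edges[!dup]
        if (length(new_edges) == 0) next
        n_reactions <- n_reactions + 1L
        rxid <- sprintf("p%03d", n_reactions)
        for (ne in new_edges) {
          p <- ne$p
          edges[[length(edges) + 1L]] <- list(
            reaction_id = rxid, substrate = cur, product = p,
            rule_id = rid, score = sc
          )
          if (ne$new && !(p %in% names(depth))) {
            depth[p] <- d + 1L
            adj[[p]] <- character(0)
            queue_smiles <- c(queue_smiles, p)
            queue_cum <- c(queue_cum, cur_cum * sc)
          }
          adj[[cur]] <- union(adj[[cur]], p)
        }
      }
    }
  }

  edge_tbl <- if (length(edges)) {
    purrr::map_dfr(edges, tibble::as_tibble)
  } else {
    tibble::tibble(reaction_id = character(), substrate = character(),
                   product = character(), rule_id = character(),
                   score = numeric())
  }
  scorer$cache[[key]] <- edge_tbl
  edge_tbl
}

#' Predict a biotransformation pathway
#'
#' Starting from the root compound, maintains a priority queue of
#' (compound, cumulative score) seeded with (root, 1), repeatedly expands
#' the highest-scoring unexpanded compound by applying every rule.
#' Re-encountered compounds gain a new in-edge but are not re-expanded at
#' greater depth; a product equal to an ancestor creates no edge
#' (acyclicity); expansion stops at the depth and node budgets.  The
#' returned pathway keeps exactly the transformations whose edge score
#' reaches `score_threshold` (and the compounds still reachable through
#' them), so raising the threshold never adds nodes.  The procedure is
#' deterministic: ties are broken by higher score, then lexicographic
#' canonical SMILES.
#'
#' @param scorer A [train_scorer()] model.
#' @param root Root compound SMILES.
#' @param config A [prediction_config()].
#' @param rules Rules tibble (default: the scorer's).
#' @return A `predicted_pathway` (subclass of [pathway()]): edges carry
#'   `score` and `rule_id`; nodes carry `cumulative_score`, the product
#'   of edge scores along the best path from the root (1 for the root).
#' @export
predict_pathway <- function(scorer, root, config = prediction_config(),
                            rules = scorer$rules) {
  stopifnot(inherits(scorer, "rule_scorer"),
            inherits(config, "prediction_config"))
  root <- canonicalize_smiles(root)
  universe <- expand_universe(scorer, root, config$max_depth,
                              config$max_nodes, rules)
  edges <- universe[universe$score >= config$score_threshold, , drop = FALSE]
  # keep the subgraph reachable from the root
  reach <- root
  repeat {
    nxt <- setdiff(edges$product[edges$substrate %in% reach], reach)
    if (length(nxt) == 0) break
    reach <- c(reach, nxt)
  }
  edges <- edges[edges$substrate %in% reach & edges$product %in% reach, ,
                 drop = FALSE]
  pw <- pathway(edges, roots = root, id = paste0("predicted:", root))
  # pruning can lengthen shortest paths: nodes pushed past the depth
  # budget are dropped (any node within budget keeps a within-budget path)
  if (max(pw$nodes$depth) > config$max_depth) {
    keep <- pw$nodes$smiles[pw$nodes$depth <= config$max_depth]
    edges <- edges[edges$substrate %in% keep & edges$product %in% keep, ,
                   drop = FALSE]
    pw <- pathway(edges, roots = root, id = paste0("predicted:", root))
  }
  pw$nodes$cumulative_score <- unname(best_path_scores(pw)[pw$nodes$smiles])
  attr(pw, "config") <- config
  class(pw) <- c("predicted_pathway", class(pw))
  pw
}

# cumulative score per node: max product of edge scores over root paths.
best_path_scores <- function(pw) {
  cum <- stats::setNames(rep(-Inf, nrow(pw$nodes)), pw$nodes$smiles)
  cum[pw$roots] <- 1
  # BFS depth order is not a topological order in general;
  # iterate to a fixed point (cheap: pathway DAGs are small)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(pw$edges))) {
      e <- pw$edges[i, ]
      cand <- cum[[e$substrate]] * e$score
      if (is.finite(cand) && cand > cum[[e$product]]) {
        cum[e$product] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cum
}
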