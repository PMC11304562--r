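# Shared fixtures (memoised: chemistry-backed objects are built once per
# test run) and independent brute-force oracles.

fixture_env <- new.env()

small_cfg <- function() {
  fixture_config(seed = 101, n_compounds = 40, n_pathways = 6)
}

small_pkg <- function() {
  if (is.null(fixture_env$pkg)) {
    fixture_env$pkg <- suppressMessages(
      generate_observed_pathways(small_cfg())
    )
  }
  fixture_env$pkg
}

small_scorer <- function() {
  if (is.null(fixture_env$scorer)) {
    fixture_env$scorer <- suppressMessages(train_scorer(small_pkg()))
  }
  fixture_env$scorer
}

# abstract pathway from "X>Y" edge strings (no chemistry involved)
apw <- function(edges, roots = "A", id = "pw") {
  if (length(edges) == 0) {
    return(pathway(tibble::tibble(substrate = character(),
                                  product = character()),
                   roots = roots, id = id))
  }
  parts <- strsplit(edges, ">", fixed = TRUE)
  pathway(
    tibble::tibble(substrate = vapply(parts, `[[`, "", 1),
                   product = vapply(parts, `[[`, "", 2)),
    roots = roots, id = id
  )
}

# every rooted DAG over `labels` whose edges respect the label order and
# whose nodes are all reachable from the root (the first label); returns
# a list of edge-string vectors (possibly empty for the single-node DAG)
enum_rooted_dags <- function(labels = c("A", "B", "C", "D")) {
  root <- labels[1]
  pairs <- list()
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (j > i) pairs[[length(pairs) + 1L]] <- c(labels[i], labels[j])
    }
  }
  out <- list()
  for (mask in 0:(2^length(pairs) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_along(pairs) - 1)) > 0)
    edges <- pairs[sel]
    nodes <- unique(c(root, unlist(edges)))
    # reachability from root
    reach <- root
    repeat {
      nxt <- unique(unlist(lapply(edges, function(e)
        if (e[1] %in% reach) e[2] else NULL)))
      nxt <- setdiff(nxt, reach)
      if (length(nxt) == 0) break
      reach <- c(reach, nxt)
    }
    if (!setequal(reach, nodes)) next
    out[[length(out) + 1L]] <-
      vapply(edges, function(e) paste0(e[1], ">", e[2]), character(1))
  }
  out
}

# random rooted DAG over a label alphabet: each non-root node gets at
# least one in-edge from an earlier node
random_dag_edges <- function(n_nodes, labels = LETTERS[1:7]) {
  labs <- labels[seq_len(n_nodes)]
  edges <- character(0)
  for (j in seq_along(labs)[-1]) {
    parents <- sample(seq_len(j - 1), sample(seq_len(j - 1), 1))
    edges <- c(edges, paste0(labs[parents], ">", labs[j]))
  }
  # extra random forward edges
  for (k in seq_len(n_nodes)) {
    i <- sample(seq_len(n_nodes), 1)
    j <- sample(seq_len(n_nodes), 1)
    if (i < j && stats::runif(1) < 0.3) {
      edges <- c(edges, paste0(labs[i], ">", labs[j]))
    }
  }
  unique(edges)
}

# ---- brute-force oracles ---------------------------------------------------

# all simple paths from `from` in an edge list (list of c(u, v))
bf_all_paths <- function(edges, from) {
  succ <- function(v) unlist(lapply(edges, function(e)
    if (e[1] == v) e[2] else NULL))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    nxt <- succ(v)
    if (length(nxt) == 0) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in nxt) {
      if (w %in% path) next
      paths[[length(paths) + 1L]] <<- c(path, w)
      walk(c(path, w))
    }
  }
  walk(from)
  paths
}

bf_edge_list <- function(pw) {
  lapply(seq_len(nrow(pw$edges)), function(i)
    c(pw$edges$substrate[i], pw$edges$product[i]))
}

# shortest-path depth by exhaustive path enumeration from every root
bf_depths <- function(pw) {
  nodes <- pw$nodes$smiles
  edges <- bf_edge_list(pw)
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  for (r in pw$roots) {
    d[r] <- 0
    for (p in bf_all_paths(edges, r)) {
      v <- p[length(p)]
      d[v] <- min(d[v], length(p) - 1)
    }
  }
  d
}

# node categorization by explicit path enumeration: a predicted-only node
# is an intermediate iff some simple path from it reaches a matched node
bf_categorize <- function(predicted, observed) {
  roots <- predicted$roots
  pn <- setdiff(predicted$nodes$smiles, roots)
  on <- setdiff(observed$nodes$smiles, roots)
  matched <- intersect(pn, on)
  pred_only <- setdiff(pn, on)
  fn <- setdiff(on, pn)
  edges <- bf_edge_list(predicted)
  cat_pred_only <- vapply(pred_only, function(v) {
    desc <- unique(unlist(bf_all_paths(edges, v)))
    desc <- setdiff(desc, v)
    if (any(desc %in% matched)) "intermediate" else "false_positive"
  }, character(1))
  list(matched = sort(matched),
       intermediate = sort(pred_only[cat_pred_only == "intermediate"]),
       false_positive = sort(pred_only[cat_pred_only == "false_positive"]),
       false_negative = sort(fn))
}

# categories of a pathway_match as a comparable list
match_as_list <- function(m) {
  list(matched = sort(m$smiles[m$category == "matched"]),
       intermediate = sort(m$smiles[m$category == "intermediate"]),
       false_positive = sort(m$smiles[m$category == "false_positive"]),
       false_negative = sort(m$smiles[m$category == "false_negative"]))
}
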