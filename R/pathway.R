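# Pathways: rooted DAGs of compounds connected by (possibly multi-product)
# reactions, with per-node generation depth.

#' Construct a pathway
#'
#' A pathway is a rooted directed acyclic graph whose nodes are compounds
#' (identified by their canonical-SMILES key) and whose edges are
#' substrate-to-product reaction arcs.  Multi-product reactions are
#' represented as several edge rows sharing one `reaction_id`.  Node depth
#' is the length of the shortest edge path from the nearest root, so every
#' compound sits at its earliest observable generation.
#'
#' @param edges A data frame with columns `substrate` and `product`, and
#'   optionally `rule_id`, `score` and `reaction_id`.  May have zero rows
#'   for a single-node pathway.
#' @param roots Character vector (non-empty) of root node keys.
#' @param id Pathway identifier.
#' @param canonicalize If `TRUE`, node keys are passed through
#'   [canonicalize_smiles()].  Off by default so that purely structural
#'   graph work (evaluation, testing) needs no chemistry backend.
#' @return An object of class `pathway` with fields `id`, `roots`,
#'   `nodes` (tibble: `smiles`, `depth`) and `edges`.
#' @export
pathway <- function(edges, roots, id = "pathway", canonicalize = FALSE) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("substrate", "product") %in% names(edges)))
  } else {
    edges <- tibble::tibble(substrate = character(), product = character())
  }
  if (length(roots) == 0) rlang::abort("pathway needs at least one root")
  if (!"rule_id" %in% names(edges)) edges$rule_id <- NA_character_
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  if (!"reaction_id" %in% names(edges)) {
    edges$reaction_id <- if (nrow(edges)) paste0("r", seq_len(nrow(edges))) else
      character(0)
  }
  if (canonicalize) {
    roots <- canonicalize_smiles(roots)
    if (nrow(edges)) {
      edges$substrate <- canonicalize_smiles(edges$substrate)
      edges$product <- canonicalize_smiles(edges$product)
    }
  }
  roots <- unique(roots)
  depths <- compute_depths(edges, roots)
  pw <- structure(
    list(
      id = id,
      roots = roots,
      nodes = tibble::tibble(smiles = names(depths),
                             depth = unname(depths)),
      edges = edges[, c("reaction_id", "substrate", "product",
                        "rule_id", "score")]
    ),
    class = "pathway"
  )
  pw
}

# BFS shortest-path depths from the nearest root; errors on cycles and on
# nodes unreachable from every root.
compute_depths <- function(edges, roots) {
  nodes <- unique(c(roots, edges$substrate, edges$product))
  g <- igraph::graph_from_data_frame(
    edges[, c("substrate", "product")],
    directed = TRUE,
    vertices = data.frame(name = nodes)
  )
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    rlang::abort(paste0("pathway contains a cycle (through edge ",
                        ends[1], " -> ", ends[2], ")"))
  }
  d <- igraph::distances(g, v = roots, to = igraph::V(g), mode = "out")
  depth <- apply(d, 2, min)
  if (any(!is.finite(depth))) {
    rlang::abort(paste0("node(s) unreachable from any root: ",
                        paste(names(depth)[!is.finite(depth)], collapse = ", ")))
  }
  # deterministic ordering: by depth then key
  depth <- depth[order(depth, names(depth))]
  storage.mode(depth) <- "integer"
  depth
}

#' Node generation depths of a pathway
#'
#' @param pw A [pathway()].
#' @return A tibble with columns `smiles` and `depth` (shortest edge-path
#'   distance from the nearest root; roots have depth 0).
#' @export
node_depths <- function(pw) {
  stopifnot(inherits(pw, "pathway"))
  pw$nodes[, c("smiles", "depth")]
}

pathway_igraph <- function(pw) {
  igraph::graph_from_data_frame(
    pw$edges[, c("substrate", "product")],
    directed = TRUE,
    vertices = data.frame(name = pw$nodes$smiles)
  )
}

# Node keys reachable from `from` (excluding itself) in the pathway DAG.
descendants_of <- function(pw, from) {
  g <- pathway_igraph(pw)
  out <- igraph::subcomponent(g, from, mode = "out")
  setdiff(names(out), from)
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> ", x$id, ": ", nrow(x$nodes), " compounds, ",
      nrow(x$edges), " edges, max depth ", max(x$nodes$depth), "\n",
      sep = "")
  cat("root(s): ", paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a pathway as Graphviz DOT text
#'
#' One DOT node per compound and one edge per substrate-product arc.  When
#' an applicability-domain assessment is supplied, node borders are
#' coloured green (in domain) or red (out of domain) and edges green when
#' both the reliability and the local goodness of fit clear the threshold
#' (an undefined local fit passes), red otherwise.
#'
#' @param pw A [pathway()].
#' @param annotations Optional [annotate_pathway()] result.
#' @param path Optional file to write the DOT text to.
#' @return The DOT source as a character scalar (invisibly when `path`
#'   is given).
#' @export
export_dot <- function(pw, annotations = NULL, path = NULL) {
  stopifnot(inherits(pw, "pathway"))
  node_col <- stats::setNames(rep(NA_character_, nrow(pw$nodes)),
                              pw$nodes$smiles)
  edge_col <- NULL
  if (!is.null(annotations)) {
    stopifnot(inherits(annotations, "ad_assessment"))
    node_col[annotations$nodes$smiles] <-
      ifelse(annotations$nodes$in_domain, "green", "red")
    if (nrow(annotations$edges)) {
      edge_col <- annotations$edges
      edge_col$color <- ifelse(edge_col$edge_ok, "green", "red")
    }
  }
  lines <- c("digraph pathway {", "  node [shape=box];")
  for (i in seq_len(nrow(pw$nodes))) {
    smi <- pw$nodes$smiles[i]
    attrs <- paste0("label=", dot_quote(smi))
    if (!is.na(node_col[[smi]])) {
      attrs <- paste0(attrs, ", color=", node_col[[smi]], ", penwidth=2")
    }
    lines <- c(lines, paste0("  ", dot_quote(smi), " [", attrs, "];"))
  }
  for (i in seq_len(nrow(pw$edges))) {
    e <- pw$edges[i, ]
    attrs <- character(0)
    if (!is.na(e$rule_id)) attrs <- c(attrs, paste0("label=", dot_quote(e$rule_id)))
    if (!is.null(edge_col)) {
      m <- edge_col[edge_col$substrate == e$substrate &
                      edge_col$product == e$product, ]
      if (nrow(m)) attrs <- c(attrs, paste0("color=", m$color[1]))
    }
    lines <- c(lines, paste0(
      "  ", dot_quote(e$substrate), " -> ", dot_quote(e$product),
      if (length(attrs)) paste0(" [", paste(attrs, collapse = ", "), "]") else "",
      ";"
    ))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
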