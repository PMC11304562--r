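# Deterministic, seeded generation of every input the other modules
# need: a compound corpus from a scaffold x substituent grid, simulated
# observed pathways with stochastic collapsing of intermediates
# (emulating short-lived metabolites missing from experimental
# pathways), labelled training packages, and EC-annotated reaction
# corpora with planted rule-EC truth.

#' Fixture-generation configuration
#'
#' @param seed Integer RNG seed (mandatory; all generation is
#'   deterministic given the seed).
#' @param n_compounds Size of the compound corpus.
#' @param active_rule_fraction Fraction of rules treated as active in
#'   the simulated biology.
#' @param p_observe_active,p_observe_inactive Probability that an
#'   active/inactive rule application at a triggered site is realized in
#'   the ground-truth pathway.
#' @param max_pathway_depth Generation depth of ground-truth pathways.
#' @param p_collapse Probability that an internal (non-root, non-leaf)
#'   ground-truth node is removed from the observed pathway, splicing its
#'   edges into multi-step reactions.
#' @param n_pathways Number of root compounds developed into pathways.
#' @param max_nodes_per_pathway Node cap per ground-truth pathway.
#' @param p_overlap Probability that a generated EC-corpus reaction is
#'   listed in both sources.
#' @param reactions_per_rule EC-corpus reactions generated per rule.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed, n_compounds = 200L,
                           active_rule_fraction = 0.5,
                           p_observe_active = 0.9,
                           p_observe_inactive = 0.05,
                           max_pathway_depth = 3L, p_collapse = 0.3,
                           n_pathways = 30L, max_nodes_per_pathway = 15L,
                           p_overlap = 1 / 3, reactions_per_rule = 8L) {
  if (missing(seed)) rlang::abort("fixture_config requires an explicit seed")
  probs <- c(active_rule_fraction, p_observe_active, p_observe_inactive,
             p_collapse, p_overlap)
  stopifnot(all(probs >= 0 & probs <= 1), n_compounds >= 1,
            max_pathway_depth >= 1, n_pathways >= 1)
  structure(list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
                 active_rule_fraction = active_rule_fraction,
                 p_observe_active = p_observe_active,
                 p_observe_inactive = p_observe_inactive,
                 max_pathway_depth = as.integer(max_pathway_depth),
                 p_collapse = p_collapse, n_pathways = as.integer(n_pathways),
                 max_nodes_per_pathway = as.integer(max_nodes_per_pathway),
                 p_overlap = p_overlap,
                 reactions_per_rule = as.integer(reactions_per_rule)),
            class = "fixture_config")
}

# substituent fragments written as SMILES branches off a benzene ring;
# chosen so that every toy12 rule triggers on a healthy share of the grid
fixture_fragments <- function() {
  c("C(=O)OC",      # methyl ester            (ester_hydrolysis)
    "COC(C)=O",     # acetoxymethyl           (ester_hydrolysis)
    "C(=O)NC",      # N-methylamide           (amide_hydrolysis, n_dealkylation)
    "NC(C)=O",      # acetamido               (amide_hydrolysis)
    "[N+](=O)[O-]", # nitro                   (nitro_reduction)
    "NC",           # methylamino             (n_dealkylation)
    "OC",           # methoxy                 (o_dealkylation)
    "Cl",           # chloro                  (aromatic_dehalogenation)
    "CO",           # hydroxymethyl           (alcohol_oxidation)
    "C#N",          # nitrile                 (nitrile_hydrolysis)
    "SC",           # methylthio              (sulfoxidation)
    "C(=O)O",       # carboxyl                (decarboxylation)
    "C",            # methyl                  (aliphatic_hydroxylation)
    "CC",           # ethyl
    "O",            # hydroxyl
    "N")            # amino
}

#' Generate the fixture compound corpus
#'
#' Enumerates para- and meta-disubstituted benzenes over a fixed
#' substituent grid, canonicalizes, deduplicates by structure key and
#' returns the first `n_compounds` in grid order.  The grid guarantees
#' that every toy12 rule triggers on many corpus members.  The output is
#' identical for every seed (the corpus is a deterministic frame; only
#' pathway observation is stochastic).
#'
#' @param cfg A [fixture_config()].
#' @return A compounds tibble (`compound_id`, `smiles`, `display_smiles`,
#'   `name`).
#' @export
generate_compounds <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  frags <- fixture_fragments()
  smi <- character(0)
  for (i in seq_along(frags)) {
    for (j in seq_along(frags)) {
      if (j < i) next   # unordered pair: disubstituted rings are symmetric
      smi <- c(smi,
               paste0("c1cc(", frags[i], ")ccc1", frags[j]),    # para
               paste0("c1cc(", frags[i], ")cc(", frags[j], ")c1"),  # meta
               paste0("c1cc(", frags[i], ")c(", frags[j], ")cc1"))  # ortho
    }
  }
  can <- canonicalize_smiles(smi)
  keep <- !duplicated(can)
  can <- can[keep]
  if (length(can) < cfg$n_compounds) {
    rlang::abort(paste0("grid yields only ", length(can),
                        " unique compounds; lower n_compounds"))
  }
  can <- can[seq_len(cfg$n_compounds)]
  tibble::tibble(
    compound_id = sprintf("cpd%03d", seq_along(can)),
    smiles = can,
    display_smiles = can,
    name = NA_character_
  )
}

# splice node v out of an edge table: every in-edge u->v and out-edge
# v->w combine into a multi-step edge u->w (rule dropped).
splice_out <- function(edges, v) {
  ine <- edges[edges$product == v, , drop = FALSE]
  oute <- edges[edges$substrate == v, , drop = FALSE]
  rest <- edges[edges$product != v & edges$substrate != v, , drop = FALSE]
  new <- tidyr::expand_grid(u = unique(ine$substrate), w = unique(oute$product))
  new <- new[new$u != new$w, , drop = FALSE]
  add <- tibble::tibble(substrate = new$u, product = new$w,
                        rule_id = NA_character_,
                        reaction_id = paste0("step|", new$u, ">", new$w))
  out <- dplyr::bind_rows(rest, add)
  out[!duplicated(out[, c("substrate", "product")]), , drop = FALSE]
}

#' Simulate observed pathways and assemble a training package
#'
#' For each of `n_pathways` root compounds, a ground-truth pathway is
#' grown to `max_pathway_depth` by applying every rule at every
#' triggered site with probability `p_observe_active` (active rules) or
#' `p_observe_inactive` (inactive rules).  Each internal node of the
#' truth is then removed with probability `p_collapse`, splicing its
#' edges into multi-step reactions -- exactly the situation where an
#' experimental pathway skips a short-lived intermediate.  The collapsed
#' pathways and their reactions form the returned package; the
#' uncollapsed truth is kept in the `ground_truth` attribute and the
#' active rule set in the `active_rules` attribute.
#'
#' @param cfg A [fixture_config()].
#' @param compounds A compounds tibble (default
#'   [generate_compounds()]).
#' @param rules A rules tibble (default [toy_rules()]).
#' @return A [bt_package()]; attributes `ground_truth` (list of truth
#'   [pathway()]s parallel to `pkg$pathways`) and `active_rules`.
#' @export
generate_observed_pathways <- function(cfg, compounds = generate_compounds(cfg),
                                       rules = toy_rules()) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(cfg$seed, {
    active <- sort(sample(rules$rule_id,
                          round(cfg$active_rule_fraction * nrow(rules))))
    roots <- sort(sample(compounds$smiles, min(cfg$n_pathways,
                                               nrow(compounds))))

    # grow all ground-truth pathways level by level so rule application
    # is batched across pathways
    state <- lapply(roots, function(r) list(
      root = r,
      nodes = stats::setNames(0L, r),
      edges = tibble::tibble(substrate = character(), product = character(),
                             rule_id = character(), reaction_id = character())
    ))
    for (d in seq_len(cfg$max_pathway_depth) - 1L) {
      frontier <- unique(unlist(lapply(state, function(s)
        names(s$nodes)[s$nodes == d])))
      if (length(frontier) == 0) break
      app <- chem_apply(rules$smirks, frontier)
      for (si in seq_along(state)) {
        s <- state[[si]]
        level <- sort(names(s$nodes)[s$nodes == d])
        for (node in level) {
          # draw all realized events for this node first, then record them
          # all or leave the node an unexpanded leaf: a node budget must
          # never truncate individual reactions or a node's label set
          events <- list()
          for (j in seq_len(nrow(rules))) {
            rid <- rules$rule_id[j]
            p_obs <- if (rid %in% active) cfg$p_observe_active else
              cfg$p_observe_inactive
            sets <- app[[rules$smirks[j]]][[node]]
            for (site in seq_along(sets)) {
              if (stats::runif(1) >= p_obs) next
              events[[length(events) + 1L]] <- list(
                rid = rid, site = site, prods = sets[[site]])
            }
          }
          if (length(events) == 0) next
          new_prods <- setdiff(unique(unlist(lapply(events, `[[`, "prods"))),
                               names(s$nodes))
          if (length(s$nodes) + length(new_prods) >
              cfg$max_nodes_per_pathway) next
          # ancestors of `node`: an edge to them would close a cycle
          anc <- character(0)
          frontier_up <- node
          while (length(frontier_up)) {
            up <- unique(s$edges$substrate[s$edges$product %in% frontier_up])
            up <- setdiff(up, anc)
            anc <- c(anc, up)
            frontier_up <- up
          }
          for (ev in events) {
            event <- paste(node, ev$rid, ev$site, sep = "|")
            for (p in ev$prods) {
              if (p == node || p %in% anc || p == s$root) next
              if (!(p %in% names(s$nodes))) {
                s$nodes[p] <- d + 1L
              }
              dup <- any(s$edges$substrate == node & s$edges$product == p)
              if (!dup) {
                s$edges <- dplyr::bind_rows(s$edges, tibble::tibble(
                  substrate = node, product = p, rule_id = ev$rid,
                  reaction_id = event))
              }
            }
          }
        }
        state[[si]] <- s
      }
    }

    truth_pws <- list()
    obs_pws <- list()
    for (si in seq_along(state)) {
      s <- state[[si]]
      truth <- pathway(s$edges, roots = s$root,
                       id = sprintf("truth%03d", si))
      # collapse internal nodes
      edges <- s$edges
      internal <- intersect(unique(edges$product), unique(edges$substrate))
      internal <- sort(setdiff(internal, s$root))
      for (v in internal) {
        if (stats::runif(1) < cfg$p_collapse) edges <- splice_out(edges, v)
      }
      obs <- pathway(edges, roots = s$root, id = sprintf("obs%03d", si))
      truth_pws[[si]] <- truth
      obs_pws[[si]] <- obs
    }

    # package reactions from observed pathway edges; one reaction per
    # rule event (multi-product) or per spliced multi-step edge,
    # deduplicated across pathways by (substrates, products, rule)
    reactions <- list()
    sig_to_id <- character(0)
    next_id <- 0L
    for (si in seq_along(obs_pws)) {
      pw <- obs_pws[[si]]
      e <- pw$edges
      # edges from the same rule event share a reaction_id; spliced
      # multi-step edges each carry their own "step|" id
      grp <- e$reaction_id
      rxid <- character(nrow(e))
      for (g in unique(grp)) {
        idx <- which(grp == g)
        subs <- e$substrate[idx][1]
        prods <- sort(e$product[idx])
        rid <- e$rule_id[idx][1]
        sig <- paste(reaction_signature(subs, prods),
                     ifelse(is.na(rid), "", rid))
        if (!sig %in% names(sig_to_id)) {
          next_id <- next_id + 1L
          id <- sprintf("rx%04d", next_id)
          sig_to_id[sig] <- id
          reactions[[id]] <- tibble::tibble(
            reaction_id = id, substrates = list(subs), products = list(prods),
            rule_id = rid, ec = list(character(0))
          )
        }
        rxid[idx] <- sig_to_id[[sig]]
      }
      e$reaction_id <- rxid
      obs_pws[[si]] <- pathway(e, roots = pw$roots, id = pw$id)
    }
    reactions <- if (length(reactions)) dplyr::bind_rows(reactions) else
      empty_reactions()

    # compound records for every structure seen anywhere
    all_smiles <- sort(unique(c(
      compounds$smiles,
      unlist(lapply(c(obs_pws, truth_pws), function(p) p$nodes$smiles))
    )))
    extra <- setdiff(all_smiles, compounds$smiles)
    comp <- dplyr::bind_rows(
      compounds,
      tibble::tibble(compound_id = sprintf("gen%03d", seq_along(extra)),
                     smiles = extra, display_smiles = extra,
                     name = NA_character_)
    )

    # a few DT50 scenarios on root compounds (metadata only)
    root_ids <- comp$compound_id[match(roots, comp$smiles)]
    scen <- tibble::tibble(
      scenario_id = sprintf("sc%03d", seq_along(root_ids)),
      entity_id = root_ids,
      key = "DT50",
      value = as.character(signif(stats::rlnorm(length(root_ids), 2, 1), 3)),
      unit = "days"
    )

    pkg <- bt_package(
      id = paste0("synthetic-seed", cfg$seed),
      name = "synthetic biotransformation fixture",
      compounds = comp, rules = rules, reactions = reactions,
      pathways = obs_pws, scenarios = scen
    )
    attr(pkg, "ground_truth") <- truth_pws
    attr(pkg, "active_rules") <- active
    pkg
  })
}

#' Generate EC-annotated reaction corpora with planted linkage truth
#'
#' Assigns each rule one or two planted 4th-level EC numbers, generates
#' corpus reactions by applying the rules to corpus compounds (skipping
#' transformations that a second rule could also have generated, so
#' every corpus reaction identifies its rule unambiguously), annotates
#' each reaction with its rule's EC, and distributes the reactions over
#' two sources with controlled overlap.
#'
#' @param cfg A [fixture_config()].
#' @param rules A rules tibble (default [toy_rules()]).
#' @param compounds A compounds tibble (default [generate_compounds()]).
#' @return A list: `corpora` (two [reaction_corpus()] objects, sources
#'   `"A"` and `"B"`), `truth` (tibble `rule_id`, `ec3`, `in_a`, `in_b`
#'   -- the exact linkage set [derive_linkages()] must recover), and
#'   `compounds` (the SMILES to use as the linkage compound corpus).
#' @export
generate_ec_corpora <- function(cfg, rules = toy_rules(),
                                compounds = generate_compounds(cfg)) {
  stopifnot(inherits(cfg, "fixture_config"))
  withr::with_seed(cfg$seed + 1L, {
    gen <- apply_rules(rules, compounds$smiles)
    # drop transformations reproducible by more than one rule
    sig <- paste(gen$smiles,
                 vapply(gen$products, function(p) paste(sort(p), collapse = "."),
                        character(1)))
    ambiguous <- sig %in% sig[duplicated(sig)]
    gen <- gen[!ambiguous, , drop = FALSE]

    planted <- lapply(seq_len(nrow(rules)), function(j) {
      n_ec <- sample(1:2, 1)
      unique(vapply(seq_len(n_ec), function(.)
        paste(sample(1:6, 1), sample(1:20, 1), sample(1:20, 1),
              sample(1:50, 1), sep = "."), character(1)))
    })
    names(planted) <- rules$rule_id

    rxA <- list()
    rxB <- list()
    truth <- list()
    n_rx <- 0L
    for (j in seq_len(nrow(rules))) {
      rid <- rules$rule_id[j]
      cand <- gen[gen$rule_id == rid, , drop = FALSE]
      if (nrow(cand) == 0) next
      take <- cand[sample.int(nrow(cand), min(cfg$reactions_per_rule,
                                              nrow(cand))), , drop = FALSE]
      ecs <- planted[[rid]]
      # source membership is drawn once per (rule, EC) linkage so that
      # p_overlap controls the overlap of derived LINKS, not of reactions
      membership <- lapply(ecs, function(.) {
        u <- stats::runif(1)
        in_a <- u < cfg$p_overlap ||
          u < cfg$p_overlap + (1 - cfg$p_overlap) / 2
        c(in_a = in_a, in_b = u < cfg$p_overlap || !in_a)
      })
      names(membership) <- ecs
      for (i in seq_len(nrow(take))) {
        n_rx <- n_rx + 1L
        ec4 <- ecs[((i - 1L) %% length(ecs)) + 1L]
        mem <- membership[[ec4]]
        row <- tibble::tibble(
          reaction_id = sprintf("ec%04d", n_rx),
          substrates = list(take$smiles[i]),
          products = list(sort(take$products[[i]])),
          rule_id = NA_character_,
          ec = list(ec4)
        )
        if (mem[["in_a"]]) rxA[[length(rxA) + 1L]] <- row
        if (mem[["in_b"]]) {
          row_b <- row
          row_b$reaction_id <- paste0(row$reaction_id, "b")
          rxB[[length(rxB) + 1L]] <- row_b
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          rule_id = rid, ec3 = truncate_ec(ec4),
          in_a = mem[["in_a"]], in_b = mem[["in_b"]]
        )
      }
    }
    truth <- dplyr::bind_rows(truth) |>
      dplyr::group_by(.data$rule_id, .data$ec3) |>
      dplyr::summarise(in_a = any(.data$in_a), in_b = any(.data$in_b),
                       .groups = "drop") |>
      dplyr::arrange(.data$rule_id, .data$ec3)
    list(
      corpora = list(
        reaction_corpus("A", dplyr::bind_rows(rxA)),
        reaction_corpus("B", dplyr::bind_rows(rxB))
      ),
      truth = truth,
      compounds = compounds$smiles
    )
  })
}
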