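# Relative-reasoning rule scorer: learns, from a training package, how
# likely each structurally triggered rule is to be realized for a given
# compound.  Two modes: a global per-rule precision baseline, and a
# fingerprint k-nearest-neighbour label average that falls back to the
# baseline when no labelled neighbour triggers the rule.

#' Derive per-compound rule labels from a package
#'
#' For every compound appearing as the substrate of a single-substrate
#' reaction in the package: `triggered` is the set of rules that
#' structurally apply to it, and `observed` is the subset of triggered
#' rules whose application reproduces the (substrate, product multiset)
#' of some package reaction.  `observed` is always a subset of
#' `triggered`; compounds triggering no rules keep empty sets.
#'
#' @param pkg A [bt_package()].
#' @param rules A rules tibble (default: the package's own rules).
#' @return A tibble with columns `smiles`, `triggered` (list column of
#'   rule ids), `observed` (list column of rule ids).
#' @export
build_training_labels <- function(pkg, rules = pkg$rules) {
  stopifnot(inherits(pkg, "bt_package"))
  rx <- pkg$reactions
  single <- vapply(rx$substrates, length, integer(1)) == 1L
  rx <- rx[single, , drop = FALSE]
  substrates <- sort(unique(unlist(rx$substrates, use.names = FALSE)))
  if (length(substrates) == 0) {
    return(tibble::tibble(smiles = character(), triggered = list(),
                          observed = list()))
  }
  app <- chem_apply(rules$smirks, substrates)
  # observed product multisets per substrate
  obs_sets <- split(
    vapply(rx$products, function(p) paste(sort(p), collapse = "."),
           character(1)),
    unlist(rx$substrates, use.names = FALSE)
  )
  purrr::map_dfr(substrates, function(smi) {
    trig <- character(0)
    obs <- character(0)
    for (j in seq_len(nrow(rules))) {
      sets <- app[[rules$smirks[j]]][[smi]]
      if (length(sets) == 0) next
      trig <- c(trig, rules$rule_id[j])
      sigs <- vapply(sets, function(s) paste(s, collapse = "."), character(1))
      if (any(sigs %in% obs_sets[[smi]])) obs <- c(obs, rules$rule_id[j])
    }
    tibble::tibble(smiles = smi, triggered = list(trig), observed = list(obs))
  })
}

#' Train a rule scorer on a package
#'
#' In `baseline` mode the scorer stores, per rule, the global precision
#' (#compounds where the rule was observed / #compounds where it
#' triggered); a rule never triggered in training defaults to the
#' uninformed prior 0.5.  In `knn` mode it additionally stores a Morgan
#' fingerprint index and the per-compound label sets, and scores a query
#' by averaging the observed-labels of its k most similar training
#' compounds among those on which the rule triggers.
#'
#' @param pkg A [bt_package()] supplying the training reactions.
#' @param rules A rules tibble.
#' @param mode `"knn"` (default) or `"baseline"`.
#' @param k Number of neighbours for knn scoring.
#' @return An object of class `rule_scorer`.
#' @export
train_scorer <- function(pkg, rules = pkg$rules, mode = c("knn", "baseline"),
                         k = 5L) {
  mode <- match.arg(mode)
  labels <- build_training_labels(pkg, rules)
  if (nrow(labels) == 0) {
    rlang::abort("package yields no labelled training compounds")
  }
  n_trig <- vapply(rules$rule_id, function(r)
    sum(purrr::map_lgl(labels$triggered, ~ r %in% .x)), integer(1))
  n_obs <- vapply(rules$rule_id, function(r)
    sum(purrr::map_lgl(labels$observed, ~ r %in% .x)), integer(1))
  base_score <- ifelse(n_trig > 0, n_obs / n_trig, 0.5)
  if (any(n_trig == 0)) {
    message("rule(s) never triggered in training, baseline defaults to 0.5: ",
            paste(rules$rule_id[n_trig == 0], collapse = ", "))
  }
  structure(
    list(
      mode = mode,
      k = as.integer(k),
      rules = rules,
      labels = labels,
      fps = chem_fingerprints(labels$smiles),
      baseline = tibble::tibble(
        rule_id = rules$rule_id,
        n_triggered = unname(n_trig), n_observed = unname(n_obs),
        score = unname(base_score)
      ),
      cache = new.env(parent = emptyenv())
    ),
    class = "rule_scorer"
  )
}

#' @export
print.rule_scorer <- function(x, ...) {
  cat("<rule_scorer> mode=", x$mode,
      if (x$mode == "knn") paste0(" (k=", x$k, ")"),
      ", ", nrow(x$labels), " training compounds, ",
      nrow(x$rules), " rules\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn train_scorer Per-rule training statistics (triggered and
#'   observed counts, baseline score).
#' @param x A `rule_scorer`.
#' @param ... Unused.
#' @method tidy rule_scorer
#' @export
tidy.rule_scorer <- function(x, ...) x$baseline

#' @describeIn train_scorer One-row model summary.
#' @method glance rule_scorer
#' @export
glance.rule_scorer <- function(x, ...) {
  tibble::tibble(mode = x$mode, k = x$k,
                 n_compounds = nrow(x$labels), n_rules = nrow(x$rules))
}

#' Score candidate transformations for a compound
#'
#' Only structurally triggered rules receive a score.  knn scores are the
#' mean observed-label of the k most similar training compounds (Tanimoto
#' on Morgan fingerprints) among those whose triggered set contains the
#' rule; with fewer than k such compounds the mean runs over those
#' available, and with none the rule falls back to its baseline score.
#'
#' @param scorer A [train_scorer()] model.
#' @param smiles A single compound SMILES.
#' @param exclude Training compounds (canonical SMILES) to drop from the
#'   neighbour index, used for leave-one-out assessment.
#' @return A tibble with columns `rule_id`, `score`, ordered by
#'   decreasing score then rule id.
#' @export
score_transformations <- function(scorer, smiles, exclude = NULL) {
  stopifnot(inherits(scorer, "rule_scorer"), length(smiles) == 1L)
  smi <- canonicalize_smiles(smiles)
  key <- paste0(smi, "\r", paste(sort(exclude), collapse = ","))
  hit <- scorer$cache[[key]]
  if (!is.null(hit)) return(hit)

  trig_tbl <- triggered_rules(scorer$rules, smi)
  trig <- trig_tbl$rule_id
  base <- stats::setNames(scorer$baseline$score, scorer$baseline$rule_id)
  if (length(trig) == 0) {
    out <- tibble::tibble(rule_id = character(), score = numeric())
    scorer$cache[[key]] <- out
    return(out)
  }
  if (scorer$mode == "baseline") {
    score <- unname(base[trig])
  } else {
    lbl <- scorer$labels
    keep <- !(lbl$smiles %in% exclude)
    lbl <- lbl[keep, , drop = FALSE]
    sims <- if (nrow(lbl)) tanimoto_many(chem_fingerprints(smi)[[1]],
                                         scorer$fps[keep]) else numeric(0)
    score <- vapply(trig, function(r) {
      cand <- which(purrr::map_lgl(lbl$triggered, ~ r %in% .x))
      if (length(cand) == 0) return(unname(base[[r]]))
      ord <- cand[order(-sims[cand], lbl$smiles[cand])]
      take <- ord[seq_len(min(scorer$k, length(ord)))]
      mean(purrr::map_lgl(lbl$observed[take], ~ r %in% .x))
    }, numeric(1))
  }
  out <- tibble::tibble(rule_id = trig, score = unname(score))
  out <- out[order(-out$score, out$rule_id), ]
  scorer$cache[[key]] <- out
  out
}
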