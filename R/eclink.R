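# Rule-to-enzyme-class linkage: apply all rules to a compound corpus,
# match the generated in-silico reactions against EC-annotated reaction
# corpora, and aggregate matches into (rule, 3rd-level EC) linkages with
# per-source provenance.

#' Truncate EC numbers to the 3rd level
#'
#' 4th-level EC numbers are summarized into their 3rd-level class;
#' shallower annotations (1st/2nd level) cannot yield a 3rd-level class
#' and are skipped, signalled as `NA`.
#'
#' @param ec Character vector of EC numbers (dot-separated, e.g.
#'   `"1.14.13.39"`; wildcard fields such as `-` count as absent).
#' @return Character vector: the 3-level EC class, or `NA` for
#'   annotations with fewer than 3 usable levels.
#' @examples
#' truncate_ec(c("1.14.13.39", "3.1.1", "3.1"))
#' @export
truncate_ec <- function(ec) {
  vapply(ec, function(e) {
    parts <- strsplit(e, ".", fixed = TRUE)[[1]]
    parts <- parts[!parts %in% c("-", "*", "")]
    if (length(parts) < 3 || anyNA(suppressWarnings(as.integer(parts)))) {
      return(NA_character_)
    }
    paste(parts[1:3], collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct an EC-annotated reaction corpus
#'
#' @param source_id Corpus identifier.
#' @param reactions A reactions tibble (see [bt_package()]) whose `ec`
#'   list column carries EC number strings.
#' @return A list of class `reaction_corpus`.
#' @export
reaction_corpus <- function(source_id, reactions) {
  reactions <- tibble::as_tibble(reactions)
  stopifnot(all(c("reaction_id", "substrates", "products", "ec") %in%
                  names(reactions)))
  ok <- vapply(reactions$substrates, length, integer(1)) >= 1L &
    vapply(reactions$products, length, integer(1)) >= 1L
  if (!all(ok)) rlang::abort("corpus reactions need >=1 substrate and product")
  structure(list(source_id = source_id, reactions = reactions),
            class = "reaction_corpus")
}

#' Match a generated reaction against a corpus
#'
#' A corpus reaction matches when its substrate multiset equals the
#' generated single substrate and its product multiset equals the
#' generated product multiset, both under stereo-stripped canonical keys,
#' after removing any `ignore` members (e.g. water or other cofactors)
#' from both sides.
#'
#' @param corpus A [reaction_corpus()].
#' @param substrate Canonical substrate SMILES.
#' @param products Character vector: the generated product multiset.
#' @param ignore Structure keys removed from both sides before comparison
#'   (default none).
#' @return The matching rows of the corpus reactions tibble.
#' @export
match_reaction <- function(corpus, substrate, products, ignore = character()) {
  stopifnot(inherits(corpus, "reaction_corpus"))
  strip <- function(x) sort(x[!x %in% ignore])
  want_sub <- strip(substrate)
  want_prod <- strip(products)
  hit <- vapply(seq_len(nrow(corpus$reactions)), function(i) {
    identical(strip(corpus$reactions$substrates[[i]]), want_sub) &&
      identical(strip(corpus$reactions$products[[i]]), want_prod)
  }, logical(1))
  corpus$reactions[hit, , drop = FALSE]
}

#' Derive rule-to-EC-class linkages
#'
#' Applies every rule to every corpus compound, matches each generated
#' (substrate, product multiset) reaction against the EC-annotated
#' reaction corpora, and emits one linkage per distinct (rule, 3rd-level
#' EC class) pair, recording the contributing sources and the number of
#' distinct matched reactions per source.  Reactions annotated only at
#' the 1st/2nd EC level are skipped; generated reactions matching nothing
#' are counted in the summary attribute and otherwise discarded.
#'
#' @param rules A rules tibble.
#' @param compounds Character vector of corpus compound SMILES.
#' @param corpora A list of [reaction_corpus()] objects.
#' @param ignore Passed to [match_reaction()].
#' @return A tibble of class `rule_ec_links`: `rule_id`, `ec3`,
#'   `sources` (comma-joined source ids), one `support_<source>` count
#'   per corpus; attribute `summary` holds generation/match totals.
#' @export
derive_linkages <- function(rules, compounds, corpora, ignore = character()) {
  stopifnot(is.list(corpora), length(corpora) >= 1)
  src_ids <- vapply(corpora, `[[`, character(1), "source_id")
  if (anyDuplicated(src_ids)) rlang::abort("duplicate corpus source ids")
  can <- unique(canonicalize_smiles(compounds))
  gen <- apply_rules(rules, can)
  n_generated <- nrow(gen)
  n_matched <- 0L

  links <- list()  # key "rule\rec3" -> list(sources=named int counts)
  for (i in seq_len(nrow(gen))) {
    sub <- gen$smiles[i]
    prods <- gen$products[[i]]
    rid <- gen$rule_id[i]
    matched_any <- FALSE
    for (corpus in corpora) {
      hits <- match_reaction(corpus, sub, prods, ignore = ignore)
      if (nrow(hits) == 0) next
      matched_any <- TRUE
      for (h in seq_len(nrow(hits))) {
        ec3s <- unique(stats::na.omit(truncate_ec(hits$ec[[h]])))
        for (ec3 in ec3s) {
          key <- paste(rid, ec3, sep = "\r")
          entry <- links[[key]]
          if (is.null(entry)) {
            entry <- list(rule_id = rid, ec3 = ec3,
                          reactions = stats::setNames(
                            rep(list(character(0)), length(src_ids)), src_ids))
          }
          entry$reactions[[corpus$source_id]] <- union(
            entry$reactions[[corpus$source_id]], hits$reaction_id[h])
          links[[key]] <- entry
        }
      }
    }
    if (matched_any) n_matched <- n_matched + 1L
  }

  out <- purrr::map_dfr(links, function(entry) {
    support <- vapply(entry$reactions, length, integer(1))
    row <- tibble::tibble(
      rule_id = entry$rule_id, ec3 = entry$ec3,
      sources = paste(src_ids[support > 0], collapse = ",")
    )
    for (s in src_ids) row[[paste0("support_", s)]] <- support[[s]]
    row
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(rule_id = character(), ec3 = character(),
                          sources = character())
    for (s in src_ids) out[[paste0("support_", s)]] <- integer()
  }
  out <- out[order(out$rule_id, out$ec3), ]
  structure(tibble::as_tibble(out),
            class = c("rule_ec_links", class(out)),
            summary = list(n_generated = n_generated, n_matched = n_matched,
                           sources = src_ids))
}

#' Source overlap of derived linkages
#'
#' Fractions of distinct (rule, EC class) linkages found in both sources,
#' only in the first, and only in the second; the three fractions sum
#' to 1.
#'
#' @param links A [derive_linkages()] result.
#' @param source_a,source_b The two source ids.
#' @return A one-row tibble: `n_links`, `both`, `a_only`, `b_only`.
#' @export
overlap_summary <- function(links, source_a, source_b) {
  for (s in c(source_a, source_b)) {
    if (!paste0("support_", s) %in% names(links)) {
      rlang::abort(paste0("unknown source id: ", s))
    }
  }
  in_a <- links[[paste0("support_", source_a)]] > 0
  in_b <- links[[paste0("support_", source_b)]] > 0
  n <- nrow(links)
  if (n == 0) {
    return(tibble::tibble(n_links = 0L, both = NA_real_, a_only = NA_real_,
                          b_only = NA_real_))
  }
  tibble::tibble(
    n_links = n,
    both = sum(in_a & in_b) / n,
    a_only = sum(in_a & !in_b) / n,
    b_only = sum(!in_a & in_b) / n
  )
}
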