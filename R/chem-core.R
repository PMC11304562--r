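# Chemistry substrate: rule libraries, rule application, fingerprint
# similarity and functional-group detection.

# TSV reader treating '#' as a comment only at line start: SMILES and
# SMARTS legitimately contain '#' (triple bonds).
read_tsv_hash <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                    quote = "", comment.char = "", stringsAsFactors = FALSE)
}

#' Read a transformation-rule library
#'
#' Rules files are UTF-8 tab-separated tables with columns `rule_id`,
#' `name` and `smirks` (lines starting with `#` are comments).  A rule is
#' a reaction SMARTS/SMIRKS with exactly one reactant template and one or
#' more product templates.  Optional columns `example_smiles` and
#' `example_products` document a worked example substrate and its expected
#' product sets (sets separated by `|`, products within a set by `.`).
#'
#' @param path Path to a rules TSV file.
#' @return A tibble with one row per rule.
#' @seealso [toy_rules()] for the shipped 12-rule library.
#' @export
read_rules <- function(path) {
  raw <- read_tsv_hash(path)
  need <- c("rule_id", "name", "smirks")
  if (!all(need %in% names(raw))) {
    rlang::abort(paste0("rules file must have columns: ",
                        paste(need, collapse = ", ")))
  }
  rules <- tibble::as_tibble(raw)
  if (anyDuplicated(rules$rule_id)) {
    rlang::abort("duplicate rule_id in rules file")
  }
  bad <- !grepl(">>", rules$smirks, fixed = TRUE)
  if (any(bad)) {
    rlang::abort(paste0("not a reaction SMIRKS: ", rules$smirks[bad][1]))
  }
  # one reactant template: no top-level '.' on the left-hand side
  lhs <- sub(">>.*$", "", rules$smirks)
  multi <- vapply(lhs, function(s) {
    depth <- 0L
    for (ch in strsplit(s, "")[[1]]) {
      if (ch == "(") depth <- depth + 1L
      else if (ch == ")") depth <- depth - 1L
      else if (ch == "." && depth == 0L) return(TRUE)
    }
    FALSE
  }, logical(1))
  if (any(multi)) {
    rlang::abort(paste0("rule has more than one reactant template: ",
                        rules$rule_id[multi][1]))
  }
  rules
}

#' The shipped "toy12" transformation-rule library
#'
#' Twelve common microbial biotransformation reaction templates (ester and
#' amide hydrolysis, aromatic and aliphatic hydroxylation, nitro
#' reduction, N- and O-dealkylation, aromatic dehalogenation, alcohol
#' oxidation, nitrile hydrolysis, sulfoxidation, decarboxylation), each
#' with a documented example substrate and its hand-verified products.
#'
#' @return A tibble of rules (see [read_rules()]).
#' @export
toy_rules <- function() {
  read_rules(system.file("extdata", "toy_rules.tsv", package = "rulepath"))
}

#' The shipped functional-group SMARTS library
#'
#' A fixed, versioned library of hetero-atom-containing functional groups
#' (hydroxyl, carboxylic acid, ester, amide, amines, nitro, nitrile,
#' ether, thioether, sulfoxide/sulfone, sulfonamide, halides, phosphate
#' ester, ketone, aldehyde, carbamate, urea, azo) used by the
#' applicability-domain coverage assessment.
#'
#' @return A tibble with columns `group_id`, `name`, `smarts`.
#' @export
fg_library <- function() {
  tibble::as_tibble(read_tsv_hash(
    system.file("extdata", "functional_groups.tsv", package = "rulepath")
  ))
}

#' Apply transformation rules to compounds
#'
#' Applies each SMIRKS rule to each compound at every distinct match site.
#' Each site yields one product multiset; identical product sets arising
#' from symmetry-equivalent sites are deduplicated.  Products failing
#' valence sanitization are dropped with a warning, never an error, so
#' exhaustive rule application over a corpus cannot abort.
#'
#' @param rules A rules tibble (see [read_rules()]).
#' @param smiles Character vector of substrate SMILES.
#' @return A tibble with one row per (rule, substrate, product set):
#'   columns `rule_id`, `smiles` (canonical substrate), `site` (1-based
#'   index of the product set), `products` (list column of sorted
#'   canonical SMILES).  Substrate/rule combinations that do not trigger
#'   contribute no rows.
#' @examples
#' \dontrun{
#' apply_rules(toy_rules(), "CCOC(C)=O")
#' }
#' @export
apply_rules <- function(rules, smiles) {
  stopifnot(is.data.frame(rules))
  can <- canonicalize_smiles(smiles)
  res <- chem_apply(rules$smirks, can)
  out <- purrr::map2_dfr(rules$rule_id, rules$smirks, function(rid, smk) {
    per_cpd <- res[[smk]]
    purrr::imap_dfr(per_cpd, function(sets, smi) {
      if (length(sets) == 0) return(NULL)
      tibble::tibble(
        rule_id = rid, smiles = smi,
        site = seq_along(sets), products = sets
      )
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(rule_id = character(), smiles = character(),
                          site = integer(), products = list())
  }
  out
}

#' Which rules trigger on each compound
#'
#' A rule triggers on a compound when [apply_rules()] yields at least one
#' product set for it.
#'
#' @inheritParams apply_rules
#' @return A tibble with columns `smiles` (canonical) and `rule_id`, one
#'   row per triggering pair.
#' @export
triggered_rules <- function(rules, smiles) {
  hits <- apply_rules(rules, smiles)
  dplyr::distinct(hits, .data$smiles, .data$rule_id)
}

#' Tanimoto similarity between fingerprints
#'
#' Fingerprints are Morgan (circular, radius 2) bit sets of fixed length
#' 2048, represented as sorted integer on-bit positions.  The similarity
#' of two empty fingerprints is defined as 1.
#'
#' @param a,b Integer vectors of on-bit positions (as returned by the
#'   internal fingerprint index), or a single SMILES string each.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (is.character(a)) a <- chem_fingerprints(a)[[1]]
  if (is.character(b)) b <- chem_fingerprints(b)[[1]]
  stopifnot(is.numeric(a) || is.integer(a), is.numeric(b) || is.integer(b))
  n_union <- length(union(a, b))
  if (n_union == 0) return(1)
  length(intersect(a, b)) / n_union
}

# Tanimoto of one fingerprint against a list of fingerprints.
tanimoto_many <- function(fp, fps) {
  vapply(fps, function(x) tanimoto(fp, x), numeric(1))
}

#' Detect hetero-atom functional groups
#'
#' Matches the shipped functional-group SMARTS library (or a custom one)
#' against each compound and reports the matched atom positions.  A
#' molecule with no hetero atoms yields no rows.
#'
#' @param smiles Character vector of SMILES.
#' @param groups A functional-group tibble (default [fg_library()]).
#' @return A tibble with columns `smiles` (canonical), `group_id`, `hit`
#'   (1-based match counter) and `atom_indices` (list column of 0-based
#'   atom positions in the query molecule).
#' @export
find_functional_groups <- function(smiles, groups = fg_library()) {
  pats <- stats::setNames(groups$smarts, groups$group_id)
  res <- chem_smarts_matches(smiles, pats)
  can <- canonicalize_smiles(smiles)
  out <- purrr::map2_dfr(res, can, function(hits, smi) {
    purrr::imap_dfr(hits, function(ms, gid) {
      tibble::tibble(smiles = smi, group_id = gid,
                     hit = seq_along(ms), atom_indices = ms)
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(smiles = character(), group_id = character(),
                          hit = integer(), atom_indices = list())
  }
  out
}
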