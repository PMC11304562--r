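# Data packages: the container entity grouping compounds, rules,
# reactions, pathways and scenario metadata, with JSON persistence and
# merging.

PKG_SCHEMA_VERSION <- 1L

empty_compounds <- function() {
  tibble::tibble(compound_id = character(), smiles = character(),
                 display_smiles = character(), name = character())
}
empty_reactions <- function() {
  tibble::tibble(reaction_id = character(), substrates = list(),
                 products = list(), rule_id = character(), ec = list())
}
empty_rules <- function() {
  tibble::tibble(rule_id = character(), name = character(),
                 smirks = character())
}
empty_scenarios <- function() {
  tibble::tibble(scenario_id = character(), entity_id = character(),
                 key = character(), value = character(), unit = character())
}

#' Construct a data package
#'
#' A package groups compounds, transformation rules, reactions, pathways
#' and scenario metadata (free-form typed key-value records such as
#' half-life DT50, pH, TSS, redox conditions or inoculum source) into one
#' self-contained unit.  All cross-references must resolve within the
#' package.
#'
#' @param id,name Package identifier and human-readable name.
#' @param compounds Tibble with columns `compound_id`, `smiles`
#'   (canonical key), `display_smiles`, `name`.
#' @param rules A rules tibble (see [read_rules()]).
#' @param reactions Tibble with columns `reaction_id`, `substrates` and
#'   `products` (list columns of canonical SMILES multisets), `rule_id`
#'   (NA when not derived from a rule) and `ec` (list column of EC number
#'   strings).
#' @param pathways A list of [pathway()] objects.
#' @param scenarios Tibble with columns `scenario_id`, `entity_id`,
#'   `key`, `value`, `unit`.
#' @param validate Check internal consistency (default `TRUE`).
#' @return An object of class `bt_package`.
#' @export
bt_package <- function(id, name = id,
                       compounds = empty_compounds(),
                       rules = empty_rules(),
                       reactions = empty_reactions(),
                       pathways = list(),
                       scenarios = empty_scenarios(),
                       validate = TRUE) {
  pkg <- structure(
    list(
      schema_version = PKG_SCHEMA_VERSION,
      id = id, name = name,
      compounds = tibble::as_tibble(compounds),
      rules = tibble::as_tibble(rules),
      reactions = tibble::as_tibble(reactions),
      pathways = pathways,
      scenarios = tibble::as_tibble(scenarios)
    ),
    class = "bt_package"
  )
  if (validate) validate_package(pkg)
  pkg
}

#' Validate a data package
#'
#' Checks id uniqueness per collection, non-empty and distinct reaction
#' sides, and that every structure key referenced by reactions and
#' pathways resolves to a compound record.  Violations are reported with
#' a JSON-style path to the offending entity.
#'
#' @param pkg A [bt_package()].
#' @return `pkg`, invisibly; aborts with class
#'   `rulepath_validation_error` on the first set of violations.
#' @export
validate_package <- function(pkg) {
  stopifnot(inherits(pkg, "bt_package"))
  errs <- character(0)
  for (coll in c("compounds", "rules", "reactions", "scenarios")) {
    idcol <- c(compounds = "compound_id", rules = "rule_id",
               reactions = "reaction_id", scenarios = "scenario_id")[[coll]]
    ids <- pkg[[coll]][[idcol]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
      errs <- c(errs, paste0("$", coll, ": duplicate id(s) ",
                             paste(dup, collapse = ", ")))
    }
  }
  pw_ids <- vapply(pkg$pathways, `[[`, character(1), "id")
  if (anyDuplicated(pw_ids)) {
    errs <- c(errs, "$pathways: duplicate pathway id(s)")
  }
  known <- pkg$compounds$smiles
  rx <- pkg$reactions
  for (i in seq_len(nrow(rx))) {
    subs <- rx$substrates[[i]]
    prods <- rx$products[[i]]
    if (length(subs) == 0 || length(prods) == 0) {
      errs <- c(errs, paste0("$reactions[", i, "] (", rx$reaction_id[i],
                             "): empty substrate or product side"))
    } else if (identical(sort(subs), sort(prods))) {
      errs <- c(errs, paste0("$reactions[", i, "] (", rx$reaction_id[i],
                             "): substrates equal products"))
    }
    missing <- setdiff(c(subs, prods), known)
    if (length(missing)) {
      errs <- c(errs, paste0("$reactions[", i, "] (", rx$reaction_id[i],
                             "): dangling reference to compound(s) ",
                             paste(missing, collapse = ", ")))
    }
  }
  for (j in seq_along(pkg$pathways)) {
    pw <- pkg$pathways[[j]]
    missing <- setdiff(pw$nodes$smiles, known)
    if (length(missing)) {
      errs <- c(errs, paste0("$pathways[", j, "] (", pw$id,
                             "): dangling reference to compound(s) ",
                             paste(missing, collapse = ", ")))
    }
  }
  if (length(errs)) {
    rlang::abort(c("invalid package", stats::setNames(errs, rep("x", length(errs)))),
                 class = "rulepath_validation_error")
  }
  invisible(pkg)
}

#' @export
print.bt_package <- function(x, ...) {
  cat("<bt_package> ", x$id, " (", x$name, ")\n", sep = "")
  s <- package_stats(x)
  cat("  compounds: ", s$compounds, ", reactions: ", s$reactions,
      ", pathways: ", s$pathways, ", rules: ", nrow(x$rules), "\n", sep = "")
  invisible(x)
}

#' Entity counts of a package
#'
#' @param pkg A [bt_package()].
#' @return A one-row tibble: `package`, `compounds`,
#'   `compounds_with_halflife` (compounds having a DT50 scenario),
#'   `reactions`, `pathways`.
#' @export
package_stats <- function(pkg) {
  stopifnot(inherits(pkg, "bt_package"))
  dt50 <- pkg$scenarios[pkg$scenarios$key == "DT50", ]
  tibble::tibble(
    package = pkg$id,
    compounds = nrow(pkg$compounds),
    compounds_with_halflife =
      length(intersect(unique(dt50$entity_id), pkg$compounds$compound_id)),
    reactions = nrow(pkg$reactions),
    pathways = length(pkg$pathways)
  )
}

# ---- JSON persistence ------------------------------------------------------

chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)
num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Save a package to JSON
#'
#' @param pkg A [bt_package()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_package()]
#' @export
save_package <- function(pkg, path) {
  stopifnot(inherits(pkg, "bt_package"))
  enc_pathway <- function(pw) {
    list(
      id = pw$id,
      roots = as.list(pw$roots),
      edges = purrr::pmap(pw$edges, function(reaction_id, substrate, product,
                                             rule_id, score) {
        list(reaction_id = reaction_id, substrate = substrate,
             product = product,
             rule_id = if (is.na(rule_id)) NULL else rule_id,
             score = if (is.na(score)) NULL else score)
      })
    )
  }
  doc <- list(
    schema_version = pkg$schema_version,
    id = pkg$id,
    name = pkg$name,
    compounds = purrr::pmap(pkg$compounds, function(compound_id, smiles,
                                                    display_smiles, name) {
      list(id = compound_id, smiles = smiles,
           display_smiles = display_smiles,
           name = if (is.na(name)) NULL else name)
    }),
    rules = purrr::pmap(
      pkg$rules[, c("rule_id", "name", "smirks")],
      function(rule_id, name, smirks) {
        list(id = rule_id, name = name, smirks = smirks)
      }),
    reactions = purrr::pmap(pkg$reactions, function(reaction_id, substrates,
                                                    products, rule_id, ec) {
      list(id = reaction_id,
           substrates = as.list(substrates),
           products = as.list(products),
           rule_id = if (is.na(rule_id)) NULL else rule_id,
           ec_numbers = as.list(ec))
    }),
    pathways = lapply(pkg$pathways, enc_pathway),
    scenarios = purrr::pmap(pkg$scenarios, function(scenario_id, entity_id,
                                                    key, value, unit) {
      list(id = scenario_id, entity_id = entity_id, key = key,
           value = value, unit = if (is.na(unit)) NULL else unit)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a package from JSON
#'
#' Reads a package written by [save_package()]; the round trip is
#' entity-wise lossless.  Schema violations, duplicate ids and dangling
#' references abort with a JSON-style path to the offending entry.
#'
#' @param path Path to a package JSON file.
#' @return A [bt_package()].
#' @export
load_package <- function(path) {
  doc <- jsonlite::read_json(path)
  need <- c("schema_version", "id", "name")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    rlang::abort(paste0("package JSON missing field(s): $",
                        paste(miss, collapse = ", $")),
                 class = "rulepath_validation_error")
  }
  if (doc$schema_version > PKG_SCHEMA_VERSION) {
    rlang::abort(paste0("unsupported schema_version ", doc$schema_version),
                 class = "rulepath_validation_error")
  }
  compounds <- purrr::map_dfr(doc$compounds, function(x) {
    tibble::tibble(compound_id = x$id, smiles = x$smiles,
                   display_smiles = chr_or_na(x$display_smiles),
                   name = chr_or_na(x$name))
  })
  if (nrow(compounds) == 0) compounds <- empty_compounds()
  rules <- purrr::map_dfr(doc$rules, function(x) {
    tibble::tibble(rule_id = x$id, name = chr_or_na(x$name),
                   smirks = x$smirks)
  })
  if (nrow(rules) == 0) rules <- empty_rules()
  reactions <- purrr::map_dfr(doc$reactions, function(x) {
    tibble::tibble(
      reaction_id = x$id,
      substrates = list(unlist(x$substrates, use.names = FALSE)),
      products = list(unlist(x$products, use.names = FALSE)),
      rule_id = chr_or_na(x$rule_id),
      ec = list(as.character(unlist(x$ec_numbers, use.names = FALSE)))
    )
  })
  if (nrow(reactions) == 0) reactions <- empty_reactions()
  pathways <- lapply(doc$pathways, function(x) {
    edges <- purrr::map_dfr(x$edges, function(e) {
      tibble::tibble(reaction_id = e$reaction_id, substrate = e$substrate,
                     product = e$product, rule_id = chr_or_na(e$rule_id),
                     score = num_or_na(e$score))
    })
    if (nrow(edges) == 0) {
      edges <- tibble::tibble(reaction_id = character(),
                              substrate = character(), product = character(),
                              rule_id = character(), score = numeric())
    }
    pathway(edges, roots = unlist(x$roots, use.names = FALSE), id = x$id)
  })
  scenarios <- purrr::map_dfr(doc$scenarios, function(x) {
    tibble::tibble(scenario_id = x$id, entity_id = x$entity_id,
                   key = x$key, value = as.character(x$value),
                   unit = chr_or_na(x$unit))
  })
  if (nrow(scenarios) == 0) scenarios <- empty_scenarios()
  bt_package(doc$id, doc$name, compounds = compounds, rules = rules,
             reactions = reactions, pathways = pathways,
             scenarios = scenarios)
}

# ---- Merging ---------------------------------------------------------------

reaction_signature <- function(substrates, products) {
  paste(paste(sort(substrates), collapse = "."),
        paste(sort(products), collapse = "."), sep = ">>")
}

pathway_signature <- function(pw) {
  paste(
    paste(sort(pw$roots), collapse = "."),
    paste(sort(paste(pw$edges$substrate, pw$edges$product, sep = ">")),
          collapse = ";"),
    sep = "|"
  )
}

#' Merge two packages
#'
#' Takes the entity union of `primary` and `incoming`.  Compounds are
#' deduplicated by canonical-structure key, rules by SMIRKS string,
#' reactions by (substrate multiset, product multiset) and pathways by
#' (root set, edge set).  On metadata conflicts the primary package's
#' values win and the conflict is reported as a message.
#'
#' @param primary,incoming Two valid [bt_package()] objects.
#' @param id Identifier for the merged package (default: primary's).
#' @return A merged [bt_package()].
#' @export
merge_packages <- function(primary, incoming, id = primary$id) {
  validate_package(primary)
  validate_package(incoming)

  # compounds: dedup by structure key
  comp <- primary$compounds
  for (i in seq_len(nrow(incoming$compounds))) {
    row <- incoming$compounds[i, ]
    if (row$smiles %in% comp$smiles) {
      kept <- comp[comp$smiles == row$smiles, ]
      if (!is.na(row$name) && !is.na(kept$name[1]) &&
          !identical(row$name, kept$name[1])) {
        message("merge: compound name conflict for ", row$smiles,
                "; keeping primary value '", kept$name[1], "'")
      }
    } else {
      if (row$compound_id %in% comp$compound_id) {
        row$compound_id <- paste0(row$compound_id, "@", incoming$id)
      }
      comp <- dplyr::bind_rows(comp, row)
    }
  }

  # rules: dedup by smirks
  rules <- primary$rules
  for (i in seq_len(nrow(incoming$rules))) {
    row <- incoming$rules[i, ]
    if (row$smirks %in% rules$smirks) next
    if (row$rule_id %in% rules$rule_id) row$rule_id <- paste0(row$rule_id, "@", incoming$id)
    rules <- dplyr::bind_rows(rules, row)
  }

  # reactions: dedup by substrate/product multisets
  rx <- primary$reactions
  sigs <- purrr::map2_chr(rx$substrates, rx$products, reaction_signature)
  for (i in seq_len(nrow(incoming$reactions))) {
    row <- incoming$reactions[i, ]
    sig <- reaction_signature(row$substrates[[1]], row$products[[1]])
    if (sig %in% sigs) {
      keep <- rx[sigs == sig, ]
      if (!is.na(row$rule_id) && !is.na(keep$rule_id[1]) &&
          !identical(row$rule_id, keep$rule_id[1])) {
        message("merge: reaction rule annotation conflict for ",
                row$reaction_id, "; keeping primary value")
      }
      next
    }
    if (row$reaction_id %in% rx$reaction_id) {
      row$reaction_id <- paste0(row$reaction_id, "@", incoming$id)
    }
    rx <- dplyr::bind_rows(rx, row)
    sigs <- c(sigs, sig)
  }

  # pathways: dedup by (root set, edge set)
  pws <- primary$pathways
  psigs <- vapply(pws, pathway_signature, character(1))
  for (pw in incoming$pathways) {
    sig <- pathway_signature(pw)
    if (sig %in% psigs) next
    if (pw$id %in% vapply(pws, `[[`, character(1), "id")) {
      pw$id <- paste0(pw$id, "@", incoming$id)
    }
    pws <- c(pws, list(pw))
    psigs <- c(psigs, sig)
  }

  # scenarios: union; primary wins per (entity_id, key)
  sc <- primary$scenarios
  for (i in seq_len(nrow(incoming$scenarios))) {
    row <- incoming$scenarios[i, ]
    clash <- sc[sc$entity_id == row$entity_id & sc$key == row$key, ]
    if (nrow(clash)) {
      if (!identical(clash$value[1], row$value)) {
        message("merge: scenario conflict for (", row$entity_id, ", ",
                row$key, "); keeping primary value")
      }
      next
    }
    if (row$scenario_id %in% sc$scenario_id) {
      row$scenario_id <- paste0(row$scenario_id, "@", incoming$id)
    }
    sc <- dplyr::bind_rows(sc, row)
  }

  bt_package(id, primary$name, compounds = comp, rules = rules,
             reactions = rx, pathways = pws, scenarios = sc)
}
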