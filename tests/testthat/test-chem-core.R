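test_that("canonicalization is idempotent and strips stereo", {
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  expect_identical(canonicalize_smiles("C[C@H](N)C(=O)O"),
                   canonicalize_smiles("CC(N)C(=O)O"))
  can <- canonicalize_smiles(c("c1ccccc1O", "N#Cc1ccc(Cl)cc1", "CC(=O)OC"))
  expect_identical(canonicalize_smiles(can), can)
  expect_error(canonicalize_smiles("not_a_smiles"),
               class = "rulepath_parse_error")
  expect_error(canonicalize_smiles(""), class = "rulepath_parse_error")
})

test_that("canonicalization is idempotent on generated corpus compounds", {
  cpds <- generate_compounds(fixture_config(seed = 7, n_compounds = 120))
  again <- canonicalize_smiles(cpds$smiles)
  expect_identical(again, cpds$smiles)
  expect_false(anyDuplicated(again) > 0)
})

test_that("every toy rule reproduces its documented example products", {
  rules <- toy_rules()
  expect_identical(nrow(rules), 12L)
  for (i in seq_len(nrow(rules))) {
    hits <- apply_rules(rules[i, ], rules$example_smiles[i])
    got <- sort(vapply(hits$products, paste, "", collapse = "."))
    want <- sort(strsplit(rules$example_products[i], "|", fixed = TRUE)[[1]])
    expect_identical(got, want, label = rules$rule_id[i])
  }
})

test_that("ester hydrolysis of ethyl acetate yields acetic acid + ethanol", {
  rules <- toy_rules()
  ester <- rules[rules$rule_id == "ester_hydrolysis", ]
  out <- apply_rules(ester, "CCOC(C)=O")
  expect_identical(nrow(out), 1L)
  expect_identical(out$products[[1]], c("CC(=O)O", "CCO"))
  # no ester in benzene
  expect_identical(nrow(apply_rules(ester, "c1ccccc1")), 0L)
})

test_that("symmetric match sites collapse to one product set", {
  rules <- toy_rules()
  hydrox <- rules[rules$rule_id == "aliphatic_hydroxylation", ]
  # propane has two equivalent terminal methyls
  out <- apply_rules(hydrox, "CCC")
  expect_identical(nrow(out), 1L)
  expect_identical(out$products[[1]], "CCCO")
})

test_that("rule application is invariant under substrate atom-order permutation", {
  rules <- toy_rules()
  spellings <- c("CCOC(C)=O", "O=C(C)OCC", "C(C)(=O)OCC")
  outs <- lapply(spellings, function(s) apply_rules(rules, s))
  for (o in outs[-1]) {
    expect_identical(o$rule_id, outs[[1]]$rule_id)
    expect_identical(o$products, outs[[1]]$products)
  }
})

test_that("triggered_rules reflects apply_rules and handles empty input", {
  rules <- toy_rules()
  trig <- triggered_rules(rules, "CCOC(C)=O")
  expect_true("ester_hydrolysis" %in% trig$rule_id)
  expect_identical(nrow(triggered_rules(rules[0, ], "CCO")), 0L)
  trig_benzene <- triggered_rules(rules[rules$rule_id == "ester_hydrolysis", ],
                                  "c1ccccc1")
  expect_identical(nrow(trig_benzene), 0L)
})

test_that("tanimoto has identity, disjoint and formula behaviour", {
  expect_identical(tanimoto("CCO", "OCC"), 1)
  expect_identical(tanimoto(c(1L, 2L), c(2L, 3L)), 1 / 3)
  expect_identical(tanimoto(integer(0), integer(0)), 1)
  expect_identical(tanimoto(c(1L, 2L), c(5L, 9L)), 0)
})

test_that("tanimoto is symmetric and bounded on corpus pairs", {
  cpds <- generate_compounds(fixture_config(seed = 7, n_compounds = 30))
  fps <- rulepath:::chem_fingerprints(cpds$smiles)
  set.seed(1)
  for (rep in 1:50) {
    ij <- sample(length(fps), 2)
    s1 <- tanimoto(fps[[ij[1]]], fps[[ij[2]]])
    s2 <- tanimoto(fps[[ij[2]]], fps[[ij[1]]])
    expect_identical(s1, s2)
    expect_gte(s1, 0)
    expect_lte(s1, 1)
  }
})

test_that("functional-group detection finds hetero groups only", {
  expect_identical(nrow(find_functional_groups("CC")), 0L)
  eth <- find_functional_groups("CCO")
  expect_true("hydroxyl" %in% eth$group_id)
  atenolol <- "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1"
  hits <- find_functional_groups(atenolol)
  expect_true(all(c("amide", "ether") %in% hits$group_id))
  # every library pattern names a hetero atom
  lib <- fg_library()
  expect_gte(nrow(lib), 20L)
  expect_true(all(grepl("[NOSP]|F|Cl|Br|I", lib$smarts)))
})

test_that("reported functional-group atom indices are valid positions", {
  hits <- find_functional_groups("CC(C)NCC(O)COc1ccc(CC(N)=O)cc1")
  n_atoms <- 21  # heavy atoms in the query
  for (ix in hits$atom_indices) {
    expect_true(all(ix >= 0 & ix < n_atoms))
  }
})

test_that("rules files are validated on read", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("rule_id\tname\tsmirks", "r1\tbroken\tCCO"), bad)
  expect_error(read_rules(bad), "not a reaction SMIRKS")
  two_reactants <- tempfile(fileext = ".tsv")
  writeLines(c("rule_id\tname\tsmirks",
               "r1\ttwo\t[C:1].[O:2]>>[C:1][O:2]"), two_reactants)
  expect_error(read_rules(two_reactants), "more than one reactant")
  unlink(c(bad, two_reactants))
})
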