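toy_package <- function() {
  compounds <- tibble::tibble(
    compound_id = c("c1", "c2", "c3"),
    smiles = c("CCOC(C)=O", "CC(=O)O", "CCO"),
    display_smiles = c("CCOC(C)=O", "CC(=O)O", "OCC"),
    name = c("ethyl acetate", "acetic acid", NA)
  )
  reactions <- tibble::tibble(
    reaction_id = "r1",
    substrates = list("CCOC(C)=O"),
    products = list(c("CC(=O)O", "CCO")),
    rule_id = "ester_hydrolysis",
    ec = list("3.1.1.1")
  )
  pw <- pathway(
    tibble::tibble(reaction_id = c("r1", "r1"),
                   substrate = c("CCOC(C)=O", "CCOC(C)=O"),
                   product = c("CC(=O)O", "CCO"),
                   rule_id = "ester_hydrolysis", score = c(0.9, 0.9)),
    roots = "CCOC(C)=O", id = "pw1"
  )
  scen <- tibble::tibble(scenario_id = "s1", entity_id = "c1", key = "DT50",
                         value = "12.5", unit = "days")
  bt_package("toy", "toy package", compounds = compounds,
             rules = toy_rules()[1, 1:3], reactions = reactions,
             pathways = list(pw), scenarios = scen)
}

test_that("package JSON round trip is entity-wise lossless", {
  pkg <- toy_package()
  f <- withr::local_tempfile(fileext = ".json")
  save_package(pkg, f)
  back <- load_package(f)
  expect_identical(back$id, pkg$id)
  expect_identical(back$compounds, pkg$compounds)
  expect_identical(back$rules$smirks, pkg$rules$smirks)
  expect_identical(back$reactions$substrates, pkg$reactions$substrates)
  expect_identical(back$reactions$products, pkg$reactions$products)
  expect_identical(back$scenarios, pkg$scenarios)
  expect_identical(length(back$pathways), 1L)
  expect_identical(back$pathways[[1]]$nodes, pkg$pathways[[1]]$nodes)
  expect_identical(back$pathways[[1]]$edges, pkg$pathways[[1]]$edges)
})

test_that("round trip preserves a generated fixture package", {
  pkg <- small_pkg()
  f <- withr::local_tempfile(fileext = ".json")
  save_package(pkg, f)
  back <- load_package(f)
  expect_identical(package_stats(back)[-1], package_stats(pkg)[-1])
  expect_identical(
    sort(vapply(back$pathways, `[[`, "", "id")),
    sort(vapply(pkg$pathways, `[[`, "", "id"))
  )
  i <- which.max(vapply(pkg$pathways, function(p) nrow(p$edges), 1L))
  expect_identical(back$pathways[[i]]$edges, pkg$pathways[[i]]$edges)
})

test_that("empty packages load and validate", {
  pkg <- bt_package("empty", "nothing here")
  f <- withr::local_tempfile(fileext = ".json")
  save_package(pkg, f)
  back <- load_package(f)
  expect_identical(nrow(back$compounds), 0L)
  expect_identical(length(back$pathways), 0L)
})

test_that("dangling references and duplicate ids are rejected", {
  pkg <- toy_package()
  pkg$reactions$products[[1]] <- c("CC(=O)O", "c1ccccc1")  # unknown compound
  expect_error(validate_package(pkg), class = "rulepath_validation_error")
  expect_error(validate_package(pkg), "dangling")
  pkg2 <- toy_package()
  pkg2$compounds$compound_id[2] <- "c1"
  expect_error(validate_package(pkg2), "duplicate")
  pkg3 <- toy_package()
  pkg3$reactions$substrates[[1]] <- character(0)
  expect_error(validate_package(pkg3), "empty substrate")
})

test_that("merge is idempotent and identity on the empty package", {
  pkg <- toy_package()
  m <- merge_packages(pkg, pkg)
  expect_identical(package_stats(m)[-1], package_stats(pkg)[-1])
  empty <- bt_package("empty")
  m2 <- merge_packages(pkg, empty)
  expect_identical(package_stats(m2)[-1], package_stats(pkg)[-1])
})

test_that("merge deduplicates alternative SMILES spellings via canonical keys", {
  a <- bt_package("a", compounds = tibble::tibble(
    compound_id = "x1", smiles = canonicalize_smiles("CCO"),
    display_smiles = "CCO", name = "ethanol"
  ))
  b <- bt_package("b", compounds = tibble::tibble(
    compound_id = "y1", smiles = canonicalize_smiles("OCC"),
    display_smiles = "OCC", name = "ethanol (alt)"
  ))
  m <- suppressMessages(merge_packages(a, b))
  expect_identical(nrow(m$compounds), 1L)
  expect_identical(m$compounds$name, "ethanol")   # primary wins
  expect_message(merge_packages(a, b), "conflict")
})

test_that("merge unions disjoint entities and resolves id collisions", {
  a <- toy_package()
  b <- bt_package("b", compounds = tibble::tibble(
    compound_id = "c1",   # id collides with a different structure in `a`
    smiles = canonicalize_smiles("c1ccccc1"),
    display_smiles = "c1ccccc1", name = "benzene"
  ))
  m <- merge_packages(a, b)
  expect_identical(nrow(m$compounds), 4L)
  expect_identical(anyDuplicated(m$compounds$compound_id), 0L)
})

test_that("package stats mirror entity counts including half-lives", {
  s <- package_stats(toy_package())
  expect_identical(s$compounds, 3L)
  expect_identical(s$compounds_with_halflife, 1L)
  expect_identical(s$reactions, 1L)
  expect_identical(s$pathways, 1L)
})
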