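write_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("id\tequation\treversible\texchange\tbiomass\tproduct", lines), f)
  f
}

test_that("TSV reactions parse with coefficients, reversibility and flags", {
  f <- write_tsv(c("r1\tA -> B\t0\t0\t1\t0"))
  net <- suppressWarnings(read_network(f))  # dead ends are expected here
  expect_s3_class(net, "flux_network")
  expect_equal(nrow(net$S), 2L)
  expect_equal(ncol(net$S), 1L)
  expect_false(net$reactions[[1]]$reversible)
  expect_equal(net$S[, 1], c(A = -1, B = 1))

  f2 <- write_tsv(c("r1\tA -> B\t0\t0\t1\t0", "r2\tA <-> B\t0\t0\t0\t0"))
  net2 <- suppressWarnings(read_network(f2))
  expect_true(net2$reactions[[2]]$reversible)

  f3 <- write_tsv(c("r1\t2 A + 0.5 B -> 3 C\t0\t0\t1\t0"))
  net3 <- suppressWarnings(read_network(f3))
  expect_equal(net3$S[, 1], c(A = -2, B = -0.5, C = 3))
})

test_that("boundary equations give single-metabolite exchange columns", {
  f <- write_tsv(c("EX_a\ta ->\t1\t1\t0\t0", "bio\ta ->\t0\t0\t1\t0"))
  net <- read_network(f)
  expect_equal(unname(exchange_map(net)), "EX_a")
  expect_equal(net$S["a", "EX_a"], -1)
})

test_that("malformed files fail with informative errors", {
  expect_error(read_network(write_tsv(c("r1\tA + -> B\t0\t0\t1\t0"))),
               "line 2")
  expect_error(read_network(write_tsv(c("r1\tA -> B\t0\t0\t1\t0",
                                        "r1\tB -> A\t0\t0\t0\t0"))),
               "duplicate reaction id")
  expect_error(read_network(write_tsv(c("r1\tA -> B\t0\t0\t0\t0"))),
               "biomass")
  expect_error(read_network("/nonexistent/net.tsv"), "not found")
})

test_that("shipped fixture network has the documented shape and is clean", {
  d <- withr::local_tempdir()
  paths <- write_fixture_bundle(d)
  net <- read_network(paths[["network"]])
  expect_equal(nrow(net$S), 11L)   # metabolites
  expect_equal(ncol(net$S), 14L)   # reactions
  expect_equal(sum(vapply(net$reactions, `[[`, NA, "is_biomass")), 1L)
  expect_identical(validate_network(net), character(0))
  # file round-trip preserves the in-code network (metabolites may be
  # reordered to file-appearance order)
  tn <- toy_network()
  expect_setequal(rownames(net$S), rownames(tn$S))
  expect_equal(net$S[rownames(tn$S), colnames(tn$S)], tn$S)
})

test_that("validate_network reports orphans, dead ends and duplicate exchanges", {
  mets <- data.frame(id = c("A", "B", "X"), name = c("A", "B", "X"),
                     extracellular = c(TRUE, FALSE, FALSE))
  rxns <- list(
    list(id = "EX_a", stoichiometry = c(A = -1), reversible = TRUE,
         is_exchange = TRUE),
    list(id = "r", stoichiometry = c(A = -1, B = 1), is_biomass = TRUE))
  net <- flux_network(mets, rxns)
  f <- validate_network(net)
  expect_true(any(grepl("orphan metabolite 'X'", f)))
  expect_true(any(grepl("dead-end metabolite 'B'", f)))

  rxns2 <- c(rxns, list(list(id = "EX_a2", stoichiometry = c(A = -1),
                             reversible = TRUE, is_exchange = TRUE)))
  net2 <- flux_network(mets, rxns2)
  expect_true(any(grepl("duplicate exchange", validate_network(net2))))
})

test_that("SBML reader agrees with the TSV reader on the fixture network", {
  net <- toy_network()
  sbml <- withr::local_tempfile(fileext = ".xml")
  # write a minimal SBML L3 + fbc document for the toy network
  sp <- paste(sprintf('      <species id="%s" name="%s" compartment="c" boundaryCondition="false"/>',
                      net$metabolites$id, net$metabolites$name),
              collapse = "\n")
  rx <- vapply(net$reactions, function(r) {
    refs <- function(sel) paste(sprintf(
      '          <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
      names(r$stoichiometry)[sel], abs(r$stoichiometry[sel])), collapse = "\n")
    paste0('      <reaction id="', r$id, '" reversible="',
           tolower(r$reversible), '">\n',
           if (any(r$stoichiometry < 0))
             paste0("        <listOfReactants>\n", refs(r$stoichiometry < 0),
                    "\n        </listOfReactants>\n") else "",
           if (any(r$stoichiometry > 0))
             paste0("        <listOfProducts>\n", refs(r$stoichiometry > 0),
                    "\n        </listOfProducts>\n") else "",
           "      </reaction>")
  }, "")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">',
    '  <model id="toy">',
    '    <listOfSpecies>', sp, '    </listOfSpecies>',
    '    <listOfReactions>', rx, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj1">',
    '      <fbc:objective fbc:id="obj1" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    '          <fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>',
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>'), sbml)
  net2 <- read_network(sbml, format = "sbml")
  expect_equal(dim(net2$S), dim(net$S))
  expect_equal(net2$S[rownames(net$S), colnames(net$S)], net$S)
  expect_equal(vapply(net2$reactions, `[[`, NA, "reversible"),
               vapply(net$reactions, `[[`, NA, "reversible"))
  ids2 <- vapply(net2$reactions, `[[`, "", "id")
  expect_true(net2$reactions[[which(ids2 == "GROWTH")]]$is_biomass)
  # and the FBA optimum is identical through either reader
  b <- toy_stage_bounds()[[1]]
  expect_equal(solve_fba(net2, b)$objective, solve_fba(net, b)$objective,
               tolerance = 1e-10)
})
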