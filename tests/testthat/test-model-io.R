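test_that("the reaction dialect parses coefficients, arrows and external species", {
  net <- parse_scrumpy("R1: A + 2 B -> C")
  expect_length(net$reactions, 1L)
  st <- net$reactions$R1$stoich
  expect_equal(st[c("A", "B", "C")], c(A = -1, B = -2, C = 1))
  expect_false(net$reactions$R1$reversible)

  net2 <- parse_scrumpy("T1: x_CO2 <> CO2")
  expect_true(net2$reactions$T1$reversible)
  expect_true("transporter" %in% net2$reactions$T1$tags)
  mets <- net2$metabolites
  expect_true(mets$is_external[mets$id == "x_CO2"])
  expect_false(mets$is_external[mets$id == "CO2"])

  # rational coefficients and empty product side
  net3 <- parse_scrumpy(c("R: 1/3 A -> B", "sink: B ->"))
  expect_equal(net3$reactions$R$stoich[["A"]], -1 / 3)
  expect_equal(net3$reactions$sink$stoich, c(B = -1))
})

test_that("malformed models are rejected with the offending line", {
  expect_error(parse_scrumpy(c("R1: A -> B", "R1: B -> C")), "duplicate")
  expect_error(parse_scrumpy("R1: A -> A"), "cancels")
  expect_error(parse_scrumpy(c("ok: A -> B", "no arrow here")), "line 2")
  expect_error(parse_scrumpy("R1: -2 A -> B"), "line 1")
})

test_that("serialize/parse round trip preserves stoichiometry, reversibility and tags", {
  nets <- c(list(build_core_leaf_model()$net),
            lapply(1:5, function(s) random_branched_network(s, 6L)$net))
  for (net in nets) {
    rt <- parse_scrumpy(serialize_scrumpy(net))
    expect_setequal(names(rt$reactions), names(net$reactions))
    for (id in names(net$reactions)) {
      a <- net$reactions[[id]]
      b <- rt$reactions[[id]]
      expect_setequal(names(a$stoich), names(b$stoich))
      expect_equal(b$stoich[names(a$stoich)], a$stoich)
      expect_identical(b$reversible, a$reversible)
      expect_setequal(b$tags, a$tags)
    }
  }
})

test_that("the stoichiometry matrix has one balance row per internal metabolite", {
  N1 <- stoichiometric_matrix(parse_scrumpy("R: A -> B"))
  expect_equal(sort(rownames(N1)), c("A", "B"))
  expect_equal(unname(N1[c("A", "B"), 1]), c(-1, 1))

  # external species carry no balance row
  N2 <- stoichiometric_matrix(parse_scrumpy("T: x_A -> A"))
  expect_equal(rownames(N2), "A")
  expect_equal(unname(N2["A", 1]), 1)

  # round trip: columns re-sum to each reaction's stoichiometry map
  for (seed in 1:5) {
    net <- random_branched_network(seed, 8L)$net
    N <- stoichiometric_matrix(net)
    expect_true(all(colSums(N != 0) >= 1))
    for (id in names(net$reactions)) {
      st <- net$reactions[[id]]$stoich
      st <- st[!startsWith(names(st), "x_")]
      expect_equal(unname(N[names(st), id]), unname(st))
    }
  }
})

test_that("SBML level 3 models load with boundary species and reversibility", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="toy">',
    '<listOfCompartments><compartment id="cyt" constant="true"/>',
    '<compartment id="ext" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="S" compartment="ext" boundaryCondition="true" constant="false"/>',
    '<species id="A" compartment="cyt" boundaryCondition="false" constant="false"/>',
    '<species id="B" compartment="cyt" boundaryCondition="false" constant="false"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="up" reversible="false">',
    '<listOfReactants><speciesReference species="S" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '<reaction id="conv" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="2" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions></model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  net <- load_model(path, format = "sbml")
  expect_setequal(names(net$reactions), c("up", "conv"))
  expect_true(net$metabolites$is_external[net$metabolites$id == "x_S"])
  expect_true("transporter" %in% net$reactions$up$tags)
  expect_false(net$reactions$up$reversible)
  expect_true(net$reactions$conv$reversible)
  expect_equal(net$reactions$conv$stoich[["A_cyt"]], -2)
})

test_that("flux capability excludes dead branches and is invariant to reformulation", {
  chain <- parse_scrumpy(c("tin: x_A -> A", "conv: A -> B",
                           "tout: B -> x_B", "dead: B -> C"))
  cap <- flux_capable_reactions(chain, "tin", "tout")
  expect_setequal(cap, c("tin", "conv", "tout"))

  # invariant under reaction reordering
  shuffled <- parse_scrumpy(c("dead: B -> C", "tout: B -> x_B",
                              "tin: x_A -> A", "conv: A -> B"))
  expect_setequal(flux_capable_reactions(shuffled, "tin", "tout"), cap)

  # splitting a reversible reaction maps the pair to the same capability
  revnet <- parse_scrumpy(c("tin: x_A -> A", "conv: A <> B",
                            "tout: B -> x_B"))
  splitnet <- parse_scrumpy(c("tin: x_A -> A", "conv_f: A -> B",
                              "conv_b: B -> A", "tout: B -> x_B"))
  expect_true("conv" %in% flux_capable_reactions(revnet, "tin", "tout"))
  cap_split <- flux_capable_reactions(splitnet, "tin", "tout")
  expect_true("conv_f" %in% cap_split)
})

test_that("every reaction of the default core-leaf model can carry flux", {
  cf <- core_fixture()
  cap <- flux_capable_reactions(
    cf$net,
    nutrients = c("photon_tx", "co2_tx", "o2_tx", "h2o_tx", "nh3_tx",
                  "no3_tx"),
    outputs = c("starch_out", "suc_out", "aa_out"))
  expect_setequal(cap, names(cf$net$reactions))
})
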