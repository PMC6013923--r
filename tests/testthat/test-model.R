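test_that("model construction enforces structural invariants", {
  expect_error(metabolite("glc__D_u", compartment = "c"),
               "does not end in compartment tag")
  expect_error(metabolite("foo_x"), "unknown compartment")
  expect_error(reaction("R", c(A_c = 0)), "zero stoichiometric")
  expect_error(reaction("R", c(A_c = -1), lower_bound = 2, upper_bound = 1),
               "lower_bound exceeds upper_bound")
  expect_error(
    metabolic_model(list(metabolite("A_c")),
                    list(reaction("R", c(A_c = -1, B_c = 1))),
                    objective_reaction = NULL),
    "undeclared metabolite")
  expect_error(
    metabolic_model(list(metabolite("A_c"), metabolite("A_c")),
                    list(reaction("R", c(A_c = -1))), NULL),
    "duplicated metabolite ids")
  expect_error(
    metabolic_model(list(metabolite("A_c")),
                    list(reaction("EX", c(A_c = -1))),
                    objective_reaction = "nope"),
    "objective reaction")
})

test_that("genes are the union of gene-rule symbols", {
  m <- metabolic_model(
    list(metabolite("A_c"), metabolite("B_c")),
    list(reaction("R1", c(A_c = -1, B_c = 1), gene_rule = "g1 and (g2 or g3)"),
         reaction("EX_A_c", c(A_c = -1), gene_rule = "g1")),
    objective_reaction = NULL)
  expect_setequal(m$genes, c("g1", "g2", "g3"))
})

test_that("stoichiometric matrix lays out coefficients metabolite x reaction", {
  m <- chain_model()
  S <- stoichiometric_matrix(m, sparse = FALSE)
  expect_identical(dim(S), c(2L, 3L))
  expect_equal(S[, "R1"], c(A_c = -1, B_c = 1))
  # exchange column has a single nonzero entry
  expect_equal(sum(S[, "EX_A_c"] != 0), 1)
  expect_equal(S["A_c", "EX_A_c"], -1)
  # sparse and dense agree
  expect_equal(as.matrix(stoichiometric_matrix(m, sparse = TRUE)),
               S, ignore_attr = TRUE)
})

test_that("dead-end detection respects reversibility and matches brute force", {
  # irreversible A -> B with only an A exchange: B is a dead end
  m <- metabolic_model(
    list(metabolite("A_c"), metabolite("B_c")),
    list(reaction("EX_A_c", c(A_c = -1), lower_bound = -1),
         reaction("R1", c(A_c = -1, B_c = 1), lower_bound = 0)),
    objective_reaction = NULL)
  expect_identical(find_dead_end_metabolites(m), "B_c")
  # a reversible reaction counts as producer and consumer of every
  # participant, so making R1 reversible clears the topological dead end
  m2 <- set_bounds(m, "R1", lower = -10)
  expect_length(find_dead_end_metabolites(m2), 0)

  for (seed in 1:20) {
    rm <- random_small_model(seed)
    expect_setequal(find_dead_end_metabolites(rm), dead_ends_bruteforce(rm))
  }
})

test_that("deleting the fixture's CO2 exchange creates a CO2 dead end", {
  m <- build_fixture_model()
  expect_length(find_dead_end_metabolites(m), 0)
  m2 <- remove_reactions(m, "EX_co2_u")
  expect_true("co2_u" %in% find_dead_end_metabolites(m2))
})

test_that("reaction classification partitions every model", {
  m <- build_fixture_model()
  cls <- classify_reactions(m)
  expect_equal(sum(cls$counts), length(m$reactions))
  expect_identical(unname(cls$assignment[["EX_glc__D_u"]]), "exchange")
  expect_identical(unname(cls$assignment[["GLCt1"]]), "transport")
  expect_identical(unname(cls$assignment[["PDHm"]]), "mitochondrial")
  expect_identical(unname(cls$assignment[["GLYCL"]]), "cytosolic")
  expect_identical(unname(cls$assignment[["LIPH160"]]), "luminal")

  for (seed in 21:35) {
    rm <- random_small_model(seed)
    cc <- classify_reactions(rm)
    expect_equal(sum(cc$counts), length(rm$reactions))
    expect_true(all(cc$assignment %in% names(cc$counts)))
  }
})

test_that("set_bounds and remove_reactions keep the model consistent", {
  m <- chain_model()
  m2 <- set_bounds(m, "EX_A_c", lower = -5)
  expect_equal(unname(lower_bounds(m2)[["EX_A_c"]]), -5)
  expect_error(set_bounds(m, "EX_A_c", lower = 2, upper = 1),
               "exceeds upper_bound")
  expect_error(set_bounds(m, "nope", lower = 0), "no reaction")
  m3 <- remove_reactions(m, "EX_B_c", prune_metabolites = FALSE)
  expect_false("EX_B_c" %in% reaction_ids(m3))
  expect_null(m3$objective_reaction)
})
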