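toy <- make_toy_model()

test_that("model validation catches structural defects", {
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = "a_c", compartment = "c"),
      reactions = tibble::tibble(id = "R1"),
      stoichiometry = tibble::tibble(reaction_id = "R1",
                                     metabolite_id = "ghost",
                                     coefficient = -1)),
    "undeclared metabolites")
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = "a_q", compartment = "q"),
      reactions = tibble::tibble(id = "R1"),
      stoichiometry = tibble::tibble(reaction_id = "R1",
                                     metabolite_id = "a_q",
                                     coefficient = -1)),
    "unknown compartments")
  expect_error(
    metabolic_model(
      metabolites = tibble::tibble(id = "a_c", compartment = "c"),
      reactions = tibble::tibble(id = "R1", lower_bound = 5, upper_bound = 1),
      stoichiometry = tibble::tibble(reaction_id = "R1",
                                     metabolite_id = "a_c",
                                     coefficient = -1)),
    "lower_bound > upper_bound")
})

test_that("reaction equations parse arrows, coefficients and compartments", {
  p <- parse_reaction_equation("glc__D[e] -> glc__D[c]")
  expect_false(p$reversible)
  expect_equal(p$stoichiometry,
               c(glc__D_c = 1, glc__D_e = -1)[names(p$stoichiometry)])
  p2 <- parse_reaction_equation("a[c] <=> b[c]")
  expect_true(p2$reversible)
  p3 <- parse_reaction_equation("2 a[c] + 0.5 b[m] -> c[x]")
  expect_equal(unname(p3$stoichiometry[c("a_c", "b_m", "c_x")]),
               c(-2, -0.5, 1))
  expect_equal(unname(p3$compartments[c("a_c", "b_m", "c_x")]),
               c("c", "m", "x"))
  p4 <- parse_reaction_equation("glc__D[e] ->")   # boundary
  expect_equal(p4$stoichiometry, c(glc__D_e = -1))
  expect_error(parse_reaction_equation("a[c] b[c]"), "malformed|arrow")
  expect_error(parse_reaction_equation("a[c] -> b"), "malformed")
})

test_that("SBML round trip preserves stoichiometry, bounds and GPR truth tables", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy, path)
  back <- read_sbml(path)
  S1 <- stoichiometric_matrix(toy)
  S2 <- stoichiometric_matrix(back)
  expect_setequal(rownames(S2), rownames(S1))
  expect_setequal(colnames(S2), colnames(S1))
  expect_equal(max(abs(S1 - S2[rownames(S1), colnames(S1)])), 0)
  ord <- match(toy$reactions$id, back$reactions$id)
  expect_equal(back$reactions$lower_bound[ord], toy$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound[ord], toy$reactions$upper_bound)
  expect_setequal(back$genes, toy$genes)
  expect_identical(back$objective, toy$objective)
  mo <- match(toy$metabolites$id, back$metabolites$id)
  expect_identical(back$metabolites$formula[mo], toy$metabolites$formula)
  # GPR truth tables survive even if the string is re-rendered
  for (i in which(!is.na(toy$reactions$gpr))) {
    rule_a <- toy$reactions$gpr[i]
    rule_b <- back$reactions$gpr[ord][i]
    genes <- gpr_genes(rule_a)
    for (mask in 0:(2^length(genes) - 1)) {
      present <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
      expect_identical(evaluate_gpr(rule_a, present),
                       evaluate_gpr(rule_b, present))
    }
  }
})

test_that("a minimal hand-written SBML file reads and re-reads identically", {
  path <- withr::local_tempfile(fileext = ".xml")
  m <- metabolic_model(
    metabolites = tibble::tibble(id = c("a_e", "a_c"),
                                 compartment = c("e", "c"),
                                 formula = c("C2H4", "C2H4")),
    reactions = tibble::tibble(id = c("EX_a_e", "At"),
                               lower_bound = c(-7.5, 0)),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_a_e", "At", "At"),
      metabolite_id = c("a_e", "a_e", "a_c"),
      coefficient = c(-1, -1, 1)),
    id = "mini")
  write_sbml(m, path)
  again <- read_sbml(path)
  expect_equal(stoichiometric_matrix(again)[c("a_e", "a_c"), c("EX_a_e", "At")],
               stoichiometric_matrix(m))
  expect_equal(again$reactions$lower_bound, m$reactions$lower_bound)
})

test_that("tabular dialect round trip equals the SBML twin", {
  dir <- withr::local_tempdir()
  write_tabular_model(toy, dir)
  back <- read_tabular_model(dir)
  S1 <- stoichiometric_matrix(toy)
  S2 <- stoichiometric_matrix(back)
  expect_equal(max(abs(S1 - S2[rownames(S1), colnames(S1)])), 0,
               tolerance = 1e-12)
  expect_identical(back$objective, toy$objective)
  expect_setequal(back$genes, toy$genes)
  # and matches what came through SBML
  sb <- withr::local_tempfile(fileext = ".xml")
  write_sbml(toy, sb)
  via_sbml <- read_sbml(sb)
  S3 <- stoichiometric_matrix(via_sbml)
  expect_equal(max(abs(S2[rownames(S1), colnames(S1)] -
                         S3[rownames(S1), colnames(S1)])), 0,
               tolerance = 1e-12)
})

test_that("malformed tabular rows report the offending row", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(id = c("R1", "R2"),
                                  equation = c("a[c] -> b[c]", "a[c] >> b[c]")),
                   file.path(dir, "reactions.csv"))
  expect_error(read_tabular_model(dir), "row 2")
})

test_that("model statistics match hand counts on the toy network", {
  stats <- model_statistics(toy)
  expect_equal(stats$totals$reactions, nrow(toy$reactions))
  expect_equal(stats$totals$genes, length(toy$genes))
  # hand count: cytosolic reactions = all reactions with a cytosolic
  # participant, transport included
  sto <- dplyr::left_join(toy$stoichiometry,
                          toy$metabolites[, c("id", "compartment")],
                          by = c(metabolite_id = "id"))
  cyt <- length(unique(sto$reaction_id[sto$compartment == "c"]))
  expect_equal(stats$by_compartment$reactions[
    stats$by_compartment$compartment == "c"], cyt)
  # metabolite counts partition the total (each lives in one compartment)
  expect_equal(sum(stats$by_compartment$metabolites), stats$totals$metabolites)
  # decoy appendages put two transporters on the c<->x boundary
  expect_equal(stats$transporters$transporters[stats$transporters$pair == "c<->x"], 2)
  expect_equal(stats$exchange_reactions, sum(is_exchange(toy)))
})

test_that("statistics of an empty model are all zero", {
  empty <- structure(list(
    metabolites = tibble::tibble(id = character(), name = character(),
                                 compartment = character(),
                                 formula = character(), charge = integer()),
    reactions = tibble::tibble(id = character(), name = character(),
                               lower_bound = numeric(), upper_bound = numeric(),
                               subsystem = character(), gpr = character()),
    stoichiometry = tibble::tibble(reaction_id = character(),
                                   metabolite_id = character(),
                                   coefficient = numeric()),
    genes = character(), objective = NULL, id = "empty"),
    class = "metabolic_model")
  stats <- model_statistics(empty)
  expect_equal(stats$totals$reactions, 0L)
  expect_equal(stats$totals$metabolites, 0L)
  expect_equal(sum(stats$by_compartment$reactions), 0L)
  expect_equal(stats$enzyme_complexes, 0L)
})

test_that("toy model with hand-built transport/cytosol mix counts correctly", {
  m <- metabolic_model(
    metabolites = tibble::tibble(id = c("a_e", "a_c", "b_c", "c_c", "d_c"),
                                 compartment = c("e", "c", "c", "c", "c")),
    reactions = tibble::tibble(id = c("T1", "T2", "R1", "R2", "R3"),
                               lower_bound = 0),
    stoichiometry = tibble::tibble(
      reaction_id = c("T1", "T1", "T2", "T2", "R1", "R1", "R2", "R2", "R3", "R3"),
      metabolite_id = c("a_e", "a_c", "a_e", "b_c",
                        "a_c", "b_c", "b_c", "c_c", "c_c", "d_c"),
      coefficient = c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1)))
  stats <- model_statistics(m)
  # 2 transport + 3 cytosolic-only reactions all touch the cytosol
  expect_equal(stats$by_compartment$reactions[
    stats$by_compartment$compartment == "c"], 5L)
  expect_equal(stats$by_compartment$reactions[
    stats$by_compartment$compartment == "e"], 2L)
})
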