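toy <- make_toy_model()

# closed-form growth optimum of the toy network, derived by hand from the
# lumped stoichiometry: precursor demand, ATP budget (2 ATP/glc glycolytic,
# 14 ATP/pyruvate respiratory) and the glucose split between anabolism and
# energy. Independent of the LP solver.
hand_toy_mu <- function(glc_uptake, xyl_uptake = 0, ngam = 0, gam = 30) {
  prec <- (0.1424 + 0.48) / 0.1621 + 2 * (0.11 / 0.4043) +
    (0.0028 + 0.00604) / 0.2421
  atp_per_mu <- prec + 0.11 / 0.4043 + (0.0028 + 0.00604) / 0.2421 + gam
  glc_total <- glc_uptake + 5 / 6 * xyl_uptake
  # glc = prec*mu + (atp_per_mu*mu + ngam)/30
  (30 * glc_total - ngam) / (30 * prec + atp_per_mu)
}

test_that("FBA growth equals the hand-derived optimal yield", {
  sol <- fba(toy)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, hand_toy_mu(10, 10), tolerance = 1e-8)
  # glucose-only growth
  glc_only <- set_medium(toy, c(stats::setNames(10, "EX_glc__D_e"),
                                stats::setNames(rep(1000, 4), toy_base_medium())))
  expect_equal(fba(glc_only)$objective_value, hand_toy_mu(10),
               tolerance = 1e-8)
  # with maintenance switched on
  ngam_model <- set_bounds(glc_only, "ATPM", lower_bound = 1.9)
  expect_equal(fba(ngam_model)$objective_value, hand_toy_mu(10, ngam = 1.9),
               tolerance = 1e-8)
})

test_that("optimal solutions satisfy steady state and bounds", {
  for (m in list(toy, make_toy_model(toy_spec(include_xylose_path = FALSE)))) {
    sol <- fba(m)
    S <- stoichiometric_matrix(m)
    v <- sol$fluxes$flux[match(colnames(S), sol$fluxes$reaction)]
    expect_lt(max(abs(S %*% v)), 1e-6)
    expect_true(all(v >= m$reactions$lower_bound - 1e-9))
    expect_true(all(v <= m$reactions$upper_bound + 1e-9))
  }
})

test_that("closing all exchanges or asking for unreachable products gives zero", {
  closed <- set_medium(toy, character())
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-9)
  # maximise citrate export with no carbon source
  expect_equal(fba(closed, objective = "EX_cit_e")$objective_value, 0,
               tolerance = 1e-9)
})

test_that("flux ranges collapse on a chain and split across isozyme routes", {
  # linear chain at fraction 1: every reaction pinned
  lin <- metabolic_model(
    metabolites = tibble::tibble(id = c("a_e", "a_c", "b_c", "b_e"),
                                 compartment = c("e", "c", "c", "e")),
    reactions = tibble::tibble(id = c("EX_a_e", "At", "AB", "Bt", "EX_b_e"),
                               lower_bound = c(-4, 0, 0, 0, 0)),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_a_e", "At", "At", "AB", "AB", "Bt", "Bt", "EX_b_e"),
      metabolite_id = c("a_e", "a_e", "a_c", "a_c", "b_c", "b_c", "b_e", "b_e"),
      coefficient = c(-1, -1, 1, -1, 1, -1, 1, -1)),
    objective = "EX_b_e")
  fva <- flux_variability(lin, fraction_of_optimum = 1)
  expect_equal(fva$min_flux, fva$max_flux, tolerance = 1e-8)
  expect_equal(fva$max_flux[fva$reaction == "AB"], 4, tolerance = 1e-8)

  # two parallel routes: individual ranges [0, total], sum fixed
  par2 <- add_reaction(lin, "AB2", c(a_c = -1, b_c = 1))
  fva2 <- flux_variability(par2, reactions = c("AB", "AB2"),
                           fraction_of_optimum = 1)
  expect_equal(fva2$min_flux, c(0, 0), tolerance = 1e-8)
  expect_equal(fva2$max_flux, c(4, 4), tolerance = 1e-8)

  # a reaction feeding a dead end has range {0} even at fraction 0
  lin2 <- lin
  lin2$metabolites <- dplyr::bind_rows(
    lin2$metabolites, tibble::tibble(id = "q_c", compartment = "c"))
  blocked <- add_reaction(lin2, "orphan", c(b_c = -1, q_c = 1))
  fva3 <- flux_variability(blocked, reactions = "orphan",
                           fraction_of_optimum = 0)
  expect_equal(c(fva3$min_flux, fva3$max_flux), c(0, 0), tolerance = 1e-8)
})

test_that("gene deletions respect isozyme redundancy and complex fragility", {
  base <- fba(toy)$objective_value
  # one isozyme of the xylose transporter pair is dispensable
  expect_equal(single_gene_deletion(toy, "gXYT1")$objective_value, base,
               tolerance = 1e-8)
  # a glycolysis complex member is essential when glucose must be used
  glc_only <- set_medium(toy, c(stats::setNames(10, "EX_glc__D_e"),
                                stats::setNames(rep(1000, 4), toy_base_medium())))
  expect_equal(single_gene_deletion(glc_only, "gGLY2")$objective_value, 0,
               tolerance = 1e-9)
  # deleting a gene absent from all GPRs changes nothing
  m <- toy
  m$genes <- c(m$genes, "gGHOST")
  expect_equal(single_gene_deletion(m, "gGHOST")$objective_value, base,
               tolerance = 1e-9)
  expect_error(single_gene_deletion(toy, "not_a_gene"), "unknown gene")
})

test_that("deletions never increase the optimum", {
  base <- fba(toy)$objective_value
  for (g in toy$genes)
    expect_lte(single_gene_deletion(toy, g)$objective_value, base + 1e-9)
})

test_that("growth_on_source returns the growth/no-growth/no-exchange tristate", {
  bm <- toy_base_medium()
  expect_equal(growth_on_source(toy, "EX_glc__D_e", bm), "growth")
  expect_equal(growth_on_source(toy, "EX_gal_e", bm), "no_growth")
  expect_equal(growth_on_source(toy, "EX_malt_e", bm), "no_exchange")
})

test_that("growth on a source is monotone in the uptake rate", {
  bm <- toy_base_medium()
  mus <- vapply(c(0.5, 2, 5, 10), function(u) {
    m <- set_medium(toy, c(stats::setNames(u, "EX_glc__D_e"),
                           stats::setNames(rep(1000, length(bm)), bm)))
    fba(m)$objective_value
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
})

test_that("phenotype comparison categorises the designed fixture exactly", {
  fix <- make_phenotype_fixture(seed = 42)
  cmp <- phenotype_array(toy, fix$observations, base_medium = toy_base_medium())
  expect_identical(cmp$category, fix$expected$category)
  expect_identical(cmp$predicted, fix$expected$predicted)
  g <- glance(cmp)
  expect_equal(unlist(g[, c("TP", "TN", "FP", "FN", "no_exchange")]),
               c(TP = 3L, TN = 3L, FP = 1L, FN = 1L, no_exchange = 2L))
  # empty observation set gives an empty comparison
  empty <- phenotype_array(toy, fix$observations[0, ],
                           base_medium = toy_base_medium())
  expect_equal(nrow(empty), 0)
})

test_that("tidiers expose solutions as tibbles", {
  sol <- fba(toy)
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(toy$reactions))
  gl <- glance(sol)
  expect_equal(gl$status, "optimal")
  expect_equal(gl$objective_value, sol$objective_value)
})
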