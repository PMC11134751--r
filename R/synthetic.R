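#' Specification for the synthetic toy model
#'
#' @param seed integer seed for the stochastic fixtures built on top of the
#'   toy model (the model itself is fully deterministic).
#' @param include_xylose_path include xylose transport and isomerisation to
#'   the glucose pool.
#' @param n_decoy_deadends number of decoy dead-end appendage reactions
#'   (peroxisomal), each producing one metabolite nothing consumes.
#' @param citrate_overflow include the mitochondrial citrate branch
#'   (pyruvate import, citrate synthesis, shuttle, secretion).
#' @param include_phenotype_sources include the extra carbon sources used
#'   by the phenotype fixture (fructose/mannose paths; galactose, sorbose
#'   and arabinose exchanges without catabolism).
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(seed = 1, include_xylose_path = TRUE,
                     n_decoy_deadends = 2, citrate_overflow = TRUE,
                     include_phenotype_sources = TRUE) {
  stopifnot(n_decoy_deadends >= 0)
  structure(list(seed = as.integer(seed),
                 include_xylose_path = include_xylose_path,
                 n_decoy_deadends = as.integer(n_decoy_deadends),
                 citrate_overflow = citrate_overflow,
                 include_phenotype_sources = include_phenotype_sources),
            class = "toy_spec")
}

## elemental formulas of the toy metabolite vocabulary (by base name)
toy_formulas <- function(n_decoys = 0) {
  f <- c(glc__D = "C6H12O6", xyl__D = "C5H10O5", pyr = "C3H4O3",
         cit = "C6H8O7", o2 = "O2", co2 = "CO2", h2o = "H2O", h = "H",
         pi = "H3O4P", atp = "C10H16N5O13P3", adp = "C10H15N5O10P2",
         prec = "C6H10O5", nuc = "C6H11O8P", plip = "C12H21O13P",
         fru = "C6H12O6", man = "C6H12O6", gal = "C6H12O6",
         srb = "C6H12O6", ara = "C5H10O5")
  if (n_decoys > 0)
    f <- c(f, stats::setNames(rep("C6H10O5", n_decoys),
                              paste0("junk", seq_len(n_decoys))))
  f
}

#' Monomer table for the toy biomass equation
#'
#' Maps the measured bulk fractions onto the toy model's lumped precursors:
#' protein and cell wall onto a generic anhydroglucose-mass precursor,
#' lipid onto a phospholipid pseudo-metabolite (1 P), DNA and RNA onto a
#' nucleotide pseudo-metabolite (1 P). Ash and pool are non-metabolic
#' drains (no monomer rows).
#'
#' @return Tibble in the format of [default_monomer_table()].
#' @export
toy_monomer_table <- function() {
  tibble::tribble(
    ~component,  ~monomer, ~molar_fraction, ~residue_mass, ~p_atoms,
    "protein",   "prec_c", 1.0,             0.1621,        0,
    "cell_wall", "prec_c", 1.0,             0.1621,        0,
    "lipid",     "plip_c", 1.0,             0.4043,        1,
    "DNA",       "nuc_c",  1.0,             0.2421,        1,
    "RNA",       "nuc_c",  1.0,             0.2421,        1)
}

#' Base (carbon-free) medium exchanges of the toy model
#' @return Character vector of exchange reaction ids.
#' @export
toy_base_medium <- function() c("EX_pi_e", "EX_o2_e", "EX_h2o_e", "EX_h_e")

#' Build the synthetic toy metabolic model
#'
#' A ~30-reaction, four-compartment caricature of a citric-acid-producing
#' fungus: glucose and xylose exchanges, a lumped glycolysis producing
#' pyruvate and ATP, lumped respiration, precursor/nucleotide/phospholipid
#' synthesis feeding a biomass equation built from the measured pelleted
#' composition, ATP maintenance, a mitochondrial citrate branch with a
#' cytosolic shuttle and secretion, and optional dead-end decoy appendages
#' in the peroxisome. All non-exchange reactions are elementally balanced,
#' with small integer (or half-integer) coefficients so LP optima are
#' hand-derivable.
#'
#' @param spec a [toy_spec()].
#' @return A `metabolic_model` with objective `BIOMASS`.
#' @export
#' @examples
#' toy <- make_toy_model()
#' fba(toy)$objective_value
make_toy_model <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  rx <- tibble::tribble(
    ~id, ~equation, ~lower_bound, ~upper_bound, ~gpr, ~subsystem,
    "EX_glc__D_e", "glc__D[e] ->",  -10, 1000, NA, "exchange",
    "EX_pi_e",     "pi[e] ->",    -1000, 1000, NA, "exchange",
    "EX_o2_e",     "o2[e] ->",    -1000, 1000, NA, "exchange",
    "EX_co2_e",    "co2[e] ->",       0, 1000, NA, "exchange",
    "EX_h2o_e",    "h2o[e] ->",   -1000, 1000, NA, "exchange",
    "EX_h_e",      "h[e] ->",     -1000, 1000, NA, "exchange",
    "GLCt", "glc__D[e] -> glc__D[c]", 0, 1000, "gGLT1", "transport",
    "PIt",  "pi[e] -> pi[c]",         0, 1000, "gPIT1", "transport",
    "O2t",  "o2[e] <=> o2[c]",    -1000, 1000, NA, "transport",
    "CO2t", "co2[c] <=> co2[e]",  -1000, 1000, NA, "transport",
    "H2Ot", "h2o[c] <=> h2o[e]",  -1000, 1000, NA, "transport",
    "Ht",   "h[c] <=> h[e]",      -1000, 1000, NA, "transport",
    "GLYC", "glc__D[c] + 2 adp[c] + 2 pi[c] -> 2 pyr[c] + 2 atp[c] + 2 h2o[c] + 4 h[c]",
            0, 1000, "gGLY1 and gGLY2", "glycolysis",
    "RESP", "pyr[c] + 2 h[c] + 3 o2[c] + 14 adp[c] + 14 pi[c] -> 3 co2[c] + 17 h2o[c] + 14 atp[c]",
            0, 1000, "gRES1 and gRES2 and gRES3", "respiration",
    "PRECS", "glc__D[c] + atp[c] -> prec[c] + adp[c] + pi[c]",
            0, 1000, "gPRE1", "anabolism",
    "NUCS",  "prec[c] + atp[c] -> nuc[c] + adp[c]",
            0, 1000, "gNUC1", "anabolism",
    "PLIPS", "2 prec[c] + atp[c] -> plip[c] + adp[c]",
            0, 1000, "gPLI1 and (gPLI2 or gPLI3)", "anabolism",
    "ATPM",  "atp[c] + h2o[c] -> adp[c] + pi[c]",
            0, 1000, NA, "maintenance")
  if (spec$citrate_overflow)
    rx <- dplyr::bind_rows(rx, tibble::tribble(
      ~id, ~equation, ~lower_bound, ~upper_bound, ~gpr, ~subsystem,
      "PYRtm", "pyr[c] -> pyr[m]",          0, 1000, NA, "transport",
      "O2tm",  "o2[c] -> o2[m]",            0, 1000, NA, "transport",
      "CITS",  "2 pyr[m] + 0.5 o2[m] -> cit[m]", 0, 1000, "gCITS1", "TCA",
      "CITtm", "cit[m] -> cit[c]",          0, 1000, "gCOC1", "transport",
      "CITt",  "cit[c] -> cit[e]",          0, 1000, "gCEX1", "transport",
      "EX_cit_e", "cit[e] ->",              0, 1000, NA, "exchange"))
  if (spec$include_xylose_path)
    rx <- dplyr::bind_rows(rx, tibble::tribble(
      ~id, ~equation, ~lower_bound, ~upper_bound, ~gpr, ~subsystem,
      "EX_xyl__D_e", "xyl__D[e] ->",           -10, 1000, NA, "exchange",
      "XYLt",   "xyl__D[e] -> xyl__D[c]",        0, 1000, "gXYT1 or gXYT2", "transport",
      "XYLISO", "6 xyl__D[c] -> 5 glc__D[c]",    0, 1000, "gXYL1", "pentose"))
  if (spec$include_phenotype_sources)
    rx <- dplyr::bind_rows(rx, tibble::tribble(
      ~id, ~equation, ~lower_bound, ~upper_bound, ~gpr, ~subsystem,
      "EX_fru_e", "fru[e] ->",        0, 1000, NA, "exchange",
      "FRUt",   "fru[e] -> fru[c]",   0, 1000, "gFRT1", "transport",
      "FRUISO", "fru[c] -> glc__D[c]", 0, 1000, "gFRU1", "sugar",
      "EX_man_e", "man[e] ->",        0, 1000, NA, "exchange",
      "MANt",   "man[e] -> man[c]",   0, 1000, "gMNT1", "transport",
      "MANISO", "man[c] -> glc__D[c]", 0, 1000, "gMAN1", "sugar",
      "EX_gal_e", "gal[e] ->",        0, 1000, NA, "exchange",
      "EX_srb_e", "srb[e] ->",        0, 1000, NA, "exchange",
      "EX_ara_e", "ara[e] ->",        0, 1000, NA, "exchange"))
  if (spec$n_decoy_deadends > 0)
    rx <- dplyr::bind_rows(rx, tibble::tibble(
      id = paste0("DECOY", seq_len(spec$n_decoy_deadends)),
      equation = paste0("prec[c] -> junk", seq_len(spec$n_decoy_deadends), "[x]"),
      lower_bound = 0, upper_bound = 1000,
      gpr = NA_character_, subsystem = "decoy"))

  sto_list <- lapply(seq_len(nrow(rx)), function(i) {
    parsed <- parse_reaction_equation(rx$equation[i])
    tibble::tibble(reaction_id = rx$id[i],
                   metabolite_id = names(parsed$stoichiometry),
                   coefficient = unname(parsed$stoichiometry),
                   compartment = unname(parsed$compartments))
  })
  sto <- dplyr::bind_rows(sto_list)
  mets <- dplyr::distinct(sto[, c("metabolite_id", "compartment")])
  formulas <- toy_formulas(spec$n_decoy_deadends)
  base <- mapply(function(id, cc) sub(paste0("_", cc, "$"), "", id),
                 mets$metabolite_id, mets$compartment)
  metabolites <- tibble::tibble(id = mets$metabolite_id,
                                compartment = mets$compartment,
                                formula = unname(formulas[base]))

  model <- metabolic_model(
    metabolites = metabolites,
    reactions = rx[, c("id", "lower_bound", "upper_bound", "gpr", "subsystem")],
    stoichiometry = sto[, c("reaction_id", "metabolite_id", "coefficient")],
    id = "toy_fungus")
  br <- build_biomass_reaction(atub_biomass_composition("pelleted"),
                               toy_monomer_table(), gam = 30,
                               gam_ids = c(atp = "atp_c", adp = "adp_c",
                                           pi = "pi_c", h2o = "h2o_c"))
  append_biomass(model, br)
}

#' Phenotype fixture for the toy model
#'
#' A designed carbon-source panel with known outcome classes: three
#' observed-and-predicted growers (glucose, xylose, fructose), a false
#' positive (mannose: catabolism present, no observed growth), a false
#' negative (arabinose: observed growth, no pathway), three true negatives
#' (galactose, sorbose, citrate) and two sources the model has no uptake
#' route for (maltose, ribose).
#'
#' @param seed integer; shuffles panel order (fixture content is fixed).
#' @return List with `observations` (tibble `source`, `exchange`,
#'   `growth`) and `expected` (tibble adding `predicted` and `category`),
#'   both in the same order.
#' @export
make_phenotype_fixture <- function(seed = 1) {
  panel <- tibble::tribble(
    ~source,       ~exchange,      ~growth, ~predicted, ~category,
    "D-glucose",   "EX_glc__D_e",  TRUE,    TRUE,       "TP",
    "D-xylose",    "EX_xyl__D_e",  TRUE,    TRUE,       "TP",
    "D-fructose",  "EX_fru_e",     TRUE,    TRUE,       "TP",
    "D-mannose",   "EX_man_e",     FALSE,   TRUE,       "FP",
    "D-galactose", "EX_gal_e",     FALSE,   FALSE,      "TN",
    "L-sorbose",   "EX_srb_e",     FALSE,   FALSE,      "TN",
    "citrate",     "EX_cit_e",     FALSE,   FALSE,      "TN",
    "L-arabinose", "EX_ara_e",     TRUE,    FALSE,      "FN",
    "maltose",     "EX_malt_e",    TRUE,    NA,         "no_exchange",
    "D-ribose",    "EX_rib_e",     FALSE,   NA,         "no_exchange")
  set.seed(seed)
  panel <- panel[sample.int(nrow(panel)), ]
  list(observations = panel[, c("source", "exchange", "growth")],
       expected = panel)
}

#' Generate a noisy synthetic fermentation dataset
#'
#' Runs the toy-model dFBA under known kinetic parameters, subsamples the
#' trajectory to `n_points` evenly spaced times and adds multiplicative
#' Gaussian noise (coefficient of variation `noise_cv`, truncated at zero)
#' independently per replicate -- emulating triplicate offline sampling of
#' a fermentation. The generating parameters are returned, so estimator
#' recovery can be scored against ground truth.
#'
#' @param p a [kinetic_parameters()] object (ground truth).
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param seed integer seed.
#' @param model model to simulate; defaults to [make_toy_model()].
#' @param initial,t_end,dt simulation setup, see [run_dfba()].
#' @param n_points,replicates sampling design.
#' @return List with `trajectory` (clean `dfba_trajectory`), `samples`
#'   (long tibble: `replicate`, `t`, species columns) and `parameters`.
#' @export
make_fermentation_dataset <- function(p = kinetic_parameters(),
                                      noise_cv = 0.02, seed = 1,
                                      model = make_toy_model(),
                                      initial = fermentation_state(t = p$t_start),
                                      t_end = 72, dt = 0.1,
                                      n_points = 10, replicates = 3) {
  stopifnot(noise_cv >= 0)
  traj <- run_dfba(model, p, initial, t_end = t_end, dt = dt)
  times <- seq(min(traj$t), max(traj$t), length.out = n_points)
  vars <- c("biomass", "glucose", "xylose", "citrate", "phosphate")
  clean <- purrr::map_dfc(vars, function(v)
    tibble::tibble(!!v := stats::approx(traj$t, traj[[v]], xout = times)$y))
  set.seed(seed)
  samples <- purrr::map_dfr(seq_len(replicates), function(r) {
    noisy <- clean
    for (v in vars)
      noisy[[v]] <- pmax(0, noisy[[v]] *
                           (1 + stats::rnorm(n_points, 0, noise_cv)))
    dplyr::bind_cols(tibble::tibble(replicate = r, t = times), noisy)
  })
  list(trajectory = traj, samples = samples, parameters = p)
}
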