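BIOMASS_COMPONENTS <- c("DNA", "protein", "lipid", "cell_wall", "RNA",
                        "ash", "pool")

#' Construct a measured biomass composition
#'
#' Bulk macromolecular fractions (g per g dry weight) of the seven
#' components a fungal biomass equation accounts for: DNA, protein, lipid,
#' cell wall, RNA, ash and a small-molecule pool.
#'
#' @param fractions named numeric vector over all seven components, g/gDW.
#' @param sd optional named numeric vector of measurement s.d., g/gDW.
#' @param morphology `"filamentous"` or `"pelleted"` (growth-form the
#'   measurement was taken under).
#' @return A `biomass_composition` object.
#' @export
biomass_composition <- function(fractions, sd = NULL,
                                morphology = c("pelleted", "filamentous")) {
  morphology <- match.arg(morphology)
  missing_c <- setdiff(BIOMASS_COMPONENTS, names(fractions))
  if (length(missing_c))
    stop("missing biomass component(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  fractions <- fractions[BIOMASS_COMPONENTS]
  if (any(fractions < 0))
    stop("negative biomass fractions", call. = FALSE)
  if (sum(fractions) > 1.05)
    stop("biomass fractions sum to ", round(sum(fractions), 4),
         " g/gDW (> 1.05)", call. = FALSE)
  structure(list(fractions = fractions,
                 sd = if (!is.null(sd)) sd[BIOMASS_COMPONENTS],
                 morphology = morphology),
            class = "biomass_composition")
}

#' Measured biomass composition of *A. tubingensis* DJU120
#'
#' Triplicate measurements of macromolecular composition under two growth
#' morphologies. DNA, protein, lipid and cell wall were assayed directly;
#' RNA, ash and pool fractions are carried over from published *A. niger*
#' biomass equations (RNA from iDU1756, ash/pool from iJB1325). The
#' `reported_total` is the published column total, which differs slightly
#' from the component sum because the components are individually rounded.
#'
#' @param morphology `"pelleted"` (used for the citric-acid biomass
#'   equation) or `"filamentous"`.
#' @return A `biomass_composition` with an extra `reported_total` field.
#' @export
#' @examples
#' comp <- atub_biomass_composition("pelleted")
#' composition_total(comp)
atub_biomass_composition <- function(morphology = c("pelleted", "filamentous")) {
  morphology <- match.arg(morphology)
  vals <- list(
    filamentous = list(
      fr = c(DNA = 0.0022, protein = 0.1279, lipid = 0.20, cell_wall = 0.43,
             RNA = 0.00604, ash = 0.0750, pool = 0.1310),
      sd = c(DNA = 0.0001, protein = 0.0110, lipid = 0.02, cell_wall = 0.02,
             RNA = NA, ash = NA, pool = NA),
      total = 0.9685),
    pelleted = list(
      fr = c(DNA = 0.0028, protein = 0.1424, lipid = 0.11, cell_wall = 0.48,
             RNA = 0.00604, ash = 0.0750, pool = 0.1310),
      sd = c(DNA = 0.0002, protein = 0.017, lipid = 0.01, cell_wall = 0.03,
             RNA = NA, ash = NA, pool = NA),
      total = 0.9481))[[morphology]]
  out <- biomass_composition(vals$fr, vals$sd, morphology)
  out$reported_total <- vals$total
  out
}

#' Total of a biomass composition
#'
#' @param composition a `biomass_composition`.
#' @return Sum of the seven component fractions, g/gDW.
#' @export
composition_total <- function(composition) {
  stopifnot(inherits(composition, "biomass_composition"))
  sum(composition$fractions)
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("<biomass_composition> ", x$morphology, " morphology, total ",
      round(composition_total(x), 4), " g/gDW\n", sep = "")
  for (k in names(x$fractions))
    cat(sprintf("  %-10s %8.5f g/gDW\n", k, x$fractions[[k]]))
  invisible(x)
}

#' Default monomer table for a biomass equation
#'
#' Maps each bulk macromolecule fraction onto model metabolites: monomer
#' ids, molar fractions within the macromolecule, residue molar masses
#' (g/mmol, polymerised-residue basis) and phosphorus atoms per monomer.
#' This default follows the convention of published *A. niger* biomass
#' equations at pseudo-monomer granularity (one representative residue per
#' macromolecule class, a glucan/chitin split for the cell wall) and is
#' meant to be replaced by a user-edited CSV for organism-specific work.
#' Ash and pool are bulk drains with no metabolic monomer.
#'
#' @return Tibble with columns `component`, `monomer`, `molar_fraction`,
#'   `residue_mass`, `p_atoms`.
#' @export
default_monomer_table <- function() {
  tibble::tribble(
    ~component,  ~monomer,          ~molar_fraction, ~residue_mass, ~p_atoms,
    "protein",   "protein_pseudo",  1.0,             0.109,         0,
    "DNA",       "dnmp_pseudo",     1.0,             0.3085,        1,
    "RNA",       "nmp_pseudo",      1.0,             0.3245,        1,
    "lipid",     "lipid_pseudo",    1.0,             0.750,         1,
    "cell_wall", "glucan_unit",     0.8,             0.1621,        0,
    "cell_wall", "chitin_unit",     0.2,             0.2032,        0)
}

#' Read / write a monomer table as CSV
#'
#' @param path CSV file with the columns of [default_monomer_table()].
#' @return Tibble monomer table.
#' @export
read_monomer_table <- function(path) {
  mt <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("component", "monomer", "molar_fraction", "residue_mass", "p_atoms")
  missing_c <- setdiff(need, names(mt))
  if (length(missing_c))
    stop("monomer table lacks column(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  mt
}

validate_monomer_table <- function(monomers) {
  bad <- monomers |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(s = sum(.data$molar_fraction)) |>
    dplyr::filter(abs(.data$s - 1) > 1e-6)
  if (nrow(bad))
    stop("monomer molar fractions do not sum to 1 for: ",
         paste(bad$component, collapse = ", "), call. = FALSE)
  if (any(!is.finite(monomers$residue_mass) | monomers$residue_mass <= 0))
    stop("monomer(s) without positive residue mass: ",
         paste(monomers$monomer[!is.finite(monomers$residue_mass) |
                                  monomers$residue_mass <= 0], collapse = ", "),
         call. = FALSE)
  invisible(monomers)
}

#' Build a biomass reaction from a measured composition
#'
#' Converts bulk fractions (g/gDW) into monomer drains (mmol/gDW): the
#' coefficient of monomer j of component k is
#' `fraction_k * molar_fraction_jk / residue_mass_jk`, consumed (negative).
#' Growth-associated ATP hydrolysis (`gam` mmol ATP/gDW) is added as
#' `gam * (atp + h2o -> adp + pi)`. Components mapped to no monomer (ash,
#' pool, by default) contribute nothing metabolic. Producing one unit of a
#' biomass metabolite is optional: by convention the reaction's flux *is*
#' the growth rate (h^-1).
#'
#' @param composition a `biomass_composition` with total in `[0.9, 1.05]`.
#' @param monomers monomer table, see [default_monomer_table()].
#' @param gam growth-associated maintenance, mmol ATP/gDW (configurable;
#'   not part of the measured composition).
#' @param gam_ids named character vector with ids of `atp`, `adp`, `pi`,
#'   `h2o` metabolites; required when `gam > 0`.
#' @param biomass_met optional id of a produced biomass metabolite (+1).
#' @param id reaction id.
#' @return A `biomass_reaction`: list with `id`, `stoichiometry` (named
#'   numeric) and `monomer_coefficients` (tibble).
#' @export
build_biomass_reaction <- function(composition, monomers, gam = 0,
                                   gam_ids = NULL, biomass_met = NULL,
                                   id = "BIOMASS") {
  stopifnot(inherits(composition, "biomass_composition"))
  total <- composition_total(composition)
  if (total < 0.9 || total > 1.05)
    stop("composition total ", round(total, 4),
         " g/gDW outside [0.9, 1.05]; not a credible dry-weight budget",
         call. = FALSE)
  validate_monomer_table(monomers)
  extra <- setdiff(monomers$component, BIOMASS_COMPONENTS)
  if (length(extra))
    stop("unknown component(s) in monomer table: ",
         paste(extra, collapse = ", "), call. = FALSE)

  mm <- monomers
  mm$fraction <- composition$fractions[mm$component]
  mm$coefficient <- -mm$fraction * mm$molar_fraction / mm$residue_mass
  sto <- tapply(mm$coefficient, mm$monomer, sum)
  sto <- stats::setNames(as.numeric(sto), names(sto))
  if (gam > 0) {
    need <- c("atp", "adp", "pi", "h2o")
    if (is.null(gam_ids) || !all(need %in% names(gam_ids)))
      stop("gam > 0 needs gam_ids naming atp, adp, pi and h2o metabolites",
           call. = FALSE)
    gam_sto <- stats::setNames(c(-gam, -gam, gam, gam),
                               gam_ids[c("atp", "h2o", "adp", "pi")])
    for (k in names(gam_sto))
      sto[k] <- (if (k %in% names(sto)) sto[k] else 0) + gam_sto[k]
  }
  if (!is.null(biomass_met)) sto[biomass_met] <- 1
  structure(list(id = id, stoichiometry = sto,
                 monomer_coefficients = mm[, c("component", "monomer",
                                               "fraction", "coefficient",
                                               "p_atoms")],
                 gam = gam, morphology = composition$morphology),
            class = "biomass_reaction")
}

#' @export
print.biomass_reaction <- function(x, ...) {
  cat("<biomass_reaction> ", x$id, " (", x$morphology,
      " composition, GAM = ", x$gam, " mmol ATP/gDW)\n", sep = "")
  for (k in names(x$stoichiometry))
    cat(sprintf("  %-16s %10.5f mmol/gDW\n", k, x$stoichiometry[[k]]))
  invisible(x)
}

#' Phosphorus demand of a biomass reaction
#'
#' Sums, over the consumed monomers, coefficient times phosphorus atoms per
#' monomer: the mmol of phosphorus fixed into each gram of new biomass.
#' This is what drives extracellular phosphate drawdown during growth.
#'
#' @param reaction a `biomass_reaction` from [build_biomass_reaction()].
#' @param monomers the monomer table the reaction was built with.
#' @return Phosphorus content, mmol P per gDW.
#' @export
phosphorus_content <- function(reaction, monomers) {
  stopifnot(inherits(reaction, "biomass_reaction"))
  mc <- reaction$monomer_coefficients
  sum(-mc$coefficient * mc$p_atoms)
}

#' Append a biomass reaction to a model
#'
#' @param model a `metabolic_model` containing every monomer metabolite.
#' @param reaction a `biomass_reaction`.
#' @param objective make it the model objective (default TRUE).
#' @return The extended model.
#' @export
append_biomass <- function(model, reaction, objective = TRUE) {
  stopifnot(inherits(reaction, "biomass_reaction"))
  model <- add_reaction(model, reaction$id, reaction$stoichiometry,
                        lower_bound = 0, upper_bound = 1000,
                        name = "biomass equation",
                        subsystem = "biomass")
  if (objective) model$objective <- reaction$id
  validate_model(model)
  model
}
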