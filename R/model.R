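#' Compartment vocabulary
#'
#' The four compartments a model may use: extracellular space, cytosol,
#' mitochondria and peroxisome, with the single-letter ids used by the
#' tabular reaction dialect (`[e]`, `[c]`, `[m]`, `[x]`).
#'
#' @format A named character vector mapping compartment id to name.
#' @export
model_compartments <- c(e = "extracellular", c = "cytosol",
                        m = "mitochondria", x = "peroxisome")

#' Construct a genome-scale metabolic model
#'
#' A metabolic model is a set of tibbles: `metabolites` (id, name,
#' compartment, formula, charge), `reactions` (id, name, lower_bound,
#' upper_bound, subsystem, gpr), and a long-format `stoichiometry` table
#' (reaction_id, metabolite_id, coefficient; negative = consumed). Gene ids
#' are taken verbatim and case-sensitively. Bounds are in mmol gDW^-1 h^-1.
#'
#' @param metabolites tibble/data frame with at least `id` and `compartment`;
#'   optional `name`, `formula`, `charge`.
#' @param reactions tibble/data frame with at least `id`; optional `name`,
#'   `lower_bound`, `upper_bound` (default -1000/1000 when a `reversible`
#'   column is present and TRUE, else 0/1000), `subsystem`, `gpr` (Boolean
#'   rule string over gene ids with `and`/`or`).
#' @param stoichiometry tibble/data frame with `reaction_id`,
#'   `metabolite_id`, `coefficient`.
#' @param genes character vector of gene ids; defaults to the genes
#'   appearing in GPR strings.
#' @param objective id of the objective (typically biomass) reaction, or
#'   `NULL`.
#' @param id short model identifier used in printing and SBML output.
#'
#' @return An object of class `metabolic_model`.
#' @export
#' @examples
#' m <- metabolic_model(
#'   metabolites = tibble::tibble(id = c("a_e", "a_c"),
#'                                compartment = c("e", "c")),
#'   reactions = tibble::tibble(id = c("EX_a", "At"),
#'                              lower_bound = c(-10, 0)),
#'   stoichiometry = tibble::tibble(
#'     reaction_id = c("EX_a", "At", "At"),
#'     metabolite_id = c("a_e", "a_e", "a_c"),
#'     coefficient = c(-1, -1, 1)))
#' m
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL, objective = NULL, id = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  metabolites <- metabolites[, c("id", "name", "compartment", "formula", "charge")]

  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"lower_bound" %in% names(reactions)) {
    rev <- if ("reversible" %in% names(reactions)) reactions$reversible else FALSE
    reactions$lower_bound <- ifelse(rev, -1000, 0)
  }
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- 1000
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  if (!"gpr" %in% names(reactions)) reactions$gpr <- NA_character_
  reactions <- reactions[, c("id", "name", "lower_bound", "upper_bound",
                             "subsystem", "gpr")]

  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(
      reactions$gpr[!is.na(reactions$gpr)],
      function(g) gpr_genes(parse_gpr(g))))))
    if (is.null(genes)) genes <- character()
  }

  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = as.character(genes),
         objective = objective, id = id),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, compartment vocabulary, bound ordering, that every
#' stoichiometry entry resolves to a declared metabolite and reaction, that
#' every GPR leaf is a declared gene, and that the objective resolves.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; errors with all violations otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  problems <- character()
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id))
    problems <- c(problems, paste("duplicated metabolite ids:",
      paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  if (anyDuplicated(rxn$id))
    problems <- c(problems, paste("duplicated reaction ids:",
      paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  bad_comp <- setdiff(unique(met$compartment), names(model_compartments))
  if (length(bad_comp))
    problems <- c(problems, paste("unknown compartments:",
                                  paste(bad_comp, collapse = ", ")))
  if (any(rxn$lower_bound > rxn$upper_bound))
    problems <- c(problems, paste("lower_bound > upper_bound for:",
      paste(rxn$id[rxn$lower_bound > rxn$upper_bound], collapse = ", ")))
  orphan_m <- setdiff(model$stoichiometry$metabolite_id, met$id)
  if (length(orphan_m))
    problems <- c(problems, paste("stoichiometry references undeclared metabolites:",
                                  paste(orphan_m, collapse = ", ")))
  orphan_r <- setdiff(model$stoichiometry$reaction_id, rxn$id)
  if (length(orphan_r))
    problems <- c(problems, paste("stoichiometry references undeclared reactions:",
                                  paste(orphan_r, collapse = ", ")))
  empty <- setdiff(rxn$id, model$stoichiometry$reaction_id)
  if (length(empty))
    problems <- c(problems, paste("reactions with empty stoichiometry:",
                                  paste(empty, collapse = ", ")))
  gpr_gene_ids <- unique(unlist(lapply(rxn$gpr[!is.na(rxn$gpr)],
                                       function(g) gpr_genes(parse_gpr(g)))))
  missing_genes <- setdiff(gpr_gene_ids, model$genes)
  if (length(missing_genes))
    problems <- c(problems, paste("GPR genes not in gene list:",
                                  paste(missing_genes, collapse = ", ")))
  if (!is.null(model$objective) && !model$objective %in% rxn$id)
    problems <- c(problems, paste("objective reaction not found:", model$objective))
  if (length(problems))
    stop("invalid metabolic model:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " in {", paste(sort(unique(x$metabolites$compartment)), collapse = ","),
      "}\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", sum(is_exchange(x)), " exchange, ",
      sum(is_transport(x)), " transport)\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n", sep = "")
  cat("  objective:   ", ifelse(is.null(x$objective), "<none>", x$objective),
      "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return A dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  S[cbind(model$stoichiometry$metabolite_id,
          model$stoichiometry$reaction_id)] <- model$stoichiometry$coefficient
  S
}

#' Classify exchange reactions
#'
#' An exchange reaction is a single-metabolite boundary pseudo-reaction on an
#' extracellular metabolite: its (unbalanced) stoichiometry lets mass enter
#' or leave the system.
#'
#' @param model a `metabolic_model`.
#' @return Logical vector along `model$reactions`.
#' @export
is_exchange <- function(model) {
  sto <- dplyr::left_join(model$stoichiometry,
                          model$metabolites[, c("id", "compartment")],
                          by = c(metabolite_id = "id"))
  info <- dplyr::summarise(dplyr::group_by(sto, .data$reaction_id),
                           n = dplyr::n(),
                           all_e = all(.data$compartment == "e"))
  ex_ids <- info$reaction_id[info$n == 1L & info$all_e]
  model$reactions$id %in% ex_ids
}

#' Classify transport reactions
#'
#' A reaction is a transporter when its participants span at least two
#' compartments.
#'
#' @param model a `metabolic_model`.
#' @return Logical vector along `model$reactions`.
#' @export
is_transport <- function(model) {
  sto <- dplyr::left_join(model$stoichiometry,
                          model$metabolites[, c("id", "compartment")],
                          by = c(metabolite_id = "id"))
  info <- dplyr::summarise(dplyr::group_by(sto, .data$reaction_id),
                           k = dplyr::n_distinct(.data$compartment))
  model$reactions$id %in% info$reaction_id[info$k >= 2L]
}

#' Is each reaction reversible?
#'
#' A reaction is reversible when its bounds admit flux in both directions.
#'
#' @param model a `metabolic_model`.
#' @return Logical vector along `model$reactions`.
#' @export
is_reversible <- function(model) {
  model$reactions$lower_bound < 0 & model$reactions$upper_bound > 0
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lower_bound,upper_bound new bounds; `NULL` leaves a bound alone.
#' @return The modified model (the input is not changed).
#' @export
set_bounds <- function(model, id, lower_bound = NULL, upper_bound = NULL) {
  i <- match(id, model$reactions$id)
  if (any(is.na(i)))
    stop("unknown reaction id(s): ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  if (!is.null(lower_bound)) model$reactions$lower_bound[i] <- lower_bound
  if (!is.null(upper_bound)) model$reactions$upper_bound[i] <- upper_bound
  model
}

#' Remove reactions (and newly orphaned metabolites) from a model
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to drop.
#' @param drop_orphans drop metabolites left without any reaction.
#' @return The reduced model.
#' @export
remove_reactions <- function(model, ids, drop_orphans = TRUE) {
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(model$objective) && model$objective %in% ids)
    stop("refusing to remove the objective reaction ", model$objective,
         call. = FALSE)
  model$reactions <- model$reactions[!model$reactions$id %in% ids, ]
  model$stoichiometry <-
    model$stoichiometry[!model$stoichiometry$reaction_id %in% ids, ]
  if (drop_orphans) {
    keep <- model$metabolites$id %in% model$stoichiometry$metabolite_id
    model$metabolites <- model$metabolites[keep, ]
  }
  model
}

#' Add one reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id,name reaction id and display name.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient
#'   (negative = consumed).
#' @param lower_bound,upper_bound flux bounds (mmol gDW^-1 h^-1).
#' @param subsystem,gpr optional annotation.
#' @return The extended model.
#' @export
add_reaction <- function(model, id, stoichiometry, lower_bound = 0,
                         upper_bound = 1000, name = id,
                         subsystem = NA_character_, gpr = NA_character_) {
  if (id %in% model$reactions$id)
    stop("reaction id already present: ", id, call. = FALSE)
  missing_m <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(missing_m))
    stop("stoichiometry references undeclared metabolites: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble::tibble(id = id, name = name, lower_bound = lower_bound,
                   upper_bound = upper_bound, subsystem = subsystem,
                   gpr = gpr))
  model$stoichiometry <- dplyr::bind_rows(
    model$stoichiometry,
    tibble::tibble(reaction_id = id, metabolite_id = names(stoichiometry),
                   coefficient = unname(stoichiometry)))
  new_genes <- if (!is.na(gpr)) setdiff(gpr_genes(parse_gpr(gpr)), model$genes)
               else character()
  model$genes <- c(model$genes, new_genes)
  model
}

#' Exchange reactions of a model
#'
#' @param model a `metabolic_model`.
#' @return Tibble of exchange reactions with the metabolite each one moves.
#' @export
exchanges <- function(model) {
  ex <- model$reactions[is_exchange(model), c("id", "lower_bound", "upper_bound")]
  sto <- model$stoichiometry[model$stoichiometry$reaction_id %in% ex$id, ]
  dplyr::left_join(ex, sto[, c("reaction_id", "metabolite_id", "coefficient")],
                   by = c(id = "reaction_id"))
}
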