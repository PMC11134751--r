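#' Flux balance analysis
#'
#' Maximises (or minimises) the flux of one reaction subject to steady-state
#' mass balance `S v = 0` and the model's flux bounds, using the built-in
#' bounded-variable simplex. The optimal objective value is unique; the
#' returned flux vector is one optimal vertex and is not asserted unique.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimise; defaults to the model objective.
#' @param direction `"max"` or `"min"`.
#' @return A `flux_solution`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `objective_value`, `objective`, `direction` and
#'   `fluxes` (tibble `reaction`, `flux`; `NULL` unless optimal).
#' @export
#' @examples
#' toy <- make_toy_model()
#' sol <- fba(toy)
#' sol$objective_value
fba <- function(model, objective = model$objective,
                direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (is.null(objective))
    stop("model has no objective reaction and none was given", call. = FALSE)
  if (!objective %in% model$reactions$id)
    stop("objective reaction not in model: ", objective, call. = FALSE)
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(model$reactions$id == objective)
  res <- solve_lp(obj, S, rep(0, nrow(S)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  direction = direction)
  fluxes <- NULL
  if (res$status == "optimal")
    fluxes <- tibble::tibble(reaction = model$reactions$id, flux = res$x)
  structure(list(status = res$status,
                 objective_value = res$objective,
                 objective = objective, direction = direction,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> ", x$direction, " ", x$objective, ": ",
      x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective = ", signif(x$objective_value, 6), sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy a flux solution into a tibble of fluxes
#'
#' @param x a `flux_solution`.
#' @param ... unused.
#' @return Tibble with `reaction` and `flux` (empty if not optimal).
#' @export
tidy.flux_solution <- function(x, ...) {
  if (is.null(x$fluxes))
    return(tibble::tibble(reaction = character(), flux = numeric()))
  x$fluxes
}

#' One-row summary of a flux solution
#'
#' @param x a `flux_solution`.
#' @param ... unused.
#' @return Tibble with `status`, `objective`, `direction`, `objective_value`.
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective = x$objective,
                 direction = x$direction, objective_value = x$objective_value)
}

#' Flux variability analysis
#'
#' Computes, for each requested reaction, the attainable flux minimum and
#' maximum while the model objective is held at at least
#' `fraction_of_optimum` times its FBA optimum.
#'
#' @param model a `metabolic_model` with an objective.
#' @param reactions reaction ids to scan; default all.
#' @param fraction_of_optimum number in `[0, 1]`.
#' @return Tibble with `reaction`, `min_flux`, `max_flux`.
#' @export
flux_variability <- function(model, reactions = model$reactions$id,
                             fraction_of_optimum = 1) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base <- fba(model)
  if (base$status != "optimal")
    stop("base model is ", base$status, "; FVA undefined", call. = FALSE)
  ## pin the objective to >= fraction * optimum via its own lower bound
  i <- match(model$objective, model$reactions$id)
  floor_v <- fraction_of_optimum * base$objective_value
  model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i],
                                        min(floor_v, model$reactions$upper_bound[i]))
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  out <- purrr::map_dfr(reactions, function(rid) {
    obj <- as.numeric(model$reactions$id == rid)
    lo <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub, "min")
    hi <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub, "max")
    tibble::tibble(reaction = rid,
                   min_flux = lo$objective, max_flux = hi$objective)
  })
  out
}

#' Simulate a single gene deletion
#'
#' Reactions whose GPR rule evaluates false without the gene are closed
#' (bounds set to zero) and the model re-optimised. Reactions without a GPR
#' are untouched.
#'
#' @param model a `metabolic_model` with an objective.
#' @param gene gene id present in the model.
#' @return A `flux_solution` for the knockout.
#' @export
single_gene_deletion <- function(model, gene) {
  if (!gene %in% model$genes)
    stop("unknown gene: ", gene, call. = FALSE)
  present <- setdiff(model$genes, gene)
  has_gpr <- !is.na(model$reactions$gpr)
  dead <- has_gpr & !vapply(model$reactions$gpr, function(g)
    is.na(g) || evaluate_gpr(g, present), logical(1))
  model$reactions$lower_bound[dead] <- 0
  model$reactions$upper_bound[dead] <- 0
  fba(model)
}

#' Constrain a model to a growth medium
#'
#' Closes the uptake direction of every exchange reaction, then reopens the
#' listed medium exchanges.
#'
#' @param model a `metabolic_model`.
#' @param medium character vector of exchange reaction ids left open, or a
#'   named numeric vector of uptake rates (positive numbers, mmol gDW^-1
#'   h^-1); unnamed ids get `default_uptake`.
#' @param default_uptake uptake rate for unnamed medium components.
#' @return The constrained model.
#' @export
set_medium <- function(model, medium, default_uptake = 1000) {
  ex <- model$reactions$id[is_exchange(model)]
  model$reactions$lower_bound[model$reactions$id %in% ex &
                                model$reactions$lower_bound < 0] <- 0
  if (is.null(names(medium))) {
    rates <- stats::setNames(rep(default_uptake, length(medium)),
                             as.character(medium))
  } else {
    rates <- medium
  }
  unknown <- setdiff(names(rates), ex)
  if (length(unknown))
    stop("medium components are not exchange reactions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  set_bounds(model, names(rates), lower_bound = -abs(unname(rates)))
}

#' Predict growth on a single carbon source
#'
#' Applies a minimal base medium (inorganic exchanges, no carbon), opens the
#' one carbon-source exchange at `uptake_rate`, and calls growth when the
#' FBA optimum exceeds `growth_threshold`.
#'
#' @param model a `metabolic_model` with a biomass objective.
#' @param source exchange reaction id of the carbon source.
#' @param base_medium exchange ids of the inorganic medium (phosphate,
#'   nitrogen, oxygen, water, protons, ...) kept open without limit.
#' @param uptake_rate carbon-source uptake bound, mmol gDW^-1 h^-1.
#' @param growth_threshold growth call threshold, h^-1.
#' @return `"growth"`, `"no_growth"`, or `"no_exchange"` when the model has
#'   no uptake route (no such exchange reaction) for the source.
#' @export
growth_on_source <- function(model, source, base_medium,
                             uptake_rate = 10, growth_threshold = 1e-3) {
  ex <- model$reactions$id[is_exchange(model)]
  if (!source %in% ex) return("no_exchange")
  m <- set_medium(model, c(stats::setNames(uptake_rate, source),
                           stats::setNames(rep(1000, length(base_medium)),
                                           base_medium)))
  sol <- fba(m)
  if (sol$status == "optimal" && sol$objective_value > growth_threshold)
    "growth" else "no_growth"
}

#' Compare observed and predicted carbon-source growth phenotypes
#'
#' Runs [growth_on_source()] for every observed source and classifies each
#' as TP/TN/FP/FN, or `no_exchange` when the model lacks an uptake route --
#' those sources are surfaced, not adjudicated.
#'
#' @param model a `metabolic_model` with a biomass objective.
#' @param observations tibble with columns `source` (name), `exchange`
#'   (exchange reaction id to test) and `growth` (logical observed call).
#' @param base_medium passed to [growth_on_source()].
#' @param uptake_rate,growth_threshold passed to [growth_on_source()].
#' @return A `phenotype_comparison` tibble: `source`, `exchange`,
#'   `observed`, `predicted`, `category`.
#' @export
phenotype_array <- function(model, observations, base_medium,
                            uptake_rate = 10, growth_threshold = 1e-3) {
  if (nrow(observations) == 0L)
    return(structure(tibble::tibble(source = character(),
                                    exchange = character(),
                                    observed = logical(),
                                    predicted = logical(),
                                    category = character()),
                     class = c("phenotype_comparison", class(tibble::tibble()))))
  stopifnot(all(c("source", "exchange", "growth") %in% names(observations)))
  calls <- vapply(observations$exchange, function(exid)
    growth_on_source(model, exid, base_medium = base_medium,
                     uptake_rate = uptake_rate,
                     growth_threshold = growth_threshold), character(1))
  predicted <- dplyr::case_when(calls == "growth" ~ TRUE,
                                calls == "no_growth" ~ FALSE,
                                TRUE ~ NA)
  category <- dplyr::case_when(
    calls == "no_exchange" ~ "no_exchange",
    observations$growth & predicted ~ "TP",
    !observations$growth & !predicted ~ "TN",
    !observations$growth & predicted ~ "FP",
    observations$growth & !predicted ~ "FN")
  out <- tibble::tibble(source = observations$source,
                        exchange = observations$exchange,
                        observed = observations$growth,
                        predicted = predicted,
                        category = category)
  class(out) <- c("phenotype_comparison", class(out))
  out
}

#' Summary counts for a phenotype comparison
#'
#' @param x a `phenotype_comparison`.
#' @param ... unused.
#' @return One-row tibble with `n`, `observed_positive`, `TP`, `TN`, `FP`,
#'   `FN`, `no_exchange` and `accuracy` (over the adjudicated sources).
#' @export
glance.phenotype_comparison <- function(x, ...) {
  cnt <- function(k) sum(x$category == k, na.rm = TRUE)
  adjudicated <- sum(x$category != "no_exchange", na.rm = TRUE)
  tibble::tibble(n = nrow(x),
                 observed_positive = sum(x$observed),
                 TP = cnt("TP"), TN = cnt("TN"),
                 FP = cnt("FP"), FN = cnt("FN"),
                 no_exchange = cnt("no_exchange"),
                 accuracy = if (adjudicated > 0)
                   (cnt("TP") + cnt("TN")) / adjudicated else NA_real_)
}
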