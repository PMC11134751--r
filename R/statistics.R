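#' Model statistics report
#'
#' Summarises a model the way genome-scale reconstructions are usually
#' reported: totals, per-compartment reaction counts (a reaction is counted
#' in every compartment where it has a participant, so transporters count at
#' both endpoints -- the "reactions + transport reactions" convention),
#' per-compartment metabolite counts, transporter counts per compartment
#' pair, exchange-reaction count, and the number of distinct enzyme
#' complexes implied by the GPR rules.
#'
#' @param model a `metabolic_model`.
#' @return A `model_statistics` object (a list of tibbles and scalars).
#' @export
model_statistics <- function(model) {
  validate_model(model)
  sto <- dplyr::left_join(model$stoichiometry,
                          model$metabolites[, c("id", "compartment")],
                          by = c(metabolite_id = "id"))
  comps <- names(model_compartments)

  rx_by_comp <- sto |>
    dplyr::distinct(.data$reaction_id, .data$compartment) |>
    dplyr::count(.data$compartment, name = "reactions")
  met_by_comp <- model$metabolites |>
    dplyr::count(.data$compartment, name = "metabolites")
  by_comp <- tibble::tibble(compartment = comps,
                            compartment_name = unname(model_compartments)) |>
    dplyr::left_join(rx_by_comp, by = "compartment") |>
    dplyr::left_join(met_by_comp, by = "compartment") |>
    dplyr::mutate(reactions = dplyr::coalesce(.data$reactions, 0L),
                  metabolites = dplyr::coalesce(.data$metabolites, 0L))

  transport <- is_transport(model)
  pair_tbl <- sto |>
    dplyr::filter(.data$reaction_id %in% model$reactions$id[transport]) |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(pair = paste(sort(unique(.data$compartment)),
                                  collapse = "<->")) |>
    dplyr::count(.data$pair, name = "transporters")

  structure(list(
    model_id = model$id,
    totals = tibble::tibble(
      reactions = nrow(model$reactions),
      metabolites = nrow(model$metabolites),
      genes = length(model$genes)),
    by_compartment = by_comp,
    transporters = pair_tbl,
    exchange_reactions = sum(is_exchange(model)),
    enzyme_complexes = length(enzyme_complexes(model))),
    class = "model_statistics")
}

#' @export
print.model_statistics <- function(x, ...) {
  cat("Model statistics:", x$model_id, "\n")
  cat(sprintf("  %-46s %6d\n", "Total reactions", x$totals$reactions))
  for (i in seq_len(nrow(x$by_compartment)))
    cat(sprintf("  %-46s %6d\n",
                paste0("Reactions touching ", x$by_compartment$compartment_name[i],
                       " (+ transport)"),
                x$by_compartment$reactions[i]))
  cat(sprintf("  %-46s %6d\n", "Total metabolites", x$totals$metabolites))
  for (i in seq_len(nrow(x$by_compartment)))
    cat(sprintf("  %-46s %6d\n",
                paste0("Metabolites in ", x$by_compartment$compartment_name[i]),
                x$by_compartment$metabolites[i]))
  cat(sprintf("  %-46s %6d\n", "Total genes", x$totals$genes))
  cat(sprintf("  %-46s %6d\n", "Exchange reactions", x$exchange_reactions))
  for (i in seq_len(nrow(x$transporters)))
    cat(sprintf("  %-46s %6d\n",
                paste0("Transporters ", x$transporters$pair[i]),
                x$transporters$transporters[i]))
  cat(sprintf("  %-46s %6d\n", "Enzyme complexes", x$enzyme_complexes))
  invisible(x)
}

#' Tidy a model-statistics report into one long tibble
#'
#' @param x a `model_statistics` object.
#' @param ... unused.
#' @return Tibble with columns `statistic` and `value`.
#' @export
tidy.model_statistics <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(statistic = c("reactions_total", "metabolites_total",
                                 "genes_total"),
                   value = as.numeric(unlist(x$totals))),
    tibble::tibble(
      statistic = paste0("reactions_", x$by_compartment$compartment_name),
      value = as.numeric(x$by_compartment$reactions)),
    tibble::tibble(
      statistic = paste0("metabolites_", x$by_compartment$compartment_name),
      value = as.numeric(x$by_compartment$metabolites)),
    tibble::tibble(statistic = paste0("transporters_", x$transporters$pair),
                   value = as.numeric(x$transporters$transporters)),
    tibble::tibble(statistic = c("exchange_reactions", "enzyme_complexes"),
                   value = c(x$exchange_reactions, x$enzyme_complexes)))
}

#' Write a statistics report as JSON
#'
#' @param x a `model_statistics` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_statistics_json <- function(x, path) {
  tb <- tidy.model_statistics(x)
  jsonlite::write_json(
    c(list(model_id = x$model_id),
      stats::setNames(as.list(tb$value), tb$statistic)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
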