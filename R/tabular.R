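#' Parse a reaction-equation string
#'
#' Equations use `->` (irreversible) or `<=>` (reversible) arrows and
#' compartment-suffixed metabolite tokens such as `glc__D[e]`; coefficients
#' prefix the token (`2 pyr[m]`). Either side may be empty, giving a
#' boundary (exchange/demand) reaction.
#'
#' @param equation equation string, e.g. `"glc__D[e] -> glc__D[c]"`.
#' @return A list with `stoichiometry` (named numeric, metabolite id ->
#'   coefficient, ids spelled `base_compartment`), `compartments` (named
#'   character) and `reversible` (logical).
#' @export
parse_reaction_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L)
  reversible <- grepl("<=>", equation, fixed = TRUE)
  sides <- strsplit(equation, if (reversible) "<=>" else "->", fixed = TRUE)[[1]]
  if (!grepl("<=>|->", equation))
    stop("no reaction arrow ('->' or '<=>') in: ", equation, call. = FALSE)
  if (length(sides) > 2L)
    stop("more than one arrow in: ", equation, call. = FALSE)
  sides <- c(sides, rep("", 2L - length(sides)))

  parse_side <- function(text, sign) {
    text <- trimws(text)
    if (!nzchar(text)) return(NULL)
    terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
    out <- list()
    for (term in terms) {
      if (!nzchar(term))
        stop("empty term in equation side: '", text, "'", call. = FALSE)
      m <- regmatches(term,
        regexec("^(?:([0-9.]+)\\s+)?([^\\s\\[\\]]+)\\[([a-z])\\]$", term,
                perl = TRUE))[[1]]
      if (length(m) == 0L)
        stop("malformed metabolite term: '", term, "'", call. = FALSE)
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      list_id <- paste0(m[3], "_", m[4])
      out[[length(out) + 1L]] <- c(id = list_id, comp = m[4], coef = sign * coef)
    }
    out
  }
  terms <- c(parse_side(sides[1], -1), parse_side(sides[2], 1))
  if (length(terms) == 0L)
    stop("equation has no metabolites: ", equation, call. = FALSE)
  sto <- vapply(terms, function(t) as.numeric(t[["coef"]]), numeric(1))
  ids <- vapply(terms, function(t) t[["id"]], character(1))
  comps <- vapply(terms, function(t) t[["comp"]], character(1))
  agg <- tapply(sto, ids, sum)   # same metabolite on both sides folds
  keep <- names(agg)[abs(agg) > 0]
  list(stoichiometry = stats::setNames(as.numeric(agg[keep]), keep),
       compartments = stats::setNames(comps, ids)[keep],
       reversible = reversible)
}

deparse_reaction_equation <- function(model, reaction_id) {
  sto <- model$stoichiometry[model$stoichiometry$reaction_id == reaction_id, ]
  comp <- model$metabolites$compartment[match(sto$metabolite_id,
                                              model$metabolites$id)]
  base <- mapply(function(id, cc) sub(paste0("_", cc, "$"), "", id),
                 sto$metabolite_id, comp)
  fmt <- function(coef, b, cc) {
    pre <- if (abs(coef - 1) < 1e-12) ""
           else paste0(format(coef, trim = TRUE, digits = 17), " ")
    paste0(pre, b, "[", cc, "]")
  }
  lhs <- sto$coefficient < 0
  arrow <- if (model$reactions$lower_bound[match(reaction_id, model$reactions$id)] < 0)
    "<=>" else "->"
  paste(
    paste(mapply(fmt, -sto$coefficient[lhs], base[lhs], comp[lhs]), collapse = " + "),
    arrow,
    paste(mapply(fmt, sto$coefficient[!lhs], base[!lhs], comp[!lhs]), collapse = " + "))
}

#' Read a model from the tabular (CSV-directory) dialect
#'
#' Expects a directory containing `reactions.csv` (columns `id`, `equation`,
#' optional `name`, `lower_bound`, `upper_bound`, `subsystem`, `gpr`,
#' `objective`), optional `metabolites.csv` (`id`, `name`, `compartment`,
#' `formula`, `charge`) and optional `genes.csv` (`id`). Metabolites absent
#' from `metabolites.csv` are declared from the equations themselves.
#'
#' @param path directory containing the CSV files.
#' @return A `metabolic_model`.
#' @export
read_tabular_model <- function(path) {
  rfile <- file.path(path, "reactions.csv")
  if (!file.exists(rfile))
    stop("no reactions.csv under ", path, call. = FALSE)
  rx <- readr::read_csv(rfile, show_col_types = FALSE)
  if (!all(c("id", "equation") %in% names(rx)))
    stop("reactions.csv needs 'id' and 'equation' columns", call. = FALSE)

  sto_list <- vector("list", nrow(rx))
  comp_seen <- character()
  reversible <- logical(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    parsed <- tryCatch(parse_reaction_equation(rx$equation[i]),
                       error = function(e)
                         stop("reactions.csv row ", i, " (", rx$id[i], "): ",
                              conditionMessage(e), call. = FALSE))
    sto_list[[i]] <- tibble::tibble(
      reaction_id = rx$id[i],
      metabolite_id = names(parsed$stoichiometry),
      coefficient = unname(parsed$stoichiometry))
    reversible[i] <- parsed$reversible
    comp_seen <- c(comp_seen, parsed$compartments)
  }
  stoichiometry <- dplyr::bind_rows(sto_list)

  mfile <- file.path(path, "metabolites.csv")
  declared <- if (file.exists(mfile))
    readr::read_csv(mfile, show_col_types = FALSE) else tibble::tibble(id = character())
  comp_seen <- comp_seen[!duplicated(names(comp_seen))]
  inferred <- tibble::tibble(id = names(comp_seen),
                             compartment = unname(comp_seen))
  metabolites <- dplyr::bind_rows(
    declared,
    inferred[!inferred$id %in% declared$id, ])

  if (!"lower_bound" %in% names(rx)) rx$lower_bound <- ifelse(reversible, -1000, 0)
  if (!"upper_bound" %in% names(rx)) rx$upper_bound <- 1000
  objective <- NULL
  if ("objective" %in% names(rx)) {
    flagged <- rx$id[which(as.logical(rx$objective))]
    if (length(flagged)) objective <- flagged[[1]]
    rx$objective <- NULL
  }

  gfile <- file.path(path, "genes.csv")
  genes <- if (file.exists(gfile))
    readr::read_csv(gfile, show_col_types = FALSE)$id else NULL

  metabolic_model(metabolites = metabolites,
                  reactions = rx[, setdiff(names(rx), "equation")],
                  stoichiometry = stoichiometry,
                  genes = genes, objective = objective,
                  id = basename(path))
}

#' Write a model in the tabular (CSV-directory) dialect
#'
#' @param model a `metabolic_model`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_tabular_model <- function(model, path) {
  validate_model(model)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rx <- model$reactions
  rx$equation <- vapply(rx$id, function(id) deparse_reaction_equation(model, id),
                        character(1))
  rx$objective <- rx$id %in% model$objective
  readr::write_csv(rx[, c("id", "name", "equation", "lower_bound",
                          "upper_bound", "subsystem", "gpr", "objective")],
                   file.path(path, "reactions.csv"))
  readr::write_csv(model$metabolites, file.path(path, "metabolites.csv"))
  readr::write_csv(tibble::tibble(id = model$genes), file.path(path, "genes.csv"))
  invisible(path)
}
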