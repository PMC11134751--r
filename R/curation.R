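## Which reactions can produce / consume each metabolite, honouring
## reversibility. Exchange reactions count as both producer and consumer:
## they are boundaries, not evidence of a missing pathway.
producer_consumer_sets <- function(model) {
  ex_ids <- model$reactions$id[is_exchange(model)]
  sto <- dplyr::left_join(
    model$stoichiometry,
    model$reactions[, c("id", "lower_bound", "upper_bound")],
    by = c(reaction_id = "id"))
  sto$is_ex <- sto$reaction_id %in% ex_ids
  sto$produces <- sto$is_ex |
    (sto$coefficient > 0 & sto$upper_bound > 0) |
    (sto$coefficient < 0 & sto$lower_bound < 0)
  sto$consumes <- sto$is_ex |
    (sto$coefficient < 0 & sto$upper_bound > 0) |
    (sto$coefficient > 0 & sto$lower_bound < 0)
  sto
}

#' Find dead-end metabolites
#'
#' A dead-end metabolite cannot support steady-state flux through its
#' reactions: nothing can produce it, nothing can consume it, or its only
#' production and consumption route is one and the same reaction (a lone
#' reversible reaction cannot both make and clear a metabolite at steady
#' state). Reaction reversibility is honoured and exchange reactions count
#' as both producer and consumer.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of dead-end metabolite ids.
#' @export
find_dead_ends <- function(model) {
  sto <- producer_consumer_sets(model)
  tab <- sto |>
    dplyr::group_by(.data$metabolite_id) |>
    dplyr::summarise(
      n_prod = dplyr::n_distinct(.data$reaction_id[.data$produces]),
      n_cons = dplyr::n_distinct(.data$reaction_id[.data$consumes]),
      # a producer and a consumer that are different reactions (or one
      # boundary exchange, which is a genuine source *and* sink)
      distinct_pair = dplyr::n_distinct(
        .data$reaction_id[.data$produces | .data$consumes]) >= 2L ||
        any(.data$is_ex))
  dead <- tab$metabolite_id[tab$n_prod == 0L | tab$n_cons == 0L |
                              !tab$distinct_pair]
  orphans <- setdiff(model$metabolites$id, tab$metabolite_id)
  c(dead, orphans)
}

#' Prune dead-end metabolites and their reactions
#'
#' Iterates [find_dead_ends()] to a fixed point: at each pass, every
#' non-exchange reaction touching a dead-end metabolite is removed (such
#' reactions can never carry steady-state flux), then newly created dead
#' ends are pruned in turn. The objective reaction is never removed; if
#' pruning would require it, the function refuses with a diagnostic.
#'
#' @param model a `metabolic_model`.
#' @return A list with `model` (pruned copy; the input is unchanged) and
#'   `report`, a `dead_end_report` with `dead_end_metabolites`,
#'   `removable_reactions` and `iterations`.
#' @export
prune_dead_ends <- function(model) {
  all_dead <- character()
  all_removed <- character()
  iterations <- 0L
  current <- model
  repeat {
    dead <- find_dead_ends(current)
    if (length(dead) == 0L) break
    ex_ids <- current$reactions$id[is_exchange(current)]
    touching <- unique(current$stoichiometry$reaction_id[
      current$stoichiometry$metabolite_id %in% dead])
    removable <- setdiff(touching, ex_ids)
    if (!is.null(current$objective) && current$objective %in% removable)
      stop("pruning would remove the objective reaction ",
           current$objective, ": dead-end metabolite(s) ",
           paste(intersect(dead, current$stoichiometry$metabolite_id[
             current$stoichiometry$reaction_id == current$objective]),
             collapse = ", "),
           " feed only the objective", call. = FALSE)
    if (length(removable) == 0L) break    # only exchanges touch them
    iterations <- iterations + 1L
    all_dead <- union(all_dead, dead)
    all_removed <- union(all_removed, removable)
    current <- remove_reactions(current, removable, drop_orphans = TRUE)
  }
  report <- structure(list(dead_end_metabolites = all_dead,
                           removable_reactions = all_removed,
                           iterations = iterations),
                      class = "dead_end_report")
  list(model = current, report = report)
}

#' @export
print.dead_end_report <- function(x, ...) {
  cat("<dead_end_report> ", length(x$dead_end_metabolites),
      " dead-end metabolites, ", length(x$removable_reactions),
      " reactions removed in ", x$iterations, " iteration(s)\n", sep = "")
  invisible(x)
}

## Parse an elemental formula into a named count vector, or NULL when the
## string is not a plain element-count formula (R-groups, '*', dashes, ...).
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]+\\.?[0-9]*|\\.[0-9]+)?", formula)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(formula))
    return(NULL)
  parts <- regmatches(formula, list(m))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  cnt <- suppressWarnings(as.numeric(sub("^[A-Z][a-z]?", "", parts)))
  cnt[is.na(cnt)] <- 1
  if (any(el %in% c("R", "X")))    # generic residue markers
    return(NULL)
  tapply(cnt, el, sum)
}

#' Flag reactions touching generic metabolites
#'
#' A metabolite is generic when it has no exact mass: its formula is absent
#' or contains residue markers (R-groups, asterisks, anything that is not a
#' plain element-count formula, e.g. `"R-COOH"`).
#'
#' @param model a `metabolic_model`.
#' @param exempt reaction ids to skip (defaults to exchange reactions and
#'   the objective, whose pseudo-metabolites legitimately lack formulas).
#' @return Character vector of flagged reaction ids.
#' @export
find_generic_reactions <- function(model,
                                   exempt = c(model$reactions$id[is_exchange(model)],
                                              model$objective)) {
  generic_mets <- model$metabolites$id[vapply(
    model$metabolites$formula, function(f) is.null(parse_formula(f)),
    logical(1))]
  flagged <- unique(model$stoichiometry$reaction_id[
    model$stoichiometry$metabolite_id %in% generic_mets])
  setdiff(flagged, exempt)
}

#' Check elemental mass balance of every reaction
#'
#' Exchange reactions, the objective (biomass) reaction and reactions with
#' unparseable or missing formulas are skipped and listed with a reason;
#' every other reaction gets a per-element net imbalance
#' (`sum(coefficient * element_count)`, zero for balanced).
#'
#' @param model a `metabolic_model`.
#' @param tol absolute tolerance below which an imbalance counts as zero.
#' @return A `balance_report`: list with `imbalances` (tibble `reaction`,
#'   `element`, `imbalance`; only nonzero rows) and `skipped` (tibble
#'   `reaction`, `reason`).
#' @export
check_mass_balance <- function(model, tol = 1e-9) {
  ex_ids <- model$reactions$id[is_exchange(model)]
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  imb <- list(); skipped <- list()
  for (rid in model$reactions$id) {
    if (rid %in% ex_ids) {
      skipped[[rid]] <- "exchange"
      next
    }
    if (!is.null(model$objective) && rid == model$objective) {
      skipped[[rid]] <- "objective/biomass"
      next
    }
    sto <- model$stoichiometry[model$stoichiometry$reaction_id == rid, ]
    counts <- lapply(sto$metabolite_id, function(mid) parse_formula(formulas[[mid]]))
    bad <- vapply(counts, is.null, logical(1))
    if (any(bad)) {
      skipped[[rid]] <- paste("unparseable or missing formula:",
                              paste(sto$metabolite_id[bad], collapse = ", "))
      next
    }
    els <- unique(unlist(lapply(counts, names)))
    net <- vapply(els, function(e) sum(vapply(seq_along(counts), function(i) {
      k <- counts[[i]]
      sto$coefficient[i] * (if (e %in% names(k)) k[[e]] else 0)
    }, numeric(1))), numeric(1))
    net <- net[abs(net) > tol]
    if (length(net))
      imb[[rid]] <- tibble::tibble(reaction = rid, element = names(net),
                                   imbalance = unname(net))
  }
  structure(list(
    imbalances = if (length(imb)) dplyr::bind_rows(imb)
                 else tibble::tibble(reaction = character(),
                                     element = character(),
                                     imbalance = numeric()),
    skipped = tibble::tibble(reaction = names(skipped),
                             reason = unlist(skipped, use.names = FALSE))),
    class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report> ", dplyr::n_distinct(x$imbalances$reaction),
      " unbalanced reaction(s), ", nrow(x$skipped), " skipped\n", sep = "")
  invisible(x)
}

#' Test producibility of every biomass precursor
#'
#' For each substrate of the biomass (objective) reaction, a temporary
#' demand reaction is opened and its maximum flux computed under the given
#' medium; the precursor is producible when that flux exceeds `tol`
#' (the LP solver noise floor). The input model is not modified.
#'
#' Currency metabolites are exempt by default: consumed metabolites without
#' carbon or nitrogen (water, protons, phosphate) and consumed metabolites
#' whose C/N backbone matches a co-produced partner (the ATP/ADP couple of
#' growth-associated maintenance) can never show *net* production -- their
#' moiety is conserved -- and are energy bookkeeping, not biosynthesis.
#'
#' @param model a `metabolic_model` with a biomass objective.
#' @param medium exchange ids (or named uptake-rate vector) for
#'   [set_medium()].
#' @param tol producibility flux threshold, mmol gDW^-1 h^-1.
#' @param exclude metabolite ids to skip; `NULL` applies the currency rule
#'   above, `character()` probes every consumed metabolite.
#' @return Tibble with `precursor` and `producible`.
#' @export
precursor_producibility <- function(model, medium, tol = 1e-6,
                                    exclude = NULL) {
  if (is.null(model$objective))
    stop("model has no biomass (objective) reaction", call. = FALSE)
  sto <- model$stoichiometry[model$stoichiometry$reaction_id == model$objective, ]
  precursors <- sto$metabolite_id[sto$coefficient < 0]
  if (is.null(exclude)) {
    backbone <- function(mid) {
      f <- parse_formula(model$metabolites$formula[
        match(mid, model$metabolites$id)])
      if (is.null(f)) return(NULL)
      c(C = if ("C" %in% names(f)) f[["C"]] else 0,
        N = if ("N" %in% names(f)) f[["N"]] else 0)
    }
    produced <- sto$metabolite_id[sto$coefficient > 0]
    produced_bb <- Filter(Negate(is.null), lapply(produced, backbone))
    is_currency <- vapply(precursors, function(mid) {
      bb <- backbone(mid)
      if (is.null(bb)) return(FALSE)
      if (sum(bb) == 0) return(TRUE)                 # no C, no N
      any(vapply(produced_bb, function(pb) all(pb == bb), logical(1)))
    }, logical(1))
    precursors <- precursors[!is_currency]
  } else {
    precursors <- setdiff(precursors, exclude)
  }
  m0 <- set_medium(model, medium)
  purrr::map_dfr(precursors, function(p) {
    m <- add_reaction(m0, "DM_producibility_probe_",
                      stats::setNames(-1, p), lower_bound = 0)
    sol <- fba(m, objective = "DM_producibility_probe_")
    tibble::tibble(precursor = p,
                   producible = sol$status == "optimal" &&
                     sol$objective_value > tol)
  })
}

#' Find blocked reactions
#'
#' A reaction is blocked on a medium when its flux range under FVA (with no
#' objective requirement, `fraction_of_optimum = 0`) is exactly `{0}`.
#'
#' @param model a `metabolic_model`.
#' @param medium passed to [set_medium()].
#' @param tol absolute flux below which a range endpoint counts as zero.
#' @return Character vector of blocked reaction ids.
#' @export
find_blocked_reactions <- function(model, medium, tol = 1e-6) {
  m <- set_medium(model, medium)
  fva <- flux_variability(m, fraction_of_optimum = 0)
  fva$reaction[abs(fva$min_flux) < tol & abs(fva$max_flux) < tol]
}

#' Apply a curation patch file
#'
#' Curation decisions that are data edits, not algorithms (cofactor-specific
#' reaction selection, literature-based removals), are kept as a declarative
#' TSV with columns `action` (`drop`), `reaction_id` and `reason`.
#'
#' @param model a `metabolic_model`.
#' @param path TSV patch file.
#' @return The patched model.
#' @export
apply_patch <- function(model, path) {
  patch <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("action", "reaction_id", "reason") %in% names(patch)))
  bad <- setdiff(unique(patch$action), "drop")
  if (length(bad))
    stop("unsupported patch action(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  remove_reactions(model, patch$reaction_id[patch$action == "drop"])
}
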