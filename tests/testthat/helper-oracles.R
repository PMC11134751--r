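# Independent oracles used by the test suite. These deliberately avoid the
# package's own algorithms: the LP oracle enumerates basic solutions, the
# dead-end oracle recomputes producer/consumer sets with plain loops and
# removes one reaction at a time, and the GPR oracle hands the rule to R's
# own parser.

# Brute-force LP oracle: enumerate all candidate vertices of
# {S v = 0, lb <= v <= ub} by fixing (n - rank(S)) variables at a bound and
# solving for the rest; return the best objective value over feasible ones.
lp_vertex_oracle <- function(obj, S, lb, ub, direction = "max", tol = 1e-7) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  nf <- n - r
  best <- NA_real_
  better <- if (direction == "max") function(a, b) a > b else function(a, b) a < b
  fix_sets <- if (nf == 0) list(integer()) else utils::combn(n, nf, simplify = FALSE)
  for (fix_idx in fix_sets) {
    free <- setdiff(seq_len(n), fix_idx)
    B <- S[, free, drop = FALSE]
    qb <- qr(B)
    if (qb$rank < length(free)) next
    n_pat <- if (nf == 0) 1L else 2L^nf
    for (pat in seq_len(n_pat) - 1L) {
      at_ub <- if (nf == 0) logical(0) else
        bitwAnd(pat, 2L^(seq_len(nf) - 1L)) > 0L
      xf <- ifelse(at_ub, ub[fix_idx], lb[fix_idx])
      rhs <- if (nf == 0) rep(0, nrow(S)) else
        -as.vector(S[, fix_idx, drop = FALSE] %*% xf)
      xfree <- qr.coef(qb, rhs)
      if (any(is.na(xfree))) next
      if (max(abs(as.vector(B %*% xfree) - rhs)) > tol) next
      x <- numeric(n)
      x[fix_idx] <- xf
      x[free] <- xfree
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      if (is.na(best) || better(val, best)) best <- val
    }
  }
  best
}

# Naive dead-end finder: double loop over the dense stoichiometric matrix,
# collecting explicit producer/consumer reaction sets.
naive_dead_ends <- function(model) {
  S <- stoichiometric_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  ex <- is_exchange(model)
  dead <- character()
  for (i in seq_len(nrow(S))) {
    prod_set <- character()
    cons_set <- character()
    touches_exchange <- FALSE
    for (j in seq_len(ncol(S))) {
      cij <- S[i, j]
      if (cij == 0) next
      rid <- colnames(S)[j]
      if (ex[j]) {
        touches_exchange <- TRUE
        prod_set <- c(prod_set, rid)
        cons_set <- c(cons_set, rid)
        next
      }
      if ((cij > 0 && ub[j] > 0) || (cij < 0 && lb[j] < 0))
        prod_set <- c(prod_set, rid)
      if ((cij < 0 && ub[j] > 0) || (cij > 0 && lb[j] < 0))
        cons_set <- c(cons_set, rid)
    }
    ok <- length(prod_set) > 0 && length(cons_set) > 0 &&
      (touches_exchange ||
         length(unique(c(prod_set, cons_set))) >= 2L)
    if (!ok) dead <- c(dead, rownames(S)[i])
  }
  dead
}

# Remove-one-recheck pruning oracle: repeatedly drop a single (non-exchange,
# non-objective) reaction touching a dead-end metabolite, rechecking after
# every removal.
prune_oracle <- function(model) {
  removed <- character()
  repeat {
    dead <- naive_dead_ends(model)
    if (length(dead) == 0L) break
    ex_ids <- model$reactions$id[is_exchange(model)]
    touching <- unique(model$stoichiometry$reaction_id[
      model$stoichiometry$metabolite_id %in% dead])
    candidates <- setdiff(touching, c(ex_ids, model$objective))
    if (length(candidates) == 0L) break
    victim <- candidates[[1L]]
    model <- remove_reactions(model, victim, drop_orphans = TRUE)
    removed <- c(removed, victim)
  }
  list(model = model, removed = removed)
}

# Seeded random metabolic network: ~n_rxn internal conversions over n_met
# metabolites plus exchanges for a random subset, some reversible.
random_network <- function(seed, n_met = 25, n_rxn = 50) {
  set.seed(seed)
  mets <- sprintf("m%02d_c", seq_len(n_met))
  sto <- list()
  rxn <- list()
  for (j in seq_len(n_rxn)) {
    k_in <- sample(1:2, 1)
    k_out <- sample(1:2, 1)
    picks <- sample(n_met, k_in + k_out)
    rid <- sprintf("R%03d", j)
    sto[[j]] <- tibble::tibble(
      reaction_id = rid,
      metabolite_id = mets[picks],
      coefficient = c(rep(-1, k_in), rep(1, k_out)))
    rev <- stats::runif(1) < 0.3
    rxn[[j]] <- tibble::tibble(id = rid, lower_bound = if (rev) -1000 else 0,
                               upper_bound = 1000)
  }
  n_ex <- sample(3:8, 1)
  ex_mets <- sample(n_met, n_ex)
  for (k in seq_along(ex_mets)) {
    rid <- sprintf("EX_m%02d_e", ex_mets[k])
    eid <- sprintf("m%02d_e", ex_mets[k])
    tid <- sprintf("T%03d", k)
    sto <- c(sto, list(
      tibble::tibble(reaction_id = rid, metabolite_id = eid, coefficient = -1),
      tibble::tibble(reaction_id = tid,
                     metabolite_id = c(eid, mets[ex_mets[k]]),
                     coefficient = c(-1, 1))))
    rxn <- c(rxn, list(
      tibble::tibble(id = rid, lower_bound = -1000, upper_bound = 1000),
      tibble::tibble(id = tid, lower_bound = -1000, upper_bound = 1000)))
  }
  sto <- dplyr::bind_rows(sto)
  mtbl <- tibble::tibble(id = unique(sto$metabolite_id))
  mtbl$compartment <- ifelse(grepl("_e$", mtbl$id), "e", "c")
  metabolic_model(metabolites = mtbl, reactions = dplyr::bind_rows(rxn),
                  stoichiometry = sto, id = sprintf("random_%d", seed))
}

# GPR oracle: translate the rule to an R logical expression and let R's own
# parser/evaluator decide.
gpr_r_oracle <- function(rule, genes, present) {
  txt <- rule
  for (g in genes) {
    txt <- gsub(paste0("\\b", g, "\\b"),
                if (g %in% present) "TRUE" else "FALSE", txt)
  }
  txt <- gsub("\\band\\b", "&&", txt, ignore.case = TRUE)
  txt <- gsub("\\bor\\b", "||", txt, ignore.case = TRUE)
  eval(parse(text = txt))
}

# Random GPR rule with at most max_leaves leaves.
random_gpr <- function(seed, max_leaves = 10) {
  set.seed(seed)
  n <- sample(2:max_leaves, 1)
  genes <- sprintf("g%d", seq_len(n))
  build <- function(ids) {
    if (length(ids) == 1L) return(ids)
    split_at <- sample(seq_len(length(ids) - 1L), 1)
    left <- build(ids[seq_len(split_at)])
    right <- build(ids[-seq_len(split_at)])
    op <- sample(c("and", "or"), 1)
    wrap <- function(x) if (stats::runif(1) < 0.5) paste0("(", x, ")") else x
    paste(wrap(left), op, wrap(right))
  }
  list(rule = build(genes), genes = genes)
}
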