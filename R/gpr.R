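#' Parse a Boolean gene-protein-reaction rule
#'
#' GPR rules link genes to reaction availability: `and` joins members of an
#' enzyme complex (all required), `or` joins isozymes (any suffices).
#' `and` binds tighter than `or`; parentheses override. Operators are
#' case-insensitive; gene ids are any other whitespace-delimited tokens.
#'
#' @param text rule string, e.g. `"g1 and (g2 or g3)"`.
#' @return A `gpr` object: a nested list with `op` in
#'   `{"gene", "and", "or"}`, and `gene` (leaf) or `args` (internal node).
#' @export
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
parse_gpr <- function(text) {
  if (inherits(text, "gpr")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- gpr_tokenize(text)
  if (length(tokens) == 0L)
    stop("empty GPR rule", call. = FALSE)
  st <- list(tokens = tokens, pos = 1L)
  res <- gpr_parse_or(st)
  if (res$st$pos <= length(tokens))
    stop("trailing tokens in GPR rule at: ",
         paste(tokens[res$st$pos:length(tokens)], collapse = " "),
         call. = FALSE)
  structure(res$node, class = "gpr")
}

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  tokens <- strsplit(trimws(text), "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$tokens)) NA_character_ else st$tokens[st$pos]
}

gpr_parse_or <- function(st) {
  left <- gpr_parse_and(st)
  st <- left$st
  args <- list(left$node)
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_and(st)
    st <- nxt$st
    args <- c(args, list(nxt$node))
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  list(node = node, st = st)
}

gpr_parse_and <- function(st) {
  left <- gpr_parse_atom(st)
  st <- left$st
  args <- list(left$node)
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    nxt <- gpr_parse_atom(st)
    st <- nxt$st
    args <- c(args, list(nxt$node))
  }
  node <- if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  list(node = node, st = st)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok))
    stop("unexpected end of GPR rule (missing operand)", call. = FALSE)
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    st <- inner$st
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("unbalanced parentheses in GPR rule", call. = FALSE)
    st$pos <- st$pos + 1L
    return(list(node = inner$node, st = st))
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or"))
    stop("empty operand in GPR rule near '", tok, "'", call. = FALSE)
  st$pos <- st$pos + 1L
  list(node = list(op = "gene", gene = tok), st = st)
}

#' Evaluate a GPR rule under a gene-presence assignment
#'
#' @param gpr a `gpr` object from [parse_gpr()] or a rule string.
#' @param present character vector of present gene ids; everything else is
#'   treated as absent/deleted.
#' @return `TRUE` when the reaction remains catalysable.
#' @export
#' @examples
#' evaluate_gpr("g1 and (g2 or g3)", present = c("g1", "g3"))
evaluate_gpr <- function(gpr, present) {
  node <- parse_gpr(gpr)
  eval_node <- function(nd) {
    switch(nd$op,
           gene = nd$gene %in% present,
           and = all(vapply(nd$args, eval_node, logical(1))),
           or = any(vapply(nd$args, eval_node, logical(1))))
  }
  eval_node(node)
}

#' Gene ids appearing in a GPR rule
#'
#' @param gpr a `gpr` object or rule string.
#' @return Character vector of unique gene ids (leaf order).
#' @export
gpr_genes <- function(gpr) {
  node <- parse_gpr(gpr)
  collect <- function(nd) {
    if (nd$op == "gene") return(nd$gene)
    unlist(lapply(nd$args, collect))
  }
  unique(collect(node))
}

#' @export
print.gpr <- function(x, ...) {
  cat(deparse_gpr(x), "\n")
  invisible(x)
}

#' Render a GPR tree back to rule text
#'
#' @param gpr a `gpr` object.
#' @return A single rule string with explicit parentheses around `or` groups
#'   nested under `and`.
#' @export
deparse_gpr <- function(gpr) {
  node <- parse_gpr(gpr)
  render <- function(nd, parent_op = "or") {
    if (nd$op == "gene") return(nd$gene)
    parts <- vapply(nd$args, render, character(1), parent_op = nd$op)
    out <- paste(parts, collapse = paste0(" ", nd$op, " "))
    if (nd$op == "or" && parent_op == "and") paste0("(", out, ")") else out
  }
  render(node)
}

#' Enzyme-complex gene sets of a model
#'
#' Expands each reaction's GPR to disjunctive normal form and collects the
#' distinct conjunction (ALL-OF) gene sets with at least two members --
#' i.e. the enzyme complexes implied by the rules, deduplicated across
#' reactions at set level.
#'
#' @param model a `metabolic_model`.
#' @return A list of character vectors, one per distinct complex.
#' @export
enzyme_complexes <- function(model) {
  rules <- model$reactions$gpr[!is.na(model$reactions$gpr)]
  sets <- list()
  for (rule in rules) {
    for (s in gpr_dnf(parse_gpr(rule))) {
      if (length(s) >= 2L) sets <- c(sets, list(sort(unique(s))))
    }
  }
  unique(sets)
}

## DNF expansion: list of gene-id vectors, one per AND-term.
gpr_dnf <- function(node) {
  switch(node$op,
         gene = list(node$gene),
         or = unlist(lapply(node$args, gpr_dnf), recursive = FALSE),
         and = {
           parts <- lapply(node$args, gpr_dnf)
           Reduce(function(a, b) {
             out <- list()
             for (x in a) for (y in b) out <- c(out, list(c(x, y)))
             out
           }, parts)
         })
}
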