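#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers, with \code{and}
#' for enzyme complexes (all subunits required) and \code{or} for isozymes
#' (any one suffices).  Rules are parsed into an expression tree so that
#' knockouts can be propagated to reactions deterministically.
#'
#' @param text GPR string, e.g. \code{"(sucA and sucB and lpdA)"} or
#'   \code{"gadA or gadB"}.  \code{""} and \code{NA} denote the empty rule.
#' @return a \code{gpr} object: \code{NULL} for the empty rule, otherwise a
#'   nested list with elements \code{op} (\code{"and"}/\code{"or"}) and
#'   \code{args}, or \code{gene} at the leaves.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) ||
      !nzchar(trimws(text)))
    return(structure(list(), class = "gpr", empty = TRUE))
  toks <- gpr_tokens(text)
  env <- new.env()
  env$toks <- toks; env$pos <- 1L
  tree <- gpr_parse_or(env)
  if (env$pos <= length(env$toks))
    stop("malformed GPR rule near '", env$toks[env$pos], "': ", text)
  class(tree) <- "gpr"
  tree
}

gpr_tokens <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(env) {
  if (env$pos > length(env$toks)) NA_character_ else env$toks[env$pos]
}

gpr_parse_or <- function(env) {
  args <- list(gpr_parse_and(env))
  while (!is.na(tk <- gpr_peek(env)) && tolower(tk) == "or") {
    env$pos <- env$pos + 1L
    args <- c(args, list(gpr_parse_and(env)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(env) {
  args <- list(gpr_parse_atom(env))
  while (!is.na(tk <- gpr_peek(env)) && tolower(tk) == "and") {
    env$pos <- env$pos + 1L
    args <- c(args, list(gpr_parse_atom(env)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(env) {
  tk <- gpr_peek(env)
  if (is.na(tk)) stop("unexpected end of GPR rule")
  if (tk == "(") {
    env$pos <- env$pos + 1L
    node <- gpr_parse_or(env)
    if (!identical(gpr_peek(env), ")")) stop("unbalanced '(' in GPR rule")
    env$pos <- env$pos + 1L
    return(node)
  }
  if (tk %in% c(")", "and", "AND", "or", "OR"))
    stop("malformed GPR rule near '", tk, "'")
  env$pos <- env$pos + 1L
  list(gene = tk)
}

gpr_is_empty <- function(gpr) {
  is.null(gpr) || isTRUE(attr(gpr, "empty")) ||
    (is.list(gpr) && length(gpr) == 0L)
}

#' Evaluate a GPR rule under a gene-knockout set
#'
#' A leaf is active iff its gene is not knocked out; an \code{and} node is
#' active iff all children are; an \code{or} node iff any child is.  The
#' empty rule is always active (spontaneous or orphan reactions).
#'
#' @param gpr a rule from [parse_gpr()] (a plain string is accepted and
#'   parsed on the fly).
#' @param knocked character vector of knocked-out gene ids.
#' @return logical: is the reaction still catalysed?
#' @export
evaluate_gpr <- function(gpr, knocked = character()) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (gpr_is_empty(gpr)) return(TRUE)
  eval_node <- function(node) {
    if (!is.null(node$gene)) return(!(node$gene %in% knocked))
    vals <- vapply(node$args, eval_node, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  eval_node(gpr)
}

#' Genes referenced by a GPR rule
#' @inheritParams evaluate_gpr
#' @return character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (gpr_is_empty(gpr)) return(character())
  collect <- function(node) {
    if (!is.null(node$gene)) return(node$gene)
    unlist(lapply(node$args, collect))
  }
  unique(collect(gpr))
}

#' Render a GPR tree back to its string form
#' @inheritParams evaluate_gpr
#' @return a single GPR string (\code{""} for the empty rule).
#' @export
gpr_to_string <- function(gpr) {
  if (is.character(gpr)) return(gpr)
  if (gpr_is_empty(gpr)) return("")
  render <- function(node, parent_op = NULL) {
    if (!is.null(node$gene)) return(node$gene)
    parts <- vapply(node$args, render, character(1), parent_op = node$op)
    s <- paste(parts, collapse = paste0(" ", node$op, " "))
    if (!is.null(parent_op) && !identical(parent_op, node$op))
      s <- paste0("(", s, ")")
    s
  }
  render(gpr)
}
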