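## KEGG module definitions: parser for the boolean step grammar and the
## completeness score with the half-missing detection rule.
##
## Grammar, as used by KEGG module DEFINITION strings:
##   space  separates serial steps (all required, in pathway order)
##   ,      separates alternatives (OR) within a step
##   +      joins subunits of a complex (AND)
##   -X     marks component X optional (excluded from requirements)
##   --     a gap step (unannotatable reaction; excluded from requirements)
##   ( )    grouping; a parenthesized serial list inside a step counts as
##          one unit that is satisfied only when all its steps are

tokenize_module <- function(definition) {
  chars <- strsplit(definition, "", fixed = TRUE)[[1L]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  push <- function(type, text, pos)
    tokens[[length(tokens) + 1L]] <<- list(type = type, text = text, pos = pos)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) {
      while (i <= n && chars[i] %in% c(" ", "\t")) i <- i + 1L
      push("space", " ", i)
    } else if (ch == "(") { push("lparen", "(", i); i <- i + 1L }
    else if (ch == ")") { push("rparen", ")", i); i <- i + 1L }
    else if (ch == ",") { push("comma", ",", i); i <- i + 1L }
    else if (ch == "+") { push("plus", "+", i); i <- i + 1L }
    else if (ch == "-") {
      if (i + 1L <= n && chars[i + 1L] == "-" &&
          (i + 2L > n || chars[i + 2L] %in% c(" ", "\t", ")"))) {
        push("gap", "--", i); i <- i + 2L
      } else { push("minus", "-", i); i <- i + 1L }
    } else if (grepl("[A-Za-z]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[j])) j <- j + 1L
      tok <- paste(chars[i:(j - 1L)], collapse = "")
      if (!grepl("^K[0-9]{5}$", tok))
        stop(sprintf("malformed KO token '%s' at position %d", tok, i),
             call. = FALSE)
      push("ko", tok, i)
      i <- j
    } else {
      stop(sprintf("unexpected character '%s' at position %d", ch, i),
           call. = FALSE)
    }
  }
  tokens
}

# Recursive-descent parser over the token stream (held in a mutable env).
mod_node <- function(kind, children = NULL, id = NULL, optional = FALSE)
  list(kind = kind, children = children, id = id, optional = optional)

parse_serial_steps <- function(st) {
  steps <- list()
  repeat {
    tok <- peek_tok(st)
    if (is.null(tok) || tok$type == "rparen") break
    if (tok$type == "space") { take_tok(st); next }
    steps[[length(steps) + 1L]] <- parse_or_expr(st)
  }
  if (length(steps) == 0L)
    stop("empty module definition", call. = FALSE)
  mod_node("serial", children = steps)
}

parse_or_expr <- function(st) {
  parts <- list(parse_and_expr(st))
  repeat {
    tok <- peek_tok(st)
    if (is.null(tok) || tok$type != "comma") break
    take_tok(st)
    parts[[length(parts) + 1L]] <- parse_and_expr(st)
  }
  if (length(parts) == 1L) parts[[1L]] else mod_node("or", children = parts)
}

parse_and_expr <- function(st) {
  first_opt <- FALSE
  tok <- peek_tok(st)
  if (!is.null(tok) && tok$type == "minus") { take_tok(st); first_opt <- TRUE }
  parts <- list(set_optional(parse_atom(st), first_opt))
  repeat {
    tok <- peek_tok(st)
    if (is.null(tok) || !tok$type %in% c("plus", "minus")) break
    optional <- tok$type == "minus"
    take_tok(st)
    parts[[length(parts) + 1L]] <- set_optional(parse_atom(st), optional)
  }
  if (length(parts) == 1L) parts[[1L]] else mod_node("and", children = parts)
}

set_optional <- function(node, optional) {
  if (optional) node$optional <- TRUE
  node
}

parse_atom <- function(st) {
  tok <- take_tok(st)
  if (is.null(tok))
    stop("unexpected end of module definition", call. = FALSE)
  if (tok$type == "ko") return(mod_node("ko", id = tok$text))
  if (tok$type == "gap") return(mod_node("gap"))
  if (tok$type == "lparen") {
    inner <- parse_serial_steps(st)
    closing <- take_tok(st)
    if (is.null(closing) || closing$type != "rparen")
      stop(sprintf("unbalanced parentheses near position %d", tok$pos),
           call. = FALSE)
    # a single-step parenthesized group is just its content
    if (length(inner$children) == 1L) return(inner$children[[1L]])
    return(inner)
  }
  stop(sprintf("unexpected token '%s' at position %d", tok$text, tok$pos),
       call. = FALSE)
}

peek_tok <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
take_tok <- function(st) {
  tok <- peek_tok(st)
  if (!is.null(tok)) st$i <- st$i + 1L
  tok
}

#' Parse a KEGG module definition
#'
#' Parses the boolean step grammar of KEGG module DEFINITION strings into an
#' expression tree.  Optional components (`-K...`) and gap steps (`--`) are
#' excluded from the required-step count.
#'
#' @param definition Definition string, e.g. `"(K00001,K00002) K00003"`.
#' @param module_id Optional module identifier carried along.
#' @return A `module_definition`: list with `module_id`, `expression`
#'   (the tree) and `step_count` (number of required top-level steps).
#' @examples
#' m <- parse_module("K00001 -K00009 K00003")
#' m$step_count  # 2 (K00009 is optional)
#' @export
parse_module <- function(definition, module_id = NA_character_) {
  stopifnot(is.character(definition), length(definition) == 1L)
  if (!nzchar(trimws(definition)))
    stop("empty module definition", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokenize_module(definition)
  st$i <- 1L
  tree <- parse_serial_steps(st)
  left <- take_tok(st)
  if (!is.null(left))
    stop(sprintf("unbalanced parentheses near position %d", left$pos),
         call. = FALSE)
  required <- !vapply(tree$children, function(s)
    s$kind == "gap" || isTRUE(s$optional), logical(1))
  if (!any(required))
    stop("module has no required steps", call. = FALSE)
  structure(list(module_id = module_id, expression = tree,
                 step_count = sum(required)),
            class = "module_definition")
}

#' Render a parsed module back to canonical definition text
#'
#' `parse_module(render_module(m))` reproduces the tree exactly.
#'
#' @param m A `module_definition` or an internal expression node.
#' @return Definition string.
#' @export
render_module <- function(m) {
  node <- if (inherits(m, "module_definition")) m$expression else m
  render_node(node, parent = "top")
}

render_node <- function(node, parent) {
  prefix <- if (isTRUE(node$optional)) "-" else ""
  body <- switch(node$kind,
    ko = node$id,
    gap = "--",
    serial = {
      txt <- paste(vapply(node$children, render_node, "", parent = "serial"),
                   collapse = " ")
      if (parent != "top") paste0("(", txt, ")") else txt
    },
    or = {
      txt <- paste(vapply(node$children, render_node, "", parent = "or"),
                   collapse = ",")
      if (parent %in% c("and")) paste0("(", txt, ")") else txt
    },
    and = paste(vapply(node$children, render_node, "", parent = "and"),
                collapse = "+"),
    stop("unknown node kind"))
  paste0(prefix, body)
}

# TRUE when the node's requirement is met by the KO set
node_satisfied <- function(node, kos) {
  switch(node$kind,
    ko = node$id %in% kos,
    gap = TRUE,
    or = any(vapply(node$children, node_satisfied, logical(1), kos = kos)),
    and = all(vapply(node$children, function(ch) {
      isTRUE(ch$optional) || node_satisfied(ch, kos)
    }, logical(1))),
    serial = all(vapply(node$children, function(ch) {
      ch$kind == "gap" || isTRUE(ch$optional) || node_satisfied(ch, kos)
    }, logical(1))),
    stop("unknown node kind"))
}

#' Module completeness under a set of detected KOs
#'
#' The fraction of required top-level steps whose boolean expression is
#' satisfied by `kos_present`.  A module is reported detected only when
#' *more* than half of its required steps are present: a pathway missing
#' half of all required genes is considered undetected, so a fraction of
#' exactly 0.5 is not a detection.
#'
#' @param m A `module_definition` from [parse_module()].
#' @param kos_present Character vector of KO ids.
#' @return List with `module_id`, `fraction_present` in `[0, 1]` and
#'   logical `detected` (`fraction_present > 0.5`).
#' @export
module_completeness <- function(m, kos_present) {
  stopifnot(inherits(m, "module_definition"))
  if (m$step_count == 0) stop("module has no required steps", call. = FALSE)
  steps <- m$expression$children
  required <- !vapply(steps, function(s)
    s$kind == "gap" || isTRUE(s$optional), logical(1))
  ok <- vapply(steps[required], node_satisfied, logical(1),
               kos = unique(kos_present))
  fraction <- sum(ok) / m$step_count
  list(module_id = m$module_id, fraction_present = fraction,
       detected = fraction > 0.5)
}

# Minimal KO set satisfying one expression node (first alternative of each
# OR); used by the synthetic generator to program completeness exactly.
node_minimal_kos <- function(node) {
  switch(node$kind,
    ko = node$id,
    gap = character(0),
    or = node_minimal_kos(node$children[[1L]]),
    and = unlist(lapply(node$children,
                        function(ch) if (isTRUE(ch$optional)) character(0)
                                     else node_minimal_kos(ch))),
    serial = unlist(lapply(node$children,
                           function(ch) if (ch$kind == "gap" || isTRUE(ch$optional))
                             character(0) else node_minimal_kos(ch))),
    stop("unknown node kind"))
}

# All KO ids appearing anywhere in the module
module_kos <- function(m) {
  node <- if (inherits(m, "module_definition")) m$expression else m
  collect <- function(nd) {
    if (nd$kind == "ko") return(nd$id)
    unlist(lapply(nd$children, collect))
  }
  unique(collect(node))
}
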