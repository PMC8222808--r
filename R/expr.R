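# Boolean expression trees and the "targets, factors" rule dialect.
#
# An expression is a nested list with a `op` field:
#   list(op = "var",  name = <chr>)
#   list(op = "const", value = 0L or 1L)
#   list(op = "not",  x = <expr>)
#   list(op = "and",  args = list(<expr>, ...))   # n-ary
#   list(op = "or",   args = list(<expr>, ...))   # n-ary
# Precedence: NOT > AND > OR; parentheses override.

bexpr_var <- function(name) list(op = "var", name = name)
bexpr_const <- function(value) list(op = "const", value = as.integer(value))
bexpr_not <- function(x) list(op = "not", x = x)
bexpr_and <- function(args) if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
bexpr_or <- function(args) if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)

#' Tokenize a Boolean rule expression
#'
#' Accepts `&`, `|`, `!`, parentheses, the constants `0`/`1`, and node
#' identifiers (letters, digits, `_`). Whitespace is ignored.
#' @noRd
bexpr_tokenize <- function(text, line = NA_integer_) {
  text <- as.character(text)
  pat <- "\\s*([A-Za-z_][A-Za-z0-9_]*|[01]|&|\\||!|\\(|\\))"
  tokens <- character(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(pat, substring(text, pos), perl = TRUE)
    if (m == -1L || m != 1L) {
      rest <- trimws(substring(text, pos))
      if (!nzchar(rest)) break
      stop(sprintf("cannot tokenize rule%s near '%s'",
                   if (is.na(line)) "" else paste0(" on line ", line),
                   substr(rest, 1L, 20L)), call. = FALSE)
    }
    len <- attr(m, "match.length")
    tok <- trimws(substring(text, pos, pos + len - 1L))
    if (nzchar(tok)) tokens <- c(tokens, tok)
    pos <- pos + len
  }
  tokens
}

#' Recursive-descent parser for one rule expression
#'
#' Grammar: or := and ('|' and)* ; and := unary ('&' unary)* ;
#' unary := '!' unary | '(' or ')' | var | const.
#' @noRd
bexpr_parse <- function(text, line = NA_integer_) {
  tokens <- bexpr_tokenize(text, line)
  if (length(tokens) == 0L)
    stop(sprintf("empty rule expression%s",
                 if (is.na(line)) "" else paste0(" on line ", line)), call. = FALSE)
  i <- 1L
  peek <- function() if (i <= length(tokens)) tokens[[i]] else NA_character_
  advance <- function() { tok <- tokens[[i]]; i <<- i + 1L; tok }
  expect <- function(tok) {
    got <- peek()
    if (is.na(got) || got != tok)
      stop(sprintf("expected '%s' but found '%s'%s", tok,
                   if (is.na(got)) "<end>" else got,
                   if (is.na(line)) "" else paste0(" on line ", line)), call. = FALSE)
    advance()
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "|")) {
      advance()
      args <- c(args, list(parse_and()))
    }
    bexpr_or(args)
  }
  parse_and <- function() {
    args <- list(parse_unary())
    while (identical(peek(), "&")) {
      advance()
      args <- c(args, list(parse_unary()))
    }
    bexpr_and(args)
  }
  parse_unary <- function() {
    tok <- peek()
    if (is.na(tok))
      stop(sprintf("unexpected end of rule%s",
                   if (is.na(line)) "" else paste0(" on line ", line)), call. = FALSE)
    if (tok == "!") { advance(); return(bexpr_not(parse_unary())) }
    if (tok == "(") { advance(); e <- parse_or(); expect(")"); return(e) }
    if (tok %in% c("0", "1")) { advance(); return(bexpr_const(as.integer(tok))) }
    if (grepl("^[A-Za-z_]", tok)) { advance(); return(bexpr_var(tok)) }
    stop(sprintf("unexpected token '%s'%s", tok,
                 if (is.na(line)) "" else paste0(" on line ", line)), call. = FALSE)
  }
  out <- parse_or()
  if (i <= length(tokens))
    stop(sprintf("trailing tokens after expression ('%s')%s", tokens[[i]],
                 if (is.na(line)) "" else paste0(" on line ", line)), call. = FALSE)
  out
}

#' Render an expression back to the rule dialect
#' @noRd
bexpr_deparse <- function(e) {
  switch(e$op,
    var = e$name,
    const = as.character(e$value),
    not = {
      inner <- bexpr_deparse(e$x)
      if (e$x$op %in% c("and", "or")) paste0("!(", inner, ")") else paste0("!", inner)
    },
    and = paste(vapply(e$args, function(a) {
      s <- bexpr_deparse(a)
      if (a$op == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " & "),
    or = paste(vapply(e$args, bexpr_deparse, character(1)), collapse = " | "),
    stop("unknown expression op: ", e$op)
  )
}

#' Collect the distinct node names referenced by an expression
#' @noRd
bexpr_vars <- function(e) {
  switch(e$op,
    var = e$name,
    const = character(0),
    not = bexpr_vars(e$x),
    unique(unlist(lapply(e$args, bexpr_vars), use.names = FALSE))
  )
}

#' Evaluate an expression on a named logical/integer environment
#'
#' Pure R evaluation; used by the validator and as an independent code path
#' from the compiled engine.
#' @noRd
bexpr_eval <- function(e, values) {
  switch(e$op,
    var = {
      v <- values[[e$name]]
      if (is.null(v)) stop("expression references unknown node: ", e$name, call. = FALSE)
      as.logical(v)
    },
    const = e$value == 1L,
    not = !bexpr_eval(e$x, values),
    and = all(vapply(e$args, bexpr_eval, logical(1), values = values)),
    or = any(vapply(e$args, bexpr_eval, logical(1), values = values))
  )
}

#' Substitute constants for a set of nodes
#' @noRd
bexpr_substitute <- function(e, assignments) {
  switch(e$op,
    var = if (e$name %in% names(assignments))
      bexpr_const(assignments[[e$name]]) else e,
    const = e,
    not = bexpr_not(bexpr_substitute(e$x, assignments)),
    and = bexpr_and(lapply(e$args, bexpr_substitute, assignments = assignments)),
    or = bexpr_or(lapply(e$args, bexpr_substitute, assignments = assignments))
  )
}

# Bytecode opcodes shared with src/engine.cpp (postfix / RPN):
#  >= 0 : push variable with that 0-based index
#   -1  : NOT, -2 : AND (binary), -3 : OR (binary), -4 : push FALSE, -5 : push TRUE
BC_NOT <- -1L; BC_AND <- -2L; BC_OR <- -3L; BC_FALSE <- -4L; BC_TRUE <- -5L

#' Compile an expression to engine bytecode
#'
#' `index` maps node name to 0-based variable slot.
#' @noRd
bexpr_compile <- function(e, index) {
  switch(e$op,
    var = {
      ix <- index[[e$name]]
      if (is.null(ix)) stop("cannot compile reference to unknown node: ", e$name)
      as.integer(ix)
    },
    const = if (e$value == 1L) BC_TRUE else BC_FALSE,
    not = c(bexpr_compile(e$x, index), BC_NOT),
    and = {
      out <- bexpr_compile(e$args[[1L]], index)
      for (a in e$args[-1L]) out <- c(out, bexpr_compile(a, index), BC_AND)
      out
    },
    or = {
      out <- bexpr_compile(e$args[[1L]], index)
      for (a in e$args[-1L]) out <- c(out, bexpr_compile(a, index), BC_OR)
      out
    }
  )
}
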