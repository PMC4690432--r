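# Expression language for local assignments.
#
# Grammar:
#   expr   := term (('+'|'-') term)*
#   term   := unary (('*'|'/') unary)*
#   unary  := '-' unary | power
#   power  := base ('^' unary)?          (right-associative)
#   base   := NUMBER | REF | '(' expr ')'
#   REF    := IDENT ('@' IDENT)?
#   IDENT  := [A-Za-z_][A-Za-z0-9_]*
#
# Precedence: ^  >  unary -  >  * /  >  + - ; all left-associative except '^'.
# A reference "k1@WT1" names parameter k1 as resolved at node WT1 (which must
# be an ancestor of the node holding the assignment, or the reserved node
# BASE, addressing the base set). A bare identifier "k1" denotes the value
# the current node would inherit for k1, ignoring all of its own local
# assignments.
#
# AST node shapes (plain lists):
#   list(t = "num",  v = <double>)
#   list(t = "ref",  key = <chr>, node = <chr or NA for bare>)
#   list(t = "neg",  x = <ast>)
#   list(t = "bin",  op = <"+","-","*","/","^">, l = <ast>, r = <ast>)
#   list(t = "call", fn = <"exp","ln","time">, args = <list of ast>)
# "call" nodes never come out of parse_expr (functions are not part of the
# assignment language); they arise only from MathML kinetic laws.

#' Reserved node name addressing the base set in references
#' @export
BASE_NODE <- "BASE"

mg_num <- function(v) list(t = "num", v = as.numeric(v))
mg_ref <- function(key, node = NA_character_) list(t = "ref", key = key, node = node)
mg_neg <- function(x) list(t = "neg", x = x)
mg_bin <- function(op, l, r) list(t = "bin", op = op, l = l, r = r)
mg_call <- function(fn, args) list(t = "call", fn = fn, args = args)

is_expr_ast <- function(x) {
  is.list(x) && !is.null(x$t) &&
    x$t %in% c("num", "ref", "neg", "bin", "call")
}

# ---- tokenizer --------------------------------------------------------------

mg_tokenize <- function(text) {
  n <- nchar(text)
  toks <- list()
  i <- 1L
  num_re <- "^([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?"
  id_re <- "^[A-Za-z_][A-Za-z0-9_]*"
  while (i <= n) {
    rest <- substr(text, i, n)
    ch <- substr(rest, 1, 1)
    if (grepl("^[ \t\r\n]", ch)) {
      i <- i + 1L
      next
    }
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")", "@")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(rest, regexpr(num_re, rest))
    if (length(m) == 1L && nzchar(m)) {
      toks[[length(toks) + 1L]] <- list(type = "NUM", text = m, pos = i)
      i <- i + nchar(m)
      next
    }
    m <- regmatches(rest, regexpr(id_re, rest))
    if (length(m) == 1L && nzchar(m)) {
      toks[[length(toks) + 1L]] <- list(type = "IDENT", text = m, pos = i)
      i <- i + nchar(m)
      next
    }
    mg_stop("mg_syntax_error",
            sprintf("unexpected character '%s' at position %d", ch, i),
            position = i)
  }
  toks[[length(toks) + 1L]] <- list(type = "EOF", text = "", pos = n + 1L)
  toks
}

# ---- recursive-descent parser ----------------------------------------------

#' Parse a local-assignment expression
#'
#' Parses the assignment expression language into an abstract syntax tree.
#' Numbers may use decimal or scientific notation; `k1@WT1` references
#' parameter `k1` at ancestor node `WT1`; `k1@BASE` addresses the base set;
#' a bare `k1` denotes the inherited value at the current node.
#'
#' @param text a single expression string.
#' @return An expression AST (opaque list; see [format_expr()], [expr_refs()],
#'   [eval_expr()]).
#' @examples
#' e <- parse_expr("2*k1@P + 4*k2@G")
#' expr_refs(e)
#' @export
parse_expr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    mg_stop("mg_syntax_error", "expression must be a non-empty string", position = 1L)
  toks <- mg_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$toks <- toks

  peek <- function() st$toks[[st$i]]
  advance <- function() {
    tok <- st$toks[[st$i]]
    st$i <- st$i + 1L
    tok
  }
  fail <- function(tok, what) {
    mg_stop("mg_syntax_error",
            sprintf("expected %s at position %d (found '%s')",
                    what, tok$pos, if (tok$type == "EOF") "end of input" else tok$text),
            position = tok$pos)
  }

  p_expr <- function() {
    node <- p_term()
    while (peek()$type %in% c("+", "-")) {
      op <- advance()$type
      node <- mg_bin(op, node, p_term())
    }
    node
  }
  p_term <- function() {
    node <- p_unary()
    while (peek()$type %in% c("*", "/")) {
      op <- advance()$type
      node <- mg_bin(op, node, p_unary())
    }
    node
  }
  p_unary <- function() {
    if (peek()$type == "-") {
      advance()
      return(mg_neg(p_unary()))
    }
    p_power()
  }
  p_power <- function() {
    node <- p_base()
    if (peek()$type == "^") {
      advance()
      node <- mg_bin("^", node, p_unary())
    }
    node
  }
  p_base <- function() {
    tok <- peek()
    if (tok$type == "NUM") {
      advance()
      return(mg_num(as.numeric(tok$text)))
    }
    if (tok$type == "IDENT") {
      advance()
      if (peek()$type == "@") {
        advance()
        ntok <- peek()
        if (ntok$type != "IDENT") fail(ntok, "a node name after '@'")
        advance()
        return(mg_ref(tok$text, ntok$text))
      }
      return(mg_ref(tok$text))
    }
    if (tok$type == "(") {
      advance()
      node <- p_expr()
      ctok <- peek()
      if (ctok$type != ")") fail(ctok, "')'")
      advance()
      return(node)
    }
    fail(tok, "a number, identifier or '('")
  }

  out <- p_expr()
  tok <- peek()
  if (tok$type != "EOF") fail(tok, "end of expression")
  out
}

# ---- printer (minimal parentheses) ------------------------------------------

expr_prec <- function(e) {
  switch(e$t,
         num = if (e$v < 0) 4L else 6L, # negative literal prints like unary minus
         ref = 6L, call = 6L,
         bin = switch(e$op, "^" = 5L, "*" = 3L, "/" = 3L, "+" = 2L, "-" = 2L),
         neg = 4L)
}

#' Print an expression AST back to canonical text
#'
#' Uses minimal parentheses; `parse_expr(format_expr(e))` reproduces `e`.
#'
#' @param e an expression AST.
#' @return A single string.
#' @export
format_expr <- function(e) {
  wrap <- function(x, need) {
    s <- format_expr(x)
    if (need) paste0("(", s, ")") else s
  }
  switch(e$t,
    num = {
      # %.17g guarantees a lossless double round trip
      s <- sprintf("%.17g", abs(e$v))
      if (e$v < 0) paste0("-", s) else s
    },
    ref = if (is.na(e$node)) e$key else paste0(e$key, "@", e$node),
    neg = paste0("-", wrap(e$x, expr_prec(e$x) < 4L || e$x$t == "neg")),
    call = paste0(e$fn, "(",
                  paste(vapply(e$args, format_expr, ""), collapse = ", "), ")"),
    bin = {
      p <- expr_prec(e)
      if (e$op == "^") {
        # right-associative: parenthesize a left child at the same level
        l <- wrap(e$l, expr_prec(e$l) <= p)
        r <- wrap(e$r, expr_prec(e$r) < p)
      } else {
        l <- wrap(e$l, expr_prec(e$l) < p)
        r <- wrap(e$r, expr_prec(e$r) <= p)
      }
      paste0(l, e$op, r)
    })
}

# ---- reference extraction ----------------------------------------------------

#' List the (key, node) references of an expression
#'
#' @param e an expression AST.
#' @return A data.frame with character columns `key` and `node`; bare
#'   references carry `node = NA`. Duplicates are removed.
#' @export
expr_refs <- function(e) {
  acc <- list()
  walk <- function(x) {
    switch(x$t,
           num = NULL,
           ref = acc[[length(acc) + 1L]] <<- c(x$key, x$node),
           neg = walk(x$x),
           call = lapply(x$args, walk),
           bin = {
             walk(x$l)
             walk(x$r)
           })
    invisible(NULL)
  }
  walk(e)
  if (length(acc) == 0L)
    return(data.frame(key = character(), node = character(),
                      stringsAsFactors = FALSE))
  df <- data.frame(key = vapply(acc, `[`, "", 1L),
                   node = vapply(acc, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  unique(df)
}

# ---- evaluator ---------------------------------------------------------------

ref_label <- function(key, node) {
  ifelse(is.na(node), key, paste0(key, "@", node))
}

#' Evaluate an expression AST
#'
#' @param e an expression AST.
#' @param env a named numeric vector or list; names are `key` for bare
#'   references and `key@node` for node references. Alternatively a function
#'   `(key, node) -> numeric` (node is `NA` for bare references).
#' @param time model time bound to the `time` symbol of kinetic laws
#'   (irrelevant for assignment expressions).
#' @return A finite numeric scalar; division by zero and other non-finite
#'   results raise an arithmetic error, unresolvable references a
#'   missing-reference error.
#' @export
eval_expr <- function(e, env = list(), time = 0) {
  lookup <- if (is.function(env)) {
    env
  } else {
    tab <- unlist(env)
    function(key, node) {
      lbl <- ref_label(key, node)
      if (!lbl %in% names(tab))
        mg_stop("mg_missing_reference",
                sprintf("no value provided for reference '%s'", lbl),
                key = key, node = node)
      tab[[lbl]]
    }
  }
  ev <- function(x) {
    switch(x$t,
      num = x$v,
      ref = {
        v <- lookup(x$key, x$node)
        if (is.null(v))
          mg_stop("mg_missing_reference",
                  sprintf("no value provided for reference '%s'",
                          ref_label(x$key, x$node)),
                  key = x$key, node = x$node)
        as.numeric(v)
      },
      neg = -ev(x$x),
      call = switch(x$fn,
        exp = exp(ev(x$args[[1L]])),
        ln = log(ev(x$args[[1L]])),
        time = time,
        mg_stop("mg_unsupported_feature",
                sprintf("unsupported function '%s'", x$fn), feature = x$fn)),
      bin = {
        l <- ev(x$l)
        r <- ev(x$r)
        if (x$op == "/" && r == 0)
          mg_stop("mg_arithmetic_error", "division by zero")
        switch(x$op,
               "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r,
               "^" = l^r)
      })
  }
  v <- ev(e)
  if (!is.finite(v))
    mg_stop("mg_arithmetic_error",
            sprintf("expression evaluated to a non-finite value (%s)", v))
  v
}

# Coerce a user-supplied local value (number, string, or AST) to an AST.
as_expr_ast <- function(value) {
  if (is_expr_ast(value)) return(value)
  if (is.numeric(value) && length(value) == 1L && is.finite(value)) {
    if (value < 0) return(mg_neg(mg_num(-value)))
    return(mg_num(value))
  }
  if (is.character(value) && length(value) == 1L) return(parse_expr(value))
  mg_stop("mg_invalid_assignment",
          "a local value must be a finite number, an expression string, or an expression AST")
}
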