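# Independent oracles and generators for property tests. Nothing here calls
# into the package's parser/evaluator internals: the shunting-yard evaluator
# below is a from-scratch second implementation of the expression semantics.

# ---- shunting-yard evaluator (reference-free expressions) ----------------------

sy_tokenize <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  num_re <- "^([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?"
  while (i <= n) {
    rest <- substr(text, i, n)
    ch <- substr(rest, 1, 1)
    if (ch == " ") { i <- i + 1L; next }
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")")) {
      toks[[length(toks) + 1L]] <- ch
      i <- i + 1L
      next
    }
    m <- regmatches(rest, regexpr(num_re, rest))
    stopifnot(nzchar(m))
    toks[[length(toks) + 1L]] <- as.numeric(m)
    i <- i + nchar(m)
  }
  toks
}

# Precedence: ^ (5, right) > unary - (4, right) > * / (3) > + - (2).
sy_eval <- function(text) {
  toks <- sy_tokenize(text)
  prec <- c("^" = 5, "u-" = 4, "*" = 3, "/" = 3, "+" = 2, "-" = 2)
  right <- c("^", "u-")
  out <- numeric()
  ops <- character()
  apply_op <- function(op) {
    if (op == "u-") {
      out[length(out)] <<- -out[length(out)]
      return(invisible(NULL))
    }
    b <- out[length(out)]; a <- out[length(out) - 1L]
    out <<- out[seq_len(length(out) - 2L)]
    out[length(out) + 1L] <<- switch(op, "+" = a + b, "-" = a - b,
                                     "*" = a * b, "/" = a / b, "^" = a^b)
  }
  prev <- "start"
  for (tk in toks) {
    if (is.numeric(tk)) {
      out[length(out) + 1L] <- tk
      prev <- "value"
    } else if (tk == "(") {
      ops[length(ops) + 1L] <- tk
      prev <- "open"
    } else if (tk == ")") {
      while (ops[length(ops)] != "(") {
        apply_op(ops[length(ops)])
        ops <- ops[-length(ops)]
      }
      ops <- ops[-length(ops)]
      prev <- "value"
    } else {
      op <- if (tk == "-" && prev %in% c("start", "open", "op")) "u-" else tk
      while (length(ops) > 0L && ops[length(ops)] != "(" &&
             (prec[[ops[length(ops)]]] > prec[[op]] ||
              (prec[[ops[length(ops)]]] == prec[[op]] && !(op %in% right)))) {
        apply_op(ops[length(ops)])
        ops <- ops[-length(ops)]
      }
      ops[length(ops) + 1L] <- op
      prev <- "op"
    }
  }
  while (length(ops) > 0L) {
    apply_op(ops[length(ops)])
    ops <- ops[-length(ops)]
  }
  stopifnot(length(out) == 1L)
  out
}

# ---- random expression generators ----------------------------------------------

# Random reference-free expression STRING (for evaluator cross-validation).
random_expr_string <- function(depth = 3L) {
  if (depth <= 0L || stats::runif(1) < 0.3)
    return(sprintf("%.4g", stats::runif(1, 0.1, 9)))
  pick <- sample(c("+", "-", "*", "/", "^", "neg", "paren"), 1L,
                 prob = c(3, 3, 3, 2, 1, 1, 1))
  if (pick == "neg") return(paste0("-", random_expr_string(depth - 1L)))
  if (pick == "paren") return(paste0("(", random_expr_string(depth - 1L), ")"))
  l <- random_expr_string(depth - 1L)
  r <- random_expr_string(depth - 1L)
  if (pick == "^") # keep magnitudes sane: small positive base, small exponent
    return(sprintf("(%s)^%.3g", l, stats::runif(1, 0.2, 2.5)))
  paste0(l, " ", pick, " ", r)
}

# Random AST built from the package's node vocabulary (for print/parse
# round-trip property).
random_ast <- function(depth = 4L) {
  if (depth <= 0L || stats::runif(1) < 0.3) {
    if (stats::runif(1) < 0.5)
      return(list(t = "num", v = round(stats::runif(1, 0, 99), 4)))
    key <- sample(c("k1", "k2", "mdt", "A_tot"), 1L)
    node <- sample(c(NA_character_, "P", "G", "BASE"), 1L)
    return(list(t = "ref", key = key, node = node))
  }
  pick <- sample(c("bin", "neg"), 1L, prob = c(4, 1))
  if (pick == "neg") return(list(t = "neg", x = random_ast(depth - 1L)))
  list(t = "bin", op = sample(c("+", "-", "*", "/", "^"), 1L),
       l = random_ast(depth - 1L), r = random_ast(depth - 1L))
}

# ---- engine wrapper used by oracle-equivalence tests ----------------------------

# Same return shape as oracle_resolve(), driven through the memoized engine.
engine_resolve <- function(graph, node, key) {
  tryCatch({
    r <- resolve_value(graph, node, key)
    list(kind = "value", value = r$value, provenance = r$provenance,
         source = r$source)
  },
  mg_conflict_error = function(c) list(kind = "conflict"),
  mg_dangling_reference = function(c) list(kind = "dangling"),
  mg_reference_cycle_error = function(c) list(kind = "cycle"))
}

expect_same_resolution <- function(graph, node, key) {
  eng <- engine_resolve(graph, node, key)
  ora <- oracle_resolve(graph, node, key)
  label <- sprintf("(%s, %s)", node, key)
  expect_identical(eng$kind, ora$kind, label = paste("kind at", label))
  if (eng$kind == "value" && ora$kind == "value") {
    if (is.numeric(eng$value)) {
      expect_equal(eng$value, ora$value, tolerance = 1e-9,
                   label = paste("value at", label))
    } else {
      expect_identical(eng$value, ora$value, label = paste("value at", label))
    }
    expect_identical(eng$provenance, ora$provenance,
                     label = paste("provenance at", label))
    expect_identical(eng$source, ora$source, label = paste("source at", label))
  }
  invisible(NULL)
}
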