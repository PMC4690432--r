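# MathML <-> AST conversion for kinetic laws and rate/assignment rules.
# Supported subset: <cn> (real, integer, e-notation, rational), <ci>,
# <csymbol> time, and <apply> with plus, minus (unary/binary/n-ary), times,
# divide, power, exp, ln. Everything else (piecewise, delay, ...) raises
# UnsupportedFeature, never a silent drop.

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

xml_local <- function(node) xml2::xml_name(node)

element_children <- function(node) {
  kids <- xml2::xml_children(node)
  kids
}

mathml_to_ast <- function(node) {
  nm <- xml_local(node)
  if (nm == "math") {
    kids <- element_children(node)
    if (length(kids) != 1L)
      mg_stop("mg_sbml_parse_error", "<math> must contain exactly one expression")
    return(mathml_to_ast(kids[[1L]]))
  }
  if (nm == "cn") return(cn_to_num(node))
  if (nm == "ci") {
    id <- trimws(xml2::xml_text(node))
    return(mg_ref(id))
  }
  if (nm == "csymbol") return(csymbol_to_ast(node))
  if (nm == "apply") {
    kids <- element_children(node)
    if (length(kids) < 2L)
      mg_stop("mg_sbml_parse_error", "<apply> needs an operator and arguments")
    op <- xml_local(kids[[1L]])
    args <- lapply(kids[-1L], mathml_to_ast)
    return(apply_to_ast(op, args, kids[[1L]]))
  }
  mg_stop("mg_unsupported_feature",
          sprintf("unsupported MathML element <%s>", nm), feature = nm)
}

cn_to_num <- function(node) {
  type <- xml2::xml_attr(node, "type")
  txts <- xml2::xml_contents(node)
  is_sep <- vapply(txts, function(x) identical(xml2::xml_name(x), "sep"), TRUE)
  parts <- trimws(vapply(txts[!is_sep], xml2::xml_text, ""))
  parts <- parts[nzchar(parts)]
  v <- if (!is.na(type) && type == "e-notation") {
    if (length(parts) != 2L)
      mg_stop("mg_sbml_parse_error", "e-notation <cn> needs mantissa<sep/>exponent")
    as.numeric(parts[1L]) * 10^as.numeric(parts[2L])
  } else if (!is.na(type) && type == "rational") {
    if (length(parts) != 2L)
      mg_stop("mg_sbml_parse_error", "rational <cn> needs numerator<sep/>denominator")
    as.numeric(parts[1L]) / as.numeric(parts[2L])
  } else {
    as.numeric(paste(parts, collapse = ""))
  }
  if (is.na(v)) mg_stop("mg_sbml_parse_error", "unparseable <cn> content")
  if (v < 0) mg_neg(mg_num(-v)) else mg_num(v)
}

csymbol_to_ast <- function(node) {
  url <- xml2::xml_attr(node, "definitionURL")
  if (!is.na(url) && grepl("symbols/time$", url)) return(mg_call("time", list()))
  if (!is.na(url) && grepl("symbols/delay$", url))
    mg_stop("mg_unsupported_feature", "delay csymbol is not supported",
            feature = "delay")
  mg_stop("mg_unsupported_feature",
          sprintf("unsupported csymbol '%s'", url), feature = "csymbol")
}

apply_to_ast <- function(op, args, op_node) {
  fold <- function(op_chr, xs) Reduce(function(a, b) mg_bin(op_chr, a, b), xs)
  switch(op,
    plus = if (length(args) == 0L) mg_num(0) else fold("+", args),
    minus = if (length(args) == 1L) mg_neg(args[[1L]]) else fold("-", args),
    times = if (length(args) == 0L) mg_num(1) else fold("*", args),
    divide = {
      if (length(args) != 2L)
        mg_stop("mg_sbml_parse_error", "<divide> takes exactly two arguments")
      mg_bin("/", args[[1L]], args[[2L]])
    },
    power = {
      if (length(args) != 2L)
        mg_stop("mg_sbml_parse_error", "<power> takes exactly two arguments")
      mg_bin("^", args[[1L]], args[[2L]])
    },
    exp = mg_call("exp", args),
    ln = mg_call("ln", args),
    csymbol = mathml_to_ast(op_node),
    mg_stop("mg_unsupported_feature",
            sprintf("unsupported MathML operator <%s>", op), feature = op)
  )
}

# AST -> MathML (as an xml2 node added under `parent`).
ast_to_mathml <- function(e, parent) {
  add <- function(p, name, ...) xml2::xml_add_child(p, name, ...)
  switch(e$t,
    num = {
      n <- add(parent, "cn")
      xml2::xml_set_text(n, sprintf("%.17g", e$v))
    },
    ref = {
      if (!is.na(e$node))
        mg_stop("mg_sbml_parse_error",
                "node-qualified references cannot appear in SBML math")
      n <- add(parent, "ci")
      xml2::xml_set_text(n, paste0(" ", e$key, " "))
    },
    neg = {
      ap <- add(parent, "apply")
      add(ap, "minus")
      ast_to_mathml(e$x, ap)
    },
    bin = {
      ap <- add(parent, "apply")
      add(ap, switch(e$op, "+" = "plus", "-" = "minus", "*" = "times",
                     "/" = "divide", "^" = "power"))
      ast_to_mathml(e$l, ap)
      ast_to_mathml(e$r, ap)
    },
    call = {
      if (e$fn == "time") {
        cs <- add(parent, "csymbol", encoding = "text",
                  definitionURL = "http://www.sbml.org/sbml/symbols/time")
        xml2::xml_set_text(cs, " time ")
      } else {
        ap <- add(parent, "apply")
        add(ap, e$fn)
        for (a in e$args) ast_to_mathml(a, ap)
      }
    })
  invisible(parent)
}

math_element <- function(parent, ast) {
  m <- xml2::xml_add_child(parent, "math", xmlns = MATHML_NS)
  ast_to_mathml(ast, m)
  m
}
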