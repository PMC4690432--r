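# The inheritance engine: a DAG of named configurations over a fixed key
# space. Each node holds local assignments (numbers or expressions over
# ancestor values); everything else is inherited as the union of the parents'
# effective changes, falling back to the base set. Multi-parent nodes whose
# parents deliver distinct effective values for a key are CONFLICTED on that
# key until the user resolves the conflict explicitly; nodes whose local
# expressions reference a node that no longer exists are INCONSISTENT.
#
# A graph is an immutable value: every operation returns the modified graph.
# Resolution memoizes per (node, key) within one resolution pass, which keeps
# deep multi-parent hierarchies linear instead of exponential.

# Numeric tolerance under which two delivered values are "the same" (no
# conflict): |a - b| <= max(1e-15, 1e-12 * max(|a|, |b|)).
values_distinct <- function(a, b) {
  abs(a - b) > max(1e-15, 1e-12 * max(abs(a), abs(b)))
}

#' Create an empty configuration graph
#'
#' @param base named list or vector of base values, one per key; numeric
#'   entries admit the expression language, non-numeric entries ("opaque",
#'   e.g. an enum string) are inherited whole and compared by identity.
#' @param kinds optional named character vector (`"numeric"` / `"opaque"`)
#'   overriding the kind inferred from `base`.
#' @return An object of class `config_graph` with no nodes.
#' @export
config_graph <- function(base, kinds = NULL) {
  base <- as.list(base)
  if (is.null(names(base)) || any(!nzchar(names(base))))
    mg_stop("mg_invalid_assignment", "base values must be named")
  if (is.null(kinds)) {
    kinds <- vapply(base, function(v)
      if (is.numeric(v) && length(v) == 1L) "numeric" else "opaque", "")
  }
  structure(list(keys = names(base),
                 kind = kinds[names(base)],
                 base = base,
                 nodes = list()),
            class = "config_graph")
}

#' Configuration graph over a model's base set
#'
#' @param bs an `mg_base_set` (see [base_set()]).
#' @return A `config_graph` whose keys are the model's assignable quantities.
#' @export
config_graph_from_base_set <- function(bs) {
  config_graph(as.list(bs$values))
}

#' @export
print.config_graph <- function(x, ...) {
  cat(sprintf("<config_graph> %d key(s), %d node(s)\n",
              length(x$keys), length(x$nodes)))
  for (nm in names(x$nodes)) {
    n <- x$nodes[[nm]]
    cat(sprintf("  %s%s%s\n", nm,
                if (length(n$parents)) paste0(" <- ", paste(n$parents, collapse = ", ")) else " (root)",
                if (length(n$locals)) sprintf(" [%d local]", length(n$locals)) else ""))
  }
  invisible(x)
}

#' Names of the nodes in a graph (insertion order)
#' @param graph a `config_graph`.
#' @export
graph_nodes <- function(graph) names(graph$nodes)

node_or_fail <- function(graph, name) {
  if (!name %in% names(graph$nodes))
    mg_stop("mg_unknown_node", sprintf("no node named '%s'", name), node = name)
  graph$nodes[[name]]
}

# All strict ancestors of `name`, walking child -> parents.
node_ancestors <- function(graph, name) {
  seen <- character()
  frontier <- graph$nodes[[name]]$parents
  while (length(frontier) > 0L) {
    frontier <- frontier[frontier %in% names(graph$nodes)]
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(new, function(p) graph$nodes[[p]]$parents)))
  }
  seen
}

node_descendants <- function(graph, name) {
  nms <- names(graph$nodes)
  nms[vapply(nms, function(x) name %in% node_ancestors(graph, x), TRUE)]
}

# ---- construction -------------------------------------------------------------

new_node <- function(name, parents, color = NULL, applies_to = character()) {
  list(name = name, parents = parents, locals = list(), color = color,
       applies_to = applies_to)
}

check_name <- function(graph, name) {
  if (!is.character(name) || length(name) != 1L ||
      !grepl("^[A-Za-z_][A-Za-z0-9_]*$", name))
    mg_stop("mg_invalid_assignment",
            sprintf("'%s' is not a valid node name (identifier charset required)", name))
  if (name %in% names(graph$nodes))
    mg_stop("mg_duplicate_name",
            sprintf("a node named '%s' already exists", name), node = name)
  if (identical(name, BASE_NODE))
    mg_stop("mg_duplicate_name", "'BASE' is reserved", node = name)
}

#' Create a root configuration node
#'
#' A root has no parents: every key resolves from the base set until locally
#' overridden.
#'
#' @param graph a `config_graph`.
#' @param name unique node name (identifier charset).
#' @param color optional display color carried into DOT export.
#' @param applies_to for settings graphs: names of the parameter nodes this
#'   configuration applies to (empty = all).
#' @return The modified graph.
#' @export
create_root <- function(graph, name, color = NULL, applies_to = character()) {
  check_name(graph, name)
  graph$nodes[[name]] <- new_node(name, character(), color, applies_to)
  graph
}

#' Create a child configuration node
#'
#' The child inherits the union of the changes of all its parents; keys no
#' parent changes fall back to the base set.
#'
#' @inheritParams create_root
#' @param parents character vector of existing node names.
#' @return The modified graph.
#' @export
create_child <- function(graph, name, parents, color = NULL,
                         applies_to = character()) {
  check_name(graph, name)
  parents <- as.character(parents)
  if (length(parents) == 0L)
    mg_stop("mg_unknown_parent", "a child needs at least one parent")
  missing <- setdiff(parents, names(graph$nodes))
  if (length(missing) > 0L)
    mg_stop("mg_unknown_parent",
            sprintf("unknown parent(s): %s", paste(missing, collapse = ", ")),
            parents = missing)
  # a fresh node cannot create a cycle (nothing points to it yet), but guard
  # anyway so the invariant is enforced in one place
  graph$nodes[[name]] <- new_node(name, parents, color, applies_to)
  if (graph_has_cycle(graph))
    mg_stop("mg_cycle_error",
            sprintf("adding '%s' would create a cycle", name), node = name)
  graph
}

graph_has_cycle <- function(graph) {
  state <- new.env(parent = emptyenv())
  for (nm in names(graph$nodes)) assign(nm, 0L, envir = state) # 0 new, 1 open, 2 done
  visit <- function(nm) {
    s <- get0(nm, envir = state, ifnotfound = 2L) # dangling parents can't cycle
    if (s == 1L) return(TRUE)
    if (s == 2L) return(FALSE)
    assign(nm, 1L, envir = state)
    for (p in graph$nodes[[nm]]$parents)
      if (p %in% names(graph$nodes) && visit(p)) return(TRUE)
    assign(nm, 2L, envir = state)
    FALSE
  }
  any(vapply(names(graph$nodes), visit, TRUE))
}

# ---- local assignments --------------------------------------------------------

#' Set a local assignment on a node
#'
#' Overrides the inherited value for `key` at `node`. For numeric keys the
#' value may be a number, an expression string, or an expression AST;
#' expression references must name strict ancestors of `node` (or `BASE`).
#' For opaque keys (e.g. enum-valued settings fields) the raw value is stored.
#'
#' @param graph a `config_graph`.
#' @param node node name.
#' @param key a key of the graph's key space.
#' @param value number, expression string/AST, or raw value for opaque keys.
#' @return The modified graph.
#' @export
set_local <- function(graph, node, key, value) {
  n <- node_or_fail(graph, node)
  if (!key %in% graph$keys)
    mg_stop("mg_unknown_key", sprintf("'%s' is not a key of this graph", key),
            key = key)
  if (graph$kind[[key]] == "opaque") {
    graph$nodes[[node]]$locals[[key]] <- list(t = "opaque", v = value)
    return(graph)
  }
  ast <- as_expr_ast(value)
  refs <- expr_refs(ast)
  bad_keys <- setdiff(refs$key, graph$keys)
  if (length(bad_keys) > 0L)
    mg_stop("mg_unknown_key",
            sprintf("expression references unknown key(s): %s",
                    paste(bad_keys, collapse = ", ")),
            keys = bad_keys)
  named <- refs$node[!is.na(refs$node) & refs$node != BASE_NODE]
  anc <- node_ancestors(graph, node)
  bad_nodes <- setdiff(named, anc)
  if (length(bad_nodes) > 0L)
    mg_stop("mg_non_ancestor_reference",
            sprintf("expression references node(s) that are not ancestors of '%s': %s",
                    node, paste(bad_nodes, collapse = ", ")),
            node = node, referenced = bad_nodes)
  nonnum <- refs$key[!is.na(refs$key) & graph$kind[refs$key] == "opaque"]
  if (length(nonnum) > 0L)
    mg_stop("mg_invalid_assignment",
            sprintf("non-numeric key(s) cannot appear in expressions: %s",
                    paste(unique(nonnum), collapse = ", ")))
  graph$nodes[[node]]$locals[[key]] <- ast
  graph
}

#' Remove a local assignment
#'
#' Inverse of [set_local()]: resolution returns to the inherited (or base)
#' value. Clearing a conflict-resolution assignment re-raises the conflict.
#'
#' @inheritParams set_local
#' @return The modified graph.
#' @export
clear_local <- function(graph, node, key) {
  n <- node_or_fail(graph, node)
  if (!key %in% names(n$locals))
    mg_stop("mg_no_local_assignment",
            sprintf("node '%s' has no local assignment for '%s'", node, key),
            node = node, key = key)
  graph$nodes[[node]]$locals[[key]] <- NULL
  graph
}

# ---- resolution ---------------------------------------------------------------

res_value <- function(value, provenance, source = NA_character_) {
  list(value = value, provenance = provenance, source = source)
}

conflict_stop <- function(node, key, candidates) {
  mg_stop("mg_conflict_error",
          sprintf("conflict at node '%s', key '%s': parents deliver %s",
                  node, key,
                  paste(sprintf("%s=%g", names(candidates), candidates),
                        collapse = ", ")),
          node = node, key = key, candidates = candidates)
}

# Recursive resolver. `memo` caches list(value, provenance, source) per
# "node\rkey"; `stack` carries the in-progress chain for cycle detection.
res_resolve <- function(graph, node, key, memo, stack) {
  id <- paste(node, key, sep = "\r")
  hit <- get0(id, envir = memo, ifnotfound = NULL)
  if (!is.null(hit)) {
    if (identical(hit$kind, "error")) stop(hit$cond)
    return(hit$res)
  }
  if (id %in% stack)
    mg_stop("mg_reference_cycle_error",
            sprintf("reference cycle while resolving '%s' at '%s'", key, node),
            node = node, key = key)
  stack <- c(stack, id)
  res <- withCallingHandlers(
    res_compute(graph, node, key, memo, stack),
    mg_error = function(c) {
      # cache the failure too so repeated resolution is cheap and identical
      assign(id, list(kind = "error", cond = c), envir = memo)
    })
  assign(id, list(kind = "ok", res = res), envir = memo)
  res
}

res_compute <- function(graph, node, key, memo, stack) {
  if (!node %in% names(graph$nodes))
    mg_stop("mg_dangling_reference",
            sprintf("referenced node '%s' does not exist", node),
            node = node, key = key)
  if (!key %in% graph$keys)
    mg_stop("mg_unknown_key", sprintf("'%s' is not a key of this graph", key),
            key = key)
  n <- graph$nodes[[node]]
  loc <- n$locals[[key]]
  if (!is.null(loc)) {
    if (identical(loc$t, "opaque"))
      return(res_value(loc$v, "LOCAL"))
    env <- function(k, nd) {
      if (!is.na(nd) && nd == BASE_NODE) {
        if (!k %in% graph$keys)
          mg_stop("mg_unknown_key", sprintf("'%s' is not a key of this graph", k),
                  key = k)
        return(as.numeric(graph$base[[k]]))
      }
      if (is.na(nd)) # bare reference: what this node would inherit for k
        return(res_inherit(graph, node, k, memo, stack)$value)
      res_resolve(graph, nd, k, memo, stack)$value
    }
    return(res_value(eval_expr(loc, env), "LOCAL"))
  }
  res_inherit(graph, node, key, memo, stack)
}

# The value `node` inherits for `key`, ignoring node's own locals: the union
# of the parents' effective changes, else the base value.
res_inherit <- function(graph, node, key, memo, stack) {
  n <- graph$nodes[[node]]
  if (length(n$parents) == 0L) {
    if (graph$kind[[key]] == "opaque")
      return(res_value(graph$base[[key]], "BASE"))
    return(res_value(as.numeric(graph$base[[key]]), "BASE"))
  }
  deliveries <- lapply(n$parents, function(p) {
    r <- res_resolve(graph, p, key, memo, stack)
    src <- switch(r$provenance, LOCAL = p, INHERITED = r$source, BASE = NA_character_)
    list(parent = p, value = r$value, source = src)
  })
  changes <- Filter(function(d) !is.na(d$source), deliveries)
  if (length(changes) == 0L)
    return(res_value(if (graph$kind[[key]] == "opaque") graph$base[[key]]
                     else as.numeric(graph$base[[key]]), "BASE"))
  if (graph$kind[[key]] == "opaque") {
    vals <- lapply(changes, `[[`, "value")
    distinct <- !vapply(vals[-1L], identical, TRUE, y = vals[[1L]])
    if (any(distinct)) {
      cand <- stats::setNames(rep(NA_real_, length(changes)),
                              vapply(changes, `[[`, "", "parent"))
      conflict_stop(node, key, cand)
    }
  } else {
    vals <- vapply(changes, `[[`, 0, "value")
    base_v <- vals[[1L]]
    if (any(vapply(vals[-1L], function(v) values_distinct(v, base_v), TRUE))) {
      cand <- stats::setNames(vals, vapply(changes, `[[`, "", "parent"))
      conflict_stop(node, key, cand)
    }
  }
  res_value(changes[[1L]]$value, "INHERITED", changes[[1L]]$source)
}

#' Resolve one value with provenance
#'
#' @param graph a `config_graph`.
#' @param node node name.
#' @param key key name.
#' @return A list with `value`, `provenance` (`"BASE"`, `"LOCAL"` or
#'   `"INHERITED"`) and `source` (the ancestor holding the governing local
#'   assignment when inherited, `NA` otherwise). Raises a conflict error on a
#'   conflicted key, a dangling-reference error when an expression references
#'   a deleted node, and a reference-cycle error on cyclic references.
#' @export
resolve_value <- function(graph, node, key) {
  node_or_fail(graph, node)
  memo <- new.env(parent = emptyenv())
  res_resolve(graph, node, key, memo, character())
}

#' Resolve every key of a node
#'
#' @inheritParams resolve_value
#' @return A named list of resolution records (see [resolve_value()]), one per
#'   key of the graph. If any key is conflicted the conflict error names every
#'   conflicted key.
#' @export
resolve_all <- function(graph, node) {
  node_or_fail(graph, node)
  memo <- new.env(parent = emptyenv())
  out <- list()
  conflicted <- list()
  first_err <- NULL
  for (key in graph$keys) {
    out[[key]] <- tryCatch(
      res_resolve(graph, node, key, memo, character()),
      mg_conflict_error = function(c) {
        conflicted[[length(conflicted) + 1L]] <<- c
        NULL
      },
      mg_error = function(c) {
        if (is.null(first_err)) first_err <<- c
        NULL
      })
  }
  if (length(conflicted) > 0L) {
    keys <- vapply(conflicted, function(c) c$key, "")
    mg_stop("mg_conflict_error",
            sprintf("node '%s' is conflicted on: %s", node,
                    paste(unique(keys), collapse = ", ")),
            node = node, key = keys, conflicts = conflicted)
  }
  if (!is.null(first_err)) stop(first_err)
  out
}

# ---- conflicts ----------------------------------------------------------------

#' Detect inheritance conflicts at a node
#'
#' A conflict exists at (node, key) when the node has no local assignment for
#' `key` and at least two parents deliver distinct effective values
#' (tolerance: `|a-b| > max(1e-15, 1e-12*max(|a|,|b|))`).
#'
#' @inheritParams resolve_value
#' @return A list of conflicts, each `list(node, key, candidates)` where
#'   `candidates` is a named numeric vector (parent -> delivered value).
#' @export
detect_conflicts <- function(graph, node) {
  n <- node_or_fail(graph, node)
  if (length(n$parents) < 2L) return(list())
  memo <- new.env(parent = emptyenv())
  out <- list()
  seen <- character()
  probe <- function(key) {
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    cand <- tryCatch(
      {
        res_inherit(graph, node, key, memo, character())
        NULL
      },
      mg_conflict_error = function(c) {
        if (identical(c$node, node) && identical(c$key, key)) c$candidates else NULL
      },
      mg_error = function(c) NULL) # upstream failures surface at their own node
    if (!is.null(cand))
      out[[length(out) + 1L]] <<- list(node = node, key = key, candidates = cand)
    invisible(NULL)
  }
  for (key in setdiff(graph$keys, names(n$locals))) probe(key)
  # a local expression's BARE references read the inherited value too, even
  # for keys this node assigns — a conflict there also blocks resolution
  for (key in names(n$locals)) {
    loc <- n$locals[[key]]
    if (identical(loc$t, "opaque")) next
    refs <- expr_refs(loc)
    for (rk in unique(refs$key[is.na(refs$node)]))
      if (rk %in% graph$keys) probe(rk)
  }
  out
}

#' Resolve a conflict explicitly
#'
#' Installs a local assignment implementing the chosen strategy:
#' `"from_parent"` assigns `key@parent`, `"from_base"` assigns `key@BASE`,
#' `"expression"` stores the given expression.
#'
#' @inheritParams resolve_value
#' @param strategy one of `"from_parent"`, `"from_base"`, `"expression"`.
#' @param parent parent name (for `"from_parent"`).
#' @param expr expression string or AST (for `"expression"`).
#' @return The modified graph.
#' @export
resolve_conflict <- function(graph, node, key,
                             strategy = c("from_parent", "from_base", "expression"),
                             parent = NULL, expr = NULL) {
  strategy <- match.arg(strategy)
  conflicts <- detect_conflicts(graph, node)
  keys <- vapply(conflicts, function(c) c$key, "")
  if (!key %in% keys)
    mg_stop("mg_no_such_conflict",
            sprintf("no conflict at node '%s' for key '%s'", node, key),
            node = node, key = key)
  value <- switch(strategy,
    from_parent = {
      if (is.null(parent) || !parent %in% graph$nodes[[node]]$parents)
        mg_stop("mg_unknown_parent",
                sprintf("'%s' is not a parent of '%s'", parent, node))
      mg_ref(key, parent)
    },
    from_base = mg_ref(key, BASE_NODE),
    expression = {
      if (is.null(expr))
        mg_stop("mg_invalid_assignment", "strategy 'expression' needs expr=")
      expr
    })
  set_local(graph, node, key, value)
}

# ---- deletion -----------------------------------------------------------------

#' Delete a node, with an impact report
#'
#' With `force = FALSE` (default) nothing is deleted: the returned report
#' lists the descendants that inherit from the node and the (node, key) pairs
#' whose local expressions reference it (these become INCONSISTENT after a
#' forced deletion). With `force = TRUE` the node and its incident edges are
#' removed; descendants that merely inherited re-resolve through remaining
#' parents or the base set.
#'
#' @param graph a `config_graph`.
#' @param name node to delete.
#' @param force actually delete (default `FALSE`: report only).
#' @return A list with `graph` (unchanged unless `force`), `deleted`,
#'   `affected_descendants` and `newly_inconsistent` (data.frame node/key).
#' @export
delete_node <- function(graph, name, force = FALSE) {
  node_or_fail(graph, name)
  descendants <- node_descendants(graph, name)
  inconsistent <- list()
  for (nm in names(graph$nodes)) {
    for (key in names(graph$nodes[[nm]]$locals)) {
      loc <- graph$nodes[[nm]]$locals[[key]]
      if (identical(loc$t, "opaque")) next
      refs <- expr_refs(loc)
      if (name %in% refs$node[!is.na(refs$node)])
        inconsistent[[length(inconsistent) + 1L]] <- c(nm, key)
    }
  }
  newly_inconsistent <- if (length(inconsistent) == 0L) {
    data.frame(node = character(), key = character(), stringsAsFactors = FALSE)
  } else {
    data.frame(node = vapply(inconsistent, `[`, "", 1L),
               key = vapply(inconsistent, `[`, "", 2L),
               stringsAsFactors = FALSE)
  }
  report <- list(deleted = name,
                 affected_descendants = descendants,
                 newly_inconsistent = newly_inconsistent)
  if (force) {
    graph$nodes[[name]] <- NULL
    for (nm in names(graph$nodes)) {
      graph$nodes[[nm]]$parents <-
        setdiff(graph$nodes[[nm]]$parents, name)
    }
  }
  c(list(graph = graph), report)
}

# ---- status -------------------------------------------------------------------

#' Status of a node
#'
#' `"INCONSISTENT"` if any local expression references a node absent from the
#' graph (or a key absent from the key space); else `"CONFLICTED"` if
#' [detect_conflicts()] is non-empty; else `"OK"`.
#'
#' @inheritParams resolve_value
#' @return One of `"OK"`, `"CONFLICTED"`, `"INCONSISTENT"`.
#' @export
node_status <- function(graph, node) {
  n <- node_or_fail(graph, node)
  for (key in names(n$locals)) {
    loc <- n$locals[[key]]
    if (!key %in% graph$keys) return("INCONSISTENT")
    if (identical(loc$t, "opaque")) next
    refs <- expr_refs(loc)
    named <- refs$node[!is.na(refs$node) & refs$node != BASE_NODE]
    if (any(!named %in% names(graph$nodes))) return("INCONSISTENT")
  }
  if (length(detect_conflicts(graph, node)) > 0L) return("CONFLICTED")
  "OK"
}
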