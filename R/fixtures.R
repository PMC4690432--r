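# Fixture generators: toy SBML models, the three worked-example projects, and
# seeded random DAG projects, plus a definitional brute-force resolution
# oracle used to validate the memoized engine. Everything is generated in
# code, so no binary or downloaded fixtures are needed anywhere.

#' Build a toy base model
#'
#' * `decay` — one species A (amount 1) degraded at rate `k*A` (k = 1) in a
#'   unit compartment.
#' * `conversion` — reversible isomerization A <-> B (mass action, kf = 1,
#'   kr = 0.5); conserves A + B.
#' * `oscillator` — a three-species negative-feedback mass-action loop
#'   (X activates Y, Y activates Z, Z catalyzes degradation of X).
#' * `growth` — one species M growing exponentially with mass doubling time
#'   `mdt` (base value 80 min), the smallest model carrying a
#'   medium-dependent quantity.
#'
#' @param kind one of `"decay"`, `"conversion"`, `"oscillator"`, `"growth"`.
#' @return An `mg_model`.
#' @export
example_model <- function(kind = c("decay", "conversion", "oscillator", "growth")) {
  kind <- match.arg(kind)
  comp <- data.frame(id = "cell", size = 1, constant = TRUE,
                     stringsAsFactors = FALSE)
  switch(kind,
    decay = base_model(
      model_id = "decay",
      compartments = comp,
      species = data.frame(id = "A", compartment = "cell", initial_amount = 1,
                           boundary = FALSE, stringsAsFactors = FALSE),
      quantities = data.frame(id = "k", value = 1, constant = TRUE,
                              stringsAsFactors = FALSE),
      reactions = list(list(id = "deg",
                            reactants = list(species = "A", stoichiometry = 1),
                            products = NULL, law = "k*A"))),
    conversion = base_model(
      model_id = "conversion",
      compartments = comp,
      species = data.frame(id = c("A", "B"), compartment = "cell",
                           initial_amount = c(1, 0), boundary = FALSE,
                           stringsAsFactors = FALSE),
      quantities = data.frame(id = c("kf", "kr"), value = c(1, 0.5),
                              constant = TRUE, stringsAsFactors = FALSE),
      reactions = list(
        list(id = "fwd", reactants = list(species = "A", stoichiometry = 1),
             products = list(species = "B", stoichiometry = 1), law = "kf*A"),
        list(id = "rev", reactants = list(species = "B", stoichiometry = 1),
             products = list(species = "A", stoichiometry = 1), law = "kr*B"))),
    oscillator = base_model(
      model_id = "oscillator",
      compartments = comp,
      species = data.frame(id = c("X", "Y", "Z"), compartment = "cell",
                           initial_amount = c(1, 0.5, 0.2), boundary = FALSE,
                           stringsAsFactors = FALSE),
      quantities = data.frame(id = c("k1", "k2", "k3", "k4", "k5", "k6"),
                              value = c(2, 1, 1, 0.6, 1, 0.6),
                              constant = TRUE, stringsAsFactors = FALSE),
      reactions = list(
        list(id = "x_in", reactants = NULL,
             products = list(species = "X", stoichiometry = 1), law = "k1"),
        list(id = "x_out", reactants = list(species = "X", stoichiometry = 1),
             products = NULL, modifiers = "Z", law = "k2*X*Z"),
        list(id = "y_in", reactants = NULL,
             products = list(species = "Y", stoichiometry = 1),
             modifiers = "X", law = "k3*X"),
        list(id = "y_out", reactants = list(species = "Y", stoichiometry = 1),
             products = NULL, law = "k4*Y"),
        list(id = "z_in", reactants = NULL,
             products = list(species = "Z", stoichiometry = 1),
             modifiers = "Y", law = "k5*Y"),
        list(id = "z_out", reactants = list(species = "Z", stoichiometry = 1),
             products = NULL, law = "k6*Z"))),
    growth = base_model(
      model_id = "growth",
      compartments = comp,
      species = data.frame(id = "M", compartment = "cell", initial_amount = 1,
                           boundary = FALSE, stringsAsFactors = FALSE),
      quantities = data.frame(id = "mdt", value = 80, constant = TRUE,
                              stringsAsFactors = FALSE),
      reactions = list(list(id = "grow",
                            reactants = list(species = "M", stoichiometry = 1),
                            products = list(species = "M", stoichiometry = 2),
                            law = "0.69314718055994531*M/mdt"))))
}

#' The three worked-example projects
#'
#' * `media` — a two-node hierarchy over the growth model: root `WT_glucose`
#'   (all base values) and child `WT_galactose` overriding the mass doubling
#'   time `mdt` to 150 (base 80), the canonical "one local change" case.
#' * `timecourse` — the `media` project plus a time-course graph: root
#'   `short` (duration 500, interval 1) applying to both mutants, child
#'   `long` (duration 1000) applying only to `WT_galactose`.
#' * `conflict` — two roots `WT1` and `WT2` locally assigning `k1 = 2` and
#'   `k1 = 4`, and a child `M` of both: the canonical unresolved two-parent
#'   conflict.
#'
#' @return A named list of three `mg_project` objects.
#' @export
example_projects <- function() {
  media <- new_project(example_model("growth"))
  media$param_graph <- create_root(media$param_graph, "WT_glucose",
                                   color = "palegreen")
  media$param_graph <- create_child(media$param_graph, "WT_galactose",
                                    parents = "WT_glucose", color = "orange")
  media$param_graph <- set_local(media$param_graph, "WT_galactose", "mdt", 150)

  tc <- media
  tc$tc_graph <- create_root(tc$tc_graph, "short",
                             applies_to = c("WT_glucose", "WT_galactose"))
  tc$tc_graph <- set_local(tc$tc_graph, "short", "duration", 500)
  tc$tc_graph <- set_local(tc$tc_graph, "short", "interval_size", 1)
  tc$tc_graph <- create_child(tc$tc_graph, "long", parents = "short",
                              applies_to = "WT_galactose")
  tc$tc_graph <- set_local(tc$tc_graph, "long", "duration", "2*duration@short")

  dm <- example_model("decay")
  dm$quantities$id <- "k1"
  dm$reactions[[1L]]$law <- parse_expr("k1*A")
  conflict <- new_project(dm)
  conflict$param_graph <- create_root(conflict$param_graph, "WT1")
  conflict$param_graph <- set_local(conflict$param_graph, "WT1", "k1", 2)
  conflict$param_graph <- create_root(conflict$param_graph, "WT2")
  conflict$param_graph <- set_local(conflict$param_graph, "WT2", "k1", 4)
  conflict$param_graph <- create_child(conflict$param_graph, "M",
                                       parents = c("WT1", "WT2"))

  list(media = media, timecourse = tc, conflict = conflict)
}

# ---- random projects -------------------------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded random project
#'
#' Builds a base model with `n_keys` global quantities (plus one species and
#' one compartment), then a random acyclic parameter hierarchy: nodes are
#' wired topologically (a node's parents precede it), each carrying random
#' numeric locals and, with probability `p_expr` within `p_local`, an
#' expression referencing a random ancestor (or `BASE`, or a bare inherited
#' reference). The same seed always yields an identical project.
#'
#' @param n_nodes number of configuration nodes.
#' @param n_keys number of global quantities in the base model.
#' @param max_parents maximum parents per node (>= 1).
#' @param p_local probability of a local assignment per (node, key).
#' @param p_expr probability that a local assignment is an expression.
#' @param seed integer seed; fully determines the output.
#' @return An `mg_project`.
#' @export
random_project <- function(n_nodes = 6, n_keys = 3, max_parents = 2,
                           p_local = 0.4, p_expr = 0.25, seed = 1) {
  stopifnot(n_nodes >= 1, n_keys >= 1, max_parents >= 1,
            p_local >= 0, p_local <= 1)
  with_seed(seed, {
    qids <- paste0("q", seq_len(n_keys))
    model <- base_model(
      model_id = sprintf("random_%d", seed),
      compartments = data.frame(id = "cell", size = 1, constant = TRUE,
                                stringsAsFactors = FALSE),
      species = data.frame(id = "A", compartment = "cell",
                           initial_amount = round(stats::runif(1, 0.5, 2), 3),
                           boundary = FALSE, stringsAsFactors = FALSE),
      quantities = data.frame(id = qids,
                              value = round(stats::runif(n_keys, 0.5, 5), 3),
                              constant = TRUE, stringsAsFactors = FALSE),
      reactions = list(list(id = "deg",
                            reactants = list(species = "A", stoichiometry = 1),
                            products = NULL, law = paste0(qids[1], "*A"))))
    project <- new_project(model)
    g <- project$param_graph
    node_names <- paste0("N", seq_len(n_nodes))
    for (i in seq_len(n_nodes)) {
      nm <- node_names[i]
      if (i == 1L || stats::runif(1) < 0.2) {
        g <- create_root(g, nm)
      } else {
        k <- sample.int(min(max_parents, i - 1L), 1L)
        parents <- sample(node_names[seq_len(i - 1L)], k)
        g <- create_child(g, nm, parents)
      }
      anc <- node_ancestors(g, nm)
      for (key in g$keys) {
        if (stats::runif(1) >= p_local) next
        value <- if (stats::runif(1) < p_expr) {
          pick <- stats::runif(1)
          if (pick < 0.25 || (length(anc) == 0L && pick < 0.6)) {
            sprintf("%s@BASE", sample(g$keys, 1L))
          } else if (length(anc) > 0L && pick < 0.6) {
            sprintf("%g*%s@%s", round(stats::runif(1, 0.5, 2), 2),
                    sample(g$keys, 1L), sample(anc, 1L))
          } else {
            # bare reference: scale the inherited value
            sprintf("%g*%s", round(stats::runif(1, 0.5, 2), 2), key)
          }
        } else {
          round(stats::runif(1, 0, 10), 3)
        }
        g <- set_local(g, nm, key, value)
      }
    }
    project$param_graph <- g
    project
  })
}

# ---- brute-force oracle ----------------------------------------------------------

#' Definitional brute-force resolution oracle
#'
#' Recomputes the resolution of (node, key) directly from the inheritance
#' definition, with no memoization and no shared code with the engine's
#' resolver. Intended for property tests: on small graphs it must agree with
#' [resolve_value()] everywhere, including where the latter raises conflict
#' or dangling-reference errors.
#'
#' @param graph a `config_graph`.
#' @param node,key the resolution target.
#' @return A list with `kind` (`"value"`, `"conflict"`, `"dangling"` or
#'   `"cycle"`), and for values: `value`, `provenance`, `source`.
#' @export
oracle_resolve <- function(graph, node, key) {
  marker <- function(kind) list(kind = kind)
  # full resolution of (nd, k); `trail` guards against reference cycles
  full <- function(nd, k, trail) {
    tag <- paste(nd, k)
    if (tag %in% trail) return(marker("cycle"))
    if (!nd %in% names(graph$nodes)) return(marker("dangling"))
    n <- graph$nodes[[nd]]
    if (k %in% names(n$locals)) {
      loc <- n$locals[[k]]
      if (identical(loc$t, "opaque"))
        return(list(kind = "value", value = loc$v, provenance = "LOCAL",
                    source = NA_character_))
      refs <- expr_refs(loc)
      env <- list()
      for (i in seq_len(nrow(refs))) {
        rk <- refs$key[i]; rn <- refs$node[i]
        sub <- if (!is.na(rn) && rn == BASE_NODE) {
          list(kind = "value", value = as.numeric(graph$base[[rk]]))
        } else if (is.na(rn)) {
          inherited(nd, rk, c(trail, tag))
        } else {
          full(rn, rk, c(trail, tag))
        }
        if (sub$kind != "value") return(marker(sub$kind))
        env[[ref_label(rk, rn)]] <- sub$value
      }
      return(list(kind = "value", value = eval_expr(loc, env),
                  provenance = "LOCAL", source = NA_character_))
    }
    inherited(nd, k, trail)
  }
  # the value nd would inherit for k, ignoring nd's own locals
  inherited <- function(nd, k, trail) {
    n <- graph$nodes[[nd]]
    if (length(n$parents) == 0L)
      return(list(kind = "value", value = base_val(k), provenance = "BASE",
                  source = NA_character_))
    deliv <- list()
    for (p in n$parents) {
      r <- full(p, k, trail)
      if (r$kind != "value") return(marker(r$kind))
      src <- if (r$provenance == "LOCAL") p
             else if (r$provenance == "INHERITED") r$source
             else NA_character_
      deliv[[length(deliv) + 1L]] <- list(parent = p, value = r$value, source = src)
    }
    changes <- Filter(function(d) !is.na(d$source), deliv)
    if (length(changes) == 0L)
      return(list(kind = "value", value = base_val(k), provenance = "BASE",
                  source = NA_character_))
    if (graph$kind[[k]] == "numeric") {
      v1 <- changes[[1L]]$value
      for (d in changes[-1L])
        if (abs(d$value - v1) > max(1e-15, 1e-12 * max(abs(d$value), abs(v1))))
          return(marker("conflict"))
    } else {
      for (d in changes[-1L])
        if (!identical(d$value, changes[[1L]]$value)) return(marker("conflict"))
    }
    list(kind = "value", value = changes[[1L]]$value, provenance = "INHERITED",
         source = changes[[1L]]$source)
  }
  base_val <- function(k) {
    if (graph$kind[[k]] == "numeric") as.numeric(graph$base[[k]])
    else graph$base[[k]]
  }
  full(node, key, character())
}
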