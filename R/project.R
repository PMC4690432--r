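# Project container and persistence.
#
# A project bundles the immutable base model with three inheritance graphs
# (parameter values, time-course settings, plot settings). It persists to a
# documented JSON format (format_version "1.0"): the SBML document is embedded
# as a string; each graph serializes its nodes in insertion order with local
# assignments as canonical expression strings (numeric keys) or raw JSON
# values (opaque keys). Conflicted and inconsistent graphs save and load
# losslessly — only simulation and export are blocked.

PROJECT_FORMAT_VERSION <- "1.0"

#' Create a project around a base model
#'
#' @param model an `mg_model` (see [load_sbml()], [example_model()]).
#' @param model_path optional provenance string recorded in the project.
#' @return An object of class `mg_project` with empty graphs.
#' @export
new_project <- function(model, model_path = NA_character_) {
  structure(list(model = model,
                 model_path = model_path,
                 param_graph = config_graph_from_base_set(base_set(model)),
                 tc_graph = timecourse_graph(),
                 plot_graph = plot_graph(),
                 format_version = PROJECT_FORMAT_VERSION),
            class = "mg_project")
}

#' @export
print.mg_project <- function(x, ...) {
  cat(sprintf("<mg_project> model '%s' | %d parameter node(s), %d time-course node(s), %d plot node(s)\n",
              x$model$model_id, length(x$param_graph$nodes),
              length(x$tc_graph$nodes), length(x$plot_graph$nodes)))
  invisible(x)
}

# ---- JSON serialization ---------------------------------------------------------

graph_to_json <- function(graph) {
  nodes <- lapply(graph$nodes, function(n) {
    locals <- lapply(n$locals, function(loc) {
      if (identical(loc$t, "opaque")) list(opaque = loc$v)
      else format_expr(loc)
    })
    list(name = n$name,
         parents = as.list(n$parents),
         locals = locals,
         color = if (is.null(n$color)) NULL else n$color,
         applies_to = as.list(n$applies_to))
  })
  list(nodes = unname(nodes))
}

#' Save a project to its JSON format
#'
#' `load_project(save_project(p))` resolves identically to `p` at every
#' (graph, node, key), including conflicted and inconsistent statuses.
#'
#' @param project an `mg_project`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_project <- function(project, path) {
  doc <- list(format_version = project$format_version,
              model_sbml = write_sbml(project$model, NULL),
              model_path = project$model_path,
              parameter_graph = graph_to_json(project$param_graph),
              timecourse_graph = graph_to_json(project$tc_graph),
              plot_graph = graph_to_json(project$plot_graph))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

schema_fail <- function(pointer, msg) {
  mg_stop("mg_schema_error", sprintf("%s (at %s)", msg, pointer),
          pointer = pointer)
}

graph_from_json <- function(js, skeleton, pointer) {
  if (is.null(js$nodes)) schema_fail(paste0(pointer, "/nodes"), "missing 'nodes'")
  g <- skeleton
  for (i in seq_along(js$nodes)) {
    nd <- js$nodes[[i]]
    ptr <- sprintf("%s/nodes/%d", pointer, i - 1L)
    if (is.null(nd$name) || !is.character(unlist(nd$name)))
      schema_fail(paste0(ptr, "/name"), "node needs a string 'name'")
    name <- as.character(nd$name)
    if (name %in% names(g$nodes))
      schema_fail(paste0(ptr, "/name"), sprintf("duplicate node name '%s'", name))
    parents <- as.character(unlist(nd$parents))
    missing <- setdiff(parents, names(g$nodes))
    if (length(missing) > 0L)
      schema_fail(paste0(ptr, "/parents"),
                  sprintf("parent(s) not defined earlier in the file: %s",
                          paste(missing, collapse = ", ")))
    color <- if (is.null(nd$color)) NULL else as.character(nd$color)
    applies_to <- as.character(unlist(nd$applies_to))
    g$nodes[[name]] <- new_node(name, parents, color, applies_to)
    for (key in names(nd$locals)) {
      lptr <- sprintf("%s/locals/%s", ptr, key)
      if (!key %in% g$keys)
        schema_fail(lptr, sprintf("'%s' is not a key of this graph", key))
      val <- nd$locals[[key]]
      if (is.list(val) && !is.null(val$opaque)) {
        if (g$kind[[key]] != "opaque")
          schema_fail(lptr, "opaque value supplied for a numeric key")
        v <- val$opaque
        # plot 'y' series come back as lists; scalars unbox
        if (is.list(v) && length(v) == 1L && !is.list(v[[1L]]) && key != "y")
          v <- v[[1L]]
        g$nodes[[name]]$locals[[key]] <- list(t = "opaque", v = v)
      } else {
        if (g$kind[[key]] != "numeric")
          schema_fail(lptr, "expression supplied for an opaque key")
        ast <- tryCatch(parse_expr(as.character(val)),
                        mg_syntax_error = function(c)
                          schema_fail(lptr, conditionMessage(c)))
        # dangling node references are allowed here (they mark the node
        # INCONSISTENT); unknown keys are schema errors
        bad <- setdiff(expr_refs(ast)$key, g$keys)
        if (length(bad) > 0L)
          schema_fail(lptr, sprintf("expression references unknown key(s): %s",
                                    paste(bad, collapse = ", ")))
        g$nodes[[name]]$locals[[key]] <- ast
      }
    }
  }
  if (graph_has_cycle(g)) schema_fail(pointer, "parent relation is cyclic")
  g
}

#' Load a project from its JSON format
#'
#' @param path a file written by [save_project()].
#' @return An `mg_project`.
#' @export
load_project <- function(path) {
  if (!file.exists(path))
    mg_stop("mg_file_not_found", sprintf("no such file: %s", path), path = path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e)
                   mg_stop("mg_schema_error",
                           sprintf("not parseable JSON: %s", conditionMessage(e)),
                           pointer = "/"))
  if (is.null(js$format_version))
    schema_fail("/format_version", "missing format_version")
  if (!identical(as.character(js$format_version), PROJECT_FORMAT_VERSION))
    mg_stop("mg_format_version_error",
            sprintf("unsupported format_version '%s' (expected '%s')",
                    js$format_version, PROJECT_FORMAT_VERSION))
  if (is.null(js$model_sbml))
    schema_fail("/model_sbml", "missing embedded model")
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp))
  writeLines(as.character(js$model_sbml), tmp)
  model <- load_sbml(tmp)
  project <- new_project(model,
                         model_path = if (is.null(js$model_path)) NA_character_
                                      else as.character(js$model_path))
  for (fld in c("parameter_graph", "timecourse_graph", "plot_graph"))
    if (is.null(js[[fld]])) schema_fail(paste0("/", fld), "missing graph")
  project$param_graph <- graph_from_json(js$parameter_graph, project$param_graph,
                                         "/parameter_graph")
  project$tc_graph <- graph_from_json(js$timecourse_graph, project$tc_graph,
                                      "/timecourse_graph")
  project$plot_graph <- graph_from_json(js$plot_graph, project$plot_graph,
                                        "/plot_graph")
  project
}

# ---- consistency ----------------------------------------------------------------

#' Full consistency report for a project
#'
#' Lists every conflicted (node, key), every inconsistent node, and every
#' `applies_to` entry naming a missing parameter node, across all three
#' graphs. An empty report is the precondition for simulation and export.
#'
#' @param project an `mg_project`.
#' @return A data.frame with columns `type`, `graph`, `node`, `key`, `detail`;
#'   zero rows when the project is consistent.
#' @export
check_consistency <- function(project) {
  rows <- list()
  add <- function(type, graph, node, key, detail) {
    rows[[length(rows) + 1L]] <<- data.frame(type = type, graph = graph,
                                             node = node, key = key,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }
  graphs <- list(params = project$param_graph,
                 timecourse = project$tc_graph,
                 plot = project$plot_graph)
  for (gname in names(graphs)) {
    g <- graphs[[gname]]
    for (nd in names(g$nodes)) {
      st <- node_status(g, nd)
      if (st == "INCONSISTENT") {
        add("inconsistent", gname, nd, NA_character_,
            "local expression references a missing node or key")
      } else if (st == "CONFLICTED") {
        for (cf in detect_conflicts(g, nd))
          add("conflict", gname, nd, cf$key,
              paste(sprintf("%s=%g", names(cf$candidates), cf$candidates),
                    collapse = ", "))
      }
    }
  }
  pnodes <- graph_nodes(project$param_graph)
  for (gname in c("timecourse", "plot")) {
    g <- graphs[[gname]]
    for (nd in names(g$nodes)) {
      dangling <- setdiff(g$nodes[[nd]]$applies_to, pnodes)
      for (d in dangling)
        add("dangling_applies_to", gname, nd, NA_character_,
            sprintf("applies_to names missing parameter node '%s'", d))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(type = character(), graph = character(),
                      node = character(), key = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# ---- SBML export ----------------------------------------------------------------

#' Export one node as a flattened SBML L3V1 file
#'
#' Writes `apply_values(base model, resolve_all(node))` with the model id
#' suffixed `_<node>`. The applicable time-course and plot settings (which
#' SBML cannot carry) go to a sidecar JSON file `<path>.settings.json`.
#' Conflicted or inconsistent nodes are blocked.
#'
#' @param project an `mg_project`.
#' @param node parameter-node name with status OK.
#' @param path output SBML file path.
#' @param sidecar write the settings sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
export_node_sbml <- function(project, node, path, sidecar = TRUE) {
  node_or_fail(project$param_graph, node)
  resolved <- resolved_or_blocked(project, node)
  vals <- vapply(resolved, `[[`, 0, "value")
  flat <- apply_values(project$model, vals)
  flat$model_id <- paste0(flat$model_id, "_", node)
  write_sbml(flat, path)
  if (sidecar) {
    tc <- applicable_settings(project, node, "timecourse")
    pl <- applicable_settings(project, node, "plot")
    side <- list(node = node,
                 timecourse = lapply(tc, unclass),
                 plot = lapply(pl, unclass))
    writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               paste0(path, ".settings.json"))
  }
  invisible(path)
}

#' Export every consistent node of the parameter graph
#'
#' One SBML file per OK node, named `<model_id>_<node>.xml`, plus a manifest
#' CSV (`node`, `file`, `status`) that also lists skipped nodes.
#'
#' @param project an `mg_project`.
#' @param dir output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
export_ensemble <- function(project, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(graph_nodes(project$param_graph), function(nd) {
    fn <- sprintf("%s_%s.xml", project$model$model_id, nd)
    status <- tryCatch(
      {
        export_node_sbml(project, nd, file.path(dir, fn))
        "OK"
      },
      mg_blocked_by_conflict = function(c) "CONFLICTED",
      mg_blocked_by_inconsistency = function(c) "INCONSISTENT")
    data.frame(node = nd, file = if (status == "OK") fn else "",
               status = status, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows) == 0L) {
    data.frame(node = character(), file = character(), status = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# ---- DOT export -----------------------------------------------------------------

dot_quote <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")

#' Render a configuration graph to Graphviz DOT
#'
#' One DOT node per configuration (label = name, fill color when set),
#' directed edges from child to parent; edges into a CONFLICTED child are
#' `style=dashed`. Nodes are emitted sorted by name, so the output is
#' byte-stable for a fixed graph.
#'
#' @param graph a `config_graph`.
#' @param name the DOT graph name.
#' @return The DOT document as a single string.
#' @export
export_graph_dot <- function(graph, name = "configurations") {
  lines <- c(sprintf("digraph %s {", dot_quote(name)),
             "  node [shape=box];")
  nms <- sort(names(graph$nodes))
  for (nm in nms) {
    n <- graph$nodes[[nm]]
    attrs <- sprintf("label=%s", dot_quote(nm))
    if (!is.null(n$color))
      attrs <- paste0(attrs, sprintf(", style=filled, fillcolor=%s",
                                     dot_quote(n$color)))
    lines <- c(lines, sprintf("  %s [%s];", dot_quote(nm), attrs))
  }
  for (nm in nms) {
    n <- graph$nodes[[nm]]
    dashed <- node_status(graph, nm) == "CONFLICTED"
    for (p in n$parents) {
      edge <- sprintf("  %s -> %s", dot_quote(nm), dot_quote(p))
      if (dashed) edge <- paste0(edge, " [style=dashed]")
      lines <- c(lines, paste0(edge, ";"))
    }
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

# ---- plot rendering -------------------------------------------------------------

#' Render ensemble results according to the plot graph
#'
#' For every successful run and every applicable plot spec, writes a CSV of
#' the plotted columns (`<param>__<tc>__<plot>.csv`) and, when `images =
#' TRUE`, a PNG honoring each series' color, width, symbol and stride. Series
#' whose variable is absent from the time series are dropped (e.g. a plot
#' spec deliberately omitting a knocked-out species); an empty `y` plots all
#' dynamic state variables.
#'
#' @param project an `mg_project`.
#' @param results an `mg_ensemble` from [run_ensemble()].
#' @param dir output directory.
#' @param images also write PNG images (default `FALSE`; CSV only).
#' @return Data.frame manifest of written files, invisibly.
#' @export
render_plots <- function(project, results, dir, images = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (entry in results) {
    if (is.null(entry$series)) next
    ts <- entry$series
    for (ps in applicable_settings(project, entry$param_node, "plot")) {
      series <- ps$y
      if (length(series) == 0L) {
        state <- build_ode(project$model)$state_ids
        series <- lapply(intersect(state, ts$labels), function(id)
          list(id = id, color = "black", width = 1, symbol = "none", stride = 1L))
      }
      series <- Filter(function(s) s$id %in% ts$labels, series)
      if (length(series) == 0L) next
      xvals <- if (identical(ps$x, "TIME")) ts$times
               else if (ps$x %in% ts$labels) ts$values[, ps$x]
               else next
      yids <- vapply(series, `[[`, "", "id")
      tab <- cbind(xvals, ts$values[, yids, drop = FALSE])
      colnames(tab) <- c(if (identical(ps$x, "TIME")) "time" else ps$x, yids)
      stem <- sprintf("%s__%s__%s", entry$param_node, entry$tc_node, ps$name)
      csv <- file.path(dir, paste0(stem, ".csv"))
      con <- file(csv, "w")
      writeLines(paste(colnames(tab), collapse = ","), con)
      writeLines(apply(tab, 1L, function(row)
        paste(sprintf("%.10g", row), collapse = ",")), con)
      close(con)
      files[[length(files) + 1L]] <-
        data.frame(param_node = entry$param_node, tc_node = entry$tc_node,
                   plot_node = ps$name, file = basename(csv), kind = "csv",
                   stringsAsFactors = FALSE)
      if (images) {
        png_path <- file.path(dir, paste0(stem, ".png"))
        grDevices::png(png_path, width = 800, height = 600)
        tryCatch({
          yl <- range(tab[, -1L, drop = FALSE], finite = TRUE)
          graphics::plot(NA, xlim = range(tab[, 1L]), ylim = yl,
                         xlab = ps$x_label, ylab = ps$y_label,
                         main = if (nzchar(ps$title)) ps$title else stem)
          for (k in seq_along(series)) {
            s <- series[[k]]
            graphics::lines(tab[, 1L], tab[, s$id], col = s$color, lwd = s$width)
            if (!identical(s$symbol, "none")) {
              idx <- seq(1L, nrow(tab), by = max(1L, as.integer(s$stride)))
              graphics::points(tab[idx, 1L], tab[idx, s$id], col = s$color,
                               pch = symbol_pch(s$symbol))
            }
          }
          graphics::legend("topright", legend = yids, lwd = 1,
                           col = vapply(series, `[[`, "", "color"))
        }, finally = grDevices::dev.off())
        files[[length(files) + 1L]] <-
          data.frame(param_node = entry$param_node, tc_node = entry$tc_node,
                     plot_node = ps$name, file = basename(png_path),
                     kind = "png", stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(files) == 0L) {
    data.frame(param_node = character(), tc_node = character(),
               plot_node = character(), file = character(), kind = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, files)
  }
  invisible(manifest)
}

symbol_pch <- function(symbol) {
  switch(symbol, circle = 1, square = 0, triangle = 2, cross = 3, diamond = 5, 1)
}
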