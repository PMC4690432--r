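# Settings hierarchies: the same inheritance engine instantiated over
# time-course fields and plot fields. Numeric fields admit the expression
# language ("2*duration@short"); enum/string/list-valued fields are inherited
# whole ("opaque"). Each settings node carries an applies_to list naming the
# parameter nodes it pertains to (empty = applies to all); applies_to is a
# per-node attribute, not an inherited value.

# Built-in defaults used when no settings node exists, and as the base set of
# every settings graph. Duration 100 model-time units with unit interval is a
# conventional desk-scale default; the tolerance pair (1e-8, 1e-12) is the
# package's documented integrator default.
TC_DEFAULTS <- list(duration = 100, interval_size = 1, output_start = 0,
                    rel_tol = 1e-8, abs_tol = 1e-12,
                    method = "DETERMINISTIC_STIFF")

PLOT_DEFAULTS <- list(x = "TIME", y = list(), title = "",
                      x_label = "time", y_label = "value")

#' Create an empty time-course settings graph
#'
#' Keys: `duration`, `interval_size`, `output_start`, `rel_tol`, `abs_tol`
#' (numeric, expression-capable) and `method` (opaque; only
#' `"DETERMINISTIC_STIFF"` is accepted at simulation time).
#'
#' @return A `config_graph`.
#' @export
timecourse_graph <- function() {
  config_graph(TC_DEFAULTS,
               kinds = c(duration = "numeric", interval_size = "numeric",
                         output_start = "numeric", rel_tol = "numeric",
                         abs_tol = "numeric", method = "opaque"))
}

#' Create an empty plot settings graph
#'
#' Keys (all opaque): `x` (`"TIME"` or a variable id), `y` (list of series,
#' each `list(id, color, width, symbol, stride)`; empty = all state
#' variables), `title`, `x_label`, `y_label`.
#'
#' @return A `config_graph`.
#' @export
plot_graph <- function() {
  config_graph(PLOT_DEFAULTS,
               kinds = c(x = "opaque", y = "opaque", title = "opaque",
                         x_label = "opaque", y_label = "opaque"))
}

#' Construct a time-course specification
#'
#' @param duration simulation end time (model time units), > 0.
#' @param interval_size output grid spacing, in (0, duration].
#' @param output_start first reported time point (default 0).
#' @param rel_tol,abs_tol integrator tolerances, > 0.
#' @param method only `"DETERMINISTIC_STIFF"` is supported.
#' @param name label used in run keys and output file names.
#' @param applies_to parameter-node names this spec applies to (empty = all).
#' @return An object of class `mg_timecourse_spec`.
#' @export
timecourse_spec <- function(duration = TC_DEFAULTS$duration,
                            interval_size = TC_DEFAULTS$interval_size,
                            output_start = TC_DEFAULTS$output_start,
                            rel_tol = TC_DEFAULTS$rel_tol,
                            abs_tol = TC_DEFAULTS$abs_tol,
                            method = TC_DEFAULTS$method,
                            name = "default", applies_to = character()) {
  spec <- structure(list(name = name, duration = duration,
                         interval_size = interval_size,
                         output_start = output_start,
                         rel_tol = rel_tol, abs_tol = abs_tol,
                         method = method, applies_to = applies_to),
                    class = "mg_timecourse_spec")
  validate_timecourse_spec(spec)
  spec
}

validate_timecourse_spec <- function(spec) {
  bad <- function(msg) mg_stop("mg_invalid_spec",
                               sprintf("time-course spec '%s': %s", spec$name, msg))
  if (!is.numeric(spec$duration) || spec$duration <= 0) bad("duration must be > 0")
  if (!is.numeric(spec$interval_size) || spec$interval_size <= 0 ||
      spec$interval_size > spec$duration)
    bad("interval_size must be in (0, duration]")
  if (spec$output_start < 0 || spec$output_start > spec$duration)
    bad("output_start must be in [0, duration]")
  if (spec$rel_tol <= 0 || spec$abs_tol <= 0) bad("tolerances must be > 0")
  if (!identical(spec$method, "DETERMINISTIC_STIFF"))
    bad(sprintf("unsupported method '%s'", spec$method))
  invisible(spec)
}

#' Construct a plot specification
#'
#' @param x `"TIME"` or a model variable id.
#' @param y list of series: each `list(id, color, width, symbol, stride)`
#'   (only `id` is required). Empty list = all state variables, default style.
#' @param title,x_label,y_label plot annotation strings.
#' @param name label used in output file names.
#' @param applies_to parameter-node names this spec applies to (empty = all).
#' @return An object of class `mg_plot_spec`.
#' @export
plot_spec <- function(x = "TIME", y = list(), title = "", x_label = "time",
                      y_label = "value", name = "default",
                      applies_to = character()) {
  y <- lapply(y, function(s) {
    if (is.character(s)) s <- list(id = s)
    if (is.null(s$id)) mg_stop("mg_invalid_spec", "every y series needs an id")
    utils::modifyList(list(color = "black", width = 1, symbol = "none",
                           stride = 1L), s)
  })
  structure(list(name = name, x = x, y = y, title = title,
                 x_label = x_label, y_label = y_label,
                 applies_to = applies_to),
            class = "mg_plot_spec")
}

# Resolve a settings node into a spec object.
spec_from_node <- function(graph, node, kind = c("timecourse", "plot")) {
  kind <- match.arg(kind)
  vals <- resolve_all(graph, node)
  fields <- lapply(vals, `[[`, "value")
  applies_to <- graph$nodes[[node]]$applies_to
  if (kind == "timecourse") {
    timecourse_spec(duration = fields$duration,
                    interval_size = fields$interval_size,
                    output_start = fields$output_start,
                    rel_tol = fields$rel_tol, abs_tol = fields$abs_tol,
                    method = fields$method,
                    name = node, applies_to = applies_to)
  } else {
    plot_spec(x = fields$x, y = fields$y, title = fields$title,
              x_label = fields$x_label, y_label = fields$y_label,
              name = node, applies_to = applies_to)
  }
}

#' Settings applicable to a parameter node
#'
#' Returns, in settings-graph insertion order, the resolved settings of every
#' node whose `applies_to` names the parameter node or is empty. With no
#' settings node defined, the single built-in default spec is returned.
#'
#' @param project an `mg_project`.
#' @param parameter_node name of a node of the parameter graph.
#' @param kind `"timecourse"` or `"plot"`.
#' @return A list of `mg_timecourse_spec` / `mg_plot_spec`.
#' @export
applicable_settings <- function(project, parameter_node,
                                kind = c("timecourse", "plot")) {
  kind <- match.arg(kind)
  node_or_fail(project$param_graph, parameter_node)
  graph <- if (kind == "timecourse") project$tc_graph else project$plot_graph
  if (length(graph$nodes) == 0L)
    return(list(if (kind == "timecourse") timecourse_spec() else plot_spec()))
  hits <- Filter(function(nm) {
    at <- graph$nodes[[nm]]$applies_to
    length(at) == 0L || parameter_node %in% at
  }, names(graph$nodes))
  lapply(hits, function(nm) spec_from_node(graph, nm, kind))
}
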