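# Deterministic time-course simulation.
#
# A flattened model is compiled to dx/dt = S v(x, p, t): S the species x
# reactions stoichiometry matrix (boundary species excluded from the state),
# v the kinetic-law rates. Rate rules are appended as extra state equations
# (a rate rule overrides any reaction contribution for its target);
# assignment rules are evaluated before the rates at every derivative call.
#
# Integration uses an adaptive Rosenbrock 2(3) pair (the classic ode23s
# scheme: L-stable, one Jacobian per step, embedded error estimate), the one
# stiff-capable method behind the DETERMINISTIC_STIFF setting. Output is
# sampled on the exact uniform grid by clamping steps to grid points.

#' Build the ODE system of a flattened model
#'
#' @param model an `mg_model` within the supported subset.
#' @return An object of class `mg_ode_system` with fields `state_ids`,
#'   `stoich` (species x reactions matrix) and the compiled derivative
#'   function.
#' @export
build_ode <- function(model) {
  validate_model(model)
  rule_targets <- vapply(model$rate_rules, function(r) r$target, character(1))
  assigned <- vapply(model$assignment_rules, function(r) r$target, character(1))

  dyn_species <- model$species$id[!model$species$boundary &
                                    !model$species$id %in% assigned]
  extra_state <- setdiff(rule_targets, model$species$id) # quantities driven by rate rules
  state_ids <- c(dyn_species, extra_state)
  n_rx <- length(model$reactions)

  stoich <- matrix(0, nrow = length(dyn_species), ncol = n_rx,
                   dimnames = list(dyn_species,
                                   vapply(model$reactions, `[[`, "", "id")))
  for (j in seq_len(n_rx)) {
    r <- model$reactions[[j]]
    for (i in seq_len(nrow(r$reactants))) {
      sp <- r$reactants$species[i]
      if (sp %in% dyn_species)
        stoich[sp, j] <- stoich[sp, j] - r$reactants$stoichiometry[i]
    }
    for (i in seq_len(nrow(r$products))) {
      sp <- r$products$species[i]
      if (sp %in% dyn_species)
        stoich[sp, j] <- stoich[sp, j] + r$products$stoichiometry[i]
    }
  }

  # constants: compartments, constant quantities, boundary species
  const_env <- new.env(parent = baseenv())
  for (i in seq_len(nrow(model$compartments)))
    assign(model$compartments$id[i], model$compartments$size[i], envir = const_env)
  for (i in seq_len(nrow(model$quantities)))
    assign(model$quantities$id[i], model$quantities$value[i], envir = const_env)
  for (i in seq_len(nrow(model$species)))
    if (model$species$boundary[i])
      assign(model$species$id[i], model$species$initial_amount[i], envir = const_env)

  rate_lang <- lapply(model$reactions, function(r) ast_to_lang(r$law))
  rule_lang <- lapply(model$rate_rules, function(r) ast_to_lang(r$math))
  assign_lang <- lapply(model$assignment_rules, function(r) ast_to_lang(r$math))

  y0 <- numeric(length(state_ids))
  names(y0) <- state_ids
  for (sp in dyn_species)
    y0[sp] <- model$species$initial_amount[model$species$id == sp]
  for (q in extra_state)
    y0[q] <- model$quantities$value[model$quantities$id == q]

  rule_rows <- match(intersect(rule_targets, dyn_species), state_ids)
  rule_idx <- match(state_ids[state_ids %in% rule_targets], rule_targets)

  deriv <- function(t, y) {
    env <- new.env(parent = const_env)
    for (i in seq_along(state_ids)) assign(state_ids[i], y[i], envir = env)
    assign("time", t, envir = env)
    for (i in seq_along(assign_lang))
      assign(assigned[i], eval(assign_lang[[i]], env), envir = env)
    dy <- numeric(length(state_ids))
    if (n_rx > 0L) {
      v <- vapply(rate_lang, function(e) eval(e, env), 0)
      dy[seq_along(dyn_species)] <- as.numeric(stoich %*% v)
    }
    # rate rules override / define their targets' derivatives
    for (k in seq_along(rule_targets)) {
      tgt <- rule_targets[k]
      pos <- match(tgt, state_ids)
      if (!is.na(pos)) dy[pos] <- eval(rule_lang[[k]], env)
    }
    dy
  }

  structure(list(state_ids = state_ids, stoich = stoich, deriv = deriv,
                 y0 = y0, model = model),
            class = "mg_ode_system")
}

# AST -> R language object, for fast evaluation inside the RHS.
ast_to_lang <- function(e) {
  switch(e$t,
    num = e$v,
    ref = {
      if (!is.na(e$node))
        mg_stop("mg_sbml_parse_error",
                "node-qualified references cannot appear in model math")
      as.name(e$key)
    },
    neg = call("-", ast_to_lang(e$x)),
    bin = call(e$op, ast_to_lang(e$l), ast_to_lang(e$r)),
    call = switch(e$fn,
      exp = call("exp", ast_to_lang(e$args[[1L]])),
      ln = call("log", ast_to_lang(e$args[[1L]])),
      time = as.name("time"),
      mg_stop("mg_unsupported_feature",
              sprintf("unsupported function '%s' in model math", e$fn),
              feature = e$fn)))
}

# ---- Rosenbrock 2(3) integrator ------------------------------------------------

# One adaptive run from t0 to t1, reporting the dense solution at out_times
# (must be sorted, within [t0, t1]). Steps are clamped to land exactly on
# each output time, so no interpolation error enters the reported values.
ros23_integrate <- function(f, y0, t0, t1, out_times, rel_tol, abs_tol) {
  n <- length(y0)
  if (n == 0L) return(matrix(0, nrow = length(out_times), ncol = 0L))
  d <- 1 / (2 + sqrt(2))
  e32 <- 6 + sqrt(2)
  eye <- diag(n)

  num_jac <- function(t, y, f0) {
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      dy <- sqrt(.Machine$double.eps) * max(abs(y[j]), 1e-5)
      yp <- y
      yp[j] <- yp[j] + dy
      J[, j] <- (f(t, yp) - f0) / dy
    }
    J
  }
  time_deriv <- function(t, y, f0) {
    dt <- sqrt(.Machine$double.eps) * max(abs(t), 1)
    (f(t + dt, y) - f0) / dt
  }

  out <- matrix(NA_real_, nrow = length(out_times), ncol = n)
  oi <- 1L
  t <- t0
  y <- y0
  while (oi <= length(out_times) && out_times[oi] <= t + 1e-12 * max(1, abs(t))) {
    out[oi, ] <- y
    oi <- oi + 1L
  }

  h <- (t1 - t0) / 100
  max_steps <- 1e6
  steps <- 0L
  while (t < t1 - 1e-12 * max(1, abs(t1))) {
    steps <- steps + 1L
    if (steps > max_steps)
      mg_stop("mg_integration_failure", "step limit exceeded")
    h <- min(h, t1 - t)
    if (oi <= length(out_times)) h <- min(h, out_times[oi] - t)
    if (h < 16 * .Machine$double.eps * max(abs(t), 1))
      mg_stop("mg_integration_failure",
              sprintf("step size collapsed at t = %g", t))

    f0 <- f(t, y)
    if (any(!is.finite(f0)))
      mg_stop("mg_integration_failure",
              sprintf("non-finite derivative at t = %g", t))
    J <- num_jac(t, y, f0)
    Tt <- time_deriv(t, y, f0)
    W <- eye - h * d * J
    sol <- tryCatch(solve(W), error = function(e)
      mg_stop("mg_integration_failure",
              sprintf("singular iteration matrix at t = %g", t)))
    k1 <- sol %*% (f0 + h * d * Tt)
    f1 <- f(t + h / 2, y + as.numeric(h / 2 * k1))
    k2 <- sol %*% (f1 - k1) + k1
    ynew <- y + as.numeric(h * k2)
    f2 <- f(t + h, ynew)
    k3 <- sol %*% (f2 - e32 * (k2 - f1) - 2 * (k1 - f0) + h * d * Tt)
    err <- as.numeric(h / 6 * (k1 - 2 * k2 + k3))
    sc <- abs_tol + rel_tol * pmax(abs(y), abs(ynew))
    errnorm <- sqrt(mean((err / sc)^2))

    if (!is.finite(errnorm)) {
      h <- h / 2
      next
    }
    if (errnorm <= 1) {
      t <- t + h
      y <- ynew
      while (oi <= length(out_times) &&
             out_times[oi] <= t + 1e-9 * max(1, abs(t))) {
        out[oi, ] <- y
        oi <- oi + 1L
      }
    }
    h <- h * min(5, max(0.2, 0.8 * errnorm^(-1 / 3)))
  }
  while (oi <= length(out_times)) { # guard against FP shortfall at t1
    out[oi, ] <- y
    oi <- oi + 1L
  }
  out
}

# ---- time courses --------------------------------------------------------------

#' Run a deterministic time course
#'
#' Integrates from model time 0 to `spec$duration` and reports the state on
#' the uniform grid `output_start, output_start + interval_size, ...,
#' duration`. Besides the dynamic state, boundary species, compartment sizes,
#' constant quantities and assignment-rule targets are emitted as columns so
#' every plottable variable is present.
#'
#' @param sys an `mg_ode_system` (from [build_ode()]) or an `mg_model`.
#' @param spec an `mg_timecourse_spec`.
#' @return An object of class `mg_timeseries`: `times`, `values` (matrix,
#'   one column per variable), `labels`.
#' @export
run_timecourse <- function(sys, spec = timecourse_spec()) {
  if (inherits(sys, "mg_model")) sys <- build_ode(sys)
  validate_timecourse_spec(spec)
  n_out <- floor((spec$duration - spec$output_start) / spec$interval_size + 1e-9) + 1L
  times <- spec$output_start + (seq_len(n_out) - 1L) * spec$interval_size

  y <- ros23_integrate(sys$deriv, sys$y0, 0, spec$duration, times,
                       spec$rel_tol, spec$abs_tol)
  colnames(y) <- sys$state_ids

  model <- sys$model
  extra_ids <- character()
  extra_cols <- list()
  add_const <- function(id, v) {
    extra_ids <<- c(extra_ids, id)
    extra_cols[[id]] <<- rep(v, n_out)
  }
  for (i in seq_len(nrow(model$species)))
    if (model$species$boundary[i])
      add_const(model$species$id[i], model$species$initial_amount[i])
  assigned <- vapply(model$assignment_rules, function(r) r$target, character(1))
  for (i in seq_len(nrow(model$quantities))) {
    id <- model$quantities$id[i]
    if (id %in% sys$state_ids || id %in% assigned) next
    add_const(id, model$quantities$value[i])
  }
  for (i in seq_len(nrow(model$compartments)))
    add_const(model$compartments$id[i], model$compartments$size[i])
  # assignment-rule targets recomputed on the grid
  if (length(model$assignment_rules) > 0L) {
    for (k in seq_along(model$assignment_rules)) {
      rl <- model$assignment_rules[[k]]
      lang <- ast_to_lang(rl$math)
      vals <- vapply(seq_len(n_out), function(i) {
        env <- new.env(parent = baseenv())
        for (j in seq_len(nrow(model$compartments)))
          assign(model$compartments$id[j], model$compartments$size[j], envir = env)
        for (j in seq_len(nrow(model$quantities)))
          assign(model$quantities$id[j], model$quantities$value[j], envir = env)
        for (j in seq_along(sys$state_ids))
          assign(sys$state_ids[j], y[i, j], envir = env)
        assign("time", times[i], envir = env)
        eval(lang, env)
      }, 0)
      extra_ids <- c(extra_ids, rl$target)
      extra_cols[[rl$target]] <- vals
    }
  }
  values <- cbind(y, do.call(cbind, c(extra_cols, list(deparse.level = 0))))
  colnames(values) <- c(sys$state_ids, extra_ids)
  if (anyNA(values))
    mg_stop("mg_integration_failure", "output contains missing values")
  structure(list(times = times, values = values,
                 labels = colnames(values)),
            class = "mg_timeseries")
}

#' @export
print.mg_timeseries <- function(x, ...) {
  cat(sprintf("<mg_timeseries> %d time points x %d variable(s): %s\n",
              length(x$times), ncol(x$values),
              paste(utils::head(x$labels, 6), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.mg_timeseries <- function(x, ...) {
  data.frame(time = x$times, x$values, check.names = FALSE)
}

#' Write a time series as CSV
#'
#' Header `time,<id>,...`, one row per grid point, `%.10g` formatting.
#'
#' @param ts an `mg_timeseries`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time", ts$labels), collapse = ","), con)
  body <- apply(cbind(ts$times, ts$values), 1L, function(row)
    paste(sprintf("%.10g", row), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

# ---- ensemble runs -------------------------------------------------------------

# Gate: can this parameter node be simulated/exported? Returns its resolved
# values or signals BlockedByConflict / BlockedByInconsistency.
resolved_or_blocked <- function(project, node) {
  tryCatch(
    resolve_all(project$param_graph, node),
    mg_conflict_error = function(c)
      mg_stop("mg_blocked_by_conflict",
              sprintf("node '%s' has unresolved conflicts (%s)", node,
                      conditionMessage(c)),
              node = node, cause = c),
    mg_dangling_reference = function(c)
      mg_stop("mg_blocked_by_inconsistency",
              sprintf("node '%s' is inconsistent (%s)", node,
                      conditionMessage(c)),
              node = node, cause = c),
    mg_reference_cycle_error = function(c)
      mg_stop("mg_blocked_by_inconsistency",
              sprintf("node '%s' is inconsistent (%s)", node,
                      conditionMessage(c)),
              node = node, cause = c))
}

#' Run every applicable time course for a selection of mutants
#'
#' One run per (selected parameter node x applicable time-course spec).
#' Every selected node must be consistent before anything runs; integration
#' failures of individual runs are reported per pair without aborting the
#' batch.
#'
#' @param project an `mg_project`.
#' @param selection character vector of parameter-node names (default: all).
#' @return A named list (names `"<node>::<tc>"`) of entries with
#'   `param_node`, `tc_node`, and either `series` (an `mg_timeseries`) or
#'   `error` (message string), of class `mg_ensemble`.
#' @export
run_ensemble <- function(project, selection = graph_nodes(project$param_graph)) {
  resolved <- lapply(selection, function(nd) {
    node_or_fail(project$param_graph, nd)
    resolved_or_blocked(project, nd)
  })
  names(resolved) <- selection
  out <- list()
  for (nd in selection) {
    vals <- vapply(resolved[[nd]], `[[`, 0, "value")
    flat <- apply_values(project$model, vals)
    sys <- build_ode(flat)
    for (spec in applicable_settings(project, nd, "timecourse")) {
      key <- paste(nd, spec$name, sep = "::")
      out[[key]] <- tryCatch(
        list(param_node = nd, tc_node = spec$name,
             series = run_timecourse(sys, spec)),
        mg_integration_failure = function(c)
          list(param_node = nd, tc_node = spec$name,
               error = conditionMessage(c)))
    }
  }
  structure(out, class = "mg_ensemble")
}
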