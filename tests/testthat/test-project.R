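# Project persistence, consistency reporting, exports, DOT, plot rendering.

resolution_fingerprint <- function(project) {
  lapply(list(project$param_graph, project$tc_graph, project$plot_graph),
         function(g) {
           lapply(graph_nodes(g), function(nd) {
             list(status = node_status(g, nd),
                  values = lapply(g$keys, function(k) engine_resolve(g, nd, k)))
           })
         })
}

test_that("save/load is a fixpoint, conflicts and inconsistencies included", {
  ps <- example_projects()
  for (nm in names(ps)) {
    f <- tempfile(fileext = ".json")
    save_project(ps[[nm]], f)
    p2 <- load_project(f)
    expect_equal(resolution_fingerprint(p2), resolution_fingerprint(ps[[nm]]),
                 label = nm)
    expect_true(mutantgraph:::models_equal(p2$model, ps[[nm]]$model))
  }
  # the conflicted project keeps its conflict across the round trip
  f <- tempfile(fileext = ".json")
  save_project(ps$conflict, f)
  expect_identical(node_status(load_project(f)$param_graph, "M"), "CONFLICTED")

  # an inconsistent project (deleted referenced node) round trips too
  p <- ps$media
  p$param_graph <- set_local(p$param_graph, "WT_galactose", "mdt",
                             "2*mdt@WT_glucose")
  p$param_graph <- delete_node(p$param_graph, "WT_glucose", force = TRUE)$graph
  expect_identical(node_status(p$param_graph, "WT_galactose"), "INCONSISTENT")
  save_project(p, f)
  expect_identical(node_status(load_project(f)$param_graph, "WT_galactose"),
                   "INCONSISTENT")
})

test_that("save/load fixpoint holds on randomized projects", {
  for (seed in 1:25) {
    p <- random_project(n_nodes = 6, n_keys = 3, p_local = 0.5, p_expr = 0.4,
                        seed = 500 + seed)
    # give some of them settings nodes as well
    if (seed %% 2L == 0L) {
      p$tc_graph <- create_root(p$tc_graph, "tc0",
                                applies_to = graph_nodes(p$param_graph)[1])
      p$tc_graph <- set_local(p$tc_graph, "tc0", "duration", 50 + seed)
      p$plot_graph <- create_root(p$plot_graph, "pl0")
      p$plot_graph <- set_local(p$plot_graph, "pl0", "y",
                                list(list(id = "A", color = "red", width = 2,
                                          symbol = "circle", stride = 5L)))
    }
    f <- tempfile(fileext = ".json")
    save_project(p, f)
    p2 <- load_project(f)
    expect_equal(resolution_fingerprint(p2), resolution_fingerprint(p),
                 label = paste("seed", seed))
  }
})

test_that("schema and version errors are explicit", {
  f <- tempfile(fileext = ".json")
  writeLines("{ truncated", f)
  expect_error(load_project(f), class = "mg_schema_error")

  p <- example_projects()$media
  save_project(p, f)
  js <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  js$format_version <- "99.0"
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE), f)
  expect_error(load_project(f), class = "mg_format_version_error")

  js$format_version <- "1.0"
  js$parameter_graph$nodes[[2]]$name <- NULL
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE), f)
  err <- tryCatch(load_project(f), mg_schema_error = function(c) c)
  expect_s3_class(err, "mg_schema_error")
  expect_match(err$pointer, "^/parameter_graph/nodes/1")
})

test_that("node export flattens values and re-imports as a fixpoint", {
  p <- example_projects()$media
  f <- tempfile(fileext = ".xml")
  export_node_sbml(p, "WT_galactose", f)
  m <- load_sbml(f)
  expect_identical(m$model_id, "growth_WT_galactose")
  expect_equal(m$quantities$value[m$quantities$id == "mdt"], 150)
  expect_true(file.exists(paste0(f, ".settings.json")))

  # fixpoint: a fresh project over the export, with one root, resolves like
  # the original node
  p2 <- new_project(m)
  p2$param_graph <- create_root(p2$param_graph, "root")
  orig <- resolve_all(p$param_graph, "WT_galactose")
  again <- resolve_all(p2$param_graph, "root")
  for (k in names(orig))
    expect_equal(again[[k]]$value, orig[[k]]$value, label = k)

  # a root node export is value-identical to the base model
  f2 <- tempfile(fileext = ".xml")
  export_node_sbml(p, "WT_glucose", f2)
  m2 <- load_sbml(f2)
  m2$model_id <- p$model$model_id
  expect_true(mutantgraph:::models_equal(m2, p$model))

  expect_error(export_node_sbml(example_projects()$conflict, "M", tempfile()),
               class = "mg_blocked_by_conflict")
})

test_that("export/re-import fixpoint holds for every OK node of random projects", {
  for (seed in c(3, 14, 25)) {
    p <- random_project(n_nodes = 6, n_keys = 3, p_local = 0.5, seed = 900 + seed)
    for (nd in graph_nodes(p$param_graph)) {
      ok <- tryCatch({
        resolve_all(p$param_graph, nd)
        TRUE
      }, mg_error = function(c) FALSE)
      if (!ok) next
      f <- tempfile(fileext = ".xml")
      export_node_sbml(p, nd, f, sidecar = FALSE)
      p2 <- new_project(load_sbml(f))
      p2$param_graph <- create_root(p2$param_graph, "root")
      orig <- resolve_all(p$param_graph, nd)
      again <- resolve_all(p2$param_graph, "root")
      for (k in names(orig))
        expect_equal(again[[k]]$value, orig[[k]]$value,
                     label = sprintf("seed %d %s.%s", seed, nd, k))
    }
  }
})

test_that("ensemble export writes one file per OK node plus a manifest", {
  dir <- file.path(tempdir(), "exp1")
  manifest <- export_ensemble(example_projects()$media, dir)
  expect_identical(manifest$status, c("OK", "OK"))
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  dir2 <- file.path(tempdir(), "exp2")
  m2 <- export_ensemble(example_projects()$conflict, dir2)
  expect_identical(m2$status[m2$node == "M"], "CONFLICTED")
  expect_identical(m2$file[m2$node == "M"], "")
  expect_identical(sum(m2$status == "OK"), 2L)

  # empty graph: manifest only
  dir3 <- file.path(tempdir(), "exp3")
  m3 <- export_ensemble(new_project(example_model("decay")), dir3)
  expect_identical(nrow(m3), 0L)
  expect_true(file.exists(file.path(dir3, "manifest.csv")))
})

test_that("DOT export is stable, with dashed edges into conflicted children", {
  p <- example_projects()$conflict
  dot <- export_graph_dot(p$param_graph)
  expect_identical(dot, export_graph_dot(p$param_graph)) # byte-stable
  expect_identical(lengths(regmatches(dot, gregexpr("style=dashed", dot))), 2L)
  expect_identical(lengths(regmatches(dot, gregexpr(" -> ", dot))), 2L)

  fixed <- p
  fixed$param_graph <- resolve_conflict(p$param_graph, "M", "k1", "from_base")
  expect_false(grepl("dashed", export_graph_dot(fixed$param_graph)))

  single <- create_root(config_graph(list(k = 1)), "only")
  dot1 <- export_graph_dot(single)
  expect_false(grepl("->", dot1))
  expect_match(dot1, "\"only\"")
})

test_that("check_consistency mirrors the three issue kinds", {
  expect_identical(nrow(check_consistency(example_projects()$media)), 0L)
  rep1 <- check_consistency(example_projects()$conflict)
  expect_identical(rep1$type, "conflict")
  expect_identical(rep1$node, "M")
  expect_identical(rep1$key, "k1")
})

test_that("render_plots writes the requested columns only", {
  p <- example_projects()$media
  p$plot_graph <- create_root(p$plot_graph, "Aonly")
  p$plot_graph <- set_local(p$plot_graph, "Aonly", "y",
                            list(list(id = "M", color = "blue")))
  res <- run_ensemble(p, "WT_glucose")
  dir <- file.path(tempdir(), "plots1")
  manifest <- render_plots(p, res, dir)
  expect_identical(nrow(manifest), 1L)
  got <- utils::read.csv(file.path(dir, manifest$file))
  expect_identical(names(got), c("time", "M"))

  # a spec naming an absent species drops that series
  p$plot_graph <- set_local(p$plot_graph, "Aonly", "y",
                            list(list(id = "M"), list(id = "Cdh1")))
  manifest2 <- render_plots(p, res, dir)
  got2 <- utils::read.csv(file.path(dir, manifest2$file))
  expect_identical(names(got2), c("time", "M"))

  # phase-plane: one variable against another
  p2 <- example_projects()$media
  p2$plot_graph <- create_root(p2$plot_graph, "phase")
  p2$plot_graph <- set_local(p2$plot_graph, "phase", "x", "mdt")
  p2$plot_graph <- set_local(p2$plot_graph, "phase", "y",
                             list(list(id = "M")))
  manifest3 <- render_plots(p2, res, file.path(tempdir(), "plots2"))
  got3 <- utils::read.csv(file.path(tempdir(), "plots2", manifest3$file))
  expect_identical(names(got3), c("mdt", "M"))
})
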