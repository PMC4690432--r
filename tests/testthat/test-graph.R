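# The inheritance engine: construction, resolution, conflicts, deletion.

two_key_graph <- function() {
  config_graph(list(k1 = 1, k2 = 10))
}

test_that("roots resolve everything from the base set; names are unique", {
  g <- create_root(two_key_graph(), "WT_glucose")
  expect_length(g$nodes, 1L)
  r <- resolve_value(g, "WT_glucose", "k1")
  expect_identical(r$provenance, "BASE")
  expect_equal(r$value, 1)
  expect_error(create_root(g, "WT_glucose"), class = "mg_duplicate_name")
})

test_that("the two-node medium shift reproduces the worked example", {
  p <- example_projects()$media
  gal <- resolve_value(p$param_graph, "WT_galactose", "mdt")
  glu <- resolve_value(p$param_graph, "WT_glucose", "mdt")
  expect_equal(gal$value, 150)
  expect_identical(gal$provenance, "LOCAL")
  expect_equal(glu$value, 80)
  expect_identical(glu$provenance, "BASE")
  # every other key inherits transparently
  all_gal <- resolve_all(p$param_graph, "WT_galactose")
  other <- setdiff(names(all_gal), "mdt")
  expect_true(all(vapply(all_gal[other], `[[`, "", "provenance") == "BASE"))
})

test_that("children take the union of their parents' changes", {
  g <- two_key_graph()
  g <- create_root(g, "WT1")
  g <- create_root(g, "WT2")
  g <- set_local(g, "WT1", "k2", 99)
  g <- create_child(g, "child", c("WT1", "WT2"))
  r <- resolve_value(g, "child", "k2")
  expect_equal(r$value, 99)
  expect_identical(r$provenance, "INHERITED")
  expect_identical(r$source, "WT1")
  # the untouched key falls through to base
  expect_identical(resolve_value(g, "child", "k1")$provenance, "BASE")
})

test_that("single-parent children are transparent", {
  g <- create_root(two_key_graph(), "P")
  g <- set_local(g, "P", "k1", 5)
  g <- create_child(g, "C", "P")
  rp <- resolve_all(g, "P")
  rc <- resolve_all(g, "C")
  for (k in names(rp)) {
    expect_equal(rc[[k]]$value, rp[[k]]$value)
    if (rp[[k]]$provenance == "LOCAL") {
      expect_identical(rc[[k]]$provenance, "INHERITED")
      expect_identical(rc[[k]]$source, "P")
    } else {
      expect_identical(rc[[k]]$provenance, rp[[k]]$provenance)
    }
  }
})

test_that("expression chains propagate ancestor edits", {
  g <- create_root(config_graph(list(k = 1)), "root")
  g <- create_child(g, "child", "root")
  g <- set_local(g, "child", "k", "2*k") # bare ref: scale the inherited value
  g <- create_child(g, "grandchild", "child")
  r <- resolve_value(g, "grandchild", "k")
  expect_equal(r$value, 2)
  expect_identical(r$provenance, "INHERITED")
  expect_identical(r$source, "child")
  # edit the root; the change flows through the expression
  g <- set_local(g, "root", "k", 10)
  expect_equal(resolve_value(g, "grandchild", "k")$value, 20)
})

test_that("set_local validates keys and ancestor references", {
  g <- create_root(two_key_graph(), "A")
  g <- create_root(g, "B")
  g <- create_child(g, "C", "A")
  expect_error(set_local(g, "C", "nope", 1), class = "mg_unknown_key")
  expect_error(set_local(g, "C", "k1", "k1@B"),
               class = "mg_non_ancestor_reference")
  expect_error(set_local(g, "A", "k1", "k1@A"),
               class = "mg_non_ancestor_reference") # self is not an ancestor
  g <- set_local(g, "C", "k1", "k1@A + k1@BASE") # ancestors and BASE are fine
  expect_equal(resolve_value(g, "C", "k1")$value, 2)
})

test_that("set_local/clear_local are inverse", {
  g <- create_root(two_key_graph(), "R")
  before <- resolve_all(g, "R")
  g2 <- clear_local(set_local(g, "R", "k1", 42), "R", "k1")
  after <- resolve_all(g2, "R")
  expect_equal(after, before)
  expect_error(clear_local(g, "R", "k1"), class = "mg_no_local_assignment")
})

test_that("conflicts: detection, candidates, and all three resolutions", {
  p <- example_projects()$conflict
  g <- p$param_graph
  conflicts <- detect_conflicts(g, "M")
  expect_length(conflicts, 1L)
  expect_identical(conflicts[[1]]$key, "k1")
  expect_equal(conflicts[[1]]$candidates, c(WT1 = 2, WT2 = 4))
  expect_identical(node_status(g, "M"), "CONFLICTED")
  err <- tryCatch(resolve_value(g, "M", "k1"), mg_conflict_error = function(c) c)
  expect_s3_class(err, "mg_conflict_error")
  expect_setequal(names(err$candidates), c("WT1", "WT2"))

  g_a <- resolve_conflict(g, "M", "k1", "from_parent", parent = "WT1")
  expect_equal(resolve_value(g_a, "M", "k1")$value, 2)
  expect_identical(node_status(g_a, "M"), "OK")

  g_b <- resolve_conflict(g, "M", "k1", "from_base")
  expect_equal(resolve_value(g_b, "M", "k1")$value, 1)

  g_c <- resolve_conflict(g, "M", "k1", "expression", expr = "k1@WT1 + k1@WT2")
  expect_equal(resolve_value(g_c, "M", "k1")$value, 6.0)

  # clearing the resolving assignment re-raises the conflict
  g_back <- clear_local(g_c, "M", "k1")
  expect_length(detect_conflicts(g_back, "M"), 1L)

  expect_error(resolve_conflict(g, "M", "k1", "from_parent", parent = "nope"),
               class = "mg_unknown_parent")
  expect_error(resolve_conflict(g_a, "M", "k1", "from_base"),
               class = "mg_no_such_conflict")
})

test_that("equal effective values do not conflict (diamond inheritance)", {
  g <- create_root(two_key_graph(), "G")
  g <- set_local(g, "G", "k1", 7)
  g <- create_child(g, "P1", "G")
  g <- create_child(g, "P2", "G")
  g <- create_child(g, "D", c("P1", "P2"))
  expect_length(detect_conflicts(g, "D"), 0L)
  r <- resolve_value(g, "D", "k1")
  expect_equal(r$value, 7)
  expect_identical(r$source, "G")

  # two different ancestors assigning the same number: also no conflict
  g2 <- create_root(two_key_graph(), "A")
  g2 <- create_root(g2, "B")
  g2 <- set_local(g2, "A", "k1", 2)
  g2 <- set_local(g2, "B", "k1", 2)
  g2 <- create_child(g2, "C", c("A", "B"))
  expect_length(detect_conflicts(g2, "C"), 0L)
})

test_that("resolve_all on a conflicted node names every conflicted key", {
  g <- two_key_graph()
  g <- create_root(g, "A")
  g <- create_root(g, "B")
  for (k in c("k1", "k2")) {
    g <- set_local(g, "A", k, 1)
    g <- set_local(g, "B", k, 2)
  }
  g <- create_child(g, "C", c("A", "B"))
  err <- tryCatch(resolve_all(g, "C"), mg_conflict_error = function(c) c)
  expect_setequal(err$key, c("k1", "k2"))
})

test_that("cycles are rejected at construction", {
  g <- create_root(two_key_graph(), "A")
  g <- create_child(g, "B", "A")
  expect_error(create_child(g, "C", c("B", "C")), class = "mg_unknown_parent")
  # direct self/descendant cycles cannot be built through the API; the
  # internal checker still guards hand-assembled graphs
  g$nodes[["A"]]$parents <- "B"
  expect_true(mutantgraph:::graph_has_cycle(g))
})

test_that("deletion: impact report, re-resolution, and inconsistency", {
  # scenario 1: child merely inherits -> re-resolves from base after deletion
  g <- create_root(two_key_graph(), "P")
  g <- set_local(g, "P", "k1", 5)
  g <- create_child(g, "C", "P")
  rep0 <- delete_node(g, "P") # report only
  expect_identical(rep0$affected_descendants, "C")
  expect_identical(nrow(rep0$newly_inconsistent), 0L)
  expect_length(rep0$graph$nodes, 2L) # nothing deleted without force

  res <- delete_node(g, "P", force = TRUE)
  expect_false("P" %in% graph_nodes(res$graph))
  r <- resolve_value(res$graph, "C", "k1")
  expect_identical(r$provenance, "BASE")
  expect_identical(node_status(res$graph, "C"), "OK")

  # scenario 2: child's expression references the deleted parent
  g2 <- create_root(two_key_graph(), "P")
  g2 <- set_local(g2, "P", "k1", 5)
  g2 <- create_child(g2, "C", "P")
  g2 <- set_local(g2, "C", "k1", "2*k1@P")
  rep2 <- delete_node(g2, "P")
  expect_identical(rep2$newly_inconsistent$node, "C")
  expect_identical(rep2$newly_inconsistent$key, "k1")
  res2 <- delete_node(g2, "P", force = TRUE)
  expect_identical(node_status(res2$graph, "C"), "INCONSISTENT")
  expect_error(resolve_value(res2$graph, "C", "k1"),
               class = "mg_dangling_reference")

  # deleting a leaf leaves everyone else untouched
  g3 <- create_child(g, "leaf", "C")
  before <- lapply(c("P", "C"), function(n) resolve_all(g3, n))
  res3 <- delete_node(g3, "leaf", force = TRUE)
  after <- lapply(c("P", "C"), function(n) resolve_all(res3$graph, n))
  expect_equal(after, before)

  expect_error(delete_node(g, "nope"), class = "mg_unknown_node")
})

test_that("locality: a local edit only changes the node and its descendants", {
  p <- random_project(n_nodes = 8, n_keys = 4, seed = 77)
  g <- p$param_graph
  target <- graph_nodes(g)[3]
  snapshot <- function(gr) {
    lapply(graph_nodes(gr), function(n)
      lapply(gr$keys, function(k) engine_resolve(gr, n, k)))
  }
  before <- snapshot(g)
  g2 <- set_local(g, target, g$keys[1], 1234.5)
  after <- snapshot(g2)
  cone <- c(target, mutantgraph:::node_descendants(g, target))
  for (i in seq_along(graph_nodes(g))) {
    nd <- graph_nodes(g)[i]
    if (!nd %in% cone)
      expect_equal(after[[i]], before[[i]], label = nd)
  }
  expect_false(identical(after[[3]], before[[3]]))
})

test_that("resolution is independent of insertion and parent order", {
  build <- function(order_flip) {
    g <- config_graph(list(k = 1, j = 2))
    if (order_flip) {
      g <- create_root(g, "B")
      g <- create_root(g, "A")
    } else {
      g <- create_root(g, "A")
      g <- create_root(g, "B")
    }
    g <- set_local(g, "A", "k", 3)
    g <- create_child(g, "C", if (order_flip) c("B", "A") else c("A", "B"))
    g
  }
  r1 <- resolve_all(build(FALSE), "C")
  r2 <- resolve_all(build(TRUE), "C")
  expect_equal(r1, r2)
})

test_that("random operation scripts keep the graph acyclic and consistent", {
  set.seed(1312)
  for (rep in seq_len(20)) {
    g <- config_graph(list(k1 = 1, k2 = 2))
    for (step in seq_len(25)) {
      nodes <- graph_nodes(g)
      op <- sample(c("root", "child", "set", "clear", "delete"), 1L)
      nm <- paste0("n", rep, "_", step)
      try_op <- function(expr) tryCatch(expr, mg_error = function(c) g)
      g <- switch(op,
        root = try_op(create_root(g, nm)),
        child = if (length(nodes) == 0L) g else
          try_op(create_child(g, nm, sample(nodes, min(2L, length(nodes))))),
        set = if (length(nodes) == 0L) g else
          try_op(set_local(g, sample(nodes, 1L), sample(g$keys, 1L),
                           round(stats::runif(1), 3))),
        clear = if (length(nodes) == 0L) g else
          try_op(clear_local(g, sample(nodes, 1L), sample(g$keys, 1L))),
        delete = if (length(nodes) == 0L) g else
          try_op(delete_node(g, sample(nodes, 1L), force = TRUE)$graph))
      expect_false(mutantgraph:::graph_has_cycle(g))
    }
  }
})

test_that("conflict detection is sound and complete against resolution", {
  set.seed(2024)
  for (seed in 1:30) {
    g <- random_project(n_nodes = 6, n_keys = 3, p_local = 0.6,
                        seed = 3000 + seed)$param_graph
    for (nd in graph_nodes(g)) {
      has_conflict_at_node <- length(detect_conflicts(g, nd)) > 0L
      raises <- any(vapply(g$keys, function(k) {
        err <- tryCatch({
          resolve_value(g, nd, k)
          NULL
        }, mg_conflict_error = function(c) c)
        !is.null(err) && identical(err$node, nd)
      }, TRUE))
      expect_identical(has_conflict_at_node, raises,
                       label = sprintf("seed %d node %s", seed, nd))
    }
  }
})
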