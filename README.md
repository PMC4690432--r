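# mutantgraph

Hierarchical management, simulation and export of many parameterizations
("mutants") of a single SBML biochemical reaction model.

## The problem

A published reaction-network model usually ships with one list of parameter
values — the wild type. Real modeling projects need dozens to hundreds of
variants: gene knockouts, overexpressions, growth in different media, double
and triple mutants. Maintaining each variant as a separate SBML file is
error-prone: the variants differ from the base model in only a handful of
values, yet every correction has to be copied by hand into every file.

`mutantgraph` stores the variants as a **directed acyclic graph of
configurations** over one base model. Each node records only its *local
changes*; everything else is inherited:

* a node's value for key *k* is its **local assignment** if it has one —
  a number or an algebraic expression `2*k1@parent + 4*k2@grandparent`
  referencing ancestor nodes (`k@BASE` addresses the base model, a bare `k`
  the value the node would inherit);
* otherwise the **union of its parents' effective changes** — a double
  mutant *A;B* is simply a child of the two single-mutant nodes;
* otherwise the **base set**, the value in the imported SBML model.

If several parents deliver *different* effective values for the same key the
node is **conflicted**: simulation and export are blocked until the user
resolves the conflict by (a) picking one parent's value, (b) reverting to the
base set, or (c) typing an expression. Deleting a node that others reference
marks them **inconsistent** (also blocking), while plain inheritors silently
re-resolve through remaining ancestors or the base set.

Two further graphs with the same inheritance semantics configure
**time-course settings** (duration, interval size, solver tolerances) and
**plot settings**, each node declaring which mutants it applies to. Any
consistent configuration can be simulated (adaptive Rosenbrock 2(3) stiff
integrator over `dx/dt = S·v(x,p,t)`), exported as a flattened SBML Level 3
Version 1 file, rendered to Graphviz DOT, or written as CSV time series.
Whole projects persist to a documented JSON format.

## Worked example

The canonical two-node hierarchy — a wild type in glucose and the same strain
in galactose, which differs only in the mass doubling time `mdt` (150 instead
of the base 80):

```r
library(mutantgraph)

p <- new_project(example_model("growth"))          # base model: mdt = 80
p$param_graph <- create_root(p$param_graph, "WT_glucose")
p$param_graph <- create_child(p$param_graph, "WT_galactose", "WT_glucose")
p$param_graph <- set_local(p$param_graph, "WT_galactose", "mdt", 150)

str(resolve_value(p$param_graph, "WT_galactose", "mdt"))
#> List of 3
#>  $ value     : num 150
#>  $ provenance: chr "LOCAL"
#>  $ source    : chr NA
resolve_value(p$param_graph, "WT_glucose", "mdt")$value   # 80, provenance BASE
```

A two-parent conflict and its resolution by expression:

```r
cf <- example_projects()$conflict    # WT1 sets k1=2, WT2 sets k1=4, M is child of both
detect_conflicts(cf$param_graph, "M")
#> [[1]]$key        : "k1"
#> [[1]]$candidates :  WT1 WT2
#>                       2   4
g <- resolve_conflict(cf$param_graph, "M", "k1", "expression",
                      expr = "k1@WT1 + k1@WT2")
resolve_value(g, "M", "k1")$value
#> [1] 6
```

While `M` is conflicted, `export_node_sbml()` and `run_ensemble()` raise
blocking errors, and `export_graph_dot()` draws its in-edges dashed:

```
"M" -> "WT1" [style=dashed];
"M" -> "WT2" [style=dashed];
```

Hierarchical simulation settings map onto mutants via `applies_to`; runs are
the cross product of the selected mutants and their applicable settings:

```r
tc <- example_projects()$timecourse  # "short" (duration 500) applies to both
                                     # mutants, "long" (1000) only to galactose
res <- run_ensemble(tc, c("WT_glucose", "WT_galactose"))
names(res)
#> [1] "WT_glucose::short"   "WT_galactose::short" "WT_galactose::long"
res[["WT_galactose::long"]]$series
#> <mg_timeseries> 1001 time points x 3 variable(s): M, mdt, cell
```

## Command line

Every operation is scriptable through `mg_cli()` / the installed front-end
(`system.file("cli", "mutantgraph.R", package = "mutantgraph")`):

```sh
Rscript $CLI init --sbml model.xml --project p.json
Rscript $CLI node add WT_glucose --project p.json
Rscript $CLI node add WT_galactose --parents WT_glucose --project p.json
Rscript $CLI node set WT_galactose mdt 150 --project p.json
Rscript $CLI run --select WT_galactose --outdir out --project p.json
Rscript $CLI export sbml --outdir sbml --project p.json
```

Exit codes: 0 ok, 1 user error, 2 blocked by a conflict/inconsistency
(the project is still saved so no work is lost), 3 internal error. Add
`--json` for machine-readable output.

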