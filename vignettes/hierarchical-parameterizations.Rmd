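---
title: "Hierarchical parameterizations of biochemical models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical parameterizations of biochemical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutantgraph)
```

## The model of the method

`mutantgraph` manages an ensemble of parameterizations of one SBML reaction
network. The *base set* `B : K -> R` maps every assignable key — global
quantities, non-boundary species initial amounts, compartment sizes — to its
value in the imported model. A *configuration graph* is a DAG of named nodes;
each node `n` carries an ordered parent list and a partial map of *local
assignments* `L_n : K -> Expr`. Resolution of `(n, k)` is defined
recursively:

1. **Local.** If `k ∈ dom(L_n)`, the value is `eval(L_n[k])`. References
   inside the expression resolve as: `k'@A` = the resolution of `(A, k')`
   (A must be a strict ancestor of `n`); `k'@BASE` = `B(k')`; a bare `k'` =
   the value `n` *would inherit* for `k'`, computed by rule 2 while ignoring
   all of `n`'s own locals (so `k = 2*k` safely means "double the inherited
   value"). Provenance: `LOCAL`.
2. **Inherited.** Otherwise collect, for each parent `p`, the *delivery*
   `(v_p, src_p)` where `v_p` is `p`'s resolved value and `src_p` the node
   holding the governing local assignment (`p` itself if local there, the
   recorded source if inherited, none if base). Deliveries with a source are
   *changes*. If all deliveries are base, the value is `B(k)` with provenance
   `BASE`. If the changes agree (see tolerance below) the value is inherited
   with provenance `INHERITED(src)`; a double mutant is thus literally the
   union of its parents' changes. If they disagree the node is **conflicted**
   on `k` and resolution raises an error — a conflict is never silently
   tie-broken, not even by parent order.

Because only deviations from ancestors are stored, editing one value at any
node propagates to every descendant that has not overridden it, including
through algebraic expressions.

### Conflicts

Two changes *conflict* when their values differ by more than
`max(1e-15, 1e-12 * max(|a|, |b|))` — i.e. comparison is by *effective
numeric value*, not by expression text, so diamond inheritance (both parents
forwarding the same grandparent's assignment) and coincidentally equal
assignments are safe. The flip side, documented as a divergence risk: two
textually different expressions that happen to be numerically equal under the
current base set do not conflict *now*; the comparison is re-run on every
resolution, so a later base-set edit can surface the conflict.

A subtlety: a *bare* reference inside a local expression reads the inherited
value of its key even when the node assigns that key locally. A conflict
among the parents on that key therefore blocks resolution although the node
"has a local value". `detect_conflicts()` probes the bare-referenced keys of
local expressions as well, so its report is sound and complete with respect
to resolution: it is non-empty exactly when some resolution at the node
raises a conflict sited there.

Resolution strategies install an ordinary local assignment: `from_parent(p)`
stores `k@p`, `from_base` stores `k@BASE`, `expression` stores the given
expression. This makes resolutions first-class, inheritable, and undoable
(`clear_local()` re-raises the conflict).

### Deletion and inconsistency

Deleting a node detaches its children (they re-resolve through remaining
parents or the base set) but cannot rewrite expressions: any node whose local
expression references the deleted name becomes `INCONSISTENT`, and resolving
it raises a dangling-reference error. `delete_node(force = FALSE)` returns
the impact report without deleting, mirroring an interactive warning dialog.
Inconsistent and conflicted graphs remain fully saveable — only simulation
and export are gated — so no work is lost.

Node status is computed, never stored: `INCONSISTENT` if a local expression
references a missing node or key, else `CONFLICTED` if `detect_conflicts()`
is non-empty, else `OK`.

## Settings hierarchies

Time-course and plot settings reuse the same engine over their own key
spaces. Numeric fields (`duration`, `interval_size`, `output_start`,
`rel_tol`, `abs_tol`) admit the expression language (`2*duration@short`);
enum/string/list fields (`method`, plot axes and series) are "opaque":
inherited whole, compared by identity, never inside expressions — an
expression over an enum is meaningless. Each settings node carries a
non-inherited `applies_to` list naming the parameter nodes it pertains to
(empty = all); with no settings node at all, one built-in default applies to
everything. When several settings apply to one mutant, the run set is the
full cross product — each applicable spec runs.

Defaults (chosen once; the method's own documented defaults): duration 100
model-time units, interval 1, output start 0, `rel_tol = 1e-8`,
`abs_tol = 1e-12`, method `DETERMINISTIC_STIFF`.

## Simulation

A flattened model compiles to `dx/dt = S·v(x, p, t)`: `S` the species ×
reactions stoichiometry matrix (boundary species are constant inputs, not
state), `v` the kinetic-law rates. Rate rules append state equations and
override reaction contributions for their targets; assignment rules are
evaluated before the rates at each derivative call. Species values are
treated as **amounts** throughout (identifiers in rate laws included), which
coincides with exact SBML concentration semantics whenever compartment sizes
are 1 — true for every shipped fixture; models exercising non-unit
compartments with concentration-based laws are outside the supported
interpretation and should be pre-converted.

The integrator is an adaptive Rosenbrock 2(3) pair (the classic `ode23s`
scheme): L-stable, one numerically differenced Jacobian per step, embedded
third-order error estimate with the step controller
`h <- h * min(5, max(0.2, 0.8 * err^(-1/3)))`. One stiff-capable method
backs the single `DETERMINISTIC_STIFF` setting; a menu of integrators is a
non-goal. Output lands exactly on the uniform grid
`output_start + i * interval_size` by clamping steps to grid points — no
interpolation error enters reported values. Step-size collapse, non-finite
derivatives and step-budget exhaustion raise an integration failure; in
ensemble runs such failures are recorded per (mutant × settings) pair without
aborting the batch, whereas conflicted/inconsistent *selections* are rejected
up front.

With the default tolerances the linear-decay fixture tracks its closed form
to < 1e-6 absolute and closed networks conserve mass to < 1e-8 relative —
both asserted by the test suite, not just claimed here.

## SBML subset and persistence

The reader accepts Level 2 and Level 3 Version 1: compartments, species,
global parameters, reactions with kinetic laws, rate and assignment rules,
and the MathML subset (+, −, ×, ÷, power, exp, ln, unary minus, numbers,
time). Events, delays, algebraic rules, function definitions, initial
assignments, constraints and local reaction parameters raise explicit
unsupported-feature errors — a refused load is better than a silently wrong
simulation. Declared `initialConcentration`s are converted to amounts via
compartment size at load, establishing one internal convention. Identifiers
live in one flat namespace; collisions across categories are load errors.
Written files are always L3V1, and `load_sbml(write_sbml(m))` reproduces `m`
field-wise. No offline third-party SBML validator exists in this toolchain,
so "valid output" is enforced by the strict re-loader plus structural
invariants (`validate_sbml_model()`).

Projects persist as JSON (`format_version` "1.0"): the SBML document embedded
as a string plus the three graphs, each node serialized as
`{name, parents, locals, color, applies_to}` with numeric locals as canonical
expression strings (minimal parentheses, `%.17g` numbers — lossless double
round trip) and opaque locals as tagged raw JSON. The opaque `.msmb` format
of the original GUI tool is *not* read; a transparent schema is the portable
equivalent. Load tolerates dangling node references inside expressions
(that's an inconsistency to report, not a schema error) but rejects unknown
keys, cyclic parent relations and malformed expressions with a JSON-pointer
location. SBML itself cannot carry the hierarchy, so per-node exports write
the applicable settings to a `*.settings.json` sidecar.

## Expression language

```
expr  := term (('+'|'-') term)*
term  := unary (('*'|'/') unary)*
unary := '-' unary | power
power := base ('^' unary)?        (right-associative)
base  := NUMBER | IDENT ('@' IDENT)? | '(' expr ')'
```

Precedence `^ > unary − > * / > + −`; everything left-associative except
`^`. (`-x^2` is `-(x^2)`, the standard convention.) References name explicit
nodes; relative keywords like `@parent` that would re-bind on graph edits are
deliberately not keywords — explicit names survive re-wiring, and referencing
a non-ancestor is rejected at assignment time. Functions, conditionals and
string values are excluded from the assignment language. Division by zero
and non-finite results raise arithmetic errors. Reference cycles cannot
arise through the validated API (references point strictly upward, and bare
references ignore the node's own locals); a resolution-time cycle guard
still protects hand-edited project files.

## Synthetic data

No external model download is required anywhere. `example_model()` provides
a one-species decay model (closed-form oracle), a reversible conversion
(conservation oracle), a three-species negative-feedback mass-action loop,
and a growth model whose only quantity is a mass doubling time `mdt` with
base value 80 — the smallest models that exercise each tested behavior.
`example_projects()` rebuilds the three canonical worked examples (medium
shift 80→150; short/long settings 500/1000 with their applicability; the
k1 = 2 vs 4 two-parent conflict). `random_project(seed)` generates seeded
random DAG hierarchies with random numeric and expression locals, emulating
the *shape* of real mutant collections (sparse local changes, occasional
multi-parent nodes, ancestor-referencing expressions). What it does not
emulate: biologically meaningful kinetics or realistic parameter
correlations — a green property suite establishes the correctness of the
bookkeeping (inheritance, conflicts, persistence), not biological validity
of any particular model. The 131-node scale test mirrors the size of a real
published mutant ensemble but with synthetic wiring.

The brute-force `oracle_resolve()` recomputes resolution from the definition
— no memoization, no shared code with the engine — and is intentionally
exponential in path count; oracle comparisons therefore cap graphs at 8
nodes, with larger graphs used only for performance smoke tests.

## Design choices where the design was open

* **Amounts, not concentrations**, as the single species convention
  (documented above).
* **Expression-equal vs value-equal conflicts**: value comparison, re-checked
  at every resolution (rationale and risk above).
* **Memoization scope**: per resolution pass, keyed on (node, key), failures
  cached alongside values. Graphs are immutable R values, so there is no
  cross-edit cache to invalidate; within one pass deep multi-parent
  hierarchies resolve in linear rather than exponential time, which is what
  the 131-node budget needs.
* **Base-set edits** (re-importing a changed model): new keys resolve as
  `BASE` everywhere; removed keys leave locally-assigning nodes
  `INCONSISTENT` — mirroring the deletion semantics.
* **Deleting a parameter from a node** is unsupported by design: knockouts
  are `value = 0`, preserving the model structure and every descendant.
* **Enum fields inherit but never appear in expressions.**
* **Plot applicability** uses the same `applies_to` mechanism as time-course
  nodes (symmetry is the simplest reading of per-mutant plot needs).

## Known limitations

* SBML packages (comp, fbc), unit checking and annotation preservation are
  out of scope; annotations are not carried through a round trip.
* The simulator excludes events, delays and algebraic rules; there is no
  stochastic engine, steady-state analysis or parameter estimation.
* One integrator only; its accuracy is order 2(3) — tight tolerances cost
  steps on long non-stiff runs where a higher-order explicit method would be
  cheaper.
* `applies_to` matching is by exact node name; renaming a parameter node does
  not rewrite settings lists (the dangling name is reported by
  `check_consistency()`).
* Graph drawing is delegated to Graphviz via DOT export; no layout
  aesthetics are computed in-package.
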