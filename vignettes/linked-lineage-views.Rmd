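---
title: "Linked views of cell lineages: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked views of cell lineages: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagelink)
```

## The problem

Modern lineage-tracing experiments produce two complementary descriptions
of a developing tissue: a *genealogy* (which cell divided into which, and
when) and a *geometry* (where each final cell sits in space, what type it
has become, what it expresses). Each is only half the story. The questions
biologists actually ask — do the descendants of this early blastomere stay
together in space? which clones contribute to this organ? is this marker
clonally restricted? — live at the join between the two. `lineagelink`
treats that join as the central object: a lineage tree and a cell table
linked by shared cell labels, with every downstream computation (clones,
cuts, relationship levels, colour overlays) defined on the joined data.

## The data model

A `lineage_tree` is a rooted tree of uniquely labelled nodes. Leaves are
the cells of the final time point; internal nodes are ancestral cells that
divided. Uniqueness of labels across the whole tree is a hard requirement,
not a convenience: labels are the join key between the lineage side and
the spatial side, so a duplicate label would make the linked views
ambiguous. For the same reason unlabelled internal nodes in an input file
are auto-named deterministically (`_n1`, `_n2`, ... breadth-first from the
root) rather than left blank.

Branch lengths, when present, carry division timing in one of two
conventions found in published lineage files:

* **relative** — each node's length is the interval between its parent's
  division and its own division (or its terminal observation);
* **absolute** — each node's length is its cumulative distance from the
  root, which must be non-decreasing towards the leaves (violations are a
  parse error, since they would imply time running backwards).

`node_times()` reduces both to one quantity, time-from-root, and
`convert_bl_mode()` maps between them; node times are the invariant (the
conversions are exact inverses to within 1e-9, property-tested). When a
file contains lengths but the user requests none, the lengths are dropped
with an explicit warning rather than silently, because the choice changes
which operations (time cuts, branch-length layout) are available.

### Accepted formats

Newick is parsed with a hand-written reader implementing the dialect this
package commits to: single-quoted labels with `''` escapes, square-bracket
comments stripped, whitespace ignored outside quotes, underscores kept
verbatim. The JSON schema is the common hierarchical form — one object per
node with `"name"`, optional `"children"`, optional `"length"` — chosen to
match widely circulated lineage JSON files; unknown keys are ignored with
a warning so that decorated files still load. Both writers are lossless:
numbers are printed with the fewest digits that re-parse to the identical
double, so write→parse is the exact identity and not merely approximate.
The test suite additionally cross-checks the Newick reader against `ape`'s
parser on a generated corpus (topology, labels and edge lengths).

## Clones, cuts and relationship levels

The **clone** of a node is the leaf set of its subtree; a leaf is its own
clone of size one. This convention makes hover counts equal clone sizes
(`descendant_summary()` reports a leaf as 1/1 when positioned).

**Depth cuts.** Depth counts edges from the root, so "after *k*
divisions" means depth exactly *k*; `k = 0` returns the single root clone.
Cells that stopped dividing before depth *k* persist as singleton
founders, which keeps every cut a partition of the full cell set.

**Time cuts.** For trees with branch lengths, an edge (*p* → *c*) is alive
at time *t* iff time(*p*) < *t* ≤ time(*c*), and each alive edge founds
the clone of its child. Two boundary conventions complete the rule, both
chosen so that cuts remain partitions at every *t*:

* leaves whose time is before *t* persist as singleton clones — the 3D
  side shows the final time point, so a cell that stopped dividing early
  must still belong to some clone late in development;
* at *t* ≤ time(root) the root founds the single all-cells clone. This is
  the package's resolution of an edge case the half-open edge rule leaves
  open when the founder divides exactly at time 0: the cut at *t* = 0 is
  the root clone, and any *t* > 0 already separates the daughters.

The simulator's division log provides an independent check: the number of
groups at *t* equals one plus the extra lineages created by divisions
before *t*, and the suite verifies this equality across 50 seeded runs at
20 random time points each.

**Relationship levels.** The "degree of lineage relationship" of cell *x*
to a focal cell *f* is formalized as depth(MRCA(*f*, *x*)). This is a
deliberate design choice, not the only possible one (path-length distance
would be an alternative); it is used because it makes the *nested clone*
property exact: the set of cells with level ≥ *L* is precisely the clone
of *f*'s ancestor at depth *L*, so a sequential colour scale over levels
paints the nested clones *f* belongs to. The suite tests that law
verbatim on random trees.

## Display reductions

`collapse`, `expand` and `prune` are overlays (`view_state`) on an
immutable tree: collapse folds a subtree into one marker carrying its
clone size, prune removes it from the displayed tree entirely. Keeping
them out of the tree object means saved selections and partitions always
refer to the full dataset, and `expand ∘ collapse` is the identity by
construction. A node may not be simultaneously collapsed and pruned; each
operation removes the node from the other set rather than erroring,
because in interactive use the later gesture expresses the current
intent.

`subset_branches()` implements the legibility reduction for very large
unresolved trees: it activates automatically above 500 cells (the
threshold the package exposes as `max_cells`), and only for trees with
polytomies, since a fully resolved binary tree has no redundant branch
fan to thin. The reduction retains, at each polytomy, the first children
in label-sorted order — never fewer than two — shrinking the largest
polytomies first until the display fits the cap. Label-sorting makes the
choice deterministic without a seed; the hidden-branch counts per
polytomy are reported so the reduction is always visible to the user.
Where the cap cannot be met (every polytomy already at its two-child
floor), the function stops at the floor rather than degenerating the
topology; the cap is therefore a contract of the form "≤ max(max_cells,
structural floor)".

## The spatial side

Coordinate files are `cell,X,Y,Z` CSVs (header matched case-insensitively
after trimming); annotations are `cell,annotation`; expression is cells ×
genes with `cell` as the first column. The expression orientation and the
annotation header are package conventions, declared here because lineage
side-files in the wild vary. Saved selections are written in the
annotation dialect precisely so that a saved clone selection can be
reloaded later as an annotation file — the save/reload contract has a
dedicated round-trip test.

`join_cells()` never requires full coverage: positions mapped for only a
subset of the lineage (a common situation when coordinates come from a
different study than the tree) produce a warning with counts, not an
error, and the `matched`/`tree_only`/`coords_only` bookkeeping satisfies
|matched| + |tree_only| = leaf count and |matched| + |coords_only| = rows.
Only an empty intersection is an error, since no linked view exists.

Tracking XML (MaMuT/TrackMate family) is imported by collapsing chains of
single-successor spots into single tree edges whose length is the frame
span; spots with two or more successors become division nodes and
terminal spots become leaves, labelled by the spot `name` when present
and by the numeric id otherwise (names are preferred because they are
what users see in the tracking tool). Coordinates are taken at each
leaf's final frame, consistent with the final-time-point 3D view. A
multi-root file is rejected with the roots listed: the importer's
contract is one lineage per file.

## Rendering

Static export must be reproducible to be useful in pipelines, so the SVG
writer is a pure function of the `scene`: fixed canvas, fixed precision
(three decimals), label-sorted element order where order is not
structural, no timestamps or generated ids. Identical scenes yield
byte-identical SVG, and the suite hashes five renders to confirm it. The
3D panel is an orthographic projection at configurable azimuth/elevation
— a static file cannot rotate, so interactive rotation is deliberately
confined to the HTML export, which embeds the same SVG plus a small
self-contained script (hover shows cell ID and descendant counts; click
highlights a clone in both panels).

Colour is the linkage: one `colour_map` per scene assigns each cell
exactly one colour, used identically in both panels, with light grey
(`#D3D3D3`) for cells outside every selected group. Categorical overlays
draw from a fixed 12-colour palette and cycle with a warning beyond 12
groups; the expression overlay uses a sequential (viridis-like) ramp with
a legend recording the numeric range, and a constant gene degenerates to
a single colour with a warning rather than an error. Exactly one overlay
is active per scene — layered overlays would make the cell → colour map
ambiguous.

## The synthetic generator

`simulate_lineage()` is a branching process: the founder divides at time
0, every daughter schedules its division after a waiting time, and the
process stops once the target number of lineages is alive, all of which
persist to a common final time. Waiting times are exponential with rate 1
by default — memoryless division is the simplest neutral assumption, and
a `fixed` option exists for analytic cases (synchronous division yields
the complete binary tree, used as a closed-form check). Polytomies are
introduced as occasional triple divisions at `polytomy_rate`. The
division log is retained as ground truth *independent of the tree object*
so that time-cut tests are not circular.

`place_cells()` positions cells by a branching random walk in which each
daughter inherits a heritable drift direction blended with fresh noise
under a `coherence` weight (default 0.9) and a unit `spatial_step` per
division. This emulates the one property of real lineage-coherent tissues
the linked views exercise — descendant cells of one clade cluster in
space, different clades separate — and nothing else: there is no cell
shape, no contact mechanics, no tissue boundary, no migration program. A
seeded statistical test verifies the emulated property itself (mean
intra-clone pairwise distance below inter-clone distance for depth-2
clones in ≥ 18 of 20 seeded runs at 200 cells). Passing tests on these
data therefore demonstrate correctness of the computations and formats,
not fidelity to any particular organism's morphogenesis.

The fixture suite writes four dataset shapes covering the feature
combinations the readers must handle — Newick + relative lengths +
annotations with deliberately partial (64%) coordinate coverage; Newick
without lengths + annotations + expression; JSON and Newick with absolute
lengths; JSON only — each at ~100 cells, small enough to generate at test
time. The partial-join checks additionally use a 558-cell lineage with
357 positioned cells, a realistic shape for a curated lineage joined to
an independently imaged coordinate set.

## Numerical and degenerate-input choices

* Serialized numbers use shortest-lossless formatting (up to 17
  significant digits), so round trips are exact, not tolerance-based.
* Missing root lengths default to 0 in both conventions.
* Missing expression values become 0 with a warning (absence of
  measurement treated as absence of signal, flagged); negative values are
  rejected outright.
* A single-node tree is legal everywhere: it is its own root, leaf and
  clone; its layout centres the one slot.
* Tie-breaks that need an order (subset retention, colour assignment,
  gene autofill, CSV output order) use radix label sort, never RNG.
* Problem sizes in the test suite (corpora of ~1,000 random trees up to
  ~80 leaves, 50 simulator runs, 558-cell join fixtures, one 2,000-leaf
  star tree) were chosen to exercise every code path at desk-fast speed.

## Known limitations

* The 3D view describes the final time point only; time-resolved
  positions from tracking data are collapsed to each leaf's last frame.
* Static SVG/PNG cannot rotate the 3D projection; choose
  azimuth/elevation per scene.
* `subset_branches()` reduces display only at polytomies; a huge fully
  resolved tree is rendered in full (collapse/prune are the manual
  remedies).
* The interactive HTML is intentionally minimal (hover + clone
  highlight); it is an export format, not an application.
* Trees above roughly 10,000 cells will render, but SVG output becomes
  large and slow to open in browsers; the same threshold at which
  interactive tools begin to struggle.
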