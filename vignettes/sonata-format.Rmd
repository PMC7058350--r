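---
title: "The SONATA format in sonatar: data model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SONATA format in sonatar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonatar)
```

## The data model

SONATA splits a network model into what is shared and what is individual.
Attributes shared by many neurons or synapses live in small, hand-editable
**type tables** (space-separated CSV, one row per `node_type_id` /
`edge_type_id`); per-instance attributes live in **HDF5 instance tables**
(one entry per node or edge). A population's instances are partitioned into
**groups**, each a homogeneous collection of attribute columns, which is
what lets a single model mix multi-compartment neurons (rich attribute
sets) with integrate-and-fire point neurons (lean ones) — the hybrid
regime this format was designed around. A node resolves to its full
attribute map by overlaying its group's per-instance values on its type
row; edges resolve the same way and additionally carry their endpoint node
ids and populations.

Around the circuit sit a three-file JSON configuration hierarchy
(primary → circuit + simulation) and activity files: spike trains as
paired `(node_id, timestamp)` datasets, and element reports as a single
N × M matrix whose rows are frames (all values at one timestamp, in ms)
and whose columns are traces (one recorded element each), located by a
mapping (`node_ids`, `index_pointer`, `element_id`, optional
`element_pos`). All elements of a node are contiguous within a frame;
nodes need not appear sorted by id.

## Conventions this package fixes

The format deliberately leaves several choices to implementations; the
ones made here are listed so files and behaviour are predictable.

**Attribute precedence.** When a name exists both in the type row and the
instance group, the instance value wins, uniformly for every attribute.
The format's own text only states that `dynamics_params` files may
initialize or overwrite template values; a single shadowing rule for all
names is the simplest semantics that is consistent with that and easy to
test (resolution is idempotent, and provenance flags partition the
attribute names).

**The null token.** `NONE`, case-sensitive, recognized only in CSV type
tables; it never survives into a resolved attribute map. The reserved
`model_type` value `single compartment` is stored verbatim, embedded space
included, via double-quote quoting in the CSV dialect (space-separated,
`#` has no comment meaning).

**Numeric CSV round-trips.** Doubles are written with 17 significant
digits; integral doubles gain a `.0` suffix so the integer/double
distinction survives a write–read cycle bit-exactly.

**HDF5 layout.** Nodes at `/nodes/<population>/` with datasets `node_id`,
`node_type_id`, `node_group_id`, `node_group_index` and one sub-group per
node group named by its id; edges analogously at `/edges/<population>/`
with the source/target population names stored as a `node_population`
attribute on the endpoint id datasets. `node_id` is always written
explicitly (`0..N-1` by default) but ids need not be contiguous on read.
All ids are 0-based; all intervals half-open. Each group carries a `size`
attribute so empty attribute-less groups round-trip. Spikes live at
`/spikes/<population>/{timestamps, node_ids}` with a `sorting` attribute
(`none` / `by_time` / `by_id`); element reports at
`/report/<name>/{data, mapping/...}` with `time = [tstart, tstop, dt]`.

**Units.** Timestamps, `tstart`, `tstop`, `dt` are milliseconds; spike
rates are Hz. The report's physical variable and units are free-text
attributes on the data matrix (the format prescribes none).

**Frame count.** `N = round((tstop − tstart) / dt)` with a 1e-9 relative
tolerance to absorb floating drift; a genuinely fractional duration falls
back to the completed frame count, and `tstop <= tstart` is an error.

**Chunking.** HDF5 chunking is essential for partial access but the
format does not prescribe shapes. Defaults: 2^16-element chunks for 1-D
instance columns; `(min(N, 1024), min(M, 512))` for report matrices; both
overridable. Tests assert that results are bit-identical across chunk
shapes, so chunking is purely a performance knob.

**Edge orderings.** `target_major` sorts by target id ascending, ties by
source id, then original position (a total order, so sorting is
deterministic); `source_major` is its mirror. The hybrid ordering divides
the connectivity matrix into B × B blocks; edge (s, t) belongs to block
(⌊t/B⌋, ⌊s/B⌋), blocks are traversed row-major, and the within-block
order alternates by block parity (even `i+j` target-major, odd
source-major). The format describes hybrid ordering only as "alternating
from block to block"; the traversal order and parity convention here are
one consistent instantiation — with B greater than every node id the
hybrid order degenerates to target-major, which the tests pin down.

**Range indices.** A per-node list of half-open `[start, end)` ranges
into the edge arrays, per direction, serialized as
`node_id_to_ranges` (row r = node id r) plus a flat `[start, end)` range
list. The index is valid for any edge order (it just fragments); after
the matching sort every node has at most one range. Queries always equal
a linear scan of the id column — the index is an access-path optimization,
never a semantic change.

**Configs.** Manifest variables use shell-style `$NAME` / `${NAME}`
(`[A-Za-z_][A-Za-z0-9_]*`), may reference each other, and are resolved
with cycle detection; values of path-like keys (`*_file`, `*_dir`,
`components`, primary `network`/`simulation`) are made absolute relative
to each file's own directory. Unknown keys are preserved and ignored
(forward compatibility), `run` accepts `tstop` or `duration`, and
simulator/version provenance rides along opaquely. Writing a loaded
bundle re-emits the unresolved file contents, so manifest variables
survive a round trip; relative manifest roots then re-resolve against the
new location by design.

**Validation.** Checks are total and non-throwing: unreadable inputs
become error-severity findings. Error codes cover dangling type ids,
group membership violations, ragged groups, dangling edge endpoints,
non-reserved `model_type` values, broken range indices, spike/report
node ids unknown to the circuit, negative timestamps, corrupt index
pointers, and shape mismatches. Warnings cover accepted oddities (e.g. a
`by_time` tag on unsorted spikes). Findings are ordered by file then
location, so fault-injection tests can assert "exactly one finding with
exactly this code".

## What the synthetic generator emulates — and what it does not

`l4_like_spec(scale)` mirrors the *structure* of a published hybrid
cortical layer-4 model: a biophysically detailed core of 10,000 neurons,
a 35,000 point-neuron annulus against boundary artifacts, and ~10,000
virtual input nodes, scaled with ceiling rounding. Connection
probabilities are constants chosen once from the published edge counts:
~40M recurrent edges over 45,000² ordered pairs gives p = 0.02, and ~8M
feedforward edges over 10,000 × 45,000 pairs gives p = 0.018, so the
generator reproduces the model's edge counts in expectation at full
scale. Core-to-core pairs draw 1–3 synapses; other rules draw one.
Edges onto biophysical targets use the rich group (log-normal
`syn_weight` with median 1e-4, `afferent_section_id` uniform on 0..9,
`afferent_section_pos` uniform on [0, 1)); edges onto point targets store
`syn_weight` only. These distributions are documented placeholders — the
real model's values derive from data that is out of scope — and node
positions are uniform in a cube rather than a cortical column.

Consequently a green test establishes structural and I/O correctness
(files round-trip, resolve, validate, index, and slice exactly), plus
first-moment statistical sanity (edge counts and Poisson spike totals
within 4σ of their means at fixed seeds). It does **not** establish
biological realism: no distance- or orientation-dependent connectivity,
no cell-type-specific rules, no correlated activity. Poisson inputs are
homogeneous and independent per node; report traces are constant,
sinusoidal, or AR(1) — fixtures, not physiology.

Every generator takes an explicit seed and runs on a private RNG stream
(the caller's `.Random.seed` is saved and restored), so fixtures are
reproducible and generation never perturbs user code.

## Degenerate inputs and edge cases

Empty populations (0 nodes, one empty group), header-only type tables,
empty spike reports and zero-length windows are all legal and round-trip;
`p = 0` rules produce 0-edge populations; unknown nodes in edge queries
return empty results rather than erroring. `tstop = tstart` reports,
negative timestamps, ragged CSV rows, duplicate type ids and manifest
cycles are rejected with classed errors (`sonatar_*` condition classes)
so callers can branch on the failure mode.

## Known limitations

- Writers are single-process. The parallel-writer pattern (each process
  owning a disjoint column span of each frame) shapes the append-by-frames
  API but is not implemented.
- Connectivity generation materializes one Bernoulli draw per ordered
  node pair, so full-scale (45,000²) generation is memory-hungry; the
  generator is intended for scaled-down fixtures.
- `model_template`, `morphology` and `dynamics_params` values are opaque
  references; the package never interprets hoc/NeuroML templates, SWC
  geometry, or dynamics JSON contents.
- Node-set expressions are flat predicate objects (conjunction of keys,
  disjunction within a key, reserved `population` / `node_id` keys);
  compound set algebra is out of scope.
- The element-report reader loads mapping metadata per call; for
  many-query workloads over one file, read the report once with
  `read_element_report()` and slice in memory.
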