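# sonatar

An R implementation of the **SONATA data format** for large-scale neuronal
network models. SONATA describes a model end to end — circuit structure,
simulation configuration, and activity — with a small set of standard files:

- **Circuits**: node and edge *instance tables* in HDF5 (one row per neuron
  or synapse, partitioned into homogeneous attribute *groups*), paired with
  small space-separated CSV *type tables* holding attributes shared by all
  instances of a `node_type_id` / `edge_type_id`. An instance's full
  attribute map is the type row overlaid by its per-instance values
  (instance wins on a name clash; the token `NONE` marks an absent value).
- **Configs**: a JSON hierarchy — a primary config pointing at a circuit
  config (where the files live) and a simulation config (`run` block with
  `tstop`/`dt` in ms, node sets, inputs, outputs, reports), with `$VAR`
  manifest substitution and per-file relative-path resolution.
- **Activity**: spike trains as paired `(node_id, timestamp)` HDF5 datasets,
  and element reports as one chunked N x M matrix — rows are *frames* (all
  values at one timestamp), columns are *traces* (one element's time
  series), located via a `node_ids` / `index_pointer` mapping with optional
  `element_id` / `element_pos` per compartment.

The package is aimed at computational neuroscientists who need to read,
write, validate, reorganize (target-major / source-major / hybrid edge
orderings with per-node range indices), or synthesize SONATA model files
from R, without a simulator in the loop.

## Worked example

Generate a small hybrid circuit (a scaled-down cortical-layer model:
biophysically detailed core, point-neuron annulus, virtual input nodes),
write a complete bundle, and poke at it:

```r
library(sonatar)

dir <- file.path(tempdir(), "demo"); dir.create(dir)
spec <- l4_like_spec(scale = 0.001, seed = 42)   # 10 + 35 + 10 nodes
cir  <- write_synth_bundle(spec, dir, rate_hz = 10, duration_ms = 1000)
print(cir)
#> SONATA circuit: 3 node population(s), 5 edge population(s)
#>   nodes/core_biophysical: 10 node(s)
#>   nodes/annulus_point: 35 node(s)
#>   nodes/inputs: 10 node(s)
#>   edges/annulus_point_to_core_biophysical: 5 edge(s) (annulus_point -> core_biophysical)
#>   ...

# type-level attributes overlaid by per-instance x/y/z positions
str(resolve_node(cir, "annulus_point", 0L)$attributes)
#> List of 6
#>  $ model_type     : chr "point_neuron"
#>  $ model_template : chr "nrn:IntFire1"
#>  $ dynamics_params: chr "if1_exc.json"
#>  $ x              : num 190
#>  ...

# node sets select by resolved attribute
nrow(evaluate_node_set(cir, list(model_type = "biophysical")))
#> [1] 10

# sort edges target-major, index, query one target's afferent edges
ep  <- sort_edges(cir$edges$core_biophysical_to_core_biophysical, "target_major")
idx <- build_edge_index(ep, "by_target")
length(query_edges(ep, 3L, "by_target", index = idx))
#> [1] 2

validate_circuit(cir)                      # 0 rows: structurally sound
read_spikes(file.path(dir, "input_spikes.h5"), window = c(0, 100))
#> SONATA spike report 'inputs': 8 event(s), sorting=by_time
dim(read_trace(file.path(dir, "voltage_report.h5"), node_id = 0L))
#> [1] 10000     1
```

The numbers above are what the code prints for this seed: 10 biophysical
nodes, 2 afferent edges onto node 3, 8 input spikes in the first 100 ms, and
a 10,000-frame voltage trace (1000 ms at dt = 0.1 ms).

## Command line

`inst/cli/sonatar` (installed under `system.file("cli", "sonatar")`) exposes
the same operations: `validate`, `info`, `sort-edges`, `index-edges`,
`spikes to-csv|from-csv`, `report slice`, and `synth`. Exit codes: 0 clean,
1 validation errors, 2 usage/IO failure.

```sh
Rscript inst/cli/sonatar synth --scale 0.01 --seed 1 --out /tmp/bundle
Rscript inst/cli/sonatar validate --config /tmp/bundle/config.json
```

## Documentation

See the methods vignette (`vignettes/sonata-format.Rmd`) for the data
model, the layout conventions this package fixes where the format leaves
choices open, the synthetic-generator assumptions, and known limitations.
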