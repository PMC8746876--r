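# unftools

Read, write, validate and convert **Unified Nanotechnology Format (UNF)**
files — a JSON-based container for coarse-grained DNA/RNA/protein
nanostructure designs that keeps CAD-level design data (origami lattices,
virtual helices, typed cells, scaffold/staple roles) and simulation-level
structural data (per-nucleotide reference frames, alpha-carbon protein
beads, ligands) in one file, together with optionally embedded,
MD5-verified copies of referenced atomistic files.

The package is for people who move nanostructures between tools: Cadnano
designs that need to become simulation-ready oxDNA files, oxDNA or
atomistic (PDB/mmCIF) structures that need a design-level container, or
pipelines that need one self-contained artifact per structure.

## What it implements

* **Data model + validator** — every UNF v1.0 object type with
  document-wide integer IDs (`-1` = none); `unf_validate()` checks ID
  uniqueness/resolvability, symmetric pairing, strand walkability, and the
  cell rules (deletion cells reference nothing, normal cells ≤ 1
  nucleotide per direction, an insertion of length *n* references *n + 1*).
* **Container I/O** — `unf_read()` / `unf_write()` handle the hybrid
  layout: a JSON body found by escape-aware brace balancing, followed by
  binary-safe attachments, each integrity-checked against its MD5.
* **Geometry engine** — `implicit_frame()` places lattice-referenced
  nucleotides with ideal B-form geometry (3.4 Å rise; 33.75°/bp on the
  square lattice, 360·2/21° on the honeycomb — Cadnano's crossover
  periodicities). Per-nucleotide frames are four vectors: backbone center,
  base center, base normal `a3`, hydrogen-face direction `a1`, with
  `a1 ⊥ a3`. Explicit position records always take precedence.
* **Converters** — Cadnano ⇄ UNF (routing reconstruction, loops/skips →
  insertions/deletions, deterministic circular-scaffold cut recorded so
  the round trip is lossless, colors preserved); oxDNA ⇄ UNF (classic
  dialect; 1 su = 8.518 Å, base/backbone sites at ±0.4 su along `a1`);
  PDB/mmCIF → UNF coarse-graining (CA beads bit-exact; base frames from
  ring cross-products and Watson–Crick edge centroids; ligands with
  CONECT or covalent-radius bonds).
* **Fixture generators** — deterministic toy Cadnano designs, idealized
  atomistic duplexes and oxDNA duplexes, so every conversion is testable
  offline.

## Worked example

Generate a four-helix origami design (circular scaffold, one skip, one
loop), convert it to UNF, inspect it, and export simulation files:

```r
library(unftools)

sp <- fixture_spec(nHelices = 4, cellsPerHelix = 32, latticeType = "square",
                   circularScaffold = TRUE, nSkips = 1, nLoops = 1, seed = 42)
design <- make_toy_cadnano(sp)

doc <- cadnano_to_unf(list(list(design = design, latticeType = "square")))
doc
#> UNF document 'cadnano import' (format version 1.0)
#>   lattices:   1
#>   structures: 1 (258 nucleotides, 0 amino acids)
#>   external files: 0

nrow(unf_validate(doc))
#> [1] 0

scaf <- Filter(function(s) s$isScaffold, doc$structures[[1]]$naStrands)[[1]]
length(scaf$nucleotides)
#> [1] 129
```

The scaffold crosses all 4 × 32 = 128 cells; at this seed the loop has
length 2 (an insertion cell referencing *n + 1* = 3 nucleotides per
crossing strand) and the skip deletes one, so the scaffold holds
128 + 2 − 1 = 129 nucleotides, and scaffold plus staples total
2 × (128 + 2 − 1) = 258. The scaffold was circular, so
it has been cut at the deterministic location and the closure recorded as
a connection; converting back reproduces the input exactly:

```r
back <- unf_to_cadnano(doc)[[1]]
identical(back$vstrands, design$vstrands)
#> [1] TRUE
```

Lattice nucleotides have no stored coordinates; the geometry engine
places them on demand (and explicit `altPositions` would win if present):

```r
fr <- resolve_nucleotide_position(doc, scaf$nucleotides[[1]]$id)
round(fr$nucleobaseCenter, 3)
#> [1] -1.7  0.0  0.0

ox <- unf_to_oxdna(doc)   # warns: bases are "N" (no sequence assigned) and
                          # the design backbone radius is not the oxDNA site
strsplit(ox$topology, "\n")[[1]][1]
#> [1] "258 15"
```

A command-line wrapper ships in `inst/exec/`:

```sh
unf cadnano2unf design.json:square:0,0,0 -o out.unf
unf validate out.unf
unf unf2oxdna out.unf -o sim          # writes sim.top / sim.dat
unf pdb2unf 1igy.pdb -o 1igy.unf --embed-source
```

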