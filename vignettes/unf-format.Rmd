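---
title: "The UNF data model, its geometry engine, and the converters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The UNF data model, its geometry engine, and the converters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unftools)
```

# The problem

DNA and RNA nanotechnology pipelines move a structure through several
tools: a lattice-based CAD editor (Cadnano), coarse-grained molecular
dynamics (oxDNA), and atomistic reference structures (PDB/mmCIF). Each
tool has its own format and most conversions lose information — above all
the *design* abstractions (virtual helices, scaffold/staple roles,
insertions and deletions) that simulation formats have no place for.

The Unified Nanotechnology Format (UNF) is a JSON-based container that
holds design data and structural data side by side: origami lattices with
typed cells, coarse-grained nucleic acid strands and protein chains,
small-molecule ligands, annotations, and optionally the raw bytes of
referenced atomistic files appended to the same file and protected by an
MD5 digest. `unftools` implements the version 1.0 data model, the
container, converters to and from Cadnano and oxDNA, an atomistic
coarse-grainer, and deterministic toy-structure generators that make every
conversion path testable without external data.

# The data model

A document is a tree: lattices contain virtual helices at (row, col)
addresses; helices contain cells indexed along the helix axis; structures
contain nucleic-acid strands and alpha-carbon protein chains. Every object
carries a document-wide unique non-negative integer ID, and `-1` always
means "none". Cross-references (base pairing, 5'/3' neighbours, cell
arrays, groups, comments) are by ID, which makes them unambiguous across
collections; `unf_validate()` checks that every reference resolves and
that structural invariants hold, returning findings as data rather than
throwing, so a half-broken file can still be inspected.

Three invariants deserve emphasis because the converters rely on them:

* **Cell typing.** A *normal* cell references at most one nucleotide per
  crossing direction. A *deletion* cell references none — it keeps its
  place in the lattice (and consumes a helical rise) but contributes no
  material. An *insertion* cell of length *n* references *n + 1*
  nucleotides per crossing strand. These are exactly Cadnano's skip and
  loop semantics.
* **Strand topology.** Walking `next` pointers from `fivePrimeId` must
  visit every nucleotide exactly once and end at `threePrimeId`; pairing
  must be symmetric.
* **Frames.** A nucleotide's spatial state is four vectors: backbone
  center, nucleobase center, the unit base-plane normal (stacking
  direction, oxDNA's `a3`), and the unit hydrogen-face direction (toward
  the Watson–Crick edge, oxDNA's `a1`), with `a1 ⊥ a3`. Splitting
  backbone and base centers — where oxDNA stores a single center of mass —
  is what lets atomistic conversions keep their geometry.

The canonical JSON field layout is documented in
`system.file("schema", "unf-schema.json", package = "unftools")`.

Two details the format leaves open were fixed as follows. Lattice
orientation is stored as intrinsic X-then-Y-then-Z Euler angles in
degrees, because no rotation convention is mandated and this matches the
row-major rotation helpers used throughout. Modification codes are free
text: the vocabulary of standard modification codes is not pinned down,
and free text never rejects a valid file. Comments attach to exactly one
object ID; a note spanning several objects can be expressed with a group.

# The container

A UNF file is a JSON body optionally followed by appended payloads. The
reader finds the end of the JSON body by string- and escape-aware brace
balancing over the raw bytes — never by scanning for a marker token — so a
payload may contain anything, including text that looks like JSON or like
a marker line. Each payload follows a marker line

```
#INCLUDED_FILE <fileId>;<filename>;<nbytes>
```

and is terminated by a newline. The byte count is part of this package's
dialect: two binary payloads in one container cannot be delimited reliably
by any sentinel, so the length is declared up front. The marker syntax is
isolated behind a single constant (`UNF_MARKER_PREFIX`) so it can be
swapped wholesale if an interoperating tool uses a different line.
Digests are computed over the raw payload bytes exactly as embedded, with
no newline normalization; `unf_read()` verifies every included file and
names the offending ID on mismatch, and a single flipped payload byte is
always caught (the MD5 here is an integrity check against accidental
corruption, not a cryptographic signature).

```{r}
doc <- unf_document("demo", "vignette")
doc <- unf_embed_file(doc, charToRaw("ATOM ...\n"), "source.pdb", "pdb")
rt <- unf_read(unf_write(doc))
rt$document$externalFiles[[1]]$hash
```

# Lattice geometry

Lattice-referenced nucleotides carry no coordinates; viewers place them
algorithmically, and explicit position records always take precedence when
present. `implicit_frame()` realizes the placement with ideal B-form
geometry. The tunable parameters (`geometry_params()`), all overridable
from the CLI:

| parameter | default | meaning |
|---|---|---|
| `interhelixSpacing` | 25 Å | center-to-center helix distance (2 nm helix + 0.5 nm gap) |
| `risePerBp` | 3.4 Å | axial rise per base pair |
| `twistPerBp` | 33.75° (square), 360·2/21 ≈ 34.29° (honeycomb) | helical twist per base pair |
| `initialAngle` | 0° | phase at cell index 0 |
| `backboneRadius` | 6 Å | backbone center distance from the axis |
| `baseRadius` | 1.7 Å | nucleobase center distance from the axis |
| `grooveOffset` | 0° | minor-groove asymmetry of the complement's `a1` |

The twist defaults are not the generic ~34.3° of solution B-DNA: they
reproduce Cadnano's crossover periodicity (32 bp = 3 turns on the square
lattice, 21 bp = 2 turns on the honeycomb), which is what lattice designs
assume. `grooveOffset = 0` places the two backbones diametrically opposite
— a deliberate simplification that keeps paired frames exactly
antiparallel; a realistic minor groove is one parameter away. Row indices
grow downward on the Cadnano canvas, so they are negated into a
right-handed frame.

Within an insertion cell of *n + 1* nucleotides the sub-positions divide
one rise and one twist step evenly, giving strictly increasing axial
positions inside `[z_i, z_{i+1})`. Deletion cells consume a cell index —
they keep the lattice registration — but emit no frames. All emitted
frames satisfy the unit-norm and orthogonality invariants to 1e−9 and are
rigid-motion equivariant by construction (the lattice rotation is applied
last).

# The Cadnano bridge

Cadnano stores routing only implicitly: per cell and per strand kind, a
4-tuple `[h5, i5, h3, i3]` naming the 5'- and 3'-side neighbour cells.
`trace_strands()` reconstructs the routed paths: linear paths start at
cells with no 5' neighbour and follow 3' pointers; whatever occupied cells
remain lie on circular paths. Circular scaffolds are cut at a *predefined,
deterministic* location — the lexicographically smallest (helixNum,
baseIndex) in the cycle — so converting a design twice gives identical
documents regardless of traversal order.

Cutting is convenient for consuming applications but would make the
conversion lossy: the re-exported design would have strand ends where the
input had none. The converter therefore records each cut as a UNF
connection with interaction `"circular strand closure"` joining the 3' and
5' terminal nucleotides — connections exist precisely to express explicit
interactions between elements — and the exporter re-closes such strands.
With that, Cadnano → UNF → Cadnano is the identity on routing, skip and
loop arrays, and staple colors (the package's randomized round-trip suite
checks 100 designs with 2–8 helices, both lattices, skips, loops, circular
scaffolds and crossovers).

Other reconstruction details:

* **Cell direction.** Whether a strand populates `fiveToThreeNts` or
  `threeToFiveNts` is derived from the actual traversal direction
  (increasing base index ⇒ 5'→3'), falling back to Cadnano's even/odd
  helix parity only for single-cell fragments.
* **Deletions on export.** A deletion cell references no nucleotides, so a
  strand's routing through it is restored by bridging same-helix gaps in
  the strand's cell path across deletion cells. A skip at a strand
  terminus or on a crossover column is not representable this way; real
  designs place skips in duplex interiors, and so does the fixture
  generator.
* **Colors.** Cadnano's decimal color integers become `#RRGGBB` strand
  colors, attached to the staple whose 5' end sits at the `stap_colors`
  base index, and are emitted back on the 5'-end helix in index order.
* **Sequence.** Bases default to `"N"`. An optional scaffold sequence is
  assigned 5'→3' and complemented onto paired staples; Cadnano keeps
  sequences in a separate CSV, which is out of container scope.
* **Pairing.** Scaffold and staple nucleotides co-occupying a cell are
  paired index-reversed (both arrays are stored in their own strand's
  5'→3' order, and the two strands traverse the cell's axial sub-slots in
  opposite directions).

# The atomistic bridge

`pdb_to_unf()` coarse-grains a PDB or mmCIF structure (parsed by bio3d;
first model, altloc blank or "A"): amino acids become alpha-carbon beads —
bit-exactly the input CA coordinates — and nucleotides become four-vector
frames. Residues are assumed listed 5'→3' (N→C for proteins). Residue
classification is by name first, then by atom content, with the O2' atom
separating RNA from DNA for nonstandard names; hetero residues that are
not water become explicit-atom ligands with bonds from CONECT records
when present, else from a covalent-radius distance rule (bonded iff
d ≤ r₁ + r₂ + 0.4 Å).

The frame recipe is pinned down in `BASE_ATOM_SETS` so it can be replaced
as a unit if an interoperating tool publishes a different one:

* `a3` = normalized sum of cross products of successive centered ring-atom
  vectors, in the fixed cyclic order of the ring table (which also fixes
  the sign). The sum is origin-independent for a closed polygon, and for
  exactly planar rings it equals the analytic plane normal.
* `a1` = the vector from the base center of mass to the centroid of the
  Watson–Crick edge atoms (purines {N1, C2, C6}, pyrimidines {N3, C2,
  C4}), projected into the base plane — orthogonal to `a3` by
  construction.
* Centers are *unweighted* atom means: sugar and phosphate atoms
  (including C1' and O2') count as backbone, all other heavy atoms as
  base. Mass weighting would move the centers by fractions of an Ångström
  without changing any downstream consumer; the split of C1' into the
  backbone group is a convention, stated here so it can be questioned.

# The oxDNA bridge

Classic-dialect oxDNA files only: topology rows `strand base n3 n5` listed
3'→5' per strand (the newer 5'→3' dialect is detected and rejected with a
clear message), configurations with ≥ 9 columns. The unit and site
constants are fixed properties of the first-generation oxDNA model: 1
simulation unit = 8.518 Å, base site at +0.4 su along `a1`, backbone site
at −0.4 su (oxDNA2's `a2`-dependent backbone site is out of scope).
Import therefore maps

```
nucleobaseCenter = (com + 0.4·a1) · 8.518
backboneCenter   = (com − 0.4·a1) · 8.518
```

and export inverts through the *base* center, `com = nucleobaseCenter /
8.518 − 0.4·a1`. UNF's extra degree of freedom — an independent backbone
center — is necessarily collapsed on export; a warning is logged when the
stored backbone center sits more than 0.5 Å from the implied site, so
silent information loss cannot happen. Base `"N"` has no oxDNA letter and
is emitted as `"T"` with a warning; protein chains are skipped with a
warning because the classic format has no protein record. Lattice-only
documents export through `resolve_nucleotide_position()`, so a Cadnano
design can go straight to a simulation-ready pair of files.

Round trips recover `com`/`a1`/`a3` to better than 1e−6 su (configuration
text carries 10 significant digits) with byte-identical topology. The
multiply-then-divide unit conversion is inverse at machine precision
(≤ 4 ulp) — bit-exactness for every double is not attainable under
round-to-nearest, and the tests assert the attainable bound.

# The fixture generators

The generators exist so that every bridge is exercised by structures whose
ground truth is known by construction, at the scale of real but small
designs (2–8 helices, ≤ 100 nt):

* `make_toy_cadnano()` lays a serpentine scaffold over all helices
  (optionally circular), covers every cell with antiparallel staples
  broken at seeded random points (segments of 7–13 cells, the scale of
  real staple domains), adds one staple crossover per helix pair, colors
  every staple from the Cadnano palette, and places skips/loops at seeded
  interior duplex positions.
* `make_toy_duplex_pdb()` builds a B-form duplex from planar per-base atom
  templates (idealized hexagons and fused rings with canonical atom names,
  not crystallographic coordinates — sufficient because only means, planes
  and edge centroids enter the frame recipe). Base atoms are exactly
  coplanar, so the analytic plane normal is known, and the second chain is
  a reflected copy so both chains read 5'→3'.
* `make_toy_oxdna()` places an ideal duplex in simulation units and
  applies a seeded random rigid motion so nothing is axis-aligned.

All three are deterministic functions of their arguments and seed, and
restore the caller's RNG state. What they do *not* emulate: thermal noise,
sequence-dependent geometry, modified residues, multi-model files, and
degenerate routing (skips at strand termini or crossover columns). A green
suite therefore demonstrates correctness of the conversion logic, not
robustness to every malformed file in the wild.

# Problem sizes and numerical choices

The randomized suites use 100 Cadnano designs of 2–8 helices × 21–64
cells, 25-document container checks with payloads up to 200 random bytes,
duplexes of 7–16 bp, and 10 oxDNA systems of 32 nt — sizes chosen so the
full suite runs in well under a minute while covering every code path and
both lattice types. Frame invariants are asserted at 1e−9 (construction)
and 1e−12 (projection identities); oxDNA recovery at 1e−6 su; containers
and Cadnano arrays at byte identity.

# Known limitations

* Cadnano2 "vstrands" dialect only; cadnano2.5/scadnano are out of scope.
* No UNF → all-atom reconstruction, and no protein side-chain orientation
  (the coarse model is one bead per residue).
* No trajectory (multi-frame) oxDNA handling and no oxView scene files.
* The container is read fully into memory; multi-gigabyte streaming is a
  non-goal.
* The attachment marker dialect is this package's own; interoperating with
  another UNF implementation may require adjusting the marker constant.
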