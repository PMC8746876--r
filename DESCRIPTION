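Package: unftools
Title: Read, Write and Convert Unified Nanotechnology Format Files
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An implementation of the Unified Nanotechnology Format (UNF)
    version 1.0, a JSON-based container for coarse-grained DNA, RNA and
    protein nanostructure designs. Provides the full UNF data model
    (lattices, virtual helices, cells, strands, nucleotides with
    four-vector reference frames, alpha-carbon protein chains, ligands
    and annotations), a reader/writer for the hybrid container format
    with MD5-verified embedded attachments, an ideal B-form geometry
    engine that places lattice-referenced nucleotides in space, and
    bidirectional converters to and from Cadnano design files and oxDNA
    topology/configuration files, plus a coarse-grainer for atomistic
    PDB/mmCIF structures. Deterministic toy-structure generators support
    fully self-contained testing of every conversion path.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    bio3d,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
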