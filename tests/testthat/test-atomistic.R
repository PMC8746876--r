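test_that("residues classify by name, atoms and the O2' rule", {
  mk <- function(name, atomNames, hetero = FALSE) {
    coords <- matrix(seq_len(3 * length(atomNames)), ncol = 3)
    rownames(coords) <- atomNames
    residue_from_coords(coords, name = name, isHetero = hetero)
  }
  expect_identical(classify_residue(mk("DA", c("P", "C1'", "N1"))),
                   "dnaNucleotide")
  expect_identical(classify_residue(mk("HOH", "O", hetero = TRUE)), "water")
  expect_identical(classify_residue(mk("ALA", c("N", "CA", "C", "O"))),
                   "aminoAcid")
  expect_identical(classify_residue(mk("MG", "MG", hetero = TRUE)), "ligand")

  sugar <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  # named G with an O2' atom: RNA; without sugar information it stays RNA
  expect_identical(classify_residue(mk("G", c(sugar, "O2'", ring))),
                   "rnaNucleotide")
  # nonstandard name, sugar + base: the O2' rule decides
  expect_identical(classify_residue(mk("XG", c(sugar, "O2'", ring),
                                       hetero = TRUE)), "rnaNucleotide")
  expect_identical(classify_residue(mk("XG", c(sugar, ring), hetero = TRUE)),
                   "dnaNucleotide")
  expect_identical(classify_residue(mk("UNX", c("C1", "C2"))), "unknown")
})

test_that("base_normal matches the cross-product oracle on a hexagon", {
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ccw <- t(vapply(0:5, function(k)
    c(cos(k * pi / 3), sin(k * pi / 3), 0), double(3)))
  rownames(ccw) <- ring
  res <- residue_from_coords(ccw, name = "DC")
  expect_equal(base_normal(res), c(0, 0, 1))

  # reversed spatial order flips the sign
  cw <- ccw[6:1, ]
  rownames(cw) <- ring
  expect_equal(base_normal(residue_from_coords(cw, name = "DC")),
               c(0, 0, -1))

  # collinear ring atoms are a geometry error
  line <- cbind(1:6, 0, 0)
  rownames(line) <- ring
  expect_error(base_normal(residue_from_coords(line, name = "DC")),
               "collinear")
})

test_that("hydrogen_face points at the Watson-Crick edge, orthogonal to a3", {
  # synthetic planar pyrimidine: WC centroid at +x of the base COM
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ang <- c(120, 60, 0, -60, -120, 180) * pi / 180
  P <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  rownames(P) <- ring
  res <- residue_from_coords(P, name = "DC")
  a3 <- base_normal(res)
  a1 <- hydrogen_face(res, a3)
  expect_unit(a1, 1e-12)
  expect_lt(abs(sum(a1 * a3)), 1e-12)
  # the WC edge (N3, C2, C4) sits at +x here
  expect_gt(a1[1], 0.9)

  incomplete <- residue_from_coords(P[c("N1", "C5", "C6"), , drop = FALSE],
                                    name = "DC")
  expect_error(hydrogen_face(incomplete), "Watson-Crick")
})

test_that("template guanine a1 is within 5 degrees of the COM -> N1 direction", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(make_toy_duplex_pdb("G"), tf)
  res <- read_atomistic(tf)[[1]]
  expect_identical(res$name, "DG")
  fr <- nucleotide_frame_from_atoms(res)
  n1 <- unlist(res$atoms[res$atoms$name == "N1", c("x", "y", "z")])
  v <- unname(n1) - fr$nucleobaseCenter
  v <- v / sqrt(sum(v^2))
  angle <- acos(min(1, sum(v * fr$hydrogenFaceDir))) * 180 / pi
  expect_lt(angle, 5)
})

test_that("frame centers are unweighted means of the atom groups", {
  coords <- rbind("P" = c(0, 0, 0), "O5'" = c(2, 0, 0),
                  "N1" = c(10, 0, 0), "C2" = c(10, 2, 0), "N3" = c(12, 2, 0),
                  "C4" = c(12, 0, 0), "C5" = c(12, -2, 0), "C6" = c(10, -2, 0),
                  "O2" = c(8, 2, 0))
  res <- residue_from_coords(coords, name = "DT")
  fr <- nucleotide_frame_from_atoms(res)
  expect_equal(fr$backboneCenter, c(1, 0, 0))
  # independent arithmetic oracle over the base atoms (ring + O2)
  expect_equal(fr$nucleobaseCenter,
               colMeans(coords[3:9, ]), ignore_attr = TRUE)

  baseOnly <- residue_from_coords(coords[3:9, ], name = "DT")
  expect_error(nucleotide_frame_from_atoms(baseOnly), "no backbone atoms")
})

test_that("ligand bonds come from CONECT or the covalent-radius rule", {
  two_c <- function(d) residue_from_coords(
    rbind(C1 = c(0, 0, 0), C2 = c(d, 0, 0)), name = "LIG", isHetero = TRUE,
    elements = c("C", "C"))
  # C-C at 1.5 A: within 0.76 + 0.76 + 0.4
  lg <- ligand_from_residue(two_c(1.5))
  expect_length(lg$bonds, 1L)
  expect_identical(lg$bonds[[1]], c(0L, 1L))
  # 5 A apart: no bond
  expect_length(ligand_from_residue(two_c(5.0))$bonds, 0L)
  # an explicit CONECT pair wins regardless of distance
  lg3 <- ligand_from_residue(two_c(5.0), conect = cbind(1L, 2L))
  expect_length(lg3$bonds, 1L)
})

test_that("amino bead positions are the CA coordinates bit-exactly", {
  set.seed(7)
  ca <- matrix(runif(9, -50, 50), 3, 3)
  lines <- character(0)
  serial <- 0L
  for (i in 1:3) {
    for (atom in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      xyz <- if (atom == "CA") ca[i, ] else ca[i, ] + runif(3)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, atom, "GLY", "A", i, xyz[1], xyz[2], xyz[3], substr(atom, 1, 1)))
    }
  }
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), tf)
  doc <- pdb_to_unf(tf)
  chain <- doc$structures[[1]]$aaChains[[1]]
  expect_length(chain$aminoAcids, 3L)
  for (i in 1:3)
    expect_identical(chain$aminoAcids[[i]]$position,
                     as.double(round(ca[i, ], 3)))  # PDB stores 3 decimals
  expect_identical(chain$aminoAcids[[1]]$code, "G")
  expect_equal(nrow(unf_validate(doc)), 0L)
})

test_that("a synthetic duplex coarse-grains to two valid strands", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(make_toy_duplex_pdb("ACGTACGT"), tf)
  doc <- pdb_to_unf(tf)
  st <- doc$structures[[1]]
  expect_length(st$naStrands, 2L)
  expect_identical(vapply(st$naStrands, function(s) length(s$nucleotides),
                          integer(1)), c(8L, 8L))
  expect_identical(unf_strand_sequence(doc, st$naStrands[[1]]), "ACGTACGT")
  # chain B is the reverse complement, read 5'->3'
  expect_identical(unf_strand_sequence(doc, st$naStrands[[2]]), "ACGTACGT")
  expect_equal(nrow(unf_validate(doc)), 0L)
  # all frames satisfy the orthonormality invariants
  for (s in st$naStrands) for (nt in s$nucleotides) {
    fr <- nt$altPositions[[1]]
    expect_unit(fr$baseNormal, 1e-9)
    expect_unit(fr$hydrogenFaceDir, 1e-9)
    expect_lt(abs(sum(fr$baseNormal * fr$hydrogenFaceDir)), 1e-12)
  }
  # RNA flavour: O2' drives strand typing
  tf2 <- tempfile(fileext = ".pdb")
  writeLines(make_toy_duplex_pdb("ACGU", rna = TRUE), tf2)
  doc2 <- pdb_to_unf(tf2)
  expect_identical(doc2$structures[[1]]$naStrands[[1]]$naType, "RNA")
})

test_that("mixed protein/DNA/water input keeps counts conserved", {
  # duplex + a glycine + waters, all in one file
  duplex <- strsplit(make_toy_duplex_pdb("ACG"), "\n")[[1]]
  duplex <- duplex[!duplex %in% c("TER", "END")]
  extra <- c(
    "ATOM   9001  N   GLY C   1      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM   9002  CA  GLY C   1      11.000  10.000  10.000  1.00  0.00           C",
    "ATOM   9003  C   GLY C   1      12.000  10.000  10.000  1.00  0.00           C",
    "HETATM 9010  O   HOH D   1      20.000  20.000  20.000  1.00  0.00           O",
    "HETATM 9011  O   HOH D   2      21.000  20.000  20.000  1.00  0.00           O",
    "HETATM 9020 MG    MG E   1      30.000  30.000  30.000  1.00  0.00          MG",
    "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(duplex, extra), tf)
  residues <- read_atomistic(tf)
  doc <- suppressMessages(pdb_to_unf(tf))
  st <- doc$structures[[1]]
  expect_length(st$aaChains, 1L)
  expect_gte(length(st$naStrands), 1L)
  expect_length(doc$molecules$ligands, 1L)
  nNt <- sum(vapply(st$naStrands, function(s) length(s$nucleotides),
                    integer(1)))
  nAa <- sum(vapply(st$aaChains, function(c) length(c$aminoAcids),
                    integer(1)))
  dropped <- attr(doc, "dropped")
  expect_identical(nNt + nAa + length(doc$molecules$ligands) +
                     sum(dropped), length(residues))
  expect_identical(unname(dropped["water"]), 2L)

  # a chain mixing polymer types is an error
  bad <- c(duplex[1:30],
           "ATOM   9001  N   GLY A 900      10.000  10.000  10.000  1.00  0.00           N",
           "ATOM   9002  CA  GLY A 900      11.000  10.000  10.000  1.00  0.00           C",
           "ATOM   9003  C   GLY A 900      12.000  10.000  10.000  1.00  0.00           C",
           "END")
  tf2 <- tempfile(fileext = ".pdb")
  writeLines(bad, tf2)
  expect_error(pdb_to_unf(tf2), "mixes nucleic and amino")
})

test_that("embedding the source attaches a hash-verified payload", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(make_toy_duplex_pdb("AC"), tf)
  doc <- pdb_to_unf(tf, embedSource = TRUE)
  expect_length(doc$externalFiles, 1L)
  expect_true(doc$externalFiles[[1]]$isIncluded)
  expect_identical(doc$structures[[1]]$naStrands[[1]]$pdbFileId,
                   doc$externalFiles[[1]]$id)
  rt <- unf_read(unf_write(doc))
  expect_identical(unf_extract_file(rt$document, doc$externalFiles[[1]]$id),
                   readBin(tf, "raw", file.info(tf)$size))
})
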