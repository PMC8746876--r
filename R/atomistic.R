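# Atomistic bridge: coarse-grains PDB/mmCIF structures into UNF strands,
# alpha-carbon chains and ligands. Atomistic parsing is delegated to bio3d;
# this module owns residue classification and the frame construction.

# Atom-name tables for the frame recipe. Cyclic ring order fixes the sign
# of the base normal; Watson-Crick edge atoms define the hydrogen face;
# sugar atoms (including C1' and O2') count as backbone, everything else
# heavy counts as base.
BASE_ATOM_SETS <- list(
  ringPurine     = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  ringPyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6"),
  wcPurine       = c("N1", "C2", "C6"),
  wcPyrimidine   = c("N3", "C2", "C4"),
  backbone       = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "C1'", "O2'")
)

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07,
                    S = 1.05, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
                    FE = 1.32, MG = 1.41, "NA" = 1.66, K = 2.03, ZN = 1.22,
                    CA = 1.76, MN = 1.39, CU = 1.32)

.norm_atom_name <- function(x) gsub("*", "'", trimws(x), fixed = TRUE)

.element_of <- function(elesy, name) {
  e <- toupper(trimws(elesy))
  ok <- !is.na(e) & nzchar(e)
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", trimws(name)), 1L, 1L))
  ifelse(ok, e, guess)
}

#' Read an atomistic structure as residue records
#'
#' Uses \code{bio3d} to parse PDB (\code{ATOM}/\code{HETATM}, first model,
#' altloc blank or "A") or mmCIF input; \code{CONECT} bond records are read
#' directly from PDB text since bio3d does not surface them. Primed atom
#' name variants (\code{O5*}) are normalized to the primed form.
#'
#' @param path Path to a \code{.pdb}, \code{.ent}, \code{.cif} or
#'   \code{.mmcif} file.
#' @return A list of residue records \code{list(chainId, serial, name,
#'   atoms, isHetero)} in file order; \code{atoms} is a data frame with
#'   columns \code{serial}, \code{name}, \code{element}, \code{x},
#'   \code{y}, \code{z}. CONECT serial pairs are in \code{attr(, "conect")}.
#' @export
read_atomistic <- function(path) {
  isCif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  parsed <- if (isCif) bio3d::read.cif(path) else
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  at <- parsed$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]

  chain <- ifelse(is.na(at$chain), "", at$chain)
  resKey <- paste(chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  resKey <- factor(resKey, levels = unique(resKey))

  residues <- lapply(split(seq_len(nrow(at)), resKey), function(rows) {
    a <- at[rows, , drop = FALSE]
    list(chainId = chain[rows[1L]],
         serial = as.integer(a$resno[1L]),
         name = toupper(trimws(a$resid[1L])),
         isHetero = any(a$type == "HETATM"),
         atoms = data.frame(serial = as.integer(a$eleno),
                            name = .norm_atom_name(a$elety),
                            element = .element_of(a$elesy, a$elety),
                            x = a$x, y = a$y, z = a$z,
                            stringsAsFactors = FALSE))
  })
  residues <- unname(residues)

  conect <- matrix(integer(0), 0L, 2L)
  if (!isCif) {
    lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
    pairs <- list()
    for (ln in lines) {
      f <- as.integer(substr(ln, 7L, 11L))
      for (k in 1:3) {
        s <- substr(ln, 12L + (k - 1L) * 5L, 16L + (k - 1L) * 5L)
        v <- suppressWarnings(as.integer(s))
        if (!is.na(v) && !is.na(f))
          pairs[[length(pairs) + 1L]] <- c(min(f, v), max(f, v))
      }
    }
    if (length(pairs) > 0L)
      conect <- unique(do.call(rbind, pairs))
  }
  attr(residues, "conect") <- conect
  residues
}

.atom_names <- function(res) res$atoms$name

#' Classify a residue
#'
#' Standard amino names map to \code{aminoAcid}; DA/DC/DG/DT to
#' \code{dnaNucleotide}; A/C/G/U to \code{rnaNucleotide}; water names to
#' \code{water}. A nonstandard residue carrying sugar and base atoms is a
#' nucleotide, disambiguated by the presence of O2' (present means RNA).
#' Remaining hetero residues are ligands; anything else is \code{unknown}.
#'
#' @param res A residue record from [read_atomistic()].
#' @return One of \code{"aminoAcid"}, \code{"dnaNucleotide"},
#'   \code{"rnaNucleotide"}, \code{"ligand"}, \code{"water"},
#'   \code{"unknown"}.
#' @export
classify_residue <- function(res) {
  nm <- res$name
  atoms <- .atom_names(res)
  if (nm %in% c("HOH", "WAT", "DOD")) return("water")
  hasSugar <- sum(c("C1'", "C2'", "C3'", "C4'", "O4'") %in% atoms) >= 3L
  hasBase <- sum(BASE_ATOM_SETS$ringPyrimidine %in% atoms) >= 3L
  if (nm %in% c("DA", "DC", "DG", "DT")) return("dnaNucleotide")
  if (nm %in% c("A", "C", "G", "U")) {
    if (hasSugar && !("O2'" %in% atoms)) return("dnaNucleotide")
    return("rnaNucleotide")
  }
  if (nm %in% AA3) return("aminoAcid")
  if (hasSugar && hasBase)
    return(if ("O2'" %in% atoms) "rnaNucleotide" else "dnaNucleotide")
  if (res$isHetero) return("ligand")
  if (all(c("N", "CA", "C") %in% atoms)) return("aminoAcid")
  "unknown"
}

.is_purine <- function(res) all(c("N9", "C8") %in% .atom_names(res))

.atom_xyz <- function(res, names) {
  k <- match(names, res$atoms$name)
  k <- k[!is.na(k)]
  as.matrix(res$atoms[k, c("x", "y", "z"), drop = FALSE])
}

.base_atoms_xyz <- function(res) {
  a <- res$atoms
  keep <- !(a$name %in% BASE_ATOM_SETS$backbone) & a$element != "H"
  as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
}

#' Base-plane normal of a nucleotide residue
#'
#' The normal (stacking direction, a3) is the normalized sum of cross
#' products of successive centered ring-atom vectors taken in the fixed
#' cyclic order of the ring table, which also fixes the sign.
#'
#' @param res A residue record classified as a nucleotide.
#' @return A unit 3-vector.
#' @export
base_normal <- function(res) {
  ring <- if (.is_purine(res)) BASE_ATOM_SETS$ringPurine else
    BASE_ATOM_SETS$ringPyrimidine
  P <- .atom_xyz(res, ring)
  if (nrow(P) < 3L)
    stop("residue ", res$name, " ", res$serial,
         ": fewer than 3 ring atoms present")
  ctr <- colMeans(P)
  V <- sweep(P, 2L, ctr)
  n <- c(0, 0, 0)
  m <- nrow(V)
  for (i in seq_len(m)) {
    a <- V[i, ]; b <- V[if (i == m) 1L else i + 1L, ]
    n <- n + c(a[2] * b[3] - a[3] * b[2],
               a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])
  }
  len <- sqrt(sum(n^2))
  if (len < 1e-9)
    stop("residue ", res$name, " ", res$serial,
         ": ring atoms are collinear or degenerate")
  unname(n / len)
}

#' Hydrogen-face direction of a nucleotide residue
#'
#' Points from the base center of mass toward the centroid of the
#' Watson-Crick edge atoms, projected into the base plane so it is exactly
#' orthogonal to the base normal.
#'
#' @param res A residue record classified as a nucleotide.
#' @param a3 The base normal from [base_normal()].
#' @return A unit 3-vector with \code{a1 . a3 = 0} by construction.
#' @export
hydrogen_face <- function(res, a3 = base_normal(res)) {
  wc <- if (.is_purine(res)) BASE_ATOM_SETS$wcPurine else
    BASE_ATOM_SETS$wcPyrimidine
  present <- wc %in% .atom_names(res)
  if (!all(present))
    stop("residue ", res$name, " ", res$serial,
         ": missing Watson-Crick edge atom(s) ",
         paste(wc[!present], collapse = ", "))
  wcMid <- colMeans(.atom_xyz(res, wc))
  baseCOM <- colMeans(.base_atoms_xyz(res))
  v <- wcMid - baseCOM
  v <- v - sum(v * a3) * a3
  len <- sqrt(sum(v^2))
  if (len < 1e-9)
    stop("residue ", res$name, " ", res$serial,
         ": Watson-Crick edge centroid projects onto the base normal")
  unname(v / len)
}

#' Coarse-grained frame of a nucleotide residue
#'
#' Backbone center is the unweighted mean of the present backbone (sugar +
#' phosphate) atoms; nucleobase center the unweighted mean of the remaining
#' heavy atoms (ring plus exocyclic substituents); orientation vectors come
#' from [base_normal()] and [hydrogen_face()].
#'
#' @param res A residue record classified as a nucleotide.
#' @return A [unf_frame()].
#' @export
nucleotide_frame_from_atoms <- function(res) {
  bb <- .atom_xyz(res, BASE_ATOM_SETS$backbone)
  if (nrow(bb) == 0L)
    stop("residue ", res$name, " ", res$serial, ": no backbone atoms")
  ba <- .base_atoms_xyz(res)
  if (nrow(ba) == 0L)
    stop("residue ", res$name, " ", res$serial, ": no base atoms")
  a3 <- base_normal(res)
  a1 <- hydrogen_face(res, a3)
  unf_frame(backboneCenter = unname(colMeans(bb)),
            nucleobaseCenter = unname(colMeans(ba)),
            baseNormal = unname(a3), hydrogenFaceDir = a1)
}

#' Build a ligand from a hetero residue
#'
#' Bonds come from CONECT records when available; otherwise two atoms are
#' bonded iff their distance is at most the sum of covalent radii plus
#' 0.4 Angstrom.
#'
#' @param res A residue record classified as a ligand.
#' @param conect Two-column matrix of bonded atom serial pairs (may be
#'   empty).
#' @param id ID for the new ligand.
#' @return A [unf_ligand()]; bond entries are 0-based atom indices within
#'   the ligand.
#' @export
ligand_from_residue <- function(res, conect = matrix(integer(0), 0, 2),
                                id = 0L) {
  a <- res$atoms
  n <- nrow(a)
  bonds <- list()
  inRes <- conect[conect[, 1] %in% a$serial & conect[, 2] %in% a$serial, ,
                  drop = FALSE]
  if (nrow(inRes) > 0L) {
    for (r in seq_len(nrow(inRes)))
      bonds[[r]] <- c(match(inRes[r, 1], a$serial),
                      match(inRes[r, 2], a$serial)) - 1L
  } else if (n > 1L) {
    rad <- COVALENT_RADII[a$element]
    rad[is.na(rad)] <- 1.2
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
      if (d <= rad[i] + rad[j] + 0.4)
        bonds[[length(bonds) + 1L]] <- c(i, j) - 1L
    }
  }
  unf_ligand(id, name = res$name,
             atoms = lapply(seq_len(n), function(i)
               list(element = a$element[i], name = a$name[i],
                    position = c(a$x[i], a$y[i], a$z[i]))),
             bonds = bonds)
}

#' Coarse-grain an atomistic structure into a UNF document
#'
#' Creates one structure record: per nucleic chain one strand (type by
#' majority classification, residues assumed listed 5' to 3') with a
#' four-vector frame per residue; per protein chain one alpha-carbon chain
#' (residues assumed N- to C-terminal); hetero residues that are not water
#' become ligands; waters and unclassifiable residues are dropped with
#' their counts reported in \code{attr(, "dropped")}. Source residue
#' serials are kept in \code{pdbResidueId}.
#'
#' @param x Path to a PDB/mmCIF file, or a residue list from
#'   [read_atomistic()].
#' @param doc Optional document to extend.
#' @param name Structure name.
#' @param embedSource When \code{x} is a path: also embed the source file
#'   in the document via [unf_embed_file()] and link strands/chains to it.
#' @return A \code{unf_document}.
#' @export
pdb_to_unf <- function(x, doc = NULL, name = "atomistic import",
                       embedSource = FALSE) {
  fileId <- -1L
  if (is.character(x)) {
    path <- x
    residues <- read_atomistic(path)
    if (is.null(doc)) doc <- unf_document(name = name)
    if (embedSource) {
      doc <- unf_embed_file(doc, readBin(path, "raw", file.info(path)$size),
                            basename(path), type = "pdb")
      fileId <- attr(doc, "fileId")
    }
  } else {
    residues <- x
    if (is.null(doc)) doc <- unf_document(name = name)
  }
  conect <- attr(residues, "conect")
  if (is.null(conect)) conect <- matrix(integer(0), 0, 2)

  cls <- vapply(residues, classify_residue, character(1))
  chains <- vapply(residues, function(r) r$chainId, character(1))

  nextId <- doc$idCounter
  newId <- function() { id <- nextId; nextId <<- nextId + 1L; id }

  naStrands <- list(); aaChains <- list(); dropped <- c(water = 0L, unknown = 0L)

  isNA_ <- cls %in% c("dnaNucleotide", "rnaNucleotide")
  isAA <- cls == "aminoAcid"
  polymerChains <- unique(chains[isNA_ | isAA])
  for (ch in polymerChains) {
    inCh <- chains == ch
    if (any(inCh & isNA_) && any(inCh & isAA))
      stop("chain '", ch, "' mixes nucleic and amino acid residues")
    members <- which(inCh & (isNA_ | isAA))
    if (any(inCh & isNA_)) {
      ids <- vapply(members, function(.) newId(), integer(1))
      nts <- vector("list", length(members))
      for (q in seq_along(members)) {
        res <- residues[[members[q]]]
        letter <- res$name
        letter <- sub("^D", "", letter)
        if (!letter %in% c("A", "C", "G", "T", "U")) letter <- "N"
        nts[[q]] <- unf_nucleotide(
          ids[q], base = letter,
          prev = if (q > 1L) ids[q - 1L] else -1L,
          next_ = if (q < length(members)) ids[q + 1L] else -1L,
          pdbResidueId = res$serial,
          altPositions = list(nucleotide_frame_from_atoms(res)))
      }
      naType <- if (sum(cls[members] == "rnaNucleotide") * 2L > length(members))
        "RNA" else "DNA"
      s <- unf_na_strand(newId(), name = paste0("chain ", ch),
                         naType = naType, fivePrimeId = ids[1L],
                         threePrimeId = ids[length(ids)], chainName = ch,
                         pdbFileId = fileId, nucleotides = nts)
      naStrands[[length(naStrands) + 1L]] <- s
    } else {
      ids <- vapply(members, function(.) newId(), integer(1))
      aas <- vector("list", length(members))
      for (q in seq_along(members)) {
        res <- residues[[members[q]]]
        k <- match("CA", res$atoms$name)
        if (is.na(k))
          stop("residue ", res$name, " ", res$serial,
               " in chain '", ch, "' has no alpha carbon")
        code <- unname(AA1[res$name])
        if (is.na(code)) code <- "X"
        aas[[q]] <- unf_amino_acid(
          ids[q], code = code,
          prev = if (q > 1L) ids[q - 1L] else -1L,
          next_ = if (q < length(members)) ids[q + 1L] else -1L,
          pdbResidueId = res$serial,
          position = c(res$atoms$x[k], res$atoms$y[k], res$atoms$z[k]))
      }
      aaChains[[length(aaChains) + 1L]] <-
        unf_aa_chain(newId(), chainName = ch, nTermId = ids[1L],
                     cTermId = ids[length(ids)], pdbFileId = fileId,
                     aminoAcids = aas)
    }
  }

  for (k in which(cls == "ligand"))
    doc$molecules$ligands[[length(doc$molecules$ligands) + 1L]] <-
      ligand_from_residue(residues[[k]], conect, id = newId())
  dropped["water"] <- sum(cls == "water")
  dropped["unknown"] <- sum(cls == "unknown")
  if (sum(dropped) > 0L)
    message("dropped ", dropped["water"], " water and ", dropped["unknown"],
            " unclassifiable residue(s)")

  st <- unf_structure(newId(), name = name, naStrands = naStrands,
                      aaChains = aaChains)
  doc$structures[[length(doc$structures) + 1L]] <- st
  doc$idCounter <- nextId
  attr(doc, "dropped") <- dropped
  doc
}
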