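# UNF data model: document container, domain-object constructors, the
# document-wide ID registry, topology traversal and the validator.

UNF_VERSION <- "1.0"

.int1 <- function(x) {
  if (is.null(x) || length(x) == 0L) return(-1L)
  as.integer(x[[1L]])
}

.num3 <- function(x) {
  x <- as.double(unlist(x, use.names = FALSE))
  stopifnot(length(x) == 3L)
  x
}

.chr1 <- function(x, default = "") {
  if (is.null(x)) return(default)
  as.character(x)[1L]
}

#' Create an empty UNF document
#'
#' Builds a new, valid Unified Nanotechnology Format document with format
#' version "1.0", Angstrom length units, degree angular units and every
#' collection empty. Object IDs are document-wide unique non-negative
#' integers; the sentinel \code{-1} means "none". Each document carries its
#' own ID counter, so IDs allocated with [unf_next_id()] in two documents
#' are independent.
#'
#' @param name Design name stored in the header.
#' @param author Author name stored in the header.
#' @param doi Optional DOI of a related publication.
#' @return An object of class \code{unf_document}.
#' @examples
#' doc <- unf_document("my design", "me")
#' unf_validate(doc)   # zero findings
#' @export
unf_document <- function(name = "", author = "", doi = "") {
  doc <- list(
    format        = "unf",
    version       = UNF_VERSION,
    lengthUnits   = "A",
    angularUnits  = "deg",
    name          = as.character(name),
    author        = as.character(author),
    creationDate  = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    doi           = as.character(doi),
    externalFiles = list(),
    lattices      = list(),
    structures    = list(),
    molecules     = list(ligands = list(), nanostructures = list(), others = list()),
    groups        = list(),
    modifications = list(),
    connections   = list(),
    comments      = list(),
    simulationBox = NULL,
    misc          = list(),
    idCounter     = 0L,
    attachments   = list()
  )
  class(doc) <- "unf_document"
  doc
}

#' Allocate fresh object IDs in a document
#'
#' Returns the next \code{n} unused IDs and the document with its internal
#' counter advanced. IDs are never reused within a document.
#'
#' @param doc A \code{unf_document}.
#' @param n Number of IDs to allocate.
#' @return A list with elements \code{doc} (updated document) and
#'   \code{ids} (integer vector of length \code{n}).
#' @export
unf_next_id <- function(doc, n = 1L) {
  n <- as.integer(n)
  ids <- doc$idCounter + seq_len(n) - 1L
  doc$idCounter <- doc$idCounter + n
  list(doc = doc, ids = ids)
}

# ---- domain-object constructors ------------------------------------------

#' @rdname unf_objects
#' @export
unf_lattice <- function(id, name = "", type = c("square", "honeycomb"),
                        position = c(0, 0, 0), orientation = c(0, 0, 0),
                        virtualHelices = list()) {
  type <- match.arg(type)
  list(id = .int1(id), name = as.character(name), type = type,
       position = .num3(position), orientation = .num3(orientation),
       virtualHelices = virtualHelices)
}

#' @rdname unf_objects
#' @export
unf_virtual_helix <- function(id, row, col, designNumber = -1L,
                              initialAngle = 0, cells = list()) {
  list(id = .int1(id), row = .int1(row), col = .int1(col),
       designNumber = .int1(designNumber),
       initialAngle = as.double(initialAngle), cells = cells)
}

#' @rdname unf_objects
#' @export
unf_cell <- function(id, index, type = c("normal", "insertion", "deletion"),
                     fiveToThreeNts = integer(), threeToFiveNts = integer()) {
  type <- match.arg(type)
  list(id = .int1(id), index = .int1(index), type = type,
       fiveToThreeNts = as.integer(fiveToThreeNts),
       threeToFiveNts = as.integer(threeToFiveNts))
}

#' @rdname unf_objects
#' @export
unf_structure <- function(id, name = "", naStrands = list(), aaChains = list()) {
  list(id = .int1(id), name = as.character(name),
       naStrands = naStrands, aaChains = aaChains)
}

#' @rdname unf_objects
#' @export
unf_na_strand <- function(id, name = "", naType = c("DNA", "RNA"),
                          isScaffold = FALSE, color = "#FFFFFF",
                          fivePrimeId = -1L, threePrimeId = -1L,
                          chainName = "", pdbFileId = -1L,
                          nucleotides = list()) {
  naType <- match.arg(naType)
  list(id = .int1(id), name = as.character(name), naType = naType,
       isScaffold = isTRUE(isScaffold), color = as.character(color),
       fivePrimeId = .int1(fivePrimeId), threePrimeId = .int1(threePrimeId),
       chainName = as.character(chainName), pdbFileId = .int1(pdbFileId),
       nucleotides = nucleotides)
}

#' @rdname unf_objects
#' @export
unf_nucleotide <- function(id, base = "N", pair = -1L, prev = -1L, next_ = -1L,
                           pdbResidueId = -1L, altPositions = list()) {
  base <- as.character(base)
  stopifnot(base %in% c("A", "C", "G", "T", "U", "N"))
  nt <- list(id = .int1(id), base = base, pair = .int1(pair),
             prev = .int1(prev), pdbResidueId = .int1(pdbResidueId),
             altPositions = altPositions)
  nt[["next"]] <- .int1(next_)
  # keep canonical key order: id, base, pair, prev, next, pdbResidueId, altPositions
  nt[c("id", "base", "pair", "prev", "next", "pdbResidueId", "altPositions")]
}

#' Construct a coarse-grained nucleotide reference frame
#'
#' A nucleotide's spatial state is four vectors: the backbone and
#' nucleobase centers plus two unit vectors, the base-plane normal (the
#' stacking direction, oxDNA's \code{a3}) and the hydrogen-face direction
#' (toward the Watson-Crick edge, oxDNA's \code{a1}). The two unit vectors
#' must be orthonormal.
#'
#' @param backboneCenter,nucleobaseCenter 3-vectors in document length units.
#' @param baseNormal,hydrogenFaceDir Unit 3-vectors, mutually orthogonal.
#' @return A named list with the four vectors.
#' @export
unf_frame <- function(backboneCenter, nucleobaseCenter, baseNormal, hydrogenFaceDir) {
  list(backboneCenter = .num3(backboneCenter),
       nucleobaseCenter = .num3(nucleobaseCenter),
       baseNormal = .num3(baseNormal),
       hydrogenFaceDir = .num3(hydrogenFaceDir))
}

#' @rdname unf_objects
#' @export
unf_aa_chain <- function(id, chainName = "", color = "#FFFFFF",
                         nTermId = -1L, cTermId = -1L, pdbFileId = -1L,
                         aminoAcids = list()) {
  list(id = .int1(id), chainName = as.character(chainName),
       color = as.character(color), nTermId = .int1(nTermId),
       cTermId = .int1(cTermId), pdbFileId = .int1(pdbFileId),
       aminoAcids = aminoAcids)
}

#' @rdname unf_objects
#' @export
unf_amino_acid <- function(id, code = "X", prev = -1L, next_ = -1L,
                           pdbResidueId = -1L, position = c(0, 0, 0)) {
  aa <- list(id = .int1(id), code = as.character(code), prev = .int1(prev),
             pdbResidueId = .int1(pdbResidueId), position = .num3(position))
  aa[["next"]] <- .int1(next_)
  aa[c("id", "code", "prev", "next", "pdbResidueId", "position")]
}

#' Domain-object constructors
#'
#' Low-level constructors for every UNF domain type. Each returns a plain
#' named list with canonical field names and coerced field types; documents
#' assembled from them serialize to the canonical JSON layout shipped in
#' \code{inst/schema/unf-schema.json}.
#'
#' @param id,row,col,index,designNumber,pair,prev,next_,pdbResidueId,fivePrimeId,threePrimeId,nTermId,cTermId,pdbFileId Integer IDs (\code{-1} = none).
#' @param name,chainName,color,base,code,type,naType,path,interaction,content Text fields.
#' @param position,orientation 3-vectors.
#' @param initialAngle Helical phase angle at cell index 0, in document angular units.
#' @param isScaffold,isIncluded Logical flags.
#' @param virtualHelices,cells,fiveToThreeNts,threeToFiveNts,naStrands,aaChains,nucleotides,aminoAcids,altPositions,includedObjects,location,atoms,bonds Child collections.
#' @param hash 32-character lowercase hex MD5 digest.
#' @param objectId ID of the object a comment refers to.
#' @name unf_objects
NULL

#' @rdname unf_objects
#' @export
unf_external_file <- function(id, path = "", type = "", isIncluded = FALSE,
                              hash = "") {
  list(id = .int1(id), path = as.character(path), type = as.character(type),
       isIncluded = isTRUE(isIncluded), hash = as.character(hash))
}

#' @rdname unf_objects
#' @export
unf_ligand <- function(id, name = "", atoms = list(), bonds = list()) {
  list(id = .int1(id), name = as.character(name), atoms = atoms, bonds = bonds)
}

#' @rdname unf_objects
#' @export
unf_group <- function(id, name = "", includedObjects = integer()) {
  list(id = .int1(id), name = as.character(name),
       includedObjects = as.integer(includedObjects))
}

#' @rdname unf_objects
#' @export
unf_connection <- function(id, includedObjects = integer(), interaction = "") {
  list(id = .int1(id), includedObjects = as.integer(includedObjects),
       interaction = as.character(interaction))
}

#' @rdname unf_objects
#' @export
unf_comment <- function(id, objectId = -1L, content = "") {
  list(id = .int1(id), objectId = .int1(objectId),
       content = as.character(content))
}

#' @rdname unf_objects
#' @export
unf_modification <- function(location = integer(), code = "") {
  list(location = as.integer(location), code = as.character(code))
}

# ---- ID registry ----------------------------------------------------------

# Walk every identifiable object in the document, calling fn(id, kind, obj).
.unf_walk <- function(doc, fn) {
  for (ef in doc$externalFiles) fn(ef$id, "externalFile", ef)
  for (lat in doc$lattices) {
    fn(lat$id, "lattice", lat)
    for (vh in lat$virtualHelices) {
      fn(vh$id, "virtualHelix", vh)
      for (cell in vh$cells) fn(cell$id, "cell", cell)
    }
  }
  for (st in doc$structures) {
    fn(st$id, "structure", st)
    for (s in st$naStrands) {
      fn(s$id, "naStrand", s)
      for (nt in s$nucleotides) fn(nt$id, "nucleotide", nt)
    }
    for (ch in st$aaChains) {
      fn(ch$id, "aaChain", ch)
      for (aa in ch$aminoAcids) fn(aa$id, "aminoAcid", aa)
    }
  }
  for (lg in doc$molecules$ligands) fn(lg$id, "ligand", lg)
  for (ns in doc$molecules$nanostructures) fn(ns$id, "nanostructure", ns)
  for (ot in doc$molecules$others) fn(ot$id, "other", ot)
  for (g in doc$groups) fn(g$id, "group", g)
  for (cn in doc$connections) fn(cn$id, "connection", cn)
  for (cm in doc$comments) fn(cm$id, "comment", cm)
  invisible(NULL)
}

#' Build the document-wide ID index
#'
#' @param doc A \code{unf_document}.
#' @return An environment mapping \code{as.character(id)} to
#'   \code{list(kind, obj)}, with attribute \code{"duplicates"} listing IDs
#'   seen more than once.
#' @keywords internal
unf_index <- function(doc) {
  env <- new.env(parent = emptyenv(), size = 256L)
  dup <- integer()
  .unf_walk(doc, function(id, kind, obj) {
    key <- as.character(id)
    if (!is.null(env[[key]])) dup[[length(dup) + 1L]] <<- id
    env[[key]] <- list(kind = kind, obj = obj)
  })
  attr(env, "duplicates") <- dup
  env
}

#' Resolve an object by ID
#'
#' Looks up the unique object carrying the given document-wide ID.
#'
#' @param doc A \code{unf_document}.
#' @param id A non-negative integer ID. The sentinel \code{-1} is not
#'   resolvable and raises an error.
#' @param index Optional prebuilt index from [unf_index()].
#' @return \code{list(kind, obj)} where \code{kind} tags the object type.
#' @export
unf_resolve <- function(doc, id, index = NULL) {
  id <- .int1(id)
  if (id < 0L) stop("ID ", id, " is a sentinel and cannot be resolved")
  if (is.null(index)) index <- unf_index(doc)
  if (id %in% attr(index, "duplicates"))
    stop("duplicate ID ", id, ": document is corrupt")
  hit <- index[[as.character(id)]]
  if (is.null(hit)) stop("unknown ID ", id)
  hit
}

# ---- topology traversal ---------------------------------------------------

# Walk a linked chain id -> next over a set of member objects.
# Returns the visiting order or stops with a topology error.
.walk_chain <- function(members, startId, endId, nextField, what) {
  byId <- new.env(parent = emptyenv())
  for (m in members) byId[[as.character(m$id)]] <- m
  n <- length(members)
  if (n == 0L) {
    if (startId != -1L || endId != -1L)
      stop(what, ": empty chain with non-sentinel termini")
    return(list())
  }
  out <- vector("list", n)
  seen <- new.env(parent = emptyenv())
  cur <- startId
  for (k in seq_len(n)) {
    key <- as.character(cur)
    if (cur == -1L) stop(what, ": chain ends before visiting all members")
    m <- byId[[key]]
    if (is.null(m)) stop(what, ": chain points at ID ", cur, " outside the chain")
    if (!is.null(seen[[key]])) stop(what, ": chain revisits ID ", cur)
    seen[[key]] <- TRUE
    out[[k]] <- m
    cur <- m[[nextField]]
  }
  if (cur != -1L) stop(what, ": chain continues past its last member (ID ", cur, ")")
  if (out[[n]]$id != endId)
    stop(what, ": chain ends at ID ", out[[n]]$id, ", expected ", endId)
  out
}

#' Strand sequence in 5' to 3' order
#'
#' Walks the strand's next-pointers from the 5' end and concatenates base
#' letters. A broken chain (cycle, dead end, or an end that is not the
#' recorded 3' terminus) raises a topology error.
#'
#' @param doc A \code{unf_document} (only needed for the signature symmetry;
#'   the walk itself is local to the strand).
#' @param strand A \code{naStrands} entry.
#' @return A single string, one letter per nucleotide.
#' @export
unf_strand_sequence <- function(doc, strand) {
  nts <- .walk_chain(strand$nucleotides, strand$fivePrimeId,
                     strand$threePrimeId, "next",
                     paste0("strand ", strand$id))
  paste(vapply(nts, function(nt) nt$base, character(1)), collapse = "")
}

# Nucleotides of a strand ordered 5' -> 3'.
.strand_order <- function(strand) {
  .walk_chain(strand$nucleotides, strand$fivePrimeId, strand$threePrimeId,
              "next", paste0("strand ", strand$id))
}

# ---- validator ------------------------------------------------------------

.finding <- function(severity, objectId, message) {
  data.frame(severity = severity, objectId = as.integer(objectId),
             message = message, stringsAsFactors = FALSE)
}

.no_findings <- function() {
  data.frame(severity = character(), objectId = integer(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a UNF document
#'
#' Checks every structural invariant of the data model: ID uniqueness and
#' resolvability of all references, symmetric base pairing, mutual prev/next
#' consistency, strand and chain walkability, cell-array length rules
#' (deletion cells reference nothing; normal cells at most one nucleotide
#' per direction; insertion cells at least two), lattice typing, (row, col)
#' uniqueness, and orthonormality of explicit nucleotide frames.
#'
#' Problems are reported, not thrown: the result is a data frame with one
#' row per finding (\code{severity}, \code{objectId}, \code{message}). A
#' valid document yields zero rows.
#'
#' @param doc A \code{unf_document}.
#' @return A data frame of findings; zero rows when the document is valid.
#' @export
unf_validate <- function(doc) {
  out <- list(.no_findings())
  add <- function(severity, objectId, message)
    out[[length(out) + 1L]] <<- .finding(severity, objectId, message)

  idx <- unf_index(doc)
  for (d in unique(attr(idx, "duplicates")))
    add("error", d, paste0("duplicate id ", d))
  .unf_walk(doc, function(id, kind, obj) {
    if (is.na(id) || id < 0L) add("error", id, paste0("invalid ", kind, " id ", id))
  })

  resolves <- function(id) id == -1L || !is.null(idx[[as.character(id)]])
  check_ref <- function(id, ownerId, what) {
    if (!resolves(id))
      add("error", ownerId, paste0(what, " references unknown id ", id))
  }

  ntKind <- function(id) {
    hit <- idx[[as.character(id)]]
    if (is.null(hit)) NULL else hit$kind
  }

  # header / external files
  for (ef in doc$externalFiles) {
    if (!grepl("^[0-9a-f]{32}$", ef$hash))
      add("error", ef$id, "external file hash is not 32-char lowercase hex MD5")
  }

  # lattices
  for (lat in doc$lattices) {
    if (!lat$type %in% c("square", "honeycomb"))
      add("error", lat$id, paste0("unknown lattice type '", lat$type, "'"))
    rc <- vapply(lat$virtualHelices, function(vh) paste(vh$row, vh$col), character(1))
    for (r in unique(rc[duplicated(rc)]))
      add("error", lat$id, paste0("duplicate virtual helix position (", r, ")"))
    for (vh in lat$virtualHelices) {
      for (cell in vh$cells) {
        n5 <- length(cell$fiveToThreeNts)
        n3 <- length(cell$threeToFiveNts)
        if (cell$type == "deletion" && (n5 > 0L || n3 > 0L))
          add("error", cell$id, "deletion cell references nucleotides")
        if (cell$type == "normal" && (n5 > 1L || n3 > 1L))
          add("error", cell$id, "normal cell references more than one nucleotide per direction")
        if (cell$type == "insertion" &&
            ((n5 > 0L && n5 < 2L) || (n3 > 0L && n3 < 2L)))
          add("error", cell$id, "insertion cell must reference n+1 >= 2 nucleotides per occupied direction")
        for (ntid in c(cell$fiveToThreeNts, cell$threeToFiveNts)) {
          check_ref(ntid, cell$id, "cell array")
          if (resolves(ntid) && ntid != -1L && !identical(ntKind(ntid), "nucleotide"))
            add("error", cell$id, paste0("cell array id ", ntid, " is not a nucleotide"))
        }
      }
    }
  }

  # structures
  for (st in doc$structures) {
    for (s in st$naStrands) {
      for (nt in s$nucleotides) {
        for (f in c("pair", "prev", "next")) check_ref(nt[[f]], nt$id, f)
        if (nt$pair != -1L) {
          mate <- idx[[as.character(nt$pair)]]
          if (!is.null(mate) && identical(mate$kind, "nucleotide") &&
              mate$obj$pair != nt$id)
            add("error", nt$id,
                paste0("asymmetric pairing: ", nt$id, ".pair=", nt$pair,
                       " but ", nt$pair, ".pair=", mate$obj$pair))
        }
        if (nt[["next"]] != -1L) {
          nx <- idx[[as.character(nt[["next"]])]]
          if (!is.null(nx) && identical(nx$kind, "nucleotide") &&
              nx$obj$prev != nt$id)
            add("error", nt$id,
                paste0("prev/next inconsistency between ", nt$id, " and ", nt[["next"]]))
        }
        for (fr in nt$altPositions) {
          n1 <- sqrt(sum(fr$baseNormal^2))
          n2 <- sqrt(sum(fr$hydrogenFaceDir^2))
          dp <- sum(fr$baseNormal * fr$hydrogenFaceDir)
          if (abs(n1 - 1) > 1e-6 || abs(n2 - 1) > 1e-6)
            add("error", nt$id, "frame vectors are not unit length")
          else if (abs(dp) > 1e-6)
            add("error", nt$id, "frame baseNormal and hydrogenFaceDir are not orthogonal")
        }
      }
      seqres <- tryCatch({ .strand_order(s); NULL }, error = function(e) conditionMessage(e))
      if (!is.null(seqres)) add("error", s$id, seqres)
      check_ref(s$pdbFileId, s$id, "pdbFileId")
    }
    for (ch in st$aaChains) {
      for (aa in ch$aminoAcids)
        for (f in c("prev", "next")) check_ref(aa[[f]], aa$id, f)
      walkres <- tryCatch({
        .walk_chain(ch$aminoAcids, ch$nTermId, ch$cTermId, "next",
                    paste0("chain ", ch$id))
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(walkres)) add("error", ch$id, walkres)
    }
  }

  # annotations
  for (g in doc$groups)
    for (oid in g$includedObjects) check_ref(oid, g$id, "group")
  for (cn in doc$connections)
    for (oid in cn$includedObjects) check_ref(oid, cn$id, "connection")
  for (cm in doc$comments) check_ref(cm$objectId, cm$id, "comment")
  for (md in doc$modifications)
    for (oid in md$location) check_ref(oid, -1L, "modification")

  do.call(rbind, out)
}

#' @export
print.unf_document <- function(x, ...) {
  nNt <- 0L; nAa <- 0L
  for (st in x$structures) {
    for (s in st$naStrands) nNt <- nNt + length(s$nucleotides)
    for (ch in st$aaChains) nAa <- nAa + length(ch$aminoAcids)
  }
  cat("UNF document '", x$name, "' (format version ", x$version, ")\n", sep = "")
  cat("  lattices:   ", length(x$lattices), "\n", sep = "")
  cat("  structures: ", length(x$structures),
      " (", nNt, " nucleotides, ", nAa, " amino acids)\n", sep = "")
  cat("  external files: ", length(x$externalFiles), "\n", sep = "")
  invisible(x)
}
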