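# Canonical JSON layout for the UNF document body. Scalars are unboxed
# explicitly so 3-vectors and ID lists always serialize as JSON arrays;
# the field order matches inst/schema/unf-schema.json.

.ub <- jsonlite::unbox

.json_frame <- function(fr) {
  list(backboneCenter = fr$backboneCenter,
       nucleobaseCenter = fr$nucleobaseCenter,
       baseNormal = fr$baseNormal,
       hydrogenFaceDir = fr$hydrogenFaceDir)
}

.json_nucleotide <- function(nt) {
  list(id = .ub(nt$id), base = .ub(nt$base), pair = .ub(nt$pair),
       prev = .ub(nt$prev), "next" = .ub(nt[["next"]]),
       pdbResidueId = .ub(nt$pdbResidueId),
       altPositions = lapply(nt$altPositions, .json_frame))
}

.json_strand <- function(s) {
  list(id = .ub(s$id), name = .ub(s$name), naType = .ub(s$naType),
       isScaffold = .ub(s$isScaffold), color = .ub(s$color),
       fivePrimeId = .ub(s$fivePrimeId), threePrimeId = .ub(s$threePrimeId),
       chainName = .ub(s$chainName), pdbFileId = .ub(s$pdbFileId),
       nucleotides = lapply(s$nucleotides, .json_nucleotide))
}

.json_amino <- function(aa) {
  list(id = .ub(aa$id), code = .ub(aa$code), prev = .ub(aa$prev),
       "next" = .ub(aa[["next"]]), pdbResidueId = .ub(aa$pdbResidueId),
       position = aa$position)
}

.json_chain <- function(ch) {
  list(id = .ub(ch$id), chainName = .ub(ch$chainName), color = .ub(ch$color),
       nTermId = .ub(ch$nTermId), cTermId = .ub(ch$cTermId),
       pdbFileId = .ub(ch$pdbFileId),
       aminoAcids = lapply(ch$aminoAcids, .json_amino))
}

.json_cell <- function(cell) {
  list(id = .ub(cell$id), index = .ub(cell$index), type = .ub(cell$type),
       fiveToThreeNts = as.integer(cell$fiveToThreeNts),
       threeToFiveNts = as.integer(cell$threeToFiveNts))
}

.json_helix <- function(vh) {
  list(id = .ub(vh$id), row = .ub(vh$row), col = .ub(vh$col),
       designNumber = .ub(vh$designNumber),
       initialAngle = .ub(vh$initialAngle),
       cells = lapply(vh$cells, .json_cell))
}

.json_lattice <- function(lat) {
  list(id = .ub(lat$id), name = .ub(lat$name), type = .ub(lat$type),
       position = lat$position, orientation = lat$orientation,
       virtualHelices = lapply(lat$virtualHelices, .json_helix))
}

.json_structure <- function(st) {
  list(id = .ub(st$id), name = .ub(st$name),
       naStrands = lapply(st$naStrands, .json_strand),
       aaChains = lapply(st$aaChains, .json_chain))
}

.json_ligand <- function(lg) {
  list(id = .ub(lg$id), name = .ub(lg$name),
       atoms = lapply(lg$atoms, function(a)
         list(element = .ub(a$element), name = .ub(a$name),
              position = a$position)),
       bonds = lapply(lg$bonds, as.integer))
}

.json_placed_ref <- function(x) {
  list(id = .ub(x$id), name = .ub(x$name),
       externalFileId = .ub(x$externalFileId),
       position = x$position, orientation = x$orientation)
}

.unf_body_list <- function(doc) {
  body <- list(
    format = .ub(doc$format), version = .ub(doc$version),
    lengthUnits = .ub(doc$lengthUnits), angularUnits = .ub(doc$angularUnits),
    name = .ub(doc$name), author = .ub(doc$author),
    creationDate = .ub(doc$creationDate), doi = .ub(doc$doi),
    externalFiles = lapply(doc$externalFiles, function(ef)
      list(id = .ub(ef$id), path = .ub(ef$path), type = .ub(ef$type),
           isIncluded = .ub(ef$isIncluded), hash = .ub(ef$hash))),
    lattices = lapply(doc$lattices, .json_lattice),
    structures = lapply(doc$structures, .json_structure),
    molecules = list(
      ligands = lapply(doc$molecules$ligands, .json_ligand),
      nanostructures = lapply(doc$molecules$nanostructures, .json_placed_ref),
      others = lapply(doc$molecules$others, .json_placed_ref)),
    groups = lapply(doc$groups, function(g)
      list(id = .ub(g$id), name = .ub(g$name),
           includedObjects = as.integer(g$includedObjects))),
    modifications = lapply(doc$modifications, function(md)
      list(location = as.integer(md$location), code = .ub(md$code))),
    connections = lapply(doc$connections, function(cn)
      list(id = .ub(cn$id), includedObjects = as.integer(cn$includedObjects),
           interaction = .ub(cn$interaction))),
    comments = lapply(doc$comments, function(cm)
      list(id = .ub(cm$id), objectId = .ub(cm$objectId),
           content = .ub(cm$content))),
    misc = doc$misc
  )
  if (!is.null(doc$simulationBox))
    body <- append(body, list(simulationBox = doc$simulationBox),
                   after = which(names(body) == "comments"))
  body
}

#' Serialize a document to its JSON body
#'
#' @param doc A \code{unf_document}.
#' @return A single JSON string, 2-space indented, keys in schema order.
#' @keywords internal
unf_to_json <- function(doc) {
  as.character(jsonlite::toJSON(.unf_body_list(doc), auto_unbox = FALSE,
                                digits = NA, null = "null", pretty = 2))
}

# ---- parsing --------------------------------------------------------------

.p_int <- function(x, default = -1L) if (is.null(x)) default else as.integer(x)
.p_ints <- function(x) as.integer(unlist(x, use.names = FALSE))
.p_num3 <- function(x, default = c(0, 0, 0)) {
  if (is.null(x)) return(as.double(default))
  .num3(x)
}
.p_chr <- function(x, default = "") if (is.null(x)) default else as.character(x)

.parse_frame <- function(x)
  unf_frame(.p_num3(x$backboneCenter), .p_num3(x$nucleobaseCenter),
            .p_num3(x$baseNormal), .p_num3(x$hydrogenFaceDir))

.parse_nucleotide <- function(x)
  unf_nucleotide(.p_int(x$id), .p_chr(x$base, "N"), .p_int(x$pair),
                 .p_int(x$prev), .p_int(x[["next"]]), .p_int(x$pdbResidueId),
                 lapply(x$altPositions, .parse_frame))

.parse_strand <- function(x)
  unf_na_strand(.p_int(x$id), .p_chr(x$name), .p_chr(x$naType, "DNA"),
                isTRUE(x$isScaffold), .p_chr(x$color, "#FFFFFF"),
                .p_int(x$fivePrimeId), .p_int(x$threePrimeId),
                .p_chr(x$chainName), .p_int(x$pdbFileId),
                lapply(x$nucleotides, .parse_nucleotide))

.parse_chain <- function(x)
  unf_aa_chain(.p_int(x$id), .p_chr(x$chainName), .p_chr(x$color, "#FFFFFF"),
               .p_int(x$nTermId), .p_int(x$cTermId), .p_int(x$pdbFileId),
               lapply(x$aminoAcids, function(a)
                 unf_amino_acid(.p_int(a$id), .p_chr(a$code, "X"),
                                .p_int(a$prev), .p_int(a[["next"]]),
                                .p_int(a$pdbResidueId), .p_num3(a$position))))

.parse_lattice <- function(x)
  unf_lattice(.p_int(x$id), .p_chr(x$name), .p_chr(x$type, "square"),
              .p_num3(x$position), .p_num3(x$orientation),
              lapply(x$virtualHelices, function(vh)
                unf_virtual_helix(.p_int(vh$id), .p_int(vh$row), .p_int(vh$col),
                                  .p_int(vh$designNumber),
                                  as.double(.p_chr(vh$initialAngle, "0")),
                                  lapply(vh$cells, function(cl)
                                    unf_cell(.p_int(cl$id), .p_int(cl$index),
                                             .p_chr(cl$type, "normal"),
                                             .p_ints(cl$fiveToThreeNts),
                                             .p_ints(cl$threeToFiveNts))))))

.parse_placed_ref <- function(x)
  list(id = .p_int(x$id), name = .p_chr(x$name),
       externalFileId = .p_int(x$externalFileId),
       position = .p_num3(x$position), orientation = .p_num3(x$orientation))

#' Parse a JSON body into a document
#'
#' Reconstructs a typed \code{unf_document} from the canonical JSON layout.
#' Version handling: a different major version is an error, a different
#' minor version a warning.
#'
#' @param jsonText The JSON body as a single string.
#' @return A \code{unf_document}.
#' @keywords internal
unf_from_json <- function(jsonText) {
  x <- jsonlite::fromJSON(jsonText, simplifyVector = FALSE)
  ver <- .p_chr(x$version, UNF_VERSION)
  own <- strsplit(UNF_VERSION, ".", fixed = TRUE)[[1L]]
  got <- strsplit(ver, ".", fixed = TRUE)[[1L]]
  if (got[1L] != own[1L])
    stop("unsupported UNF major version ", ver, " (this reader implements ",
         UNF_VERSION, ")")
  if (length(got) > 1L && length(own) > 1L && got[2L] != own[2L])
    warning("UNF minor version mismatch: file is ", ver, ", reader is ",
            UNF_VERSION)

  doc <- unf_document(.p_chr(x$name), .p_chr(x$author), .p_chr(x$doi))
  doc$version <- ver
  doc$lengthUnits <- .p_chr(x$lengthUnits, "A")
  doc$angularUnits <- .p_chr(x$angularUnits, "deg")
  doc$creationDate <- .p_chr(x$creationDate)
  doc$externalFiles <- lapply(x$externalFiles, function(ef)
    unf_external_file(.p_int(ef$id), .p_chr(ef$path), .p_chr(ef$type),
                      isTRUE(ef$isIncluded), .p_chr(ef$hash)))
  doc$lattices <- lapply(x$lattices, .parse_lattice)
  doc$structures <- lapply(x$structures, function(st)
    unf_structure(.p_int(st$id), .p_chr(st$name),
                  lapply(st$naStrands, .parse_strand),
                  lapply(st$aaChains, .parse_chain)))
  doc$molecules <- list(
    ligands = lapply(x$molecules$ligands, function(lg)
      unf_ligand(.p_int(lg$id), .p_chr(lg$name),
                 lapply(lg$atoms, function(a)
                   list(element = .p_chr(a$element), name = .p_chr(a$name),
                        position = .p_num3(a$position))),
                 lapply(lg$bonds, .p_ints))),
    nanostructures = lapply(x$molecules$nanostructures, .parse_placed_ref),
    others = lapply(x$molecules$others, .parse_placed_ref))
  doc$groups <- lapply(x$groups, function(g)
    unf_group(.p_int(g$id), .p_chr(g$name), .p_ints(g$includedObjects)))
  doc$modifications <- lapply(x$modifications, function(md)
    unf_modification(.p_ints(md$location), .p_chr(md$code)))
  doc$connections <- lapply(x$connections, function(cn)
    unf_connection(.p_int(cn$id), .p_ints(cn$includedObjects),
                   .p_chr(cn$interaction)))
  doc$comments <- lapply(x$comments, function(cm)
    unf_comment(.p_int(cm$id), .p_int(cm$objectId), .p_chr(cm$content)))
  if (!is.null(x$simulationBox)) doc$simulationBox <- .num3(x$simulationBox)
  doc$misc <- if (is.null(x$misc)) list() else x$misc

  maxId <- -1L
  .unf_walk(doc, function(id, kind, obj) {
    if (!is.na(id) && id > maxId) maxId <<- id
  })
  doc$idCounter <- maxId + 1L
  doc
}
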