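# oxDNA bridge: classic topology + configuration text files, and the map
# between oxDNA's single center-of-mass-plus-versors nucleotide and UNF's
# split backbone/base representation.
#
# Fixed constants of this bridge (oxDNA model, first generation): one
# simulation length unit is 8.518 Angstrom; the base interaction site sits
# +0.4 su along a1 from the center of mass and the backbone site -0.4 su.

OXDNA_SU_TO_ANGSTROM <- 8.518
OXDNA_BASE_OFFSET_SU <- 0.4

su_to_angstrom <- function(x) x * OXDNA_SU_TO_ANGSTROM
angstrom_to_su <- function(x) x / OXDNA_SU_TO_ANGSTROM

#' Read an oxDNA topology + configuration pair
#'
#' Classic dialect only: topology header \code{"N Ns"} followed by one
#' line per nucleotide \code{"strand base n3 n5"} with nucleotides listed
#' in 3' to 5' strand order; configuration header lines \code{t}, \code{b},
#' \code{E} followed by one row of at least 9 columns (center of mass, a1,
#' a3, then optional velocity and angular velocity) per nucleotide. The
#' newer 5' to 3' topology dialect is rejected. Orientation vectors off
#' unit length by more than 1e-3 trigger a warning and are renormalized.
#'
#' @param topology Path to, or the text of, the topology file.
#' @param configuration Path to, or the text of, the configuration file.
#' @return An \code{ox_system}: \code{list(nNucleotides, nStrands, box,
#'   time, energies, perNucleotide)} where \code{perNucleotide} is a data
#'   frame with columns \code{strandId}, \code{base}, \code{n3}, \code{n5}
#'   and matrix columns \code{com}, \code{a1}, \code{a3}, \code{velocity},
#'   \code{angularVelocity} (simulation units).
#' @export
read_oxdna <- function(topology, configuration) {
  topLines <- .text_lines(topology)
  confLines <- .text_lines(configuration)

  if (grepl("5\\s*->\\s*3", topLines[1L]) ||
      any(grepl("type=", topLines, fixed = TRUE)))
    stop("topology is in the new 5'->3' dialect; only the classic ",
         "3'->5' dialect is supported")
  hdr <- scan(text = topLines[1L], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L)
    stop("malformed topology header: ", topLines[1L])
  nNuc <- hdr[1L]; nStr <- hdr[2L]
  body <- topLines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nNuc)
    stop("topology declares ", nNuc, " nucleotides but has ",
         length(body), " rows")
  tok <- strsplit(trimws(body), "\\s+")
  strandId <- vapply(tok, function(t) as.integer(t[1L]), integer(1))
  base <- vapply(tok, function(t) t[2L], character(1))
  n3 <- vapply(tok, function(t) as.integer(t[3L]), integer(1))
  n5 <- vapply(tok, function(t) as.integer(t[4L]), integer(1))
  if (length(unique(strandId)) != nStr)
    stop("topology declares ", nStr, " strands but rows name ",
         length(unique(strandId)))

  confLines <- confLines[nzchar(trimws(confLines))]
  if (length(confLines) < 3L) stop("configuration file too short")
  parseHeader <- function(line) {
    as.double(scan(text = sub("^[A-Za-z]+\\s*=", "", line), what = double(),
                   quiet = TRUE))
  }
  timeVal <- parseHeader(confLines[1L])[1L]
  box <- parseHeader(confLines[2L])
  energies <- parseHeader(confLines[3L])
  rows <- confLines[-(1:3)]
  if (length(rows) != nNuc)
    stop("configuration has ", length(rows), " rows but topology declares ",
         nNuc, " nucleotides")
  M <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.double))
  if (ncol(M) < 9L)
    stop("configuration rows must have at least 9 columns, got ", ncol(M))
  com <- M[, 1:3, drop = FALSE]
  a1 <- M[, 4:6, drop = FALSE]
  a3 <- M[, 7:9, drop = FALSE]
  vel <- if (ncol(M) >= 15L) M[, 10:12, drop = FALSE] else matrix(0, nNuc, 3L)
  ang <- if (ncol(M) >= 15L) M[, 13:15, drop = FALSE] else matrix(0, nNuc, 3L)

  renorm <- function(V, what) {
    len <- sqrt(rowSums(V^2))
    if (any(abs(len - 1) > 1e-3)) {
      warning("non-unit ", what, " vectors renormalized (max deviation ",
              format(max(abs(len - 1)), digits = 3), ")")
    }
    V / len
  }
  a1 <- renorm(a1, "a1")
  a3 <- renorm(a3, "a3")

  sys <- list(nNucleotides = nNuc, nStrands = nStr, box = box,
              time = timeVal, energies = energies,
              perNucleotide = list(strandId = strandId, base = base,
                                   n3 = n3, n5 = n5, com = com, a1 = a1,
                                   a3 = a3, velocity = vel,
                                   angularVelocity = ang))
  class(sys) <- "ox_system"
  sys
}

.text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    readLines(x, warn = FALSE)
  else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Convert an oxDNA system to a UNF document
#'
#' Strands are rebuilt from the n3/n5 links and stored in UNF's 5' to 3'
#' order. Each nucleotide gets an explicit position record with
#' \code{nucleobaseCenter = (com + 0.4 a1) * 8.518} A,
#' \code{backboneCenter = (com - 0.4 a1) * 8.518} A,
#' \code{hydrogenFaceDir = a1} and \code{baseNormal = a3}. The simulation
#' box is converted to Angstrom.
#'
#' @param sys An \code{ox_system} from [read_oxdna()].
#' @param doc Optional document to extend.
#' @param rna Label strands RNA instead of DNA.
#' @return A \code{unf_document}.
#' @export
oxdna_to_unf <- function(sys, doc = NULL, rna = FALSE) {
  if (is.null(doc)) doc <- unf_document(name = "oxDNA import")
  pn <- sys$perNucleotide
  nextId <- doc$idCounter
  newId <- function() { id <- nextId; nextId <<- nextId + 1L; id }

  strands <- list()
  for (sid in unique(pn$strandId)) {
    rows <- which(pn$strandId == sid)
    # find the 5' terminus of this strand (row whose n5 is -1)
    fivePrimeRow <- rows[pn$n5[rows] == -1L]
    if (length(fivePrimeRow) != 1L)
      stop("strand ", sid, " has ", length(fivePrimeRow),
           " 5' termini; broken or circular n3/n5 chain")
    order53 <- integer(length(rows))
    cur <- fivePrimeRow
    for (q in seq_along(rows)) {
      if (length(cur) != 1L || is.na(cur) || cur < 1L)
        stop("strand ", sid, ": broken n3/n5 chain")
      order53[q] <- cur
      nxt <- pn$n3[cur]       # toward the 3' end
      cur <- if (nxt == -1L) NA_integer_ else nxt + 1L
    }
    if (!is.na(cur)) stop("strand ", sid, ": n3/n5 chain longer than strand")

    ids <- vapply(order53, function(.) newId(), integer(1))
    nts <- vector("list", length(order53))
    for (q in seq_along(order53)) {
      r <- order53[q]
      base <- toupper(pn$base[r])
      if (!base %in% c("A", "C", "G", "T", "U", "N")) base <- "N"
      fr <- unf_frame(
        backboneCenter = su_to_angstrom(pn$com[r, ] -
                                          OXDNA_BASE_OFFSET_SU * pn$a1[r, ]),
        nucleobaseCenter = su_to_angstrom(pn$com[r, ] +
                                            OXDNA_BASE_OFFSET_SU * pn$a1[r, ]),
        baseNormal = pn$a3[r, ], hydrogenFaceDir = pn$a1[r, ])
      nts[[q]] <- unf_nucleotide(
        ids[q], base = base,
        prev = if (q > 1L) ids[q - 1L] else -1L,
        next_ = if (q < length(order53)) ids[q + 1L] else -1L,
        altPositions = list(fr))
    }
    strands[[length(strands) + 1L]] <-
      unf_na_strand(newId(), name = paste0("strand ", sid),
                    naType = if (rna) "RNA" else "DNA",
                    fivePrimeId = ids[1L], threePrimeId = ids[length(ids)],
                    nucleotides = nts)
  }
  st <- unf_structure(newId(), name = "oxDNA import", naStrands = strands)
  doc$structures[[length(doc$structures) + 1L]] <- st
  doc$simulationBox <- su_to_angstrom(sys$box)
  doc$idCounter <- nextId
  doc
}

#' Export a UNF document to oxDNA topology + configuration
#'
#' Every nucleotide must be placeable (explicit position record, or a
#' lattice cell resolved through [resolve_nucleotide_position()]). The
#' center of mass is recovered as \code{nucleobaseCenter/8.518 - 0.4 a1},
#' the exact inverse of the import map; a warning is logged when a stored
#' backbone center deviates more than 0.5 A from the site implied by that
#' relation. Strands are listed 3' to 5' (classic dialect); base \code{"N"}
#' is emitted as \code{"T"} with a warning; protein chains are skipped with
#' a warning. The box is the document's simulation box or the coordinate
#' bounding box plus 20 su padding.
#'
#' @param doc A \code{unf_document}.
#' @param params Geometry for lattice-implied placement.
#' @return \code{list(topology, configuration)}, each a single string.
#' @export
unf_to_oxdna <- function(doc, params = geometry_params()) {
  strands <- list()
  nAa <- 0L
  for (st in doc$structures) {
    for (s in st$naStrands) strands[[length(strands) + 1L]] <- s
    nAa <- nAa + length(st$aaChains)
  }
  if (nAa > 0L)
    warning(nAa, " protein chain(s) skipped: the classic oxDNA format ",
            "has no protein record")
  if (length(strands) == 0L) stop("document contains no nucleic acid strands")

  topRows <- character(0)
  confRows <- character(0)
  nNuc <- 0L
  allCom <- list()
  nWarned <- 0L

  fmt <- function(x) sprintf("%.10g", x)
  for (k in seq_along(strands)) {
    s <- strands[[k]]
    nts <- .strand_order(s)
    n <- length(nts)
    # classic listing: 3' -> 5'
    nts <- rev(nts)
    for (q in seq_len(n)) {
      nt <- nts[[q]]
      fr <- resolve_nucleotide_position(doc, nt$id, params)
      a1 <- fr$hydrogenFaceDir
      a3 <- fr$baseNormal
      com <- angstrom_to_su(fr$nucleobaseCenter) - OXDNA_BASE_OFFSET_SU * a1
      implBb <- su_to_angstrom(com - OXDNA_BASE_OFFSET_SU * a1)
      if (sqrt(sum((implBb - fr$backboneCenter)^2)) > 0.5)
        nWarned <- nWarned + 1L
      base <- nt$base
      if (base == "N") base <- "T"
      gi <- nNuc + q - 1L
      n3 <- if (q > 1L) gi - 1L else -1L
      n5 <- if (q < n) gi + 1L else -1L
      topRows <- c(topRows, paste(k, base, n3, n5))
      confRows <- c(confRows,
                    paste(c(fmt(com), fmt(a1), fmt(a3),
                            "0 0 0 0 0 0"), collapse = " "))
      allCom[[length(allCom) + 1L]] <- com
    }
    nNuc <- nNuc + n
  }
  if (any(vapply(strands, function(s)
    any(vapply(s$nucleotides, function(nt) nt$base == "N", logical(1))),
    logical(1))))
    warning("base 'N' emitted as 'T'")
  if (nWarned > 0L)
    warning(nWarned, " nucleotide(s) whose stored backbone center deviates ",
            "> 0.5 A from the site implied by the base-center relation")

  box <- if (!is.null(doc$simulationBox)) angstrom_to_su(doc$simulationBox)
  else {
    C <- do.call(rbind, allCom)
    apply(C, 2L, function(v) diff(range(v))) + 20
  }
  topology <- paste0(paste(nNuc, length(strands)), "\n",
                     paste(topRows, collapse = "\n"), "\n")
  configuration <- paste0("t = 0\n",
                          "b = ", paste(fmt(box), collapse = " "), "\n",
                          "E = 0 0 0\n",
                          paste(confRows, collapse = "\n"), "\n")
  list(topology = topology, configuration = configuration)
}
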