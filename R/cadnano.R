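# Cadnano bridge: reads/writes the cadnano2 "vstrands" JSON dialect,
# reconstructs strand routing from the per-cell neighbor tuples, and
# converts designs to and from UNF documents.
#
# Routing model: each occupied cell of a helix carries a 4-tuple
# [h5, i5, h3, i3] naming the 5'-side and 3'-side neighbor cells (-1
# sentinels at strand ends). Scaffold and staple routing are stored in
# separate arrays; loops (insertions) and skips (deletions) are per-cell
# integer annotations shared by both strands crossing the cell.

CADNANO_SCAFFOLD_COLOR <- "#0066CC"
CIRCULAR_CLOSURE_TAG <- "circular strand closure"

.tuple_mat <- function(x, n) {
  if (length(x) == 0L) return(matrix(-1L, n, 4L))
  m <- do.call(rbind, lapply(x, function(t) as.integer(unlist(t))))
  stopifnot(ncol(m) == 4L)
  m
}

#' Read a Cadnano design file
#'
#' @param x Path to a cadnano2 JSON file, or the JSON text itself.
#' @return A \code{cadnano_design}: \code{list(name, vstrands)} where each
#'   vstrand holds \code{num}, \code{row}, \code{col}, integer matrices
#'   \code{scaf}/\code{stap} (one [h5,i5,h3,i3] row per cell), integer
#'   vectors \code{skip} (0 or -1) and \code{loop} (>= 0), and
#'   \code{stap_colors} (list of \code{c(baseIndex, colorInt)}).
#' @export
read_cadnano <- function(x) {
  txt <- if (length(x) == 1L && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "\n") else paste(x, collapse = "\n")
  j <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  vstrands <- lapply(j$vstrands, function(v) {
    n <- max(length(v$scaf), length(v$stap))
    list(num = .p_int(v$num), row = .p_int(v$row), col = .p_int(v$col),
         scaf = .tuple_mat(v$scaf, n), stap = .tuple_mat(v$stap, n),
         skip = if (is.null(v$skip)) integer(n) else .p_ints(v$skip),
         loop = if (is.null(v$loop)) integer(n) else .p_ints(v$loop),
         stap_colors = lapply(v$stap_colors, .p_ints))
  })
  design <- list(name = .p_chr(j$name, "design"), vstrands = vstrands)
  class(design) <- "cadnano_design"
  .check_cadnano(design)
  design
}

.check_cadnano <- function(design) {
  for (v in design$vstrands) {
    n <- nrow(v$scaf)
    if (nrow(v$stap) != n || length(v$skip) != n || length(v$loop) != n)
      stop("vstrand ", v$num, ": scaf/stap/skip/loop arrays differ in length")
    if (!all(v$skip %in% c(0L, -1L)))
      stop("vstrand ", v$num, ": skip values must be 0 or -1")
    if (any(v$loop < 0L))
      stop("vstrand ", v$num, ": loop values must be non-negative")
  }
  invisible(design)
}

#' Write a Cadnano design file
#'
#' @param design A \code{cadnano_design}.
#' @param path Optional output path.
#' @return The JSON text (invisibly when \code{path} is given).
#' @export
write_cadnano <- function(design, path = NULL) {
  body <- list(
    name = .ub(design$name),
    vstrands = lapply(design$vstrands, function(v)
      list(row = .ub(v$row), col = .ub(v$col), num = .ub(v$num),
           scaf = v$scaf, stap = v$stap,
           loop = as.integer(v$loop), skip = as.integer(v$skip),
           scafLoop = list(), stapLoop = list(),
           stap_colors = lapply(v$stap_colors, as.integer))))
  txt <- as.character(jsonlite::toJSON(body, auto_unbox = FALSE, digits = NA))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# ---- routing reconstruction ----------------------------------------------

.vs_by_num <- function(design) {
  env <- new.env(parent = emptyenv())
  for (k in seq_along(design$vstrands))
    env[[as.character(design$vstrands[[k]]$num)]] <- k
  env
}

.tuple_at <- function(design, byNum, kind, h, i) {
  k <- byNum[[as.character(h)]]
  if (is.null(k)) return(NULL)
  v <- design$vstrands[[k]]
  if (i < 0L || i >= nrow(v$scaf)) return(NULL)
  v[[kind]][i + 1L, ]
}

.occupied <- function(tuple) !is.null(tuple) && any(tuple != -1L)

#' Trace strand routing through a Cadnano design
#'
#' Reconstructs the routed paths that Cadnano stores only implicitly.
#' Linear paths start at a 5' end (a cell whose tuple has no 5' neighbor)
#' and follow 3' pointers; occupied cells left over after all linear paths
#' are traced form circular paths (flagged \code{isCircular}), each started
#' at its lexicographically smallest (helixNum, baseIndex) cell for
#' determinism.
#'
#' @param design A \code{cadnano_design}.
#' @param kind \code{"scaffold"} or \code{"staple"}.
#' @return List of routed paths: \code{list(kind, cells, isCircular)} with
#'   \code{cells} a two-column integer matrix (helixNum, baseIndex).
#' @export
trace_strands <- function(design, kind = c("scaffold", "staple")) {
  kind <- match.arg(kind)
  arr <- if (kind == "scaffold") "scaf" else "stap"
  byNum <- .vs_by_num(design)

  occ <- list()   # every occupied cell, as c(h, i)
  starts <- list()
  for (v in design$vstrands) {
    m <- v[[arr]]
    for (i in seq_len(nrow(m))) {
      t <- m[i, ]
      if (any(t != -1L)) {
        occ[[length(occ) + 1L]] <- c(v$num, i - 1L)
        if (t[1] == -1L && t[2] == -1L)
          starts[[length(starts) + 1L]] <- c(v$num, i - 1L)
      }
    }
  }
  visited <- new.env(parent = emptyenv())
  key <- function(c2) paste0(c2[1], ":", c2[2])

  walk <- function(start, stopAtStart) {
    cells <- list()
    cur <- start
    repeat {
      k <- key(cur)
      if (!is.null(visited[[k]]))
        stop("routing revisits cell (", cur[1], ", ", cur[2], ")")
      visited[[k]] <- TRUE
      cells[[length(cells) + 1L]] <- cur
      t <- .tuple_at(design, byNum, arr, cur[1], cur[2])
      if (t[3] == -1L && t[4] == -1L) return(list(cells = cells, closed = FALSE))
      nxt <- c(t[3], t[4])
      nt <- .tuple_at(design, byNum, arr, nxt[1], nxt[2])
      if (!.occupied(nt))
        stop("dangling ", kind, " pointer from (", cur[1], ", ", cur[2],
             ") to empty cell (", nxt[1], ", ", nxt[2], ")")
      if (stopAtStart && all(nxt == start))
        return(list(cells = cells, closed = TRUE))
      cur <- nxt
    }
  }

  paths <- list()
  for (s in starts) {
    if (!is.null(visited[[key(s)]])) next
    w <- walk(s, stopAtStart = FALSE)
    paths[[length(paths) + 1L]] <-
      list(kind = kind, cells = do.call(rbind, w$cells), isCircular = FALSE)
  }
  # remaining occupied cells are on circular paths
  for (c2 in occ) {
    if (!is.null(visited[[key(c2)]])) next
    # find the lexicographic minimum of this cycle first
    probe <- c2; best <- c2
    seen <- new.env(parent = emptyenv())
    repeat {
      if (!is.null(seen[[key(probe)]])) break
      seen[[key(probe)]] <- TRUE
      if (probe[1] < best[1] || (probe[1] == best[1] && probe[2] < best[2]))
        best <- probe
      t <- .tuple_at(design, byNum, arr, probe[1], probe[2])
      probe <- c(t[3], t[4])
    }
    w <- walk(best, stopAtStart = TRUE)
    paths[[length(paths) + 1L]] <-
      list(kind = kind, cells = do.call(rbind, w$cells), isCircular = TRUE)
  }
  paths
}

#' Cut a circular routed path at its predefined location
#'
#' The cut location is deterministic and order-independent: the resulting
#' linear path starts (5' end) at the cell with the lexicographically
#' smallest (helixNum, baseIndex) in the cycle.
#'
#' @param path A circular routed path from [trace_strands()].
#' @return The same cells as a linear path.
#' @export
cut_circular <- function(path) {
  if (!isTRUE(path$isCircular))
    stop("path is not circular; nothing to cut")
  n <- nrow(path$cells)
  if (n < 2L) stop("degenerate circular path of length ", n)
  ord <- order(path$cells[, 1], path$cells[, 2])
  k <- ord[1L]
  idx <- if (k == 1L) seq_len(n) else c(k:n, 1:(k - 1L))
  list(kind = path$kind, cells = path$cells[idx, , drop = FALSE],
       isCircular = FALSE)
}

#' Per-cell nucleotide multiplicities along a routed path
#'
#' A skip (-1) means the cell contributes no nucleotide (deletion); a loop
#' value n means it contributes n + 1 (insertion); otherwise 1.
#'
#' @param path A linear routed path.
#' @param design The owning \code{cadnano_design}.
#' @return Integer vector, one multiplicity per path cell.
#' @export
apply_loops_skips <- function(path, design) {
  if (isTRUE(path$isCircular)) stop("path must be linear (cut it first)")
  byNum <- .vs_by_num(design)
  vapply(seq_len(nrow(path$cells)), function(j) {
    h <- path$cells[j, 1]; i <- path$cells[j, 2]
    v <- design$vstrands[[byNum[[as.character(h)]]]]
    sk <- v$skip[i + 1L]; lp <- v$loop[i + 1L]
    if (sk == -1L && lp > 0L)
      stop("cell (", h, ", ", i, ") has both a skip and a loop")
    if (sk == -1L) 0L else lp + 1L
  }, integer(1))
}

# Direction of a path's crossing at cell j: +1 = increasing base index
# (fiveToThree), -1 = decreasing. Derived from same-helix neighbors, with
# Cadnano even/odd parity as fallback for single-cell fragments.
.path_direction <- function(cells, j, kind) {
  h <- cells[j, 1]; i <- cells[j, 2]
  n <- nrow(cells)
  if (j < n && cells[j + 1L, 1] == h && cells[j + 1L, 2] != i)
    return(sign(cells[j + 1L, 2] - i))
  if (j > 1L && cells[j - 1L, 1] == h && cells[j - 1L, 2] != i)
    return(sign(i - cells[j - 1L, 2]))
  fwd <- (h %% 2L) == 0L
  if (kind == "staple") fwd <- !fwd
  if (fwd) 1L else -1L
}

.color_hex <- function(colorInt) sprintf("#%06X", as.integer(colorInt))
.color_int <- function(hex) strtoi(sub("^#", "", hex), base = 16L)

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C", N = "N", U = "A")

# ---- Cadnano -> UNF -------------------------------------------------------

#' Convert Cadnano designs to a UNF document
#'
#' For n input designs, n lattice records and n structure records are
#' created. Nucleotides are created per loop/skip multiplicity, chained
#' 5' to 3', and referenced from directional cell arrays (a strand crossing
#' a helix with increasing base index populates \code{fiveToThreeNts}).
#' Scaffold/staple flags come from the source arrays; scaffold and staple
#' nucleotides co-occupying a cell are paired; staple colors become
#' \code{"#RRGGBB"} strand colors. Circular scaffolds are cut at the
#' deterministic location of [cut_circular()], and the cut is recorded as a
#' connection (interaction \code{"circular strand closure"}) joining the 3'
#' and 5' terminal nucleotides so the conversion stays lossless.
#'
#' @param inputs A list; each element is \code{list(design, latticeType,
#'   position, orientation)} (a bare \code{cadnano_design} is promoted to a
#'   square lattice at the origin).
#' @param doc Optional existing document to extend.
#' @param scaffold_seq Optional character scaffold sequence, assigned 5' to
#'   3' across scaffold strands and complemented onto paired staples;
#'   unassigned bases stay \code{"N"}.
#' @return A \code{unf_document} that passes [unf_validate()].
#' @export
cadnano_to_unf <- function(inputs, doc = NULL, scaffold_seq = NULL) {
  if (inherits(inputs, "cadnano_design")) inputs <- list(inputs)
  inputs <- lapply(inputs, function(inp) {
    if (inherits(inp, "cadnano_design"))
      inp <- list(design = inp)
    if (is.null(inp$latticeType)) inp$latticeType <- "square"
    if (is.null(inp$position)) inp$position <- c(0, 0, 0)
    if (is.null(inp$orientation)) inp$orientation <- c(0, 0, 0)
    inp
  })
  if (is.null(doc)) doc <- unf_document(name = "cadnano import")

  nextId <- doc$idCounter
  newId <- function() { id <- nextId; nextId <<- nextId + 1L; id }

  scafBases <- if (!is.null(scaffold_seq))
    strsplit(toupper(paste(scaffold_seq, collapse = "")), "")[[1L]] else NULL
  scafPos <- 0L

  for (inp in inputs) {
    design <- inp$design
    .check_cadnano(design)

    cells <- new.env(parent = emptyenv())   # "h:i" -> cell record
    byNum <- .vs_by_num(design)
    cellFor <- function(h, i) {
      k <- paste0(h, ":", i)
      cl <- cells[[k]]
      if (is.null(cl)) {
        v <- design$vstrands[[byNum[[as.character(h)]]]]
        type <- if (v$skip[i + 1L] == -1L) "deletion"
                else if (v$loop[i + 1L] > 0L) "insertion" else "normal"
        cl <- unf_cell(newId(), i, type)
        cells[[k]] <- cl
      }
      cl
    }
    # materialize a cell for every occupied position of either kind
    for (v in design$vstrands)
      for (i in seq_len(nrow(v$scaf)) - 1L)
        if (any(v$scaf[i + 1L, ] != -1L) || any(v$stap[i + 1L, ] != -1L))
          cellFor(v$num, i)

    strands <- list()
    closures <- list()
    ntById <- new.env(parent = emptyenv())

    buildStrand <- function(path, kind) {
      wasCircular <- isTRUE(path$isCircular)
      if (wasCircular) path <- cut_circular(path)
      mult <- apply_loops_skips(path, design)
      ntIds <- integer(0)
      for (j in seq_len(nrow(path$cells))) {
        m <- mult[j]
        if (m == 0L) next
        h <- path$cells[j, 1]; i <- path$cells[j, 2]
        dir <- .path_direction(path$cells, j, kind)
        ids <- vapply(seq_len(m), function(q) newId(), integer(1))
        cl <- cellFor(h, i)
        fld <- if (dir > 0L) "fiveToThreeNts" else "threeToFiveNts"
        cl[[fld]] <- c(cl[[fld]], ids)
        cells[[paste0(h, ":", i)]] <- cl
        ntIds <- c(ntIds, ids)
      }
      if (length(ntIds) == 0L) return(NULL)
      nts <- vector("list", length(ntIds))
      for (q in seq_along(ntIds)) {
        base <- "N"
        if (kind == "scaffold" && !is.null(scafBases) &&
            scafPos < length(scafBases)) {
          scafPos <<- scafPos + 1L
          base <- scafBases[scafPos]
        }
        nt <- unf_nucleotide(ntIds[q], base = base,
                             prev = if (q > 1L) ntIds[q - 1L] else -1L,
                             next_ = if (q < length(ntIds)) ntIds[q + 1L] else -1L)
        nts[[q]] <- nt
        ntById[[as.character(ntIds[q])]] <- q
      }
      s <- unf_na_strand(newId(), naType = "DNA",
                         isScaffold = (kind == "scaffold"),
                         color = if (kind == "scaffold")
                           CADNANO_SCAFFOLD_COLOR else "#888888",
                         fivePrimeId = ntIds[1L],
                         threePrimeId = ntIds[length(ntIds)],
                         nucleotides = nts)
      s$name <- paste0(kind, " ", s$id)
      if (wasCircular)
        closures[[length(closures) + 1L]] <<-
          c(ntIds[length(ntIds)], ntIds[1L])
      s$startCell <- path$cells[1L, ]   # transient, used for coloring
      s
    }

    for (p in trace_strands(design, "scaffold")) {
      s <- buildStrand(p, "scaffold")
      if (!is.null(s)) strands[[length(strands) + 1L]] <- s
    }
    for (p in trace_strands(design, "staple")) {
      s <- buildStrand(p, "staple")
      if (!is.null(s)) strands[[length(strands) + 1L]] <- s
    }

    # staple colors: entry [baseIndex, colorInt] on the helix hosting the
    # staple's 5' end
    colorAt <- new.env(parent = emptyenv())
    for (v in design$vstrands)
      for (sc in v$stap_colors)
        colorAt[[paste0(v$num, ":", sc[1])]] <- sc[2]
    for (k in seq_along(strands)) {
      s <- strands[[k]]
      if (!s$isScaffold) {
        ci <- colorAt[[paste0(s$startCell[1], ":", s$startCell[2])]]
        if (!is.null(ci)) strands[[k]]$color <- .color_hex(ci)
      }
      strands[[k]]$startCell <- NULL
    }

    # pairing: index-reversed match of the two directional arrays
    strandNts <- new.env(parent = emptyenv())
    for (k in seq_along(strands))
      for (q in seq_along(strands[[k]]$nucleotides))
        strandNts[[as.character(strands[[k]]$nucleotides[[q]]$id)]] <- c(k, q)
    for (k in ls(cells)) {
      cl <- cells[[k]]
      f <- cl$fiveToThreeNts; t <- cl$threeToFiveNts
      if (length(f) > 0L && length(f) == length(t)) {
        n <- length(f)
        for (q in seq_len(n)) {
          a <- strandNts[[as.character(f[q])]]
          b <- strandNts[[as.character(t[n + 1L - q])]]
          strands[[a[1]]]$nucleotides[[a[2]]]$pair <- t[n + 1L - q]
          strands[[b[1]]]$nucleotides[[b[2]]]$pair <- f[q]
        }
      }
    }

    # complement scaffold sequence onto paired staples
    if (!is.null(scafBases)) {
      baseOf <- new.env(parent = emptyenv())
      for (s in strands) if (s$isScaffold)
        for (nt in s$nucleotides) baseOf[[as.character(nt$id)]] <- nt$base
      for (k in seq_along(strands)) {
        if (strands[[k]]$isScaffold) next
        for (q in seq_along(strands[[k]]$nucleotides)) {
          p <- strands[[k]]$nucleotides[[q]]$pair
          if (p != -1L) {
            b <- baseOf[[as.character(p)]]
            if (!is.null(b))
              strands[[k]]$nucleotides[[q]]$base <- unname(DNA_COMPLEMENT[b])
          }
        }
      }
    }

    # lattice record
    helices <- lapply(design$vstrands, function(v) {
      idx <- sort(vapply(
        Filter(function(kk) startsWith(kk, paste0(v$num, ":")), ls(cells)),
        function(kk) cells[[kk]]$index, integer(1)))
      vhCells <- lapply(idx, function(i) cells[[paste0(v$num, ":", i)]])
      unf_virtual_helix(newId(), v$row, v$col, designNumber = v$num,
                        cells = vhCells)
    })
    lat <- unf_lattice(newId(), name = design$name, type = inp$latticeType,
                       position = inp$position, orientation = inp$orientation,
                       virtualHelices = helices)
    st <- unf_structure(newId(), name = design$name, naStrands = strands)
    doc$lattices[[length(doc$lattices) + 1L]] <- lat
    doc$structures[[length(doc$structures) + 1L]] <- st
    for (cl in closures)
      doc$connections[[length(doc$connections) + 1L]] <-
        unf_connection(newId(), includedObjects = cl,
                       interaction = CIRCULAR_CLOSURE_TAG)
  }
  doc$idCounter <- nextId
  doc
}

# ---- UNF -> Cadnano -------------------------------------------------------

.round_up <- function(x, m) as.integer(ceiling(max(x, 1L) / m) * m)

#' Convert a UNF document to Cadnano designs
#'
#' Each lattice becomes one Cadnano design; routing tuples, skip/loop
#' arrays and staple colors are reconstructed from the cells and strand
#' topology. Helix numbers reuse \code{designNumber} when present and are
#' otherwise assigned by checkerboard parity of (row, col). Strand routing
#' through deletion cells (which reference no nucleotides) is restored by
#' bridging same-helix gaps in a strand's cell path. Strands whose termini
#' are joined by a \code{"circular strand closure"} connection are
#' re-closed. Free-form structures and molecules are ignored with a
#' warning.
#'
#' @param doc A \code{unf_document}.
#' @return List of \code{cadnano_design}, one per lattice.
#' @export
unf_to_cadnano <- function(doc) {
  # nucleotide id -> (latticeIndex, helixNum, cellIndex) and cell-type maps
  ntCell <- new.env(parent = emptyenv())
  designs <- list()

  latticeNts <- vector("list", length(doc$lattices))

  for (li in seq_along(doc$lattices)) {
    lat <- doc$lattices[[li]]
    mod <- if (lat$type == "honeycomb") 21L else 32L

    # helix numbering
    helices <- lat$virtualHelices
    nums <- vapply(helices, function(vh) vh$designNumber, integer(1))
    if (any(nums < 0L)) {
      evenN <- 0L; oddN <- 0L
      ordh <- order(vapply(helices, function(vh) vh$row, integer(1)),
                    vapply(helices, function(vh) vh$col, integer(1)))
      for (k in ordh) {
        if (nums[k] >= 0L) next
        if ((helices[[k]]$row + helices[[k]]$col) %% 2L == 0L) {
          nums[k] <- 2L * evenN; evenN <- evenN + 1L
        } else {
          nums[k] <- 2L * oddN + 1L; oddN <- oddN + 1L
        }
      }
    }

    maxIdx <- 0L
    for (vh in helices) for (cl in vh$cells)
      if (cl$index > maxIdx) maxIdx <- cl$index
    L <- .round_up(maxIdx + 1L, mod)

    vs <- list()
    deletion <- new.env(parent = emptyenv())
    for (k in seq_along(helices)) {
      vh <- helices[[k]]
      v <- list(num = nums[k], row = vh$row, col = vh$col,
                scaf = matrix(-1L, L, 4L), stap = matrix(-1L, L, 4L),
                skip = integer(L), loop = integer(L), stap_colors = list())
      for (cl in vh$cells) {
        if (cl$type == "deletion") {
          v$skip[cl$index + 1L] <- -1L
          deletion[[paste0(nums[k], ":", cl$index)]] <- TRUE
        }
        if (cl$type == "insertion")
          v$loop[cl$index + 1L] <-
            max(length(cl$fiveToThreeNts), length(cl$threeToFiveNts)) - 1L
        for (ntid in c(cl$fiveToThreeNts, cl$threeToFiveNts))
          ntCell[[as.character(ntid)]] <- c(li, nums[k], cl$index)
      }
      vs[[length(vs) + 1L]] <- v
    }
    vs <- vs[order(vapply(vs, function(v) v$num, integer(1)))]
    byNum <- new.env(parent = emptyenv())
    for (k in seq_along(vs)) byNum[[as.character(vs[[k]]$num)]] <- k

    designs[[li]] <- list(name = if (nzchar(lat$name)) lat$name else doc$name,
                          vstrands = vs, byNum = byNum)
  }

  # circular closures by 3'-terminus id
  closure <- new.env(parent = emptyenv())
  for (cn in doc$connections)
    if (identical(cn$interaction, CIRCULAR_CLOSURE_TAG) &&
        length(cn$includedObjects) == 2L)
      closure[[as.character(cn$includedObjects[1])]] <- cn$includedObjects[2]

  freeForm <- 0L
  for (st in doc$structures) {
    for (s in st$naStrands) {
      nts <- .strand_order(s)
      ref <- ntCell[[as.character(nts[[1L]]$id)]]
      if (is.null(ref)) { freeForm <- freeForm + 1L; next }
      li <- ref[1]
      des <- designs[[li]]

      # cell path: consecutive distinct cells visited by the strand
      cellPath <- list()
      for (nt in nts) {
        r <- ntCell[[as.character(nt$id)]]
        if (is.null(r))
          stop("strand ", s$id, " mixes lattice-referenced and free ",
               "nucleotides (nucleotide ", nt$id, " is in no cell)")
        c2 <- r[2:3]
        m <- length(cellPath)
        if (m == 0L || any(cellPath[[m]] != c2))
          cellPath[[m + 1L]] <- c2
      }
      # bridge same-helix gaps across deletion cells
      bridged <- list(cellPath[[1L]])
      for (j in seq_along(cellPath)[-1L]) {
        a <- bridged[[length(bridged)]]; b <- cellPath[[j]]
        if (a[1] == b[1] && abs(b[2] - a[2]) > 1L) {
          stepDir <- as.integer(sign(b[2] - a[2]))
          for (i in seq.int(a[2] + stepDir, b[2] - stepDir, by = stepDir)) {
            if (is.null(deletion[[paste0(a[1], ":", i)]]))
              stop("strand ", s$id, " jumps over non-deletion cell (",
                   a[1], ", ", i, ")")
            bridged[[length(bridged) + 1L]] <- c(a[1], i)
          }
        }
        bridged[[length(bridged) + 1L]] <- b
      }
      cellPath <- bridged

      # re-close circular strands
      cls <- closure[[as.character(s$threePrimeId)]]
      isClosed <- !is.null(cls) && cls == s$fivePrimeId

      arr <- if (s$isScaffold) "scaf" else "stap"
      n <- length(cellPath)
      link <- function(a, b) {
        ka <- des$byNum[[as.character(a[1])]]
        kb <- des$byNum[[as.character(b[1])]]
        designs[[li]]$vstrands[[ka]][[arr]][a[2] + 1L, 3:4] <<-
          as.integer(c(b[1], b[2]))
        designs[[li]]$vstrands[[kb]][[arr]][b[2] + 1L, 1:2] <<-
          as.integer(c(a[1], a[2]))
      }
      for (j in seq_len(n - 1L)) link(cellPath[[j]], cellPath[[j + 1L]])
      if (isClosed && n > 1L) link(cellPath[[n]], cellPath[[1L]])
      if (n == 1L) {
        # lone cell: mark occupancy so the tuple is not all -1? A single
        # unlinked nucleotide has no routing; cadnano cannot represent it.
        warning("strand ", s$id, " occupies a single cell; ",
                "emitted without routing")
      }

      if (!s$isScaffold) {
        e5 <- cellPath[[1L]]
        k5 <- des$byNum[[as.character(e5[1])]]
        designs[[li]]$vstrands[[k5]]$stap_colors[[
          length(designs[[li]]$vstrands[[k5]]$stap_colors) + 1L]] <-
          as.integer(unname(c(e5[2], .color_int(s$color))))
      }
    }
    if (length(st$aaChains) > 0L) freeForm <- freeForm + length(st$aaChains)
  }
  nMol <- length(doc$molecules$ligands) + length(doc$molecules$nanostructures) +
    length(doc$molecules$others)
  if (freeForm + nMol > 0L)
    warning(freeForm + nMol,
            " free-form structure(s)/molecule(s) ignored: ",
            "Cadnano cannot represent them")

  lapply(designs, function(d) {
    d$byNum <- NULL
    d$vstrands <- lapply(d$vstrands, function(v) {
      if (length(v$stap_colors) > 1L)
        v$stap_colors <- v$stap_colors[order(vapply(v$stap_colors,
                                                    function(x) x[1], double(1)))]
      v
    })
    class(d) <- "cadnano_design"
    d
  })
}
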