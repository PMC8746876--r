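# Deterministic toy-structure generators: Cadnano designs, idealized
# atomistic duplexes and oxDNA duplex systems at 2-8 helix / <= 100 nt
# scale, so every bridge and round-trip property is testable without any
# external data.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

CADNANO_PALETTE <- c(13369344L, 16204552L, 16225054L, 11184640L, 5749504L,
                     29184L, 243362L, 1507550L, 7536862L, 12060012L,
                     29174L, 8947848L)

#' Specify a toy Cadnano design
#'
#' The generator lays a serpentine scaffold over all helices (optionally
#' closed into a circle), covers every cell with antiparallel staples
#' broken at seeded random points, adds one staple crossover per helix
#' pair, colors every staple from the Cadnano palette, and places the
#' requested number of skips and loops at seeded random interior duplex
#' positions (never at strand termini or crossover columns, where real
#' designs do not put them either).
#'
#' @param nHelices Number of virtual helices (2-8 is the intended range).
#' @param cellsPerHelix Cells per helix; a multiple of 32 (square) or 21
#'   (honeycomb).
#' @param latticeType \code{"square"} or \code{"honeycomb"}.
#' @param circularScaffold Close the scaffold into a circle.
#' @param nSkips,nLoops Number of deletion/insertion sites.
#' @param pattern \code{"cross"} (staple crossovers between helix pairs)
#'   or \code{"linear"} (per-helix staples only).
#' @param seed Integer seed; identical specs give byte-identical designs.
#' @return A list of class \code{unf_fixture_spec}.
#' @export
fixture_spec <- function(nHelices = 4L, cellsPerHelix = 32L,
                         latticeType = c("square", "honeycomb"),
                         circularScaffold = FALSE, nSkips = 0L, nLoops = 0L,
                         pattern = c("cross", "linear"), seed = 1L) {
  latticeType <- match.arg(latticeType)
  pattern <- match.arg(pattern)
  if (nHelices < 2L && pattern == "cross")
    stop("a crossover pattern needs at least 2 helices")
  mod <- if (latticeType == "honeycomb") 21L else 32L
  if (cellsPerHelix %% mod != 0L || cellsPerHelix < mod)
    stop("cellsPerHelix must be a positive multiple of ", mod,
         " for the ", latticeType, " lattice")
  structure(list(nHelices = as.integer(nHelices),
                 cellsPerHelix = as.integer(cellsPerHelix),
                 latticeType = latticeType,
                 circularScaffold = isTRUE(circularScaffold),
                 nSkips = as.integer(nSkips), nLoops = as.integer(nLoops),
                 pattern = pattern, seed = as.integer(seed)),
            class = "unf_fixture_spec")
}

#' Generate a toy Cadnano design
#'
#' @param spec A [fixture_spec()].
#' @return A \code{cadnano_design} satisfying all design invariants.
#' @export
make_toy_cadnano <- function(spec) {
  stopifnot(inherits(spec, "unf_fixture_spec"))
  .with_seed(spec$seed, {
    nH <- spec$nHelices
    L <- spec$cellsPerHelix
    M <- L - 1L

    # scaffold serpentine: even helices run 0..M, odd helices M..0
    scafPath <- do.call(rbind, lapply(seq_len(nH) - 1L, function(h) {
      idx <- if (h %% 2L == 0L) 0:M else M:0
      cbind(h, idx)
    }))

    # staple coverage, antiparallel to the scaffold, with one crossover
    # per helix pair at a seeded interior column
    staplePaths <- list()
    crossCols <- integer(0)
    nPairs <- nH %/% 2L
    for (k in seq_len(nPairs)) {
      h1 <- 2L * (k - 1L); h2 <- h1 + 1L
      if (spec$pattern == "cross" && L >= 16L) {
        c0 <- sample(7:(M - 7L), 1L)
        crossCols <- c(crossCols, c0)
        staplePaths[[length(staplePaths) + 1L]] <-
          rbind(cbind(h1, M:c0), cbind(h2, c0:M))
        staplePaths[[length(staplePaths) + 1L]] <-
          rbind(cbind(h2, 0:(c0 - 1L)), cbind(h1, (c0 - 1L):0))
      } else {
        staplePaths[[length(staplePaths) + 1L]] <- cbind(h1, M:0)
        staplePaths[[length(staplePaths) + 1L]] <- cbind(h2, 0:M)
      }
    }
    if (nH %% 2L == 1L) {
      h <- nH - 1L
      idx <- if (h %% 2L == 0L) M:0 else 0:M
      staplePaths[[length(staplePaths) + 1L]] <- cbind(h, idx)
    }

    # break staple paths into strands of length >= 7
    segments <- list()
    for (p in staplePaths) {
      n <- nrow(p)
      cuts <- integer(0)
      pos <- 0L
      while (n - pos > 13L) {
        hi <- min(13L, n - pos - 7L)
        step <- if (hi <= 7L) 7L else sample(7:hi, 1L)
        pos <- pos + step
        cuts <- c(cuts, pos)
      }
      bounds <- c(0L, cuts, n)
      for (b in seq_len(length(bounds) - 1L))
        segments[[length(segments) + 1L]] <-
          p[(bounds[b] + 1L):bounds[b + 1L], , drop = FALSE]
    }

    # cells where a skip/loop may sit: interior duplex positions away from
    # any strand terminus and from crossover columns
    termini <- unique(do.call(rbind, lapply(segments, function(s)
      rbind(s[1L, ], s[nrow(s), ]))))
    if (!spec$circularScaffold)
      termini <- rbind(termini, scafPath[1L, ], scafPath[nrow(scafPath), ])
    badCols <- unique(c(0L, M, crossCols, crossCols - 1L, crossCols + 1L))
    eligible <- list()
    for (h in seq_len(nH) - 1L) for (i in setdiff(2:(M - 2L), badCols)) {
      if (!any(termini[, 1] == h & termini[, 2] == i))
        eligible[[length(eligible) + 1L]] <- c(h, i)
    }
    nSites <- spec$nSkips + spec$nLoops
    sites <- if (nSites > 0L) {
      if (length(eligible) < nSites)
        stop("not enough eligible cells for ", nSites, " skip/loop sites")
      eligible[sample.int(length(eligible), nSites)]
    } else list()
    skips <- sites[seq_len(spec$nSkips)]
    loops <- if (spec$nLoops > 0L)
      sites[spec$nSkips + seq_len(spec$nLoops)] else list()

    vs <- lapply(seq_len(nH) - 1L, function(h)
      list(num = h, row = h %% 2L, col = h %/% 2L,
           scaf = matrix(-1L, L, 4L), stap = matrix(-1L, L, 4L),
           skip = integer(L), loop = integer(L), stap_colors = list()))

    lay <- function(vs, path, arr, closed = FALSE) {
      n <- nrow(path)
      for (j in seq_len(n - 1L)) {
        a <- path[j, ]; b <- path[j + 1L, ]
        vs[[a[1] + 1L]][[arr]][a[2] + 1L, 3:4] <- b
        vs[[b[1] + 1L]][[arr]][b[2] + 1L, 1:2] <- a
      }
      if (closed && n > 1L) {
        a <- path[n, ]; b <- path[1L, ]
        vs[[a[1] + 1L]][[arr]][a[2] + 1L, 3:4] <- b
        vs[[b[1] + 1L]][[arr]][b[2] + 1L, 1:2] <- a
      }
      vs
    }
    vs <- lay(vs, scafPath, "scaf", closed = spec$circularScaffold)
    for (k in seq_along(segments)) {
      seg <- segments[[k]]
      vs <- lay(vs, seg, "stap")
      e5 <- seg[1L, ]
      color <- CADNANO_PALETTE[1L + (k - 1L) %% length(CADNANO_PALETTE)]
      vs[[e5[1] + 1L]]$stap_colors[[
        length(vs[[e5[1] + 1L]]$stap_colors) + 1L]] <-
        as.integer(unname(c(e5[2], color)))
    }
    for (s in skips) vs[[s[1] + 1L]]$skip[s[2] + 1L] <- -1L
    for (l in loops) vs[[l[1] + 1L]]$loop[l[2] + 1L] <- sample(1:2, 1L)
    vs <- lapply(vs, function(v) {
      if (length(v$stap_colors) > 1L)
        v$stap_colors <- v$stap_colors[order(vapply(v$stap_colors,
                                                    function(x) x[1],
                                                    double(1)))]
      v
    })

    design <- list(name = sprintf("toy-%s-%dx%d-seed%d", spec$latticeType,
                                  nH, L, spec$seed),
                   vstrands = vs)
    class(design) <- "cadnano_design"
    .check_cadnano(design)
  })
}

# ---- atomistic duplex fixture --------------------------------------------

# Planar base-atom templates (local coordinates, Angstrom; base plane z=0,
# hexagon centered at the origin). Idealized geometry, not crystallographic:
# sufficient for coarse-graining because only means, planes and edges enter
# the frame recipe.
.hexagon <- local({
  ang <- c(N1 = 120, C2 = 60, N3 = 0, C4 = -60, C5 = -120, C6 = 180) * pi / 180
  cbind(x = 1.4 * cos(ang), y = 1.4 * sin(ang), z = 0)
})

.base_template <- function(base) {
  hx <- .hexagon
  purineExtra <- rbind(N7 = c(-1.15, -2.45, 0), C8 = c(0.0, -3.10, 0),
                       N9 = c(1.15, -2.45, 0))
  atoms <- switch(base,
    A = rbind(hx, purineExtra, N6 = c(0.0, 2.80, 0)),
    G = rbind(hx, purineExtra, O6 = c(0.0, 2.80, 0), N2 = c(2.40, 1.40, 0)),
    C = rbind(hx, O2 = c(1.40, -1.40, 0), N4 = c(0.0, 2.80, 0)),
    T = rbind(hx, O2 = c(1.40, -1.40, 0), O4 = c(0.0, 2.80, 0),
              C7 = c(-2.40, 1.40, 0)),
    U = rbind(hx, O2 = c(1.40, -1.40, 0), O4 = c(0.0, 2.80, 0)),
    stop("unknown base ", base))
  atoms
}

.backbone_template <- rbind(
  "C1'" = c(3.8,  0.8,  0.3), "C2'" = c(4.9,  1.5,  0.5),
  "C3'" = c(5.9,  0.7,  0.2), "O3'" = c(7.0,  1.2,  0.4),
  "C4'" = c(5.5, -0.7,  0.5), "O4'" = c(4.1, -0.9,  0.4),
  "C5'" = c(6.4, -1.8,  0.3), "O5'" = c(7.2, -1.2, -0.2),
  "P"   = c(8.3, -2.0, -0.6), "OP1" = c(9.2, -1.5, -1.4),
  "OP2" = c(8.8, -2.9,  0.4))

.residue_atoms <- function(base, rna = FALSE) {
  b <- .base_template(base)
  b[, 1] <- b[, 1] + 2.2   # shift the base off the helix axis
  bb <- .backbone_template
  if (rna) bb <- rbind(bb, "O2'" = c(5.4, 2.6, 0.6))
  rbind(b, bb)
}

.rz <- function(theta)
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)

#' Generate an idealized B-form duplex as PDB text
#'
#' Builds a two-chain duplex from planar per-base atom templates placed on
#' an ideal helix (3.38 A rise, 36 deg twist). Residues are listed 5' to 3'
#' in each chain; chain B is the reverse complement of \code{sequence}.
#' Base atoms are exactly coplanar, so the analytic base-plane normal is
#' known by construction.
#'
#' @param sequence DNA sequence over A/C/G/T (chain A, 5' to 3').
#' @param rna Emit an RNA duplex instead (A/C/G/U residue names, O2' atom).
#' @return PDB text (ATOM records, TER, END) as one string.
#' @export
make_toy_duplex_pdb <- function(sequence, rna = FALSE) {
  seqv <- strsplit(toupper(sequence), "")[[1L]]
  if (length(seqv) == 0L) stop("empty sequence")
  alphabet <- if (rna) c("A", "C", "G", "U") else c("A", "C", "G", "T")
  if (!all(seqv %in% alphabet))
    stop("sequence must be over {", paste(alphabet, collapse = ","), "}")
  comp <- if (rna) c(A = "U", U = "A", C = "G", G = "C")
          else c(A = "T", T = "A", C = "G", G = "C")
  n <- length(seqv)
  rise <- 3.38; twist <- 36 * pi / 180

  lines <- character(0)
  serial <- 0L
  emit <- function(chain, resno, resname, atoms) {
    for (k in seq_len(nrow(atoms))) {
      serial <<- serial + 1L
      nm <- rownames(atoms)[k]
      el <- substr(gsub("[^A-Za-z].*$", "", nm), 1L, 1L)
      lines[[length(lines) + 1L]] <<- sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, nm, resname, chain, resno,
        atoms[k, 1], atoms[k, 2], atoms[k, 3], el)
    }
  }
  resname <- function(b) if (rna) b else paste0("D", b)

  for (i in seq_len(n)) {
    A <- .residue_atoms(seqv[i], rna)
    R <- .rz((i - 1L) * twist)
    pos <- t(R %*% t(A))
    pos[, 3] <- pos[, 3] + (i - 1L) * rise
    rownames(pos) <- rownames(A)
    emit("A", i, resname(seqv[i]), pos)
  }
  lines[[length(lines) + 1L]] <- "TER"
  Fflip <- diag(c(1, -1, -1))
  for (j in seq_len(n)) {
    p <- n - j + 1L                      # partner index on chain A (1-based)
    b <- unname(comp[seqv[p]])
    A <- .residue_atoms(b, rna)
    R <- .rz((p - 1L) * twist + pi)
    pos <- t((R %*% Fflip) %*% t(A))
    pos[, 3] <- pos[, 3] + (p - 1L) * rise
    rownames(pos) <- rownames(A)
    emit("B", j, resname(b), pos)
  }
  lines[[length(lines) + 1L]] <- "TER"
  lines[[length(lines) + 1L]] <- "END"
  paste0(paste(unlist(lines), collapse = "\n"), "\n")
}

# ---- oxDNA duplex fixture -------------------------------------------------

#' Generate a toy oxDNA duplex
#'
#' An ideal-helix duplex in the classic oxDNA dialect (strands listed 3' to
#' 5'), with orthonormal a1/a3 frames, rigidly rotated and translated by a
#' seeded random motion so nothing is axis-aligned. Deterministic for a
#' given sequence and seed.
#'
#' @param sequence DNA sequence over A/C/G/T for strand 1, 5' to 3'.
#' @param seed Integer seed for the rigid motion.
#' @return \code{list(topology, configuration)}, each one string.
#' @export
make_toy_oxdna <- function(sequence, seed = 1L) {
  seqv <- strsplit(toupper(sequence), "")[[1L]]
  if (length(seqv) == 0L) stop("empty sequence")
  stopifnot(all(seqv %in% c("A", "C", "G", "T")))
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  n <- length(seqv)
  r <- 0.6; rise <- 0.39; twist <- 0.6

  .with_seed(seed, {
    # random rotation via a normalized quaternion
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                  2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                  2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
                3, 3)
    tr <- stats::runif(3, -5, 5)

    place <- function(theta, zpos, flip) {
      a1 <- c(-cos(theta), -sin(theta), 0)
      a3 <- c(0, 0, 1)
      com <- c(r * cos(theta), r * sin(theta), zpos)
      if (flip) { a1 <- -a1; a3 <- -a3 }
      list(com = as.double(R %*% com + tr), a1 = as.double(R %*% a1),
           a3 = as.double(R %*% a3))
    }
    s1 <- lapply(seq_len(n) - 1L, function(i)
      place(i * twist, i * rise, flip = FALSE))
    # strand 2: paired with partner p at the same z, diametrically opposite
    s2 <- lapply(seq_len(n), function(j) {
      p <- n - j          # 0-based partner index on strand 1
      place(p * twist + pi, p * rise, flip = TRUE)
    })
    bases1 <- seqv
    bases2 <- unname(comp[rev(seqv)])

    fmt <- function(v) sprintf("%.10g", v)
    topRows <- character(0); confRows <- character(0)
    addStrand <- function(k, bases, frames, offset) {
      m <- length(bases)
      for (q in seq_len(m)) {
        # listing is 3'->5': row q is construction index m - q + 1
        ci <- m - q + 1L
        gi <- offset + q - 1L
        n3 <- if (q > 1L) gi - 1L else -1L
        n5 <- if (q < m) gi + 1L else -1L
        topRows <<- c(topRows, paste(k, bases[ci], n3, n5))
        f <- frames[[ci]]
        confRows <<- c(confRows, paste(c(fmt(f$com), fmt(f$a1), fmt(f$a3),
                                         "0 0 0 0 0 0"), collapse = " "))
      }
    }
    addStrand(1L, bases1, s1, 0L)
    addStrand(2L, bases2, s2, n)

    list(topology = paste0(paste(2L * n, 2L), "\n",
                           paste(topRows, collapse = "\n"), "\n"),
         configuration = paste0("t = 0\nb = 40 40 40\nE = 0 0 0\n",
                                paste(confRows, collapse = "\n"), "\n"))
  })
}
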