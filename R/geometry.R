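# Ideal B-form helix geometry for lattice-referenced nucleotides, and the
# explicit-position precedence rule: a nucleotide with position records uses
# them; otherwise its frame is derived from the unique lattice cell that
# references it.

#' Geometry parameters for lattice-implied nucleotide placement
#'
#' Defaults describe idealized B-form DNA on a Cadnano-style lattice:
#' 25 A center-to-center interhelix spacing (a 2 nm helix plus a 0.5 nm
#' gap), 3.4 A rise per base pair, and a twist matching Cadnano's crossover
#' periodicity -- 33.75 deg/bp on the square lattice (32 bp = 3 turns) and
#' 360*2/21 = 34.286 deg/bp on the honeycomb lattice (21 bp = 2 turns).
#' The groove offset rotates the complementary strand's hydrogen-face
#' direction away from diametric opposition; 0 keeps the two backbones
#' diametrically opposed, a deliberate simplification.
#'
#' @param interhelixSpacing Center-to-center helix spacing, Angstrom.
#' @param risePerBp Axial rise per base pair, Angstrom.
#' @param twistPerBp Helical twist per base pair, degrees; when \code{NULL}
#'   the lattice-type default is used (33.75 square, 34.2857... honeycomb).
#' @param initialAngle Default helical phase at cell index 0, degrees.
#' @param backboneRadius Distance of the backbone center from the helix
#'   axis, Angstrom.
#' @param baseRadius Distance of the nucleobase center from the helix axis,
#'   Angstrom.
#' @param grooveOffset Minor-groove asymmetry angle, degrees.
#' @return A list of class \code{unf_geometry_params}.
#' @export
geometry_params <- function(interhelixSpacing = 25.0, risePerBp = 3.4,
                            twistPerBp = NULL, initialAngle = 0,
                            backboneRadius = 6.0, baseRadius = 1.7,
                            grooveOffset = 0) {
  stopifnot(interhelixSpacing > 0, risePerBp > 0,
            backboneRadius > 0, baseRadius > 0)
  structure(list(interhelixSpacing = interhelixSpacing,
                 risePerBp = risePerBp, twistPerBp = twistPerBp,
                 initialAngle = initialAngle,
                 backboneRadius = backboneRadius, baseRadius = baseRadius,
                 grooveOffset = grooveOffset),
            class = "unf_geometry_params")
}

.twist_for <- function(params, latticeType) {
  if (!is.null(params$twistPerBp)) return(params$twistPerBp)
  if (latticeType == "honeycomb") 360 * 2 / 21 else 33.75
}

#' Lattice site coordinates
#'
#' Maps a (row, col) virtual-helix address to in-plane coordinates. Rows
#' grow downward on the Cadnano canvas, negated here into a right-handed
#' frame, so y decreases with increasing row. On the honeycomb lattice
#' (circumradius r = spacing/2): \code{x = sqrt(3) r col},
#' \code{y = -r (3 row + ((row + col) mod 2))}.
#'
#' @param type \code{"square"} or \code{"honeycomb"}.
#' @param row,col Integer lattice address.
#' @param params A [geometry_params()] list.
#' @return Numeric \code{c(x, y)} in Angstrom.
#' @export
lattice_point <- function(type, row, col, params = geometry_params()) {
  d <- params$interhelixSpacing
  if (type == "square") {
    c(col * d, -row * d)
  } else if (type == "honeycomb") {
    r <- d / 2
    c(sqrt(3) * r * col, -r * (3 * row + ((row + col) %% 2)))
  } else {
    stop("unknown lattice type '", type, "'")
  }
}

# Rotation matrix for intrinsic X-then-Y-then-Z Euler angles in degrees.
.euler_xyz <- function(angles) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Helix axis point for a lattice cell
#'
#' The lattice-local axis point is the lattice site at height
#' \code{cellIndex * risePerBp}, rotated by the lattice orientation
#' (intrinsic X-Y-Z Euler angles, degrees) and translated by the lattice
#' position.
#'
#' @param lattice A \code{lattices} entry.
#' @param helix A \code{virtualHelices} entry of that lattice.
#' @param cellIndex Base-pair index along the helix (may be fractional for
#'   insertion sub-positions).
#' @param params A [geometry_params()] list.
#' @return Numeric 3-vector in Angstrom.
#' @export
helix_axis_position <- function(lattice, helix, cellIndex,
                                params = geometry_params()) {
  xy <- lattice_point(lattice$type, helix$row, helix$col, params)
  local <- c(xy, cellIndex * params$risePerBp)
  R <- .euler_xyz(lattice$orientation)
  as.double(R %*% local + lattice$position)
}

#' Implicit B-form frame for a lattice-referenced nucleotide
#'
#' Places a nucleotide that has no explicit position record. The helical
#' phase is \code{theta = theta0 + (cellIndex + subIndex/subCount) * twist};
#' the hydrogen-face direction a1 is \code{(cos theta, sin theta, 0)} for
#' the 5'-to-3' strand and its negation (plus the groove offset) for the
#' complement; the base normal a3 is the helix axis direction pointing
#' 3' to 5' for that strand; base and backbone centers sit at
#' \code{baseRadius} and \code{backboneRadius} from the axis opposite a1.
#' Everything is then mapped by the lattice rigid motion.
#'
#' @param lattice,helix Lattice and virtual helix records.
#' @param cellIndex Integer cell index along the helix.
#' @param direction \code{"fiveToThree"} or \code{"threeToFive"}: which
#'   directional cell array the nucleotide sits in.
#' @param subIndex 0-based sub-position within an insertion cell.
#' @param subCount Number of nucleotides this strand places in the cell
#'   (1 for normal cells, n+1 for an insertion of length n).
#' @param params A [geometry_params()] list.
#' @return A [unf_frame()] satisfying the unit-norm and orthogonality
#'   invariants.
#' @export
implicit_frame <- function(lattice, helix, cellIndex,
                           direction = c("fiveToThree", "threeToFive"),
                           subIndex = 0L, subCount = 1L,
                           params = geometry_params()) {
  direction <- match.arg(direction)
  stopifnot(subIndex >= 0L, subIndex < subCount)
  twist <- .twist_for(params, lattice$type)
  theta0 <- helix$initialAngle + params$initialAngle
  frac <- cellIndex + subIndex / subCount
  theta <- (theta0 + frac * twist) * pi / 180

  a1 <- c(cos(theta), sin(theta), 0)
  if (direction == "threeToFive") {
    g <- params$grooveOffset * pi / 180
    # complement: antiparallel hydrogen face, optionally rotated off the
    # diameter by the groove offset
    phi <- theta + pi + g
    a1 <- c(cos(phi), sin(phi), 0)
    a3 <- c(0, 0, 1)   # this strand's 5'->3' runs toward -z; 3'->5' is +z
  } else {
    a3 <- c(0, 0, -1)  # 5'->3' runs toward +z; 3'->5' is -z
  }

  axis <- c(lattice_point(lattice$type, helix$row, helix$col, params),
            frac * params$risePerBp)
  nb <- axis - params$baseRadius * a1
  bb <- axis - params$backboneRadius * a1

  R <- .euler_xyz(lattice$orientation)
  t <- lattice$position
  unf_frame(backboneCenter = as.double(R %*% bb + t),
            nucleobaseCenter = as.double(R %*% nb + t),
            baseNormal = as.double(R %*% a3),
            hydrogenFaceDir = as.double(R %*% a1))
}

# Locate the unique (lattice, helix, cell, direction, subIndex, subCount)
# referencing a nucleotide id; NULL if none, error if ambiguous.
.find_cell_ref <- function(doc, nucleotideId) {
  hit <- NULL
  for (lat in doc$lattices) for (vh in lat$virtualHelices) for (cell in vh$cells) {
    for (dirField in c("fiveToThreeNts", "threeToFiveNts")) {
      arr <- cell[[dirField]]
      p <- which(arr == nucleotideId)
      if (length(p) > 0L) {
        if (!is.null(hit))
          stop("nucleotide ", nucleotideId,
               " is referenced by more than one lattice cell")
        m <- length(arr)
        # arrays store the strand's own 5'->3' order; the threeToFive
        # strand traverses the cell's axial sub-slots in reverse
        sub <- if (dirField == "fiveToThreeNts") p[1L] - 1L else m - p[1L]
        hit <- list(lattice = lat, helix = vh, cell = cell,
                    direction = if (dirField == "fiveToThreeNts")
                      "fiveToThree" else "threeToFive",
                    subIndex = sub, subCount = m)
      }
    }
  }
  hit
}

#' Resolve a nucleotide's spatial frame
#'
#' Explicit position records take precedence over the lattice-based
#' representation: if the nucleotide's \code{altPositions} is non-empty its
#' first entry (the current position) is returned. Otherwise the frame is
#' computed with [implicit_frame()] from the unique lattice cell that
#' references the nucleotide.
#'
#' @param doc A \code{unf_document}.
#' @param nucleotideId ID of a nucleotide in the document.
#' @param params A [geometry_params()] list.
#' @return A [unf_frame()].
#' @export
resolve_nucleotide_position <- function(doc, nucleotideId,
                                        params = geometry_params()) {
  hit <- unf_resolve(doc, nucleotideId)
  if (!identical(hit$kind, "nucleotide"))
    stop("ID ", nucleotideId, " is a ", hit$kind, ", not a nucleotide")
  nt <- hit$obj
  if (length(nt$altPositions) > 0L) return(nt$altPositions[[1L]])
  ref <- .find_cell_ref(doc, nucleotideId)
  if (is.null(ref))
    stop("nucleotide ", nucleotideId, " has neither an explicit position ",
         "nor a referencing lattice cell: unplaceable")
  implicit_frame(ref$lattice, ref$helix, ref$cell$index, ref$direction,
                 ref$subIndex, ref$subCount, params)
}
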