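test_that("lattice_point matches the stated square and honeycomb formulas", {
  p <- geometry_params()
  expect_equal(lattice_point("square", 0, 0, p), c(0, 0))
  expect_equal(lattice_point("square", 1, 2, p), c(50, -25))
  expect_equal(lattice_point("honeycomb", 0, 1, p), c(sqrt(3) * 12.5, -12.5))
  # honeycomb parity term: (row + col) odd shifts y by -r
  expect_equal(lattice_point("honeycomb", 1, 0, p), c(0, -12.5 * (3 + 1)))
  expect_error(lattice_point("hexagonal", 0, 0, p), "unknown lattice type")
})

test_that("helix axis points advance by the rise and move rigidly", {
  p <- geometry_params()
  lat <- unf_lattice(0L, type = "square")
  vh <- unf_virtual_helix(1L, 1L, 2L)
  a0 <- helix_axis_position(lat, vh, 0, p)
  expect_equal(a0, c(50, -25, 0))
  a1 <- helix_axis_position(lat, vh, 1, p)
  expect_equal(sqrt(sum((a1 - a0)^2)), p$risePerBp)

  latT <- lat; latT$position <- c(7, -3, 11)
  expect_equal(helix_axis_position(latT, vh, 5, p),
               helix_axis_position(lat, vh, 5, p) + c(7, -3, 11))
})

test_that("implicit frames follow the ideal B-form construction", {
  p <- geometry_params()
  lat <- unf_lattice(0L, type = "square")
  vh <- unf_virtual_helix(1L, 0L, 0L)

  f <- implicit_frame(lat, vh, 0L, "fiveToThree", 0L, 1L, p)
  expect_equal(f$hydrogenFaceDir, c(1, 0, 0))
  expect_equal(sum(f$hydrogenFaceDir * f$baseNormal), 0)
  # base and backbone sit opposite a1 at their radii
  expect_equal(f$nucleobaseCenter, c(-p$baseRadius, 0, 0))
  expect_equal(f$backboneCenter, c(-p$backboneRadius, 0, 0))

  # paired nucleotides in one normal cell are antiparallel (gamma = 0)
  g <- implicit_frame(lat, vh, 0L, "threeToFive", 0L, 1L, p)
  expect_equal(sum(f$hydrogenFaceDir * g$hydrogenFaceDir), -1)
  expect_equal(sum(f$baseNormal * g$baseNormal), -1)

  # successive cells are rotated by exactly the twist
  f1 <- implicit_frame(lat, vh, 1L, "fiveToThree", 0L, 1L, p)
  ang <- acos(sum(f$hydrogenFaceDir * f1$hydrogenFaceDir)) * 180 / pi
  expect_equal(ang, 33.75)
  # honeycomb default twist is 360*2/21
  lath <- unf_lattice(0L, type = "honeycomb")
  h0 <- implicit_frame(lath, vh, 0L, "fiveToThree", 0L, 1L, p)
  h1 <- implicit_frame(lath, vh, 1L, "fiveToThree", 0L, 1L, p)
  expect_equal(acos(sum(h0$hydrogenFaceDir * h1$hydrogenFaceDir)) * 180 / pi,
               360 * 2 / 21)
})

test_that("frames satisfy unit and orthogonality invariants under rigid motion", {
  p <- geometry_params(grooveOffset = 24)
  set.seed(42)
  for (k in 1:25) {
    lat <- unf_lattice(0L, type = sample(c("square", "honeycomb"), 1),
                       position = runif(3, -100, 100),
                       orientation = runif(3, -180, 180))
    vh <- unf_virtual_helix(1L, sample(0:5, 1), sample(0:5, 1),
                            initialAngle = runif(1, 0, 360))
    dir <- sample(c("fiveToThree", "threeToFive"), 1)
    subCount <- sample(1:3, 1)
    f <- implicit_frame(lat, vh, sample(0:40, 1), dir,
                        sample(seq_len(subCount), 1) - 1L, subCount, p)
    expect_unit(f$baseNormal, 1e-9)
    expect_unit(f$hydrogenFaceDir, 1e-9)
    expect_lt(abs(sum(f$baseNormal * f$hydrogenFaceDir)), 1e-9)
  }

  # rotating the lattice rotates every frame identically
  lat0 <- unf_lattice(0L, type = "square")
  latR <- lat0; latR$orientation <- c(0, 0, 90)
  vh <- unf_virtual_helix(1L, 0L, 1L)
  f0 <- implicit_frame(lat0, vh, 3L, "fiveToThree", 0L, 1L, p)
  fR <- implicit_frame(latR, vh, 3L, "fiveToThree", 0L, 1L, p)
  rot90 <- function(v) c(-v[2], v[1], v[3])
  expect_equal(fR$backboneCenter, rot90(f0$backboneCenter))
  expect_equal(fR$hydrogenFaceDir, rot90(f0$hydrogenFaceDir))
})

test_that("insertion sub-positions fill [z_i, z_{i+1}) with increasing z", {
  p <- geometry_params()
  lat <- unf_lattice(0L, type = "square")
  vh <- unf_virtual_helix(1L, 0L, 0L)
  i <- 4L; n1 <- 3L   # insertion of length 2 -> 3 nucleotides
  z <- vapply(seq_len(n1) - 1L, function(s)
    implicit_frame(lat, vh, i, "fiveToThree", s, n1, p)$nucleobaseCenter[3],
    double(1))
  expect_true(all(diff(z) > 0))
  expect_true(all(z >= i * p$risePerBp & z < (i + 1) * p$risePerBp))
})

test_that("explicit positions take precedence over the lattice frame", {
  doc <- tiny_strand_doc(c("A", "C"))
  al <- unf_next_id(doc, 2); doc <- al$doc
  cellA <- unf_cell(al$ids[1], 0L, "normal", fiveToThreeNts = 0L)
  cellB <- unf_cell(al$ids[2], 1L, "normal", fiveToThreeNts = 1L)
  al <- unf_next_id(doc, 2); doc <- al$doc
  vh <- unf_virtual_helix(al$ids[1], 0L, 0L, cells = list(cellA, cellB))
  doc$lattices <- list(unf_lattice(al$ids[2], type = "square",
                                   virtualHelices = list(vh)))

  explicit <- unf_frame(c(1, 2, 3), c(4, 5, 6), c(0, 0, 1), c(1, 0, 0))
  doc$structures[[1]]$naStrands[[1]]$nucleotides[[1]]$altPositions <-
    list(explicit)

  # nucleotide 0: explicit record wins over the cell reference
  expect_identical(resolve_nucleotide_position(doc, 0L), explicit)
  # nucleotide 1: lattice-implied frame
  p <- geometry_params()
  expect_equal(resolve_nucleotide_position(doc, 1L),
               implicit_frame(doc$lattices[[1]], vh, 1L, "fiveToThree",
                              0L, 1L, p))
  # dropping the explicit record switches resolution to the implicit frame
  doc2 <- doc
  doc2$structures[[1]]$naStrands[[1]]$nucleotides[[1]]$altPositions <- list()
  expect_equal(resolve_nucleotide_position(doc2, 0L),
               implicit_frame(doc$lattices[[1]], vh, 0L, "fiveToThree",
                              0L, 1L, p))
})

test_that("unplaceable and ambiguous nucleotides raise targeted errors", {
  doc <- tiny_strand_doc(c("A", "C"))
  expect_error(resolve_nucleotide_position(doc, 0L), "unplaceable")

  al <- unf_next_id(doc, 4); doc <- al$doc
  c1 <- unf_cell(al$ids[1], 0L, "normal", fiveToThreeNts = 0L)
  c2 <- unf_cell(al$ids[2], 1L, "normal", fiveToThreeNts = 0L)
  vh <- unf_virtual_helix(al$ids[3], 0L, 0L, cells = list(c1, c2))
  doc$lattices <- list(unf_lattice(al$ids[4], type = "square",
                                   virtualHelices = list(vh)))
  expect_error(resolve_nucleotide_position(doc, 0L), "more than one")
  expect_error(resolve_nucleotide_position(doc, doc$lattices[[1]]$id),
               "not a nucleotide")
})
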