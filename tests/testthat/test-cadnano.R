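blank_vstrand <- function(num, L, row = 0L, col = num) {
  list(num = as.integer(num), row = as.integer(row), col = as.integer(col),
       scaf = matrix(-1L, L, 4L), stap = matrix(-1L, L, 4L),
       skip = integer(L), loop = integer(L), stap_colors = list())
}

as_design <- function(vstrands, name = "hand") {
  d <- list(name = name, vstrands = vstrands)
  class(d) <- "cadnano_design"
  d
}

# independent pointer-walk oracle: follow 3' tuples from a given cell
walk_oracle <- function(design, kind, start) {
  arr <- if (kind == "scaffold") "scaf" else "stap"
  byNum <- new.env()
  for (k in seq_along(design$vstrands))
    byNum[[as.character(design$vstrands[[k]]$num)]] <- k
  out <- list()
  cur <- start
  repeat {
    out[[length(out) + 1L]] <- cur
    t <- design$vstrands[[byNum[[as.character(cur[1])]]]][[arr]][cur[2] + 1L, ]
    if (t[3] == -1L) break
    cur <- c(t[3], t[4])
    if (length(out) > 1000L) stop("oracle runaway")
  }
  do.call(rbind, out)
}

test_that("contiguous staple tuples trace to a single path", {
  v <- blank_vstrand(0L, 8L)
  # 4 staples cells 2..5 running left to right
  for (i in 2:5) {
    v$stap[i + 1L, ] <- c(0L, i - 1L, 0L, i + 1L)
  }
  v$stap[3L, 1:2] <- c(-1L, -1L)   # 5' end at index 2
  v$stap[6L, 3:4] <- c(-1L, -1L)   # 3' end at index 5
  d <- as_design(list(v))
  paths <- trace_strands(d, "staple")
  expect_length(paths, 1L)
  expect_equal(nrow(paths[[1]]$cells), 4L)
  expect_false(paths[[1]]$isCircular)
  expect_equal(paths[[1]]$cells, walk_oracle(d, "staple", c(0L, 2L)),
               ignore_attr = TRUE)
})

test_that("a crossover path visits both helices in tuple order", {
  # hand-built 8-cell scaffold: helix 0 cells 0..3 then helix 1 cells 3..0
  v0 <- blank_vstrand(0L, 4L); v1 <- blank_vstrand(1L, 4L)
  v0$scaf[1, ] <- c(-1L, -1L, 0L, 1L)
  v0$scaf[2, ] <- c(0L, 0L, 0L, 2L)
  v0$scaf[3, ] <- c(0L, 1L, 0L, 3L)
  v0$scaf[4, ] <- c(0L, 2L, 1L, 3L)
  v1$scaf[4, ] <- c(0L, 3L, 1L, 2L)
  v1$scaf[3, ] <- c(1L, 3L, 1L, 1L)
  v1$scaf[2, ] <- c(1L, 2L, 1L, 0L)
  v1$scaf[1, ] <- c(1L, 1L, -1L, -1L)
  d <- as_design(list(v0, v1))
  paths <- trace_strands(d, "scaffold")
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$cells, walk_oracle(d, "scaffold", c(0L, 0L)),
               ignore_attr = TRUE)
  expect_equal(paths[[1]]$cells[, 1], rep(0:1, each = 4))
})

test_that("dangling pointers are reported with coordinates", {
  v <- blank_vstrand(0L, 8L)
  v$stap[1, ] <- c(-1L, -1L, 0L, 5L)   # points at empty cell (0, 5)
  expect_error(trace_strands(as_design(list(v)), "staple"),
               "dangling.*\\(0, 5\\)")
})

test_that("scaffold loops are detected and cut at the minimum-lex cell", {
  v <- blank_vstrand(0L, 4L)
  # circular: 0 -> 1 -> 2 -> 3 -> 0
  v$scaf[1, ] <- c(0L, 3L, 0L, 1L)
  v$scaf[2, ] <- c(0L, 0L, 0L, 2L)
  v$scaf[3, ] <- c(0L, 1L, 0L, 3L)
  v$scaf[4, ] <- c(0L, 2L, 0L, 0L)
  d <- as_design(list(v))
  paths <- trace_strands(d, "scaffold")
  expect_length(paths, 1L)
  expect_true(paths[[1]]$isCircular)

  cut <- cut_circular(paths[[1]])
  expect_false(cut$isCircular)
  expect_equal(cut$cells[1, ], c(0L, 0L), ignore_attr = TRUE)
  expect_equal(sort(cut$cells[, 2]), 0:3)
  # cutting a linear path is a precondition violation
  expect_error(cut_circular(cut), "not circular")
  # deterministic: the same cycle entered elsewhere cuts identically
  rotated <- paths[[1]]
  rotated$cells <- rotated$cells[c(3, 4, 1, 2), ]
  expect_equal(cut_circular(rotated)$cells[1, ], c(0L, 0L),
               ignore_attr = TRUE)
})

test_that("loops and skips map to multiplicities n+1 and 0", {
  v <- blank_vstrand(0L, 8L)
  for (i in 0:3) v$scaf[i + 1L, ] <- c(if (i > 0) c(0L, i - 1L) else c(-1L, -1L),
                                       if (i < 3) c(0L, i + 1L) else c(-1L, -1L))
  v$loop[2] <- 2L   # index 1
  v$skip[3] <- -1L  # index 2
  d <- as_design(list(v))
  path <- trace_strands(d, "scaffold")[[1]]
  expect_identical(apply_loops_skips(path, d), c(1L, 3L, 0L, 1L))

  conflicted <- d
  conflicted$vstrands[[1]]$skip[2] <- -1L
  expect_error(apply_loops_skips(path, conflicted), "both a skip and a loop")
})

test_that("staple color integers convert to #RRGGBB and back", {
  expect_identical(unftools:::.color_hex(13369344L), "#CC0000")
  expect_identical(unftools:::.color_int("#CC0000"), 13369344L)
  for (c0 in c(0L, 255L, 65280L, 16777215L, 29184L))
    expect_identical(unftools:::.color_int(unftools:::.color_hex(c0)), c0)
})

test_that("n input designs give n lattices and n structures", {
  for (n in 1:3) {
    inputs <- lapply(seq_len(n), function(k)
      list(design = make_toy_cadnano(fixture_spec(2, 32, seed = k)),
           latticeType = "square", position = c(100 * k, 0, 0)))
    doc <- cadnano_to_unf(inputs)
    expect_length(doc$lattices, n)
    expect_length(doc$structures, n)
    expect_equal(nrow(unf_validate(doc)), 0L)
  }
})

test_that("insertion and deletion change nucleotide totals by the n+1 rule", {
  base <- make_toy_cadnano(fixture_spec(2, 32, seed = 5))
  with_sites <- make_toy_cadnano(fixture_spec(2, 32, nSkips = 1, nLoops = 1,
                                              seed = 5))
  count_nts <- function(doc) {
    n <- 0L
    for (st in doc$structures) for (s in st$naStrands)
      n <- n + length(s$nucleotides)
    n
  }
  n0 <- count_nts(cadnano_to_unf(base))
  docS <- cadnano_to_unf(with_sites)
  # the loop has value 1 or 2; recover it from the design
  loopVal <- sum(vapply(with_sites$vstrands, function(v) sum(v$loop),
                        integer(1)))
  # each site lies on a cell crossed by both scaffold and staple:
  # the skip removes 2 nucleotides, the loop adds 2 * loopVal
  expect_equal(count_nts(docS), n0 + 2L * loopVal - 2L)

  # multiplicity sum equals the nucleotide count, and cell arrays agree
  for (lat in docS$lattices) for (vh in lat$virtualHelices)
    for (cell in vh$cells) {
      if (cell$type == "deletion") {
        expect_length(cell$fiveToThreeNts, 0L)
        expect_length(cell$threeToFiveNts, 0L)
      }
      if (cell$type == "insertion") {
        expect_gte(length(cell$fiveToThreeNts), 2L)
        expect_equal(length(cell$fiveToThreeNts),
                     length(cell$threeToFiveNts))
      }
    }
})

test_that("conversion output pairs scaffold against staples symmetrically", {
  doc <- cadnano_to_unf(make_toy_cadnano(fixture_spec(4, 32, nLoops = 2,
                                                      seed = 9)))
  idx <- unftools:::unf_index(doc)
  nPaired <- 0L
  for (st in doc$structures) for (s in st$naStrands)
    for (nt in s$nucleotides) if (nt$pair != -1L) {
      mate <- idx[[as.character(nt$pair)]]$obj
      expect_identical(mate$pair, nt$id)
      nPaired <- nPaired + 1L
    }
  expect_gt(nPaired, 0L)
})

test_that("scaffold sequence assignment complements paired staples", {
  des <- make_toy_cadnano(fixture_spec(2, 32, seed = 3))
  seq64 <- paste(rep(c("A", "C", "G", "T"), 16), collapse = "")
  doc <- cadnano_to_unf(list(list(design = des)), scaffold_seq = seq64)
  scaf <- Filter(function(s) s$isScaffold, doc$structures[[1]]$naStrands)[[1]]
  expect_identical(unf_strand_sequence(doc, scaf), seq64)
  idx <- unftools:::unf_index(doc)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  for (s in doc$structures[[1]]$naStrands) {
    if (s$isScaffold) next
    for (nt in s$nucleotides) if (nt$pair != -1L)
      expect_identical(nt$base,
                       unname(comp[idx[[as.character(nt$pair)]]$obj$base]))
  }
})

test_that("Cadnano -> UNF -> Cadnano is the identity on randomized designs", {
  for (seed in 1:25) {
    sp <- random_cadnano_spec(seed)
    des <- make_toy_cadnano(sp)
    doc <- cadnano_to_unf(list(list(design = des,
                                    latticeType = sp$latticeType)))
    expect_equal(nrow(unf_validate(doc)), 0L)
    back <- unf_to_cadnano(doc)
    expect_length(back, 1L)
    expect_identical(back[[1]]$vstrands, des$vstrands)
    # converting the same design twice yields identical documents
    # (modulo the header timestamp, which records wall-clock time)
    if (sp$circularScaffold) {
      doc2 <- cadnano_to_unf(list(list(design = des,
                                       latticeType = sp$latticeType)))
      doc2$creationDate <- doc$creationDate
      expect_identical(unf_write(doc2), unf_write(doc))
    }
  }
})

test_that("cadnano file I/O round trips through JSON", {
  des <- make_toy_cadnano(fixture_spec(3, 32, nSkips = 1, seed = 11))
  tf <- tempfile(fileext = ".json")
  write_cadnano(des, tf)
  again <- read_cadnano(tf)
  expect_identical(again$vstrands, des$vstrands)
  expect_identical(again$name, des$name)
})

test_that("free-form documents export to an empty list with a warning", {
  doc <- tiny_strand_doc(c("A", "C", "G"))
  expect_warning(out <- unf_to_cadnano(doc), "ignored")
  expect_length(out, 0L)

  # an empty lattice gives a design with zero vstrands
  doc2 <- unf_document("empty", "t")
  al <- unf_next_id(doc2); doc2 <- al$doc
  doc2$lattices <- list(unf_lattice(al$ids, type = "square"))
  out2 <- unf_to_cadnano(doc2)
  expect_length(out2, 1L)
  expect_length(out2[[1]]$vstrands, 0L)
})
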