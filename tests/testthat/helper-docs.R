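# Shared in-code fixtures: tiny documents built by hand, residue records
# built from coordinates, and a random-document generator for container
# property tests.

tiny_strand_doc <- function(bases = c("A", "C", "G")) {
  doc <- unf_document("tiny", "test")
  n <- length(bases)
  ids <- seq_len(n) - 1L
  nts <- lapply(seq_len(n), function(q)
    unf_nucleotide(ids[q], bases[q],
                   prev = if (q > 1L) ids[q - 1L] else -1L,
                   next_ = if (q < n) ids[q + 1L] else -1L))
  s <- unf_na_strand(n, name = "s", fivePrimeId = 0L, threePrimeId = n - 1L,
                     nucleotides = nts)
  doc$structures <- list(unf_structure(n + 1L, name = "st",
                                       naStrands = list(s)))
  doc$idCounter <- n + 2L
  doc
}

# residue record from a named coordinate matrix
residue_from_coords <- function(coords, name = "DG", chainId = "A",
                                serial = 1L, isHetero = FALSE,
                                elements = NULL) {
  if (is.null(elements))
    elements <- substr(gsub("[^A-Za-z].*$", "", rownames(coords)), 1L, 1L)
  list(chainId = chainId, serial = serial, name = name, isHetero = isHetero,
       atoms = data.frame(serial = seq_len(nrow(coords)),
                          name = rownames(coords), element = elements,
                          x = coords[, 1], y = coords[, 2], z = coords[, 3],
                          stringsAsFactors = FALSE))
}

# small random document with annotations and 0..3 random binary payloads
random_unf_doc <- function(seed) {
  set.seed(seed)
  doc <- tiny_strand_doc(sample(c("A", "C", "G", "T"), sample(2:6, 1),
                                replace = TRUE))
  doc$name <- paste0("random-", seed)
  al <- unf_next_id(doc); doc <- al$doc
  doc$comments <- list(unf_comment(al$ids, objectId = 0L,
                                   content = "a note with \"quotes\" and }"))
  nAtt <- sample(0:3, 1)
  for (k in seq_len(nAtt)) {
    payload <- as.raw(sample(0:255, sample(0:200, 1), replace = TRUE))
    doc <- unf_embed_file(doc, payload, sprintf("blob%d.bin", k), "bin")
  }
  doc
}

random_cadnano_spec <- function(seed) {
  set.seed(seed + 1000L)
  nH <- sample(2:8, 1)
  lt <- sample(c("square", "honeycomb"), 1)
  L <- if (lt == "honeycomb") sample(c(21L, 42L), 1) else sample(c(32L, 64L), 1)
  fixture_spec(nH, L, lt,
               circularScaffold = sample(c(TRUE, FALSE), 1),
               nSkips = sample(0:3, 1), nLoops = sample(0:3, 1),
               pattern = sample(c("cross", "linear"), 1), seed = seed)
}

expect_unit <- function(v, tol = 1e-9) {
  expect_lt(abs(sqrt(sum(v^2)) - 1), tol)
}
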