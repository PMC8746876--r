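# The hybrid UNF container: a JSON body optionally followed by appended
# external-file payloads, each introduced by a marker line and protected by
# an MD5 digest recorded in the document header.

# Marker dialect is isolated here so it can be swapped wholesale.
UNF_MARKER_PREFIX <- "#INCLUDED_FILE "

#' MD5 digest of a raw vector
#'
#' @param payload A raw vector (possibly empty).
#' @return 32-character lowercase hex digest.
#' @keywords internal
md5_raw <- function(payload) {
  stopifnot(is.raw(payload))
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeBin(payload, tf)
  unname(tools::md5sum(tf))
}

#' Split a UNF container into its JSON body and attachment region
#'
#' The boundary is found by string- and escape-aware brace balancing over
#' the raw bytes, never by scanning for the marker token, so payloads may
#' contain arbitrary binary data (including text that looks like a marker
#' line or JSON).
#'
#' @param raw Raw vector holding the whole container.
#' @return \code{list(jsonText, attachmentRegion)}; the attachment region
#'   is a raw vector with the single leading newline (LF or CRLF) after the
#'   JSON body stripped.
#' @export
unf_split_payload <- function(raw) {
  if (is.character(raw)) raw <- charToRaw(paste(raw, collapse = "\n"))
  stopifnot(is.raw(raw))
  n <- length(raw)
  QUOTE <- as.raw(34L); BSLASH <- as.raw(92L)
  OPEN <- as.raw(c(123L, 91L)); CLOSE <- as.raw(c(125L, 93L))

  first <- which(!raw %in% as.raw(c(32L, 9L, 10L, 13L)))[1L]
  if (is.na(first) || !raw[first] %in% OPEN)
    stop("container does not start with a JSON value (byte offset ",
         if (is.na(first)) n else first, ")")

  events <- which(raw == QUOTE | raw %in% OPEN | raw %in% CLOSE)
  events <- events[events >= first]
  inString <- FALSE
  depth <- 0L
  end <- NA_integer_
  for (p in events) {
    b <- raw[p]
    if (b == QUOTE) {
      # a quote is escaped iff preceded by an odd run of backslashes
      k <- 0L
      while (p - 1L - k >= 1L && raw[p - 1L - k] == BSLASH) k <- k + 1L
      if (k %% 2L == 0L) inString <- !inString
    } else if (!inString) {
      if (b %in% OPEN) depth <- depth + 1L
      else {
        depth <- depth - 1L
        if (depth == 0L) { end <- p; break }
        if (depth < 0L)
          stop("unbalanced JSON in container at byte offset ", p)
      }
    }
  }
  if (is.na(end))
    stop("truncated JSON in container (depth ", depth,
         " at byte offset ", n, ")")

  jsonText <- rawToChar(raw[first:end])
  rest <- if (end < n) raw[(end + 1L):n] else raw(0)
  if (length(rest) >= 2L && rest[1L] == as.raw(13L) && rest[2L] == as.raw(10L))
    rest <- rest[-(1:2)]
  else if (length(rest) >= 1L && rest[1L] == as.raw(10L))
    rest <- rest[-1L]
  list(jsonText = jsonText, attachmentRegion = rest)
}

# Parse the attachment region into a list of attachments.
.parse_attachments <- function(region) {
  out <- list()
  pos <- 1L
  n <- length(region)
  NL <- as.raw(10L)
  nl_at <- which(region == NL)
  while (pos <= n) {
    # skip separator newlines (LF or CRLF) between attachments
    while (pos <= n && region[pos] %in% as.raw(c(10L, 13L))) pos <- pos + 1L
    if (pos > n) break
    lineEnd <- nl_at[nl_at >= pos][1L]
    if (is.na(lineEnd)) lineEnd <- n + 1L
    header <- rawToChar(region[pos:(lineEnd - 1L)])
    header <- sub("\r$", "", header)
    if (!startsWith(header, sub(" $", "", UNF_MARKER_PREFIX)) ||
        !startsWith(header, UNF_MARKER_PREFIX))
      stop("malformed attachment marker at container byte offset ", pos,
           ": ", substr(header, 1, 40))
    spec <- substring(header, nchar(UNF_MARKER_PREFIX) + 1L)
    semi <- regexpr(";", spec, fixed = TRUE)
    if (semi < 0L) stop("attachment marker missing ';': ", header)
    fileId <- as.integer(substr(spec, 1L, semi - 1L))
    filename <- substring(spec, semi + 1L)
    # the payload length is declared in the marker itself so arbitrary
    # binary payloads (which may contain marker-lookalike bytes) are safe
    semi2 <- regexpr(";", filename, fixed = TRUE)
    if (semi2 < 0L) stop("attachment marker missing payload size: ", header)
    nbytes <- as.integer(substring(filename, semi2 + 1L))
    filename <- substr(filename, 1L, semi2 - 1L)
    payloadStart <- lineEnd + 1L
    payloadEnd <- payloadStart + nbytes - 1L
    if (payloadEnd > n)
      stop("attachment ", fileId, " truncated: expected ", nbytes,
           " bytes, container ends early")
    payload <- if (nbytes > 0L) region[payloadStart:payloadEnd] else raw(0)
    if (payloadEnd + 1L <= n && region[payloadEnd + 1L] != NL)
      stop("attachment ", fileId, " payload not followed by newline")
    out[[length(out) + 1L]] <-
      list(fileId = fileId, filename = filename, payload = payload)
    pos <- payloadEnd + 2L
  }
  out
}

#' Write a UNF container
#'
#' Serializes the document's JSON body and appends each attachment after a
#' marker line \code{#INCLUDED_FILE <fileId>;<filename>;<nbytes>}, followed
#' by the raw payload bytes and a terminating newline. Attachments are
#' emitted in increasing \code{fileId} order. The payload byte count in the
#' marker makes the container binary-safe to re-read.
#'
#' @param doc A valid \code{unf_document}. Every external file flagged
#'   \code{isIncluded} must be covered by an attachment.
#' @param attachments List of \code{list(fileId, filename, payload)};
#'   defaults to the attachments queued on the document by
#'   [unf_embed_file()].
#' @param path Optional file path; when given the container is also written
#'   to disk.
#' @return The container as a raw vector, invisibly when \code{path} is given.
#' @export
unf_write <- function(doc, attachments = doc$attachments, path = NULL) {
  efIds <- vapply(doc$externalFiles, function(ef) ef$id, integer(1))
  for (a in attachments)
    if (!a$fileId %in% efIds)
      stop("attachment references unknown external file id ", a$fileId)
  included <- efIds[vapply(doc$externalFiles, function(ef) isTRUE(ef$isIncluded),
                           logical(1))]
  attIds <- vapply(attachments, function(a) as.integer(a$fileId), integer(1))
  missing <- setdiff(included, attIds)
  if (length(missing) > 0L)
    stop("external file(s) flagged isIncluded but no attachment given: ",
         paste(missing, collapse = ", "))

  parts <- list(charToRaw(unf_to_json(doc)))
  if (length(attachments) > 0L) {
    attachments <- attachments[order(attIds)]
    for (a in attachments) {
      marker <- sprintf("\n%s%d;%s;%d\n", UNF_MARKER_PREFIX,
                        as.integer(a$fileId), a$filename, length(a$payload))
      parts[[length(parts) + 1L]] <- charToRaw(marker)
      parts[[length(parts) + 1L]] <- a$payload
      parts[[length(parts) + 1L]] <- as.raw(10L)
    }
  }
  out <- do.call(c, parts)
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

#' Read a UNF container
#'
#' Splits the container, parses and validates the JSON body (validation
#' findings of severity warning are surfaced as R warnings; errors in the
#' body are reported by [unf_validate()] on the returned document, not
#' thrown), parses attachments, and verifies that every external file
#' flagged \code{isIncluded} is present with a matching MD5 digest.
#'
#' @param x A raw vector, or a path to a UNF file.
#' @return \code{list(document, attachments)}; the attachments are also
#'   queued on \code{document$attachments} so the pair round-trips through
#'   [unf_write()] unchanged.
#' @export
unf_read <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- readBin(x, "raw", file.info(x)$size)
  sp <- unf_split_payload(x)
  doc <- unf_from_json(sp$jsonText)
  atts <- .parse_attachments(sp$attachmentRegion)

  attIds <- vapply(atts, function(a) a$fileId, integer(1))
  for (ef in doc$externalFiles) {
    if (!isTRUE(ef$isIncluded)) next
    k <- which(attIds == ef$id)
    if (length(k) == 0L)
      stop("external file ", ef$id, " (", ef$path,
           ") is flagged isIncluded but has no attachment")
    got <- md5_raw(atts[[k[1L]]]$payload)
    if (!identical(got, ef$hash))
      stop("integrity error for external file ", ef$id, ": stored MD5 ",
           ef$hash, " but attachment hashes to ", got)
  }
  doc$attachments <- atts
  list(document = doc, attachments = atts)
}

#' Embed a file payload in a document
#'
#' Registers a new external-file record with a fresh ID,
#' \code{isIncluded = TRUE} and the MD5 digest of the payload, and queues
#' the attachment on the document for the next [unf_write()].
#'
#' @param doc A \code{unf_document}.
#' @param payload Raw vector with the file content.
#' @param filename Name recorded in the marker line and the \code{path} field.
#' @param type Free-text file type tag, e.g. \code{"pdb"}.
#' @return The updated document; the new record's ID is in
#'   \code{attr(, "fileId")}.
#' @export
unf_embed_file <- function(doc, payload, filename, type = "") {
  if (is.character(payload)) payload <- charToRaw(paste(payload, collapse = "\n"))
  al <- unf_next_id(doc)
  doc <- al$doc
  id <- al$ids
  doc$externalFiles[[length(doc$externalFiles) + 1L]] <-
    unf_external_file(id, path = filename, type = type, isIncluded = TRUE,
                      hash = md5_raw(payload))
  doc$attachments[[length(doc$attachments) + 1L]] <-
    list(fileId = id, filename = filename, payload = payload)
  attr(doc, "fileId") <- id
  doc
}

#' Extract an embedded file payload
#'
#' @param doc A \code{unf_document}.
#' @param attachments Attachment list (defaults to those on the document).
#' @param fileId ID of an external file with \code{isIncluded = TRUE}.
#' @return The payload bytes; the MD5 digest is re-verified before return.
#' @export
unf_extract_file <- function(doc, fileId, attachments = doc$attachments) {
  efIds <- vapply(doc$externalFiles, function(ef) ef$id, integer(1))
  k <- which(efIds == fileId)
  if (length(k) == 0L) stop("unknown external file id ", fileId)
  ef <- doc$externalFiles[[k[1L]]]
  if (!isTRUE(ef$isIncluded))
    stop("external file ", fileId, " is not included in the container; ",
         "its content lives at path '", ef$path, "'")
  attIds <- vapply(attachments, function(a) a$fileId, integer(1))
  j <- which(attIds == fileId)
  if (length(j) == 0L) stop("no attachment present for file id ", fileId)
  payload <- attachments[[j[1L]]]$payload
  got <- md5_raw(payload)
  if (!identical(got, ef$hash))
    stop("integrity error for external file ", fileId, ": stored MD5 ",
         ef$hash, " but attachment hashes to ", got)
  payload
}
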