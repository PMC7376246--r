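#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a StructuralEvent
#'
#' @param kind One of `"NRT"`, `"RT"`, `"FUSION"`, `"RING"`.
#' @param participants Character (or numeric) vector of chromosome labels in
#'   written order; length >= 2.
#' @param copies Positive integer number of copies of the derivative.
#' @param breakpointId Optional opaque breakpoint tag; cells sharing it carry
#'   the same nucleotide-level breakpoint.
#' @param uncertain Logical, `TRUE` for calls marked `?`.
#' @return A [StructuralEvent-class] object.
#' @export
#' @examples
#' structuralEvent("NRT", c(2, 4))
structuralEvent <- function(kind, participants, copies = 1L,
                            breakpointId = NA_character_, uncertain = FALSE) {
  new("StructuralEvent", kind = kind,
      participants = as.character(participants),
      copies = as.integer(copies),
      breakpointId = as.character(breakpointId), uncertain = uncertain)
}

#' Parse ISCN-like event notation
#'
#' Parses the compact notation used in SKY karyotype tables:
#' `t(a;b)` for a nonreciprocal translocation, `t(a;b)&t(b;a)` for a
#' reciprocal pair, `f(a;b)` for a fusion and `ring(a;b)` for a ring
#' chromosome; a trailing `?` marks an uncertain call. Two optional suffixes
#' extend the dialect for lossless round-trips: `xN` records N copies of the
#' derivative and `@tag` attaches a breakpoint identity tag, e.g.
#' `"t(2;4)x2@bp7"`.
#'
#' @param text A single notation string.
#' @return A [StructuralEvent-class].
#' @seealso [formatEventNotation()] for the inverse.
#' @export
#' @examples
#' parseEventNotation("t(2;4)")
#' parseEventNotation("ring(11;11)")
#' parseEventNotation("t(13;19)?")
parseEventNotation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- trimws(text)

  breakpointId <- NA_character_
  if (grepl("@", raw, fixed = TRUE)) {
    parts <- strsplit(raw, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[2]))
      .stopf("malformed event notation '%s': bad breakpoint tag", text)
    raw <- parts[1]
    breakpointId <- parts[2]
  }
  copies <- 1L
  m <- regmatches(raw, regexec("^(.*)x([0-9]+)$", raw))[[1]]
  if (length(m) == 3L && grepl(")", m[2], fixed = TRUE)) {
    raw <- m[2]
    copies <- as.integer(m[3])
    if (copies < 1L) .stopf("malformed event notation '%s': copies must be >= 1", text)
  }

  halves <- strsplit(raw, "&", fixed = TRUE)[[1]]
  parseOne <- function(s) {
    mm <- regmatches(s, regexec("^(t|f|ring)\\(([0-9XY]+(;[0-9XY]+)+)\\)(\\?)?$", s))[[1]]
    if (length(mm) == 0L) {
      tok <- sub("\\(.*$", "", s)
      .stopf("malformed event notation '%s': unrecognized token '%s'", text, tok)
    }
    labels <- strsplit(mm[3], ";", fixed = TRUE)[[1]]
    bad <- setdiff(labels, mouseChromosomes())
    if (length(bad))
      .stopf("invalid chromosome label(s) %s in '%s'", paste(bad, collapse = ", "), text)
    list(kind = mm[2], participants = labels, uncertain = identical(mm[5], "?"))
  }

  if (length(halves) == 2L) {
    a <- parseOne(trimws(halves[1]))
    b <- parseOne(trimws(halves[2]))
    if (a$kind != "t" || b$kind != "t")
      .stopf("malformed event notation '%s': '&' joins only t(...) forms", text)
    if (!identical(rev(a$participants), b$participants))
      .stopf("malformed event notation '%s': '&' halves must be reciprocal", text)
    return(structuralEvent("RT", a$participants, copies = copies,
                           breakpointId = breakpointId,
                           uncertain = a$uncertain || b$uncertain))
  }
  if (length(halves) != 1L)
    .stopf("malformed event notation '%s'", text)

  p <- parseOne(halves[1])
  kind <- switch(p$kind, t = "NRT", f = "FUSION", ring = "RING")
  structuralEvent(kind, p$participants, copies = copies,
                  breakpointId = breakpointId, uncertain = p$uncertain)
}

#' Serialize a StructuralEvent back to notation
#'
#' Inverse of [parseEventNotation()]; copies > 1 and breakpoint tags are
#' emitted as `xN` and `@tag` suffixes.
#'
#' @param event A [StructuralEvent-class].
#' @return A single notation string.
#' @export
formatEventNotation <- function(event) {
  stopifnot(is(event, "StructuralEvent"))
  core <- function(kindTok, labels) {
    sprintf("%s(%s)", kindTok, paste(labels, collapse = ";"))
  }
  q <- if (event@uncertain) "?" else ""
  base <- switch(event@kind,
    NRT = paste0(core("t", event@participants), q),
    FUSION = paste0(core("f", event@participants), q),
    RING = paste0(core("ring", event@participants), q),
    RT = paste0(core("t", event@participants), q, "&",
                core("t", rev(event@participants)), q)
  )
  if (event@copies > 1L) base <- paste0(base, "x", event@copies)
  if (!is.na(event@breakpointId)) base <- paste0(base, "@", event@breakpointId)
  base
}

#' Event identity key
#'
#' The identity predicate used everywhere in the package: two events are the
#' same iff kind and the ordered participant tuple match and, when both carry a
#' breakpoint tag, the tags match. An event with a breakpoint tag is keyed by
#' the tag (sequence-level identity); an untagged event is keyed by notation
#' within the scope given (events from different animals are never identified
#' by notation alone, since independent recurrence of the same breakpoint is
#' negligible).
#'
#' @param x A [StructuralEvent-class].
#' @param scope Character scope for untagged events (typically the animal id);
#'   default `""`.
#' @return Character key.
#' @export
setMethod("eventKey", "StructuralEvent", function(x, scope = "") {
  base <- sprintf("%s(%s)", x@kind, paste(x@participants, collapse = ";"))
  if (!is.na(x@breakpointId)) {
    sprintf("%s@%s", base, x@breakpointId)
  } else if (nzchar(scope)) {
    sprintf("%s|%s", base, scope)
  } else {
    base
  }
})
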