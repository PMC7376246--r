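#' @include AllClasses.R AllGenerics.R event-notation.R
NULL

#' Construct a MetaphaseKaryotype
#'
#' @param cellId,sampleId Identifiers.
#' @param counts Named integer vector of intact-chromosome copy numbers over
#'   [mouseChromosomes()]; missing labels default to 0.
#' @param events List of [StructuralEvent-class] objects (or notation strings,
#'   which are parsed).
#' @return A [MetaphaseKaryotype-class].
#' @export
#' @examples
#' metaphaseKaryotype("c1", "s1", baselineCounts())
metaphaseKaryotype <- function(cellId, sampleId, counts, events = list()) {
  full <- stats::setNames(rep(0L, 21L), mouseChromosomes())
  full[names(counts)] <- as.integer(counts)
  events <- lapply(events, function(e)
    if (is.character(e)) parseEventNotation(e) else e)
  new("MetaphaseKaryotype", cellId = cellId, sampleId = sampleId,
      counts = full, events = events)
}

#' Construct a SampleKaryotypeSet
#'
#' @param sampleId,animalId Identifiers.
#' @param site One of `"SVZ_L"`, `"SVZ_R"`, `"PARENCHYMA"`, `"OTHER"`.
#' @param cells List of [MetaphaseKaryotype-class] objects.
#' @param passage Optional integer passage.
#' @return A [SampleKaryotypeSet-class].
#' @export
sampleKaryotypeSet <- function(sampleId, animalId, site, cells,
                               passage = NA_integer_) {
  new("SampleKaryotypeSet", sampleId = sampleId, animalId = animalId,
      site = site, passage = as.integer(passage), cells = cells)
}

#' Accessors for karyoevo classes
#'
#' Standard slot accessors: `cellId`, `sampleId`, `animalId`, `site`,
#' `counts`, `events`, `cells`, `totalCount`, `bins`.
#'
#' `totalCount` counts every chromosomal body on the metaphase spread: the sum
#' of intact-chromosome copy numbers plus the copies of every derivative
#' (translocation product, fusion, ring).
#'
#' @param x An object of the documented classes.
#' @param ... Passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("cellId", "MetaphaseKaryotype", function(x) x@cellId)

#' @rdname accessors
#' @export
setMethod("sampleId", "MetaphaseKaryotype", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "SampleKaryotypeSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "CNVProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("animalId", "SampleKaryotypeSet", function(x) x@animalId)

#' @rdname accessors
#' @export
setMethod("site", "SampleKaryotypeSet", function(x) x@site)

#' @rdname accessors
#' @export
setMethod("counts", "MetaphaseKaryotype", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("events", "MetaphaseKaryotype", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("cells", "SampleKaryotypeSet", function(x) x@cells)

#' @rdname accessors
#' @export
setMethod("totalCount", "MetaphaseKaryotype", function(x) {
  sum(x@counts) + sum(vapply(x@events, function(e) e@copies, integer(1)))
})

#' @rdname accessors
#' @export
setMethod("bins", "CNVProfile", function(x) x@bins)

setMethod("show", "StructuralEvent", function(object) {
  cat(sprintf("StructuralEvent %s\n", formatEventNotation(object)))
})

setMethod("show", "MetaphaseKaryotype", function(object) {
  cat(sprintf("MetaphaseKaryotype %s (sample %s): %d chromosomes, %d event(s)\n",
              object@cellId, object@sampleId, totalCount(object),
              length(object@events)))
})

setMethod("show", "SampleKaryotypeSet", function(object) {
  cat(sprintf("SampleKaryotypeSet %s (animal %s, site %s): %d cell(s)\n",
              object@sampleId, object@animalId, object@site,
              length(object@cells)))
})

setMethod("show", "CNVProfile", function(object) {
  cat(sprintf("CNVProfile %s: %d bins of %d bp on %d chromosome(s)\n",
              object@sampleId, length(object@bins), object@binSize,
              length(unique(as.character(GenomicRanges::seqnames(object@bins))))))
})

setMethod("show", "DistanceConfig", function(object) {
  cat(sprintf("DistanceConfig: wCopy=%g wNrt=%g wOtherEvent=%g wWgd=%g\n",
              object@wCopy, object@wNrt, object@wOtherEvent, object@wWgd))
})

setMethod("show", "FounderClone", function(object) {
  cat(sprintf("FounderClone %s: %d member(s), %d shared event(s), wgd=%s\n",
              object@fcId, length(object@memberCells),
              length(object@eventKeys), object@wgd))
})

setMethod("show", "CloneLineage", function(object) {
  cat(sprintf("CloneLineage: %d FC(s), %d ordered edge(s), %d unresolved\n",
              length(object@fcs), nrow(object@edges), nrow(object@unresolved)))
})
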