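#' @include utils.R
#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.EVENT_KINDS <- c("NRT", "RT", "FUSION", "RING")
.SITES <- c("SVZ_L", "SVZ_R", "PARENCHYMA", "OTHER")
.PLOIDY_CLASSES <- c("NEAR_2N", "SUB_4N")
.ACQUISITION_CLASSES <- c("CNRT_2N", "CNRT_4N", "UNDETERMINED", "NOT_APPLICABLE")
.CASE_TYPES <- c("TYPE_1", "TYPE_2", "UNDETERMINED")

#' StructuralEvent: a typed chromosomal aberration
#'
#' Represents one abnormal chromosomal body observed by SKY: a nonreciprocal
#' translocation (`NRT`, written `t(a;b)`), a reciprocal translocation pair
#' (`RT`, written `t(a;b)&t(b;a)`), a fusion (`FUSION`, `f(a;b)`) or a ring
#' chromosome (`RING`, `ring(a;b)`). Participant order is preserved as written:
#' `t(2;4)` and `t(4;2)` are distinct derivatives.
#'
#' Two events are "the same" when kind and the ordered participant tuple match
#' and, when both carry a breakpoint tag, the tags match; breakpoint tags model
#' sequence-level breakpoint identity and override notation-level identity.
#'
#' @slot kind One of `"NRT"`, `"RT"`, `"FUSION"`, `"RING"`.
#' @slot participants Character vector of chromosome labels, length >= 2.
#' @slot copies Positive integer: copies of this derivative in the cell.
#' @slot breakpointId Optional opaque tag (`NA_character_` when absent).
#' @slot uncertain Logical; `TRUE` for calls marked `?`.
#' @export
setClass("StructuralEvent",
  representation(
    kind = "character",
    participants = "character",
    copies = "integer",
    breakpointId = "character",
    uncertain = "logical"
  ),
  prototype(copies = 1L, breakpointId = NA_character_, uncertain = FALSE)
)

setValidity("StructuralEvent", function(object) {
  msgs <- character(0)
  if (length(object@kind) != 1L || !object@kind %in% .EVENT_KINDS)
    msgs <- c(msgs, sprintf("kind must be one of %s",
                            paste(.EVENT_KINDS, collapse = ", ")))
  if (length(object@participants) < 2L)
    msgs <- c(msgs, "participants must have length >= 2")
  bad <- setdiff(object@participants, mouseChromosomes())
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown chromosome label(s): %s",
                            paste(bad, collapse = ", ")))
  if (length(object@copies) != 1L || is.na(object@copies) || object@copies < 1L)
    msgs <- c(msgs, "copies must be a positive integer")
  if (length(msgs)) msgs else TRUE
})

#' MetaphaseKaryotype: one cell's karyotype
#'
#' The single-cell unit of the SKY analysis: the copy number of each of the 21
#' mouse chromosomes plus all structural events recorded for one metaphase.
#'
#' The total chromosome count (see [totalCount()]) counts every chromosomal
#' body on the spread: intact chromosomes plus derivative chromosomes
#' (translocation products, fusions, rings), each weighted by its copy number.
#'
#' @slot cellId Character scalar.
#' @slot sampleId Character scalar.
#' @slot counts Named integer vector over [mouseChromosomes()]: copies of each
#'   intact chromosome.
#' @slot events List of [StructuralEvent-class] objects.
#' @export
setClass("MetaphaseKaryotype",
  representation(
    cellId = "character",
    sampleId = "character",
    counts = "integer",
    events = "list"
  ),
  prototype(events = list())
)

setValidity("MetaphaseKaryotype", function(object) {
  msgs <- character(0)
  if (length(object@cellId) != 1L || !nzchar(object@cellId))
    msgs <- c(msgs, "cellId must be a non-empty string")
  if (!identical(sort(names(object@counts)), sort(mouseChromosomes())))
    msgs <- c(msgs, "counts must be named by the 21 mouse chromosome labels")
  if (any(is.na(object@counts)) || any(object@counts < 0L))
    msgs <- c(msgs, "counts must be non-negative integers")
  total <- sum(object@counts) +
    sum(vapply(object@events, function(e) e@copies, integer(1)))
  if (total < 1L)
    msgs <- c(msgs, "total chromosome count must be >= 1")
  if (!all(vapply(object@events, is, logical(1), "StructuralEvent")))
    msgs <- c(msgs, "events must all be StructuralEvent objects")
  if (length(msgs)) msgs else TRUE
})

#' SampleKaryotypeSet: all metaphases of one sample
#'
#' Groups the metaphase karyotypes of one sample (e.g. one tumor site at one
#' passage) together with the animal and anatomical site it came from. The
#' animal id defines the lineage used by the inter-lineage sharing null.
#'
#' @slot sampleId Character scalar.
#' @slot animalId Character scalar.
#' @slot site One of `"SVZ_L"`, `"SVZ_R"`, `"PARENCHYMA"`, `"OTHER"`.
#' @slot passage Integer passage number or `NA`.
#' @slot cells Non-empty list of [MetaphaseKaryotype-class] objects, all with
#'   this sample's `sampleId`.
#' @export
setClass("SampleKaryotypeSet",
  representation(
    sampleId = "character",
    animalId = "character",
    site = "character",
    passage = "integer",
    cells = "list"
  ),
  prototype(passage = NA_integer_)
)

setValidity("SampleKaryotypeSet", function(object) {
  msgs <- character(0)
  if (!object@site %in% .SITES)
    msgs <- c(msgs, sprintf("site must be one of %s", paste(.SITES, collapse = ", ")))
  if (length(object@cells) == 0L)
    msgs <- c(msgs, "a sample must contain at least one cell")
  ok <- vapply(object@cells, function(x)
    is(x, "MetaphaseKaryotype") && identical(x@sampleId, object@sampleId),
    logical(1))
  if (!all(ok))
    msgs <- c(msgs, "all cells must be MetaphaseKaryotype objects carrying this sampleId")
  if (length(msgs)) msgs else TRUE
})

#' DistanceConfig: weights of the event-weighted distance
#'
#' Weights converting chromosomal events into distance units. Every ordinary
#' event (a single chromosome gain or loss) costs `wCopy`; de novo acquisition
#' of a nonreciprocal translocation costs `wNrt` (the NRT breakpoint is unique
#' at the nucleotide level, hence the high weight); presence differences of
#' other structural events (fusion, ring, reciprocal translocation) cost
#' `wOtherEvent`; whole-genome duplication is one genetic event and costs
#' `wWgd` rather than one unit per duplicated chromosome.
#'
#' @slot wCopy Weight per unit copy-number difference (default 1).
#' @slot wNrt Weight for de novo NRT acquisition (default 5).
#' @slot wOtherEvent Weight for other structural-event presence difference
#'   (default 1).
#' @slot wWgd Weight for whole-genome duplication (default 1).
#' @export
setClass("DistanceConfig",
  representation(wCopy = "numeric", wNrt = "numeric",
                 wOtherEvent = "numeric", wWgd = "numeric"),
  prototype(wCopy = 1, wNrt = 5, wOtherEvent = 1, wWgd = 1)
)

setValidity("DistanceConfig", function(object) {
  w <- c(object@wCopy, object@wNrt, object@wOtherEvent, object@wWgd)
  if (any(!is.finite(w)) || any(w <= 0)) "all weights must be finite and > 0" else TRUE
})

#' CanonicalProfile: a karyotype reduced to distance features
#'
#' Internal normal form on which the pairwise distance is defined: the WGD
#' flag, per-chromosome deviations from the (ploidy-adjusted) euploid
#' baseline, and the structural events with copies and inferred pre-/post-WGD
#' status.
#'
#' @slot cellId Character scalar.
#' @slot wgd Logical.
#' @slot deviations Named numeric vector (counts minus baseline; baseline is
#'   doubled in WGD cells).
#' @slot events data.frame with columns `key`, `kind`, `copies`, `preWgd`.
#' @export
setClass("CanonicalProfile",
  representation(cellId = "character", wgd = "logical",
                 deviations = "numeric", events = "data.frame")
)

#' CNVProfile: binned log2 copy-ratio profile
#'
#' One sample's genome-wide copy-number profile on a fixed-width bin grid
#' (10 kb by default), stored as a `GRanges` with a `log2Ratio` metadata
#' column. Coordinates are 0-based half-open on input and output files;
#' internally the `GRanges` uses the usual 1-based convention.
#'
#' @slot sampleId Character scalar.
#' @slot bins `GRanges` with numeric `log2Ratio` metadata column, sorted and
#'   disjoint.
#' @slot binSize Integer bin width in bp.
#' @export
setClass("CNVProfile",
  representation(sampleId = "character", bins = "GRanges", binSize = "integer"),
  prototype(binSize = 10000L)
)

setValidity("CNVProfile", function(object) {
  msgs <- character(0)
  if (!"log2Ratio" %in% names(S4Vectors::mcols(object@bins)))
    msgs <- c(msgs, "bins must carry a log2Ratio metadata column")
  if (GenomicRanges::isDisjoint(object@bins) == FALSE)
    msgs <- c(msgs, "bins must be non-overlapping")
  st <- GenomicRanges::start(object@bins) - 1L
  if (length(st) && any(st %% object@binSize != 0L))
    msgs <- c(msgs, "bin starts must sit on the bin-size grid")
  if (length(msgs)) msgs else TRUE
})

#' FounderClone: inferred ancestor of a clade of metaphases
#'
#' A founder cell/clone (FC): the extrapolated genotype shared by a maximal
#' clade of metaphases carrying an identical structural-event set and WGD
#' state.
#'
#' @slot fcId Character scalar.
#' @slot wgd Logical.
#' @slot eventKeys Character vector of structural-event identity keys shared
#'   by all members.
#' @slot eventCopies Integer vector parallel to `eventKeys` (minimum copies
#'   over members).
#' @slot deviations Named numeric vector of shared copy-number deviations.
#' @slot memberCells Character vector of member cell ids.
#' @slot sampleIds Character vector: sample of each member.
#' @slot sites Character vector: site of each member.
#' @export
setClass("FounderClone",
  representation(fcId = "character", wgd = "logical",
                 eventKeys = "character", eventCopies = "integer",
                 deviations = "numeric", memberCells = "character",
                 sampleIds = "character", sites = "character")
)

#' CloneLineage: ordered forest of founder clones
#'
#' Parent/child ordering of founder clones under the two evolution rules:
#' whole-genome duplication is irreversible (edges only run from non-WGD to
#' WGD genotypes) and genomes transition from simple to complex (a parent's
#' genotype is a proper subset of its child's, after WGD rescaling).
#'
#' @slot fcs List of [FounderClone-class] objects.
#' @slot edges data.frame with columns `parent`, `child` (fc ids).
#' @slot unresolved data.frame with columns `child`, `candidateParent` for
#'   ambiguous parentage left undecided.
#' @export
setClass("CloneLineage",
  representation(fcs = "list", edges = "data.frame", unresolved = "data.frame")
)

#' SimulationConfig: parameters of the karyotype-evolution simulator
#'
#' See [simulationConfig()] for the user constructor and the meaning and
#' defaults of each rate.
#'
#' @slot seed,nGenerations,nSites,cellsPerSite,binSize Integers.
#' @slot rateGain,rateLoss,rateNrt,rateFusion,rateRing,pWgdPerGeneration,noiseSdLog2 Numerics.
#' @slot postWgdLossTarget Integer vector of length 2 (inclusive range).
#' @slot scenario `"TYPE1"` or `"TYPE2"`.
#' @slot seeding `"PARALLEL"`, `"POLYCLONAL"` or `"MIXED"`.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer", nGenerations = "integer",
    rateGain = "numeric", rateLoss = "numeric",
    rateNrt = "numeric", rateFusion = "numeric", rateRing = "numeric",
    pWgdPerGeneration = "numeric", postWgdLossTarget = "integer",
    scenario = "character", nSites = "integer", cellsPerSite = "integer",
    seeding = "character", noiseSdLog2 = "numeric", binSize = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  pr <- c(object@rateGain, object@rateLoss, object@rateNrt, object@rateFusion,
          object@rateRing, object@pWgdPerGeneration)
  if (any(pr < 0) || any(pr > 1))
    msgs <- c(msgs, "all per-generation probabilities must lie in [0, 1]")
  if (length(object@postWgdLossTarget) != 2L ||
      object@postWgdLossTarget[1] > object@postWgdLossTarget[2])
    msgs <- c(msgs, "postWgdLossTarget must be a valid [lo, hi] range")
  if (!object@scenario %in% c("TYPE1", "TYPE2"))
    msgs <- c(msgs, "scenario must be TYPE1 or TYPE2")
  if (!object@seeding %in% c("PARALLEL", "POLYCLONAL", "MIXED"))
    msgs <- c(msgs, "seeding must be PARALLEL, POLYCLONAL or MIXED")
  if (object@scenario == "TYPE2" && object@rateNrt == 0)
    msgs <- c(msgs, "TYPE2 scenario requires rateNrt > 0 (a founding NRT must be acquirable)")
  if (object@nGenerations < 3L)
    msgs <- c(msgs, "nGenerations must be >= 3")
  if (length(msgs)) msgs else TRUE
})
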