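#' @include accessors.R
NULL

#' Classify ploidy / whole-genome duplication from the chromosome count
#'
#' Mouse tumors with and without whole-genome duplication separate bimodally
#' at ploidy 2.5, i.e. 50 chromosomes in mouse cells; a cell whose total
#' chromosomal body count reaches the cutoff is classified as post-WGD
#' (`SUB_4N`), otherwise near-diploid (`NEAR_2N`). The boundary count itself
#' (exactly 50) falls on the WGD side.
#'
#' @param cell A [MetaphaseKaryotype-class], or an integer total count.
#' @param thresholdCount WGD cutoff, default 50.
#' @return A one-row data.frame with columns `cell_id`, `total_count`, `wgd`,
#'   `class`.
#' @export
#' @examples
#' classifyPloidy(40)$class  # "NEAR_2N"
#' classifyPloidy(70)$class  # "SUB_4N"
classifyPloidy <- function(cell, thresholdCount = 50L) {
  if (is(cell, "MetaphaseKaryotype")) {
    total <- totalCount(cell)
    id <- cellId(cell)
  } else {
    total <- as.integer(cell)
    id <- NA_character_
  }
  stopifnot(total >= 1L)
  wgd <- total >= thresholdCount
  data.frame(cell_id = id, total_count = total, wgd = wgd,
             class = if (wgd) "SUB_4N" else "NEAR_2N",
             stringsAsFactors = FALSE)
}

# Per-cell event table within one sample scope: one row per (cell, event key).
.sampleEventTable <- function(sample) {
  scope <- sample@animalId
  do.call(rbind, c(list(data.frame(cell_id = character(0), key = character(0),
                                   kind = character(0), copies = integer(0),
                                   notation = character(0),
                                   stringsAsFactors = FALSE)),
    lapply(sample@cells, function(cell) {
      if (!length(cell@events)) return(NULL)
      data.frame(
        cell_id = cellId(cell),
        key = vapply(cell@events, eventKey, character(1), scope = scope),
        kind = vapply(cell@events, function(e) e@kind, character(1)),
        copies = vapply(cell@events, function(e) e@copies, integer(1)),
        notation = vapply(cell@events, formatEventNotation, character(1)),
        stringsAsFactors = FALSE
      )
    })))
}

#' Call clonal events in a sample
#'
#' An event is clonal when observed in strictly more than half of the sample's
#' metaphases (frequency > 0.5). Event identity follows [eventKey()] (kind +
#' ordered participants, breakpoint tag overriding when present), scoped to
#' the sample's animal. For clonal NRTs the acquisition class (before vs
#' after whole-genome duplication) is filled in by
#' [classifyCnrtAcquisition()]; non-NRT events get `NOT_APPLICABLE` and
#' non-clonal NRTs `UNDETERMINED`.
#'
#' @param sample A [SampleKaryotypeSet-class].
#' @param includeUncertain Keep events marked `?` (default `TRUE`).
#' @return data.frame with one row per distinct event identity: `key`,
#'   `notation`, `kind`, `sample_id`, `n_carrying`, `n_total`, `frequency`,
#'   `clonal`, `acquisition`.
#' @export
callClonalEvents <- function(sample, includeUncertain = TRUE) {
  stopifnot(is(sample, "SampleKaryotypeSet"))
  nTotal <- length(sample@cells)
  tab <- .sampleEventTable(sample)
  if (!includeUncertain && nrow(tab)) {
    unc <- grepl("?", tab$notation, fixed = TRUE)
    tab <- tab[!unc, , drop = FALSE]
  }
  if (!nrow(tab)) {
    return(data.frame(key = character(0), notation = character(0),
                      kind = character(0), sample_id = character(0),
                      n_carrying = integer(0), n_total = integer(0),
                      frequency = numeric(0), clonal = logical(0),
                      acquisition = character(0), stringsAsFactors = FALSE))
  }
  keys <- unique(tab$key)
  out <- lapply(keys, function(k) {
    sub <- tab[tab$key == k, , drop = FALSE]
    carriers <- unique(sub$cell_id)
    freq <- length(carriers) / nTotal
    clonal <- freq > 0.5
    kind <- sub$kind[1]
    acq <- if (kind != "NRT") {
      "NOT_APPLICABLE"
    } else if (!clonal) {
      "UNDETERMINED"
    } else {
      carryingCells <- Filter(function(cell) cellId(cell) %in% carriers,
                              sample@cells)
      classifyCnrtAcquisition(k, carryingCells, scope = sample@animalId)
    }
    data.frame(key = k, notation = sub("x[0-9]+($|@)", "\\1", sub$notation[1]),
               kind = kind, sample_id = sample@sampleId,
               n_carrying = length(carriers), n_total = nTotal,
               frequency = freq, clonal = clonal, acquisition = acq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify cNRT acquisition relative to whole-genome duplication
#'
#' A clonal NRT acquired at the 2N stage and carried through WGD is present in
#' two copies with two copies of each translocated (participant) chromosome in
#' sub-4N cells, while an NRT acquired after WGD is present in one copy with
#' three copies of each participant. The classifier takes the modal NRT copy
#' number `m` and the modal participant-chromosome count `k` among sub-4N
#' carriers: `m = 2` gives `CNRT_2N`; `m = 1` with `k >= 3` gives `CNRT_4N`.
#' When only near-2N carriers exist and they carry a single copy, the event is
#' the one-copy pre-WGD state (`CNRT_2N`). Modal ties and all other patterns
#' give `UNDETERMINED`.
#'
#' @param event A [StructuralEvent-class] or an event key string.
#' @param carryingCells List of [MetaphaseKaryotype-class] cells all carrying
#'   the event.
#' @param scope Identity scope (animal id) used when `event` is an object.
#' @return `"CNRT_2N"`, `"CNRT_4N"` or `"UNDETERMINED"`.
#' @export
classifyCnrtAcquisition <- function(event, carryingCells, scope = "") {
  if (length(carryingCells) == 0L)
    .stopf("classifyCnrtAcquisition: empty carrier set")
  key <- if (is(event, "StructuralEvent")) eventKey(event, scope = scope) else event

  cellInfo <- lapply(carryingCells, function(cell) {
    evs <- Filter(function(e) eventKey(e, scope = scope) == key, cell@events)
    if (!length(evs))
      .stopf("cell %s does not carry event %s", cellId(cell), key)
    participants <- unique(evs[[1]]@participants)
    list(
      wgd = classifyPloidy(cell)$wgd,
      copies = sum(vapply(evs, function(e) e@copies, integer(1))),
      participantCounts = as.integer(counts(cell)[participants])
    )
  })
  wgdFlags <- vapply(cellInfo, `[[`, logical(1), "wgd")
  sub4n <- cellInfo[wgdFlags]

  if (length(sub4n)) {
    m <- .strictMode(vapply(sub4n, `[[`, integer(1), "copies"))
    k <- .strictMode(unlist(lapply(sub4n, `[[`, "participantCounts")))
    if (!is.na(m) && m == 2L) return("CNRT_2N")
    if (!is.na(m) && !is.na(k) && m == 1L && k >= 3L) return("CNRT_4N")
    return("UNDETERMINED")
  }
  # only near-2N carriers: the one-copy pre-WGD state
  m <- .strictMode(vapply(cellInfo, `[[`, integer(1), "copies"))
  if (!is.na(m) && m == 1L) return("CNRT_2N")
  "UNDETERMINED"
}

#' Classify the evolution pattern of an animal from its clonal NRTs
#'
#' Karyotype-based correlate of the radiographic growth pattern: any clonal
#' NRT acquired at the 2N stage (`CNRT_2N`) marks the multifocal `TYPE_2`
#' pattern; otherwise at least one post-WGD clonal NRT (`CNRT_4N`) marks the
#' single-mass `TYPE_1` pattern; animals with no classifiable clonal NRT are
#' `UNDETERMINED`.
#'
#' @param samples List of [SampleKaryotypeSet-class] objects from one animal.
#' @param includeUncertain Passed to [callClonalEvents()].
#' @return `"TYPE_1"`, `"TYPE_2"` or `"UNDETERMINED"`.
#' @export
classifyCaseType <- function(samples, includeUncertain = TRUE) {
  if (is(samples, "SampleKaryotypeSet")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  calls <- do.call(rbind, lapply(samples, callClonalEvents,
                                 includeUncertain = includeUncertain))
  if (is.null(calls) || !nrow(calls)) return("UNDETERMINED")
  clonalNrt <- calls[calls$clonal & calls$kind == "NRT", , drop = FALSE]
  if (any(clonalNrt$acquisition == "CNRT_2N")) return("TYPE_2")
  if (any(clonalNrt$acquisition == "CNRT_4N")) return("TYPE_1")
  "UNDETERMINED"
}
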