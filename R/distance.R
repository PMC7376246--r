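#' @include ploidy.R
NULL

#' Construct a DistanceConfig
#'
#' @param wCopy Weight per unit chromosome copy-number difference (default 1).
#' @param wNrt Weight for de novo NRT acquisition (default 5).
#' @param wOtherEvent Weight for fusion/ring/reciprocal-translocation presence
#'   difference (default 1).
#' @param wWgd Weight for whole-genome duplication (default 1).
#' @return A [DistanceConfig-class].
#' @export
distanceConfig <- function(wCopy = 1, wNrt = 5, wOtherEvent = 1, wWgd = 1) {
  new("DistanceConfig", wCopy = wCopy, wNrt = wNrt,
      wOtherEvent = wOtherEvent, wWgd = wWgd)
}

#' The euploid CONTROL cell
#'
#' A normal progenitor cell without any chromosomal aberration: 40
#' chromosomes (2 per autosome, X = 1, Y = 1 by default), no events. Used as
#' the outgroup/ancestry when building trees.
#'
#' @param sexChromCounts Passed to [baselineCounts()].
#' @param cellId Leaf label, default `"CONTROL"`.
#' @return A [MetaphaseKaryotype-class].
#' @export
controlCell <- function(sexChromCounts = c(X = 1, Y = 1), cellId = "CONTROL") {
  metaphaseKaryotype(cellId, "CONTROL", baselineCounts(sexChromCounts))
}

#' Reduce a karyotype to its canonical distance profile
#'
#' Normal form on which the event-weighted distance is defined:
#' the WGD flag (from [classifyPloidy()]); per-chromosome deviations from the
#' euploid baseline, where the baseline (2 per autosome, 1 per sex chromosome
#' by default) is doubled in WGD cells; and the structural events with copies
#' and pre-/post-WGD status. Within a WGD cell an event present in >= 2 copies
#' is taken as acquired before the duplication (its copies were doubled along
#' with the genome), a single-copy event as acquired after; ties go to
#' post-WGD.
#'
#' @param cell A [MetaphaseKaryotype-class].
#' @param scope Event-identity scope (animal id), default `""`.
#' @param sexChromCounts Baseline sex-chromosome copies, default X=1, Y=1.
#' @param thresholdCount WGD cutoff passed to [classifyPloidy()].
#' @return A [CanonicalProfile-class].
#' @export
canonicalize <- function(cell, scope = "", sexChromCounts = c(X = 1, Y = 1),
                         thresholdCount = 50L) {
  stopifnot(is(cell, "MetaphaseKaryotype"))
  wgd <- classifyPloidy(cell, thresholdCount)$wgd
  base <- baselineCounts(sexChromCounts)
  if (wgd) base <- base * 2L
  dev <- as.numeric(counts(cell)) - as.numeric(base)
  names(dev) <- names(base)

  evs <- cell@events
  etab <- if (length(evs)) {
    keys <- vapply(evs, eventKey, character(1), scope = scope)
    agg <- tapply(vapply(evs, function(e) e@copies, integer(1)), keys, sum)
    kinds <- vapply(evs, function(e) e@kind, character(1))
    kindOf <- kinds[!duplicated(keys)]
    names(kindOf) <- keys[!duplicated(keys)]
    data.frame(key = names(agg), kind = as.character(kindOf[names(agg)]),
               copies = as.integer(agg),
               preWgd = wgd & as.integer(agg) >= 2L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(0), kind = character(0), copies = integer(0),
               preWgd = logical(0), stringsAsFactors = FALSE)
  }
  new("CanonicalProfile", cellId = cellId(cell), wgd = wgd,
      deviations = dev, events = etab)
}

#' Event-weighted distance between two canonical profiles
#'
#' The pairwise dissimilarity underlying the single-cell trees. Every
#' chromosomal event counts by its weight:
#' \deqn{d = w_{wgd}\,|wgd_a - wgd_b| + w_{copy}\sum_{chr}|dev_a - dev_b|
#'       + \sum_{events} w(e)}
#' where an event present in exactly one profile contributes `wNrt` (NRT) or
#' `wOtherEvent` (fusion/ring/RT), and an event present in both contributes
#' `wCopy` per unit difference of ploidy-adjusted copies (copies are halved in
#' a WGD cell when the event predates the duplication, so a cell that acquired
#' an NRT at 2N and then doubled its genome sits at distance 5 + 1 = 6 from
#' normal, not 10).
#'
#' @param a,b [CanonicalProfile-class] objects (or
#'   [MetaphaseKaryotype-class]s, which are canonicalized with defaults).
#' @param cfg A [DistanceConfig-class].
#' @return Non-negative numeric distance; 0 iff the profiles are equal.
#' @export
#' @examples
#' ctrl <- canonicalize(controlCell())
#' nrtCell <- metaphaseKaryotype("c1", "s", baselineCounts(),
#'                               list("t(2;4)"))
#' pairDistance(ctrl, canonicalize(nrtCell))  # 5
pairDistance <- function(a, b, cfg = distanceConfig()) {
  if (is(a, "MetaphaseKaryotype")) a <- canonicalize(a)
  if (is(b, "MetaphaseKaryotype")) b <- canonicalize(b)
  stopifnot(is(a, "CanonicalProfile"), is(b, "CanonicalProfile"),
            identical(names(a@deviations), names(b@deviations)))

  d <- cfg@wWgd * abs(as.numeric(a@wgd) - as.numeric(b@wgd)) +
    cfg@wCopy * sum(abs(a@deviations - b@deviations))

  keys <- union(a@events$key, b@events$key)
  for (k in keys) {
    ia <- match(k, a@events$key)
    ib <- match(k, b@events$key)
    if (is.na(ia) || is.na(ib)) {
      kind <- if (is.na(ia)) b@events$kind[ib] else a@events$kind[ia]
      d <- d + if (kind == "NRT") cfg@wNrt else cfg@wOtherEvent
    } else {
      ca <- a@events$copies[ia] / (if (a@events$preWgd[ia]) 2 else 1)
      cb <- b@events$copies[ib] / (if (b@events$preWgd[ib]) 2 else 1)
      d <- d + cfg@wCopy * abs(ca - cb)
    }
  }
  d
}

#' Build the pairwise distance matrix over a set of cells
#'
#' Computes the full symmetric event-weighted distance matrix, optionally
#' adding a synthetic normal euploid `CONTROL` leaf to serve as the ancestry
#' when rooting the tree.
#'
#' @param cells List of [MetaphaseKaryotype-class] objects (>= 2, unique cell
#'   ids).
#' @param cfg A [DistanceConfig-class].
#' @param includeControl Add the `CONTROL` leaf (default `TRUE`).
#' @param scope Event-identity scope (animal id).
#' @param sexChromCounts,thresholdCount Passed to [canonicalize()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = cell ids.
#' @export
buildDistanceMatrix <- function(cells, cfg = distanceConfig(),
                                includeControl = TRUE, scope = "",
                                sexChromCounts = c(X = 1, Y = 1),
                                thresholdCount = 50L) {
  stopifnot(length(cells) >= 2L)
  if (includeControl)
    cells <- c(cells, list(controlCell(sexChromCounts)))
  ids <- vapply(cells, cellId, character(1))
  if (anyDuplicated(ids))
    .stopf("duplicate cell id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  profs <- lapply(cells, canonicalize, scope = scope,
                  sexChromCounts = sexChromCounts,
                  thresholdCount = thresholdCount)
  n <- length(profs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      m[i, j] <- m[j, i] <- pairDistance(profs[[i]], profs[[j]], cfg)
    }
  }
  m
}
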