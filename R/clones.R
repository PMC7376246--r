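#' @include nj.R
NULL

# signature used to delimit founder clones: the full canonical genotype —
# structural-event identity set, WGD flag and per-chromosome deviations
# (a clone that only lost one more chromosome is a distinct clone)
.cloneSignature <- function(profile) {
  paste(c(if (profile@wgd) "WGD" else "2N", sort(profile@events$key),
          paste(names(profile@deviations), profile@deviations, sep = ":",
                collapse = ",")),
        collapse = "|")
}

# shared per-chromosome deviation across members: common sign, magnitude
# closest to zero; chromosomes disagreeing in sign share nothing
.sharedDeviations <- function(devList) {
  mat <- do.call(rbind, devList)
  apply(mat, 2, function(col) {
    if (all(col > 0)) min(col)
    else if (all(col < 0)) max(col)
    else 0
  })
}

#' Identify founder clones on a rooted single-cell tree
#'
#' A founder cell/clone (FC) is the extrapolated ancestor of a maximal clade
#' whose member metaphases all share an identical structural-event set and WGD
#' state. The FC genotype is the shared material: the common event set (with
#' the minimum copy number over members), the WGD flag, and the shared
#' per-chromosome deviations (the common-sign portion closest to zero).
#' Singleton clades are allowed but flagged low-confidence by callers that
#' filter on clade size.
#'
#' @param tree A rooted `phylo` over the cells (the `CONTROL` leaf, if
#'   present, is ignored).
#' @param cells List of [MetaphaseKaryotype-class] objects covering the tree's
#'   leaves.
#' @param scope Event-identity scope (animal id).
#' @param sites Optional named character vector mapping cell id to site.
#' @return List of [FounderClone-class] objects, in tree (preorder) order.
#'   Singleton FCs (one member cell) are low-confidence by nature; filter on
#'   the member count for the "major clusters" of a cohort-level analysis.
#' @export
identifyFounderClones <- function(tree, cells, scope = "", sites = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ids <- vapply(cells, cellId, character(1))
  names(cells) <- ids
  tips <- setdiff(tree$tip.label, "CONTROL")
  if (!all(tips %in% ids))
    .stopf("cells missing for leaf/leaves: %s",
           paste(setdiff(tips, ids), collapse = ", "))
  if ("CONTROL" %in% tree$tip.label)
    tree <- ape::drop.tip(tree, "CONTROL")

  profs <- lapply(cells[tree$tip.label], canonicalize, scope = scope)
  sig <- vapply(profs, .cloneSignature, character(1))

  nTips <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rootNode <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]

  groups <- list()
  walk <- function(node) {
    if (node <= nTips) {
      groups[[length(groups) + 1L]] <<- node
      return(invisible(NULL))
    }
    kids <- children[[as.character(node)]]
    tipIdx <- .cladeTips(tree, node, children, nTips)
    if (length(unique(sig[tipIdx])) == 1L) {
      groups[[length(groups) + 1L]] <<- tipIdx
    } else {
      for (k in kids) walk(k)
    }
  }
  walk(rootNode)
  # zero-length grades of identical cells can come out paraphyletic; clades
  # carrying the same genotype signature are one clone
  groupSig <- vapply(groups, function(idx) sig[idx[1]], character(1))
  groups <- lapply(split(seq_along(groups), groupSig)[unique(groupSig)],
                   function(gi) unlist(groups[gi]))

  fcs <- lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    members <- tree$tip.label[idx]
    p <- profs[idx]
    etabs <- lapply(p, function(x) x@events)
    keys <- if (nrow(etabs[[1]])) sort(etabs[[1]]$key) else character(0)
    copies <- if (length(keys)) {
      vapply(keys, function(k) {
        min(vapply(etabs, function(et) et$copies[match(k, et$key)], integer(1)))
      }, integer(1))
    } else integer(0)
    memberSamples <- vapply(cells[members], sampleId, character(1))
    memberSites <- if (is.null(sites)) rep(NA_character_, length(members))
                   else unname(sites[members])
    new("FounderClone", fcId = sprintf("FC%d", g), wgd = p[[1]]@wgd,
        eventKeys = keys, eventCopies = unname(copies),
        deviations = .sharedDeviations(lapply(p, function(x) x@deviations)),
        memberCells = members, sampleIds = unname(memberSamples),
        sites = memberSites)
  })
  fcs
}

.cladeTips <- function(tree, node, children, nTips) {
  if (node <= nTips) return(node)
  unlist(lapply(children[[as.character(node)]], .cladeTips,
                tree = tree, children = children, nTips = nTips))
}

# genotype complexity: number of events in the genotype (structural events +
# WGD + aneuploid chromosomes)
.fcComplexity <- function(fc) {
  length(fc@eventKeys) + as.integer(fc@wgd) + sum(fc@deviations != 0)
}

# is genotype of g contained in genotype of h (g a potential ancestor of h)?
# WGD is irreversible; when g is pre-WGD and h post-WGD, g's copies and
# deviations are doubled before comparison, and subsequent losses in h are
# allowed.
.fcContained <- function(g, h) {
  if (g@wgd && !h@wgd) return(FALSE)
  if (!all(g@eventKeys %in% h@eventKeys)) return(FALSE)
  rescale <- (!g@wgd) && h@wgd
  devG <- g@deviations * (if (rescale) 2 else 1)
  # losses established in the ancestor persist (possibly deepen); gains may be
  # extended or reverted only by explicitly recorded loss events, which the
  # deviation sign tracks, so require gains not to flip sign
  ok <- all(ifelse(devG < 0, h@deviations <= devG + 1e-9,
                   ifelse(devG > 0, h@deviations >= -1e-9, TRUE)))
  ok
}

.fcProperSubset <- function(g, h) {
  .fcContained(g, h) && .fcComplexity(g) < .fcComplexity(h)
}

#' Order founder clones into a lineage
#'
#' Determines the evolutionary order of founder clones under the two rules
#' used for SKY-based trees: (1) whole-genome duplication is an irreversible
#' transition from a near-2N to a sub-4N clone followed by random chromosome
#' losses, and (2) genomes transition from simple to complex by accumulating
#' events. Each FC's parent is the FC whose genotype is the maximal proper
#' subset of its own (after WGD rescaling); when two incomparable candidates
#' tie at maximal complexity the parentage is recorded as unresolved rather
#' than guessed.
#'
#' @param fcs List of [FounderClone-class] objects from one animal.
#' @return A [CloneLineage-class].
#' @export
orderFounderClones <- function(fcs) {
  stopifnot(length(fcs) >= 1L)
  ids <- vapply(fcs, function(f) f@fcId, character(1))
  names(fcs) <- ids
  edges <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  unresolved <- data.frame(child = character(0), candidateParent = character(0),
                           stringsAsFactors = FALSE)
  for (child in ids) {
    cand <- ids[vapply(ids, function(p)
      p != child && .fcProperSubset(fcs[[p]], fcs[[child]]), logical(1))]
    if (!length(cand)) next
    comp <- vapply(fcs[cand], .fcComplexity, numeric(1))
    best <- cand[comp == max(comp)]
    if (length(best) == 1L) {
      edges <- rbind(edges, data.frame(parent = best, child = child,
                                       stringsAsFactors = FALSE))
    } else {
      unresolved <- rbind(unresolved,
                          data.frame(child = child, candidateParent = best,
                                     stringsAsFactors = FALSE))
    }
  }
  new("CloneLineage", fcs = fcs, edges = edges, unresolved = unresolved)
}

#' Infer multi-site seeding patterns from founder clones
#'
#' Classifies the dispersal mode across anatomical sites: a site seeded by
#' more than one FC shows polyclonal seeding; an FC whose descendants occupy
#' more than one site shows parallel seeding.
#'
#' @param fcs List of [FounderClone-class] objects with site annotations.
#' @return List with `siteTable` (site by FC count matrix),
#'   `polyclonalSeeding` (sites seeded by > 1 FC) and `parallelSeeding`
#'   (FCs seeding > 1 site).
#' @export
inferSeedingPattern <- function(fcs) {
  stopifnot(length(fcs) >= 1L)
  rows <- do.call(rbind, lapply(fcs, function(fc) {
    data.frame(fc = fc@fcId, site = fc@sites, stringsAsFactors = FALSE)
  }))
  rows <- rows[!is.na(rows$site), , drop = FALSE]
  if (!nrow(rows)) .stopf("no site annotations on the founder clones")
  tab <- table(rows$site, rows$fc)
  fcPerSite <- apply(tab > 0, 1, sum)
  sitePerFc <- apply(tab > 0, 2, sum)
  list(
    siteTable = tab,
    polyclonalSeeding = names(fcPerSite)[fcPerSite > 1],
    parallelSeeding = names(sitePerFc)[sitePerFc > 1]
  )
}
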