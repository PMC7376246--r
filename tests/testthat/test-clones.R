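buildTreeFor <- function(cellList, scope = "A1") {
  d <- buildDistanceMatrix(cellList, scope = scope)
  rootWithOutgroup(neighborJoining(d))
}

test_that("identical cells collapse into a single founder clone", {
  nrt <- structuralEvent("NRT", c("2", "4"), breakpointId = "bp1")
  cellList <- lapply(1:5, function(i)
    makeCell(sprintf("c%d", i), delta = c("16" = -1), events = list(nrt)))
  fcs <- identifyFounderClones(buildTreeFor(cellList), cellList, scope = "A1")
  expect_length(fcs, 1)
  expect_setequal(fcs[[1]]@memberCells, sprintf("c%d", 1:5))
  expect_equal(fcs[[1]]@eventKeys, eventKey(nrt, scope = "A1"))
  expect_equal(unname(fcs[[1]]@deviations[["16"]]), -1)
})

test_that("nested genotypes split into nested founder clones", {
  nrt <- structuralEvent("NRT", c("2", "4"), breakpointId = "bp1")
  plain <- lapply(1:4, function(i) makeCell(sprintf("p%d", i),
                                            delta = c("16" = -1)))
  withNrt <- lapply(1:4, function(i) makeCell(sprintf("w%d", i),
                                              delta = c("16" = -1),
                                              events = list(nrt)))
  cellList <- c(plain, withNrt)
  fcs <- identifyFounderClones(buildTreeFor(cellList), cellList, scope = "A1")
  expect_length(fcs, 2)
  keySets <- lapply(fcs, function(f) f@eventKeys)
  expect_true(any(vapply(keySets, length, integer(1)) == 0))
  expect_true(any(vapply(keySets, length, integer(1)) == 1))
  # chr16 loss is shared by both clones
  for (f in fcs) expect_equal(unname(f@deviations[["16"]]), -1)

  lin <- orderFounderClones(fcs)
  expect_equal(nrow(lin@edges), 1)
  parent <- lin@fcs[[lin@edges$parent]]
  expect_length(parent@eventKeys, 0)  # simpler genome is ancestral
})

test_that("a planted four-clone chain is ordered along its true path", {
  # FC0 {chr16-} -> FC1 {+t(2;4) 1x} -> FC2 {+chr18-} -> FC3 {WGD, t(2;4) 2x}
  nrt1 <- function(k) structuralEvent("NRT", c("2", "4"), copies = k,
                                      breakpointId = "bp1")
  mk <- function(pfx, n, ...) lapply(seq_len(n), function(i)
    makeCell(sprintf("%s%d", pfx, i), ...))
  fc0 <- mk("a", 3, delta = c("16" = -1))
  fc1 <- mk("b", 3, delta = c("16" = -1), events = list(nrt1(1L)))
  fc2 <- mk("c", 3, delta = c("16" = -1, "18" = -1), events = list(nrt1(1L)))
  fc3 <- mk("d", 3, delta = c("16" = -2, "18" = -2), events = list(nrt1(2L)),
            wgdTimes = 2L)
  cellList <- c(fc0, fc1, fc2, fc3)
  fcs <- identifyFounderClones(buildTreeFor(cellList), cellList, scope = "A1")
  expect_length(fcs, 4)
  lin <- orderFounderClones(fcs)
  expect_equal(nrow(lin@edges), 3)

  # reconstruct the chain: member prefix identifies the planted clone
  cloneOf <- function(fcId) {
    f <- lin@fcs[[fcId]]
    unique(substr(f@memberCells, 1, 1))
  }
  chain <- setNames(vapply(lin@edges$child, cloneOf, character(1)),
                    vapply(lin@edges$parent, cloneOf, character(1)))
  expect_equal(unname(chain[c("a", "b", "c")]), c("b", "c", "d"))
})

test_that("WGD edges only run from near-2N to sub-4N genotypes", {
  nrt <- function(k) structuralEvent("NRT", c("2", "4"), copies = k,
                                     breakpointId = "bp1")
  near <- lapply(1:3, function(i) makeCell(sprintf("n%d", i),
                                           events = list(nrt(1L))))
  post <- lapply(1:3, function(i) makeCell(sprintf("p%d", i), wgdTimes = 2L,
                                           events = list(nrt(2L))))
  cellList <- c(near, post)
  fcs <- identifyFounderClones(buildTreeFor(cellList), cellList, scope = "A1")
  lin <- orderFounderClones(fcs)
  expect_equal(nrow(lin@edges), 1)
  expect_false(lin@fcs[[lin@edges$parent]]@wgd)
  expect_true(lin@fcs[[lin@edges$child]]@wgd)
})

test_that("clones with disjoint private events stay unordered siblings", {
  e1 <- structuralEvent("NRT", c("2", "4"), breakpointId = "bp1")
  e2 <- structuralEvent("NRT", c("3", "8"), breakpointId = "bp2")
  g1 <- lapply(1:3, function(i) makeCell(sprintf("x%d", i), events = list(e1)))
  g2 <- lapply(1:3, function(i) makeCell(sprintf("y%d", i), events = list(e2)))
  cellList <- c(g1, g2)
  fcs <- identifyFounderClones(buildTreeFor(cellList), cellList, scope = "A1")
  lin <- orderFounderClones(fcs)
  expect_equal(nrow(lin@edges), 0)
})

test_that("founder-clone genotypes equal the intersection of member event sets", {
  for (sd in c(5, 9)) {
    case <- simulateCase(simulationConfig(seed = sd))
    cellsAll <- unlist(lapply(case$samples, cells), recursive = FALSE)
    tr <- buildTreeFor(cellsAll, scope = "M1")
    fcs <- identifyFounderClones(tr, cellsAll, scope = "M1")
    byId <- setNames(cellsAll, vapply(cellsAll, cellId, character(1)))
    for (fc in fcs) {
      memberKeySets <- lapply(byId[fc@memberCells], function(cl)
        canonicalize(cl, scope = "M1")@events$key)
      expect_setequal(fc@eventKeys, Reduce(intersect, memberKeySets))
    }
    # the lineage is a forest with WGD monotone along edges
    lin <- orderFounderClones(fcs)
    for (i in seq_len(nrow(lin@edges)))
      expect_true(lin@fcs[[lin@edges$parent[i]]]@wgd <=
                    lin@fcs[[lin@edges$child[i]]]@wgd)
  }
})

test_that("seeding patterns flag multi-FC sites and multi-site FCs", {
  fcA <- new("FounderClone", fcId = "FC1", wgd = FALSE,
             eventKeys = character(0), eventCopies = integer(0),
             deviations = setNames(rep(0, 21), mouseChromosomes()),
             memberCells = c("a", "b", "c"),
             sampleIds = c("S1", "S2", "S3"),
             sites = c("SVZ_R", "PARENCHYMA", "OTHER"))
  fcB <- new("FounderClone", fcId = "FC2", wgd = FALSE,
             eventKeys = "k", eventCopies = 1L,
             deviations = setNames(rep(0, 21), mouseChromosomes()),
             memberCells = "d", sampleIds = "S2", sites = "PARENCHYMA")
  rep1 <- inferSeedingPattern(list(fcA, fcB))
  expect_true("FC1" %in% rep1$parallelSeeding)       # one FC, three sites
  expect_true("PARENCHYMA" %in% rep1$polyclonalSeeding)  # site with two FCs

  solo <- inferSeedingPattern(list(fcB))
  expect_length(solo$parallelSeeding, 0)
  expect_length(solo$polyclonalSeeding, 0)
})
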