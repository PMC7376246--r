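test_that("a null configuration yields only normal euploid cells", {
  cfg <- simulationConfig(seed = 1, scenario = "TYPE1", nGenerations = 5,
                          rateGain = 0, rateLoss = 0, rateNrt = 0,
                          rateFusion = 0, rateRing = 0)
  case <- simulateCase(cfg)
  cellsAll <- unlist(lapply(case$samples, cells), recursive = FALSE)
  expect_true(all(vapply(cellsAll, totalCount, integer(1)) == 40L))
  d <- buildDistanceMatrix(cellsAll, includeControl = FALSE)
  expect_true(all(d == 0))
  expect_equal(nrow(case$truth$plantedEvents), 0)
})

test_that("TYPE2 requires an acquirable NRT", {
  expect_error(simulationConfig(seed = 1, scenario = "TYPE2", rateNrt = 0),
               "rateNrt")
})

test_that("the founding NRT shows 1 copy in near-2N and 2 copies in sub-4N cells", {
  case <- simulateCase(simulationConfig(seed = 6))
  bp <- case$truth$foundingNrtId
  copiesIn <- function(cell) {
    hit <- Filter(function(e) identical(e@breakpointId, bp), events(cell))
    if (!length(hit)) NA_integer_ else sum(vapply(hit, function(e) e@copies,
                                                  integer(1)))
  }
  svz <- cells(case$samples$SVZR)
  near <- Filter(function(c) !classifyPloidy(c)$wgd, svz)
  nearCopies <- stats::na.omit(vapply(near, copiesIn, integer(1)))
  expect_gt(length(nearCopies), 0)
  expect_equal(sort(unique(nearCopies)), 1L)

  tum <- cells(case$samples$T1)
  subCopies <- stats::na.omit(vapply(tum, copiesIn, integer(1)))
  modal <- as.integer(names(sort(table(subCopies), decreasing = TRUE))[1])
  expect_equal(modal, 2L)
})

test_that("simulation is deterministic per seed, byte for byte", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sizes <- c("1" = 60000L, "11" = 40000L)
  p1 <- exportFixtures(simulateCase(simulationConfig(seed = 12)), dir1,
                       chromSizes = sizes)
  p2 <- exportFixtures(simulateCase(simulationConfig(seed = 12)), dir2,
                       chromSizes = sizes)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  # a different seed gives a different cohort
  dir3 <- withr::local_tempdir()
  p3 <- exportFixtures(simulateCase(simulationConfig(seed = 13)), dir3,
                       chromSizes = sizes)
  expect_false(identical(readLines(p1[["karyotypes"]]),
                         readLines(p3[["karyotypes"]])))
})

test_that("every sampled cell replays exactly from its ledger", {
  for (scenario in c("TYPE2", "TYPE1")) {
    case <- simulateCase(simulationConfig(seed = 8, scenario = scenario))
    byId <- list()
    for (s in case$samples) for (cl in cells(s)) byId[[cellId(cl)]] <- cl
    for (nm in names(case$truth$ledgers)) {
      rp <- replayCellLedger(case$truth$ledgers[[nm]])
      expect_identical(rp$counts, counts(byId[[nm]]), info = nm)
      evCopies <- vapply(events(byId[[nm]]), function(e) e@copies, integer(1))
      names(evCopies) <- vapply(events(byId[[nm]]), function(e) e@breakpointId,
                                character(1))
      rpCopies <- vapply(rp$events, `[[`, integer(1), "copies")
      expect_length(rpCopies, length(evCopies))
      for (bp in names(evCopies))
        expect_equal(rpCopies[[bp]], evCopies[[bp]], info = paste(nm, bp))
    }
  }
})

test_that("sub-4N cells land in the 60-80 chromosome range on average", {
  totals <- unlist(lapply(1:10, function(sd) {
    case <- simulateCase(simulationConfig(seed = sd))
    cellsAll <- unlist(lapply(case$samples, cells), recursive = FALSE)
    tc <- vapply(cellsAll, totalCount, integer(1))
    tc[tc >= 50L]
  }))
  expect_gt(length(totals), 50)
  expect_gte(mean(totals), 60)
  expect_lte(mean(totals), 80)
})

test_that("the true genealogy covers the sampled cells with finite branch lengths", {
  case <- simulateCase(simulationConfig(seed = 14))
  tr <- case$trueTree
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, case$truth$cellTruth$cell_id)
  expect_true(all(is.finite(tr$edge.length)))
  expect_true(all(tr$edge.length >= 0))
})

test_that("binned profiles reflect the karyotype on the 10-kb grid", {
  sizes <- c("1" = 100000L, "19" = 60000L)
  # normal cell, zero noise: autosome bins sit at log2(1) = 0
  prof <- karyotypeToBins(makeCell("n"), chromSizes = sizes)
  expect_true(all(S4Vectors::mcols(bins(prof))$log2Ratio == 0))
  # chr19 single copy against a diploid median: -1
  prof19 <- karyotypeToBins(makeCell("l", delta = c("19" = -1)),
                            chromSizes = sizes)
  vals <- split(S4Vectors::mcols(bins(prof19))$log2Ratio,
                as.character(GenomicRanges::seqnames(bins(prof19))))
  expect_true(all(vals[["19"]] == -1))
  expect_true(all(vals[["1"]] == 0))
  # with noise sigma = 0.1 the per-chromosome median stays within 0.05
  profN <- karyotypeToBins(makeCell("m", delta = c("19" = -1)),
                           noiseSdLog2 = 0.1, seed = 9)
  med <- wgsChromLog2(profN)
  expect_lt(abs(med[["19"]] - (-1)), 0.05)
  expect_lt(max(abs(med[as.character(1:18)])), 0.05)
})
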