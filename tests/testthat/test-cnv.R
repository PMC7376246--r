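flatProfile <- function(id, chroms = c("1" = 5L), value = 0, binSize = 10000L) {
  df <- do.call(rbind, lapply(names(chroms), function(chr) {
    starts <- (seq_len(chroms[[chr]]) - 1L) * binSize
    data.frame(chrom = chr, start = starts, end = starts + binSize,
               log2_ratio = value, stringsAsFactors = FALSE)
  }))
  cnvProfile(id, df, binSize = binSize)
}

setBin <- function(profile, i, value) {
  gr <- bins(profile)
  S4Vectors::mcols(gr)$log2Ratio[i] <- value
  methods::new("CNVProfile", sampleId = sampleId(profile), bins = gr,
               binSize = profile@binSize)
}

test_that("both bin-table dialects read onto the 10-kb grid", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tlog2_ratio",
               "1\t0\t10000\t0.2", "1\t10000\t20000\t-0.3",
               "2\t0\t10000\t0.1"), p)
  prof <- readBinTable(p, sampleId = "s")
  expect_s4_class(prof, "CNVProfile")
  expect_length(bins(prof), 3)
  expect_equal(S4Vectors::mcols(bins(prof))$log2Ratio, c(0.2, -0.3, 0.1))

  # Control-FREEC dialect: linear ratio 1.0 -> log2 0
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chrom\tstart\tratio", "1\t0\t1", "1\t10000\t0.5"), p2)
  prof2 <- readBinTable(p2, sampleId = "s2")
  expect_equal(S4Vectors::mcols(bins(prof2))$log2Ratio, c(0, -1))

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tlog2_ratio", "1\t5000\t15000\t0"), p3)
  expect_error(readBinTable(p3), "off-grid.*1:5000")

  pr <- flatProfile("rt", c("1" = 4L, "2" = 3L), value = 0.25)
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeBinTable(pr, p4)
  expect_equal(readBinTable(p4, sampleId = "rt"), pr, ignore_attr = TRUE)
})

test_that("SKY per-chromosome log2 follows log2(ci / median(c))", {
  expect_true(all(skyChromLog2(list(makeCell("n"), makeCell("n2"))) ==
                    c(rep(0, 19), -1)))  # X sits at half the autosome median
  # chr19 at half the median
  sky <- skyChromLog2(list(makeCell("a", delta = c("19" = -1, "X" = 1))))
  expect_equal(unname(sky[["19"]]), -1)
  expect_equal(unname(sky[["1"]]), 0)
  # ploidy cancels: a pure-WGD population maps onto its diploid ancestor
  diploid <- list(makeCell("d1"), makeCell("d2", delta = c("3" = 1)))
  doubled <- list(makeCell("w1", wgdTimes = 2L),
                  makeCell("w2", wgdTimes = 2L, delta = c("3" = 2)))
  expect_equal(skyChromLog2(doubled), skyChromLog2(diploid))
  # averaged over a mixed population
  sky2 <- skyChromLog2(list(makeCell("m1", delta = c("5" = 2)),
                            makeCell("m2")))
  expect_equal(unname(sky2[["5"]]), log2(3 / 2))
})

test_that("WGS per-chromosome value is a median robust to outlier bins", {
  prof <- flatProfile("s", c("1" = 9L), value = 0.585)
  expect_equal(unname(wgsChromLog2(prof)[["1"]]), 0.585)
  spiked <- setBin(prof, 5, 8)
  expect_equal(unname(wgsChromLog2(spiked)[["1"]]), 0.585)
})

test_that("SKY/WGS comparison computes Pearson r over shared chromosomes", {
  sky <- c("1" = 0.5, "2" = -1, "3" = 0, "4" = 0.3)
  expect_equal(compareSkyWgs(sky, sky)$pearson_r, 1)
  expect_equal(compareSkyWgs(sky, -sky)$pearson_r, -1)
  flat <- c("1" = 0, "2" = 0, "3" = 0)
  expect_true(compareSkyWgs(flat, flat)$undefined)
  expect_error(compareSkyWgs(sky[1:2], sky[1:2]), ">= 3")

  # noiseless matched synthetic pair: bins generated from the same karyotype
  cell <- makeCell("cl", delta = c("19" = -1, "3" = 1, "X" = 1))
  cmp <- compareSkyWgs(skyChromLog2(list(cell)),
                       wgsChromLog2(karyotypeToBins(cell)))
  expect_equal(cmp$pearson_r, 1, tolerance = 1e-12)
})

test_that("the L1 distance is the summed absolute bin difference and a metric", {
  a <- flatProfile("a", c("1" = 3L))
  expect_equal(cnvL1Distance(a, a), 0)
  b <- setBin(a, 2, 0.5)
  expect_equal(cnvL1Distance(a, b), 0.5)
  toy1 <- flatProfile("t1", c("1" = 3L))
  toy2 <- setBin(setBin(setBin(toy1, 1, 0.2), 2, -0.3), 3, 0.1)
  expect_equal(cnvL1Distance(toy1, toy2), 0.6)

  set.seed(41)
  profs <- lapply(1:6, function(i) {
    pr <- flatProfile(sprintf("p%d", i), c("1" = 8L))
    gr <- bins(pr)
    S4Vectors::mcols(gr)$log2Ratio <- round(rnorm(8, 0, 0.5), 3)
    methods::new("CNVProfile", sampleId = sampleId(pr), bins = gr,
                 binSize = 10000L)
  })
  for (i in 1:6) for (j in 1:6) {
    dij <- cnvL1Distance(profs[[i]], profs[[j]])
    expect_gte(dij, 0)
    expect_equal(dij, cnvL1Distance(profs[[j]], profs[[i]])) # symmetry
    for (k in 1:6)  # triangle inequality
      expect_lte(dij, cnvL1Distance(profs[[i]], profs[[k]]) +
                        cnvL1Distance(profs[[k]], profs[[j]]) + 1e-12)
  }
})

test_that("CNV trees isolate divergent clones and order WGD states", {
  base <- flatProfile("x", c("1" = 6L))
  same <- lapply(1:3, function(i) {
    methods::new("CNVProfile", sampleId = sprintf("s%d", i),
                 bins = bins(base), binSize = 10000L)
  })
  div <- flatProfile("div", c("1" = 6L), value = 1.5)
  res <- cnvNjTree(c(same, list(div)), includeControl = FALSE)
  lens <- setNames(res$tree$edge.length[
    match(seq_along(res$tree$tip.label), res$tree$edge[, 2])],
    res$tree$tip.label)
  expect_gt(lens[["div"]], max(lens[c("s1", "s2", "s3")]))

  # near-2N clones sit closer to the normal outgroup than their sub-4N
  # counterparts carrying the same lesions plus post-WGD losses
  near <- lapply(1:2, function(i) {
    pr <- flatProfile(sprintf("near%d", i), c("1" = 4L, "2" = 4L, "3" = 4L))
    setBin(pr, 1, -1)
  })
  sub <- lapply(1:2, function(i) {
    pr <- flatProfile(sprintf("sub%d", i), c("1" = 4L, "2" = 4L, "3" = 4L))
    setBin(setBin(setBin(pr, 1, -1), 5, -0.6), 9, -0.6)
  })
  res2 <- cnvNjTree(c(near, sub))
  ro <- rootWithOutgroup(res2$tree)
  rp <- rootPathLengths(ro)
  expect_gt(min(rp[c("sub1", "sub2")]), max(rp[c("near1", "near2")]))
})

test_that("segment events partition into shared and private by exact boundaries", {
  mkprof <- function(id, lossBins) {
    pr <- flatProfile(id, c("1" = 10L, "2" = 10L))
    for (i in lossBins) pr <- setBin(pr, i, -1)
    pr
  }
  # identical two-bin deletion in two samples; third sample shifted by one bin
  pA <- mkprof("A", 3:4)
  pB <- mkprof("B", 3:4)
  pC <- mkprof("C", 4:5)
  seg <- classifySegmentEvents(list(A = pA, B = pB, C = pC))
  ev <- seg$events
  expect_equal(sum(ev$shared), 2)          # the identical deletion, in A and B
  expect_equal(ev$direction[ev$shared], rep("LOSS", 2))
  expect_equal(unique(ev$start[ev$shared]), 20000)
  expect_false(any(ev$shared[ev$sample == "C"]))  # one-bin shift -> private

  # whole-chromosome loss is excluded as nonspecific
  wA <- mkprof("A", 1:10)
  wB <- mkprof("B", 1:10)
  segW <- classifySegmentEvents(list(A = wA, B = wB))
  expect_equal(nrow(segW$events), 0)
  expect_equal(nrow(segW$excludedWholeChrom), 2)
})

test_that("manual trees scale trunk and branches with event counts", {
  mkprof <- function(id, extra) {
    pr <- flatProfile(id, c("1" = 40L))
    for (i in c(2, 5, 8, 11)) pr <- setBin(pr, i, -1)   # 4 shared events
    for (i in extra) pr <- setBin(pr, i, 1)             # private gains
    pr
  }
  part <- classifySegmentEvents(list(s1 = mkprof("s1", c(20, 25)),
                                     s2 = mkprof("s2", c(30, 33, 36))))
  mt <- buildManualTree(part)
  expect_equal(mt$trunk, 4)
  expect_equal(unname(mt$branches[c("s1", "s2")]), c(2L, 3L))

  # no shared events -> zero trunk
  part2 <- classifySegmentEvents(list(
    s1 = setBin(flatProfile("s1", c("1" = 10L)), 2, 1),
    s2 = setBin(flatProfile("s2", c("1" = 10L)), 6, 1)))
  expect_equal(buildManualTree(part2)$trunk, 0)

  # a planted early driver deletion shared by both phases lands on the trunk
  drv <- data.frame(chrom = "11", start = 20000, end = 40000, delta_log2 = -2)
  early <- karyotypeToBins(makeCell("early"), focalEvents = drv)
  late <- karyotypeToBins(makeCell("late", delta = c("19" = -1)),
                          focalEvents = drv)
  part3 <- classifySegmentEvents(list(early = early, late = late))
  mt3 <- buildManualTree(part3)
  expect_true(any(mt3$trunkEvents$chrom == "11" &
                    mt3$trunkEvents$start == 20000 &
                    mt3$trunkEvents$direction == "LOSS"))
})
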