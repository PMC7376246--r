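test_that("three taxa solve the three-point equations in closed form", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  expect_equal(ape::Ntip(tr), 3)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(lens["A"]), 1)  # x + y = 3, x + z = 5, y + z = 6
  expect_equal(unname(lens["B"]), 2)
  expect_equal(unname(lens["C"]), 4)
})

test_that("identical rows join as a zero-length cherry", {
  d <- matrix(c(0, 0, 4, 4,
                0, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(d)
  ab <- ape::getMRCA(ape::root(tr, "C", resolve.root = TRUE), c("A", "B"))
  idx <- match(match(c("A", "B"), tr$tip.label), tr$edge[, 2])
  expect_equal(tr$edge.length[idx], c(0, 0))
})

test_that("invalid matrices are rejected", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighborJoining(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(neighborJoining(d3), "symmetric")
  d4 <- matrix(c(0, -1, 2, -1, 0, 3, 2, 3, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_error(neighborJoining(d4), "negative")
})

test_that("additive matrices recover the generating tree for every topology up to 6 leaves", {
  set.seed(101)
  for (n in 4:6) {
    topos <- enumerateTopologies(n)
    for (tp in topos) {
      lengths <- sample(1:5, nrow(tp$edges), replace = TRUE)
      d <- additiveMatrix(tp$edges, lengths, n)
      tr <- neighborJoining(d)
      truth <- edgeListToPhylo(tp$edges, lengths, n)
      expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(truth)), 0)
      # branch lengths: leaf-to-leaf path lengths must match the input exactly
      coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
      expect_equal(coph, d, tolerance = 1e-6)
    }
  }
})

test_that("the NJ agglomeration agrees with ape's reference implementation", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 8
    pts <- matrix(runif(n * 4), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighborJoining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
  }
})

test_that("identical input produces byte-identical Newick output", {
  case <- simulateCase(simulationConfig(seed = 3))
  d <- buildDistanceMatrix(unlist(lapply(case$samples, cells),
                                  recursive = FALSE), scope = "M1")
  s1 <- writeNewick(neighborJoining(d))
  s2 <- writeNewick(neighborJoining(d))
  expect_identical(s1, s2)
})

test_that("rooting places the ancestry on the CONTROL edge without distorting paths", {
  nrtCell <- makeCell("a", events = list(structuralEvent("NRT", c("2", "4"))))
  wgdCell <- makeCell("b", wgdTimes = 2L,
                      events = list(structuralEvent("NRT", c("2", "4"),
                                                    copies = 2L)))
  d <- buildDistanceMatrix(list(makeCell("n"), nrtCell, wgdCell))
  un <- neighborJoining(d)
  ro <- rootWithOutgroup(un)
  expect_true(ape::is.rooted(ro))
  # leaf-to-leaf path lengths unchanged by rooting
  labs <- un$tip.label
  expect_equal(ape::cophenetic.phylo(ro)[labs, labs],
               ape::cophenetic.phylo(un)[labs, labs], tolerance = 1e-9)
  # accumulated event weight: the NRT+WGD cell sits 6 from the root
  rp <- rootPathLengths(ro)
  expect_equal(unname(rp["b"]), 6)
  expect_equal(unname(rp["a"]), 5)
  expect_equal(unname(rp["n"]), 0)
  expect_error(rootWithOutgroup(un, "NOPE"), "not found")
})

test_that("tree depth tracks distance from the ancestor on simulated cohorts", {
  # independent check of the NJ + rooting machinery: root-to-leaf path
  # lengths should rank-correlate with the brute-force distance to the
  # euploid ancestor, across replicate simulations
  rhos <- vapply(1:10, function(sd) {
    case <- simulateCase(simulationConfig(seed = sd))
    cellsAll <- unlist(lapply(case$samples, cells), recursive = FALSE)
    d <- buildDistanceMatrix(cellsAll, scope = "M1")
    tr <- rootWithOutgroup(neighborJoining(d))
    rp <- rootPathLengths(tr)
    truth <- vapply(cellsAll, function(cl)
      oracleDistance(controlCell(), cl, scope = "M1"), numeric(1))
    names(truth) <- vapply(cellsAll, cellId, character(1))
    cor(rp[names(truth)], truth, method = "spearman")
  }, numeric(1))
  expect_gte(median(rhos), 0.9)
})

test_that("Newick serialization is fixed-format and round-trips", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  s <- writeNewick(tr)
  expect_match(s, "^\\(.*\\);$")
  expect_match(s, ":[0-9]+\\.[0-9]{6}[,)]")
  p <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, p)
  back <- ape::read.tree(p)
  expect_equal(sort(back$tip.label), c("A", "B", "C"))
  expect_equal(ape::cophenetic.phylo(back)[c("A", "B", "C"), c("A", "B", "C")],
               d, tolerance = 1e-6)

  # a larger simulated tree survives a round trip topologically intact
  case <- simulateCase(simulationConfig(seed = 4, nSites = 3, cellsPerSite = 13))
  dBig <- buildDistanceMatrix(unlist(lapply(case$samples, cells),
                                     recursive = FALSE), scope = "M1")
  trBig <- neighborJoining(dBig)
  expect_equal(ape::Ntip(trBig), 40)
  p2 <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(trBig, p2)
  back2 <- ape::read.tree(p2)
  expect_equal(phangorn::RF.dist(ape::unroot(back2), ape::unroot(trBig)), 0)
})
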