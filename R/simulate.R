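#' @include distance.R cnv.R
NULL

#' Construct a SimulationConfig
#'
#' Parameters of the forward karyotype-evolution simulator. Cells divide
#' synchronously once per generation from a single normal founder; per
#' generation each daughter may gain or lose single chromosomes, acquire
#' structural events (each NRT gets a globally unique breakpoint tag), or —
#' once per lineage — undergo whole-genome duplication followed by random
#' chromosome losses down to a target count. The scenario scripts the
#' founding events: `TYPE2` plants one NRT before WGD (so post-WGD cells carry
#' two copies) and retains a near-2N subpopulation at an SVZ site; `TYPE1`
#' plants WGD first and the NRT after it.
#'
#' Default rates are chosen to reproduce the qualitative structure of
#' SKY cohorts (sub-4N counts of 60–80, clonal founding NRTs, a minority of
#' private events per cell); no field-measured per-generation rates exist, so
#' the defaults are deliberately modest drift rates.
#'
#' @param seed Integer RNG seed.
#' @param nGenerations Synchronous generations (default 9, i.e. 512 final
#'   cells).
#' @param rateGain,rateLoss Per-chromosome per-generation gain/loss
#'   probabilities (default 0.02).
#' @param rateNrt,rateFusion,rateRing Per-generation structural-event
#'   probabilities (defaults 0.01, 0.005, 0.003).
#' @param pWgdPerGeneration Random WGD probability per generation for
#'   non-scripted lineages (default 0; the scenario scripts the WGD).
#' @param postWgdLossTarget Inclusive range of total counts targeted by the
#'   loss burst after WGD (default c(60, 80)).
#' @param scenario `"TYPE1"` or `"TYPE2"`.
#' @param nSites Number of sampled anatomical sites (default 2).
#' @param cellsPerSite Metaphases sampled per site (default 12).
#' @param seeding `"PARALLEL"`, `"POLYCLONAL"` or `"MIXED"`.
#' @param noiseSdLog2 Gaussian noise sd for simulated CNV bins (default 0.1).
#' @param binSize CNV bin width (default 10000).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nGenerations = 9L,
                             rateGain = 0.02, rateLoss = 0.02,
                             rateNrt = 0.01, rateFusion = 0.005,
                             rateRing = 0.003, pWgdPerGeneration = 0,
                             postWgdLossTarget = c(60L, 80L),
                             scenario = c("TYPE2", "TYPE1"),
                             nSites = 2L, cellsPerSite = 12L,
                             seeding = c("PARALLEL", "POLYCLONAL", "MIXED"),
                             noiseSdLog2 = 0.1, binSize = 10000L) {
  scenario <- match.arg(scenario)
  seeding <- match.arg(seeding)
  new("SimulationConfig", seed = as.integer(seed),
      nGenerations = as.integer(nGenerations),
      rateGain = rateGain, rateLoss = rateLoss, rateNrt = rateNrt,
      rateFusion = rateFusion, rateRing = rateRing,
      pWgdPerGeneration = pWgdPerGeneration,
      postWgdLossTarget = as.integer(postWgdLossTarget),
      scenario = scenario, nSites = as.integer(nSites),
      cellsPerSite = as.integer(cellsPerSite), seeding = seeding,
      noiseSdLog2 = noiseSdLog2, binSize = as.integer(binSize))
}

# --- internal simulator cell representation -------------------------------

.newSimCell <- function(id, parent, gen) {
  list(id = id, parent = parent, gen = gen,
       counts = baselineCounts(), events = list(), wgd = FALSE,
       history = list(), cumWeight = 0)
}

.simTotalBodies <- function(cell) {
  sum(cell$counts) + sum(vapply(cell$events, function(e) e$copies, integer(1)))
}

.simAddHistory <- function(cell, entry, weight) {
  cell$history[[length(cell$history) + 1L]] <- entry
  cell$cumWeight <- cell$cumWeight + weight
  cell
}

.simApplyNrt <- function(cell, participants, bp, gen, weight = 5) {
  for (p in participants)
    if (cell$counts[p] > 0L) cell$counts[p] <- cell$counts[p] - 1L
  cell$events[[bp]] <- list(kind = "NRT", participants = participants,
                            copies = 1L, breakpointId = bp,
                            genAcquired = gen, preWgd = !cell$wgd)
  .simAddHistory(cell, list(type = "NRT", participants = participants,
                            id = bp, gen = gen), weight)
}

.simApplyOtherEvent <- function(cell, kind, participants, id, gen) {
  for (p in participants)
    if (cell$counts[p] > 0L) cell$counts[p] <- cell$counts[p] - 1L
  cell$events[[id]] <- list(kind = kind, participants = participants,
                            copies = 1L, breakpointId = id,
                            genAcquired = gen, preWgd = !cell$wgd)
  .simAddHistory(cell, list(type = kind, participants = participants,
                            id = id, gen = gen), 1)
}

.simApplyWgd <- function(cell, gen, lossTarget) {
  cell$counts <- cell$counts * 2L
  cell$events <- lapply(cell$events, function(e) {
    e$copies <- e$copies * 2L
    e
  })
  cell$wgd <- TRUE
  cell <- .simAddHistory(cell, list(type = "WGD", gen = gen), 1)
  # random loss of (intact) chromosomes down to the target count; ongoing
  # per-generation losses can additionally remove derivative copies later
  target <- sample(seq(lossTarget[1], lossTarget[2]), 1L)
  while (.simTotalBodies(cell) > target && sum(cell$counts) > 0L) {
    chr <- sample(names(cell$counts), 1L, prob = cell$counts)
    cell$counts[chr] <- cell$counts[chr] - 1L
    cell <- .simAddHistory(cell, list(type = "LOSS", chrom = chr, gen = gen), 1)
  }
  cell
}

.simMutate <- function(cell, cfg, gen, bpCounter) {
  chroms <- names(cell$counts)
  gains <- chroms[stats::runif(21) < cfg@rateGain]
  for (chr in gains) {
    cell$counts[chr] <- cell$counts[chr] + 1L
    cell <- .simAddHistory(cell, list(type = "GAIN", chrom = chr, gen = gen), 1)
  }
  losses <- chroms[stats::runif(21) < cfg@rateLoss & cell$counts > 0L]
  for (chr in losses) {
    cell$counts[chr] <- cell$counts[chr] - 1L
    cell <- .simAddHistory(cell, list(type = "LOSS", chrom = chr, gen = gen), 1)
  }
  if (length(cell$events)) {
    dropIds <- names(cell$events)[stats::runif(length(cell$events)) < cfg@rateLoss]
    for (id in dropIds) {
      cell$events[[id]]$copies <- cell$events[[id]]$copies - 1L
      cell <- .simAddHistory(cell, list(type = "DERIV_LOSS", id = id, gen = gen), 1)
      if (cell$events[[id]]$copies == 0L) cell$events[[id]] <- NULL
    }
  }
  if (stats::runif(1) < cfg@rateNrt) {
    avail <- chroms[cell$counts > 0L]
    if (length(avail) >= 2L) {
      participants <- sample(avail, 2L)
      bpCounter <- bpCounter + 1L
      cell <- .simApplyNrt(cell, participants, sprintf("bp%04d", bpCounter), gen)
    }
  }
  if (stats::runif(1) < cfg@rateFusion) {
    avail <- chroms[cell$counts >= 2L]
    if (length(avail)) {
      chr <- sample(avail, 1L)
      bpCounter <- bpCounter + 1L
      cell <- .simApplyOtherEvent(cell, "FUSION", c(chr, chr),
                                  sprintf("bp%04d", bpCounter), gen)
    }
  }
  if (stats::runif(1) < cfg@rateRing) {
    avail <- chroms[cell$counts >= 2L]
    if (length(avail)) {
      chr <- sample(avail, 1L)
      bpCounter <- bpCounter + 1L
      cell <- .simApplyOtherEvent(cell, "RING", c(chr, chr),
                                  sprintf("bp%04d", bpCounter), gen)
    }
  }
  if (!cell$wgd && stats::runif(1) < cfg@pWgdPerGeneration) {
    cell <- .simApplyWgd(cell, gen, cfg@postWgdLossTarget)
  }
  list(cell = cell, bpCounter = bpCounter)
}

.simCellToKaryotype <- function(cell, cellName, sampleId) {
  evs <- lapply(cell$events, function(e)
    structuralEvent(e$kind, e$participants, copies = e$copies,
                    breakpointId = e$breakpointId))
  metaphaseKaryotype(cellName, sampleId, cell$counts, unname(evs))
}

# --- main entry -----------------------------------------------------------

#' Simulate one animal's karyotype evolution with full ground truth
#'
#' Runs the forward simulator described at [simulationConfig()] and samples
#' metaphases from `nSites` anatomical sites. For `TYPE2` the first site is an
#' SVZ niche retaining near-2N cells (a dominant near-2N clone carrying one
#' copy of the founding NRT, mixed with NRT-free normal cells), and the
#' remaining sites are parenchymal tumors of post-WGD sub-4N cells carrying
#' two copies of it; `PARALLEL` seeding draws all tumor sites from one
#' post-WGD founder lineage, `POLYCLONAL` mixes the two post-WGD sister
#' lineages in each tumor site, `MIXED` mixes only the first tumor site.
#' For `TYPE1` every site is a sub-4N tumor and the founding NRT postdates
#' the WGD.
#'
#' @param cfg A [SimulationConfig-class].
#' @param animalId Animal (lineage) identifier, default `"M1"`.
#' @return A list of class `"SimulatedCase"` with elements `config`,
#'   `animalId`, `samples` (named list of [SampleKaryotypeSet-class]),
#'   `trueTree` (genealogy `phylo` over the sampled cells, branch lengths in
#'   weighted events), and `truth`: `plantedEvents` (data.frame of every
#'   structural event with generation and pre/post-WGD flag),
#'   `foundingNrtId`, `wgdGeneration`, `cellTruth` (per sampled cell: total
#'   weighted events, WGD flag, founding-NRT carrier flag) and `ledgers`
#'   (per-cell replayable event history; see [replayCellLedger()]).
#' @export
simulateCase <- function(cfg, animalId = "M1") {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)

  nGen <- cfg@nGenerations
  nrtGen <- if (cfg@scenario == "TYPE2") 1L else 2L
  wgdGen <- if (cfg@scenario == "TYPE2") max(2L, nGen %/% 3L) else 1L
  # a null configuration (no NRT acquirable) runs unscripted: nothing is
  # planted and, with all rates zero, every cell stays a normal euploid
  scriptActive <- cfg@rateNrt > 0

  founder <- .newSimCell("cell1", NA_character_, 0L)
  population <- list(founder)
  allCells <- list(cell1 = founder)
  bpCounter <- 0L
  nextId <- 2L
  mainline <- "cell1"   # lineage carrying the scripted founding events
  foundingNrtId <- NULL
  wgdCellId <- NULL

  for (gen in seq_len(nGen)) {
    nextPop <- vector("list", 2L * length(population))
    k <- 0L
    newMainline <- NULL
    for (cell in population) {
      for (childIdx in 1:2) {
        child <- cell
        child$parent <- cell$id
        child$id <- sprintf("cell%d", nextId)
        nextId <- nextId + 1L
        child$gen <- gen
        isMainline <- identical(cell$id, mainline) && childIdx == 1L

        if (scriptActive && isMainline && gen == nrtGen &&
            cfg@scenario == "TYPE2") {
          participants <- sample(as.character(1:19), 2L)
          bpCounter <- bpCounter + 1L
          foundingNrtId <- sprintf("bp%04d", bpCounter)
          child <- .simApplyNrt(child, participants, foundingNrtId, gen)
        }
        if (scriptActive && isMainline && gen == wgdGen) {
          child <- .simApplyWgd(child, gen, cfg@postWgdLossTarget)
          wgdCellId <- child$id
        }
        if (scriptActive && isMainline && gen == nrtGen &&
            cfg@scenario == "TYPE1") {
          # post-WGD acquisition: prefer chromosomes still at 4 copies so the
          # 1-copy/3-partner pattern is realized
          four <- names(child$counts)[child$counts >= 4L]
          pool <- if (length(four) >= 2L) four else
            names(child$counts)[child$counts > 0L]
          participants <- sample(setdiff(pool, c("X", "Y")), 2L)
          bpCounter <- bpCounter + 1L
          foundingNrtId <- sprintf("bp%04d", bpCounter)
          child <- .simApplyNrt(child, participants, foundingNrtId, gen)
        }

        res <- .simMutate(child, cfg, gen, bpCounter)
        child <- res$cell
        bpCounter <- res$bpCounter

        if (isMainline) newMainline <- child$id
        k <- k + 1L
        nextPop[[k]] <- child
        allCells[[child$id]] <- child
      }
    }
    population <- nextPop
    mainline <- newMainline
  }

  final <- population
  ids <- vapply(final, `[[`, character(1), "id")
  names(final) <- ids
  carries <- if (is.null(foundingNrtId)) rep(FALSE, length(final)) else
    vapply(final, function(c) foundingNrtId %in% names(c$events), logical(1))
  isWgd <- vapply(final, `[[`, logical(1), "wgd")

  # pools
  if (cfg@scenario == "TYPE2") {
    near2nNrt <- ids[carries & !isWgd]
    normalPool <- ids[!carries & !isWgd]
    sub4n <- ids[isWgd]
    # partition the post-WGD pool by the two children of the WGD cell
    branchOf <- vapply(sub4n, function(i) {
      cur <- i
      repeat {
        p <- allCells[[cur]]$parent
        if (is.na(p) || identical(p, wgdCellId)) return(cur)
        cur <- p
      }
    }, character(1))
    branches <- split(sub4n, branchOf)
  } else {
    sub4nNrt <- ids[carries & isWgd]
    sub4nOther <- ids[!carries & isWgd]
    if (!length(sub4nNrt) && !length(sub4nOther))
      sub4nOther <- ids  # unscripted null run: sample from the whole population
  }

  drawCells <- function(pool, n) {
    if (length(pool) == 0L) return(character(0))
    sample(pool, min(n, length(pool)))
  }

  samples <- list()
  sampledTruth <- list()
  addSample <- function(sampleId, siteLabel, cellIds) {
    cellNames <- sprintf("%s_%s_c%02d", animalId, sampleId, seq_along(cellIds))
    karyos <- mapply(function(cid, nm)
      .simCellToKaryotype(allCells[[cid]], nm, sampleId),
      cellIds, cellNames, SIMPLIFY = FALSE)
    samples[[sampleId]] <<- sampleKaryotypeSet(sampleId, animalId, siteLabel,
                                               unname(karyos))
    for (i in seq_along(cellIds))
      sampledTruth[[cellNames[i]]] <<- cellIds[i]
  }

  nPer <- cfg@cellsPerSite
  if (cfg@scenario == "TYPE2") {
    nNrt <- max(1L, round(0.8 * nPer))
    svzCells <- drawCells(near2nNrt, nNrt)
    svzCells <- c(svzCells, drawCells(normalPool, nPer - length(svzCells)))
    addSample("SVZR", "SVZ_R", svzCells)
    branchIds <- names(branches)
    for (s in seq_len(cfg@nSites - 1L)) {
      mix <- switch(cfg@seeding,
        PARALLEL = branches[[branchIds[1]]],
        POLYCLONAL = unlist(branches),
        MIXED = if (s == 1L) unlist(branches) else branches[[branchIds[1]]])
      addSample(sprintf("T%d", s), "PARENCHYMA", drawCells(mix, nPer))
    }
  } else {
    nNrt <- max(1L, round(0.85 * nPer))
    for (s in seq_len(cfg@nSites)) {
      cellsDrawn <- drawCells(sub4nNrt, nNrt)
      cellsDrawn <- c(cellsDrawn,
                      drawCells(sub4nOther, nPer - length(cellsDrawn)))
      addSample(sprintf("T%d", s), "PARENCHYMA", cellsDrawn)
    }
  }

  # ground-truth tables ------------------------------------------------------
  evRows <- list()
  seen <- character(0)
  for (c in allCells) {
    for (h in c$history) {
      if (h$type %in% c("NRT", "FUSION", "RING") && !(h$id %in% seen)) {
        seen <- c(seen, h$id)
        # pre-WGD iff the acquiring cell had not yet duplicated; reconstruct
        # from the history order
        wgdBefore <- FALSE
        for (h2 in c$history) {
          if (identical(h2, h)) break
          if (h2$type == "WGD") wgdBefore <- TRUE
        }
        evRows[[h$id]] <- data.frame(
          event_id = h$id, kind = h$type,
          participants = paste(h$participants, collapse = ";"),
          generation = h$gen, pre_wgd = !wgdBefore, stringsAsFactors = FALSE)
      }
    }
  }
  plantedEvents <- if (length(evRows)) do.call(rbind, unname(evRows)) else
    data.frame(event_id = character(0), kind = character(0),
               participants = character(0), generation = integer(0),
               pre_wgd = logical(0), stringsAsFactors = FALSE)

  cellTruth <- do.call(rbind, lapply(names(sampledTruth), function(nm) {
    sc <- allCells[[sampledTruth[[nm]]]]
    data.frame(cell_id = nm, sim_id = sc$id,
               true_event_weight = sc$cumWeight, wgd = sc$wgd,
               carries_founding_nrt = !is.null(foundingNrtId) &&
                 foundingNrtId %in% names(sc$events),
               n_events = length(sc$history), stringsAsFactors = FALSE)
  }))
  ledgers <- lapply(sampledTruth, function(simId) allCells[[simId]]$history)

  trueTree <- .simTrueTree(allCells, sampledTruth)

  structure(list(
    config = cfg, animalId = animalId, samples = samples,
    trueTree = trueTree,
    truth = list(plantedEvents = plantedEvents,
                 foundingNrtId = foundingNrtId,
                 wgdGeneration = wgdGen,
                 cellTruth = cellTruth, ledgers = ledgers)
  ), class = "SimulatedCase")
}

# genealogy of the sampled cells as a phylo; branch lengths in accumulated
# weighted events (unary internal nodes collapsed)
.simTrueTree <- function(allCells, sampledTruth) {
  if (length(sampledTruth) < 2L) return(NULL)
  leafOf <- stats::setNames(names(sampledTruth),
                            unlist(sampledTruth, use.names = FALSE))
  needed <- character(0)
  for (simId in unlist(sampledTruth, use.names = FALSE)) {
    cur <- simId
    while (!is.na(cur) && !(cur %in% needed)) {
      needed <- c(needed, cur)
      cur <- allCells[[cur]]$parent
    }
  }
  parents <- vapply(needed, function(i) allCells[[i]]$parent, character(1))
  hasParent <- !is.na(parents)
  kids <- split(needed[hasParent], parents[hasParent])
  rec <- function(id) {
    ch <- kids[[id]]
    isLeaf <- id %in% names(leafOf)
    w <- allCells[[id]]$cumWeight
    if (is.null(ch) || !length(ch)) {
      return(list(nwk = leafOf[[id]], w = w))
    }
    parts <- lapply(ch, rec)
    if (length(parts) == 1L && !isLeaf) {
      return(list(nwk = parts[[1]]$nwk, w = parts[[1]]$w, via = w))
    }
    inner <- vapply(parts, function(p)
      sprintf("%s:%.6f", p$nwk, max(p$w - w, 0)), character(1))
    if (isLeaf)  # sampled internal cell: attach as zero-length leaf
      inner <- c(inner, sprintf("%s:0.000000", leafOf[[id]]))
    list(nwk = sprintf("(%s)", paste(inner, collapse = ",")), w = w)
  }
  root <- needed[is.na(vapply(needed, function(i) allCells[[i]]$parent,
                              character(1)))][1]
  res <- rec(root)
  if (!grepl("^\\(", res$nwk)) return(NULL)
  ape::read.tree(text = paste0(res$nwk, ";"))
}

#' Replay a simulated cell's event ledger
#'
#' Reconstructs a cell's karyotype by applying its recorded event history to
#' the normal founder karyotype; used to verify that every simulated cell is
#' exactly reproducible from its lineage's ledger.
#'
#' @param ledger One element of `case$truth$ledgers`.
#' @return List with `counts` (named integer) and `events` (named list with
#'   `copies` per surviving event id).
#' @export
replayCellLedger <- function(ledger) {
  counts <- baselineCounts()
  evs <- list()
  for (h in ledger) {
    switch(h$type,
      GAIN = { counts[h$chrom] <- counts[h$chrom] + 1L },
      LOSS = { counts[h$chrom] <- counts[h$chrom] - 1L },
      NRT = ,
      FUSION = ,
      RING = {
        for (p in h$participants)
          if (counts[p] > 0L) counts[p] <- counts[p] - 1L
        evs[[h$id]] <- list(kind = h$type, copies = 1L)
      },
      DERIV_LOSS = {
        evs[[h$id]]$copies <- evs[[h$id]]$copies - 1L
        if (evs[[h$id]]$copies == 0L) evs[[h$id]] <- NULL
      },
      WGD = {
        counts <- counts * 2L
        evs <- lapply(evs, function(e) { e$copies <- e$copies * 2L; e })
      }
    )
  }
  list(counts = counts, events = evs)
}

#' Synthetic reduced chromosome sizes
#'
#' A scaled-down genome for simulated binned profiles: chromosome lengths
#' proportional to the mouse genome at roughly 1/100 scale, rounded to the
#' bin grid, so a full profile has a few thousand bins. The true mm9 sizes
#' are shipped in `inst/extdata/mm9.chrom.sizes` and can be used instead via
#' [readChromSizes()].
#'
#' @param binSize Grid to round to (default 10000).
#' @return Named integer vector over [mouseChromosomes()].
#' @export
syntheticChromSizes <- function(binSize = 10000L) {
  sizes <- readChromSizes(system.file("extdata", "mm9.chrom.sizes",
                                      package = "karyoevo"))
  scaled <- pmax(round(sizes / 100 / binSize) * binSize, 2 * binSize)
  stats::setNames(as.integer(scaled), names(sizes))
}

#' Read a chromosome-sizes file
#'
#' Two-column tab-separated file: chromosome name (with or without a "chr"
#' prefix) and length in bp.
#'
#' @param path File path.
#' @return Named integer vector.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  nm <- sub("^chr", "", df[[1]])
  stats::setNames(as.integer(df[[2]]), nm)
}

#' Convert a karyotype to a binned log2 copy-ratio profile
#'
#' Emulates the binned coverage profile a WGS pipeline would produce for a
#' clone with this karyotype: each chromosome's bins take the value
#' `log2(count / median(count))` (median over chromosomes 1–19 and X, so the
#' normalization matches the SKY-side estimate and cancels ploidy), plus
#' optional Gaussian noise and optional focal events (e.g. an early driver
#' deletion) overlaid on the whole-chromosome states. Derivative chromosomes
#' are not redistributed onto their participants; the profile reflects
#' intact-chromosome counts only.
#'
#' @param cell A [MetaphaseKaryotype-class].
#' @param chromSizes Named integer vector of chromosome sizes (default
#'   [syntheticChromSizes()]).
#' @param noiseSdLog2 Per-bin Gaussian noise sd (default 0).
#' @param seed Optional RNG seed for the noise.
#' @param focalEvents Optional data.frame `chrom`, `start`, `end`,
#'   `delta_log2` added onto overlapping bins.
#' @param binSize Bin width (default 10000).
#' @return A [CNVProfile-class].
#' @export
karyotypeToBins <- function(cell, chromSizes = syntheticChromSizes(),
                            noiseSdLog2 = 0, seed = NULL, focalEvents = NULL,
                            binSize = 10000L) {
  stopifnot(is(cell, "MetaphaseKaryotype"))
  if (!is.null(seed)) set.seed(seed)
  cts <- counts(cell)
  med <- stats::median(as.numeric(cts[c(as.character(1:19), "X")]))
  if (med == 0) .stopf("median chromosome count is zero")
  rows <- lapply(names(chromSizes), function(chr) {
    nBins <- max(1L, chromSizes[[chr]] %/% binSize)
    starts <- (seq_len(nBins) - 1L) * binSize
    ends <- pmin(starts + binSize, chromSizes[[chr]])
    val <- if (cts[[chr]] == 0) -10 else log2(cts[[chr]] / med)
    data.frame(chrom = chr, start = starts, end = ends, log2_ratio = val,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(focalEvents)) {
    for (i in seq_len(nrow(focalEvents))) {
      hit <- df$chrom == as.character(focalEvents$chrom[i]) &
        df$start < focalEvents$end[i] & df$end > focalEvents$start[i]
      df$log2_ratio[hit] <- df$log2_ratio[hit] + focalEvents$delta_log2[i]
    }
  }
  if (noiseSdLog2 > 0)
    df$log2_ratio <- df$log2_ratio + stats::rnorm(nrow(df), 0, noiseSdLog2)
  cnvProfile(cellId(cell), df, binSize = binSize)
}

#' Export a simulated case as plain-text fixtures
#'
#' Writes the karyotype TSV, one bin table per sample (from the sample's
#' first cell, with the configured noise), the true genealogy in Newick, and
#' the ground-truth ledger as JSON. The karyotype table re-imports to objects
#' equal to the in-memory ones.
#'
#' @param case A `"SimulatedCase"` from [simulateCase()].
#' @param dir Output directory (created if needed).
#' @param chromSizes Sizes for the bin tables (default
#'   [syntheticChromSizes()]).
#' @return Named character vector of the written paths, invisibly.
#' @export
exportFixtures <- function(case, dir, chromSizes = syntheticChromSizes()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(karyotypes = file.path(dir, "karyotypes.tsv"))
  writeKaryotypeTable(case$samples, paths[["karyotypes"]])
  for (sid in names(case$samples)) {
    p <- file.path(dir, sprintf("cnv_%s.tsv", sid))
    prof <- karyotypeToBins(cells(case$samples[[sid]])[[1]],
                            chromSizes = chromSizes,
                            noiseSdLog2 = case$config@noiseSdLog2,
                            seed = case$config@seed + match(sid, names(case$samples)),
                            binSize = case$config@binSize)
    writeBinTable(prof, p)
    paths[[paste0("cnv_", sid)]] <- p
  }
  if (!is.null(case$trueTree)) {
    paths[["true_tree"]] <- file.path(dir, "true_tree.nwk")
    writeNewick(case$trueTree, paths[["true_tree"]])
  }
  paths[["truth"]] <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(planted_events = case$truth$plantedEvents,
         founding_nrt_id = case$truth$foundingNrtId,
         wgd_generation = case$truth$wgdGeneration,
         cell_truth = case$truth$cellTruth),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
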