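#' @include clones.R sharing.R cnv.R simulate.R stats.R karyo-io.R
NULL

#' Assemble a pipeline configuration
#'
#' One configuration object for [runPipeline()]; any subset can be given and
#' the rest defaults. Serializable to/from YAML with [yaml::read_yaml()].
#'
#' @param karyotypePath Path to a karyotype table (TSV/JSON).
#' @param binTablePaths Optional named character vector (sample id -> bin
#'   table path).
#' @param outDir Output directory (default `"karyoevo_out"`).
#' @param weights List with `wCopy`, `wNrt`, `wOtherEvent`, `wWgd` (defaults
#'   1, 5, 1, 1).
#' @param wgdThreshold WGD chromosome-count cutoff (default 50).
#' @param sharingPairs,seed Monte-Carlo pair count (default 100000) and root
#'   seed.
#' @param cnvGainThr,cnvLossThr Segment-event thresholds (defaults 0.3, -0.3).
#' @return A validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(karyotypePath = NULL, binTablePaths = NULL,
                           outDir = "karyoevo_out",
                           weights = list(wCopy = 1, wNrt = 5,
                                          wOtherEvent = 1, wWgd = 1),
                           wgdThreshold = 50L, sharingPairs = 100000L,
                           seed = 1L, cnvGainThr = 0.3, cnvLossThr = -0.3) {
  cfg <- list(karyotypePath = karyotypePath, binTablePaths = binTablePaths,
              outDir = outDir, weights = weights,
              wgdThreshold = as.integer(wgdThreshold),
              sharingPairs = as.integer(sharingPairs), seed = as.integer(seed),
              cnvGainThr = cnvGainThr, cnvLossThr = cnvLossThr)
  stopifnot(cfg$wgdThreshold > 0L, cfg$sharingPairs >= 1L,
            cfg$cnvGainThr > 0, cfg$cnvLossThr < 0)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full per-animal analysis pipeline
#'
#' Composes the package end to end: reads (or accepts) the karyotype sets,
#' and per animal produces the ploidy table, clonality calls, the case-type
#' classification, a rooted event-weighted NJ tree per sample (written as
#' Newick), the founder-clone lineage, and — across animals, when there are
#' at least two — the inter-lineage sharing estimate; when bin tables are
#' supplied, the CNV L1 NJ tree and the shared/private segment partition are
#' added. All randomness flows from the single configured seed, so reruns on
#' the same inputs are identical.
#'
#' @param cfg A `"PipelineConfig"` from [pipelineConfig()].
#' @param samples Optional list of [SampleKaryotypeSet-class] objects,
#'   bypassing `karyotypePath`.
#' @return A report list of class `"AnimalReport"`: `config` echo, `animals`
#'   (per animal: `ploidy`, `clonality`, `case_type`, `trees` (Newick
#'   strings), `lineage`), `sharing`, and `cnv` when profiles were given.
#' @export
runPipeline <- function(cfg, samples = NULL) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (is.null(samples)) {
    if (is.null(cfg$karyotypePath)) .stopf("run_pipeline: no samples (no input path given)")
    samples <- readKaryotypeTable(cfg$karyotypePath)
  }
  if (!length(samples)) .stopf("run_pipeline: no samples")
  if (!is.null(cfg$outDir) && !dir.exists(cfg$outDir))
    dir.create(cfg$outDir, recursive = TRUE)
  w <- cfg$weights
  dcfg <- distanceConfig(w$wCopy, w$wNrt, w$wOtherEvent, w$wWgd)

  byAnimal <- split(samples, vapply(samples, animalId, character(1)))
  animals <- lapply(names(byAnimal), function(an) {
    sams <- byAnimal[[an]]
    ploidy <- do.call(rbind, lapply(sams, function(s) {
      cbind(sample_id = sampleId(s),
            do.call(rbind, lapply(cells(s), classifyPloidy,
                                  thresholdCount = cfg$wgdThreshold)))
    }))
    clonality <- do.call(rbind, lapply(sams, callClonalEvents))
    caseType <- classifyCaseType(sams)

    trees <- list()
    lineages <- list()
    for (s in sams) {
      if (length(cells(s)) < 2L) next
      d <- buildDistanceMatrix(cells(s), dcfg, includeControl = TRUE,
                               scope = an, thresholdCount = cfg$wgdThreshold)
      tr <- rootWithOutgroup(neighborJoining(d))
      nwk <- writeNewick(tr)
      if (!is.null(cfg$outDir))
        writeNewick(tr, file.path(cfg$outDir,
                                  sprintf("tree_%s.nwk", sampleId(s))))
      trees[[sampleId(s)]] <- nwk
      siteMap <- stats::setNames(rep(site(s), length(cells(s))),
                                 vapply(cells(s), cellId, character(1)))
      fcs <- identifyFounderClones(tr, cells(s), scope = an, sites = siteMap)
      lineages[[sampleId(s)]] <- orderFounderClones(fcs)
    }
    list(animal_id = an, ploidy = ploidy, clonality = clonality,
         case_type = caseType, trees = trees, lineages = lineages)
  })
  names(animals) <- names(byAnimal)

  sharing <- if (length(byAnimal) >= 2L) {
    estimateInterlineageP(samples, nPairs = cfg$sharingPairs, seed = cfg$seed)
  } else NULL

  cnv <- NULL
  if (!is.null(cfg$binTablePaths) && length(cfg$binTablePaths) >= 2L) {
    profiles <- lapply(names(cfg$binTablePaths), function(sid)
      readBinTable(cfg$binTablePaths[[sid]], sampleId = sid))
    names(profiles) <- names(cfg$binTablePaths)
    njRes <- cnvNjTree(profiles)
    seg <- classifySegmentEvents(profiles, log2GainThr = cfg$cnvGainThr,
                                 log2LossThr = cfg$cnvLossThr)
    cnv <- list(tree = writeNewick(njRes$tree),
                segments = seg$events,
                manual_tree = buildManualTree(seg))
    if (!is.null(cfg$outDir))
      writeNewick(njRes$tree, file.path(cfg$outDir, "cnv_tree.nwk"))
  }

  report <- list(config = unclass(cfg), animals = animals,
                 sharing = sharing, cnv = cnv)
  class(report) <- "AnimalReport"
  report
}

#' Render a pipeline report
#'
#' Writes the report as machine-readable JSON or human-readable Markdown
#' (one section per animal and sample, trees referenced inline as Newick).
#'
#' @param report An `"AnimalReport"` from [runPipeline()].
#' @param path Output path.
#' @param format `"JSON"` or `"Markdown"`; default from the extension.
#' @return `path`, invisibly.
#' @export
renderReport <- function(report, path, format = c("auto", "JSON", "Markdown")) {
  stopifnot(inherits(report, "AnimalReport"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "JSON" else "Markdown"
  if (format == "JSON") {
    ser <- rapply(unclass(report), function(x) {
      if (inherits(x, "CloneLineage"))
        list(fcs = lapply(x@fcs, function(f)
               list(fc_id = f@fcId, wgd = f@wgd, events = f@eventKeys,
                    members = f@memberCells)),
             edges = x@edges, unresolved = x@unresolved)
      else x
    }, classes = "ANY", how = "replace")
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
  } else {
    lines <- c("# karyoevo report", "")
    for (an in names(report$animals)) {
      a <- report$animals[[an]]
      lines <- c(lines, sprintf("## Animal %s", an),
                 sprintf("- case type: %s", a$case_type), "")
      for (sid in names(a$trees)) {
        lines <- c(lines, sprintf("### Sample %s", sid), "",
                   sprintf("Tree: `%s`", a$trees[[sid]]), "")
      }
      if (!is.null(a$clonality) && nrow(a$clonality)) {
        lines <- c(lines, "### Clonal events", "",
                   utils::capture.output(print(
                     a$clonality[a$clonality$clonal, , drop = FALSE])), "")
      }
    }
    if (!is.null(report$sharing))
      lines <- c(lines, sprintf("Inter-lineage sharing p = %g (n_r = %d, n_d = %d)",
                                report$sharing$p, report$sharing$n_r,
                                report$sharing$n_d))
    writeLines(lines, path)
  }
  invisible(path)
}
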