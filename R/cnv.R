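#' @include nj.R
#' @importFrom GenomicRanges GRanges seqnames start end width mcols
#' @importFrom IRanges IRanges
NULL

#' Construct a CNVProfile from a bin table
#'
#' @param sampleId Sample identifier.
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `log2_ratio`.
#' @param binSize Grid width in bp (default 10000).
#' @return A [CNVProfile-class].
#' @export
cnvProfile <- function(sampleId, df, binSize = 10000L) {
  stopifnot(all(c("chrom", "start", "end", "log2_ratio") %in% names(df)))
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  S4Vectors::mcols(gr)$log2Ratio <- as.numeric(df$log2_ratio)
  new("CNVProfile", sampleId = sampleId, bins = gr,
      binSize = as.integer(binSize))
}

#' Read a binned copy-ratio table
#'
#' Accepts two tab-separated dialects: the package's bin table
#' (`chrom`, `start`, `end`, `log2_ratio`; 0-based half-open coordinates) and
#' the Control-FREEC-style ratio file (`chrom`, `start`, `ratio` with linear
#' copy ratios, converted to log2; each window spans `binSize` from its
#' start). Off-grid bins are an error naming the offending position.
#'
#' @param path File path.
#' @param sampleId Sample identifier; default the file base name.
#' @param binSize Grid width in bp (default 10000).
#' @return A [CNVProfile-class].
#' @export
readBinTable <- function(path, sampleId = NULL, binSize = 10000L) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("chrom", "start", "end", "log2_ratio") %in% names(df))) {
    # native dialect
  } else if (all(c("chrom", "start", "ratio") %in% names(df))) {
    if (any(df$ratio <= 0))
      .stopf("linear ratios must be > 0 (found %g)", min(df$ratio))
    df <- data.frame(chrom = df$chrom, start = df$start,
                     end = df$start + binSize,
                     log2_ratio = log2(df$ratio), stringsAsFactors = FALSE)
  } else {
    .stopf("unrecognized bin-table columns: %s", paste(names(df), collapse = ", "))
  }
  off <- which(df$start %% binSize != 0L)
  if (length(off))
    .stopf("off-grid bin at %s:%d", df$chrom[off[1]], df$start[off[1]])
  cnvProfile(sampleId, df, binSize = binSize)
}

#' Write a CNVProfile as a bin table
#'
#' Writes the native dialect (`chrom`, `start`, `end`, `log2_ratio`, 0-based
#' half-open, tab-separated); a write/read round trip is lossless.
#'
#' @param profile A [CNVProfile-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBinTable <- function(profile, path) {
  stopifnot(is(profile, "CNVProfile"))
  gr <- bins(profile)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    log2_ratio = S4Vectors::mcols(gr)$log2Ratio
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-chromosome log2 copy ratio from SKY counts
#'
#' For a set of metaphases, the per-chromosome log2 ratio is
#' `log2(ci / median(c))` where `ci` is the average count of chromosome `i`
#' over the cells and `c` is the set of `ci` for chromosomes 1–19 and X
#' (chromosome Y is excluded). The median normalization cancels ploidy, so a
#' pure-WGD population maps onto its diploid ancestor.
#'
#' @param cellList List of [MetaphaseKaryotype-class] objects (>= 1).
#' @return Named numeric vector over chromosomes 1–19 and X.
#' @export
skyChromLog2 <- function(cellList) {
  stopifnot(length(cellList) >= 1L)
  chroms <- c(as.character(1:19), "X")
  mat <- do.call(rbind, lapply(cellList, function(cell)
    as.numeric(counts(cell)[chroms])))
  ci <- colMeans(mat)
  med <- stats::median(ci)
  if (med == 0) .stopf("median chromosome count is zero")
  stats::setNames(log2(ci / med), chroms)
}

#' Per-chromosome median log2 ratio from a binned profile
#'
#' The WGS-side counterpart of [skyChromLog2()]: the median of the bin log2
#' ratios of each chromosome.
#'
#' @param profile A [CNVProfile-class].
#' @return Named numeric vector over the profile's chromosomes.
#' @export
wgsChromLog2 <- function(profile) {
  stopifnot(is(profile, "CNVProfile"))
  gr <- bins(profile)
  vals <- split(S4Vectors::mcols(gr)$log2Ratio,
                as.character(GenomicRanges::seqnames(gr)))
  vapply(vals, stats::median, numeric(1))
}

#' Compare SKY and WGS per-chromosome copy-number estimates
#'
#' Pearson correlation of the per-chromosome log2 ratios estimated from SKY
#' counts and from binned WGS coverage, over the chromosomes present in both.
#'
#' @param sky Named numeric vector from [skyChromLog2()].
#' @param wgs Named numeric vector from [wgsChromLog2()].
#' @return List with `pearson_r` (`NA` with `undefined = TRUE` when either
#'   side has zero variance) and `pairs` (data.frame chrom/sky/wgs).
#' @export
compareSkyWgs <- function(sky, wgs) {
  shared <- intersect(names(sky), names(wgs))
  if (length(shared) < 3L) .stopf("need >= 3 shared chromosomes")
  x <- as.numeric(sky[shared]); y <- as.numeric(wgs[shared])
  undefined <- stats::sd(x) == 0 || stats::sd(y) == 0
  r <- if (undefined) NA_real_ else stats::cor(x, y)
  list(pearson_r = r, undefined = undefined,
       pairs = data.frame(chrom = shared, sky = x, wgs = y,
                          stringsAsFactors = FALSE))
}

#' L1 distance between two binned profiles
#'
#' The distance between two clones is the sum over bins of the absolute
#' difference of their log2 ratios. Profiles on different grids are
#' intersected (with a message); an empty intersection is an error.
#'
#' @param a,b [CNVProfile-class] objects.
#' @return Non-negative numeric.
#' @export
cnvL1Distance <- function(a, b) {
  stopifnot(is(a, "CNVProfile"), is(b, "CNVProfile"))
  ka <- paste0(GenomicRanges::seqnames(bins(a)), ":", GenomicRanges::start(bins(a)))
  kb <- paste0(GenomicRanges::seqnames(bins(b)), ":", GenomicRanges::start(bins(b)))
  if (!identical(ka, kb)) {
    shared <- intersect(ka, kb)
    if (!length(shared)) .stopf("profiles share no bins")
    message(sprintf("cnvL1Distance: grids differ; using %d shared bins",
                    length(shared)))
    va <- S4Vectors::mcols(bins(a))$log2Ratio[match(shared, ka)]
    vb <- S4Vectors::mcols(bins(b))$log2Ratio[match(shared, kb)]
  } else {
    va <- S4Vectors::mcols(bins(a))$log2Ratio
    vb <- S4Vectors::mcols(bins(b))$log2Ratio
  }
  sum(abs(va - vb))
}

#' Neighbor-joining tree from binned CNV profiles
#'
#' Builds the pairwise L1 distance matrix over the profiles (optionally adding
#' an all-zero normal outgroup labelled `CONTROL`) and reconstructs the
#' neighbor-joining tree with [neighborJoining()].
#'
#' @param profiles List of >= 2 [CNVProfile-class] objects on one grid.
#' @param includeControl Add the flat (log2 = 0) normal profile as outgroup
#'   (default `TRUE`).
#' @return List with `tree` (`phylo`) and `distance` (matrix).
#' @export
cnvNjTree <- function(profiles, includeControl = TRUE) {
  stopifnot(length(profiles) >= 2L)
  if (includeControl) {
    tmpl <- profiles[[1]]
    gr <- bins(tmpl)
    S4Vectors::mcols(gr)$log2Ratio <- 0
    ctrl <- new("CNVProfile", sampleId = "CONTROL", bins = gr,
                binSize = tmpl@binSize)
    profiles <- c(profiles, list(ctrl))
  }
  ids <- vapply(profiles, sampleId, character(1))
  if (anyDuplicated(ids)) .stopf("duplicate profile sample ids")
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    d[i, j] <- d[j, i] <- cnvL1Distance(profiles[[i]], profiles[[j]])
  list(tree = neighborJoining(d), distance = d)
}

#' Call gain/loss segment events and partition them into shared vs private
#'
#' Contiguous runs of bins with |log2 ratio| beyond the thresholds become
#' segment events. Events with identical boundaries (chromosome, start, end
#' and direction) in at least two samples are shared; the rest are private.
#' Whole-chromosome gains or losses (covering at least `wholeChromFrac` of the
#' chromosome's binned length) are excluded from both sets as nonspecific.
#'
#' @param profiles Named list of >= 2 [CNVProfile-class] objects.
#' @param log2GainThr Gain threshold (default 0.3).
#' @param log2LossThr Loss threshold (default -0.3).
#' @param wholeChromFrac Fraction of the chromosome's binned length above
#'   which an event counts as whole-chromosome (default 0.95).
#' @return List with `events` (data.frame sample/chrom/start/end/direction/
#'   shared) and `excludedWholeChrom` (same shape, the excluded events).
#' @export
classifySegmentEvents <- function(profiles, log2GainThr = 0.3,
                                  log2LossThr = -0.3, wholeChromFrac = 0.95) {
  stopifnot(length(profiles) >= 2L)
  perSample <- lapply(profiles, function(p) {
    gr <- bins(p)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     v = S4Vectors::mcols(gr)$log2Ratio,
                     stringsAsFactors = FALSE)
    out <- NULL
    for (chr in unique(df$chrom)) {
      sub <- df[df$chrom == chr, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      state <- ifelse(sub$v >= log2GainThr, "GAIN",
                      ifelse(sub$v <= log2LossThr, "LOSS", "NEUTRAL"))
      runs <- rle(state)
      endsIdx <- cumsum(runs$lengths)
      startsIdx <- endsIdx - runs$lengths + 1L
      chromLen <- sum(sub$end - sub$start)
      for (r in seq_along(runs$values)) {
        if (runs$values[r] == "NEUTRAL") next
        s <- sub$start[startsIdx[r]]; e <- sub$end[endsIdx[r]]
        out <- rbind(out, data.frame(
          chrom = chr, start = s, end = e, direction = runs$values[r],
          whole_chromosome = (e - s) >= wholeChromFrac * chromLen,
          stringsAsFactors = FALSE))
      }
    }
    out
  })
  ids <- names(profiles)
  if (is.null(ids))
    ids <- vapply(profiles, sampleId, character(1))
  evs <- do.call(rbind, lapply(seq_along(perSample), function(i) {
    if (is.null(perSample[[i]])) return(NULL)
    cbind(sample = ids[i], perSample[[i]], stringsAsFactors = FALSE)
  }))
  if (is.null(evs))
    evs <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      direction = character(0), whole_chromosome = logical(0),
                      stringsAsFactors = FALSE)
  excluded <- evs[evs$whole_chromosome, , drop = FALSE]
  evs <- evs[!evs$whole_chromosome, , drop = FALSE]
  key <- paste(evs$chrom, evs$start, evs$end, evs$direction)
  nSamples <- tapply(evs$sample, key, function(x) length(unique(x)))
  evs$shared <- as.vector(nSamples[key] >= 2L)
  list(events = evs, excludedWholeChrom = excluded)
}

#' Build a shared/private ("manual") event tree
#'
#' Summarizes a shared-vs-private event partition as a tree model in which the
#' trunk length is proportional to the number of shared events and each
#' sample's branch length to its number of private events; shared events
#' determine the phylogenetic order of the samples.
#'
#' @param partition Result of [classifySegmentEvents()].
#' @return List with `trunk` (shared-event count), `trunkEvents`, `branches`
#'   (named private-event counts per sample) and `branchEvents`.
#' @export
buildManualTree <- function(partition) {
  evs <- partition$events
  sharedKeys <- unique(paste(evs$chrom, evs$start, evs$end, evs$direction)[evs$shared])
  priv <- evs[!evs$shared, , drop = FALSE]
  samplesAll <- unique(evs$sample)
  branches <- vapply(samplesAll, function(s) sum(priv$sample == s), integer(1))
  list(
    trunk = length(sharedKeys),
    trunkEvents = unique(evs[evs$shared,
                             c("chrom", "start", "end", "direction")]),
    branches = branches,
    branchEvents = priv
  )
}
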