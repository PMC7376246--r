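#' @include ploidy.R
NULL

# NRT identity keys of one cell, scoped by animal (breakpoint tags override)
.cellNrtKeys <- function(cell, animal) {
  evs <- Filter(function(e) e@kind == "NRT", cell@events)
  unique(vapply(evs, eventKey, character(1), scope = animal))
}

#' Build the metaphase-wise NRT sharing matrix
#'
#' Entry (i, j) is the number of NRT identities shared between metaphases i
#' and j (0 when none); the diagonal is 0 by convention. Identity follows
#' [eventKey()]: untagged NRTs are identified by notation within one animal
#' only, while breakpoint tags establish identity across animals.
#'
#' @param samples List of [SampleKaryotypeSet-class] objects (>= 2 metaphases
#'   in total).
#' @return List with `matrix` (symmetric integer matrix over cell ids),
#'   `animal` (named character vector: animal of each metaphase) and
#'   `sample` (named character vector).
#' @export
buildSharingMatrix <- function(samples) {
  if (is(samples, "SampleKaryotypeSet")) samples <- list(samples)
  cellsAll <- unlist(lapply(samples, cells), recursive = FALSE)
  animals <- unlist(lapply(samples, function(s)
    rep(s@animalId, length(s@cells))))
  sampleIds <- unlist(lapply(samples, function(s)
    rep(s@sampleId, length(s@cells))))
  ids <- vapply(cellsAll, cellId, character(1))
  if (length(ids) < 2L) .stopf("need at least 2 metaphases")
  if (anyDuplicated(ids)) .stopf("duplicate cell ids across samples")

  keySets <- mapply(.cellNrtKeys, cellsAll, animals, SIMPLIFY = FALSE)
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    ki <- keySets[[i]]
    if (!length(ki)) next
    for (j in seq((i + 1L), n)) {
      shared <- length(intersect(ki, keySets[[j]]))
      m[i, j] <- m[j, i] <- shared
    }
  }
  list(matrix = m, animal = stats::setNames(animals, ids),
       sample = stats::setNames(sampleIds, ids))
}

#' Monte-Carlo estimate of the inter-lineage NRT-sharing probability
#'
#' Estimates the probability that two metaphases from different animals
#' (lineages) share an NRT, by uniformly sampling unordered pairs of distinct
#' metaphases with replacement from the pooled cohort. With `n_r` sampled
#' pairs sharing at least one NRT, `n_d` of them from different animals and
#' `n_a` animals, the estimate is
#' \deqn{p = \frac{n_d}{n_r} \cdot \frac{1}{n_a - 1}}
#' where the factor `1/(n_a - 1)` normalizes for inter-lineage pairs being
#' `(n_a - 1)` times as likely as intra-lineage pairs under uniform sampling.
#' When no sampled pair shares an NRT the estimate is reported as 0 with
#' `undefined = TRUE`.
#'
#' @param samples List of [SampleKaryotypeSet-class] objects covering >= 2
#'   animals.
#' @param nPairs Number of sampled pairs (default 100000).
#' @param seed Integer seed; the estimate is reproducible per seed.
#' @return List with `n_pairs_sampled`, `n_r`, `n_d`, `n_a`, `p`,
#'   `undefined`, `seed`.
#' @export
estimateInterlineageP <- function(samples, nPairs = 100000L, seed = 1L) {
  stopifnot(nPairs >= 1L)
  sm <- buildSharingMatrix(samples)
  animals <- sm$animal
  nA <- length(unique(animals))
  if (nA < 2L) .stopf("need metaphases from at least 2 animals")
  n <- length(animals)
  shareMat <- sm$matrix > 0L

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  idx <- withr_seed({
    i <- sample.int(n, nPairs, replace = TRUE)
    j <- sample.int(n - 1L, nPairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # uniform over distinct partners
    cbind(i, j)
  })
  sharing <- shareMat[idx]
  diffAnimal <- animals[idx[, 1]] != animals[idx[, 2]]
  nR <- sum(sharing)
  nD <- sum(sharing & diffAnimal)
  undefined <- nR == 0L
  p <- if (undefined) 0 else (nD / nR) / (nA - 1)
  list(n_pairs_sampled = as.integer(nPairs), n_r = as.integer(nR),
       n_d = as.integer(nD), n_a = as.integer(nA), p = p,
       undefined = undefined, seed = as.integer(seed))
}

#' Exhaustive inter-lineage sharing probability
#'
#' Exact counterpart of [estimateInterlineageP()]: enumerates all C(n, 2)
#' unordered pairs of metaphases instead of sampling. Serves as the reference
#' the Monte-Carlo estimate converges to.
#'
#' @param samples As in [estimateInterlineageP()].
#' @return List with `n_r`, `n_d`, `n_a`, `p`, `undefined`.
#' @export
exactInterlineageP <- function(samples) {
  sm <- buildSharingMatrix(samples)
  animals <- sm$animal
  nA <- length(unique(animals))
  if (nA < 2L) .stopf("need metaphases from at least 2 animals")
  share <- sm$matrix > 0L
  ut <- upper.tri(share)
  diffAnimal <- outer(animals, animals, `!=`)
  nR <- sum(share[ut])
  nD <- sum((share & diffAnimal)[ut])
  undefined <- nR == 0L
  p <- if (undefined) 0 else (nD / nR) / (nA - 1)
  list(n_r = as.integer(nR), n_d = as.integer(nD), n_a = as.integer(nA),
       p = p, undefined = undefined)
}
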