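#' @include distance.R
NULL

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou–Nei neighbor joining under the minimum-evolution principle:
#' iteratively join the pair minimizing the Q criterion
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j`, attach the pair at branch lengths
#' `l_i = d(i,j)/2 + (r_i - r_j)/(2(n-2))`, and reduce the matrix, until three
#' nodes remain, which are joined at a trifurcating base (the tree is
#' unrooted). Ties in Q are broken towards the lexicographically lowest label
#' pair (internal nodes are labelled by the smallest leaf label in their
#' subtree), so the result is fully deterministic. Negative branch-length
#' estimates are clamped to zero with the deficit moved to the sibling edge,
#' preserving the pair's joint length.
#'
#' Non-metric dissimilarities are accepted (the event-weighted distance does
#' not guarantee the triangle inequality); on an additive matrix the
#' generating tree is recovered exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal, non-negative entries
#'   and unique dimnames; at least 3 labels.
#' @return An unrooted `phylo` object (ape).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighborJoining(d)
neighborJoining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    .stopf("distance matrix must be square")
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels))
    .stopf("distance matrix must have unique dimnames")
  if (nrow(d) < 3L)
    .stopf("neighbor joining needs at least 3 labels")
  if (any(d < 0)) .stopf("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-9) .stopf("distance matrix is not symmetric")
  if (any(diag(d) != 0)) .stopf("distance matrix diagonal must be zero")

  fmt <- function(x) sprintf("%.10g", max(x, 0))
  # active nodes: subtree newick fragments and tie-break labels
  nwk <- labels
  tie <- labels
  D <- d

  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pair <- sort(c(tie[cand[k, 1]], tie[cand[k, 2]]))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj - li; li <- 0 }
    if (lj < 0) { li <- li - lj; lj <- 0 }

    newNwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    newTie <- min(tie[i], tie[j])
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dNew <- pmax(dNew, 0)[-c(i, j)]

    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew),
               c(dNew, 0))
    nwk <- c(nwk[keep], newNwk)
    tie <- c(tie[keep], newTie)
    rownames(D) <- colnames(D) <- tie
  }

  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- D[1, 2] - l1
  l3 <- D[1, 3] - l1
  tree <- ape::read.tree(text = sprintf("(%s:%s,%s:%s,%s:%s);",
                                        nwk[1], fmt(l1), nwk[2], fmt(l2),
                                        nwk[3], fmt(l3)))
  tree
}

#' Root a tree on its outgroup
#'
#' Places the root on the pendant edge of the outgroup leaf (the normal
#' euploid `CONTROL` cell), so that evolutionary direction points away from
#' the root and the path length from the root to any leaf measures the
#' accumulated event weight of that cell. Leaf-to-leaf path lengths are
#' unchanged by rooting.
#'
#' @param tree An unrooted `phylo`.
#' @param outgroupLabel Leaf label to root on, default `"CONTROL"`.
#' @return A rooted `phylo`.
#' @export
rootWithOutgroup <- function(tree, outgroupLabel = "CONTROL") {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroupLabel %in% tree$tip.label)
    .stopf("outgroup leaf '%s' not found in tree", outgroupLabel)
  ape::root(tree, outgroup = outgroupLabel, resolve.root = TRUE)
}

#' Path lengths from the root to every leaf
#'
#' @param tree A rooted `phylo`.
#' @return Named numeric vector over tip labels.
#' @export
rootPathLengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_along(tree$tip.label)], tree$tip.label)
}

#' Write a tree in Newick format
#'
#' Serializes a `phylo` object as standard Newick with branch lengths in
#' fixed 6-decimal format; unrooted trees are written with their trifurcating
#' base. Byte-identical output for identical input.
#'
#' @param tree A `phylo`.
#' @param path Optional output file; when `NULL` only the string is returned.
#' @param digits Decimal places, default 6.
#' @return The Newick string, invisibly when writing to a file.
#' @export
writeNewick <- function(tree, path = NULL, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  nTips <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rootNode <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  fmt <- sprintf("%%.%df", digits)
  rec <- function(node) {
    if (node <= nTips) return(tree$tip.label[node])
    kid <- children[[as.character(node)]]
    parts <- vapply(kid, function(eidx) {
      child <- tree$edge[eidx, 2]
      len <- if (is.null(tree$edge.length)) 0 else tree$edge.length[eidx]
      sprintf("%s:%s", rec(child), sprintf(fmt, len))
    }, character(1))
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  s <- paste0(rec(rootNode), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
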