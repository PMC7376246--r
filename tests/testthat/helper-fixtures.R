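# Shared fixture builders and independent oracles.

# a cell at baseline plus named count deltas and optional events
makeCell <- function(id, sample = "S1", delta = c(), events = list(),
                     wgdTimes = 1L) {
  cts <- baselineCounts() * wgdTimes
  for (chr in names(delta)) cts[chr] <- cts[chr] + delta[[chr]]
  metaphaseKaryotype(id, sample, cts, events)
}

makeSample <- function(cellList, sampleId = "S1", animalId = "A1",
                       site = "PARENCHYMA") {
  sampleKaryotypeSet(sampleId, animalId, site, cellList)
}

# Independent brute-force reimplementation of the event-weighted distance,
# written directly from the weighting rules (no CanonicalProfile machinery).
oracleDistance <- function(cellA, cellB, wCopy = 1, wNrt = 5, wOther = 1,
                           wWgd = 1, scope = "") {
  tc <- function(cell) sum(counts(cell)) +
    sum(vapply(events(cell), function(e) e@copies, integer(1)))
  wgdA <- tc(cellA) >= 50
  wgdB <- tc(cellB) >= 50
  base <- c(rep(2, 19), 1, 1)
  names(base) <- mouseChromosomes()
  devA <- counts(cellA) - base * (if (wgdA) 2 else 1)
  devB <- counts(cellB) - base * (if (wgdB) 2 else 1)
  d <- wWgd * abs(wgdA - wgdB) + wCopy * sum(abs(devA - devB))
  keyTab <- function(cell, wgd) {
    out <- list()
    for (e in events(cell)) {
      k <- eventKey(e, scope = scope)
      if (is.null(out[[k]])) out[[k]] <- list(kind = e@kind, copies = 0L)
      out[[k]]$copies <- out[[k]]$copies + e@copies
    }
    for (k in names(out))
      out[[k]]$adj <- out[[k]]$copies / (if (wgd && out[[k]]$copies >= 2) 2 else 1)
    out
  }
  ta <- keyTab(cellA, wgdA)
  tb <- keyTab(cellB, wgdB)
  for (k in union(names(ta), names(tb))) {
    inA <- k %in% names(ta)
    inB <- k %in% names(tb)
    if (inA && inB) {
      d <- d + wCopy * abs(ta[[k]]$adj - tb[[k]]$adj)
    } else {
      kind <- if (inA) ta[[k]]$kind else tb[[k]]$kind
      d <- d + (if (kind == "NRT") wNrt else wOther)
    }
  }
  d
}

# --- exhaustive unrooted topology oracle ----------------------------------
# Enumerate every unrooted binary leaf-labelled topology on n leaves by
# sequential leaf insertion; trees are edge lists over node ids (leaves
# 1..n, internal nodes n+1...).
enumerateTopologies <- function(n) {
  stopifnot(n >= 3, n <= 7)
  base <- list(list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                    nextNode = n + 2))
  trees <- base
  for (leaf in seq(4, length.out = max(0, n - 3))) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edges)), function(ei) {
        mid <- tr$nextNode
        e <- tr$edges[ei, ]
        edges <- tr$edges[-ei, , drop = FALSE]
        edges <- rbind(edges, c(e[1], mid), c(mid, e[2]), c(mid, leaf))
        list(edges = edges, nextNode = mid + 1)
      })
    }), recursive = FALSE)
  }
  trees
}

# additive path-length matrix of an edge-list tree with given edge lengths
additiveMatrix <- function(edges, lengths, nLeaves) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) NULL)
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    adj[[a]] <- rbind(adj[[a]], c(edges[i, 2], lengths[i]))
    adj[[b]] <- rbind(adj[[b]], c(edges[i, 1], lengths[i]))
  }
  dist1 <- function(from) {
    d <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
    d[as.character(from)] <- 0
    queue <- from
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (r in seq_len(nrow(adj[[as.character(cur)]]))) {
        nb <- adj[[as.character(cur)]][r, 1]
        w <- adj[[as.character(cur)]][r, 2]
        if (is.na(d[as.character(nb)])) {
          d[as.character(nb)] <- d[as.character(cur)] + w
          queue <- c(queue, nb)
        }
      }
    }
    d
  }
  m <- matrix(0, nLeaves, nLeaves,
              dimnames = list(paste0("L", 1:nLeaves), paste0("L", 1:nLeaves)))
  for (i in seq_len(nLeaves)) {
    di <- dist1(i)
    for (j in seq_len(nLeaves)) m[i, j] <- di[as.character(j)]
  }
  m
}

# edge-list topology -> phylo (for Robinson-Foulds comparison)
edgeListToPhylo <- function(edges, lengths, nLeaves) {
  labels <- c(paste0("L", 1:nLeaves),
              paste0("n", seq_len(max(edges) - nLeaves)))
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
    adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
  }
  lenOf <- function(a, b) {
    for (i in seq_len(nrow(edges)))
      if ((edges[i, 1] == a && edges[i, 2] == b) ||
          (edges[i, 1] == b && edges[i, 2] == a)) return(lengths[i])
    stop("edge not found")
  }
  rec <- function(node, parent) {
    kids <- setdiff(adj[[as.character(node)]], parent)
    if (!length(kids)) return(labels[node])
    inner <- vapply(kids, function(k)
      sprintf("%s:%.6f", rec(k, node), lenOf(node, k)), character(1))
    sprintf("(%s)", paste(inner, collapse = ","))
  }
  root <- nLeaves + 1
  ape::read.tree(text = paste0(rec(root, NA), ";"))
}
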