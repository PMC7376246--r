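#' @include utils.R
NULL

#' Exact Fisher test for a 2x2 table
#'
#' Two-sided Fisher exact test computed by direct hypergeometric enumeration:
#' with margins fixed, every admissible table's probability is computed and
#' the p-value is the sum of probabilities not exceeding that of the observed
#' table ("probability mass <= observed" rule, as in common implementations).
#' Degenerate tables (an all-zero row or column) return p = 1 with a warning.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are groups, columns
#'   outcome yes/no, so the table is `rbind(c(a, b), c(c, d))`.
#' @param alternative Only `"two_sided"` is provided.
#' @return The p-value in (0, 1].
#' @export
#' @examples
#' fisherExact2x2(8, 6, 1, 8)  # < 0.05
fisherExact2x2 <- function(a, b, c, d, alternative = "two_sided") {
  stopifnot(identical(alternative, "two_sided"))
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    .stopf("cell counts must be non-negative integers")
  if (sum(cells) < 1L) .stopf("table total must be >= 1")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
    warning("degenerate margins (all-zero row or column); p = 1")
    return(1)
  }
  n <- r1 + r2
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, c1, c2, r1)
  pObs <- stats::dhyper(a, c1, c2, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Group proportions with pairwise Fisher tests
#'
#' Summarizes labeled yes/total counts as percentages (one decimal, as
#' conventionally reported) and computes all pairwise two-sided Fisher exact
#' p-values, optionally Holm-adjusted (off by default; raw p-values are the
#' reporting convention for these small-cohort comparisons).
#'
#' @param yes Named integer vector of successes per group.
#' @param total Named integer vector of group sizes (same names).
#' @param holm Apply Holm adjustment across the pairwise tests (default
#'   `FALSE`).
#' @return List with `proportions` (data.frame group/yes/total/fraction/
#'   percent) and `pairwise` (data.frame group1/group2/p, plus `p_adj` when
#'   `holm`).
#' @export
proportionReport <- function(yes, total, holm = FALSE) {
  stopifnot(length(yes) >= 2L, identical(names(yes), names(total)))
  if (any(total < 1L)) .stopf("empty group")
  if (any(yes > total)) .stopf("yes counts exceed totals")
  props <- data.frame(
    group = names(yes), yes = as.integer(yes), total = as.integer(total),
    fraction = as.numeric(yes / total),
    percent = round(100 * yes / total, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pairs <- utils::combn(names(yes), 2)
  pw <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p = apply(pairs, 2, function(g) {
      fisherExact2x2(yes[[g[1]]], total[[g[1]]] - yes[[g[1]]],
                     yes[[g[2]]], total[[g[2]]] - yes[[g[2]]])
    }),
    stringsAsFactors = FALSE
  )
  if (holm) pw$p_adj <- stats::p.adjust(pw$p, method = "holm")
  list(proportions = props, pairwise = pw)
}
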