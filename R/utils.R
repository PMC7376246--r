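# Internal helpers shared across modules.

#' Mouse chromosome labels
#'
#' The 21 chromosome labels of the mouse karyotype (19 autosomes plus X and Y),
#' in canonical order. All per-chromosome count vectors in the package are
#' named by these labels.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' mouseChromosomes()
mouseChromosomes <- function() {
  c(as.character(1:19), "X", "Y")
}

#' Baseline diploid chromosome counts
#'
#' Euploid baseline copy numbers used for deviation and distance computations:
#' two copies per autosome and, by default, one X and one Y (male mice).
#'
#' @param sexChromCounts Named numeric/integer vector giving baseline copies of
#'   the sex chromosomes; default `c(X = 1, Y = 1)`.
#' @return Named integer vector over [mouseChromosomes()].
#' @export
#' @examples
#' sum(baselineCounts())  # 40 chromosomes
baselineCounts <- function(sexChromCounts = c(X = 1, Y = 1)) {
  counts <- stats::setNames(rep(2L, 21L), mouseChromosomes())
  counts["X"] <- as.integer(sexChromCounts[["X"]])
  counts["Y"] <- as.integer(sexChromCounts[["Y"]])
  counts
}

.validChromLabel <- function(x) x %in% mouseChromosomes()

# Split a semicolon-joined list of event notations, ignoring semicolons that
# sit inside parentheses (the notation itself uses ";" between participants).
.splitEventList <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  out <- character(0)
  buf <- character(0)
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == ";" && depth == 0L) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
  }
  out <- c(out, paste(buf, collapse = ""))
  out <- trimws(out)
  out[nzchar(out)]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Mode of an integer vector; returns NA when the maximum is tied.
.strictMode <- function(x) {
  if (length(x) == 0L) return(NA_integer_)
  tab <- table(x)
  top <- tab[tab == max(tab)]
  if (length(top) > 1L) return(NA_integer_)
  as.integer(names(top))
}
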