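#' @include accessors.R
NULL

.KARYO_COLS <- c("cell_id", "sample_id", "animal_id", "site", "passage",
                 paste0("chr", mouseChromosomes()), "events")

#' Read a per-metaphase karyotype table
#'
#' Reads the karyotype TSV dialect (or its JSON mirror): one row per metaphase
#' with columns `cell_id`, `sample_id`, `animal_id`, `site`, `passage`, the 21
#' count columns `chr1..chr19`, `chrX`, `chrY`, and `events` — a
#' semicolon-joined list of event notation strings (`""` for none; see
#' [parseEventNotation()] for the grammar).
#'
#' @param path File path.
#' @param format `"TSV"` or `"JSON"`; default guessed from the extension.
#' @return A named list of [SampleKaryotypeSet-class] objects (one per
#'   `sample_id`, in order of first appearance).
#' @export
readKaryotypeTable <- function(path, format = c("auto", "TSV", "JSON")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "JSON" else "TSV"
  if (!file.exists(path)) .stopf("file not found: %s", path)

  df <- if (format == "TSV") {
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      colClasses = "character", na.strings = NULL,
                      fileEncoding = "UTF-8")
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  missing <- setdiff(.KARYO_COLS, names(df))
  if (length(missing))
    .stopf("missing column(s): %s", paste(missing, collapse = ", "))

  parseRow <- function(i) {
    row <- df[i, ]
    cts <- suppressWarnings(as.integer(row[paste0("chr", mouseChromosomes())]))
    if (any(is.na(cts)) || any(cts < 0L))
      .stopf("row %d: chromosome counts must be non-negative integers", i)
    if (!row[["site"]] %in% .SITES)
      .stopf("row %d: invalid site '%s'", i, row[["site"]])
    evs <- tryCatch(lapply(.splitEventList(as.character(row[["events"]])),
                           parseEventNotation),
                    error = function(e) .stopf("row %d: %s", i, conditionMessage(e)))
    metaphaseKaryotype(row[["cell_id"]], row[["sample_id"]],
                       stats::setNames(cts, mouseChromosomes()), evs)
  }
  cellsAll <- lapply(seq_len(nrow(df)), parseRow)

  sampleIds <- unique(df$sample_id)
  sets <- lapply(sampleIds, function(sid) {
    idx <- which(df$sample_id == sid)
    if (length(unique(df$animal_id[idx])) > 1L)
      .stopf("sample_id '%s' appears under more than one animal_id", sid)
    pass <- unique(df$passage[idx])
    sampleKaryotypeSet(
      sampleId = sid,
      animalId = unique(df$animal_id[idx])[1],
      site = unique(df$site[idx])[1],
      cells = cellsAll[idx],
      passage = if (nzchar(pass[1])) as.integer(pass[1]) else NA_integer_
    )
  })
  stats::setNames(sets, sampleIds)
}

#' Write sample karyotype sets to a table
#'
#' Inverse of [readKaryotypeTable()]: writes the karyotype TSV dialect (UTF-8,
#' tab-separated, canonical column order) or its JSON mirror. A write/read
#' round trip reproduces the input objects exactly.
#'
#' @param sets A list of [SampleKaryotypeSet-class] objects (or a single one).
#' @param path Output file path.
#' @param format `"TSV"` or `"JSON"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
writeKaryotypeTable <- function(sets, path, format = c("auto", "TSV", "JSON")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "JSON" else "TSV"
  if (is(sets, "SampleKaryotypeSet")) sets <- list(sets)

  rows <- do.call(rbind, lapply(sets, function(s) {
    do.call(rbind, lapply(s@cells, function(cell) {
      cts <- counts(cell)
      data.frame(
        cell_id = cellId(cell), sample_id = s@sampleId,
        animal_id = s@animalId, site = s@site,
        passage = if (is.na(s@passage)) "" else as.character(s@passage),
        as.list(stats::setNames(as.integer(cts),
                                paste0("chr", mouseChromosomes()))),
        events = paste(vapply(events(cell), formatEventNotation, character(1)),
                       collapse = ";"),
        check.names = FALSE, stringsAsFactors = FALSE
      )
    }))
  }))
  rows <- rows[, .KARYO_COLS]

  if (format == "TSV") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(rows, path, dataframe = "columns", auto_unbox = FALSE,
                         digits = NA)
  }
  invisible(path)
}
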