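# Plain-CSV input contract and result serialization. Instrument-native
# file dialects are deliberately not parsed; convert to a delimited table
# with a header first. Units are assumed umol-based throughout.

.header_synonyms <- list(
  i = c("i", "irradiance", "pari", "par", "qin", "q", "ppfd"),
  a_n = c("a_n", "an", "photo", "a", "anet"),
  phi_psii = c("phi_psii", "phips2", "phipsii", "phi"),
  j = c("j", "etr"),
  replicate = c("replicate", "rep", "leaf", "curve", "id"))

#' Read a table of gas-exchange / fluorescence light steps
#'
#' Reads a delimited text file (CSV, or TSV by extension) with a header
#' row into the standard step table used throughout the package: columns
#' `i`, `a_n`, `phi_psii`, `j`, `replicate` as available. Common
#' instrument-export headers are recognised case-insensitively
#' (`PARi`/`Qin` for irradiance, `Photo`/`A` for net photosynthesis,
#' `PhiPS2` for the PSII yield); `column_map` overrides the mapping.
#' Rows whose irradiance does not parse as a number are dropped with a
#' message; a missing replicate column is filled with a single replicate.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping standard names
#'   (`i`, `a_n`, `phi_psii`, `j`, `replicate`) to file headers, e.g.
#'   `c(i = "PARi", a_n = "Photo")`.
#' @param sep Field separator; default by extension (`\\t` for `.tsv`,
#'   `,` otherwise).
#' @return Data frame with standardized columns.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(PARi = c(1000, 0), Photo = c(20, -3), rep = 1), f,
#'           row.names = FALSE)
#' read_steps(f)
#' @export
read_steps <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) == 0L)
    stop("empty file: ", path, call. = FALSE)
  hdr <- tolower(trimws(names(raw)))
  pick <- function(std) {
    if (!is.null(column_map) && std %in% names(column_map)) {
      k <- match(tolower(column_map[[std]]), hdr)
      if (is.na(k)) stop("mapped column '", column_map[[std]],
                         "' not in file", call. = FALSE)
      return(k)
    }
    k <- match(.header_synonyms[[std]], hdr)
    k <- k[!is.na(k)]
    if (length(k)) k[1] else NA_integer_
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (std in names(.header_synonyms)) {
    k <- pick(std)
    if (!is.na(k)) out[[std]] <- raw[[k]]
  }
  if (!"i" %in% names(out))
    stop("no irradiance column found (looked for: ",
         paste(.header_synonyms$i, collapse = ", "), ")", call. = FALSE)
  for (col in intersect(c("i", "a_n", "phi_psii", "j"), names(out)))
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  bad <- !is.finite(out$i)
  if (any(bad)) {
    message("dropped ", sum(bad), " row(s) with unparseable irradiance")
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no usable rows in ", path, call. = FALSE)
  if (!"replicate" %in% names(out)) out$replicate <- "rep1"
  out$replicate <- as.character(out$replicate)
  rownames(out) <- NULL
  out
}

.results_as_df <- function(x) {
  if (inherits(x, "lrc_comparison")) x$table
  else if (inherits(x, "lrc_fit_list")) summary(x)
  else if (inherits(x, "lrc_fit")) summary(structure(
    list(x), class = "lrc_fit_list",
    model = x$model, response = x$response))
  else if (is.data.frame(x)) x
  else stop("don't know how to serialize a ", class(x)[1], call. = FALSE)
}

#' Write results to CSV or JSON
#'
#' Serializes fit results, comparison tables or plain data frames with a
#' deterministic column order. Floats are written at 6 significant digits
#' in CSV; JSON uses full precision and round-trips losslessly.
#'
#' @param x An `lrc_fit`, `lrc_fit_list`, `lrc_comparison` or data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; default by extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  df <- .results_as_df(x)
  if (is.null(df) || nrow(df) == 0L)
    stop("empty results: nothing to write", call. = FALSE)
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
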