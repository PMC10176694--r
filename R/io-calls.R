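#' Read a per-accession CNV call table
#'
#' Reads a TSV of CNV calls with header columns
#' \code{accession chrom start end svtype}. The coordinate dialect must be
#' declared, either by a leading directive line \code{#coords=0half} /
#' \code{#coords=1incl} (as written by \code{\link{write_cnv_calls}}) or
#' via the \code{coords} argument. Coordinates are normalised to the
#' package-internal 0-based half-open convention. Rows whose interval is
#' empty after normalisation (\code{end <= start}) are rejected with a
#' warning reporting their line numbers.
#'
#' @param path input TSV file.
#' @param coords \code{"0half"} or \code{"1incl"}; overrides/replaces the
#'   in-file directive.
#' @return data.frame with columns accession, chrom, start, end, svtype.
#' @export
read_cnv_calls <- function(path, coords = NULL) {
  lines <- readLines(path)
  offset <- 0L
  if (length(lines) > 0L && grepl("^#coords=", lines[1L])) {
    dialect <- sub("^#coords=", "", lines[1L])
    lines <- lines[-1L]
    offset <- 1L
    if (is.null(coords)) coords <- dialect
  }
  if (is.null(coords)) {
    stop("coordinate dialect not declared: add a '#coords=' line or pass ",
         "coords = '0half' or '1incl'")
  }
  if (!coords %in% c("0half", "1incl")) {
    stop("unknown coordinate dialect: ", coords)
  }
  if (length(lines) == 0L) stop("missing header line")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("accession", "chrom", "start", "end", "svtype")
  if (!identical(header[seq_along(required)], required)) {
    stop("missing or malformed header: expected columns ",
         paste(required, collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(data.frame(accession = character(), chrom = character(),
                      start = integer(), end = integer(),
                      svtype = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 5L)) {
    stop("malformed row at line ",
         which(n_fields < 5L)[1L] + 1L + offset)
  }
  df <- data.frame(
    accession = vapply(fields, `[[`, "", 1L),
    chrom = vapply(fields, `[[`, "", 2L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))),
    svtype = vapply(fields, `[[`, "", 5L),
    stringsAsFactors = FALSE
  )
  line_no <- seq_along(body) + 1L + offset
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("malformed coordinates at line ",
         line_no[which(is.na(df$start) | is.na(df$end))[1L]])
  }
  bad_type <- !df$svtype %in% c("DEL", "DUP")
  if (any(bad_type)) {
    stop("unknown svtype '", df$svtype[bad_type][1L], "' at line ",
         line_no[bad_type][1L])
  }
  if (coords == "1incl") {
    df$start <- df$start - 1L   # end stays: 1-based inclusive end == half-open end
  }
  empty <- df$end <= df$start
  if (any(empty)) {
    warning("rejected ", sum(empty), " row(s) with end <= start at line(s) ",
            paste(line_no[empty], collapse = ", "))
    df <- df[!empty, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a per-accession CNV call table
#'
#' Writes the dialect directive line, a header, and one row per call.
#'
#' @param calls data.frame with columns accession, chrom, start, end,
#'   svtype (0-based half-open).
#' @param path output file.
#' @param coords dialect to write in: \code{"0half"} (default) or
#'   \code{"1incl"}.
#' @export
write_cnv_calls <- function(calls, path, coords = c("0half", "1incl")) {
  coords <- match.arg(coords)
  assert_columns(calls, c("accession", "chrom", "start", "end", "svtype"),
                 "calls")
  out <- calls[, c("accession", "chrom", "start", "end", "svtype")]
  if (coords == "1incl") out$start <- out$start + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#coords=", coords), con)
  writeLines(paste(c("accession", "chrom", "start", "end", "svtype"),
                   collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  }
  invisible(path)
}
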