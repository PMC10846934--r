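#' Read a localization table from a delimited text file
#'
#' Supports the table dialects commonly produced by SMLM fitting software.
#' Whatever the source dialect, the returned table always carries
#' coordinates in nanometres.
#'
#' Dialects:
#' \describe{
#'   \item{`thunderstorm_csv`}{Comma-separated with unit-annotated headers
#'     such as `"x [nm]"`, `"y [nm]"`, `"frame"`, `"intensity [photon]"`.}
#'   \item{`rapidstorm_txt`}{Whitespace-separated values preceded by a
#'     `#`-comment header declaring the columns, either as plain names or
#'     as XML-style `field identifier="Position-0-0"` declarations
#'     (best-effort: the exact export schema varies between versions).}
#'   \item{`generic_csv`}{Delimiter sniffed from comma, semicolon or tab;
#'     case-insensitive header matching on `x`, `y`, `frame`, `intensity`,
#'     `track_id`, ignoring a bracketed unit suffix.}
#' }
#'
#' Columns whose header declares pixel units (`[px]`) are converted to nm
#' using `pixel_size`, which must then be supplied.
#'
#' @param path Path to an existing file.
#' @param dialect One of `"generic_csv"`, `"thunderstorm_csv"`,
#'   `"rapidstorm_txt"`.
#' @param pixel_size nm per pixel, required only when a coordinate column
#'   is declared in pixel units.
#' @return A localization table (see [localizations()]).
#' @export
read_localizations <- function(path,
                               dialect = c("generic_csv", "thunderstorm_csv",
                                           "rapidstorm_txt"),
                               pixel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  parsed <- switch(dialect,
    thunderstorm_csv = read_delimited_locs(path, sep = ",", pixel_size),
    generic_csv = read_delimited_locs(path, sep = NULL, pixel_size),
    rapidstorm_txt = read_rapidstorm_locs(path, pixel_size)
  )
  validate_localizations(parsed)
  parsed
}

#' Write a localization table to a delimited text file
#'
#' The written file is re-readable with [read_localizations()] using the
#' same dialect, with values preserved to better than 1e-6 nm.
#'
#' @param table A localization table.
#' @param path Output path.
#' @inheritParams read_localizations
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path,
                                dialect = c("generic_csv", "thunderstorm_csv",
                                            "rapidstorm_txt")) {
  dialect <- match.arg(dialect)
  validate_localizations(table)
  cols <- loc_columns(table)
  out <- as.data.frame(table)[, cols, drop = FALSE]
  header_name <- function(col) {
    switch(col,
      x = "x [nm]", y = "y [nm]",
      intensity = "intensity [photon]",
      col)
  }
  if (dialect == "thunderstorm_csv") {
    names(out) <- vapply(cols, header_name, character(1))
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, qmethod = "double", quote = TRUE)
  } else if (dialect == "generic_csv") {
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  } else {
    ident <- function(col) {
      switch(col,
        x = "Position-0-0", y = "Position-1-0", frame = "ImageNumber-0-0",
        intensity = "Amplitude-0-0", col)
    }
    fields <- vapply(cols, function(col) {
      unit <- if (col %in% c("x", "y")) " unit=\"nanometer\"" else ""
      sprintf("<field identifier=\"%s\"%s />", ident(col), unit)
    }, character(1))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", paste(fields, collapse = "")), con)
    utils::write.table(out, con, sep = " ", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Map a raw header label to a canonical column name plus declared unit.
canonical_column <- function(label) {
  label <- trimws(gsub("\"", "", label))
  unit <- NA_character_
  m <- regmatches(label, regexec("^(.*?)\\s*\\[([^]]*)\\]\\s*$", label))[[1]]
  if (length(m) == 3L) {
    label <- m[2]
    unit <- tolower(m[3])
  }
  name <- switch(tolower(trimws(label)),
    x = "x", y = "y", frame = "frame", intensity = "intensity",
    track_id = "track_id", NA_character_)
  list(name = name, unit = unit)
}

# Shared reader for comma/semicolon/tab-delimited dialects. `sep = NULL`
# sniffs the delimiter from the header line.
read_delimited_locs <- function(path, sep, pixel_size) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("file is empty (no header line)", call. = FALSE)
  }
  if (is.null(sep)) {
    counts <- vapply(c(",", ";", "\t"), function(s) {
      lengths(regmatches(first, gregexpr(s, first, fixed = TRUE)))
    }, integer(1))
    sep <- names(which.max(counts))
    if (max(counts) == 0L) sep <- ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  build_loc_table(raw, names(raw), pixel_size)
}

read_rapidstorm_locs <- function(path, pixel_size) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  header <- lines[is_comment]
  if (length(header) == 0L) {
    stop("rapidstorm_txt file has no '#' header comment declaring columns",
         call. = FALSE)
  }
  header <- paste(sub("^\\s*#\\s*", "", header), collapse = " ")
  idents <- regmatches(header,
                       gregexpr("identifier=\"[^\"]+\"", header))[[1]]
  if (length(idents) > 0L) {
    idents <- sub("^identifier=\"", "", sub("\"$", "", idents))
    labels <- vapply(idents, function(id) {
      if (grepl("^Position-0", id)) "x"
      else if (grepl("^Position-1", id)) "y"
      else if (grepl("^ImageNumber", id)) "frame"
      else if (grepl("^Amplitude", id)) "intensity"
      else id
    }, character(1))
  } else {
    labels <- strsplit(trimws(header), "\\s+")[[1]]
  }
  body <- lines[!is_comment]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    raw <- as.data.frame(matrix(character(), 0, length(labels)))
  } else {
    raw <- utils::read.table(text = body, header = FALSE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
  }
  if (ncol(raw) != length(labels) && nrow(raw) > 0L) {
    stop(sprintf(
      "rapidstorm_txt: header declares %d columns but rows have %d",
      length(labels), ncol(raw)), call. = FALSE)
  }
  names(raw) <- labels[seq_len(ncol(raw))]
  if (ncol(raw) == 0L) names(raw) <- character(0)
  if (nrow(raw) == 0L) {
    raw <- stats::setNames(
      as.data.frame(replicate(length(labels), character(0),
                              simplify = FALSE)), labels)
  }
  build_loc_table(raw, labels, pixel_size)
}

# Assemble the canonical localization table from a character data.frame,
# converting pixel-unit coordinate columns and reporting the first
# unparsable row by number.
build_loc_table <- function(raw, labels, pixel_size) {
  mapped <- lapply(labels, canonical_column)
  names(mapped) <- labels
  out <- list()
  for (i in seq_along(labels)) {
    cc <- mapped[[i]]
    if (is.na(cc$name) || cc$name %in% names(out)) next
    vals <- raw[[i]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num) & !is.na(vals) & nzchar(trimws(vals)))
    if (length(bad) > 0L) {
      stop(sprintf("unparsable value '%s' in column '%s' at data row %d",
                   vals[bad[1]], labels[i], bad[1]), call. = FALSE)
    }
    if (cc$name %in% c("x", "y") && !is.na(cc$unit) &&
        cc$unit %in% c("px", "pixel", "pixels")) {
      if (is.null(pixel_size)) {
        stop(sprintf(
          "column '%s' is in pixel units; supply pixel_size to convert to nm",
          labels[i]), call. = FALSE)
      }
      num <- num * pixel_size
    }
    out[[cc$name]] <- num
  }
  for (col in c("x", "y", "frame")) {
    if (!col %in% names(out)) {
      stop(sprintf("localization table is missing mandatory column '%s'", col),
           call. = FALSE)
    }
  }
  localizations(x = out$x, y = out$y, frame = out$frame,
                intensity = out$intensity, track_id = out$track_id)
}
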