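#' Construct a mass spectrum
#'
#' A spectrum is an ordered set of (m/z, intensity) pairs plus free-form
#' metadata. The m/z axis must be strictly increasing; raw input
#' intensities must be non-negative (negative residuals may appear only
#' after smoothing / baseline subtraction, which the pipeline records in
#' `metadata$stage`).
#'
#' @param mz numeric vector of m/z values (u), strictly increasing.
#' @param intensity numeric vector of intensities, same length as `mz`.
#' @param metadata named list of annotations (source file, stage, ...).
#' @param allow_negative logical; permit negative intensities (used
#'   internally for processed spectra).
#' @return An object of class `mass_spectrum`.
#' @export
#' @examples
#' s <- mass_spectrum(c(100, 101, 102), c(0, 5, 0))
#' s
mass_spectrum <- function(mz, intensity, metadata = list(),
                          allow_negative = FALSE) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (length(mz) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(mz) || anyNA(intensity))
    stop("mz/intensity must not contain NA", call. = FALSE)
  if (is.unsorted(mz, strictly = TRUE))
    stop("mz must be strictly increasing", call. = FALSE)
  if (!allow_negative && any(intensity < 0))
    stop("raw intensities must be non-negative", call. = FALSE)
  structure(list(mz = mz, intensity = intensity, metadata = metadata),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, m/z [%.4g, %.4g]\n",
              length(x$mz), x$mz[1], x$mz[length(x$mz)]))
  if (!is.null(x$metadata$stage))
    cat("  stage:", paste(x$metadata$stage, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mass_spectrum <- function(x, ...) {
  data.frame(mz = x$mz, intensity = x$intensity)
}

#' @export
length.mass_spectrum <- function(x) length(x$mz)

is_spectrum <- function(x) inherits(x, "mass_spectrum")

spectrum_stage <- function(s) {
  st <- s$metadata$stage
  if (is.null(st)) character() else st
}

add_stage <- function(s, stage) {
  s$metadata$stage <- c(spectrum_stage(s), stage)
  s
}

# ---- reading -----------------------------------------------------------

#' Read a spectrum from mzML or delimited text
#'
#' Text files must contain two numeric columns (m/z, intensity),
#' separated by whitespace, tabs or commas; lines starting with `#` and
#' an optional non-numeric header line are ignored. mzML files are
#' parsed for their m/z and intensity binary arrays (profile mode
#' expected); `index` selects the spectrum when the file holds several.
#' Out-of-order rows are sorted with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (sniff by content), `"mzml"` or `"text"`.
#' @param index 1-based spectrum selector for multi-spectrum mzML.
#' @return A [mass_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "mzml", "text"),
                          index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read spectrum: file not found: ", path, call. = FALSE)
  if (format == "auto") {
    head <- suppressWarnings(readLines(path, n = 5L))
    format <- if (any(grepl("<mzML|<indexedmzML", head))) "mzml" else "text"
  }
  sp <- switch(format,
               text = read_spectrum_text(path),
               mzml = read_spectrum_mzml(path, index))
  sp$metadata$source <- path
  sp
}

read_spectrum_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty spectrum file: ", path, call. = FALSE)
  # sniff delimiter: comma beats tab beats whitespace
  delim <- if (grepl(",", lines[[1]])) "," else ""
  parse_row <- function(l) {
    f <- if (nzchar(delim)) strsplit(l, delim, fixed = TRUE)[[1]]
         else strsplit(trimws(l), "[[:space:]]+")[[1]]
    suppressWarnings(as.numeric(trimws(f)))
  }
  first <- parse_row(lines[[1]])
  if (anyNA(first)) lines <- lines[-1L]  # header line
  vals <- lapply(lines, parse_row)
  n_col <- lengths(vals)
  if (any(n_col < 2L))
    stop("text spectrum must have two numeric columns", call. = FALSE)
  mz <- vapply(vals, `[`, numeric(1), 1L)
  it <- vapply(vals, `[`, numeric(1), 2L)
  if (anyNA(mz) || anyNA(it))
    stop("non-numeric content in spectrum file: ", path, call. = FALSE)
  if (length(mz) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (is.unsorted(mz, strictly = TRUE)) {
    warning("m/z values out of order in ", path, "; sorting", call. = FALSE)
    o <- order(mz)
    mz <- mz[o]; it <- it[o]
  }
  mass_spectrum(mz, it)
}

# Minimal mzML reader: extracts the m/z and intensity binary arrays of
# one <spectrum>. Supports 32/64-bit floats, uncompressed or zlib.
read_spectrum_mzml <- function(path, index = 1L) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(specs) == 0L)
    stop("no spectra found in mzML file: ", path, call. = FALSE)
  if (index < 1L || index > length(specs))
    stop("spectrum index out of range (file has ", length(specs), ")",
         call. = FALSE)
  node <- specs[[index]]
  arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
  mz <- NULL; it <- NULL
  for (arr in arrays) {
    acc <- xml2::xml_attr(xml2::xml_find_all(arr, ".//cvParam"), "accession")
    raw <- decode_mzml_binary(arr, acc)
    if ("MS:1000514" %in% acc) mz <- raw
    if ("MS:1000515" %in% acc) it <- raw
  }
  if (is.null(mz) || is.null(it))
    stop("mzML spectrum lacks m/z or intensity array", call. = FALSE)
  if (any(it < 0)) stop("negative raw intensity in mzML file", call. = FALSE)
  if (is.unsorted(mz, strictly = TRUE)) {
    warning("m/z values out of order in ", path, "; sorting", call. = FALSE)
    o <- order(mz)
    mz <- mz[o]; it <- it[o]
  }
  mass_spectrum(mz, it)
}

decode_mzml_binary <- function(arr, acc) {
  b64 <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
  raw <- base64enc::base64decode(gsub("\\s", "", b64))
  if ("MS:1000574" %in% acc) {  # zlib
    raw <- tryCatch(memDecompress(raw, type = "gzip"),
                    error = function(e) memDecompress(raw, type = "unknown"))
  }
  size <- if ("MS:1000521" %in% acc) 4L else 8L  # default 64-bit float
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = "little")
}

# ---- writing -----------------------------------------------------------

#' Write a spectrum as two-column text
#'
#' @param s a [mass_spectrum()].
#' @param path output path.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.*g %.*g", 17L, s$mz, 17L, s$intensity), con)
  invisible(path)
}

# ---- peak tables -------------------------------------------------------

peak_table_columns <- c("summit_mz", "height", "sigma1", "sigma2",
                        "beta1", "beta2", "area", "asymmetry",
                        "start_mz", "end_mz", "sse")

#' Construct a peak table
#'
#' A data frame of fitted peaks, one row per peak, with the fixed column
#' set `summit_mz, height, sigma1, sigma2, beta1, beta2, area,
#' asymmetry, start_mz, end_mz, sse`. Rows must be sorted by summit
#' m/z, every summit must lie within its `[start_mz, end_mz]` window and
#' asymmetry must be >= 1.
#'
#' @param df data frame holding (at least) the peak-table columns, or
#'   nothing for an empty table.
#' @return A `peak_table` (also a data.frame).
#' @export
peak_table <- function(df = NULL) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)),
                                     length(peak_table_columns)),
                                 peak_table_columns))
  }
  df <- as.data.frame(df)[, peak_table_columns, drop = FALSE]
  validate_peak_table(df)
  structure(df, class = c("peak_table", "data.frame"))
}

validate_peak_table <- function(df) {
  missing_cols <- setdiff(peak_table_columns, names(df))
  if (length(missing_cols))
    stop("peak table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(invisible(df))
  if (is.unsorted(df$summit_mz))
    stop("peak table rows must be sorted by summit_mz", call. = FALSE)
  if (any(df$asymmetry < 1))
    stop("peak asymmetry must be >= 1", call. = FALSE)
  if (any(df$summit_mz < df$start_mz | df$summit_mz > df$end_mz))
    stop("summit_mz must lie within [start_mz, end_mz]", call. = FALSE)
  invisible(df)
}

#' Write a peak table to CSV
#'
#' Numbers are written at full double precision (>= 15 significant
#' digits) so that `read_peak_table()` reproduces the values.
#'
#' @param peaks a [peak_table()].
#' @param path output path.
#' @export
write_peak_table <- function(peaks, path) {
  validate_peak_table(peaks)
  df <- as.data.frame(peaks)
  chr <- as.data.frame(lapply(df, function(col) sprintf("%.17g", col)),
                       stringsAsFactors = FALSE)
  names(chr) <- names(df)
  if (nrow(df) == 0L) chr <- df
  write.table(chr, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a peak table written by `write_peak_table()`
#'
#' @param path CSV path.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path))
    stop("cannot read peak table: file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = ",", header = TRUE)
  peak_table(df)
}
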