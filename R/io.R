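# File-format plumbing: TIFF images and CSV/TSV tables.

#' Read a TIFF image
#'
#' Integer TIFFs (8/16-bit) are returned on their native integer scale;
#' 32-bit float TIFFs as stored. A single-frame file gives a numeric
#' matrix; a multi-frame stack gives a list of matrices.
#'
#' @param path TIFF file path.
#' @return numeric matrix, or list of matrices for a stack.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                   error = function(e)
                     stopf("cannot read TIFF '%s': %s", path,
                           conditionMessage(e)))
  imgs <- lapply(imgs, function(m) {
    if (length(dim(m)) != 2L)
      stopf("'%s': expected a single-channel 2-D frame, got dims %s",
            path, paste(dim(m), collapse = "x"))
    storage.mode(m) <- "double"
    m
  })
  if (length(imgs) == 1L) imgs[[1]] else imgs
}

#' Write a matrix (or list of matrices) as an integer TIFF
#'
#' Values are rounded and clamped to the unsigned integer range of
#' `bits` (16 by default, the common microscopy dialect); the round trip
#' through [read_image()] is lossless for in-range integer data.
#'
#' @param img numeric matrix or list of matrices (multi-frame stack).
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  top <- 2^bits - 1
  enc <- function(m) pmin(pmax(round(m), 0), top) / top
  x <- if (is.list(img)) lapply(img, enc) else enc(img)
  tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read and write delimited tables
#'
#' UTF-8 tables with a header row and `.` decimal separator; `.tsv` paths
#' are tab-delimited, everything else comma-delimited. Numbers are written
#' at full precision (17 significant digits), so numeric round trips are
#' exact up to float formatting.
#'
#' @param records data.frame to write.
#' @param path file path.
#' @return `read_table()` returns a data.frame; `write_table()` returns
#'   `path` invisibly.
#' @export
write_table <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  num <- vapply(records, is.double, logical(1))
  records[num] <- lapply(records[num], function(x) {
    s <- formatC(x, digits = 17, format = "g")
    s[is.na(x)] <- NA
    trimws(s)
  })
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stopf("table not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    na.strings = "", check.names = FALSE)
}
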