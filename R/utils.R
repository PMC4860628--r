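#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper setNames runif
#' @importFrom utils head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

tox_log <- function(..., prefix = "toxlinker") {
  message(sprintf("[%s] %s", prefix, paste0(...)))
}

trim <- function(x) {
  sub("[ \t\r]+$", "", sub("^[ \t\r]+", "", x))
}

#' Read a tab-separated table in one of the package dialects
#'
#' All input tables share one convention: UTF-8, tab-delimited, lines
#' beginning with `#` ignored, first non-comment line an exact header.
#' Returns a character data frame with a `line` column carrying the
#' 1-based physical line number of each row (used for provenance and
#' error reporting) and the source path in attribute `source_file`.
#'
#' @param path file to read.
#' @param expected_header character vector of required column names, in order.
#' @return data.frame of character columns named after the header, plus `line`.
#' @keywords internal
read_tox_tsv <- function(path, expected_header) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(lines, "#")
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("no header line in ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(trim(header), expected_header)) {
    stop(sprintf("malformed header in %s (line %d): expected '%s', got '%s'",
                 path, lineno[[1L]],
                 paste(expected_header, collapse = "\\t"),
                 paste(header, collapse = "\\t")), call. = FALSE)
  }
  body <- lines[-1L]
  body_lineno <- lineno[-1L]
  nonblank <- nzchar(trim(body))
  body <- body[nonblank]
  body_lineno <- body_lineno[nonblank]
  ncol <- length(expected_header)
  if (length(body) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), ncol),
                                  expected_header))
    out$line <- integer(0)
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    # strsplit drops trailing empty fields; pad rather than reject
    fields <- lapply(fields, function(f) c(f, rep("", max(0L, ncol - length(f)))))
    bad <- which(vapply(fields, length, 1L) != ncol)
    if (length(bad) > 0L) {
      stop(sprintf("%s line %d: expected %d tab-separated fields, found %d",
                   path, body_lineno[bad[[1L]]], ncol,
                   length(fields[[bad[[1L]]]])), call. = FALSE)
    }
    mat <- do.call(rbind, fields)
    out <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(out) <- expected_header
    out[] <- lapply(out, trim)
    out$line <- body_lineno
  }
  attr(out, "source_file") <- path
  out
}

write_tox_tsv <- function(df, path, header) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(df) > 0L) {
    rows <- do.call(paste, c(unname(df[header]), list(sep = "\t")))
    writeLines(rows, con)
  }
  invisible(path)
}

# split a |-delimited multi-valued field (CTD convention); "" -> character(0)
split_pipes <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1L]]
}

join_pipes <- function(x) paste(x, collapse = "|")
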