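#' Read a master taxonomy from a delimited file
#'
#' The file format is a plain CSV or TSV table with a header row naming the
#' taxonomic levels from lowest to highest, one row per OTU and one column
#' per level, UTF-8 encoded; lines beginning with `#` are ignored.  The first
#' column holds the OTU names.
#'
#' @param file path to the file.
#' @param sep field separator; by default inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param level_names optional character vector overriding the header names.
#' @return a validated [taxonomy()].
#' @seealso [write_master_list()], [read_sample()]
#' @export
read_master_list <- function(file, sep = NULL, level_names = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           comment.char = "#", colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           fileEncoding = "UTF-8",
                           strip.white = TRUE)
  if (!is.null(level_names)) {
    if (length(level_names) != ncol(tab)) {
      stop("'level_names' must match the number of columns in ", file)
    }
    names(tab) <- level_names
  }
  taxonomy(tab)
}

#' Write a master taxonomy to a delimited file
#'
#' @param tx a `taxonomy`.
#' @param file output path.
#' @param sep field separator (default comma).
#' @param header_lines optional character vector written first, each line
#'   prefixed with `"# "` (used to echo run configuration).
#' @return `file`, invisibly.
#' @export
write_master_list <- function(tx, file, sep = ",", header_lines = NULL) {
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste("#", header_lines), con)
  }
  utils::write.table(tx$classification, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' Read a sample of OTU names
#'
#' A sample file lists one OTU name per line (or the first column of a
#' delimited file); `#` comment lines and blank lines are ignored.  When a
#' master list is supplied the names are checked against it.
#'
#' @param file path to the file.
#' @param master optional `taxonomy` to validate against.
#' @return character vector of OTU names.
#' @export
read_sample <- function(file, master = NULL) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  otus <- vapply(strsplit(lines, "[,\t]"), `[[`, character(1), 1L)
  otus <- trimws(otus)
  if (anyDuplicated(otus)) {
    stop("duplicate OTU name(s) in sample file: ",
         paste(unique(otus[duplicated(otus)]), collapse = ", "))
  }
  if (!is.null(master)) {
    missing <- setdiff(otus, otu_names(master))
    if (length(missing)) {
      stop("sample OTU(s) absent from master list: ",
           paste(missing, collapse = ", "))
    }
  }
  otus
}

#' Write a sample of OTU names
#'
#' @param otus character vector of OTU names.
#' @param file output path.
#' @param header_lines optional `#`-prefixed header lines.
#' @return `file`, invisibly.
#' @export
write_sample <- function(otus, file, header_lines = NULL) {
  con <- file(file, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) {
    writeLines(paste("#", header_lines), con)
  }
  writeLines(as.character(otus), con)
  invisible(file)
}
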