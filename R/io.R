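# Format I/O. Missing values are empty fields in TSV, never zero.
# Protein positions are 1-based inclusive; image pixel coordinates are
# 0-based. Images and label masks are serialized as plain-text TSV
# matrices (no binary image dependency is assumed).

#' Read / write a data frame as TSV
#'
#' Empty fields are the missing-value marker in both directions.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_df` returns a data.frame.
#' @export
read_tsv_df <- function(path) {
  utils::read.delim(path, check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
}

#' @rdname read_tsv_df
#' @export
write_tsv_df <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an intensity table (values + sample sheet)
#'
#' Two TSVs: `<stem>.tsv` holds the feature metadata and one intensity
#' column per sample; `<stem>.samples.tsv` holds the sample sheet.
#'
#' @param table an [intensity_table()].
#' @param stem path stem (no extension).
#' @return `read_intensity_table` returns an [intensity_table()].
#' @export
write_intensity_table <- function(table, stem) {
  df <- cbind(table$features, as.data.frame(table$values, row.names = NULL))
  write_tsv_df(df, paste0(stem, ".tsv"))
  write_tsv_df(table$samples, paste0(stem, ".samples.tsv"))
  invisible(stem)
}

#' @rdname write_intensity_table
#' @param log2 whether the stored values are log2-scale.
#' @export
read_intensity_table <- function(stem, log2 = FALSE) {
  df <- read_tsv_df(paste0(stem, ".tsv"))
  samples <- read_tsv_df(paste0(stem, ".samples.tsv"))
  feat_cols <- setdiff(names(df), samples$sample)
  intensity_table(as.matrix(df[samples$sample]), df[feat_cols], samples,
                  log2 = log2)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around Biostrings; sequences are plain named character
#' vectors on the R side.
#'
#' @param path FASTA file.
#' @param sequences named character vector.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read / write GMT annotation sets
#'
#' One set per line: `set_id TAB description TAB member1 TAB member2 ...`.
#'
#' @param path GMT file.
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT record: '", substr(l, 1, 40), "'")
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a numeric (or integer label) matrix as TSV
#'
#' Text stand-in for image formats: one row per pixel row, tab-separated.
#' Integer label masks round-trip exactly.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_image_tsv` returns a matrix.
#' @export
write_image_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Read / write a flat key-value configuration file
#'
#' YAML-style flat `key: value` lines; `#` starts a comment. Values are
#' parsed as numeric when possible, comma-separated values become
#' vectors.
#'
#' @param path config file.
#' @param config named list of scalars / vectors.
#' @return `read_config` returns a named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    if (!grepl(":", l, fixed = TRUE))
      stop("malformed config line: '", l, "'")
    key <- trimws(sub(":.*$", "", l))
    val <- trimws(sub("^[^:]*:", "", l))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, ": ", paste(config[[k]], collapse = ", ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an object as JSON
#'
#' @param x list / data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
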