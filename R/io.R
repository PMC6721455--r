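#' Read a FASTA file into a named character vector
#'
#' Sequences are normalized to the RNA alphabet (uppercase, T -> U);
#' record order is preserved and the description line is parsed for the
#' first whitespace-delimited token only. Duplicate ids and empty records
#' are rejected.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record: ", ids[nchar(seqs) == 0L][1], call. = FALSE)
  }
  setNames(vapply(seqs, normalize_rna, character(1), USE.NAMES = FALSE), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a typed tab-separated table
#'
#' Tab-separated, header row, UTF-8, locale-independent decimal point.
#' Columns listed in `schema` are checked for presence and coerced to the
#' stated type; unknown extra columns are carried through untouched with
#' a warning. A header-only file yields an empty typed table.
#'
#' @param path TSV path.
#' @param schema Named character vector mapping required column names to
#'   types ("character", "integer", "double", "logical"), or NULL for no
#'   validation.
#' @return A tibble.
#' @export
read_table_tsv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = NA, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(df))
    if (length(missing)) {
      stop("missing column(s) in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(df), names(schema))
    if (length(extra)) {
      warning("extra column(s) carried through: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    for (col in names(schema)) {
      coerce <- switch(schema[[col]], character = as.character,
                       integer = as.integer, double = as.numeric,
                       logical = as.logical,
                       stop("unknown schema type ", schema[[col]]))
      val <- suppressWarnings(coerce(df[[col]]))
      bad <- which(is.na(val) & !is.na(df[[col]]))
      if (length(bad)) {
        stop("unparsable ", schema[[col]], " in ", path, ", column '", col,
             "', row ", bad[1], ": '", df[[col]][bad[1]], "'", call. = FALSE)
      }
      df[[col]] <- val
    }
  }
  tibble::as_tibble(df)
}

#' Write a tab-separated table with a provenance header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param provenance Optional named list echoed as `# key: value` comment
#'   lines above the header.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# generated-by: mirep ",
                    as.character(utils::packageVersion("mirep"))), con)
  for (key in names(provenance)) {
    writeLines(paste0("# ", key, ": ", provenance[[key]]), con)
  }
  # write.table warns when adding a header after the provenance comments;
  # the layout is intentional
  suppressWarnings(
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ""))
  invisible(path)
}
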