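#' Normalize read containers to a plain record list
#'
#' Accepts a [Biostrings::QualityScaledDNAStringSet], a
#' [Biostrings::DNAStringSet], or a character vector of sequences, and
#' returns the parallel id/bases/qualities vectors used internally.
#' Qualities are `NULL` when the input carries none.
#'
#' @param x Reads in any supported container.
#' @return A list with elements `id` (character), `bases` (character)
#'   and `quals` (character or `NULL`).
#' @keywords internal
#' @export
as_read_records <- function(x) {
  if (is.list(x) && !is.null(x$bases)) return(x)
  if (methods::is(x, "QualityScaledXStringSet")) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("read_", seq_along(x))
    return(list(id = ids,
                bases = as.character(x),
                quals = as.character(Biostrings::quality(x))))
  }
  if (methods::is(x, "XStringSet")) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("read_", seq_along(x))
    return(list(id = ids, bases = as.character(x), quals = NULL))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("read_", seq_along(x))
    return(list(id = unname(ids), bases = unname(x), quals = NULL))
  }
  stop("unsupported read container of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

# rebuild a QualityScaledDNAStringSet from a record list
records_to_qsdss <- function(rec) {
  quals <- rec$quals
  if (is.null(quals)) quals <- strrep("I", nchar(rec$bases))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(rec$bases),
    Biostrings::PhredQuality(quals)
  )
  names(x) <- rec$id
  x
}

#' Read a FASTQ file
#'
#' Reads a (possibly gzip-compressed) FASTQ file with Sanger (Phred+33)
#' qualities into a [Biostrings::QualityScaledDNAStringSet], preserving
#' record order.  The file structure is validated first so that a
#' malformed record (missing `+` separator, truncation, or a
#' base/quality length mismatch) raises a parse error naming the
#' offending record index.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  n <- validate_fastq(path)
  if (n == 0L) {
    empty <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(character()),
      Biostrings::PhredQuality(character()))
    return(empty)
  }
  suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  )
}

# structural scan: 4-line records, '@' header, '+' separator, equal lengths
validate_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    block <- readLines(con, n = 4L)
    if (length(block) == 0L) break
    i <- i + 1L
    if (length(block) < 4L)
      stop("FASTQ parse error: record ", i, " is truncated", call. = FALSE)
    if (!startsWith(block[1L], "@"))
      stop("FASTQ parse error: record ", i, " does not start with '@'",
           call. = FALSE)
    if (!startsWith(block[3L], "+"))
      stop("FASTQ parse error: record ", i, " is missing the '+' separator",
           call. = FALSE)
    if (nchar(block[2L]) != nchar(block[4L]))
      stop("FASTQ parse error: record ", i,
           " has a base/quality length mismatch", call. = FALSE)
  }
  invisible(i)
}

#' Write reads to a FASTQ file
#'
#' Sanger (Phred+33) encoding; writes gzip output when `path` ends in
#' `.gz`.  Reads without qualities are written at Q40.
#'
#' @param reads Reads in any container accepted by [as_read_records()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- records_to_qsdss(as_read_records(reads))
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
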