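#' Telomeric hexamer motifs
#'
#' The four hexamers used for telomeric read detection: the canonical
#' G-strand repeat `TTAGGG`, the variant repeat `TTAGGT`, and their
#' reverse complements `CCCTAA` and `ACCTAA` (the C-strand forms).
#'
#' @format Named character vector of length 4 with names
#'   `wt_g`, `var_g`, `wt_c`, `var_c`.
#' @export
TELOMERE_MOTIFS <- c(
  wt_g  = "TTAGGG",
  var_g = "TTAGGT",
  wt_c  = "CCCTAA",
  var_c = "ACCTAA"
)

WT_HEXAMER  <- "TTAGGG"
VAR_HEXAMER <- "TTAGGT"

#' Greedy non-overlapping motif scan
#'
#' Scans each sequence left to right and records non-overlapping
#' occurrences of any of the supplied motifs: at each position the first
#' motif (in the order given) that matches is consumed and the scan
#' resumes immediately after it; otherwise the scan advances one base.
#' For the telomeric hexamers no two motifs can match at the same start
#' (they differ within their first six bases), so the result does not
#' depend on motif order for telomere sequence.
#'
#' @param seqs Character vector of DNA sequences (or anything
#'   [as_read_records()] accepts).
#' @param motifs Character vector of motifs, all of the same length.
#' @return A list with one element per sequence: a data.frame with
#'   columns `start` (1-based) and `motif`.
#' @examples
#' motif_scan("TTAGGGTTAGGT", c("TTAGGG", "TTAGGT"))
#' @export
motif_scan <- function(seqs, motifs = TELOMERE_MOTIFS) {
  seqs <- as_read_records(seqs)$bases
  flat <- motif_scan_flat(seqs, motifs)
  out <- rep(list(data.frame(start = integer(), motif = character())),
             length(seqs))
  if (length(flat$read)) {
    sp <- split(data.frame(start = flat$start, motif = flat$motif),
                factor(flat$read, levels = seq_along(seqs)))
    out <- lapply(sp, `rownames<-`, NULL)
  }
  unname(out)
}

# flat greedy scan: parallel vectors read (index into seqs), start
# (1-based), motif — already filtered to the greedy non-overlapping set
motif_scan_flat <- function(seqs, motifs = TELOMERE_MOTIFS) {
  motifs <- unname(motifs)
  k <- unique(nchar(motifs))
  if (length(k) != 1L)
    stop("all motifs must have the same length", call. = FALSE)
  n <- length(seqs)
  empty <- list(read = integer(), start = integer(), motif = character())
  if (n == 0L) return(empty)

  # all candidate starts per motif (overlapping search: occurrences of
  # one motif may overlap occurrences of another)
  read <- integer(); start <- integer(); midx <- integer()
  for (m in seq_along(motifs)) {
    loc <- stringi::stri_locate_all_fixed(seqs, motifs[m],
                                          overlap = TRUE,
                                          omit_no_match = TRUE)
    lens <- vapply(loc, nrow, integer(1))
    if (sum(lens) == 0L) next
    read <- c(read, rep.int(seq_len(n), lens))
    start <- c(start, unlist(lapply(loc, function(x) x[, 1L]),
                             use.names = FALSE))
    midx <- c(midx, rep.int(m, sum(lens)))
  }
  if (length(read) == 0L) return(empty)

  o <- order(read, start, midx)
  read <- read[o]; start <- start[o]; midx <- midx[o]
  keep <- logical(length(read))
  cur <- 0L; cur_read <- 0L
  for (j in seq_along(read)) {
    if (read[j] != cur_read) { cur_read <- read[j]; cur <- 1L }
    if (start[j] >= cur) {
      keep[j] <- TRUE
      cur <- start[j] + k
    }
  }
  list(read = read[keep], start = start[keep], motif = motifs[midx[keep]])
}

#' Count non-overlapping motif occurrences
#'
#' Total greedy non-overlapping motif count per sequence (all motifs
#' pooled in a single scan, see [motif_scan()]).
#'
#' @inheritParams motif_scan
#' @return Integer vector, one count per sequence.
#' @export
motif_count <- function(seqs, motifs = TELOMERE_MOTIFS) {
  seqs <- as_read_records(seqs)$bases
  flat <- motif_scan_flat(seqs, motifs)
  tabulate(flat$read, nbins = length(seqs))
}

#' All cyclic rotations of a hexamer
#'
#' @param hexamer A 6-base string.
#' @return Character vector of the 6 rotations, starting with the input
#'   itself.
#' @examples
#' hexamer_rotations("TTAGGG")
#' @export
hexamer_rotations <- function(hexamer) {
  stopifnot(nchar(hexamer) == 6L)
  dbl <- paste0(hexamer, hexamer)
  vapply(0:5, function(k) substr(dbl, k + 1L, k + 6L), character(1))
}

# reverse complement for plain character vectors (delegates to Biostrings)
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
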