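#' Detect telomeric reads
#'
#' A read is telomeric when the pooled greedy non-overlapping count of
#' the configured motifs (both strands, anywhere in the untrimmed read)
#' reaches `config$min_repeats`.  `N` bases never match a motif.
#'
#' @param reads Reads in any container accepted by [as_read_records()].
#' @param config A [detection_config()].
#' @return A tibble with columns `read_id`, `motif_count`, `telomeric`.
#' @examples
#' is_telomeric(strrep("TTAGGG", 25))
#' @export
is_telomeric <- function(reads, config = detection_config()) {
  rec <- as_read_records(reads)
  counts <- motif_count(rec$bases, config$motifs)
  tibble::tibble(read_id = rec$id, motif_count = counts,
                 telomeric = counts >= config$min_repeats)
}

#' Trim reads to their high-quality head
#'
#' Keeps the first `config$trim_point` bases of each read (the whole
#' read when shorter); qualities are trimmed in lockstep.
#'
#' @inheritParams is_telomeric
#' @return Reads in the same kind of container as the input.
#' @export
trim_reads <- function(reads, config = detection_config()) {
  rec <- as_read_records(reads)
  tp <- config$trim_point
  rec$bases <- substr(rec$bases, 1L, tp)
  if (!is.null(rec$quals)) rec$quals <- substr(rec$quals, 1L, tp)
  rebuild_like(reads, rec)
}

#' Orient reads to the G-strand
#'
#' If a read's C-strand motif count (`CCCTAA` + `ACCTAA`) strictly
#' exceeds its G-strand count (`TTAGGG` + `TTAGGT`), it is replaced by
#' its reverse complement and labelled `"C"`; otherwise it is returned
#' unchanged with label `"G"` (ties keep the read as given).  Counts
#' come from the same pooled greedy scan used for detection.
#'
#' @inheritParams is_telomeric
#' @return A list with `reads` (same kind of container as the input,
#'   oriented) and `strand` (character vector of `"G"`/`"C"` labels).
#' @export
orient_reads <- function(reads, config = detection_config()) {
  rec <- as_read_records(reads)
  flat <- motif_scan_flat(rec$bases, config$motifs)
  # a motif is C-strand iff it is C-richer than G-rich (the telomere
  # G-strand repeats are G-rich, their complements C-rich)
  is_c <- vapply(config$motifs,
                 function(m) stringi::stri_count_fixed(m, "C") >
                   stringi::stri_count_fixed(m, "G"),
                 logical(1))
  c_set <- config$motifs[is_c]
  n <- length(rec$bases)
  c_counts <- tabulate(flat$read[flat$motif %in% c_set], nbins = n)
  g_counts <- tabulate(flat$read[!(flat$motif %in% c_set)], nbins = n)
  flip <- c_counts > g_counts
  if (any(flip)) {
    rec$bases[flip] <- revcomp(rec$bases[flip])
    if (!is.null(rec$quals))
      rec$quals[flip] <- stringi::stri_reverse(rec$quals[flip])
  }
  list(reads = rebuild_like(reads, rec),
       strand = ifelse(flip, "C", "G"))
}

# return records in the same container family as the template input
rebuild_like <- function(template, rec) {
  if (methods::is(template, "QualityScaledXStringSet"))
    return(records_to_qsdss(rec))
  if (methods::is(template, "XStringSet")) {
    x <- Biostrings::DNAStringSet(rec$bases)
    names(x) <- rec$id
    return(x)
  }
  stats::setNames(rec$bases, rec$id)
}

#' Quantify wild-type / variant / other telomere composition
#'
#' Applies the full composition stage: telomeric reads are detected on
#' the untrimmed sequence, trimmed to `config$trim_point` bases,
#' oriented to the G-strand, and scanned greedily for non-overlapping
#' `TTAGGG` and `TTAGGT`.  `bases_wt`/`bases_var` are 6x the motif
#' counts; everything else in the trimmed reads is `bases_other`.
#' Fractions are of `bases_considered` (the summed trimmed lengths) and
#' are `NA` when no telomeric read exists.  A repeat-count variant
#' fraction (`frac_var_repeats` = variant motifs / all counted motifs)
#' is also reported for comparison with normalizations per repeat
#' rather than per base.
#'
#' @inheritParams is_telomeric
#' @return An object of class `telomere_composition`: a list with
#'   `n_reads_total`, `n_reads_telomeric`, `bases_considered`,
#'   `bases_wt`, `bases_var`, `bases_other`, `frac_wt`, `frac_var`,
#'   `frac_other`, `frac_wt_repeats`, `frac_var_repeats`.
#' @examples
#' telomere_composition(strrep("TTAGGG", 25))
#' @export
telomere_composition <- function(reads, config = detection_config()) {
  rec <- as_read_records(reads)
  det <- is_telomeric(rec, config)
  telo <- list(id = rec$id[det$telomeric], bases = rec$bases[det$telomeric],
               quals = rec$quals[det$telomeric])
  telo$bases <- substr(telo$bases, 1L, config$trim_point)
  telo <- orient_records(telo, config)

  flat <- motif_scan_flat(telo$bases, config$motifs)
  n_wt <- sum(flat$motif == WT_HEXAMER)
  n_var <- sum(flat$motif == VAR_HEXAMER)
  bases_considered <- sum(nchar(telo$bases))
  bases_wt <- 6L * n_wt
  bases_var <- 6L * n_var
  bases_other <- bases_considered - bases_wt - bases_var

  frac <- function(x) if (bases_considered > 0) x / bases_considered
                      else NA_real_
  n_motifs <- n_wt + n_var
  structure(list(
    n_reads_total = length(rec$bases),
    n_reads_telomeric = sum(det$telomeric),
    bases_considered = bases_considered,
    bases_wt = bases_wt, bases_var = bases_var, bases_other = bases_other,
    frac_wt = frac(bases_wt), frac_var = frac(bases_var),
    frac_other = frac(bases_other),
    frac_wt_repeats = if (n_motifs > 0) n_wt / n_motifs else NA_real_,
    frac_var_repeats = if (n_motifs > 0) n_var / n_motifs else NA_real_
  ), class = "telomere_composition")
}

# orientation on a record list (internal, avoids container round trips)
orient_records <- function(rec, config) {
  if (length(rec$bases) == 0L) return(rec)
  res <- orient_reads(stats::setNames(rec$bases, rec$id), config)
  rec$bases <- unname(res$reads)
  rec
}

#' @export
print.telomere_composition <- function(x, ...) {
  cat("Telomere composition\n")
  cat(sprintf("  reads: %d total, %d telomeric\n",
              x$n_reads_total, x$n_reads_telomeric))
  cat(sprintf("  bases considered (trimmed): %d\n", x$bases_considered))
  fmt <- function(f) if (is.na(f)) "." else sprintf("%.4f", f)
  cat(sprintf("  frac wt %s | var %s | other %s (of bases)\n",
              fmt(x$frac_wt), fmt(x$frac_var), fmt(x$frac_other)))
  cat(sprintf("  frac var %s (of counted repeats)\n",
              fmt(x$frac_var_repeats)))
  invisible(x)
}

#' Tabulate consecutive-repeat run lengths
#'
#' A run is a maximal block of tandem, exactly adjacent, in-frame
#' hexamers of the same class (`TTAGGG` = wt, `TTAGGT` = var) within a
#' single read.  Runs truncated by a read boundary count at their
#' observed length (right-censoring; see the package vignette).  Reads
#' are expected to be trimmed and oriented already — use
#' [telomere_runs_from_reads()] for the full pipeline from raw reads —
#' and a `telovar_array` may be passed directly, in which case runs are
#' taken over the whole array.
#'
#' @param x Oriented G-strand reads (any container accepted by
#'   [as_read_records()]) or a `telovar_array`.
#' @param config A [detection_config()] (motif set).
#' @return An object of class `run_length_table`: a tibble with columns
#'   `class` (`"wt"`/`"var"`), `run_length`, `n_runs`, and per-class
#'   total repeat counts in `attr(, "total_repeats")`.
#' @export
run_length_table <- function(x, config = detection_config()) {
  UseMethod("run_length_table")
}

#' @export
run_length_table.telovar_array <- function(x, config = detection_config()) {
  cls <- ifelse(x$hexamer == WT_HEXAMER, "wt",
                ifelse(x$hexamer == VAR_HEXAMER, "var", NA_character_))
  runs_from_blocks(rep(1L, nrow(x)), x$unit, cls, step = 1L)
}

#' @export
run_length_table.default <- function(x, config = detection_config()) {
  rec <- as_read_records(x)
  flat <- motif_scan_flat(rec$bases, config$motifs)
  cls <- ifelse(flat$motif == WT_HEXAMER, "wt",
                ifelse(flat$motif == VAR_HEXAMER, "var", NA_character_))
  runs_from_blocks(flat$read, flat$start, cls, step = 6L)
}

# tabulate maximal same-class runs from (read, position, class) triples
# sorted by read then position; a run continues when the next entry is
# in the same read, `step` bases/units downstream, and same class
runs_from_blocks <- function(read, pos, cls, step) {
  n <- length(cls)
  if (n == 0L)
    return(empty_run_table())
  adjacent <- c(FALSE, diff(pos) == step & diff(read) == 0L)
  same_cls <- c(FALSE, cls[-1L] == cls[-n] & !is.na(cls[-1L]) &
                  !is.na(cls[-n]))
  new_block <- !(adjacent & same_cls)
  block <- cumsum(new_block)
  keep <- !is.na(cls)
  if (!any(keep)) return(empty_run_table())
  lens <- tapply(block[keep], block[keep], length)
  block_cls <- cls[keep][!duplicated(block[keep])]
  rows <- lapply(c("wt", "var"), function(class) {
    len <- as.integer(lens[block_cls == class])
    if (!length(len))
      return(tibble::tibble(class = character(), run_length = integer(),
                            n_runs = integer()))
    tab <- table(len)
    tibble::tibble(class = class,
                   run_length = as.integer(names(tab)),
                   n_runs = as.integer(tab))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("run_length_table", class(out))
  attr(out, "total_repeats") <-
    c(wt = sum(as.integer(lens[block_cls == "wt"])),
      var = sum(as.integer(lens[block_cls == "var"])))
  out
}

empty_run_table <- function() {
  out <- tibble::tibble(class = character(), run_length = integer(),
                        n_runs = integer())
  class(out) <- c("run_length_table", class(out))
  attr(out, "total_repeats") <- c(wt = 0L, var = 0L)
  out
}

#' Run-length table from raw reads
#'
#' Convenience wrapper: detect telomeric reads, trim, orient, and
#' tabulate runs.
#'
#' @inheritParams is_telomeric
#' @return A `run_length_table` (see [run_length_table()]).
#' @export
telomere_runs_from_reads <- function(reads, config = detection_config()) {
  rec <- as_read_records(reads)
  det <- is_telomeric(rec, config)
  telo <- list(id = rec$id[det$telomeric], bases = rec$bases[det$telomeric],
               quals = NULL)
  telo$bases <- substr(telo$bases, 1L, config$trim_point)
  telo <- orient_records(telo, config)
  run_length_table(stats::setNames(telo$bases, telo$id), config)
}
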