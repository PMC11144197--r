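#' Terminal permutation rotation sets
#'
#' The 6 cyclic rotations of the wild-type (`TTAGGG`) and variant
#' (`TTAGGT`) repeats.  The two sets are disjoint (asserted when the
#' package is loaded), so terminal classification is unambiguous.
#'
#' @return A list with character vectors `wt` and `var`.
#' @export
terminal_rotations <- function() {
  list(wt = hexamer_rotations(WT_HEXAMER),
       var = hexamer_rotations(VAR_HEXAMER))
}

.onLoad <- function(libname, pkgname) {
  rot <- terminal_rotations()
  all12 <- c(rot$wt, rot$var)
  if (anyDuplicated(all12))
    stop("internal error: wild-type and variant rotation sets overlap")
  invisible()
}

CTAIL_MOTIFS <- c("CTAACC", "CTAAAC")

#' Locate the C-tail G-run
#'
#' Returns the first (smallest start) maximal run of at least
#' `min_g_run` consecutive `G` per read.  Coordinates are 0-based;
#' reads without a qualifying run get `NA`.
#'
#' @param reads Reads in any container accepted by [as_read_records()].
#' @param min_g_run Minimum run length (default 6).
#' @return A tibble with columns `read_id`, `g_run_start` (0-based),
#'   `g_run_length`.
#' @export
locate_g_run <- function(reads, min_g_run = 6L) {
  rec <- as_read_records(reads)
  pat <- paste0("G{", min_g_run, ",}")
  loc <- stringi::stri_locate_first_regex(rec$bases, pat)
  tibble::tibble(read_id = rec$id,
                 g_run_start = as.integer(loc[, 1L]) - 1L,
                 g_run_length = as.integer(loc[, 2L] - loc[, 1L] + 1L))
}

#' Apply the terminal read quality filters
#'
#' The three filters, in order: (a) pooled non-overlapping count of
#' `CTAACC`/`CTAAAC` at least `min_ctail_motifs`; (b) a run of at least
#' `min_g_run` consecutive `G`; (c) the `defined_window` bases
#' immediately after the first maximal such run exist and contain no
#' `N`.  The reported `reason` is the first violated criterion
#' (`"ctail_motifs"`, `"g_run"`, `"undefined_window"`), `NA` for
#' passing reads.
#'
#' @inheritParams locate_g_run
#' @param config A [terminal_filter_config()].
#' @return A tibble with `read_id`, `pass`, `reason`, `motif_count`,
#'   `g_run_start` (0-based), `g_run_length`.
#' @export
filter_terminal_reads <- function(reads, config = terminal_filter_config()) {
  rec <- as_read_records(reads)
  n <- length(rec$bases)
  counts <- motif_count(rec$bases, CTAIL_MOTIFS)
  g <- locate_g_run(rec, config$min_g_run)

  window_start <- g$g_run_start + g$g_run_length + 1L # 1-based
  window <- substr(rec$bases, window_start,
                   window_start + config$defined_window - 1L)
  window_ok <- !is.na(g$g_run_start) &
    nchar(window) == config$defined_window &
    !stringi::stri_detect_fixed(window, "N")

  reason <- rep(NA_character_, n)
  reason[!window_ok] <- "undefined_window"
  reason[is.na(g$g_run_start)] <- "g_run"
  reason[counts < config$min_ctail_motifs] <- "ctail_motifs"

  tibble::tibble(read_id = rec$id, pass = is.na(reason), reason = reason,
                 motif_count = counts,
                 g_run_start = g$g_run_start, g_run_length = g$g_run_length)
}

#' Extract the G-strand terminal 12-mer
#'
#' The read is the complement strand of the C-tailed terminus, so the
#' `window` bases immediately after the G-run, reverse-complemented,
#' give the G-strand 3' terminal sequence with the chromosome's final
#' nucleotide rightmost.
#'
#' @inheritParams locate_g_run
#' @param g_runs A tibble as returned by [locate_g_run()] (0-based
#'   coordinates), matched by position to `reads`.
#' @param window Number of bases to extract (default 12).
#' @return Character vector of G-strand-oriented terminal 12-mers
#'   (`NA` where the window is unavailable).
#' @export
extract_terminal <- function(reads, g_runs, window = 12L) {
  rec <- as_read_records(reads)
  start <- g_runs$g_run_start + g_runs$g_run_length + 1L # 1-based
  raw <- substr(rec$bases, start, start + window - 1L)
  ok <- !is.na(start) & nchar(raw) == window
  out <- rep(NA_character_, length(raw))
  if (any(ok)) out[ok] <- revcomp(raw[ok])
  out
}

#' Classify a terminal 12-mer
#'
#' The terminal hexamer (last 6 bases, the 3'-most repeat unit) is
#' matched exactly against the 12 rotations of `TTAGGG`/`TTAGGT`; a
#' hexamer matching neither set is classed `"other"`.
#'
#' @param terminal_12mer Character vector of G-strand terminal 12-mers.
#' @return A tibble with `terminal_12mer`, `terminal_hexamer`,
#'   `repeat_class` (`"wt"`/`"var"`/`"other"`), `permutation_label`
#'   (the terminal hexamer string).
#' @examples
#' classify_terminal("GGTTAGGGTTAG")  # wild type, permutation GGTTAG
#' @export
classify_terminal <- function(terminal_12mer) {
  rot <- terminal_rotations()
  hex <- substr(terminal_12mer, nchar(terminal_12mer) - 5L,
                nchar(terminal_12mer))
  cls <- ifelse(hex %in% rot$wt, "wt",
                ifelse(hex %in% rot$var, "var", "other"))
  cls[is.na(terminal_12mer)] <- NA_character_
  tibble::tibble(terminal_12mer = terminal_12mer, terminal_hexamer = hex,
                 repeat_class = cls, permutation_label = hex)
}

#' Terminal permutation spectrum
#'
#' Full terminal stage: filter each read, locate the G-run, extract
#' and classify the terminal sequence, and tabulate the permutation
#' spectrum — counts per rotation, within-class permutation fractions,
#' and overall wild-type/variant/other class fractions — together with
#' per-criterion rejection tallies.
#'
#' @inheritParams filter_terminal_reads
#' @return An object of class `permutation_spectrum`: a list with
#'   `counts` (named over the 12 rotations), `other_count`,
#'   `class_counts`, `class_fractions`, `within_class_fractions`,
#'   `n_total`, `n_pass`, `rejections` (named tallies), and `calls`
#'   (per-read tibble of passing calls).
#' @export
terminal_spectrum <- function(reads, config = terminal_filter_config()) {
  rec <- as_read_records(reads)
  filt <- filter_terminal_reads(rec, config)
  rot <- terminal_rotations()
  all12 <- c(rot$wt, rot$var)

  pass <- filt$pass
  rejections <- c(
    ctail_motifs = sum(filt$reason == "ctail_motifs", na.rm = TRUE),
    g_run = sum(filt$reason == "g_run", na.rm = TRUE),
    undefined_window = sum(filt$reason == "undefined_window", na.rm = TRUE)
  )

  if (!any(pass)) {
    warning("no reads passed the terminal filters", call. = FALSE)
    calls <- tibble::tibble(read_id = character(),
                            g_run_start = integer(),
                            g_run_length = integer(),
                            terminal_12mer = character(),
                            terminal_hexamer = character(),
                            repeat_class = character(),
                            permutation_label = character())
    counts <- stats::setNames(integer(12), all12)
    return(structure(list(
      counts = counts, other_count = 0L,
      class_counts = c(wt = 0L, var = 0L, other = 0L),
      class_fractions = c(wt = NA_real_, var = NA_real_, other = NA_real_),
      within_class_fractions = list(
        wt = stats::setNames(rep(NA_real_, 6), rot$wt),
        var = stats::setNames(rep(NA_real_, 6), rot$var)),
      n_total = nrow(filt), n_pass = 0L, rejections = rejections,
      calls = calls), class = "permutation_spectrum"))
  }

  sub <- list(id = rec$id[pass], bases = rec$bases[pass], quals = NULL)
  g <- filt[pass, c("g_run_start", "g_run_length")]
  # the terminal 12-mer is defined on the 12 bases after the G-run,
  # independent of the configured defined_window
  twelve <- extract_terminal(sub, g, window = 12L)
  cls <- classify_terminal(twelve)

  calls <- tibble::tibble(read_id = sub$id,
                          g_run_start = g$g_run_start,
                          g_run_length = g$g_run_length,
                          terminal_12mer = cls$terminal_12mer,
                          terminal_hexamer = cls$terminal_hexamer,
                          repeat_class = cls$repeat_class,
                          permutation_label = cls$permutation_label)

  counts <- stats::setNames(integer(12), all12)
  tab <- table(cls$permutation_label[cls$repeat_class != "other"])
  counts[names(tab)] <- as.integer(tab)
  other_count <- sum(cls$repeat_class == "other")

  class_counts <- c(wt = sum(counts[rot$wt]), var = sum(counts[rot$var]),
                    other = other_count)
  n_pass <- sum(pass)
  within <- lapply(rot, function(r) {
    s <- sum(counts[r])
    if (s > 0) counts[r] / s else stats::setNames(rep(NA_real_, 6), r)
  })

  structure(list(
    counts = counts, other_count = other_count,
    class_counts = class_counts,
    class_fractions = class_counts / n_pass,
    within_class_fractions = within,
    n_total = nrow(filt), n_pass = n_pass, rejections = rejections,
    calls = calls), class = "permutation_spectrum")
}

#' @export
print.permutation_spectrum <- function(x, ...) {
  cat("Terminal permutation spectrum\n")
  cat(sprintf("  reads: %d total, %d passing (rejected: %s)\n",
              x$n_total, x$n_pass,
              paste(names(x$rejections), x$rejections,
                    sep = "=", collapse = ", ")))
  fmt <- function(f) if (is.na(f)) "." else sprintf("%.3f", f)
  cat(sprintf("  class fractions: wt %s, var %s, other %s\n",
              fmt(x$class_fractions[["wt"]]),
              fmt(x$class_fractions[["var"]]),
              fmt(x$class_fractions[["other"]])))
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  if (length(top))
    cat("  top permutations:",
        paste(names(top)[seq_len(min(4, length(top)))],
              top[seq_len(min(4, length(top)))], collapse = ", "), "\n")
  invisible(x)
}
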