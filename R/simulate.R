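#' Simulate a telomere repeat array under the two-allele model
#'
#' Deposits `n_units` hexamer units one at a time.  After each unit the
#' enzyme continues processively with probability `p_x` of the engaged
#' allele; otherwise it dissociates and a re-associating enzyme carries
#' the variant template with probability `rho`.  Each deposited unit is
#' then independently overwritten with a uniformly random hexamer that
#' is neither `TTAGGG` nor `TTAGGT`, with probability `degeneracy`; the
#' allele label always records the generating template, so ground truth
#' survives the overwrite.
#'
#' @param params A [model_params()] object.
#' @param n_units Number of hexamer units to deposit (`>= 1`).
#' @param seed Integer seed (the simulation is deterministic given it).
#' @param initial_allele Optional `"wt"` or `"var"` for the first unit;
#'   by default the first unit is variant with probability `rho`.
#' @return A tibble of class `telovar_array` with columns `unit`
#'   (1-based index), `hexamer`, and `allele` (`"wt"`/`"var"`), and the
#'   generating parameters in `attr(, "params")`.
#' @examples
#' arr <- simulate_telomere_array(model_params(0.9, 0.4, degeneracy = 0),
#'                                n_units = 20, seed = 1)
#' table(arr$allele)
#' @export
simulate_telomere_array <- function(params, n_units, seed = 1L,
                                    initial_allele = NULL) {
  if (!inherits(params, "telovar_model_params"))
    stop("params must be created by model_params()", call. = FALSE)
  check_count(n_units, "n_units")
  n_units <- as.integer(n_units)
  set.seed(as.integer(seed))

  # P(next unit is variant | current allele)
  p_var_given_var <- params$p_x_var + (1 - params$p_x_var) * params$rho
  p_var_given_wt  <- (1 - params$p_x_wt) * params$rho

  allele <- integer(n_units) # 1 = var, 0 = wt
  allele[1L] <- if (is.null(initial_allele)) {
    as.integer(stats::runif(1) < params$rho)
  } else {
    match.arg(initial_allele, c("wt", "var")) == "var"
  }
  if (n_units > 1L) {
    u <- stats::runif(n_units - 1L)
    for (i in 2:n_units) {
      p <- if (allele[i - 1L] == 1L) p_var_given_var else p_var_given_wt
      allele[i] <- (u[i - 1L] < p)
    }
  }
  allele <- as.integer(allele)

  hexamer <- ifelse(allele == 1L, VAR_HEXAMER, WT_HEXAMER)
  if (params$degeneracy > 0) {
    hit <- which(stats::runif(n_units) < params$degeneracy)
    if (length(hit)) hexamer[hit] <- random_other_hexamers(length(hit))
  }

  out <- tibble::tibble(
    unit = seq_len(n_units),
    hexamer = hexamer,
    allele = c("wt", "var")[allele + 1L]
  )
  class(out) <- c("telovar_array", class(out))
  attr(out, "params") <- params
  attr(out, "seed") <- as.integer(seed)
  out
}

# uniform random hexamers excluding TTAGGG and TTAGGT
random_other_hexamers <- function(n) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- matrix(sample(bases, 6L * length(todo), replace = TRUE), ncol = 6L)
    hx <- apply(m, 1L, paste0, collapse = "")
    out[todo] <- hx
    todo <- todo[hx %in% c(WT_HEXAMER, VAR_HEXAMER)]
  }
  out
}

#' Concatenate a telomere array into one DNA string
#'
#' @param array A `telovar_array` (or character vector of hexamers).
#' @return A single character string, the G-strand array sequence.
#' @export
array_sequence <- function(array) {
  hex <- if (is.character(array)) array else array$hexamer
  paste0(hex, collapse = "")
}

#' Simulate WGS-like reads from a telomere array
#'
#' Draws reads of fixed length from the array, start positions uniform
#' over the repeat units (reads begin on unit boundaries); each read is
#' emitted on the G- or C-strand with probability 0.5.  A fraction of
#' reads is replaced by uniform random background sequence.  Positional
#' substitution errors are applied at `error_rate_head` up to
#' `trim_point` and `error_rate_tail` beyond it, and the quality string
#' encodes the Phred score of the generating rate per region (capped at
#' Q40 for a zero rate).
#'
#' @param array A `telovar_array` from [simulate_telomere_array()] (or
#'   a character vector of hexamer units).
#' @param params A [read_sim_params()] object.
#' @return A list of class `telovar_wgs_sim` with elements `reads` (a
#'   [Biostrings::QualityScaledDNAStringSet]) and `truth` (a tibble
#'   with `read_id`, `start_unit`, `start_base` (0-based), `strand`
#'   (`"G"`/`"C"`), `background`).
#' @export
simulate_wgs_reads <- function(array, params) {
  if (!inherits(params, "telovar_read_sim_params"))
    stop("params must be created by read_sim_params()", call. = FALSE)
  seq_full <- array_sequence(array)
  L <- nchar(seq_full)
  rl <- params$read_length
  if (L < rl)
    stop("array (", L, " bases) is shorter than read_length (", rl, ")",
         call. = FALSE)
  set.seed(params$seed)
  n <- params$n_reads

  qual_string <- error_rate_quality(rl, params)
  if (n == 0L) {
    empty <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(character()),
      Biostrings::PhredQuality(character()))
    return(structure(list(
      reads = empty,
      truth = tibble::tibble(read_id = character(), start_unit = integer(),
                             start_base = integer(), strand = character(),
                             background = logical())),
      class = "telovar_wgs_sim"))
  }

  # unit-aligned start positions: last unit u with 6*(u-1) + rl <= L
  max_start_unit <- (L - rl) %/% 6L + 1L
  start_unit <- sample.int(max_start_unit, n, replace = TRUE)
  background <- stats::runif(n) < params$background_fraction
  strand <- ifelse(stats::runif(n) < 0.5, "C", "G")

  start_base0 <- (start_unit - 1L) * 6L
  bases <- substring(seq_full, start_base0 + 1L, start_base0 + rl)
  if (any(background)) {
    nb <- sum(background)
    bases[background] <- vapply(
      seq_len(nb),
      function(i) paste0(sample(c("A", "C", "G", "T"), rl, replace = TRUE),
                         collapse = ""),
      character(1))
    start_unit[background] <- NA_integer_
    start_base0[background] <- NA_integer_
  }
  flip <- strand == "C"
  if (any(flip)) bases[flip] <- revcomp(bases[flip])

  bases <- apply_substitution_errors(bases, params)

  ids <- paste0("wgs_", seq_len(n))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(bases),
    Biostrings::PhredQuality(rep(qual_string, n)))
  names(reads) <- ids

  structure(list(
    reads = reads,
    truth = tibble::tibble(read_id = ids, start_unit = start_unit,
                           start_base = start_base0, strand = strand,
                           background = background)),
    class = "telovar_wgs_sim")
}

# Phred+33 quality string matching the generating head/tail rates
error_rate_quality <- function(read_length, params) {
  phred <- function(rate) {
    q <- if (rate <= 0) 40L else as.integer(round(-10 * log10(rate)))
    min(max(q, 2L), 40L)
  }
  head_n <- min(params$trim_point, read_length)
  paste0(strrep(intToUtf8(phred(params$error_rate_head) + 33L), head_n),
         strrep(intToUtf8(phred(params$error_rate_tail) + 33L),
                read_length - head_n))
}

# positional substitution errors; vectorized over a char matrix
apply_substitution_errors <- function(bases, params) {
  if (params$error_rate_head <= 0 && params$error_rate_tail <= 0) return(bases)
  n <- length(bases)
  rl <- unique(nchar(bases))
  stopifnot(length(rl) == 1L)
  m <- matrix(unlist(strsplit(bases, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  rate <- ifelse(seq_len(rl) <= params$trim_point,
                 params$error_rate_head, params$error_rate_tail)
  hit <- which(matrix(stats::runif(n * rl), nrow = n) <
                 matrix(rate, nrow = n, ncol = rl, byrow = TRUE))
  if (length(hit)) {
    old <- m[hit]
    # substitute with a uniformly chosen different base
    alt <- matrix(c("C", "G", "T",
                    "A", "G", "T",
                    "A", "C", "T",
                    "A", "C", "G"), nrow = 4L, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    m[hit] <- alt[cbind(match(old, rownames(alt)), pick)]
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate C-tail terminal sequencing reads
#'
#' Emulates the reverse read of a C-tailed terminal telomere library.
#' Each passing read is `[random prefix][G-run of the drawn C-tail
#' length][reverse complement of the G-strand terminal sequence]`, where
#' the terminal sequence ends (3'-terminally) in the drawn permutation
#' and continues upstream in the same repeat register, padded so every
#' read is 150 bases.  Because the telomere complement contains no `G`,
#' the C-tail G-run never merges with telomeric sequence.  Junk reads
#' violate exactly one of the three terminal filters (too few C-strand
#' motifs, G-run shorter than 6, or an `N` inside the 12-base window
#' after the G-run), in rotation.
#'
#' @param params A [terminal_sim_params()] object.
#' @return A list of class `telovar_terminal_sim` with elements `reads`
#'   (a [Biostrings::QualityScaledDNAStringSet]) and `truth` (a tibble
#'   with `read_id`, `kind` (`"terminal"`/`"junk"`), `permutation`,
#'   `repeat_class`, `tail_length`, `violation`).
#' @export
simulate_terminal_reads <- function(params) {
  if (!inherits(params, "telovar_terminal_sim_params"))
    stop("params must be created by terminal_sim_params()", call. = FALSE)
  set.seed(params$seed)
  n <- params$n_reads
  read_len <- 150L
  wt_rot <- hexamer_rotations(WT_HEXAMER)
  var_rot <- hexamer_rotations(VAR_HEXAMER)

  n_junk <- round(n * params$junk_fraction)
  kind <- rep("terminal", n)
  if (n_junk > 0) kind[sample.int(n, n_junk)] <- "junk"

  tails <- draw_tail_lengths(params$tail_length_distribution, n)
  w <- params$permutation_weights
  perm <- if (n > 0)
    sample(names(w), n, replace = TRUE, prob = w) else character()
  violation <- rep(NA_character_, n)
  if (n_junk > 0)
    violation[kind == "junk"] <-
      rep_len(c("ctail_motifs", "g_run", "undefined_window"), n_junk)

  bases <- character(n)
  for (i in seq_len(n)) {
    bases[i] <- build_terminal_read(perm[i], tails[i], violation[i], read_len)
  }
  perm_class <- ifelse(perm %in% wt_rot, "wt",
                       ifelse(perm %in% var_rot, "var", "other"))
  perm[kind == "junk"] <- NA_character_
  perm_class[kind == "junk"] <- NA_character_

  ids <- paste0("term_", seq_len(n))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(bases),
    Biostrings::PhredQuality(strrep("I", nchar(bases))))
  names(reads) <- ids

  structure(list(
    reads = reads,
    truth = tibble::tibble(read_id = ids, kind = kind, permutation = perm,
                           repeat_class = perm_class,
                           tail_length = tails, violation = violation)),
    class = "telovar_terminal_sim")
}

draw_tail_lengths <- function(dist, n) {
  if (n == 0L) return(integer())
  tl <- if (is.function(dist)) dist(n)
        else dist[sample.int(length(dist), n, replace = TRUE)]
  tl <- as.integer(tl)
  if (any(tl < 6L)) stop("drawn C-tail length < 6", call. = FALSE)
  tl
}

# G-strand terminal region of tel_len bases ending in the permutation
terminal_region <- function(perm, tel_len) {
  wt_rot <- hexamer_rotations(WT_HEXAMER)
  var_rot <- hexamer_rotations(VAR_HEXAMER)
  if (perm %in% wt_rot) {
    unit <- WT_HEXAMER; k <- match(perm, wt_rot) - 1L
  } else if (perm %in% var_rot) {
    unit <- VAR_HEXAMER; k <- match(perm, var_rot) - 1L
  } else {
    # non-telomeric terminal hexamer on a wild-type upstream register
    body <- strrep(WT_HEXAMER, ceiling(tel_len / 6) + 1L)
    body <- substr(body, nchar(body) - (tel_len - 6L) + 1L, nchar(body))
    return(paste0(body, perm))
  }
  # periodic repeat string cut so that the last 6 bases are rotation k
  long <- strrep(unit, ceiling(tel_len / 6) + 2L)
  end <- nchar(long) - ((6L - k) %% 6L)
  substr(long, end - tel_len + 1L, end)
}

# assemble one simulated terminal read of fixed length
build_terminal_read <- function(perm, tail_len, violation, read_len) {
  prefix_len <- sample(0:12, 1L)
  g_len <- tail_len
  if (!is.na(violation) && violation == "g_run") g_len <- 5L
  tel_len <- read_len - prefix_len - g_len
  if (!is.na(violation) && violation == "ctail_motifs") {
    # only 3 telomeric hexamers -> at most 3 C-strand motifs; pad with
    # motif-free filler
    tel_len <- 18L
    filler_len <- read_len - prefix_len - g_len - tel_len
    filler <- random_motif_free(filler_len,
                                forbid = c("CTAACC", "CTAAAC", "GGGGGG"))
  } else {
    filler <- ""
  }
  region <- terminal_region(if (is.na(perm)) "GGTTAG" else perm, tel_len)
  body <- revcomp(region)
  if (!is.na(violation) && violation == "undefined_window") {
    pos <- sample.int(12L, 1L)
    substr(body, pos, pos) <- "N"
  }
  paste0(random_prefix(prefix_len), strrep("G", g_len), body, filler)
}

# random bases with no G at the final position and no >=4 G-run
random_prefix <- function(len) {
  if (len == 0L) return("")
  repeat {
    p <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
    if (!grepl("GGGG", p) && substr(p, len, len) != "G") return(p)
  }
}

random_motif_free <- function(len, forbid) {
  if (len <= 0L) return("")
  repeat {
    s <- paste0(sample(c("A", "C", "T"), len, replace = TRUE), collapse = "")
    if (!any(vapply(forbid, grepl, logical(1), x = s, fixed = TRUE))) return(s)
  }
}

#' Write a telomere array's ground truth to TSV
#'
#' Sidecar table (unit index, hexamer, allele label) for recovery tests
#' against simulated data.
#'
#' @param array A `telovar_array`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_array_truth <- function(array, path) {
  utils::write.table(as.data.frame(array)[, c("unit", "hexamer", "allele")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
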