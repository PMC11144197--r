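# Independent oracles and fixture builders used across the suite.

# Naive position-by-position greedy scanner: at each position try every
# motif in order; on a match, record it and jump past it.  Written
# deliberately with substr() so it shares no code with the package's
# stringi-based scanner.
oracle_scan <- function(seq, motifs = TELOMERE_MOTIFS) {
  motifs <- unname(motifs)
  k <- nchar(motifs[1L])
  n <- nchar(seq)
  starts <- integer()
  hits <- character()
  i <- 1L
  while (i <= n - k + 1L) {
    hit <- NA_character_
    for (m in motifs) {
      if (substr(seq, i, i + k - 1L) == m) { hit <- m; break }
    }
    if (!is.na(hit)) {
      starts <- c(starts, i)
      hits <- c(hits, hit)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, motif = hits)
}

# random test strings, half uniform, half motif-dense (telomere-like
# fragments, spacers, partial motifs) to exercise the scanner
random_scan_string <- function(max_len = 300L) {
  if (stats::runif(1) < 0.5) {
    len <- sample.int(max_len, 1L)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
           collapse = "")
  } else {
    parts <- sample(c(unname(TELOMERE_MOTIFS), "A", "T", "GG", "TTAG",
                      "CCCT", "TAGGGT", "ACCTA"),
                    size = sample(3:40, 1L), replace = TRUE)
    substr(paste0(parts, collapse = ""), 1L, max_len)
  }
}

# concatenate hexamers into a single read string
hx <- function(...) paste0(c(...), collapse = "")

# quick geometric survival table check helper
sum_x_count <- function(table, cls) {
  tab <- table[table$class == cls, ]
  sum(tab$run_length * tab$n_runs)
}
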