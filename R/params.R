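#' Two-allele telomerase addition model parameters
#'
#' Parameters of the generative model for telomere repeat deposition by
#' a heterozygous telomerase pool.  After each hexamer addition the
#' enzyme either continues processively with probability `p_x` of the
#' allele currently engaged, or dissociates; a re-associating enzyme
#' carries the variant template with probability `rho` (wild type
#' otherwise).  Deposited hexamers are independently overwritten with a
#' random non-canonical hexamer with probability `degeneracy`, emulating
#' the non-telomeric/degenerate fraction observed in real telomeres.
#'
#' @param p_x_wt Processive-continuation probability for the wild-type
#'   template, in `[0,1]`.
#' @param p_x_var Processive-continuation probability for the variant
#'   template, in `[0,1]`.
#' @param rho Probability that a re-associating telomerase carries the
#'   variant template (default 0.5: equal availability of both alleles).
#' @param degeneracy Per-unit probability that a deposited hexamer is
#'   replaced by a uniformly random hexamer that is neither `TTAGGG` nor
#'   `TTAGGT` (default 0.15).
#' @return An object of class `telovar_model_params`.
#' @seealso [simulate_telomere_array()], [forward_p_add()]
#' @export
model_params <- function(p_x_wt, p_x_var, rho = 0.5, degeneracy = 0.15) {
  check_prob(p_x_wt, "p_x_wt")
  check_prob(p_x_var, "p_x_var")
  check_prob(rho, "rho")
  check_prob(degeneracy, "degeneracy")
  structure(
    list(p_x_wt = p_x_wt, p_x_var = p_x_var,
         rho = rho, degeneracy = degeneracy),
    class = "telovar_model_params"
  )
}

#' WGS-like read simulation parameters
#'
#' Controls the emulation of 150 bp whole-genome sequencing reads drawn
#' from a telomere array.  Substitution error rates are positional: a
#' low `error_rate_head` up to `trim_point` and a strictly
#' larger-or-equal `error_rate_tail` after it, mirroring the quality
#' decay of telomeric reads beyond ~60 bp.  Emitted quality strings
#' carry the Phred score of the generating rate for each region.
#'
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length in bases (default 150).
#' @param error_rate_head Per-base substitution probability for
#'   positions `<= trim_point`.
#' @param error_rate_tail Per-base substitution probability for
#'   positions `> trim_point`; must be `>= error_rate_head`.
#' @param trim_point Position of the quality break (default 60).
#' @param background_fraction Fraction of reads drawn from uniform
#'   random (non-telomeric) sequence.
#' @param seed Integer seed; all randomness of the simulation derives
#'   from it.
#' @return An object of class `telovar_read_sim_params`.
#' @seealso [simulate_wgs_reads()]
#' @export
read_sim_params <- function(n_reads,
                            read_length = 150L,
                            error_rate_head = 0.001,
                            error_rate_tail = 0.02,
                            trim_point = 60L,
                            background_fraction = 0,
                            seed = 1L) {
  check_count(n_reads, "n_reads", min = 0L)
  check_count(read_length, "read_length")
  check_prob(error_rate_head, "error_rate_head")
  check_prob(error_rate_tail, "error_rate_tail")
  if (error_rate_tail < error_rate_head)
    stop("error_rate_tail must be >= error_rate_head", call. = FALSE)
  check_count(trim_point, "trim_point")
  check_prob(background_fraction, "background_fraction")
  structure(
    list(n_reads = as.integer(n_reads), read_length = as.integer(read_length),
         error_rate_head = error_rate_head, error_rate_tail = error_rate_tail,
         trim_point = as.integer(trim_point),
         background_fraction = background_fraction, seed = as.integer(seed)),
    class = "telovar_read_sim_params"
  )
}

#' C-tail terminal read simulation parameters
#'
#' @param permutation_weights Named numeric vector of probabilities over
#'   terminal hexamers: any of the 12 rotations of `TTAGGG`/`TTAGGT`
#'   plus optionally `"other"`.  Must sum to 1 (tolerance 1e-9).
#' @param n_reads Number of reads to simulate.
#' @param tail_length_distribution Either an integer vector of C-tail
#'   lengths to sample uniformly (all `>= 6`), or a function `f(n)`
#'   returning `n` integer tail lengths.
#' @param junk_fraction Fraction of reads constructed to fail exactly
#'   one of the three terminal quality filters.
#' @param seed Integer seed.
#' @return An object of class `telovar_terminal_sim_params`.
#' @seealso [simulate_terminal_reads()]
#' @export
terminal_sim_params <- function(permutation_weights,
                                n_reads,
                                tail_length_distribution = 6:20,
                                junk_fraction = 0,
                                seed = 1L) {
  if (is.null(names(permutation_weights)) ||
      any(!nzchar(names(permutation_weights))))
    stop("permutation_weights must be a fully named vector", call. = FALSE)
  allowed <- c(hexamer_rotations(WT_HEXAMER),
               hexamer_rotations(VAR_HEXAMER), "other")
  bad <- setdiff(names(permutation_weights), allowed)
  if (length(bad))
    stop("unknown permutation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(permutation_weights < 0))
    stop("permutation_weights must be non-negative", call. = FALSE)
  if (abs(sum(permutation_weights) - 1) > 1e-9)
    stop("permutation_weights must sum to 1 (tolerance 1e-9)", call. = FALSE)
  if (is.numeric(tail_length_distribution)) {
    if (any(tail_length_distribution < 6))
      stop("C-tail lengths must be >= 6", call. = FALSE)
  } else if (!is.function(tail_length_distribution)) {
    stop("tail_length_distribution must be an integer vector or a function",
         call. = FALSE)
  }
  check_count(n_reads, "n_reads", min = 0L)
  check_prob(junk_fraction, "junk_fraction")
  structure(
    list(permutation_weights = permutation_weights,
         n_reads = as.integer(n_reads),
         tail_length_distribution = tail_length_distribution,
         junk_fraction = junk_fraction, seed = as.integer(seed)),
    class = "telovar_terminal_sim_params"
  )
}

#' Telomeric read detection configuration
#'
#' A read is deemed telomeric when the pooled greedy non-overlapping
#' count of the four hexamer motifs anywhere in the (untrimmed) read
#' reaches `min_repeats`.  With the defaults, 13 repeats x 6 bases =
#' 78 bases, more than half of a 150 bp read.  Detected reads are then
#' trimmed to their first `trim_point` bases before composition and
#' run-length analysis, reflecting the quality decay of telomeric reads
#' beyond ~60 bp.
#'
#' @param motifs The telomeric hexamers searched on both strands.
#' @param min_repeats Minimum pooled motif count (default 13).
#' @param trim_point Number of leading bases retained after detection
#'   (default 60).
#' @return An object of class `telovar_detection_config`.
#' @export
detection_config <- function(motifs = TELOMERE_MOTIFS,
                             min_repeats = 13L,
                             trim_point = 60L) {
  motifs <- unname(motifs)
  if (length(unique(nchar(motifs))) != 1L)
    stop("all motifs must have the same length", call. = FALSE)
  check_count(min_repeats, "min_repeats")
  check_count(trim_point, "trim_point")
  structure(
    list(motifs = motifs, min_repeats = as.integer(min_repeats),
         trim_point = as.integer(trim_point)),
    class = "telovar_detection_config"
  )
}

#' Terminal read quality-filter configuration
#'
#' The three filters applied to C-tail-anchored reverse reads, in
#' order: (a) at least `min_ctail_motifs` pooled non-overlapping
#' occurrences of `CTAACC` or `CTAAAC`; (b) a run of at least
#' `min_g_run` consecutive `G` (the C-tail complement); (c) the
#' `defined_window` bases immediately after the first such maximal
#' G-run must exist and contain no `N`.
#'
#' @param min_ctail_motifs Minimum pooled `CTAACC`/`CTAAAC` count
#'   (default 5).
#' @param min_g_run Minimum G-run length (default 6).
#' @param defined_window Number of N-free bases required after the
#'   G-run (default 12).
#' @return An object of class `telovar_terminal_filter_config`.
#' @export
terminal_filter_config <- function(min_ctail_motifs = 5L,
                                   min_g_run = 6L,
                                   defined_window = 12L) {
  check_count(min_ctail_motifs, "min_ctail_motifs")
  check_count(min_g_run, "min_g_run")
  check_count(defined_window, "defined_window")
  structure(
    list(min_ctail_motifs = as.integer(min_ctail_motifs),
         min_g_run = as.integer(min_g_run),
         defined_window = as.integer(defined_window)),
    class = "telovar_terminal_filter_config"
  )
}

# ---- internal validators ----------------------------------------------

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a single probability in [0, 1]", call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < min || x != as.integer(x))
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  invisible(x)
}
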