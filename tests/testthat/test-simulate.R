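test_that("a fully processive enzyme never switches template", {
  arr <- simulate_telomere_array(model_params(1, 1, 0.5, 0), 200,
                                 seed = 1, initial_allele = "wt")
  expect_true(all(arr$hexamer == "TTAGGG"))
  expect_true(all(arr$allele == "wt"))
  arr2 <- simulate_telomere_array(model_params(1, 1, 0.5, 0), 200,
                                  seed = 1, initial_allele = "var")
  expect_true(all(arr2$hexamer == "TTAGGT"))
})

test_that("a non-processive enzyme yields coin-flip repeats and
           geometric runs (0.5, 0.25)", {
  arr <- simulate_telomere_array(model_params(0, 0, 0.5, 0), 1e5, seed = 2)
  expect_equal(mean(arr$allele == "var"), 0.5, tolerance = 0.01)
  runs <- run_length_table(arr)
  sv <- survival_from_runs(runs, "var", min_runs = 1)
  expect_equal(sv$S[2], 0.5, tolerance = 0.02)
  expect_equal(sv$S[3], 0.25, tolerance = 0.02)
})

test_that("degeneracy overwrites ~15% of units with non-canonical
           hexamers, binomially", {
  n <- 1e5
  arr <- simulate_telomere_array(model_params(0.9, 0.4, 0.5, 0.15), n,
                                 seed = 3)
  other <- !(arr$hexamer %in% c("TTAGGG", "TTAGGT"))
  # binomial oracle on the overwrite step: a degenerate unit shows a
  # non-canonical hexamer with certainty, so P(other) = degeneracy
  se <- sqrt(0.15 * 0.85 / n)
  expect_lt(abs(mean(other) - 0.15), 5 * se)
  # allele labels are unaffected by the overwrite
  expect_true(all(arr$allele %in% c("wt", "var")))
  # with degeneracy 0 every hexamer is canonical and labels match
  arr0 <- simulate_telomere_array(model_params(0.7, 0.3, 0.5, 0), 5000,
                                  seed = 4)
  expect_true(all(arr0$hexamer %in% c("TTAGGG", "TTAGGT")))
  expect_identical(sum(arr0$hexamer == "TTAGGT"),
                   sum(arr0$allele == "var"))
})

test_that("variant run lengths follow the geometric law with
           continuation P(Add)", {
  p_x <- 0.4
  rho <- 0.5
  arr <- simulate_telomere_array(model_params(p_x, p_x, rho, 0), 1e5,
                                 seed = 5)
  p_add <- forward_p_add(p_x, rho)
  runs <- run_length_table(arr)
  tab <- runs[runs$class == "var", ]
  grid <- seq_len(max(tab$run_length))
  obs <- integer(length(grid))
  obs[tab$run_length] <- tab$n_runs
  # pool the tail so every expected bin has decent mass
  kmax <- max(which(cumsum(stats::dgeom(grid - 1, 1 - p_add)) < 0.999))
  obs_pooled <- c(obs[seq_len(kmax)], sum(obs[-seq_len(kmax)]))
  probs <- c(stats::dgeom(seq_len(kmax) - 1, 1 - p_add),
             1 - stats::pgeom(kmax - 1, 1 - p_add))
  gof <- stats::chisq.test(obs_pooled, p = probs)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated WGS reads are error-free substrings at zero error
           rate and reproducible byte-for-byte", {
  arr <- simulate_telomere_array(model_params(1, 1, 0.5, 0), 500,
                                 seed = 6, initial_allele = "wt")
  params <- read_sim_params(n_reads = 50, error_rate_head = 0,
                            error_rate_tail = 0, seed = 7)
  sim <- simulate_wgs_reads(arr, params)
  expect_length(sim$reads, 50)
  ref <- array_sequence(arr)
  for (b in as.character(sim$reads)) {
    expect_true(grepl(b, ref, fixed = TRUE) ||
                  grepl(as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(b))), ref, fixed = TRUE))
  }
  # determinism: identical seed, byte-identical FASTQ
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_wgs_reads(arr, params)$reads, f1)
  write_fastq(simulate_wgs_reads(arr, params)$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # n_reads = 0 gives an empty FASTQ
  sim0 <- simulate_wgs_reads(arr, read_sim_params(n_reads = 0, seed = 1))
  expect_length(sim0$reads, 0)

  # array shorter than the read length is an input error
  short <- simulate_telomere_array(model_params(1, 1, 0.5, 0), 10, seed = 1)
  expect_error(simulate_wgs_reads(short, read_sim_params(n_reads = 5,
                                                         seed = 1)),
               "shorter than read_length")
})

test_that("observed mismatch rates match the configured head and tail
           error rates", {
  arr <- simulate_telomere_array(model_params(0.9, 0.4, 0.5, 0.15), 2000,
                                 seed = 8)
  params <- read_sim_params(n_reads = 5000, error_rate_head = 0.001,
                            error_rate_tail = 0.02, seed = 9)
  sim <- simulate_wgs_reads(arr, params)
  ref <- array_sequence(arr)
  bases <- as.character(sim$reads)
  # undo the strand flip so reads align to known source coordinates
  flip <- sim$truth$strand == "C"
  bases[flip] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(bases[flip])))
  src <- substring(ref, sim$truth$start_base + 1,
                   sim$truth$start_base + params$read_length)
  mism <- function(a, b) {
    m <- mapply(function(x, y) {
      xa <- strsplit(x, "")[[1]]; ya <- strsplit(y, "")[[1]]
      xa != ya
    }, a, b, SIMPLIFY = TRUE)
    m # matrix positions x reads
  }
  # errors on C-strand reads land at mirrored positions; measure rates
  # on G-strand reads only, where head/tail regions are untouched
  g <- which(!flip & !sim$truth$background)
  mm <- mism(bases[g], src[g])
  head_rate <- mean(mm[1:60, ])
  tail_rate <- mean(mm[61:150, ])
  expect_equal(head_rate, 0.001, tolerance = 0.3)
  expect_equal(tail_rate, 0.02, tolerance = 0.1)
  # quality strings encode the Phred of the generating rates (Q30/Q17)
  q <- as.character(Biostrings::quality(sim$reads))[1]
  expect_identical(substr(q, 1, 60), strrep(intToUtf8(33 + 30), 60))
  expect_identical(substr(q, 61, 150), strrep(intToUtf8(33 + 17), 90))
})

test_that("terminal read simulation places the drawn permutation right
           after the C-tail G-run", {
  # reverse complement of GGTTAG is CTAACC, by hand
  p <- terminal_sim_params(c(GGTTAG = 1), n_reads = 30,
                           tail_length_distribution = 7L, seed = 10)
  sim <- simulate_terminal_reads(p)
  expect_true(all(grepl("G{7}CTAACC", as.character(sim$reads))))
  # reverse complement of GGTTTA is TAAACC, by hand
  p2 <- terminal_sim_params(c(GGTTTA = 1), n_reads = 30,
                            tail_length_distribution = 7L, seed = 11)
  sim2 <- simulate_terminal_reads(p2)
  expect_true(all(grepl("G{7}TAAACC", as.character(sim2$reads))))
  # all-junk input passes nothing through the terminal filters
  pj <- terminal_sim_params(c(GGTTAG = 1), n_reads = 30,
                            junk_fraction = 1, seed = 12)
  simj <- simulate_terminal_reads(pj)
  filt <- filter_terminal_reads(simj$reads)
  expect_identical(sum(filt$pass), 0L)
})
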