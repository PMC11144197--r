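test_that("telomeric read detection counts pooled motifs greedily", {
  expect_identical(is_telomeric(strrep("TTAGGG", 25))$motif_count, 25L)
  expect_true(is_telomeric(strrep("TTAGGG", 25))$telomeric)

  # 12 C-strand motifs followed by 78 motif-free bases: below threshold
  read <- paste0(strrep("CCCTAA", 12), strrep("ACT", 26))
  det <- is_telomeric(read)
  expect_identical(det$motif_count, 12L)
  expect_false(det$telomeric)

  # interleaved motifs with 1-nt spacers still count individually
  read13 <- paste0(rep(c("TTAGGG", "ACCTAA"), times = c(7, 6)),
                   collapse = "C")
  expect_identical(nrow(oracle_scan(read13)), 13L)  # brute-force check
  det13 <- is_telomeric(read13)
  expect_identical(det13$motif_count, 13L)
  expect_true(det13$telomeric)

  # N bases never match
  expect_identical(is_telomeric(strrep("TTAGGN", 25))$motif_count, 0L)
})

test_that("trimming keeps the first 60 bases with qualities in
           lockstep", {
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(c(a = strrep("TTAGGG", 25),
                               b = strrep("ACGT", 10))),
    Biostrings::PhredQuality(c(paste0(strrep("I", 60), strrep("#", 90)),
                               strrep("I", 40))))
  tr <- trim_reads(reads)
  expect_identical(Biostrings::width(tr), c(60L, 40L))
  expect_identical(as.character(Biostrings::quality(tr))[[1]],
                   strrep("I", 60))
  # an empty read stays empty
  expect_identical(unname(trim_reads("")), "")
})

test_that("orientation flips C-strand reads and is idempotent", {
  res <- orient_reads("CCCTAACCCTAA")
  expect_identical(unname(res$reads), "TTAGGGTTAGGG")
  expect_identical(res$strand, "C")

  res2 <- orient_reads("TTAGGGTTAGGT")
  expect_identical(unname(res2$reads), "TTAGGGTTAGGT")
  expect_identical(res2$strand, "G")

  # ties (motif-free reads) stay as given with the G label
  res3 <- orient_reads("ACGTACGTACGT")
  expect_identical(unname(res3$reads), "ACGTACGTACGT")
  expect_identical(res3$strand, "G")

  # idempotence over random simulated reads
  arr <- simulate_telomere_array(model_params(0.8, 0.3, 0.5, 0.1), 1000,
                                 seed = 20)
  sim <- simulate_wgs_reads(arr, read_sim_params(n_reads = 100, seed = 21))
  once <- orient_reads(sim$reads)
  twice <- orient_reads(once$reads)
  expect_identical(as.character(twice$reads), as.character(once$reads))
  expect_true(all(twice$strand == "G"))
})

test_that("composition fractions follow the greedy base counts", {
  cfg <- detection_config(min_repeats = 10)
  comp <- telomere_composition(hx(rep("TTAGGG", 10)), cfg)
  expect_identical(comp$n_reads_telomeric, 1L)
  expect_equal(comp$frac_wt, 1.0)
  expect_equal(comp$frac_var, 0.0)

  # 7 wild-type + 3 variant hexamers: 18/60 variant by hand
  comp2 <- telomere_composition(hx(rep("TTAGGG", 7), rep("TTAGGT", 3)),
                                cfg)
  expect_equal(comp2$frac_var, 0.3)
  expect_equal(comp2$frac_wt, 0.7)
  expect_equal(comp2$frac_other, 0)
  expect_equal(comp2$frac_var_repeats, 0.3)
  expect_identical(comp2$bases_wt + comp2$bases_var + comp2$bases_other,
                   comp2$bases_considered)

  # no telomeric reads: fractions are undefined, not 0/0
  comp0 <- telomere_composition("ACGTACGT")
  expect_identical(comp0$n_reads_telomeric, 0L)
  expect_true(is.na(comp0$frac_wt))
  expect_true(is.na(comp0$frac_var_repeats))
})

test_that("run-length tables record maximal tandem in-frame runs", {
  cfg <- detection_config(min_repeats = 1)
  tab <- telomere_runs_from_reads(hx("TTAGGT", "TTAGGT", "TTAGGG",
                                     "TTAGGT"), cfg)
  var <- tab[tab$class == "var", ]
  expect_identical(var$run_length, c(1L, 2L))
  expect_identical(var$n_runs, c(1L, 1L))
  wt <- tab[tab$class == "wt", ]
  expect_identical(wt$run_length, 1L)
  expect_identical(wt$n_runs, 1L)

  # a single 10-repeat read is one run of length 10
  tab2 <- telomere_runs_from_reads(hx(rep("TTAGGG", 10)), cfg)
  expect_identical(tab2$run_length[tab2$class == "wt"], 10L)

  # a 1-nt spacer breaks adjacency into two runs of length 1
  tab3 <- telomere_runs_from_reads(paste0("TTAGGT", "A", "TTAGGT"), cfg)
  var3 <- tab3[tab3$class == "var", ]
  expect_identical(var3$run_length, 1L)
  expect_identical(var3$n_runs, 2L)
})

test_that("greedy scanning matches the brute-force oracle and run
           totals conserve motif counts", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_scan_string()
    got <- motif_scan(s)[[1]]
    want <- oracle_scan(s)
    expect_identical(got$start, want$start)
    expect_identical(got$motif, want$motif)
  }
  # conservation on simulated telomeric reads
  arr <- simulate_telomere_array(model_params(0.8, 0.5, 0.5, 0.1), 2000,
                                 seed = 22)
  sim <- simulate_wgs_reads(arr, read_sim_params(n_reads = 200,
                                                 error_rate_head = 0.005,
                                                 error_rate_tail = 0.03,
                                                 seed = 23))
  oriented <- orient_reads(trim_reads(sim$reads))$reads
  tab <- run_length_table(oriented)
  scans <- motif_scan(as.character(oriented))
  n_wt <- sum(vapply(scans, function(df) sum(df$motif == "TTAGGG"),
                     integer(1)))
  n_var <- sum(vapply(scans, function(df) sum(df$motif == "TTAGGT"),
                      integer(1)))
  expect_identical(sum_x_count(tab, "wt"), n_wt)
  expect_identical(sum_x_count(tab, "var"), n_var)
  expect_identical(unname(attr(tab, "total_repeats")),
                   c(n_wt, n_var))
})

test_that("composition recovers the simulator's variant fraction on
           clean reads", {
  arr <- simulate_telomere_array(model_params(0.6, 0.6, 0.5, 0), 10000,
                                 seed = 24)
  sim <- simulate_wgs_reads(arr, read_sim_params(n_reads = 2000,
                                                 error_rate_head = 0,
                                                 error_rate_tail = 0,
                                                 seed = 25))
  comp <- telomere_composition(sim$reads)
  truth <- mean(arr$allele == "var")
  expect_equal(comp$frac_var, truth, tolerance = 0.05)
  expect_equal(comp$frac_other, 0)
})
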