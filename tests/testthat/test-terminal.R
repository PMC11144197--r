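test_that("the twelve terminal rotations are pairwise distinct", {
  rot <- terminal_rotations()
  all12 <- c(rot$wt, rot$var)
  expect_length(all12, 12)
  expect_identical(anyDuplicated(all12), 0L)
  expect_true("GGTTAG" %in% rot$wt)
  expect_true("GGTTTA" %in% rot$var)
})

test_that("the three terminal filters fire in order with the right
           reasons", {
  # 7 Gs, 5 C-strand motifs, 12 defined bases after the run: pass
  ok <- paste0(strrep("G", 7), strrep("CTAACC", 5))
  f <- filter_terminal_reads(ok)
  expect_true(f$pass)
  expect_true(is.na(f$reason))

  # G-run of 5 fails criterion (b)
  f2 <- filter_terminal_reads(paste0(strrep("G", 5), strrep("CTAACC", 5)))
  expect_false(f2$pass)
  expect_identical(f2$reason, "g_run")

  # 4 motifs fail criterion (a), reported first
  f3 <- filter_terminal_reads(paste0(strrep("G", 6), strrep("CTAACC", 4),
                                     strrep("ACTGAT", 5)))
  expect_false(f3$pass)
  expect_identical(f3$reason, "ctail_motifs")

  # an N inside the 12-base window fails criterion (c)
  bad <- paste0(strrep("G", 6), "CTAACCCTANCC", strrep("CTAACC", 5))
  f4 <- filter_terminal_reads(bad)
  expect_false(f4$pass)
  expect_identical(f4$reason, "undefined_window")

  # too few bases after the G-run also fails (c)
  f5 <- filter_terminal_reads(paste0(strrep("CTAACC", 5), strrep("G", 8),
                                     "CTAACC"))
  expect_false(f5$pass)
  expect_identical(f5$reason, "undefined_window")
})

test_that("the first maximal G-run is located with 0-based
           coordinates", {
  g <- locate_g_run("AAGGGGGGCTAACC")
  expect_identical(g$g_run_start, 2L)
  expect_identical(g$g_run_length, 6L)

  g2 <- locate_g_run("GGGGGGGCTAACC")
  expect_identical(g2$g_run_start, 0L)
  expect_identical(g2$g_run_length, 7L)

  # with two qualifying runs the first is returned
  g3 <- locate_g_run(paste0("AAGGGGGGAA", "GGGGGGGG"))
  expect_identical(g3$g_run_start, 2L)
  expect_identical(g3$g_run_length, 6L)

  # no qualifying run
  g4 <- locate_g_run("GGGGGAAAA")
  expect_true(is.na(g4$g_run_start))
})

test_that("terminal 12-mers are reverse complements of the window
           after the G-run", {
  mk <- function(window) paste0("AA", strrep("G", 6), window)
  g <- locate_g_run(mk("CTAACCCTAACC"))
  expect_identical(extract_terminal(mk("CTAACCCTAACC"), g), "GGTTAGGGTTAG")
  expect_identical(
    extract_terminal(mk("CTAAACCTAAAC"), locate_g_run(mk("CTAAACCTAAAC"))),
    "GTTTAGGTTTAG")
  expect_identical(
    extract_terminal(mk("TAAACCTAAACC"), locate_g_run(mk("TAAACCTAAACC"))),
    "GGTTTAGGTTTA")
})

test_that("terminal hexamers classify into wt/var/other by rotation
           membership", {
  c1 <- classify_terminal("GGTTAGGGTTAG")
  expect_identical(c1$repeat_class, "wt")
  expect_identical(c1$permutation_label, "GGTTAG")

  c2 <- classify_terminal("GGTTTAGGTTTA")
  expect_identical(c2$repeat_class, "var")
  expect_identical(c2$permutation_label, "GGTTTA")

  c3 <- classify_terminal("GGTTAGGGTTAA")
  expect_identical(c3$repeat_class, "other")
  expect_identical(c3$terminal_hexamer, "GGTTAA")
})

test_that("every permutation survives the simulate-filter-classify
           round trip", {
  rot <- terminal_rotations()
  for (p in c(rot$wt, rot$var)) {
    w <- stats::setNames(1, p)
    sim <- simulate_terminal_reads(
      terminal_sim_params(w, n_reads = 10, seed = 40))
    spec <- terminal_spectrum(sim$reads)
    expect_identical(spec$n_pass, 10L)
    expect_identical(unname(spec$counts[p]), 10L)
    expect_identical(sum(spec$counts), 10L)
  }
})

test_that("the C-tail G-run never absorbs telomeric sequence at zero
           error rate", {
  rot <- terminal_rotations()
  for (p in c(rot$wt, rot$var)) {
    for (tail in c(6L, 11L, 20L)) {
      sim <- simulate_terminal_reads(
        terminal_sim_params(stats::setNames(1, p), n_reads = 2,
                            tail_length_distribution = tail,
                            seed = tail))
      g <- locate_g_run(sim$reads)
      expect_identical(g$g_run_length, rep(tail, 2L))
      expect_identical(sim$truth$tail_length, rep(tail, 2L))
    }
  }
})

test_that("the spectrum tabulates classes, permutations and rejection
           reasons consistently", {
  w <- c(GGTTAG = 0.7, GGTTTA = 0.3)
  sim <- simulate_terminal_reads(
    terminal_sim_params(w, n_reads = 5000, seed = 41))
  spec <- terminal_spectrum(sim$reads)
  expect_identical(spec$n_pass, 5000L)
  # pipeline conservation
  expect_identical(sum(spec$counts) + spec$other_count, spec$n_pass)
  # binomial oracle on the class split
  se <- sqrt(0.7 * 0.3 / 5000)
  expect_lt(abs(spec$class_fractions[["wt"]] - 0.7), 5 * se)
  expect_lt(abs(spec$class_fractions[["var"]] - 0.3), 5 * se)
  expect_equal(sum(spec$within_class_fractions$wt), 1)
  expect_equal(sum(spec$within_class_fractions$var), 1)

  # constructed junk is rejected with per-criterion tallies
  simj <- simulate_terminal_reads(
    terminal_sim_params(w, n_reads = 300, junk_fraction = 0.5, seed = 42))
  spec2 <- suppressWarnings(terminal_spectrum(simj$reads))
  truth_tally <- table(simj$truth$violation)
  expect_identical(spec2$n_pass, sum(simj$truth$kind == "terminal"))
  for (r in names(truth_tally))
    expect_identical(unname(spec2$rejections[r]),
                     as.integer(truth_tally[[r]]))

  # all-junk input: empty spectrum with a warning
  sim3 <- simulate_terminal_reads(
    terminal_sim_params(w, n_reads = 30, junk_fraction = 1, seed = 43))
  expect_warning(spec3 <- terminal_spectrum(sim3$reads), "no reads")
  expect_identical(spec3$n_pass, 0L)
  expect_identical(sum(spec3$counts), 0L)
  expect_identical(sum(spec3$rejections), 30L)
})
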