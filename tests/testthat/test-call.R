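test_that("site bases translate to M/U/N pattern calls", {
  toy <- toy_amplicon()
  full_u <- expected_read(toy, c("U", "U"))
  res <- call_pattern(full_u, toy)
  expect_identical(res$pattern, "UU")
  expect_identical(res$k_demethylated, 2L)
  expect_true(res$passed)

  res <- call_pattern("ACGTTG", toy)
  expect_identical(res$pattern, "MU")
  expect_identical(res$k_demethylated, 1L)

  # G at a site position is ambiguous, not a wrong state
  res <- call_pattern("AGGTTG", toy)
  expect_identical(res$pattern, "NU")
  expect_identical(res$n_ambiguous, 1L)
  expect_false(res$passed)                       # max_n = 0 default
  expect_identical(res$fail_reason, "TOO_MANY_N")
  expect_true(call_pattern("AGGTTG", toy, max_n = 1)$passed)
  expect_identical(nrow(eligible_calls(call_pattern("AGGTTG", toy,
                                                    max_n = 1))), 0L)

  # read not covering the last site
  res <- call_pattern("ACG", toy)
  expect_false(res$passed)
  expect_identical(res$fail_reason, "TOO_SHORT")
  expect_true(is.na(res$pattern))
})

test_that("round trip: calling an expected read recovers every pattern", {
  # exhaustive over a 3-site amplicon with primer regions
  amp <- small_amplicon()
  fwd <- nchar(amp$forward_primer)
  states <- expand.grid(rep(list(c("M", "U")), 3), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(states))) {
    pat <- unlist(states[i, ])
    read <- substring(expected_read(amp, pat), fwd + 1L)
    res <- call_pattern(read, amp)
    expect_identical(res$pattern, paste(pat, collapse = ""))
    expect_true(res$passed)
    expect_identical(res$noncpg_c_unconverted, 0L)
    expect_identical(res$identity_frac, 1)
  }

  # sampled 10-site patterns on the TSDR-like amplicon: excluded site sA
  # is dropped from the output pattern
  foxp3 <- example_panel()$amplicons$FOXP3_TSDR_synth
  fwd <- nchar(foxp3$forward_primer)
  inc <- foxp3$cpg_sites$included
  set.seed(42)
  pats <- c(list(rep("M", 10), rep("U", 10)),
            lapply(1:40, function(i) sample(c("M", "U"), 10, replace = TRUE)))
  for (pat in pats) {
    read <- substring(expected_read(foxp3, pat), fwd + 1L)
    res <- call_pattern(read, foxp3)
    expect_identical(res$pattern, paste(pat[inc], collapse = ""))
    expect_identical(nchar(res$pattern), 9L)
    expect_true(res$passed)
  }
})

test_that("caller matches the position-by-position oracle under mutation", {
  amp <- small_amplicon()
  fwd <- nchar(amp$forward_primer)
  set.seed(99)
  for (i in 1:60) {
    pat <- sample(c("M", "U"), 3, replace = TRUE)
    read <- substring(expected_read(amp, pat), fwd + 1L)
    # random substitutions anywhere in the read
    ch <- strsplit(read, "")[[1]]
    nmut <- sample(0:4, 1)
    pos <- sample(seq_along(ch), nmut)
    ch[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    read <- paste(ch, collapse = "")
    got <- call_pattern(read, amp)
    want <- oracle_call(read, amp)
    expect_identical(got$pattern, want$pattern)
    expect_identical(got$k_demethylated, want$k)
    expect_identical(got$n_ambiguous, want$n_ambiguous)
    expect_identical(got$noncpg_c_total, want$noncpg_c_total)
    expect_identical(got$noncpg_c_unconverted, want$noncpg_c_unconverted)
    expect_equal(got$identity_frac, want$identity)
  }
})

test_that("amplicon assignment matches primers in either orientation", {
  pnl <- example_panel()
  foxp3 <- pnl$amplicons$FOXP3_TSDR_synth
  read <- substring(expected_read(foxp3, rep("U", 10)), 1L)  # starts at primer
  asg <- assign_amplicon(read, pnl)
  expect_identical(asg$amplicon, "FOXP3_TSDR_synth")
  expect_identical(asg$orientation, "forward")

  rc <- oracle_revcomp(read)
  asg <- assign_amplicon(rc, pnl)
  expect_identical(asg$amplicon, "FOXP3_TSDR_synth")
  expect_identical(asg$orientation, "reverse")
  # calling after reorientation gives the same pattern
  calls <- call_reads(tibble::tibble(read_id = c("f", "r"),
                                     seq = c(read, rc)), pnl)
  expect_identical(calls$pattern[1], calls$pattern[2])
  expect_identical(calls$pattern[1], strrep("U", 9))

  expect_identical(assign_amplicon(random_dna(1, 60), pnl)$amplicon,
                   "UNMATCHED")
})

test_that("conversion efficiency pools non-CpG cytosines over passed reads", {
  calls <- fake_calls(c("UU", "MM"), c(50, 50))
  calls$noncpg_c_total <- 10L
  calls$noncpg_c_unconverted <- 0L
  calls$noncpg_c_unconverted[1:10] <- 1L   # 10 failures in 1000 observations
  expect_equal(conversion_efficiency(calls), 99.0)
  calls$noncpg_c_unconverted <- 0L
  expect_equal(conversion_efficiency(calls), 100)
  calls$noncpg_c_total <- 0L
  expect_warning(expect_true(is.na(conversion_efficiency(calls))),
                 "undefined")
})

test_that("efficiency estimate recovers the simulated conversion rate", {
  pnl <- example_panel()
  d <- sim_design(
    pnl, tibble::tibble(sample_id = "S1", sex = "male", treg_fraction = 0.5),
    conversion_rate = 0.995, seq_error_rate = 0,
    reads_per_replicate = 1000, amplicon_names = "FOXP3_TSDR_synth",
    seed = 77
  )
  sim <- simulate_reads(d)
  dm <- demultiplex(sim$reads, sim$sheet)
  calls <- call_reads(dm[dm$sample_id != "UNASSIGNED", ], pnl)
  tot <- sum(calls$noncpg_c_total[calls$passed])
  expect_gte(tot, 10000)                     # enough observations
  se <- 100 * sqrt(0.995 * 0.005 / tot)
  expect_lt(abs(conversion_efficiency(calls) - 99.5), 3 * se)
})
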