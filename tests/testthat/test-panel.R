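test_that("bisulfite conversion follows the C/T readout rules", {
  expect_identical(bisulfite_convert("ACGTCG", FALSE), "ATGTTG")
  expect_identical(bisulfite_convert("ACGTCG", TRUE), "ACGTCG")
  expect_identical(bisulfite_convert("CCGG", TRUE), "TCGG")
  expect_identical(bisulfite_convert("CCGG", FALSE), "TTGG")
  expect_error(bisulfite_convert("ACGN"), "non-ACGT")
  expect_error(bisulfite_convert(""), "non-empty")
})

test_that("bisulfite conversion is idempotent and length-preserving", {
  set.seed(7)
  for (s in random_dna(20, 60)) {
    for (m in c(TRUE, FALSE)) {
      conv <- bisulfite_convert(s, m)
      expect_identical(nchar(conv), nchar(s))
      expect_identical(bisulfite_convert(conv, m), conv)
    }
  }
})

test_that("expected_read realises per-site patterns over the converted reference", {
  toy <- toy_amplicon()
  expect_identical(expected_read(toy, c("U", "U")), "ATGTTG")
  expect_identical(expected_read(toy, c("M", "U")), "ACGTTG")
  expect_identical(expected_read(toy, "MM"), "ACGTCG")
  one <- amplicon("one", "CCGG", data.frame(label = "1", position = 1L))
  expect_identical(expected_read(one, "M"), "TCGG")
  expect_error(expected_read(toy, "M"), "pattern length")
  expect_error(expected_read(toy, c("M", "X")), "'M' or 'U'")
})

test_that("all-methylated / all-demethylated reads equal direct conversion", {
  for (amp in list(toy_amplicon(), small_amplicon(),
                   example_panel()$amplicons$FOXP3_TSDR_synth)) {
    S <- nrow(amp$cpg_sites)
    expect_identical(expected_read(amp, rep("M", S)),
                     bisulfite_convert(amp$reference, TRUE))
    expect_identical(expected_read(amp, rep("U", S)),
                     bisulfite_convert(amp$reference, FALSE))
  }
})

test_that("amplicon validation rejects malformed definitions", {
  expect_error(
    amplicon("bad", "ACGTCG", data.frame(label = "1", position = 0L)),
    "not a CG dinucleotide"
  )
  expect_error(
    amplicon("bad", "ACGTCG",
             data.frame(label = c("1", "1"), position = c(1L, 4L))),
    "duplicate"
  )
  expect_error(
    amplicon("bad", "ACGNCG", data.frame(label = "1", position = 4L)),
    "non-ACGT"
  )
  # primer must match the converted reference prefix
  expect_error(
    amplicon("bad", "TTCATTACGTT", data.frame(label = "1", position = 7L),
             forward_primer = "TTCAT"),
    "forward_primer"
  )
})

test_that("non-CpG cytosine positions are derived outside primer regions", {
  amp <- small_amplicon()
  ref <- strsplit(amp$reference, "")[[1]]
  fwd <- nchar(amp$forward_primer)
  rev_len <- nchar(amp$reverse_primer)
  manual <- integer(0)
  for (p in seq_along(ref) - 1L) {
    if (ref[p + 1L] == "C" &&
        (p + 2L > length(ref) || ref[p + 2L] != "G") &&
        p >= fwd && p < length(ref) - rev_len) {
      manual <- c(manual, p)
    }
  }
  expect_identical(amp$noncpg_c_positions, manual)
  expect_error(
    amplicon("small2", amp$reference, amp$cpg_sites,
             forward_primer = amp$forward_primer,
             reverse_primer = amp$reverse_primer,
             noncpg_c_positions = c(manual, 0L)),
    "disagree"
  )
})

test_that("lowercase adaptor tails are stripped from primers", {
  amp <- small_amplicon()
  tailed <- amplicon("tailed", amp$reference, amp$cpg_sites,
                     forward_primer = paste0("acactctttccctacacg",
                                             amp$forward_primer),
                     reverse_primer = amp$reverse_primer)
  expect_identical(tailed$forward_primer, amp$forward_primer)
})

test_that("panels load from YAML with validation and site exclusion", {
  cfg <- "
version: 't'
amplicons:
  - name: tiny
    reference: ACGTCG
    cpg_sites:
      - {label: '1', position: 1}
      - {label: '2', position: 4}
"
  pnl <- load_panel(cfg)
  expect_s3_class(pnl, "panel_config")
  expect_identical(n_sites(pnl$amplicons$tiny), 2L)

  bad <- sub("position: 1\\}", "position: 0}", cfg)
  expect_error(load_panel(bad), "not a CG dinucleotide")

  shipped <- load_panel(system.file("extdata", "synthetic_panel.yaml",
                                    package = "bisamp"))
  foxp3 <- shipped$amplicons$FOXP3_TSDR_synth
  expect_identical(nrow(foxp3$cpg_sites), 10L)      # ten declared sites
  expect_identical(n_sites(foxp3), 9L)              # sA excluded
  expect_false(foxp3$cpg_sites$included[foxp3$cpg_sites$label == "sA"])
  expect_identical(n_sites(shipped$amplicons$CTLA4_ex2_synth), 7L)
  expect_true(foxp3$x_linked)
  expect_false(shipped$amplicons$CTLA4_ex2_synth$x_linked)
})

test_that("panels load references from FASTA with a BED-like site file", {
  amp <- small_amplicon()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "small.fasta")
  writeLines(c(">small synthetic", amp$reference), fa)
  bed <- file.path(dir, "small_sites.bed")
  writeLines(sprintf("small\t%d\t%d\t%s\t%d", amp$cpg_sites$position,
                     amp$cpg_sites$position + 2L, amp$cpg_sites$label,
                     as.integer(amp$cpg_sites$included)), bed)
  cfg <- file.path(dir, "panel.yaml")
  yaml::write_yaml(list(version = "fa", amplicons = list(list(
    name = "small", reference_fasta = "small.fasta",
    sites_bed = "small_sites.bed",
    forward_primer = amp$forward_primer,
    reverse_primer = amp$reverse_primer
  ))), cfg)
  pnl <- load_panel(cfg)
  expect_identical(pnl$amplicons$small$reference, amp$reference)
  expect_identical(pnl$amplicons$small$cpg_sites, amp$cpg_sites)
})
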