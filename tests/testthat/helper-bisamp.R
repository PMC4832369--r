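# Shared fixtures and independent oracles. The oracles deliberately use
# plain character loops, not the package's vectorized internals.

# toy amplicon without primers: ref ACGTCG, CpG sites at 0-based 1 and 4
toy_amplicon <- function() {
  amplicon("toy", "ACGTCG",
           data.frame(label = c("1", "2"), position = c(1L, 4L)))
}

# three-site amplicon with real primer regions for round-trip tests
small_amplicon <- function() {
  prefix <- "GATTAGGTTG"
  spacer <- "TTACAT"
  suffix <- "ATGGTAGGTT"
  ref <- paste0(prefix, strrep(paste0(spacer, "CG"), 3), suffix)
  amplicon("small", ref,
           data.frame(label = as.character(1:3),
                      position = nchar(prefix) +
                        (0:2) * (nchar(spacer) + 2L) + nchar(spacer)),
           forward_primer = bisulfite_convert(prefix, TRUE),
           reverse_primer = oracle_revcomp(bisulfite_convert(suffix, TRUE)))
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

# exhaustive minimum-distance demultiplexing oracle (same layout convention:
# forward index = read head, reverse index = reverse-complemented read tail)
oracle_assign <- function(seq, sheet, max_mismatch) {
  ilen <- attr(sheet, "index_length")
  if (nchar(seq) < ilen) return("UNASSIGNED")
  d <- numeric(nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    region <- if (sheet$placement[j] == "forward") {
      substr(seq, 1L, ilen)
    } else {
      oracle_revcomp(substring(seq, nchar(seq) - ilen + 1L))
    }
    d[j] <- oracle_hamming(region, sheet$index_seq[j])
  }
  best <- which(d == min(d))
  if (min(d) > max_mismatch || length(best) > 1L) "UNASSIGNED"
  else sheet$sample_id[best]
}

# position-by-position calling oracle for a primer-trimmed, oriented read
oracle_call <- function(seq, amp) {
  ref <- strsplit(amp$reference, "")[[1]]
  fwd <- nchar(amp$forward_primer)
  rev_len <- nchar(amp$reverse_primer)
  L <- length(ref)
  rd <- strsplit(seq, "")[[1]]
  at <- function(pos0) {
    j <- pos0 - fwd + 1L
    if (j >= 1L && j <= length(rd) && j <= L - rev_len - fwd) rd[j]
    else NA_character_
  }
  inc <- amp$cpg_sites[amp$cpg_sites$included, ]
  pattern <- ""
  k <- 0L
  nN <- 0L
  for (p in inc$position) {
    b <- at(p)
    s <- if (identical(b, "C")) "M" else if (identical(b, "T")) "U" else "N"
    if (s == "U") k <- k + 1L
    if (s == "N") nN <- nN + 1L
    pattern <- paste0(pattern, s)
  }
  tot <- unconv <- 0L
  for (p in amp$noncpg_c_positions) {
    b <- at(p)
    if (identical(b, "C")) { tot <- tot + 1L; unconv <- unconv + 1L }
    if (identical(b, "T")) tot <- tot + 1L
  }
  n_obs <- n_match <- 0L
  for (p in setdiff(seq.int(fwd, L - rev_len - 1L), amp$cpg_sites$position)) {
    b <- at(p)
    if (is.na(b)) next
    expect_b <- if (p %in% amp$noncpg_c_positions) "T" else ref[p + 1L]
    n_obs <- n_obs + 1L
    if (b == expect_b) n_match <- n_match + 1L
  }
  list(pattern = pattern, k = k, n_ambiguous = nN,
       noncpg_c_total = tot, noncpg_c_unconverted = unconv,
       identity = if (n_obs > 0) n_match / n_obs else 0)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# minimal call table for quantification tests
fake_calls <- function(patterns, counts,
                       sample_id = "S1", amplicon = "A",
                       replicate_id = "R1") {
  pat <- rep(patterns, counts)
  tibble::tibble(
    read_id = sprintf("r%04d", seq_along(pat)),
    sample_id = sample_id, replicate_id = replicate_id,
    amplicon = amplicon, pattern = pat,
    k_demethylated = nchar(pat) - nchar(gsub("U", "", pat, fixed = TRUE)),
    n_ambiguous = 0L, noncpg_c_total = 10L, noncpg_c_unconverted = 0L,
    identity_frac = 1, passed = TRUE, fail_reason = ""
  )
}
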