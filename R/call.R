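# Per-read methylation pattern calling.
#
# Reads are placed against their amplicon by ungapped anchoring at the
# forward primer: read position j corresponds to reference position
# fwd_len + j. Amplicons are short fixed-length products, so reads bearing
# indels or chimeric joins simply fail the identity filter rather than
# being realigned.

UNMATCHED <- "UNMATCHED"

# Hamming distance of each read prefix to a primer; Inf for short reads
.primer_dist <- function(seqs, primer) {
  pl <- nchar(primer)
  d <- rep(Inf, length(seqs))
  ok <- nchar(seqs) >= pl
  if (any(ok)) d[ok] <- .hamming_to(substr(seqs[ok], 1L, pl), primer)
  d
}

#' Assign reads to amplicons by forward primer
#'
#' Compares each read's prefix to every amplicon's forward primer; a read is
#' assigned to the unique amplicon within `max_primer_mismatch` Hamming
#' distance. Reads with no forward-orientation match are tried in
#' reverse-complement orientation. Ties and non-matches are `UNMATCHED`.
#'
#' @param seqs Character vector of index-trimmed read sequences.
#' @param pnl A [panel()].
#' @param max_primer_mismatch Maximum primer Hamming distance (default 2).
#' @return Tibble with columns `amplicon` (name or `"UNMATCHED"`) and
#'   `orientation` (`"forward"`, `"reverse"`, or `NA`).
#' @export
assign_amplicon <- function(seqs, pnl, max_primer_mismatch = 2L) {
  stopifnot(inherits(pnl, "panel_config"), length(pnl$amplicons) >= 1L)
  amps <- pnl$amplicons
  n <- length(seqs)
  res <- tibble::tibble(amplicon = rep(UNMATCHED, n),
                        orientation = rep(NA_character_, n))
  if (n == 0L) return(res)
  match_orient <- function(sq) {
    D <- vapply(amps, function(a) .primer_dist(sq, a$forward_primer),
                numeric(length(sq)))
    D <- matrix(D, nrow = length(sq))
    dmin <- apply(D, 1L, min)
    nbest <- rowSums(D == dmin)
    hit <- is.finite(dmin) & dmin <= max_primer_mismatch & nbest == 1L
    list(hit = hit, best = apply(D, 1L, which.min))
  }
  fw <- match_orient(seqs)
  res$amplicon[fw$hit] <- names(amps)[fw$best[fw$hit]]
  res$orientation[fw$hit] <- "forward"
  todo <- which(!fw$hit)
  if (length(todo) > 0L) {
    rc <- match_orient(.revcomp_vec(seqs[todo]))
    take <- todo[rc$hit]
    res$amplicon[take] <- names(amps)[rc$best[rc$hit]]
    res$orientation[take] <- "reverse"
  }
  res
}

# Vectorized core: seqs are oriented, forward-primer-trimmed sequences
.call_amplicon <- function(seqs, amp, min_identity = 0.9, max_n = 0L) {
  n <- length(seqs)
  L <- nchar(amp$reference)
  fwd <- nchar(amp$forward_primer)
  rev_len <- nchar(amp$reverse_primer)
  sites <- amp$cpg_sites
  inc <- sites[sites$included, , drop = FALSE]
  if (nrow(inc) == 0L) stop("amplicon has no included CpG sites", call. = FALSE)
  W <- L - rev_len - fwd                      # scored inner width
  need <- max(inc$position) - fwd + 1L        # bases needed to cover last site
  nch <- nchar(seqs)
  too_short <- nch < need

  sp <- strsplit(substr(seqs, 1L, W), "", fixed = TRUE)
  m <- t(vapply(sp, function(x) { length(x) <- W; x }, character(W)))

  inc_cols <- inc$position - fwd + 1L
  base <- m[, inc_cols, drop = FALSE]
  pch <- matrix("N", n, length(inc_cols))
  pch[base == "C"] <- "M"
  pch[base == "T"] <- "U"
  pattern <- do.call(paste0, asplit(pch, 2L))
  k <- rowSums(pch == "U")
  n_amb <- rowSums(pch == "N")

  nc_cols <- amp$noncpg_c_positions - fwd + 1L
  if (length(nc_cols) > 0L) {
    ncm <- m[, nc_cols, drop = FALSE]
    nc_total <- rowSums(ncm == "C" | ncm == "T", na.rm = TRUE)
    nc_unconv <- rowSums(ncm == "C", na.rm = TRUE)
  } else {
    nc_total <- nc_unconv <- rep(0L, n)
  }

  refch <- .chars(amp$reference)
  id_pos0 <- setdiff(seq.int(fwd, L - rev_len - 1L), sites$position)
  id_exp <- ifelse(id_pos0 %in% amp$noncpg_c_positions, "T", refch[id_pos0 + 1L])
  obs <- m[, id_pos0 - fwd + 1L, drop = FALSE]
  n_obs <- rowSums(!is.na(obs))
  n_match <- rowSums(obs == matrix(id_exp, n, length(id_pos0), byrow = TRUE),
                     na.rm = TRUE)
  identity <- ifelse(n_obs > 0L, n_match / n_obs, 0)

  passed <- !too_short & identity >= min_identity & n_amb <= max_n
  fail <- rep("", n)
  fail[n_amb > max_n] <- "TOO_MANY_N"
  fail[identity < min_identity] <- "LOW_IDENTITY"
  fail[too_short] <- "TOO_SHORT"
  pattern[too_short] <- NA_character_
  k[too_short] <- NA_integer_
  n_amb[too_short] <- NA_integer_

  tibble::tibble(
    amplicon = amp$name, pattern = pattern,
    k_demethylated = as.integer(k), n_ambiguous = as.integer(n_amb),
    noncpg_c_total = as.integer(nc_total),
    noncpg_c_unconverted = as.integer(nc_unconv),
    identity_frac = identity, passed = passed, fail_reason = fail
  )
}

#' Call the methylation pattern of one read
#'
#' Places an oriented, primer-trimmed read against its amplicon by ungapped
#' primer anchoring and reads out, at each included CpG position, C as
#' methylated ("M"), T as demethylated ("U") and anything else as ambiguous
#' ("N"). Non-CpG reference cytosines are scored converted (T) or
#' unconverted (C) for conversion QC, and the fraction of non-CpG positions
#' matching the converted reference is reported as `identity_frac`. A call
#' passes when `identity_frac >= min_identity` and its N count is at most
#' `max_n`; reads not covering the last included CpG fail with reason
#' `TOO_SHORT`.
#'
#' @param seq Oriented read sequence with index and forward primer removed.
#' @param amp An [amplicon()].
#' @param min_identity Minimum non-CpG identity to pass (default 0.90).
#' @param max_n Maximum ambiguous site calls to pass (default 0).
#' @return One-row tibble with columns `amplicon`, `pattern`,
#'   `k_demethylated`, `n_ambiguous`, `noncpg_c_total`,
#'   `noncpg_c_unconverted`, `identity_frac`, `passed`, `fail_reason`.
#' @examples
#' amp <- amplicon("toy", "ACGTCG",
#'                 data.frame(label = c("1", "2"), position = c(1, 4)))
#' call_pattern("ACGTTG", amp)$pattern # "MU"
#' @export
call_pattern <- function(seq, amp, min_identity = 0.9, max_n = 0L) {
  stopifnot(inherits(amp, "amplicon"), is.character(seq), length(seq) == 1L)
  .call_amplicon(seq, amp, min_identity = min_identity, max_n = max_n)
}

#' Assign and call a set of demultiplexed reads
#'
#' Runs amplicon assignment ([assign_amplicon()]) and per-read pattern
#' calling ([call_pattern()]) over a table of index-trimmed reads. Reads
#' matching no primer are retained with `amplicon = "UNMATCHED"` and
#' `fail_reason = "NO_PRIMER"` so read counts are conserved.
#'
#' @param reads Tibble with columns `read_id` and `trimmed_seq` (or `seq`);
#'   `sample_id` and `replicate_id` are carried through when present.
#' @param pnl A [panel()].
#' @param max_primer_mismatch,min_identity,max_n Caller thresholds, see
#'   [assign_amplicon()] and [call_pattern()].
#' @return Tibble of per-read calls (one row per input read).
#' @export
call_reads <- function(reads, pnl, max_primer_mismatch = 2L,
                       min_identity = 0.9, max_n = 0L) {
  stopifnot(inherits(pnl, "panel_config"))
  reads <- tibble::as_tibble(reads)
  seq_col <- if ("trimmed_seq" %in% names(reads)) "trimmed_seq" else "seq"
  seqs <- reads[[seq_col]]
  n <- nrow(reads)
  keep <- intersect(c("read_id", "sample_id", "replicate_id"), names(reads))
  meta <- reads[keep]

  asg <- assign_amplicon(seqs, pnl, max_primer_mismatch = max_primer_mismatch)
  out <- vector("list", length(pnl$amplicons) + 1L)
  for (i in seq_along(pnl$amplicons)) {
    amp <- pnl$amplicons[[i]]
    sel <- which(asg$amplicon == amp$name)
    if (length(sel) == 0L) next
    sq <- seqs[sel]
    rc <- asg$orientation[sel] == "reverse"
    if (any(rc)) sq[rc] <- .revcomp_vec(sq[rc])
    sq <- substring(sq, nchar(amp$forward_primer) + 1L)
    calls <- .call_amplicon(sq, amp, min_identity = min_identity,
                            max_n = max_n)
    out[[i]] <- dplyr::bind_cols(meta[sel, , drop = FALSE],
                                 orientation = asg$orientation[sel], calls)
  }
  un <- which(asg$amplicon == UNMATCHED)
  if (length(un) > 0L) {
    out[[length(out)]] <- dplyr::bind_cols(
      meta[un, , drop = FALSE],
      tibble::tibble(
        orientation = NA_character_, amplicon = UNMATCHED,
        pattern = NA_character_, k_demethylated = NA_integer_,
        n_ambiguous = NA_integer_, noncpg_c_total = 0L,
        noncpg_c_unconverted = 0L, identity_frac = NA_real_,
        passed = FALSE, fail_reason = "NO_PRIMER"
      )
    )
  }
  res <- dplyr::bind_rows(out)
  stopifnot(nrow(res) == n)
  res
}

#' Bisulfite conversion efficiency from non-CpG cytosines
#'
#' Cytosines outside CpG context cannot be methylated, so any read as C
#' reflects a conversion failure. Efficiency is
#' `100 * converted / (converted + unconverted)` pooled over all passed
#' calls.
#'
#' @param calls Tibble of calls from [call_reads()] or [call_pattern()].
#' @return Efficiency as a percentage in \[0, 100\]; `NA` with a warning if
#'   no passed call contributes a non-CpG cytosine observation.
#' @export
conversion_efficiency <- function(calls) {
  ok <- calls[calls$passed, , drop = FALSE]
  tot <- sum(ok$noncpg_c_total)
  if (tot == 0L) {
    warning("no non-CpG cytosine observations in passed calls; ",
            "conversion efficiency undefined")
    return(NA_real_)
  }
  100 * (tot - sum(ok$noncpg_c_unconverted)) / tot
}

#' Conversion-efficiency QC per sample and amplicon
#'
#' @param calls Tibble of calls from [call_reads()].
#' @return Tibble with one row per (sample_id, amplicon): reads in, reads
#'   passed, and conversion efficiency (%).
#' @export
conversion_qc <- function(calls) {
  grp <- intersect(c("sample_id", "amplicon"), names(calls))
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      reads_in = dplyr::n(),
      reads_passed = sum(.data$passed),
      efficiency = {
        tot <- sum(.data$noncpg_c_total[.data$passed])
        if (tot == 0L) NA_real_
        else 100 * (tot - sum(.data$noncpg_c_unconverted[.data$passed])) / tot
      },
      .groups = "drop"
    )
}
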