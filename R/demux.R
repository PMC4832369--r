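# Demultiplexing of dual-placement indexed reads.
#
# Index layout convention: an index synthesized on the forward adaptor is
# the first index_length bases of the read; an index synthesized on the
# reverse adaptor appears reverse-complemented as the last index_length
# bases (it sits on the opposite end of the sequenced strand). The same
# index sequence can therefore serve two different samples, one per
# placement, doubling the number of addressable samples.

UNASSIGNED <- "UNASSIGNED"

#' Number of sample assignments addressable by an index pool
#'
#' Each index can be synthesized on either the forward or the reverse
#' adaptor, so a pool of `n` distinct indexes addresses `2 * n` samples.
#'
#' @param index_pool Character vector of distinct index sequences.
#' @return Integer count of distinct (index, placement) sample assignments.
#' @examples
#' enumerate_combinations(character(0)) # 0
#' @export
enumerate_combinations <- function(index_pool) {
  if (anyDuplicated(index_pool)) {
    stop("index pool contains duplicate sequences", call. = FALSE)
  }
  2L * length(index_pool)
}

#' Construct or read a sample sheet
#'
#' A sample sheet maps (index sequence, adaptor placement) pairs to
#' sample/replicate identities. All indexes must share one length and each
#' (index_seq, placement) pair must be unique.
#'
#' @param assignments Data frame with columns `index_seq`, `placement`
#'   ("forward" or "reverse"), `sample_id`, `replicate_id`.
#' @return A `sample_sheet` object (a tibble with an `index_length`
#'   attribute).
#' @export
sample_sheet <- function(assignments) {
  sh <- tibble::as_tibble(assignments)
  req <- c("index_seq", "placement", "sample_id", "replicate_id")
  if (!all(req %in% names(sh))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  sh$index_seq <- toupper(sh$index_seq)
  if (any(grepl("[^ACGT]", sh$index_seq))) {
    stop("index sequences must be A/C/G/T", call. = FALSE)
  }
  if (!all(sh$placement %in% c("forward", "reverse"))) {
    stop("placement must be 'forward' or 'reverse'", call. = FALSE)
  }
  lens <- unique(nchar(sh$index_seq))
  if (length(lens) != 1L) {
    stop("all index sequences must have the same length", call. = FALSE)
  }
  if (anyDuplicated(sh[c("index_seq", "placement")])) {
    stop("(index_seq, placement) pairs must be unique", call. = FALSE)
  }
  structure(sh, index_length = as.integer(lens),
            class = c("sample_sheet", class(sh)))
}

#' @rdname sample_sheet
#' @param path Path to a tab-separated sheet with the columns above.
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(readr::read_tsv(path, comment = "#", show_col_types = FALSE))
}

#' Write a sample sheet to TSV
#'
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(tibble::as_tibble(sheet), path)
  invisible(path)
}

# Hamming distances from each string in `strs` (all same length L) to `target`
.hamming_to <- function(strs, target) {
  L <- nchar(target)
  tc <- .chars(target)
  m <- matrix(unlist(strsplit(strs, "", fixed = TRUE)),
              nrow = length(strs), ncol = L, byrow = TRUE)
  rowSums(m != matrix(tc, nrow = length(strs), ncol = L, byrow = TRUE))
}

# Per-read candidate index region for a given placement
.index_region <- function(seqs, placement, index_len) {
  if (placement == "forward") {
    substr(seqs, 1L, index_len)
  } else {
    .revcomp_vec(substring(seqs, nchar(seqs) - index_len + 1L))
  }
}

.revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Demultiplex reads against a sample sheet
#'
#' Extracts each read's candidate index regions (read head for
#' forward-placement entries, reverse-complemented read tail for
#' reverse-placement entries), finds the sheet entry at minimum Hamming
#' distance, and assigns the read when that minimum is at most
#' `max_mismatch` and attained by exactly one entry; ambiguous or distant
#' reads are left `UNASSIGNED`. Assigned reads are index-trimmed.
#'
#' @param reads Tibble with columns `read_id` and `seq`, e.g. from
#'   [read_fastq()].
#' @param sheet A [sample_sheet()].
#' @param max_mismatch Maximum Hamming distance tolerated (default 1).
#' @return The input tibble with columns `sample_id`, `replicate_id`,
#'   `placement`, `index_distance` and `trimmed_seq` (`sample_id` is
#'   `"UNASSIGNED"` for unassigned reads).
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 1L) {
  stopifnot(inherits(sheet, "sample_sheet"))
  reads <- tibble::as_tibble(reads)
  ilen <- attr(sheet, "index_length")
  n <- nrow(reads)
  out <- reads
  out$sample_id <- rep(UNASSIGNED, n)
  out$replicate_id <- rep(NA_character_, n)
  out$placement <- rep(NA_character_, n)
  out$index_distance <- rep(NA_integer_, n)
  out$trimmed_seq <- rep(NA_character_, n)
  if (n == 0L) return(out)

  long_enough <- nchar(reads$seq) >= ilen
  if (!any(long_enough)) return(out)
  idx <- which(long_enough)
  seqs <- reads$seq[idx]
  region <- list(
    forward = .index_region(seqs, "forward", ilen),
    reverse = .index_region(seqs, "reverse", ilen)
  )
  D <- vapply(seq_len(nrow(sheet)), function(j) {
    .hamming_to(region[[sheet$placement[j]]], sheet$index_seq[j])
  }, numeric(length(idx)))
  D <- matrix(D, nrow = length(idx))
  dmin <- apply(D, 1L, min)
  nbest <- rowSums(D == dmin)
  hit <- dmin <= max_mismatch & nbest == 1L
  best <- apply(D, 1L, which.min)
  take <- idx[hit]
  j <- best[hit]
  out$sample_id[take] <- sheet$sample_id[j]
  out$replicate_id[take] <- sheet$replicate_id[j]
  out$placement[take] <- sheet$placement[j]
  out$index_distance[take] <- as.integer(dmin[hit])
  fwd <- out$placement[take] == "forward"
  sq <- out$seq[take]
  out$trimmed_seq[take] <- ifelse(
    fwd, substring(sq, ilen + 1L), substr(sq, 1L, nchar(sq) - ilen)
  )
  out
}

#' Assign one read to a sample
#'
#' Scalar convenience wrapper around [demultiplex()].
#'
#' @param seq Read sequence.
#' @param sheet A [sample_sheet()].
#' @param max_mismatch Maximum Hamming distance tolerated.
#' @return A one-row tibble with `sample_id` (`"UNASSIGNED"` when no unique
#'   match exists), `replicate_id`, `placement`, `index_distance`.
#' @export
assign_read <- function(seq, sheet, max_mismatch = 1L) {
  res <- demultiplex(tibble::tibble(read_id = "r", seq = seq), sheet,
                     max_mismatch = max_mismatch)
  res[, c("sample_id", "replicate_id", "placement", "index_distance")]
}

#' Demultiplexing report
#'
#' @param demux Output of [demultiplex()].
#' @return Tibble with one row per (sample_id, replicate_id) plus an
#'   `UNASSIGNED` row, with assigned read counts.
#' @export
demux_report <- function(demux) {
  dplyr::count(demux, sample_id, replicate_id, name = "reads")
}
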