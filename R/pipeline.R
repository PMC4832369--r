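# End-to-end orchestration: demultiplex -> amplicon assignment -> pattern
# calling -> quantification, with TSV reports and a run manifest. The
# pipeline itself is deterministic; all randomness lives in the simulator.

.write_report <- function(df, path, params = NULL) {
  lines <- character(0)
  if (!is.null(params) && length(params) > 0L) {
    lines <- sprintf("# %s=%s", names(params),
                     vapply(params, function(x) paste(x, collapse = ","),
                            character(1)))
  }
  writeLines(lines, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.empty_calls <- function() {
  tibble::tibble(
    read_id = character(0), sample_id = character(0),
    replicate_id = character(0), orientation = character(0),
    amplicon = character(0), pattern = character(0),
    k_demethylated = integer(0), n_ambiguous = integer(0),
    noncpg_c_total = integer(0), noncpg_c_unconverted = integer(0),
    identity_frac = numeric(0), passed = logical(0),
    fail_reason = character(0)
  )
}

#' Treg-like read fraction per replicate
#'
#' Computes, for every (sample, amplicon, replicate) group, the percentage
#' of eligible reads with at least the amplicon's `treg_min_k` demethylated
#' sites.
#'
#' @param calls Tibble from [call_reads()].
#' @param pnl A [panel()] supplying each amplicon's default threshold.
#' @param min_k Optional named integer vector (by amplicon name) overriding
#'   the panel thresholds.
#' @return Tibble with keys, `min_k`, `n_eligible`, `treg_like_pct`.
#' @export
treg_like_by_replicate <- function(calls, pnl, min_k = NULL) {
  el <- eligible_calls(calls)
  el <- el[el$amplicon %in% names(pnl$amplicons), , drop = FALSE]
  if (nrow(el) == 0L) {
    return(tibble::tibble(sample_id = character(0), amplicon = character(0),
                          replicate_id = character(0), min_k = integer(0),
                          n_eligible = integer(0),
                          treg_like_pct = numeric(0)))
  }
  thr <- vapply(pnl$amplicons, `[[`, integer(1), "treg_min_k")
  if (!is.null(min_k)) thr[names(min_k)] <- as.integer(min_k)
  el |>
    dplyr::group_by(.data$sample_id, .data$amplicon, .data$replicate_id) |>
    dplyr::summarise(
      min_k = thr[[.data$amplicon[1]]],
      n_eligible = dplyr::n(),
      treg_like_pct = 100 * mean(.data$k_demethylated >= thr[[.data$amplicon[1]]]),
      .groups = "drop"
    )
}

#' Run the full analysis pipeline
#'
#' Reads a FASTQ file, demultiplexes against a sample sheet, assigns reads
#' to panel amplicons by primer, calls per-read methylation patterns,
#' quantifies pattern frequencies / k distributions / Treg-like fractions
#' with replicate summaries, and writes TSV reports plus a YAML run
#' manifest (parameters, package version, input checksums, stage read
#' counts) to `out_dir`. Reruns with identical inputs produce
#' byte-identical reports.
#'
#' @param fastq Path to the input FASTQ (optionally gzipped).
#' @param sheet A [sample_sheet()] or path to a sheet TSV.
#' @param pnl A [panel()] or path to a YAML panel config.
#' @param out_dir Output directory, created if needed.
#' @param max_mismatch Index mismatch tolerance (default 1).
#' @param max_primer_mismatch Primer mismatch tolerance (default 2).
#' @param min_identity Caller identity threshold (default 0.90).
#' @param max_n Maximum ambiguous sites per passing read (default 0).
#' @param treg_min_k Optional named vector overriding per-amplicon
#'   Treg-like thresholds.
#' @return (Invisibly) a list with elements `demux`, `calls`, `qc`,
#'   `patterns`, `kdist`, `treg_by_replicate`, `summary`, `manifest`.
#' @export
run_pipeline <- function(fastq, sheet, pnl, out_dir,
                         max_mismatch = 1L, max_primer_mismatch = 2L,
                         min_identity = 0.9, max_n = 0L,
                         treg_min_k = NULL) {
  if (is.character(pnl)) pnl <- load_panel(pnl)
  stopifnot(inherits(pnl, "panel_config"))
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  stopifnot(inherits(sheet, "sample_sheet"))
  if (!file.exists(fastq)) stop("FASTQ not found: ", fastq, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  params <- list(max_mismatch = max_mismatch,
                 max_primer_mismatch = max_primer_mismatch,
                 min_identity = min_identity, max_n = max_n,
                 panel_version = pnl$version,
                 bisamp_version = as.character(packageVersion("bisamp")))

  reads <- read_fastq(fastq)
  dm <- demultiplex(reads, sheet, max_mismatch = max_mismatch)
  rep_demux <- demux_report(dm)
  .write_report(rep_demux, file.path(out_dir, "demux_report.tsv"), params)

  assigned <- dm[dm$sample_id != UNASSIGNED, , drop = FALSE]
  calls <- if (nrow(assigned) > 0L) {
    call_reads(assigned, pnl, max_primer_mismatch = max_primer_mismatch,
               min_identity = min_identity, max_n = max_n)
  } else {
    .empty_calls()
  }
  .write_report(calls, file.path(out_dir, "calls.tsv"), params)

  qc <- if (nrow(calls) > 0L) conversion_qc(calls) else
    tibble::tibble(sample_id = character(0), amplicon = character(0),
                   reads_in = integer(0), reads_passed = integer(0),
                   efficiency = numeric(0))
  .write_report(qc, file.path(out_dir, "conversion_qc.tsv"), params)

  has_eligible <- nrow(calls) > 0L && nrow(eligible_calls(calls)) > 0L
  patterns <- if (has_eligible) pattern_frequencies(calls) else {
    warning("no reads eligible for quantification; writing empty tables")
    tibble::tibble(sample_id = character(0), amplicon = character(0),
                   replicate_id = character(0), pattern = character(0),
                   count = integer(0), frequency = numeric(0))
  }
  .write_report(patterns, file.path(out_dir, "pattern_frequencies.tsv"),
                params)

  kdist <- if (has_eligible) k_distribution(calls) else
    tibble::tibble(sample_id = character(0), amplicon = character(0),
                   replicate_id = character(0), k = integer(0),
                   fraction = numeric(0))
  .write_report(kdist, file.path(out_dir, "k_distribution.tsv"), params)

  tlr <- treg_like_by_replicate(calls, pnl, min_k = treg_min_k)
  .write_report(tlr, file.path(out_dir, "treg_like_by_replicate.tsv"),
                params)

  summary_tbl <- if (nrow(tlr) > 0L) {
    tlr |>
      dplyr::group_by(.data$sample_id, .data$amplicon) |>
      dplyr::reframe(replicate_summary(.data$treg_like_pct,
                                       statistic = "treg_like_pct"))
  } else {
    tibble::tibble(sample_id = character(0), amplicon = character(0),
                   statistic = character(0), median = numeric(0),
                   min = numeric(0), max = numeric(0),
                   n_replicates = integer(0))
  }
  .write_report(summary_tbl, file.path(out_dir, "replicate_summary.tsv"),
                params)

  counts <- list(
    reads_in = nrow(reads),
    reads_assigned = nrow(assigned),
    reads_unassigned = nrow(reads) - nrow(assigned),
    reads_called = sum(calls$amplicon != UNMATCHED),
    reads_unmatched_primer = sum(calls$amplicon == UNMATCHED),
    reads_passed = sum(calls$passed),
    reads_eligible = if (nrow(calls) > 0L) nrow(eligible_calls(calls)) else 0L
  )
  stopifnot(counts$reads_in == counts$reads_assigned + counts$reads_unassigned,
            counts$reads_assigned ==
              counts$reads_called + counts$reads_unmatched_primer)

  manifest <- list(
    parameters = params,
    inputs = list(fastq = unname(tools::md5sum(fastq))),
    counts = counts
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(demux = dm, calls = calls, qc = qc, patterns = patterns,
                 kdist = kdist, treg_by_replicate = tlr,
                 summary = summary_tbl, manifest = manifest))
}
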