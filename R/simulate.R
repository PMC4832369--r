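# Seeded simulator for multiplexed bisulfite amplicon reads.
#
# A simulated molecule is drawn from a cell-type profile (per-site
# methylation probabilities), optionally replaced by a fully methylated
# inactive-X copy in females (X-linked amplicons only), bisulfite-converted
# with a given success rate, read with uniform substitution errors, and
# tagged with its replicate's index on the forward or reverse adaptor.

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Cell-type methylation profile
#'
#' @param name Profile name (e.g. "treg", "naive").
#' @param meth_prob Named list, one numeric vector per amplicon giving the
#'   methylation probability of each declared CpG site (in position order,
#'   excluded sites included).
#' @return A `cell_type_profile` object.
#' @export
cell_type_profile <- function(name, meth_prob) {
  stopifnot(is.character(name), length(name) == 1L, is.list(meth_prob))
  for (v in meth_prob) stopifnot(all(v >= 0 & v <= 1))
  structure(list(name = name, meth_prob = meth_prob),
            class = "cell_type_profile")
}

#' Default Treg / naive profile pair for a panel
#'
#' Treg molecules are fully demethylated (methylation probability 0 at
#' every site); naive/effector molecules are fully methylated (probability
#' 1). Real cells show small deviations from these extremes; pass custom
#' profiles to model them.
#'
#' @param pnl A [panel()].
#' @return Named list of two [cell_type_profile()]s, `treg` and `naive`.
#' @export
default_profiles <- function(pnl) {
  mk <- function(p) {
    lapply(pnl$amplicons, function(a) rep(p, nrow(a$cpg_sites)))
  }
  list(treg = cell_type_profile("treg", mk(0)),
       naive = cell_type_profile("naive", mk(1)))
}

# indexes with pairwise Hamming distance >= 3, avoiding exact collisions
# with any amplicon's read head/tail so placement is never ambiguous
.generate_indexes <- function(n, index_length, pnl) {
  forbid_head <- forbid_tail <- character(0)
  for (a in pnl$amplicons) {
    conv <- bisulfite_convert(a$reference, cpg_methylated = TRUE)
    forbid_head <- c(forbid_head, substr(conv, 1L, index_length))
    forbid_tail <- c(forbid_tail,
                     substring(conv, nchar(conv) - index_length + 1L))
  }
  pool <- character(0)
  bases <- c("A", "C", "G", "T")
  tries <- 0L
  while (length(pool) < n) {
    tries <- tries + 1L
    if (tries > 10000L) stop("could not generate an index pool")
    cand <- paste(sample(bases, index_length, replace = TRUE), collapse = "")
    if (cand %in% forbid_head || .revcomp(cand) %in% forbid_tail) next
    if (length(pool) > 0L && any(.hamming_to(pool, cand) < 3)) next
    pool <- c(pool, cand)
  }
  pool
}

#' Generate a sample sheet for a simulation
#'
#' Assigns each (sample, replicate) well a unique (index, placement) pair.
#' Consecutive wells reuse one index on alternating adaptor placements,
#' exercising the dual-placement scheme that doubles index capacity.
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_replicates Replicates per sample.
#' @param index_length Index length in bases (default 8).
#' @param pnl Panel, used to avoid indexes colliding with amplicon ends.
#' @param seed Integer seed.
#' @return A [sample_sheet()].
#' @export
make_sample_sheet <- function(sample_ids, n_replicates = 1L,
                              index_length = 8L, pnl = example_panel(),
                              seed = 1L) {
  wells <- expand.grid(replicate_id = paste0("R", seq_len(n_replicates)),
                       sample_id = sample_ids, stringsAsFactors = FALSE)
  wells <- wells[order(match(wells$sample_id, sample_ids)), ]
  A <- nrow(wells)
  .with_seed(seed, {
    pool <- .generate_indexes(ceiling(A / 2), index_length, pnl)
    sample_sheet(tibble::tibble(
      index_seq = pool[ceiling(seq_len(A) / 2)],
      placement = rep_len(c("forward", "reverse"), A),
      sample_id = wells$sample_id,
      replicate_id = wells$replicate_id
    ))
  })
}

#' Specify a read simulation
#'
#' @param pnl A [panel()].
#' @param samples Tibble with columns `sample_id`, `sex` ("male"/"female")
#'   and `treg_fraction` (mixture proportion of the `treg` profile; the
#'   remainder is `naive`), or a `weights` list-column of named profile
#'   weights.
#' @param profiles Named list of [cell_type_profile()]s; defaults to
#'   [default_profiles()].
#' @param conversion_rate Probability an unmethylated cytosine reads T
#'   (default 0.995; a well-run assay exceeds 0.99).
#' @param inappropriate_conversion Probability a methylated cytosine reads
#'   T (default 0).
#' @param seq_error_rate Per-base uniform substitution probability
#'   (default 0.001).
#' @param reads_per_replicate Reads per sample-replicate-amplicon
#'   (default 2000).
#' @param n_replicates PCR replicates per sample (default 1).
#' @param amplicon_names Amplicons to simulate (default: all in the panel).
#' @param index_length Index length (default 8).
#' @param sheet Optional pre-built [sample_sheet()]; generated
#'   deterministically from `seed` when `NULL`.
#' @param seed Integer seed controlling all randomness.
#' @return A `sim_design` object.
#' @export
sim_design <- function(pnl, samples, profiles = NULL,
                       conversion_rate = 0.995,
                       inappropriate_conversion = 0,
                       seq_error_rate = 0.001,
                       reads_per_replicate = 2000L, n_replicates = 1L,
                       amplicon_names = NULL, index_length = 8L,
                       sheet = NULL, seed = 1L) {
  stopifnot(inherits(pnl, "panel_config"))
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "sex") %in% names(samples)),
            all(samples$sex %in% c("male", "female")),
            !anyDuplicated(samples$sample_id))
  if (is.null(profiles)) profiles <- default_profiles(pnl)
  if (!"weights" %in% names(samples)) {
    stopifnot("treg_fraction" %in% names(samples),
              all(samples$treg_fraction >= 0 & samples$treg_fraction <= 1))
    samples$weights <- lapply(samples$treg_fraction, function(p) {
      c(treg = p, naive = 1 - p)
    })
  }
  for (w in samples$weights) {
    stopifnot(all(names(w) %in% names(profiles)), all(w >= 0),
              abs(sum(w) - 1) < 1e-9)
  }
  stopifnot(conversion_rate >= 0, conversion_rate <= 1,
            inappropriate_conversion >= 0, inappropriate_conversion <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1)
  if (is.null(amplicon_names)) amplicon_names <- names(pnl$amplicons)
  stopifnot(all(amplicon_names %in% names(pnl$amplicons)))
  if (is.null(sheet)) {
    sheet <- make_sample_sheet(samples$sample_id, n_replicates,
                               index_length, pnl, seed = seed + 1000003L)
  }
  structure(
    list(panel = pnl, samples = samples, profiles = profiles,
         conversion_rate = conversion_rate,
         inappropriate_conversion = inappropriate_conversion,
         seq_error_rate = seq_error_rate,
         reads_per_replicate = as.integer(reads_per_replicate),
         n_replicates = as.integer(n_replicates),
         amplicon_names = amplicon_names,
         index_length = as.integer(index_length),
         sheet = sheet, seed = as.integer(seed)),
    class = "sim_design"
  )
}

# simulate one (sample, replicate, amplicon) block; returns reads + truth
.sim_block <- function(design, amp, sample_row, replicate_id, index_seq,
                       placement) {
  n <- design$reads_per_replicate
  sites <- amp$cpg_sites
  S <- nrow(sites)
  L <- nchar(amp$reference)
  w <- sample_row$weights[[1]]
  prof_names <- sample(names(w), n, replace = TRUE, prob = w)
  P <- do.call(rbind, lapply(prof_names, function(p) {
    design$profiles[[p]]$meth_prob[[amp$name]]
  }))
  meth <- matrix(runif(n * S), n, S) < P
  x_inactive <- rep(FALSE, n)
  if (sample_row$sex == "female" && amp$x_linked) {
    x_inactive <- runif(n) < 0.5
    meth[x_inactive, ] <- TRUE
  }
  inc <- sites$included
  true_pattern <- do.call(paste0, asplit(
    matrix(ifelse(meth[, inc, drop = FALSE], "M", "U"), n), 2L))

  # converted template: primer regions read as the synthesized primers
  tmpl <- .chars(bisulfite_convert(amp$reference, cpg_methylated = TRUE))
  fwd <- nchar(amp$forward_primer)
  rev_len <- nchar(amp$reverse_primer)
  if (fwd > 0L) tmpl[seq_len(fwd)] <- .chars(amp$forward_primer)
  if (rev_len > 0L) {
    tmpl[(L - rev_len + 1L):L] <- .chars(.revcomp(amp$reverse_primer))
  }
  M <- matrix(tmpl, n, L, byrow = TRUE)
  ncp <- amp$noncpg_c_positions
  if (length(ncp) > 0L) {
    sub <- M[, ncp + 1L, drop = FALSE]
    sub[matrix(runif(n * length(ncp)) >= design$conversion_rate,
               n, length(ncp))] <- "C"
    M[, ncp + 1L] <- sub
  }
  r1 <- matrix(runif(n * S), n, S)
  M[, sites$position + 1L] <- ifelse(
    meth,
    ifelse(r1 < design$inappropriate_conversion, "T", "C"),
    ifelse(r1 < design$conversion_rate, "T", "C")
  )

  ilen <- design$index_length
  W <- ilen + L
  R <- matrix("", n, W)
  if (placement == "forward") {
    R[, seq_len(ilen)] <- matrix(.chars(index_seq), n, ilen, byrow = TRUE)
    R[, ilen + seq_len(L)] <- M
  } else {
    R[, seq_len(L)] <- M
    R[, L + seq_len(ilen)] <- matrix(.chars(.revcomp(index_seq)),
                                     n, ilen, byrow = TRUE)
  }
  if (design$seq_error_rate > 0) {
    ne <- rbinom(1L, n * W, design$seq_error_rate)
    if (ne > 0L) {
      pos <- sample.int(n * W, ne)
      bases <- c("A", "C", "G", "T")
      shift <- sample.int(3L, ne, replace = TRUE)
      R[pos] <- bases[(match(R[pos], bases) - 1L + shift) %% 4L + 1L]
    }
  }
  seqs <- do.call(paste0, asplit(R, 2L))
  ids <- sprintf("%s:%s:%s:%05d", sample_row$sample_id, replicate_id,
                 amp$name, seq_len(n))
  list(
    reads = tibble::tibble(read_id = ids, seq = seqs,
                           qual = strrep("I", W)),
    truth = tibble::tibble(
      read_id = ids, sample_id = sample_row$sample_id,
      replicate_id = replicate_id, amplicon = amp$name,
      profile = prof_names, x_inactive = x_inactive,
      true_pattern = true_pattern,
      true_k = nchar(true_pattern) -
        nchar(gsub("U", "", true_pattern, fixed = TRUE)),
      fully_demethylated = true_pattern == strrep("U", sum(inc))
    )
  )
}

#' Simulate multiplexed bisulfite amplicon reads
#'
#' Generates reads for every (sample, replicate, amplicon) combination of a
#' design: molecules are drawn from the sample's profile mixture, females
#' contribute a fully methylated inactive-X molecule with probability 1/2
#' at X-linked amplicons, conversion and sequencing-error processes are
#' applied, and each read carries its replicate's index on the configured
#' adaptor placement. Fully deterministic given the design seed.
#'
#' @param design A [sim_design()].
#' @return A `sim_result` list: `reads` (read_id, seq, qual), `truth`
#'   (per-read generating profile and true pattern), `truth_by_sample`
#'   (per sample x amplicon x replicate true demethylated-molecule
#'   fraction), `sheet`, `design`.
#' @export
simulate_reads <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  .with_seed(design$seed, {
    blocks <- list()
    for (si in seq_len(nrow(design$samples))) {
      srow <- design$samples[si, , drop = FALSE]
      for (r in seq_len(design$n_replicates)) {
        rid <- paste0("R", r)
        entry <- design$sheet[design$sheet$sample_id == srow$sample_id &
                                design$sheet$replicate_id == rid, ]
        stopifnot(nrow(entry) == 1L)
        for (an in design$amplicon_names) {
          amp <- design$panel$amplicons[[an]]
          blocks[[length(blocks) + 1L]] <-
            .sim_block(design, amp, srow, rid, entry$index_seq,
                       entry$placement)
        }
      }
    }
    reads <- dplyr::bind_rows(lapply(blocks, `[[`, "reads"))
    truth <- dplyr::bind_rows(lapply(blocks, `[[`, "truth"))
    truth_by_sample <- truth |>
      dplyr::group_by(.data$sample_id, .data$amplicon, .data$replicate_id) |>
      dplyr::summarise(
        n_molecules = dplyr::n(),
        true_demethylated_fraction = mean(.data$fully_demethylated),
        .groups = "drop"
      )
    structure(list(reads = reads, truth = truth,
                   truth_by_sample = truth_by_sample,
                   sheet = design$sheet, design = design),
              class = "sim_result")
  })
}

#' Titration design series
#'
#' One single-sample male design per mixture fraction, emulating a defined
#' Treg/naive titration used to check assay linearity.
#'
#' @param pnl A [panel()].
#' @param p_values Treg mixture fractions (e.g. `c(0, .2, .4, .6, .8, 1)`).
#' @param reads_per_point Reads per titration point (default 2000).
#' @param seed Base seed; point i uses `seed + i`.
#' @param ... Further arguments to [sim_design()] (e.g. `amplicon_names`,
#'   `conversion_rate`, `seq_error_rate`).
#' @return List of [sim_design()]s, one per element of `p_values`.
#' @export
titration_design <- function(pnl, p_values, reads_per_point = 2000L,
                             seed = 1L, ...) {
  lapply(seq_along(p_values), function(i) {
    sim_design(
      pnl,
      samples = tibble::tibble(
        sample_id = sprintf("titr_p%02d", i), sex = "male",
        treg_fraction = p_values[i]
      ),
      reads_per_replicate = reads_per_point, n_replicates = 1L,
      seed = seed + i, ...
    )
  })
}

#' Write reads to FASTQ
#'
#' @param x A `sim_result` or a tibble with `read_id`, `seq` and
#'   optionally `qual`.
#' @param path Output path; a `.gz` suffix enables compression.
#' @return The path, invisibly.
#' @export
write_fastq <- function(x, path) {
  tbl <- if (inherits(x, "sim_result")) x$reads else tibble::as_tibble(x)
  dna <- Biostrings::DNAStringSet(setNames(tbl$seq, tbl$read_id))
  qual <- if ("qual" %in% names(tbl)) tbl$qual
          else strrep("I", nchar(tbl$seq))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return Tibble with columns `read_id` (first header token) and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 seq = unname(as.character(x)))
}

#' Write the per-read simulation truth to TSV
#'
#' @param sim A `sim_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sim_truth <- function(sim, path) {
  readr::write_tsv(sim$truth, path)
  invisible(path)
}
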