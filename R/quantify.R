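# Aggregation of per-read calls into epiallele tables and summary
# statistics. All denominators here use "eligible" reads: passed calls
# whose pattern contains no ambiguous (N) site, consistent with the
# caller's default table policy.

#' Eligible calls for quantification
#'
#' Filters a call table to passed, N-free pattern calls.
#'
#' @param calls Tibble from [call_reads()].
#' @return Filtered tibble.
#' @export
eligible_calls <- function(calls) {
  keep <- calls$passed & !is.na(calls$pattern) & !grepl("N", calls$pattern,
                                                        fixed = TRUE)
  calls[keep, , drop = FALSE]
}

.group_cols <- function(calls) {
  intersect(c("sample_id", "amplicon", "replicate_id"), names(calls))
}

#' Epiallele (pattern) frequency table
#'
#' Counts each distinct per-read methylation pattern within every
#' (sample, amplicon, replicate) group and expresses it as a percentage of
#' the group's eligible reads. Rows are ordered by descending count, ties
#' broken lexicographically by pattern.
#'
#' @param calls Tibble from [call_reads()]; filtered with
#'   [eligible_calls()] internally.
#' @return Tibble with grouping keys, `pattern`, `count` and `frequency`
#'   (percent; sums to 100 within each group).
#' @export
pattern_frequencies <- function(calls) {
  el <- eligible_calls(calls)
  if (nrow(el) == 0L) {
    warning("no eligible reads; empty pattern table")
    return(tibble::tibble(pattern = character(0), count = integer(0),
                          frequency = numeric(0)))
  }
  grp <- .group_cols(el)
  el |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grp, "pattern"))),
                 name = "count") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(frequency = 100 * .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pattern,
                   .by_group = TRUE) |>
    dplyr::ungroup()
}

#' Distribution of demethylated-site counts per read
#'
#' Bins eligible reads by `k`, the number of demethylated (U) sites in the
#' pattern, over k = 0..n for an n-site amplicon.
#'
#' @param calls Tibble from [call_reads()].
#' @param n_sites Number of analysed sites; inferred from the pattern width
#'   when `NULL`.
#' @return Tibble with grouping keys, `k` (0..n) and `fraction` (sums to 1
#'   within each group).
#' @export
k_distribution <- function(calls, n_sites = NULL) {
  el <- eligible_calls(calls)
  if (nrow(el) == 0L) {
    warning("no eligible reads; empty k distribution")
    return(tibble::tibble(k = integer(0), fraction = numeric(0)))
  }
  grp <- .group_cols(el)
  el |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::reframe({
      n <- if (is.null(n_sites)) nchar(.data$pattern[1]) else n_sites
      tab <- tabulate(.data$k_demethylated + 1L, nbins = n + 1L)
      tibble::tibble(k = 0:n, fraction = tab / sum(tab))
    })
}

#' Fraction of Treg-like reads
#'
#' Percentage of eligible reads with at least `min_k` of the analysed CpG
#' sites demethylated — e.g. 8 of 9 TSDR sites for a Treg-like FOXP3 read,
#' or all 7 sites for CTLA4.
#'
#' @param calls Tibble from [call_reads()] (one sample/amplicon group;
#'   pooled if more).
#' @param min_k Minimum demethylated-site count.
#' @return Percentage in \[0, 100\]; `NA` with a warning when no read is
#'   eligible.
#' @export
treg_like_fraction <- function(calls, min_k) {
  el <- eligible_calls(calls)
  if (nrow(el) == 0L) {
    warning("no eligible reads")
    return(NA_real_)
  }
  n <- nchar(el$pattern[1])
  if (min_k > n) stop("min_k exceeds the number of analysed sites",
                      call. = FALSE)
  100 * mean(el$k_demethylated >= min_k)
}

#' Fraction of reads with intermediate demethylation
#'
#' Percentage of eligible reads whose demethylated-site count k falls in
#' `k_set` — e.g. `k_set = 3:6` for the 3T-6T intermediate patterns of a
#' 7-site amplicon.
#'
#' @param calls Tibble from [call_reads()].
#' @param k_set Integer set of k values to count.
#' @return Percentage in \[0, 100\].
#' @export
intermediate_fraction <- function(calls, k_set) {
  el <- eligible_calls(calls)
  if (nrow(el) == 0L) {
    warning("no eligible reads")
    return(NA_real_)
  }
  n <- nchar(el$pattern[1])
  if (length(k_set) > 0 && (min(k_set) < 0 || max(k_set) > n)) {
    stop("k_set must lie within 0..n", call. = FALSE)
  }
  100 * mean(el$k_demethylated %in% k_set)
}

#' Median and range across PCR replicates
#'
#' Summarises a per-replicate statistic as the median (mean of the central
#' pair for an even replicate count) with its min-max range.
#'
#' @param values Numeric vector, one value per replicate.
#' @param statistic Name of the statistic being summarised.
#' @return One-row tibble: `statistic`, `median`, `min`, `max`,
#'   `n_replicates`.
#' @export
replicate_summary <- function(values, statistic = "treg_like_pct") {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no replicate values", call. = FALSE)
  tibble::tibble(statistic = statistic, median = stats::median(values),
                 min = min(values), max = max(values),
                 n_replicates = length(values))
}

#' Titration linearity regression
#'
#' Ordinary least squares of the pipeline-estimated demethylated fraction
#' on the known mixture fraction, as used to validate assay linearity on
#' defined Treg/naive cell mixtures.
#'
#' @param known_fractions Numeric vector of true mixture fractions.
#' @param estimated_demethylation Numeric vector of estimates, same length
#'   (at least 3 points).
#' @return List with `slope`, `intercept` and `r_squared` (coefficient of
#'   determination; 0 with a warning for zero-variance responses).
#' @export
mixture_regression <- function(known_fractions, estimated_demethylation) {
  x <- as.numeric(known_fractions)
  y <- as.numeric(estimated_demethylation)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with at least 3 points", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("zero variance in estimates; r_squared set to 0")
    return(list(slope = 0, intercept = mean(y), r_squared = 0))
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Sex-adjusted Treg estimate from an X-linked demethylated fraction
#'
#' FOXP3 lies on the X chromosome; X inactivation leaves one methylated
#' copy per female cell, so even a pure female Treg sample shows only ~50%
#' demethylated TSDR molecules. The female fraction is therefore doubled
#' (capped at 1) to estimate the Treg cell fraction; male fractions pass
#' through unchanged.
#'
#' @param demethylated_fraction Proportion in \[0, 1\].
#' @param sex `"male"` or `"female"`.
#' @param factor Female adjustment multiplier (default 2).
#' @return Adjusted proportion in \[0, 1\].
#' @export
sex_adjusted_treg_estimate <- function(demethylated_fraction, sex,
                                       factor = 2) {
  stopifnot(all(demethylated_fraction >= 0 & demethylated_fraction <= 1))
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") demethylated_fraction
  else pmin(1, factor * demethylated_fraction)
}
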