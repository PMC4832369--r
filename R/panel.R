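#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm median runif rbinom coef setNames
#' @importFrom utils packageVersion head
#' @importFrom dplyr .data
NULL

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(x) > 0L && grepl("[^ACGT]", x)) {
    stop(what, " contains non-ACGT characters", call. = FALSE)
  }
  invisible(x)
}

#' Bisulfite-convert a DNA sequence in silico
#'
#' Applies the cytosine deamination readout of sodium bisulfite treatment to
#' the top strand of a genomic sequence: every cytosine not followed by a
#' guanine reads as thymine; a CpG cytosine reads as cytosine when methylated
#' and as thymine when unmethylated.
#'
#' @param reference Genomic (pre-conversion, top strand) DNA string, A/C/G/T.
#' @param cpg_methylated Logical; if `TRUE` CpG cytosines are protected
#'   (remain C), if `FALSE` they convert to T.
#' @return The converted sequence, same length as the input.
#' @examples
#' bisulfite_convert("ACGTCG", cpg_methylated = FALSE) # "ATGTTG"
#' bisulfite_convert("CCGG", cpg_methylated = TRUE)    # "TCGG"
#' @export
bisulfite_convert <- function(reference, cpg_methylated = FALSE) {
  .check_dna(reference, "reference")
  if (nchar(reference) == 0L) stop("reference must be non-empty", call. = FALSE)
  ch <- .chars(reference)
  is_c <- ch == "C"
  next_g <- c(ch[-1] == "G", FALSE)
  convert <- is_c & (!next_g | !isTRUE(cpg_methylated))
  ch[convert] <- "T"
  paste(ch, collapse = "")
}

#' Define one targeted bisulfite amplicon
#'
#' An amplicon is a genomic reference subsequence (pre-conversion, top
#' strand), the primers used against its bisulfite-converted template, and
#' the CpG sites interrogated within it. Primers may carry a lowercase
#' adaptor tail in configuration files; lowercase letters are stripped
#' before validation. Coordinates are 0-based offsets of the CpG cytosine
#' within `reference`.
#'
#' @param name Amplicon name, unique within a panel.
#' @param reference Genomic DNA string (uppercase A/C/G/T).
#' @param cpg_sites Data frame with columns `label`, `position` (0-based
#'   offset of the CpG cytosine) and optionally `included` (default `TRUE`).
#'   Excluded sites are validated and tracked but never emitted in patterns
#'   nor counted in conversion QC.
#' @param forward_primer,reverse_primer Primer sequences as synthesized
#'   against the converted template (forward primer equals the converted
#'   reference prefix; reverse primer equals the reverse complement of the
#'   converted reference suffix). May be empty for toy amplicons.
#' @param noncpg_c_positions Optional integer vector of 0-based offsets of
#'   non-CpG cytosines outside the primer regions; derived from `reference`
#'   when `NULL`, validated against the derivation otherwise.
#' @param x_linked Logical; `TRUE` for X-chromosome amplicons (FOXP3 TSDR),
#'   where the simulator applies female X-inactivation dosage.
#' @param treg_min_k Default minimum number of demethylated sites for a read
#'   to count as Treg-like at this amplicon; defaults to the included-site
#'   count (fully demethylated).
#' @return An object of class `amplicon`.
#' @export
amplicon <- function(name, reference, cpg_sites,
                     forward_primer = "", reverse_primer = "",
                     noncpg_c_positions = NULL, x_linked = FALSE,
                     treg_min_k = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .check_dna(reference, paste0("amplicon '", name, "' reference"))
  if (nchar(reference) == 0L) {
    stop("amplicon '", name, "' reference must be non-empty", call. = FALSE)
  }
  # lowercase letters in primers denote the second-round adaptor tail
  forward_primer <- gsub("[a-z]", "", forward_primer %||% "")
  reverse_primer <- gsub("[a-z]", "", reverse_primer %||% "")
  .check_dna(forward_primer, paste0("amplicon '", name, "' forward_primer"))
  .check_dna(reverse_primer, paste0("amplicon '", name, "' reverse_primer"))

  sites <- tibble::as_tibble(cpg_sites)
  if (!all(c("label", "position") %in% names(sites))) {
    stop("amplicon '", name, "': cpg_sites needs columns label, position",
         call. = FALSE)
  }
  if (!"included" %in% names(sites)) sites$included <- TRUE
  sites$label <- as.character(sites$label)
  sites$position <- as.integer(sites$position)
  sites$included <- as.logical(sites$included)
  sites <- sites[order(sites$position), c("label", "position", "included")]
  if (anyDuplicated(sites$label)) {
    stop("amplicon '", name, "': duplicate CpG site labels", call. = FALSE)
  }
  if (anyDuplicated(sites$position)) {
    stop("amplicon '", name, "': duplicate CpG site positions", call. = FALSE)
  }

  L <- nchar(reference)
  ch <- .chars(reference)
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    if (p < 0L || p + 1L >= L ||
        ch[p + 1L] != "C" || ch[p + 2L] != "G") {
      stop("amplicon '", name, "': site '", sites$label[i],
           "' at position ", p, " is not a CG dinucleotide", call. = FALSE)
    }
  }

  fwd_len <- nchar(forward_primer)
  rev_len <- nchar(reverse_primer)
  if (fwd_len + rev_len >= L) {
    stop("amplicon '", name, "': primers overlap", call. = FALSE)
  }
  if (fwd_len > 0L) {
    prefix <- substr(reference, 1L, fwd_len)
    ok <- forward_primer %in% c(bisulfite_convert(prefix, TRUE),
                                bisulfite_convert(prefix, FALSE))
    if (!ok) {
      stop("amplicon '", name, "': forward_primer does not match the ",
           "bisulfite-converted reference prefix", call. = FALSE)
    }
  }
  if (rev_len > 0L) {
    suffix <- substr(reference, L - rev_len + 1L, L)
    ok <- reverse_primer %in% c(.revcomp(bisulfite_convert(suffix, TRUE)),
                                .revcomp(bisulfite_convert(suffix, FALSE)))
    if (!ok) {
      stop("amplicon '", name, "': reverse_primer does not match the ",
           "reverse complement of the converted reference suffix",
           call. = FALSE)
    }
  }
  if (any(sites$position < fwd_len | sites$position + 1L >= L - rev_len)) {
    stop("amplicon '", name, "': CpG sites must lie between the primer ",
         "regions", call. = FALSE)
  }

  derived <- .derive_noncpg_c(reference, fwd_len, rev_len)
  if (is.null(noncpg_c_positions)) {
    noncpg_c_positions <- derived
  } else {
    noncpg_c_positions <- sort(as.integer(noncpg_c_positions))
    if (!identical(noncpg_c_positions, derived)) {
      stop("amplicon '", name, "': noncpg_c_positions disagree with the ",
           "positions derived from the reference", call. = FALSE)
    }
  }

  n_inc <- sum(sites$included)
  if (is.null(treg_min_k)) treg_min_k <- n_inc
  treg_min_k <- as.integer(treg_min_k)
  if (treg_min_k < 0L || treg_min_k > n_inc) {
    stop("amplicon '", name, "': treg_min_k must be in [0, ", n_inc, "]",
         call. = FALSE)
  }

  structure(
    list(name = name, reference = reference,
         forward_primer = forward_primer, reverse_primer = reverse_primer,
         cpg_sites = sites, noncpg_c_positions = noncpg_c_positions,
         x_linked = isTRUE(x_linked), treg_min_k = treg_min_k),
    class = "amplicon"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based positions of C-not-followed-by-G outside the primer regions
.derive_noncpg_c <- function(reference, fwd_len, rev_len) {
  ch <- .chars(reference)
  L <- length(ch)
  is_c <- ch == "C"
  next_g <- c(ch[-1] == "G", FALSE)
  pos0 <- which(is_c & !next_g) - 1L
  pos0[pos0 >= fwd_len & pos0 < L - rev_len]
}

#' Number of analysed CpG sites in an amplicon
#'
#' @param amp An [amplicon()].
#' @param included_only Count only included sites (default) or all declared
#'   sites.
#' @return Integer site count.
#' @export
n_sites <- function(amp, included_only = TRUE) {
  stopifnot(inherits(amp, "amplicon"))
  if (included_only) sum(amp$cpg_sites$included) else nrow(amp$cpg_sites)
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s: %d bp, %d CpG sites (%d analysed)%s\n",
              x$name, nchar(x$reference), nrow(x$cpg_sites),
              sum(x$cpg_sites$included),
              if (x$x_linked) ", X-linked" else ""))
  invisible(x)
}

#' Assemble a panel of amplicons
#'
#' @param amplicons List of [amplicon()] objects with unique names.
#' @param version Free-text panel version tag.
#' @return An object of class `panel_config`: a named list of amplicons.
#' @export
panel <- function(amplicons, version = "1") {
  if (inherits(amplicons, "amplicon")) amplicons <- list(amplicons)
  stopifnot(length(amplicons) >= 1L,
            all(vapply(amplicons, inherits, logical(1), "amplicon")))
  nm <- vapply(amplicons, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("amplicon names must be unique", call. = FALSE)
  names(amplicons) <- nm
  structure(list(amplicons = amplicons, version = as.character(version)),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config> version %s, %d amplicon(s)\n",
              x$version, length(x$amplicons)))
  for (a in x$amplicons) print(a)
  invisible(x)
}

#' Load an amplicon panel from a YAML configuration
#'
#' The configuration holds a `version` and a list of `amplicons`, each with
#' `name`, `reference` (or `reference_fasta` pointing to a FASTA file),
#' `forward_primer`, `reverse_primer` and `cpg_sites` (list of
#' `{label, position, included}`; alternatively `sites_bed` pointing to a
#' BED-like file with 0-based half-open intervals, the `name` column as site
#' label and `score` 0 marking excluded sites). Lowercase primer letters are
#' stripped as adaptor sequence; `noncpg_c_positions` are derived when
#' absent.
#'
#' @param config_source Path to a YAML file, or a YAML string.
#' @return A validated [panel()] object.
#' @export
load_panel <- function(config_source) {
  cfg <- if (length(config_source) == 1L && file.exists(config_source)) {
    yaml::read_yaml(config_source)
  } else {
    yaml::yaml.load(paste(config_source, collapse = "\n"))
  }
  if (is.null(cfg$amplicons) || length(cfg$amplicons) == 0L) {
    stop("panel config has no amplicons", call. = FALSE)
  }
  base_dir <- if (file.exists(config_source[1])) dirname(config_source[1]) else "."
  amps <- lapply(cfg$amplicons, function(a) {
    if (is.null(a$name)) stop("amplicon entry missing 'name'", call. = FALSE)
    ref <- a[["reference"]]   # exact: 'reference_fasta' must not partial-match
    if (is.null(ref) && !is.null(a$reference_fasta)) {
      fa_path <- a$reference_fasta
      if (!file.exists(fa_path)) fa_path <- file.path(base_dir, a$reference_fasta)
      fa <- Biostrings::readDNAStringSet(fa_path)
      ref <- as.character(fa[[1]])
    }
    if (is.null(ref)) {
      stop("amplicon '", a$name, "': no reference or reference_fasta",
           call. = FALSE)
    }
    sites <- a$cpg_sites
    if (is.null(sites) && !is.null(a$sites_bed)) {
      bed_path <- a$sites_bed
      if (!file.exists(bed_path)) bed_path <- file.path(base_dir, a$sites_bed)
      bed <- readr::read_tsv(bed_path, col_names = FALSE, comment = "#",
                             show_col_types = FALSE)
      sites <- tibble::tibble(
        label = as.character(bed[[4]]),
        position = as.integer(bed[[2]]),
        included = if (ncol(bed) >= 5) as.numeric(bed[[5]]) != 0 else TRUE
      )
    } else if (!is.null(sites)) {
      sites <- dplyr::bind_rows(lapply(sites, tibble::as_tibble))
      if (!"included" %in% names(sites)) sites$included <- TRUE
      sites$included[is.na(sites$included)] <- TRUE
    }
    if (is.null(sites)) {
      stop("amplicon '", a$name, "': no cpg_sites or sites_bed", call. = FALSE)
    }
    amplicon(
      name = a$name, reference = ref, cpg_sites = sites,
      forward_primer = a$forward_primer %||% "",
      reverse_primer = a$reverse_primer %||% "",
      noncpg_c_positions = a$noncpg_c_positions,
      x_linked = isTRUE(a$x_linked),
      treg_min_k = a$treg_min_k
    )
  })
  panel(amps, version = cfg$version %||% "1")
}

#' Expected error-free read for a methylation pattern
#'
#' Returns the fully converted read sequence a molecule with the given
#' per-site methylation states would produce without conversion failure or
#' sequencing error: each declared CpG cytosine reads C if methylated ("M")
#' and T if demethylated ("U"); every non-CpG cytosine reads T. Any CpG not
#' declared as a site is treated as methylated.
#'
#' @param amp An [amplicon()].
#' @param pattern Character vector of "M"/"U" (or a single string) over all
#'   declared CpG sites of the amplicon, in position order — including
#'   excluded sites.
#' @return The full-length expected read sequence (primer regions included,
#'   in converted form).
#' @export
expected_read <- function(amp, pattern) {
  stopifnot(inherits(amp, "amplicon"))
  if (length(pattern) == 1L && nchar(pattern) > 1L) pattern <- .chars(pattern)
  pattern <- as.character(pattern)
  if (length(pattern) != nrow(amp$cpg_sites)) {
    stop("pattern length ", length(pattern), " does not match the ",
         nrow(amp$cpg_sites), " declared CpG sites", call. = FALSE)
  }
  if (!all(pattern %in% c("M", "U"))) {
    stop("pattern states must be 'M' or 'U'", call. = FALSE)
  }
  ch <- .chars(bisulfite_convert(amp$reference, cpg_methylated = TRUE))
  ch[amp$cpg_sites$position + 1L] <- ifelse(pattern == "M", "C", "T")
  paste(ch, collapse = "")
}
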