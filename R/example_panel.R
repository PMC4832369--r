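# Synthetic two-amplicon panel used in examples, tests and simulations.
# The sequences are constructed, not genomic: the assay's published target
# regions are not reproduced here, only their structure (a 10-CpG X-linked
# TSDR-like amplicon with one site excluded from analysis, and a 7-CpG
# autosomal exon-2-like amplicon).

.build_synth_amplicon <- function(name, prefix, spacer, labels, included,
                                  suffix, x_linked, treg_min_k) {
  n <- length(labels)
  unit <- paste0(spacer, "CG")
  ref <- paste0(prefix, strrep(unit, n), suffix)
  pos <- nchar(prefix) + (seq_len(n) - 1L) * nchar(unit) + nchar(spacer)
  amplicon(
    name = name, reference = ref,
    cpg_sites = tibble::tibble(label = labels, position = pos,
                               included = included),
    forward_primer = bisulfite_convert(prefix, cpg_methylated = TRUE),
    reverse_primer = .revcomp(bisulfite_convert(suffix, cpg_methylated = TRUE)),
    x_linked = x_linked, treg_min_k = treg_min_k
  )
}

#' Synthetic example panel
#'
#' Builds a two-amplicon panel mirroring the structure of a Treg
#' methylation assay: `FOXP3_TSDR_synth`, an X-linked amplicon declaring
#' ten CpG sites of which site "sA" is excluded so nine are analysed per
#' read (Treg-like threshold: at least 8 of 9 demethylated), and
#' `CTLA4_ex2_synth`, an autosomal amplicon with seven analysed CpG sites
#' (Treg-like threshold: all 7). Sequences are synthetic; each amplicon
#' carries two non-CpG cytosines per inter-site spacer for conversion QC.
#'
#' @return A [panel()] with two amplicons.
#' @examples
#' pnl <- example_panel()
#' n_sites(pnl$amplicons$FOXP3_TSDR_synth) # 9
#' @export
example_panel <- function() {
  foxp3 <- .build_synth_amplicon(
    name = "FOXP3_TSDR_synth",
    prefix = "GATTAGGCATAGAGGATTTG",
    spacer = "TTACATTCAT",
    labels = c("sA", as.character(1:9)),
    included = c(FALSE, rep(TRUE, 9)),
    suffix = "ATTGGATCAGGATGTAGGTT",
    x_linked = TRUE, treg_min_k = 8L
  )
  ctla4 <- .build_synth_amplicon(
    name = "CTLA4_ex2_synth",
    prefix = "GGATTGAGTTGGATTAGTTG",
    spacer = "TAACTTCATT",
    labels = as.character(1:7),
    included = rep(TRUE, 7),
    suffix = "ATGGTTAGGTTGATAGGATT",
    x_linked = FALSE, treg_min_k = 7L
  )
  panel(list(foxp3, ctla4), version = "example-1")
}
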