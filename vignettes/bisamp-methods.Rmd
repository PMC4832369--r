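---
title: "Methods: per-read CpG methylation analysis of bisulfite amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-read CpG methylation analysis of bisulfite amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisamp)
```

# The assay model

`bisamp` models a two-stage PCR bisulfite amplicon assay. A
gene-specific first-round PCR amplifies a bisulfite-converted target
region with primers carrying adaptor tails; a second-round PCR adds an
index sequence to one of the two adaptors. Because an index can sit on
either the forward or the reverse adaptor, a pool of $n$ index
sequences addresses $2n$ samples on one run — the package's
`enumerate_combinations()` is exactly this $|pool| \times 2$ count.

Bisulfite treatment deaminates unmethylated cytosine to uracil, read as
T after PCR, while 5-methylcytosine remains C. On the top strand this
gives the deterministic readout implemented by `bisulfite_convert()`:
every C not followed by G reads T; a CpG cytosine reads C if methylated
and T if not. Only the top converted strand is modelled — the assay's
primers select a single strand, and a read therefore carries one
pattern. A read's joint state over all analysed CpG sites (its
*epiallele*) is the unit of inference: the fraction of reads
demethylated at essentially all sites of the FOXP3 TSDR estimates the
Treg content of the sample at single-molecule resolution.

Coordinates throughout are 0-based offsets of the CpG cytosine within
the amplicon reference, the convention of BED-like interval files. An
amplicon may declare CpG sites that are excluded from analysis (the
TSDR-like panel declares ten and analyses nine, mirroring assays where
one site is dropped). Excluded sites are validated like any other site
but are omitted from the output pattern *and* from the conversion-QC
counts: their methylation state is unknown, so counting their C/T
status as conversion evidence would bias the efficiency estimate.

# Processing pipeline

## Demultiplexing

The physical location of the index is a sequencer-layout detail the
package has to fix by convention: a forward-placement index is the
first `index_length` bases of the read, and a reverse-placement index
appears reverse-complemented as the last `index_length` bases (an index
on the reverse adaptor ends up at the opposite end of the sequenced
strand). The simulator emits the same layout, so the convention is
self-consistent; real data with a separate index read can be
demultiplexed upstream and fed in per sample.

A read is assigned to the sheet entry at minimum Hamming distance over
both candidate regions, accepted only when that minimum is at most
`max_mismatch` (default 1, standard demultiplexing practice) and
attained by exactly one entry; ties are rejected as ambiguous rather
than guessed. With indexes at pairwise distance $> 2 \cdot$
`max_mismatch` and error-free index regions this provably yields zero
cross-talk, a property the test suite checks by simulation, and the
assignment is compared against an exhaustive minimum-distance oracle.

## Amplicon assignment and pattern calling

Reads are matched to amplicons by their forward primer (default
tolerance 2 mismatches), trying the reverse-complement orientation when
the forward orientation fails. Calling then uses *ungapped anchoring at
the primer*: amplicons are short fixed-length products, so instead of
alignment the read is laid against the reference position-by-position.
Reads with indels or chimeric joins drift out of register and are
removed by the identity filter (`min_identity`, default 0.90, computed
over non-CpG, non-primer positions against the converted reference;
unconverted cytosines count as mismatches there, costing a well-behaved
read well under 1% identity). This is a deliberate design choice: an
aligner would add a dependency and gapped calls of no value for
fixed-length amplicons.

At each analysed CpG position, C calls `M`, T calls `U`, and any other
base calls `N` — a substitution to A or G is reported as ambiguity, not
converted into a methylation state, which keeps the per-site miscall
probability below the sequencing error rate. A read passes when its
identity clears the threshold and its `N` count is at most `max_n`
(default 0); failing reads stay in the per-read call file with a reason
code (`TOO_SHORT`, `LOW_IDENTITY`, `TOO_MANY_N`, `NO_PRIMER`) so read
counts are conserved at every stage boundary.

Base qualities are parsed but not used by default; the assay's
decisions ride on C/T at a handful of positions and the identity filter
already removes degraded reads. A mean-quality filter can be layered on
by pre-filtering the FASTQ.

## Conversion QC

Cytosines outside CpG context cannot be methylated, so after complete
conversion they must read T. Pooling all passed reads,

$$\mathrm{efficiency} = 100 \cdot
  \frac{\#\,\mathrm{converted}}{\#\,\mathrm{converted} +
  \#\,\mathrm{unconverted}}$$

over those positions. Efficiency is reported as QC per sample and
amplicon, *not* applied as a read filter by default — incomplete
conversion inflates apparent methylation and should be visible, not
silently truncated. Bases other than C/T at such positions (sequencing
errors) are excluded from both numerator and denominator.

## Quantification

Eligible reads (passed, no `N`) are tabulated per sample × amplicon ×
replicate into pattern frequencies (percentages summing to 100, rows
ordered by descending count with lexicographic tie-break) and into the
distribution of $k$, the number of demethylated sites per read. The
"Treg-like" fraction is the upper tail $k \ge k_{\min}$, with
$k_{\min}$ a per-amplicon panel property: 8 of 9 for the TSDR-like
amplicon — demethylation of only eight sites is a reproducible
biological observation in Tregs, so requiring all nine would undercount
— and all 7 for the CTLA4-like amplicon. An "intermediate" fraction
(e.g. $k \in \{3,4,5,6\}$, the 3T–6T patterns) summarises the
heterogeneous demethylation seen in memory cells at CTLA4.

Replicate statistics are reported as median with min–max range; for an
even replicate count the median is the mean of the central pair, the
standard convention. Titration linearity is assessed by OLS of the
estimated demethylated fraction on the known mixture fraction; the
coefficient of determination is returned, defined as 0 (with a warning)
for a zero-variance response.

FOXP3 is X-linked: X-inactivation leaves one methylated TSDR copy per
female cell, so a pure female Treg sample reads ~50% demethylated.
`sex_adjusted_treg_estimate()` doubles female fractions (capped at 1,
factor configurable) to recover the cell-level estimate; the adjustment
is exposed as a function rather than silently applied inside the
pipeline, since the right factor can deviate from 2 under skewed
X-inactivation.

# The simulator

`simulate_reads()` generates the data the pipeline is validated on.
Per read: a generating cell-type profile is drawn from the sample's
mixture weights (default profiles: Treg = methylation probability 0 at
every site, naive = 1); in females, with probability 1/2 the molecule
is replaced by a fully methylated inactive-X copy — applied only to
amplicons flagged `x_linked`, because dosage is a property of the locus
(an autosomal amplicon like the CTLA4-like one sees no dosage effect);
per-site methylation states are drawn; conversion is applied with
success probability `conversion_rate` (default 0.995 — a well-run assay
exceeds 99%) and inappropriate conversion of methylated C with
probability 0 by default (real chemistry has a small rate; the knob
exists); uniform substitution errors at `seq_error_rate` (default
0.001, typical for the high-quality span of short amplicon reads)
hit every base including the index region; the replicate's index is
attached per its adaptor placement. Qualities are constant placeholders
since calling ignores them. All randomness flows from one integer seed
and reruns are byte-identical, which the tests assert.

Default problem sizes mirror a realistic bench design scaled to
desk-top runtimes: 2000 reads per replicate (comfortably above the
point where counting error is negligible relative to replicate
scatter), six-point titrations at 2000 reads/point, and 10,000 reads
for error-floor measurements.

What the simulator deliberately does **not** model: PCR duplicates and
amplification bias, indel sequencing errors, quality-score structure,
index hopping, and partially methylated biological epialleles (unless
supplied as custom profiles). Passing tests therefore demonstrate the
*processing* is correct and the statistical machinery recovers known
truth — not that any particular biological sample will show a given
demethylation level.

# Numerical and degenerate-input choices

* Frequencies are exact ratios of integer counts; normalisation checks
  use a $10^{-9}$ tolerance.
* Zero eligible reads yield empty tables with a warning, not an error;
  a zero denominator in conversion QC reports `NA` with a warning.
* Ambiguous demultiplex/assignment ties always go to
  `UNASSIGNED`/`UNMATCHED`; nothing is guessed.
* The synthetic panel is constructed (labelled as such everywhere): no
  claimed genomic sequence is embedded, since the real amplicon
  sequences are a property of a specific assay design. Users supply
  their own panel YAML (or FASTA + BED sites) for real data.
* Index pools for simulated sample sheets are generated at pairwise
  Hamming distance ≥ 3 and screened against exact collisions with
  amplicon read ends, so placement is never intrinsically ambiguous.

# Known limitations

Single-end reads spanning the amplicon from the forward primer are
assumed; paired-end merging is upstream scope. Gapped alignment,
hemimethylation and non-CpG methylation calling are out of scope. The
female adjustment assumes balanced X-inactivation. The demultiplexer
models in-read indexes only — separate index-read FASTQs should be
demultiplexed with the sequencer's tooling first.
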