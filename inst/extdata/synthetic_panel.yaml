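# Synthetic example panel (constructed sequences, not genomic).
# Mirrors the structure of a Treg methylation assay: a 10-CpG X-linked
# TSDR-like amplicon with site sA excluded (9 analysed) and a 7-CpG
# autosomal exon-2-like amplicon. Positions are 0-based offsets of the
# CpG cytosine within the amplicon reference.
version: synthetic-1
amplicons:
- name: FOXP3_TSDR_synth
  reference: GATTAGGCATAGAGGATTTGTTACATTCATCGTTACATTCATCGTTACATTCATCGTTACATTCATCGTTACATTCATCGTTACATTCATCGTTACATTCATCGTTACATTCATCGTTACATTCATCGTTACATTCATCGATTGGATCAGGATGTAGGTT
  forward_primer: GATTAGGTATAGAGGATTTG
  reverse_primer: AACCTACATCCTAATCCAAT
  x_linked: yes
  treg_min_k: 8
  cpg_sites:
  - label: sA
    position: 30
    included: no
  - label: '1'
    position: 42
    included: yes
  - label: '2'
    position: 54
    included: yes
  - label: '3'
    position: 66
    included: yes
  - label: '4'
    position: 78
    included: yes
  - label: '5'
    position: 90
    included: yes
  - label: '6'
    position: 102
    included: yes
  - label: '7'
    position: 114
    included: yes
  - label: '8'
    position: 126
    included: yes
  - label: '9'
    position: 138
    included: yes
- name: CTLA4_ex2_synth
  reference: GGATTGAGTTGGATTAGTTGTAACTTCATTCGTAACTTCATTCGTAACTTCATTCGTAACTTCATTCGTAACTTCATTCGTAACTTCATTCGTAACTTCATTCGATGGTTAGGTTGATAGGATT
  forward_primer: GGATTGAGTTGGATTAGTTG
  reverse_primer: AATCCTATCAACCTAACCAT
  x_linked: no
  treg_min_k: 7
  cpg_sites:
  - label: '1'
    position: 30
    included: yes
  - label: '2'
    position: 42
    included: yes
  - label: '3'
    position: 54
    included: yes
  - label: '4'
    position: 66
    included: yes
  - label: '5'
    position: 78
    included: yes
  - label: '6'
    position: 90
    included: yes
  - label: '7'
    position: 102
    included: yes
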