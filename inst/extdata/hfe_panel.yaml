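# Default HFE multiplex PCR-RFLP panel.
#
# Primer sequences and dye labels are the assay's published multiplex.
# HFE amplicon lengths, diagnostic site positions and the STR size
# offsets are self-consistent fixture constants of this in-silico twin
# (chosen so every dye channel keeps >= 10 bp between expected fragment
# sizes); they are not measured values.
schema_version: 1
dyes:
  - ATTO 565
  - Yakima Yellow
  - FAM
  - ATTO 550
enzymes:
  - name: SexAI
    recognition: ACCWGGT
    cut_offset: 1
  - name: BspHI
    recognition: TCATGA
    cut_offset: 1
primer_pairs:
  - marker: HFE_exon2
    upper_seq: ACATGGTTAAGGCCTGTTGC
    lower_seq: GCCACATCTGGCTTGAAATT
    upper_dye: ATTO 565
    lower_dye: null
  - marker: HFE_exon4
    upper_seq: CGGGCCTTGAACTACTACCC
    lower_seq: ACCTCCTCAGGCACTCCTCT
    upper_dye: ATTO 565
    lower_dye: null
  - marker: SE33
    upper_seq: AATCTGGGCGACAAGAGTGA
    lower_seq: ACATCTCCCCTACCGCTATA
    upper_dye: Yakima Yellow
    lower_dye: null
  - marker: FGA
    upper_seq: GGCTGCAGGGCATAACATTA
    lower_seq: ATTCTATGACTTTGCGCTTCAGGA
    upper_dye: FAM
    lower_dye: null
  - marker: FZD1
    upper_seq: CTTGTCCGGCTGTTACACG
    lower_seq: CAGGATGGTGATGGTCTTGAT
    upper_dye: ATTO 550
    lower_dye: ATTO 550
rflp_markers:
  - name: H63D
    enzyme: BspHI
    primer_pair: HFE_exon2
    amplicon_length: 208
    site_position: 77
    variant_creates_site: true
    labeled_end: five_prime
    dye: ATTO 565
  - name: C282Y
    enzyme: SexAI
    primer_pair: HFE_exon4
    amplicon_length: 390
    site_position: 247
    variant_creates_site: true
    labeled_end: five_prime
    dye: ATTO 565
str_loci:
  - name: FGA
    repeat_unit_length: 4
    size_offset: 140
    allele_min: 12.2
    allele_max: 51.2
    stutter_mean: 0.080
    stutter_sd: 0.024
    dye: FAM
  - name: SE33
    repeat_unit_length: 4
    size_offset: 120
    allele_min: 7
    allele_max: 39.2
    stutter_mean: 0.106
    stutter_sd: 0.024
    dye: Yakima Yellow
control:
  name: FZD1
  amplicon_length: 309
  sexai_site_start: 113
  bsphi_site_start: 161
  double_digest_sizes:
    SexAI: 114
    BspHI: 147
  single_failure_sizes:
    SexAI: 171
    BspHI: 204
  uncut_size: 309
  dye: ATTO 550
thresholds:
  noise_ceiling: 50
  cutoff_multiplier: 5
  analytical_cutoff: 250
  saturation: 32000
  stutter_sd_multiplier: 2
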