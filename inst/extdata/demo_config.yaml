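# Demonstration scenario: one tumor with matched control, a 5-sample
# control panel, plasma cfDNA at 10% tumor fraction, and digital-PCR
# assays, on a 5 x 10 Mb synthetic genome.
seed: 7
genome:
  n_chromosomes: 5
  chromosome_length: 10000000
library:
  insert_mean: 2500
  insert_sd: 300
  read_length: 50
  n_pairs: 200000
  purity: 1.0
n_panel_controls: 5
cfdna:
  tumor_fraction: 0.10
  n_pairs: 200000
somatic_cn:
  - {chrom: chr1, start: 0, end: 10000000, copy_number: 3}
  - {chrom: chr2, start: 0, end: 5000000, copy_number: 4}
  - {chrom: chr3, start: 0, end: 10000000, copy_number: 1}
somatic_svs:
  - {sv_type: deletion, chrom1: chr4, pos1: 2000000, pos2: 2060000, zygosity: homozygous}
  - {sv_type: inversion, chrom1: chr4, pos1: 6000000, pos2: 6100000, zygosity: homozygous}
  - {sv_type: duplication, chrom1: chr5, pos1: 1000000, pos2: 1080000, zygosity: homozygous}
  - {sv_type: translocation, chrom1: chr4, pos1: 8000000, chrom2: chr5, pos2: 5000000, zygosity: homozygous}
germline_svs:
  - {sv_type: deletion, chrom1: chr5, pos1: 8000000, pos2: 8050000, zygosity: heterozygous}
doc:
  p_prime: 1.0e-4
  r_prime: 0.6
  window_multiplier: 4
  step_fraction: 0.5
  kernel_bandwidth: 2
  bh_alpha: 1.0e-4
pem:
  min_support_tumor: 3
  min_support_control: 1
  filter_window: 3000
zscore:
  tile: 5000000
ddpcr:
  n_partitions: 14121
  lambda_ref: 0.5
  lambda_deletion_tumor: 0.25
  lambda_deletion_normal: 0.5
  lambda_her2_tumor: 0.575
  lambda_her2_normal: 0.5
wells:
  breakpoint_fraction: 0.11
  wells_per_assay: 192
  genome_equivalents_per_well: 0.5
write_pairs: false
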