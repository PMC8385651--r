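seed: 1.0
outdir: sdrase_out
simulate:
  n_males: 10.0
  n_females: 10.0
  n_het_sites_per_gene: 6.0
  wgs_depth_male: 18.0
  wgs_depth_female: 26.0
  rna_depth: 100.0
  amplicon_depth: 2000.0
  seq_error: 0.005
  overdispersion_rho: 0.02
  n_background_genes: 2000.0
ase:
  min_phred: 15.0
  dna_min_depth: 20.0
  het_band:
  - 0.2
  - 0.8
  error_rate: 0.01
  mono_threshold: 0.9
  rna_min_depth: 20.0
  min_sites: 2.0
  site_agreement: 0.8
  alpha: 0.05
  correction: none
hemizygosity:
  male_min: 0.3
  female_max: 0.1
  min_run: 2.0
  expressed_min: 0.1
expression:
  min_cpm: 8.0
  min_fold: 2.0
  min_mean_cpm: 16.0
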