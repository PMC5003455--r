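# Demo configuration: a small simulated pooling experiment with three
# embedded CNV events, run end to end against the bundled synthetic
# reference map and gene annotation. Paths are relative to this file.
sim:
  n_markers: 3000
  chroms: ["1", "2"]
  marker_spacing: 2500
  lrr_noise_sd: 0.01
  seed: 20140228
  events:
    - chrom: "1"          # case-only gain, absent from the reference map
      start: 1000000
      end: 1400000
      copy_number: 3
      carriers: {case01: 2, case02: 2, case03: 2}
    - chrom: "1"          # case-only loss, absent from the reference map
      start: 2500000
      end: 2750000
      copy_number: 1
      carriers: {case01: 2}
    - chrom: "2"          # control-only gain, present in the reference map
      start: 550000
      end: 900000
      copy_number: 3
      carriers: {ctrl01: 2, ctrl02: 2, ctrl03: 2, ctrl04: 2}
refmap_path: demo_refmap_synthetic.bed
genes_path: demo_genes_synthetic.bed
candidates_path: demo_candidates.txt
seed: 20140228
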