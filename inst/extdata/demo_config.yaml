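# Demo pipeline: synthetic multi-copy coarse-grained scene with a planted
# trimer + dimer + 31 monomers; clustering, protein-protein contacts and
# lipid-free RDF of copy beads around copy 1.  All cutoffs carry explicit
# units (Angstrom or nm).
seed: 42
out_prefix: demo
stages: [simulate, cluster, protein_contacts]
scene:
  kind: multicopy_scene
  planted: [3, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
            1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
  n_frames: 5
  diffusion_sd: 0
  cutoff: "6.5 A"
cluster:
  cutoff: "6.5 A"
  window: 1
protein_contacts:
  cutoff: "6.5 A"
  threshold: 0.025
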