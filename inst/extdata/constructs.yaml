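# Construct presets for the dimer experiments.
#
# Residue counts and rigid spans follow the published estimates: a spectrin
# repeat (SR) of ~110 residues folds into a ~5 nm body; a full four-repeat
# rod of ~480 residues (helical linkers included) spans ~24 nm; the looped
# flexible linker is ~170 residues in the shear geometry and ~218 in the
# unzip geometry. In-dimer loop end-to-end distances are 24 / 18 / 12 nm for
# the full, three-repeat and two-repeat shear dimers and ~2 nm for the unzip
# dimer. Spans of partial rods are proportional estimates (24 nm x k/4) --
# the source reports spans only for the full rod and single repeats.
# Entries are editable; all lengths in nm, residues in amino acids.

actn1_shear_full:
  geometry: shear
  n_domains: 4
  domain_residues: 110
  domain_span: 5
  rod_residues: 480
  rod_span: 24
  loop_residues: 170
  dimer_span_before: 24
  dimer_span_after: [24]
  loop_end_to_end: 24

actn4_shear_full:
  geometry: shear
  n_domains: 4
  domain_residues: 110
  domain_span: 5
  rod_residues: 480
  rod_span: 24
  loop_residues: 170
  dimer_span_before: 24
  dimer_span_after: [24]
  loop_end_to_end: 24

hetero_shear_full:
  geometry: shear
  n_domains: 4
  domain_residues: 110
  domain_span: 5
  rod_residues: 480
  rod_span: 24
  loop_residues: 170
  dimer_span_before: 24
  dimer_span_after: [24]
  loop_end_to_end: 24

actn1_unzip:
  geometry: unzip
  n_domains: 4
  domain_residues: 110
  domain_span: 5
  rod_residues: 480
  rod_span: 24
  loop_residues: 218
  dimer_span_before: 2
  dimer_span_after: [24, 24]
  loop_end_to_end: 2

sr234_sr123:
  # three-repeat partial dimer (one terminal pair removed)
  geometry: shear
  n_domains: 3
  domain_residues: 110
  domain_span: 5
  rod_residues: 360
  rod_span: 18
  loop_residues: 170
  dimer_span_before: 18
  dimer_span_after: [18]
  loop_end_to_end: 18

sr23_sr23:
  # two-repeat partial dimer (both terminal pairs removed)
  geometry: shear
  n_domains: 2
  domain_residues: 110
  domain_span: 5
  rod_residues: 240
  rod_span: 12
  loop_residues: 170
  dimer_span_before: 12
  dimer_span_after: [12]
  loop_end_to_end: 12

sr1_sr4:
  # single-pair construct
  geometry: shear
  n_domains: 1
  domain_residues: 110
  domain_span: 5
  rod_residues: 120
  rod_span: 6
  loop_residues: 170
  dimer_span_before: 6
  dimer_span_after: [6]
  loop_end_to_end: 6

eh_actinin2_two_sr:
  # ancestral protozoan two-repeat dimer
  geometry: shear
  n_domains: 2
  domain_residues: 110
  domain_span: 5
  rod_residues: 240
  rod_span: 12
  loop_residues: 170
  dimer_span_before: 12
  dimer_span_after: [12]
  loop_end_to_end: 12
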