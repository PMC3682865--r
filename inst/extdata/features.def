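# Default feature definition: one feature name per line.
# Comment a line out to exclude the feature from dataset building,
# training and prediction.

# sequential
residue_type
prev_residue_type
next_residue_type
sequence_length
alignment_score

# structural
phi
psi
chi1
secondary_structure
dist_N_CA
dist_CA_C
dist_C_O
dist_N_C_prev
dist_CA_CA_prev
dist_CA_CA_next
atom_sas
residue_sas
atomic_density
has_hbond
has_disulfide

# force-field based
ff_atom_type
structure_energy

# experimental
has_h_shifts
has_c_shifts
has_n_shifts
temperature
ph
pressure
solvent
spectrometer

# semi-classical contributions
random_coil
ring_current
electric_field
hbond_effect
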